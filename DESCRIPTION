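Package: xpoo
Title: Parent-of-Origin Effects on the X Chromosome in Case-Parent Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects parent-of-origin effects for X-linked markers from
    case-parent triads (an affected child and both parents). Fits a
    conditional log-linear likelihood in which the relative risks carried by
    maternally and paternally inherited alleles (RRm, RRf) are estimated
    separately, combines information from boys and girls under either an
    X-inactivation constraint (RRm*RRf = RRB) or a no-X-inactivation
    constraint (RRm = RRB), and reports the relative risk ratio RRR = RRm/RRf
    as the measure of parent-of-origin effect. Supports sliding-window
    haplotype scans of one to four SNPs with maximum-likelihood handling of
    missing parental genotypes and phase ambiguity, X-aware quality control
    (Mendelian-error detection, minor-allele frequency, exact Hardy-Weinberg
    tests), Storey q-value false-discovery-rate post-processing, and an exact
    simulator of ascertained case-parent triads for power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
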