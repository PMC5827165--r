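#' Construct a case-parent triad genotype set for X-linked SNPs
#'
#' Bundles the SNP map, the triad roster, and the three dose matrices
#' (variant-allele counts) into a validated container. Doses are counts of the
#' variant allele: mothers and daughters carry 0--2 copies, fathers and sons
#' are hemizygous and carry 0--1. `NA` encodes a missing call.
#'
#' @param snps Tibble with columns `snp_id`, `position` (1-based base pairs),
#'   `allele_ref`, `allele_var`. The variant allele may be `NA` for a
#'   monomorphic SNP.
#' @param triads Tibble with columns `triad_id` and `child_sex`
#'   (`"female"` or `"male"`).
#' @param mother,father,child Integer matrices, one row per triad and one
#'   column per SNP, holding variant-allele doses (`NA` = missing).
#' @param mask Optional logical matrix of the same shape; `TRUE` marks a
#'   triad-by-SNP slot excluded from the likelihood (Mendelian inconsistency).
#'   Defaults to all `FALSE`.
#'
#' @return An object of class `triad_data`.
#' @seealso [read_triads()], [as_tibble.triad_data()], [apply_qc()]
#' @export
triad_data <- function(snps, triads, mother, father, child, mask = NULL) {
  snps <- as_tibble(snps)
  triads <- as_tibble(triads)
  need <- c("snp_id", "position", "allele_ref", "allele_var")
  if (!all(need %in% names(snps))) {
    abort(paste0("`snps` must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(snps$snp_id)) {
    abort("duplicate SNP id(s) in `snps`")
  }
  if (any(snps$position <= 0)) abort("SNP positions must be positive")
  poly <- !is.na(snps$allele_var)
  if (any(poly & snps$allele_ref == snps$allele_var)) {
    abort("reference and variant allele labels must differ")
  }
  if (!all(c("triad_id", "child_sex") %in% names(triads))) {
    abort("`triads` must have columns triad_id, child_sex")
  }
  if (!all(triads$child_sex %in% c("female", "male"))) {
    abort("child_sex must be \"female\" or \"male\"")
  }
  n <- nrow(triads)
  m <- nrow(snps)
  mother <- as.matrix(mother); father <- as.matrix(father); child <- as.matrix(child)
  for (nm in c("mother", "father", "child")) {
    mat <- get(nm)
    if (!all(dim(mat) == c(n, m))) {
      abort(sprintf("`%s` must be a %d x %d matrix", nm, n, m))
    }
  }
  check_range <- function(mat, lo, hi, what) {
    v <- mat[!is.na(mat)]
    if (length(v) && (any(v < lo) || any(v > hi))) {
      abort(sprintf("%s doses must lie in %d..%d or be NA", what, lo, hi))
    }
  }
  check_range(mother, 0L, 2L, "mother")
  check_range(father, 0L, 1L, "father (hemizygous)")
  girls <- triads$child_sex == "female"
  check_range(child[girls, , drop = FALSE], 0L, 2L, "girl child")
  check_range(child[!girls, , drop = FALSE], 0L, 1L, "boy child (hemizygous)")
  if (is.null(mask)) mask <- matrix(FALSE, n, m)
  storage.mode(mother) <- "integer"
  storage.mode(father) <- "integer"
  storage.mode(child) <- "integer"
  new_triad_data(snps, triads, mother, father, child, mask)
}

# no-validation constructor for internal callers whose inputs are correct
# by construction (the simulator, QC subsetting)
new_triad_data <- function(snps, triads, mother, father, child, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(triads), nrow(snps))
  structure(
    list(snps = snps, triads = triads,
         mother = mother, father = father, child = child,
         mask = mask),
    class = "triad_data"
  )
}

#' @export
print.triad_data <- function(x, ...) {
  cat(sprintf("<triad_data> %d triads (%d girls, %d boys) x %d X-linked SNPs\n",
              n_triads(x), sum(x$triads$child_sex == "female"),
              sum(x$triads$child_sex == "male"), n_snps(x)))
  miss <- mean(is.na(c(x$mother, x$father, x$child)))
  cat(sprintf("  missing calls: %.2f%%; masked slots: %d\n",
              100 * miss, sum(x$mask)))
  invisible(x)
}

#' Number of triads / SNPs in a dataset
#' @param x A `triad_data` object.
#' @return Integer count.
#' @export
n_triads <- function(x) nrow(x$triads)

#' @rdname n_triads
#' @export
n_snps <- function(x) nrow(x$snps)

#' Convert triad genotypes to the long one-row-per-triad-per-SNP form
#'
#' @param x A `triad_data` object.
#' @param ... Unused.
#' @return A tibble with columns `triad_id`, `snp_id`, `child_sex`,
#'   `mother_dose`, `father_dose`, `child_dose`.
#' @export
as_tibble.triad_data <- function(x, ...) {
  n <- n_triads(x); m <- n_snps(x)
  tibble(
    triad_id = rep(x$triads$triad_id, times = m),
    snp_id = rep(x$snps$snp_id, each = n),
    child_sex = rep(x$triads$child_sex, times = m),
    mother_dose = as.vector(x$mother),
    father_dose = as.vector(x$father),
    child_dose = as.vector(x$child)
  )
}

# verdict lookup over all (sex, mother, father, child) dose combinations,
# built once by enumerating completions of missing members
verdict_env <- new.env(parent = emptyenv())

triad_rule_ok <- function(m, f, c, sex) {
  if (sex == "male") {
    if (c == 1L) m >= 1L else m <= 1L
  } else {
    cm <- c - f
    if (cm < 0L || cm > 1L) return(FALSE)
    if (cm == 1L) m >= 1L else m <= 1L
  }
}

verdict_table <- function() {
  if (!is.null(verdict_env$tab)) return(verdict_env$tab)
  tab <- array("", dim = c(2L, 4L, 3L, 4L)) # sex, mother, father, child (last level = NA)
  for (si in 1:2) {
    sex <- c("female", "male")[si]
    cmax <- if (sex == "female") 2L else 1L
    for (mi in 1:4) for (fi in 1:3) for (ci in 1:4) {
      ms <- if (mi == 4L) 0:2 else mi - 1L
      fs <- if (fi == 3L) 0:1 else fi - 1L
      cs <- if (ci == 4L) 0:cmax else ci - 1L
      if (ci != 4L && max(cs) > cmax) { tab[si, mi, fi, ci] <- NA_character_; next }
      oks <- logical(0)
      for (m in ms) for (f in fs) for (c in cs) {
        oks <- c(oks, triad_rule_ok(m, f, c, sex))
      }
      tab[si, mi, fi, ci] <-
        if (all(oks)) "consistent" else if (!any(oks)) "inconsistent" else "unknown"
    }
  }
  verdict_env$tab <- tab
  tab
}

#' Check a triad genotype for X-linked Mendelian consistency
#'
#' Applies the X-chromosome transmission rules: a boy's single allele must be
#' one of his mother's; a girl carries her father's allele plus one maternal
#' allele. Missing members yield `"unknown"` unless every completion of the
#' missing calls is impossible (`"inconsistent"`) or every completion is
#' possible (`"consistent"`, e.g. a boy whose father is missing -- fathers do
#' not transmit X to sons).
#'
#' @param mother_dose,father_dose,child_dose Integer vectors of variant-allele
#'   doses (`NA` = missing); recycled to a common length.
#' @param child_sex Character vector, `"female"` or `"male"`.
#' @return Character vector with values `"consistent"`, `"inconsistent"`,
#'   `"unknown"`.
#' @export
check_triad_consistency <- function(mother_dose, father_dose, child_dose, child_sex) {
  nn <- max(length(mother_dose), length(father_dose), length(child_dose), length(child_sex))
  m <- rep_len(as.integer(mother_dose), nn)
  f <- rep_len(as.integer(father_dose), nn)
  c_ <- rep_len(as.integer(child_dose), nn)
  sex <- rep_len(child_sex, nn)
  if (!all(sex %in% c("female", "male"))) abort("child_sex must be female/male")
  if (any(!is.na(m) & (m < 0L | m > 2L))) abort("mother_dose outside 0..2")
  if (any(!is.na(f) & (f < 0L | f > 1L))) abort("father_dose outside 0..1")
  bad_c <- !is.na(c_) & (c_ < 0L | c_ > ifelse(sex == "female", 2L, 1L))
  if (any(bad_c)) abort("child_dose outside the valid range for the child's sex")
  tab <- verdict_table()
  si <- ifelse(sex == "female", 1L, 2L)
  mi <- ifelse(is.na(m), 4L, m + 1L)
  fi <- ifelse(is.na(f), 3L, f + 1L)
  ci <- ifelse(is.na(c_), 4L, c_ + 1L)
  tab[cbind(si, mi, fi, ci)]
}

#' Count Mendelian errors at one SNP
#'
#' A Mendelian error is a triad whose genotypes at the SNP are impossible
#' under X-linked inheritance for any completion of missing calls.
#'
#' @param dataset A `triad_data` object.
#' @param snp_index Column index of the SNP.
#' @return Integer count of inconsistent triads.
#' @export
count_mendelian_errors <- function(dataset, snp_index) {
  stopifnot(inherits(dataset, "triad_data"))
  if (snp_index < 1L || snp_index > n_snps(dataset)) abort("snp_index out of range")
  v <- check_triad_consistency(dataset$mother[, snp_index],
                               dataset$father[, snp_index],
                               dataset$child[, snp_index],
                               dataset$triads$child_sex)
  sum(v == "inconsistent")
}

#' Flag Mendelian-inconsistent triad-by-SNP slots
#'
#' Recomputes the exclusion mask: each triad found inconsistent at a SNP is
#' masked at that SNP only (its other SNPs stay informative) and enters the
#' likelihood there as missing.
#'
#' @param dataset A `triad_data` object.
#' @return The dataset with an updated `mask`.
#' @export
mask_mendelian <- function(dataset) {
  stopifnot(inherits(dataset, "triad_data"))
  for (j in seq_len(n_snps(dataset))) {
    v <- check_triad_consistency(dataset$mother[, j], dataset$father[, j],
                                 dataset$child[, j], dataset$triads$child_sex)
    dataset$mask[, j] <- v == "inconsistent"
  }
  dataset
}

# doses with the Mendelian mask applied (likelihood view of the data)
masked_doses <- function(dataset) {
  m <- dataset$mother; f <- dataset$father; c_ <- dataset$child
  m[dataset$mask] <- NA_integer_
  f[dataset$mask] <- NA_integer_
  c_[dataset$mask] <- NA_integer_
  list(mother = m, father = f, child = c_)
}

# unfolded variant-allele frequency with hemizygosity-aware weights
variant_freq <- function(dataset, snp_index) {
  md <- dataset$mother[, snp_index]; fd <- dataset$father[, snp_index]
  cd <- dataset$child[, snp_index]
  girls <- dataset$triads$child_sex == "female"
  var_ct <- sum(md, na.rm = TRUE) + sum(fd, na.rm = TRUE) + sum(cd, na.rm = TRUE)
  tot <- 2 * sum(!is.na(md)) + sum(!is.na(fd)) +
    2 * sum(!is.na(cd) & girls) + sum(!is.na(cd) & !girls)
  if (tot == 0) abort(sprintf("SNP %s: all genotypes missing", dataset$snps$snp_id[snp_index]))
  var_ct / tot
}

#' Minor-allele frequency at one SNP, X-aware
#'
#' Females (mothers and daughters) contribute two alleles, hemizygous males
#' (fathers and sons) one — the standard X-chromosome counting convention.
#'
#' @param dataset A `triad_data` object.
#' @param snp_index Column index of the SNP.
#' @return Minor-allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(dataset, snp_index) {
  p <- variant_freq(dataset, snp_index)
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg test from female genotype counts
#'
#' Exact test conditioning on the allele counts: enumerates every possible
#' heterozygote count with the observed allele totals, weights each by its
#' multinomial probability under Hardy-Weinberg proportions, and sums the
#' probabilities of configurations no more probable than the observed one.
#' Computed from the mothers' genotype counts (fathers are hemizygous; the
#' affected children are ascertained).
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of female genotype counts
#'   (reference homozygote, heterozygote, variant homozygote).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 3L) abort("`counts` must be (n_AA, n_Aa, n_aa)")
  if (any(is.na(counts)) || any(counts < 0L)) abort("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0L) abort("no individuals in HWE test")
  n_het_obs <- counts[2]
  n_var <- 2L * counts[3] + n_het_obs
  n_ref <- 2L * counts[1] + n_het_obs
  rare <- min(n_var, n_ref)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  lw <- vapply(hs, function(h) {
    n_hom_var <- (n_var - h) / 2
    n_hom_ref <- (n_ref - h) / 2
    lfactorial(n) - lfactorial(n_hom_ref) - lfactorial(h) - lfactorial(n_hom_var) +
      h * log(2)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  w_obs <- w[match(n_het_obs, hs)]
  sum(w[w <= w_obs * (1 + 1e-9)])
}
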