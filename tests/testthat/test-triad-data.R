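test_that("ped/map round trip preserves triads, SNPs and doses", {
  fx <- write_ped_fixture(
    ped_lines = c(
      "f1 mom 0 0 2 1  A A  G T",
      "f1 dad 0 0 1 1  A A  T T",
      "f1 kid dad mom 2 2  A A  G T"
    ),
    map_lines = c("X rs1 0 1000", "X rs2 0 2000")
  )
  d <- read_triads(fx$ped, fx$map)
  expect_s3_class(d, "triad_data")
  expect_equal(n_triads(d), 1L)
  expect_equal(n_snps(d), 2L)
  expect_equal(d$snps$snp_id, c("rs1", "rs2"))
  expect_equal(d$snps$position, c(1000L, 2000L))
  expect_equal(d$triads$child_sex, "female")
  # rs2: alleles G/T with T the majority call -> reference T, variant G
  expect_equal(d$snps$allele_ref[2], "T")
  expect_equal(d$snps$allele_var[2], "G")
  expect_equal(d$mother[1, 2], 1L)
  expect_equal(d$father[1, 2], 0L)
  expect_equal(d$child[1, 2], 1L)
})

test_that("male X parsing: heterozygous calls become missing, homozygous collapse to dose 0/1", {
  fx <- write_ped_fixture(
    ped_lines = c(
      "f1 mom 0 0 2 1  A G",
      "f1 dad 0 0 1 1  G G",
      "f1 son dad mom 1 2  A G"
    ),
    map_lines = "X rs1 0 500"
  )
  expect_warning(d <- read_triads(fx$ped, fx$map), "heterozygous male")
  expect_true(is.na(d$child[1, 1]))
  # G is the majority call (reference); the homozygous father carries dose 0
  expect_equal(d$snps$allele_var[1], "A")
  expect_equal(d$father[1, 1], 0L)
})

test_that("missing codes, rejected families and malformed input behave as documented", {
  fx <- write_ped_fixture(
    ped_lines = c(
      "f1 mom 0 0 2 1  0 0",
      "f1 dad 0 0 1 1  A A",
      "f1 kid dad mom 2 2  A C",
      "f2 mom 0 0 2 1  A A",
      "f2 dad 0 0 1 1  A A",
      "f2 kid dad mom 2 1  A A" # unaffected child -> family rejected
    ),
    map_lines = "X rs1 0 500"
  )
  expect_warning(d <- read_triads(fx$ped, fx$map), "without an affected child")
  expect_equal(n_triads(d), 1L)
  expect_true(is.na(d$mother[1, 1]))

  bad <- write_ped_fixture("f1 mom 0 0 2 1 A", "X rs1 0 500")
  expect_error(read_triads(bad$ped, bad$map), "line 1")

  dup <- write_ped_fixture(
    c("f1 mom 0 0 2 1 A A A A", "f1 dad 0 0 1 1 A A A A",
      "f1 kid dad mom 2 2 A A A A"),
    c("X rs1 0 1", "X rs1 0 2")
  )
  expect_error(read_triads(dup$ped, dup$map), "duplicate SNP id")

  nosex <- write_ped_fixture(
    c("f1 mom 0 0 2 1 A A", "f1 dad 0 0 1 1 A A", "f1 kid dad mom 0 2 A A"),
    "X rs1 0 1"
  )
  expect_error(read_triads(nosex$ped, nosex$map), "unknown sex")
})

test_that("native long TSV round-trips a dataset", {
  d <- simulate_triads(sim_spec(maf = 0.3, n_triads = 40, seed = 11,
                                missing_rate_parent = 0.1))
  gt <- tempfile(fileext = ".tsv"); sn <- tempfile(fileext = ".tsv")
  write_triads_tsv(d, gt, sn)
  d2 <- read_triads_tsv(gt, sn)
  expect_equal(d2$mother, d$mother, ignore_attr = TRUE)
  expect_equal(d2$father, d$father, ignore_attr = TRUE)
  expect_equal(d2$child, d$child, ignore_attr = TRUE)
  expect_equal(d2$triads$child_sex, d$triads$child_sex)
})

test_that("X-linked consistency verdicts match the rules and the brute-force oracle", {
  expect_equal(check_triad_consistency(0, NA, 1, "male"), "inconsistent")
  expect_equal(check_triad_consistency(1, 1, 0, "female"), "inconsistent")
  expect_equal(check_triad_consistency(1, 0, 1, "female"), "consistent")
  # boy with missing father: father is irrelevant, verdict still reached
  expect_equal(check_triad_consistency(2, NA, 1, "male"), "consistent")
  # girl needing the missing member for a verdict
  expect_equal(check_triad_consistency(1, NA, 2, "female"), "unknown")

  # exhaustive agreement with the enumeration oracle, including missing slots
  for (sex in c("female", "male")) {
    cmax <- if (sex == "female") 2 else 1
    for (m in c(0:2, NA)) for (f in c(0:1, NA)) for (c_ in c(0:cmax, NA)) {
      expect_equal(check_triad_consistency(m, f, c_, sex),
                   oracle_verdict(m, f, c_, sex),
                   info = sprintf("sex=%s m=%s f=%s c=%s", sex, m, f, c_))
    }
  }
})

test_that("consistency verdicts are invariant under allele relabeling", {
  for (sex in c("female", "male")) {
    cmax <- if (sex == "female") 2 else 1
    for (m in c(0:2, NA)) for (f in c(0:1, NA)) for (c_ in c(0:cmax, NA)) {
      expect_equal(check_triad_consistency(m, f, c_, sex),
                   check_triad_consistency(2L - m, 1L - f, cmax - c_, sex))
    }
  }
})

make_dataset <- function(mother, father, child, sex) {
  triad_data(
    snps = tibble::tibble(snp_id = "s1", position = 1L,
                          allele_ref = "A", allele_var = "a"),
    triads = tibble::tibble(triad_id = sprintf("t%d", seq_along(sex)),
                            child_sex = sex),
    mother = matrix(mother), father = matrix(father), child = matrix(child)
  )
}

test_that("Mendelian error counts match planted errors and the brute-force oracle", {
  clean <- simulate_triads(sim_spec(maf = 0.25, n_triads = 10, seed = 3))
  expect_equal(count_mendelian_errors(clean, 1), 0L)

  # plant exactly 3 inconsistencies among 8 triads
  d <- make_dataset(
    mother = c(0L, 0L, 2L, 1L, 1L, 2L, 0L, 1L),
    father = c(0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L),
    child  = c(1L, 0L, 0L, 1L, 1L, 1L, 1L, 2L),
    sex    = c("male", "female", "male", "female",
               "female", "male", "female", "female")
  )
  expect_equal(count_mendelian_errors(d, 1), 3L)
  expect_equal(count_mendelian_errors(d, 1), oracle_mendel_count(d, 1))

  # property: agreement with the oracle on random noisy fixtures
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    sex <- sample(c("female", "male"), n, replace = TRUE)
    m <- sample(c(0:2, NA), n, replace = TRUE)
    f <- sample(c(0:1, NA), n, replace = TRUE)
    c_ <- ifelse(sex == "female", sample(c(0:2, NA), n, replace = TRUE),
                 sample(c(0:1, NA), n, replace = TRUE))
    d <- make_dataset(as.integer(m), as.integer(f), as.integer(c_), sex)
    expect_equal(count_mendelian_errors(d, 1), oracle_mendel_count(d, 1))
  }
})

test_that("minor allele frequency uses 2 alleles per female, 1 per hemizygous male", {
  # 2 mothers dose 2 + 1 father dose 1, everyone else missing: monomorphic variant
  d <- make_dataset(mother = c(2L, 2L, NA), father = c(NA, NA, 1L),
                    child = c(NA, NA, NA), sex = rep("female", 3))
  expect_equal(compute_maf(d, 1), 0)

  d2 <- make_dataset(mother = 1L, father = NA_integer_, child = NA_integer_,
                     sex = "female")
  expect_equal(compute_maf(d2, 1), 0.5)

  # hand tally: 10 triads, all girls -> 20 females (mothers + daughters), 10 males
  # mothers: five dose 1, five dose 0 -> 5 variant / 20 alleles
  # fathers: three dose 1             -> 3 variant / 10 alleles
  # daughters: four dose 1            -> 4 variant / 20 alleles
  # total 12 / 50
  d3 <- make_dataset(
    mother = c(rep(1L, 5), rep(0L, 5)),
    father = c(rep(1L, 3), rep(0L, 7)),
    child = c(rep(1L, 4), rep(0L, 6)),
    sex = rep("female", 10)
  )
  expect_equal(compute_maf(d3, 1), 12 / 50)

  d_all_na <- make_dataset(NA_integer_, NA_integer_, NA_integer_, "female")
  expect_error(compute_maf(d_all_na, 1), "missing")
})

test_that("exact HWE test agrees with enumeration oracles", {
  expect_equal(hwe_exact_test(c(50, 0, 0)), 1)
  expect_equal(hwe_exact_test(c(1, 0, 1)), oracle_hwe_slots(1, 0, 1))
  expect_equal(hwe_exact_test(c(1, 0, 1)), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(c(25, 50, 25)), oracle_hwe_enum(25, 50, 25),
               tolerance = 1e-9)
  expect_error(hwe_exact_test(c(-1, 2, 3)), "non-negative")

  # property: agreement with exact choose() enumeration for totals <= 50
  set.seed(42)
  for (r in 1:20) {
    cnt <- as.vector(stats::rmultinom(1, sample(5:50, 1), prob = c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact_test(cnt), oracle_hwe_enum(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-9, info = paste(cnt, collapse = ","))
  }
  # and with the allele-slot enumeration for tiny totals
  for (cnt in list(c(2, 1, 1), c(0, 2, 2), c(3, 0, 1), c(1, 1, 1))) {
    expect_equal(hwe_exact_test(cnt), oracle_hwe_slots(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-9, info = paste(cnt, collapse = ","))
  }
})

test_that("QC removes what the thresholds dictate, in order, and is idempotent", {
  base <- sim_dataset_multi(mafs = c(0.3, 0.25, 0.4), n = 120, seed = 9)
  clean <- apply_qc(base)
  expect_equal(nrow(clean$report$individuals), 0L)
  expect_equal(nrow(clean$report$snps), 0L)
  expect_equal(sum(clean$report$snp_stats$mendelian_errors), 0L)

  # one mother at 2/3 missing -> blanked
  d <- base
  d$mother[1, c(1, 2)] <- NA_integer_
  res <- apply_qc(d, snp_miss_max = 0.05)
  expect_equal(res$report$individuals$triad_id, base$triads$triad_id[1])
  expect_equal(res$report$individuals$member, "mother")
  expect_true(all(is.na(res$dataset$mother[1, ])))

  # SNP with MAF below 0.01 -> removed with the MAF reason
  d2 <- base
  d2$mother[, 2] <- 0L; d2$father[, 2] <- 0L; d2$child[, 2] <- 0L
  d2$mother[1, 2] <- 1L # MAF 1/(2*?) << 0.01
  res2 <- apply_qc(d2)
  expect_equal(res2$report$snps$snp_id, "s002")
  expect_match(res2$report$snps$reason, "MAF")
  expect_equal(n_snps(res2$dataset), 2L)

  # SNP with 31 Mendelian errors removed, 30 kept
  d3 <- base
  boys <- which(d3$triads$child_sex == "male")
  plant <- function(dat, col, k) {
    idx <- boys[seq_len(k)]
    dat$mother[idx, col] <- 0L
    dat$child[idx, col] <- 1L
    dat
  }
  d3 <- plant(d3, 1, 31)
  d3 <- plant(d3, 3, 30)
  res3 <- apply_qc(d3, snp_miss_max = 1, maf_min = 0)
  expect_equal(res3$report$snps$snp_id, "s001")
  expect_match(res3$report$snps$reason, "Mendelian")
  expect_true("s003" %in% res3$dataset$snps$snp_id)
  # surviving SNP has its 30 inconsistent triads masked, others untouched
  expect_equal(sum(res3$dataset$mask[, res3$dataset$snps$snp_id == "s003"]), 30L)

  # idempotence: second pass removes nothing and returns the same data
  twice <- apply_qc(res3$dataset, snp_miss_max = 1, maf_min = 0)
  expect_equal(nrow(twice$report$individuals), 0L)
  expect_equal(nrow(twice$report$snps), 0L)
  expect_equal(twice$dataset$mother, res3$dataset$mother)
  expect_equal(twice$dataset$mask, res3$dataset$mask)

  # QC report serialization
  out <- tempfile(fileext = ".tsv"); lg <- tempfile(fileext = ".log")
  write_qc_report(res3$report, out, lg)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(any(tab$removed))
  expect_true(file.size(lg) > 0)
})
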