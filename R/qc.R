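#' Quality-control filtering of an X-linked triad dataset
#'
#' Filters in a fixed order: (1) individuals whose genotype missingness
#' exceeds `ind_miss_max` are blanked (a removed parent's calls are set to
#' missing so the triad's remaining members stay usable; a removed child drops
#' the whole triad, since the affected child defines the triad); (2) SNP
#' missingness is recomputed and SNPs above `snp_miss_max` are removed;
#' (3) SNPs with minor-allele frequency below `maf_min` are removed; (4) SNPs
#' with more than `mendel_max` Mendelian errors are removed. Surviving SNPs
#' have their Mendelian-inconsistent triads masked per SNP (they enter the
#' likelihood as missing there but are kept at other SNPs).
#'
#' Individuals that already have no genotype calls at all are not re-reported
#' as removals, which makes the filter idempotent: running it on its own
#' output removes nothing further.
#'
#' @param dataset A [triad_data()] object.
#' @param ind_miss_max Maximum tolerated per-individual missing fraction
#'   (strictly greater is removed). Default 0.10.
#' @param snp_miss_max Maximum tolerated per-SNP missing fraction. Default 0.01.
#' @param maf_min Minimum minor-allele frequency. Default 0.01.
#' @param mendel_max Maximum tolerated Mendelian-error count per SNP
#'   (strictly greater is removed). Default 30.
#' @return A list with elements `dataset` (the filtered, masked `triad_data`)
#'   and `report` (class `xpoo_qc`): tibbles of removed individuals and SNPs
#'   with reasons, plus per-SNP statistics (missing rate, MAF, Mendelian
#'   errors, exact HWE p-value from mothers' genotype counts).
#' @export
apply_qc <- function(dataset, ind_miss_max = 0.10, snp_miss_max = 0.01,
                     maf_min = 0.01, mendel_max = 30) {
  stopifnot(inherits(dataset, "triad_data"))
  if (n_triads(dataset) == 0L || n_snps(dataset) == 0L) abort("empty dataset")
  m <- n_snps(dataset)

  # 1. individual missingness (skip already-blank individuals)
  miss_of <- function(mat) rowMeans(is.na(mat))
  ind_tbl <- tibble(
    triad_id = rep(dataset$triads$triad_id, 3L),
    member = rep(c("mother", "father", "child"), each = n_triads(dataset)),
    missing_rate = c(miss_of(dataset$mother), miss_of(dataset$father),
                     miss_of(dataset$child))
  )
  removed_ind <- dplyr::filter(ind_tbl,
                               .data$missing_rate > ind_miss_max,
                               .data$missing_rate < 1)
  removed_ind$reason <- sprintf("missingness %.3f > %.2f",
                                removed_ind$missing_rate, ind_miss_max)
  drop_triads <- character(0)
  for (r in seq_len(nrow(removed_ind))) {
    k <- match(removed_ind$triad_id[r], dataset$triads$triad_id)
    mem <- removed_ind$member[r]
    if (mem == "child") drop_triads <- c(drop_triads, removed_ind$triad_id[r])
    else dataset[[mem]][k, ] <- NA_integer_
  }
  if (length(drop_triads)) {
    keep <- !dataset$triads$triad_id %in% drop_triads
    dataset <- triad_data(dataset$snps, dataset$triads[keep, ],
                          dataset$mother[keep, , drop = FALSE],
                          dataset$father[keep, , drop = FALSE],
                          dataset$child[keep, , drop = FALSE])
  }
  if (n_triads(dataset) == 0L) abort("all triads removed by individual missingness filter")

  # 2-4. per-SNP statistics on the post-individual-filter data
  girls <- dataset$triads$child_sex == "female"
  snp_miss <- vapply(seq_len(m), function(j) {
    mean(is.na(c(dataset$mother[, j], dataset$father[, j], dataset$child[, j])))
  }, numeric(1))
  maf <- vapply(seq_len(m), function(j) {
    if (snp_miss[j] == 1) return(NA_real_)
    compute_maf(dataset, j)
  }, numeric(1))
  mendel <- vapply(seq_len(m), function(j) count_mendelian_errors(dataset, j), integer(1))
  hwe <- vapply(seq_len(m), function(j) {
    md <- dataset$mother[, j]
    cnt <- c(sum(md == 0L, na.rm = TRUE), sum(md == 1L, na.rm = TRUE),
             sum(md == 2L, na.rm = TRUE))
    if (sum(cnt) == 0L) return(NA_real_)
    hwe_exact_test(cnt)
  }, numeric(1))
  snp_stats <- tibble(snp_id = dataset$snps$snp_id, missing_rate = snp_miss,
                      maf = maf, mendelian_errors = mendel, hwe_p = hwe)

  reason <- rep(NA_character_, m)
  reason[is.na(reason) & snp_miss > snp_miss_max] <-
    sprintf("missingness > %.3g", snp_miss_max)[1]
  reason[is.na(reason) & (is.na(maf) | maf < maf_min)] <-
    sprintf("MAF < %.3g", maf_min)[1]
  reason[is.na(reason) & mendel > mendel_max] <-
    sprintf("Mendelian errors > %d", as.integer(mendel_max))[1]
  keep_snp <- is.na(reason)
  if (!any(keep_snp)) abort("all SNPs removed by QC; review the thresholds")
  removed_snp <- tibble(snp_id = dataset$snps$snp_id[!keep_snp],
                        reason = reason[!keep_snp])

  filtered <- triad_data(dataset$snps[keep_snp, ], dataset$triads,
                         dataset$mother[, keep_snp, drop = FALSE],
                         dataset$father[, keep_snp, drop = FALSE],
                         dataset$child[, keep_snp, drop = FALSE])
  filtered <- mask_mendelian(filtered)

  report <- structure(
    list(individuals = removed_ind,
         triads_dropped = drop_triads,
         snps = removed_snp,
         snp_stats = snp_stats,
         thresholds = c(ind_miss_max = ind_miss_max, snp_miss_max = snp_miss_max,
                        maf_min = maf_min, mendel_max = mendel_max),
         filter_order = c("individual missingness", "SNP missingness",
                          "MAF", "Mendelian errors")),
    class = "xpoo_qc"
  )
  list(dataset = filtered, report = report)
}

#' @export
print.xpoo_qc <- function(x, ...) {
  cat("<xpoo_qc> quality-control report\n")
  cat(sprintf("  filter order: %s\n", paste(x$filter_order, collapse = " -> ")))
  cat(sprintf("  individuals blanked: %d (triads dropped: %d)\n",
              nrow(x$individuals), length(x$triads_dropped)))
  cat(sprintf("  SNPs removed: %d\n", nrow(x$snps)))
  if (nrow(x$snps)) {
    tb <- table(x$snps$reason)
    for (r in names(tb)) cat(sprintf("    %s: %d\n", r, tb[[r]]))
  }
  invisible(x)
}

#' Tidy a QC report into its per-SNP statistics table
#'
#' @param x An `xpoo_qc` report.
#' @param ... Unused.
#' @return A tibble with one row per input SNP: missing rate, MAF, Mendelian
#'   error count, exact HWE p-value, and whether/why the SNP was removed.
#' @export
tidy.xpoo_qc <- function(x, ...) {
  dplyr::left_join(x$snp_stats,
                   dplyr::mutate(x$snps, removed = TRUE),
                   by = "snp_id") |>
    dplyr::mutate(removed = !is.na(.data$removed))
}

#' Write a QC report as TSV plus a readable log
#'
#' @param report An `xpoo_qc` report.
#' @param stats_path Path for the per-SNP statistics TSV.
#' @param log_path Optional path for the human-readable log.
#' @export
write_qc_report <- function(report, stats_path, log_path = NULL) {
  readr::write_tsv(tidy(report), stats_path, progress = FALSE)
  if (!is.null(log_path)) {
    con <- file(log_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(stats_path)
}
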