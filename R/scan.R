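#' Consecutive sliding windows over a SNP map
#'
#' @param n_snps Number of SNPs in map order.
#' @param size Window size, 1 to 4 SNPs.
#' @return A tibble with one row per window: `window_id`, `start`, `end`
#'   (inclusive column indices). There are `n_snps - size + 1` windows.
#' @export
sliding_windows <- function(n_snps, size) {
  n_snps <- as.integer(n_snps); size <- as.integer(size)
  if (size < 1L || size > 4L) abort("window size must be between 1 and 4")
  if (size > n_snps) abort("window size exceeds the number of SNPs")
  starts <- seq_len(n_snps - size + 1L)
  tibble(window_id = starts, start = starts, end = starts + size - 1L)
}

#' Storey q-values
#'
#' Converts p-values to q-values: with p sorted ascending,
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, capped at 1. The null
#' proportion `pi0` is estimated on the grid lambda = 0.05, 0.10, ..., 0.95
#' by a cubic smoothing spline through `pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda))`, evaluated at lambda = 0.95 and clamped to (0, 1]. For
#' fewer than 100 p-values the estimate is unstable and the conservative
#' `pi0 = 1` (Benjamini-Hochberg behaviour) is used instead.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return Numeric vector of q-values in the input order.
#' @export
qvalues <- function(pvals, pi0 = NULL) {
  p <- as.numeric(pvals)
  if (!length(p)) abort("need at least one p-value")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# lambda-grid estimator of the null proportion (cubic smoother at 0.95)
estimate_pi0 <- function(p) {
  m <- length(p)
  if (m < 100L) return(1)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = 0.95)$y
  min(max(pi0, 1 / m), 1)
}

#' Scan a chromosome with single-marker or sliding haplotype windows
#'
#' Fits every window with [fit_window()] under the requested model, attaches
#' Storey [qvalues()] over the windows that fitted cleanly, and returns one
#' row per window in map order (Manhattan/table-ready). Windows whose fit
#' fails (monomorphic after pooling, too few informative triads) are kept
#' with `status` recording the reason and are excluded from the
#' false-discovery-rate computation. q-values are computed within this scan
#' only: each model-by-sex analysis is its own testing family.
#'
#' @param dataset A QC'd [triad_data()] object.
#' @param model `"x_inactivation"`, `"no_x_inactivation"`, or `"girls_only"`.
#' @param window_size 1 (single-marker) to 4 SNPs per window.
#' @param sex_restriction `"all"` or `"females"`; `"females"` forces the
#'   girls-only model.
#' @param window_p_kind `"overall"` (default) uses each fit's window-level
#'   test of `RRR = 1`; `"min_haplotype"` instead uses the smallest
#'   per-haplotype `RRR` Wald p-value in the window (no multiplicity
#'   adjustment across haplotypes — interpret accordingly).
#' @param ... Further arguments passed to [fit_window()].
#' @return A tibble of class `xpoo_scan`, one row per window: window SNP ids
#'   (hyphen-joined), position of the first SNP, model, sex restriction,
#'   window p-value and `-log10(p)`, q-value, best and reference haplotype,
#'   window Mendelian-error count (triads inconsistent at any window SNP),
#'   minimum exact HWE p across window SNPs, the best haplotype's RRm / RRf /
#'   RRR estimates with CIs and p-values, a `status` column, and the full
#'   per-haplotype estimate tables in the `estimates` list-column.
#' @export
run_scan <- function(dataset, model, window_size = 1,
                     sex_restriction = c("all", "females"),
                     window_p_kind = c("overall", "min_haplotype"), ...) {
  stopifnot(inherits(dataset, "triad_data"))
  if (n_triads(dataset) == 0L) abort("empty dataset")
  sex_restriction <- match.arg(sex_restriction)
  window_p_kind <- match.arg(window_p_kind)
  if (sex_restriction == "females") model <- "girls_only"
  check_model(model)
  wins <- sliding_windows(n_snps(dataset), window_size)

  mendel_by_snp <- matrix(FALSE, n_triads(dataset), n_snps(dataset))
  for (j in seq_len(n_snps(dataset))) {
    v <- check_triad_consistency(dataset$mother[, j], dataset$father[, j],
                                 dataset$child[, j], dataset$triads$child_sex)
    mendel_by_snp[, j] <- v == "inconsistent"
  }
  dataset$mask <- dataset$mask | mendel_by_snp
  hwe_by_snp <- vapply(seq_len(n_snps(dataset)), function(j) {
    md <- dataset$mother[, j]
    cnt <- c(sum(md == 0L, na.rm = TRUE), sum(md == 1L, na.rm = TRUE),
             sum(md == 2L, na.rm = TRUE))
    if (sum(cnt) == 0L) return(NA_real_)
    hwe_exact_test(cnt)
  }, numeric(1))

  rows <- purrr::pmap(wins, function(window_id, start, end) {
    window <- start:end
    snp_ids <- paste(dataset$snps$snp_id[window], collapse = "-")
    base <- tibble(
      window_id = window_id,
      window_snp_ids = snp_ids,
      position = dataset$snps$position[start],
      model = model,
      sex_restriction = sex_restriction,
      mendelian_errors = sum(rowSums(mendel_by_snp[, window, drop = FALSE]) > 0L),
      hwe_p = suppressWarnings(min(hwe_by_snp[window], na.rm = TRUE))
    )
    fit <- tryCatch(fit_window(dataset, window, model, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      return(dplyr::mutate(base, status = fit, window_p = NA_real_,
                           reference_haplotype = NA_character_))
    }
    best <- best_haplotype(fit)
    b <- fit$estimates[match(best, fit$estimates$haplotype), ]
    wp <- if (window_p_kind == "overall") fit$window_p
          else suppressWarnings(min(fit$estimates$rrr_p, na.rm = TRUE))
    dplyr::bind_cols(
      base,
      tibble(status = "ok",
             window_p = wp,
             reference_haplotype = fit$reference_haplotype,
             best_haplotype = best,
             rrm = b$rrm, rrm_lo = b$rrm_lo, rrm_hi = b$rrm_hi, rrm_p = b$rrm_p,
             rrf = b$rrf, rrf_lo = b$rrf_lo, rrf_hi = b$rrf_hi, rrf_p = b$rrf_p,
             rrr = b$rrr, rrr_lo = b$rrr_lo, rrr_hi = b$rrr_hi, rrr_p = b$rrr_p,
             converged = fit$converged,
             n_triads_used = fit$n_triads_used,
             estimates = list(fit$estimates))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$neg_log10_p <- -log10(out$window_p)
  out$q_value <- NA_real_
  ok <- !is.na(out$window_p)
  if (any(ok)) out$q_value[ok] <- qvalues(out$window_p[ok])
  class(out) <- c("xpoo_scan", class(out))
  out
}

#' Best haplotype of a fitted window
#'
#' The non-reference haplotype with the smallest parent-of-origin (RRR)
#' p-value; ties are broken lexicographically by allele string.
#'
#' @param fit An [fit_window()] result.
#' @return The allele string of the best haplotype.
#' @export
best_haplotype <- function(fit) {
  est <- fit$estimates
  if (is.null(est) || !nrow(est)) abort("fit carries no per-haplotype estimates")
  p <- est$rrr_p
  p[is.na(p)] <- Inf
  est$haplotype[order(p, est$haplotype)][1]
}

#' Manhattan-ready table for a scan
#'
#' @param rows An `xpoo_scan` tibble from [run_scan()].
#' @return A tibble with columns `position`, `neg_log10_p`, `model`,
#'   `sex_restriction` (map order preserved; failed windows dropped), with
#'   the genome-wide reference line `1e-4` attached as the
#'   `"reference_line"` attribute.
#' @export
manhattan_table <- function(rows) {
  if (!nrow(rows)) abort("no scan rows")
  out <- dplyr::select(dplyr::filter(as_tibble(rows), !is.na(.data$window_p)),
                       "position", "neg_log10_p", "model", "sex_restriction")
  attr(out, "reference_line") <- 1e-4
  out
}

#' Manhattan plot of a scan
#'
#' @param object An `xpoo_scan` tibble.
#' @param ... Unused.
#' @return A ggplot: `-log10(p)` against position with a dashed line at the
#'   `p = 1e-4` cutoff.
#' @export
autoplot.xpoo_scan <- function(object, ...) {
  tab <- manhattan_table(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$position, y = .data$neg_log10_p)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(tab, "reference_line")),
                        linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  title = sprintf("%s (%s)", tab$model[1], tab$sex_restriction[1]))
}

#' Write / read scan results as TSV
#'
#' The nested per-haplotype estimate tables are dropped; all flat columns
#' (including the best-haplotype relative risks) are written at full
#' precision and round-trip exactly.
#'
#' @param rows An `xpoo_scan` tibble.
#' @param path Output path.
#' @export
write_scan <- function(rows, path) {
  flat <- dplyr::select(as_tibble(rows), -dplyr::any_of("estimates"))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("xpoo_scan", class(out))
  out
}
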