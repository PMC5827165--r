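#' Specify a triad simulation
#'
#' Collects the generative parameters for the exact ascertainment sampler and
#' the power engine. The defaults mirror the reference study conditions for a
#' single X-linked SNP: minor allele frequency 0.2, equal numbers of boys and
#' girls, 1,000 replicates, and a nominal significance level of 0.05.
#' Baseline absolute risks (0.4% for girls, 0.5% for boys) are documentation
#' only: conditioning on an affected child of known sex cancels them exactly,
#' so they never enter the sampler or the likelihood.
#'
#' For multi-SNP windows pass a vector `maf` (one per SNP; within-window
#' haplotype frequencies are the product, i.e. linkage equilibrium) or supply
#' `hap_freqs` directly, plus per-haplotype `rrm`/`rrf` vectors aligned to
#' the non-reference haplotypes in catalogue order.
#'
#' @param maf Variant-allele frequency (scalar, in (0, 0.5]) or one per SNP.
#' @param rrm,rrf Relative risks for the maternally / paternally inherited
#'   variant (scalars, or one per non-reference haplotype).
#' @param true_model `"x_inactivation"` or `"no_x_inactivation"`; fixes the
#'   boys' `RRB` via [rrb_from_constraint()].
#' @param n_triads Number of case-parent triads to draw.
#' @param prop_female Expected proportion of affected girls (default 0.5).
#' @param baseline_girl,baseline_boy Documentation-only absolute risks.
#' @param missing_rate_parent Probability that a parental genotype call is
#'   masked (applied independently per parent per SNP; default 0).
#' @param n_reps Replicates for [estimate_power()] (default 1000).
#' @param alpha Nominal significance level for power (default 0.05).
#' @param seed Integer seed; every random draw is reproducible from it.
#' @param hap_freqs Optional explicit haplotype frequency simplex.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(maf = 0.2, rrm = 1, rrf = 1,
                     true_model = c("x_inactivation", "no_x_inactivation"),
                     n_triads = 600, prop_female = 0.5,
                     baseline_girl = 0.004, baseline_boy = 0.005,
                     missing_rate_parent = 0, n_reps = 1000,
                     alpha = 0.05, seed = 1, hap_freqs = NULL) {
  true_model <- match.arg(true_model)
  if (is.null(hap_freqs)) {
    if (any(maf <= 0)) abort("maf must be positive")
    if (any(maf > 0.5)) abort("maf must not exceed 0.5")
    w <- length(maf)
    if (w > 4L) abort("at most 4 SNPs per simulated window")
    H <- window_haplotypes(w)
    hap_freqs <- apply(H, 1L, function(h) prod(ifelse(h == 1L, maf, 1 - maf)))
  }
  K <- length(hap_freqs)
  if (prop_female < 0 || prop_female > 1) abort("prop_female must be in [0, 1]")
  if (n_triads < 1) abort("n_triads must be at least 1")
  if (n_reps < 1) abort("n_reps must be at least 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (missing_rate_parent < 0 || missing_rate_parent >= 1) {
    abort("missing_rate_parent must be in [0, 1)")
  }
  reference <- order(-hap_freqs, seq_len(K))[1]
  expand <- function(rr) {
    if (length(rr) == 1L) { out <- rep(rr, K); out[reference] <- 1; out }
    else if (length(rr) == K - 1L) { out <- rep(1, K); out[-reference] <- rr; out }
    else if (length(rr) == K) rr
    else abort("rrm/rrf must be a scalar or have one entry per non-reference haplotype")
  }
  structure(
    list(maf = maf, hap_freqs = hap_freqs, reference = reference,
         rrm = expand(rrm), rrf = expand(rrf),
         true_model = true_model, n_triads = as.integer(n_triads),
         prop_female = prop_female,
         baseline_girl = baseline_girl, baseline_boy = baseline_boy,
         missing_rate_parent = missing_rate_parent,
         n_reps = as.integer(n_reps), alpha = alpha, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

spec_params <- function(spec) {
  risk_params(spec$hap_freqs, spec$rrm, spec$rrf, reference = spec$reference,
              baseline_girl = spec$baseline_girl, baseline_boy = spec$baseline_boy)
}

#' Simulate ascertained case-parent triads
#'
#' Draws triads directly from the conditional-on-affected configuration
#' distribution ([config_conditional_probability()]) under the spec's true
#' parameters — exact ascertainment sampling with no rejection loop. Child
#' sex is Bernoulli(`prop_female`); parental calls are then masked
#' independently at `missing_rate_parent`. Identical seeds give identical
#' datasets.
#'
#' @param spec A [sim_spec()].
#' @param seed Optional seed overriding `spec$seed` (used by the power
#'   engine's per-replicate scheme).
#' @return A [triad_data()] object with `length(spec$maf)` SNPs, alleles
#'   labelled `A` (reference) and `a` (variant).
#' @export
simulate_triads <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  params <- spec_params(spec)
  K <- length(spec$hap_freqs)
  w <- as.integer(round(log2(K)))
  H <- window_haplotypes(w)
  n <- spec$n_triads
  sex <- ifelse(runif(n) < spec$prop_female, "female", "male")

  cfg <- config_grid(K)
  draw_block <- function(sx) {
    configs <- enumerate_configs(K, sx)
    probs <- config_conditional_probability(configs, params, spec$true_model)
    sample.int(nrow(configs), sum(sex == sx), replace = TRUE, prob = probs)
  }
  mother <- father <- child <- matrix(NA_integer_, n, w)
  for (sx in c("female", "male")) {
    idx <- which(sex == sx)
    if (!length(idx)) next
    ci <- draw_block(sx)
    t <- cfg$t[ci]; u <- cfg$u[ci]; f <- cfg$f[ci]
    mother[idx, ] <- H[t, , drop = FALSE] + H[u, , drop = FALSE]
    father[idx, ] <- H[f, , drop = FALSE]
    child[idx, ] <- if (sx == "female") H[t, , drop = FALSE] + H[f, , drop = FALSE]
                    else H[t, , drop = FALSE]
  }
  if (spec$missing_rate_parent > 0) {
    mother[matrix(runif(n * w) < spec$missing_rate_parent, n, w)] <- NA_integer_
    father[matrix(runif(n * w) < spec$missing_rate_parent, n, w)] <- NA_integer_
  }
  new_triad_data(
    snps = tibble::new_tibble(list(snp_id = sprintf("snp%d", seq_len(w)),
                                   position = 1000L * seq_len(w),
                                   allele_ref = rep("A", w),
                                   allele_var = rep("a", w)), nrow = w),
    triads = tibble::new_tibble(list(triad_id = sprintf("t%04d", seq_len(n)),
                                     child_sex = sex), nrow = n),
    mother = mother, father = father, child = child
  )
}

#' Estimate statistical power of the window-level parent-of-origin test
#'
#' Simulates `spec$n_reps` datasets under the spec's true parameters, fits
#' `fit_model` to the (single) window of each, and reports the fraction of
#' replicates whose window-level RRR test rejects at `spec$alpha`, with its
#' Monte-Carlo standard error `sqrt(power * (1 - power) / n_reps)`.
#' Per-replicate seeds are `spec$seed + replicate index`, so grid cells are
#' reproducible independently. Replicates whose fit fails are counted,
#' excluded from the denominator, and trigger a warning when they exceed 1%.
#'
#' @param spec A [sim_spec()].
#' @param fit_model Analysis model: `"x_inactivation"`,
#'   `"no_x_inactivation"`, or `"girls_only"`.
#' @return A one-row tibble: `power`, `mc_standard_error`, `n_reps_used`,
#'   `n_failed`, the fitted model and the spec's generative parameters.
#' @export
estimate_power <- function(spec, fit_model) {
  stopifnot(inherits(spec, "sim_spec"))
  check_model(fit_model)
  w <- length(spec$maf)
  rejected <- logical(spec$n_reps)
  failed <- logical(spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    dat <- simulate_triads(spec, seed = (spec$seed + r) %% .Machine$integer.max)
    p <- tryCatch(
      fit_window(dat, seq_len(w), fit_model)$window_p,
      error = function(e) NA_real_
    )
    if (is.na(p)) failed[r] <- TRUE else rejected[r] <- p < spec$alpha
  }
  n_used <- sum(!failed)
  if (n_used == 0L) abort("every simulation replicate failed to fit")
  if (sum(failed) > 0.01 * spec$n_reps) {
    warn(sprintf("%d of %d power replicates failed to fit and were excluded",
                 sum(failed), spec$n_reps))
  }
  pow <- sum(rejected[!failed]) / n_used
  tibble(
    power = pow,
    mc_standard_error = sqrt(pow * (1 - pow) / n_used),
    n_reps_used = n_used,
    n_failed = sum(failed),
    fit_model = fit_model,
    true_model = spec$true_model,
    rrm = spec$rrm[-spec$reference][1],
    rrf = spec$rrf[-spec$reference][1],
    rrr = spec$rrm[-spec$reference][1] / spec$rrf[-spec$reference][1],
    maf = spec$maf[1],
    n_triads = spec$n_triads,
    prop_female = spec$prop_female,
    alpha = spec$alpha,
    seed = spec$seed
  )
}

#' Power over a grid of effect sizes, allele frequencies and sample sizes
#'
#' One [estimate_power()] call per grid cell. The defaults trace the
#' reference design: the paternal relative risk stays at 1 while the maternal
#' relative risk (hence the relative risk ratio) increases; the allele
#' frequency sweep holds 600 triads for the combined models and 300 for
#' girls-only; the sample-size sweep holds MAF 0.2.
#'
#' @param rrm_values Maternal relative risks to sweep (RRf fixed at 1).
#' @param maf_values Minor allele frequencies to sweep.
#' @param n_values Triad counts to sweep; `NULL` (the default) uses the
#'   reference design sizes per analysis model — 300 triads for girls-only
#'   cells, 600 for the combined models.
#' @param fit_models Analysis models to evaluate.
#' @param true_model Generative constraint model.
#' @param n_reps,alpha,seed,prop_female Passed to [sim_spec()]; each grid
#'   cell derives its own seed offset so cells are independent.
#' @return A tibble of class `xpoo_power`, one row per
#'   (rrm, maf, n, fit_model) cell.
#' @export
power_grid <- function(rrm_values = c(1, 1.5, 2, 2.5, 3),
                       maf_values = 0.2,
                       n_values = NULL,
                       fit_models = c("x_inactivation", "no_x_inactivation", "girls_only"),
                       true_model = "x_inactivation",
                       n_reps = 1000, alpha = 0.05, seed = 1,
                       prop_female = 0.5) {
  if (!length(rrm_values) || !length(maf_values) || !length(fit_models)) {
    abort("grids must be non-empty")
  }
  if (is.null(n_values)) {
    # reference design: girls-only analyses draw 300 all-girl triads, the
    # combined models 600 triads with an equal sex split
    grid <- tidyr::expand_grid(rrm = rrm_values, maf = maf_values,
                               fit_model = fit_models)
    grid$n_triads <- ifelse(grid$fit_model == "girls_only", 300L, 600L)
    grid$pf <- ifelse(grid$fit_model == "girls_only", 1, prop_female)
  } else {
    if (!length(n_values)) abort("grids must be non-empty")
    grid <- tidyr::expand_grid(rrm = rrm_values, maf = maf_values,
                               n_triads = n_values, fit_model = fit_models)
    grid$pf <- prop_female
  }
  grid$cell <- seq_len(nrow(grid))
  out <- purrr::pmap(grid, function(rrm, maf, n_triads, fit_model, pf, cell) {
    cell_seed <- (seed + 7919L * cell) %% .Machine$integer.max
    spec <- sim_spec(maf = maf, rrm = rrm, rrf = 1, true_model = true_model,
                     n_triads = n_triads, prop_female = pf,
                     n_reps = n_reps, alpha = alpha, seed = cell_seed)
    estimate_power(spec, fit_model)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("xpoo_power", class(out))
  out
}

#' Power curves
#'
#' @param object An `xpoo_power` tibble from [power_grid()].
#' @param x One of `"rrr"`, `"maf"`, `"n_triads"` for the horizontal axis.
#' @param ... Unused.
#' @return A ggplot of power against the chosen sweep, one line per analysis
#'   model, faceted over the remaining varying dimension when present.
#' @export
autoplot.xpoo_power <- function(object, x = c("rrr", "maf", "n_triads"), ...) {
  x <- match.arg(x)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$power,
                               colour = .data$fit_model, group = .data$fit_model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "power", colour = "analysis model")
}
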