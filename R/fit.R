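#' Wald confidence interval and p-value on the log relative-risk scale
#'
#' The interval is `exp(log_estimate +/- z * se)` and the p-value is the
#' two-sided normal tail probability of `log_estimate / se`, with the
#' standard error taken from the inverse observed information. A non-finite
#' or non-positive standard error yields `NA` markers rather than an error.
#'
#' @param log_estimate Estimate on the log scale.
#' @param standard_error Standard error of the log estimate.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `ci_low`, `ci_high`, `p` (on the
#'   relative-risk scale), vectorized over the inputs.
#' @export
wald_interval_and_p <- function(log_estimate, standard_error, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  bad <- !is.finite(log_estimate) | !is.finite(standard_error) | standard_error <= 0
  lo <- exp(log_estimate - z * standard_error)
  hi <- exp(log_estimate + z * standard_error)
  p <- 2 * pnorm(-abs(log_estimate / standard_error))
  lo[bad] <- NA_real_; hi[bad] <- NA_real_; p[bad] <- NA_real_
  tibble(ci_low = lo, ci_high = hi, p = p)
}

#' Likelihood-ratio test of the parent-of-origin contrast for a window
#'
#' Compares a free fit against the nested null fit in which every
#' non-reference haplotype's maternal and paternal relative risks are equal
#' (`RRR = 1`; a common fetal effect is still allowed). The statistic
#' `2 * (loglik_free - loglik_null)` is referred to a chi-square distribution
#' with one degree of freedom per free (non-reference, non-pooled) haplotype.
#'
#' @param fit_free A [fit_window()] result.
#' @param fit_null The matching null fit (`constrain_rrr = TRUE`) on the same
#'   data and model.
#' @return The test p-value.
#' @export
overall_window_test <- function(fit_free, fit_null) {
  stat <- 2 * (fit_free$loglik - fit_null$loglik)
  if (stat < -1e-6) {
    abort("free-fit log-likelihood is below the null fit: optimizer failure")
  }
  stat <- max(stat, 0)
  df <- length(fit_free$free_haps)
  pchisq(stat, df = df, lower.tail = FALSE)
}

# softmax frequencies with the reference haplotype's logit fixed at 0
alpha_to_pi <- function(alpha, K, reference) {
  a <- numeric(K)
  a[-reference] <- alpha
  e <- exp(a - max(a))
  e / sum(e)
}

# frequency-only ML fit (all relative risks 1); used for initialization,
# reference choice and rare-haplotype pooling
fit_freqs_only <- function(pat, pi0) {
  K <- pat$K
  ref <- 1L # arbitrary anchor; softmax is invariant to the choice
  one <- rep(1, K)
  nll <- function(alpha) {
    -patterns_loglik(pat, alpha_to_pi(alpha, K, ref), one, one, one)
  }
  if (K == 1L) return(1)
  a0 <- log(pmax(pi0, 1e-6) / pmax(pi0[ref], 1e-6))[-ref]
  opt <- optim(a0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  alpha_to_pi(opt$par, K, ref)
}

# pack/unpack (alpha, beta_m, beta_f) given free-haplotype set
theta_to_params <- function(theta, K, reference, free_haps, constrain_rrr) {
  nfree <- length(free_haps)
  alpha <- theta[seq_len(K - 1L)]
  pi <- alpha_to_pi(alpha, K, reference)
  rrm <- rrf <- rep(1, K)
  if (constrain_rrr) {
    b <- theta[K - 1L + seq_len(nfree)]
    rrm[free_haps] <- exp(b); rrf[free_haps] <- exp(b)
  } else {
    bm <- theta[K - 1L + seq_len(nfree)]
    bf <- theta[K - 1L + nfree + seq_len(nfree)]
    rrm[free_haps] <- exp(bm); rrf[free_haps] <- exp(bf)
  }
  list(pi = pi, rrm = rrm, rrf = rrf)
}

make_nll <- function(pat, K, reference, free_haps, model, constrain_rrr) {
  function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    p <- theta_to_params(theta, K, reference, free_haps, constrain_rrr)
    rrb <- switch(model,
                  x_inactivation = p$rrm * p$rrf,
                  no_x_inactivation = p$rrm,
                  girls_only = rep(1, K))
    ll <- patterns_loglik(pat, p$pi, p$rrm, p$rrf, rrb)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# central finite-difference Hessian, step on the log/logit scale
numeric_hessian <- function(fn, theta, h = 1e-5) {
  d <- length(theta)
  H <- matrix(NA_real_, d, d)
  f0 <- fn(theta)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' Fit the parent-of-origin relative-risk model to one haplotype window
#'
#' Maximizes the observed-data log-likelihood (see [observed_loglik()]) over
#' the haplotype frequencies and the per-haplotype log relative risks
#' `log RRm`, `log RRf`, subject to the chosen X-inactivation constraint.
#' Optimization is direct ascent (BFGS) on the pattern-collapsed likelihood
#' from a deterministic start (frequency-only estimates, all log RR = 0),
#' optionally followed by seeded random restarts. Haplotypes whose
#' frequency-only estimate falls below `rare_haplotype_min_freq` keep their
#' frequency parameters but have both relative risks pinned to the reference
#' level and are excluded from the per-haplotype output and the test's
#' degrees of freedom.
#'
#' @param dataset A [triad_data()] object (QC'd; see [apply_qc()]).
#' @param window Integer vector of 1--4 consecutive SNP column indices.
#' @param model `"x_inactivation"`, `"no_x_inactivation"`, or `"girls_only"`.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum optimizer iterations (default 1000).
#' @param restarts Number of seeded random restarts (default 0).
#' @param seed_for_restarts Integer seed used only when `restarts > 0`.
#' @param rare_haplotype_min_freq Pooling threshold (default 0.01).
#' @param min_informative Minimum number of informative triads (default 10).
#' @param constrain_rrr Fit the null model with `RRm = RRf` per haplotype
#'   (used internally for the window-level test).
#' @return An object of class `xpoo_fit`; see [tidy.xpoo_fit()] and
#'   [glance.xpoo_fit()]. Fields include the estimate table, `window_p`
#'   (the default window-level test of `RRR = 1`: a joint Wald test on the
#'   log relative-risk ratios, continuous even when the discrete genotype
#'   counts put the free maximum exactly on the null), `window_p_lrt` (the
#'   likelihood-ratio alternative; see [overall_window_test()]), `loglik`,
#'   `converged`, `n_iter`, and `n_triads_used`.
#' @export
fit_window <- function(dataset, window, model,
                       tol = 1e-8, max_iter = 1000, restarts = 0,
                       seed_for_restarts = NULL,
                       rare_haplotype_min_freq = 0.01,
                       min_informative = 10,
                       constrain_rrr = FALSE) {
  check_model(model)
  window <- as.integer(window)
  sexes <- if (model == "girls_only") "female" else c("female", "male")
  pat <- window_patterns(dataset, window, sexes)
  K <- pat$K
  if (pat$n_informative < min_informative) {
    abort(sprintf("only %d informative triads in window (minimum %d)",
                  pat$n_informative, min_informative))
  }

  # initialization: linkage-equilibrium product of per-SNP variant frequencies
  pi0 <- rep(1, K)
  for (s in seq_along(window)) {
    p_s <- min(max(variant_freq(dataset, window[s]), 1e-4), 1 - 1e-4)
    pi0 <- pi0 * ifelse(pat$H[, s] == 1L, p_s, 1 - p_s)
  }
  pi_hat0 <- fit_freqs_only(pat, pi0)

  ord <- order(-pi_hat0, pat$labels)
  reference <- ord[1]
  pooled <- setdiff(which(pi_hat0 < rare_haplotype_min_freq), reference)
  free_haps <- setdiff(seq_len(K), c(reference, pooled))
  if (!length(free_haps)) {
    abort("monomorphic window: no non-reference haplotype above the pooling threshold")
  }
  nfree <- length(free_haps)

  a0 <- log(pmax(pi_hat0, 1e-10) / pi_hat0[reference])[-reference]
  run_fit <- function(constrain, theta0 = NULL) {
    nll <- make_nll(pat, K, reference, free_haps, model, constrain)
    n_beta <- if (constrain) nfree else 2L * nfree
    if (is.null(theta0)) theta0 <- c(a0, rep(0, n_beta))
    one_opt <- function(th) {
      optim(th, nll, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol))
    }
    opt <- one_opt(theta0)
    n_iter <- opt$counts[["function"]]
    # chained restarts from the current optimum: resetting the BFGS Hessian
    # approximation resolves premature line-search stalls on flat stretches
    for (round in 1:5) {
      opt2 <- one_opt(opt$par)
      n_iter <- n_iter + opt2$counts[["function"]]
      improved <- opt$value - opt2$value
      if (opt2$value < opt$value) opt <- opt2
      if (improved < 1e-9) break
    }
    if (restarts > 0) {
      if (!is.null(seed_for_restarts)) set.seed(seed_for_restarts)
      for (r in seq_len(restarts)) {
        cand <- one_opt(theta0 + stats::rnorm(length(theta0), sd = 0.5))
        n_iter <- n_iter + cand$counts[["function"]]
        if (cand$value < opt$value - 1e-10) opt <- cand
      }
    }
    opt$n_iter <- n_iter
    opt$nll <- nll
    opt
  }

  if (constrain_rrr) {
    opt <- run_fit(TRUE)
  } else {
    # null (RRm = RRf) fit first; the free fit warm-starts from its solution
    # so the likelihood-ratio statistic is resolved even when it is tiny
    opt_null <- run_fit(TRUE)
    b_null <- opt_null$par[K - 1L + seq_len(nfree)]
    warm <- c(opt_null$par[seq_len(K - 1L)], b_null, b_null)
    opt <- run_fit(FALSE, theta0 = warm)
  }
  converged <- opt$convergence == 0L
  if (!converged) warn("fit_window: optimizer did not report convergence")

  est <- theta_to_params(opt$par, K, reference, free_haps, constrain_rrr)
  loglik <- -opt$value

  fit <- structure(
    list(params_hat = risk_params(est$pi, est$rrm, est$rrf, reference = reference),
         hap_freqs = est$pi, rrm_hat = est$rrm, rrf_hat = est$rrf,
         hap_labels = pat$labels, reference = reference,
         reference_haplotype = pat$labels[reference],
         free_haps = free_haps, pooled_haps = pat$labels[pooled],
         model = model, constrained = constrain_rrr,
         theta = opt$par, loglik = loglik,
         converged = converged, n_iter = opt$n_iter,
         n_triads_used = pat$n_informative,
         window = window),
    class = "xpoo_fit"
  )
  if (constrain_rrr) return(fit)

  fit$loglik_null <- -opt_null$value
  stat <- 2 * (fit$loglik - fit$loglik_null)
  if (stat < -1e-6) abort("free-fit log-likelihood is below the null fit: optimizer failure")
  fit$window_p_lrt <- pchisq(max(stat, 0), df = nfree, lower.tail = FALSE)
  fit$df <- nfree

  bm <- log(est$rrm[free_haps]); bf <- log(est$rrf[free_haps])
  log_rrr <- bm - bf
  log_rrb <- switch(model, x_inactivation = bm + bf, no_x_inactivation = bm,
                    girls_only = rep(NA_real_, nfree))
  se_m <- se_f <- se_r <- se_b <- rep(NA_real_, nfree)
  wald_stat <- NA_real_
  H <- numeric_hessian(opt$nll, opt$par)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) {
    im <- K - 1L + seq_len(nfree)
    i_f <- K - 1L + nfree + seq_len(nfree)
    vm <- diag(V)[im]; vf <- diag(V)[i_f]
    cv <- V[cbind(im, i_f)]
    se_m <- sqrt(pmax(vm, 0))
    se_f <- sqrt(pmax(vf, 0))
    se_r <- sqrt(pmax(vm + vf - 2 * cv, 0))
    se_b <- switch(model,
                   x_inactivation = sqrt(pmax(vm + vf + 2 * cv, 0)),
                   no_x_inactivation = se_m,
                   girls_only = rep(NA_real_, nfree))
    # joint Wald test of RRR = 1 across the free haplotypes
    V_r <- V[im, im, drop = FALSE] + V[i_f, i_f, drop = FALSE] -
      V[im, i_f, drop = FALSE] - V[i_f, im, drop = FALSE]
    wald_stat <- tryCatch(drop(crossprod(log_rrr, solve(V_r, log_rrr))),
                          error = function(e) NA_real_)
  } else {
    warn("fit_window: singular observed information; standard errors unavailable")
  }
  fit$window_p_wald <- if (is.finite(wald_stat) && wald_stat >= 0) {
    pchisq(wald_stat, df = nfree, lower.tail = FALSE)
  } else NA_real_
  # default window p: the Wald form, falling back to the likelihood ratio
  # when the information matrix is singular
  fit$window_p <- if (is.na(fit$window_p_wald)) fit$window_p_lrt else fit$window_p_wald
  wm <- wald_interval_and_p(bm, se_m)
  wf <- wald_interval_and_p(bf, se_f)
  wr <- wald_interval_and_p(log_rrr, se_r)
  wb <- wald_interval_and_p(log_rrb, se_b)
  fit$estimates <- tibble::new_tibble(list(
    haplotype = pat$labels[free_haps],
    freq = est$pi[free_haps],
    rrm = exp(bm), rrm_lo = wm$ci_low, rrm_hi = wm$ci_high, rrm_p = wm$p,
    rrf = exp(bf), rrf_lo = wf$ci_low, rrf_hi = wf$ci_high, rrf_p = wf$p,
    rrb = exp(log_rrb), rrb_lo = wb$ci_low, rrb_hi = wb$ci_high, rrb_p = wb$p,
    rrr = exp(log_rrr), rrr_lo = wr$ci_low, rrr_hi = wr$ci_high, rrr_p = wr$p
  ), nrow = nfree)
  fit
}

#' @export
print.xpoo_fit <- function(x, ...) {
  cat(sprintf("<xpoo_fit> model %s, window of %d SNP(s), %d triads\n",
              x$model, length(x$window), x$n_triads_used))
  cat(sprintf("  reference haplotype: %s; loglik %.4f%s\n",
              x$reference_haplotype, x$loglik,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  if (!is.null(x$window_p)) {
    cat(sprintf("  window RRR test: p = %.3g (df = %d)\n", x$window_p, x$df))
  }
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Tidy per-haplotype estimates of a fitted window
#'
#' @param x An `xpoo_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free haplotype: frequency, `rrm`,
#'   `rrf`, `rrb`, `rrr`, each with 95% CI bounds and Wald p-value.
#' @export
tidy.xpoo_fit <- function(x, ...) {
  if (is.null(x$estimates)) abort("constrained null fits carry no estimate table")
  x$estimates
}

#' One-row summary of a fitted window
#'
#' @param x An `xpoo_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: model, reference haplotype, log-likelihood,
#'   window-level RRR-test p-value, degrees of freedom, convergence flag,
#'   iteration count and number of triads used.
#' @export
glance.xpoo_fit <- function(x, ...) {
  tibble(model = x$model,
         reference_haplotype = x$reference_haplotype,
         loglik = x$loglik,
         window_p = x$window_p %||% NA_real_,
         window_p_lrt = x$window_p_lrt %||% NA_real_,
         df = x$df %||% NA_integer_,
         converged = x$converged,
         n_iter = x$n_iter,
         n_triads_used = x$n_triads_used,
         n_pooled = length(x$pooled_haps))
}
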