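#' @keywords internal
xpoo_models <- c("x_inactivation", "no_x_inactivation", "girls_only")

check_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% xpoo_models) {
    abort(paste0("`model` must be one of: ", paste(xpoo_models, collapse = ", ")))
  }
  model
}

#' Boys' relative risk implied by the X-inactivation constraint
#'
#' Links the relative risk `RRB` carried by a boy's single, maternally
#' derived X allele to the girls' maternal and paternal relative risks.
#' Under X-inactivation a girl's double dose acts like a boy's single dose,
#' `RRm * RRf = RRB`; without X-inactivation the maternally inherited allele
#' acts identically in both sexes, `RRm = RRB`.
#'
#' @param rrm,rrf Positive relative risks for the maternally / paternally
#'   inherited allele (vectors recycle).
#' @param model `"x_inactivation"` or `"no_x_inactivation"`; `"girls_only"`
#'   is an error because boys do not enter that analysis and `RRB` is
#'   undefined there.
#' @return `RRB`, same length as the inputs.
#' @export
rrb_from_constraint <- function(rrm, rrf, model) {
  check_model(model)
  if (model == "girls_only") {
    abort("RRB is undefined in the girls-only model (no boys are analyzed)")
  }
  if (any(rrm <= 0) || any(rrf <= 0)) abort("relative risks must be positive")
  if (model == "x_inactivation") rrm * rrf else rrm
}

#' Risk-parameter set for a haplotype window
#'
#' Holds the haplotype frequency simplex and per-haplotype relative risks.
#' The reference haplotype has `RRm = RRf = 1` by definition; `RRB` is never
#' stored — it is derived from the model constraint via
#' [rrb_from_constraint()]. Baseline absolute risks for girls and boys are
#' carried for the simulator's documentation only; they cancel exactly in the
#' conditional-on-affected likelihood.
#'
#' @param hap_freqs Positive frequencies, one per haplotype, summing to 1
#'   (renormalized if within 1e-8 of 1).
#' @param rrm,rrf Relative risks, either scalars (applied to every
#'   non-reference haplotype) or length-K vectors whose reference entry is 1.
#' @param reference Index of the reference haplotype
#'   (default: the most frequent).
#' @param baseline_girl,baseline_boy Absolute baseline risks (defaults 0.004
#'   and 0.005).
#' @return A list of class `risk_params`.
#' @export
risk_params <- function(hap_freqs, rrm = 1, rrf = 1,
                        reference = which.max(hap_freqs),
                        baseline_girl = 0.004, baseline_boy = 0.005) {
  K <- length(hap_freqs)
  if (K < 2L) abort("need at least 2 haplotypes")
  if (any(hap_freqs <= 0)) abort("haplotype frequencies must be positive")
  s <- sum(hap_freqs)
  if (abs(s - 1) > 1e-8) abort("haplotype frequencies must sum to 1")
  hap_freqs <- hap_freqs / s
  expand_rr <- function(rr, what) {
    if (length(rr) == 1L) {
      out <- rep(rr, K); out[reference] <- 1
    } else if (length(rr) == K) {
      out <- rr
      if (abs(out[reference] - 1) > 1e-12) {
        abort(sprintf("%s at the reference haplotype must be 1", what))
      }
    } else abort(sprintf("%s must be a scalar or length-%d vector", what, K))
    if (any(out <= 0)) abort(sprintf("%s must be positive", what))
    out
  }
  structure(
    list(hap_freqs = hap_freqs, rrm = expand_rr(rrm, "rrm"),
         rrf = expand_rr(rrf, "rrf"), reference = as.integer(reference),
         baseline_girl = baseline_girl, baseline_boy = baseline_boy),
    class = "risk_params"
  )
}

#' Relative risk of an affected child given its inherited haplotypes
#'
#' Girls carry one maternally and one paternally derived X haplotype and,
#' under the multiplicative model, have risk multiplier
#' `RRm[maternal] * RRf[paternal]`. Boys carry only the maternal haplotype
#' and have multiplier `RRB[maternal]` from the model constraint. The
#' reference haplotype contributes a factor of 1.
#'
#' @param maternal_hap Haplotype index (1-based) inherited from the mother.
#' @param paternal_hap Haplotype index inherited from the father, or `NA`
#'   for boys.
#' @param child_sex `"female"` or `"male"` (vectors recycle).
#' @param params A [risk_params()] object.
#' @param model Constraint model; see [rrb_from_constraint()].
#' @return Positive relative risk, vectorized over the inputs.
#' @export
child_relative_risk <- function(maternal_hap, paternal_hap, child_sex, params, model) {
  check_model(model)
  nn <- max(length(maternal_hap), length(paternal_hap), length(child_sex))
  mh <- rep_len(as.integer(maternal_hap), nn)
  ph <- rep_len(as.integer(paternal_hap), nn)
  sex <- rep_len(child_sex, nn)
  if (any(sex == "female" & is.na(ph))) {
    abort("a girl must have a paternal haplotype")
  }
  out <- numeric(nn)
  g <- sex == "female"
  out[g] <- params$rrm[mh[g]] * params$rrf[ph[g]]
  if (any(!g)) {
    rrb <- rrb_from_constraint(params$rrm, params$rrf, model)
    out[!g] <- rrb[mh[!g]]
  }
  out
}

#' Enumerate complete-data triad configurations
#'
#' A configuration is the ordered triple (maternal transmitted haplotype `t`,
#' maternal untransmitted haplotype `u`, paternal haplotype `f`) for a child
#' of given sex. Under Hardy-Weinberg proportions, random mating, and fair
#' Mendelian transmission the prior probability of `(t, u, f)` is
#' `pi_t * pi_u * pi_f`, which sums to 1 over all `K^3` configurations per
#' sex. A girl's haplotype pair is `(t, f)`; a boy carries `t` alone, but his
#' father is retained because the paternal genotype still informs the
#' haplotype frequencies.
#'
#' @param n_haplotypes Number of haplotype categories `K` (at least 2).
#' @param child_sex `"female"` or `"male"`.
#' @param hap_freqs Optional frequency simplex; when given, the
#'   `prior_prob` column is filled in.
#' @return A tibble with columns `mother_transmitted`, `mother_untransmitted`,
#'   `father_hap`, `child_sex` and (optionally) `prior_prob`.
#' @export
enumerate_configs <- function(n_haplotypes, child_sex, hap_freqs = NULL) {
  K <- as.integer(n_haplotypes)
  if (K < 2L) abort("monomorphic window: need at least 2 haplotypes")
  if (!child_sex %in% c("female", "male")) abort("child_sex must be female/male")
  grid <- expand.grid(mother_transmitted = seq_len(K),
                      mother_untransmitted = seq_len(K),
                      father_hap = seq_len(K))
  out <- tibble::new_tibble(
    list(mother_transmitted = grid$mother_transmitted,
         mother_untransmitted = grid$mother_untransmitted,
         father_hap = grid$father_hap,
         child_sex = rep(child_sex, nrow(grid))),
    nrow = nrow(grid))
  if (!is.null(hap_freqs)) {
    if (length(hap_freqs) != K) abort("hap_freqs must have one entry per haplotype")
    out$prior_prob <- hap_freqs[out$mother_transmitted] *
      hap_freqs[out$mother_untransmitted] * hap_freqs[out$father_hap]
  }
  out
}

#' Conditional probability of a configuration given an affected child
#'
#' Multiplies each configuration's Hardy-Weinberg/Mendelian prior by the
#' child's relative risk and normalizes within child sex. The sex-specific
#' baseline risks cancel in the normalization, which is why they are never
#' estimated. For girls the normalizer factorizes as
#' `sum(pi*RRm) * sum(pi*RRf)`; for boys it is `sum(pi*RRB)`.
#'
#' @param configs A tibble of configurations from [enumerate_configs()]
#'   (any subset of rows; the normalizer is always taken over the complete
#'   configuration set of each sex).
#' @param params A [risk_params()] object.
#' @param model Constraint model.
#' @return Numeric vector of conditional probabilities, one per row.
#' @export
config_conditional_probability <- function(configs, params, model) {
  check_model(model)
  pi <- params$hap_freqs
  t <- configs$mother_transmitted
  u <- configs$mother_untransmitted
  f <- configs$father_hap
  prior <- pi[t] * pi[u] * pi[f]
  out <- numeric(nrow(configs))
  g <- configs$child_sex == "female"
  if (any(g)) {
    denom <- sum(pi * params$rrm) * sum(pi * params$rrf)
    out[g] <- prior[g] * params$rrm[t[g]] * params$rrf[f[g]] / denom
  }
  if (any(!g)) {
    if (model == "girls_only") abort("boys have no configurations in the girls-only model")
    rrb <- rrb_from_constraint(params$rrm, params$rrf, model)
    out[!g] <- prior[!g] * rrb[t[!g]] / sum(pi * rrb)
  }
  out
}

# --- window machinery ------------------------------------------------------

# ordered configuration index triples (t, u, f), t varying fastest --
# the same order as expand.grid over three haplotype indices
config_grid <- function(K) {
  list(t = rep.int(seq_len(K), K * K),
       u = rep.int(rep(seq_len(K), each = K), K),
       f = rep(seq_len(K), each = K * K))
}

# haplotype catalogue for a window: K x w matrix of variant indicators,
# rows ordered with SNP 1 as the fastest-varying bit
window_haplotypes <- function(w) {
  grid <- as.matrix(expand.grid(rep(list(0:1), w)))
  dimnames(grid) <- NULL
  grid
}

hap_labels <- function(H, snps) {
  apply(H, 1L, function(row) {
    paste(ifelse(row == 1L,
                 ifelse(is.na(snps$allele_var), "?", snps$allele_var),
                 snps$allele_ref),
          collapse = "-")
  })
}

# collapse a window's triads into unique observed patterns with counts and
# config-compatibility matrices, one block per sex
window_patterns <- function(dataset, window, sexes = c("female", "male")) {
  window <- as.integer(window)
  if (any(window < 1L) || any(window > n_snps(dataset))) abort("window indices out of range")
  w <- length(window)
  if (w < 1L || w > 4L) abort("windows span 1 to 4 SNPs")
  H <- window_haplotypes(w)
  K <- nrow(H)
  doses <- masked_doses(dataset)
  md <- doses$mother[, window, drop = FALSE]
  fd <- doses$father[, window, drop = FALSE]
  cd <- doses$child[, window, drop = FALSE]
  sex <- dataset$triads$child_sex
  keep <- sex %in% sexes
  informative <- keep & (rowSums(!is.na(md)) + rowSums(!is.na(fd)) +
                           rowSums(!is.na(cd))) > 0L

  cfg <- config_grid(K)
  m_cfg <- H[cfg$t, , drop = FALSE] + H[cfg$u, , drop = FALSE]
  f_cfg <- H[cfg$f, , drop = FALSE]

  blocks <- list()
  for (sx in sexes) {
    idx <- which(informative & sex == sx)
    if (!length(idx)) next
    c_cfg <- if (sx == "female") H[cfg$t, , drop = FALSE] + H[cfg$f, , drop = FALSE]
             else H[cfg$t, , drop = FALSE]
    obs <- cbind(md[idx, , drop = FALSE], fd[idx, , drop = FALSE],
                 cd[idx, , drop = FALSE])
    key <- do.call(paste, c(lapply(seq_len(ncol(obs)), function(s) obs[, s]),
                            sep = ","))
    first <- !duplicated(key)
    uidx <- idx[first]
    counts <- as.vector(table(factor(key, levels = key[first])))
    np <- length(uidx)
    C <- matrix(TRUE, np, K^3)
    for (p in seq_len(np)) {
      i <- uidx[p]
      ok <- rep(TRUE, K^3)
      for (s in seq_len(w)) {
        if (!is.na(md[i, s])) ok <- ok & m_cfg[, s] == md[i, s]
        if (!is.na(fd[i, s])) ok <- ok & f_cfg[, s] == fd[i, s]
        if (!is.na(cd[i, s])) ok <- ok & c_cfg[, s] == cd[i, s]
      }
      if (!any(ok)) {
        abort(sprintf(
          "triad %s has no haplotype configuration compatible with its genotypes in window [%s]; Mendelian-inconsistent triads should be masked first (see mask_mendelian/apply_qc)",
          dataset$triads$triad_id[i],
          paste(dataset$snps$snp_id[window], collapse = ", ")))
      }
      C[p, ] <- ok
    }
    blocks[[sx]] <- list(C = C, counts = counts)
  }
  list(H = H, K = K, w = w, cfg = cfg, blocks = blocks,
       n_informative = sum(informative),
       labels = hap_labels(H, dataset$snps[window, , drop = FALSE]))
}

# log-likelihood of collapsed patterns at given (pi, rrm, rrf, rrb)
patterns_loglik <- function(pat, pi, rrm, rrf, rrb) {
  t <- pat$cfg$t; u <- pat$cfg$u; f <- pat$cfg$f
  prior <- pi[t] * pi[u] * pi[f]
  ll <- 0
  bg <- pat$blocks[["female"]]
  if (!is.null(bg)) {
    num <- prior * rrm[t] * rrf[f]
    probs <- as.vector(bg$C %*% num) / (sum(pi * rrm) * sum(pi * rrf))
    if (anyNA(probs) || any(probs <= 0)) return(-Inf)
    ll <- ll + sum(bg$counts * log(probs))
  }
  bb <- pat$blocks[["male"]]
  if (!is.null(bb)) {
    num <- prior * rrb[t]
    probs <- as.vector(bb$C %*% num) / sum(pi * rrb)
    if (anyNA(probs) || any(probs <= 0)) return(-Inf)
    ll <- ll + sum(bb$counts * log(probs))
  }
  ll
}

#' Observed-data log-likelihood of a haplotype window
#'
#' Sums, over triads, the log of the total conditional probability of every
#' complete-data configuration compatible with the observed genotypes. Phase
#' ambiguity and missing members (including Mendelian-masked slots) are
#' handled by this marginalization — an incomplete triad simply sums over a
#' larger compatible set.
#'
#' @param dataset A [triad_data()] object.
#' @param window Integer vector of 1 to 4 consecutive SNP column indices.
#' @param params A [risk_params()] object with one frequency per window
#'   haplotype (haplotypes ordered with the first SNP's allele varying
#'   fastest; see [enumerate_configs()]).
#' @param model Constraint model; `"girls_only"` restricts to female-child
#'   triads.
#' @return The log-likelihood (scalar).
#' @export
observed_loglik <- function(dataset, window, params, model) {
  check_model(model)
  sexes <- if (model == "girls_only") "female" else c("female", "male")
  pat <- window_patterns(dataset, window, sexes)
  if (length(params$hap_freqs) != pat$K) {
    abort(sprintf("params has %d haplotype frequencies but the window has %d haplotypes",
                  length(params$hap_freqs), pat$K))
  }
  rrb <- if (model == "girls_only") rep(1, pat$K)
         else rrb_from_constraint(params$rrm, params$rrf, model)
  patterns_loglik(pat, params$hap_freqs, params$rrm, params$rrf, rrb)
}
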