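# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written from first principles, separate from the package's
# likelihood machinery, so package results can be checked against it.

# direct statement of the X-linked transmission rule for one fully observed
# triad (no lookup tables)
rule_ok_direct <- function(m, f, c, sex) {
  if (sex == "male") {
    if (c == 1) return(m >= 1)
    return(m <= 1)
  }
  maternal <- c - f
  if (maternal < 0 || maternal > 1) return(FALSE)
  if (maternal == 1) m >= 1 else m <= 1
}

# brute-force verdict by enumerating completions of missing members
oracle_verdict <- function(m, f, c, sex) {
  ms <- if (is.na(m)) 0:2 else m
  fs <- if (is.na(f)) 0:1 else f
  cs <- if (is.na(c)) 0:(if (sex == "female") 2 else 1) else c
  oks <- c()
  for (mm in ms) for (ff in fs) for (cc in cs) {
    oks <- c(oks, rule_ok_direct(mm, ff, cc, sex))
  }
  if (all(oks)) "consistent" else if (!any(oks)) "inconsistent" else "unknown"
}

oracle_mendel_count <- function(dataset, j) {
  n_bad <- 0L
  for (k in seq_len(n_triads(dataset))) {
    v <- oracle_verdict(dataset$mother[k, j], dataset$father[k, j],
                        dataset$child[k, j], dataset$triads$child_sex[k])
    if (v == "inconsistent") n_bad <- n_bad + 1L
  }
  n_bad
}

# exact HWE null by enumerating every placement of the variant alleles into
# the 2n genotype slots (alleles are exchangeable, so placements are
# equally likely); feasible for a handful of individuals
oracle_hwe_slots <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_var <- 2 * n_aa + n_Aa
  slots <- 2 * n
  hets <- function(var_slots) {
    per_ind <- tabulate(ceiling(var_slots / 2), nbins = n)
    sum(per_ind == 1)
  }
  if (n_var == 0) {
    counts <- setNames(1, "0")
  } else {
    placements <- utils::combn(slots, n_var)
    h <- apply(placements, 2, hets)
    counts <- table(h)
  }
  probs <- as.numeric(counts) / sum(as.numeric(counts))
  names(probs) <- names(counts)
  p_obs <- probs[as.character(n_Aa)]
  sum(probs[probs <= p_obs + 1e-12])
}

# exact HWE null by enumerating heterozygote counts with exact choose()
# arithmetic (independent of the package's lgamma route)
oracle_hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_var <- 2 * n_aa + n_Aa
  n_ref <- 2 * n_AA + n_Aa
  rare <- min(n_var, n_ref)
  hs <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hs, function(h) {
    choose(n, (n_var - h) / 2) *
      choose(n - (n_var - h) / 2, h) * 2^h
  }, numeric(1))
  w <- w / sum(w)
  w_obs <- w[match(n_Aa, hs)]
  sum(w[w <= w_obs * (1 + 1e-12)])
}

# independent single-SNP likelihood: per grid point, sum the conditional
# probabilities of the configurations compatible with each triad's doses;
# coarse pass over a wide box, then a fine pass around the coarse argmax
oracle_grid_search <- function(dataset, model) {
  coarse <- oracle_grid_pass(dataset, model,
                             pi_grid = seq(0.02, 0.98, length.out = 25),
                             b_grid = seq(-2.5, 2.5, length.out = 26))
  pi_step <- 0.04; b_step <- 0.2
  fine <- oracle_grid_pass(
    dataset, model,
    pi_grid = seq(max(coarse$pi - pi_step, 0.005),
                  min(coarse$pi + pi_step, 0.995), length.out = 21),
    b_grid = seq(coarse$bm - b_step, coarse$bm + b_step, length.out = 21),
    b_grid_f = seq(coarse$bf - b_step, coarse$bf + b_step, length.out = 21)
  )
  max(coarse$best, fine$best)
}

oracle_grid_pass <- function(dataset, model, pi_grid, b_grid,
                             b_grid_f = b_grid) {
  sex <- dataset$triads$child_sex
  md <- dataset$mother[, 1]; fd <- dataset$father[, 1]; cd <- dataset$child[, 1]
  if (model == "girls_only") {
    keep <- sex == "female"
    sex <- sex[keep]; md <- md[keep]; fd <- fd[keep]; cd <- cd[keep]
  }
  # configuration table: t, u, f in {0,1} variant indicators
  cfg <- expand.grid(t = 0:1, u = 0:1, f = 0:1)
  compat <- matrix(FALSE, length(md), 8)
  for (i in seq_along(md)) {
    for (cix in 1:8) {
      t <- cfg$t[cix]; u <- cfg$u[cix]; f <- cfg$f[cix]
      cd_cfg <- if (sex[i] == "female") t + f else t
      ok <- TRUE
      if (!is.na(md[i]) && md[i] != t + u) ok <- FALSE
      if (!is.na(fd[i]) && fd[i] != f) ok <- FALSE
      if (!is.na(cd[i]) && cd[i] != cd_cfg) ok <- FALSE
      compat[i, cix] <- ok
    }
  }
  girls <- sex == "female"
  best <- -Inf
  arg <- c(pi = NA_real_, bm = NA_real_, bf = NA_real_)
  for (p in pi_grid) for (bm in b_grid) for (bf in b_grid_f) {
    pv <- c(1 - p, p)[c(cfg$t, cfg$u, cfg$f) + 1]
    dim(pv) <- c(8, 3)
    prior <- pv[, 1] * pv[, 2] * pv[, 3]
    rm_ <- c(1, exp(bm)); rf_ <- c(1, exp(bf))
    rb_ <- switch(model,
                  x_inactivation = rm_ * rf_,
                  no_x_inactivation = rm_,
                  girls_only = c(1, 1))
    num_g <- prior * rm_[cfg$t + 1] * rf_[cfg$f + 1]
    den_g <- sum(c(1 - p, p) * rm_) * sum(c(1 - p, p) * rf_)
    num_b <- prior * rb_[cfg$t + 1]
    den_b <- sum(c(1 - p, p) * rb_)
    lg <- as.vector(compat %*% num_g) / den_g
    lb <- as.vector(compat %*% num_b) / den_b
    li <- ifelse(girls, lg, lb)
    ll <- sum(log(li))
    if (ll > best) { best <- ll; arg <- c(pi = p, bm = bm, bf = bf) }
  }
  list(best = best, pi = arg[["pi"]], bm = arg[["bm"]], bf = arg[["bf"]])
}

# analytic power approximation for the single-SNP RRR likelihood-ratio test:
# noncentrality = 2 n KL(truth || closest null), chi-square df 1
oracle_power_lrt <- function(spec, fit_model) {
  params <- risk_params(spec$hap_freqs, spec$rrm, spec$rrf,
                        reference = spec$reference)
  pattern_probs <- function(pi, rrm, rrf, rrb, sex) {
    cfg <- expand.grid(t = 0:1, u = 0:1, f = 0:1)
    prior <- c(1 - pi, pi)[cfg$t + 1] * c(1 - pi, pi)[cfg$u + 1] *
      c(1 - pi, pi)[cfg$f + 1]
    if (sex == "female") {
      w <- prior * rrm[cfg$t + 1] * rrf[cfg$f + 1] /
        (sum(c(1 - pi, pi) * rrm) * sum(c(1 - pi, pi) * rrf))
      key <- paste(cfg$t + cfg$u, cfg$f, cfg$t + cfg$f)
    } else {
      w <- prior * rrb[cfg$t + 1] / sum(c(1 - pi, pi) * rrb)
      key <- paste(cfg$t + cfg$u, cfg$f, cfg$t)
    }
    tapply(w, key, sum)
  }
  pi_true <- spec$hap_freqs[2]
  rrb_true <- rrb_from_constraint(spec$rrm, spec$rrf, spec$true_model)
  pg_true <- pattern_probs(pi_true, spec$rrm, spec$rrf, rrb_true, "female")
  pb_true <- pattern_probs(pi_true, spec$rrm, spec$rrf, rrb_true, "male")
  # per-analyzed-triad KL from the truth to the closest null (RRm = RRf) law
  kl_null <- function(th) {
    pi <- plogis(th[1]); b <- th[2]
    rr <- c(1, exp(b))
    rrb <- switch(fit_model, x_inactivation = rr * rr,
                  no_x_inactivation = rr, girls_only = c(1, 1))
    pg <- pattern_probs(pi, rr, rr, rrb, "female")
    kl_g <- sum(pg_true * log(pg_true / pg[names(pg_true)]))
    if (fit_model == "girls_only") return(kl_g)
    pb <- pattern_probs(pi, rr, rr, rrb, "male")
    kl_b <- sum(pb_true * log(pb_true / pb[names(pb_true)]))
    spec$prop_female * kl_g + (1 - spec$prop_female) * kl_b
  }
  opt <- optim(c(qlogis(pi_true), 0), kl_null, method = "BFGS")
  n_eff <- if (fit_model == "girls_only") spec$n_triads * spec$prop_female
           else spec$n_triads
  ncp <- 2 * n_eff * opt$value
  crit <- qchisq(1 - spec$alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

# build a multi-SNP dataset of independent SNPs with a shared sex vector,
# drawing each SNP's configurations from the package's conditional law
sim_dataset_multi <- function(mafs, n, prop_female = 0.5, seed = 1,
                              rrm = rep(1, length(mafs)),
                              rrf = rep(1, length(mafs)),
                              true_model = "x_inactivation") {
  set.seed(seed)
  sexes <- ifelse(runif(n) < prop_female, "female", "male")
  m_snps <- length(mafs)
  mother <- father <- child <- matrix(NA_integer_, n, m_snps)
  for (j in seq_len(m_snps)) {
    params <- risk_params(c(1 - mafs[j], mafs[j]),
                          rrm = c(1, rrm[j]), rrf = c(1, rrf[j]),
                          reference = 1)
    for (sx in c("female", "male")) {
      idx <- which(sexes == sx)
      if (!length(idx)) next
      cfgs <- enumerate_configs(2, sx)
      pr <- config_conditional_probability(cfgs, params, true_model)
      ci <- sample.int(nrow(cfgs), length(idx), replace = TRUE, prob = pr)
      t <- cfgs$mother_transmitted[ci] - 1L
      u <- cfgs$mother_untransmitted[ci] - 1L
      f <- cfgs$father_hap[ci] - 1L
      mother[idx, j] <- t + u
      father[idx, j] <- f
      child[idx, j] <- if (sx == "female") t + f else t
    }
  }
  triad_data(
    snps = tibble::tibble(snp_id = sprintf("s%03d", seq_len(m_snps)),
                          position = 10000L * seq_len(m_snps),
                          allele_ref = "A", allele_var = "a"),
    triads = tibble::tibble(triad_id = sprintf("t%05d", seq_len(n)),
                            child_sex = sexes),
    mother = mother, father = father, child = child
  )
}

# tiny ped/map fixture written to tempfiles; returns the two paths
write_ped_fixture <- function(ped_lines, map_lines) {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}
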