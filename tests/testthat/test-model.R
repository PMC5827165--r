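test_that("the X-inactivation constraints link RRB to RRm and RRf", {
  expect_equal(rrb_from_constraint(1, 1, "x_inactivation"), 1)
  expect_equal(rrb_from_constraint(1, 1, "no_x_inactivation"), 1)
  expect_equal(rrb_from_constraint(2.0, 1.4286, "no_x_inactivation"), 2.0)
  # solve RRm*RRf = 2 with RRm/RRf = 1.4: RRm = sqrt(2.8), RRf = sqrt(2/1.4)
  expect_equal(rrb_from_constraint(1.6733, 1.1952, "x_inactivation"), 2.0,
               tolerance = 1e-4)
  expect_equal(sqrt(2 * 1.4) * sqrt(2 / 1.4), 2.0)
  expect_error(rrb_from_constraint(2, 1, "girls_only"), "undefined")
  expect_error(rrb_from_constraint(-1, 1, "x_inactivation"), "positive")
})

test_that("a girl's double-dose risk follows the multiplicative model", {
  # boys' risk 2.0 and a parent-of-origin ratio of 1.4 without X-inactivation:
  # RRm = RRB = 2, RRf = 2/1.4, so an 'aa' girl carries 2.857 ~ 2.86
  p <- risk_params(c(0.8, 0.2), rrm = c(1, 2), rrf = c(1, 2 / 1.4),
                   reference = 1)
  rraa <- child_relative_risk(2, 2, "female", p, "no_x_inactivation")
  expect_equal(round(rraa, 2), 2.86)
  expect_gt(rraa, 2.0) # exceeds the boys' single-dose risk

  expect_equal(child_relative_risk(1, 1, "female", p, "no_x_inactivation"), 1)

  # under X-inactivation RRm = RRf = sqrt(2) gives boys RRB = 2
  p2 <- risk_params(c(0.8, 0.2), rrm = c(1, sqrt(2)), rrf = c(1, sqrt(2)),
                    reference = 1)
  expect_equal(child_relative_risk(2, NA, "male", p2, "x_inactivation"), 2.0)
  # ... and the girls' double dose equals the boys' single dose for every hap
  expect_equal(child_relative_risk(2, 2, "female", p2, "x_inactivation"),
               child_relative_risk(2, NA, "male", p2, "x_inactivation"))

  expect_error(child_relative_risk(2, NA, "female", p, "no_x_inactivation"),
               "paternal")
})

test_that("configuration enumeration is exhaustive with normalized priors", {
  for (sex in c("female", "male")) {
    cf <- enumerate_configs(2, sex)
    expect_equal(nrow(cf), 8L)
    expect_equal(unique(cf$child_sex), sex)
  }
  expect_error(enumerate_configs(1, "female"), "monomorphic")

  set.seed(1)
  for (K in 2:4) {
    pi <- as.vector(stats::rgamma(K, 2)); pi <- pi / sum(pi)
    cf <- enumerate_configs(K, "female", hap_freqs = pi)
    expect_equal(nrow(cf), K^3)
    expect_equal(sum(cf$prior_prob), 1, tolerance = 1e-12)
  }
})

test_that("conditional configuration probabilities match hand calculations", {
  cfg <- enumerate_configs(2, "female")
  null_params <- risk_params(c(0.5, 0.5), reference = 1)
  pr <- config_conditional_probability(cfg, null_params, "x_inactivation")
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # mother het transmitting the variant, father carries the variant:
  # 0.5 * 0.5 * 0.5 under the null
  i <- which(cfg$mother_transmitted == 2 & cfg$mother_untransmitted == 1 &
               cfg$father_hap == 2)
  expect_equal(pr[i], 0.125)

  # with all RR = 1 the conditional law equals the Mendelian/HWE prior exactly
  set.seed(2)
  for (K in 2:3) {
    pi <- as.vector(stats::rgamma(K, 2)); pi <- pi / sum(pi)
    ref <- which.max(pi)
    par0 <- risk_params(pi, reference = ref)
    for (sex in c("female", "male")) {
      cf <- enumerate_configs(K, sex, hap_freqs = pi)
      expect_equal(config_conditional_probability(cf, par0, "no_x_inactivation"),
                   cf$prior_prob, tolerance = 1e-12)
    }
  }

  # RRm = 2: numerator 0.125 * 2, girl normalizer (0.5 + 0.5*2) * 1 = 1.5
  p2 <- risk_params(c(0.5, 0.5), rrm = c(1, 2), rrf = c(1, 1), reference = 1)
  pr2 <- config_conditional_probability(cfg, p2, "x_inactivation")
  j <- which(cfg$mother_transmitted == 2 & cfg$mother_untransmitted == 1 &
               cfg$father_hap == 1)
  expect_equal(pr2[j], 1 / 6, tolerance = 1e-12)
  expect_equal(sum(pr2), 1, tolerance = 1e-12)

  boys <- enumerate_configs(2, "male")
  prb <- config_conditional_probability(boys, p2, "x_inactivation")
  expect_equal(sum(prb), 1, tolerance = 1e-12)
})

one_triad <- function(m, f, c_, sex) {
  triad_data(
    snps = tibble::tibble(snp_id = "s1", position = 1L,
                          allele_ref = "A", allele_var = "a"),
    triads = tibble::tibble(triad_id = "t1", child_sex = sex),
    mother = matrix(m), father = matrix(f), child = matrix(c_)
  )
}

test_that("observed log-likelihood marginalizes over compatible configurations", {
  p <- risk_params(c(0.7, 0.3), rrm = c(1, 1.5), rrf = c(1, 0.8), reference = 1)
  cfg <- enumerate_configs(2, "female")
  pr <- config_conditional_probability(cfg, p, "x_inactivation")

  # fully observed girl: mother het, father variant, child hom variant ->
  # the single configuration (t=a, u=A, f=a)
  d1 <- one_triad(1L, 1L, 2L, "female")
  i <- which(cfg$mother_transmitted == 2 & cfg$mother_untransmitted == 1 &
               cfg$father_hap == 2)
  expect_equal(observed_loglik(d1, 1, p, "x_inactivation"), log(pr[i]))

  # het girl of a het mother with the father missing: two-term mixture,
  # variant from the mother (father ref) or from the father (mother's ref copy)
  d2 <- one_triad(1L, NA_integer_, 1L, "female")
  i2a <- which(cfg$mother_transmitted == 2 & cfg$mother_untransmitted == 1 &
                 cfg$father_hap == 1)
  i2b <- which(cfg$mother_transmitted == 1 & cfg$mother_untransmitted == 2 &
                 cfg$father_hap == 2)
  expect_equal(observed_loglik(d2, 1, p, "x_inactivation"),
               log(pr[i2a] + pr[i2b]))

  # duplicating every triad doubles the log-likelihood
  d4 <- triad_data(d1$snps,
                   tibble::tibble(triad_id = c("t1", "t2"),
                                  child_sex = rep("female", 2)),
                   mother = matrix(c(1L, 1L)), father = matrix(c(1L, 1L)),
                   child = matrix(c(2L, 2L)))
  expect_equal(observed_loglik(d4, 1, p, "x_inactivation"),
               2 * observed_loglik(d1, 1, p, "x_inactivation"))

  # girls-only likelihood ignores boys entirely
  db <- one_triad(2L, 0L, 1L, "male")
  expect_equal(observed_loglik(db, 1, p, "girls_only"), 0)

  # a fully observed impossible triad must be masked before fitting
  bad <- one_triad(0L, 0L, 2L, "female")
  expect_error(observed_loglik(bad, 1, p, "x_inactivation"), "masked")
  masked <- mask_mendelian(bad)
  expect_equal(observed_loglik(masked, 1, p, "x_inactivation"), 0)
})

test_that("the likelihood is equivariant under allele relabeling", {
  set.seed(7)
  spec <- sim_spec(maf = 0.3, rrm = 1.8, rrf = 0.9, n_triads = 150,
                   missing_rate_parent = 0.15, seed = 77)
  d <- simulate_triads(spec)
  p <- risk_params(c(0.65, 0.35), rrm = c(1, 1.7), rrf = c(1, 0.8),
                   reference = 1)
  # relabel: swap reference and variant everywhere
  d_swapped <- d
  d_swapped$mother <- 2L - d$mother
  d_swapped$father <- 1L - d$father
  girls <- d$triads$child_sex == "female"
  d_swapped$child[girls, ] <- 2L - d$child[girls, , drop = FALSE]
  d_swapped$child[!girls, ] <- 1L - d$child[!girls, , drop = FALSE]
  # parameters map to (1 - pi, 1/RRm, 1/RRf): the old variant becomes the new
  # reference (catalogue position 1 in the relabeled data), and the old
  # reference allele now carries the inverted relative risks
  p_swapped <- risk_params(c(0.35, 0.65), rrm = c(1, 1 / 1.7),
                           rrf = c(1, 1 / 0.8), reference = 1)
  for (model in c("x_inactivation", "no_x_inactivation", "girls_only")) {
    expect_equal(observed_loglik(d_swapped, 1, p_swapped, model),
                 observed_loglik(d, 1, p, model),
                 tolerance = 1e-10, info = model)
  }
})
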