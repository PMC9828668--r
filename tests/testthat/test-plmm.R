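make_grouped_data <- function(n_sp = 12, m = 5, sd_a = 0.8, sd_e = 0.4,
                              beta = c(2, 0.5), seed = 1) {
  set.seed(seed)
  sp <- rep(sprintf("s%02d", seq_len(n_sp)), each = m)
  x <- rnorm(n_sp * m)
  y <- beta[1] + beta[2] * x + rep(rnorm(n_sp, 0, sd_a), each = m) +
    rnorm(n_sp * m, 0, sd_e)
  Ci <- diag(n_sp)
  dimnames(Ci) <- list(unique(sp), unique(sp))
  list(data = data.frame(y = y, x = x, species = sp), C = Ci)
}

test_that("the mixed model reproduces lme4 exactly for an identity covariance", {
  skip_if_not_installed("lme4")
  gd <- make_grouped_data()
  f <- fit_phylo_lmm(y ~ x, gd$data, C = gd$C)
  l <- lme4::lmer(y ~ x + (1 | species), gd$data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(l))$vcov
  expect_equal(unname(coef(f)), unname(lme4::fixef(l)), tolerance = 1e-6)
  expect_equal(unname(f$variance_components), vc, tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(stats::logLik(l)), tolerance = 1e-6)
})

test_that("estimates are invariant to observation order", {
  gd <- make_grouped_data(seed = 4)
  f1 <- fit_phylo_lmm(y ~ x, gd$data, C = gd$C)
  perm <- sample(nrow(gd$data))
  f2 <- fit_phylo_lmm(y ~ x, gd$data[perm, ], C = gd$C)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(f2$variance_components, f1$variance_components,
               tolerance = 1e-6)
})

test_that("zero species variance yields lambda near 0 and OLS-like estimates", {
  set.seed(9)
  lams <- replicate(10, {
    gd <- make_grouped_data(n_sp = 20, m = 8, sd_a = 0, sd_e = 0.5,
                            seed = sample.int(1e6, 1))
    f <- fit_phylo_lmm(y ~ x, gd$data, C = gd$C)
    o <- stats::lm(y ~ x, gd$data)
    expect_equal(unname(coef(f)), unname(coef(o)), tolerance = 0.05)
    f$lambda
  })
  expect_lt(median(lams), 0.1)
})

test_that("with one observation per species and tiny residuals the LMM approaches PGLS", {
  tr <- simulate_tree(20, seed = 13)
  C <- phylo_covariance(tr)$C
  set.seed(14)
  x <- rnorm(20)
  y <- 1 + 0.8 * x + drop(MASS::mvrnorm(1, rep(0, 20), 0.5 * C)) +
    rnorm(20, 0, 1e-8)
  dat <- data.frame(y = y, x = x, species = tr$tip.label)
  fl <- fit_phylo_lmm(y ~ x, dat, tree = tr)
  fp <- fit_pgls(y ~ x, dat, tree = tr, lambda = 1)
  expect_equal(coef(fl), coef(fp), tolerance = 1e-3)
  expect_gt(fl$lambda, 0.999)
})

test_that("interaction dropping follows the ML likelihood-ratio rule", {
  gd <- make_grouped_data(n_sp = 10, m = 6, seed = 3)
  gd$data$z <- rnorm(nrow(gd$data))
  full <- fit_phylo_lmm(y ~ x * z, gd$data, C = gd$C)
  red <- fit_phylo_lmm(y ~ x + z, gd$data, C = gd$C)
  chosen <- drop_nonsignificant_interaction(full, red, alpha = 0.05)
  it <- attr(chosen, "interaction_test")
  expect_identical(it$df, 1L)
  expect_identical(it$interaction_kept, it$p_value < 0.05)

  # identical log-likelihoods: reduced model chosen
  fake_full <- full; fake_full$loglik_ml <- red$loglik_ml
  ch2 <- drop_nonsignificant_interaction(fake_full, red)
  expect_false(attr(ch2, "interaction_test")$interaction_kept)

  expect_error(drop_nonsignificant_interaction(red, full), "not nested")
})

test_that("strong interactions are kept and absent ones dropped at the expected rates", {
  set.seed(31)
  n_rep <- 20
  kept_null <- kept_strong <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n_sp <- 12; m <- 6
    sp <- rep(sprintf("s%02d", 1:n_sp), each = m)
    Ci <- diag(n_sp); dimnames(Ci) <- list(unique(sp), unique(sp))
    x <- rnorm(n_sp * m); z <- rnorm(n_sp * m)
    a <- rep(rnorm(n_sp, 0, 0.5), each = m)
    base <- 1 + x + z + a + rnorm(n_sp * m, 0, 0.5)
    for (case in c("null", "strong")) {
      y <- base + if (case == "strong") 2 * x * z else 0
      d <- data.frame(y = y, x = x, z = z, species = sp)
      full <- fit_phylo_lmm(y ~ x * z, d, C = Ci)
      red <- fit_phylo_lmm(y ~ x + z, d, C = Ci)
      kept <- attr(drop_nonsignificant_interaction(full, red),
                   "interaction_test")$interaction_kept
      if (case == "null") kept_null[r] <- kept else kept_strong[r] <- kept
    }
  }
  expect_lte(mean(kept_null), 0.25)    # ~alpha = 0.05 type-I rate
  expect_gte(mean(kept_strong), 0.95)  # effect >> SE
})

test_that("repeatability equals the variance ratio and respects its bounds", {
  # between-point SD = within-point SD: R near 0.5
  set.seed(17)
  n_pt <- 40; n_rep <- 8
  tv <- rnorm(n_pt, 10, 1)
  y <- rep(tv, each = n_rep) + rnorm(n_pt * n_rep, 0, 1)
  r <- repeatability(y, rep(seq_len(n_pt), each = n_rep), nboot = 100,
                     seed = 18)
  icc_realized <- var(tv) / (var(tv) + 1)   # plug-in ratio of the draw
  expect_equal(r$R, icc_realized, tolerance = 0.15)
  expect_true(r$R >= 0 && r$R <= 1)
  expect_true(r$ci[1] <= r$R && r$R <= r$ci[2])

  # all repeats identical: R is exactly 1
  r1 <- repeatability(rep(c(5, 7, 9, 11), each = 3),
                      rep(1:4, each = 3), nboot = 20)
  expect_identical(r1$R, 1)

  expect_error(repeatability(1:4, c(1, 1, 1, 1)), "degenerate")
  expect_error(repeatability(1:4, c(1, 1, 2, 3)), "repeats")
})

test_that("repeatability with a kind fixed effect recovers the generator", {
  sim <- simulate_repeat_measures(cv = 0.02, seed = 23)
  r <- repeatability(sim$data$value, sim$data$point_id, sim$data$kind,
                     nboot = 100, seed = 24)
  expect_equal(r$R, sim$truth$icc, tolerance = 0.01)
})
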