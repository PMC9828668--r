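test_that("tree covariance holds shared path lengths", {
  Cs <- phylo_covariance(star_tree_3())
  expect_equal(unname(Cs$C), diag(3))

  Ct <- phylo_covariance(sisters_tree())
  expect_equal(Ct$C["a", "b"], 0.6)
  expect_equal(Ct$C["a", "c"], 0)
  expect_equal(unname(diag(Ct$C)), rep(1, 3))

  tr <- simulate_tree(20, seed = 2)
  expect_silent(chol(phylo_covariance(tr)$C))  # PSD

  nolen <- ape::read.tree(text = "((a,b),c);")
  expect_error(phylo_covariance(nolen), "branch lengths")
})

test_that("lambda transform scales off-diagonals only", {
  C <- phylo_covariance(sisters_tree())
  expect_equal(lambda_transform(C, 0), diag(3), ignore_attr = TRUE)
  expect_equal(lambda_transform(C, 1), C$C)
  half <- lambda_transform(C, 0.5)
  expect_equal(half["a", "b"], 0.3)
  expect_equal(diag(half), diag(C$C))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
})

test_that("gls_fit equals the explicit-inverse oracle and OLS under V = I", {
  set.seed(42)
  for (i in 1:25) {
    X <- cbind(1, rnorm(5))
    y <- rnorm(5)
    A <- matrix(rnorm(25), 5)
    V <- crossprod(A) + diag(5)
    f <- gls_fit(X, y, V)
    expect_lt(max(abs(f$coefficients - gls_oracle(X, y, V))), 1e-10)
  }
  X <- cbind(1, rnorm(30), rnorm(30))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(30)
  f <- gls_fit(X, y, diag(30))
  o <- stats::lm.fit(X, y)
  expect_equal(unname(f$coefficients), unname(o$coefficients),
               tolerance = 1e-12)
  expect_equal(f$se,
               sqrt(diag(solve(crossprod(X))) * sum(o$residuals^2) / 27),
               tolerance = 1e-12)
})

test_that("duplicating the system block-diagonally leaves beta unchanged", {
  set.seed(7)
  X <- cbind(1, rnorm(6)); y <- rnorm(6)
  A <- matrix(rnorm(36), 6); V <- crossprod(A) + diag(6)
  f1 <- gls_fit(X, y, V)
  Z <- matrix(0, 6, 6)
  f2 <- gls_fit(rbind(X, X), c(y, y), rbind(cbind(V, Z), cbind(Z, V)))
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-10)
})

test_that("gls_fit rejects singular inputs", {
  X <- cbind(1, 1:4, 2 * (1:4))
  expect_error(gls_fit(X, rnorm(4), diag(4)), "rank deficient")
  expect_error(gls_fit(cbind(1, 1:4), rnorm(4), matrix(1, 4, 4)),
               "positive definite")
})

test_that("PGLS on a star tree equals OLS for any lambda", {
  set.seed(3)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  dat <- data.frame(species = star$tip.label, y = rnorm(6), x = rnorm(6))
  # identity covariance regardless of lambda on a star tree
  f <- fit_pgls(y ~ x, dat, tree = star)
  o <- stats::lm(y ~ x, dat)
  expect_equal(unname(coef(f)), unname(coef(o)), tolerance = 1e-8)
  f5 <- fit_pgls(y ~ x, dat, tree = star, lambda = 0.5)
  expect_equal(unname(coef(f5)), unname(coef(o)), tolerance = 1e-8)
})

test_that("PGLS is invariant to species reordering and branch rescaling", {
  tr <- simulate_tree(25, seed = 11)
  dat <- simulate_species_traits(tr, comparative_spec(n_species = 25,
                                                      seed = 12))
  f1 <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr)
  perm <- sample(nrow(dat))
  f2 <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat[perm, ],
                 tree = tr)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)

  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  f3 <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr10)
  expect_equal(coef(f3), coef(f1), tolerance = 1e-8)
  expect_equal(f3$lambda, f1$lambda, tolerance = 1e-5)
  expect_equal(f3$sigma2, f1$sigma2 / 10, tolerance = 1e-6)
})

test_that("profiled likelihood at the lambda estimate dominates the endpoints", {
  tr <- simulate_tree(30, seed = 21)
  dat <- simulate_species_traits(tr, comparative_spec(n_species = 30,
                                                      seed = 22))
  f <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr)
  l0 <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr,
                 lambda = 0)$loglik
  l1 <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr,
                 lambda = 1)$loglik
  expect_gte(f$loglik, l0 - 1e-8)
  expect_gte(f$loglik, l1 - 1e-8)
  expect_true(f$lambda >= f$lambda_ci[1] && f$lambda <= f$lambda_ci[2])
  expect_true(all(coef(f) >= f$ci95[, 1] & coef(f) <= f$ci95[, 2]))
})

test_that("PGLS matches nlme::gls with a fixed Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(18, seed = 31)
  dat <- simulate_species_traits(tr, comparative_spec(n_species = 18,
                                                      seed = 32))
  rownames(dat) <- dat$species
  f <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), dat, tree = tr,
                lambda = 0.6)
  g <- nlme::gls(log(midpiece_um) ~ log(flagellum_um), dat,
                 correlation = ape::corPagel(0.6, tr, fixed = TRUE,
                                             form = ~species),
                 method = "ML")
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-9)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-9)
})

test_that("lambda is recovered near zero for independent data", {
  set.seed(55)
  lams <- replicate(15, {
    tr <- simulate_tree(40)
    dat <- data.frame(species = tr$tip.label, y = rnorm(40), x = rnorm(40))
    fit_pgls(y ~ x, dat, tree = tr)$lambda
  })
  expect_lt(median(lams), 0.1)
})

test_that("PGLS refuses unidentifiable problems", {
  star4 <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  dat4 <- data.frame(species = c("a", "b", "c", "d"),
                     y = rnorm(4), x = rnorm(4))
  expect_silent(fit_pgls(y ~ x, dat4, tree = star4, lambda = 0.5))
  dat3 <- dat4[1:3, ]
  expect_error(fit_pgls(y ~ x, dat3, tree = star4), "p \\+ 2")
})
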