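# a minimal "fit-like" shim so prediction can be tested at known parameters
shim_fit <- function(params, part, parameterization = "intercept_slope") {
  list(params = params, partition = part,
       parameterization = parameterization)
}

test_that("posterior_b reduces to the Gaussian prior/posterior when gamma = 0", {
  part <- toy_partition(2)
  p0 <- toy_params(2, gamma = c(0, 0))
  fit <- shim_fit(p0, part)
  # no measurements: prior
  sub <- toy_subject(part, numeric(0), numeric(0), 2, 0)
  post <- posterior_b(fit, sub, r = 1)
  expect_equal(post$mu, rep(0, 3))
  expect_equal(post$Omega, build_sigma(p0, 2))
  expect_equal(post$D, matrix(0, 1, 3))
  # with data: Gaussian conjugacy moments, no skewness
  sub2 <- toy_subject(part, c(.1, .3), c(1, .6), 2, 0)
  post2 <- posterior_b(fit, sub2, r = 1)
  gc_ <- gaussian_conjugacy(sub2, p0, part)
  expect_equal(post2$mu, gc_$mu_post)
  expect_equal(post2$Omega, gc_$Sigma_post)
  set.seed(1)
  draws <- sample_posterior(post2, 4000L, seed = 2)
  expect_equal(colMeans(draws), gc_$mu_post, tolerance = 0.05)
  expect_error(posterior_b(fit, sub2, r = 2), "future")
  expect_error(posterior_b(fit, sub2, r = 0), "future")
})

test_that("posterior density integrates to 1 against the stated normalizer", {
  part <- toy_partition(2)
  params <- toy_params(2)
  fit <- shim_fit(params, part)
  sub <- toy_subject(part, c(.1, .45), c(1.4, .9), 2, 0)
  post <- posterior_b(fit, sub, r = 1)
  # grid integral of N(b; mu, Omega) Phi_K(Db + c) over R^3 must equal the
  # skew-normal normalizer Phi_K(D mu + c; I + D Omega D')
  sds <- sqrt(diag(post$Omega))
  ax <- lapply(1:3, function(j)
    seq(post$mu[j] - 6 * sds[j], post$mu[j] + 6 * sds[j], length.out = 61))
  gr <- as.matrix(expand.grid(ax))
  dif <- sweep(gr, 2, post$mu)
  Oi <- solve(post$Omega)
  ld <- -0.5 * rowSums((dif %*% Oi) * dif) -
    0.5 * (3 * log(2 * pi) + determinant(post$Omega)$modulus[1])
  U <- gr %*% t(post$D) + matrix(post$c, nrow(gr), post$K, byrow = TRUE)
  ld <- ld + rowSums(pnorm(U, log.p = TRUE))
  cell <- prod(vapply(ax, function(a) a[2] - a[1], numeric(1)))
  integral <- sum(exp(ld)) * cell
  m_v <- drop(post$D %*% post$mu) + post$c
  C <- post$D %*% post$Omega %*% t(post$D) + diag(post$K)
  expect_equal(integral, as.numeric(mvn_cdf(m_v, C)), tolerance = 1e-3)
})

test_that("sample_posterior matches grid-quadrature moments on a 3-dim toy", {
  part <- toy_partition(2)
  params <- toy_params(2)
  fit <- shim_fit(params, part)
  sub <- toy_subject(part, c(.2, .5), c(1.2, .7), 2, 0)
  post <- posterior_b(fit, sub, r = 1)
  oracle <- grid_posterior_3d(post, lim = 6, npts = 71)
  draws <- sample_posterior(post, 2e4, seed = 3)
  mc_se <- sqrt(diag(oracle$cov) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - oracle$mean) < 4 * mc_se))
  expect_equal(diag(stats::cov(draws)), unname(diag(oracle$cov)),
               tolerance = 0.05)
})

test_that("sampler is deterministic given the seed", {
  part <- toy_partition(2)
  fit <- shim_fit(toy_params(2), part)
  sub <- toy_subject(part, c(.2), c(1), 2, 0)
  post <- posterior_b(fit, sub, r = 1)
  d1 <- sample_posterior(post, 50, seed = 11)
  d2 <- sample_posterior(post, 50, seed = 11)
  expect_identical(d1, d2)
  d3 <- sample_posterior(post, 50, seed = 12)
  expect_false(identical(d1, d3))
})

test_that("predict_survival obeys the probability identities", {
  part <- toy_partition(4)
  params <- toy_params(4, alpha_tilde = c(0, 0), gamma = c(0, 0))
  fit <- shim_fit(params, part)
  sub <- toy_subject(part, c(.05), c(.5), 4, 0)
  # all linear predictors zero: one-interval-ahead probability is 1/2
  pr <- predict_survival(fit, sub, r = 1, s = 2, L = 50, seed = 5)
  expect_equal(pr$pi, 0.5, tolerance = 1e-12)
  # gamma = 0: pi is the product of covariate-only Phi terms
  p2 <- toy_params(4, alpha_tilde = c(1.1, -0.4), gamma = c(0, 0))
  fit2 <- shim_fit(p2, part)
  pr2 <- predict_survival(fit2, sub, r = 1, s = 3, L = 50, seed = 5)
  etas <- as.numeric(sub$x_surv[2:3, ] %*% p2$alpha_tilde)
  expect_equal(pr2$pi, prod(pnorm(etas)), tolerance = 1e-12)
  # telescoping: pi(s|r) = pi(s-1|r) * Phi(eta_s(b_hat)); and monotone in s
  p3 <- toy_params(4)
  fit3 <- shim_fit(p3, part)
  pis <- vapply(2:4, function(s)
    predict_survival(fit3, sub, r = 1, s = s, L = 100, seed = 6)$pi,
    numeric(1))
  expect_true(all(diff(pis) < 0))
  pr_s <- predict_survival(fit3, sub, r = 1, s = 4, L = 100, seed = 6)
  step <- psjm:::survival_product(fit3, sub, 3, 4, pr_s$b_hat)
  expect_equal(pis[3], pis[2] * step, tolerance = 1e-10)
  expect_true(all(pis >= 0 & pis <= 1))
  expect_error(predict_survival(fit3, sub, r = 3, s = 3), "r < s")
})

test_that("appending an on-trajectory measurement shrinks the posterior mean
           toward the observation", {
  part <- toy_partition(3)
  params <- toy_params(3, gamma = c(0, 0))
  fit <- shim_fit(params, part)
  # high observed level relative to the population trajectory
  sub_lo <- toy_subject(part, c(0.05), c(2), 3, 0)
  sub_hi <- toy_subject(part, c(0.05, 0.30), c(2, 2.2), 3, 0)
  m1 <- posterior_b(fit, sub_lo, r = 1)$mu
  m2 <- posterior_b(fit, sub_hi, r = 1)$mu
  # current-interval intercept estimate moves toward the repeated high value
  lvl1 <- sum(intercept_map(1, part) * (params$beta + m1))
  lvl2 <- sum(intercept_map(1, part) * (params$beta + m2))
  expect_gt(lvl2, lvl1)
})
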