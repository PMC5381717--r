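# Independent numerical oracles and small fixture builders used across the
# suite. Everything here deliberately avoids the package's analytic
# marginalization path: integrals are done by (adaptive) Gauss-Hermite
# product rules or dense grids, orthant probabilities by closed forms.

# Gauss-Hermite nodes/weights (Golub-Welsch)
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- a
  J[cbind(i + 1, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ]^2) * sqrt(pi))
}

# complete-data log integrand of one subject's likelihood (direct from the
# model definition: Gaussian outcome density x probit survival factors x
# Gaussian random-effect prior)
log_integrand <- function(b, subject, params, part,
                          parameterization = "intercept_slope") {
  Sigma <- build_sigma(params, part$M)
  Ls <- t(chol(Sigma))
  z <- forwardsolve(Ls, b)
  lp <- -0.5 * length(b) * log(2 * pi) - sum(log(diag(Ls))) - 0.5 * sum(z^2)
  n <- length(subject$y)
  if (n > 0) {
    B <- design_matrix(subject$times, part)
    mu <- drop(B %*% (params$beta + b))
    if (length(params$alpha)) mu <- mu + drop(subject$x_long %*% params$alpha)
    lp <- lp + sum(stats::dnorm(subject$y, mu, params$sigma_eps, log = TRUE))
  }
  coefs <- params$beta + b
  for (k in seq_len(subject$s_star)) {
    A <- association_design(k, part, parameterization)
    gk <- if (is.matrix(params$gamma)) params$gamma[k, ] else params$gamma
    eta <- sum(gk * drop(A %*% coefs))
    if (length(params$alpha_tilde))
      eta <- eta + sum(subject$x_surv[k, ] * params$alpha_tilde)
    lp <- lp + if (k == subject$s_star && subject$delta == 1)
      stats::pnorm(-eta, log.p = TRUE) else stats::pnorm(eta, log.p = TRUE)
  }
  lp
}

# vectorized variant: log integrand at each row of Bpts
log_integrand_mat <- function(Bpts, subject, params, part,
                              parameterization = "intercept_slope") {
  d <- ncol(Bpts)
  np <- nrow(Bpts)
  Sigma <- build_sigma(params, part$M)
  Ls <- t(chol(Sigma))
  Z <- forwardsolve(Ls, t(Bpts))
  lp <- -0.5 * d * log(2 * pi) - sum(log(diag(Ls))) - 0.5 * colSums(Z^2)
  n <- length(subject$y)
  if (n > 0) {
    B <- design_matrix(subject$times, part)
    MU <- matrix(drop(B %*% params$beta), np, n, byrow = TRUE) +
      Bpts %*% t(B)
    if (length(params$alpha))
      MU <- MU + matrix(drop(subject$x_long %*% params$alpha), np, n,
                        byrow = TRUE)
    lp <- lp + rowSums(stats::dnorm(matrix(subject$y, np, n, byrow = TRUE),
                                    MU, params$sigma_eps, log = TRUE))
  }
  coefs <- sweep(Bpts, 2, params$beta, "+")
  for (k in seq_len(subject$s_star)) {
    A <- association_design(k, part, parameterization)
    gk <- if (is.matrix(params$gamma)) params$gamma[k, ] else params$gamma
    eta <- drop(coefs %*% drop(crossprod(A, gk)))
    if (length(params$alpha_tilde))
      eta <- eta + sum(subject$x_surv[k, ] * params$alpha_tilde)
    lp <- lp + if (k == subject$s_star && subject$delta == 1)
      stats::pnorm(-eta, log.p = TRUE) else stats::pnorm(eta, log.p = TRUE)
  }
  lp
}

# adaptive Gauss-Hermite evaluation of the marginal log-likelihood:
# centered/scaled at the numerically located mode of the integrand
oracle_subject_loglik <- function(subject, params, part, nq = 12,
                                  parameterization = "intercept_slope") {
  d <- part$M + 1L
  f <- function(b) -log_integrand(b, subject, params, part, parameterization)
  m <- stats::optim(rep(0, d), f, method = "BFGS",
                    control = list(maxit = 300))$par
  h <- 1e-4
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- rep(0, d); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(m + ei + ej) - f(m + ei - ej) - f(m - ei + ej) + f(m - ei - ej)) /
      (4 * h * h)
  }
  C <- t(chol(solve(H)))
  g <- gh_rule(nq)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nq)), d)))
  Z <- matrix(g$x[grid], ncol = d)
  lw <- rowSums(matrix(log(g$w[grid]), ncol = d)) + rowSums(Z^2)
  Bpts <- Z %*% t(sqrt(2) * C) + matrix(m, nrow(Z), d, byrow = TRUE)
  lg <- log_integrand_mat(Bpts, subject, params, part, parameterization)
  v <- lw + lg
  mm <- max(v)
  mm + log(sum(exp(v - mm))) + 0.5 * d * log(2) + sum(log(diag(C)))
}

# dense-grid moments and marginal CDFs of a 3-dimensional skew-normal
# posterior (density known up to a constant)
grid_posterior_3d <- function(post, lim = 6, npts = 81) {
  stopifnot(length(post$mu) == 3L)
  sds <- sqrt(diag(post$Omega))
  ax <- lapply(1:3, function(j)
    seq(post$mu[j] - lim * sds[j], post$mu[j] + lim * sds[j],
        length.out = npts))
  gr <- as.matrix(expand.grid(ax))
  dif <- sweep(gr, 2, post$mu)
  Oi <- solve(post$Omega)
  ld <- -0.5 * rowSums((dif %*% Oi) * dif)
  U <- gr %*% t(post$D) + matrix(post$c, nrow(gr), length(post$c),
                                 byrow = TRUE)
  ld <- ld + rowSums(stats::pnorm(U, log.p = TRUE))
  w <- exp(ld - max(ld))
  w <- w / sum(w)
  mean_b <- drop(crossprod(w, gr))
  cov_b <- crossprod(gr * w, gr) - tcrossprod(mean_b)
  marg <- lapply(1:3, function(j) {
    m <- tapply(w, factor(gr[, j], levels = ax[[j]]), sum)
    list(x = ax[[j]], cdf = cumsum(as.numeric(m)))
  })
  list(mean = mean_b, cov = cov_b, marginals = marg, axes = ax)
}

# small fixture builders ----------------------------------------------------

toy_partition <- function(M = 3, Tmax = 1) {
  time_partition(seq(0, Tmax, length.out = M + 1))
}

toy_params <- function(M = 3, gamma = c(0.6, 0.3), alpha_tilde = c(1.2, -0.5),
                       sigma2 = 0.5, rho = 0.2) {
  model_params(beta = c(1, -1, seq(0.5, by = -0.2, length.out = M - 1)),
               alpha_tilde = alpha_tilde, gamma = gamma,
               sigma_eps = 0.4, sigma0 = 0.9, sigma1 = 0.7,
               sigma2 = sigma2, rho = rho)
}

toy_subject <- function(part, times, y, s_star, delta,
                        q_tilde = 2) {
  rs <- part$boundaries[seq_len(part$M)]
  xs <- cbind(rep(1, part$M), rs)[, seq_len(q_tilde), drop = FALSE]
  list(id = "toy", times = times, y = y,
       x_long = matrix(numeric(0), length(times), 0L),
       x_surv = xs, s_star = as.integer(s_star), delta = as.integer(delta),
       baseline = c(z = 0))
}

# random small configuration for the likelihood-oracle sweeps
random_config <- function(seed) {
  set.seed(seed)
  M <- sample(2:4, 1)
  part <- time_partition(c(0, sort(stats::runif(M - 1)), 1))
  params <- model_params(
    beta = stats::rnorm(M + 1, 0, 0.8),
    alpha_tilde = stats::rnorm(2, 0, 0.8),
    gamma = stats::rnorm(2, 0.4, 0.3),
    sigma_eps = stats::runif(1, 0.3, 0.7),
    sigma0 = stats::runif(1, 0.5, 1.2),
    sigma1 = stats::runif(1, 0.4, 1),
    sigma2 = stats::runif(1, 0.3, 0.9),
    rho = stats::runif(1, -0.6, 0.6))
  s_star <- sample(seq_len(min(M, 3)), 1)
  n_i <- sample(0:3, 1)
  times <- sort(stats::runif(n_i, 0, part$boundaries[s_star + 1]))
  y <- stats::rnorm(n_i, 0, 1.2)
  sub <- toy_subject(part, times, y, s_star, delta = stats::rbinom(1, 1, 0.5))
  list(part = part, params = params, subject = sub)
}

# quick simulated dataset at reduced size for fitting tests
small_sim <- function(N = 60, seed = 1, M = 6) {
  bnd <- seq(0, 1, length.out = M + 1)
  tp <- default_true_params()
  beta <- numeric(M + 1)
  beta[2] <- -1.5
  beta[min(M, 4) + 1] <- 0.8
  beta[min(M, 5) + 1] <- 0.8
  pars <- model_params(beta = beta, alpha_tilde = tp$alpha_tilde,
                       gamma = tp$gamma, sigma_eps = tp$sigma_eps,
                       sigma0 = tp$sigma0, sigma1 = tp$sigma1,
                       sigma2 = tp$sigma2, rho = tp$rho)
  cfg <- sim_config(N = N, partition = time_partition(bnd),
                    true_params = pars, seed = seed)
  list(cfg = cfg, sim = simulate_dataset(cfg))
}

fast_settings <- function(...) {
  fit_settings(npts = 16, nshift = 1, hessian = FALSE, reltol = 1e-6,
               maxit = 200, ...)
}

# fine-grid marginal CDF of coordinate j of a 3-dim skew-normal posterior:
# coarse quadrature over the other two coordinates, trapezoid in x_j
marginal_cdf_3d <- function(post, j, nfine = 301, ncoarse = 41, lim = 6.5) {
  stopifnot(length(post$mu) == 3L)
  sds <- sqrt(diag(post$Omega))
  ax <- lapply(1:3, function(k) {
    n <- if (k == j) nfine else ncoarse
    seq(post$mu[k] - lim * sds[k], post$mu[k] + lim * sds[k], length.out = n)
  })
  gr <- as.matrix(expand.grid(ax))
  dif <- sweep(gr, 2, post$mu)
  Oi <- solve(post$Omega)
  ld <- -0.5 * rowSums((dif %*% Oi) * dif)
  U <- gr %*% t(post$D) + matrix(post$c, nrow(gr), length(post$c),
                                 byrow = TRUE)
  ld <- ld + rowSums(stats::pnorm(U, log.p = TRUE))
  w <- exp(ld - max(ld))
  dens <- tapply(w, factor(gr[, j], levels = ax[[j]]), sum)
  dens <- as.numeric(dens)
  dx <- ax[[j]][2] - ax[[j]][1]
  cdf <- cumsum((dens + c(0, dens[-length(dens)])) / 2) * dx
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(ax[[j]], cdf, yleft = 0, yright = 1)
}
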