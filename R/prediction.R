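#' Skew-normal posterior of the random coefficients given a history
#'
#' Conditioning a subject's random spline coefficients on their
#' longitudinal measurements up to `t(r)` (the right endpoint of interval
#' `r`) and on survival of intervals `1..r` yields a multivariate
#' skew-normal law: density proportional to
#' `N(b; mu, Omega) * Phi_K(D b + c)` with `K = r` all-positive-sign probit
#' constraints, whose normalizer is
#' `Phi_K(D mu + c; 0, I_K + D Omega D')`. The Gaussian part `(mu, Omega)`
#' comes from [gaussian_conjugacy()] on the truncated measurement series.
#'
#' @param fit A `psjm_fit` (or any list with `params`, `partition`,
#'   `parameterization` — e.g. a truth plug-in).
#' @param subject A subject record; measurements after `t(r)` are dropped,
#'   and the subject must have survival covariates for intervals `1..r`.
#' @param r Conditioning interval, `1 <= r < M`.
#' @return Object of class `sn_posterior` with `mu`, `Omega`, `D`, `c`,
#'   `K`, and the conditioning metadata.
#' @export
posterior_b <- function(fit, subject, r) {
  part <- fit$partition
  if (r < 1L || r >= part$M)
    stop("posterior_b: r must be in 1..(M-1) so a future interval exists")
  tr <- part$boundaries[r + 1L] # right endpoint of interval r
  keep <- subject$times <= tr + 1e-12
  sub <- subject
  sub$times <- subject$times[keep]
  sub$y <- subject$y[keep]
  if (length(dim(subject$x_long)))
    sub$x_long <- subject$x_long[keep, , drop = FALSE]
  gc_ <- gaussian_conjugacy(sub, fit$params, part)
  sub$s_star <- as.integer(r)
  sub$delta <- 0L # conditioning event is survival of intervals 1..r
  ps <- build_probit_system(sub, fit$params, part, fit$parameterization)
  structure(list(mu = gc_$mu_post, Omega = gc_$Sigma_post,
                 D = ps$loadings, c = ps$offsets, K = as.integer(r),
                 log_marginal_y = gc_$log_marginal_y,
                 r = as.integer(r)),
            class = "sn_posterior")
}

#' Exact draws from a skew-normal posterior
#'
#' Uses the latent-Gaussian representation: the slack variables
#' `V = D b + c - Z` (with `Z` iid standard normal) are jointly Gaussian
#' with `b`, and the conditioning event is `V >= 0`. `V` is drawn from
#' `N(D mu + c, I_K + D Omega D')` restricted to the nonnegative orthant by
#' exact rejection when the acceptance probability (the posterior
#' normalizer) is at least `1e-3`; otherwise a Gibbs sweep over truncated
#' normal full conditionals (50 burn-in sweeps) is used as a fallback.
#' Given `V`, `b` is drawn from the implied Gaussian conditional. With
#' `K = 0` constraints this reduces to plain Gaussian sampling.
#'
#' @param post An [posterior_b()] object.
#' @param L Number of draws.
#' @param seed Integer seed (same seed, same draws).
#' @return `L x (M+1)` matrix of draws; attribute `"acceptance"` records
#'   the rejection-sampler acceptance probability (or `NA` for the Gibbs
#'   branch).
#' @export
sample_posterior <- function(post, L, seed = 1L) {
  stopifnot(inherits(post, "sn_posterior"), L >= 1L)
  set.seed(seed)
  K <- post$K
  Mb <- length(post$mu)
  if (K == 0L || all(abs(post$D) < 1e-14)) {
    # no b-information in the constraints: Gaussian draws (the constraints
    # still condition the event, but independently of b)
    Lo <- chol_psd(post$Omega)
    return(structure(
      matrix(stats::rnorm(L * Mb), L, Mb) %*% t(Lo) +
        matrix(post$mu, L, Mb, byrow = TRUE),
      acceptance = 1))
  }
  m_v <- drop(post$D %*% post$mu) + post$c
  C <- post$D %*% post$Omega %*% t(post$D)
  diag(C) <- diag(C) + 1
  # the normalizer only steers the rejection/Gibbs branch and the batch
  # size; a coarse estimate is ample
  acc <- as.numeric(mvn_cdf(m_v, C, tol = 1e-4, max_pts = 2048))
  if (acc < 1e-12)
    stop("sample_posterior: posterior normalizer underflows; the history is ",
         "implausible under the fitted model (or reduce the constraints)")
  Lc <- chol_psd(C)
  if (acc >= 1e-3) {
    V <- matrix(NA_real_, 0L, K)
    while (nrow(V) < L) {
      ndraw <- ceiling((L - nrow(V) + 5) / max(acc, 1e-3)) + 10L
      cand <- matrix(stats::rnorm(ndraw * K), ndraw, K) %*% t(Lc) +
        matrix(m_v, ndraw, K, byrow = TRUE)
      # orthant constraint is on -V <= 0, i.e. every slack nonnegative
      ok <- rowSums(cand >= 0) == K
      V <- rbind(V, cand[ok, , drop = FALSE])
    }
    V <- V[seq_len(L), , drop = FALSE]
    used_acc <- acc
  } else {
    V <- gibbs_orthant(m_v, C, L, burn = 50L)
    used_acc <- NA_real_
  }
  # b | V is Gaussian: mean mu + Omega D' C^{-1} (V - m_v)
  OD <- post$Omega %*% t(post$D)
  Ci_DO <- solve(C, t(OD))
  cond_cov <- post$Omega - OD %*% Ci_DO
  Lb <- chol_psd(cond_cov)
  mu_mat <- matrix(post$mu, L, Mb, byrow = TRUE) +
    (V - matrix(m_v, L, K, byrow = TRUE)) %*% Ci_DO
  structure(mu_mat + matrix(stats::rnorm(L * Mb), L, Mb) %*% t(Lb),
            acceptance = used_acc)
}

# lower-triangular factor tolerant of semidefinite matrices
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(v), length(v))
}

# Gibbs sampler for N(m, C) truncated to the nonnegative orthant
gibbs_orthant <- function(m, C, L, burn = 50L) {
  K <- length(m)
  Ci <- solve(C)
  sd_c <- 1 / sqrt(diag(Ci))
  v <- pmax(m, 0.1)
  out <- matrix(NA_real_, L, K)
  total <- burn + L
  for (it in seq_len(total)) {
    for (k in seq_len(K)) {
      mu_k <- v[k] - (Ci[k, ] %*% (v - m)) / Ci[k, k]
      lo <- stats::pnorm(0, mu_k, sd_c[k])
      u <- stats::runif(1, lo, 1)
      v[k] <- stats::qnorm(pmin(u, 1 - 1e-16), mu_k, sd_c[k])
    }
    if (it > burn) out[it - burn, ] <- v
  }
  out
}

#' Dynamic prediction of conditional survival probabilities
#'
#' Predicts `pi(s | r)`, the probability of surviving through interval `s`
#' given survival of interval `r` and the longitudinal history up to
#' `t(r)`: draws `L` samples from the skew-normal posterior of the random
#' coefficients, summarizes them to a point estimate `b_hat`
#' (componentwise median by default), and evaluates
#' `prod_{r* = r+1..s} Phi(x_surv[r*,]' alpha_tilde + gamma' A_{r*}
#' (beta + b_hat))`. Setting `average = TRUE` instead averages the product
#' of survival probabilities over the posterior draws.
#'
#' @inheritParams posterior_b
#' @param s Target interval, `r < s <= M`.
#' @param L Number of posterior draws (default 200).
#' @param summary `"median"` (default), `"mean"`, or `"mode"` (posterior
#'   mode by quasi-Newton started at the median).
#' @param seed Integer seed.
#' @param average Average `pi` over draws instead of plugging in `b_hat`.
#' @return Object of class `psjm_prediction`: list with `pi`, `samples_b`,
#'   `b_hat`, `r`, `s`, `seed`.
#' @export
predict_survival <- function(fit, subject, r, s, L = 200L,
                             summary = c("median", "mean", "mode"),
                             seed = 1L, average = FALSE) {
  summary <- match.arg(summary)
  part <- fit$partition
  if (!(r < s && s <= part$M))
    stop("predict_survival: need r < s <= M")
  if (is.null(subject$x_surv))
    stop("predict_survival: survival covariates missing")
  post <- posterior_b(fit, subject, r)
  draws <- sample_posterior(post, L, seed = seed)
  b_hat <- switch(summary,
                  median = apply(draws, 2L, stats::median),
                  mean = colMeans(draws),
                  mode = posterior_mode(post, apply(draws, 2L, stats::median)))
  if (average) {
    pis <- apply(draws, 1L, function(b)
      survival_product(fit, subject, r, s, b))
    pi_hat <- mean(pis)
  } else {
    pi_hat <- survival_product(fit, subject, r, s, b_hat)
  }
  structure(list(pi = pi_hat, samples_b = draws, b_hat = b_hat,
                 r = as.integer(r), s = as.integer(s), seed = seed),
            class = "psjm_prediction")
}

# product of interval survival probabilities for a fixed coefficient draw
survival_product <- function(fit, subject, r, s, b) {
  params <- fit$params
  part <- fit$partition
  coefs <- params$beta + b
  p <- 1
  for (k in seq(r + 1L, s)) {
    A <- association_design(k, part, fit$parameterization, kind = params$kind)
    gk <- if (is.matrix(params$gamma)) params$gamma[k, ] else params$gamma
    eta <- sum(gk * drop(A %*% coefs))
    if (length(params$alpha_tilde)) {
      if (nrow(subject$x_surv) < k)
        stop("survival_product: missing survival covariates for interval ", k)
      eta <- eta + sum(subject$x_surv[k, ] * params$alpha_tilde)
    }
    p <- p * stats::pnorm(eta)
  }
  p
}

# posterior log-density maximizer (up to the normalizer)
posterior_mode <- function(post, start) {
  Oi <- solve(post$Omega)
  negld <- function(b) {
    d <- b - post$mu
    u <- drop(post$D %*% b) + post$c
    0.5 * drop(t(d) %*% Oi %*% d) - sum(stats::pnorm(u, log.p = TRUE))
  }
  stats::optim(start, negld, method = "BFGS",
               control = list(maxit = 200))$par
}
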