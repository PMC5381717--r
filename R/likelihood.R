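#' Random-effects covariance matrix
#'
#' Builds the `(M+1) x (M+1)` covariance of the random spline coefficients:
#' a 2x2 intercept/slope block `[[s0^2, rho s0 s1], [rho s0 s1, s1^2]]` and
#' an independent `sigma2^2 I_{M-1}` block for the truncated-basis
#' increments; `sigma2^2` is the individual-level smoothing variance. For
#' `kind = "rirs"` only the 2x2 block is returned.
#'
#' @param params A [model_params()].
#' @param M Number of intervals (ignored for `kind = "rirs"`).
#' @return Symmetric positive-definite covariance matrix.
#' @export
build_sigma <- function(params, M) {
  stopifnot(inherits(params, "model_params"))
  if (params$kind == "rirs") {
    Mb <- 2L
  } else {
    if (M < 1L) stop("build_sigma: M must be >= 1")
    Mb <- M + 1L
  }
  S <- matrix(0, Mb, Mb)
  S[1, 1] <- params$sigma0^2
  S[2, 2] <- params$sigma1^2
  S[1, 2] <- S[2, 1] <- params$rho * params$sigma0 * params$sigma1
  if (Mb > 2L) diag(S)[3:Mb] <- params$sigma2^2
  S
}

#' Gaussian conjugacy: posterior of b given the longitudinal data only
#'
#' With `Y | b ~ N(x alpha + B beta + B b, sigma_eps^2 I)` and
#' `b ~ N(0, Sigma)`, returns the posterior moments of `b` and the log
#' marginal density of `Y`. Computed through a Cholesky factorization of the
#' `n_i x n_i` marginal covariance `G = sigma_eps^2 I + B Sigma B^T`, so no
#' near-singular matrix is inverted explicitly (valid at the
#' `sigma2 -> 0` boundary). With no measurements the prior is returned and
#' the log marginal is 0.
#'
#' @param subject A subject record (see [joint_dataset()]).
#' @param params A [model_params()].
#' @param part A [time_partition()].
#' @return List with `mu_post`, `Sigma_post`, `log_marginal_y`.
#' @export
gaussian_conjugacy <- function(subject, params, part) {
  Sigma <- build_sigma(params, part$M)
  Mb <- nrow(Sigma)
  n <- length(subject$y)
  if (n == 0L)
    return(list(mu_post = numeric(Mb), Sigma_post = Sigma,
                log_marginal_y = 0))
  if (any(!is.finite(subject$y)))
    stop(sprintf("gaussian_conjugacy: non-finite outcome for subject %s",
                 subject$id))
  B <- if (params$kind == "rirs") cbind(1, subject$times)
       else design_matrix(subject$times, part)
  r <- subject$y - drop(B %*% params$beta)
  if (length(params$alpha))
    r <- r - drop(subject$x_long %*% params$alpha)
  BS <- B %*% Sigma
  G <- BS %*% t(B)
  diag(G) <- diag(G) + params$sigma_eps^2
  Lg <- t(chol(G))
  z <- forwardsolve(Lg, r)
  W <- forwardsolve(Lg, BS)
  list(mu_post = drop(crossprod(W, z)),
       Sigma_post = Sigma - crossprod(W),
       log_marginal_y = -0.5 * n * log(2 * pi) - sum(log(diag(Lg))) -
         0.5 * sum(z^2))
}

#' Probit system of a subject's survival record
#'
#' Encodes the `K = s_star` probit factors of the discrete-time survival
#' likelihood. Interval `k` has survival probability
#' `Phi(c_k + d_k' b)` with offset
#' `c_k = x_surv[k,]' alpha_tilde + gamma_k' A_k beta` (the fixed part,
#' including the population spline contribution) and loading
#' `d_k = A_k' gamma_k` acting on the random coefficients. Signs are `+1`
#' for every survived interval and `-1` at `s_star` when the event occurred
#' (`delta = 1`), using `1 - Phi(a) = Phi(-a)`.
#'
#' @inheritParams gaussian_conjugacy
#' @param parameterization Association parameterization tag; see
#'   [association_design()].
#' @return List with `offsets` (length K), `loadings` (`K x (M+1)`),
#'   `signs`.
#' @export
build_probit_system <- function(subject, params, part,
                                parameterization = "intercept_slope") {
  K <- subject$s_star
  if (K < 1L || K > part$M) stop("build_probit_system: s_star outside 1..M")
  if (is.null(subject$x_surv) && length(params$alpha_tilde))
    stop(sprintf("build_probit_system: survival covariates missing for %s",
                 subject$id))
  Mb <- if (params$kind == "rirs") 2L else part$M + 1L
  loadings <- matrix(0, K, Mb)
  offsets <- numeric(K)
  for (k in seq_len(K)) {
    A <- association_design(k, part, parameterization, kind = params$kind)
    gk <- if (is.matrix(params$gamma)) params$gamma[k, ] else params$gamma
    d <- if (length(gk)) drop(crossprod(A, gk)) else numeric(Mb)
    off <- sum(d * params$beta)
    if (length(params$alpha_tilde))
      off <- off + sum(subject$x_surv[k, ] * params$alpha_tilde)
    loadings[k, ] <- d
    offsets[k] <- off
  }
  signs <- rep(1, K)
  if (subject$delta == 1) signs[K] <- -1
  list(offsets = offsets, loadings = loadings, signs = signs)
}

#' Multivariate normal CDF (Genz-type randomized QMC)
#'
#' `P(Z <= upper)` for `Z ~ N(0, cov)`, via a deterministic (internally
#' seeded) randomized Richtmyer lattice rule with antithetic pairing; the
#' number of lattice points is doubled until the estimated error is below
#' `tol` or `max_pts` is reached. `K = 0` returns 1; `K = 1` is exact.
#'
#' @param upper Numeric vector of upper limits (length K >= 0).
#' @param cov `K x K` symmetric positive-semidefinite covariance.
#' @param tol Absolute error target (default `1e-8`).
#' @param max_pts Cap on lattice points per shift.
#' @param seed Internal integer seed (fixed default keeps results
#'   reproducible to well over 6 digits).
#' @return Probability, with attribute `"error"` (~3 standard errors).
#' @export
mvn_cdf <- function(upper, cov, tol = 1e-8, max_pts = 2^17, seed = 20170122) {
  K <- length(upper)
  if (K == 0L) return(structure(1, error = 0))
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("mvn_cdf: covariance must be symmetric")
  npts <- 256L
  repeat {
    est <- cpp_mvn_cdf(upper, cov, npts, 10L, seed)
    if (est$error < tol || npts >= max_pts) break
    npts <- npts * 4L
  }
  structure(est$value, error = est$error)
}

#' Exact marginal log-likelihood of one subject
#'
#' Evaluates the subject's joint-model likelihood in closed form:
#' `log L_i = log f(Y_i) + log Phi_K(D mu_post + c; 0, I_K + D Sigma_post
#' D')`, where `(mu_post, Sigma_post)` come from [gaussian_conjugacy()] and
#' `D`, `c` are the signed loadings/offsets of [build_probit_system()].
#' This equals the log of the integral of the complete-data likelihood over
#' the random coefficients (the multivariate skew-normal marginalization).
#'
#' @inheritParams build_probit_system
#' @param tol MVN CDF error tolerance.
#' @return Scalar log-likelihood.
#' @export
subject_loglik <- function(subject, params, part,
                           parameterization = "intercept_slope",
                           tol = 1e-8) {
  gc_ <- gaussian_conjugacy(subject, params, part)
  ps <- build_probit_system(subject, params, part, parameterization)
  D <- ps$signs * ps$loadings
  cc <- ps$signs * ps$offsets
  upper <- drop(D %*% gc_$mu_post) + cc
  C <- D %*% gc_$Sigma_post %*% t(D)
  diag(C) <- diag(C) + 1
  p <- mvn_cdf(upper, C, tol = tol)
  gc_$log_marginal_y + log(max(as.numeric(p), 1e-300))
}

#' Penalized negative log-likelihood of the whole dataset
#'
#' `-sum_i log L_i + lambda * sum_{l>=2} beta_l^2`; the intercept and slope
#' coefficients `beta_0, beta_1` are unpenalized. `method = "cpp"` uses the
#' compiled batch path (used by the optimizer); `method = "r"` sums
#' [subject_loglik()] (reference path, used for cross-checking).
#'
#' @param params A [model_params()].
#' @param lambda Nonnegative smoothing parameter.
#' @param data A [joint_dataset()].
#' @param parameterization Association tag.
#' @param method `"cpp"` or `"r"`.
#' @param npts,nshift QMC effort for the compiled path.
#' @return Scalar objective value.
#' @export
penalized_negloglik <- function(params, lambda, data,
                                parameterization = "intercept_slope",
                                method = c("cpp", "r"),
                                npts = 256L, nshift = 8L) {
  method <- match.arg(method)
  stopifnot(lambda >= 0)
  if (method == "r") {
    ll <- sum(vapply(data$subjects, subject_loglik, numeric(1),
                     params = params, part = data$partition,
                     parameterization = parameterization))
    pen <- if (params$kind == "pspline" && length(params$beta) > 2L)
      lambda * sum(params$beta[-(1:2)]^2) else 0
    return(-ll + pen)
  }
  prep <- prep_data(data, parameterization, kind = params$kind,
                    gamma_tv = is.matrix(params$gamma))
  cpp_pen_negloglik(to_unconstrained(params), prep, lambda,
                    as.integer(npts), as.integer(nshift), 20170122,
                    TRUE, TRUE)
}

#' Preprocess a dataset for the compiled likelihood
#'
#' Flattens subjects into contiguous arrays and precomputes the per-interval
#' association design matrices, so the optimizer's objective involves no R
#' per-subject overhead. Returned as a plain list consumed by the compiled
#' code; also records the [param_layout()].
#'
#' @inheritParams penalized_negloglik
#' @param kind `"pspline"` or `"rirs"`.
#' @param gamma_tv Interval-specific association coefficients?
#' @return List with flat arrays plus `$layout`.
#' @export
prep_data <- function(data, parameterization = "intercept_slope",
                      kind = c("pspline", "rirs"), gamma_tv = FALSE) {
  kind <- match.arg(kind)
  part <- data$partition
  M <- part$M
  Mb <- if (kind == "pspline") M + 1L else 2L
  subs <- data$subjects
  p <- length(data$covariate_names_long)
  qt <- if (is.null(subs[[1]]$x_surv)) 0L else ncol(subs[[1]]$x_surv)
  q <- switch(parameterization, intercept_slope = 2L, 1L)
  ni <- vapply(subs, function(s) length(s$y), integer(1))
  sstar <- vapply(subs, function(s) as.integer(s$s_star), integer(1))
  delta <- vapply(subs, function(s) as.integer(s$delta), integer(1))
  Bs <- lapply(subs, function(s) {
    if (!length(s$times)) matrix(numeric(0), 0L, Mb)
    else if (kind == "rirs") cbind(1, s$times)
    else design_matrix(s$times, part)
  })
  A <- array(0, dim = c(q, Mb, M))
  for (r in seq_len(M))
    A[, , r] <- association_design(r, part, parameterization, kind = kind)
  Xs <- do.call(rbind, lapply(subs, function(s)
    if (qt > 0) s$x_surv[seq_len(s$s_star), , drop = FALSE]
    else matrix(numeric(0), s$s_star, 0L)))
  layout <- param_layout(p, M, qt, q, gamma_tv, kind)
  list(p = p, Mb = Mb, qt = qt, q = q, gv = as.integer(gamma_tv), M = M,
       kind = if (kind == "pspline") 0L else 1L,
       nsub = length(subs),
       ni = ni, ni_off = c(0L, cumsum(ni))[seq_along(ni)],
       sstar = sstar, delta = delta,
       xs_off = c(0L, cumsum(sstar))[seq_along(sstar)],
       y_all = c(numeric(0), unlist(lapply(subs, function(s) as.numeric(s$y)))),
       B_all = do.call(rbind, Bs),
       X_all = if (p > 0) do.call(rbind, lapply(subs, function(s) s$x_long))
               else matrix(numeric(0), sum(ni), 0L),
       Xs_all = Xs,
       A = A,
       layout = layout,
       parameterization = parameterization)
}
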