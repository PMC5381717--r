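#' Optimizer and accuracy settings for joint-model fitting
#'
#' @param npts,nshift Lattice points and random shifts per MVN CDF during
#'   optimization (the final log-likelihood is re-evaluated at higher
#'   accuracy).
#' @param npts_final,nshift_final QMC effort for the reported log-likelihood.
#' @param maxit,reltol BFGS iteration cap and relative objective tolerance.
#' @param grad_step Relative central-difference step for the gradient.
#' @param hess_step Relative step for the observed-information Hessian.
#'   The default (0.03) is deliberately large: second differences of the
#'   quasi-Monte-Carlo objective are noise-dominated at classical 1e-5
#'   steps, while the truncation error at 0.03 is negligible for standard
#'   errors.
#' @param hess_npts,hess_nshift QMC effort for the Hessian evaluations;
#'   finer than the optimization lattice because second differences are
#'   far more sensitive to the lattice wiggle than line searches are.
#' @param hessian Compute standard errors (numeric observed information)?
#' @return Settings list.
#' @export
fit_settings <- function(npts = 16L, nshift = 2L,
                         npts_final = 512L, nshift_final = 10L,
                         maxit = 500L, reltol = 1e-8,
                         grad_step = 1e-6, hess_step = 0.03,
                         hess_npts = 32L, hess_nshift = 2L,
                         hessian = TRUE) {
  list(npts = as.integer(npts), nshift = as.integer(nshift),
       npts_final = as.integer(npts_final),
       nshift_final = as.integer(nshift_final),
       maxit = as.integer(maxit), reltol = reltol,
       grad_step = grad_step, hess_step = hess_step,
       hess_npts = as.integer(hess_npts),
       hess_nshift = as.integer(hess_nshift),
       hessian = isTRUE(hessian))
}

# BFGS over a subset of coordinates of a full parameter vector, with
# central finite-difference gradients.
masked_optim <- function(theta0, objfn, free = NULL, maxit = 500L,
                         reltol = 1e-8, grad_step = 1e-6) {
  n <- length(theta0)
  if (is.null(free)) free <- rep(TRUE, n)
  full <- theta0
  fn <- function(par) {
    full[free] <- par
    objfn(full)
  }
  gr <- function(par) {
    full[free] <- par
    f0 <- objfn(full)
    vapply(which(free), function(i) {
      h <- grad_step * (1 + abs(full[i]))
      up <- full; up[i] <- up[i] + h
      (objfn(up) - f0) / h
    }, numeric(1))
  }
  # restart BFGS (fresh Hessian memory) until no further progress; escapes
  # premature line-search stalls on the quasi-Monte-Carlo objective
  res <- stats::optim(theta0[free], fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  n_ev <- res$counts[["function"]]
  for (restart in 1:2) {
    res2 <- stats::optim(res$par, fn, gr, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
    n_ev <- n_ev + res2$counts[["function"]]
    improved <- res$value - res2$value
    res <- res2
    if (improved < reltol * (abs(res$value) + reltol) * 10) break
  }
  full[free] <- res$par
  list(theta = full, value = res$value,
       converged = res$convergence == 0L,
       n_iter = n_ev)
}

# numeric Hessian of fn at x: symmetrized Jacobian of forward-difference
# gradients, (n+1)(n+2) evaluations instead of the ~2n^2 of the classical
# four-point scheme; with the wide steps used here the schemes agree to
# the accuracy relevant for standard errors
fd_hessian <- function(fn, x, rel_step = 1e-5) {
  n <- length(x)
  h <- rel_step * (1 + abs(x))
  grad_at <- function(z) {
    f0 <- fn(z)
    vapply(seq_len(n), function(i) {
      zp <- z; zp[i] <- zp[i] + h[i]
      (fn(zp) - f0) / h[i]
    }, numeric(1))
  }
  g0 <- grad_at(x)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xj <- x; xj[j] <- xj[j] + h[j]
    H[, j] <- (grad_at(xj) - g0) / h[j]
  }
  0.5 * (H + t(H))
}

#' Effective degrees of freedom of the population P-spline
#'
#' `df(lambda) = tr((B'B + 2 lambda sigma_eps^2 D)^{-1} B'B)` with
#' `D = blockdiag(0_{2x2}, I_{M-1})`, evaluated via a linear solve. At
#' `lambda = 0` this is `M + 1`; as `lambda -> Inf` it tends to 2 (the two
#' unpenalized columns).
#'
#' @param lambda Nonnegative smoothing parameter.
#' @param Btilde All subjects' basis rows stacked (`sum(n_i) x (M+1)`).
#' @param sigma_eps_hat Estimated measurement-error SD.
#' @return Scalar effective degrees of freedom.
#' @export
df_lambda <- function(lambda, Btilde, sigma_eps_hat) {
  stopifnot(lambda >= 0, sigma_eps_hat > 0)
  BtB <- crossprod(Btilde)
  Mb <- ncol(BtB)
  A <- BtB
  if (Mb > 2L) {
    idx <- 3:Mb
    diag(A)[idx] <- diag(A)[idx] + 2 * lambda * sigma_eps_hat^2
  }
  sum(diag(solve(A, BtB)))
}

#' Fit the joint model by maximum penalized likelihood
#'
#' Quasi-Newton (BFGS) maximization of the penalized log-likelihood over
#' the unconstrained parameterization (log SDs, Fisher-z correlation), with
#' finite-difference gradients. Standard errors come from the inverse of
#' the numerically evaluated observed information at the optimum, mapped to
#' the natural scale by the delta method. The reported AIC is
#' `-2 log L + 2 df(lambda) + 2 dim(theta_tilde)` where `theta_tilde`
#' excludes the penalized spline coefficients `beta_2..beta_M`.
#'
#' @param data A [joint_dataset()] with survival covariates built.
#' @param lambda Nonnegative smoothing parameter for the population spline.
#' @param init A [model_params()], a numeric unconstrained vector, or
#'   `"auto"` (two-stage starting values).
#' @param settings A [fit_settings()] list.
#' @param parameterization Association tag; see [association_design()].
#' @param kind `"pspline"` (default) or `"rirs"` (random intercept+slope).
#' @param gamma_tv Interval-specific association coefficients?
#' @return Object of class `psjm_fit` with elements `params`, `se` (table),
#'   `vcov_unconstrained`, `loglik` (unpenalized), `lambda`, `df_lambda`,
#'   `aic`, `converged`, `n_iter`, plus the layout/partition metadata
#'   needed for prediction.
#' @export
psjm_fit <- function(data, lambda = 0, init = "auto",
                     settings = fit_settings(),
                     parameterization = "intercept_slope",
                     kind = c("pspline", "rirs"), gamma_tv = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "joint_dataset"), lambda >= 0)
  prep <- prep_data(data, parameterization, kind, gamma_tv)
  layout <- prep$layout
  theta0 <- if (identical(init, "auto")) {
    auto_init(data, lambda, prep, settings)
  } else if (inherits(init, "model_params")) {
    to_unconstrained(init)
  } else as.numeric(init)
  if (length(theta0) != layout$n_par)
    stop("psjm_fit: initialization has wrong length")

  seed <- 20170122
  objfn <- function(th)
    cpp_pen_negloglik(th, prep, lambda, settings$npts, settings$nshift,
                      seed, TRUE, TRUE)
  opt <- masked_optim(theta0, objfn, maxit = settings$maxit,
                      reltol = settings$reltol,
                      grad_step = settings$grad_step)
  if (!opt$converged)
    warning("psjm_fit: optimizer did not converge; returning best iterate")
  theta <- opt$theta
  params <- from_unconstrained(theta, layout)

  # unpenalized log-likelihood at higher QMC accuracy
  parts <- cpp_subject_logliks(theta, prep, settings$npts_final,
                               settings$nshift_final, seed)
  loglik <- sum(parts)

  if (kind == "pspline") {
    # AIC(lambda) = -2 log L + 2 df(lambda) + 2 dim(theta_tilde), where
    # theta_tilde drops only the penalized coefficients beta_2..beta_M
    dfl <- df_lambda(lambda, prep$B_all, params$sigma_eps)
    dim_tilde <- layout$n_par - (layout$M - 1L)
    aic <- -2 * loglik + 2 * dfl + 2 * dim_tilde
  } else {
    # no penalty: ordinary AIC over all parameters
    dfl <- NA_real_
    aic <- -2 * loglik + 2 * layout$n_par
  }

  se_unc <- rep(NA_real_, layout$n_par)
  vcov_unc <- NULL
  if (settings$hessian) {
    hobj <- function(th)
      cpp_pen_negloglik(th, prep, lambda, settings$hess_npts,
                        settings$hess_nshift, seed, TRUE, TRUE)
    H <- fd_hessian(hobj, theta, settings$hess_step)
    H <- 0.5 * (H + t(H))
    vcov_unc <- tryCatch(solve(H), error = function(e) NULL)
    bad <- is.null(vcov_unc) || any(diag(vcov_unc) <= 0)
    if (bad) {
      # near-flat ridge or residual FD noise left the numeric observed
      # information indefinite; fall back to the outer product of the
      # per-subject scores (BHHH), which is positive semidefinite and a
      # consistent information estimate under the fitted model
      warning("psjm_fit: observed information indefinite; standard ",
              "errors use the outer-product-of-scores estimate")
      vcov_unc <- opg_vcov(prep, theta, lambda, settings, seed)
    }
    if (!is.null(vcov_unc)) se_unc <- sqrt(pmax(diag(vcov_unc), 0))
    else warning("psjm_fit: information matrix singular; ",
                 "standard errors unavailable")
  }
  nm <- param_names(layout)
  est_unc <- theta
  natural <- natural_scale(theta, se_unc, layout)
  se_tab <- data.frame(parameter = nm, estimate = natural$est,
                       se = natural$se, unconstrained = est_unc,
                       se_unconstrained = se_unc)

  structure(list(params = params, se = se_tab,
                 vcov_unconstrained = vcov_unc,
                 loglik = loglik, lambda = lambda, df_lambda = dfl,
                 aic = aic, converged = opt$converged, n_iter = opt$n_iter,
                 layout = layout, partition = data$partition,
                 parameterization = parameterization, kind = kind,
                 covariate_names_surv = data$covariate_names_surv,
                 covariate_names_long = data$covariate_names_long,
                 settings = settings),
            class = "psjm_fit")
}

# outer-product-of-scores (BHHH) covariance: central-difference scores per
# subject at a step wide enough to stand above the QMC lattice wiggle, plus
# the analytic penalty curvature on the penalized spline coefficients
opg_vcov <- function(prep, theta, lambda, settings, seed) {
  npar <- length(theta)
  S <- matrix(0, prep$nsub, npar)
  for (i in seq_len(npar)) {
    h <- 0.01 * (1 + abs(theta[i]))
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    lu <- rowSums(cpp_subject_logliks(up, prep, settings$hess_npts,
                                      settings$hess_nshift, seed))
    ld <- rowSums(cpp_subject_logliks(dn, prep, settings$hess_npts,
                                      settings$hess_nshift, seed))
    S[, i] <- (lu - ld) / (2 * h)
  }
  info <- crossprod(S)
  if (prep$kind == 0L && lambda > 0 && prep$Mb > 2L) {
    idx <- prep$p + 3:prep$Mb
    diag(info)[idx] <- diag(info)[idx] + 2 * lambda
  }
  out <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(out) && any(diag(out) <= 0)) out <- NULL
  out
}

# delta-method map of unconstrained estimates/SEs to the natural scale
natural_scale <- function(theta, se_unc, layout) {
  n_reg <- layout$p + layout$Mb + layout$q_tilde +
    (if (layout$gamma_tv) layout$M * layout$q else layout$q)
  n_sd <- 3L + (layout$kind == "pspline")
  est <- theta
  se <- se_unc
  sd_idx <- n_reg + seq_len(n_sd)
  est[sd_idx] <- exp(theta[sd_idx])
  se[sd_idx] <- se_unc[sd_idx] * est[sd_idx]
  rho_idx <- n_reg + n_sd + 1L
  est[rho_idx] <- tanh(theta[rho_idx])
  se[rho_idx] <- se_unc[rho_idx] * (1 - est[rho_idx]^2)
  list(est = est, se = se)
}

#' @export
print.psjm_fit <- function(x, ...) {
  cat("Joint model fit (", x$kind, ", ", x$parameterization, ")\n", sep = "")
  cat(sprintf("  log-likelihood %.3f  lambda %.4g  df(lambda) %.2f  AIC %.2f\n",
              x$loglik, x$lambda, x$df_lambda, x$aic))
  cat(sprintf("  converged: %s (%d objective evaluations)\n",
              x$converged, x$n_iter))
  print(x$se[, c("parameter", "estimate", "se")], digits = 4,
        row.names = FALSE)
  invisible(x)
}

# Two-stage starting values: longitudinal-only penalized fit for
# (alpha, beta, sigmas, rho); person-interval probit for (alpha_tilde, gamma).
auto_init <- function(data, lambda, prep, settings) {
  layout <- prep$layout
  stage1 <- fit_longitudinal(data, lambda,
                             kind = if (prep$kind == 0L) "pspline" else "rirs",
                             settings = settings)
  theta <- stage1$theta
  if (layout$q_tilde + layout$q > 0) {
    s2 <- stage2_probit(data, stage1$params,
                        parameterization = prep$parameterization)
    i0 <- layout$p + layout$Mb
    if (layout$q_tilde > 0)
      theta[i0 + seq_len(layout$q_tilde)] <- s2$alpha_tilde
    ng <- if (layout$gamma_tv) layout$M * layout$q else layout$q
    if (ng > 0)
      theta[i0 + layout$q_tilde + seq_len(ng)] <-
        rep(s2$gamma, length.out = ng)
  }
  theta
}

#' Longitudinal-only penalized maximum likelihood (stage 1)
#'
#' Fits the linear mixed model implied by the longitudinal sub-model alone
#' (survival factors removed): coefficients `alpha`, `beta` and variance
#' parameters, with the same quadratic penalty on `beta_2..beta_M`. Used as
#' stage 1 of the two-stage comparator and for automatic initialization.
#'
#' @inheritParams psjm_fit
#' @return List with `theta` (full-layout unconstrained vector, survival
#'   coefficients zero), `params`, `value`, `converged`.
#' @export
fit_longitudinal <- function(data, lambda = 0,
                             kind = c("pspline", "rirs"),
                             settings = fit_settings(),
                             parameterization = "intercept_slope") {
  kind <- match.arg(kind)
  prep <- prep_data(data, parameterization, kind)
  layout <- prep$layout
  theta0 <- init_longitudinal(data, layout)
  free <- rep(FALSE, layout$n_par)
  reg <- seq_len(layout$p + layout$Mb)
  tail_n <- 4L + (kind == "pspline")
  free[reg] <- TRUE
  free[layout$n_par - seq_len(tail_n) + 1L] <- TRUE
  objfn <- function(th)
    cpp_pen_negloglik(th, prep, lambda, settings$npts, settings$nshift,
                      20170122, TRUE, FALSE)
  opt <- masked_optim(theta0, objfn, free, maxit = settings$maxit,
                      reltol = settings$reltol,
                      grad_step = settings$grad_step)
  list(theta = opt$theta, params = from_unconstrained(opt$theta, layout),
       value = opt$value, converged = opt$converged, layout = layout,
       prep = prep)
}

# crude moment-based starting values for the longitudinal fit
init_longitudinal <- function(data, layout) {
  y <- unlist(lapply(data$subjects, function(s) s$y))
  t <- unlist(lapply(data$subjects, function(s) s$times))
  theta <- numeric(layout$n_par)
  b0 <- if (length(y)) mean(y) else 0
  b1 <- 0
  if (length(y) > 2 && stats::var(t) > 0) {
    cf <- stats::coef(stats::lm(y ~ t))
    b0 <- cf[[1]]; b1 <- cf[[2]]
  }
  theta[layout$p + 1L] <- b0
  theta[layout$p + 2L] <- b1
  sub_means <- vapply(data$subjects, function(s)
    if (length(s$y)) mean(s$y) else NA_real_, numeric(1))
  s0 <- stats::sd(sub_means, na.rm = TRUE)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  sde <- stats::sd(y - b0 - b1 * t)
  if (!is.finite(sde) || sde <= 0) sde <- 1
  tail_n <- 4L + (layout$kind == "pspline")
  tail_idx <- layout$n_par - tail_n + 1L
  # log sigma_eps, log sigma0, log sigma1, (log sigma2), z(rho)
  vals <- c(log(sde / 2), log(s0), log(max(s0, 0.5)),
            if (layout$kind == "pspline") log(0.5), 0)
  theta[tail_idx + seq_along(vals) - 1L] <- vals
  theta
}

# Stage-2 probit regression on the person-interval table with empirical
# Bayes trajectory summaries plugged in. Shares expand_person_intervals()
# with the time-varying-covariate comparator.
stage2_probit <- function(data, stage1_params,
                          parameterization = "intercept_slope") {
  pi_tab <- expand_person_intervals(data)
  part <- data$partition
  W <- matrix(0, nrow(pi_tab), if (parameterization == "intercept_slope") 2L else 1L)
  row <- 1L
  for (s in data$subjects) {
    gc_ <- gaussian_conjugacy(s, stage1_params, part)
    coefs <- stage1_params$beta + gc_$mu_post
    for (r in seq_len(s$s_star)) {
      A <- association_design(r, part, parameterization,
                              kind = stage1_params$kind)
      W[row, ] <- drop(A %*% coefs)
      row <- row + 1L
    }
  }
  X <- as.matrix(pi_tab[, data$covariate_names_surv, drop = FALSE])
  fitg <- suppressWarnings(
    stats::glm.fit(cbind(X, W), pi_tab$event,
                   family = stats::binomial(link = "probit")))
  cf <- -fitg$coefficients # P(event) = Phi(-(x'at + g'W))
  qn <- ncol(W)
  list(alpha_tilde = cf[seq_len(ncol(X))],
       gamma = cf[ncol(X) + seq_len(qn)])
}

#' AIC of a fitted joint model
#' @param fit A `psjm_fit`.
#' @return Scalar AIC value (smaller is better).
#' @export
psjm_aic <- function(fit) {
  stopifnot(inherits(fit, "psjm_fit"))
  fit$aic
}

#' Smoothing-parameter selection by AIC
#'
#' Fits the model at each grid value (warm-started from the previous
#' optimum), computes `AIC(lambda)`, and returns the minimizer together
#' with the full grid table. Failed grid fits are flagged and skipped in
#' the selection; an error is raised only if every fit fails.
#'
#' @inheritParams psjm_fit
#' @param grid Nonempty vector of nonnegative smoothing values.
#' @return List with `best_lambda`, `best_fit`, and `table`
#'   (`lambda, loglik, df, aic, converged`).
#' @export
select_lambda <- function(data, grid, init = "auto",
                          settings = fit_settings(),
                          parameterization = "intercept_slope",
                          kind = "pspline") {
  stopifnot(length(grid) >= 1L, all(grid >= 0))
  grid <- sort(grid)
  fits <- vector("list", length(grid))
  tab <- data.frame(lambda = grid, loglik = NA_real_, df = NA_real_,
                    aic = NA_real_, converged = NA)
  cur_init <- init
  for (i in seq_along(grid)) {
    fi <- tryCatch(
      psjm_fit(data, grid[i], init = cur_init, settings = settings,
               parameterization = parameterization, kind = kind),
      error = function(e) e)
    if (inherits(fi, "error")) {
      warning(sprintf("select_lambda: fit at lambda=%g failed: %s",
                      grid[i], conditionMessage(fi)))
      next
    }
    fits[[i]] <- fi
    tab$loglik[i] <- fi$loglik
    tab$df[i] <- fi$df_lambda
    tab$aic[i] <- fi$aic
    tab$converged[i] <- fi$converged
    cur_init <- c(to_unconstrained(fi$params))
  }
  if (all(is.na(tab$aic))) stop("select_lambda: all grid fits failed")
  best <- which.min(tab$aic)
  list(best_lambda = grid[best], best_fit = fits[[best]], table = tab)
}
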