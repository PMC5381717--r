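#' Probit survival model with the outcome as a time-varying covariate
#'
#' Expands the dataset to the person-interval table, attaches the last
#' observed outcome at or before each interval start (`k_{r-1}`,
#' last-value-carried-forward; the baseline measurement serves when no
#' earlier one exists), and fits a maximum-likelihood probit regression of
#' the interval event indicator on the survival covariates plus the
#' carried-forward outcome. Subjects with no measurements at all are
#' dropped with a warning.
#'
#' @param data A [joint_dataset()] with survival covariates built.
#' @return A `comparator_fit` with `method = "tvc"`; `params$coef` holds
#'   the coefficients on the survival (`Phi(eta)`) scale, last element the
#'   outcome coefficient.
#' @export
fit_tvc <- function(data) {
  pit <- tvc_table(data)
  if (any(!pit$has_y)) {
    warning(sprintf("fit_tvc: dropping %d subjects with no measurements",
                    length(unique(pit$id[!pit$has_y]))))
    pit <- pit[pit$has_y, , drop = FALSE]
  }
  X <- cbind(as.matrix(pit[, data$covariate_names_surv, drop = FALSE]),
             lastY = pit$lastY)
  fitg <- suppressWarnings(
    stats::glm.fit(X, pit$event,
                   family = stats::binomial(link = "probit")))
  cf <- -fitg$coefficients # survival scale: P(event) = Phi(-eta)
  structure(list(method = "tvc",
                 params = list(coef = cf,
                               surv_names = data$covariate_names_surv),
                 partition = data$partition),
            class = "comparator_fit")
}

# person-interval table with LOCF outcome at each interval start
tvc_table <- function(data) {
  pit <- expand_person_intervals(data)
  part <- data$partition
  lastY <- numeric(nrow(pit))
  has_y <- logical(nrow(pit))
  row <- 1L
  for (s in data$subjects) {
    for (r in seq_len(s$s_star)) {
      lastY[row] <- locf_outcome(s, part$boundaries[r])
      has_y[row] <- length(s$y) > 0L
      row <- row + 1L
    }
  }
  pit$lastY <- lastY
  pit$has_y <- has_y
  pit
}

# most recent measurement at or before cut; baseline value if none
locf_outcome <- function(subject, cut) {
  if (!length(subject$y)) return(NA_real_)
  idx <- which(subject$times <= cut + 1e-12)
  if (!length(idx)) subject$y[1L] else subject$y[max(idx)]
}

#' Two-stage approach: longitudinal fit, then probit survival fit
#'
#' Stage 1 maximizes the longitudinal-only penalized likelihood
#' ([fit_longitudinal()]; smoothing chosen on `lambda_grid` by the
#' longitudinal AIC when the grid has several values). Stage 2 plugs the
#' empirical Bayes trajectory summaries (posterior means of the random
#' coefficients given the longitudinal data only) into a probit regression
#' on the person-interval table. Because stage 1 ignores the survival
#' process, its population trajectory is biased upward at late times under
#' outcome-dependent truncation.
#'
#' @inheritParams fit_tvc
#' @param lambda_grid Smoothing grid for stage 1.
#' @param settings A [fit_settings()].
#' @param parameterization Association tag.
#' @return A `comparator_fit` with `method = "two_stage"`: stage-1
#'   [model_params()] and stage-2 `alpha_tilde`, `gamma`.
#' @export
fit_two_stage <- function(data, lambda_grid = 0.4,
                          settings = fit_settings(),
                          parameterization = "intercept_slope") {
  best <- NULL
  best_aic <- Inf
  for (lam in lambda_grid) {
    st1 <- fit_longitudinal(data, lam, kind = "pspline",
                            settings = settings,
                            parameterization = parameterization)
    if (!st1$converged)
      stop("fit_two_stage: stage-1 fit did not converge at lambda = ", lam)
    dfl <- df_lambda(lam, st1$prep$B_all, st1$params$sigma_eps)
    n_long <- st1$layout$p + 2L + 5L # alpha, beta0, beta1, sigmas, rho
    ll <- -(st1$value - lam * sum(st1$params$beta[-(1:2)]^2))
    aic <- -2 * ll + 2 * dfl + 2 * n_long
    if (aic < best_aic) {
      best_aic <- aic
      best <- list(stage1 = st1, lambda = lam)
    }
  }
  s2 <- stage2_probit(data, best$stage1$params, parameterization)
  structure(list(method = "two_stage",
                 params = list(stage1 = best$stage1$params,
                               alpha_tilde = s2$alpha_tilde,
                               gamma = s2$gamma,
                               lambda = best$lambda),
                 partition = data$partition,
                 parameterization = parameterization),
            class = "comparator_fit")
}

#' Random intercept-and-slope joint model
#'
#' The same joint-likelihood machinery restricted to the basis `{1, t}`:
#' two correlated random effects, interval association maps `(1, k_{r-1})`
#' and `(0, 1)` (the slope is constant over follow-up). No smoothing
#' penalty applies.
#'
#' @inheritParams fit_two_stage
#' @param init Passed to [psjm_fit()].
#' @return A `comparator_fit` with `method = "ri_rs_joint"` wrapping the
#'   underlying `psjm_fit`.
#' @export
fit_ri_rs_joint <- function(data, init = "auto", settings = fit_settings(),
                            parameterization = "intercept_slope") {
  fit <- psjm_fit(data, lambda = 0, init = init, settings = settings,
                  parameterization = parameterization, kind = "rirs")
  structure(list(method = "ri_rs_joint", params = list(fit = fit),
                 partition = data$partition,
                 parameterization = parameterization),
            class = "comparator_fit")
}

#' Wrap a fitted flexible joint model as a comparator
#' @param fit A `psjm_fit` (P-spline kind).
#' @return A `comparator_fit` with `method = "pspline_joint"`.
#' @export
as_pspline_comparator <- function(fit) {
  stopifnot(inherits(fit, "psjm_fit"))
  structure(list(method = "pspline_joint", params = list(fit = fit),
                 partition = fit$partition,
                 parameterization = fit$parameterization),
            class = "comparator_fit")
}

#' Gold-standard predictor from the simulation truth
#'
#' Evaluates conditional survival probabilities with the true simulated
#' random coefficients and the true parameters; the reference against
#' which all methods' prediction errors are measured.
#'
#' @param true_params The generating [model_params()].
#' @param partition The generating [time_partition()].
#' @param parameterization Association tag.
#' @return A `comparator_fit` with `method = "gold_standard"`.
#' @export
gold_standard <- function(true_params, partition,
                          parameterization = "intercept_slope") {
  structure(list(method = "gold_standard",
                 params = list(params = true_params),
                 partition = partition,
                 parameterization = parameterization),
            class = "comparator_fit")
}

#' Predict a conditional survival probability from any comparator
#'
#' Dispatches on the comparator's method tag. Joint-model comparators use
#' the skew-normal posterior machinery ([predict_survival()]); the
#' two-stage comparator uses empirical Bayes coefficients from the
#' longitudinal data only; the time-varying-covariate model carries the
#' last observed outcome forward; the gold standard plugs in the true
#' random coefficients (`truth_b`).
#'
#' @param cfit A `comparator_fit`.
#' @param subject Subject record (with `x_surv` built over all intervals).
#' @param r,s Conditioning and target intervals (`r < s <= M`).
#' @param L,seed Posterior draw count and seed for joint-model methods.
#' @param truth_b True random coefficients (gold standard only).
#' @return Scalar probability.
#' @export
predict_comparator <- function(cfit, subject, r, s, L = 200L, seed = 1L,
                               truth_b = NULL) {
  pis <- predict_comparator_multi(cfit, subject, r, s, L = L, seed = seed,
                                  truth_b = truth_b)
  pis[[length(pis)]]
}

#' Conditional survival probabilities for all horizons up to `smax`
#'
#' Like [predict_comparator()] but returns
#' `pi(r+1 | r), pi(r+2 | r), ..., pi(smax | r)` in one pass, sharing one
#' set of posterior draws across horizons (the probabilities telescope).
#'
#' @inheritParams predict_comparator
#' @param smax Largest target interval.
#' @return Numeric vector of length `smax - r`.
#' @export
predict_comparator_multi <- function(cfit, subject, r, smax, L = 200L,
                                     seed = 1L, truth_b = NULL) {
  stopifnot(inherits(cfit, "comparator_fit"), smax > r)
  part <- cfit$partition
  ks <- seq(r + 1L, smax)
  etas <- switch(cfit$method,
    pspline_joint = ,
    ri_rs_joint = {
      fit <- cfit$params$fit
      post <- posterior_b(fit, subject, r)
      draws <- sample_posterior(post, L, seed = seed)
      b_hat <- apply(draws, 2L, stats::median)
      trajectory_etas(fit$params, part, cfit$parameterization, subject,
                      ks, b_hat)
    },
    gold_standard = {
      if (is.null(truth_b))
        stop("predict_comparator: truth_b required for the gold standard")
      trajectory_etas(cfit$params$params, part, cfit$parameterization,
                      subject, ks, truth_b)
    },
    two_stage = {
      st1 <- cfit$params$stage1
      tr <- part$boundaries[r + 1L]
      keep <- subject$times <= tr + 1e-12
      sub <- subject
      sub$times <- subject$times[keep]
      sub$y <- subject$y[keep]
      if (length(dim(subject$x_long)))
        sub$x_long <- subject$x_long[keep, , drop = FALSE]
      bhat <- gaussian_conjugacy(sub, st1, part)$mu_post
      coefs <- st1$beta + bhat
      vapply(ks, function(k) {
        A <- association_design(k, part, cfit$parameterization,
                                kind = st1$kind)
        sum(subject$x_surv[k, ] * cfit$params$alpha_tilde) +
          sum(cfit$params$gamma * drop(A %*% coefs))
      }, numeric(1))
    },
    tvc = {
      cf <- cfit$params$coef
      ylast <- locf_outcome(subject, part$boundaries[r + 1L])
      if (!is.finite(ylast)) stop("predict_comparator: no outcome history")
      vapply(ks, function(k)
        sum(subject$x_surv[k, ] * cf[-length(cf)]) +
          cf[[length(cf)]] * ylast, numeric(1))
    },
    stop("predict_comparator: unknown method ", cfit$method))
  cumprod(stats::pnorm(etas))
}

# probit linear predictors of intervals ks at coefficient deviation b
trajectory_etas <- function(params, part, parameterization, subject, ks, b) {
  coefs <- params$beta + b
  vapply(ks, function(k) {
    A <- association_design(k, part, parameterization, kind = params$kind)
    gk <- if (is.matrix(params$gamma)) params$gamma[k, ] else params$gamma
    eta <- sum(gk * drop(A %*% coefs))
    if (length(params$alpha_tilde)) {
      if (nrow(subject$x_surv) < k)
        stop("prediction: missing survival covariates for interval ", k)
      eta <- eta + sum(subject$x_surv[k, ] * params$alpha_tilde)
    }
    eta
  }, numeric(1))
}

#' Dynamic-prediction error against the gold standard
#'
#' For each method and each `(r, dt)` cell, computes the mean squared
#' difference on the probability scale between the method's predicted
#' `pi(r + dt | r)` and the gold-standard value over all test subjects
#' still event-free after interval `r` (true `S > r`). Cells with an empty
#' risk set are flagged (`mse = NA`).
#'
#' @param fits Named list of `comparator_fit` objects (a gold-standard fit
#'   is constructed from `true_params` automatically).
#' @param testset A [joint_dataset()] of held-out subjects.
#' @param truth Truth list from [simulate_dataset()] for `testset`.
#' @param true_params,parameterization Generating model for the gold
#'   standard.
#' @param r_grid,dt_grid Prediction times and windows.
#' @param L,seed Posterior draws and base seed.
#' @return Data frame `method, r, dt, mse, n_at_risk`.
#' @export
prediction_error <- function(fits, testset, truth, true_params,
                             r_grid, dt_grid, L = 100L, seed = 1L,
                             parameterization = "intercept_slope") {
  gold <- gold_standard(true_params, testset$partition, parameterization)
  M <- testset$partition$M
  out <- list()
  for (r in r_grid) {
    dts <- dt_grid[r + dt_grid <= M]
    if (!length(dts)) next
    smax <- r + max(dts)
    at_risk <- Filter(function(sub) {
      tt <- truth[[as.character(sub$id)]]
      # event-free beyond r and history observed through interval r
      (!is.finite(tt$S) || tt$S > r) && sub$s_star >= r
    }, testset$subjects)
    if (!length(at_risk)) {
      for (nm in names(fits)) for (dt in dts)
        out[[length(out) + 1L]] <- data.frame(method = nm, r = r, dt = dt,
                                              mse = NA_real_, n_at_risk = 0L)
      next
    }
    # one pass per subject per method: probabilities telescope over dt
    as_rows <- function(x) if (is.matrix(x)) t(x) else matrix(x, ncol = 1L)
    pg <- as_rows(vapply(at_risk, function(sub)
      predict_comparator_multi(gold, sub, r, smax,
                               truth_b = truth[[as.character(sub$id)]]$b),
      numeric(smax - r)))
    for (nm in names(fits)) {
      pm <- as_rows(vapply(seq_along(at_risk), function(j)
        predict_comparator_multi(fits[[nm]], at_risk[[j]], r, smax, L = L,
                                 seed = seed + j), numeric(smax - r)))
      for (dt in dts)
        out[[length(out) + 1L]] <- data.frame(
          method = nm, r = r, dt = dt,
          mse = mean((pm[, dt] - pg[, dt])^2), n_at_risk = length(at_risk))
    }
  }
  if (!length(out))
    return(data.frame(method = character(0), r = integer(0),
                      dt = integer(0), mse = numeric(0),
                      n_at_risk = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
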