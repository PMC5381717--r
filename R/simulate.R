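#' Default "truth-like" simulation parameters
#'
#' Survival coefficients, association coefficients and variance components
#' are the fitted values reported for the flexible joint model on the
#' motivating HIV cohort (survival design
#' `1 + rstart + rstart^2 + age + V2 + V3 + V4`). The population spline
#' coefficients, which are not reported numerically anywhere, encode a
#' declining standardized sqrt-CD4 trajectory whose slope recovers in the
#' second half of follow-up (mimicking the therapy-era upturn): slope -1.5
#' through interval 6, then increments at intervals 7-10 bring it to +0.5.
#'
#' @return A [model_params()] for the 12-interval default partition.
#' @export
default_true_params <- function() {
  beta <- numeric(13)
  beta[2] <- -1.5 # slope (coefficient of t)
  beta[8] <- 0.6 # increments at intervals 7..10 (0-based beta_7..beta_10)
  beta[9] <- 0.6
  beta[10] <- 0.5
  beta[11] <- 0.3
  model_params(
    beta = beta,
    alpha_tilde = c(4.006, -2.328, 2.701, -0.211, -0.345, -0.606, -0.536),
    gamma = c(0.775, 0.277),
    sigma_eps = 0.353, sigma0 = 0.916, sigma1 = 0.778, sigma2 = 0.658,
    rho = 0.123, kind = "pspline")
}

#' Simulation scenario configuration
#'
#' Describes the generative world: cohort size, time partition, true
#' parameters, visit schedule (one scheduled measurement per interval at
#' its left endpoint, jittered uniformly within +10% of the interval
#' width; the baseline visit at t = 0 is always taken), missed-visit
#' probability, an interval-constant discrete dropout-censoring hazard with
#' administrative censoring after interval `M`, and the baseline covariate
#' laws (standardized age ~ N(0,1); viral-load group with probabilities
#' `viral_probs` expanded to dummies V2, V3, V4).
#'
#' @param N Number of subjects (default 850, the motivating cohort size).
#' @param partition A [time_partition()]; default 12 intervals (one 3-month
#'   interval then 11 ~6-month intervals, scale 2093 days).
#' @param true_params A [model_params()]; default [default_true_params()].
#' @param missed_visit_prob Probability a non-baseline scheduled visit is
#'   skipped (default 0.1).
#' @param censor_hazard Per-interval discrete dropout hazard (default
#'   0.05), independent of the random effects given covariates.
#' @param viral_probs Length-4 probabilities of the viral-load groups
#'   (reference, V2, V3, V4).
#' @param parameterization Association tag.
#' @param seed Integer seed for [simulate_dataset()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(N = 850L,
                       partition = config_partition(default_model_config()),
                       true_params = default_true_params(),
                       missed_visit_prob = 0.1,
                       censor_hazard = 0.05,
                       viral_probs = c(0.30, 0.25, 0.25, 0.20),
                       parameterization = "intercept_slope",
                       seed = 1L) {
  stopifnot(inherits(partition, "time_partition"),
            inherits(true_params, "model_params"),
            missed_visit_prob >= 0, missed_visit_prob <= 1,
            censor_hazard >= 0, censor_hazard <= 1,
            length(viral_probs) == 4L, abs(sum(viral_probs) - 1) < 1e-8)
  structure(list(N = as.integer(N), partition = partition,
                 true_params = true_params,
                 missed_visit_prob = missed_visit_prob,
                 censor_hazard = censor_hazard,
                 viral_probs = viral_probs,
                 parameterization = parameterization,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one subject
#'
#' Draws the random spline coefficients `b ~ N(0, Sigma)` and baseline
#' covariates, then walks the intervals `r = 1..M`: in each, the event
#' occurs with the probit discrete hazard `1 - Phi(eta_r)` and dropout
#' censoring with probability `censor_hazard` (censoring is applied after
#' the event draw within an interval, so `delta = I(S <= C)`). Scheduled
#' measurements are emitted for every interval reached, at jittered times,
#' as `m_i(t) + e`, `e ~ N(0, sigma_eps^2)`. The event terminates
#' observation: no measurement time exceeds `k_{S*}`.
#'
#' @param cfg A [sim_config()].
#' @param id Subject identifier.
#' @return List with `subject` (a subject record) and `truth`
#'   (`b`, `S`, `C` — `Inf` when the corresponding time exceeds `M`).
#' @export
simulate_subject <- function(cfg, id = "s1") {
  part <- cfg$partition
  M <- part$M
  tp <- cfg$true_params
  Sigma <- build_sigma(tp, M)
  b <- drop(t(chol(Sigma)) %*% stats::rnorm(nrow(Sigma)))

  age <- stats::rnorm(1)
  grp <- sample.int(4L, 1L, prob = cfg$viral_probs)
  baseline <- c(age = age * 7 + 35, # stored raw; standardized when built
                V2 = as.numeric(grp == 2L),
                V3 = as.numeric(grp == 3L),
                V4 = as.numeric(grp == 4L))
  x_surv_std <- c(1, NA, NA, age, baseline[["V2"]], baseline[["V3"]],
                  baseline[["V4"]])

  coefs <- tp$beta + b
  S <- Inf
  C <- Inf
  for (r in seq_len(M)) {
    A <- association_design(r, part, cfg$parameterization, kind = tp$kind)
    gk <- if (is.matrix(tp$gamma)) tp$gamma[r, ] else tp$gamma
    rs <- part$boundaries[r]
    x_surv_std[2:3] <- c(rs, rs^2)
    eta <- sum(x_surv_std * tp$alpha_tilde) + sum(gk * drop(A %*% coefs))
    event <- stats::runif(1) > stats::pnorm(eta)
    if (event) S <- r
    if (stats::runif(1) < cfg$censor_hazard && !is.finite(C)) C <- r
    if (is.finite(S) || is.finite(C)) break
  }
  s_star <- as.integer(min(S, C, M))
  delta <- as.integer(S <= C & is.finite(S))

  # scheduled visits: one per interval reached, jittered into the interval
  times <- numeric(0)
  for (r in seq_len(s_star)) {
    if (r > 1L && stats::runif(1) < cfg$missed_visit_prob) next
    w <- part$boundaries[r + 1L] - part$boundaries[r]
    tt <- if (r == 1L) 0 else part$boundaries[r] + stats::runif(1) * 0.1 * w
    times <- c(times, tt)
  }
  Bm <- design_matrix(times, part)
  y <- drop(Bm %*% coefs) + stats::rnorm(length(times), 0, tp$sigma_eps)

  subject <- list(id = id, times = times, y = y,
                  x_long = matrix(numeric(0), length(times), 0L),
                  x_surv = NULL, s_star = s_star, delta = delta,
                  baseline = baseline)
  list(subject = subject, truth = list(id = id, b = b, S = S, C = C))
}

#' Simulate a full joint dataset plus hidden truth
#'
#' `N` independent subjects from [simulate_subject()], assembled into a
#' validated [joint_dataset()] with survival covariates built from the
#' default design, together with a truth table (random coefficients and
#' latent event/censoring intervals) supporting gold-standard prediction.
#' Byte-identical output for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a [joint_dataset()]) and `truth` (list of
#'   per-subject truth records, names = ids).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sims <- lapply(seq_len(cfg$N), function(i)
    simulate_subject(cfg, id = sprintf("s%04d", i)))
  subjects <- lapply(sims, `[[`, "subject")
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- vapply(truth, `[[`, character(1), "id")
  ds <- joint_dataset(subjects, cfg$partition)
  ds <- build_survival_covariates(
    ds, terms = c("1", "rstart", "rstart^2", "age", "V2", "V3", "V4"),
    transforms = list(age = c(35, 7)))
  list(dataset = ds, truth = truth)
}
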