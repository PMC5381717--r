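#' Joint-model parameter container
#'
#' Collects all unknowns of the joint model: longitudinal covariate effects
#' `alpha` (length `p`, may be empty), population spline coefficients `beta`
#' (length `M + 1`, or 2 for the random intercept-and-slope reduction),
#' survival covariate effects `alpha_tilde`, association coefficients
#' `gamma` (length `q`, or an `M x q` matrix when interval-specific),
#' measurement-error SD `sigma_eps`, random-effect SDs `sigma0`, `sigma1`
#' (intercept/slope) and `sigma2` (spline increments; the individual-level
#' smoothing scale), and the intercept-slope correlation `rho`.
#'
#' @param alpha,beta,alpha_tilde,gamma Regression coefficient vectors (see
#'   above); `gamma` may be an `M x q` matrix for interval-specific
#'   association.
#' @param sigma_eps,sigma0,sigma1,sigma2 Positive standard deviations.
#'   `sigma2` must be `NULL` for `kind = "rirs"`.
#' @param rho Correlation in `(-1, 1)`.
#' @param kind `"pspline"` or `"rirs"`.
#' @return Object of class `model_params`.
#' @export
model_params <- function(alpha = numeric(0), beta, alpha_tilde = numeric(0),
                         gamma = numeric(0), sigma_eps, sigma0, sigma1,
                         sigma2 = NULL, rho = 0,
                         kind = c("pspline", "rirs")) {
  kind <- match.arg(kind)
  if (kind == "rirs") {
    if (length(beta) != 2L) stop("model_params: rirs model needs length-2 beta")
    if (!is.null(sigma2)) stop("model_params: rirs model has no sigma2")
  } else {
    if (length(beta) < 2L) stop("model_params: beta must have length M + 1 >= 2")
    if (is.null(sigma2)) stop("model_params: sigma2 required for pspline kind")
    if (sigma2 <= 0) stop("model_params: sigma2 must be positive")
  }
  for (s in c(sigma_eps, sigma0, sigma1))
    if (!is.finite(s) || s <= 0) stop("model_params: SDs must be positive")
  if (abs(rho) >= 1) stop("model_params: |rho| must be < 1")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         alpha_tilde = as.numeric(alpha_tilde),
         gamma = if (is.matrix(gamma)) gamma else as.numeric(gamma),
         sigma_eps = sigma_eps, sigma0 = sigma0, sigma1 = sigma1,
         sigma2 = sigma2, rho = rho, kind = kind),
    class = "model_params")
}

#' Parameter layout descriptor
#'
#' Records the dimensions needed to flatten a `model_params` object into the
#' unconstrained vector used by the optimizer (and back).
#'
#' @param p,M Longitudinal covariate count and number of intervals.
#' @param q_tilde,q Survival covariate and association dimensions.
#' @param gamma_tv Logical: interval-specific gamma (`M x q`)?
#' @param kind `"pspline"` or `"rirs"`.
#' @return A `param_layout` list, with `$n_par` the flattened length.
#' @export
param_layout <- function(p, M, q_tilde, q, gamma_tv = FALSE,
                         kind = c("pspline", "rirs")) {
  kind <- match.arg(kind)
  Mb <- if (kind == "pspline") M + 1L else 2L
  ng <- if (gamma_tv) M * q else q
  n_par <- p + Mb + q_tilde + ng + 3L + (kind == "pspline") + 1L
  structure(list(p = as.integer(p), M = as.integer(M), Mb = as.integer(Mb),
                 q_tilde = as.integer(q_tilde), q = as.integer(q),
                 gamma_tv = isTRUE(gamma_tv), kind = kind,
                 n_par = as.integer(n_par)),
            class = "param_layout")
}

#' Map parameters to the unconstrained scale
#'
#' Regression coefficients pass through unchanged; standard deviations are
#' log-transformed and `rho` uses Fisher's z-transform
#' `z(rho) = atanh(rho)`, so any finite vector maps back to a valid
#' parameter set.
#'
#' @param params A [model_params()] object.
#' @return Numeric vector of length `layout$n_par`.
#' @seealso [from_unconstrained()]
#' @export
to_unconstrained <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(params$alpha, params$beta, params$alpha_tilde,
    as.numeric(params$gamma),
    log(params$sigma_eps), log(params$sigma0), log(params$sigma1),
    if (params$kind == "pspline") log(params$sigma2),
    atanh(params$rho))
}

#' Map an unconstrained vector back to parameters
#'
#' Inverse of [to_unconstrained()] for the given layout.
#'
#' @param v Numeric vector of length `layout$n_par`; must be finite.
#' @param layout A [param_layout()].
#' @return A [model_params()] object.
#' @export
from_unconstrained <- function(v, layout) {
  stopifnot(inherits(layout, "param_layout"))
  if (length(v) != layout$n_par)
    stop(sprintf("from_unconstrained: expected length %d, got %d",
                 layout$n_par, length(v)))
  if (any(!is.finite(v))) stop("from_unconstrained: non-finite input")
  i <- 0L
  take <- function(n) {
    out <- v[seq_len(n) + i]
    i <<- i + n
    out
  }
  alpha <- take(layout$p)
  beta <- take(layout$Mb)
  at <- take(layout$q_tilde)
  ng <- if (layout$gamma_tv) layout$M * layout$q else layout$q
  g <- take(ng)
  if (layout$gamma_tv) g <- matrix(g, nrow = layout$M, byrow = FALSE)
  se <- exp(take(1L)); s0 <- exp(take(1L)); s1 <- exp(take(1L))
  s2 <- if (layout$kind == "pspline") exp(take(1L)) else NULL
  rho <- tanh(take(1L))
  model_params(alpha = alpha, beta = beta, alpha_tilde = at, gamma = g,
               sigma_eps = se, sigma0 = s0, sigma1 = s1, sigma2 = s2,
               rho = rho, kind = layout$kind)
}

#' Names of the flattened parameter vector
#' @param layout A [param_layout()].
#' @return Character vector of length `layout$n_par`.
#' @export
param_names <- function(layout) {
  ng <- if (layout$gamma_tv) layout$M * layout$q else layout$q
  gnm <- if (layout$gamma_tv) {
    as.vector(outer(seq_len(layout$M), seq_len(layout$q) - 1L,
                    function(r, j) sprintf("gamma%d_r%d", j, r)))
  } else if (ng > 0) sprintf("gamma%d", seq_len(ng) - 1L) else character(0)
  c(if (layout$p > 0) sprintf("alpha%d", seq_len(layout$p)),
    sprintf("beta%d", seq_len(layout$Mb) - 1L),
    if (layout$q_tilde > 0) sprintf("alpha_tilde%d", seq_len(layout$q_tilde) - 1L),
    gnm,
    "sigma_eps", "sigma0", "sigma1",
    if (layout$kind == "pspline") "sigma2",
    "rho")
}
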