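#' Discretized follow-up time partition
#'
#' Builds the discrete time scale used by the survival sub-model: the
#' follow-up window is cut into `M` left-open/right-closed intervals
#' `(k_{r-1}, k_r]` whose boundaries also serve as the internal knots of the
#' truncated linear spline basis. All internal computation happens on the
#' scaled axis `t / scale`; `scale` records how many original time units
#' (e.g. days) correspond to one scaled unit.
#'
#' @param boundaries Strictly increasing numeric vector of interval
#'   boundaries in original time units, starting at 0.
#' @param scale Positive scalar: original time units per scaled unit. The
#'   stored boundaries are `boundaries / scale`.
#' @return An object of class `time_partition` with elements `boundaries`
#'   (scaled), `M`, and `scale`.
#' @export
time_partition <- function(boundaries, scale = 1) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L)
    stop("time_partition: need at least two boundaries")
  if (boundaries[1L] != 0)
    stop("time_partition: first boundary must be 0")
  if (any(diff(boundaries) <= 0))
    stop("time_partition: boundaries must be strictly increasing")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("time_partition: scale must be a positive scalar")
  structure(
    list(boundaries = boundaries / scale,
         M = length(boundaries) - 1L,
         scale = scale),
    class = "time_partition")
}

#' @export
print.time_partition <- function(x, ...) {
  cat("Time partition: ", x$M, " intervals on [0, ",
      format(max(x$boundaries)), "] (scale = ", format(x$scale), ")\n",
      sep = "")
  invisible(x)
}

#' Interval index of a time point
#'
#' Maps scaled time `t` to its interval `r` with `k_{r-1} < t <= k_r`;
#' `t = 0` belongs to interval 1 by convention.
#'
#' @param t Numeric vector of scaled times in `[0, k_M]`.
#' @param part A [time_partition()].
#' @return Integer vector of interval indices in `1..M`.
#' @export
interval_index <- function(t, part) {
  stopifnot(inherits(part, "time_partition"))
  b <- part$boundaries
  bad <- t < 0 | t > b[length(b)]
  if (any(bad))
    stop(sprintf("interval_index: time %g outside [0, %g]",
                 t[which(bad)[1L]], b[length(b)]))
  pmax(findInterval(t, b, left.open = TRUE), 1L)
}

#' Truncated linear basis evaluated at one time point
#'
#' The basis is `{1, t, (t - k_1)_+, ..., (t - k_{M-1})_+}`, giving
#' continuous piecewise-linear functions whose slope changes only at the
#' internal knots (the partition boundaries).
#'
#' @param t Scaled time, `t >= 0`.
#' @inheritParams interval_index
#' @return Numeric vector of length `M + 1`.
#' @export
basis_row <- function(t, part) {
  stopifnot(inherits(part, "time_partition"), t >= 0)
  knots <- part$boundaries[2:part$M] # k_1 .. k_{M-1}
  c(1, t, pmax(t - knots, 0))
}

#' Basis design matrix for a vector of times
#'
#' @param times Numeric vector of scaled times (may be empty).
#' @inheritParams interval_index
#' @return Numeric matrix with one row per time and `M + 1` columns, rows in
#'   input order; attribute `"times"` carries the evaluated times.
#' @export
design_matrix <- function(times, part) {
  stopifnot(inherits(part, "time_partition"))
  M <- part$M
  if (length(times) == 0L) {
    out <- matrix(numeric(0), nrow = 0L, ncol = M + 1L)
  } else {
    if (any(times < 0)) stop("design_matrix: negative time")
    knots <- part$boundaries[2:M]
    out <- cbind(1, times,
                 pmax(outer(times, knots, "-"), 0), deparse.level = 0)
  }
  attr(out, "times") <- as.numeric(times)
  out
}

#' Linear map extracting the interval-specific random intercept
#'
#' Returns the weight vector `w` such that `w %*% c` equals the value of the
#' spline with coefficients `c` at the interval start `k_{r-1}`; applied to
#' `beta + b` it gives `m_i(k_{r-1})`. Equals `basis_row(k_{r-1})` exactly.
#'
#' @param r Interval index in `1..M`.
#' @inheritParams interval_index
#' @return Numeric vector of length `M + 1`.
#' @export
intercept_map <- function(r, part) {
  stopifnot(inherits(part, "time_partition"))
  if (r < 1L || r > part$M) stop("intercept_map: interval index out of range")
  basis_row(part$boundaries[r], part)
}

#' Linear map extracting the interval-specific random slope
#'
#' Weight vector `w` with `w %*% c = c_1 + ... + c_r` (0-based coefficient
#' indices), the constant slope of the spline inside interval `r`.
#'
#' @inheritParams intercept_map
#' @return Numeric vector of length `M + 1`.
#' @export
slope_map <- function(r, part) {
  stopifnot(inherits(part, "time_partition"))
  M <- part$M
  if (r < 1L || r > M) stop("slope_map: interval index out of range")
  c(0, rep(1, r), rep(0, M - r))
}

#' Association design matrix for one interval
#'
#' Stacks the intercept and/or slope maps into the `q x (M+1)` matrix `A_r`
#' such that `A_r %*% (beta + b)` yields the interval-level summaries of the
#' longitudinal trajectory entering the survival linear predictor (for
#' `"intercept_slope"`: `(m_i(k_{r-1}), m_i'(k_{r-1}))`).
#'
#' @inheritParams intercept_map
#' @param parameterization One of `"intercept_slope"`, `"intercept_only"`,
#'   `"slope_only"`.
#' @param kind `"pspline"` for the full truncated linear basis, `"rirs"` for
#'   the random intercept-and-slope reduction (basis `{1, t}`), where the
#'   maps are `(1, k_{r-1})` and `(0, 1)`.
#' @return Numeric matrix `q x (M+1)` (or `q x 2` for `kind = "rirs"`).
#' @export
association_design <- function(r, part,
                               parameterization = c("intercept_slope",
                                                    "intercept_only",
                                                    "slope_only"),
                               kind = c("pspline", "rirs")) {
  parameterization <- match.arg(parameterization)
  kind <- match.arg(kind)
  if (kind == "rirs") {
    if (r < 1L || r > part$M) stop("association_design: index out of range")
    im <- c(1, part$boundaries[r])
    sm <- c(0, 1)
  } else {
    im <- intercept_map(r, part)
    sm <- slope_map(r, part)
  }
  switch(parameterization,
         intercept_slope = rbind(im, sm, deparse.level = 0),
         intercept_only  = matrix(im, nrow = 1L),
         slope_only      = matrix(sm, nrow = 1L))
}
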