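#' Assemble a joint longitudinal/survival dataset
#'
#' The canonical in-memory container pairing each subject's longitudinal
#' measurements with their discrete-time survival record. Measurement times
#' are stored on the scaled axis of `partition`.
#'
#' @param subjects List of subject records; each is a list with elements
#'   `id`, `times` (ascending scaled times), `y`, `x_long` (`n_i x p`
#'   matrix), `x_surv` (`M x q_tilde` matrix or `NULL` until
#'   [build_survival_covariates()] runs), `s_star` (observed interval in
#'   `1..M`), `delta` (0/1 event indicator), and `baseline` (named numeric
#'   vector of baseline covariates).
#' @param partition A [time_partition()].
#' @param covariate_names_long,covariate_names_surv Column labels.
#' @return Object of class `joint_dataset`.
#' @export
joint_dataset <- function(subjects, partition,
                          covariate_names_long = character(0),
                          covariate_names_surv = character(0)) {
  stopifnot(inherits(partition, "time_partition"))
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("joint_dataset: duplicate subject ids")
  kM <- partition$boundaries[partition$M + 1L]
  for (s in subjects) {
    if (length(s$times) != length(s$y))
      stop(sprintf("joint_dataset: subject %s: times/y length mismatch", s$id))
    if (is.unsorted(s$times, strictly = FALSE))
      stop(sprintf("joint_dataset: subject %s: non-monotone times", s$id))
    if (!(s$delta %in% c(0, 1)))
      stop(sprintf("joint_dataset: subject %s: delta must be 0 or 1", s$id))
    if (s$s_star < 1L || s$s_star > partition$M)
      stop(sprintf("joint_dataset: subject %s: s_star outside 1..%d",
                   s$id, partition$M))
    ks <- partition$boundaries[s$s_star + 1L]
    if (length(s$times) && max(s$times) > ks + 1e-9)
      stop(sprintf(
        "joint_dataset: subject %s: measurement after observed interval", s$id))
  }
  structure(list(subjects = subjects, partition = partition,
                 covariate_names_long = covariate_names_long,
                 covariate_names_surv = covariate_names_surv),
            class = "joint_dataset")
}

#' @export
print.joint_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) length(s$y), numeric(1)))
  n_ev <- sum(vapply(x$subjects, function(s) s$delta, numeric(1)))
  cat("Joint dataset: ", length(x$subjects), " subjects, ", n_obs,
      " longitudinal measurements, ", n_ev, " events, M = ",
      x$partition$M, "\n", sep = "")
  invisible(x)
}

#' Read a joint dataset from delimited text files
#'
#' The longitudinal file must have columns `id`, `time`, `y` and then any
#' longitudinal covariates; the survival file `id`, `s_star`, `delta` and
#' then baseline covariates. Times in the file are in original units and are
#' divided by the partition scale. Rows with a missing outcome are dropped
#' (a message reports how many). A censored subject (`delta = 0`) with
#' `s_star = s` is taken to have survived through interval `s`.
#'
#' @param long_path,surv_path CSV file paths (header row, comma-separated).
#' @param config A model config list as returned by [read_model_config()] or
#'   [default_model_config()]; supplies the partition and covariate names.
#' @return A validated [joint_dataset()] with `x_surv` built from
#'   `config$surv_terms`.
#' @export
read_joint_dataset <- function(long_path, surv_path, config) {
  part <- config_partition(config)
  long <- utils::read.csv(long_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(surv_path, stringsAsFactors = FALSE)
  need_l <- c("id", "time", "y")
  need_s <- c("id", "s_star", "delta")
  if (!all(need_l %in% names(long)))
    stop("read_joint_dataset: longitudinal file needs columns id,time,y")
  if (!all(need_s %in% names(surv)))
    stop("read_joint_dataset: survival file needs columns id,s_star,delta")
  if (anyDuplicated(surv$id)) stop("read_joint_dataset: duplicate survival rows")
  miss <- !is.finite(long$y)
  if (any(miss)) {
    message(sprintf("read_joint_dataset: dropping %d rows with missing outcome",
                    sum(miss)))
    long <- long[!miss, , drop = FALSE]
  }
  orphan <- setdiff(unique(long$id), surv$id)
  if (length(orphan))
    stop(sprintf("read_joint_dataset: subject %s absent from survival file",
                 orphan[1L]))
  if (any(!surv$delta %in% c(0, 1)))
    stop("read_joint_dataset: delta must be 0 or 1")
  cn_long <- as.character(unlist(config$long_covariates %||% character(0)))
  if (!all(cn_long %in% names(long)))
    stop("read_joint_dataset: missing longitudinal covariate column")
  base_cols <- setdiff(names(surv), need_s)
  subjects <- lapply(seq_len(nrow(surv)), function(i) {
    id <- surv$id[i]
    li <- long[long$id == id, , drop = FALSE]
    li <- li[order(li$time), , drop = FALSE]
    list(id = id,
         times = li$time / part$scale,
         y = li$y,
         x_long = as.matrix(li[, cn_long, drop = FALSE]),
         x_surv = NULL,
         s_star = as.integer(surv$s_star[i]),
         delta = as.integer(surv$delta[i]),
         baseline = unlist(surv[i, base_cols, drop = FALSE]))
  })
  ds <- joint_dataset(subjects, part, covariate_names_long = cn_long)
  build_survival_covariates(ds, config$surv_terms %||% "1",
                            config$transforms %||% list())
}

#' Write a joint dataset to delimited text files
#'
#' Inverse of [read_joint_dataset()]: times are written back in original
#' units (`time * scale`). Baseline covariates are written untransformed as
#' stored on each subject.
#'
#' @param dataset A [joint_dataset()].
#' @param long_path,surv_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_joint_dataset <- function(dataset, long_path, surv_path) {
  stopifnot(inherits(dataset, "joint_dataset"))
  sc <- dataset$partition$scale
  long <- do.call(rbind, lapply(dataset$subjects, function(s) {
    if (!length(s$times)) return(NULL)
    df <- data.frame(id = s$id, time = s$times * sc, y = s$y)
    if (length(dataset$covariate_names_long)) {
      xl <- as.data.frame(s$x_long)
      names(xl) <- dataset$covariate_names_long
      df <- cbind(df, xl)
    }
    df
  }))
  if (is.null(long))
    long <- data.frame(id = character(0), time = numeric(0), y = numeric(0))
  surv <- do.call(rbind, lapply(dataset$subjects, function(s) {
    df <- data.frame(id = s$id, s_star = s$s_star, delta = s$delta)
    if (length(s$baseline)) df <- cbind(df, as.data.frame(t(s$baseline)))
    df
  }))
  utils::write.csv(long, long_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(surv, surv_path, row.names = FALSE, quote = FALSE)
  invisible(c(long_path, surv_path))
}

#' Build interval-level survival covariates
#'
#' Fills each subject's `M x q_tilde` survival design from a vector of term
#' strings: `"1"` (intercept), `"rstart"` (scaled time at the start of the
#' interval, `k_{r-1}`), `"rstart^2"`, or the name of a baseline covariate.
#' Baseline covariates may be standardized via `transforms`, a named list of
#' `c(center, scale)` applied as `(value - center) / scale`.
#'
#' @param dataset A [joint_dataset()].
#' @param terms Character vector of term strings, e.g.
#'   `c("1", "rstart", "rstart^2", "age", "V2", "V3", "V4")`.
#' @param transforms Named list of length-2 numeric vectors
#'   `c(center, scale)` keyed by baseline covariate name.
#' @return The dataset with `x_surv` and `covariate_names_surv` filled.
#' @export
build_survival_covariates <- function(dataset, terms, transforms = list()) {
  stopifnot(inherits(dataset, "joint_dataset"))
  part <- dataset$partition
  rstart <- part$boundaries[seq_len(part$M)]
  dataset$subjects <- lapply(dataset$subjects, function(s) {
    cols <- lapply(terms, function(tm) {
      if (tm == "1") rep(1, part$M)
      else if (tm == "rstart") rstart
      else if (tm == "rstart^2") rstart^2
      else {
        if (!tm %in% names(s$baseline))
          stop(sprintf("build_survival_covariates: unknown covariate '%s'", tm))
        v <- s$baseline[[tm]]
        if (tm %in% names(transforms)) {
          tr <- transforms[[tm]]
          v <- (v - tr[[1L]]) / tr[[2L]]
        }
        rep(v, part$M)
      }
    })
    s$x_surv <- do.call(cbind, cols)
    colnames(s$x_surv) <- terms
    s
  })
  dataset$covariate_names_surv <- terms
  dataset
}

#' Expand a dataset into the person-interval (discrete-time at-risk) table
#'
#' One row per subject per interval survived or failed: subject `i`
#' contributes rows `r = 1..s_star` with event indicator 0 except possibly
#' `delta` at `r = s_star`. Shared by the time-varying-covariate comparator
#' and the two-stage survival fit so both use the same at-risk construction.
#'
#' @param dataset A [joint_dataset()] with `x_surv` built.
#' @return Data frame with columns `id`, `r`, `event`, and the survival
#'   covariate columns.
#' @export
expand_person_intervals <- function(dataset) {
  stopifnot(inherits(dataset, "joint_dataset"))
  rows <- lapply(dataset$subjects, function(s) {
    if (is.null(s$x_surv)) stop("expand_person_intervals: x_surv not built")
    r <- seq_len(s$s_star)
    df <- data.frame(id = s$id, r = r,
                     event = c(rep(0L, s$s_star - 1L), s$delta))
    cbind(df, as.data.frame(s$x_surv[r, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
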