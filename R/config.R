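#' Default model configuration
#'
#' Returns the configuration emulating the motivating HIV cohort design:
#' follow-up of 2093 days cut into 12 intervals (a first 3-month interval
#' followed by 11 roughly 6-month intervals), time scaled to about `[0, 1]`,
#' no longitudinal covariates, survival design
#' `1 + rstart + rstart^2 + age + V2 + V3 + V4` with age standardized as
#' `(age - 35) / 7`, intercept-plus-slope association with constant gamma,
#' and a 16-point logarithmic smoothing grid on `[1e-3, 1e2]`.
#'
#' @return A named list understood by [read_joint_dataset()], [psjm_fit()]
#'   and the CLI.
#' @export
default_model_config <- function() {
  first <- 91 # ~3 months, days
  total <- 2093
  bnd <- c(0, first + (0:11) * (total - first) / 11)
  list(
    partition_boundaries = bnd,
    scale = total,
    long_covariates = character(0),
    surv_terms = c("1", "rstart", "rstart^2", "age", "V2", "V3", "V4"),
    transforms = list(age = c(35, 7)),
    association = "intercept_slope",
    gamma_tv = FALSE,
    lambda_grid = exp(seq(log(1e-3), log(1e2), length.out = 16)),
    seed = 1L
  )
}

#' Time partition described by a model config
#' @param config A config list (see [default_model_config()]).
#' @return A [time_partition()].
#' @export
config_partition <- function(config) {
  time_partition(config$partition_boundaries, config$scale %||% 1)
}

#' Read / write a model configuration file (JSON)
#'
#' The config names the time partition (boundaries in original units plus
#' the scale constant), covariate terms, association structure, and the
#' smoothing grid. JSON is used as the structured config dialect.
#'
#' @param path File path.
#' @return For `read_model_config`, the config list (missing fields filled
#'   from [default_model_config()]).
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_model_config()
  if (!is.null(cfg$transforms)) cfg$transforms <- as.list(cfg$transforms)
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  # empty JSON arrays read back as empty lists
  cfg$long_covariates <- as.character(unlist(cfg$long_covariates))
  cfg$surv_terms <- as.character(unlist(cfg$surv_terms))
  cfg
}

#' @rdname read_model_config
#' @param config Config list to serialize.
#' @export
write_model_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
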