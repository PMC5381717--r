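make_toy_files <- function(dir) {
  long <- data.frame(
    id = c("a", "a", "a", "b"),
    time = c(0, 250, 600, 0),
    y = c(1.2, 0.8, 0.5, -0.3))
  surv <- data.frame(id = c("a", "b", "c"), s_star = c(2, 1, 3),
                     delta = c(1, 0, 0), age = c(40, 31, 35),
                     V2 = c(1, 0, 0), V3 = c(0, 1, 0), V4 = c(0, 0, 0))
  lp <- file.path(dir, "long.csv")
  sp <- file.path(dir, "surv.csv")
  write.csv(long, lp, row.names = FALSE, quote = FALSE)
  write.csv(surv, sp, row.names = FALSE, quote = FALSE)
  list(long = lp, surv = sp)
}

toy_config <- function() {
  cfg <- default_model_config()
  cfg$partition_boundaries <- c(0, 300, 700, 1200)
  cfg$scale <- 1200
  cfg
}

test_that("read_joint_dataset builds a validated dataset and round-trips", {
  dir <- withr::local_tempdir()
  fp <- make_toy_files(dir)
  cfg <- toy_config()
  ds <- read_joint_dataset(fp$long, fp$surv, cfg)
  expect_s3_class(ds, "joint_dataset")
  expect_length(ds$subjects, 3L)
  a <- ds$subjects[[1]]
  expect_equal(a$times, c(0, 250, 600) / 1200)
  # subject c has a survival row but no measurements: accepted with n_i = 0
  expect_length(ds$subjects[[3]]$y, 0L)
  # survival design: rstart terms plus standardized age
  expect_equal(a$x_surv[, "rstart"], c(0, 300, 700) / 1200)
  expect_equal(unname(a$x_surv[1, "age"]), (40 - 35) / 7)
  # round trip through write/read is lossless
  lp2 <- file.path(dir, "long2.csv"); sp2 <- file.path(dir, "surv2.csv")
  write_joint_dataset(ds, lp2, sp2)
  ds2 <- read_joint_dataset(lp2, sp2, cfg)
  for (i in seq_along(ds$subjects)) {
    expect_equal(ds2$subjects[[i]]$times, ds$subjects[[i]]$times)
    expect_equal(ds2$subjects[[i]]$y, ds$subjects[[i]]$y)
    expect_equal(ds2$subjects[[i]]$s_star, ds$subjects[[i]]$s_star)
    expect_equal(ds2$subjects[[i]]$x_surv, ds$subjects[[i]]$x_surv)
  }
})

test_that("reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  fp <- make_toy_files(dir)
  cfg <- toy_config()
  # delta = 2
  surv <- read.csv(fp$surv); surv$delta[1] <- 2
  write.csv(surv, fp$surv, row.names = FALSE)
  expect_error(read_joint_dataset(fp$long, fp$surv, cfg), "delta")
  # s_star outside 1..M
  fp <- make_toy_files(dir)
  surv <- read.csv(fp$surv); surv$s_star[1] <- 9
  write.csv(surv, fp$surv, row.names = FALSE)
  expect_error(read_joint_dataset(fp$long, fp$surv, cfg), "s_star")
  # subject in longitudinal file absent from survival file
  fp <- make_toy_files(dir)
  surv <- read.csv(fp$surv)[-1, ]
  write.csv(surv, fp$surv, row.names = FALSE)
  expect_error(read_joint_dataset(fp$long, fp$surv, cfg), "absent")
  # measurement after the observed interval
  fp <- make_toy_files(dir)
  surv <- read.csv(fp$surv); surv$s_star[1] <- 1
  write.csv(surv, fp$surv, row.names = FALSE)
  expect_error(read_joint_dataset(fp$long, fp$surv, cfg), "after")
})

test_that("missing outcomes are dropped with a message", {
  dir <- withr::local_tempdir()
  fp <- make_toy_files(dir)
  long <- read.csv(fp$long)
  long$y[2] <- NA
  write.csv(long, fp$long, row.names = FALSE)
  expect_message(ds <- read_joint_dataset(fp$long, fp$surv, toy_config()),
                 "dropping 1")
  expect_length(ds$subjects[[1]]$y, 2L)
})

test_that("build_survival_covariates computes interval-level terms", {
  part <- time_partition(c(0, .25, .5, 1))
  sub <- list(id = "x", times = numeric(0), y = numeric(0),
              x_long = matrix(numeric(0), 0, 0), x_surv = NULL,
              s_star = 3L, delta = 0L, baseline = c(age = 42))
  ds <- joint_dataset(list(sub), part)
  ds1 <- build_survival_covariates(ds, c("1", "rstart", "rstart^2"))
  expect_equal(unname(ds1$subjects[[1]]$x_surv),
               cbind(1, c(0, .25, .5), c(0, .0625, .25)))
  ds2 <- build_survival_covariates(ds, "1")
  expect_equal(unname(ds2$subjects[[1]]$x_surv), cbind(rep(1, 3)))
  ds3 <- build_survival_covariates(ds, c("1", "age"),
                                   transforms = list(age = c(35, 7)))
  expect_equal(ds3$subjects[[1]]$x_surv[, "age"], rep(1, 3))
  expect_error(build_survival_covariates(ds, c("1", "bmi")), "unknown")
})

test_that("parameter transforms are mutual inverses and always valid", {
  lay <- param_layout(p = 1, M = 4, q_tilde = 2, q = 2, kind = "pspline")
  # sigma = 1 <-> 0 under log, rho = 0 <-> 0 under Fisher z
  p0 <- model_params(alpha = 0.3, beta = rep(0, 5), alpha_tilde = c(1, -1),
                     gamma = c(0.5, 0.2), sigma_eps = 1, sigma0 = 1,
                     sigma1 = 1, sigma2 = 1, rho = 0)
  v0 <- to_unconstrained(p0)
  expect_equal(v0[lay$n_par - 4:1], rep(0, 4)) # four log-SDs are zero
  expect_equal(v0[lay$n_par], 0)
  set.seed(5)
  for (i in 1:100) {
    v <- rnorm(lay$n_par, 0, 2)
    p <- from_unconstrained(v, lay)
    expect_true(all(c(p$sigma_eps, p$sigma0, p$sigma1, p$sigma2) > 0))
    expect_lt(abs(p$rho), 1)
    expect_equal(to_unconstrained(p), v, tolerance = 1e-10)
  }
  expect_error(from_unconstrained(rep(Inf, lay$n_par), lay), "non-finite")
  expect_error(from_unconstrained(numeric(3), lay), "length")
})

test_that("person-interval expansion produces the at-risk rows", {
  part <- time_partition(c(0, .25, .5, 1))
  subs <- list(
    list(id = "a", times = 0, y = 1, x_long = matrix(numeric(0), 1, 0),
         x_surv = NULL, s_star = 3L, delta = 1L, baseline = c(age = 40)),
    list(id = "b", times = numeric(0), y = numeric(0),
         x_long = matrix(numeric(0), 0, 0), x_surv = NULL,
         s_star = 1L, delta = 0L, baseline = c(age = 30)))
  ds <- build_survival_covariates(joint_dataset(subs, part), c("1", "rstart"))
  pit <- expand_person_intervals(ds)
  expect_equal(nrow(pit), 4L)
  expect_equal(pit$event[pit$id == "a"], c(0L, 0L, 1L))
  expect_equal(pit$event[pit$id == "b"], 0L)
  expect_equal(pit$rstart[pit$id == "a"], c(0, .25, .5))
})

test_that("model config round-trips through JSON and drives the reader", {
  d <- withr::local_tempdir()
  cfg <- default_model_config()
  p <- file.path(d, "cfg.json")
  write_model_config(cfg, p)
  cfg2 <- read_model_config(p)
  expect_equal(cfg2$partition_boundaries, cfg$partition_boundaries)
  expect_equal(cfg2$surv_terms, cfg$surv_terms)
  expect_identical(cfg2$long_covariates, character(0))
  expect_equal(cfg2$transforms$age, c(35, 7))
  # a simulated cohort written to disk reads back through the same config
  sim <- simulate_dataset(sim_config(N = 10, seed = 2))
  write_joint_dataset(sim$dataset, file.path(d, "l.csv"),
                      file.path(d, "s.csv"))
  ds <- read_joint_dataset(file.path(d, "l.csv"), file.path(d, "s.csv"), cfg2)
  expect_length(ds$subjects, 10L)
  expect_equal(ds$covariate_names_surv, cfg$surv_terms)
})
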