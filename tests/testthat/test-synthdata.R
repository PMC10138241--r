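test_that("the packaged marginal set matches the cohort tables", {
  margins <- default_margins()
  expect_length(margins, 68L)
  kinds <- vapply(margins, function(m) m$kind, character(1))
  expect_identical(sum(kinds == "binary"), 8L)
  expect_identical(sum(kinds == "continuous"), 60L)

  h19 <- margins[["H19_placenta"]]
  expect_identical(h19$mean, 58.32)
  expect_identical(h19$sd, 10.57)
  expect_identical(h19$valid_range, c(0, 100))

  expect_identical(margins[["stressful_events"]]$prevalence, 0.322)
  expect_identical(margins[["vanadium"]]$sd, 0)
  expect_identical(margins[["dioxins_pcbdl"]]$valid_range, c(0, Inf))
})

test_that("simulation is deterministic given the seed", {
  c1 <- simulate_cohort(cohort_sim_config(seed = 17))
  c2 <- simulate_cohort(cohort_sim_config(seed = 17))
  expect_identical(c1$data, c2$data)
  c3 <- simulate_cohort(cohort_sim_config(seed = 18))
  expect_false(identical(c1$data, c3$data))
})

test_that("default simulation yields 28 records respecting every range", {
  co <- simulate_cohort(cohort_sim_config(seed = 4))
  expect_identical(length(co$subjects), 28L)
  expect_s3_class(validate_cohort(co), "cohort_table")
  meth <- vapply(co$variables, function(v)
    v$kind == "continuous" && identical(v$valid_range, c(0, 100)),
    logical(1))
  for (nm in names(co$variables)[meth]) {
    expect_true(all(co$data[[nm]] >= 0 & co$data[[nm]] <= 100))
  }
  expect_true(all(co$data$vanadium == 0))
})

test_that("marginal moments are recovered at large n", {
  margins <- default_margins()[c("H19_placenta", "LEP_placenta",
                                 "NR3C1_placenta", "MGMT_maternal_buccal",
                                 "arsenic", "stressful_events",
                                 "maternal_age")]
  co <- simulate_cohort(cohort_sim_config(n_subjects = 50000, seed = 12,
                                          marginals = margins))
  # tolerance ~3 standard errors of each estimator: 2% is ample for the
  # low-cv marginals; the cv = 3 trace-metal gamma needs more room
  tol <- c(H19_placenta = 0.02, LEP_placenta = 0.02, NR3C1_placenta = 0.02,
           MGMT_maternal_buccal = 0.03, arsenic = 0.05)
  for (nm in names(tol)) {
    sp <- margins[[nm]]
    x <- co$data[[nm]]
    expect_lt(abs(mean(x) - sp$mean) / sp$mean, tol[[nm]], label = nm)
    expect_lt(abs(stats::sd(x) - sp$sd) / sp$sd, tol[[nm]], label = nm)
  }
  expect_lt(abs(mean(co$data$stressful_events == "yes") - 0.322), 0.01)
  expect_lt(abs(mean(co$data$maternal_age == "under40") - 0.893), 0.01)
})

test_that("extreme prevalences yield constant binary columns", {
  margins <- list(
    marginal_spec("never", "binary", prevalence = 0, levels = c("yes", "no")),
    marginal_spec("always", "binary", prevalence = 1,
                  levels = c("yes", "no")))
  co <- simulate_cohort(cohort_sim_config(n_subjects = 50, seed = 3,
                                          marginals = margins))
  expect_true(all(co$data$never == "no"))
  expect_true(all(co$data$always == "yes"))
})

test_that("planted latent correlation shows up as rank correlation", {
  margins <- list(
    marginal_spec("u", "continuous", mean = 50, sd = 10,
                  valid_range = c(0, 100)),
    marginal_spec("v", "continuous", mean = 5, sd = 4,
                  valid_range = c(0, 100)))
  dep <- dependence_spec(list(list(members = c("u", "v"),
                                   correlation = 0.95)))
  co <- simulate_cohort(cohort_sim_config(n_subjects = 1000, seed = 5,
                                          marginals = margins,
                                          dependence = dep))
  rho <- stats::cor(co$data$u, co$data$v, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("planted truth echoes the generative structure", {
  dep <- block_dependence()
  cfg <- cohort_sim_config(marginals = block_margins(), dependence = dep)
  expect_identical(planted_truth(cfg), dep)
  expect_length(planted_truth(cfg)$blocks, 3L)
  cfg0 <- cohort_sim_config()
  expect_length(planted_truth(cfg0)$blocks, 0L)
  expect_identical(planted_truth(cfg0)$background, 0)
})

test_that("infeasible dependence and marginals raise named errors", {
  dep <- dependence_spec(list(list(members = c("a", "b"),
                                   correlation = 0.9),
                              list(members = c("b", "c"),
                                   correlation = -0.9),
                              list(members = c("a", "c"),
                                   correlation = 0.9)))
  margins <- lapply(c("a", "b", "c"), function(nm)
    marginal_spec(nm, "continuous", mean = 50, sd = 10,
                  valid_range = c(0, 100)))
  expect_error(
    simulate_cohort(cohort_sim_config(n_subjects = 10, seed = 1,
                                      marginals = margins,
                                      dependence = dep)),
    "positive-semi-definite")

  # sd larger than any distribution on [0, 100] with this mean can have
  bad <- list(marginal_spec("impossible", "continuous", mean = 50, sd = 60,
                            valid_range = c(0, 100)))
  expect_error(
    simulate_cohort(cohort_sim_config(n_subjects = 10, seed = 1,
                                      marginals = bad)),
    "impossible")
})

test_that("written cohorts feed straight back into the dataset module", {
  co <- simulate_cohort(cohort_sim_config(n_subjects = 12, seed = 9))
  tf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".yml")
  write_cohort(co, tf)
  write_schema(co, sf)
  back <- read_cohort(tf, sf)
  expect_identical(back$data, co$data)
})
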