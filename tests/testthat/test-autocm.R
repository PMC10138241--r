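# Reference forward/update closed forms evaluated by hand, then the
# monotone-contraction dynamics checked against the compiled trainer.

test_that("forward pass matches its closed forms", {
  cfg <- autocm_config(C = 10)
  m <- autocm_init(3, cfg)
  m$v <- rep(0, 3); m$w <- matrix(0, 3, 3)
  r <- c(0.2, 0.5, 0.9)
  fw <- autocm_forward(m, r)
  expect_equal(fw$hidden, r)
  expect_equal(fw$net, rep(sum(r), 3))
  expect_equal(fw$output, r * (1 - sum(r) / 10))

  # full hidden contraction kills the signal
  m$v <- rep(10, 3)
  fw <- autocm_forward(m, r)
  expect_equal(fw$hidden, rep(0, 3))
  expect_equal(fw$output, rep(0, 3))

  # N = 2, C = 2, v = w = 0, r = (1,1): net = 2 and 1 - 2/2 = 0
  m2 <- autocm_init(2, autocm_config(C = 2))
  m2$v <- rep(0, 2); m2$w <- matrix(0, 2, 2)
  fw2 <- autocm_forward(m2, c(1, 1))
  expect_equal(fw2$output, c(0, 0))

  expect_error(autocm_forward(m, c(1, 0)), "does not match")
})

test_that("update increments match hand-evaluated values and are nonnegative", {
  m <- autocm_init(2, autocm_config(C = 2, alpha = 1))
  m$v <- rep(0, 2); m$w <- matrix(0, 2, 2)

  # all-zero record changes nothing
  m0 <- autocm_update(m, c(0, 0))
  expect_identical(m0$v, m$v)
  expect_identical(m0$w, m$w)

  # r = (1,1): hidden = r so dv = 0; dw[i,s] = (1-0)*1*1 = 1 everywhere
  m1 <- autocm_update(m, c(1, 1))
  expect_equal(m1$v, c(0, 0))
  expect_equal(m1$w, matrix(1, 2, 2))

  # increments are never negative for inputs in [0,1], any state
  set.seed(42)
  for (k in 1:20) {
    mm <- autocm_init(4, autocm_config(C = 4, alpha = 0.3))
    mm$v <- runif(4, 0, 4)
    mm$w <- matrix(runif(16, 0, 4), 4)
    up <- autocm_update(mm, runif(4))
    expect_true(all(up$v - mm$v >= 0))
    expect_true(all(up$w - mm$w >= 0))
    expect_true(all(up$v <= 4) && all(up$w <= 4))
  }
})

test_that("training contracts: monotone weights, unimodal trace, bounds", {
  set.seed(7)
  for (k in 1:5) {
    n <- sample(3:8, 1)
    x <- matrix(runif(20 * n), 20, n)
    cfg <- autocm_config(max_epochs = 40)
    fit <- autocm_train(x, cfg)
    expect_true(all(fit$v >= 0 & fit$v <= fit$C))
    expect_true(all(fit$w >= 0 & fit$w <= fit$C))
    # weights end above their strictly positive start
    expect_true(all(fit$v >= cfg$init * fit$C))
    expect_true(all(fit$w >= cfg$init * fit$C))
    # trace nonincreasing after its burn-in peak
    pk <- which.max(fit$trace)
    expect_true(all(diff(fit$trace[pk:length(fit$trace)]) <= 1e-12))
  }
})

test_that("compiled trainer reproduces the R reference update loop", {
  set.seed(11)
  x <- matrix(runif(8 * 5), 8, 5)
  cfg <- autocm_config(max_epochs = 7, tol = 1e-300)
  fit <- autocm_train(x, cfg)

  ref <- autocm_init(5, cfg)
  for (e in 1:7) for (r in 1:8) ref <- autocm_update(ref, x[r, ])
  expect_equal(fit$v, ref$v, tolerance = 1e-12)
  expect_equal(unname(fit$w), unname(ref$w), tolerance = 1e-12)
})

test_that("training in dataset order is bit-deterministic", {
  set.seed(3)
  x <- matrix(runif(15 * 6), 15, 6)
  f1 <- autocm_train(x, autocm_config(max_epochs = 100))
  f2 <- autocm_train(x, autocm_config(max_epochs = 100))
  expect_identical(f1$v, f2$v)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$trace, f2$trace)

  # shuffled order is reproducible under its seed and leaves the caller's
  # RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  s1 <- autocm_train(x, autocm_config(max_epochs = 20,
                                      record_order = "shuffled", seed = 5))
  expect_identical(runif(1), before)
  s2 <- autocm_train(x, autocm_config(max_epochs = 20,
                                      record_order = "shuffled", seed = 5))
  expect_identical(s1$w, s2$w)
})

test_that("degenerate inputs behave: all-zero matrix, single saturating node", {
  z <- matrix(0, 5, 3)
  fit <- autocm_train(z)
  expect_true(fit$converged)
  expect_identical(fit$epochs_run, 1L)
  cfg <- autocm_config()
  expect_equal(unname(fit$w), matrix(cfg$init * 3, 3, 3))

  # two nodes always on together: v saturates toward C, trace decays to 0
  one <- matrix(1, 50, 2)
  f1 <- autocm_train(one, autocm_config(max_epochs = 5000))
  expect_true(f1$converged)
  expect_gt(min(f1$v), 0.99 * f1$C)
  expect_lt(f1$trace[length(f1$trace)], 1e-6)
})

test_that("duplicated columns attain the maximal symmetrized weight", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    z <- matrix(runif(200 * 3), 200, 3)
    x <- cbind(z[, 1], z[, 1], z[, 2], z[, 3])
    fit <- autocm_train(x, autocm_config(max_epochs = 2000))
    ws <- (fit$w + t(fit$w)) / 2
    diag(ws) <- -Inf
    hits <- hits + (which.max(ws) %in% c(2L, 5L))
  }
  expect_gte(hits, 19L)
})

test_that("models round-trip through the YAML + CSV bundle", {
  set.seed(21)
  x <- matrix(runif(10 * 4), 10, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  fit <- autocm_train(x, autocm_config(max_epochs = 50))
  dir <- withr::local_tempdir()
  write_autocm(fit, dir)
  back <- read_autocm(dir)
  expect_identical(back$v, fit$v)
  expect_identical(back$w, fit$w)
  expect_identical(back$nodes, fit$nodes)
  expect_equal(back$C, fit$C)
  expect_identical(back$epochs_run, fit$epochs_run)
})
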