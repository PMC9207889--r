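test_that("sojourn dwell means match the reciprocal exit rates", {
  sc <- two_state_scheme(1, 3)
  path <- simulate_path(sc, 10000, seed = 41)
  mo <- mean(path$dwell[path$substate == "O"])
  mc <- mean(path$dwell[path$substate == "C"])
  no <- sum(path$substate == "O")
  nc <- sum(path$substate == "C")
  expect_lt(abs(mo - 1), 3 * 1 / sqrt(no))
  expect_lt(abs(mc - 3), 3 * 3 / sqrt(nc))
})

test_that("simulation is reproducible and leaves the caller's RNG alone", {
  sc <- fixture_scheme("fig1")
  a <- simulate_path(sc, 500, seed = 7)
  b <- simulate_path(sc, 500, seed = 7)
  expect_identical(a, b)

  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_path(sc, 100, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("deterministic single-exit routing alternates exactly", {
  sc <- kinetic_scheme(
    c(O = "O", C = "C"),
    data.frame(from = c("O", "C"), to = c("C", "O"), rate = c(2, 1))
  )
  path <- simulate_path(sc, 50, seed = 3)
  expect_equal(path$substate, rep(c("O", "C"), 25))
})

test_that("per-substate dwell distributions are exponential (KS)", {
  sc <- fixture_scheme("fig1")
  path <- simulate_path(sc, 10000, seed = 13)
  md <- scheme_mean_dwells(sc)
  for (id in c("O3", "C7")) {
    d <- path$dwell[path$substate == id]
    ks <- suppressWarnings(
      stats::ks.test(d, "pexp", rate = 1 / md$mean_dwell[md$id == id])
    )
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("aggregation sums same-class sojourns and conserves total time", {
  sc <- fixture_scheme("fig1")
  path <- tibble::tibble(
    substate = c("O3", "C6", "C7", "O4"),
    dwell = c(2, 3, 9, 1)
  )
  s <- aggregate_path(path, sc)
  expect_equal(s$state, c("O", "C", "O"))
  expect_equal(s$duration[2], 12) # 3 + 9 composite closure

  # already alternating classes: aggregation is the identity
  alt <- tibble::tibble(substate = c("O3", "C6", "O4", "C7"), dwell = 1:4)
  expect_equal(aggregate_path(alt, sc)$duration, as.numeric(1:4))

  # degenerate: one functional class only
  allc <- tibble::tibble(substate = c("C6", "C7", "C5"), dwell = c(1, 2, 3))
  sc3 <- aggregate_path(allc, sc)
  expect_equal(nrow(sc3), 1L)
  expect_equal(sc3$duration, 6)

  long <- simulate_path(sc, 2000, seed = 17)
  expect_equal(sum(aggregate_path(long, sc)$duration), sum(long$dwell))
})

test_that("aggregated composite routes have additive hypoexponential means", {
  # forced O -> Ca -> Cb -> O cycle: every closure visits both closed
  # substates, so the mean observed closed dwell is 3 + 9
  sc <- kinetic_scheme(
    c(O = "O", Ca = "C", Cb = "C"),
    data.frame(
      from = c("O", "Ca", "Cb"), to = c("Ca", "Cb", "O"),
      rate = c(1, 1 / 3, 1 / 9)
    )
  )
  s <- aggregate_path(simulate_path(sc, 15000, seed = 19), sc)
  closed <- s$duration[s$state == "C" & !s$censored]
  se <- sqrt(9 + 81) / sqrt(length(closed)) # sd of Exp(3)+Exp(9)
  expect_lt(abs(mean(closed) - 12), 3 * se)
})

test_that("trace synthesis renders events at the right levels and seeds", {
  s <- dwell_series(c("C", "O"), c(3, 9))
  syn <- synthesize_trace(s, level_C = 0, level_O = 10, noise_sd = 0, dt = 0.1)
  expect_equal(syn$trace$current, rep(c(0, 10), c(30, 90)))
  expect_equal(syn$truth$n_samples, c(30L, 90L))
  expect_equal(syn$truth$onset_sample, c(1L, 31L))

  n1 <- synthesize_trace(s, noise_sd = 2, seed = 5)
  n2 <- synthesize_trace(s, noise_sd = 2, seed = 5)
  expect_identical(n1$trace$current, n2$trace$current)

  expect_warning(
    sub <- synthesize_trace(dwell_series(c("O", "C"), c(0.01, 1)), dt = 0.1),
    "1 sample"
  )
  expect_equal(sub$truth$n_samples, c(1L, 10L))

  # noisy round trip: idealization recovers the quantized event list
  # (Erlang-composite dwells keep every true event well above the dead time)
  sc <- erlang_cycle_scheme(4)
  ser <- aggregate_path(simulate_path(sc, 50, seed = 23), sc)
  noisy <- synthesize_trace(ser, 0, 10, noise_sd = 2, dt = 0.1, seed = 24)
  ideal <- idealize(noisy$trace, 5, min_duration = 0.2)
  expect_equal(ideal$state, noisy$truth$state)
  expect_equal(round(ideal$duration / 0.1), noisy$truth$n_samples,
    ignore_attr = TRUE
  )
})

test_that("fixture schemes encode the documented mean dwells", {
  md <- scheme_mean_dwells(fixture_scheme("fig1"))
  expect_equal(
    md$mean_dwell[match(c("C5", "O3", "O4", "C6", "C7"), md$id)],
    c(5, 1, 3, 3, 9)
  )

  tp <- scheme_mean_dwells(fixture_scheme("two_pathway"))
  expect_equal(
    tp$mean_dwell[match(c("Oa", "Ca", "Ob", "Cb"), tp$id)],
    c(2, 8, 8, 2)
  )

  bk <- fixture_scheme("bk_like")
  expect_equal(sum(bk$substates$class == "O"), 3L)
  expect_equal(sum(bk$substates$class == "C"), 5L)

  expect_error(fixture_scheme("nope"))
})
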