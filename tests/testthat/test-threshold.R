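test_that("single-exponential MLE equals the sample mean and is accepted", {
  x <- withr::with_seed(101, rexp(2000, rate = 1 / 5))
  fit <- fit_exponential_mixture(x, k = 1)
  expect_equal(fit$time_constants, mean(x)) # closed-form MLE
  expect_lt(abs(fit$time_constants - 5) / 5, 0.05)
  expect_true(fit$accepted)
  expect_equal(sum(fit$amplitudes), 1)
})

test_that("a second component adds nothing on pure exponential data", {
  x <- withr::with_seed(102, rexp(2000, rate = 1 / 5))
  f1 <- fit_exponential_mixture(x, k = 1)
  f2 <- fit_exponential_mixture(x, k = 2)
  expect_gte(f2$loglik, f1$loglik) # nesting
  # no significant improvement by the likelihood-ratio yardstick
  expect_lt(2 * (f2$loglik - f1$loglik), stats::qchisq(0.99, df = 2))
  expect_true(f2$degenerate)
})

test_that("a well-separated two-component mixture is recovered", {
  x <- withr::with_seed(103, c(rexp(1000, 1), rexp(1000, 1 / 20)))
  f1 <- fit_exponential_mixture(x, k = 1)
  f2 <- fit_exponential_mixture(x, k = 2)
  expect_false(f1$accepted)
  expect_true(f2$accepted)
  expect_lt(abs(f2$time_constants[1] - 1), 0.15)
  expect_lt(abs(f2$time_constants[2] - 20) / 20, 0.15)
  expect_equal(sum(f2$amplitudes), 1)
  expect_true(all(f2$time_constants > 0))

  td <- tidy(f2)
  expect_equal(nrow(td), 2L)
  expect_equal(td$time_constant, f2$time_constants)
})

test_that("mixture fitting validates its inputs", {
  expect_error(fit_exponential_mixture(rexp(10), 1),
    "20 samples",
    class = "dwellclust_insufficient_data"
  )
  expect_error(fit_exponential_mixture(c(rexp(30), -1), 1),
    "positive",
    class = "dwellclust_error"
  )
})

test_that("log-likelihood nesting holds across random datasets", {
  withr::with_seed(104, {
    for (i in 1:10) {
      x <- rexp(200, rate = runif(1, 0.1, 2))
      f1 <- fit_exponential_mixture(x, 1)
      f2 <- fit_exponential_mixture(x, 2)
      expect_gte(f2$loglik, f1$loglik - 1e-9)
      expect_true(all(f2$time_constants > 0))
      expect_equal(sum(f2$amplitudes), 1)
    }
  })
})

test_that("threshold scoring separates pure-route from mixed-route clusters", {
  pure <- withr::with_seed(105, {
    lapply(1:3, function(i) cbind(rexp(200, 1), rexp(200, 1 / 5), rexp(200, 1)))
  })
  mixed <- withr::with_seed(106, {
    cbind(
      c(rexp(100, 1), rexp(100, 1 / 25)),
      c(rexp(100, 1 / 2), rexp(100, 1 / 40)),
      c(rexp(100, 1), rexp(100, 1 / 25))
    )
  })
  mk <- function(vals, id) {
    tibble::tibble(
      cluster = id, start_state = "O", weight = nrow(vals),
      template = list(colMeans(vals)),
      members = list(seq_len(nrow(vals))), values = list(vals)
    )
  }
  pure_cl <- dplyr::bind_rows(purrr::imap(pure, mk))
  sc_pure <- score_threshold(pure_cl)
  expect_equal(sc_pure$n_single_ok, 3L)
  expect_equal(sc_pure$ratio, 0)

  both <- dplyr::bind_rows(pure_cl, mk(mixed, 4L))
  sc_both <- score_threshold(both)
  expect_equal(sc_both$n_double_needed, 1L)
  expect_equal(sc_both$ratio, 1 / 3)

  none <- score_threshold(pure_cl[0, ])
  expect_false(none$ratio_defined)
  expect_true(is.na(none$ratio))
})

test_that("R0 scan handles degenerate grids and audits the retention rule", {
  sc <- fixture_scheme("two_pathway")
  s <- aggregate_path(simulate_path(sc, 6000, seed = 31), sc)
  s <- as_dwell_series(s[seq_len(1500), ])
  seqs2 <- extract_sequences(s, 3)

  one <- scan_r0(seqs2,
    coarse_grid = 0.9, fine_step = NULL,
    min_cluster_size = 30
  )
  expect_equal(one$optimum, 0.9)
  expect_equal(nrow(one$grid), 1L)

  scan <- scan_r0(seqs2,
    coarse_grid = c(0.80, 0.90, 0.95), fine_step = NULL,
    min_cluster_size = 30
  )
  g <- scan$grid
  # small-data branch: every eligible candidate retains >= 75% of the
  # grid-maximum count of highly occupied clusters
  expect_true(scan$small_data)
  expect_true(all(g$n_large[g$eligible] >= 0.75 * max(g$n_large)))
  expect_true(scan$optimum %in% g$r0)
  # the optimum minimizes the ratio over eligible candidates
  cand <- g[g$eligible & !is.na(g$ratio), ]
  expect_equal(g$ratio[g$r0 == scan$optimum], min(cand$ratio))

  # too few sequences for a trustworthy scan -> warning
  few <- seqs2[seq_len(60), ]
  attr(few, "n") <- 3
  expect_warning(
    tryCatch(
      scan_r0(few, coarse_grid = 0.9, fine_step = NULL, min_cluster_size = 5),
      error = function(e) NULL
    ),
    "unreliable"
  )
})
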