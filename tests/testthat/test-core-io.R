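test_that("dwell series construction enforces alternation and positivity", {
  s <- dwell_series(c("O", "C", "O"), c(2, 3, 5))
  expect_s3_class(s, "dwell_series")
  expect_equal(nrow(s), 3L)
  expect_error(
    dwell_series(c("O", "O"), c(2, 3)),
    "alternate at row 2",
    class = "dwellclust_error"
  )
  expect_error(
    dwell_series(c("O", "C"), c(2, -1)),
    "positive",
    class = "dwellclust_error"
  )
  expect_error(
    dwell_series(c("O", "X"), c(2, 3)),
    "invalid state",
    class = "dwellclust_error"
  )
})

test_that("dwell series round-trips losslessly through CSV at full precision", {
  sc <- two_state_scheme()
  s <- aggregate_path(simulate_path(sc, 10000, seed = 3), sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dwell_series(s, path)
  s2 <- read_dwell_series(path)
  expect_identical(s2$state, s$state)
  expect_identical(s2$duration, s$duration)
  expect_identical(s2$censored, s$censored)
})

test_that("trace reader handles dialects and reports bad rows by line", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "t,I", "0,0.1", "0.1,9.9", "0.2,10.2"), p)
  tr <- read_trace(p)
  expect_equal(trace_dt(tr), 0.1)
  expect_equal(tr$current, c(0.1, 9.9, 10.2))

  p1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.1", "9.9", "10.2"), p1)
  tr1 <- read_trace(p1, dt = 0.05)
  expect_equal(trace_dt(tr1), 0.05)
  expect_equal(tr1$current, c(0.1, 9.9, 10.2))

  pbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.1", "0.1,oops", "0.2,3"), pbad)
  expect_error(read_trace(pbad), "line 2", class = "dwellclust_error")
  expect_error(read_trace("no/such/file.csv"), "not found",
    class = "dwellclust_error"
  )
})

test_that("kinetic schemes round-trip through YAML and reject bad input", {
  sc <- fixture_scheme("fig1")
  p <- withr::local_tempfile(fileext = ".yaml")
  write_kinetic_scheme(sc, p)
  sc2 <- read_kinetic_scheme(p)
  expect_equal(
    dplyr::arrange(sc2$rates, from, to),
    dplyr::arrange(sc$rates, from, to)
  )
  expect_identical(sc2$initial_state, sc$initial_state)
  expect_equal(scheme_mean_dwells(sc2), scheme_mean_dwells(sc))

  expect_error(
    kinetic_scheme(c(A = "O", B = "C"), data.frame(from = "A", to = "B", rate = 1)),
    "absorbing",
    class = "dwellclust_error"
  )
  expect_error(
    kinetic_scheme(
      c(A = "O", B = "C"),
      data.frame(from = c("A", "B"), to = c("B", "Z"), rate = 1)
    ),
    "undeclared",
    class = "dwellclust_error"
  )
})

test_that("cluster reports serialize templates and dispersion faithfully", {
  seqs <- make_sequences(rbind(c(10, 2, 10), c(20, 4, 20), c(1, 5, 1)))
  cl <- refine_clusters(cluster_pass(seqs, 0.9))
  p <- withr::local_tempfile(fileext = ".json")
  write_cluster_report(cl, p)
  rep <- read_cluster_report(p)
  expect_equal(rep$n_clusters, nrow(cl))
  expect_equal(rep$r0, 0.9)
  expect_equal(rep$clusters$template, cl$template, ignore_attr = TRUE)
  expect_equal(rep$clusters$weight, cl$weight)
  expect_equal(rep$clusters$members, cl$members, ignore_attr = TRUE)

  empty <- cluster_pass(make_sequences(matrix(numeric(), 0, 3)), 0.9)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cluster_report(empty, p2)
  rep2 <- read_cluster_report(p2)
  expect_equal(rep2$n_clusters, 0L)
  expect_equal(nrow(rep2$clusters), 0L)
})
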