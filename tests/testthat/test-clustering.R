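test_that("greedy pass reproduces the hand-computed aggregation", {
  # products: 1600, 200, 5 -> scan order (20,4,20), (10,2,10), (1,5,1);
  # the proportional pair correlates at exactly 1 and averages to
  # (15,3,15); the anti-correlated third seeds its own cluster
  seqs <- make_sequences(rbind(c(10, 2, 10), c(20, 4, 20), c(1, 5, 1)))
  cl <- cluster_pass(seqs, 0.9)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$template[[1]], c(15, 3, 15), ignore_attr = TRUE)
  expect_setequal(cl$members[[1]], c(1L, 2L))
  expect_equal(cl$weight, c(2L, 1L))
  expect_equal(cl$template[[2]], c(1, 5, 1), ignore_attr = TRUE)
})

test_that("degenerate inputs: singletons, identical sequences, empty input", {
  one <- cluster_pass(make_sequences(rbind(c(1, 2, 3))), 0.9)
  expect_equal(nrow(one), 1L)
  expect_equal(one$template[[1]], c(1, 2, 3), ignore_attr = TRUE)

  same <- cluster_pass(make_sequences(matrix(rep(c(1, 2, 3), 5),
    ncol = 3, byrow = TRUE
  )), 0.99)
  expect_equal(nrow(same), 1L)
  expect_equal(same$weight, 5L)
  expect_equal(same$template[[1]], c(1, 2, 3), ignore_attr = TRUE)

  empty <- cluster_pass(make_sequences(matrix(numeric(), 0, 3)), 0.9)
  expect_equal(nrow(empty), 0L)

  mixed <- make_sequences(rbind(c(1, 2, 3), c(2, 3, 4)))
  mixed$start_state <- c("O", "C")
  expect_error(cluster_pass(mixed, 0.9), "mixes start states",
    class = "dwellclust_error"
  )
})

test_that("constant sequences are excluded with a warning, not clustered", {
  seqs <- make_sequences(rbind(c(1, 2, 3), c(4, 4, 4), c(2, 4, 6)))
  expect_warning(cl <- cluster_pass(seqs, 0.9), "constant")
  expect_equal(attr(cl, "excluded"), 2L)
  expect_equal(sum(cl$weight), 2L)
})

test_that("refinement of an already-consistent clustering is the identity", {
  seqs <- make_sequences(rbind(c(10, 2, 10), c(20, 4, 20), c(1, 5, 1)))
  cl <- cluster_pass(seqs, 0.9)
  ref <- refine_clusters(cl, 0.9)
  expect_true(attr(ref, "converged"))
  expect_equal(attr(ref, "iterations"), 1L)
  expect_equal(ref$template, cl$template)
  expect_equal(ref$members, cl$members)
})

test_that("refinement displaces drifted members until the audit passes", {
  # sequences chosen so the adaptive pass accepts an early member that the
  # final template no longer supports
  seqs <- random_motif_sequences(200, seed = 23)
  cl <- cluster_pass(seqs, 0.9)
  expect_false(audit_clusters(cl, 0.9)) # the pass alone leaves drift
  ref <- refine_clusters(cl, 0.9)
  expect_true(attr(ref, "converged"))
  expect_true(audit_clusters(ref, 0.9))

  # partition is preserved
  expect_setequal(unlist(ref$members), seqs$origin_index)
  expect_equal(sum(ref$weight), nrow(seqs))

  # idempotence at the fixed point
  ref2 <- refine_clusters(ref, 0.9)
  expect_equal(ref2$members, ref$members)
  expect_equal(ref2$template, ref$template)
})

test_that("templates equal the independently recomputed member means", {
  seqs <- random_motif_sequences(120, seed = 33)
  ref <- refine_clusters(cluster_pass(seqs, 0.9), 0.9)
  m <- as.matrix(seqs[, c("tau1", "tau2", "tau3")])
  for (i in seq_len(nrow(ref))) {
    rows <- match(ref$members[[i]], seqs$origin_index)
    expect_equal(ref$template[[i]], colMeans(m[rows, , drop = FALSE]),
      ignore_attr = TRUE
    )
  }
})

test_that("clustering is deterministic and tightens with rising R0", {
  seqs <- random_motif_sequences(150, seed = 5)
  a <- refine_clusters(cluster_pass(seqs, 0.9), 0.9)
  b <- refine_clusters(cluster_pass(seqs, 0.9), 0.9)
  expect_identical(a$members, b$members)
  expect_identical(a$template, b$template)

  max_card <- vapply(c(0.8, 0.85, 0.9, 0.95, 0.99), function(r0) {
    max(refine_clusters(cluster_pass(seqs, r0), r0)$weight)
  }, numeric(1))
  expect_true(all(diff(max_card) <= 0))
})

test_that("series-level clustering conserves sequences and reports coverage", {
  s <- dwell_series(c("O", "C", "O", "C", "O"), c(2, 3, 5, 1, 4))
  fit <- cluster_dwell_series(s, n = 3, r0 = 0.9)
  expect_equal(sum(fit$clusters$weight), 3L) # 2 O-seqs + 1 C-seq
  expect_equal(fit$diagnostics$n_sequences, c(O = 2L, C = 1L),
    ignore_attr = TRUE
  )

  # R0 = 1 on noisy data: nearly all singletons, coverage by 10+ clusters ~ 0
  sc <- fixture_scheme("two_pathway")
  noisy <- aggregate_path(simulate_path(sc, 600, seed = 2), sc)
  strict <- cluster_dwell_series(noisy, n = 3, r0 = 1)
  expect_gt(mean(strict$clusters$weight == 1L), 0.95)
  expect_lt(strict$coverage, 0.05)

  g <- glance(strict)
  expect_equal(g$n_clusters, nrow(strict$clusters))
  expect_true(all(c("coverage", "converged") %in% names(g)))
})
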