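# Shared fixtures, all generated in code.

# simple two-state scheme with given mean open/closed dwells (ms)
two_state_scheme <- function(mean_open = 1, mean_closed = 3) {
  kinetic_scheme(
    c(O = "O", C = "C"),
    data.frame(
      from = c("O", "C"), to = c("C", "O"),
      rate = c(1 / mean_open, 1 / mean_closed)
    )
  )
}

# cycle of `k` open then `k` closed substates, unit exit rate each, so the
# observed dwells are Erlang(k, mean k ms): low-variance ground truth for
# idealization recovery experiments
erlang_cycle_scheme <- function(k = 4) {
  ids <- c(paste0("O", seq_len(k)), paste0("C", seq_len(k)))
  kinetic_scheme(
    stats::setNames(rep(c("O", "C"), each = k), ids),
    data.frame(from = ids, to = c(ids[-1], ids[1]), rate = 1)
  )
}

# build a sequence tibble directly from a matrix of dwell triples
make_sequences <- function(m, start_state = "O") {
  m <- as.matrix(m)
  colnames(m) <- paste0("tau", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(
      origin_index = seq_len(nrow(m)),
      start_state = start_state
    ),
    tibble::as_tibble(m)
  )
  out$product <- apply(m, 1, prod)
  attr(out, "n") <- ncol(m)
  out
}

# random positive sequences with repeated shape motifs (lognormal noise
# around a few base shapes), deterministic given seed
random_motif_sequences <- function(n_seq, seed, n = 3) {
  withr::with_seed(seed, {
    shapes <- list(c(1, 4, 1), c(5, 1, 5), c(1, 2, 4), c(4, 2, 1))
    m <- t(vapply(seq_len(n_seq), function(i) {
      base <- shapes[[sample.int(length(shapes), 1)]]
      scale <- exp(stats::rnorm(1, 0, 1))
      base * scale * exp(stats::rnorm(n, 0, 0.25))
    }, numeric(n)))
    make_sequences(m)
  })
}

# detected transition onsets (sample index) of an idealized series
detected_onsets <- function(series, dt) {
  cs <- cumsum(round(series$duration / dt))
  cs[-length(cs)] + 1L
}
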