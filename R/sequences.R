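# N-element dwell-time sequences and their cross-correlation.

#' Extract N-element dwell-time sequences from a series
#'
#' Slides a window of `n` consecutive events over the series and records
#' every window that starts from an event of the requested class, giving
#' the overlapping O–C–O–... and C–O–C–... sequences the clustering
#' operates on. Each sequence keeps the index of its first event in the
#' source series (`origin_index`) and the product of its durations, the
#' sort key that lets the search start from the longest observed
#' sequences. Windows touching a censored boundary event are excluded by
#' default since their durations are truncated.
#'
#' @param series A [dwell_series()].
#' @param n Sequence length, >= 2. `n = 2` is degenerate for clustering
#'   (any two 2-element sequences correlate to exactly +-1) and triggers a
#'   warning; the practical choice is 3.
#' @param start_state `"O"`, `"C"` or both (default): which pool(s) of
#'   sequences to extract.
#' @param drop_censored Exclude windows containing a censored event
#'   (default `TRUE`).
#'
#' @return A tibble with columns `origin_index`, `start_state`,
#'   `tau1..tau<n>` and `product`, carrying `n` as an attribute. Empty
#'   (zero-row) when the series is shorter than `n`.
#' @export
#' @examples
#' s <- dwell_series(c("O", "C", "O", "C", "O"), c(2, 3, 5, 1, 4))
#' extract_sequences(s, n = 3, start_state = "O", drop_censored = FALSE)
extract_sequences <- function(series, n = 3, start_state = c("O", "C"),
                              drop_censored = TRUE) {
  stopifnot(inherits(series, "dwell_series"))
  n <- as.integer(n)
  if (n < 2L) {
    abort("`n` must be at least 2", class = "dwellclust_error")
  }
  if (n == 2L) {
    warn(paste0(
      "n = 2 is degenerate: every pair of 2-element sequences has ",
      "cross-correlation +1 or -1, so clustering collapses to rising/",
      "falling pairs"
    ))
  }
  start_state <- match.arg(start_state, c("O", "C"), several.ok = TRUE)
  n_ev <- nrow(series)
  empty <- tibble(
    origin_index = integer(), start_state = character(),
    !!!setNames(
      rep(list(numeric()), n),
      paste0("tau", seq_len(n))
    ),
    product = numeric()
  )
  attr(empty, "n") <- n
  if (n_ev < n) {
    return(empty)
  }
  starts <- seq_len(n_ev - n + 1L)
  starts <- starts[series$state[starts] %in% start_state]
  if (drop_censored) {
    cens <- which(series$censored)
    if (length(cens)) {
      touches <- vapply(
        starts,
        function(i) any(cens >= i & cens <= i + n - 1L), logical(1L)
      )
      starts <- starts[!touches]
    }
  }
  if (!length(starts)) {
    return(empty)
  }
  vals <- vapply(
    starts, function(i) series$duration[i:(i + n - 1L)],
    numeric(n)
  )
  vals <- matrix(vals, ncol = n, byrow = TRUE)
  colnames(vals) <- paste0("tau", seq_len(n))
  out <- dplyr::bind_cols(
    tibble(
      origin_index = as.integer(starts),
      start_state = series$state[starts]
    ),
    as_tibble(vals)
  )
  out$product <- apply(vals, 1L, prod)
  attr(out, "n") <- n
  out
}

#' Sort sequences by decreasing dwell-time product
#'
#' Orders sequences by the decreasing product of their dwell times, so
#' that the search for correlated sequences starts from the longest
#' observed ones (the tails of the broadly overlapping exponential
#' dwell-time distributions). Ties keep ascending origin order.
#'
#' @param sequences A sequence tibble from [extract_sequences()].
#' @return The same tibble, reordered.
#' @export
sort_by_product <- function(sequences) {
  n <- attr(sequences, "n")
  out <- dplyr::arrange(sequences, dplyr::desc(.data$product), .data$origin_index)
  attr(out, "n") <- n
  out
}

#' Cross-correlation between two dwell-time sequences
#'
#' The similarity criterion of the method: the ratio of the covariance of
#' the two sequences to the root product of their variances,
#' `R = sum((X - mean(X)) * (Y - mean(Y))) /
#'    sqrt(sum((X - mean(X))^2) * sum((Y - mean(Y))^2))`.
#' The normalization makes R invariant under positive affine rescaling of
#' either argument, which is what lets sequences that are similar in
#' shape but rescaled in amplitude — the signature of the broad
#' exponential dwell-time distributions — be recognised as realizations
#' of the same substate route.
#'
#' @param x,y Numeric vectors of equal length >= 2 (or single rows of a
#'   sequence tibble), each with nonzero variance.
#' @return The correlation, in `[-1, 1]`.
#' @export
#' @examples
#' cross_correlation(c(1, 2, 3), c(3, 2, 1))
cross_correlation <- function(x, y) {
  x <- .seq_values(x)
  y <- .seq_values(y)
  if (length(x) != length(y)) {
    abort("sequences must have the same length", class = "dwellclust_error")
  }
  if (length(x) < 2L) {
    abort("sequences must have at least 2 elements", class = "dwellclust_error")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0) {
    abort(
      "cross-correlation is undefined for a constant (zero-variance) sequence",
      class = "dwellclust_zero_variance"
    )
  }
  max(-1, min(1, sum(xc * yc) / denom))
}

# coerce a sequence-tibble row (or plain vector) to its duration vector
.seq_values <- function(x) {
  if (is.data.frame(x)) {
    x <- as.numeric(x[1L, grep("^tau", names(x)), drop = TRUE])
  }
  as.numeric(x)
}

# correlation of every row of M against template t; zero-variance rows -> NA
.row_cor <- function(M, t) {
  tc <- t - mean(t)
  t_ss <- sum(tc^2)
  Mc <- M - rowMeans(M)
  ss <- rowSums(Mc^2)
  r <- as.numeric(Mc %*% tc) / sqrt(ss * t_ss)
  r[ss == 0 | t_ss == 0] <- NA_real_
  pmax(-1, pmin(1, r))
}

# matrix of sequence values (rows = sequences) from a sequence tibble
.seq_matrix <- function(sequences) {
  as.matrix(sequences[, grep("^tau", names(sequences)), drop = FALSE])
}
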