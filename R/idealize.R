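# Threshold idealization: current trace -> two-state (O/C) dwell series.

#' Estimate the open/closed discrimination threshold
#'
#' Fits a two-component Gaussian mixture to the amplitude distribution of
#' the trace and returns the equal-posterior crossing between the two
#' fitted modes — the half-amplitude family of threshold rules used in
#' single-channel analysis. Falls back to the midpoint of the two modes
#' when the crossing cannot be located (e.g. noiseless data). If the two
#' modes are not separated well enough to call the histogram bimodal, an
#' error advises setting the threshold manually.
#'
#' @param trace A [current_trace()] with at least 100 samples.
#' @param min_separation Required separation of the modes, as a multiple
#'   of the summed component standard deviations; below it the amplitude
#'   histogram is declared unimodal.
#'
#' @return Threshold current in pA, strictly between the two modes.
#' @export
estimate_threshold <- function(trace, min_separation = 2) {
  x <- trace$current
  if (length(x) < 100L) {
    abort("need at least 100 samples to estimate a threshold",
      class = "dwellclust_error"
    )
  }
  rng <- range(x)
  if (diff(rng) <= 0) {
    abort("cannot separate O/C levels: constant trace; set the threshold manually",
      class = "dwellclust_error"
    )
  }
  # deterministic split at mid-range, then k-means polish of the two modes
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(rng, ncol = 1L)))
  mu <- sort(km$centers[, 1L])
  grp <- x > mean(mu)
  s1 <- sd(x[!grp])
  s2 <- sd(x[grp])
  if (!is.finite(s1)) s1 <- 0
  if (!is.finite(s2)) s2 <- 0
  eps <- diff(rng) * 1e-9
  if (s1 <= eps && s2 <= eps) {
    return(mean(mu)) # noiseless two-level signal: midpoint
  }
  # EM refinement of the two-Gaussian mixture (unequal variances),
  # initialized from the deterministic split above
  z <- cbind(as.numeric(!grp), as.numeric(grp))
  fit <- tryCatch(
    mclust::me(data = x, modelName = "V", z = z),
    error = function(e) NULL
  )
  if (!is.null(fit) && !anyNA(fit$parameters$mean)) {
    ord <- order(fit$parameters$mean)
    mu <- fit$parameters$mean[ord]
    sig <- sqrt(fit$parameters$variance$sigmasq)[ord]
    pro <- fit$parameters$pro[ord]
  } else {
    sig <- c(max(s1, eps), max(s2, eps))
    pro <- c(mean(!grp), mean(grp))
  }
  if (diff(mu) < min_separation * (sig[1L] + sig[2L])) {
    abort(paste0(
      "cannot separate O/C levels: amplitude histogram is not bimodal; ",
      "set the threshold manually"
    ), class = "dwellclust_error")
  }
  post_diff <- function(t) {
    pro[1L] * dnorm(t, mu[1L], sig[1L]) - pro[2L] * dnorm(t, mu[2L], sig[2L])
  }
  thr <- tryCatch(
    uniroot(post_diff, lower = mu[1L], upper = mu[2L])$root,
    error = function(e) mean(mu)
  )
  if (thr <= mu[1L] || thr >= mu[2L]) thr <- mean(mu)
  thr
}

#' Idealize a current trace into a dwell-time series
#'
#' Labels every sample open or closed by comparison with an amplitude
#' threshold and merges runs of same-state samples into dwell events of
#' duration `count * dt`. Events shorter than `min_duration` are treated
#' as noise: each is merged into the preceding event (the first event,
#' having no predecessor, merges into the following one), after which
#' same-state neighbours are re-merged; the rule is applied until no
#' internal event is shorter than `min_duration`. The first and last
#' events are retained but flagged `censored` because their durations are
#' truncated by the recording window. The summed output duration always
#' equals the trace duration.
#'
#' @param trace A [current_trace()].
#' @param threshold Discrimination threshold in pA, or `"auto"` to call
#'   [estimate_threshold()].
#' @param min_duration Minimum event duration in ms; shorter events are
#'   merged away. Default 0 (no filtering — analog low-pass filtering
#'   during acquisition usually makes digital event filtering
#'   unnecessary).
#' @param open_is_above If `TRUE` (default) samples above the threshold
#'   are open; set `FALSE` for inward currents recorded with opposite
#'   polarity.
#'
#' @return A [dwell_series()].
#' @export
#' @examples
#' tr <- current_trace(rep(c(0, 10), c(30, 90)), dt = 0.1)
#' idealize(tr, threshold = 5)
idealize <- function(trace, threshold, min_duration = 0, open_is_above = TRUE) {
  if (identical(threshold, "auto")) {
    threshold <- estimate_threshold(trace)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number (pA) or \"auto\"",
      class = "dwellclust_error"
    )
  }
  if (min_duration < 0) {
    abort("`min_duration` must be >= 0", class = "dwellclust_error")
  }
  dt <- trace_dt(trace)
  above <- trace$current > threshold
  open <- if (open_is_above) above else !above
  r <- rle(open)
  state <- ifelse(r$values, "O", "C")
  duration <- r$lengths * dt
  if (length(state) == 1L) {
    warn("all samples fall on one side of the threshold; single-event series")
  }
  if (min_duration > 0) {
    merged <- .merge_short_events(state, duration, min_duration)
    state <- merged$state
    duration <- merged$duration
  }
  censored <- rep(FALSE, length(state))
  censored[1L] <- TRUE
  censored[length(censored)] <- TRUE
  dwell_series(state, duration, censored)
}

# merge events shorter than min_duration into their preceding neighbour
# (first event into its follower), re-merging same-state runs, until the
# series is stable
.merge_short_events <- function(state, duration, min_duration) {
  repeat {
    if (length(state) <= 1L) break
    short <- which(duration < min_duration)
    if (!length(short)) break
    i <- short[1L]
    if (i == 1L) {
      duration[2L] <- duration[2L] + duration[1L]
      state <- state[-1L]
      duration <- duration[-1L]
    } else {
      duration[i - 1L] <- duration[i - 1L] + duration[i]
      state <- state[-i]
      duration <- duration[-i]
    }
    # re-merge neighbours that now share a state
    r <- rle(state)
    if (any(r$lengths > 1L)) {
      grp <- rep(seq_along(r$lengths), r$lengths)
      duration <- as.numeric(tapply(duration, grp, sum))
      state <- r$values
    }
  }
  list(state = state, duration = duration)
}

#' Open-state probability of a dwell series
#'
#' The fraction of the total recorded time the channel spends open,
#' `p_op = sum(open durations) / sum(all durations)`.
#'
#' @param series A [dwell_series()].
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' open_probability(dwell_series(c("O", "C"), c(3, 9)))
open_probability <- function(series) {
  stopifnot(inherits(series, "dwell_series"))
  sum(series$duration[series$state == "O"]) / sum(series$duration)
}
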