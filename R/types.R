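#' Construct a single-channel current trace
#'
#' A current trace is a tibble with columns `time` (ms) and `current` (pA)
#' carrying the sampling interval `dt` (ms) and free-form metadata (for
#' example the membrane potential) as attributes. The default `dt` of
#' 0.1 ms corresponds to 10 kHz acquisition, the standard sampling rate for
#' single-channel recordings of BK-type channels.
#'
#' @param current Numeric vector of current samples (pA), length >= 2, all
#'   finite.
#' @param dt Sampling interval in ms, strictly positive.
#' @param time Optional numeric vector of sample times (ms); defaults to
#'   `(seq_along(current) - 1) * dt`.
#' @param meta Named list of free-form metadata (e.g. `voltage_mV`).
#'
#' @return A tibble of class `current_trace` with columns `time` and
#'   `current` and attributes `dt` and `meta`.
#' @export
#' @examples
#' tr <- current_trace(c(0, 0, 10, 10, 10), dt = 0.1)
#' trace_dt(tr)
current_trace <- function(current, dt = 0.1, time = NULL, meta = list()) {
  current <- as.numeric(current)
  if (length(current) < 2L) {
    abort("a current trace needs at least 2 samples", class = "dwellclust_error")
  }
  if (!all(is.finite(current))) {
    abort("all current samples must be finite", class = "dwellclust_error")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (ms)", class = "dwellclust_error")
  }
  if (is.null(time)) {
    time <- (seq_along(current) - 1) * dt
  }
  out <- tibble(time = as.numeric(time), current = current)
  attr(out, "dt") <- dt
  attr(out, "meta") <- meta
  class(out) <- c("current_trace", class(out))
  out
}

#' @rdname current_trace
#' @param trace A `current_trace`.
#' @export
trace_dt <- function(trace) {
  dt <- attr(trace, "dt")
  if (is.null(dt)) {
    abort("object has no `dt` attribute; is it a current_trace?",
      class = "dwellclust_error"
    )
  }
  dt
}

#' Construct a dwell-time series
#'
#' A dwell-time series is the idealized representation of single-channel
#' activity: an ordered table of sojourns in the functionally discernible
#' open (`"O"`) and closed (`"C"`) states. States must strictly alternate
#' and every duration must be positive; violations are reported, never
#' silently repaired. The first and last events of an idealized record are
#' usually flagged `censored` because their true durations are cut off by
#' the recording window.
#'
#' @param state Character vector of states, each `"O"` or `"C"`.
#' @param duration Numeric vector of dwell times (ms), all > 0.
#' @param censored Logical vector marking boundary events with truncated
#'   durations; defaults to all `FALSE`.
#'
#' @return A tibble of class `dwell_series` with columns `state`,
#'   `duration`, `censored`.
#' @export
#' @examples
#' dwell_series(c("O", "C", "O"), c(2, 3, 5))
dwell_series <- function(state, duration, censored = NULL) {
  state <- as.character(state)
  duration <- as.numeric(duration)
  if (length(state) != length(duration)) {
    abort("`state` and `duration` must have the same length",
      class = "dwellclust_error"
    )
  }
  if (length(state) == 0L) {
    abort("a dwell series must contain at least one event",
      class = "dwellclust_error"
    )
  }
  bad_state <- which(!state %in% c("O", "C"))
  if (length(bad_state)) {
    abort(sprintf(
      "invalid state %s at row %d (must be \"O\" or \"C\")",
      dQuote(state[bad_state[1L]]), bad_state[1L]
    ), class = "dwellclust_error")
  }
  bad_dur <- which(!is.finite(duration) | duration <= 0)
  if (length(bad_dur)) {
    abort(sprintf(
      "durations must be positive and finite; offending row %d (value %s)",
      bad_dur[1L], format(duration[bad_dur[1L]])
    ), class = "dwellclust_error")
  }
  if (length(state) > 1L) {
    same <- which(state[-1L] == state[-length(state)])
    if (length(same)) {
      abort(sprintf("states must alternate at row %d", same[1L] + 1L),
        class = "dwellclust_error"
      )
    }
  }
  if (is.null(censored)) {
    censored <- rep(FALSE, length(state))
  }
  out <- tibble(
    state = state, duration = duration,
    censored = as.logical(censored)
  )
  class(out) <- c("dwell_series", class(out))
  out
}

#' @rdname dwell_series
#' @param x A data frame with columns `state`, `duration` and optionally
#'   `censored`.
#' @export
as_dwell_series <- function(x) {
  if (!all(c("state", "duration") %in% names(x))) {
    abort("need columns `state` and `duration`", class = "dwellclust_error")
  }
  dwell_series(x$state, x$duration, x$censored)
}

#' Define an aggregated-Markov kinetic scheme
#'
#' A kinetic scheme lists the channel's conformational substates, each
#' assigned to a functional class (open `"O"` or closed `"C"`), and the
#' first-order rate constants k_ij (ms^-1) of the allowed transitions.
#' The mean dwell time of substate i is `1 / sum_j k_ij`. Because the
#' recording only resolves the functional class, consecutive sojourns in
#' same-class substates merge into one observed dwell (see
#' [aggregate_path()]).
#'
#' @param substates Named character vector mapping substate id to class,
#'   e.g. `c(O1 = "O", C2 = "C")`, or a data frame with columns `id`,
#'   `class`.
#' @param rates Data frame with columns `from`, `to`, `rate` (ms^-1), or a
#'   named list of named numeric vectors `list(O1 = c(C2 = 1))`.
#' @param initial_state Substate id the simulated chain starts from;
#'   defaults to the first substate.
#'
#' @return An object of class `kinetic_scheme`.
#' @seealso [fixture_scheme()] for ready-made example schemes,
#'   [simulate_path()] for simulation.
#' @export
#' @examples
#' sc <- kinetic_scheme(
#'   c(O1 = "O", C2 = "C"),
#'   data.frame(from = c("O1", "C2"), to = c("C2", "O1"), rate = c(1, 1 / 3))
#' )
#' scheme_mean_dwells(sc)
kinetic_scheme <- function(substates, rates, initial_state = NULL) {
  if (is.data.frame(substates)) {
    sub <- tibble(id = as.character(substates$id), class = as.character(substates$class))
  } else {
    sub <- tibble(id = names(substates), class = as.character(unname(substates)))
  }
  if (is.null(sub$id) || any(!nzchar(sub$id))) {
    abort("every substate needs an id", class = "dwellclust_error")
  }
  if (anyDuplicated(sub$id)) {
    abort("duplicated substate ids", class = "dwellclust_error")
  }
  if (!all(sub$class %in% c("O", "C"))) {
    abort("substate classes must be \"O\" or \"C\"", class = "dwellclust_error")
  }
  if (is.data.frame(rates)) {
    rt <- tibble(
      from = as.character(rates$from), to = as.character(rates$to),
      rate = as.numeric(rates$rate)
    )
  } else {
    rt <- purrr::imap_dfr(rates, function(v, from) {
      tibble(from = from, to = names(v), rate = as.numeric(v))
    })
  }
  unknown <- setdiff(unique(c(rt$from, rt$to)), sub$id)
  if (length(unknown)) {
    abort(sprintf(
      "rates reference undeclared substate(s): %s",
      paste(unknown, collapse = ", ")
    ), class = "dwellclust_error")
  }
  if (any(!is.finite(rt$rate) | rt$rate < 0)) {
    abort("rate constants must be finite and >= 0", class = "dwellclust_error")
  }
  if (any(rt$from == rt$to)) {
    abort("self-transitions (i -> i) are not allowed", class = "dwellclust_error")
  }
  rt <- rt[rt$rate > 0, , drop = FALSE]
  exit <- tapply(rt$rate, factor(rt$from, levels = sub$id), sum)
  dead <- sub$id[is.na(exit) | exit <= 0]
  if (length(dead)) {
    abort(sprintf(
      "substate(s) with no exit rate (absorbing): %s",
      paste(dead, collapse = ", ")
    ), class = "dwellclust_error")
  }
  initial_state <- initial_state %||% sub$id[1L]
  if (!initial_state %in% sub$id) {
    abort(sprintf("unknown initial_state %s", dQuote(initial_state)),
      class = "dwellclust_error"
    )
  }
  structure(
    list(substates = sub, rates = rt, initial_state = initial_state),
    class = "kinetic_scheme"
  )
}

#' @rdname kinetic_scheme
#' @param scheme A `kinetic_scheme`.
#' @return `scheme_mean_dwells()` returns a tibble with columns `id`,
#'   `class`, `mean_dwell` (ms, the reciprocal total exit rate).
#' @export
scheme_mean_dwells <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  exit <- tapply(
    scheme$rates$rate,
    factor(scheme$rates$from, levels = scheme$substates$id), sum
  )
  tibble(
    id = scheme$substates$id,
    class = scheme$substates$class,
    mean_dwell = 1 / as.numeric(exit)
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  md <- scheme_mean_dwells(x)
  cat(sprintf(
    "<kinetic_scheme> %d substates (%d open, %d closed), %d transitions\n",
    nrow(x$substates), sum(x$substates$class == "O"),
    sum(x$substates$class == "C"), nrow(x$rates)
  ))
  cat(sprintf("initial state: %s\n", x$initial_state))
  cat("mean dwell times (ms):\n")
  cat(sprintf("  %s [%s]: %.4g\n", md$id, md$class, md$mean_dwell), sep = "")
  invisible(x)
}
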