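# Aggregated-Markov gating simulator: continuous-time Markov chain over
# conformational substates, observed only through the open/closed class
# of each substate.

#' Simulate a substate path from a kinetic scheme
#'
#' Continuous-time Markov chain simulation: from substate i the chain
#' dwells an Exponential time with mean `1 / sum_j k_ij`, then jumps to
#' substate j with probability `k_ij / sum_j k_ij`. Every simulation is
#' reproducible given `seed`; the caller's RNG state is left untouched.
#'
#' @param scheme A [kinetic_scheme()].
#' @param n_sojourns Number of substate sojourns to draw, >= 1.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#'
#' @return A tibble with columns `substate` and `dwell` (ms), one row per
#'   sojourn.
#' @export
#' @examples
#' sc <- fixture_scheme("fig1")
#' simulate_path(sc, 5, seed = 1)
simulate_path <- function(scheme, n_sojourns, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n_sojourns <- as.integer(n_sojourns)
  if (n_sojourns < 1L) {
    abort("`n_sojourns` must be >= 1", class = "dwellclust_error")
  }
  ids <- scheme$substates$id
  by_from <- split(scheme$rates, factor(scheme$rates$from, levels = ids))
  exit <- vapply(by_from, function(d) sum(d$rate), numeric(1L))
  targets <- lapply(by_from, function(d) match(d$to, ids))
  probs <- lapply(by_from, function(d) d$rate / sum(d$rate))
  if (any(!is.finite(exit) | exit <= 0)) {
    dead <- ids[!is.finite(exit) | exit <= 0]
    abort(sprintf(
      "absorbing substate reached: %s", paste(dead, collapse = ", ")
    ), class = "dwellclust_error")
  }
  with_seed(seed, {
    state <- match(scheme$initial_state, ids)
    out_state <- integer(n_sojourns)
    out_dwell <- numeric(n_sojourns)
    u_dwell <- rexp(n_sojourns) # unit-rate draws, rescaled per state
    for (i in seq_len(n_sojourns)) {
      out_state[i] <- state
      out_dwell[i] <- u_dwell[i] / exit[state]
      p <- probs[[state]]
      state <- if (length(p) == 1L) {
        targets[[state]][1L]
      } else {
        targets[[state]][sample.int(length(p), 1L, prob = p)]
      }
    }
    tibble(substate = ids[out_state], dwell = out_dwell)
  })
}

#' Aggregate a substate path to the observable dwell series
#'
#' The recording resolves only the functional class of each substate, so
#' consecutive sojourns in same-class substates merge into a single
#' observed dwell whose duration is their sum — e.g. a closed substate
#' lasting 3 time units followed by another closed substate lasting 9
#' is observed as one closed dwell of 12. The result strictly
#' alternates open and closed. The final event is flagged censored: had
#' the simulation continued, further same-class sojourns could have
#' extended it.
#'
#' @param path A tibble from [simulate_path()].
#' @param scheme The [kinetic_scheme()] the path was drawn from.
#' @return A [dwell_series()].
#' @export
aggregate_path <- function(path, scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (nrow(path) == 0L) {
    abort("empty path", class = "dwellclust_error")
  }
  cls <- scheme$substates$class[match(path$substate, scheme$substates$id)]
  if (anyNA(cls)) {
    abort("path contains substates not in the scheme", class = "dwellclust_error")
  }
  r <- rle(cls)
  grp <- rep(seq_along(r$lengths), r$lengths)
  duration <- as.numeric(tapply(path$dwell, grp, sum))
  censored <- rep(FALSE, length(r$values))
  censored[length(censored)] <- TRUE
  dwell_series(r$values, duration, censored)
}

#' Synthesize a noisy current trace from a dwell series
#'
#' Renders each dwell event as `round(duration / dt)` samples (at least
#' 1, with a warning for sub-sample events) at the conductance level of
#' its class, adds i.i.d. Gaussian noise, and returns both the trace and
#' the quantized ground-truth event list for recovery experiments. The
#' default `dt` of 0.1 ms matches 10 kHz sampling.
#'
#' @param series A [dwell_series()].
#' @param level_C,level_O Closed and open current levels (pA).
#' @param noise_sd Gaussian noise standard deviation (pA), >= 0.
#' @param dt Sampling interval (ms).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   stream.
#'
#' @return A list with elements `trace` (a [current_trace()]) and
#'   `truth` (tibble: `state`, `n_samples`, `onset_sample` — the 1-based
#'   first sample of each event).
#' @export
synthesize_trace <- function(series, level_C = 0, level_O = 10,
                             noise_sd = 0, dt = 0.1, seed = NULL) {
  stopifnot(inherits(series, "dwell_series"))
  if (dt <= 0) {
    abort("`dt` must be > 0", class = "dwellclust_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "dwellclust_error")
  }
  n_samp <- round(series$duration / dt)
  if (any(n_samp < 1L)) {
    warn(sprintf(
      "%d event(s) shorter than dt rendered as 1 sample", sum(n_samp < 1L)
    ))
    n_samp <- pmax(n_samp, 1L)
  }
  level <- ifelse(series$state == "O", level_O, level_C)
  samples <- rep(level, n_samp)
  samples <- with_seed(seed, {
    samples + if (noise_sd > 0) stats::rnorm(length(samples), 0, noise_sd) else 0
  })
  truth <- tibble(
    state = series$state,
    n_samples = as.integer(n_samp),
    onset_sample = c(1L, head(cumsum(n_samp), -1L) + 1L)
  )
  list(
    trace = current_trace(samples, dt = dt,
      meta = list(level_C = level_C, level_O = level_O, noise_sd = noise_sd)
    ),
    truth = truth
  )
}

#' Ready-made kinetic schemes
#'
#' Three example schemes used throughout the package's tests and
#' documentation:
#'
#' * `"fig1"` — a 5-substate toy scheme (C5, O3, O4, C6, C7 with mean
#'   dwells 5, 1, 3, 3 and 9 time units). The routing probabilities make
#'   the O3 -> O4 opening (observed as one open dwell of 1 + 3 = 4) and
#'   the C6 -> C7 closure (observed as one closed dwell of 3 + 9 = 12)
#'   the modal paths (probability 0.9 at each branch point), so the
#'   composite dwells dominate the aggregated record.
#' * `"two_pathway"` — two O/C loops, one with mean open 2 ms and mean
#'   closed 8 ms, the other with mean open 8 ms and mean closed 2 ms,
#'   weakly coupled (2% switch probability per closed exit). The two
#'   loops produce O-C-O mean triples (2, 8, 2) and (8, 2, 8) whose
#'   shapes are perfectly anti-correlated, so the cross-correlation
#'   criterion can never merge their mean shapes; a recovery benchmark
#'   for the clustering.
#' * `"bk_like"` — 3 open and 5 closed substates in a connected ladder
#'   with mean dwells spanning 0.5 to 40 ms, qualitatively mimicking
#'   BK-channel gating at fixed voltage and calcium.
#'
#' @param name One of `"fig1"`, `"two_pathway"`, `"bk_like"`.
#' @return A [kinetic_scheme()].
#' @export
#' @examples
#' scheme_mean_dwells(fixture_scheme("fig1"))
fixture_scheme <- function(name = c("fig1", "two_pathway", "bk_like")) {
  name <- match.arg(name)
  switch(name,
    fig1 = kinetic_scheme(
      substates = c(C5 = "C", O3 = "O", O4 = "O", C6 = "C", C7 = "C"),
      rates = tibble(
        from = c("C5", "O3", "O3", "O4", "O4", "C6", "C6", "C7", "C7"),
        to = c("O3", "O4", "C6", "C6", "C5", "C7", "O3", "O3", "C5"),
        rate = c(
          0.2, # C5 -> O3 (mean dwell 5)
          0.9, 0.1, # O3: mean 1, 90% to O4
          0.3, 1 / 30, # O4: mean 3, 90% to C6
          0.3, 1 / 30, # C6: mean 3, 90% to C7
          0.1, 1 / 90 # C7: mean 9, 90% to O3
        )
      ),
      initial_state = "O3"
    ),
    two_pathway = kinetic_scheme(
      substates = c(Oa = "O", Ca = "C", Ob = "O", Cb = "C"),
      rates = tibble(
        from = c("Oa", "Ca", "Ca", "Ob", "Cb", "Cb"),
        to = c("Ca", "Oa", "Ob", "Cb", "Ob", "Oa"),
        rate = c(
          0.5, # Oa: mean 2 ms
          0.1225, 0.0025, # Ca: mean 8 ms, 2% leak to loop b
          0.125, # Ob: mean 8 ms
          0.49, 0.01 # Cb: mean 2 ms, 2% leak to loop a
        )
      ),
      initial_state = "Oa"
    ),
    bk_like = kinetic_scheme(
      substates = c(
        O1 = "O", O2 = "O", O3 = "O",
        C4 = "C", C5 = "C", C6 = "C", C7 = "C", C8 = "C"
      ),
      rates = tibble(
        from = c(
          "O1", "O1", "O2", "O2", "O2", "O3", "O3",
          "C4", "C4", "C5", "C5", "C5", "C6", "C6", "C6",
          "C7", "C7", "C8"
        ),
        to = c(
          "C4", "O2", "O1", "O3", "C5", "O2", "C6",
          "O1", "C5", "C4", "O2", "C6", "C5", "O3", "C7",
          "C6", "C8", "C7"
        ),
        rate = c(
          0.6, 0.4, # O1: mean 1 ms
          0.075, 0.075, 0.1, # O2: mean 4 ms
          0.05, 0.05, # O3: mean 10 ms
          1.4, 0.6, # C4: mean 0.5 ms
          0.15, 0.2, 0.15, # C5: mean 2 ms
          0.08, 0.06, 0.06, # C6: mean 5 ms
          1 / 15 * 0.7, 1 / 15 * 0.3, # C7: mean 15 ms
          0.025 # C8: mean 40 ms
        )
      ),
      initial_state = "O1"
    )
  )
}

#' True mean O-C-O / C-O-C triples of the two-pathway fixture
#'
#' The ground truth for recovery experiments: the mean dwell-time
#' triples generated by each loop of the `"two_pathway"` scheme, for the
#' requested start state.
#'
#' @param start_state `"O"` or `"C"`.
#' @return A 2 x 3 matrix, one row per pathway.
#' @export
two_pathway_truth <- function(start_state = c("O", "C")) {
  start_state <- match.arg(start_state)
  if (start_state == "O") {
    rbind(a = c(2, 8, 2), b = c(8, 2, 8))
  } else {
    rbind(a = c(8, 2, 8), b = c(2, 8, 2))
  }
}
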