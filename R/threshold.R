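# Selection of the correlation threshold R0: clusters obtained at each
# candidate R0 are scored by whether the dwell-time distribution along
# every coordinate of a cluster is mono-exponential (one transition
# route) or needs a double exponential (a mixture of routes); the
# optimal R0 minimizes the double/single ratio.

#' Fit a mixture of exponentials to dwell-time samples
#'
#' Maximum-likelihood fit of a k-component exponential mixture by
#' expectation-maximization with deterministic moment-based
#' initialization (time constants start at a geometric spread around the
#' sample mean, `{mean/2, 2 mean}` for k = 2; amplitudes start equal), so
#' repeated fits of the same data are identical. For k = 1 the MLE is the
#' sample mean in closed form.
#'
#' Goodness of fit is a Pearson chi-square on log-spaced histogram bins
#' (adjacent bins merged until every expected count is at least 5,
#' Poisson errors), with `length(bins) - 1 - (2k - 1)` degrees of
#' freedom. The fit is `accepted` when the curve agrees with the data
#' within that uncertainty, i.e. p >= `gof_level`.
#'
#' @param x Positive dwell-time samples (ms), at least 20.
#' @param k Number of exponential components, >= 1.
#' @param gof_level Acceptance level for the chi-square p-value
#'   (default 0.05).
#' @param tol Relative log-likelihood convergence tolerance for EM.
#' @param max_iter EM iteration cap.
#'
#' @return An object of class `exp_mixture_fit` with elements `k`,
#'   `amplitudes` (summing to 1), `time_constants` (ms), `loglik`,
#'   `gof_statistic`, `gof_df`, `gof_pvalue`, `accepted`, `degenerate`
#'   (time-constant collision or vanishing amplitude), `converged`, `n`.
#'   Supports [tidy()] and [glance()].
#' @export
#' @examples
#' x <- rexp(500, rate = 1 / 5)
#' fit <- fit_exponential_mixture(x, k = 1)
#' glance(fit)
fit_exponential_mixture <- function(x, k = 1, gof_level = 0.05,
                                    tol = 1e-8, max_iter = 500) {
  x <- as.numeric(x)
  if (length(x) < 20L) {
    abort("need at least 20 samples to fit an exponential mixture",
      class = "dwellclust_insufficient_data"
    )
  }
  if (any(!is.finite(x) | x <= 0)) {
    abort("all samples must be positive and finite", class = "dwellclust_error")
  }
  k <- as.integer(k)
  if (k < 1L) {
    abort("`k` must be >= 1", class = "dwellclust_error")
  }
  n <- length(x)
  m <- mean(x)
  converged <- TRUE
  iterations <- 0L
  if (k == 1L) {
    amp <- 1
    tau <- m
    loglik <- sum(dexp(x, rate = 1 / m, log = TRUE))
  } else {
    tau <- m * 2^seq(-1, 1, length.out = k)
    amp <- rep(1 / k, k)
    loglik <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) amp[j] / tau[j] * exp(-x / tau[j]), numeric(n))
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      resp <- dens / tot
      amp <- colMeans(resp)
      tau <- colSums(resp * x) / pmax(colSums(resp), .Machine$double.eps)
      tau[!is.finite(tau) | tau <= 0] <- m
      iterations <- it
      if (is.finite(loglik) && abs(ll - loglik) <= tol * (abs(loglik) + tol)) {
        loglik <- ll
        converged <- TRUE
        break
      }
      loglik <- ll
    }
    mix_ll <- function(amp, tau) {
      sum(log(pmax(
        rowSums(vapply(
          seq_along(tau),
          function(j) amp[j] / tau[j] * exp(-x / tau[j]), numeric(n)
        )),
        .Machine$double.xmin
      )))
    }
    loglik <- mix_ll(amp, tau)
    # the k-component family nests k = 1; if EM stalled below the single-
    # exponential optimum, collapse onto it (equal time constants)
    ll1 <- sum(dexp(x, rate = 1 / m, log = TRUE))
    if (loglik < ll1) {
      amp <- rep(1 / k, k)
      tau <- rep(m, k)
      loglik <- ll1
    }
  }
  ord <- order(tau)
  tau <- tau[ord]
  amp <- amp[ord]
  # exponential components closer than ~1.5-fold in time constant are not
  # practically identifiable from dwell-time data; flag the collision
  degenerate <- k > 1L &&
    (any(amp < 1e-3) || any(tau[-1L] / tau[-k] < 1.5))
  cdf <- function(q) {
    mat <- matrix(
      vapply(q, function(qi) pexp(qi, rate = 1 / tau), numeric(k)),
      nrow = k
    )
    as.numeric(amp %*% mat)
  }
  gof <- .gof_chisq(x, cdf, n_params = 2L * k - 1L)
  structure(list(
    k = k, amplitudes = amp, time_constants = tau,
    loglik = loglik, n = n,
    gof_statistic = gof$statistic, gof_df = gof$df,
    gof_pvalue = gof$pvalue, gof_bins = gof$bins,
    accepted = !is.na(gof$pvalue) && gof$pvalue >= gof_level,
    gof_level = gof_level,
    degenerate = degenerate, converged = converged,
    iterations = iterations
  ), class = "exp_mixture_fit")
}

# Pearson chi-square GOF on log-spaced bins with >= 5 expected counts
.gof_chisq <- function(x, cdf, n_params, min_expected = 5) {
  n <- length(x)
  nb <- max(6L, min(40L, ceiling(2 * n^0.4)))
  lo <- min(x)
  hi <- max(x)
  inner <- exp(seq(log(lo), log(hi), length.out = nb + 1L))
  breaks <- unique(c(0, inner[-c(1L, length(inner))], Inf))
  obs <- as.numeric(table(cut(x, breaks, right = TRUE)))
  expd <- n * diff(cdf(breaks))
  # merge adjacent bins left to right until expected counts reach the floor
  i <- 1L
  while (i <= length(expd)) {
    if (expd[i] < min_expected && length(expd) > 1L) {
      j <- if (i < length(expd)) i + 1L else i - 1L
      k0 <- min(i, j)
      expd[k0] <- expd[i] + expd[j]
      obs[k0] <- obs[i] + obs[j]
      expd <- expd[-max(i, j)]
      obs <- obs[-max(i, j)]
    } else {
      i <- i + 1L
    }
  }
  df <- length(obs) - 1L - n_params
  if (df < 1L || length(obs) < 2L) {
    return(list(statistic = NA_real_, df = df, pvalue = NA_real_, bins = length(obs)))
  }
  stat <- sum((obs - expd)^2 / expd)
  list(
    statistic = stat, df = df,
    pvalue = pchisq(stat, df, lower.tail = FALSE),
    bins = length(obs)
  )
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_mixture_fit> k = %d, n = %d, logLik = %.2f, %s\n",
    x$k, x$n, x$loglik,
    if (isTRUE(x$accepted)) "accepted" else "rejected"
  ))
  cat(sprintf(
    "  component %d: amplitude %.3f, tau = %.4g ms\n",
    seq_len(x$k), x$amplitudes, x$time_constants
  ), sep = "")
  if (!is.na(x$gof_pvalue)) {
    cat(sprintf(
      "  chi-square %.2f on %d df, p = %.3g\n",
      x$gof_statistic, x$gof_df, x$gof_pvalue
    ))
  }
  invisible(x)
}

#' @rdname fit_exponential_mixture
#' @param x,object An `exp_mixture_fit`.
#' @param ... Unused.
#' @method tidy exp_mixture_fit
#' @export
tidy.exp_mixture_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$k),
    amplitude = x$amplitudes,
    time_constant = x$time_constants
  )
}

#' @rdname fit_exponential_mixture
#' @method glance exp_mixture_fit
#' @export
glance.exp_mixture_fit <- function(x, ...) {
  tibble(
    k = x$k, n = x$n, logLik = x$loglik,
    gof_statistic = x$gof_statistic, gof_df = x$gof_df,
    gof_pvalue = x$gof_pvalue, accepted = x$accepted,
    degenerate = x$degenerate, converged = x$converged
  )
}

#' Score a clustering by mono- vs. double-exponential fits
#'
#' For every cluster with more than `min_cluster_size` members, fits
#' single (k = 1) and double (k = 2) exponential mixtures to the
#' members' dwell-time distribution along each of the N coordinate
#' dimensions. A cluster counts as *single-ok* when the
#' single-exponential fit is accepted in all N dimensions — the
#' signature of a unique transition route — and as *double-needed*
#' otherwise. The score of the clustering is the ratio
#' `n_double_needed / n_single_ok`.
#'
#' @param clusters A refined cluster tibble (or `dwell_cluster_fit`).
#' @param min_cluster_size Only clusters with more members than this are
#'   scored (default 50).
#' @param gof_level Acceptance level passed to
#'   [fit_exponential_mixture()].
#'
#' @return A one-row tibble: `n_large`, `n_single_ok`,
#'   `n_double_needed`, `ratio` (NA with `ratio_defined = FALSE` when no
#'   cluster is large enough or no cluster is single-ok).
#' @export
score_threshold <- function(clusters, min_cluster_size = 50, gof_level = 0.05) {
  if (inherits(clusters, "dwell_cluster_fit")) {
    clusters <- clusters$clusters
  }
  big <- which(clusters$weight > min_cluster_size & clusters$weight >= 20L)
  n_single <- 0L
  n_double <- 0L
  for (i in big) {
    vals <- clusters$values[[i]]
    single_ok <- TRUE
    for (d in seq_len(ncol(vals))) {
      f1 <- fit_exponential_mixture(vals[, d], k = 1, gof_level = gof_level)
      if (!f1$accepted) {
        single_ok <- FALSE
        break
      }
    }
    if (single_ok) n_single <- n_single + 1L else n_double <- n_double + 1L
  }
  ratio_defined <- length(big) > 0L && n_single > 0L
  tibble(
    n_large = length(big),
    n_single_ok = n_single,
    n_double_needed = n_double,
    ratio = if (ratio_defined) n_double / n_single else NA_real_,
    ratio_defined = ratio_defined
  )
}

#' Screen correlation thresholds and pick the optimum
#'
#' Clusters and refines the sequences at every R0 of a coarse grid
#' (default 0.80 to 0.97 in steps of 0.05, both endpoints included),
#' scores each clustering with [score_threshold()], then fine-tunes with
#' step `fine_step` between the neighbours of the coarse minimum. The
#' optimal R0 is the candidate whose double/single exponential-fit ratio
#' is minimal (ties resolved towards the larger, stricter R0).
#'
#' With limited data (fewer than `small_data_n` sequences), high R0
#' values fragment the data into poorly occupied clusters; candidates
#' are then restricted to those retaining at least `retention` (75%) of
#' the maximum-over-grid number of highly occupied clusters (those with
#' at least `min_cluster_size` representatives).
#'
#' @param sequences A sequence tibble from [extract_sequences()]; both
#'   start-state pools may be present and are clustered separately at
#'   each R0.
#' @param coarse_grid Coarse R0 grid.
#' @param fine_step Fine grid step; `NULL` or 0 disables fine-tuning.
#' @param min_cluster_size Occupancy floor used both for scoring and the
#'   retention rule (default 50).
#' @param gof_level Acceptance level for the exponential fits.
#' @param small_data_n Sequence count below which the retention rule
#'   applies (default 6000).
#' @param retention Retention fraction of the small-data rule.
#' @param max_iter Refinement sweep cap per clustering.
#'
#' @return An object of class `r0_scan`: list with `grid` (one row per
#'   screened R0: `r0`, `n_clusters`, `n_large`, `n_single_ok`,
#'   `n_double_needed`, `ratio`, `eligible`), `optimum`, and the scan
#'   parameters. Supports [tidy()], [glance()] and [autoplot()].
#' @export
scan_r0 <- function(sequences,
                    coarse_grid = c(0.80, 0.85, 0.90, 0.95, 0.97),
                    fine_step = 0.01,
                    min_cluster_size = 50,
                    gof_level = 0.05,
                    small_data_n = 6000,
                    retention = 0.75,
                    max_iter = 100) {
  n_seq <- nrow(sequences)
  if (n_seq < 100L) {
    warn(sprintf(
      "only %d sequences; the R0 scan is unreliable below 100", n_seq
    ))
  }
  n <- attr(sequences, "n") %||% length(grep("^tau", names(sequences)))
  pools <- split(sequences, sequences$start_state)
  eval_one <- function(r0) {
    cl <- dplyr::bind_rows(lapply(pools, function(p) {
      attr(p, "n") <- n
      suppressWarnings(
        refine_clusters(cluster_pass(p, r0), r0 = r0, max_iter = max_iter)
      )
    }))
    sc <- score_threshold(cl, min_cluster_size = min_cluster_size, gof_level = gof_level)
    tibble(
      r0 = r0,
      n_clusters = nrow(cl),
      n_large = sum(cl$weight >= min_cluster_size),
      n_single_ok = sc$n_single_ok,
      n_double_needed = sc$n_double_needed,
      ratio = sc$ratio
    )
  }
  coarse_grid <- sort(unique(coarse_grid))
  grid <- purrr::map_dfr(coarse_grid, eval_one)
  mark_eligible <- function(g) {
    if (n_seq < small_data_n && any(g$n_large > 0)) {
      g$eligible <- g$n_large >= retention * max(g$n_large)
    } else {
      g$eligible <- TRUE
    }
    g
  }
  pick_opt <- function(g) {
    cand <- which(g$eligible & !is.na(g$ratio))
    if (!length(cand)) {
      return(NA_real_)
    }
    best <- cand[g$ratio[cand] == min(g$ratio[cand])]
    g$r0[max(best)] # ties -> stricter threshold
  }
  grid <- mark_eligible(grid)
  coarse_opt <- pick_opt(grid)
  if (!is.null(fine_step) && fine_step > 0 && !is.na(coarse_opt) &&
    length(coarse_grid) > 1L) {
    i <- which(coarse_grid == coarse_opt)
    lo <- coarse_grid[max(1L, i - 1L)]
    hi <- coarse_grid[min(length(coarse_grid), i + 1L)]
    fine <- setdiff(round(seq(lo, hi, by = fine_step), 10), grid$r0)
    if (length(fine)) {
      grid <- dplyr::bind_rows(grid[, setdiff(names(grid), "eligible")],
        purrr::map_dfr(fine, eval_one)
      )
      grid <- dplyr::arrange(grid, .data$r0)
      grid <- mark_eligible(grid)
    }
  }
  optimum <- pick_opt(grid)
  if (is.na(optimum)) {
    abort(paste0(
      "no candidate R0 has a defined double/single ratio; ",
      "too few large clusters - choose R0 manually"
    ), class = "dwellclust_error")
  }
  structure(list(
    grid = grid,
    optimum = optimum,
    n_sequences = n_seq,
    min_cluster_size = min_cluster_size,
    small_data = n_seq < small_data_n,
    retention = retention
  ), class = "r0_scan")
}

#' @export
print.r0_scan <- function(x, ...) {
  cat(sprintf(
    "<r0_scan> %d candidate thresholds, %d sequences%s\n",
    nrow(x$grid), x$n_sequences,
    if (x$small_data) " (small-data retention rule active)" else ""
  ))
  cat(sprintf("optimum R0 = %.3g\n", x$optimum))
  print(x$grid)
  invisible(x)
}

#' @rdname scan_r0
#' @param x,object An `r0_scan`.
#' @param ... Unused.
#' @method tidy r0_scan
#' @export
tidy.r0_scan <- function(x, ...) {
  x$grid
}

#' @rdname scan_r0
#' @method glance r0_scan
#' @export
glance.r0_scan <- function(x, ...) {
  opt <- x$grid[x$grid$r0 == x$optimum, ]
  tibble(
    optimum = x$optimum,
    ratio = opt$ratio,
    n_clusters = opt$n_clusters,
    n_large = opt$n_large,
    n_sequences = x$n_sequences,
    small_data = x$small_data
  )
}

#' @rdname scan_r0
#' @method autoplot r0_scan
#' @export
autoplot.r0_scan <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$r0, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$eligible), size = 2.5) +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(
      x = expression(R[0]),
      y = "double / single exponential fits",
      shape = "eligible"
    ) +
    ggplot2::theme_minimal()
}
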