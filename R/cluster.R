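# Greedy template-growing clustering of product-sorted dwell-time
# sequences, followed by a consistency refinement that re-audits every
# member against its cluster's final template. This is the core of the
# method: each resulting cluster collects the repeated realizations of
# one entry/exit route through the channel's substates.

.empty_clusters <- function(n, r0) {
  out <- tibble(
    cluster = integer(), start_state = character(), weight = integer(),
    template = list(), members = list(), values = list()
  )
  attr(out, "n") <- n
  attr(out, "r0") <- r0
  out
}

.clusters_tibble <- function(tpl, mem, val, rows, start_state, n, r0) {
  out <- tibble(
    cluster = seq_along(tpl),
    start_state = start_state,
    weight = vapply(mem, length, integer(1L)),
    template = tpl,
    members = mem,
    values = val,
    rows = rows
  )
  attr(out, "n") <- n
  attr(out, "r0") <- r0
  out
}

#' Single greedy clustering pass over sorted sequences
#'
#' Implements the template-growing aggregation: the first (largest
#' product) unassigned sequence becomes the comparative template of a new
#' cluster; the remaining unassigned sequences are scanned in sorted
#' order and whenever one reaches cross-correlation `>= r0` with the
#' current template it is absorbed — the template becomes the weighted
#' average `(w * template + sequence) / (w + 1)` (so it always equals the
#' plain mean of the members absorbed so far) and the sequence's origin
#' index is excluded from further consideration. When the scan exhausts
#' the data, the next unassigned sequence seeds the next cluster, picking
#' up the search at lower maximum tail dwell-times; this repeats until
#' every sequence is assigned. The procedure is fully deterministic.
#'
#' Constant (zero-variance) sequences, for which the correlation is
#' undefined, are set aside with a warning and reported via the
#' `excluded` attribute.
#'
#' @param sequences A sequence tibble from [extract_sequences()], all of
#'   one `start_state`. Sorted internally with [sort_by_product()]
#'   (already-sorted input is unchanged).
#' @param r0 Cross-correlation threshold, in `(0, 1]`.
#'
#' @return A cluster tibble with one row per cluster: `cluster` id,
#'   `start_state`, `weight` (cardinality), `template` (list of N means),
#'   `members` (list of origin indices, in acceptance order) and `values`
#'   (list of member-by-dimension matrices). Attributes: `n`, `r0`,
#'   `excluded`.
#' @seealso [refine_clusters()], [cluster_dwell_series()]
#' @export
cluster_pass <- function(sequences, r0) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0 || r0 > 1) {
    abort("`r0` must be in (0, 1]", class = "dwellclust_error")
  }
  n <- attr(sequences, "n") %||% length(grep("^tau", names(sequences)))
  if (nrow(sequences) == 0L) {
    return(.empty_clusters(n, r0))
  }
  if (length(unique(sequences$start_state)) > 1L) {
    abort("`sequences` mixes start states; cluster each pool separately",
      class = "dwellclust_error"
    )
  }
  sequences <- sort_by_product(sequences)
  M <- .seq_matrix(sequences)
  ss <- rowSums((M - rowMeans(M))^2)
  usable <- which(ss > 0)
  excluded <- sequences$origin_index[ss == 0]
  if (length(excluded)) {
    warn(sprintf(
      "%d constant sequence(s) excluded (cross-correlation undefined)",
      length(excluded)
    ))
  }
  tpl <- list()
  mem <- list()
  rows <- list()
  remaining <- usable
  while (length(remaining)) {
    seed <- remaining[1L]
    remaining <- remaining[-1L]
    template <- M[seed, ]
    w <- 1L
    members <- seed
    pos <- 1L
    while (pos <= length(remaining)) {
      rr <- .row_cor(M[remaining[pos:length(remaining)], , drop = FALSE], template)
      hit <- which(rr >= r0)[1L]
      if (is.na(hit)) break
      at <- pos + hit - 1L
      idx <- remaining[at]
      template <- (w * template + M[idx, ]) / (w + 1L)
      w <- w + 1L
      members <- c(members, idx)
      remaining <- remaining[-at]
      pos <- at
    }
    tpl[[length(tpl) + 1L]] <- template
    mem[[length(mem) + 1L]] <- members
    rows[[length(rows) + 1L]] <- members
  }
  out <- .clusters_tibble(
    tpl,
    lapply(rows, function(r) sequences$origin_index[r]),
    lapply(rows, function(r) M[r, , drop = FALSE]),
    rows, sequences$start_state[1L], n, r0
  )
  out$rows <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Consistency refinement of a clustering
#'
#' The greedy pass updates each template adaptively while the cluster
#' grows, so an early member can end up insufficiently correlated with
#' the final template. The refinement audits every member against its
#' cluster's current template (the plain mean of its members): a member
#' with correlation below `r0` is removed, the template is updated, and
#' the member joins the first existing cluster — tried in descending
#' cardinality order — whose template it reaches `r0` with, or seeds a
#' new singleton cluster. Sweeps repeat until a fixed point where no
#' member moves (so the all-members-`>= r0` audit holds), or `max_iter`
#' sweeps, in which case the result carries `converged = FALSE` with a
#' warning. Refinement is idempotent: refining a converged result again
#' changes nothing.
#'
#' @param clusters A cluster tibble from [cluster_pass()].
#' @param r0 Cross-correlation threshold; defaults to the one stored on
#'   `clusters`.
#' @param max_iter Maximum number of audit sweeps.
#'
#' @return A cluster tibble like [cluster_pass()]'s, with attributes
#'   `converged` (logical) and `iterations`.
#' @export
refine_clusters <- function(clusters, r0 = NULL, max_iter = 100) {
  r0 <- r0 %||% attr(clusters, "r0")
  if (is.null(r0)) {
    abort("`r0` is neither given nor stored on `clusters`",
      class = "dwellclust_error"
    )
  }
  if (max_iter < 1) {
    abort("`max_iter` must be >= 1", class = "dwellclust_error")
  }
  n <- attr(clusters, "n")
  if (nrow(clusters) == 0L) {
    out <- .empty_clusters(n, r0)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  start_state <- clusters$start_state[1L]
  val <- clusters$values
  mem <- clusters$members
  tpl <- lapply(val, colMeans)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    moved <- FALSE
    sweep_order <- order(-vapply(mem, length, integer(1L)), seq_along(mem))
    for (ci in sweep_order) {
      j <- 1L
      while (j <= length(mem[[ci]])) {
        if (length(mem[[ci]]) == 1L) break # singleton: R with own template is 1
        r <- .row_cor(val[[ci]][j, , drop = FALSE], tpl[[ci]])
        if (!is.na(r) && r >= r0) {
          j <- j + 1L
          next
        }
        # displace member j
        x <- val[[ci]][j, ]
        oi <- mem[[ci]][j]
        val[[ci]] <- val[[ci]][-j, , drop = FALSE]
        mem[[ci]] <- mem[[ci]][-j]
        tpl[[ci]] <- colMeans(val[[ci]])
        # try existing clusters in descending cardinality order
        cand <- order(-vapply(mem, length, integer(1L)), seq_along(mem))
        placed <- FALSE
        for (tj in cand) {
          r2 <- .row_cor(matrix(x, nrow = 1L), tpl[[tj]])
          if (!is.na(r2) && r2 >= r0) {
            val[[tj]] <- rbind(val[[tj]], x)
            mem[[tj]] <- c(mem[[tj]], oi)
            tpl[[tj]] <- colMeans(val[[tj]])
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          val[[length(val) + 1L]] <- matrix(x, nrow = 1L)
          mem[[length(mem) + 1L]] <- oi
          tpl[[length(tpl) + 1L]] <- x
        }
        moved <- TRUE
      }
    }
    if (!moved) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("refinement did not converge within %d sweeps", max_iter))
  }
  out <- .clusters_tibble(
    tpl, mem, val,
    rows = vector("list", length(tpl)),
    start_state = start_state, n = n, r0 = r0
  )
  out$rows <- NULL
  attr(out, "excluded") <- attr(clusters, "excluded")
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  out
}

#' Audit a clustering against the correlation threshold
#'
#' Checks the defining postcondition of a refined clustering: every
#' member of every (non-singleton) cluster reaches cross-correlation
#' `>= r0` with its cluster's template, and each template equals the
#' plain mean of its members.
#'
#' @param clusters A cluster tibble.
#' @param r0 Threshold; defaults to the stored one.
#' @param tol Numeric tolerance for the template-mean identity.
#' @return `TRUE` if the audit passes, otherwise `FALSE` with attribute
#'   `violations` (a tibble of offending cluster/member pairs).
#' @export
audit_clusters <- function(clusters, r0 = NULL, tol = 1e-8) {
  r0 <- r0 %||% attr(clusters, "r0")
  bad <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    vals <- clusters$values[[i]]
    tpl <- clusters$template[[i]]
    probs <- tibble(
      cluster = integer(), member = integer(),
      problem = character()
    )
    if (max(abs(colMeans(vals) - tpl)) > tol) {
      probs <- dplyr::bind_rows(probs, tibble(
        cluster = clusters$cluster[i], member = NA_integer_,
        problem = "template != mean of members"
      ))
    }
    if (nrow(vals) > 1L) {
      rr <- .row_cor(vals, tpl)
      low <- which(is.na(rr) | rr < r0 - tol)
      if (length(low)) {
        probs <- dplyr::bind_rows(probs, tibble(
          cluster = clusters$cluster[i],
          member = clusters$members[[i]][low],
          problem = "member correlation below r0"
        ))
      }
    }
    probs
  })
  ok <- nrow(bad) == 0L
  attr(ok, "violations") <- bad
  ok
}

#' Cluster the dwell-time sequences of a series
#'
#' End-to-end driver: extracts the N-element sequences of both pools
#' (O–C–O–... and C–O–C–...), product-sorts each pool, runs the greedy
#' clustering pass and the consistency refinement independently per pool,
#' and reports coverage diagnostics. Sequences starting from the open
#' state are only ever compared with open-starting ones, and likewise for
#' closed.
#'
#' Coverage is the fraction of dwell events that appear in at least one
#' sequence belonging to a cluster with at least `min_members` members.
#' As a rule of thumb the chosen `n` should leave clusters with at least
#' 10 representatives covering more than half of the raw data.
#'
#' @param series A [dwell_series()].
#' @param n Sequence length (default 3).
#' @param r0 Cross-correlation threshold (default 0.96; see [scan_r0()]
#'   for a data-driven choice).
#' @param min_members Cluster size counted as well-represented in the
#'   coverage diagnostic (default 10).
#' @param max_iter Refinement sweep cap.
#' @param drop_censored Exclude sequences touching censored boundary
#'   events (default `TRUE`).
#'
#' @return An object of class `dwell_cluster_fit`: a list with
#'   `clusters` (combined cluster tibble of both pools, globally
#'   renumbered), `sequences`, `coverage`, `n`, `r0` and `diagnostics`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' sc <- fixture_scheme("two_pathway")
#' s <- aggregate_path(simulate_path(sc, 400, seed = 1), sc)
#' fit <- cluster_dwell_series(s, n = 3, r0 = 0.9)
#' glance(fit)
cluster_dwell_series <- function(series, n = 3, r0 = 0.96, min_members = 10,
                                 max_iter = 100, drop_censored = TRUE) {
  seqs <- extract_sequences(series,
    n = n, start_state = c("O", "C"),
    drop_censored = drop_censored
  )
  pools <- list(
    O = seqs[seqs$start_state == "O", , drop = FALSE],
    C = seqs[seqs$start_state == "C", , drop = FALSE]
  )
  fits <- lapply(pools, function(p) {
    attr(p, "n") <- n
    refine_clusters(cluster_pass(p, r0), r0 = r0, max_iter = max_iter)
  })
  clusters <- dplyr::bind_rows(fits$O, fits$C)
  if (nrow(clusters)) {
    clusters$cluster <- seq_len(nrow(clusters))
  }
  attr(clusters, "n") <- n
  attr(clusters, "r0") <- r0
  covered <- logical(nrow(series))
  big <- which(clusters$weight >= min_members)
  for (i in big) {
    for (o in clusters$members[[i]]) {
      covered[o:(o + n - 1L)] <- TRUE
    }
  }
  structure(list(
    clusters = clusters,
    sequences = seqs,
    coverage = mean(covered),
    n = n,
    r0 = r0,
    min_members = min_members,
    series_length = nrow(series),
    diagnostics = list(
      n_sequences = setNames(vapply(pools, nrow, integer(1L)), names(pools)),
      n_excluded = setNames(
        vapply(fits, function(f) length(attr(f, "excluded")), integer(1L)),
        names(fits)
      ),
      converged = setNames(
        vapply(fits, function(f) isTRUE(attr(f, "converged")), logical(1L)),
        names(fits)
      ),
      iterations = setNames(
        vapply(fits, function(f) attr(f, "iterations") %||% 0L, integer(1L)),
        names(fits)
      )
    )
  ), class = "dwell_cluster_fit")
}

#' @export
print.dwell_cluster_fit <- function(x, ...) {
  cat(sprintf(
    "<dwell_cluster_fit> n = %d, r0 = %.3g: %d clusters from %d sequences\n",
    x$n, x$r0, nrow(x$clusters), nrow(x$sequences)
  ))
  cat(sprintf(
    "coverage by clusters with >= %d members: %.1f%% of %d events\n",
    x$min_members, 100 * x$coverage, x$series_length
  ))
  invisible(x)
}

#' @rdname cluster_dwell_series
#' @param x A `dwell_cluster_fit`.
#' @param ... Unused.
#' @method tidy dwell_cluster_fit
#' @export
tidy.dwell_cluster_fit <- function(x, ...) {
  summarize_clusters(x$clusters)
}

#' @rdname cluster_dwell_series
#' @method glance dwell_cluster_fit
#' @export
glance.dwell_cluster_fit <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_dominant = sum(summarize_clusters(x$clusters)$dominant),
    n_sequences = nrow(x$sequences),
    coverage = x$coverage,
    n = x$n,
    r0 = x$r0,
    converged = all(x$diagnostics$converged)
  )
}

#' @rdname cluster_dwell_series
#' @param object A `dwell_cluster_fit`.
#' @method autoplot dwell_cluster_fit
#' @export
autoplot.dwell_cluster_fit <- function(object, ...) {
  plot_phase_space(summarize_clusters(object$clusters), ...)
}
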