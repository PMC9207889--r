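# Phase-space view of a clustering: each cluster is a point in the
# N-dimensional dwell-time space, with cardinality-scaled spheres and
# distances between cluster centers.

#' Summarize clusters as phase-space points
#'
#' Each cluster is reduced to its center (the template, i.e. the mean
#' dwell-time sequence of its members), its cardinality, the fraction of
#' all sequences it absorbs (occupancy, normalized within each
#' start-state pool), and the per-dimension standard deviation of its
#' members. Clusters above `dominant_threshold` occupancy (default 5%)
#' are flagged dominant — typically a handful of routes dominate the
#' gating.
#'
#' @param clusters A cluster tibble (from [cluster_pass()],
#'   [refine_clusters()] or a `dwell_cluster_fit`).
#' @param total_sequences Denominator for occupancy; defaults to the
#'   summed cardinality of the same start-state pool, so occupancies sum
#'   to 1 per pool.
#' @param dominant_threshold Occupancy above which a cluster is flagged
#'   dominant.
#'
#' @return A tibble with one row per cluster: `cluster`, `start_state`,
#'   `cardinality`, `occupancy`, `dominant`, center coordinates
#'   `tau1..tauN` and dispersions `sd1..sdN`.
#' @export
summarize_clusters <- function(clusters, total_sequences = NULL,
                               dominant_threshold = 0.05) {
  if (inherits(clusters, "dwell_cluster_fit")) {
    clusters <- clusters$clusters
  }
  if (nrow(clusters) == 0L) {
    return(tibble(
      cluster = integer(), start_state = character(),
      cardinality = integer(), occupancy = numeric(), dominant = logical()
    ))
  }
  nd <- length(clusters$template[[1L]])
  centers <- do.call(rbind, clusters$template)
  colnames(centers) <- paste0("tau", seq_len(nd))
  disp <- t(vapply(clusters$values, function(v) {
    if (nrow(v) > 1L) apply(v, 2L, sd) else rep(0, nd)
  }, numeric(nd)))
  colnames(disp) <- paste0("sd", seq_len(nd))
  pool_tot <- tapply(clusters$weight, clusters$start_state, sum)
  denom <- total_sequences %||% as.numeric(pool_tot[clusters$start_state])
  occ <- clusters$weight / denom
  dplyr::bind_cols(
    tibble(
      cluster = clusters$cluster,
      start_state = clusters$start_state,
      cardinality = clusters$weight,
      occupancy = occ,
      dominant = occ > dominant_threshold
    ),
    as_tibble(centers),
    as_tibble(disp)
  )
}

#' Euclidean distances between cluster centers
#'
#' Pairwise distances (ms) between cluster centers, the
#' multidimensional Pythagorean distance in dwell-time phase space.
#'
#' @param centers A summary tibble from [summarize_clusters()], or a
#'   numeric matrix / list of equal-length center vectors.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
#' @examples
#' cluster_distances(rbind(c(0, 0, 0), c(3, 4, 0)))
cluster_distances <- function(centers) {
  if (is.data.frame(centers)) {
    m <- as.matrix(centers[, grep("^tau", names(centers)), drop = FALSE])
    rownames(m) <- centers$cluster
  } else if (is.list(centers) && !is.matrix(centers)) {
    len <- unique(vapply(centers, length, integer(1L)))
    if (length(len) != 1L) {
      abort("all centers must have the same dimension", class = "dwellclust_error")
    }
    m <- do.call(rbind, centers)
  } else {
    m <- as.matrix(centers)
  }
  as.matrix(stats::dist(m))
}

#' Plot clusters in dwell-time phase space
#'
#' Draws the cluster centers of three chosen dimensions in an
#' orthographic 3D projection: each cluster is a sphere whose volume is
#' proportional to `log(1 + scale * occupancy)` (the logarithm keeps
#' rarely visited routes visible next to dominant ones), and every
#' center is additionally projected as a small dot onto the tau1–tau3
#' base plane. Summaries from several experimental conditions can be
#' overlaid in colour, optionally with arrows connecting
#' nearest-matching clusters across consecutive conditions to expose
#' systematic translations of the routes.
#'
#' @param summary A tibble from [summarize_clusters()], optionally with a
#'   `condition` column, or a named list of such tibbles (names become
#'   conditions).
#' @param dims Integer vector of the three tau-dimensions to draw.
#' @param scale Cardinality rescaling factor `s` in
#'   `V = log(1 + s * occupancy)` (default 100).
#' @param azimuth,elevation Viewing angles of the orthographic
#'   projection, degrees.
#' @param connect Draw arrows between matched clusters of consecutive
#'   conditions (default `FALSE`).
#' @param match_cap Distance cap for the greedy nearest-center matching
#'   used by `connect`, as a fraction of the phase-space diagonal.
#' @param path Optional file path (png/svg/pdf); the figure is saved
#'   there with [ggplot2::ggsave()].
#'
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_phase_space <- function(summary, dims = c(1, 2, 3), scale = 100,
                             azimuth = 35, elevation = 22,
                             connect = FALSE, match_cap = 0.25,
                             path = NULL) {
  if (is.list(summary) && !is.data.frame(summary)) {
    nm <- names(summary) %||% as.character(seq_along(summary))
    keep <- vapply(summary, nrow, integer(1L)) > 0L
    if (any(!keep)) {
      warn(sprintf(
        "skipping empty condition(s): %s",
        paste(nm[!keep], collapse = ", ")
      ))
    }
    summary <- dplyr::bind_rows(setNames(summary[keep], nm[keep]), .id = "condition")
  }
  if (!nrow(summary)) {
    abort("nothing to plot: no clusters", class = "dwellclust_error")
  }
  cols <- paste0("tau", dims)
  if (!all(cols %in% names(summary))) {
    abort(sprintf(
      "summary lacks dimension column(s) %s",
      paste(setdiff(cols, names(summary)), collapse = ", ")
    ), class = "dwellclust_error")
  }
  xyz <- as.matrix(summary[, cols])
  vol <- log1p(scale * summary$occupancy)
  radius <- (3 * vol / (4 * pi))^(1 / 3)

  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  proj <- function(m) {
    # orthographic: rotate about the vertical axis, then tilt
    x <- m[, 1L] * cos(az) - m[, 3L] * sin(az)
    depth <- m[, 1L] * sin(az) + m[, 3L] * cos(az)
    y <- m[, 2L] * cos(el) - depth * sin(el)
    cbind(px = x, py = y)
  }
  pts <- as_tibble(proj(xyz))
  pts$radius <- radius
  pts$condition <- if ("condition" %in% names(summary)) {
    summary$condition
  } else {
    "all"
  }
  base <- xyz
  base[, 2L] <- min(xyz[, 2L]) # dots on the tau1-tau3 plane
  dots <- as_tibble(proj(base))
  dots$condition <- pts$condition

  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(
      data = dots, colour = "grey55", size = 0.8, shape = 16
    ) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$radius, colour = .data$condition),
      alpha = 0.65
    ) +
    ggplot2::scale_size_continuous(range = c(1, 12), guide = "none") +
    ggplot2::labs(
      x = sprintf("projection (tau%d, tau%d)", dims[1L], dims[3L]),
      y = sprintf("tau%d (ms)", dims[2L]),
      colour = "condition"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (length(unique(pts$condition)) == 1L) {
    p <- p + ggplot2::guides(colour = "none")
  }
  if (connect && "condition" %in% names(summary)) {
    seg <- .match_conditions(summary, cols, proj, match_cap)
    if (nrow(seg)) {
      p <- p + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(
          x = .data$px, y = .data$py,
          xend = .data$px_end, yend = .data$py_end
        ),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "black", linewidth = 0.3, inherit.aes = FALSE
      )
    }
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

# greedy nearest-center matching between consecutive conditions, with a
# cap on the jump length; cosmetic only
.match_conditions <- function(summary, cols, proj, match_cap) {
  conds <- unique(summary$condition)
  all_xyz <- as.matrix(summary[, cols])
  cap <- match_cap * sqrt(sum((apply(all_xyz, 2L, max) - apply(all_xyz, 2L, min))^2))
  segs <- list()
  for (i in seq_len(length(conds) - 1L)) {
    a <- summary[summary$condition == conds[i], ]
    b <- summary[summary$condition == conds[i + 1L], ]
    if (!nrow(a) || !nrow(b)) next
    da <- as.matrix(a[, cols])
    db <- as.matrix(b[, cols])
    dmat <- as.matrix(stats::dist(rbind(da, db)))[
      seq_len(nrow(da)), nrow(da) + seq_len(nrow(db)),
      drop = FALSE
    ]
    while (any(is.finite(dmat)) && min(dmat, na.rm = TRUE) <= cap) {
      ij <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      pa <- proj(da[ij[1L], , drop = FALSE])
      pb <- proj(db[ij[2L], , drop = FALSE])
      segs[[length(segs) + 1L]] <- tibble(
        px = pa[1L, "px"], py = pa[1L, "py"],
        px_end = pb[1L, "px"], py_end = pb[1L, "py"]
      )
      dmat[ij[1L], ] <- Inf
      dmat[, ij[2L]] <- Inf
    }
  }
  if (length(segs)) dplyr::bind_rows(segs) else tibble()
}
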