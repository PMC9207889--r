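# Readers and writers for the plain-text formats used throughout:
# CSV/TSV for traces and dwell series, YAML for kinetic schemes, JSON for
# cluster/scan reports. Comma, tab or whitespace delimiters are sniffed
# and '#'-prefixed comment lines are skipped, tolerating typical lab
# exports.

.read_table_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dwellclust_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) {
    abort(sprintf("no data rows in %s", path), class = "dwellclust_error")
  }
  list(lines = raw[keep], line_no = keep)
}

.sniff_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line, fixed = TRUE)) "\t" else ""
}

.split_fields <- function(lines, sep) {
  if (sep == "") {
    strsplit(trimws(lines), "\\s+")
  } else {
    strsplit(lines, sep, fixed = TRUE)
  }
}

#' Read a single-channel current trace from delimited text
#'
#' Accepts either a two-column file of (time, current) — in which case the
#' sampling interval is inferred from the first two timestamps unless `dt`
#' is given — or a single column of current samples with `dt` supplied.
#' The delimiter (comma, tab or whitespace) is auto-detected, a non-numeric
#' header row is skipped, and `#` comment lines are ignored. Non-numeric
#' data rows raise a parse error naming the offending line.
#'
#' @param path Path to the text file.
#' @param dt Sampling interval in ms; `NULL` to infer from timestamps
#'   (two-column input) or fall back to 0.1 ms.
#' @param column Index of the current column; `NULL` picks column 2 when
#'   two or more columns are present, else column 1.
#' @param meta Metadata list stored on the trace.
#'
#' @return A [current_trace()].
#' @export
read_trace <- function(path, dt = NULL, column = NULL, meta = list()) {
  tbl <- .read_table_lines(path)
  sep <- .sniff_sep(tbl$lines[1L])
  fields <- .split_fields(tbl$lines, sep)
  ncol <- length(fields[[1L]])
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  if (has_header) {
    fields <- fields[-1L]
    tbl$line_no <- tbl$line_no[-1L]
    if (!length(fields)) {
      abort(sprintf("no data rows in %s", path), class = "dwellclust_error")
    }
  }
  column <- column %||% if (ncol >= 2L) 2L else 1L
  if (column > ncol) {
    abort(sprintf("requested column %d but file has %d column(s)", column, ncol),
      class = "dwellclust_error"
    )
  }
  get_col <- function(j) {
    vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), j)))
    bad <- which(is.na(vals))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric value in column %d at line %d of %s",
        j, tbl$line_no[bad[1L]], path
      ), class = "dwellclust_error")
    }
    vals
  }
  current <- get_col(column)
  time <- NULL
  if (ncol >= 2L && column == 2L) {
    time <- get_col(1L)
    if (is.null(dt) && length(time) >= 2L) {
      dt <- time[2L] - time[1L]
      if (!is.finite(dt) || dt <= 0) {
        abort("cannot infer dt from timestamps; pass `dt` explicitly",
          class = "dwellclust_error"
        )
      }
    }
  }
  current_trace(current, dt = dt %||% 0.1, time = time, meta = meta)
}

#' Read or write a dwell-time series
#'
#' Series are stored as delimited text with columns `state`, `duration`
#' and optionally `censored`. Writing then reading restores the series
#' exactly, including full float precision of the durations. Validation
#' (state alternation, positive durations) runs on read and names the
#' offending row.
#'
#' @param path File path.
#' @return `read_dwell_series()` returns a [dwell_series()].
#' @export
read_dwell_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dwellclust_error")
  }
  # base parser: correctly-rounded strtod, so the %.17g written by
  # write_dwell_series() restores durations bit for bit
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("state", "duration") %in% names(df))) {
    abort(sprintf("%s lacks state/duration columns", path),
      class = "dwellclust_error"
    )
  }
  if (!is.numeric(df$duration)) {
    abort(sprintf("non-numeric duration in %s", path), class = "dwellclust_error")
  }
  as_dwell_series(df)
}

#' @rdname read_dwell_series
#' @param series A [dwell_series()].
#' @export
write_dwell_series <- function(series, path) {
  stopifnot(inherits(series, "dwell_series"))
  df <- as.data.frame(series)
  df$duration <- sprintf("%.17g", df$duration) # bit-exact round trip
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a kinetic scheme config
#'
#' Schemes are stored as YAML with a `substates:` block (id -> class), a
#' `rates:` block (nested from -> to -> rate in ms^-1) and an
#' `initial_state` key.
#'
#' @param path File path.
#' @return `read_kinetic_scheme()` returns a [kinetic_scheme()].
#' @export
read_kinetic_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dwellclust_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$substates) || is.null(cfg$rates)) {
    abort("scheme config needs `substates:` and `rates:` blocks",
      class = "dwellclust_error"
    )
  }
  kinetic_scheme(
    substates = unlist(cfg$substates),
    rates = purrr::imap_dfr(cfg$rates, function(v, from) {
      tibble(from = from, to = names(v), rate = as.numeric(unlist(v)))
    }),
    initial_state = cfg$initial_state
  )
}

#' @rdname read_kinetic_scheme
#' @param scheme A [kinetic_scheme()].
#' @export
write_kinetic_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  rates <- split(scheme$rates, scheme$rates$from)
  yaml::write_yaml(list(
    substates = as.list(setNames(scheme$substates$class, scheme$substates$id)),
    rates = lapply(rates, function(d) as.list(setNames(d$rate, d$to))),
    initial_state = scheme$initial_state
  ), path, precision = 17L)
  invisible(path)
}

#' Write or read a cluster report
#'
#' The report is a JSON document holding, for every cluster: the start
#' state, the template (weighted-mean dwell-time sequence), the
#' cardinality, the member origin indices and the per-dimension standard
#' deviation of the members; plus the correlation threshold R0 the
#' clustering was run at and, optionally, the R0-scan grid.
#'
#' @param clusters A cluster tibble from [cluster_pass()] /
#'   [refine_clusters()], or the `clusters` element of a
#'   [cluster_dwell_series()] fit.
#' @param path Output path.
#' @param r0 Correlation threshold used; taken from the `r0` attribute of
#'   `clusters` when present.
#' @param scan Optional [scan_r0()] result whose grid is embedded.
#' @param extra Optional named list merged into the document top level
#'   (e.g. run parameters for provenance).
#' @return `write_cluster_report()` invisibly returns `path`;
#'   `read_cluster_report()` returns the parsed report as a list with a
#'   `clusters` tibble.
#' @export
write_cluster_report <- function(clusters, path, r0 = NULL, scan = NULL,
                                 extra = NULL) {
  r0 <- r0 %||% attr(clusters, "r0")
  recs <- purrr::pmap(
    list(
      clusters$cluster, clusters$start_state, clusters$weight,
      clusters$template, clusters$members, clusters$values
    ),
    function(id, ss, w, tpl, mem, vals) {
      disp <- if (nrow(vals) > 1L) apply(vals, 2L, sd) else rep(0, ncol(vals))
      list(
        cluster = id, start_state = ss, cardinality = w,
        template = as.numeric(tpl), members = as.integer(mem),
        dispersion = as.numeric(disp)
      )
    }
  )
  doc <- list(r0 = r0, n_clusters = nrow(clusters), clusters = recs)
  if (!is.null(scan)) {
    doc$scan <- list(optimum = scan$optimum, grid = scan$grid)
  }
  if (!is.null(extra)) {
    doc <- c(doc, extra)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dwellclust_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  clusters <- purrr::map_dfr(doc$clusters, function(r) {
    tibble(
      cluster = as.integer(r$cluster),
      start_state = r$start_state,
      weight = as.integer(r$cardinality),
      template = list(as.numeric(unlist(r$template))),
      members = list(as.integer(unlist(r$members))),
      dispersion = list(as.numeric(unlist(r$dispersion)))
    )
  })
  list(
    r0 = doc$r0, n_clusters = doc$n_clusters, clusters = clusters,
    scan = doc$scan
  )
}
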