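#' Trajectory container
#'
#' A `track_set` is a data frame of single-molecule localizations grouped into
#' trajectories, the common currency of all analysis stages. Required columns
#' are `track_id`, `frame` (integer, consecutive within a track), `x` and `y`
#' (micrometres). A column `t` (seconds) is derived from the frame interval.
#' Optional columns (`true_state`, `cell_id`) are carried along untouched.
#'
#' @param tracks data frame with columns `track_id`, `frame`, `x`, `y`.
#' @param tau frame interval in seconds.
#' @return object of class `track_set` (a data frame with attribute `tau`).
#' @export
track_set <- function(tracks, tau) {
  stopifnot(is.data.frame(tracks), is.numeric(tau), length(tau) == 1L, tau > 0)
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  d <- unlist(tapply(tracks$frame, tracks$track_id, diff, simplify = FALSE),
              use.names = FALSE)
  if (length(d) && any(d != 1L))
    stop("frames must increase by exactly 1 within each track (no gap closing)")
  tracks$t <- tracks$frame * tau
  structure(tracks, tau = tau, class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(unique(x$track_id))
  cat(sprintf("track_set: %d tracks, %d localizations, tau = %g s\n",
              n, nrow(x), attr(x, "tau")))
  len <- table(factor(tabulate(factor(x$track_id))))
  cat(sprintf("  track length (points): median %g, range %d-%d\n",
              stats::median(tabulate(factor(x$track_id))),
              min(tabulate(factor(x$track_id))),
              max(tabulate(factor(x$track_id)))))
  invisible(x)
}

#' @export
summary.track_set <- function(object, ...) {
  len <- tabulate(factor(object$track_id))
  out <- list(n_tracks = length(len), n_loc = nrow(object),
              tau = attr(object, "tau"), length_summary = summary(len))
  class(out) <- "summary.track_set"
  out
}

#' @export
print.summary.track_set <- function(x, ...) {
  cat(sprintf("track_set with %d tracks (%d localizations), tau = %g s\n",
              x$n_tracks, x$n_loc, x$tau))
  cat("track lengths (points):\n"); print(x$length_summary)
  invisible(x)
}

#' Frame interval of a track set
#' @param tracks a `track_set`.
#' @return the frame interval in seconds.
#' @export
track_interval <- function(tracks) {
  tau <- attr(tracks, "tau")
  if (is.null(tau)) stop("object has no frame-interval attribute")
  tau
}

## internal: split a track_set into per-track data frames (ordered)
track_split <- function(tracks) {
  split(as.data.frame(tracks), factor(tracks$track_id, levels = unique(tracks$track_id)))
}

#' Read / write trajectory tables
#'
#' Tracks are exchanged as plain CSV with columns `track_id`, `frame`, `t`,
#' `x`, `y` (micrometres) and any extra columns present.
#'
#' @param path file path.
#' @param tracks a `track_set`.
#' @param tau frame interval in seconds; if `NULL`, inferred from the `t`
#'   column.
#' @return `read_tracks` returns a `track_set`; `write_tracks` returns `path`
#'   invisibly.
#' @export
read_tracks <- function(path, tau = NULL) {
  d <- utils::read.csv(path)
  if (is.null(tau)) {
    if (!"t" %in% names(d)) stop("no 't' column and no tau supplied")
    dt <- diff(sort(unique(d$t)))
    tau <- min(dt[dt > 0])
  }
  track_set(d[setdiff(names(d), "t")], tau = tau)
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
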