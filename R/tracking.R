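# Sparse-field centroid tracking and segmentation of trajectories into
# actuation windows. The tracker is intentionally simple: intensity
# thresholding, connected components, darkness-weighted subpixel centroids,
# nearest-neighbour linking. It is sufficient for well-separated beads.

#' Detect and link rollers in an image stack
#'
#' Per frame, pixels darker than `detect_threshold` times the frame's maximum
#' darkness (background minus intensity, background estimated as the median
#' pixel) are segmented into connected components; components whose
#' area-equivalent diameter falls within `[min_diameter, max_diameter]` become
#' detections with a darkness-weighted subpixel centroid.  Detections are
#' linked frame to frame by nearest neighbour within `max_link_distance`;
#' rollers for which a link was ever ambiguous (more than one candidate in
#' range) are flagged, not silently resolved.
#'
#' Coordinates are 0-based pixel centres scaled by `pixel_size`, origin at the
#' top-left pixel; x runs along columns, y along rows.
#'
#' @param stack An `image_stack` (see [render_image_stack()] /
#'   [read_image_stack()]).
#' @param detect_threshold Relative darkness threshold in (0, 1).
#' @param min_diameter,max_diameter Acceptable component diameters, um.
#' @param max_link_distance Maximum frame-to-frame displacement, um.
#'
#' @return A `track_table` with estimated per-roller diameters and ambiguity
#'   flags in its metadata ([roller_metadata()]).
#' @export
track_particles <- function(stack, detect_threshold = 0.5, min_diameter = 4,
                            max_diameter = 30, max_link_distance = 20) {
  stopifnot(inherits(stack, "image_stack"))
  if (detect_threshold <= 0 || detect_threshold >= 1)
    stop("'detect_threshold' must be in (0, 1)", call. = FALSE)
  if (min_diameter >= max_diameter)
    stop("'min_diameter' must be smaller than 'max_diameter'", call. = FALSE)
  if (!length(stack$frames)) stop("empty image stack", call. = FALSE)
  px <- stack$pixel_size

  detect <- function(img) {
    dark <- stats::median(img) - img
    dmax <- max(dark)
    if (dmax <= 0)
      return(data.frame(x = numeric(), y = numeric(), diameter = numeric()))
    mask <- dark > detect_threshold * dmax
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(img), ncol(img)))
    lab <- as.vector(lab)
    ids <- setdiff(unique(lab), 0)
    res <- lapply(ids, function(k) {
      idx <- which(lab == k)
      row <- (idx - 1) %% nrow(img) + 1
      col <- (idx - 1) %/% nrow(img) + 1
      d <- 2 * sqrt(length(idx) / pi) * px
      w <- dark[idx]
      data.frame(x = sum(w * (col - 1)) / sum(w) * px,
                 y = sum(w * (row - 1)) / sum(w) * px,
                 diameter = d)
    })
    res <- do.call(rbind, res)
    res[res$diameter >= min_diameter & res$diameter <= max_diameter, ,
        drop = FALSE]
  }

  tracks <- list()   # per id: list(x, y, frame, diam, flagged, last)
  next_id <- 1L
  rows <- list()
  for (f in seq_along(stack$frames)) {
    det <- detect(stack$frames[[f]])
    assigned <- rep(FALSE, nrow(det))
    if (length(tracks) && nrow(det)) {
      last <- do.call(rbind, lapply(tracks, function(tr) tr$last))
      dmat <- sqrt(outer(last[, 1], det$x, "-")^2 +
                   outer(last[, 2], det$y, "-")^2)
      # greedy mutual nearest-neighbour within range
      repeat {
        if (!any(is.finite(dmat)) || min(dmat, na.rm = TRUE) > max_link_distance)
          break
        ij <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)[1, ]
        ti <- ij[1]; di <- ij[2]
        n_cand <- sum(dmat[ti, ] <= max_link_distance, na.rm = TRUE)
        if (n_cand > 1) tracks[[ti]]$flagged <- TRUE
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x[di])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y[di])
        tracks[[ti]]$frame <- c(tracks[[ti]]$frame, f - 1L)
        tracks[[ti]]$diam <- c(tracks[[ti]]$diam, det$diameter[di])
        tracks[[ti]]$last <- c(det$x[di], det$y[di])
        assigned[di] <- TRUE
        dmat[ti, ] <- NA
        dmat[, di] <- NA
      }
    }
    for (di in which(!assigned)) {
      tracks[[next_id]] <- list(x = det$x[di], y = det$y[di], frame = f - 1L,
                                diam = det$diameter[di], flagged = FALSE,
                                last = c(det$x[di], det$y[di]))
      next_id <- next_id + 1L
    }
  }

  if (!length(tracks)) {
    empty <- data.frame(roller_id = integer(), frame = integer(),
                        time_s = numeric(), x_um = numeric(), y_um = numeric(),
                        condition = character(), stringsAsFactors = FALSE)
    meta <- data.frame(roller_id = integer(), diameter_um = numeric(),
                       est_diameter_um = numeric(), is_dimer = logical(),
                       flagged = logical())
    return(new_track_table(empty, rollers = meta, condition = "tracked"))
  }

  df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(roller_id = i, frame = tr$frame,
               time_s = stack$times[tr$frame + 1L],
               x_um = tr$x, y_um = tr$y, condition = "tracked",
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$roller_id, df$frame), ]
  meta <- data.frame(
    roller_id = seq_along(tracks),
    diameter_um = vapply(tracks, function(tr) mean(tr$diam), numeric(1)),
    est_diameter_um = vapply(tracks, function(tr) mean(tr$diam), numeric(1)),
    is_dimer = NA,
    flagged = vapply(tracks, function(tr) tr$flagged, logical(1)))
  new_track_table(df, rollers = meta, condition = "tracked")
}

#' Write / read a track table as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `roller_id, frame, time_s, x_um, y_um, condition`.  Reading validates that
#' time is strictly increasing within each roller, that `(roller_id, frame)`
#' pairs are unique, and that coordinates are finite; violations raise errors
#' naming the offending row.
#'
#' @param tracks A `track_table`.
#' @param path File path.
#' @return `read_tracks()` returns a `track_table`; `write_tracks()` returns
#'   `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[, c("roller_id", "frame", "time_s",
                                             "x_um", "y_um", "condition")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roller_id", "frame", "time_s", "x_um", "y_um", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))[1]
    stop("non-finite coordinate at row ", bad, call. = FALSE)
  }
  key <- paste(df$roller_id, df$frame)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate (roller_id, frame) at row ", bad, call. = FALSE)
  }
  for (id in unique(df$roller_id)) {
    tt <- df$time_s[df$roller_id == id]
    if (any(diff(tt) <= 0)) {
      local_bad <- which(diff(tt) <= 0)[1] + 1L
      bad <- which(df$roller_id == id)[local_bad]
      stop("time not strictly increasing for roller ", id, " at row ", bad,
           call. = FALSE)
    }
  }
  cond <- unique(df$condition)
  new_track_table(df, rollers = NULL,
                  condition = if (length(cond) == 1) cond else cond[1])
}

#' Segment trajectories into actuation windows
#'
#' Cuts each roller's trajectory into the `2 * n_cycles` field-on windows of
#' the protocol.  Window `k` spans `[t0 + (k-1)(tau + off), + tau]`; its
#' boundary positions are taken at the nearest frame at or before each
#' boundary time, so no window mixes field-on and field-off frames.
#' Directions alternate starting from the protocol's `first_direction`.
#'
#' @param tracks A `track_table`.
#' @param protocol An [actuation_protocol()].
#' @param t0 Start of the first actuation relative to the recording, s.
#'
#' @return A data frame of class `actuation_segments` with one row per roller
#'   per window: `condition`, `roller_id`, `window`, `direction`, `t_start`,
#'   `t_end`, `x_start`, `y_start`, `x_end`, `y_end`.
#' @export
segment_actuations <- function(tracks, protocol, t0 = 0) {
  stopifnot(inherits(protocol, "actuation_protocol"))
  n_win <- 2L * protocol$n_cycles
  dirs <- rep_len(if (protocol$first_direction == "CW") c("CW", "CCW")
                  else c("CCW", "CW"), n_win)
  out <- data.frame(condition = character(), roller_id = integer(),
                    window = integer(), direction = character(),
                    t_start = numeric(), t_end = numeric(),
                    x_start = numeric(), y_start = numeric(),
                    x_end = numeric(), y_end = numeric(),
                    stringsAsFactors = FALSE)
  if (n_win == 0L || !nrow(tracks))
    return(structure(out, class = c("actuation_segments", "data.frame")))

  eps <- 1e-9
  step <- protocol$tau + protocol$off_period
  starts <- t0 + (seq_len(n_win) - 1) * step
  ends <- starts + protocol$tau
  res <- lapply(unique(tracks$roller_id), function(id) {
    sub <- tracks[tracks$roller_id == id, ]
    sub <- sub[order(sub$time_s), ]
    if (max(sub$time_s) + eps < ends[n_win]) {
      fit <- sum(ends <= max(sub$time_s) + eps)
      stop(sprintf(
        "trajectory of roller %s ends at %.3f s; only %d of %d actuation windows fit",
        id, max(sub$time_s), fit, n_win), call. = FALSE)
    }
    i0 <- findInterval(starts + eps, sub$time_s)
    i1 <- findInterval(ends + eps, sub$time_s)
    data.frame(condition = sub$condition[1], roller_id = id,
               window = seq_len(n_win), direction = dirs,
               t_start = starts, t_end = ends,
               x_start = sub$x_um[i0], y_start = sub$y_um[i0],
               x_end = sub$x_um[i1], y_end = sub$y_um[i1],
               stringsAsFactors = FALSE)
  })
  structure(rbind(out, do.call(rbind, res)),
            class = c("actuation_segments", "data.frame"))
}

#' Quality-control exclusion of dimers and mistracked rollers
#'
#' Removes rollers whose apparent diameter lies outside `diameter_limits`
#' (magnetically stuck bead pairs appear as one oversized blob) and rollers
#' whose linking was ever flagged as ambiguous.  Exclusions are recorded, with
#' reasons, in the `qc_log` attribute of the result.
#'
#' @param tracks A `track_table` with roller metadata.
#' @param diameter_limits Length-2 numeric, acceptable apparent diameters in
#'   um; default `c(7, 14)`, i.e. 0.7-1.4 times the 10-um nominal bead.
#' @param drop_flagged Also drop link-ambiguity-flagged rollers (default
#'   `TRUE`).
#'
#' @return The filtered `track_table`; `attr(, "qc_log")` is a data frame of
#'   `roller_id`, `reason` for every exclusion.  Raises an error if no roller
#'   survives.
#' @export
qc_exclude <- function(tracks, diameter_limits = c(7, 14),
                       drop_flagged = TRUE) {
  stopifnot(length(diameter_limits) == 2, diameter_limits[1] < diameter_limits[2])
  meta <- roller_metadata(tracks)
  d <- ifelse(is.na(meta$est_diameter_um), meta$diameter_um,
              meta$est_diameter_um)
  if (all(is.na(d)))
    stop("tracks carry no estimated diameters; run track_particles() or supply metadata",
         call. = FALSE)
  bad_d <- !is.na(d) & (d < diameter_limits[1] | d > diameter_limits[2])
  bad_f <- drop_flagged & meta$flagged %in% TRUE
  log <- rbind(
    data.frame(roller_id = meta$roller_id[bad_d],
               reason = sprintf("diameter %.1f um outside [%g, %g]",
                                d[bad_d], diameter_limits[1], diameter_limits[2])),
    data.frame(roller_id = meta$roller_id[bad_f & !bad_d],
               reason = rep("ambiguous link", sum(bad_f & !bad_d))))
  keep <- meta$roller_id[!(bad_d | bad_f)]
  if (!length(keep))
    stop("all rollers excluded by QC; nothing to analyze", call. = FALSE)
  out <- tracks[tracks$roller_id %in% keep, ]
  out <- new_track_table(as.data.frame(out),
                         rollers = meta[meta$roller_id %in% keep, ],
                         condition = attr(tracks, "condition"))
  attr(out, "qc_log") <- log
  out
}
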