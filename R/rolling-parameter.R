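# The rolling parameter RP = dx / (pi * D * tau * omega): per-actuation
# displacement of a roller normalised by the maximum theoretical displacement
# of a perfectly rolling sphere of diameter D rotated for tau seconds at
# omega Hz. 0 = no effective friction, 1 = perfect rolling.

#' Per-actuation displacement of a segment
#'
#' @param segments An `actuation_segments` data frame
#'   (see [segment_actuations()]).
#' @param mode `"magnitude"` (Euclidean norm of the 2D displacement, default)
#'   or `"axis_projection"` (absolute displacement along the rolling x-axis).
#'   The two agree when motion is axis-aligned; magnitude is direction
#'   agnostic and is used throughout the standard analysis.
#'
#' @return Numeric vector of displacements in micrometres, one per segment.
#' @export
displacement <- function(segments, mode = c("magnitude", "axis_projection")) {
  mode <- match.arg(mode)
  need <- c("x_start", "y_start", "x_end", "y_end")
  if (!all(need %in% names(segments)))
    stop("'segments' must carry start/end positions", call. = FALSE)
  dx <- segments$x_end - segments$x_start
  dy <- segments$y_end - segments$y_start
  if (any(!is.finite(dx)) || any(!is.finite(dy)))
    stop("segment positions must be finite", call. = FALSE)
  switch(mode,
         magnitude = sqrt(dx^2 + dy^2),
         axis_projection = abs(dx))
}

#' The rolling parameter
#'
#' `RP = delta_x / (pi * diameter * tau * omega)`.  Values are never clamped:
#' measurement noise can push an RP above 1, and such values are flagged with
#' a warning but returned unaltered so they stay auditable.
#'
#' @param delta_x Displacement over one actuation window, um, `>= 0`.
#' @param diameter Roller diameter D, um.
#' @param tau Actuation period, s.
#' @param omega Field rotation frequency, Hz.
#'
#' @return Unitless rolling parameter(s); 1 corresponds to a sphere rolling
#'   without slip for the whole window.
#' @examples
#' rolling_parameter(144.199, diameter = 10, tau = 5, omega = 1)  # ~0.918
#' @export
rolling_parameter <- function(delta_x, diameter, tau, omega) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("'diameter' must be > 0", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("'tau' must be > 0", call. = FALSE)
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("'omega' must be > 0", call. = FALSE)
  if (any(delta_x < 0)) stop("'delta_x' must be >= 0", call. = FALSE)
  rp <- delta_x / (pi * diameter * tau * omega)
  n_over <- sum(rp > 1)
  if (n_over > 0)
    warning(n_over, " rolling parameter(s) exceed 1 (noise above the ",
            "theoretical maximum); values kept unaltered", call. = FALSE)
  rp
}

new_rp_set <- function(df, condition) {
  rownames(df) <- NULL
  structure(df, condition = condition, class = c("rp_set", "data.frame"))
}

#' Construct a rolling-parameter set from raw values
#'
#' For rolling parameters that do not come out of the tracking pipeline
#' (external analyses, deposited per-roll tables already in long form).
#'
#' @param rp Numeric vector of rolling parameters.
#' @param roller_id Roller labels, recycled along `rp`.
#' @param condition Condition label.
#' @param window Actuation window indices; default numbers each roller's
#'   measurements consecutively.
#' @param direction Optional CW/CCW labels.
#' @param delta_x_um Optional raw displacements, um.
#' @return An `rp_set`.
#' @export
rp_set <- function(rp, roller_id = 1L, condition = "condition",
                   window = NULL, direction = NA_character_,
                   delta_x_um = NA_real_) {
  n <- length(rp)
  roller_id <- rep_len(roller_id, n)
  if (is.null(window))
    window <- if (n) stats::ave(seq_len(n), roller_id, FUN = seq_along)
              else integer(0)
  new_rp_set(data.frame(condition = rep_len(condition, n),
                        roller_id = roller_id, window = window,
                        direction = rep_len(direction, n),
                        delta_x_um = rep_len(delta_x_um, n), rp = rp,
                        stringsAsFactors = FALSE),
             condition = condition)
}

#' Rolling parameters from actuation segments
#'
#' Computes one rolling parameter per roller per actuation window.
#'
#' @param segments An `actuation_segments` data frame.
#' @param protocol The [actuation_protocol()] that produced the segments
#'   (source of `tau` and `omega`, which are controlled inputs, never
#'   inferred from the data).
#' @param diameter Roller diameter(s), um: a single value (nominal beads are
#'   10 um) or a named vector keyed by roller id.
#' @param mode Displacement mode, see [displacement()].
#'
#' @return An `rp_set`: data frame with columns `condition`, `roller_id`,
#'   `window`, `direction`, `delta_x_um`, `rp`.
#' @seealso [summary.rp_set()], [write_source_data()]
#' @export
rp_from_segments <- function(segments, protocol, diameter = 10,
                             mode = c("magnitude", "axis_projection")) {
  stopifnot(inherits(protocol, "actuation_protocol"))
  mode <- match.arg(mode)
  dx <- displacement(segments, mode)
  d <- if (length(diameter) == 1) rep(diameter, nrow(segments))
       else {
         if (is.null(names(diameter)))
           stop("multiple diameters must be named by roller id", call. = FALSE)
         unname(diameter[as.character(segments$roller_id)])
       }
  if (any(is.na(d))) stop("missing diameter for some rollers", call. = FALSE)
  rp <- rolling_parameter(dx, d, protocol$tau, protocol$omega)
  cond <- unique(segments$condition)
  new_rp_set(data.frame(condition = segments$condition,
                        roller_id = segments$roller_id,
                        window = segments$window,
                        direction = segments$direction,
                        delta_x_um = dx, rp = rp,
                        stringsAsFactors = FALSE),
             condition = if (length(cond)) cond[1] else NA_character_)
}

#' Summarise a rolling-parameter set
#'
#' Pools all per-actuation measurements of a condition and reports the mean,
#' SD and SEM over the pooled measurements (the reported "+/-" convention),
#' the per-roller means and their mean (rollers are the independent units; the
#' two aggregations agree exactly for balanced designs), the percent error
#' `100 * SEM / mean`, and normality diagnostics (skewness, excess kurtosis,
#' Shapiro-Wilk p) for the pooled distribution.
#'
#' @param object An `rp_set`.
#' @param ... Unused.
#' @return An object of class `rp_summary` (a list; see Details) with a print
#'   method.
#' @export
summary.rp_set <- function(object, ...) {
  if (!nrow(object)) stop("empty rolling-parameter set", call. = FALSE)
  rp <- object$rp
  n <- length(rp)
  roller_means <- tapply(rp, object$roller_id, mean)
  s <- stats::sd(rp)
  res <- list(
    condition = attr(object, "condition"),
    n_rollers = length(roller_means),
    n_measurements = n,
    mean = mean(rp),
    sd = s,
    sem = if (n > 1) s / sqrt(n) else 0,
    roller_means = roller_means,
    mean_of_roller_means = mean(roller_means),
    percent_error = if (mean(rp) != 0 && n > 1) 100 * s / sqrt(n) / mean(rp)
                    else 0,
    skewness = if (n > 2 && s > 0) e1071::skewness(rp) else 0,
    kurtosis = if (n > 3 && s > 0) e1071::kurtosis(rp) else 0,
    shapiro_p = if (n >= 3 && n <= 5000 && s > 0)
                  stats::shapiro.test(rp)$p.value else NA_real_)
  class(res) <- "rp_summary"
  res
}

#' @export
print.rp_summary <- function(x, ...) {
  cat(sprintf("Rolling parameters: %s\n", x$condition))
  cat(sprintf("  %d rollers, %d measurements\n", x$n_rollers, x$n_measurements))
  cat(sprintf("  mean RP %.3f +/- %.3f (SEM; SD %.3f, %%error %.2f%%)\n",
              x$mean, x$sem, x$sd, x$percent_error))
  cat(sprintf("  mean of roller means %.3f\n", x$mean_of_roller_means))
  cat(sprintf("  normality: skewness %.2f, excess kurtosis %.2f, Shapiro p %.3g\n",
              x$skewness, x$kurtosis, x$shapiro_p))
  invisible(x)
}

#' Write / read rolling parameters in the deposited source-data layout
#'
#' The deposited per-roll tables have one row per roller and one column per
#' actuation (`actuation_01` ... `actuation_36` for the standard protocol),
#' preceded by a `roller_id` column.  `write_source_data()` emits that layout;
#' `read_source_data()` ingests it (from this package or from a deposited
#' file) and returns an `rp_set`.  The round trip is lossless to full
#' precision.
#'
#' @param rp_set An `rp_set` with an equal number of actuations per roller
#'   (ragged sets are an error).
#' @param path File path (CSV).
#' @return `write_source_data()` returns `path` invisibly;
#'   `read_source_data()` returns an `rp_set` (with `delta_x_um = NA`, since
#'   the layout stores only the dimensionless RP).
#' @export
write_source_data <- function(rp_set, path) {
  stopifnot(inherits(rp_set, "rp_set"))
  counts <- table(rp_set$roller_id)
  if (nrow(rp_set) && length(unique(counts)) > 1)
    stop("ragged actuation counts per roller: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  n_win <- if (nrow(rp_set)) unique(counts) else 0L
  ids <- unique(rp_set$roller_id)
  wide <- matrix(NA_real_, length(ids), n_win,
                 dimnames = list(NULL, sprintf("actuation_%02d", seq_len(n_win))))
  for (i in seq_along(ids)) {
    sub <- rp_set[rp_set$roller_id == ids[i], ]
    wide[i, ] <- sub$rp[order(sub$window)]
  }
  out <- cbind(data.frame(roller_id = ids), as.data.frame(wide))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_source_data
#' @param condition Condition label to attach on read.
#' @param expected_windows Expected actuations per roller; a different count
#'   is accepted with a warning.
#' @export
read_source_data <- function(path, condition = NA_character_,
                             expected_windows = 36) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  has_id <- length(names(df)) && names(df)[1] == "roller_id"
  ids <- if (has_id) df[[1]] else seq_len(nrow(df))
  vals <- if (has_id) df[, -1, drop = FALSE] else df
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   if (is.na(bad)) 1L else bad, names(vals)[j]), call. = FALSE)
    }
  }
  n_win <- ncol(vals)
  if (nrow(vals) && n_win != expected_windows)
    warning(sprintf("expected %d actuations per roller, found %d",
                    expected_windows, n_win), call. = FALSE)
  if (!nrow(vals))
    return(new_rp_set(data.frame(condition = character(),
                                 roller_id = integer(), window = integer(),
                                 direction = character(),
                                 delta_x_um = numeric(), rp = numeric(),
                                 stringsAsFactors = FALSE), condition))
  long <- data.frame(
    condition = condition,
    roller_id = rep(ids, each = n_win),
    window = rep(seq_len(n_win), times = nrow(vals)),
    direction = NA_character_,
    delta_x_um = NA_real_,
    rp = as.vector(t(as.matrix(vals))),
    stringsAsFactors = FALSE)
  new_rp_set(long, condition)
}

#' One-call rolling-parameter pipeline for a track table
#'
#' Convenience wrapper chaining [segment_actuations()] and
#' [rp_from_segments()], using per-roller diameters from the track metadata
#' when available.
#'
#' @param tracks A `track_table`.
#' @param protocol An [actuation_protocol()].
#' @param t0 Protocol start time, s.
#' @param diameter Fallback diameter (um) for tracks without metadata.
#' @inheritParams rp_from_segments
#' @return An `rp_set`.
#' @export
rp_from_tracks <- function(tracks, protocol, t0 = 0, diameter = 10,
                           mode = c("magnitude", "axis_projection")) {
  mode <- match.arg(mode)
  seg <- segment_actuations(tracks, protocol, t0)
  meta <- roller_metadata(tracks)
  d <- meta$diameter_um
  if (all(is.na(d))) d <- rep(diameter, nrow(meta))
  names(d) <- as.character(meta$roller_id)
  rp_from_segments(seg, protocol, diameter = d, mode = mode)
}
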