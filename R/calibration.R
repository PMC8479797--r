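# Anchored log-log calibration of rolling parameter against dissociation
# constant. Across known interactions, log10(Kd) falls on a line in
# log10(RP) spanning ~15 orders of magnitude between a null anchor (Kd = 1 M)
# and the biotin-streptavidin anchor (Kd = 1e-15 M); unknown affinities are
# read off the fitted line by inverse prediction.

#' Build a calibration point table
#'
#' @param label Character labels, one per interaction.
#' @param rp Mean rolling parameter per interaction, `> 0`.
#' @param kd Dissociation constant in molar, `> 0`.
#' @param family Grouping label for the interaction system (e.g. one reader
#'   domain and its peptide series); rolling parameters from different
#'   systems are only comparable after scaling-factor correction.
#' @param kd_source `"literature"` or `"anchor"`.
#'
#' @return A data frame of class `calibration_points`.
#' @seealso [anchor_points()], [fit_calibration()]
#' @export
calibration_points <- function(label, rp, kd, family = "default",
                               kd_source = "literature") {
  if (any(!is.finite(rp)) || any(rp <= 0))
    stop("'rp' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be finite and > 0 M", call. = FALSE)
  structure(data.frame(label = label, family = family, rp = rp, kd = kd,
                       kd_source = kd_source, stringsAsFactors = FALSE),
            class = c("calibration_points", "data.frame"))
}

#' Anchor points for the calibration
#'
#' The two ends of the measurable range, entered into the fit as ordinary
#' points: a null interaction (streptavidin rolling on avidin) assigned
#' `Kd = 1 M`, and the essentially covalent biotin-streptavidin pair at
#' `Kd = 1e-15 M`.  Both rolling parameters default to the measured reference
#' values and both constants can be overridden.
#'
#' @param null_rp,null_kd Rolling parameter and assigned Kd of the null
#'   surface.
#' @param biotin_rp,biotin_kd Rolling parameter and Kd of
#'   biotin-streptavidin.
#' @param family Family label to attach.
#' @return A `calibration_points` table with two rows, `kd_source = "anchor"`.
#' @export
anchor_points <- function(null_rp = 0.081, null_kd = 1,
                          biotin_rp = 0.918, biotin_kd = 1e-15,
                          family = "default") {
  calibration_points(label = c("null", "biotin_streptavidin"),
                     rp = c(null_rp, biotin_rp), kd = c(null_kd, biotin_kd),
                     family = family, kd_source = "anchor")
}

#' Fit the log-log affinity calibration
#'
#' Ordinary least squares of `log10(kd)` on `log10(rp)`:
#' `log10(Kd) = a + b * log10(RP)`.  With exactly two points the line
#' interpolates both (R^2 reported as 1) but has no residual degrees of
#' freedom, so intervals are undefined.  A fit containing both anchors always
#' has `b < 0`: a higher rolling parameter means a tighter interaction.
#'
#' @param points A `calibration_points` table (or any data frame with `rp`
#'   and `kd` columns); at least two distinct `rp` values.
#'
#' @return An object of class `metris_calibration` with components `slope`,
#'   `intercept`, `r_squared`, `residual_sd`, `n`, `points`, `family`, and
#'   the underlying `lm` fit.  Supports `print()`, `summary()`, `coef()`,
#'   `predict()` ([predict.metris_calibration()]), `residuals()` and
#'   `plot()`.
#' @examples
#' fit <- fit_calibration(anchor_points())
#' coef(fit)                       # a ~ -15.53, b ~ -14.23
#' predict(fit, rp = 0.233)
#' @export
fit_calibration <- function(points) {
  if (!all(c("rp", "kd") %in% names(points)))
    stop("'points' needs 'rp' and 'kd' columns", call. = FALSE)
  if (any(points$rp <= 0) || any(points$kd <= 0))
    stop("rolling parameters and dissociation constants must be > 0",
         call. = FALSE)
  if (length(unique(points$rp)) < 2)
    stop("need at least 2 points with distinct rolling parameters",
         call. = FALSE)
  fit <- stats::lm(log10(kd) ~ log10(rp), data = points)
  # summary.lm warns on exactly collinear points; a perfect calibration line
  # is a legitimate input here (e.g. the two anchors plus a point on line)
  sm <- suppressWarnings(summary(fit))
  fam <- if ("family" %in% names(points)) unique(points$family) else "default"
  res <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (nrow(points) == 2) 1 else sm$r.squared,
    residual_sd = if (fit$df.residual > 0) sm$sigma else 0,
    n = nrow(points),
    df_residual = fit$df.residual,
    points = as.data.frame(points),
    family = if (length(fam) == 1) fam else "global",
    lm = fit)
  if (res$slope >= 0)
    warning("calibration slope is non-negative; higher RP should mean ",
            "tighter binding", call. = FALSE)
  class(res) <- "metris_calibration"
  res
}

#' @export
print.metris_calibration <- function(x, ...) {
  cat("Log-log affinity calibration (", x$family, ")\n", sep = "")
  cat(sprintf("  log10(Kd) = %.4f %+.4f * log10(RP)   [n = %d]\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4f, residual SD = %.4f log10 units\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' @export
coef.metris_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.metris_calibration <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
summary.metris_calibration <- function(object, ...) {
  pts <- object$points
  pts$log10_rp <- log10(pts$rp)
  pts$log10_kd <- log10(pts$kd)
  pts$residual <- stats::residuals(object$lm)
  structure(list(model = object, points = pts), class = "summary.metris_calibration")
}

#' @export
print.summary.metris_calibration <- function(x, ...) {
  print(x$model)
  cat("\nPoints:\n")
  print(x$points, digits = 4)
  invisible(x)
}

#' Predict dissociation constants from rolling parameters
#'
#' Inverse-reads the calibration: `Kd = 10^(a + b * log10(rp))`, with a 95%
#' interval obtained on the log10 scale from the t-distribution with `n - 2`
#' degrees of freedom and back-transformed.  The default interval is a
#' *prediction* interval (the extrapolated quantity is a new observation's
#' Kd); the narrower confidence interval of the mean line is available via
#' `interval = "confidence"`.  With a two-point model the interval is
#' undefined (zero residual degrees of freedom) and reported as `NA` with a
#' warning.
#'
#' @param object A `metris_calibration`.
#' @param rp Rolling parameter(s), `> 0`.
#' @param level Interval coverage, default 0.95.
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @param labels Optional labels for the estimates.
#' @param ... Unused.
#'
#' @return A data frame of class `affinity_estimate`: `label`, `rp`, `kd`
#'   (M), `kd_lower`, `kd_upper`.
#' @export
predict.metris_calibration <- function(object, rp, level = 0.95,
                                       interval = c("prediction", "confidence"),
                                       labels = NULL, ...) {
  interval <- match.arg(interval)
  if (any(!is.finite(rp)) || any(rp <= 0))
    stop("'rp' must be finite and > 0", call. = FALSE)
  nd <- data.frame(rp = rp)
  if (object$df_residual > 0) {
    p <- suppressWarnings(stats::predict(object$lm, newdata = nd,
                                         interval = interval, level = level))
    kd <- 10^p[, "fit"]; lo <- 10^p[, "lwr"]; hi <- 10^p[, "upr"]
  } else {
    warning("interval undefined: calibration has 0 residual degrees of freedom",
            call. = FALSE)
    kd <- 10^(object$intercept + object$slope * log10(rp))
    lo <- hi <- rep(NA_real_, length(rp))
  }
  structure(data.frame(label = if (is.null(labels)) as.character(seq_along(rp))
                               else labels,
                       rp = rp, kd = kd, kd_lower = lo, kd_upper = hi,
                       stringsAsFactors = FALSE),
            level = level, interval = interval,
            class = c("affinity_estimate", "data.frame"))
}

#' @export
plot.metris_calibration <- function(x, rp_grid = NULL, level = 0.95, ...) {
  pts <- x$points
  if (is.null(rp_grid))
    rp_grid <- 10^seq(log10(min(pts$rp)) - 0.2, log10(max(pts$rp)) + 0.2,
                      length.out = 100)
  graphics::plot(log10(pts$rp), log10(pts$kd),
                 xlab = "log10(rolling parameter)", ylab = "log10(Kd / M)",
                 pch = ifelse(pts$kd_source %in% "anchor", 17, 19), ...)
  graphics::abline(x$intercept, x$slope)
  if (x$df_residual > 0) {
    p <- stats::predict(x$lm, newdata = data.frame(rp = rp_grid),
                        interval = "prediction", level = level)
    graphics::lines(log10(rp_grid), p[, "lwr"], lty = 2)
    graphics::lines(log10(rp_grid), p[, "upr"], lty = 2)
  }
  invisible(x)
}

#' Scaling factor against published affinities
#'
#' Rolling parameters from different interaction systems are not directly
#' comparable, but within one system the deviations of the calibrated Kd from
#' the published Kd are systematic.  The scaling factor of a family is the
#' arithmetic mean of the ratios `published / calibrated`; multiplying the
#' calibrated values by it places them on the literature scale while leaving
#' every within-family fold change and free-energy difference untouched.
#'
#' @param published Published dissociation constants, M.
#' @param metris Calibrated (extrapolated) dissociation constants, M, same
#'   length and order.
#' @param family Optional family label vector; supplying more than one
#'   distinct family is an error, since factors are defined per family.
#'
#' @return The scaling factor (a single positive number).
#' @export
scaling_factor <- function(published, metris, family = NULL) {
  if (length(published) != length(metris) || !length(published))
    stop("'published' and 'metris' must be equal-length, non-empty",
         call. = FALSE)
  if (any(published <= 0) || any(metris <= 0))
    stop("dissociation constants must be > 0", call. = FALSE)
  if (!is.null(family) && length(unique(family)) > 1)
    stop("scaling factors are per-family; got families: ",
         paste(unique(family), collapse = ", "), call. = FALSE)
  mean(published / metris)
}

#' @rdname scaling_factor
#' @param estimates An `affinity_estimate` (or numeric Kd vector).
#' @param factor A scaling factor from `scaling_factor()`.
#' @return `apply_scaling()` returns the estimates with `kd` (and interval
#'   bounds, when present) multiplied by the factor; a numeric input returns
#'   a numeric.
#' @export
apply_scaling <- function(estimates, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  if (is.numeric(estimates)) return(estimates * factor)
  stopifnot(is.data.frame(estimates))
  for (col in intersect(c("kd", "kd_lower", "kd_upper"), names(estimates)))
    estimates[[col]] <- estimates[[col]] * factor
  estimates$scaled <- TRUE
  estimates
}

#' Compare per-family and global calibrations
#'
#' Fits one calibration per family plus a pooled global calibration and
#' reports slopes, intercepts, R^2 and residual spreads side by side,
#' together with per-point residuals from the global fit.  A family whose
#' mean global-fit residual exceeds that family's own residual SD (its
#' internal scatter around its own line) is flagged as deviating
#' systematically -- the situation the scaling-factor correction exists for.
#'
#' @param points A `calibration_points` table with a `family` column.
#' @return A list of class `metris_fit_report`: `models` (comparison data
#'   frame), `residuals` (per point), `family_flags` (per family), and the
#'   fitted model objects in `fits`.
#' @export
fit_report <- function(points) {
  if (!"family" %in% names(points)) points$family <- "default"
  fams <- unique(points$family)
  fits <- lapply(fams, function(f) fit_calibration(points[points$family == f, ]))
  names(fits) <- fams
  global <- fit_calibration(points)
  global$family <- "global"
  all_fits <- c(fits, list(global = global))
  models <- do.call(rbind, lapply(names(all_fits), function(nm) {
    m <- all_fits[[nm]]
    data.frame(model = nm, n = m$n, slope = m$slope, intercept = m$intercept,
               r_squared = m$r_squared, residual_sd = m$residual_sd,
               stringsAsFactors = FALSE)
  }))
  res <- data.frame(label = points$label, family = points$family,
                    residual = stats::residuals(global$lm),
                    stringsAsFactors = FALSE)
  fam_mean <- tapply(res$residual, res$family, mean)
  fam_sd <- vapply(names(fam_mean), function(f) fits[[f]]$residual_sd,
                   numeric(1))
  flags <- data.frame(family = names(fam_mean),
                      mean_residual = as.numeric(fam_mean),
                      family_residual_sd = unname(fam_sd),
                      flagged = abs(as.numeric(fam_mean)) > unname(fam_sd),
                      stringsAsFactors = FALSE)
  structure(list(models = models, residuals = res, family_flags = flags,
                 fits = all_fits),
            class = "metris_fit_report")
}

#' @export
print.metris_fit_report <- function(x, ...) {
  cat("Calibration comparison (per family + global):\n")
  print(x$models, digits = 4, row.names = FALSE)
  if (any(x$family_flags$flagged)) {
    cat("\nFamilies deviating systematically from the global fit:\n")
    print(x$family_flags[x$family_flags$flagged, ], digits = 3,
          row.names = FALSE)
  }
  invisible(x)
}

#' Serialise / restore a calibration as JSON
#'
#' Stores the coefficients, fit statistics and the full point table; reading
#' refits the stored points, so the round trip is exact.
#'
#' @param model A `metris_calibration`.
#' @param path File path (JSON).
#' @return `read_calibration()` returns a `metris_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "metris_calibration"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept, n = model$n,
         r_squared = model$r_squared, residual_sd = model$residual_sd,
         family = model$family, points = model$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- fit_calibration(obj$points)
  model$family <- obj$family
  model
}
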