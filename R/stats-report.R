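# Condition comparison, microarray-style normalisation, and report tables.

#' Compare two rolling-parameter distributions
#'
#' Unpaired two-tailed Student's t-test between two conditions.  The default
#' is the classical pooled-variance test on the individual per-actuation
#' measurements (the convention of the assay: N rollers x 36 rolls per
#' condition).  Because rolls within one roller are not independent, a
#' conservative roller-level alternative (`unit = "roller"`, comparing
#' per-roller means) and Welch's unequal-variance test (`var_equal = FALSE`)
#' are available.
#'
#' @param a,b `rp_set` objects (see [rp_from_segments()]).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param unit `"measurement"` (pool all rolls, default) or `"roller"`
#'   (per-roller means).
#'
#' @return An object of class `rp_comparison`: conditions, `t`, `df`, `p`,
#'   group sizes, means, mean difference, and percent error
#'   (`100 * SEM / mean`) per group.  Swapping the groups negates `t` and
#'   leaves `p` unchanged.  If both groups are degenerate (zero variance)
#'   with equal means, `t = 0` and `p = 1`.
#' @export
compare_conditions <- function(a, b, var_equal = TRUE,
                               unit = c("measurement", "roller")) {
  unit <- match.arg(unit)
  stopifnot(inherits(a, "rp_set"), inherits(b, "rp_set"))
  pick <- function(s) switch(unit,
                             measurement = s$rp,
                             roller = as.numeric(tapply(s$rp, s$roller_id, mean)))
  xa <- pick(a); xb <- pick(b)
  if (length(xa) < 2 || length(xb) < 2)
    stop("each condition needs at least 2 observations", call. = FALSE)
  pe <- function(x) if (mean(x) != 0)
    100 * stats::sd(x) / sqrt(length(x)) / abs(mean(x)) else NA_real_
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    if (mean(xa) == mean(xb)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(xa) + length(xb) - 2),
                 p.value = 1)
    } else stop("zero variance in both groups with unequal means", call. = FALSE)
  } else {
    tt <- stats::t.test(xa, xb, var.equal = var_equal,
                        alternative = "two.sided")
  }
  structure(list(
    condition_a = attr(a, "condition"), condition_b = attr(b, "condition"),
    unit = unit, pooled = var_equal,
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    n_a = length(xa), n_b = length(xb),
    mean_a = mean(xa), mean_b = mean(xb),
    mean_difference = mean(xa) - mean(xb),
    percent_error_a = pe(xa), percent_error_b = pe(xb)),
    class = "rp_comparison")
}

#' @export
print.rp_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s level, %s t-test)\n", x$condition_a, x$condition_b,
              x$unit, if (x$pooled) "pooled" else "Welch"))
  cat(sprintf("  means %.4f vs %.4f (diff %+.4f), n = %d vs %d\n",
              x$mean_a, x$mean_b, x$mean_difference, x$n_a, x$n_b))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  cat(sprintf("  percent error: %.2f%% vs %.2f%%\n",
              x$percent_error_a, x$percent_error_b))
  invisible(x)
}

#' Min-max normalisation of peptide-array intensities
#'
#' For a single numeric vector, linearly rescales so the minimum maps to 0
#' and the maximum to 1.  For one array given as a matrix (peptides x
#' replicate spots), replicate intensities are averaged per peptide first and
#' the means rescaled.  For a list of such arrays each is normalised
#' independently and then combined into a per-peptide mean and SD across
#' arrays.
#'
#' @param x Numeric vector, matrix/data frame with peptides in rows and
#'   replicates in columns, or a list of such matrices (the arrays).
#' @return For vector/matrix input, the scaled numeric vector (named by row
#'   names when present).  For a list, a data frame `peptide`, `mean`, `sd`.
#'   A constant array (no distinct values) is an error: the scaling is
#'   undefined.
#' @export
minmax_normalize_array <- function(x) {
  scale1 <- function(v) {
    if (any(!is.finite(v))) stop("intensities must be finite", call. = FALSE)
    rng <- range(v)
    if (rng[1] == rng[2])
      stop("constant array: min-max scaling undefined", call. = FALSE)
    (v - rng[1]) / (rng[2] - rng[1])
  }
  one <- function(arr) {
    if (is.data.frame(arr)) arr <- as.matrix(arr)
    if (is.matrix(arr)) {
      m <- rowMeans(arr)
      s <- scale1(m)
      names(s) <- rownames(arr)
      s
    } else scale1(arr)
  }
  if (is.list(x) && !is.data.frame(x)) {
    scaled <- lapply(x, one)
    lens <- lengths(scaled)
    if (length(unique(lens)) != 1)
      stop("arrays have differing peptide counts", call. = FALSE)
    mat <- do.call(cbind, scaled)
    data.frame(peptide = if (is.null(rownames(mat)))
                 as.character(seq_len(nrow(mat))) else rownames(mat),
               mean = rowMeans(mat),
               sd = apply(mat, 1, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  } else one(x)
}

#' Build the per-condition affinity report
#'
#' Assembles the standard results table: one row per condition with the mean
#' rolling parameter and its SEM, the calibrated Kd with its 95% interval,
#' the fold change and free-energy difference against a stated reference
#' condition, and, when published affinities are supplied, the
#' scaling-factor-corrected Kd.
#'
#' @param rpsets Named list of `rp_set` objects (names are condition labels),
#'   or a list of `rp_summary` objects.
#' @param model A `metris_calibration`.
#' @param reference Label of the reference condition for fold changes and
#'   delta-delta-G (its own row shows fold change 1 and ddG 0).
#' @param published Optional named numeric vector of published Kd values (M)
#'   for a subset of the conditions; used to compute one scaling factor for
#'   the whole (single-family) report and the `scaled_kd` column.
#' @param temperature Temperature for free energies, K.
#'
#' @return A data frame of class `metris_report` with one row per condition;
#'   attributes carry the scaling factor (if any) and the model.  Label
#'   mismatches (unknown reference, published names not among the conditions)
#'   raise errors listing the orphans.
#' @seealso [write_report()]
#' @export
build_report <- function(rpsets, model, reference, published = NULL,
                         temperature = 298) {
  stopifnot(inherits(model, "metris_calibration"))
  sums <- lapply(rpsets, function(s)
    if (inherits(s, "rp_summary")) s else summary(s))
  labels <- if (!is.null(names(rpsets)) && all(nzchar(names(rpsets))))
    names(rpsets) else vapply(sums, `[[`, character(1), "condition")
  if (anyDuplicated(labels))
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (!reference %in% labels)
    stop("reference condition '", reference, "' not among: ",
         paste(labels, collapse = ", "), call. = FALSE)
  if (!is.null(published)) {
    orphans <- setdiff(names(published), labels)
    if (length(orphans))
      stop("published Kd labels not among the conditions: ",
           paste(orphans, collapse = ", "), call. = FALSE)
  }

  mean_rp <- vapply(sums, `[[`, numeric(1), "mean")
  est <- predict(model, rp = mean_rp, labels = labels)
  kd_ref <- est$kd[match(reference, labels)]
  report <- data.frame(
    condition = labels,
    n_rollers = vapply(sums, `[[`, numeric(1), "n_rollers"),
    n_measurements = vapply(sums, `[[`, numeric(1), "n_measurements"),
    mean_rp = mean_rp,
    sem_rp = vapply(sums, `[[`, numeric(1), "sem"),
    percent_error = vapply(sums, `[[`, numeric(1), "percent_error"),
    kd = est$kd, kd_lower = est$kd_lower, kd_upper = est$kd_upper,
    fold_change = fold_change(est$kd, kd_ref),
    ddg_kcal_mol = delta_delta_g(est$kd, kd_ref, temperature = temperature),
    row.names = NULL, stringsAsFactors = FALSE)

  factor <- NA_real_
  if (!is.null(published)) {
    idx <- match(names(published), labels)
    factor <- scaling_factor(unname(published), report$kd[idx])
    report$scaled_kd <- report$kd * factor
    report$published_kd <- NA_real_
    report$published_kd[idx] <- unname(published)
  }
  structure(report, reference = reference, scaling_factor = factor,
            temperature = temperature,
            class = c("metris_report", "data.frame"))
}

#' @export
print.metris_report <- function(x, ...) {
  cat(sprintf("Affinity report (reference: %s", attr(x, "reference")))
  if (!is.na(attr(x, "scaling_factor")))
    cat(sprintf(", scaling factor %.3g", attr(x, "scaling_factor")))
  cat(")\n")
  fmt <- as.data.frame(x)
  fmt$mean_rp <- sprintf("%.3f +/- %.3f", x$mean_rp, x$sem_rp)
  fmt$sem_rp <- NULL
  for (col in intersect(c("kd", "kd_lower", "kd_upper", "scaled_kd",
                          "published_kd"), names(fmt)))
    fmt[[col]] <- signif(fmt[[col]], 3)
  fmt$ddg_kcal_mol <- round(fmt$ddg_kcal_mol, 1)  # report to one decimal
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write a report to CSV and JSON
#'
#' @param report A `metris_report`.
#' @param dir Output directory (created if needed); writes `report.csv` and
#'   `report.json`.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "metris_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(report), file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(reference = attr(report, "reference"),
         scaling_factor = attr(report, "scaling_factor"),
         temperature = attr(report, "temperature"),
         rows = as.data.frame(report)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
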