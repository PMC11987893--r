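# SEUROP grading: equation evaluation, class assignment, and
# population-level comparison of two prediction equations.

seurop_levels <- c("S", "E", "U", "R", "O", "P")

#' Predict lean meat percentage from probe measurements
#'
#' Evaluates a prediction equation at backfat depth F2 and loin depth M2.
#' Predictions falling outside [0, 100] are clamped with a warning rather
#' than rejected, since extreme but real carcasses occur in commercial
#' populations.
#'
#' @param eq a [prediction_equation()].
#' @param f2 backfat depth(s), mm (positive).
#' @param m2 loin depth(s), mm (positive).
#' @return predicted LMP (percent), vectorized over `f2`/`m2`.
#' @examples
#' predict_lmp(cgm_equation("2023"), f2 = 13.86, m2 = 62.20)
#' @export
predict_lmp <- function(eq, f2, m2) {
  if (!inherits(eq, "prediction_equation"))
    stop("'eq' must be a prediction_equation", call. = FALSE)
  if (any(!is.finite(f2)) || any(!is.finite(m2)))
    stop("'f2' and 'm2' must be finite", call. = FALSE)
  if (any(f2 <= 0) || any(m2 <= 0))
    stop("'f2' and 'm2' must be positive", call. = FALSE)
  y <- eq$intercept + eq$coef_f2 * f2 + eq$coef_m2 * m2
  out <- sum(y < 0 | y > 100)
  if (out > 0) {
    warning(out, " prediction(s) outside [0, 100] clamped", call. = FALSE)
    y <- pmin(pmax(y, 0), 100)
  }
  y
}

#' Assign SEUROP classes
#'
#' Maps lean meat percentages to the six-class EU scale. The default
#' thresholds encode the standard grid — S >= 60, E in [55, 60),
#' U in [50, 55), R in [45, 50), O in [40, 45), P < 40 — lower-inclusive;
#' they are a parameter, not a constant, because member-state scales can
#' differ at the S/E boundary.
#'
#' @param lmp lean meat percentage(s), in (0, 100].
#' @param thresholds named decreasing vector of lower class bounds for all
#'   classes except the lowest.
#' @return a factor with levels `S, E, U, R, O, P` (best to worst).
#' @export
classify_seurop <- function(lmp, thresholds = c(S = 60, E = 55, U = 50,
                                                R = 45, O = 40)) {
  if (any(!is.finite(lmp)) || any(lmp <= 0) || any(lmp > 100))
    stop("'lmp' must lie in (0, 100]", call. = FALSE)
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("'thresholds' must be strictly decreasing", call. = FALSE)
  labels <- c(names(thresholds), setdiff(seurop_levels,
                                         names(thresholds))[1])
  idx <- length(thresholds) + 1L - findInterval(lmp, rev(thresholds))
  factor(labels[idx], levels = labels)
}

#' Class structure of a carcass population
#'
#' Tabulates counts and shares per SEUROP class.
#'
#' @param lmp lean meat percentages, or an already-classified factor from
#'   [classify_seurop()].
#' @param thresholds passed to [classify_seurop()] when `lmp` is numeric.
#' @return an object of class `class_structure` with integer `counts`,
#'   proportion `shares` and `n_total`.
#' @export
class_structure <- function(lmp, thresholds = c(S = 60, E = 55, U = 50,
                                                R = 45, O = 40)) {
  if (length(lmp) == 0L) stop("'lmp' is empty", call. = FALSE)
  cls <- if (is.factor(lmp)) lmp else classify_seurop(lmp, thresholds)
  counts <- table(cls)
  structure(list(counts = as.vector(counts),
                 shares = as.vector(counts) / length(cls),
                 labels = names(counts),
                 n_total = length(cls)),
            class = "class_structure")
}

#' @export
print.class_structure <- function(x, ...) {
  cat("SEUROP class structure (n =", format(x$n_total, big.mark = ","),
      ")\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %s: %6.2f%%  (%s)\n", x$labels[i], 100 * x$shares[i],
                format(x$counts[i], big.mark = ",")))
  invisible(x)
}

#' Compare two prediction equations on a carcass population
#'
#' Evaluates both equations on every carcass and summarizes the
#' population-level consequences of switching equations: the mean LMP under
#' each, the mean shift in percentage points, the class-migration matrix
#' (rows = class under the old equation, columns = under the new), the two
#' class structures, and 1-percentage-point LMP histograms.
#'
#' @param carcasses data frame with `f2_mm` and `m2_mm` columns.
#' @param eq_old,eq_new [prediction_equation()] objects.
#' @param thresholds SEUROP class bounds (see [classify_seurop()]).
#' @param hist_breaks histogram bin edges for the LMP distributions;
#'   predictions outside the span are counted in `n_outside_hist`.
#' @return an object of class `equation_comparison`.
#' @export
compare_equations <- function(carcasses, eq_old, eq_new,
                              thresholds = c(S = 60, E = 55, U = 50,
                                             R = 45, O = 40),
                              hist_breaks = seq(30, 75, by = 1)) {
  if (NROW(carcasses) == 0L) stop("'carcasses' is empty", call. = FALSE)
  lmp_old <- predict_lmp(eq_old, carcasses$f2_mm, carcasses$m2_mm)
  lmp_new <- predict_lmp(eq_new, carcasses$f2_mm, carcasses$m2_mm)
  cls_old <- classify_seurop(lmp_old, thresholds)
  cls_new <- classify_seurop(lmp_new, thresholds)
  migration <- table(old = cls_old, new = cls_new)
  hist_counts <- function(x) {
    inside <- x >= hist_breaks[1] & x <= hist_breaks[length(hist_breaks)]
    h <- graphics::hist(x[inside], breaks = hist_breaks, plot = FALSE,
                        right = FALSE, include.lowest = TRUE)
    list(counts = h$counts, n_outside = sum(!inside))
  }
  h_old <- hist_counts(lmp_old)
  h_new <- hist_counts(lmp_new)
  structure(list(
    mean_lmp_old = mean(lmp_old),
    mean_lmp_new = mean(lmp_new),
    mean_shift = mean(lmp_new) - mean(lmp_old),
    class_migration = migration,
    structure_old = class_structure(cls_old),
    structure_new = class_structure(cls_new),
    hist_breaks = hist_breaks,
    hist_old = h_old$counts,
    hist_new = h_new$counts,
    n_outside_hist = c(old = h_old$n_outside, new = h_new$n_outside),
    eq_old = eq_old, eq_new = eq_new,
    n = NROW(carcasses)
  ), class = "equation_comparison")
}

#' @export
print.equation_comparison <- function(x, ...) {
  cat("Equation comparison on", format(x$n, big.mark = ","), "carcasses\n")
  cat("  old: "); print(x$eq_old)
  cat("  new: "); print(x$eq_new)
  cat(sprintf("  mean LMP: %.2f%% (old) -> %.2f%% (new); shift %+.2f pp\n",
              x$mean_lmp_old, x$mean_lmp_new, x$mean_shift))
  cat("  class shares (old -> new):\n")
  for (i in seq_along(x$structure_old$labels))
    cat(sprintf("    %s: %6.2f%% -> %6.2f%%\n", x$structure_old$labels[i],
                100 * x$structure_old$shares[i],
                100 * x$structure_new$shares[i]))
  invisible(x)
}
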