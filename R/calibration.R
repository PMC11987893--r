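# Device-equation fitting: PLS1 (NIPALS) on the two probe measurements,
# PRESS/leave-one-out cross-validation of RMSEP, authorization verdict.

# normalize a calibration data frame to columns f2, m2, lmp_ref
as_calibration_df <- function(data) {
  d <- as.data.frame(data)
  alias <- c(f2 = "f2_mm", m2 = "m2_mm")
  for (nm in names(alias))
    if (!nm %in% names(d) && alias[[nm]] %in% names(d))
      d[[nm]] <- d[[alias[[nm]]]]
  miss <- setdiff(c("f2", "m2", "lmp_ref"), names(d))
  if (length(miss))
    stop("calibration data must have columns f2 (or f2_mm), m2 (or m2_mm), ",
         "lmp_ref; missing: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(d[c("f2", "m2", "lmp_ref")]))
    stop("calibration data contain missing values", call. = FALSE)
  d[c("f2", "m2", "lmp_ref")]
}

# NIPALS PLS1 on centered data; returns coefficients on the original scale
pls1_fit <- function(X, y, n_components) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Xa <- Xc
  ya <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("degenerate component ", a,
           ": predictors carry no residual covariance with the response ",
           "(collinear or constant predictors)", call. = FALSE)
    w <- w / nw
    t_ <- drop(Xa %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12)
      stop("degenerate score vector in component ", a, call. = FALSE)
    P[, a] <- drop(crossprod(Xa, t_)) / tt
    q[a] <- sum(ya * t_) / tt
    W[, a] <- w
    Xa <- Xa - tcrossprod(t_, P[, a])
    ya <- ya - t_ * q[a]
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = drop(B), intercept = ybar - sum(xbar * drop(B)))
}

#' A device prediction equation
#'
#' A linear lean-meat prediction equation of the form
#' `LMP = intercept + coef_f2 * F2 + coef_m2 * M2`, with F2 the backfat
#' depth (mm) and M2 the loin muscle depth (mm) at the third/fourth-last
#' rib, 6 cm off the dorsal midline.
#'
#' @param intercept intercept (percent lean meat).
#' @param coef_f2 coefficient on backfat depth (% per mm, typically
#'   negative).
#' @param coef_m2 coefficient on loin depth (% per mm, typically positive).
#' @param label provenance label (e.g. `"CGM 2023"`).
#' @return an object of class `prediction_equation`.
#' @seealso [cgm_equation()] for the published CGM coefficients.
#' @export
prediction_equation <- function(intercept, coef_f2, coef_m2,
                                label = "custom") {
  for (nm in c("intercept", "coef_f2", "coef_m2"))
    stop_if_not_scalar_number(get(nm), nm)
  structure(list(intercept = intercept, coef_f2 = coef_f2,
                 coef_m2 = coef_m2, label = label),
            class = "prediction_equation")
}

#' @export
print.prediction_equation <- function(x, ...) {
  cat(sprintf("LMP = %.4f %+.4f*F2 %+.4f*M2   [%s]\n",
              x$intercept, x$coef_f2, x$coef_m2, x$label))
  invisible(x)
}

#' Published CGM prediction equations
#'
#' The lean-meat prediction equations authorized for the CGM optical-needle
#' probe in Poland: the 2011 equation
#' `LMP = 59.42 - 0.6275 F2 + 0.1322 M2` and the 2023 equation
#' `LMP = 60.7538 - 0.6465 F2 + 0.1243 M2`.
#'
#' @param year `"2023"` or `"2011"`.
#' @return a [prediction_equation()].
#' @export
cgm_equation <- function(year = c("2023", "2011")) {
  year <- match.arg(as.character(year), c("2023", "2011"))
  switch(year,
         "2023" = prediction_equation(60.7538, -0.6465, 0.1243,
                                      label = "CGM 2023"),
         "2011" = prediction_equation(59.42, -0.6275, 0.1322,
                                      label = "CGM 2011"))
}

#' Fit a prediction equation by partial least squares
#'
#' Fits the lean-meat prediction equation from (F2, M2, reference LMP)
#' triples using PLS1 (NIPALS) on centered predictors — the
#' regression family permitted for grading-device calibration. With two
#' predictors and `n_components = 2` (full rank) the PLS solution
#' coincides with ordinary least squares, which is the default and serves
#' as a numerical anchor; `n_components = 1` gives the shrunken
#' single-component fit.
#'
#' @param data data frame with columns `f2`/`f2_mm`, `m2`/`m2_mm`,
#'   `lmp_ref`.
#' @param n_components number of latent components (1 or 2).
#' @return a [prediction_equation()] labelled with the fit provenance.
#' @export
fit_pls_pcr <- function(data, n_components = 2) {
  d <- as_calibration_df(data)
  if (!n_components %in% c(1, 2))
    stop("'n_components' must be 1 or 2", call. = FALSE)
  if (nrow(d) < n_components + 1)
    stop("need at least n_components + 1 = ", n_components + 1,
         " observations", call. = FALSE)
  X <- as.matrix(d[c("f2", "m2")])
  f <- pls1_fit(X, d$lmp_ref, n_components)
  prediction_equation(f$intercept, f$coef[1], f$coef[2],
                      label = sprintf("PLS fit (%d component%s, n = %d)",
                                      n_components,
                                      if (n_components > 1) "s" else "",
                                      nrow(d)))
}

#' Cross-validated prediction error (RMSEP) via PRESS
#'
#' Computes the root mean squared error of prediction from the PRESS
#' statistic: each observation (leave-one-out, the classical PRESS) or each
#' fold (`folds = k`) is held out, the equation is refitted on the
#' remainder, and the held-out residuals are pooled:
#' `RMSEP = sqrt(sum((y_i - yhat_(-i))^2) / n)`.
#'
#' @param data calibration data frame (see [fit_pls_pcr()]).
#' @param n_components number of PLS components.
#' @param folds `NULL` for leave-one-out, or an integer number of folds
#'   (assigned round-robin after a seeded shuffle).
#' @param seed seed for the fold shuffle (k-fold only).
#' @return the RMSEP in lean-meat percentage points.
#' @export
press_loo_rmsep <- function(data, n_components = 2, folds = NULL,
                            seed = NULL) {
  d <- as_calibration_df(data)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  X <- as.matrix(d[c("f2", "m2")])
  y <- d$lmp_ref
  fold_id <- if (is.null(folds)) {
    seq_len(n)
  } else {
    if (folds < 2 || folds > n)
      stop("'folds' must be between 2 and n", call. = FALSE)
    with_seed(seed, sample(rep_len(seq_len(folds), n)))
  }
  press <- 0
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    fit <- pls1_fit(X[!hold, , drop = FALSE], y[!hold], n_components)
    pred <- fit$intercept + X[hold, , drop = FALSE] %*% fit$coef
    press <- press + sum((y[hold] - pred)^2)
  }
  sqrt(press / n)
}

#' Authorization verdict for a grading device
#'
#' A tested device is authorized when its cross-validated RMSEP is strictly
#' below the regulatory limit (2.5 lean-meat percentage points by default).
#'
#' @param rmsep cross-validated RMSEP (percentage points, non-negative).
#' @param limit authorization limit.
#' @return `TRUE` if authorized.
#' @export
authorize <- function(rmsep, limit = 2.5) {
  if (!is.finite(rmsep) || rmsep < 0)
    stop("'rmsep' must be non-negative", call. = FALSE)
  rmsep < limit
}

#' Full calibration of a grading device
#'
#' Convenience wrapper chaining [fit_pls_pcr()], [press_loo_rmsep()] and
#' [authorize()] into a single calibration report.
#'
#' @inheritParams press_loo_rmsep
#' @param limit RMSEP authorization limit.
#' @return an object of class `calibration_report` with `equation`,
#'   `rmsep`, `n`, `n_components`, `authorized`.
#' @export
calibrate <- function(data, n_components = 2, folds = NULL, limit = 2.5,
                      seed = NULL) {
  d <- as_calibration_df(data)
  eq <- fit_pls_pcr(d, n_components)
  rmsep <- press_loo_rmsep(d, n_components, folds = folds, seed = seed)
  structure(list(equation = eq, rmsep = rmsep, n = nrow(d),
                 n_components = n_components, limit = limit,
                 authorized = authorize(rmsep, limit)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Grading-device calibration (n =", x$n, ")\n  ")
  print(x$equation)
  cat(sprintf("  RMSEP (cross-validated) = %.4f pp; limit %.2f -> %s\n",
              x$rmsep, x$limit,
              if (x$authorized) "AUTHORIZED" else "NOT authorized"))
  invisible(x)
}
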