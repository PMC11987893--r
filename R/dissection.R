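#' Cut weights of one half carcass
#'
#' Container for the weights entering the EU reference (partial) dissection:
#' the tenderloin plus the joint (pre-dissection) and lean weights of the
#' shoulder, loin, ham and belly, the half-carcass weight, and — when a
#' total dissection was performed — the total lean weight.
#'
#' @param tenderloin tenderloin weight (kg).
#' @param joint_shoulder,joint_loin,joint_ham,joint_belly joint weights
#'   before dissection (kg).
#' @param lean_shoulder,lean_loin,lean_ham,lean_belly lean meat weights
#'   after dissection (kg); each must not exceed its joint weight.
#' @param half_carcass_weight weight of the half carcass (kg).
#' @param total_lean_weight total lean of the half carcass (kg), from total
#'   dissection; `NA` when only a partial dissection was done.
#' @return an object of class `cut_weights` (a named list).
#' @export
cut_weights <- function(tenderloin,
                        joint_shoulder, joint_loin, joint_ham, joint_belly,
                        lean_shoulder, lean_loin, lean_ham, lean_belly,
                        half_carcass_weight,
                        total_lean_weight = NA_real_) {
  w <- list(tenderloin = tenderloin,
            joint_shoulder = joint_shoulder, joint_loin = joint_loin,
            joint_ham = joint_ham, joint_belly = joint_belly,
            lean_shoulder = lean_shoulder, lean_loin = lean_loin,
            lean_ham = lean_ham, lean_belly = lean_belly,
            half_carcass_weight = half_carcass_weight,
            total_lean_weight = total_lean_weight)
  num <- unlist(w[1:10])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all cut weights must be finite and non-negative", call. = FALSE)
  joints <- c(joint_shoulder, joint_loin, joint_ham, joint_belly)
  leans <- c(lean_shoulder, lean_loin, lean_ham, lean_belly)
  if (any(leans > joints + 1e-9))
    stop("lean weight exceeds joint weight for at least one cut",
         call. = FALSE)
  if (tenderloin + sum(joints) > half_carcass_weight + 1e-9)
    stop("cut weights exceed the half-carcass weight", call. = FALSE)
  if (!is.na(total_lean_weight) &&
      total_lean_weight > half_carcass_weight + 1e-9)
    stop("total lean weight exceeds the half-carcass weight", call. = FALSE)
  structure(w, class = "cut_weights")
}

#' @export
print.cut_weights <- function(x, ...) {
  cat(sprintf("Half carcass %.2f kg; tenderloin %.3f kg\n",
              x$half_carcass_weight, x$tenderloin))
  cuts <- c("shoulder", "loin", "ham", "belly")
  for (cc in cuts)
    cat(sprintf("  %-8s joint %.3f kg, lean %.3f kg\n", cc,
                x[[paste0("joint_", cc)]], x[[paste0("lean_", cc)]]))
  if (!is.na(x$total_lean_weight))
    cat(sprintf("  total lean (full dissection) %.3f kg\n",
                x$total_lean_weight))
  invisible(x)
}

as_cut_weights_df <- function(cw) {
  if (inherits(cw, "cut_weights")) cw <- as.data.frame(unclass(cw))
  cw
}

#' Partial-dissection lean meat percentage (YPD)
#'
#' The EU reference-method statistic: 100 times the tenderloin plus the
#' lean of the four dissected cuts (shoulder, loin, ham, belly), divided by
#' the tenderloin plus the four joint weights before dissection.
#'
#' @param cw a [cut_weights()] object, or a data frame with one row per
#'   carcass and the `cut_weights` columns.
#' @return lean meat percentage(s) in (0, 100].
#' @examples
#' cw <- cut_weights(0.4, 8, 7, 10, 5, 6, 5, 8, 2,
#'                   half_carcass_weight = 45)
#' compute_ypd(cw)  # 100 * 21.4 / 30.4
#' @export
compute_ypd <- function(cw) {
  d <- as_cut_weights_df(cw)
  need <- c("tenderloin", "joint_shoulder", "joint_loin", "joint_ham",
            "joint_belly", "lean_shoulder", "lean_loin", "lean_ham",
            "lean_belly")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing cut-weight columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  joints <- d$joint_shoulder + d$joint_loin + d$joint_ham + d$joint_belly
  leans <- d$lean_shoulder + d$lean_loin + d$lean_ham + d$lean_belly
  if (any(c(d$lean_shoulder > d$joint_shoulder + 1e-9,
            d$lean_loin > d$joint_loin + 1e-9,
            d$lean_ham > d$joint_ham + 1e-9,
            d$lean_belly > d$joint_belly + 1e-9)))
    stop("lean weight exceeds joint weight for at least one cut",
         call. = FALSE)
  denom <- d$tenderloin + joints
  if (any(denom <= 0))
    stop("zero dissection denominator (tenderloin + joint weights)",
         call. = FALSE)
  100 * (d$tenderloin + leans) / denom
}

#' Total-dissection lean meat percentage (YTD)
#'
#' @param total_lean_weight total lean meat of the half carcass (kg).
#' @param half_carcass_weight half-carcass weight (kg).
#' @return 100 * total lean / half-carcass weight (vectorized).
#' @export
compute_ytd <- function(total_lean_weight, half_carcass_weight) {
  if (any(!is.finite(half_carcass_weight)) || any(half_carcass_weight <= 0))
    stop("'half_carcass_weight' must be positive", call. = FALSE)
  if (any(total_lean_weight < 0) ||
      any(total_lean_weight > half_carcass_weight + 1e-9))
    stop("'total_lean_weight' must lie in [0, half_carcass_weight]",
         call. = FALSE)
  100 * total_lean_weight / half_carcass_weight
}

#' Scaling factor between total and partial dissection
#'
#' The bias-correction ratio SF = YTD / YPD estimated on a total-dissection
#' subsample, computed as the ratio of the subsample means (not the mean of
#' per-carcass ratios) and rounded half-up to `round_to` decimals, the form
#' in which it is applied in practice. The unrounded means are kept for
#' diagnostics.
#'
#' @param ytd_values total-dissection LMP values (percent).
#' @param ypd_values paired partial-dissection LMP values (percent).
#' @param round_to decimals to round the factor to (default 2); `NULL`
#'   keeps full precision.
#' @return an object of class `scaling_factor` with fields `value`,
#'   `ytd_mean`, `ypd_mean`, `n_subsample`, `rounded`.
#' @examples
#' compute_sf(59.62, 67.12)  # 0.89
#' @export
compute_sf <- function(ytd_values, ypd_values, round_to = 2) {
  if (length(ytd_values) == 0L || length(ypd_values) == 0L)
    stop("dissection value lists must be non-empty", call. = FALSE)
  if (length(ytd_values) != length(ypd_values))
    stop("'ytd_values' and 'ypd_values' must be paired (equal length)",
         call. = FALSE)
  ytd_mean <- mean(ytd_values)
  ypd_mean <- mean(ypd_values)
  if (ypd_mean == 0)
    stop("mean partial-dissection LMP is zero", call. = FALSE)
  value <- ytd_mean / ypd_mean
  rounded <- !is.null(round_to)
  if (rounded) value <- round_half_up(value, round_to)
  if (value <= 0)
    stop("scaling factor must be positive", call. = FALSE)
  structure(list(value = value, ytd_mean = ytd_mean, ypd_mean = ypd_mean,
                 n_subsample = length(ytd_values), rounded = rounded),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("Scaling factor SF = %.4g (%s; n = %d)\n", x$value,
              if (x$rounded) "rounded" else "unrounded", x$n_subsample))
  cat(sprintf("  mean YTD = %.4f, mean YPD = %.4f\n", x$ytd_mean,
              x$ypd_mean))
  invisible(x)
}

#' Bias-corrected reference lean meat percentage
#'
#' Applies the scaling factor to partial-dissection values:
#' `LMP_ref = YPD * SF`.
#'
#' @param ypd partial-dissection LMP values (percent, in (0, 100]).
#' @param sf a [compute_sf()] result or a positive number.
#' @return corrected LMP values (vectorized).
#' @export
apply_sf <- function(ypd, sf) {
  value <- if (inherits(sf, "scaling_factor")) sf$value else sf
  stop_if_not_scalar_number(value, "sf", positive = TRUE)
  if (any(!is.finite(ypd)) || any(ypd <= 0) || any(ypd > 100))
    stop("'ypd' values must lie in (0, 100]", call. = FALSE)
  ypd * value
}
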