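#' Parameters of a synthetic carcass population
#'
#' Bundles the moments, correlations and noise levels that drive
#' [generate_population()]. Defaults emulate the Polish slaughter-pig
#' population surveyed for CGM device testing: hot carcass weight
#' 95.0 (SD 10.6) kg, backfat depth F2 13.86 (SD 4.26) mm, loin muscle
#' depth M2 62.20 (SD 8.40) mm, a 50/50 gilt/castrate split, a linear
#' lean-meat relationship with the 2023 CGM equation coefficients and
#' residual SD 2.2 percentage points, and a partial/total dissection
#' scaling factor of 0.89.
#'
#' The latent total-dissection lean meat percentage is
#' `ytd_true = beta0 + beta_f * f2 + beta_m * m2 + eps`,
#' `eps ~ N(0, sigma_ytd)`, and the observable partial-dissection value is
#' `ypd_obs = ytd_true / sf_true + delta`, `delta ~ N(0, sigma_delta)`,
#' so that the population ratio of total to partial dissection equals
#' `sf_true` by construction.
#'
#' @param n number of carcasses.
#' @param mean_weight,sd_weight hot carcass weight moments (kg).
#' @param mean_f2,sd_f2 backfat depth moments (mm).
#' @param mean_m2,sd_m2 loin depth moments (mm).
#' @param corr_weight_f2,corr_f2_m2,corr_weight_m2 pairwise correlations
#'   of the trivariate Gaussian before truncation.
#' @param gilt_fraction proportion of gilts (rest are castrates).
#' @param beta0,beta_f,beta_m coefficients of the lean-meat model
#'   (percent, percent per mm).
#' @param sigma_ytd residual SD of true LMP about the linear model (pp).
#' @param sf_true true total/partial dissection ratio (unitless, in (0, 1.2]).
#' @param sigma_delta measurement noise SD of the partial-dissection LMP (pp).
#' @param weight_range,f2_range,m2_range truncation bounds (kg, mm, mm).
#' @param seed integer seed making generation reproducible, or `NULL`.
#' @return an object of class `population_params`.
#' @seealso [generate_population()]
#' @export
population_params <- function(n,
                              mean_weight = 95.0, sd_weight = 10.6,
                              mean_f2 = 13.86, sd_f2 = 4.26,
                              mean_m2 = 62.20, sd_m2 = 8.40,
                              corr_weight_f2 = 0.15,
                              corr_f2_m2 = 0,
                              corr_weight_m2 = 0,
                              gilt_fraction = 0.5,
                              beta0 = 60.7538, beta_f = -0.6465,
                              beta_m = 0.1243,
                              sigma_ytd = 2.2,
                              sf_true = 0.89,
                              sigma_delta = 0.5,
                              weight_range = c(60, 120),
                              f2_range = c(3, 55),
                              m2_range = c(21, 99),
                              seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  for (nm in c("sd_weight", "sd_f2", "sd_m2"))
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  if (sigma_ytd < 0 || sigma_delta < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (gilt_fraction < 0 || gilt_fraction > 1)
    stop("'gilt_fraction' must be in [0, 1]", call. = FALSE)
  if (sf_true <= 0 || sf_true > 1.2)
    stop("'sf_true' must be in (0, 1.2]", call. = FALSE)
  for (r in list(corr_weight_f2, corr_f2_m2, corr_weight_m2))
    if (abs(r) >= 1) stop("correlations must lie in (-1, 1)", call. = FALSE)

  R <- matrix(c(1, corr_weight_f2, corr_weight_m2,
                corr_weight_f2, 1, corr_f2_m2,
                corr_weight_m2, corr_f2_m2, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)

  structure(list(
    n = n,
    mean_weight = mean_weight, sd_weight = sd_weight,
    mean_f2 = mean_f2, sd_f2 = sd_f2,
    mean_m2 = mean_m2, sd_m2 = sd_m2,
    corr_weight_f2 = corr_weight_f2, corr_f2_m2 = corr_f2_m2,
    corr_weight_m2 = corr_weight_m2,
    gilt_fraction = gilt_fraction,
    beta0 = beta0, beta_f = beta_f, beta_m = beta_m,
    sigma_ytd = sigma_ytd, sf_true = sf_true, sigma_delta = sigma_delta,
    weight_range = weight_range, f2_range = f2_range, m2_range = m2_range,
    seed = seed
  ), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Carcass population parameters (n =", x$n, ")\n")
  cat(sprintf("  hot weight %.2f (SD %.2f) kg, F2 %.2f (SD %.2f) mm, M2 %.2f (SD %.2f) mm\n",
              x$mean_weight, x$sd_weight, x$mean_f2, x$sd_f2,
              x$mean_m2, x$sd_m2))
  cat(sprintf("  LMP model: %.4f %+.4f*F2 %+.4f*M2, residual SD %.2f pp\n",
              x$beta0, x$beta_f, x$beta_m, x$sigma_ytd))
  cat(sprintf("  scaling factor %.2f, partial-dissection noise SD %.2f pp\n",
              x$sf_true, x$sigma_delta))
  invisible(x)
}

#' Generate a synthetic carcass population
#'
#' Draws `params$n` carcasses whose (hot weight, F2, M2) follow a truncated
#' trivariate Gaussian with the requested moments and correlations, assigns
#' sex i.i.d. Bernoulli(`gilt_fraction`), and attaches the latent
#' total-dissection lean meat percentage `ytd_true` and the observable
#' partial-dissection value `ypd_obs` (see [population_params()] for the
#' model). Truncation is by rejection: rows outside the measurement bounds,
#' or with lean meat percentages outside (0, 100), are redrawn.
#'
#' @param params a [population_params()] object.
#' @param seed optional integer seed; overrides `params$seed`.
#' @return a `data.frame` (class `carcass_population`) with columns
#'   `id`, `sex` (`"gilt"`/`"castrate"`), `hot_weight_kg`, `f2_mm`,
#'   `m2_mm`, `ytd_true`, `ypd_obs`.
#' @examples
#' pop <- generate_population(population_params(500, seed = 1))
#' summary(pop$f2_mm)
#' @export
generate_population <- function(params, seed = NULL) {
  if (!inherits(params, "population_params"))
    stop("'params' must be a population_params object", call. = FALSE)
  if (is.null(seed)) seed <- params$seed

  mu <- c(params$mean_weight, params$mean_f2, params$mean_m2)
  sd <- c(params$sd_weight, params$sd_f2, params$sd_m2)
  R <- matrix(c(1, params$corr_weight_f2, params$corr_weight_m2,
                params$corr_weight_f2, 1, params$corr_f2_m2,
                params$corr_weight_m2, params$corr_f2_m2, 1), 3, 3)
  Sigma <- diag(sd) %*% R %*% diag(sd)
  lo <- c(params$weight_range[1], params$f2_range[1], params$m2_range[1])
  hi <- c(params$weight_range[2], params$f2_range[2], params$m2_range[2])

  with_seed(seed, {
    n <- params$n
    acc <- matrix(numeric(0), ncol = 5)
    # rejection sampling in batches; acceptance rate is high for the
    # default bounds so a modest over-draw suffices
    while (nrow(acc) < n) {
      m <- max(1000L, ceiling((n - nrow(acc)) * 1.25))
      x <- MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
      keep <- x[, 1] >= lo[1] & x[, 1] <= hi[1] &
        x[, 2] >= lo[2] & x[, 2] <= hi[2] &
        x[, 3] >= lo[3] & x[, 3] <= hi[3]
      x <- x[keep, , drop = FALSE]
      if (nrow(x) == 0L) next
      ytd <- params$beta0 + params$beta_f * x[, 2] + params$beta_m * x[, 3] +
        stats::rnorm(nrow(x), 0, params$sigma_ytd)
      ypd <- ytd / params$sf_true +
        stats::rnorm(nrow(x), 0, params$sigma_delta)
      ok <- ytd > 0 & ytd < 100 & ypd > 0 & ypd < 100
      acc <- rbind(acc, cbind(x[ok, , drop = FALSE], ytd[ok], ypd[ok]))
    }
    acc <- acc[seq_len(n), , drop = FALSE]
    sex <- ifelse(stats::runif(n) < params$gilt_fraction, "gilt", "castrate")
    out <- data.frame(
      id = sprintf("C%06d", seq_len(n)),
      sex = sex,
      hot_weight_kg = acc[, 1],
      f2_mm = acc[, 2],
      m2_mm = acc[, 3],
      ytd_true = acc[, 4],
      ypd_obs = acc[, 5],
      stringsAsFactors = FALSE
    )
    class(out) <- c("carcass_population", "data.frame")
    out
  })
}

#' Generate dissection cut weights consistent with a carcass
#'
#' Realizes joint (pre-dissection) and lean weights for the five reference
#' cuts — tenderloin, shoulder, loin, ham, belly — of one half carcass so
#' that the partial-dissection formula reproduces the carcass's `ypd_obs`
#' and the total-dissection formula its `ytd_true`, both to machine
#' precision. Joint weights are a Dirichlet perturbation of fixed cut
#' proportions applied to a cut-out fraction of the half carcass; lean is
#' allocated across the four dissected cuts proportionally to joint weight,
#' which guarantees lean <= joint whenever the target is feasible.
#'
#' @param carcass one-row data frame or list with `hot_weight_kg`,
#'   `ypd_obs` and `ytd_true`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param cutout_fraction fraction of the half carcass made up by the five
#'   reference cuts.
#' @param cut_props named proportions (tenderloin, shoulder, loin, ham,
#'   belly) of the cut-out pool; rescaled to sum to one.
#' @param concentration Dirichlet concentration; larger = less perturbation.
#' @return a [cut_weights()] object.
#' @export
generate_cut_weights <- function(carcass, seed = NULL,
                                 cutout_fraction = 0.75,
                                 cut_props = c(tenderloin = 0.015,
                                               shoulder = 0.25,
                                               loin = 0.23,
                                               ham = 0.30,
                                               belly = 0.20),
                                 concentration = 300) {
  hw <- carcass$hot_weight_kg
  ypd <- carcass$ypd_obs
  ytd <- carcass$ytd_true
  stop_if_not_scalar_number(hw, "hot_weight_kg", positive = TRUE)
  if (is.null(ypd) || ypd <= 0 || ypd >= 100)
    stop("carcass 'ypd_obs' must lie in (0, 100)", call. = FALSE)
  if (is.null(ytd) || ytd <= 0 || ytd >= 100)
    stop("carcass 'ytd_true' must lie in (0, 100)", call. = FALSE)
  if (length(cut_props) != 5L)
    stop("'cut_props' must have five entries", call. = FALSE)
  props <- cut_props / sum(cut_props)

  with_seed(seed, {
    half <- hw / 2
    pool <- cutout_fraction * half
    # Dirichlet(concentration * props) via independent gammas
    g <- stats::rgamma(5, shape = concentration * props, rate = 1)
    shares <- g / sum(g)
    w <- pool * shares
    tenderloin <- w[1]
    joints <- w[2:5]

    denom <- tenderloin + sum(joints)
    lean_total <- ypd / 100 * denom - tenderloin
    if (lean_total < 0)
      stop("infeasible lean allocation: partial-dissection LMP below the ",
           "tenderloin share", call. = FALSE)
    if (lean_total > sum(joints) + 1e-12)
      stop("infeasible lean allocation: required lean exceeds joint weight",
           call. = FALSE)
    leans <- lean_total * joints / sum(joints)

    cut_weights(
      tenderloin = tenderloin,
      joint_shoulder = joints[1], joint_loin = joints[2],
      joint_ham = joints[3], joint_belly = joints[4],
      lean_shoulder = leans[1], lean_loin = leans[2],
      lean_ham = leans[3], lean_belly = leans[4],
      half_carcass_weight = half,
      total_lean_weight = ytd / 100 * half
    )
  })
}
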