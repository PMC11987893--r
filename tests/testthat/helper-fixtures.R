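# shared fixture builders (everything generated in code, nothing on disk)

# closed-form moments of a univariate normal truncated to [l, u]
tnorm_moments <- function(m, s, l, u) {
  a <- (l - m) / s
  b <- (u - m) / s
  Z <- pnorm(b) - pnorm(a)
  mu <- m + s * (dnorm(a) - dnorm(b)) / Z
  v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = mu, sd = sqrt(v), mass = Z)
}

# exact moments of (weight, f2) under the box-truncated bivariate normal:
# f2 | weight is normal, so its truncated moments are closed-form and the
# weight dimension is integrated by quadrature
box_moments_wf <- function(p) {
  mw <- p$mean_weight; sw <- p$sd_weight
  mf <- p$mean_f2; sf2 <- p$sd_f2; rho <- p$corr_weight_f2
  lw <- p$weight_range[1]; uw <- p$weight_range[2]
  lf <- p$f2_range[1]; uf <- p$f2_range[2]
  sc <- sf2 * sqrt(1 - rho^2)
  integrand <- function(w, fun) {
    mc <- mf + rho * sf2 / sw * (w - mw)
    a <- (lf - mc) / sc
    b <- (uf - mc) / sc
    Z <- pnorm(b) - pnorm(a)
    Ef <- mc + sc * (dnorm(a) - dnorm(b)) / Z
    Vf <- sc^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
    dnorm(w, mw, sw) * Z * fun(w, Ef, Vf + Ef^2)
  }
  quad <- function(fun)
    integrate(function(w) integrand(w, fun), lw, uw,
              rel.tol = 1e-10)$value
  mass <- quad(function(w, Ef, Ef2) 1)
  Ew <- quad(function(w, Ef, Ef2) w) / mass
  Ef <- quad(function(w, Ef, Ef2) Ef) / mass
  Ew2 <- quad(function(w, Ef, Ef2) w^2) / mass
  Ef2 <- quad(function(w, Ef, Ef2) Ef2) / mass
  list(mean_weight = Ew, sd_weight = sqrt(Ew2 - Ew^2),
       mean_f2 = Ef, sd_f2 = sqrt(Ef2 - Ef^2))
}

# small calibration dataset generated from a known linear truth
make_calib_data <- function(n, seed, sigma = 0, eq = cgm_equation("2023")) {
  set.seed(seed)
  f2 <- runif(n, 5, 30)
  m2 <- runif(n, 40, 85)
  data.frame(
    f2 = f2, m2 = m2,
    lmp_ref = eq$intercept + eq$coef_f2 * f2 + eq$coef_m2 * m2 +
      rnorm(n, 0, sigma)
  )
}

# independent least-squares oracle (normal equations via lm)
ols_oracle <- function(d) {
  unname(coef(lm(lmp_ref ~ f2 + m2, data = d)))
}

# a carcass row with fully specified latent values
make_carcass <- function(hot_weight_kg = 96, ytd_true = 59,
                         ypd_obs = ytd_true / 0.89) {
  data.frame(id = "X1", sex = "gilt", hot_weight_kg = hot_weight_kg,
             f2_mm = 14, m2_mm = 62, ytd_true = ytd_true,
             ypd_obs = ypd_obs)
}

# population parameters scaled down for fast tests
small_params <- function(n = 2000, seed = 42, ...) {
  population_params(n = n, seed = seed, ...)
}
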