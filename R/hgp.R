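# Heteroscedastic Gaussian-process interpolation of cultivation time series.
#
# Model: y_i = f(t_i) + e_i, f ~ GP(0, sf^2 SE(ell)) on mean-centered,
# SD-scaled values; e_i ~ N(0, sem_i^2 + exp(2 g_i)) where the log noise SD
# g has a GP prior (SE kernel, constant mean m_g). Only the observation
# noise is input-dependent; signal variance and lengthscale are stationary
# (identifiability with as few as 7 time points). Hyperparameters and g are
# estimated by MAP with multi-start L-BFGS-B from fixed seeds. The
# derivative of the posterior is itself a GP with analytic mean/variance,
# which yields the specific uptake/secretion/growth rates.

se_kernel <- function(t1, t2, sf2, ell) {
  D <- outer(t1, t2, "-")
  sf2 * exp(-D^2 / (2 * ell^2))
}

chol_jitter <- function(M) {
  for (j in c(0, 10^seq(-10, -6))) {
    R <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("covariance not positive definite after jitter escalation")
}

#' Configuration for heteroscedastic GP fitting
#'
#' @param restarts number of random optimizer restarts (MAP, deterministic
#'   given `seed`).
#' @param seed integer seed for the restarts.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param tol relative objective tolerance.
#' @param lengthscale_g lengthscale of the log-noise GP prior in hours;
#'   default one fifth of the time range.
#' @param sigma_g prior SD scale of the log-noise GP.
#' @return A list of settings for [fit_hgp()].
#' @export
hgp_config <- function(restarts = 5, seed = 1, maxit = 500, tol = 1e-8,
                       lengthscale_g = NULL, sigma_g = 1) {
  list(restarts = restarts, seed = seed, maxit = maxit, tol = tol,
       lengthscale_g = lengthscale_g, sigma_g = sigma_g)
}

#' Fit a heteroscedastic GP to one concentration/biomass series
#'
#' @param times observation times (hours), at least 3 distinct.
#' @param values observed values (any unit); fitted after mean/SD scaling.
#' @param config settings from [hgp_config()].
#' @param sem optional per-point standard errors of the mean (same unit as
#'   `values`); they enter as an additive floor on the observation variance.
#' @param log_transform fit the GP to log(values) (requires positive values).
#'   Appropriate for biomass, where growth is multiplicative: the posterior
#'   mean/derivative are mapped back through the chain rule, and
#'   [growth_rate()] becomes the latent derivative directly.
#' @return An `hgp_model` with kernel hyperparameters, the fitted log-noise
#'   vector `g` (on the scaled-data axis), and the log posterior attained.
#' @export
fit_hgp <- function(times, values, config = hgp_config(), sem = NULL,
                    log_transform = FALSE) {
  if (length(unique(times)) < 3) stop("need at least 3 distinct time points")
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite")
  }
  o <- order(times)
  t <- as.numeric(times[o]); y_raw <- as.numeric(values[o])
  sem <- if (is.null(sem)) rep(0, length(t)) else as.numeric(sem[o])
  sem[!is.finite(sem)] <- 0
  if (log_transform) {
    if (any(y_raw <= 0)) stop("log_transform requires positive values")
    sem <- sem / y_raw      # delta method: SD on the log scale
    y_raw <- log(y_raw)
  }
  n <- length(t)
  m_off <- mean(y_raw)
  s <- stats::sd(y_raw)
  if (!is.finite(s) || s == 0) s <- 1
  y <- (y_raw - m_off) / s
  sem_n <- sem / s
  rng <- diff(range(t))
  if (rng == 0) stop("degenerate time range")
  ell_g <- if (is.null(config$lengthscale_g)) rng / 5 else config$lengthscale_g
  Kg <- se_kernel(t, t, config$sigma_g^2, ell_g) + diag(1e-6, n)
  Kg_inv <- chol2inv(chol(Kg))
  ell0 <- log(rng / 3)
  mg0 <- log(0.1)
  D2 <- outer(t, t, "-")^2

  unpack <- function(th) {
    list(lsf = th[1], lell = th[2], mg = th[3], g = th[4:(3 + n)])
  }
  nll <- function(th) {
    p <- unpack(th)
    K <- exp(2 * p$lsf) * exp(-D2 / (2 * exp(2 * p$lell)))
    C <- K + diag(sem_n^2 + exp(2 * p$g), n)
    R <- tryCatch(chol_jitter(C), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    a <- backsolve(R, forwardsolve(t(R), y))
    val <- 0.5 * sum(y * a) + sum(log(diag(R))) + 0.5 * n * log(2 * pi)
    dg <- p$g - p$mg
    val <- val + 0.5 * sum(dg * (Kg_inv %*% dg))
    val + 0.5 * (p$lsf / 1.5)^2 + 0.5 * ((p$lell - ell0) / 1.5)^2 +
      0.5 * ((p$mg - mg0) / 2)^2
  }
  grad <- function(th) {
    p <- unpack(th)
    ell2 <- exp(2 * p$lell)
    K <- exp(2 * p$lsf) * exp(-D2 / (2 * ell2))
    C <- K + diag(sem_n^2 + exp(2 * p$g), n)
    R <- tryCatch(chol_jitter(C), error = function(e) NULL)
    if (is.null(R)) return(rep(0, length(th)))
    Cinv <- chol2inv(R)
    a <- Cinv %*% y
    W <- a %*% t(a) - Cinv            # dL/dC multiplier (L = log posterior)
    d_lsf <- -0.5 * sum(W * (2 * K)) + p$lsf / 1.5^2
    d_lell <- -0.5 * sum(W * (K * D2 / ell2)) + (p$lell - ell0) / 1.5^2
    dg_prior <- Kg_inv %*% (p$g - p$mg)
    d_g <- -(diag(W)) * exp(2 * p$g) + as.numeric(dg_prior)
    d_mg <- -sum(dg_prior) + (p$mg - mg0) / 2^2
    c(d_lsf, d_lell, d_mg, d_g)
  }
  lower <- c(-7, log(rng) - 6, -12, rep(-12, n))
  upper <- c(5, log(rng) + 3, 3, rep(3, n))
  set.seed(config$seed)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    init <- c(0, ell0, mg0, rep(mg0, n))
    if (r > 1) {
      init <- init + stats::rnorm(length(init), 0, c(0.5, 0.5, 1, rep(0.3, n)))
    }
    init <- pmin(pmax(init, lower), upper)
    fit <- tryCatch(
      stats::optim(init, nll, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = config$maxit,
                                  factr = config$tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  p <- unpack(best$par)
  sf2 <- exp(2 * p$lsf); ell <- exp(p$lell)
  C <- se_kernel(t, t, sf2, ell) + diag(sem_n^2 + exp(2 * p$g), n)
  R <- chol_jitter(C)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  structure(list(train_times = t, train_values = y_raw,
                 mean_offset = m_off, scale = s,
                 kernel = list(signal_variance = sf2, lengthscale = ell),
                 g = p$g, noise_sd = sqrt(sem_n^2 + exp(2 * p$g)) * s,
                 log_noise_prior = list(sigma_g2 = config$sigma_g^2,
                                        lengthscale_g = ell_g, mean_g = p$mg),
                 sem = sem, alpha = alpha, chol = R,
                 log_transform = log_transform,
                 log_posterior = -best$value),
            class = "hgp_model")
}

#' @export
print.hgp_model <- function(x, ...) {
  cat("hgp_model: n =", length(x$train_times),
      "| lengthscale =", signif(x$kernel$lengthscale, 4), "h",
      "| log posterior =", signif(x$log_posterior, 6), "\n")
  invisible(x)
}

#' GP posterior mean of the interpolated series
#'
#' @param model a fitted `hgp_model`.
#' @param t_star prediction times (hours). Extrapolation beyond the training
#'   range is allowed but flagged via the `extrapolated` attribute.
#' @return Numeric vector of posterior means (original units).
#' @export
posterior_mean <- function(model, t_star) {
  ks <- se_kernel(t_star, model$train_times,
                  model$kernel$signal_variance, model$kernel$lengthscale)
  out <- model$scale * as.numeric(ks %*% model$alpha) + model$mean_offset
  if (isTRUE(model$log_transform)) out <- exp(out)
  attr(out, "extrapolated") <- t_star < min(model$train_times) |
    t_star > max(model$train_times)
  out
}

# latent-scale posterior mean (identical to posterior_mean for untransformed
# models; the log-scale mean for log-fitted ones)
latent_mean <- function(model, t_star) {
  ks <- se_kernel(t_star, model$train_times,
                  model$kernel$signal_variance, model$kernel$lengthscale)
  model$scale * as.numeric(ks %*% model$alpha) + model$mean_offset
}

#' GP posterior derivative (rate) distribution
#'
#' The derivative of a GP with squared-exponential kernel is itself a GP:
#' mean d/dt* k(t*, t)^T (K + Sigma)^-1 (y - m) with
#' dk/dt* = -((t* - t)/ell^2) k, and variance from the second mixed kernel
#' derivative sf^2/ell^2 at lag 0. Estimates at the first and last training
#' time are flagged low-confidence (no preceding/subsequent data).
#'
#' @param model a fitted `hgp_model`.
#' @param t_star evaluation times (hours).
#' @return data.frame with columns `time`, `rate_mean`, `rate_sd`,
#'   `boundary` (flag).
#' @export
posterior_derivative <- function(model, t_star) {
  t <- model$train_times
  ell2 <- model$kernel$lengthscale^2
  ks <- se_kernel(t_star, t, model$kernel$signal_variance,
                  model$kernel$lengthscale)
  dks <- -(outer(t_star, t, "-") / ell2) * ks
  mean_d <- model$scale * as.numeric(dks %*% model$alpha)
  V <- backsolve(model$chol, forwardsolve(t(model$chol), t(dks)))
  var_prior <- model$kernel$signal_variance / ell2
  var_d <- pmax(var_prior - colSums(t(dks) * V), 0)
  sd_d <- model$scale * sqrt(var_d)
  if (isTRUE(model$log_transform)) {
    # chain rule: d exp(f)/dt = exp(f) f'; delta-method SD
    ex <- exp(latent_mean(model, t_star))
    mean_d <- ex * mean_d
    sd_d <- ex * sd_d
  }
  data.frame(time = t_star, rate_mean = mean_d,
             rate_sd = sd_d,
             boundary = t_star <= min(t) | t_star >= max(t))
}

# latent-scale derivative (log-derivative for log-fitted models)
latent_derivative <- function(model, t_star) {
  t <- model$train_times
  ell2 <- model$kernel$lengthscale^2
  ks <- se_kernel(t_star, t, model$kernel$signal_variance,
                  model$kernel$lengthscale)
  dks <- -(outer(t_star, t, "-") / ell2) * ks
  mean_d <- model$scale * as.numeric(dks %*% model$alpha)
  V <- backsolve(model$chol, forwardsolve(t(model$chol), t(dks)))
  var_d <- pmax(model$kernel$signal_variance / ell2 - colSums(t(dks) * V), 0)
  list(mean = mean_d, sd = model$scale * sqrt(var_d))
}

#' Specific (per-biomass) production or uptake rates
#'
#' q(t) = (dC/dt at t) / X(t), with X the biomass posterior mean. With
#' `uptake = TRUE` the sign is flipped so consumption is reported positive.
#' Points with non-positive biomass posterior are masked with a warning.
#'
#' @param conc fitted `hgp_model` of the concentration (same strain).
#' @param biomass fitted `hgp_model` of the biomass (CDW, g/l).
#' @param times evaluation times (hours).
#' @param uptake report consumption as a positive rate.
#' @return data.frame: `time`, `concentration`, `rate_mean`, `rate_sd`,
#'   `specific_rate` (unit/(gCDW*h)), `boundary`.
#' @export
specific_rates <- function(conc, biomass, times, uptake = FALSE) {
  d <- posterior_derivative(conc, times)
  X <- posterior_mean(biomass, times)
  bad <- X <= 0
  if (any(bad)) {
    warning("biomass posterior non-positive at ", sum(bad),
            " point(s); specific rates masked")
  }
  q <- ifelse(bad, NA_real_, d$rate_mean / X)
  if (uptake) q <- -q
  data.frame(time = times, concentration = posterior_mean(conc, times),
             rate_mean = d$rate_mean, rate_sd = d$rate_sd,
             specific_rate = q, boundary = d$boundary)
}

#' Specific growth rate from the biomass GP
#'
#' mu(t) = X'(t)/X(t) from the biomass posterior mean and derivative.
#'
#' @param biomass fitted `hgp_model` of CDW.
#' @param times evaluation times (hours).
#' @return data.frame: `time`, `mu`, `mu_sd` (delta-method SD), `boundary`.
#' @export
growth_rate <- function(biomass, times) {
  if (isTRUE(biomass$log_transform)) {
    # mu = d log X/dt, the latent derivative of a log-fitted model (and
    # identically X'(t)/X(t) by the chain rule)
    d <- latent_derivative(biomass, times)
    return(data.frame(time = times, mu = d$mean, mu_sd = d$sd,
                      boundary = times <= min(biomass$train_times) |
                        times >= max(biomass$train_times)))
  }
  d <- posterior_derivative(biomass, times)
  X <- posterior_mean(biomass, times)
  bad <- X <= 0
  if (any(bad)) warning("biomass posterior non-positive; mu masked")
  data.frame(time = times,
             mu = ifelse(bad, NA_real_, d$rate_mean / X),
             mu_sd = ifelse(bad, NA_real_, d$rate_sd / abs(X)),
             boundary = d$boundary)
}

#' Convert a mass rate to a molar rate
#'
#' @param rate rate in g/l/h or g/(gCDW*h).
#' @param mw molecular weight (g/mol), > 0.
#' @return The rate in mmol (per the same denominator).
#' @export
to_molar <- function(rate, mw) {
  if (is.null(mw) || is.na(mw) || mw <= 0) stop("molecular weight required")
  rate * 1000 / mw
}
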