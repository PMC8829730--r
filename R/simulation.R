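#' Covariate correlation matrix for the scenario generator
#'
#' Reads the 10x10 latent-Gaussian correlation structure shipped with the
#' package (pairwise entries; unlisted pairs are 0) and checks positive
#' definiteness.
#'
#' @return A symmetric positive definite 10x10 matrix.
#' @export
sim_correlation <- function() {
  path <- system.file("extdata", "sim_correlation.csv", package = "poisfl",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  S <- diag(10)
  for (r in seq_len(nrow(tab))) {
    S[tab$i[r], tab$j[r]] <- S[tab$j[r], tab$i[r]] <- tab$rho[r]
  }
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("correlation matrix is not positive definite")
  S
}

#' Generate the ten scenario covariates
#'
#' Latent standard-normal variables `Z1..Z10` with correlation
#' [sim_correlation()] are transformed to four binary covariates
#' (`x1 = I(z1 > 1.28)`, `x2 = I(z2 > 0.35)`, `x3 = I(z3 > 0)`,
#' `x4 = I(z4 > 0)`), two three-level ordinal covariates
#' (`x5 = I(z5 >= -1.2) + I(z5 >= 0.75)`,
#' `x6 = I(z6 >= 0.5) + I(z6 >= 1.5)`) and four continuous covariates
#' (`x7 = [10 z7 + 55]`, `x8 = [max(0, 100 e^{z8} - 20)]`,
#' `x9 = [max(0, 80 e^{z9} - 20)]`, `x10 = [10 z10 + 120]`, where `[.]`
#' truncates toward zero). To avoid extreme values, `z8` and `z9` are
#' truncated at their 99th percentile by the copula-preserving inverse-CDF
#' map `z -> qnorm(0.99 pnorm(z))` before exponentiation.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param n Number of rows.
#' @param sigma Latent correlation matrix (default [sim_correlation()]).
#' @return `n x 10` numeric matrix with columns `x1..x10`.
#' @export
sim_covariates <- function(n, sigma = sim_correlation()) {
  Z <- matrix(stats::rnorm(n * 10L), n, 10L) %*% chol(sigma)
  for (jc in 8:9) Z[, jc] <- stats::qnorm(0.99 * stats::pnorm(Z[, jc]))
  X <- cbind(
    x1 = as.numeric(Z[, 1] > 1.28),
    x2 = as.numeric(Z[, 2] > 0.35),
    x3 = as.numeric(Z[, 3] > 0),
    x4 = as.numeric(Z[, 4] > 0),
    x5 = as.numeric(Z[, 5] >= -1.2) + as.numeric(Z[, 5] >= 0.75),
    x6 = as.numeric(Z[, 6] >= 0.5) + as.numeric(Z[, 6] >= 1.5),
    x7 = trunc(10 * Z[, 7] + 55),
    x8 = trunc(pmax(0, 100 * exp(Z[, 8]) - 20)),
    x9 = trunc(pmax(0, 80 * exp(Z[, 9]) - 20)),
    x10 = trunc(10 * Z[, 10] + 120))
  X
}

#' Intersextile range
#'
#' The difference between the empirical 5/6- and 1/6-quantiles; used to put
#' the effect sizes of continuous covariates on a comparable scale
#' (coefficients `+/- 0.69/ISR`).
#'
#' @param x Numeric vector.
#' @return Scalar ISR.
#' @export
compute_isr <- function(x) {
  q <- stats::quantile(x, c(1 / 6, 5 / 6), names = FALSE)
  isr <- q[2] - q[1]
  if (isr <= 0) stop("constant column: ISR is zero")
  isr
}

# zero-truncated Poisson sampler (support >= 1) by inverse CDF
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Define a simulation scenario
#'
#' One cell of the factorial sparse-event design: `k` covariates (the first
#' `k` of [sim_covariates()]), an events-per-variable ratio fixing the
#' sample size `n = round(EPV * k / incidence)`, and the effect `beta1` of
#' the rare binary covariate `x1`. The remaining coefficients are fixed at
#' `beta2 = beta4 = 0.69`, `beta3 = -0.69`, `beta5 = 0.35`,
#' `beta6 = -0.35`, `beta7 = beta9 = 0.69/ISR`, `beta8 = beta10 = -0.69/ISR`.
#' Each row carries a zero-truncated Poisson rate multiplier `psi` entering
#' as offset `log(psi)`.
#'
#' @param k Number of covariates: 2, 5 or 10.
#' @param epv Events-per-variable ratio: 3, 5 or 10.
#' @param beta1 True log-IRR of `x1` (the reference evaluation grid spans
#'   `-log 16 .. log 16`).
#' @param reps Default number of replicate datasets.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param psi_mean Nominal mean of the multiplier distribution (1.6).
#' @param psi_mode `"underlying"`: Poisson parameter `psi_mean` truncated at
#'   zero (truncated mean about 2.0); `"truncated"`: the truncated mean
#'   itself equals `psi_mean`.
#' @param incidence Target marginal event incidence per row (0.1).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(k, epv, beta1, reps = 10000L, seed = 1L,
                            psi_mean = 1.6,
                            psi_mode = c("underlying", "truncated"),
                            incidence = 0.1) {
  if (!k %in% c(2L, 5L, 10L)) stop("'k' must be 2, 5 or 10")
  psi_mode <- match.arg(psi_mode)
  lambda <- if (psi_mode == "underlying") psi_mean else
    stats::uniroot(function(l) l / (1 - exp(-l)) - psi_mean,
                   c(1e-8, 10 * psi_mean))$root
  structure(list(k = as.integer(k), epv = epv, beta1 = beta1,
                 n = as.integer(round(epv * k / incidence)),
                 reps = as.integer(reps), seed = as.integer(seed),
                 psi_lambda = lambda, incidence = incidence,
                 calibrated = FALSE),
            class = "scenario_config")
}

#' Calibrate a scenario's coefficients and intercept
#'
#' Draws a large calibration sample with a seed derived from the scenario
#' seed, computes the ISR of each continuous covariate, assembles the
#' coefficient vector, and sets the intercept so that the Monte-Carlo mean
#' of `mu = exp(beta0 + x beta) psi` equals the target incidence (closed
#' form, since `beta0` enters multiplicatively).
#'
#' @param config A [scenario_config()].
#' @param calibration_n Calibration sample size (default 1e6).
#' @return The config with `beta` (length `k`), `beta0`, `isr`,
#'   `calibrated = TRUE`.
#' @export
calibrate_scenario <- function(config, calibration_n = 1e6) {
  stopifnot(inherits(config, "scenario_config"))
  sigma <- sim_correlation()
  set.seed(config$seed %% 2147483647L)
  X <- sim_covariates(calibration_n, sigma)
  psi <- rztpois(calibration_n, config$psi_lambda)
  isr <- apply(X[, 7:10, drop = FALSE], 2, compute_isr)
  beta_full <- c(config$beta1, 0.69, -0.69, 0.69, 0.35, -0.35,
                 0.69 / isr[1], -0.69 / isr[2], 0.69 / isr[3],
                 -0.69 / isr[4])
  beta <- beta_full[seq_len(config$k)]
  eta <- drop(X[, seq_len(config$k), drop = FALSE] %*% beta)
  m <- mean(exp(eta) * psi)
  if (!is.finite(m) || m <= 0) stop("intercept calibration failed")
  config$beta0 <- log(config$incidence) - log(m)
  config$beta <- beta
  config$isr <- isr
  config$sigma <- sigma
  config$calibrated <- TRUE
  config
}

#' Draw one replicate dataset from a calibrated scenario
#'
#' `psi_i` zero-truncated Poisson, `y_i ~ Poisson(exp(beta0 + x_i beta) psi_i)`;
#' the multiplier is recorded as offset `log(psi_i)` and the true means are
#' attached for prediction-error evaluation.
#'
#' @param config A calibrated [scenario_config()].
#' @param rep_seed Integer seed for this replicate.
#' @return A [pois_data] with attribute `true_mu`.
#' @export
sim_dataset <- function(config, rep_seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!isTRUE(config$calibrated)) stop("calibrate the scenario first")
  set.seed(rep_seed %% 2147483647L)
  X <- sim_covariates(config$n, config$sigma)[, seq_len(config$k),
                                              drop = FALSE]
  psi <- rztpois(config$n, config$psi_lambda)
  mu <- exp(config$beta0 + drop(X %*% config$beta)) * psi
  y <- stats::rpois(config$n, mu)
  d <- pois_data(y, X, multiplier = psi)
  attr(d, "true_mu") <- mu
  d
}

#' Run a simulation scenario
#'
#' Fits the requested methods to `reps` replicate datasets and aggregates
#' the performance measures used in sparse-event method comparisons: bias
#' and `RMSE(beta1) * sqrt(n)`, `RMSPE(mu) * sqrt(n)` (root of the averaged
#' per-dataset mean squared prediction error), one-sided left/right CI
#' coverage (nominal 0.975 each), power to exclude 0, median CI width,
#' separation incidence and MUE-fallback incidence.
#'
#' CI conventions follow the usual mapping: Wald for ML, profile likelihood
#' of the `h/2`-augmented data for FL/FLAC, profile likelihood of the
#' prior-augmented data for BDA, exact/mid-p tail inversion for EP.
#'
#' @param config A [scenario_config()] (calibrated or not).
#' @param methods Subset of `"ml"`, `"fl"`, `"flac"`, `"bda"`, `"exact"`.
#'   `"exact"` requires `n <= 250`, `k <= 5`.
#' @param reps Number of replicates (default from config).
#' @param ci Compute confidence intervals? Skipping them (default) makes
#'   large grids much faster; coverage/power/width are then `NA`.
#' @param level CI level.
#' @param calibration_n Calibration sample size.
#' @return List with `metrics` (one row per method) and `reps` (long
#'   per-replicate data frame).
#' @export
run_scenario <- function(config, methods = c("ml", "fl", "flac", "bda"),
                         reps = config$reps, ci = FALSE, level = 0.95,
                         calibration_n = 1e6) {
  methods <- match.arg(methods, c("ml", "fl", "flac", "bda", "exact"),
                       several.ok = TRUE)
  if ("exact" %in% methods && (config$n > 250 || config$k > 5))
    stop("exact method infeasible for n > 250 or k > 5")
  if (!isTRUE(config$calibrated))
    config <- calibrate_scenario(config, calibration_n)
  priors <- prior_spec(upper = c(rep(1000, 6), rep(100, 4))[seq_len(config$k)])
  rows <- vector("list", reps * length(methods))
  ri <- 0L
  for (r in seq_len(reps)) {
    d <- sim_dataset(config, config$seed + r)
    true_mu <- attr(d, "true_mu")
    sep <- detect_separation(d)$separated
    for (m in methods) {
      ri <- ri + 1L
      row <- list(rep = r, method = m, separated = sep,
                  b1 = NA_real_, lo = NA_real_, hi = NA_real_,
                  pse = NA_real_, mue_fallback = NA, finite = NA)
      res <- tryCatch({
        if (m == "exact") {
          er <- exact_poisson(d, j = 2L, level = level)
          row$b1 <- er$estimate
          row$mue_fallback <- identical(er$estimate_type, "MUE")
          row$finite <- is.finite(er$estimate)
          if (ci) { row$lo <- er$ci_midp[1]; row$hi <- er$ci_midp[2] }
        } else {
          fit <- switch(m,
                        ml = fit_ml(d),
                        fl = fit_fl(d),
                        flac = fit_flac(d),
                        bda = fit_bda(d, priors))
          row$b1 <- unname(fit$coefficients[2L])
          row$finite <- abs(row$b1) < 50
          row$pse <- mean((fit$mu_hat - true_mu)^2)
          if (ci) {
            bounds <- if (m == "ml") wald_ci(fit, parm = 2L, level = level)
            else profile_ci(fit, parm = 2L, level = level,
                            mode = if (m == "bda") "ml_pl" else "pl_fixed")
            row$lo <- bounds[1, 1]; row$hi <- bounds[1, 2]
          }
        }
        row
      }, error = function(e) { row$finite <- FALSE; row })
      rows[[ri]] <- res
    }
  }
  long <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  metrics <- do.call(rbind, lapply(unique(long$method), function(m) {
    sub <- long[long$method == m, ]
    ok <- is.finite(sub$b1)
    data.frame(
      method = m,
      n = config$n, k = config$k, epv = config$epv, beta1 = config$beta1,
      reps = reps,
      bias_b1 = mean(sub$b1[ok]) - config$beta1,
      rmse_b1_sqrtn = sqrt(mean((sub$b1[ok] - config$beta1)^2)) *
        sqrt(config$n),
      rmspe_sqrtn = if (all(is.na(sub$pse))) NA_real_ else
        sqrt(mean(sub$pse, na.rm = TRUE)) * sqrt(config$n),
      cover_left = if (ci) mean(sub$lo <= config$beta1, na.rm = TRUE)
                   else NA_real_,
      cover_right = if (ci) mean(sub$hi >= config$beta1, na.rm = TRUE)
                    else NA_real_,
      power = if (ci) mean(sub$lo > 0 | sub$hi < 0, na.rm = TRUE)
              else NA_real_,
      median_width = if (ci) stats::median(sub$hi - sub$lo, na.rm = TRUE)
                     else NA_real_,
      separation_rate = mean(sub$separated),
      finite_rate = mean(sub$finite, na.rm = TRUE),
      mue_rate = if (m == "exact") mean(sub$mue_fallback, na.rm = TRUE)
                 else NA_real_,
      stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, reps = long, config = config)
}
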