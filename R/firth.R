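#' Firth-penalized Poisson log-likelihood
#'
#' `l*(beta) = l(beta) + (1/2) log |I(beta)|`, the Jeffreys-prior penalized
#' likelihood. Its maximizer exists and is finite even under separation.
#'
#' @inheritParams pois_loglik
#' @return Scalar; `-Inf` when the information matrix is numerically
#'   singular at `beta`.
#' @export
penalized_loglik <- function(data, beta) {
  check_beta(data, beta)
  mu <- exp(drop(data$X %*% beta) + data$z)
  R <- tryCatch(chol(crossprod(data$X * sqrt(mu))),
                error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  pois_loglik(data, beta) + sum(log(diag(R)))
}

#' Firth-penalized (FL) Poisson regression
#'
#' Solves the modified score equations
#' `U*_j(beta) = sum_i x_ij (y_i + h_i/2 - mu_i) = 0`,
#' i.e. ML on event counts augmented by half the hat diagonals, with the
#' leverages recomputed at every iteration. The solution maximizes the
#' penalized likelihood [penalized_loglik()] and is finite on separated data.
#' An intercept-model identity follows from the `j = 0` equation:
#' `sum(mu_hat) = sum(y) + (k+1)/2`.
#'
#' @inheritParams fit_ml
#' @return A `pois_fit` object (`method = "fl"`) with `penloglik` set.
#' @examples
#' covid <- pois_data(c(0, 3, 3), cbind(nursing = c(0, 1, 0),
#'                                      hospital = c(0, 0, 1)),
#'                    multiplier = c(352, 444, 365))
#' exp(coef(fit_fl(covid))[-1])   # IRR 5.55, 6.75
#' @export
fit_fl <- function(data, control = pois_control()) {
  stopifnot(inherits(data, "pois_data"))
  check_full_rank(data$X)
  sep <- detect_separation(data)$separated
  res <- newton_pois(data$y, data$X, data$z, penalized = TRUE,
                     control = control)
  new_pois_fit(res, data, "fl", sep)
}

#' FL with added covariate (FLAC)
#'
#' Runs FL only to obtain the leverages `h_i`, then fits ordinary ML on an
#' augmented dataset: each observation gets a pseudo-copy (same covariates
#' and offset) with event count `h_i/2`, and an added indicator covariate
#' `G` (0 = original, 1 = pseudo) receives its own coefficient `gamma_flac`.
#' Predictions set `G = 0`; the intercept score equation then recalibrates
#' the predicted total to the observed total, `sum(mu_hat) = sum(y)`, while
#' all non-intercept coefficients coincide with FL.
#'
#' @inheritParams fit_ml
#' @return A `pois_fit` object (`method = "flac"`) with extras `gamma_flac`
#'   and `augmented` (the augmented-data pieces).
#' @export
fit_flac <- function(data, control = pois_control()) {
  stopifnot(inherits(data, "pois_data"))
  check_full_rank(data$X)
  fl <- fit_fl(data, control)
  aug <- flac_augment(data, fl$hat)
  res <- newton_pois(aug$y, aug$X, aug$z, penalized = FALSE,
                     start = c(fl$coefficients, 0), control = control)
  p <- ncol(data$X)
  beta <- res$beta[seq_len(p)]
  mu0 <- exp(drop(data$X %*% beta) + data$z)   # predictions with G = 0
  res2 <- res
  res2$beta <- beta
  res2$mu <- mu0
  res2$cov <- res$cov[seq_len(p), seq_len(p), drop = FALSE]
  res2$hat <- hat_diagonals(data, beta)
  res2$loglik <- ll_raw(data$y, data$X, data$z, beta)
  res2$penloglik <- penalized_loglik(data, beta)
  new_pois_fit(res2, data, "flac", fl$separated,
               extra = list(gamma_flac = unname(res$beta[p + 1L]),
                            fl_fit = fl, augmented = aug))
}

# AugmentedDataset for FLAC: original rows (G = 0) plus one pseudo-row per
# observation (G = 1) carrying count h_i/2 and the source row's covariates
# and offset.
flac_augment <- function(data, hat) {
  n <- data$n
  X <- cbind(rbind(data$X, data$X), G = c(numeric(n), rep(1, n)))
  list(y = c(data$y, hat / 2), X = X, z = c(data$z, data$z),
       pseudo_counts = hat / 2, source = rep(seq_len(n), 2L),
       G = X[, ncol(X)])
}

#' FL with intercept correction (FLIC)
#'
#' Keeps the FL slopes and shifts the intercept by
#' `delta = log(sum(y) / sum(mu_FL))` — the closed-form ML solution of a
#' second Poisson regression with the FL linear predictor as offset and only
#' an intercept free — so that the predicted total equals the observed
#' total. For Poisson models FLIC and FLAC coincide coefficient-by-
#' coefficient; by the FL conservation identity,
#' `delta = log(sum(y) / (sum(y) + (k+1)/2))` exactly.
#'
#' @inheritParams fit_ml
#' @return A `pois_fit` object (`method = "flic"`) with extra `delta_flic`.
#' @export
fit_flic <- function(data, control = pois_control()) {
  stopifnot(inherits(data, "pois_data"))
  if (sum(data$y) == 0) stop("FLIC undefined when no events are observed")
  fl <- fit_fl(data, control)
  delta <- log(sum(data$y) / sum(fl$mu_hat))
  beta <- fl$coefficients
  beta[1L] <- beta[1L] + delta
  out <- fl
  out$coefficients <- beta
  out$mu_hat <- fl$mu_hat * exp(delta)
  out$loglik <- ll_raw(data$y, data$X, data$z, beta)
  out$penloglik <- penalized_loglik(data, beta)
  out$method <- "flic"
  out$delta_flic <- delta
  out$fl_fit <- fl
  out
}
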