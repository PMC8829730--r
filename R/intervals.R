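#' Wald confidence intervals
#'
#' `beta_j +/- z_{1-alpha/2} * SE_j` from the inverse information at the
#' estimate. Under separation Wald intervals are unreliable (in practice
#' they collapse at the point estimate); the returned object is flagged.
#'
#' @param fit A `pois_fit` object with a covariance matrix.
#' @param parm Coefficient indices (1 = intercept); default all.
#' @param level Confidence level.
#' @return Matrix with columns `lower`, `upper` (log-IRR scale), class
#'   `pois_ci`; attributes `level`, `mode = "wald"` and `unreliable`.
#' @export
wald_ci <- function(fit, parm = NULL, level = 0.95) {
  stopifnot(inherits(fit, "pois_fit"))
  if (is.null(fit$cov) || anyNA(diag(fit$cov)))
    stop("fit carries no usable covariance matrix")
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)")
  est <- fit$coefficients
  if (is.null(parm)) parm <- seq_along(est)
  se <- sqrt(diag(fit$cov))[parm]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = est[parm] - zq * se, upper = est[parm] + zq * se)
  rownames(ci) <- names(est)[parm]
  structure(ci, class = c("pois_ci", "matrix"), level = level,
            mode = "wald", unreliable = isTRUE(fit$separated))
}

# Profile machinery ----------------------------------------------------------

# Returns list(lmax, prof(j, value) -> profiled objective, est) for a mode.
profile_context <- function(fit, mode, control) {
  data <- fit$data
  p <- ncol(data$X)
  if (mode == "ppl") {
    fl <- if (fit$method == "fl") fit else fit_fl(data, control)
    est <- fl$coefficients
    lmax <- fl$penloglik
    prof <- function(j, val) {
      start <- est
      start[j] <- val
      newton_pois(data$y, data$X, data$z, penalized = TRUE, start = start,
                  fixed = j, control = control)$penloglik
    }
  } else if (mode == "pl_fixed") {
    fl <- if (fit$method == "fl") fit else fit_fl(data, control)
    est <- fl$coefficients
    yaug <- data$y + fl$hat / 2      # pseudo counts frozen at the FL leverages
    lmax <- ll_raw(yaug, data$X, data$z, est)
    prof <- function(j, val) {
      start <- est
      start[j] <- val
      r <- newton_pois(yaug, data$X, data$z, penalized = FALSE,
                       start = start, fixed = j, control = control)
      ll_raw(yaug, data$X, data$z, r$beta)
    }
  } else if (mode == "ml_pl") {
    if (fit$method == "bda") {
      aug <- fit$augmented
      y <- aug$y; X <- aug$X; z <- aug$z
      est <- fit$coefficients
    } else {
      y <- data$y; X <- data$X; z <- data$z
      est <- fit$coefficients
    }
    lmax <- ll_raw(y, X, z, est)
    prof <- function(j, val) {
      start <- est
      start[j] <- val
      r <- newton_pois(y, X, z, penalized = FALSE, start = start,
                       fixed = j, control = control)
      ll_raw(y, X, z, r$beta)
    }
  } else stop("unknown profile mode: ", mode)
  list(lmax = lmax, prof = prof, est = est)
}

# Locate one root of the profile-deviance equation on one side of the
# estimate. Brackets by doubling steps; a profile that never crosses the
# cutoff before |beta_j| = bound is reported as an infinite limit.
profile_root <- function(ctx, j, cutoff, side, bound = 40, tol = 1e-7) {
  est <- ctx$est[j]
  g <- function(v) 2 * (ctx$lmax - ctx$prof(j, v)) - cutoff
  step <- 0.25
  lo <- est
  repeat {
    hi <- est + side * step
    if (abs(hi) > bound) return(side * Inf)
    ghi <- g(hi)
    if (is.finite(ghi) && ghi > 0) break
    lo <- hi
    step <- step * 2
  }
  br <- sort(c(lo, hi))
  stats::uniroot(g, br, tol = tol)$root
}

#' Profile-likelihood confidence intervals
#'
#' Inverts the (penalized) likelihood-ratio statistic: a bound is a root of
#' `2[l(max) - l_profile(beta_j*)] = qchisq(level, 1)`.
#'
#' Three profiles are available:
#' \describe{
#'   \item{`ppl`}{profile *penalized* likelihood: at each fixed `beta_j*`
#'     the Firth-penalized likelihood is re-maximized over the remaining
#'     coefficients, with the leverages recomputed (the reference method for
#'     FL/FLAC/FLIC fits).}
#'   \item{`pl_fixed`}{ordinary profile likelihood of the augmented data with
#'     pseudo-counts frozen at `h_i/2` from the FL solution — a cheaper
#'     approximation that is typically slightly narrower than `ppl` and
#'     exact for saturated designs (where `h == 1` at every `beta`).}
#'   \item{`ml_pl`}{ordinary profile likelihood of the fitted data; for BDA
#'     fits the profile runs over the prior-augmented data.}
#' }
#' A profile that stays below the cutoff out to `|beta_j| = 40` on the log
#' scale yields an infinite bound (e.g. the upper ML limit under separation).
#'
#' @param fit A `pois_fit` from [fit_ml()], [fit_fl()], [fit_flac()],
#'   [fit_flic()] or [fit_bda()].
#' @param parm Coefficient indices (1 = intercept); default all.
#' @param level Confidence level in (0,1).
#' @param mode One of `"ppl"`, `"pl_fixed"`, `"ml_pl"`; the default picks
#'   `ppl` for Firth-type fits and `ml_pl` otherwise.
#' @param control A [pois_control()] list for the inner maximizations.
#' @return Matrix of class `pois_ci` (log-IRR scale) with columns
#'   `lower`/`upper`; `attr(, "mode")` records the profile used.
#' @examples
#' covid <- pois_data(c(0, 3, 3), cbind(nursing = c(0, 1, 0),
#'                                      hospital = c(0, 0, 1)),
#'                    multiplier = c(352, 444, 365))
#' exp(profile_ci(fit_fl(covid), parm = 2:3))   # (0.54, 746), (0.65, 908)
#' @export
profile_ci <- function(fit, parm = NULL, level = 0.95, mode = NULL,
                       control = pois_control()) {
  stopifnot(inherits(fit, "pois_fit"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)")
  if (is.null(mode))
    mode <- switch(fit$method, fl = , flac = , flic = "ppl", "ml_pl")
  mode <- match.arg(mode, c("ppl", "pl_fixed", "ml_pl"))
  p <- length(fit$coefficients)
  if (is.null(parm)) parm <- seq_len(p)
  if (any(parm < 1 | parm > p)) stop("'parm' out of range")
  # tighter inner tolerance so profile values are stable near the roots
  control$tol_score <- min(control$tol_score, 1e-8)
  ctx <- profile_context(fit, mode, control)
  cutoff <- stats::qchisq(level, df = 1)
  ci <- t(vapply(parm, function(j) {
    c(profile_root(ctx, j, cutoff, -1), profile_root(ctx, j, cutoff, +1))
  }, numeric(2)))
  dimnames(ci) <- list(names(fit$coefficients)[parm], c("lower", "upper"))
  structure(ci, class = c("pois_ci", "matrix"), level = level, mode = mode,
            unreliable = FALSE)
}

#' @export
print.pois_ci <- function(x, ...) {
  cat(attr(x, "level") * 100, "% CI (", attr(x, "mode"), "):\n", sep = "")
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, 4))
  if (isTRUE(attr(x, "unreliable")))
    cat("WARNING: Wald interval under separation is unreliable\n")
  invisible(x)
}
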