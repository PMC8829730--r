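#' Fitter control parameters
#'
#' @param max_iter Maximum Newton iterations.
#' @param tol_score Convergence: largest absolute (modified) score component.
#' @param tol_step Convergence: Euclidean norm of the last Newton step.
#' @param max_halving Maximum step-halvings per iteration.
#' @return A list of class `pois_control`.
#' @export
pois_control <- function(max_iter = 100L, tol_score = 1e-6,
                         tol_step = 1e-8, max_halving = 30L) {
  structure(list(max_iter = as.integer(max_iter), tol_score = tol_score,
                 tol_step = tol_step, max_halving = as.integer(max_halving)),
            class = "pois_control")
}

check_beta <- function(data, beta) {
  if (length(beta) != ncol(data$X))
    stop("'beta' must have length k+1 = ", ncol(data$X))
  if (any(!is.finite(beta))) stop("'beta' must be finite")
  invisible(beta)
}

# Raw-matrix log-likelihood; y may be fractional (internal augmented data).
ll_raw <- function(y, X, z, beta) {
  eta <- drop(X %*% beta) + z
  sum(-exp(eta) + eta * y - lgamma(y + 1))
}

#' Poisson log-likelihood
#'
#' Includes the `-log(y!)` constant so that likelihood values are comparable
#' across methods and augmented-data representations.
#'
#' @param data A [pois_data] object.
#' @param beta Coefficient vector of length `k+1` (intercept first).
#' @return The log-likelihood (scalar; `-Inf` if a fitted mean overflows).
#' @export
pois_loglik <- function(data, beta) {
  check_beta(data, beta)
  ll_raw(data$y, data$X, data$z, beta)
}

#' Poisson score vector
#'
#' `U_j(beta) = sum_i x_ij (y_i - mu_i)` with `mu_i = exp(x_i beta + z_i)`.
#'
#' @inheritParams pois_loglik
#' @return Numeric vector of length `k+1`.
#' @export
pois_score <- function(data, beta) {
  check_beta(data, beta)
  mu <- exp(drop(data$X %*% beta) + data$z)
  drop(crossprod(data$X, data$y - mu))
}

#' Fisher information matrix
#'
#' `I(beta) = X' W X` with `W = diag(mu_i)`; symmetric positive definite for
#' a full-rank design.
#'
#' @inheritParams pois_loglik
#' @return `(k+1) x (k+1)` matrix.
#' @export
pois_information <- function(data, beta) {
  check_beta(data, beta)
  mu <- exp(drop(data$X %*% beta) + data$z)
  crossprod(data$X * sqrt(mu))
}

# hat diagonals from the Cholesky factor of X'WX
hat_from_chol <- function(Xs, R) {
  V <- Xs %*% chol2inv(R)
  rowSums(V * Xs)
}

#' Hat-matrix diagonals (leverages)
#'
#' Diagonal of `W^{1/2} X (X'WX)^{-1} X' W^{1/2}`. Satisfies `h_i` in (0, 1]
#' and `sum(h) = k+1` at every `beta`.
#'
#' @inheritParams pois_loglik
#' @return Numeric vector of length `n`.
#' @export
hat_diagonals <- function(data, beta) {
  check_beta(data, beta)
  check_full_rank(data$X)
  mu <- exp(drop(data$X %*% beta) + data$z)
  Xs <- data$X * sqrt(mu)
  R <- tryCatch(chol(crossprod(Xs)),
                error = function(e) stop("singular information matrix"))
  hat_from_chol(Xs, R)
}

# Newton engine with step-halving on raw matrices. Handles ordinary ML
# (penalized = FALSE) and Firth (penalized = TRUE, modified score
# U* = X'(y + h/2 - mu), ascent direction from the expected information).
# 'fixed' indexes coefficients frozen at their value in 'start' (profiling).
newton_pois <- function(y, X, z, penalized = FALSE, start = NULL,
                        fixed = integer(0), control = pois_control()) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  if (is.null(start)) {
    b0 <- log(max(sum(y), 0.25) / sum(exp(z)))
    start <- c(b0, numeric(p - 1L))
  }
  beta <- as.numeric(start)

  objective <- function(beta) {
    eta <- drop(X %*% beta) + z
    mu <- exp(eta)
    ll <- sum(-mu + eta * y - lgamma(y + 1))
    if (!penalized) return(ll)
    R <- tryCatch(chol(crossprod(X * sqrt(mu))), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    ll + sum(log(diag(R)))
  }

  obj <- objective(beta)
  converged <- FALSE
  singular <- FALSE
  iter <- 0L
  U <- rep(NA_real_, p)
  h <- NULL

  while (iter < control$max_iter && length(free) > 0L) {
    iter <- iter + 1L
    mu <- exp(drop(X %*% beta) + z)
    if (any(!is.finite(mu))) break
    Xs <- X * sqrt(mu)
    R <- tryCatch(chol(crossprod(Xs)), error = function(e) NULL)
    if (is.null(R)) { singular <- TRUE; break }
    if (penalized) {
      h <- hat_from_chol(Xs, R)
      U <- drop(crossprod(X, y + h / 2 - mu))
    } else {
      U <- drop(crossprod(X, y - mu))
    }
    info_ff <- crossprod(Xs[, free, drop = FALSE])
    Rf <- tryCatch(chol(info_ff), error = function(e) NULL)
    if (is.null(Rf)) { singular <- TRUE; break }
    step <- backsolve(Rf, forwardsolve(t(Rf), U[free]))

    lambda <- 1
    improved <- FALSE
    # once the score is small, Newton is locally convergent; skip the ascent
    # check, which drowns in floating-point noise when |objective| is huge
    # (e.g. BDA pseudo-counts of order S^2/v)
    near_opt <- max(abs(U[free])) < 1e-3
    for (half in seq_len(control$max_halving)) {
      cand <- beta
      cand[free] <- beta[free] + lambda * step
      ocand <- objective(cand)
      if (is.finite(ocand) && (near_opt || ocand > obj - 1e-12)) {
        beta <- cand; obj <- ocand; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (max(abs(U[free])) < control$tol_score &&
        sqrt(sum((lambda * step)^2)) < control$tol_step) {
      converged <- TRUE
      break
    }
  }
  if (length(free) == 0L) converged <- TRUE

  # final quantities at the returned iterate
  mu <- exp(drop(X %*% beta) + z)
  Xs <- X * sqrt(mu)
  R <- tryCatch(chol(crossprod(Xs)), error = function(e) NULL)
  if (is.null(R)) {
    cov <- matrix(NA_real_, p, p)
    h <- rep(NA_real_, nrow(X))
    logdet <- -Inf
  } else {
    cov <- chol2inv(R)
    h <- hat_from_chol(Xs, R)
    logdet <- 2 * sum(log(diag(R)))
  }
  ll <- ll_raw(y, X, z, beta)
  # re-check the score criterion at the final iterate
  Ufin <- if (penalized && !is.null(R))
    drop(crossprod(X, y + h / 2 - mu)) else drop(crossprod(X, y - mu))
  if (length(free) > 0L && !is.null(R) &&
      max(abs(Ufin[free])) < control$tol_score) converged <- TRUE

  list(beta = beta, mu = mu, cov = cov, hat = h,
       loglik = ll, penloglik = ll + 0.5 * logdet,
       converged = converged, singular = singular, iterations = iter,
       score = Ufin)
}

new_pois_fit <- function(res, data, method, separated, extra = list()) {
  cf <- res$beta
  names(cf) <- data$col_names
  out <- c(list(coefficients = cf, mu_hat = res$mu[seq_len(data$n)],
                cov = res$cov, hat = res$hat[seq_len(data$n)],
                loglik = res$loglik, penloglik = res$penloglik,
                method = method, converged = res$converged,
                separated = separated, iterations = res$iterations,
                data = data),
           extra)
  class(out) <- "pois_fit"
  out
}

#' Maximum likelihood Poisson regression
#'
#' Newton optimization with step-halving. If the data are separated
#' (see [detect_separation()]) the maximizer does not exist; rather than
#' aborting, the last Newton iterate is returned with `separated = TRUE`,
#' mirroring common software behaviour of reporting last-iteration values.
#'
#' @param data A [pois_data] object.
#' @param control A [pois_control()] list.
#' @return A `pois_fit` object with elements `coefficients`, `mu_hat`, `cov`,
#'   `hat`, `loglik`, `penloglik`, `method`, `converged`, `separated`,
#'   `iterations`.
#' @examples
#' d <- pois_data(rpois(30, 1), cbind(x = rnorm(30)))
#' fit_ml(d)
#' @export
fit_ml <- function(data, control = pois_control()) {
  stopifnot(inherits(data, "pois_data"))
  check_full_rank(data$X)
  sep <- detect_separation(data)$separated
  res <- newton_pois(data$y, data$X, data$z, penalized = FALSE,
                     control = control)
  new_pois_fit(res, data, "ml", sep)
}

#' @export
print.pois_fit <- function(x, ...) {
  cat("Poisson regression (", toupper(x$method), ")\n", sep = "")
  est <- x$coefficients
  tab <- cbind(estimate = est, IRR = exp(est),
               se = sqrt(diag(x$cov))[seq_along(est)])
  print(round(tab, 4))
  cat("logLik:", format(x$loglik, digits = 6),
      if (is.finite(x$penloglik))
        paste(" penalized:", format(x$penloglik, digits = 6)) else "", "\n")
  if (x$separated) cat("NOTE: data are separated; ML estimates do not exist\n")
  if (!x$converged) cat("WARNING: fitter did not converge\n")
  invisible(x)
}

#' @export
coef.pois_fit <- function(object, ...) object$coefficients

#' @export
fitted.pois_fit <- function(object, ...) object$mu_hat

#' @export
logLik.pois_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}
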