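#' Exact conditional distribution of a sufficient statistic
#'
#' For target coefficient `beta_j` the sufficient statistic is
#' `T_j = sum_i x_ij y_i`; exact inference conditions on the observed
#' sufficient statistics of *all* other coefficients (including the
#' intercept's, the total event count). The conditional law is
#' `P(T_j = t | nuisance; beta_j) = c(t) e^{t beta_j} / sum_s c(s) e^{s beta_j}`
#' with combinatorial weights
#' `c(t) = sum over outcome vectors matching the nuisance statistics of
#' prod_i E_i^{y_i} / y_i!`, `E_i = e^{z_i}`.
#'
#' Enumeration is a depth-first recursion over rows with memoization on the
#' remaining nuisance budgets and log-sum-exp accumulation. All covariate
#' columns must be integer-valued: conditioning on a continuous covariate
#' forces a singleton (degenerate) support from which no inference is
#' possible. Feasibility guards (`sum(y) <= 60`, `n <= 250`, `k <= 5`)
#' bound the enumeration to the scale where exact inference is practical.
#'
#' @param data A [pois_data] object with integer-valued covariates.
#' @param j Coefficient index of the target, `2..k+1` (not the intercept).
#' @return A `cond_dist` list: `j`, `t_obs`, `support` (ordered), `logw`
#'   (log weights `log c(t)`), `degenerate`.
#' @examples
#' covid <- pois_data(c(0, 3, 3), cbind(nursing = c(0, 1, 0),
#'                                      hospital = c(0, 0, 1)),
#'                    multiplier = c(352, 444, 365))
#' conditional_support(covid, j = 2)   # support 0..3, binomial-type weights
#' @export
conditional_support <- function(data, j) {
  stopifnot(inherits(data, "pois_data"))
  p <- ncol(data$X)
  if (j < 2 || j > p) stop("'j' must index a non-intercept coefficient")
  for (col in 2:p) {
    v <- data$X[, col]
    if (any(abs(v - round(v)) > 1e-8))
      stop("exact conditional inference needs integer-valued covariates; ",
           "column '", data$col_names[col], "' is not")
  }
  tot <- sum(data$y)
  if (tot > 60) stop("enumeration guard: sum(y) = ", tot, " exceeds 60")
  if (data$n > 250) stop("enumeration guard: n exceeds 250")
  if (data$k > 5) stop("enumeration guard: k exceeds 5")

  X <- round(data$X)
  nuis_idx <- setdiff(seq_len(p), j)          # includes the intercept column
  Xn <- X[, nuis_idx, drop = FALSE]
  xj <- X[, j]
  t_nuis <- drop(crossprod(Xn, data$y))
  t_obs <- sum(xj * data$y)
  z <- data$z
  n <- data$n

  # suffix extrema for pruning: the remaining budget b of events, all of
  # which must land on rows i..n, moves each nuisance statistic by an amount
  # in [b * min(v_i..v_n), b * max(v_i..v_n)]
  lo_coef <- apply(Xn, 2, function(v) rev(cummin(rev(v))))
  hi_coef <- apply(Xn, 2, function(v) rev(cummax(rev(v))))
  if (data$n == 1L) { lo_coef <- matrix(lo_coef, 1); hi_coef <- matrix(hi_coef, 1) }
  intercept_col <- match(1L, nuis_idx)        # position of the total-count stat

  memo <- new.env(parent = emptyenv())
  logsumexp2 <- function(a, b) {
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
  }
  recurse <- function(i, rem) {
    # rem: remaining nuisance statistic vector; rem[intercept_col] = budget
    budget <- rem[intercept_col]
    if (i > n) {
      if (all(rem == 0)) return(c(`0` = 0)) else return(NULL)
    }
    if (budget < 0) return(NULL)
    lo <- lo_coef[i, ] * budget
    hi <- hi_coef[i, ] * budget
    if (any(rem < lo - 1e-9) || any(rem > hi + 1e-9)) return(NULL)
    key <- paste(i, paste(rem, collapse = ","), sep = ";")
    hit <- memo[[key]]
    if (!is.null(hit)) return(if (identical(hit, NA)) NULL else hit)
    acc <- NULL
    for (a in 0:budget) {
      sub <- recurse(i + 1L, rem - a * Xn[i, ])
      if (is.null(sub)) next
      w <- a * z[i] - lgamma(a + 1)
      tadd <- a * xj[i]
      names(sub) <- as.character(as.numeric(names(sub)) + tadd)
      sub <- sub + w
      if (is.null(acc)) {
        acc <- sub
      } else {
        common <- intersect(names(acc), names(sub))
        if (length(common))
          acc[common] <- logsumexp2(acc[common], sub[common])
        new <- setdiff(names(sub), names(acc))
        acc <- c(acc, sub[new])
      }
    }
    memo[[key]] <- if (is.null(acc)) NA else acc
    acc
  }

  res <- recurse(1L, t_nuis)
  if (is.null(res))
    stop("internal error: observed statistics not reproduced") # nocov
  tv <- as.numeric(names(res))
  o <- order(tv)
  support <- tv[o]
  logw <- unname(res[o])
  structure(list(j = j, t_obs = t_obs, support = support, logw = logw,
                 degenerate = length(support) == 1L),
            class = "cond_dist")
}

# log P-masses of the conditional distribution at log-IRR beta
cond_logprob <- function(dist, beta) {
  lp <- dist$logw + dist$support * beta
  lp - logsumexp(lp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# P(T >= t), P(T <= t), and mid-p upper/lower tails at beta
cond_tail <- function(dist, beta, t, type = c("ge", "le", "midp_ge", "midp_le")) {
  type <- match.arg(type)
  lp <- cond_logprob(dist, beta)
  s <- dist$support
  eq <- exp(logsumexp(lp[abs(s - t) < 1e-9]))
  switch(type,
         ge = sum(exp(lp[s >= t - 1e-9])),
         le = sum(exp(lp[s <= t + 1e-9])),
         midp_ge = sum(exp(lp[s > t + 1e-9])) + 0.5 * eq,
         midp_le = sum(exp(lp[s < t - 1e-9])) + 0.5 * eq)
}

# root of f over the log-IRR scale; f must be monotone increasing in beta.
# Returns -Inf/Inf when no sign change occurs inside [-bound, bound].
exact_root <- function(f, bound = 40, tol = 1e-8) {
  flo <- f(-bound); fhi <- f(bound)
  if (flo > 0) return(-Inf)
  if (fhi < 0) return(Inf)
  stats::uniroot(f, c(-bound, bound), tol = tol)$root
}

#' Maximum conditional likelihood estimate (MCLE)
#'
#' The value of `beta_j` maximizing the conditional likelihood; equivalently
#' the root of `E_beta[T] = t_obs`. The MCLE is finite exactly when the
#' observed statistic is interior to the support; at a support boundary it
#' degenerates to +/- infinity and the caller should fall back to the MUE.
#'
#' @param dist A `cond_dist` from [conditional_support()].
#' @return List `estimate` (log-IRR; `+/-Inf` at a boundary, `NA` if
#'   degenerate), `exists`, `degenerate`.
#' @export
mcle <- function(dist) {
  stopifnot(inherits(dist, "cond_dist"))
  if (dist$degenerate)
    return(list(estimate = NA_real_, exists = FALSE, degenerate = TRUE))
  smin <- min(dist$support); smax <- max(dist$support)
  if (dist$t_obs <= smin + 1e-9)
    return(list(estimate = -Inf, exists = FALSE, degenerate = FALSE))
  if (dist$t_obs >= smax - 1e-9)
    return(list(estimate = Inf, exists = FALSE, degenerate = FALSE))
  cmean <- function(beta) sum(exp(cond_logprob(dist, beta)) * dist$support)
  est <- exact_root(function(b) cmean(b) - dist$t_obs)
  list(estimate = est, exists = is.finite(est), degenerate = FALSE)
}

#' Median unbiased estimate (MUE)
#'
#' Boundary cases solve the half-median tail equations
#' `P(T >= t_obs | beta) = 0.5` (upper boundary) or
#' `P(T <= t_obs | beta) = 0.5` (lower boundary); for interior `t_obs` the
#' estimate is the midpoint of the two half-median solutions (Hirji-style
#' convention). Equivariant under sign recoding of the covariate.
#'
#' @inheritParams mcle
#' @return List `estimate` (log-IRR; `NA` if degenerate), `degenerate`.
#' @export
mue <- function(dist) {
  stopifnot(inherits(dist, "cond_dist"))
  if (dist$degenerate)
    return(list(estimate = NA_real_, degenerate = TRUE))
  t <- dist$t_obs
  smin <- min(dist$support); smax <- max(dist$support)
  b_ge <- function() exact_root(function(b) cond_tail(dist, b, t, "ge") - 0.5)
  b_le <- function() exact_root(function(b) 0.5 - cond_tail(dist, b, t, "le"))
  est <- if (t >= smax - 1e-9) b_ge()
         else if (t <= smin + 1e-9) b_le()
         else (b_ge() + b_le()) / 2
  list(estimate = est, degenerate = FALSE)
}

#' Exact and mid-p conditional confidence intervals
#'
#' Tail inversion at level `1 - alpha`: the lower bound solves
#' `P(T >= t_obs | beta) = alpha/2`, the upper bound the mirrored
#' lower-tail equation. The mid-p variant counts only half the probability
#' of the observed point (`P(T > t) + 0.5 P(T = t) = alpha/2`), is never
#' wider than the exact interval, and corrects its conservatism. A bound is
#' infinite when `t_obs` sits on the corresponding support boundary.
#'
#' @inheritParams mcle
#' @param level Confidence level in (0,1).
#' @param midp Use the mid-p tail equations?
#' @return `c(lower, upper)` on the log-IRR scale.
#' @export
exact_ci <- function(dist, level = 0.95, midp = FALSE) {
  stopifnot(inherits(dist, "cond_dist"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)")
  if (dist$degenerate) return(c(lower = NA_real_, upper = NA_real_))
  a2 <- (1 - level) / 2
  t <- dist$t_obs
  smin <- min(dist$support); smax <- max(dist$support)
  ge <- if (midp) "midp_ge" else "ge"
  le <- if (midp) "midp_le" else "le"
  lower <- if (t <= smin + 1e-9) -Inf else
    exact_root(function(b) cond_tail(dist, b, t, ge) - a2)
  upper <- if (t >= smax - 1e-9) Inf else
    exact_root(function(b) a2 - cond_tail(dist, b, t, le))
  c(lower = lower, upper = upper)
}

#' Exact conditional Poisson inference for one coefficient
#'
#' Convenience wrapper: enumerates the conditional distribution, computes
#' the MCLE (falling back to the MUE when the observed statistic is on the
#' support boundary), and both exact and mid-p confidence intervals.
#'
#' @param data A [pois_data] with integer-valued covariates.
#' @param j Target coefficient index (`2..k+1`).
#' @param level Confidence level.
#' @return An `exact_result` list: `estimate` (log-IRR), `estimate_type`
#'   (`"MCLE"`, `"MUE"` or `"none"`), `ci_exact`, `ci_midp`, `level`,
#'   `dist`.
#' @export
exact_poisson <- function(data, j, level = 0.95) {
  dist <- conditional_support(data, j)
  if (dist$degenerate) {
    out <- list(estimate = NA_real_, estimate_type = "none",
                ci_exact = c(lower = NA_real_, upper = NA_real_),
                ci_midp = c(lower = NA_real_, upper = NA_real_),
                level = level, dist = dist)
    return(structure(out, class = "exact_result"))
  }
  m <- mcle(dist)
  if (m$exists) {
    est <- m$estimate; type <- "MCLE"
  } else {
    est <- mue(dist)$estimate; type <- "MUE"
  }
  structure(list(estimate = est, estimate_type = type,
                 ci_exact = exact_ci(dist, level, midp = FALSE),
                 ci_midp = exact_ci(dist, level, midp = TRUE),
                 level = level, dist = dist),
            class = "exact_result")
}

#' @export
print.exact_result <- function(x, ...) {
  cat("Exact conditional Poisson inference\n")
  if (x$estimate_type == "none") {
    cat("degenerate conditional distribution: no inference possible\n")
    return(invisible(x))
  }
  cat(sprintf("  %s (IRR): %.4f\n", x$estimate_type, exp(x$estimate)))
  cat(sprintf("  exact %g%% CI (IRR): (%.4f, %.4f)\n", 100 * x$level,
              exp(x$ci_exact[1]), exp(x$ci_exact[2])))
  cat(sprintf("  mid-p %g%% CI (IRR): (%.4f, %.4f)\n", 100 * x$level,
              exp(x$ci_midp[1]), exp(x$ci_midp[2])))
  invisible(x)
}
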