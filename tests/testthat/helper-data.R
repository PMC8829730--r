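# dataset builders used across the suite

covid_data <- function() {
  pois_data(y = c(0, 3, 3),
            x = cbind(nursing = c(0, 1, 0), hospital = c(0, 0, 1)),
            multiplier = c(352, 444, 365))
}

two_group_data <- function() {
  # symmetric toy: equal exposure, one event in each group
  pois_data(y = c(1, 1), x = cbind(group = c(0, 1)))
}

# random Poisson regression data; optionally resample until non-separated
rand_data <- function(n, k, seed, beta = NULL, nonseparated = FALSE,
                      binary = FALSE, offset = FALSE) {
  set.seed(seed)
  if (is.null(beta)) beta <- c(0, stats::rnorm(k, 0, 0.5))
  repeat {
    x <- matrix(if (binary) stats::rbinom(n * k, 1, 0.4)
                else stats::rnorm(n * k), n, k)
    z <- if (offset) stats::runif(n, -0.5, 0.5) else rep(0, n)
    mu <- exp(beta[1] + drop(x %*% beta[-1]) + z)
    y <- stats::rpois(n, mu)
    d <- pois_data(y, x, offset = z)
    if (qr(d$X)$rank < ncol(d$X)) next
    if (!nonseparated || !detect_separation(d)$separated) return(d)
  }
}
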