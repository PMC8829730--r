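test_that("penalized loglik: single-cell closed form and determinant oracle", {
  d1 <- pois_data(2)
  # l*(b) = -e^b + 2b - log 2 + b/2, maximized at log 2.5
  expect_equal(penalized_loglik(d1, 0.7),
               pois_loglik(d1, 0.7) + 0.5 * 0.7)
  opt <- stats::optimize(function(b) penalized_loglik(d1, b), c(-3, 3),
                         maximum = TRUE)
  expect_equal(opt$maximum, log(2.5), tolerance = 1e-5)

  for (s in 1:3) {
    d <- rand_data(10, 2, seed = 500 + s)
    b <- stats::rnorm(3, 0, 0.4)
    mu <- exp(drop(d$X %*% b) + d$z)
    ld <- determinant(t(d$X) %*% diag(mu) %*% d$X)$modulus
    expect_equal(penalized_loglik(d, b),
                 pois_loglik(d, b) + 0.5 * as.numeric(ld),
                 tolerance = 1e-9)
  }
})

test_that("fit_fl reproduces the COVID risk ratios and the saturated rule", {
  f <- fit_fl(covid_data())
  expect_true(f$converged)
  expect_equal(unname(exp(coef(f)[2:3])), c(5.55, 6.75), tolerance = 5e-4)

  # saturated: FL equals ML on y + 0.5 exactly (h == 1)
  g <- suppressWarnings(
    stats::glm((c(0, 3, 3) + 0.5) ~ covid_data()$X - 1 +
                 offset(covid_data()$z), family = stats::poisson))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(f$hat), rep(1, 3), tolerance = 1e-8)
})

test_that("fit_fl equals generic numeric maximization of the penalty objective", {
  for (s in 1:5) {
    d <- rand_data(25, 2, seed = 600 + s, nonseparated = TRUE, offset = TRUE)
    f <- fit_fl(d)
    o <- stats::optim(coef(f) * 0, function(b) -penalized_loglik(d, b),
                      method = "BFGS", control = list(reltol = 1e-14))
    expect_equal(unname(coef(f)), unname(o$par), tolerance = 1e-5)
    expect_gte(f$penloglik, -o$value - 1e-7)
    # modified score is zero at the solution
    U <- drop(crossprod(d$X, d$y + f$hat / 2 - f$mu_hat))
    expect_lt(max(abs(U)), 1e-6)
  }
})

test_that("FL conservation and finiteness under separation", {
  for (s in 1:8) {
    d <- rand_data(20, 2, seed = 700 + s, binary = TRUE)
    f <- fit_fl(d)
    k1 <- ncol(d$X)
    expect_equal(sum(f$mu_hat) - sum(d$y), k1 / 2, tolerance = 1e-7)
    expect_true(all(abs(coef(f)) < 50))
    expect_true(f$converged)
  }
})

test_that("FLAC: slope identity, conservation, gamma reported", {
  d <- covid_data()
  fl <- fit_fl(d)
  fa <- fit_flac(d)
  expect_equal(coef(fa)[2:3], coef(fl)[2:3], tolerance = 1e-7)
  expect_equal(unname(coef(fa)[1]), unname(coef(fl)[1]) + log(6 / 7.5),
               tolerance = 1e-7)
  expect_equal(sum(fa$mu_hat), sum(d$y), tolerance = 1e-8 * sum(d$y))
  expect_true(is.finite(fa$gamma_flac))
  # augmented pseudo-counts sum to (k+1)/2
  expect_equal(sum(fa$augmented$pseudo_counts), ncol(d$X) / 2,
               tolerance = 1e-8)

  # saturated single cell: FLAC intercept recalibrated from log 2.5 to log 2
  d1 <- pois_data(2)
  expect_equal(unname(coef(fit_flac(d1))), log(2), tolerance = 1e-7)
})

test_that("k = 4 with 37 events: FL predicts 39.5, FLAC recalibrates to 37", {
  set.seed(42)
  x <- matrix(stats::rbinom(200 * 4, 1, 0.3), 200, 4)
  y <- drop(stats::rmultinom(1, 37, prob = stats::runif(200)))
  d <- pois_data(y, x)
  expect_equal(sum(fit_fl(d)$mu_hat), 39.5, tolerance = 1e-6)
  expect_equal(sum(fit_flac(d)$mu_hat), 37, tolerance = 1e-6)
})

test_that("FLIC: closed-form delta and coincidence with FLAC", {
  d <- covid_data()
  fi <- fit_flic(d)
  expect_equal(fi$delta_flic, log(6 / 7.5), tolerance = 1e-9)
  for (s in 1:25) {
    d <- rand_data(15, 2, seed = 800 + s, binary = TRUE)
    if (sum(d$y) == 0) next
    fi <- fit_flic(d)
    fa <- fit_flac(d)
    expect_equal(coef(fi), coef(fa), tolerance = 1e-6)
    k1 <- ncol(d$X)
    expect_equal(fi$delta_flic, log(sum(d$y) / (sum(d$y) + k1 / 2)),
                 tolerance = 1e-9)
  }
  expect_error(fit_flic(pois_data(c(0, 0), cbind(x = c(0, 1)))),
               "no events")
})

test_that("FL bias toward zero beats ML on sparse simulated data", {
  # small stochastic check at beta1 = -log 4: FL closer to truth on average
  beta1 <- -log(4)
  b_ml <- b_fl <- c()
  for (s in 1:150) {
    set.seed(900 + s)
    x <- stats::rbinom(40, 1, 0.15)
    y <- stats::rpois(40, exp(-1.2 + beta1 * x))
    d <- pois_data(y, cbind(x = x))
    if (qr(d$X)$rank < 2) next
    ffl <- fit_fl(d)
    b_fl <- c(b_fl, coef(ffl)[2])
    fml <- fit_ml(d)
    if (!fml$separated) b_ml <- c(b_ml, coef(fml)[2])
  }
  expect_lt(abs(mean(b_fl) - beta1), abs(mean(b_ml) - beta1))
})
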