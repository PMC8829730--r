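test_that("COVID conditional distribution reduces to the binomial form", {
  d <- covid_data()
  cd <- conditional_support(d, j = 2)
  expect_equal(cd$support, 0:3)
  expect_equal(cd$t_obs, 3)
  # two-group reduction: P(T = t | r) = C(3,t) (444 r)^t 352^(3-t) / (...)^3,
  # so at r = 1 the weights are proportional to C(3,t) 444^t 352^(3-t)
  w <- exp(cd$logw - cd$logw[1])
  expect_equal(w, choose(3, 0:3) * (444 / 352)^(0:3), tolerance = 1e-9)
})

test_that("two equal groups with one event each give symmetric weights", {
  cd <- conditional_support(two_group_data(), j = 2)
  expect_equal(cd$support, 0:2)
  w <- exp(cd$logw)
  expect_equal(w / w[2], c(0.5, 1, 0.5), tolerance = 1e-9)
})

test_that("enumeration matches brute-force product-space oracle", {
  for (s in 1:8) {
    set.seed(1400 + s)
    n <- sample(3:6, 1)
    k <- sample(1:2, 1)
    x <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
    y <- stats::rpois(n, 0.6)
    if (sum(y) == 0 || sum(y) > 5) next
    d <- pois_data(y, x, offset = stats::runif(n, -0.3, 0.3))
    j <- 2L
    cd <- conditional_support(d, j)
    br <- brute_cond(d, j)
    expect_equal(cd$support, br$support)
    expect_equal(exp(cd$logw), br$w, tolerance = 1e-10)
  }
})

test_that("degenerate and guard cases are flagged", {
  # events only where the covariate duplicates the intercept pattern:
  # conditioning forces a singleton support
  d <- pois_data(c(1, 1, 0), cbind(a = c(1, 1, 1)))
  cd <- conditional_support(d, 2)
  expect_true(cd$degenerate)
  r <- exact_poisson(d, 2)
  expect_identical(r$estimate_type, "none")
  expect_true(is.na(r$estimate))

  dc <- pois_data(c(1, 0), cbind(a = c(0.5, 1)))
  expect_error(conditional_support(dc, 2), "integer")
  expect_error(conditional_support(covid_data(), 1), "non-intercept")
})

test_that("MCLE: symmetry, boundary nonexistence, numeric-optimizer oracle", {
  cd <- conditional_support(two_group_data(), j = 2)
  expect_equal(mcle(cd)$estimate, 0, tolerance = 1e-8)

  # COVID: t_obs at the support maximum, MCLE does not exist
  m <- mcle(conditional_support(covid_data(), 2))
  expect_false(m$exists)
  expect_identical(m$estimate, Inf)

  set.seed(1500)
  x <- c(0, 0, 1, 1, 2)
  y <- c(1, 0, 1, 1, 0)
  d <- pois_data(y, cbind(x = x), offset = stats::runif(5, -0.2, 0.2))
  cd <- conditional_support(d, 2)
  m <- mcle(cd)
  clik <- function(b) cd$logw[match(cd$t_obs, cd$support)] + cd$t_obs * b -
    poisfl:::logsumexp(cd$logw + cd$support * b)
  o <- stats::optimize(clik, c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(m$estimate, o$maximum, tolerance = 1e-6)
})

test_that("MUE reproduces the COVID estimates and is sign-equivariant", {
  # frozen closed forms: solve p^3 = 0.5, p = E1 r/(E1 r + 352)
  expect_equal(exp(mue(conditional_support(covid_data(), 2))$estimate),
               3.05012923, tolerance = 1e-6)
  expect_equal(exp(mue(conditional_support(covid_data(), 3))$estimate),
               3.71029419, tolerance = 1e-6)
  expect_equal(mue(conditional_support(two_group_data(), 2))$estimate, 0,
               tolerance = 1e-8)

  # recoding the binary covariate flips the sign of the estimate
  set.seed(1600)
  x <- stats::rbinom(8, 1, 0.5)
  y <- stats::rpois(8, 0.7)
  d1 <- pois_data(y, cbind(x = x))
  d2 <- pois_data(y, cbind(x = 1 - x))
  m1 <- mue(conditional_support(d1, 2))$estimate
  m2 <- mue(conditional_support(d2, 2))$estimate
  expect_equal(m1, -m2, tolerance = 1e-7)
})

test_that("exact and mid-p CIs: COVID bounds, nesting, antisymmetry", {
  cd_n <- conditional_support(covid_data(), 2)
  cd_h <- conditional_support(covid_data(), 3)
  expect_equal(exp(exact_ci(cd_n, midp = TRUE)[1]), 0.46242688,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(exp(exact_ci(cd_h, midp = TRUE)[1]), 0.56251380,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(exact_ci(cd_n, midp = TRUE)[2]), Inf)
  expect_identical(unname(exact_ci(cd_n, midp = FALSE)[2]), Inf)
  # exact lower bound solves p^3 = 0.025 instead
  expect_equal(exp(exact_ci(cd_n, midp = FALSE)[1]), 0.32760684,
               tolerance = 1e-6, ignore_attr = TRUE)

  # mid-p interval is contained in the exact interval
  for (s in 1:6) {
    set.seed(1700 + s)
    x <- stats::rbinom(8, 1, 0.5)
    y <- stats::rpois(8, 0.8)
    d <- pois_data(y, cbind(x = x))
    cd <- tryCatch(conditional_support(d, 2), error = function(e) NULL)
    if (is.null(cd) || cd$degenerate) next
    ce <- exact_ci(cd)
    cm <- exact_ci(cd, midp = TRUE)
    expect_gte(cm[1], ce[1])
    expect_lte(cm[2], ce[2])
  }

  # symmetric toy: interval endpoints reciprocal on the IRR scale
  cd <- conditional_support(two_group_data(), 2)
  ci <- exact_ci(cd)
  expect_equal(ci[1], -ci[2], tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(exact_ci(cd, level = 0), "level")
})

test_that("hypergeometric closed form at beta = 0, equal offsets", {
  # single binary covariate, equal offsets: c(t) proportional to
  # C(m1, t)-type factorial allocations; verify against the factorial formula
  x <- c(1, 1, 0, 0, 0)
  y <- c(1, 0, 1, 1, 0)
  d <- pois_data(y, cbind(x = x))
  cd <- conditional_support(d, 2)
  tot <- sum(y)
  m1 <- sum(x)
  m0 <- length(x) - m1
  # allocations of 'tot' events: weight(t) = m1^t m0^(tot-t)/(t!(tot-t)!)
  w_formula <- vapply(cd$support, function(t)
    m1^t * m0^(tot - t) / (factorial(t) * factorial(tot - t)), numeric(1))
  w <- exp(cd$logw)
  expect_equal(w / w[1], w_formula / w_formula[1], tolerance = 1e-9)
})
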