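#' Construct a Poisson count dataset
#'
#' Bundles an event-count vector, a covariate matrix and an exposure offset
#' into the object consumed by all fitters. The design matrix stored in the
#' object always carries an intercept column of 1s as its first column.
#'
#' @param y Nonnegative integer event counts, length `n`.
#' @param x Covariate matrix or data frame (`n` rows, `k` columns), *without*
#'   an intercept column; an intercept is prepended. May be `NULL` for an
#'   intercept-only model.
#' @param offset Optional per-observation log-offset (e.g. log follow-up
#'   time). Defaults to 0.
#' @param multiplier Optional positive rate multiplier (e.g. persons tested,
#'   number of implantations); converted internally to `offset = log(multiplier)`.
#'   At most one of `offset`/`multiplier` may be given.
#' @return An object of class `pois_data` with elements `y`, `X` (including
#'   intercept), `z` (log-offset), `n`, `k` and `col_names`.
#' @examples
#' d <- pois_data(y = c(0, 3, 3),
#'                x = cbind(nursing = c(0, 1, 0), hospital = c(0, 0, 1)),
#'                multiplier = c(352, 444, 365))
#' d
#' @export
pois_data <- function(y, x = NULL, offset = NULL, multiplier = NULL) {
  if (length(y) == 0L) stop("empty dataset: 'y' has length 0")
  if (anyNA(y)) stop("'y' contains missing values")
  if (any(y < 0)) stop("'y' must be nonnegative")
  if (any(abs(y - round(y)) > 1e-8))
    stop("'y' must be integer-valued event counts (row ",
         which(abs(y - round(y)) > 1e-8)[1L], ")")
  y <- as.numeric(round(y))
  n <- length(y)

  if (!is.null(offset) && !is.null(multiplier))
    stop("supply at most one of 'offset' and 'multiplier'")
  if (!is.null(multiplier)) {
    if (length(multiplier) != n) stop("'multiplier' length mismatch")
    if (any(!is.finite(multiplier)) || any(multiplier <= 0))
      stop("'multiplier' must be strictly positive (row ",
           which(!(is.finite(multiplier) & multiplier > 0))[1L], ")")
    z <- log(multiplier)
  } else if (!is.null(offset)) {
    if (length(offset) != n) stop("'offset' length mismatch")
    if (any(!is.finite(offset))) stop("'offset' must be finite")
    z <- as.numeric(offset)
  } else {
    z <- numeric(n)
  }

  if (is.null(x)) {
    X <- matrix(1, n, 1)
    cn <- "(Intercept)"
  } else {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
    if (nrow(x) != n) stop("'x' must have length(y) rows")
    if (anyNA(x) || any(!is.finite(x))) stop("'x' contains non-finite values")
    cn <- colnames(x)
    if (is.null(cn)) cn <- paste0("x", seq_len(ncol(x)))
    X <- cbind(1, x)
    cn <- c("(Intercept)", cn)
  }
  colnames(X) <- cn
  structure(list(y = y, X = X, z = z, n = n, k = ncol(X) - 1L,
                 col_names = cn),
            class = "pois_data")
}

#' @export
print.pois_data <- function(x, ...) {
  cat("Poisson count dataset: n =", x$n, ", k =", x$k,
      "covariate(s) + intercept\n")
  cat("  total events:", sum(x$y),
      if (any(x$z != 0)) " (with offset)" else "", "\n", sep = "")
  invisible(x)
}

# Full-column-rank check shared by the fitters.
check_full_rank <- function(X) {
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient; drop collinear covariates")
  invisible(TRUE)
}

#' Read a count dataset from a CSV file
#'
#' @param path CSV file with a header row.
#' @param outcome Name of the nonnegative integer count column.
#' @param covariates Character vector of covariate column names. Factor or
#'   character columns are expanded to treatment-contrast dummies with the
#'   alphabetically first level as reference; numeric columns are taken
#'   as-is (pass precomputed columns for custom codings such as ordinal
#'   contrasts). `NULL` uses every column except outcome/offset/multiplier.
#' @param multiplier,offset Optional column names holding a positive rate
#'   multiplier or a log-offset (at most one).
#' @return A [pois_data] object.
#' @export
read_dataset <- function(path, outcome, covariates = NULL,
                         multiplier = NULL, offset = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  need <- c(outcome, covariates, multiplier, offset)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(outcome, multiplier, offset))

  cols <- list()
  for (v in covariates) {
    col <- df[[v]]
    if (is.character(col) || is.factor(col)) {
      lev <- sort(unique(as.character(col)))
      for (l in lev[-1L])
        cols[[paste0(v, l)]] <- as.numeric(col == l)
    } else {
      cols[[v]] <- as.numeric(col)
    }
  }
  x <- if (length(cols)) do.call(cbind, cols) else NULL
  pois_data(y = df[[outcome]], x = x,
            offset = if (!is.null(offset)) df[[offset]],
            multiplier = if (!is.null(multiplier)) df[[multiplier]])
}

#' Write a coefficient table and run manifest
#'
#' Writes `<prefix>_coefficients.csv` (term, estimate, IRR, CI bounds,
#' method) and `<prefix>_manifest.json` (seed, package version, config).
#'
#' @param fit A `pois_fit` object.
#' @param prefix Output path prefix.
#' @param ci Optional interval object from [wald_ci()] or [profile_ci()].
#' @param seed Seed recorded in the manifest.
#' @param config Optional list recorded verbatim in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, prefix, ci = NULL, seed = NA_integer_,
                          config = list()) {
  est <- fit$coefficients
  tab <- data.frame(term = names(est), estimate = unname(est),
                    irr = exp(unname(est)),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    method = fit$method, stringsAsFactors = FALSE)
  if (!is.null(ci)) {
    # intervals are computed on the log-IRR scale; the table reports IRRs
    m <- match(rownames(ci), tab$term)
    tab$ci_lower[m] <- exp(ci[, 1L])
    tab$ci_upper[m] <- exp(ci[, 2L])
  }
  csv <- paste0(prefix, "_coefficients.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("poisfl")),
                   method = fit$method,
                   converged = fit$converged, separated = fit$separated,
                   config = config)
  js <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

#' Write bundled example datasets
#'
#' Creates four small CSV fixtures in `dir`: the Austrian COVID-19 testing
#' table (three occupation groups, 6 events among 1161 tests), a symmetric
#' two-group toy, a randomly generated dataset guaranteed to be separated,
#' and one guaranteed not to be (both verified with [detect_separation()]).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the random fixtures.
#' @return Named character vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(covid = file.path(dir, "covid_tests.csv"),
             toy = file.path(dir, "two_group_toy.csv"),
             separated = file.path(dir, "separated.csv"),
             nonseparated = file.path(dir, "nonseparated.csv"))
  utils::write.csv(data.frame(
    employment = c("Supermarket", "Nursing home", "Hospital"),
    positive = c(0L, 3L, 3L),
    tested = c(352L, 444L, 365L)), paths["covid"], row.names = FALSE)
  utils::write.csv(data.frame(group = c(0L, 1L), events = c(1L, 1L),
                              exposure = c(10, 10)),
                   paths["toy"], row.names = FALSE)
  set.seed(seed)
  # separated: binary covariate whose x=1 stratum has no events
  x1 <- stats::rbinom(40, 1, 0.3)
  y1 <- ifelse(x1 == 1, 0L, stats::rpois(40, 0.8))
  utils::write.csv(data.frame(y = y1, x = x1), paths["separated"],
                   row.names = FALSE)
  # non-separated: resample until every fitter-relevant stratum has events
  repeat {
    x2 <- stats::rbinom(40, 1, 0.5)
    y2 <- stats::rpois(40, exp(-0.5 + 0.4 * x2))
    d <- pois_data(y2, cbind(x = x2))
    if (!detect_separation(d)$separated) break
  }
  utils::write.csv(data.frame(y = y2, x = x2), paths["nonseparated"],
                   row.names = FALSE)
  paths
}
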