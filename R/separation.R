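# Dense tableau simplex for  max c'x  s.t.  A x <= b,  x >= 0,  b >= 0.
# Bland's rule (smallest-index entering/leaving), so termination is
# guaranteed despite the heavy degeneracy of the separation LP (b = 0 rows).
# Only small problems reach this code (ncol <= 2(k+1), nrow <= n + 2(k+1)).
simplex_max <- function(cvec, A, b, tol = 1e-9, max_pivots = 100000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, all(b >= -tol))
  b <- pmax(b, 0)
  Tab <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  zrow <- c(cvec, numeric(m))     # reduced costs of the current dictionary
  zval <- 0
  for (pivot in seq_len(max_pivots)) {
    ent <- which(zrow > tol)
    if (!length(ent)) {
      x <- numeric(n + m); x[basis] <- b
      return(list(status = 0L, value = zval, x = x[seq_len(n)]))
    }
    j <- ent[1L]                               # Bland: smallest index
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = 1L, value = Inf, x = NULL))
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    r <- cand[which.min(basis[cand])]          # Bland: smallest basis index
    piv <- Tab[r, j]
    Tab[r, ] <- Tab[r, ] / piv
    b[r] <- b[r] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(Tab[i, j]) > 0) {
        f <- Tab[i, j]
        Tab[i, ] <- Tab[i, ] - f * Tab[r, ]
        b[i] <- b[i] - f * b[r]
      }
    }
    f <- zrow[j]
    zrow <- zrow - f * Tab[r, ]
    zval <- zval + f * b[r]
    b[b < 0 & b > -tol] <- 0
    basis[r] <- j
  }
  stop("simplex did not terminate")
}

# Orthonormal basis of the null space of M (rows as constraints),
# via the spectral decomposition of M'M.
nullspace <- function(M, tol = 1e-9) {
  if (nrow(M) == 0L) return(diag(ncol(M)))
  e <- eigen(crossprod(M), symmetric = TRUE)
  null <- e$values < tol * max(e$values[1], 1)
  e$vectors[, null, drop = FALSE]
}

#' Detect separation (nonexistence of the Poisson ML estimate)
#'
#' The ML estimate fails to exist exactly when there is a nonzero direction
#' `gamma` with `x_i gamma = 0` for every row with events (`y_i > 0`) and
#' `x_i gamma <= 0` for every event-free row, strictly negative for at least
#' one of them. Geometrically: the event rows lie on a hyperplane and the
#' event-free rows lie on one side of it. The verdict depends only on the
#' event/no-event pattern and the design, never on offsets or on how large
#' the positive counts are.
#'
#' The search is a linear program: `gamma` is restricted to the null space of
#' the event rows, and `sum_i(-x_i gamma)` over event-free rows is maximized
#' subject to `x_i gamma <= 0` and box bounds (the condition is
#' scale-invariant, so bounding is harmless). A strictly positive optimum
#' certifies separation.
#'
#' @param data A [pois_data] object.
#' @param tol Strictness tolerance for the LP optimum.
#' @return A `separation_report` list: `separated` (logical), `gamma`
#'   (certificate direction, `NULL` when not separated), `strict_rows`
#'   (indices of event-free rows with `x_i gamma < 0`).
#' @examples
#' covid <- pois_data(c(0, 3, 3), cbind(nursing = c(0, 1, 0),
#'                                      hospital = c(0, 0, 1)),
#'                    multiplier = c(352, 444, 365))
#' detect_separation(covid)
#' @export
detect_separation <- function(data, tol = 1e-7) {
  stopifnot(inherits(data, "pois_data"))
  X <- data$X
  pos <- data$y > 0
  N <- nullspace(X[pos, , drop = FALSE])
  report <- function(sep, gamma = NULL) {
    strict <- integer(0)
    if (sep) {
      gamma <- gamma / max(abs(gamma))
      xg <- drop(X %*% gamma)
      strict <- which(!pos & xg < -1e-8)
    }
    structure(list(separated = sep, gamma = gamma, strict_rows = strict),
              class = "separation_report")
  }
  if (ncol(N) == 0L || all(pos)) return(report(FALSE))
  A <- X[!pos, , drop = FALSE] %*% N       # constraints A c <= 0
  if (nrow(A) == 0L) return(report(FALSE))
  p <- ncol(A)
  # c = u - w with u, w in [0, 1]: all right-hand sides nonnegative
  f <- -colSums(A)
  Alp <- rbind(cbind(A, -A), diag(2 * p))
  blp <- c(numeric(nrow(A)), rep(1, 2 * p))
  sol <- simplex_max(c(f, -f), Alp, blp)
  if (sol$value <= tol) return(report(FALSE))
  cdir <- sol$x[seq_len(p)] - sol$x[p + seq_len(p)]
  report(TRUE, drop(N %*% cdir))
}

#' @export
print.separation_report <- function(x, ...) {
  if (x$separated) {
    cat("Separation detected: ML estimate does not exist.\n")
    cat("certificate direction gamma*:",
        paste(format(x$gamma, digits = 4), collapse = " "), "\n")
    cat("strictly separated event-free rows:",
        paste(x$strict_rows, collapse = " "), "\n")
  } else {
    cat("No separation detected: ML estimate exists.\n")
  }
  invisible(x)
}
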