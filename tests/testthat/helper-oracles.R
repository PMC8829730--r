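# independent oracles kept deliberately naive

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

num_hess <- function(f, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- numeric(p); ei[i] <- eps
    ej <- numeric(p); ej[j] <- eps
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                f(x - ei + ej) + f(x - ei - ej)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}

# explicit dense hat-matrix product
hat_oracle <- function(data, beta) {
  mu <- exp(drop(data$X %*% beta) + data$z)
  W2 <- diag(sqrt(mu))
  H <- W2 %*% data$X %*% solve(t(data$X) %*% diag(mu) %*% data$X) %*%
    t(data$X) %*% W2
  diag(H)
}

# brute-force conditional weights: loop over the full product space of
# outcome vectors with the observed total
brute_cond <- function(data, j) {
  tot <- sum(data$y)
  X <- round(data$X)
  p <- ncol(X)
  nuis <- setdiff(seq_len(p), j)
  t_nuis <- drop(crossprod(X[, nuis, drop = FALSE], data$y))
  grid <- as.matrix(expand.grid(rep(list(0:tot), data$n)))
  keep <- rowSums(grid) == tot
  grid <- grid[keep, , drop = FALSE]
  E <- exp(data$z)
  res <- list()
  for (r in seq_len(nrow(grid))) {
    yy <- grid[r, ]
    if (any(abs(drop(crossprod(X[, nuis, drop = FALSE], yy)) - t_nuis) >
            1e-9)) next
    t <- sum(X[, j] * yy)
    w <- prod(E^yy / factorial(yy))
    key <- as.character(t)
    res[[key]] <- (res[[key]] %||% 0) + w
  }
  tv <- as.numeric(names(res))
  o <- order(tv)
  list(support = tv[o], w = unlist(res, use.names = FALSE)[o])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive separation oracle: enumerate the vertices of the polytope
# {A c <= 0, -1 <= c <= 1} in the event-row null space and take the best
# objective value sum(-A c); separated iff positive
sep_oracle <- function(data, tol = 1e-7) {
  X <- data$X
  pos <- data$y > 0
  M <- X[pos, , drop = FALSE]
  if (nrow(M) == 0L) {
    N <- diag(ncol(X))
  } else {
    e <- eigen(crossprod(M), symmetric = TRUE)
    N <- e$vectors[, e$values < 1e-9 * max(e$values[1], 1), drop = FALSE]
  }
  if (ncol(N) == 0L || all(pos)) return(FALSE)
  A <- X[!pos, , drop = FALSE] %*% N
  p <- ncol(A)
  G <- rbind(A, diag(p), -diag(p))
  h <- c(numeric(nrow(A)), rep(1, 2 * p))
  best <- 0
  idx <- utils::combn(nrow(G), p)
  for (c_ in seq_len(ncol(idx))) {
    S <- G[idx[, c_], , drop = FALSE]
    if (abs(det(S)) < 1e-10) next
    v <- solve(S, h[idx[, c_]])
    if (all(G %*% v <= h + 1e-9)) best <- max(best, sum(-A %*% v))
  }
  best > tol
}
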