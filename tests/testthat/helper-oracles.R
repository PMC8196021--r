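# Independent slow oracles used to cross-check the fast implementations.

# ISTA (proximal gradient) LASSO solver: deliberately different algorithm
# from the coordinate-descent path it checks.
lasso_pg_oracle <- function(s, D, lambda, iters = 50000L, tol = 1e-12) {
  L <- max(eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values)
  a <- numeric(ncol(D))
  step <- 1 / L
  for (i in seq_len(iters)) {
    g <- crossprod(D, D %*% a - s)
    a1 <- a - step * g
    a1 <- sign(a1) * pmax(abs(a1) - lambda * step, 0)
    if (max(abs(a1 - a)) < tol) { a <- a1; break }
    a <- a1
  }
  a
}

lasso_objective <- function(s, D, a, lambda) {
  0.5 * sum((s - D %*% a)^2) + lambda * sum(abs(a))
}

# Textbook Welch statistic with Welch-Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Textbook Pearson correlation written out longhand.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
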