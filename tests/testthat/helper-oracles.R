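# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately written as direct, unoptimized computations.

# symmetric (edge-repeating) reflection of a scalar index into 1..n
refl_scalar <- function(i, n) {
  if (n == 1L) return(1L)
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# direct 2-D convolution with an explicitly sampled truncated Gaussian
# kernel (no separability), reflective boundaries
oracle_gaussian_blur <- function(x, sigma) {
  r <- ceiling(4 * sigma)
  d <- seq(-r, r)
  k2 <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k2 <- k2 / sum(k2)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_along(d)) for (b in seq_along(d)) {
      acc <- acc + k2[a, b] *
        x[refl_scalar(i + d[a], nr), refl_scalar(j + d[b], nc)]
    }
    out[i, j] <- acc
  }
  out
}

# per-pixel loop over the explicit circular window: Phansalkar threshold map
oracle_phansalkar <- function(x, radius, k = 0.25, rNorm = 0.5,
                              p = 2, q = 10) {
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- mapply(function(a, b)
      x[refl_scalar(i + a, nr), refl_scalar(j + b, nc)],
      offs$a, offs$b)
    mu <- mean(vals)
    sig <- sqrt(mean((vals - mu)^2))  # population sd
    out[i, j] <- mu * (1 + p * exp(-q * mu) + k * (sig / rNorm - 1))
  }
  out
}

# recursive flood fill (8-neighbourhood) component labelling
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (a in -1:1) for (b in -1:1) {
          qi <- p[1] + a; qj <- p[2] + b
          if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
              mask[qi, qj] && lab[qi, qj] == 0L) {
            lab[qi, qj] <- cur
            queue[[length(queue) + 1L]] <- c(qi, qj)
          }
        }
      }
    }
  }
  lab
}

# two-sided Fisher p by explicit enumeration of the hypergeometric support
# using binomial coefficients (minimum-likelihood rule)
oracle_fisher <- function(a, b, c, d) {
  k <- a + b; K <- a + c; N <- a + b + c + d
  supp <- max(0, k - (N - K)):min(k, K)
  pr <- choose(K, supp) * choose(N - K, k - supp) / choose(N, k)
  pObs <- choose(K, a) * choose(N - K, k - a) / choose(N, k)
  min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration of all rank splits
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  ws <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  pLo <- mean(ws <= wObs)
  pHi <- mean(ws >= wObs)
  min(1, 2 * min(pLo, pHi))
}
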