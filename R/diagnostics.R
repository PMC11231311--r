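# MCMC diagnostics: split potential-scale-reduction (R-hat) and a basic
# autocorrelation-based effective sample size. `draws` is iterations x chains.

split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x)
  n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  # average per-chain autocorrelations, truncated at first negative pair sum
  rho <- sapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j] - mean(draws[, j])
    v <- sum(x^2)
    if (v < .Machine$double.eps) return(rep(0, min(n - 2, 100)))
    sapply(seq_len(min(n - 2, 100)), function(l)
      sum(x[1:(n - l)] * x[(l + 1):n]) / v)
  })
  rho <- rowMeans(as.matrix(rho))
  s <- 0
  l <- 1
  while (l + 1 <= length(rho)) {
    pair <- rho[l] + rho[l + 1]
    if (pair < 0) break
    s <- s + pair
    l <- l + 2
  }
  max(1, (n * ncol(draws)) / (1 + 2 * s))
}
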