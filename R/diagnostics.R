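#' Split R-hat of a single parameter
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, and the usual between/within variance ratio is formed over the
#' resulting sequences. Values near 1 indicate that the chains agree;
#' values well above 1.01 flag non-convergence. Returns `NA` for constant
#' draws.
#'
#' @param x draws of one scalar parameter: an iterations x chains matrix
#'   (a vector is treated as one chain).
#' @return scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2L
  sp <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch)
    cbind(x[seq_len(half), ch], x[(n - half + 1):n, ch])))
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of a single parameter
#'
#' Multi-chain effective sample size from the chain-averaged autocorrelation
#' function, truncated with Geyer's initial positive-pair sequence. For
#' independent draws the estimate is close to the total draw count.
#'
#' @inheritParams split_rhat
#' @return scalar effective sample size (`NA` for constant draws).
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- if (m > 1) n * stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  lag_max <- min(n - 2L, 2000L)
  acov <- sapply(seq_len(m), function(ch)
    stats::acf(x[, ch], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  acov <- matrix(acov, ncol = m)
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer: sum autocorrelations over consecutive pairs while the pair sums
  # stay positive (and enforce monotone non-increase)
  tau <- 1
  t <- 1
  prev_pair <- Inf
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(m * n / tau, 1e-8)
}
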