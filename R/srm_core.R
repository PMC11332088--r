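#' Hyperpriors for the multiplex social relations model
#'
#' Bundles the prior settings shared by fitting and simulation:
#' Exponential(`scale_rate`) priors on all random-effect standard deviations,
#' LKJ-Cholesky(`lkj_eta`) priors on the two correlation Cholesky factors,
#' a Normal(0, `eta_sd`) prior on intercepts and covariate coefficients, and
#' the scale `epsilon` of the soft block-symmetry penalty on the dyadic
#' correlation matrix.
#'
#' @param scale_rate rate of the exponential prior on standard deviations
#'   (default 2.5, prior mean 0.4).
#' @param lkj_eta LKJ concentration for both correlation factors (default
#'   2.5; values > 1 shrink towards the identity).
#' @param epsilon symmetry-penalty scale (default 0.1). As `epsilon -> 0` the
#'   posterior dyadic correlation matrix is forced onto the exchangeable
#'   block structure `[[C, B], [B, C]]`.
#' @param eta_sd standard deviation of the normal prior on intercepts and
#'   covariate coefficients (default 5, weakly informative on the log-odds
#'   scale; the model is identified through its priors, so a flat intercept
#'   prior is avoided).
#' @return a list of class `srm_hyper`.
#' @export
hyper_priors <- function(scale_rate = 2.5, lkj_eta = 2.5, epsilon = 0.1,
                         eta_sd = 5) {
  stopifnot(scale_rate > 0, lkj_eta > 0, epsilon > 0, eta_sd > 0)
  structure(list(scale_rate = scale_rate, lkj_eta = lkj_eta,
                 epsilon = epsilon, eta_sd = eta_sd),
            class = "srm_hyper")
}

#' Fixed effects of the multiplex SRM
#'
#' Per-layer intercepts on the log-odds scale, plus optional covariate
#' coefficients. The covariate hook follows the standard SRM form: for
#' sender covariate `W`, receiver covariate `W` and dyadic covariate `R`,
#' the linear predictor gains `lambda[1,m] W[j] + lambda[2,m] W[k] +
#' lambda[3,m] R[j,k]`, generalized to any number of sender / receiver /
#' dyadic covariates.
#'
#' @param eta numeric vector of per-layer intercepts (length M, finite).
#' @param lambda optional list with matrices `sender` (Ps x M), `receiver`
#'   (Pr x M), `dyadic` (Pd x M) of coefficients.
#' @param covariates optional list with `sender` (J x Ps matrix), `receiver`
#'   (J x Pr), `dyadic` (J x J x Pd array) matching `lambda`.
#' @return list of class `srm_fixed`.
#' @export
fixed_effects <- function(eta, lambda = NULL, covariates = NULL) {
  stopifnot(is.numeric(eta), all(is.finite(eta)), length(eta) >= 1)
  if (is.null(lambda) != is.null(covariates))
    stop("'lambda' and 'covariates' must be supplied together")
  if (!is.null(lambda)) {
    M <- length(eta)
    for (kind in names(lambda)) {
      if (!kind %in% c("sender", "receiver", "dyadic"))
        stop("unknown covariate kind: ", kind)
      if (ncol(lambda[[kind]]) != M)
        stop("lambda$", kind, " must have M = ", M, " columns")
    }
  }
  structure(list(eta = as.numeric(eta), lambda = lambda,
                 covariates = covariates), class = "srm_fixed")
}

#' Generalized (sender/receiver) random effects, non-centered
#'
#' Holds the raw per-person effects and the parameters of their joint
#' distribution. For person j the transformed 2M-vector
#' `(alpha[j,1..M], beta[j,1..M]) = sigma * (L %*% raw[j, ])` is multivariate
#' normal with covariance `diag(sigma) L L' diag(sigma)` when the raws are
#' unit normal.
#'
#' @param raw J x 2M matrix of raw effects (rows = people; first M columns
#'   feed sender effects, last M receiver effects).
#' @param sigma positive standard deviations, length 2M.
#' @param L lower-triangular Cholesky factor of a 2M x 2M correlation matrix.
#' @return list of class `srm_gen`.
#' @export
generalized_effects <- function(raw, sigma, L) {
  raw <- as.matrix(raw)
  K <- length(sigma)
  if (ncol(raw) != K) stop("raw must have 2M = ", K, " columns")
  check_chol_corr(L, K)
  stopifnot(all(sigma > 0))
  structure(list(raw = raw, sigma = as.numeric(sigma), L = L),
            class = "srm_gen")
}

#' Dyadic random effects, non-centered, with tied scales
#'
#' For dyad {j,k} (j before k in roster order) the transformed 2M-vector
#' `(delta[j,k,1..M], delta[k,j,1..M]) = varsigma_full * (Gamma %*% raw[d, ])`.
#' Because the two directions of a dyad are exchangeable, the scale vector is
#' tied: `varsigma_full = c(varsigma, varsigma)` uses only M free values, so
#' the marginal scale of `delta[j,k,m]` equals that of `delta[k,j,m]` exactly.
#'
#' @param raw D x 2M matrix of raw effects (rows = dyads in [dyad_index()]
#'   order; first M columns are the j->k direction, last M the k->j).
#' @param varsigma positive free scales, length M.
#' @param Gamma lower-triangular Cholesky factor of a 2M x 2M correlation
#'   matrix.
#' @return list of class `srm_dyad`.
#' @export
dyadic_effects <- function(raw, varsigma, Gamma) {
  raw <- as.matrix(raw)
  M <- length(varsigma)
  K <- 2L * M
  if (ncol(raw) != K) stop("raw must have 2M = ", K, " columns")
  check_chol_corr(Gamma, K)
  stopifnot(all(varsigma > 0))
  structure(list(raw = raw, varsigma = as.numeric(varsigma), Gamma = Gamma),
            class = "srm_dyad")
}

#' Full parameter state of the multiplex SRM
#'
#' @param fixed a [fixed_effects()] object.
#' @param gen a [generalized_effects()] object.
#' @param dyad a [dyadic_effects()] object.
#' @return list of class `srm_state`.
#' @export
parameter_state <- function(fixed, gen, dyad) {
  stopifnot(inherits(fixed, "srm_fixed"), inherits(gen, "srm_gen"),
            inherits(dyad, "srm_dyad"))
  M <- length(fixed$eta)
  if (length(gen$sigma) != 2L * M || length(dyad$varsigma) != M)
    stop("component dimensions disagree on the number of layers")
  structure(list(fixed = fixed, gen = gen, dyad = dyad), class = "srm_state")
}

check_chol_corr <- function(L, K, tol = 1e-8) {
  L <- as.matrix(L)
  if (!all(dim(L) == c(K, K))) stop("Cholesky factor must be ", K, " x ", K)
  if (any(abs(L[upper.tri(L)]) > tol)) stop("Cholesky factor must be lower triangular")
  if (any(diag(L) <= 0)) stop("Cholesky factor must have positive diagonal")
  if (any(abs(rowSums(L^2) - 1) > 1e-6))
    stop("rows of a correlation Cholesky factor must have unit norm")
  invisible(L)
}

#' Transform raw generalized effects to sender/receiver effects
#'
#' Applies the non-centered scale-and-rotate map per person. With
#' unit-normal raws the result is multivariate normal with covariance
#' `diag(sigma) L L' diag(sigma)`.
#'
#' @param gen a [generalized_effects()] object.
#' @return list with `alpha` (J x M sender effects) and `beta` (J x M
#'   receiver effects).
#' @export
transform_generalized <- function(gen) {
  stopifnot(inherits(gen, "srm_gen"))
  K <- length(gen$sigma); M <- K %/% 2L
  V <- gen$raw %*% t(gen$L)
  V <- sweep(V, 2L, gen$sigma, "*")
  list(alpha = V[, seq_len(M), drop = FALSE],
       beta = V[, M + seq_len(M), drop = FALSE])
}

#' Transform raw dyadic effects to directed dyad effects
#'
#' @param dyad a [dyadic_effects()] object.
#' @return list with `delta_12` (D x M, effect of the j->k direction, j the
#'   lower roster index) and `delta_21` (D x M, k->j direction).
#' @export
transform_dyadic <- function(dyad) {
  stopifnot(inherits(dyad, "srm_dyad"))
  M <- length(dyad$varsigma); K <- 2L * M
  vs_full <- c(dyad$varsigma, dyad$varsigma)
  W <- dyad$raw %*% t(dyad$Gamma)
  W <- sweep(W, 2L, vs_full, "*")
  list(delta_12 = W[, seq_len(M), drop = FALSE],
       delta_21 = W[, M + seq_len(M), drop = FALSE])
}

# J x J x M array of linear predictors for a full roster
theta_array <- function(state, J) {
  M <- length(state$fixed$eta)
  tg <- transform_generalized(state$gen)
  td <- transform_dyadic(state$dyad)
  dy <- dyad_index(J)
  th <- array(0, dim = c(J, J, M))
  for (m in seq_len(M)) {
    thm <- outer(tg$alpha[, m], tg$beta[, m], "+") + state$fixed$eta[m]
    thm[cbind(dy$i1, dy$i2)] <- thm[cbind(dy$i1, dy$i2)] + td$delta_12[, m]
    thm[cbind(dy$i2, dy$i1)] <- thm[cbind(dy$i2, dy$i1)] + td$delta_21[, m]
    cv <- state$fixed$covariates
    la <- state$fixed$lambda
    if (!is.null(la)) {
      if (!is.null(la$sender))
        thm <- thm + matrix(cv$sender %*% la$sender[, m], J, J)
      if (!is.null(la$receiver))
        thm <- thm + matrix(cv$receiver %*% la$receiver[, m], J, J,
                            byrow = TRUE)
      if (!is.null(la$dyadic))
        for (p in seq_len(nrow(la$dyadic)))
          thm <- thm + la$dyadic[p, m] * cv$dyadic[, , p]
    }
    diag(thm) <- NA_real_
    th[, , m] <- thm
  }
  th
}

#' Linear predictor of a directed tie
#'
#' The log-odds of a tie from sender `j` to receiver `k` in layer `m`:
#' intercept + sender effect + receiver effect + dyadic effect + covariate
#' terms. Vectorized over `j`, `k`, `m` (recycled to a common length).
#'
#' @param state a [parameter_state()].
#' @param j,k sender and receiver indices (1-based roster positions), `j != k`.
#' @param m layer index.
#' @return numeric vector of log-odds.
#' @export
linear_predictor <- function(state, j, k, m) {
  stopifnot(inherits(state, "srm_state"))
  n <- max(length(j), length(k), length(m))
  j <- rep_len(j, n); k <- rep_len(k, n); m <- rep_len(m, n)
  if (any(j == k)) stop("self-ties (j == k) have no linear predictor")
  J <- nrow(state$gen$raw)
  th <- theta_array(state, J)
  th[cbind(j, k, m)]
}

#' Bernoulli log-likelihood of a multiplex network
#'
#' Sum over observed cells of the Bernoulli log-mass at
#' `logistic(theta[j,k,m])`; unobserved cells (diagonal, non-ego senders)
#' contribute zero. Computed via the numerically stable log-sigmoid.
#'
#' @param net a `multiplex_network`.
#' @param state a [parameter_state()] whose dimensions match `net`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(net, state) {
  stopifnot(inherits(net, "multiplex_network"), inherits(state, "srm_state"))
  J <- nrow(net$roster); M <- nrow(net$layers)
  if (nrow(state$gen$raw) != J || length(state$fixed$eta) != M)
    stop("state dimensions do not match the network")
  th <- theta_array(state, J)
  obs <- !is.na(net$G)
  y <- net$G[obs]; t_obs <- th[obs]
  sum(ifelse(y == 1L, stats::plogis(t_obs, log.p = TRUE),
             stats::plogis(-t_obs, log.p = TRUE)))
}

#' Correlation matrix from its Cholesky factor
#'
#' @param Gamma lower-triangular Cholesky factor of a correlation matrix.
#' @return the correlation matrix `Gamma %*% t(Gamma)` (unit diagonal,
#'   symmetric positive semidefinite).
#' @export
corr_from_cholesky <- function(Gamma) {
  K <- nrow(as.matrix(Gamma))
  check_chol_corr(Gamma, K)
  tcrossprod(Gamma)
}

#' Soft block-symmetry penalty on the dyadic correlation matrix
#'
#' Exchangeability of the two directions of a dyad requires the 2M x 2M
#' dyadic correlation matrix to have the block form `[[C, B], [B, C]]` with
#' `B = B'`. No constructive parameterization guarantees this and positive
#' definiteness simultaneously, so the constraint is imposed softly: for
#' every layer pair m < n, the discrepancies
#' `|rho[m+M, n+M] - rho[m, n]|` (C blocks) and
#' `|rho[m, n+M] - rho[n, m+M]|` (B block) receive Normal(0, epsilon)
#' log-density penalties. The penalty is maximal exactly on the block
#' structure and strictly decreases in each discrepancy; for M = 1 it is 0.
#'
#' @param rho 2M x 2M correlation matrix.
#' @param epsilon penalty scale (> 0), default 0.1.
#' @return scalar log-density contribution.
#' @export
symmetry_penalty <- function(rho, epsilon = 0.1) {
  rho <- as.matrix(rho)
  K <- nrow(rho)
  if (ncol(rho) != K || K %% 2L != 0L) stop("'rho' must be 2M x 2M")
  stopifnot(epsilon > 0)
  M <- K %/% 2L
  if (M < 2L) return(0)
  lp <- 0
  for (m in seq_len(M - 1L)) {
    for (n in (m + 1L):M) {
      dC <- abs(rho[m + M, n + M] - rho[m, n])
      dB <- abs(rho[m, n + M] - rho[n, m + M])
      lp <- lp + stats::dnorm(dC, 0, epsilon, log = TRUE) +
        stats::dnorm(dB, 0, epsilon, log = TRUE)
    }
  }
  lp
}

# LKJ-Cholesky log-density, unnormalized (the concentration-dependent
# normalizer cancels in MCMC and in all comparisons made here)
lkj_chol_lpdf <- function(L, eta) {
  K <- nrow(L)
  if (K < 2L) return(0)
  i <- 2:K
  sum((K - i + 2 * eta - 2) * log(diag(L)[i]))
}

#' Joint log-prior of the multiplex SRM
#'
#' Unit-normal log-densities on all raw effects; Exponential(`scale_rate`)
#' on the 2M generalized scales and the M free dyadic scales;
#' LKJ-Cholesky(`lkj_eta`) on both correlation factors (unnormalized);
#' Normal(0, `eta_sd`) on intercepts and covariate coefficients; plus the
#' block-symmetry penalty on the dyadic correlation matrix.
#'
#' @param state a [parameter_state()].
#' @param hyper a [hyper_priors()] object.
#' @return scalar log-prior.
#' @export
log_prior <- function(state, hyper = hyper_priors()) {
  stopifnot(inherits(state, "srm_state"), inherits(hyper, "srm_hyper"))
  lp <- sum(stats::dnorm(state$gen$raw, log = TRUE)) +
    sum(stats::dnorm(state$dyad$raw, log = TRUE)) +
    sum(stats::dexp(state$gen$sigma, hyper$scale_rate, log = TRUE)) +
    sum(stats::dexp(state$dyad$varsigma, hyper$scale_rate, log = TRUE)) +
    lkj_chol_lpdf(state$gen$L, hyper$lkj_eta) +
    lkj_chol_lpdf(state$dyad$Gamma, hyper$lkj_eta) +
    sum(stats::dnorm(state$fixed$eta, 0, hyper$eta_sd, log = TRUE)) +
    symmetry_penalty(corr_from_cholesky(state$dyad$Gamma), hyper$epsilon)
  if (!is.null(state$fixed$lambda))
    lp <- lp + sum(stats::dnorm(unlist(state$fixed$lambda), 0, hyper$eta_sd,
                                log = TRUE))
  lp
}

#' Joint log-posterior (unnormalized) of the multiplex SRM
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return `log_likelihood(net, state) + log_prior(state, hyper)`.
#' @export
log_posterior <- function(net, state, hyper = hyper_priors()) {
  log_likelihood(net, state) + log_prior(state, hyper)
}
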