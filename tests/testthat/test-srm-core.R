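test_that("generalized transform is the advertised scale-and-rotate map", {
  M <- 2; K <- 4; J <- 6
  set.seed(21)
  raw <- matrix(rnorm(J * K), J, K)
  # identity parameters: transform is the identity on raws
  id <- generalized_effects(raw, rep(1, K), diag(K))
  tg <- transform_generalized(id)
  expect_equal(cbind(tg$alpha, tg$beta), raw, ignore_attr = TRUE)
  # zero raws map to zero effects
  z <- transform_generalized(generalized_effects(matrix(0, J, K),
                                                 runif(K, 0.5, 2), diag(K)))
  expect_true(all(z$alpha == 0) && all(z$beta == 0))

  # Monte-Carlo: empirical covariance of transformed draws matches
  # diag(sigma) L L' diag(sigma)
  sigma <- c(0.5, 1.5, 1, 2)
  R <- matrix(0.4, K, K); diag(R) <- 1; R[1, 3] <- R[3, 1] <- -0.3
  L <- t(chol(R))
  big <- generalized_effects(matrix(rnorm(1e5 * K), 1e5, K), sigma, L)
  tb <- transform_generalized(big)
  emp <- stats::cov(cbind(tb$alpha, tb$beta))
  expect_lt(max(abs(emp - diag(sigma) %*% R %*% diag(sigma))), 0.05)
})

test_that("dyadic transform ties the directional scales exactly", {
  M <- 2; K <- 4; D <- 1e5
  set.seed(22)
  vs <- c(0.7, 1.3)
  R <- diag(K); R[1, 3] <- R[3, 1] <- 0.6
  dy <- dyadic_effects(matrix(rnorm(D * K), D, K), vs, t(chol(R)))
  td <- transform_dyadic(dy)
  # marginal scale of the two directions equal within MC error, exactly tied
  # in expectation (rows of the Cholesky factor have unit norm)
  expect_lt(max(abs(apply(td$delta_12, 2, sd) - vs)), 0.02)
  expect_lt(max(abs(apply(td$delta_21, 2, sd) - vs)), 0.02)
  # identity map and zero raws
  id <- dyadic_effects(matrix(rnorm(8), 2, K), c(1, 1), diag(K))
  tid <- transform_dyadic(id)
  expect_equal(cbind(tid$delta_12, tid$delta_21), id$raw, ignore_attr = TRUE)
  zz <- transform_dyadic(dyadic_effects(matrix(0, 3, K), vs, t(chol(R))))
  expect_true(all(zz$delta_12 == 0) && all(zz$delta_21 == 0))
})

test_that("linear predictor assembles intercept + effects + covariates", {
  J <- 5; M <- 2; K <- 4; D <- 10
  # all-zero state: theta = 0 everywhere
  zero <- parameter_state(
    fixed_effects(c(0, 0)),
    generalized_effects(matrix(0, J, K), rep(1, K), diag(K)),
    dyadic_effects(matrix(0, D, K), rep(1, M), diag(K)))
  expect_equal(linear_predictor(zero, 1, 2, 1), 0)
  expect_error(linear_predictor(zero, 2, 2, 1), "self-ties")
  # intercept only
  ic <- zero; ic$fixed$eta <- c(-2, 1)
  expect_equal(linear_predictor(ic, 1, 2, 1), -2)
  expect_equal(linear_predictor(ic, 4, 3, 2), 1)

  # random state matches naive term-by-term summation
  set.seed(23)
  st <- random_state(J, M)
  tg <- transform_generalized(st$gen)
  td <- transform_dyadic(st$dyad)
  dy <- dyad_index(J)
  for (i in 1:20) {
    j <- sample(J, 1); k <- sample(setdiff(seq_len(J), j), 1)
    m <- sample(M, 1)
    d <- dy$of[j, k]
    delta <- if (dy$i1[d] == j) td$delta_12[d, m] else td$delta_21[d, m]
    expect_equal(linear_predictor(st, j, k, m),
                 st$fixed$eta[m] + tg$alpha[j, m] + tg$beta[k, m] + delta)
  }

  # covariate hook: sender W, receiver W, dyadic R
  W <- rnorm(J); Rd <- matrix(rnorm(J * J), J, J)
  lam <- list(sender = matrix(c(0.5, -1), 1), receiver = matrix(c(2, 0), 1),
              dyadic = matrix(c(-0.7, 0.3), 1))
  cov <- list(sender = cbind(W), receiver = cbind(W),
              dyadic = array(Rd, c(J, J, 1)))
  stc <- parameter_state(fixed_effects(c(0, 0), lam, cov), st$gen, st$dyad)
  base <- linear_predictor(st, 2, 4, 1) - st$fixed$eta[1]
  expect_equal(linear_predictor(stc, 2, 4, 1),
               base + 0.5 * W[2] + 2 * W[4] - 0.7 * Rd[2, 4])
})

test_that("log-likelihood sums observed cells only, stably", {
  # single observed cell at theta = 0: log(1/2)
  ros <- data.frame(id = c("a", "b"), is_ego = c(TRUE, FALSE))
  net <- multiplex_network(ros, "L")
  net$G["a", "b", 1] <- 1L
  zero <- parameter_state(
    fixed_effects(0),
    generalized_effects(matrix(0, 2, 2), c(1, 1), diag(2)),
    dyadic_effects(matrix(0, 1, 2), 1, diag(2)))
  expect_equal(log_likelihood(net, zero), log(0.5))
  # all-zero network: log-lik -> 0 as eta -> -Inf
  net$G["a", "b", 1] <- 0L
  low <- zero; low$fixed$eta <- -40
  expect_equal(log_likelihood(net, low), 0, tolerance = 1e-12)
  expect_true(is.finite(log_likelihood(net, low)))

  # random small network/state matches a cell-by-cell oracle
  set.seed(24)
  sim <- simulate_multiplex(simulation_config(J = 7, ego_fraction = 0.7),
                            seed = 3)
  st <- random_state(7, 3)
  ll <- log_likelihood(sim$net, st)
  oracle <- 0
  for (j in 1:7) for (k in 1:7) for (m in 1:3) {
    g <- sim$net$G[j, k, m]
    if (is.na(g)) next
    p <- stats::plogis(linear_predictor(st, j, k, m))
    oracle <- oracle + dbinom(g, 1, p, log = TRUE)
  }
  expect_equal(ll, oracle)

  # masked cells are ignored: perturbing unobserved entries changes nothing
  # exactly the observed cells contribute: at theta = 0 every observed cell
  # adds log(1/2) and masked cells (diagonal, non-ego senders) add nothing
  flat <- parameter_state(
    fixed_effects(rep(0, 3)),
    generalized_effects(matrix(0, 7, 6), rep(1, 6), diag(6)),
    dyadic_effects(matrix(0, 21, 6), rep(1, 3), diag(6)))
  expect_equal(log_likelihood(sim$net, flat),
               observed_cells(sim$net) * log(0.5))
})

test_that("corr_from_cholesky returns valid correlation matrices", {
  expect_equal(corr_from_cholesky(diag(3)), diag(3))
  # 2 x 2 factor with known angle
  r <- 0.6
  G2 <- rbind(c(1, 0), c(r, sqrt(1 - r^2)))
  expect_equal(corr_from_cholesky(G2)[1, 2], r)
  set.seed(25)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    X <- matrix(rnorm(K * K), K)
    G <- t(chol(stats::cov2cor(crossprod(X) + diag(K))))
    rho <- corr_from_cholesky(G)
    expect_equal(diag(rho), rep(1, K))
    expect_equal(rho, t(rho))
    expect_gt(min(eigen(rho, symmetric = TRUE)$values), -1e-8)
  }
  expect_error(corr_from_cholesky(matrix(c(1, 0.5, 0, 1), 2, byrow = TRUE)),
               "lower triangular")
  expect_error(corr_from_cholesky(matrix(c(1, 0, 0.5, 1), 2, byrow = TRUE)),
               "unit norm")
})

test_that("symmetry penalty is maximal on the block structure", {
  eps <- 0.1
  # M = 1: empty index set
  expect_equal(symmetry_penalty(diag(2), eps), 0)
  # exactly block-symmetric rho attains M(M-1) x NormalLogPdf(0 | 0, eps)
  C <- matrix(c(1, 0.3, 0.3, 1), 2); B <- diag(c(0.5, 0.2))
  rho <- assemble_block_rho(C, B)
  M <- 2
  expect_equal(symmetry_penalty(rho, eps),
               M * (M - 1) * dnorm(0, 0, eps, log = TRUE))
  # random rho matches a term-by-term oracle, and deviations reduce it
  set.seed(26)
  for (i in 1:5) {
    K <- 6; M <- 3
    X <- matrix(rnorm(K * K), K)
    r <- stats::cov2cor(crossprod(X) + diag(K))
    oracle <- 0
    for (m in 1:(M - 1)) for (n in (m + 1):M) {
      oracle <- oracle +
        dnorm(abs(r[m + M, n + M] - r[m, n]), 0, eps, log = TRUE) +
        dnorm(abs(r[m, n + M] - r[n, m + M]), 0, eps, log = TRUE)
    }
    expect_equal(symmetry_penalty(r, eps), oracle)
    expect_lte(symmetry_penalty(r, eps),
               3 * 2 * dnorm(0, 0, eps, log = TRUE) + 1e-12)
  }
  # strictly decreasing in a single discrepancy
  rho2 <- rho
  rho2[1, 2] <- rho2[2, 1] <- rho2[1, 2] + 0.05
  expect_lt(symmetry_penalty(rho2, eps), symmetry_penalty(rho, eps))
})

test_that("log-prior assembles its closed-form components", {
  J <- 4; M <- 2; K <- 4; D <- 6
  hyper <- hyper_priors()
  st <- parameter_state(
    fixed_effects(c(0, 0)),
    generalized_effects(matrix(0, J, K), rep(1, K), diag(K)),
    dyadic_effects(matrix(0, D, K), rep(1, M), diag(K)))
  # assembled independently, term by term
  expected <- (J * K + D * K) * dnorm(0, log = TRUE) +
    (K + M) * dexp(1, hyper$scale_rate, log = TRUE) +
    M * dnorm(0, 0, hyper$eta_sd, log = TRUE) +
    0 + # LKJ terms vanish at the identity (unnormalized)
    M * (M - 1) * dnorm(0, 0, hyper$epsilon, log = TRUE)
  expect_equal(log_prior(st, hyper), expected)

  # doubling one raw value lowers the raw-prior term quadratically
  st2 <- st
  st2$gen$raw[1, 1] <- 2
  st1 <- st
  st1$gen$raw[1, 1] <- 1
  expect_equal(log_prior(st1, hyper) - log_prior(st2, hyper), 0.5 * (4 - 1))

  # penalty term responds to epsilon exactly as symmetry_penalty
  h2 <- hyper_priors(epsilon = 0.03)
  expect_equal(log_prior(st, h2) - log_prior(st, hyper),
               symmetry_penalty(diag(K), 0.03) - symmetry_penalty(diag(K), 0.1))
})

test_that("log-posterior is likelihood plus prior and behaves coherently", {
  set.seed(27)
  sim <- simulate_multiplex(simulation_config(J = 6), seed = 4)
  st <- random_state(6, 3)
  expect_equal(log_posterior(sim$net, st),
               log_likelihood(sim$net, st) + log_prior(st))

  # invariance under node relabeling with consistently permuted effects
  # (identity Gamma so that swapping dyad direction slots is exact)
  st <- random_state(6, 3, gamma_identity = TRUE)
  ll <- log_likelihood(sim$net, st)
  p <- sample(6)
  net2 <- sim$net
  net2$G <- sim$net$G[p, p, , drop = FALSE]
  net2$roster <- sim$net$roster[p, ]
  class(net2) <- "multiplex_network"
  dy <- dyad_index(6)
  inv <- order(p) # position of original node i in the permuted roster
  st2 <- st
  st2$gen$raw <- st$gen$raw[p, ]
  M <- 3
  for (d in seq_len(dy$n_dyads)) {
    a <- p[dy$i1[d]]; b <- p[dy$i2[d]] # original labels of permuted dyad d
    d_old <- dy$of[a, b]
    row <- st$dyad$raw[d_old, ]
    if (dy$i1[d_old] != a) row <- row[c(M + 1:M, 1:M)] # direction flip
    st2$dyad$raw[d, ] <- row
  }
  expect_equal(log_likelihood(net2, st2), ll)
  expect_equal(log_posterior(net2, st2), log_posterior(sim$net, st))

  # likelihood is monotone in a raw dyadic effect's agreement with its cell
  ros <- data.frame(id = c("a", "b"), is_ego = c(TRUE, FALSE))
  net1 <- multiplex_network(ros, "L")
  net1$G["a", "b", 1] <- 1L
  lls <- sapply(c(-1, 0, 1, 2), function(v) {
    s <- parameter_state(
      fixed_effects(0),
      generalized_effects(matrix(0, 2, 2), c(1, 1), diag(2)),
      dyadic_effects(matrix(c(v, 0), 1, 2), 1, diag(2)))
    log_likelihood(net1, s)
  })
  expect_true(all(diff(lls) > 0))
})

test_that("the C++ joint density and gradient match the R reference", {
  set.seed(28)
  cfg <- simulation_config(J = 8, layer_names = c("a", "b"),
                           target_density = c(0.3, 0.2),
                           sigma = c(0.8, 1.2, 0.5, 0.9),
                           varsigma = c(0.7, 1.1))
  sim <- simulate_multiplex(cfg, seed = 7)
  hyper <- hyper_priors()
  dat <- multisrm:::srm_model_data(sim$net, hyper = hyper)
  dim <- multisrm:::srm_param_dim(dat)
  q <- rnorm(dim, 0, 0.5)

  # unpack the unconstrained vector into a constrained state
  M <- dat$M; K <- 2 * M; T2 <- K * (K - 1) / 2; J <- dat$J; D <- dat$D
  eta <- q[1:M]
  ls <- q[M + 1:K]; lv <- q[M + K + 1:M]
  yL <- q[M + K + M + 1:T2]; yG <- q[M + K + M + T2 + 1:T2]
  zg <- matrix(q[M + K + M + 2 * T2 + 1:(J * K)], J, K)
  zd <- matrix(q[M + K + M + 2 * T2 + J * K + 1:(D * K)], D, K)
  st <- parameter_state(
    fixed_effects(eta),
    generalized_effects(zg, exp(ls), multisrm:::.srm_chol_from_y(yL, K)),
    dyadic_effects(zd, exp(lv), multisrm:::.srm_chol_from_y(yG, K)))

  res <- multisrm:::.srm_lp_grad(q, dat, FALSE)
  expect_equal(res$lp, log_posterior(sim$net, st, hyper), tolerance = 1e-10)

  # analytic gradient matches central finite differences (with Jacobian, as
  # used by the sampler)
  res_j <- multisrm:::.srm_lp_grad(q, dat, TRUE)
  h <- 1e-6
  idx <- sort(sample(dim, 40))
  fd <- sapply(idx, function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (multisrm:::.srm_lp_grad(qp, dat, TRUE)$lp -
       multisrm:::.srm_lp_grad(qm, dat, TRUE)$lp) / (2 * h)
  })
  expect_lt(max(abs(fd - res_j$grad[idx]) / pmax(1, abs(fd))), 1e-5)
})
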