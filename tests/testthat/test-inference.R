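# minimal hand-built fit object for testing summaries and reports on
# synthetic draws with known properties
fake_fit <- function(draws_per_chain, layers = c("a", "b"), has_re = TRUE) {
  M <- length(layers)
  structure(list(draws = draws_per_chain,
                 parameters = colnames(draws_per_chain[[1]]),
                 dims = list(J = NA, M = M, D = NA, P = 0, layers = layers,
                             has_re = has_re),
                 config = list(chains = length(draws_per_chain),
                               iter = nrow(draws_per_chain[[1]]),
                               warmup = 0, seed = 0),
                 sampler_info = list()),
            class = "srm_fit")
}

corr_par_names <- function(layers, prefix, slots) {
  K <- length(slots)
  out <- character(0)
  for (a in 1:(K - 1)) for (b in (a + 1):K)
    out <- c(out, paste0(prefix, "[", slots[a], ",", slots[b], "]"))
  out
}

test_that("split R-hat detects agreement and divergence between chains", {
  set.seed(31)
  ch <- rnorm(500)
  # chains that are exact copies
  expect_equal(split_rhat(cbind(ch, ch, ch)), 1, tolerance = 0.01)
  # one chain offset by a large constant
  expect_gt(split_rhat(cbind(ch, ch + 50)), 1.5)
  # a within-chain trend is caught by the split
  expect_gt(split_rhat(cbind(seq(0, 5, length.out = 500) + rnorm(500, 0, .1),
                             seq(0, 5, length.out = 500) + rnorm(500, 0, .1))),
            1.2)
})

test_that("effective sample size is near the draw count for white noise", {
  set.seed(32)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_equal(effective_sample_size(x), 4000, tolerance = 0.2)
  # strongly autocorrelated draws have far fewer effective samples
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.95), 1000)))
  expect_lt(effective_sample_size(ar), 1000)
})

test_that("posterior summaries use means and equal-tailed quantiles", {
  # constant draws: mean c, CI [c, c]
  d <- list(matrix(2.5, 100, 1, dimnames = list(NULL, "eta[a]")),
            matrix(2.5, 100, 1, dimnames = list(NULL, "eta[a]")))
  s <- summary(fake_fit(d), pars = "eta[a]")
  expect_equal(s$mean, 2.5)
  expect_equal(s$ci_low, 2.5)
  expect_equal(s$ci_high, 2.5)

  # 10^6 standard-normal draws: 89% CI ~ [-1.598, 1.598]
  set.seed(33)
  big <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "eta[a]"))
  s <- summary(fake_fit(list(big)), level = 0.89, pars = "eta[a]")
  expect_equal(s$ci_low, qnorm(0.055), tolerance = 0.01)
  expect_equal(s$ci_high, qnorm(0.945), tolerance = 0.01)
  expect_equal(s$mean, 0, tolerance = 0.01)

  # arbitrary level matches direct quantile computation
  v <- sort(rnorm(999))
  dd <- list(matrix(v, ncol = 1, dimnames = list(NULL, "eta[a]")))
  s <- summary(fake_fit(dd), level = 0.5, pars = "eta[a]")
  expect_equal(s$ci_low, unname(quantile(v, 0.25)))
  expect_equal(s$ci_high, unname(quantile(v, 0.75)))
  expect_error(summary(fake_fit(dd), level = 1.2), "level")
})

test_that("correlation report flags exactly the CI-excludes-zero entries", {
  layers <- c("a", "b")
  gl <- c("a:sender", "b:sender", "a:receiver", "b:receiver")
  dl <- c("a:12", "b:12", "a:21", "b:21")
  pars <- c(corr_par_names(layers, "rho_gen", gl),
            corr_par_names(layers, "rho_dyad", dl))
  n <- 400
  set.seed(34)
  # identity-concentrated draws: tiny noise around 0 -> nothing reliable
  dr <- matrix(rnorm(n * length(pars), 0, 0.05), n,
               dimnames = list(NULL, pars))
  rep0 <- correlation_report(fake_fit(list(dr), layers))
  expect_false(any(rep0$dyadic$reliable))
  expect_false(any(rep0$generalized$reliable))
  expect_equal(diag(attr(rep0$dyadic, "matrix")), rep(1, 4),
               ignore_attr = TRUE)

  # draws concentrated at a known rho reproduce it entrywise
  truth <- seq(-0.6, 0.5, length.out = length(pars))
  names(truth) <- pars
  dr2 <- sweep(matrix(rnorm(n * length(pars), 0, 0.01), n,
                      dimnames = list(NULL, pars)), 2, truth, "+")
  rep2 <- correlation_report(fake_fit(list(dr2), layers))
  all_rows <- rbind(rep2$dyadic, rep2$generalized)
  got <- c(rep2$generalized$mean, rep2$dyadic$mean)
  expect_equal(got, unname(truth), tolerance = 0.01)
  # reliability flag is exactly (ci_low > 0 | ci_high < 0)
  for (tab in list(rep2$dyadic, rep2$generalized))
    expect_equal(tab$reliable, tab$ci_low > 0 | tab$ci_high < 0)
})

test_that("intercept-only posterior matches 1-D grid integration", {
  ros <- data.frame(id = letters[1:4], is_ego = TRUE)
  set.seed(3)
  G <- array(rbinom(16, 1, 0.3), c(4, 4, 1))
  net <- multiplex_network(ros, "L1", G)
  fit <- srm_fit(net, chains = 2, iter = 2500, warmup = 500, seed = 11,
                 include_random_effects = FALSE)
  s <- summary(fit)
  y <- net$G[!is.na(net$G)]
  grid <- seq(-10, 10, length.out = 8001)
  lp <- sapply(grid, function(e)
    sum(dbinom(y, 1, plogis(e), log = TRUE)) + dnorm(e, 0, 5, log = TRUE))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  gmean <- sum(w * grid)
  gsd <- sqrt(sum(w * grid^2) - gmean^2)
  expect_equal(s$mean, gmean, tolerance = 0.05)
  expect_equal(s$sd, gsd, tolerance = 0.05)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_multiplex(simulation_config(J = 8), seed = 2)
  f1 <- srm_fit(sim$net, chains = 2, iter = 50, warmup = 50, seed = 99)
  f2 <- srm_fit(sim$net, chains = 2, iter = 50, warmup = 50, seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- srm_fit(sim$net, chains = 2, iter = 50, warmup = 50, seed = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("fit validates its inputs and reports sampler failure context", {
  sim <- simulate_multiplex(simulation_config(J = 6), seed = 2)
  expect_error(srm_fit(sim$net, chains = 2, iter = 0, warmup = 10), "iter")
  expect_error(diagnose(srm_fit(sim$net, chains = 1, iter = 20, warmup = 20,
                                seed = 5)),
               "at least 2 chains")
})

test_that("covariate coefficients are recovered in the logistic model", {
  # simulate an intercept + sender-covariate logistic model and compare the
  # posterior against maximum likelihood (flat-ish prior, n large enough)
  set.seed(41)
  J <- 25
  W <- rnorm(J)
  ros <- data.frame(id = paste0("p", 1:J), is_ego = TRUE)
  th <- outer(-1 + 0.9 * W, rep(0, J), "+")
  G <- array(NA_integer_, c(J, J, 1))
  for (j in 1:J) for (k in 1:J) if (j != k)
    G[j, k, 1] <- rbinom(1, 1, plogis(th[j, k]))
  net <- multiplex_network(ros, "L", G)
  fit <- srm_fit(net, covariates = list(sender = cbind(w = W)),
                 chains = 2, iter = 800, warmup = 400, seed = 8,
                 include_random_effects = FALSE)
  s <- summary(fit)
  expect_setequal(s$parameter, c("eta[L]", "lambda[sender:w,L]"))
  # ML oracle on the same observed cells
  obs <- which(!is.na(net$G[, , 1]), arr.ind = TRUE)
  d <- data.frame(y = net$G[, , 1][obs], w = W[obs[, 1]])
  ml <- glm(y ~ w, binomial, d)
  expect_equal(s$mean[s$parameter == "eta[L]"], unname(coef(ml)[1]),
               tolerance = 0.1)
  expect_equal(s$mean[s$parameter == "lambda[sender:w,L]"],
               unname(coef(ml)[2]), tolerance = 0.1)
})
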