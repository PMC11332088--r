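#' @useDynLib multisrm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Assemble the data list consumed by the C++ log-density/sampler.
srm_model_data <- function(net, covariates = NULL, hyper = hyper_priors(),
                           include_random_effects = TRUE) {
  J <- nrow(net$roster); M <- nrow(net$layers)
  if (J < 2L) stop("at least 2 roster members are required")
  obs <- which(!is.na(net$G), arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("the network has no observed cells")
  s <- obs[, 1]; r <- obs[, 2]; l <- obs[, 3]
  dy <- dyad_index(J)
  X <- matrix(0, nrow(obs), 0)
  lambda_names <- character(0)
  if (!is.null(covariates)) {
    cols <- list()
    if (!is.null(covariates$sender)) {
      W <- as.matrix(covariates$sender)
      stopifnot(nrow(W) == J)
      cn <- colnames(W); if (is.null(cn)) cn <- paste0("s", seq_len(ncol(W)))
      for (p in seq_len(ncol(W))) cols[[paste0("sender:", cn[p])]] <- W[s, p]
    }
    if (!is.null(covariates$receiver)) {
      W <- as.matrix(covariates$receiver)
      stopifnot(nrow(W) == J)
      cn <- colnames(W); if (is.null(cn)) cn <- paste0("r", seq_len(ncol(W)))
      for (p in seq_len(ncol(W))) cols[[paste0("receiver:", cn[p])]] <- W[r, p]
    }
    if (!is.null(covariates$dyadic)) {
      A <- covariates$dyadic
      if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
      stopifnot(all(dim(A)[1:2] == J))
      cn <- dimnames(A)[[3]]
      if (is.null(cn)) cn <- paste0("d", seq_len(dim(A)[3]))
      for (p in seq_len(dim(A)[3]))
        cols[[paste0("dyadic:", cn[p])]] <- A[cbind(s, r, p)]
    }
    if (length(cols) > 0) {
      X <- do.call(cbind, cols)
      lambda_names <- names(cols)
    }
  }
  list(J = J, M = M, D = dy$n_dyads, P = ncol(X),
       has_re = as.integer(include_random_effects),
       obs_s = as.integer(s - 1L), obs_r = as.integer(r - 1L),
       obs_l = as.integer(l - 1L), obs_y = as.integer(net$G[obs]),
       obs_d = as.integer(dy$of[cbind(s, r)] - 1L),
       obs_slot = as.integer(ifelse(s < r, l, l + M) - 1L),
       X = X, lambda_names = lambda_names,
       scale_rate = hyper$scale_rate, lkj_eta = hyper$lkj_eta,
       epsilon = hyper$epsilon, eta_sd = hyper$eta_sd)
}

srm_param_dim <- function(dat) {
  K <- 2L * dat$M; T2 <- K * (K - 1L) / 2L
  if (dat$has_re == 1L)
    dat$M + dat$P * dat$M + K + dat$M + 2L * T2 + (dat$J + dat$D) * K
  else dat$M + dat$P * dat$M
}

# Initial point: intercepts/coefficients at 0, scales at the prior mean,
# correlation factors at the identity, raw effects at 0; a small jitter
# breaks exact symmetry between chains.
srm_init <- function(dat, jitter = 0.01) {
  K <- 2L * dat$M
  dim <- srm_param_dim(dat)
  init <- numeric(dim)
  if (dat$has_re == 1L) {
    off <- dat$M + dat$P * dat$M
    init[off + seq_len(K + dat$M)] <- log(1 / dat$scale_rate)
  }
  init + stats::rnorm(dim, 0, jitter)
}

# Labels for the 2M random-effect slots
gen_slot_labels <- function(layers) c(paste0(layers, ":sender"),
                                      paste0(layers, ":receiver"))
dyad_slot_labels <- function(layers) c(paste0(layers, ":12"),
                                       paste0(layers, ":21"))

# Map one unconstrained draw to the constrained quantities that are reported.
constrain_names <- function(dat, layers) {
  K <- 2L * dat$M
  gl <- gen_slot_labels(layers); dl <- dyad_slot_labels(layers)
  ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  nm <- c(paste0("eta[", layers, "]"))
  if (dat$P > 0)
    nm <- c(nm, paste0("lambda[", rep(dat$lambda_names, dat$M), ",",
                       rep(layers, each = dat$P), "]"))
  if (dat$has_re == 1L)
    nm <- c(nm,
            paste0("sigma[", gl, "]"),
            paste0("varsigma[", layers, "]"),
            paste0("rho_gen[", gl[ut[, 1]], ",", gl[ut[, 2]], "]"),
            paste0("rho_dyad[", dl[ut[, 1]], ",", dl[ut[, 2]], "]"))
  nm
}

constrain_draws <- function(unc, dat) {
  K <- 2L * dat$M; M <- dat$M; T2 <- K * (K - 1L) / 2L
  n <- nrow(unc)
  p_fixed <- M + dat$P * M
  if (dat$has_re == 0L) return(unc[, seq_len(p_fixed), drop = FALSE])
  ut <- upper.tri(matrix(0, K, K))
  out <- matrix(NA_real_, n, p_fixed + K + M + 2L * T2)
  for (i in seq_len(n)) {
    q <- unc[i, ]
    ls <- q[p_fixed + seq_len(K)]
    lv <- q[p_fixed + K + seq_len(M)]
    yL <- q[p_fixed + K + M + seq_len(T2)]
    yG <- q[p_fixed + K + M + T2 + seq_len(T2)]
    L <- .srm_chol_from_y(yL, K)
    G <- .srm_chol_from_y(yG, K)
    rg <- tcrossprod(L); rd <- tcrossprod(G)
    out[i, ] <- c(q[seq_len(p_fixed)], exp(ls), exp(lv),
                  t(rg)[t(ut)], t(rd)[t(ut)])
  }
  out
}

#' Fit the multiplex social relations model
#'
#' Samples the joint posterior of the multiplex SRM — per-layer intercepts,
#' correlated sender/receiver ("generalized") effects, correlated dyadic
#' effects with tied directional scales, and the soft block-symmetry penalty
#' on the dyadic correlation matrix — with a gradient-based No-U-Turn
#' sampler. Only observed cells (ego senders, off-diagonal) enter the
#' likelihood.
#'
#' @param net a [multiplex_network()] with at least one observed cell.
#' @param covariates optional list with entries `sender` (J x Ps matrix),
#'   `receiver` (J x Pr matrix), `dyadic` (J x J x Pd array) of predictors
#'   entering the linear predictor with layer-specific coefficients.
#' @param chains number of MCMC chains (>= 2 for split R-hat; default 4).
#' @param iter post-warmup draws per chain.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param epsilon block-symmetry penalty scale; overrides `hyper$epsilon`.
#' @param hyper a [hyper_priors()] object.
#' @param seed integer seed; fits are deterministic given seed, chain count
#'   and iteration counts on a fixed platform.
#' @param adapt_delta target acceptance statistic (default 0.8).
#' @param max_treedepth maximum doublings per NUTS transition (default 10).
#' @param include_random_effects set `FALSE` for an intercept-plus-covariates
#'   Bernoulli-logit model without SRM random effects.
#' @param refresh progress-print interval in iterations (0 silences).
#' @return an object of class `srm_fit`; see [summary.srm_fit()],
#'   [diagnose()], [correlation_report()].
#' @export
srm_fit <- function(net, covariates = NULL, chains = 4, iter = 500,
                    warmup = 500, epsilon = NULL, hyper = hyper_priors(),
                    seed = 1, adapt_delta = 0.8, max_treedepth = 10,
                    include_random_effects = TRUE, refresh = 0) {
  stopifnot(inherits(net, "multiplex_network"), chains >= 1, iter > 0,
            warmup > 0)
  if (!is.null(epsilon)) hyper$epsilon <- epsilon
  dat <- srm_model_data(net, covariates, hyper, include_random_effects)
  nm <- constrain_names(dat, net$layers$name)
  set.seed(seed)
  draws <- vector("list", chains)
  sampler_info <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- srm_init(dat)
    res <- .srm_nuts(dat, init, as.integer(warmup), as.integer(iter),
                     adapt_delta, as.integer(max_treedepth),
                     as.integer(refresh), as.integer(ch))
    con <- constrain_draws(res$draws, dat)
    colnames(con) <- nm
    draws[[ch]] <- con
    sampler_info[[ch]] <- res[c("step_size", "n_grad", "warmup_divergences")]
    sampler_info[[ch]]$divergences <- sum(res$divergent)
    sampler_info[[ch]]$mean_treedepth <- mean(res$treedepth)
    sampler_info[[ch]]$accept_stat <- mean(res$accept_stat)
    sampler_info[[ch]]$lp <- res$lp
  }
  structure(list(draws = draws, parameters = nm, net = net,
                 dims = list(J = dat$J, M = dat$M, D = dat$D, P = dat$P,
                             layers = net$layers$name,
                             has_re = dat$has_re == 1L),
                 config = list(chains = chains, iter = iter, warmup = warmup,
                               seed = seed, adapt_delta = adapt_delta,
                               max_treedepth = max_treedepth, hyper = hyper),
                 sampler_info = sampler_info),
            class = "srm_fit")
}

# iter x chain matrix of one parameter's draws
param_matrix <- function(fit, par) {
  sapply(fit$draws, function(d) d[, par])
}

#' @export
print.srm_fit <- function(x, ...) {
  cat("Multiplex social relations model fit\n")
  cat(sprintf("  %d people, %d layer%s, %d dyads; %s\n", x$dims$J, x$dims$M,
              if (x$dims$M == 1) "" else "s", x$dims$D,
              if (x$dims$has_re) "full random-effect structure"
              else "intercept-only"))
  cat(sprintf("  %d chain%s x %d draws (+%d warmup), seed %d\n",
              x$config$chains, if (x$config$chains == 1) "" else "s",
              x$config$iter, x$config$warmup, x$config$seed))
  div <- sum(vapply(x$sampler_info, function(s) s$divergences, numeric(1)))
  cat(sprintf("  divergent transitions after warmup: %d\n", div))
  cat("  use summary(), diagnose(), correlation_report()\n")
  invisible(x)
}

#' Posterior summary of an SRM fit
#'
#' Posterior mean, sd, equal-tailed credible interval (89% by default:
#' 5.5% and 94.5% quantiles), split R-hat, and effective sample size per
#' reported parameter.
#'
#' @param object an `srm_fit`.
#' @param level credible level in (0, 1); default 0.89.
#' @param pars optional character vector restricting the parameters.
#' @param ... unused.
#' @return data frame of class `srm_summary`.
#' @export
summary.srm_fit <- function(object, level = 0.89, pars = NULL, ...) {
  if (!(is.numeric(level) && length(level) == 1 && level > 0 && level < 1))
    stop("'level' must be a single number in (0, 1)")
  sel <- if (is.null(pars)) object$parameters else pars
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(sel, function(p) {
    m <- param_matrix(object, p)
    v <- as.vector(m)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               ci_low = unname(stats::quantile(v, probs[1])),
               ci_high = unname(stats::quantile(v, probs[2])),
               rhat = split_rhat(m), ess = effective_sample_size(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("srm_summary", "data.frame")
  out
}

#' @export
print.srm_summary <- function(x, digits = 3, max_rows = 40, ...) {
  cat(sprintf("Posterior summary (%d%% equal-tailed intervals)\n",
              round(100 * attr(x, "level"))))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, digits))
  if (nrow(y) > max_rows) {
    print.data.frame(utils::head(y, max_rows), row.names = FALSE)
    cat("... (", nrow(y) - max_rows, " more rows)\n", sep = "")
  } else print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Posterior means of the main parameters
#'
#' @param object an `srm_fit`.
#' @param ... unused.
#' @return named numeric vector of posterior means.
#' @export
coef.srm_fit <- function(object, ...) {
  vapply(object$parameters,
         function(p) mean(param_matrix(object, p)), numeric(1))
}

#' Convergence diagnostics of an SRM fit
#'
#' Split R-hat and effective sample size for every reported parameter.
#' R-hat near 1 (conventionally below 1.01-1.05) and adequate effective
#' samples indicate converged, well-mixed chains.
#'
#' @param fit an `srm_fit` with at least 2 chains.
#' @return data frame with columns `parameter`, `rhat`, `ess`.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "srm_fit"))
  if (fit$config$chains < 2) stop("split R-hat requires at least 2 chains")
  data.frame(parameter = fit$parameters,
             rhat = vapply(fit$parameters,
                           function(p) split_rhat(param_matrix(fit, p)),
                           numeric(1)),
             ess = vapply(fit$parameters,
                          function(p) effective_sample_size(param_matrix(fit, p)),
                          numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trace plots of an SRM fit
#'
#' @param x an `srm_fit`.
#' @param pars parameters to plot (default: intercepts and scales).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.srm_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- grep("^(eta|sigma|varsigma)\\[", x$parameters, value = TRUE)
  pars <- intersect(pars, x$parameters)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(2.5, 2.5, 2, 0.5), mgp = c(1.5, 0.4, 0))
  on.exit(graphics::par(old))
  for (p in pars)
    graphics::matplot(param_matrix(x, p), type = "l", lty = 1,
                      xlab = "iteration", ylab = "", main = p, ...)
  invisible(x)
}

#' Posterior summaries of the dyadic and generalized correlation matrices
#'
#' The headline output of the multiplex SRM: the 2M x 2M dyadic correlation
#' matrix (within-layer dyadic reciprocity on the C/B block structure,
#' within-person and between-person cross-layer blocks) and the 2M x 2M
#' generalized (sender/receiver) correlation matrix. Off-diagonal entries
#' whose credible interval excludes zero are flagged `reliable` — a display
#' convention, not a hypothesis test.
#'
#' @param fit an `srm_fit` with random effects.
#' @param level credible level (default 0.89).
#' @return list of class `srm_correlation_report` with components `dyadic`
#'   and `generalized`, each a long data frame (`row_label`, `col_label`,
#'   `mean`, `ci_low`, `ci_high`, `reliable`) carrying the posterior-mean
#'   matrix as attribute `"matrix"`.
#' @export
correlation_report <- function(fit, level = 0.89) {
  stopifnot(inherits(fit, "srm_fit"))
  if (!fit$dims$has_re)
    stop("the fit has no random effects, so no correlation structure")
  layers <- fit$dims$layers
  one <- function(prefix, labels) {
    K <- length(labels)
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    Mn <- diag(1, K); dimnames(Mn) <- list(labels, labels)
    rows <- list()
    for (a in seq_len(K - 1)) {
      for (b in (a + 1):K) {
        par <- paste0(prefix, "[", labels[a], ",", labels[b], "]")
        v <- as.vector(param_matrix(fit, par))
        ci <- unname(stats::quantile(v, probs))
        Mn[a, b] <- Mn[b, a] <- mean(v)
        rows[[par]] <- data.frame(row_label = labels[a],
                                  col_label = labels[b],
                                  mean = mean(v), ci_low = ci[1],
                                  ci_high = ci[2],
                                  reliable = ci[1] > 0 | ci[2] < 0,
                                  stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    attr(out, "matrix") <- Mn
    out
  }
  structure(list(dyadic = one("rho_dyad", dyad_slot_labels(layers)),
                 generalized = one("rho_gen", gen_slot_labels(layers)),
                 level = level),
            class = "srm_correlation_report")
}

#' @export
print.srm_correlation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Correlation report (%d%% equal-tailed intervals)\n",
              round(100 * x$level)))
  for (nm in c("dyadic", "generalized")) {
    cat("\n", nm, " correlations (posterior means):\n", sep = "")
    print(round(attr(x[[nm]], "matrix"), digits))
    rel <- x[[nm]][x[[nm]]$reliable, , drop = FALSE]
    if (nrow(rel) == 0) {
      cat("no reliable off-diagonal correlations\n")
    } else {
      cat("reliable entries (CI excludes 0):\n")
      print.data.frame(transform(rel, mean = round(mean, digits),
                                 ci_low = round(ci_low, digits),
                                 ci_high = round(ci_high, digits)),
                       row.names = FALSE)
    }
  }
  invisible(x)
}

#' Simulate replicate networks from a fitted model
#'
#' Draws population parameters (intercepts, scales, correlation matrices)
#' from the posterior and generates a fresh multiplex network from the
#' generative model for each draw: a "new community" replicate, with new
#' random effects, not a reconstruction of the fitted community's latent
#' effects.
#'
#' @param object an `srm_fit` with random effects.
#' @param nsim number of replicate networks.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `srm_sim` objects (see [simulate_multiplex()]).
#' @export
simulate.srm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(inherits(object, "srm_fit"))
  if (!object$dims$has_re)
    stop("simulate() requires a fit with random effects")
  if (!is.null(seed)) set.seed(seed)
  layers <- object$dims$layers
  M <- object$dims$M; K <- 2L * M
  all_draws <- do.call(rbind, object$draws)
  idx <- sample.int(nrow(all_draws), nsim, replace = nsim > nrow(all_draws))
  unpack_corr <- function(draw, prefix, labels) {
    R <- diag(1, K)
    for (a in seq_len(K - 1))
      for (b in (a + 1):K)
        R[a, b] <- R[b, a] <-
          draw[paste0(prefix, "[", labels[a], ",", labels[b], "]")]
    R
  }
  lapply(idx, function(i) {
    dr <- all_draws[i, ]
    cfg <- simulation_config(
      J = object$dims$J,
      ego_fraction = mean(object$net$roster$is_ego),
      layer_names = layers,
      eta = unname(dr[paste0("eta[", layers, "]")]),
      sigma = unname(dr[paste0("sigma[", gen_slot_labels(layers), "]")]),
      varsigma = unname(dr[paste0("varsigma[", layers, "]")]),
      rho_gen = unpack_corr(dr, "rho_gen", gen_slot_labels(layers)),
      rho_dyad = unpack_corr(dr, "rho_dyad", dyad_slot_labels(layers)))
    simulate_multiplex(cfg)
  })
}
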