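## Internal JAGS engine: model-string assembly, sampling, and summaries.
##
## Half-Cauchy and half-Student-t hyperpriors are expressed through their
## inverse-gamma scale-mixture representations, which give the Gibbs sampler
## conjugate updates and much better mixing than sampling the truncated
## scales directly:
##   x ~ C+(0, A)      <=>  1/x^2 | a ~ Gamma(1/2, rate 1/a),
##                          1/a ~ Gamma(1/2, rate 1/A^2)
##   x ~ half-t(nu, A) <=>  1/x^2 | a ~ Gamma(nu/2, rate nu/a),
##                          1/a ~ Gamma(1/2, rate 1/A^2)

jags_variance_block <- function(fixed = FALSE) {
  if (fixed) {
    # sigw2 / sigb2 supplied as data
    "  sigma_w <- sqrt(sigw2)\n  sigma_b <- sqrt(sigb2)\n"
  } else {
    paste0(
      "  lw ~ dnorm(4, 16)\n",          # log-normal(4, 0.25) on sigma_w
      "  sigma_w <- exp(lw)\n",
      "  sigw2 <- sigma_w * sigma_w\n",
      "  lb ~ dnorm(4, 16)\n",          # log-normal(4, 0.25) on sigma_b
      "  sigma_b <- exp(lb)\n",
      "  sigb2 <- sigma_b * sigma_b\n"
    )
  }
}

jags_half_cauchy <- function(prec_node, aux_node, scale) {
  sprintf(
    "  %s ~ dgamma(0.5, %s)\n  %s ~ dgamma(0.5, %.10g)\n",
    prec_node, aux_node, aux_node, 1 / scale^2
  )
}

jags_beta_block <- function(regime, tau_scale, c_scale, c_df) {
  hc_tau <- jags_half_cauchy("itau2", "iat", tau_scale)
  switch(regime,
    fixed = paste0(
      "  for (j in 1:D) {\n",
      "    beta[j] ~ dnorm(0, 1.0E-6)\n",
      "  }\n"
    ),
    gaussian = paste0(
      hc_tau,
      "  tau <- 1 / sqrt(itau2)\n",
      "  for (j in 1:D) {\n",
      "    beta[j] ~ dnorm(0, itau2)\n",
      "  }\n"
    ),
    horseshoe = paste0(
      hc_tau,
      "  tau <- 1 / sqrt(itau2)\n",
      "  for (j in 1:D) {\n",
      "    ilam2[j] ~ dgamma(0.5, ialam[j])\n",
      "    ialam[j] ~ dgamma(0.5, 1)\n",
      "    lam2[j] <- 1 / ilam2[j]\n",
      "    beta[j] ~ dnorm(0, itau2 * ilam2[j])\n",
      "  }\n"
    ),
    reg_horseshoe = paste0(
      hc_tau,
      "  tau <- 1 / sqrt(itau2)\n",
      "  tau2 <- 1 / itau2\n",
      sprintf("  ic2 ~ dgamma(%.10g, %.10g * iac)\n", c_df / 2, c_df),
      sprintf("  iac ~ dgamma(0.5, %.10g)\n", 1 / c_scale^2),
      "  c2 <- 1 / ic2\n",
      "  c <- sqrt(c2)\n",
      "  for (j in 1:D) {\n",
      "    ilam2[j] ~ dgamma(0.5, ialam[j])\n",
      "    ialam[j] ~ dgamma(0.5, 1)\n",
      "    lam2[j] <- 1 / ilam2[j]\n",
      "    xi2[j] <- c2 * lam2[j] / (c2 + tau2 * lam2[j])\n",
      "    beta[j] ~ dnorm(0, 1 / (tau2 * xi2[j]))\n",
      "  }\n"
    ),
    stop("unknown prior regime: ", regime, call. = FALSE)
  )
}

jags_theta_block <- function(K) {
  if (K == 0) return("")
  paste0(
    "  for (k in 1:K) {\n",
    "    theta[k] ~ dnorm(0, 1.0E-6)\n",
    "  }\n"
  )
}

jags_adjustment_model <- function(regime, K, tau_scale, c_scale, c_df,
                                  fixed_variance = FALSE) {
  mu <- if (K > 0) {
    "    mu[i] <- inprod(X[i,], beta) + inprod(R[i,], theta)\n"
  } else {
    "    mu[i] <- inprod(X[i,], beta)\n"
  }
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    mu,
    "    y[i] ~ dnorm(mu[i], 1 / (sigw2 / n[i] + sigb2))\n",
    "  }\n",
    jags_variance_block(fixed_variance),
    jags_theta_block(K),
    jags_beta_block(regime, tau_scale, c_scale, c_df),
    "}\n"
  )
}

## Draw from a JAGS model with deterministic per-chain seeds.
run_jags <- function(model_string, data, monitors, chains = 3, adapt = 1000,
                     warmup = 1000, iter = 2000, thin = 1, seed = 1,
                     extra_inits = NULL) {
  seed <- as.integer(seed %% .Machine$integer.max)
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed * 97L + ch * 1009L) %% 2147483647L + 1L)
    if (!is.null(extra_inits)) ini <- c(ini, extra_inits(ch))
    ini
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) stats::update(model, warmup, progress.bar = "none")
  rjags::coda.samples(model, variable.names = monitors, n.iter = iter,
                      thin = thin, progress.bar = "none")
}

## Split-chain potential scale reduction; falls back to splitting a single
## chain in half. Returns a named vector over parameters.
split_rhat <- function(samples) {
  if (coda::nchain(samples) == 1) {
    m <- as.matrix(samples)
    h <- floor(nrow(m) / 2)
    samples <- coda::mcmc.list(coda::mcmc(m[seq_len(h), , drop = FALSE]),
                               coda::mcmc(m[(h + 1):(2 * h), , drop = FALSE]))
  } else {
    split_one <- function(ch) {
      m <- as.matrix(ch)
      h <- floor(nrow(m) / 2)
      list(coda::mcmc(m[seq_len(h), , drop = FALSE]),
           coda::mcmc(m[(h + 1):(2 * h), , drop = FALSE]))
    }
    halves <- unlist(lapply(samples, split_one), recursive = FALSE)
    samples <- do.call(coda::mcmc.list, halves)
  }
  keep <- apply(as.matrix(samples), 2, stats::sd) > 0
  out <- rep(NA_real_, coda::nvar(samples))
  names(out) <- coda::varnames(samples)
  if (any(keep)) {
    gd <- try(coda::gelman.diag(samples[, keep, drop = FALSE],
                                autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1],
              silent = TRUE)
    if (!inherits(gd, "try-error")) out[keep] <- gd
  }
  out[!keep] <- 1  # constant (e.g. exactly-zero) parameters have converged
  out
}

## Tidy per-parameter posterior summary: median, central interval, rhat, ess.
summarize_draws <- function(samples, level = 0.9) {
  m <- as.matrix(samples)
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  q <- t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
  data.frame(
    parameter = colnames(m),
    median = q[, 2], lower = q[, 1], upper = q[, 3],
    mean = colMeans(m),
    rhat = unname(split_rhat(samples)[colnames(m)]),
    ess = unname(coda::effectiveSize(samples)[colnames(m)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## Pull the rows of a summary whose parameter names match "name[1]", ... and
## relabel them with `labels`.
indexed_summary <- function(summ, name, labels) {
  if (length(labels) == 1) {
    rows <- summ[summ$parameter %in% c(name, paste0(name, "[1]")), ,
                 drop = FALSE]
  } else {
    rows <- summ[match(paste0(name, "[", seq_along(labels), "]"),
                       summ$parameter), , drop = FALSE]
  }
  rows$parameter <- labels
  names(rows)[1] <- "term"
  rownames(rows) <- NULL
  rows
}

## Monte-Carlo standard error of the posterior mean from the effective size.
mcse_mean <- function(samples) {
  m <- as.matrix(samples)
  apply(m, 2, stats::sd) / sqrt(pmax(coda::effectiveSize(samples), 1))
}
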