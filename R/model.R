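#' Specify the hierarchical richness model
#'
#' The detection-effectiveness model treats the number of species detected by
#' protocol i at transect j as Poisson:
#' `s_ij ~ Pois(lambda_ij)`, `ln(lambda_ij) = eta_i + gamma_j`, where `eta_i`
#' is the protocol log-rate (the sum of a global intercept and a protocol
#' effect, both given vague Normal(0, 1e12) priors — only their sum is
#' identified, so the default parameterization samples `eta_i` directly) and
#' `gamma_j` is a transect random effect, `gamma_j ~ Normal(0, theta^2)` with
#' `theta ~ Uniform(0, 100)`.
#'
#' @param n_protocols,n_transects Model dimensions (defaults: the case
#'   study's 7 protocols x 10 transects).
#' @param prior_intercept_mean,prior_intercept_var Normal prior on each
#'   protocol log-rate (vague by default: mean 0, variance 1e12).
#' @param scale_prior_upper Upper bound of the uniform prior on the
#'   transect-effect standard deviation `theta`.
#' @param parameterization `"protocol_intercepts"` (default) samples the
#'   identified `eta_i = alpha + beta_i` directly; `"corner_constraint"`
#'   samples a global intercept plus protocol offsets with the first protocol
#'   as reference (`beta_1 = 0`), for comparison.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(n_protocols = 7, n_transects = 10,
                       prior_intercept_mean = 0,
                       prior_intercept_var = 1e12,
                       scale_prior_upper = 100,
                       parameterization = c("protocol_intercepts",
                                            "corner_constraint")) {
  stopifnot(prior_intercept_var > 0, scale_prior_upper > 0,
            n_protocols >= 1, n_transects >= 1)
  structure(
    list(
      n_protocols = as.integer(n_protocols),
      n_transects = as.integer(n_transects),
      prior_intercept_mean = prior_intercept_mean,
      prior_intercept_var = prior_intercept_var,
      scale_prior_upper = scale_prior_upper,
      parameterization = match.arg(parameterization)
    ),
    class = "model_spec"
  )
}

#' MCMC sampler settings
#'
#' @param n_chains Number of chains (at least 2, so convergence can be
#'   assessed).
#' @param n_iter Iterations per chain; the first `burn_in_fraction` are
#'   discarded as burn-in (and used for step-size adaptation).
#' @param burn_in_fraction Fraction of each chain discarded (default 0.5).
#' @param seed Integer seed; the full run is reproducible from it.
#' @param retained_target Minimum pooled post-burn-in draw count the run
#'   should provide (default 10000); a shorter run warns.
#' @param init_step Initial random-walk standard deviation for every scalar
#'   update; adapted during burn-in towards 20-50% acceptance, then frozen.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 12000,
                        burn_in_fraction = 0.5, seed = 1,
                        retained_target = 10000, init_step = 0.2) {
  stopifnot(n_chains >= 2, n_iter >= 10,
            burn_in_fraction > 0, burn_in_fraction < 1, init_step > 0)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in_fraction = burn_in_fraction, seed = as.integer(seed),
         retained_target = as.integer(retained_target),
         init_step = init_step),
    class = "mcmc_config"
  )
}

#' Log joint density of the hierarchical richness model
#'
#' Evaluates, up to the constant of proportionality in the priors' support,
#' `sum_ij [s_ij (eta_i + gamma_j) - exp(eta_i + gamma_j) - log(s_ij!)]
#'  + sum_i logNormal(eta_i; mean, var) + sum_j logNormal(gamma_j; 0, theta^2)
#'  + log 1(0 < theta < upper)`.
#' Returns `-Inf` outside the prior support.
#'
#' @param state A list with elements `eta` (length `n_protocols`), `gamma`
#'   (length `n_transects`) and `theta` (scalar). Under the corner-constraint
#'   parameterization, `alpha` (scalar) and `beta` (length `n_protocols`,
#'   first element 0) replace `eta`.
#' @param s Richness data: the tibble from [richness_matrix()] or an
#'   equivalent protocols x transects matrix.
#' @param spec A [model_spec()].
#' @return A single numeric log density.
#' @export
log_posterior <- function(state, s, spec = model_spec()) {
  m <- as_richness_wide(s)
  if (!identical(dim(m), c(spec$n_protocols, spec$n_transects)) &&
      !all(dim(m) == c(spec$n_protocols, spec$n_transects))) {
    stop("richness data is ", nrow(m), " x ", ncol(m),
         " but the model spec declares ", spec$n_protocols, " x ",
         spec$n_transects, call. = FALSE)
  }
  if (spec$parameterization == "corner_constraint") {
    if (is.null(state$alpha) || is.null(state$beta)) {
      stop("corner-constraint state needs 'alpha' and 'beta'", call. = FALSE)
    }
    eta <- state$alpha + state$beta
    prior_eta <- stats::dnorm(state$alpha, spec$prior_intercept_mean,
                              sqrt(spec$prior_intercept_var), log = TRUE) +
      sum(stats::dnorm(state$beta[-1], spec$prior_intercept_mean,
                       sqrt(spec$prior_intercept_var), log = TRUE))
  } else {
    eta <- state$eta
    prior_eta <- sum(stats::dnorm(eta, spec$prior_intercept_mean,
                                  sqrt(spec$prior_intercept_var), log = TRUE))
  }
  gamma <- state$gamma
  theta <- state$theta
  if (length(eta) != spec$n_protocols || length(gamma) != spec$n_transects ||
      length(theta) != 1) {
    stop("state dimensions do not match the model spec", call. = FALSE)
  }
  if (!is.finite(theta) || theta <= 0 || theta >= spec$scale_prior_upper) {
    return(-Inf)
  }
  log_lambda <- outer(eta, gamma, `+`)
  loglik <- sum(m * log_lambda - exp(log_lambda) - lgamma(m + 1))
  loglik + prior_eta +
    sum(stats::dnorm(gamma, 0, theta, log = TRUE)) -
    log(spec$scale_prior_upper)
}

#' Fit the hierarchical richness model by MCMC
#'
#' Metropolis-within-Gibbs: each protocol log-rate, each transect effect and
#' the transect-effect scale `theta` is updated in turn by a scalar
#' random-walk Metropolis step. Step sizes adapt during burn-in (targeting
#' 20-50% acceptance) and are frozen afterwards. Post-burn-in draws are
#' pooled across chains; the Gelman-Rubin potential scale reduction factor
#' is computed per parameter and the fit is flagged unconverged if any
#' exceeds 1.05. Identical configurations (including seed) give identical
#' draws.
#'
#' @param s Richness data ([richness_matrix()] tibble or matrix).
#' @param spec A [model_spec()]; dimensions are taken from the data if the
#'   defaults do not match.
#' @param config An [mcmc_config()].
#' @return An object of class `richness_fit` with elements `draws` (tibble:
#'   `chain`, `iteration`, one column per parameter), `psrf` (tibble of
#'   per-parameter diagnostics), `converged`, `spec`, `config`, `protocols`.
#' @export
#' @examples
#' \donttest{
#' s <- richness_matrix(reconstruct_incidence(load_detection_table()))
#' fit <- run_mcmc(s, config = mcmc_config(n_iter = 2000, seed = 1))
#' glance(fit)
#' }
run_mcmc <- function(s, spec = model_spec(), config = mcmc_config()) {
  m <- as_richness_wide(s)
  if (nrow(m) != spec$n_protocols || ncol(m) != spec$n_transects) {
    spec$n_protocols <- nrow(m)
    spec$n_transects <- ncol(m)
  }
  protocols <- rownames(m)
  if (is.null(protocols)) protocols <- paste0("p", seq_len(nrow(m)))
  n_burn <- floor(config$n_iter * config$burn_in_fraction)
  n_keep <- config$n_iter - n_burn

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_single_chain(m, spec, config, chain_seeds[ch], n_burn)
  })

  par_names <- colnames(chains[[1]])
  draws <- purrr::imap_dfr(chains, function(mat, ch) {
    out <- tibble::as_tibble(mat)
    dplyr::bind_cols(
      tibble::tibble(chain = ch, iteration = seq_len(nrow(mat)) + n_burn),
      out
    )
  })
  if (config$n_chains * n_keep < config$retained_target) {
    warning("pooled post-burn-in draws (", config$n_chains * n_keep,
            ") fall short of the retained target (", config$retained_target,
            ")", call. = FALSE)
  }

  psrf <- tibble::tibble(
    parameter = par_names,
    psrf = vapply(par_names, function(p) {
      gelman_rubin(vapply(chains, function(mat) mat[, p],
                          numeric(n_keep)))
    }, numeric(1)),
    ess = vapply(par_names, function(p) {
      sum(vapply(chains, function(mat) ess_single(mat[, p]), numeric(1)))
    }, numeric(1))
  )
  structure(
    list(
      draws = draws,
      psrf = psrf,
      converged = all(is.finite(psrf$psrf)) && all(psrf$psrf < 1.05),
      spec = spec, config = config,
      protocols = protocols,
      n_retained = config$n_chains * n_keep
    ),
    class = "richness_fit"
  )
}

# one chain; returns a (n_iter - n_burn) x n_params matrix of retained draws
run_single_chain <- function(m, spec, config, seed, n_burn) {
  set.seed(seed)
  np <- nrow(m); nt <- ncol(m)
  corner <- spec$parameterization == "corner_constraint"
  row_tot <- rowSums(m); col_tot <- colSums(m)
  eta <- log((row_tot + 0.5) / nt)
  gamma <- rep(0, nt)
  theta <- min(1, spec$scale_prior_upper / 2)
  alpha <- 0; beta <- rep(0, np)
  if (corner) {
    alpha <- eta[1]
    beta <- eta - alpha
    beta[1] <- 0
  }
  prior_sd <- sqrt(spec$prior_intercept_var)
  prior_mu <- spec$prior_intercept_mean
  upper <- spec$scale_prior_upper

  # blocks: eta_1..np (or alpha, beta_2..np), gamma_1..nt, theta
  n_blocks <- np + nt + 1L
  step <- rep(config$init_step, n_blocks)
  acc <- integer(n_blocks); att <- integer(n_blocks)

  exp_eta <- exp(eta); exp_gamma <- exp(gamma)
  sum_exp_gamma <- sum(exp_gamma); sum_exp_eta <- sum(exp_eta)

  keep <- matrix(NA_real_, nrow = config$n_iter - n_burn,
                 ncol = np + nt + 1L)
  eta_names <- paste0("eta_", gsub("[^A-Za-z0-9]+", "_", rownames(m)))
  colnames(keep) <- c(eta_names, paste0("gamma_", seq_len(nt)), "theta")

  for (it in seq_len(config$n_iter)) {
    if (!corner) {
      for (i in seq_len(np)) {
        att[i] <- att[i] + 1L
        prop <- eta[i] + stats::rnorm(1, 0, step[i])
        # conditional: s_i. * eta_i - exp(eta_i) * sum_j exp(gamma_j) + prior
        cur <- row_tot[i] * eta[i] - exp_eta[i] * sum_exp_gamma +
          stats::dnorm(eta[i], prior_mu, prior_sd, log = TRUE)
        new <- row_tot[i] * prop - exp(prop) * sum_exp_gamma +
          stats::dnorm(prop, prior_mu, prior_sd, log = TRUE)
        if (log(stats::runif(1)) < new - cur) {
          eta[i] <- prop
          sum_exp_eta <- sum_exp_eta - exp_eta[i] + exp(prop)
          exp_eta[i] <- exp(prop)
          acc[i] <- acc[i] + 1L
        }
      }
    } else {
      # alpha block (shifts every protocol), then beta_2..np
      att[1] <- att[1] + 1L
      prop <- alpha + stats::rnorm(1, 0, step[1])
      cur <- sum(row_tot) * alpha - sum_exp_eta * sum_exp_gamma +
        stats::dnorm(alpha, prior_mu, prior_sd, log = TRUE)
      prop_exp_eta <- exp(prop + beta)
      new <- sum(row_tot) * prop - sum(prop_exp_eta) * sum_exp_gamma +
        stats::dnorm(prop, prior_mu, prior_sd, log = TRUE)
      if (log(stats::runif(1)) < new - cur) {
        alpha <- prop
        exp_eta <- prop_exp_eta
        sum_exp_eta <- sum(exp_eta)
        acc[1] <- acc[1] + 1L
      }
      for (i in seq_len(np)[-1]) {
        att[i] <- att[i] + 1L
        prop <- beta[i] + stats::rnorm(1, 0, step[i])
        cur <- row_tot[i] * beta[i] - exp_eta[i] * sum_exp_gamma +
          stats::dnorm(beta[i], prior_mu, prior_sd, log = TRUE)
        new <- row_tot[i] * prop - exp(alpha + prop) * sum_exp_gamma +
          stats::dnorm(prop, prior_mu, prior_sd, log = TRUE)
        if (log(stats::runif(1)) < new - cur) {
          beta[i] <- prop
          sum_exp_eta <- sum_exp_eta - exp_eta[i] + exp(alpha + prop)
          exp_eta[i] <- exp(alpha + prop)
          acc[i] <- acc[i] + 1L
        }
      }
      eta <- alpha + beta
    }
    for (j in seq_len(nt)) {
      b <- np + j
      att[b] <- att[b] + 1L
      prop <- gamma[j] + stats::rnorm(1, 0, step[b])
      cur <- col_tot[j] * gamma[j] - exp_gamma[j] * sum_exp_eta +
        stats::dnorm(gamma[j], 0, theta, log = TRUE)
      new <- col_tot[j] * prop - exp(prop) * sum_exp_eta +
        stats::dnorm(prop, 0, theta, log = TRUE)
      if (log(stats::runif(1)) < new - cur) {
        gamma[j] <- prop
        sum_exp_gamma <- sum_exp_gamma - exp_gamma[j] + exp(prop)
        exp_gamma[j] <- exp(prop)
        acc[b] <- acc[b] + 1L
      }
    }
    b <- np + nt + 1L
    att[b] <- att[b] + 1L
    prop <- theta + stats::rnorm(1, 0, step[b])
    if (prop > 0 && prop < upper) {
      cur <- sum(stats::dnorm(gamma, 0, theta, log = TRUE))
      new <- sum(stats::dnorm(gamma, 0, prop, log = TRUE))
      if (log(stats::runif(1)) < new - cur) {
        theta <- prop
        acc[b] <- acc[b] + 1L
      }
    }

    if (it <= n_burn && it %% 50L == 0L) {
      rate <- ifelse(att > 0, acc / att, 0.35)
      step <- pmin(pmax(step * exp(rate - 0.35), 1e-4), 10)
      acc[] <- 0L; att[] <- 0L
    }
    if (it > n_burn) {
      keep[it - n_burn, ] <- c(eta, gamma, theta)
    }
  }
  keep
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The between/within-chain variance ratio for one parameter:
#' `PSRF = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means. Values near 1 indicate
#' the chains have mixed over the same distribution; the package's
#' convergence flag requires PSRF < 1.05 for every parameter.
#'
#' @param chains A numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors, at least two chains of length >= 10.
#' @return The PSRF (numeric). Returns `NaN` with a warning when the
#'   within-chain variance is numerically zero (degenerate chains).
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(cbind(rnorm(500), rnorm(500)))
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2) stop("at least two chains are required", call. = FALSE)
  if (n < 10) stop("chains must have length >= 10", call. = FALSE)
  w <- mean(apply(chains, 2, stats::var))
  b_over_n <- stats::var(colMeans(chains))
  if (!is.finite(w) || w <= .Machine$double.eps * max(1, b_over_n)) {
    warning("degenerate chains: within-chain variance is (numerically) zero",
            call. = FALSE)
    return(NaN)
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

# effective sample size of one chain: initial positive-sequence estimator
ess_single <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  acf_vals <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                         demean = TRUE)$acf[-1]
  pos <- which(acf_vals < 0)
  if (length(pos) > 0) acf_vals <- acf_vals[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(acf_vals))
}

#' Pooled posterior draws of a protocol's detection rate
#'
#' `lambda_i = exp(eta_i)`: the expected number of species the protocol
#' detects at a typical transect (transect effect 0).
#'
#' @param fit A [run_mcmc()] fit.
#' @param protocol One of the fitted protocol labels.
#' @param n_draws Optionally cap at the first `n_draws` pooled draws.
#' @return Numeric vector of rate draws.
#' @export
rate_draws <- function(fit, protocol, n_draws = NULL) {
  stopifnot(inherits(fit, "richness_fit"))
  idx <- match(protocol, fit$protocols)
  if (is.na(idx)) {
    stop("unknown protocol '", protocol, "'; fitted: ",
         paste(fit$protocols, collapse = ", "), call. = FALSE)
  }
  col <- paste0("eta_", gsub("[^A-Za-z0-9]+", "_", protocol))
  x <- exp(fit$draws[[col]])
  if (!is.null(n_draws)) {
    if (length(x) < n_draws) {
      stop("fit has only ", length(x), " pooled draws; ", n_draws,
           " requested", call. = FALSE)
    }
    x <- x[seq_len(n_draws)]
  }
  x
}

#' Pairwise protocol superiority probabilities
#'
#' For each ordered protocol pair (x, y), the fraction of paired posterior
#' draws with `lambda_x >= lambda_y` — the posterior probability that
#' protocol x detects at least as many species per transect as protocol y.
#' Ties count towards "at least as many"; the diagonal is 1 by definition.
#'
#' @param fit A [run_mcmc()] fit.
#' @param n_draws Number of pooled post-burn-in draws to use (default 10000).
#' @return A tibble of class `superiority_tbl` with columns `protocol_x`,
#'   `protocol_y`, `prob`. Use [superiority_matrix()] for the square form.
#' @export
pairwise_superiority <- function(fit, n_draws = 10000) {
  stopifnot(inherits(fit, "richness_fit"))
  lam <- vapply(fit$protocols, function(p) rate_draws(fit, p, n_draws),
                numeric(n_draws))
  out <- tidyr::expand_grid(protocol_x = fit$protocols,
                            protocol_y = fit$protocols) |>
    dplyr::mutate(prob = purrr::map2_dbl(
      .data$protocol_x, .data$protocol_y,
      function(x, y) if (x == y) 1 else mean(lam[, x] >= lam[, y])
    ))
  class(out) <- c("superiority_tbl", class(out))
  out
}

#' @rdname pairwise_superiority
#' @param x A `superiority_tbl` from [pairwise_superiority()].
#' @return `superiority_matrix()` returns the square numeric matrix with
#'   protocols as dimnames.
#' @export
superiority_matrix <- function(x) {
  stopifnot(inherits(x, "superiority_tbl"))
  protocols <- unique(x$protocol_x)
  m <- matrix(x$prob, nrow = length(protocols), byrow = TRUE,
              dimnames = list(protocols, protocols))
  m
}

#' @export
print.richness_fit <- function(x, ...) {
  cat("Hierarchical Poisson richness model fit\n")
  cat("  protocols:", paste(x$protocols, collapse = ", "), "\n")
  cat("  chains:", x$config$n_chains, " iterations/chain:", x$config$n_iter,
      " pooled retained draws:", x$n_retained, "\n")
  cat("  max PSRF:", format(max(x$psrf$psrf), digits = 4),
      if (x$converged) "(converged, all < 1.05)" else "(NOT converged)", "\n")
  invisible(x)
}
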