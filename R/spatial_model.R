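# ---------------------------------------------------------------------------
# Matern covariance and hyperparameters
# ---------------------------------------------------------------------------

#' Matern spatial-field hyperparameters
#'
#' Parameterized by the range `rho` (km) -- the distance beyond which
#' correlation becomes negligible (about 0.1-0.14 under this convention) --
#' the marginal standard deviation `sigma`, and the smoothness `nu`
#' (default 1, the convention under which `kappa = sqrt(8 nu) / rho`).
#'
#' @param range_rho spatial range in km, > 0.
#' @param sigma marginal standard deviation, >= 0.
#' @param nu smoothness, > 0 (default 1; `nu = 0.5` gives the exponential
#'   correlation model).
#' @return an object of class `matern_params` with the derived scale `kappa`.
#' @export
matern_params <- function(range_rho, sigma, nu = 1) {
  if (!is.finite(range_rho) || range_rho <= 0) {
    stop("range_rho must be > 0", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0", call. = FALSE)
  structure(list(range_rho = range_rho, sigma = sigma, nu = nu,
                 kappa = sqrt(8 * nu) / range_rho),
            class = "matern_params")
}

#' Matern correlation function
#'
#' `r(d) = 2^(1-nu)/Gamma(nu) * (kappa d)^nu * K_nu(kappa d)` with
#' `r(0) = 1`, where `K_nu` is the modified Bessel function of the second
#' kind. Monotone decreasing in `d`; for `nu = 0.5` it reduces to
#' `exp(-kappa d)`. At `d = range_rho` (with `kappa = sqrt(8 nu)/rho`) the
#' correlation is approximately 0.1.
#'
#' @param d distance(s), km, >= 0.
#' @param params a `matern_params` object.
#' @return correlation value(s) in `[0, 1]`.
#' @export
matern_correlation <- function(d, params) {
  stopifnot(inherits(params, "matern_params"))
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  kd <- params$kappa * d
  out <- numeric(length(kd))
  zero <- kd == 0
  out[zero] <- 1
  if (any(!zero)) {
    x <- kd[!zero]
    nu <- params$nu
    # besselK underflows around x ~ 700; the correlation is 0 there anyway
    lr <- (1 - nu) * log(2) - lgamma(nu) + nu * log(x) +
      log(besselK(x, nu, expon.scaled = TRUE)) - x
    out[!zero] <- exp(lr)
  }
  dim(out) <- dim(d)
  out
}

#' Build a Matern covariance matrix over projected points
#'
#' `Sigma_ij = sigma^2 * r(||x_i - x_j||) + jitter * 1{i=j}`. The result is
#' checked by Cholesky factorization; on failure the jitter is escalated
#' (x10, at most 3 times) before a numerical error is raised.
#'
#' @param coords_km numeric matrix with columns `x`, `y` in km.
#' @param params a `matern_params` object.
#' @param jitter diagonal nugget; default `1e-8 * sigma^2 + 1e-12`.
#' @return symmetric positive-definite matrix with the (possibly escalated)
#'   jitter recorded in attribute `jitter`.
#' @export
build_covariance <- function(coords_km, params,
                             jitter = 1e-8 * params$sigma^2 + 1e-12) {
  stopifnot(inherits(params, "matern_params"))
  coords_km <- as.matrix(coords_km)
  n <- nrow(coords_km)
  stopifnot(n >= 1, jitter >= 0)
  D <- as.matrix(stats::dist(coords_km[, 1:2, drop = FALSE]))
  S0 <- params$sigma^2 * matern_correlation(D, params)
  j <- jitter
  for (attempt in 0:3) {
    S <- S0 + diag(j, n)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) {
      attr(S, "jitter") <- j
      return(S)
    }
    j <- if (j > 0) j * 10 else 1e-12
  }
  stop(sprintf(
    "covariance factorization failed after jitter escalation (n = %d, rho = %g, sigma = %g, final jitter = %g)",
    n, params$range_rho, params$sigma, j), call. = FALSE)
}

# Fast Matern correlation on a plain distance vector (no class dispatch,
# direct formula; scaled Bessel only where the argument is large enough to
# underflow). Used in the MCMC hot loop.
matern_corr_vec <- function(d, kappa, nu) {
  x <- kappa * d
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- 1
  big <- !zero & x > 600
  if (any(big)) {
    xb <- x[big]
    out[big] <- exp((1 - nu) * log(2) - lgamma(nu) + nu * log(xb) +
                      log(besselK(xb, nu, expon.scaled = TRUE)) - xb)
  }
  mid <- !zero & !big
  if (any(mid)) {
    xm <- x[mid]
    out[mid] <- 2^(1 - nu) / gamma(nu) * xm^nu * besselK(xm, nu)
  }
  out
}

# Symmetric correlation matrix from the n(n-1)/2 lower-triangle distance
# vector produced by stats::dist.
corr_matrix_from_dvec <- function(rvec, n) {
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- rvec
  S <- S + t(S)
  diag(S) <- 1
  S
}

# Cholesky with escalation, returning the upper factor. Used where the
# factor itself is needed (likelihood, simulation, kriging).
chol_with_jitter <- function(S0, jitter) {
  n <- nrow(S0)
  j <- jitter
  for (attempt in 0:3) {
    U <- tryCatch(chol(S0 + diag(j, n)), error = function(e) NULL)
    if (!is.null(U)) {
      attr(U, "jitter") <- j
      return(U)
    }
    j <- if (j > 0) j * 10 else 1e-12
  }
  stop("Cholesky factorization failed after jitter escalation", call. = FALSE)
}

# ---------------------------------------------------------------------------
# Priors
# ---------------------------------------------------------------------------

#' Prior specification for the spatial binomial model
#'
#' The intercept gets an improper flat prior (contributes 0 to the log
#' posterior). Each regression coefficient gets a Normal(0, precision
#' `beta_precision`) prior; the default precision 1e-4 corresponds to a
#' standard deviation of 100. The field hyperparameters (range, marginal SD)
#' get the penalized-complexity prior with tail conditions
#' `P(rho < rho0) = p_rho` and `P(sigma > sigma0) = p_sigma`.
#'
#' @param beta_precision prior precision for each coefficient (> 0).
#' @param rho0 range threshold, km (same units as the projected distances).
#' @param p_rho tail probability for the range, in (0, 1).
#' @param sigma0 marginal-SD threshold.
#' @param p_sigma tail probability for the SD, in (0, 1).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(beta_precision = 1e-4, rho0 = 100, p_rho = 0.05,
                       sigma0 = 1, p_sigma = 0.05) {
  stopifnot(beta_precision > 0, rho0 > 0, sigma0 > 0,
            p_rho > 0, p_rho < 1, p_sigma > 0, p_sigma < 1)
  structure(list(beta_precision = beta_precision, rho0 = rho0, p_rho = p_rho,
                 sigma0 = sigma0, p_sigma = p_sigma),
            class = "prior_spec")
}

# PC prior log-density for (rho, sigma) in d = 2 dimensions:
#   pi(rho)   = lambda1 * rho^-2 * exp(-lambda1 / rho),  lambda1 = -log(p_rho) * rho0
#   pi(sigma) = lambda2 * exp(-lambda2 * sigma),         lambda2 = -log(p_sigma) / sigma0
# evaluated on the log scale with the Jacobians of the log transforms.
log_pc_prior <- function(log_rho, log_sigma, priors) {
  lambda1 <- -log(priors$p_rho) * priors$rho0
  lambda2 <- -log(priors$p_sigma) / priors$sigma0
  rho <- exp(log_rho); sigma <- exp(log_sigma)
  lp_rho <- log(lambda1) - 2 * log_rho - lambda1 / rho + log_rho
  lp_sigma <- log(lambda2) - lambda2 * sigma + log_sigma
  lp_rho + lp_sigma
}

# ---------------------------------------------------------------------------
# Likelihood and posterior
# ---------------------------------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Per-observation binomial log-likelihood at linear predictor eta.
loglik_terms <- function(y, n, eta) {
  lchoose(n, y) + y * eta - n * softplus(eta)
}

#' Binomial log-likelihood on the logit scale
#'
#' `sum_j [ log C(n_j, y_j) + y_j eta_j - n_j log(1 + exp(eta_j)) ]`,
#' computed overflow-safely.
#'
#' @param records a `cluster_records` data.frame (uses `n_underweight`,
#'   `n_children`), or a list with elements `y` and `n`.
#' @param eta linear predictor, one value per cluster.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(records, eta) {
  if (inherits(records, "cluster_records") || is.data.frame(records)) {
    y <- records$n_underweight; n <- records$n_children
  } else {
    y <- records$y; n <- records$n
  }
  stopifnot(length(eta) == length(y), all(is.finite(eta)))
  sum(loglik_terms(y, n, eta))
}

# Zero-mean MVN log-density given the upper Cholesky factor of Sigma.
mvn_logpdf_chol <- function(x, U) {
  n <- length(x)
  z <- backsolve(U, x, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

#' Log posterior density of the full model state
#'
#' Log-likelihood plus the Normal prior on the coefficients, the zero-mean
#' MVN prior on the latent field under `Sigma(rho, sigma)`, and the PC prior
#' (with log-transform Jacobians) on the hyperparameters. The flat intercept
#' prior contributes 0. Non-finite states return `-Inf` (a rejected move),
#' never an error.
#'
#' @param state list with `alpha`, `beta`, `zeta`, `log_rho`, `log_sigma`.
#' @param data list with `y`, `n`, `X` (matrix, possibly 0 columns), and
#'   `coords_km`.
#' @param priors a `prior_spec`.
#' @return scalar log posterior (possibly `-Inf`).
#' @export
log_posterior <- function(state, data, priors) {
  vals <- c(state$alpha, state$beta, state$zeta, state$log_rho,
            state$log_sigma)
  if (any(!is.finite(vals))) return(-Inf)
  zeta <- if (is.null(state$zeta)) 0 else state$zeta
  eta <- state$alpha + drop(data$X %*% state$beta) + zeta
  lp <- sum(loglik_terms(data$y, data$n, eta))
  if (length(state$beta)) {
    prec <- priors$beta_precision
    lp <- lp + sum(0.5 * log(prec) - 0.5 * log(2 * pi) -
                     0.5 * prec * state$beta^2)
  }
  if (!is.null(state$log_rho) && !is.null(state$log_sigma) &&
      !is.null(state$zeta)) {
    params <- matern_params(exp(state$log_rho), exp(state$log_sigma))
    S <- params$sigma^2 *
      matern_correlation(as.matrix(stats::dist(data$coords_km)), params)
    U <- chol_with_jitter(S, 1e-8 * params$sigma^2 + 1e-12)
    lp <- lp + mvn_logpdf_chol(state$zeta, U)
    lp <- lp + log_pc_prior(state$log_rho, state$log_sigma, priors)
  }
  if (!is.finite(lp)) return(-Inf)
  lp
}

# ---------------------------------------------------------------------------
# MCMC engine: elliptical slice for zeta, adaptive RW-MH for the rest
# ---------------------------------------------------------------------------

# One elliptical slice sampling update of zeta ~ N(0, Sigma) against the
# binomial likelihood. U is the upper Cholesky factor of Sigma.
ess_update <- function(zeta, U, loglik_fn) {
  n <- length(zeta)
  nu <- drop(crossprod(U, stats::rnorm(n)))
  logy <- loglik_fn(zeta) + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi; hi <- theta
  repeat {
    prop <- zeta * cos(theta) + nu * sin(theta)
    if (loglik_fn(prop) > logy) return(prop)
    if (theta < 0) lo <- theta else hi <- theta
    theta <- stats::runif(1, lo, hi)
    if (hi - lo < 1e-12) return(zeta)  # degenerate bracket: keep state
  }
}

#' Fit the Bayesian binomial spatial model by MCMC
#'
#' Binomial likelihood with logit link: `logit(p_j) = alpha + X_j beta +
#' zeta_j`, where `zeta` is a zero-mean Gaussian field with Matern
#' covariance (smoothness fixed by `nu`, default 1). Inference uses
#' elliptical slice sampling for `zeta | rest` (exact use of the Gaussian
#' prior), joint adaptive random-walk Metropolis for `(alpha, beta)`, and
#' joint adaptive random-walk Metropolis for `(log rho, log sigma)`.
#' Robbins-Monro adaptation targets 0.234 acceptance and is frozen after
#' burn-in, so the post-burn-in chain is a valid Markov chain. Fully
#' reproducible under `seed`.
#'
#' @param records a `cluster_records` data.frame (>= 10 rows for a spatial
#'   fit).
#' @param X design matrix: a `design_matrix` from [standardize()], a plain
#'   numeric matrix, or `NULL` for an intercept-only model.
#' @param priors a [prior_spec()]. When `NULL`, PC-prior thresholds default
#'   to `rho0 =` 10% of the projected domain diameter and `sigma0 = 1`.
#' @param init optional `matern_params` used as the chain starting value for
#'   the field hyperparameters.
#' @param include_field logical; `FALSE` fits the pure fixed-effects model
#'   (no latent field, no hyperparameters).
#' @param chains number of chains (default 2).
#' @param iter post-burn-in iterations per chain (default 20000).
#' @param burnin burn-in iterations per chain (default 5000).
#' @param thin thinning interval; `NULL` picks the smallest interval that
#'   keeps the total stored values across all parameters within
#'   `store_budget`.
#' @param store_budget storage budget in total stored values (default
#'   150000).
#' @param nu Matern smoothness (fixed during sampling).
#' @param hyper_every update the field hyperparameters every this many
#'   iterations (default 1; 2 halves the dominant Cholesky cost in a
#'   systematic scan that leaves the target invariant).
#' @param seed integer master seed; chain c uses a derived sub-seed.
#' @return an object of class `geoprev_posterior`: stored draws, acceptance
#'   rates, per-parameter summaries (posterior mean and equal-tailed 95%
#'   credible interval), and the training data needed for prediction.
#' @export
fit_mcmc <- function(records, X = NULL, priors = NULL, init = NULL,
                     include_field = TRUE, chains = 2, iter = 20000,
                     burnin = 5000, thin = NULL, store_budget = 150000,
                     nu = 1, hyper_every = 1L, seed = 1) {
  df <- as.data.frame(records)
  y <- df$n_underweight; n_kids <- df$n_children
  n <- length(y)
  if (include_field && n < 10) {
    stop("a spatial fit needs at least 10 clusters", call. = FALSE)
  }
  std <- NULL
  if (inherits(X, "design_matrix")) {
    std <- X
    X <- X$values
  }
  if (is.null(X)) X <- matrix(0, n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  z <- ncol(X)

  proj <- project_equirect(df$lon, df$lat)
  ref_lat <- attr(proj, "ref_lat")
  coords <- unname(proj[, 1:2, drop = FALSE])
  if (is.null(priors)) {
    diam <- if (n > 1) max(stats::dist(coords)) else 1
    priors <- prior_spec(rho0 = max(0.1 * diam, 1e-6))
  }
  if (is.null(init)) {
    diam <- if (n > 1) max(stats::dist(coords)) else 1
    init <- matern_params(max(0.25 * diam, 1e-3), 0.5, nu = nu)
  }
  dvec <- as.vector(stats::dist(coords))

  n_par <- 1L + z + (if (include_field) n + 2L else 0L)
  total_iter <- chains * iter
  if (is.null(thin)) {
    thin <- max(1L, ceiling(total_iter * n_par / store_budget))
  }
  n_store_chain <- floor(iter / thin)

  # empirical-logit start for the intercept
  p_hat <- min(max(sum(y) / sum(n_kids), 1e-3), 1 - 1e-3)

  run_chain <- function(chain_id) {
    set.seed(sub_seed(seed, paste0("mcmc-chain-", chain_id)))
    alpha <- stats::qlogis(p_hat)
    beta <- rep(0, z)
    zeta <- rep(0, n)
    log_rho <- log(init$range_rho)
    log_sigma <- log(max(init$sigma, 1e-3))

    cov_chol <- NULL
    field_logprior <- -Inf
    refresh_cov <- function(lr, ls) {
      rho_c <- exp(lr); sigma_c <- exp(ls)
      rvec <- matern_corr_vec(dvec, sqrt(8 * nu) / rho_c, nu)
      S <- sigma_c^2 * corr_matrix_from_dvec(rvec, n)
      chol_with_jitter(S, 1e-8 * sigma_c^2 + 1e-12)
    }
    if (include_field) {
      cov_chol <- refresh_cov(log_rho, log_sigma)
      field_logprior <- mvn_logpdf_chol(zeta, cov_chol)
    }

    loglik_eta <- function(zz) {
      eta <- alpha + drop(X %*% beta) + zz
      sum(loglik_terms(y, n_kids, eta))
    }
    fixed_logpost <- function(a, b, zz) {
      eta <- a + drop(X %*% b) + zz
      lp <- sum(loglik_terms(y, n_kids, eta))
      if (z) lp <- lp - 0.5 * priors$beta_precision * sum(b^2)
      lp
    }
    cur_fixed_lp <- fixed_logpost(alpha, beta, zeta)
    if (!is.finite(cur_fixed_lp)) {
      stop("non-finite log posterior at initialization", call. = FALSE)
    }

    # Robbins-Monro adapted log step sizes
    ls_fixed <- log(0.1); ls_hyper <- log(0.3)
    acc_fixed <- 0L; acc_hyper <- 0L; n_fixed <- 0L; n_hyper <- 0L

    draws_alpha <- numeric(n_store_chain)
    draws_beta <- matrix(0, n_store_chain, z)
    draws_zeta <- matrix(0, n_store_chain, if (include_field) n else 0)
    draws_lr <- numeric(n_store_chain)
    draws_lsg <- numeric(n_store_chain)
    stored <- 0L

    for (t in seq_len(burnin + iter)) {
      # --- (alpha, beta) joint RW-MH ---
      step <- exp(ls_fixed)
      prop_a <- alpha + step * stats::rnorm(1)
      prop_b <- if (z) beta + step * stats::rnorm(z) else beta
      prop_lp <- fixed_logpost(prop_a, prop_b, zeta)
      accepted <- is.finite(prop_lp) &&
        log(stats::runif(1)) < prop_lp - cur_fixed_lp
      if (accepted) {
        alpha <- prop_a; beta <- prop_b; cur_fixed_lp <- prop_lp
      }
      if (t <= burnin) {
        ls_fixed <- ls_fixed + t^-0.6 * ((accepted) - 0.234)
      } else {
        n_fixed <- n_fixed + 1L; acc_fixed <- acc_fixed + accepted
      }

      if (include_field) {
        # --- zeta | rest via elliptical slice sampling ---
        zeta <- ess_update(zeta, cov_chol, loglik_eta)
        cur_fixed_lp <- fixed_logpost(alpha, beta, zeta)
        field_logprior <- mvn_logpdf_chol(zeta, cov_chol)

        # --- (log rho, log sigma) joint RW-MH ---
        if (t %% hyper_every == 0) {
        step_h <- exp(ls_hyper)
        prop_lr <- log_rho + step_h * stats::rnorm(1)
        prop_ls <- log_sigma + step_h * stats::rnorm(1)
        acc_h <- FALSE
        prop_chol <- tryCatch(refresh_cov(prop_lr, prop_ls),
                              error = function(e) NULL)
        if (!is.null(prop_chol)) {
          prop_fp <- mvn_logpdf_chol(zeta, prop_chol)
          num <- prop_fp + log_pc_prior(prop_lr, prop_ls, priors)
          den <- field_logprior + log_pc_prior(log_rho, log_sigma, priors)
          if (is.finite(num) && log(stats::runif(1)) < num - den) {
            log_rho <- prop_lr; log_sigma <- prop_ls
            cov_chol <- prop_chol; field_logprior <- prop_fp
            acc_h <- TRUE
          }
        }
        if (t <= burnin) {
          ls_hyper <- ls_hyper + t^-0.6 * ((acc_h) - 0.234)
        } else {
          n_hyper <- n_hyper + 1L; acc_hyper <- acc_hyper + acc_h
        }
        }
      }

      if (t > burnin && (t - burnin) %% thin == 0 &&
          stored < n_store_chain) {
        stored <- stored + 1L
        draws_alpha[stored] <- alpha
        if (z) draws_beta[stored, ] <- beta
        if (include_field) {
          draws_zeta[stored, ] <- zeta
          draws_lr[stored] <- log_rho
          draws_lsg[stored] <- log_sigma
        }
      }
    }
    list(alpha = draws_alpha[seq_len(stored)],
         beta = draws_beta[seq_len(stored), , drop = FALSE],
         zeta = draws_zeta[seq_len(stored), , drop = FALSE],
         log_rho = draws_lr[seq_len(stored)],
         log_sigma = draws_lsg[seq_len(stored)],
         acc_fixed = if (n_fixed) acc_fixed / n_fixed else NA_real_,
         acc_hyper = if (n_hyper) acc_hyper / n_hyper else NA_real_)
  }

  chain_results <- lapply(seq_len(chains), run_chain)
  alpha_d <- unlist(lapply(chain_results, `[[`, "alpha"))
  beta_d <- do.call(rbind, lapply(chain_results, `[[`, "beta"))
  zeta_d <- do.call(rbind, lapply(chain_results, `[[`, "zeta"))
  lr_d <- unlist(lapply(chain_results, `[[`, "log_rho"))
  lsg_d <- unlist(lapply(chain_results, `[[`, "log_sigma"))
  colnames(beta_d) <- colnames(X)

  acc <- list(
    fixed = vapply(chain_results, `[[`, numeric(1), "acc_fixed"),
    hyper = vapply(chain_results, `[[`, numeric(1), "acc_hyper"))
  for (blk in names(acc)) {
    r <- acc[[blk]][!is.na(acc[[blk]])]
    if (length(r) && any(r < 0.05 | r > 0.95)) {
      warning(sprintf(
        "acceptance rate for block '%s' outside [0.05, 0.95]: %s",
        blk, paste(sprintf("%.3f", r), collapse = ", ")), call. = FALSE)
    }
  }

  summarize <- function(v) {
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    c(mean = mean(v), lower95 = q[1], upper95 = q[2])
  }
  summ <- rbind(alpha = summarize(alpha_d))
  if (z) {
    bsum <- t(apply(beta_d, 2, summarize))
    rownames(bsum) <- colnames(X)
    summ <- rbind(summ, bsum)
  }
  if (include_field) {
    summ <- rbind(summ,
                  rho = summarize(exp(lr_d)),
                  sigma = summarize(exp(lsg_d)))
  }

  structure(list(
    draws = list(alpha = alpha_d, beta = beta_d, zeta = zeta_d,
                 log_rho = lr_d, log_sigma = lsg_d),
    n_stored = length(alpha_d),
    thin = thin, chains = chains, iter = iter, burnin = burnin,
    include_field = include_field, nu = nu,
    acceptance = acc,
    summaries = summ,
    priors = priors,
    standardization = std,
    data = list(y = y, n = n_kids, X = X, coords_km = coords,
                ref_lat = ref_lat, lon = df$lon, lat = df$lat),
    seed = seed
  ), class = "geoprev_posterior")
}

#' @export
print.geoprev_posterior <- function(x, ...) {
  cat(sprintf(
    "<geoprev_posterior: %d stored draws (%d chain%s), %s latent field>\n",
    x$n_stored, x$chains, if (x$chains > 1) "s" else "",
    if (x$include_field) "with" else "without"))
  print(round(x$summaries, 4))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `geoprev_posterior`.
#' @param ... unused.
#' @return data.frame with posterior mean and equal-tailed 95% credible
#'   interval per parameter, plus a `significant` flag (CrI excludes 0) for
#'   the regression coefficients.
#' @export
summary.geoprev_posterior <- function(object, ...) {
  s <- as.data.frame(object$summaries)
  s$parameter <- rownames(s)
  rownames(s) <- NULL
  s$significant <- s$lower95 > 0 | s$upper95 < 0
  s$significant[s$parameter %in% c("rho", "sigma")] <- NA
  s[, c("parameter", "mean", "lower95", "upper95", "significant")]
}

# ---------------------------------------------------------------------------
# WAIC
# ---------------------------------------------------------------------------

# Column-wise log-sum-exp
col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  m + log(colSums(exp(sweep(M, 2, m))))
}

#' Widely applicable information criterion (WAIC)
#'
#' `lppd = sum_j log mean_s p(y_j | theta_s)` (log-sum-exp over draws),
#' `p_waic = sum_j var_s log p(y_j | theta_s)` (sample variance, n-1),
#' `waic = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param x a `geoprev_posterior`, or a draws-by-observations matrix of
#'   per-draw per-observation log-likelihoods.
#' @param records training records (ignored when `x` is already a fitted
#'   posterior carrying its data, or a log-likelihood matrix).
#' @return list with `waic`, `p_waic`, `lppd`, and the pointwise log-lik
#'   matrix dimensions.
#' @export
waic <- function(x, records = NULL) {
  if (inherits(x, "geoprev_posterior")) {
    ll <- pointwise_loglik(x)
  } else {
    ll <- as.matrix(x)
  }
  if (nrow(ll) < 2) stop("WAIC needs at least 2 stored draws", call. = FALSE)
  lppd <- sum(col_logsumexp(ll) - log(nrow(ll)))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
       n_draws = nrow(ll), n_obs = ncol(ll))
}

# draws x observations matrix of log p(y_j | theta_s)
pointwise_loglik <- function(posterior) {
  d <- posterior$draws
  dat <- posterior$data
  S <- posterior$n_stored
  eta <- matrix(d$alpha, S, length(dat$y))
  if (ncol(dat$X)) eta <- eta + d$beta %*% t(dat$X)
  if (posterior$include_field) eta <- eta + d$zeta
  t(vapply(seq_len(S), function(s) loglik_terms(dat$y, dat$n, eta[s, ]),
           numeric(length(dat$y))))
}

#' Rank fitted models by WAIC
#'
#' @param fits named list of `waic()` results (or of fitted posteriors, in
#'   which case WAIC is computed here).
#' @return data.frame sorted ascending by WAIC (best first) with
#'   `delta_waic` relative to the best model; ties keep the input order.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  labels <- names(fits)
  if (is.null(labels)) labels <- paste0("model", seq_along(fits))
  ws <- lapply(fits, function(f) {
    if (inherits(f, "geoprev_posterior")) waic(f) else f
  })
  tab <- data.frame(
    label = labels,
    waic = vapply(ws, `[[`, numeric(1), "waic"),
    p_waic = vapply(ws, `[[`, numeric(1), "p_waic"),
    lppd = vapply(ws, `[[`, numeric(1), "lppd"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$waic, seq_len(nrow(tab))), , drop = FALSE]
  tab$delta_waic <- tab$waic - tab$waic[1]
  rownames(tab) <- NULL
  tab
}
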