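# ---------------------------------------------------------------------------
# Kriging-style prediction surfaces
# ---------------------------------------------------------------------------

# Exact Gaussian conditional of the latent field at new locations given its
# values at observed locations:
#   mean = S_no S_oo^-1 zeta_obs
#   cov  = S_nn - S_no S_oo^-1 S_on
cond_field_moments <- function(zeta_obs, params, obs_km, new_km,
                               jitter = 1e-8 * params$sigma^2 + 1e-12) {
  obs_km <- as.matrix(obs_km); new_km <- as.matrix(new_km)
  n_obs <- nrow(obs_km); n_new <- nrow(new_km)
  if (params$sigma == 0) {
    return(list(mean = rep(0, n_new), cov = matrix(0, n_new, n_new)))
  }
  cross_dist <- function(A, B) {
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  }
  s2 <- params$sigma^2
  S_oo <- s2 * matern_correlation(cross_dist(obs_km, obs_km), params)
  S_no <- s2 * matern_correlation(cross_dist(new_km, obs_km), params)
  S_nn <- s2 * matern_correlation(cross_dist(new_km, new_km), params)
  U <- chol_with_jitter(S_oo, jitter)
  # S_oo^-1 zeta and S_oo^-1 S_on via the factor
  sol <- function(b) backsolve(U, backsolve(U, b, transpose = TRUE))
  mean_new <- drop(S_no %*% sol(zeta_obs))
  cov_new <- S_nn - S_no %*% sol(t(S_no))
  cov_new <- (cov_new + t(cov_new)) / 2
  list(mean = mean_new, cov = cov_new)
}

#' Conditional draw of the latent field at new locations
#'
#' Kriging update for one posterior state: the exact Gaussian conditional of
#' the zero-mean Matern field at `new_points` given the state's field values
#' at `obs_points`, with one random draw per call. A new point coincident
#' with an observed point reproduces the observed value with (near-)zero
#' variance; a point far beyond the range reverts to the prior
#' (mean 0, variance `sigma^2`).
#'
#' @param zeta_obs field values at the observed locations (one posterior
#'   state).
#' @param params a [matern_params()] for that state.
#' @param obs_points,new_points matrices/data.frames of projected `x`, `y`
#'   km coordinates (same projection for both).
#' @param seed optional seed for the conditional noise.
#' @param draw logical; `FALSE` returns the conditional mean and covariance
#'   without sampling.
#' @return if `draw`, a numeric vector of field values at `new_points`
#'   (attributes `mean` and `var` carry the conditional moments); otherwise
#'   a list with `mean` and `cov`.
#' @export
conditional_field <- function(zeta_obs, params, obs_points, new_points,
                              seed = NULL, draw = TRUE) {
  mom <- cond_field_moments(zeta_obs, params, obs_points, new_points)
  if (!draw) return(mom)
  if (!is.null(seed)) set.seed(seed)
  n_new <- length(mom$mean)
  v <- pmax(diag(mom$cov), 0)
  if (all(v < 1e-14)) {
    out <- mom$mean
  } else {
    U <- chol_with_jitter(mom$cov, 1e-10 * max(v))
    out <- mom$mean + drop(crossprod(U, stats::rnorm(n_new)))
  }
  attr(out, "mean") <- mom$mean
  attr(out, "var") <- v
  out
}

#' Posterior prevalence prediction surface
#'
#' For each retained posterior draw s and grid cell g the linear predictor
#' `eta_g^s = alpha^s + X_g beta^s + zeta_g^s` is formed -- with `zeta_g^s`
#' a conditional (kriging) draw of the latent field given that state's
#' field at the data locations -- and back-transformed to the probability
#' scale. The surface reports the per-cell posterior mean and equal-tailed
#' 95% interval over draws. Grid covariates are standardized with the SAME
#' constants as the training design matrix. Cells with nodata covariates
#' are nodata in the output.
#'
#' @param posterior a `geoprev_posterior` from [fit_mcmc()].
#' @param grids list of `covariate_grid` layers; must cover every training
#'   covariate by name (extra layers are ignored). May be empty for an
#'   intercept-only model.
#' @param n_draws number of posterior draws used (default 200, thinned
#'   evenly from the stored draws).
#' @param seed seed for the conditional-field noise.
#' @return object of class `prediction_surface`: grid geometry plus
#'   matrices `mean_prevalence`, `lower95`, `upper95` and `n_draws_used`.
#' @export
predict_surface <- function(posterior, grids, n_draws = 200, seed = 1) {
  stopifnot(inherits(posterior, "geoprev_posterior"))
  if (inherits(grids, "covariate_grid")) grids <- list(grids)
  train_cols <- colnames(posterior$data$X)
  if (length(train_cols)) {
    grid_names <- vapply(grids, function(g) g$name, character(1))
    if (!all(train_cols %in% grid_names)) {
      stop("prediction grids are missing training covariate(s): ",
           paste(setdiff(train_cols, grid_names), collapse = ", "),
           call. = FALSE)
    }
    grids <- grids[match(train_cols, grid_names)]
  }
  if (!length(grids)) {
    stop("at least one grid is required to define the prediction lattice",
         call. = FALSE)
  }
  g1 <- grids[[1]]
  centers <- grid_cell_centers(g1)
  n_cells <- nrow(centers)

  # raw covariates per cell; nodata cells masked out
  ok <- rep(TRUE, n_cells)
  X_raw <- matrix(0, n_cells, length(train_cols))
  colnames(X_raw) <- train_cols
  for (k in seq_along(train_cols)) {
    vals <- grids[[k]]$values[cbind(centers$row, centers$col)]
    ok <- ok & vals != grids[[k]]$nodata_flag
    X_raw[, k] <- vals
  }
  Xg <- if (length(train_cols)) {
    if (!is.null(posterior$standardization)) {
      apply_standardization(posterior$standardization, X_raw)
    } else X_raw
  } else matrix(0, n_cells, 0)

  S <- posterior$n_stored
  use <- if (S <= n_draws) seq_len(S) else
    unique(round(seq(1, S, length.out = n_draws)))
  d <- posterior$draws

  obs_km <- posterior$data$coords_km
  ref_lat <- posterior$data$ref_lat
  new_proj <- project_equirect(centers$lon[ok], centers$lat[ok], ref_lat)

  P <- matrix(NA_real_, length(use), n_cells)
  set.seed(sub_seed(seed, "surface-draws"))
  for (si in seq_along(use)) {
    s <- use[si]
    eta <- rep(d$alpha[s], n_cells)
    if (length(train_cols)) eta <- eta + drop(Xg %*% d$beta[s, ])
    if (posterior$include_field) {
      params_s <- matern_params(exp(d$log_rho[s]), exp(d$log_sigma[s]),
                                nu = posterior$nu)
      zeta_new <- conditional_field(d$zeta[s, ], params_s, obs_km, new_proj)
      eta[ok] <- eta[ok] + zeta_new
    }
    P[si, ] <- stats::plogis(eta)
  }
  P[, !ok] <- NA_real_

  q <- apply(P, 2, function(col) {
    if (anyNA(col)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(col), stats::quantile(col, c(0.025, 0.975), names = FALSE))
  })
  shape <- function(v) {
    m <- matrix(v, g1$n_rows, g1$n_cols, byrow = TRUE)
    m
  }
  structure(list(
    name = "prevalence",
    origin_lon = g1$origin_lon, origin_lat = g1$origin_lat,
    cell_size = g1$cell_size, n_rows = g1$n_rows, n_cols = g1$n_cols,
    nodata_flag = g1$nodata_flag,
    mean_prevalence = shape(q[1, ]),
    lower95 = shape(q[2, ]),
    upper95 = shape(q[3, ]),
    n_draws_used = length(use)
  ), class = "prediction_surface")
}

#' @export
print.prediction_surface <- function(x, ...) {
  m <- x$mean_prevalence
  cat(sprintf(
    "<prediction_surface: %d x %d cells, %d draws; mean prevalence %.3f (cell range %.3f-%.3f)>\n",
    x$n_rows, x$n_cols, x$n_draws_used, mean(m, na.rm = TRUE),
    min(m, na.rm = TRUE), max(m, na.rm = TRUE)))
  invisible(x)
}

#' Write the three bands of a prediction surface as text rasters
#'
#' @param surface a `prediction_surface`.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"surface"`).
#' @return character vector of paths, invisibly.
#' @export
write_surface <- function(surface, dir, prefix = "surface") {
  bands <- c(mean = "mean_prevalence", lower95 = "lower95",
             upper95 = "upper95")
  paths <- character(0)
  for (b in names(bands)) {
    vals <- surface[[bands[[b]]]]
    vals[is.na(vals)] <- surface$nodata_flag
    g <- covariate_grid(paste0(prefix, "_", b), surface$origin_lon,
                        surface$origin_lat, surface$cell_size, vals,
                        surface$nodata_flag)
    p <- file.path(dir, paste0(prefix, "_", b, ".asc"))
    write_raster(g, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
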