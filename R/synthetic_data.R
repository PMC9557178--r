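# ---------------------------------------------------------------------------
# Synthetic DHS-like data with known ground truth
# ---------------------------------------------------------------------------

DEFAULT_WAVE_COUNTS <- c(535L, 517L, 571L, 619L, 305L)
DEFAULT_WAVE_LABELS <- c("2000", "2005", "2011", "2016", "2019")

#' Derive a stable component sub-seed from a master seed
#'
#' Deterministic 31-bit hash of `(seed, name)` so that each generator
#' component draws from its own reproducible stream. Stable across sessions
#' and platforms.
#'
#' @param seed non-negative integer master seed.
#' @param name component name.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), seed >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Default grid geometry for synthetic runs
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param origin_lon,origin_lat top-left cell-center coordinates (degrees).
#' @param cell_size degrees per cell.
#' @return a plain list understood by the simulators.
#' @export
grid_spec <- function(n_rows = 50, n_cols = 50, origin_lon = 34,
                      origin_lat = 14, cell_size = 0.2) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
       origin_lon = origin_lon, origin_lat = origin_lat,
       cell_size = cell_size)
}

#' Simulate smooth standardized covariate surfaces
#'
#' Each layer is white noise smoothed with a separable Gaussian kernel of
#' length scale `smoothness_range` (degrees) over cell-center distance, then
#' standardized to mean 0 and SD 1 (population convention) across cells.
#' Layers are mutually independent given distinct sub-seeds. Stands in for
#' gridded environmental covariates (temperature, precipitation, travel
#' time, ...).
#'
#' @param n_layers number of layers (>= 1).
#' @param spec a [grid_spec()] (dims >= 2x2).
#' @param smoothness_range kernel length scale in degrees (> 0); values much
#'   smaller than the cell size give essentially independent cells.
#' @param seed master seed.
#' @param names layer names; default `cov1`, `cov2`, ...
#' @return list of `covariate_grid` objects.
#' @export
simulate_covariate_surfaces <- function(n_layers, spec, smoothness_range,
                                        seed, names = NULL) {
  stopifnot(n_layers >= 1, spec$n_rows >= 2, spec$n_cols >= 2)
  if (!is.finite(smoothness_range) || smoothness_range <= 0) {
    stop("smoothness_range must be > 0", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("cov", seq_len(n_layers))
  stopifnot(length(names) == n_layers)

  kernel_1d <- function(k) {
    # Gaussian weights between cell centers along one axis
    d <- outer(seq_len(k), seq_len(k),
               function(i, j) (i - j) * spec$cell_size)
    K <- exp(-d^2 / (2 * smoothness_range^2))
    sweep(K, 1, rowSums(K), "/")
  }
  Kr <- kernel_1d(spec$n_rows)
  Kc <- kernel_1d(spec$n_cols)

  lapply(seq_len(n_layers), function(l) {
    set.seed(sub_seed(seed, paste0("covariate-", names[l])))
    W <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                spec$n_rows, spec$n_cols)
    Sm <- Kr %*% W %*% t(Kc)
    mu <- mean(Sm)
    sd_pop <- sqrt(mean((Sm - mu)^2))
    vals <- if (sd_pop > 0) (Sm - mu) / sd_pop else Sm * 0
    covariate_grid(names[l], spec$origin_lon, spec$origin_lat,
                   spec$cell_size, vals)
  })
}

#' Simulate multi-wave cluster locations
#'
#' Cluster locations are uniform over the grid bounding box; per-wave counts
#' default to the five-survey design 535, 517, 571, 619, 305 (2,547 in
#' total).
#'
#' @param counts_per_wave integer vector of cluster counts, one per wave.
#' @param spec a [grid_spec()].
#' @param seed master seed.
#' @param waves wave labels (default `"2000"`, `"2005"`, `"2011"`, `"2016"`,
#'   `"2019"`).
#' @return data.frame with `lon`, `lat`, `wave`.
#' @export
simulate_clusters <- function(counts_per_wave = DEFAULT_WAVE_COUNTS, spec,
                              seed, waves = NULL) {
  if (!length(counts_per_wave)) {
    stop("counts_per_wave must be non-empty", call. = FALSE)
  }
  if (any(counts_per_wave < 1)) {
    stop("all per-wave counts must be >= 1", call. = FALSE)
  }
  if (is.null(waves)) {
    waves <- if (length(counts_per_wave) == length(DEFAULT_WAVE_LABELS))
      DEFAULT_WAVE_LABELS else as.character(seq_along(counts_per_wave))
  }
  stopifnot(length(waves) == length(counts_per_wave))
  g <- covariate_grid("bbox", spec$origin_lon, spec$origin_lat,
                      spec$cell_size,
                      matrix(0, spec$n_rows, spec$n_cols))
  bb <- grid_bbox(g)
  total <- sum(counts_per_wave)
  set.seed(sub_seed(seed, "cluster-locations"))
  data.frame(
    lon = stats::runif(total, bb$lon_min, bb$lon_max),
    lat = stats::runif(total, bb$lat_min, bb$lat_max),
    wave = rep(as.character(waves), counts_per_wave),
    stringsAsFactors = FALSE
  )
}

#' Simulate the latent Matern field at point locations
#'
#' Exact multivariate normal draw with mean 0 and covariance from
#' [build_covariance()] over the equirectangular projection of the points.
#' Duplicate points are allowed (the diagonal jitter keeps the covariance
#' valid). `sigma = 0` returns a zero field.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param params a [matern_params()].
#' @param seed master seed.
#' @return numeric vector, one field value per point.
#' @export
simulate_field <- function(points, params, seed) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  stopifnot(n >= 1)
  if (params$sigma == 0) return(rep(0, n))
  coords <- project_equirect(pts$lon, pts$lat)
  S <- build_covariance(coords, params)
  U <- chol_with_jitter(S, 0)
  set.seed(sub_seed(seed, "matern-field"))
  drop(crossprod(U, stats::rnorm(n)))
}

#' Simulate binomial cluster outcomes from known truth
#'
#' `p_j = plogis(alpha + X_j beta + zeta_j)` and
#' `Y_j ~ Binomial(n_j, p_j)`; cluster sizes are drawn uniformly from
#' `children_per_cluster` (a fixed integer or an inclusive `[min, max]`
#' range, default 5-25).
#'
#' @param points data.frame with `lon`, `lat`.
#' @param waves wave label per point.
#' @param design numeric covariate matrix, rows matching `points`.
#' @param truth a `synthetic_truth` (see [synthetic_truth()]).
#' @param children_per_cluster integer scalar or length-2 range.
#' @param seed master seed.
#' @param region_ids optional region label per point (default `"R1"`).
#' @return a `cluster_records` data.frame.
#' @export
simulate_outcomes <- function(points, waves, design, truth,
                              children_per_cluster = c(5L, 25L), seed,
                              region_ids = NULL) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  design <- as.matrix(design)
  if (nrow(design) != n) {
    stop("design rows must match the number of points", call. = FALSE)
  }
  if (length(truth$beta_true) != ncol(design)) {
    stop("length(beta_true) must match the number of design columns",
         call. = FALSE)
  }
  if (length(truth$field_values) != n) {
    stop("truth$field_values must have one value per point", call. = FALSE)
  }
  rng <- if (length(children_per_cluster) == 1)
    rep(children_per_cluster, 2) else sort(children_per_cluster[1:2])
  eta <- truth$alpha_true + drop(design %*% truth$beta_true) +
    truth$field_values
  p <- stats::plogis(eta)
  set.seed(sub_seed(seed, "binomial-outcomes"))
  n_kids <- sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) + rng[1] - 1L
  y <- stats::rbinom(n, n_kids, p)
  cluster_records(data.frame(
    cluster_id = seq_len(n),
    wave = as.character(waves),
    lon = pts$lon, lat = pts$lat,
    n_children = n_kids, n_underweight = y,
    region_id = if (is.null(region_ids)) "R1" else as.character(region_ids),
    stringsAsFactors = FALSE
  ))
}

#' Bundle the generating values of a synthetic dataset
#'
#' @param alpha_true intercept on the logit scale.
#' @param beta_true coefficient vector, one per covariate layer.
#' @param matern_true a [matern_params()].
#' @param field_values latent field at every generated cluster location.
#' @param seed master seed used throughout the generation.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(alpha_true, beta_true, matern_true, field_values,
                            seed) {
  stopifnot(all(is.finite(field_values)), inherits(matern_true,
                                                   "matern_params"))
  structure(list(alpha_true = alpha_true, beta_true = beta_true,
                 matern_true = matern_true, field_values = field_values,
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate a complete synthetic multi-wave dataset
#'
#' One call producing covariate surfaces, cluster locations, the latent
#' Matern field, and binomial outcomes, with the generating truth attached.
#' Defaults emulate the five-survey design: wave cluster counts 535, 517,
#' 571, 619, 305; cluster sizes uniform on \[5, 25\]; intercept -0.55 on the
#' logit scale (pooled prevalence around 37% at covariate means) and
#' realistic effect sizes (e.g. -0.39 on a standardized temperature-like
#' layer, +0.09 on a travel-time-like layer).
#'
#' @param counts_per_wave per-wave cluster counts.
#' @param spec a [grid_spec()].
#' @param n_layers number of covariate layers; defaults to
#'   `length(beta_true)`.
#' @param alpha_true generating intercept.
#' @param beta_true generating coefficients.
#' @param matern_true generating field parameters; default range = 25% of
#'   the projected domain diameter, sigma 0.5, nu 1.
#' @param smoothness_range covariate smoothing length scale (degrees);
#'   default 5 cells.
#' @param children_per_cluster cluster-size range.
#' @param seed master seed.
#' @param covariate_names layer names.
#' @return list with `records`, `grids`, `design` (raw extracted covariate
#'   matrix), `points`, and `truth`.
#' @export
simulate_dataset <- function(counts_per_wave = DEFAULT_WAVE_COUNTS,
                             spec = grid_spec(),
                             alpha_true = -0.55,
                             beta_true = c(-0.39, 0.09),
                             n_layers = length(beta_true),
                             matern_true = NULL,
                             smoothness_range = 5 * spec$cell_size,
                             children_per_cluster = c(5L, 25L),
                             seed = 1,
                             covariate_names = NULL) {
  stopifnot(n_layers == length(beta_true))
  grids <- simulate_covariate_surfaces(n_layers, spec, smoothness_range,
                                       seed, names = covariate_names)
  pts <- simulate_clusters(counts_per_wave, spec, seed)
  if (is.null(matern_true)) {
    proj <- project_equirect(pts$lon, pts$lat)
    diam <- max(stats::dist(proj))
    matern_true <- matern_params(0.25 * diam, 0.5, nu = 1)
  }
  zeta <- simulate_field(pts, matern_true, seed)
  truth <- synthetic_truth(alpha_true, beta_true, matern_true, zeta, seed)
  design <- extract_covariates(grids, pts)
  records <- simulate_outcomes(pts, pts$wave, design, truth,
                               children_per_cluster, seed)
  list(records = records, grids = grids, design = design, points = pts,
       truth = truth)
}

#' Write a synthetic truth sidecar as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    alpha_true = truth$alpha_true,
    beta_true = truth$beta_true,
    matern_true = list(range_rho = truth$matern_true$range_rho,
                       sigma = truth$matern_true$sigma,
                       nu = truth$matern_true$nu),
    field_values = truth$field_values,
    seed = truth$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
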