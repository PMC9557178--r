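# Small programmatic fixtures shared across test files.

toy_clusters <- function() {
  cluster_records(data.frame(
    cluster_id = 1:6,
    wave = c("2000", "2000", "2005", "2000", "2005", "2005"),
    lon = c(36.1, 37.2, 38.3, 36.4, 39.5, 37.6),
    lat = c(7.1, 8.2, 9.3, 7.4, 8.5, 9.6),
    n_children = c(2L, 6L, 10L, 4L, 8L, 5L),
    n_underweight = c(1L, 0L, 3L, 1L, 2L, 0L),
    region_id = c("A", "A", "B", "B", "A", "B"),
    stringsAsFactors = FALSE
  ))
}

# grid whose value at (row, col) is a known function of the indices
indexed_grid <- function(n_rows = 4, n_cols = 5, origin_lon = 30,
                         origin_lat = 10, cell_size = 0.5,
                         f = function(r, c) 100 * r + c) {
  vals <- outer(seq_len(n_rows), seq_len(n_cols), f)
  covariate_grid("idx", origin_lon, origin_lat, cell_size, vals)
}

unit_square_polygon <- function(id = "SQ", x0 = 0, y0 = 0, w = 1, h = 1) {
  ring <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h),
                c(x0, y0 + h), c(x0, y0))
  region_polygon(id, ring)
}

# independent winding-number point-in-polygon oracle (crossing form)
winding_inside <- function(lon, lat, rings) {
  wn <- 0L
  for (ring in rings) {
    n <- nrow(ring) - 1L
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      if (y1 <= lat) {
        if (y2 > lat &&
            (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1) > 0) {
          wn <- wn + 1L
        }
      } else if (y2 <= lat &&
                 (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1) < 0) {
        wn <- wn - 1L
      }
    }
  }
  wn != 0L
}

# records for a given vector of (y, n) at arbitrary locations
records_from_counts <- function(y, n, wave = "2000", region = "A") {
  k <- length(y)
  cluster_records(data.frame(
    cluster_id = seq_len(k), wave = wave,
    lon = seq(30, 31, length.out = k), lat = seq(5, 6, length.out = k),
    n_children = n, n_underweight = y, region_id = region,
    stringsAsFactors = FALSE
  ))
}

# deterministic grid-quadrature posterior moments for an intercept-only,
# no-field binomial model with a flat prior on alpha
quad_posterior_alpha <- function(y, n, lo = -8, hi = 8, len = 40001) {
  a <- seq(lo, hi, length.out = len)
  lp <- y * a - n * log1p(exp(a))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * a)
  list(mean = m, var = sum(w * (a - m)^2))
}
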