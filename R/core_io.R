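# ---------------------------------------------------------------------------
# Cluster records
# ---------------------------------------------------------------------------

CLUSTER_COLUMNS <- c("cluster_id", "wave", "lon", "lat",
                     "n_children", "n_underweight", "region_id")

#' Construct and validate a table of survey cluster records
#'
#' A cluster record describes one georeferenced survey cluster (a DHS-style
#' enumeration area): how many children were measured (`n_children`), how
#' many were underweight (`n_underweight`), where the cluster sits
#' (`lon`/`lat`, geographic degrees), which survey wave it belongs to, and an
#' administrative region label.
#'
#' @param df data.frame with columns `cluster_id`, `wave`, `lon`, `lat`,
#'   `n_children`, `n_underweight`, `region_id`.
#' @return the validated data.frame with class `cluster_records`.
#' @export
cluster_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CLUSTER_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("cluster table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, CLUSTER_COLUMNS, drop = FALSE]
  df$cluster_id <- as.integer(df$cluster_id)
  df$wave <- as.character(df$wave)
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  df$n_children <- as.integer(df$n_children)
  df$n_underweight <- as.integer(df$n_underweight)
  df$region_id <- as.character(df$region_id)
  validate_clusters(df)
  class(df) <- c("cluster_records", "data.frame")
  df
}

validate_clusters <- function(df) {
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("invalid cluster record at row %d: %s", idx[1], what),
           call. = FALSE)
    }
  }
  bad_row(is.na(df$n_children) | df$n_children < 1L,
          "n_children must be a positive integer")
  bad_row(is.na(df$n_underweight) | df$n_underweight < 0L,
          "n_underweight must be non-negative")
  bad_row(df$n_underweight > df$n_children,
          "n_underweight exceeds n_children")
  bad_row(is.na(df$lon) | df$lon < -180 | df$lon > 180,
          "lon outside [-180, 180]")
  bad_row(is.na(df$lat) | df$lat < -90 | df$lat > 90,
          "lat outside [-90, 90]")
  key <- paste(df$cluster_id, df$wave, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (cluster_id, wave) pair at row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  invisible(df)
}

#' Read cluster records from a CSV file
#'
#' Expects a header row naming at least the seven required columns
#' (`cluster_id,wave,lon,lat,n_children,n_underweight,region_id`). Row order
#' is preserved and every row is validated.
#'
#' @param path path to a delimited text file.
#' @return a `cluster_records` data.frame.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  cluster_records(df)
}

#' Write cluster records to CSV
#'
#' @param records a `cluster_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(records, path) {
  stopifnot(inherits(records, "cluster_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Covariate grids (regular raster lattices)
# ---------------------------------------------------------------------------

#' Construct a covariate grid
#'
#' A regular raster lattice holding one covariate layer. The grid is
#' registered by the CENTER of the top-left (north-west) cell; rows run
#' north to south (row 1 = northernmost), columns west to east, and the cell
#' size is equal in both axes (degrees).
#'
#' @param name covariate label.
#' @param origin_lon,origin_lat coordinates of the top-left cell center.
#' @param cell_size degrees per cell, equal in both axes.
#' @param values numeric matrix, `n_rows` x `n_cols`, row 1 = north.
#' @param nodata_flag sentinel value used for missing cells (default -9999).
#' @return an object of class `covariate_grid`.
#' @export
covariate_grid <- function(name, origin_lon, origin_lat, cell_size, values,
                           nodata_flag = -9999) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive number", call. = FALSE)
  }
  if (any(!is.finite(values) & values != nodata_flag, na.rm = TRUE) ||
      anyNA(values)) {
    stop("grid values must be finite or equal to the nodata flag",
         call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    origin_lon = as.numeric(origin_lon),
    origin_lat = as.numeric(origin_lat),
    cell_size = as.numeric(cell_size),
    n_rows = nrow(values),
    n_cols = ncol(values),
    values = values,
    nodata_flag = as.numeric(nodata_flag)
  ), class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf("<covariate_grid '%s': %d x %d cells, %.6g deg/cell, origin (%.4f, %.4f)>\n",
              x$name, x$n_rows, x$n_cols, x$cell_size,
              x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid a `covariate_grid`.
#' @return data.frame with `lon`, `lat`, `row`, `col` in row-major order
#'   (row 1 first, west to east within a row).
#' @export
grid_cell_centers <- function(grid) {
  stopifnot(inherits(grid, "covariate_grid"))
  rows <- seq_len(grid$n_rows)
  cols <- seq_len(grid$n_cols)
  expand <- expand.grid(col = cols, row = rows)
  data.frame(
    lon = grid$origin_lon + (expand$col - 1L) * grid$cell_size,
    lat = grid$origin_lat - (expand$row - 1L) * grid$cell_size,
    row = expand$row,
    col = expand$col
  )
}

grid_bbox <- function(grid) {
  h <- grid$cell_size / 2
  list(
    lon_min = grid$origin_lon - h,
    lon_max = grid$origin_lon + (grid$n_cols - 1L) * grid$cell_size + h,
    lat_min = grid$origin_lat - (grid$n_rows - 1L) * grid$cell_size - h,
    lat_max = grid$origin_lat + h
  )
}

# Nearest cell under the documented rule: axes are separable, so the nearest
# cell is (nearest row, nearest col); exact ties go to the smaller index.
nearest_cell <- function(grid, lon, lat) {
  col_f <- (lon - grid$origin_lon) / grid$cell_size + 1
  row_f <- (grid$origin_lat - lat) / grid$cell_size + 1
  # round halves DOWN so the tie goes to the smaller index
  col <- ceiling(col_f - 0.5)
  row <- ceiling(row_f - 0.5)
  col <- pmin(pmax(col, 1L), grid$n_cols)
  row <- pmin(pmax(row, 1L), grid$n_rows)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract covariate values at point locations (nearest-cell rule)
#'
#' Builds the design-matrix columns for a set of point locations by looking
#' up, in each grid, the value of the cell whose center is nearest the point.
#' A point exactly equidistant between cells is assigned the cell with the
#' smaller (row, col) index pair. Column order follows the grid list order.
#'
#' @param grids list of `covariate_grid` objects sharing geometry.
#' @param points data.frame or matrix with columns `lon`, `lat`.
#' @return numeric matrix, `nrow(points)` x `length(grids)`, with grid names
#'   as column names.
#' @export
extract_covariates <- function(grids, points) {
  if (inherits(grids, "covariate_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1)
  pts <- as.data.frame(points)
  stopifnot(all(c("lon", "lat") %in% names(pts)))
  g1 <- grids[[1]]
  for (g in grids) {
    same <- isTRUE(all.equal(c(g$origin_lon, g$origin_lat, g$cell_size,
                               g$n_rows, g$n_cols),
                             c(g1$origin_lon, g1$origin_lat, g1$cell_size,
                               g1$n_rows, g1$n_cols)))
    if (!same) stop("all grids must share origin, cell size and dimensions",
                    call. = FALSE)
  }
  bb <- grid_bbox(g1)
  out_of_bounds <- pts$lon < bb$lon_min | pts$lon > bb$lon_max |
    pts$lat < bb$lat_min | pts$lat > bb$lat_max
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    stop(sprintf("point (%g, %g) falls outside the grid extent",
                 pts$lon[i], pts$lat[i]), call. = FALSE)
  }
  rc <- nearest_cell(g1, pts$lon, pts$lat)
  out <- matrix(NA_real_, nrow(pts), length(grids))
  colnames(out) <- vapply(grids, function(g) g$name, character(1))
  for (k in seq_along(grids)) {
    vals <- grids[[k]]$values[cbind(rc[, "row"], rc[, "col"])]
    if (any(vals == grids[[k]]$nodata_flag)) {
      i <- which(vals == grids[[k]]$nodata_flag)[1]
      stop(sprintf(
        "missing covariate '%s' at point (%g, %g): nearest cell is nodata",
        grids[[k]]$name, pts$lon[i], pts$lat[i]), call. = FALSE)
    }
    out[, k] <- vals
  }
  out
}

#' Read a covariate grid from the portable text raster dialect
#'
#' The dialect is an ESRI-ASCII-like plain-text format with a six-line
#' header (`ncols`, `nrows`, `origin_lon`, `origin_lat`, `cellsize`,
#' `nodata_value`; origin = top-left CELL CENTER) followed by the value
#' matrix, one row per line, north first.
#'
#' @param path input path.
#' @param name covariate label; defaults to the file name without extension.
#' @return a `covariate_grid`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "origin_lon", "origin_lat", "cellsize",
            "nodata_value")
  if (!all(need %in% names(header))) {
    stop("raster header must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("raster body has %d values, expected %d",
                 length(vals), nr * nc), call. = FALSE)
  }
  covariate_grid(
    name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name,
    origin_lon = header$origin_lon, origin_lat = header$origin_lat,
    cell_size = header$cellsize,
    values = matrix(vals, nr, nc, byrow = TRUE),
    nodata_flag = header$nodata_value
  )
}

#' Write a covariate grid in the portable text raster dialect
#'
#' @param grid a `covariate_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "covariate_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("origin_lon", format(grid$origin_lon, digits = 17)),
    paste("origin_lat", format(grid$origin_lat, digits = 17)),
    paste("cellsize", format(grid$cell_size, digits = 17)),
    paste("nodata_value", format(grid$nodata_flag, digits = 17))
  ), con)
  writeLines(apply(grid$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Region polygons
# ---------------------------------------------------------------------------

#' Construct a region polygon
#'
#' @param region_id label.
#' @param rings list of closed coordinate rings; each a two-column
#'   (lon, lat) matrix with at least 4 vertices, first vertex == last.
#'   The first ring is the outer boundary; additional rings are holes.
#' @return an object of class `region_polygon`.
#' @export
region_polygon <- function(region_id, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2)
    if (nrow(r) < 4 || !isTRUE(all.equal(r[1, ], r[nrow(r), ],
                                         check.attributes = FALSE))) {
      stop("each ring needs >= 4 vertices with first == last", call. = FALSE)
    }
    storage.mode(r) <- "double"
    colnames(r) <- c("lon", "lat")
    r
  })
  structure(list(region_id = as.character(region_id), rings = rings),
            class = "region_polygon")
}

# Even-odd rule point-in-polygon over all rings (holes flip parity).
point_in_polygon <- function(lon, lat, polygon) {
  inside <- FALSE
  for (ring in polygon$rings) {
    n <- nrow(ring) - 1L
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2]; yj <- ring[j, 2]
      xi <- ring[i, 1]; xj <- ring[j, 1]
      if ((yi > lat) != (yj > lat)) {
        x_cross <- xi + (lat - yi) / (yj - yi) * (xj - xi)
        if (lon < x_cross) inside <- !inside
        else if (lon == x_cross) return(TRUE)  # exactly on an edge
      } else if (yi == lat && yj == lat &&
                 lon >= min(xi, xj) && lon <= max(xi, xj)) {
        return(TRUE)  # on a horizontal edge
      }
      j <- i
    }
  }
  inside
}

#' Assign points to administrative regions
#'
#' Even-odd point-in-polygon test. Polygons are considered in ascending
#' `region_id` order, and a point on a shared boundary goes to the first
#' polygon containing it; a point inside no polygon gets the sentinel
#' `"UNASSIGNED"` (never an error).
#'
#' @param points data.frame or matrix with columns `lon`, `lat`.
#' @param polygons list of `region_polygon` objects.
#' @return character vector of region ids, one per point.
#' @export
assign_regions <- function(points, polygons) {
  pts <- as.data.frame(points)
  stopifnot(all(c("lon", "lat") %in% names(pts)))
  ids <- vapply(polygons, function(p) p$region_id, character(1))
  polygons <- polygons[order(ids)]
  ids <- ids[order(ids)]
  out <- rep("UNASSIGNED", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    for (k in seq_along(polygons)) {
      if (point_in_polygon(pts$lon[i], pts$lat[i], polygons[[k]])) {
        out[i] <- ids[k]
        break
      }
    }
  }
  out
}

#' Read region polygons from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features carrying a `region_id`
#' property. MultiPolygon parts are flattened into one ring list.
#'
#' @param path input path.
#' @return list of `region_polygon` objects.
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  lapply(feats, function(f) {
    geom <- f$geometry
    rid <- f$properties$region_id
    if (is.null(rid)) stop("feature lacks a region_id property", call. = FALSE)
    ring_from_coords <- function(cc) {
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    }
    rings <- switch(
      geom$type,
      Polygon = lapply(geom$coordinates, ring_from_coords),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_from_coords)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    region_polygon(rid, rings)
  })
}

#' Write region polygons as GeoJSON
#'
#' @param polygons list of `region_polygon` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    coords <- lapply(p$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(region_id = p$region_id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Projection
# ---------------------------------------------------------------------------

EARTH_RADIUS_KM <- 6371

#' Project geographic coordinates to planar kilometers
#'
#' Equirectangular approximation centered on a reference latitude:
#' `x = R * dlon * cos(lat_ref)`, `y = R * dlat` with `R = 6371` km and
#' angles in radians. Adequate at country scale; all model distances are
#' computed in this projection.
#'
#' @param lon,lat coordinates in degrees.
#' @param ref_lat reference latitude (degrees); defaults to `mean(lat)`.
#' @return matrix with columns `x`, `y` (km) and attribute `ref_lat`.
#' @export
project_equirect <- function(lon, lat, ref_lat = mean(lat)) {
  to_rad <- pi / 180
  out <- cbind(x = EARTH_RADIUS_KM * lon * to_rad * cos(ref_lat * to_rad),
               y = EARTH_RADIUS_KM * lat * to_rad)
  attr(out, "ref_lat") <- ref_lat
  out
}
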