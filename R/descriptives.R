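# ---------------------------------------------------------------------------
# Descriptive prevalence tables and trend statistics
# ---------------------------------------------------------------------------

# Round half away from zero at `digits` decimals (presentation only).
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Region-by-wave prevalence table (count-weighted)
#'
#' Aggregates cluster records to child-weighted prevalences: counts are
#' summed within each region x wave cell (never averaged over cluster
#' proportions), a `NATIONAL` row aggregates all regions, and a `pooled`
#' column aggregates all waves. Records with no region keep their
#' `UNASSIGNED` label and form their own row. No survey weights are
#' applied.
#'
#' @param records a `cluster_records` data.frame (non-empty).
#' @return long-format data.frame of class `prevalence_table` with columns
#'   `region_id` (including `"NATIONAL"`), `wave` (including `"pooled"`),
#'   `n_children`, `n_underweight`, `prevalence_percent` (exact, unrounded).
#' @export
prevalence_table <- function(records) {
  df <- as.data.frame(records)
  stopifnot(nrow(df) >= 1)
  cell <- function(sub, region, wave) {
    data.frame(region_id = region, wave = wave,
               n_children = sum(sub$n_children),
               n_underweight = sum(sub$n_underweight),
               stringsAsFactors = FALSE)
  }
  regions <- sort(unique(df$region_id))
  waves <- sort(unique(df$wave))
  rows <- list()
  for (r in c(regions, "NATIONAL")) {
    sub_r <- if (r == "NATIONAL") df else df[df$region_id == r, ,
                                             drop = FALSE]
    for (w in c(waves, "pooled")) {
      sub <- if (w == "pooled") sub_r else sub_r[sub_r$wave == w, ,
                                                 drop = FALSE]
      if (nrow(sub)) rows[[length(rows) + 1L]] <- cell(sub, r, w)
    }
  }
  out <- do.call(rbind, rows)
  out$prevalence_percent <- 100 * out$n_underweight / out$n_children
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' @export
print.prevalence_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$prevalence_percent <- format(round_half_away(df$prevalence_percent, 1),
                                  nsmall = 1)
  wide <- stats::reshape(
    df[, c("region_id", "wave", "prevalence_percent")],
    idvar = "region_id", timevar = "wave", direction = "wide")
  names(wide) <- sub("^prevalence_percent\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Total percentage reduction between two prevalences
#'
#' `100 * (p_start - p_end) / p_start`, e.g. a fall from 44.7% to 23.8%
#' is a total reduction rate of 46.8%.
#'
#' @param p_start starting prevalence in percent (> 0).
#' @param p_end ending prevalence in percent.
#' @param digits decimals for presentation rounding (half away from zero);
#'   default 1.
#' @return reduction rate in percent, rounded to `digits`.
#' @export
reduction_rate <- function(p_start, p_end, digits = 1) {
  if (!is.finite(p_start) || p_start <= 0) {
    stop("p_start must be > 0", call. = FALSE)
  }
  round_half_away(100 * (p_start - p_end) / p_start, digits)
}

#' Prevalence trend series for one region or the national aggregate
#'
#' @param table a `prevalence_table`.
#' @param level region id, or `"NATIONAL"` (default).
#' @return data.frame with `wave` (ascending order, pooled column excluded)
#'   and `prevalence_percent`.
#' @export
trend_series <- function(table, level = "NATIONAL") {
  stopifnot(inherits(table, "prevalence_table"))
  sub <- table[table$region_id == level & table$wave != "pooled", ,
               drop = FALSE]
  if (!nrow(sub)) stop("unknown level: ", level, call. = FALSE)
  sub <- sub[order(sub$wave), c("wave", "prevalence_percent"), drop = FALSE]
  rownames(sub) <- NULL
  as.data.frame(sub)
}
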