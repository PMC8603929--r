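#' Extract per-region voxel values from a parametric map
#'
#' @param map a [conductivity_map()] or [md_map()].
#' @param vois a [voi_set()] on the same grid.
#' @return named list of numeric vectors, one per region, valid voxels only.
#' @export
region_values <- function(map, vois) {
  stopifnot(inherits(map, c("conductivity_map", "md_map")),
            inherits(vois, "voi_set"))
  check_same_grid(dim(map$values), dim(vois$labels), "map and vois")
  ids <- sort(unique(vois$labels[vois$labels > 0]))
  out <- list()
  for (id in ids) {
    sel <- vois$labels == id & map$mask
    out[[vois$label_names[[as.character(id)]]]] <- map$values[sel]
  }
  out
}

#' Per-region summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and median of the
#' valid voxels of a parametric map within every labelled region. Empty
#' regions are reported with `n_voxels = 0` and NA statistics.
#'
#' @param map a [conductivity_map()] or [md_map()].
#' @param vois a [voi_set()].
#' @param map_name label for the `map_name` column (e.g. "conductivity").
#' @return data.frame with columns region, day, map_name, n_voxels, mean,
#'   sd, median.
#' @export
region_summary <- function(map, vois, map_name = "map") {
  vals <- region_values(map, vois)
  ids <- sort(unique(vois$labels[vois$labels > 0]))
  rows <- lapply(seq_along(ids), function(i) {
    v <- vals[[i]]
    data.frame(region = vois$label_names[[as.character(ids[i])]],
               day = vois$day, map_name = map_name,
               n_voxels = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Two-tailed t-test between two samples
#'
#' Welch's unequal-variance t-test by default (Welch-Satterthwaite degrees
#' of freedom), with a pooled-variance option. Two samples with zero
#' variance and equal means return t = 0, p = 1 by convention.
#'
#' @param a,b numeric samples, each of length >= 2, finite.
#' @param pooled logical; TRUE for the classical pooled-variance test.
#' @return list with elements `t`, `dof`, `p`.
#' @export
ttest_two_tailed <- function(a, b, pooled = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("samples must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, dof = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                dof = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the usual t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` for the two-sided p-value.
#'
#' @param x,y paired numeric vectors, n >= 3, finite.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need n >= 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("pairs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' All pairwise region comparisons on one map
#'
#' @param values_by_region named list of numeric vectors (see
#'   [region_values()]).
#' @param day day tag recorded in the output rows.
#' @param map_name map label recorded in the output rows.
#' @param pooled passed to [ttest_two_tailed()].
#' @return data.frame with region_a, region_b, day, map_name, t, dof, p.
#' @export
pairwise_region_tests <- function(values_by_region, day = NA, map_name = "map",
                                  pooled = FALSE) {
  regions <- names(values_by_region)
  rows <- list()
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (j <= i) next
    a <- values_by_region[[i]]; b <- values_by_region[[j]]
    if (length(a) < 2 || length(b) < 2) next
    tt <- ttest_two_tailed(a, b, pooled)
    rows[[length(rows) + 1L]] <-
      data.frame(region_a = regions[i], region_b = regions[j], day = day,
                 map_name = map_name, t = tt$t, dof = tt$dof, p = tt$p)
  }
  if (length(rows) == 0) return(empty_test_table(longitudinal = FALSE))
  do.call(rbind, rows)
}

#' Compare region distributions across acquisition days
#'
#' Runs a two-tailed t-test between every pair of days, per region and map.
#'
#' @param samples_by_day named list: day tag -> named list of per-region
#'   numeric vectors (as from [region_values()]).
#' @param map_name map label recorded in the output rows.
#' @param pooled passed to [ttest_two_tailed()].
#' @return data.frame with region, day_a, day_b, map_name, t, dof, p; empty
#'   (with a warning) when fewer than two days are present.
#' @export
longitudinal_compare <- function(samples_by_day, map_name = "map",
                                 pooled = FALSE) {
  days <- names(samples_by_day)
  if (length(days) < 2) {
    warning("longitudinal comparison needs >= 2 days; returning no records")
    return(empty_test_table(longitudinal = TRUE))
  }
  regions <- unique(unlist(lapply(samples_by_day, names)))
  rows <- list()
  for (reg in regions) {
    for (i in seq_along(days)) for (j in seq_along(days)) {
      if (j <= i) next
      a <- samples_by_day[[i]][[reg]]
      b <- samples_by_day[[j]][[reg]]
      if (is.null(a) || is.null(b) || length(a) < 2 || length(b) < 2) next
      tt <- ttest_two_tailed(a, b, pooled)
      rows[[length(rows) + 1L]] <-
        data.frame(region = reg, day_a = days[i], day_b = days[j],
                   map_name = map_name, t = tt$t, dof = tt$dof, p = tt$p)
    }
  }
  if (length(rows) == 0) return(empty_test_table(longitudinal = TRUE))
  do.call(rbind, rows)
}

empty_test_table <- function(longitudinal) {
  if (longitudinal)
    data.frame(region = character(0), day_a = character(0),
               day_b = character(0), map_name = character(0),
               t = numeric(0), dof = numeric(0), p = numeric(0))
  else
    data.frame(region_a = character(0), region_b = character(0),
               day = numeric(0), map_name = character(0),
               t = numeric(0), dof = numeric(0), p = numeric(0))
}
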