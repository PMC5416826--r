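# Chromatin density distribution statistics on a 60 x 60 nm grid:
# per-square counts, skewness, normalized median, cumulative curves and
# between-condition comparison.

#' Bin localizations into a density grid
#'
#' Counts single-molecule signals per square of a `bin_nm` x `bin_nm`
#' grid (half-open bins, as in [render_histogram()]). Only occupied
#' squares are kept: the nuclear outline would otherwise dominate every
#' distribution statistic with structural zeros.
#'
#' @param table a nonempty `loc_table`.
#' @param bin_nm grid square side, nm (default 60, the standard fBALM
#'   analysis grid).
#' @return object of class `density_grid`: list with `bin_nm`, `counts`
#'   (positive integers, one per occupied square), `n_total`,
#'   `n_occupied`.
#' @export
bin_counts <- function(table, bin_nm = 60) {
  check_positive(bin_nm, "bin_nm")
  if (nrow(table) == 0L) stop_param("empty localization table")
  key <- paste(floor(table$x_nm / bin_nm), floor(table$y_nm / bin_nm))
  counts <- as.integer(table(key))
  structure(list(bin_nm = bin_nm, counts = counts,
                 n_total = nrow(table), n_occupied = length(counts)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid (%g nm): %d signals in %d occupied squares\n",
              x$bin_nm, x$n_total, x$n_occupied))
  invisible(x)
}

# Biased moment skewness g1 = m3 / m2^(3/2); 0 when all values equal.
skewness_g1 <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(0)
  mean((v - m)^3) / m2^1.5
}

#' Distribution statistics of per-square signal counts
#'
#' Computes the chromatin density descriptors used to compare cells and
#' conditions: median and mean signals per occupied grid-square, their
#' ratio (the "normalized median", dimensionless and comparable across
#' cells with different totals), the moment skewness
#' `g1 = m3 / m2^(3/2)` (asymmetry of the count distribution around its
#' mean), and the empirical cumulative step curve.
#'
#' @param grid a `density_grid`, or a plain numeric vector of values
#'   (e.g. conventional-image pixel intensities).
#' @param floor_value optional intensity floor: values strictly below it
#'   are discarded before computing statistics. Intended for
#'   conventional-image pixel histograms, where the peak at low values
#'   is background outside the nucleus.
#' @return object of class `density_stats`: list with
#'   `median_per_square`, `mean_per_square`, `normalized_median`,
#'   `skewness`, `n_squares` and `cumulative` (data frame `value`,
#'   `cum_prob`).
#' @export
density_stats <- function(grid, floor_value = NULL) {
  v <- if (inherits(grid, "density_grid")) grid$counts else as.numeric(grid)
  if (!is.null(floor_value)) v <- v[v >= floor_value]
  if (length(v) < 3L) stop_param("need at least 3 occupied squares/values")
  vs <- sort(unique(v))
  cum <- data.frame(value = vs,
                    cum_prob = cumsum(tabulate(match(sort(v), vs))) /
                      length(v))
  structure(list(median_per_square = median(v), mean_per_square = mean(v),
                 normalized_median = median(v) / mean(v),
                 skewness = skewness_g1(v), n_squares = length(v),
                 cumulative = cum),
            class = "density_stats")
}

#' @export
print.density_stats <- function(x, ...) {
  cat(sprintf(paste0("Density stats: median/square %.3g, mean/square ",
                     "%.3g, normalized median %.3f, skewness %.3f ",
                     "(%d squares)\n"),
              x$median_per_square, x$mean_per_square,
              x$normalized_median, x$skewness, x$n_squares))
  invisible(x)
}

#' Compare chromatin density statistics between conditions
#'
#' Summarizes per-cell density statistics per condition (mean +/- SD of
#' the normalized median and of the skewness) and reports the direction
#' of the shift between the first and every other group, as in
#' untreated vs. ischemia comparisons.
#'
#' @param groups named list; each element is a list of `density_stats`
#'   objects, one per cell, with at least 2 cells per group.
#' @return object of class `density_comparison`: list with `cells`
#'   (per-cell scatter table: `group`, `cell`, `normalized_median`,
#'   `skewness`), `summary` (per-group mean and SD of both metrics) and
#'   `shift` (per non-reference group: signed difference of group means
#'   vs. the first group, for both metrics).
#' @export
compare_conditions <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_param("`groups` must be a named list")
  for (g in names(groups))
    if (length(groups[[g]]) < 2L)
      stop_param("group '%s' has fewer than 2 cells", g)
  cells <- do.call(rbind, lapply(names(groups), function(g) {
    st <- groups[[g]]
    data.frame(group = g, cell = seq_along(st),
               normalized_median = vapply(st, `[[`, numeric(1),
                                          "normalized_median"),
               skewness = vapply(st, `[[`, numeric(1), "skewness"))
  }))
  summ <- do.call(rbind, lapply(split(cells, cells$group), function(d)
    data.frame(group = d$group[1], n_cells = nrow(d),
               normalized_median_mean = mean(d$normalized_median),
               normalized_median_sd = sd(d$normalized_median),
               skewness_mean = mean(d$skewness),
               skewness_sd = sd(d$skewness))))
  summ <- summ[match(names(groups), summ$group), ]
  rownames(summ) <- NULL
  ref <- summ[1, ]
  shift <- if (nrow(summ) > 1L)
    data.frame(group = summ$group[-1],
               d_normalized_median = summ$normalized_median_mean[-1] -
                 ref$normalized_median_mean,
               d_skewness = summ$skewness_mean[-1] - ref$skewness_mean)
  else NULL
  structure(list(cells = cells, summary = summ, shift = shift,
                 reference = ref$group),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("Condition comparison (mean +/- SD per group):\n")
  print(x$summary)
  if (!is.null(x$shift)) {
    cat(sprintf("Shift vs. reference group '%s':\n", x$reference))
    print(x$shift)
  }
  invisible(x)
}

#' Genomic coverage of a single-molecule dataset
#'
#' Converts a count of single-molecule signals in one optical section of
#' a nucleus into an average genomic coverage, assuming the section
#' contains a fixed fraction of the nuclear (hence genomic) content: the
#' classic arithmetic is 1e6 signals over one tenth of a 1e9 bp genome,
#' i.e. one observation per 100 bp.
#'
#' @param n_signals single-molecule signals detected in the section.
#' @param genome_bp genome size in base pairs (default 1e9).
#' @param plane_fraction fraction of the nuclear volume sampled by the
#'   imaging plane (default 0.1).
#' @return list with `bp_in_plane` and `bp_per_signal` (average base
#'   pairs per observation).
#' @export
genomic_coverage <- function(n_signals, genome_bp = 1e9,
                             plane_fraction = 0.1) {
  check_positive(n_signals, "n_signals")
  check_positive(genome_bp, "genome_bp")
  if (plane_fraction <= 0 || plane_fraction > 1)
    stop_param("`plane_fraction` must be in (0, 1]")
  bp <- genome_bp * plane_fraction
  list(bp_in_plane = bp, bp_per_signal = bp / n_signals)
}
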