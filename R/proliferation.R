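# Proliferation scoring: labelled-cell percentages per region from centre
# lists or from raw nuclear channels, and the cross-species summary table
# relating proliferation rate to apico-basal length.

#' One-row proliferation summary
#'
#' @param n_total,n_positive In-region counts, `0 <= n_positive <= n_total`.
#' @param species,stage,region Free-text metadata labels.
#' @param mean_ab_length Mean apico-basal length (µm) of the region, or NA.
#' @return A one-row data.frame of class `prolif_summary`.
#' @export
proliferation_summary <- function(n_total, n_positive, species = "",
                                  stage = "", region = "",
                                  mean_ab_length = NA_real_) {
  if (n_positive < 0 || n_positive > n_total)
    stop("need 0 <= n_positive <= n_total", call. = FALSE)
  out <- data.frame(species = species, stage = stage, region = region,
                    n_total = as.integer(n_total),
                    n_positive = as.integer(n_positive),
                    percent_positive = 100 * n_positive / n_total,
                    mean_ab_length_um = mean_ab_length,
                    stringsAsFactors = FALSE)
  class(out) <- c("prolif_summary", class(out))
  out
}

#' Labelled fraction among nucleus centres inside a region
#'
#' Counts only the centres whose containing voxel lies inside the region
#' mask; the percentage is `100 * positives / total` among those.
#'
#' @param centres n x 3 matrix of nucleus centre coordinates (µm).
#' @param positive_flags Logical vector aligned with `centres`.
#' @param region_mask A [seg_mask()] delimiting the scored region.
#' @param ... Metadata passed to [proliferation_summary()].
#' @return A [proliferation_summary()] row.
#' @export
count_positive_fraction <- function(centres, positive_flags, region_mask,
                                    ...) {
  centres <- as.matrix(centres)
  stopifnot(nrow(centres) == length(positive_flags),
            inherits(region_mask, "seg_mask"))
  d <- dim(region_mask$values)
  ijk <- round(sweep(centres, 2, region_mask$origin) /
                 rep(region_mask$spacing, each = nrow(centres))) + 1
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  inside[inside] <- region_mask$values[ijk[inside, , drop = FALSE]]
  n_total <- sum(inside)
  if (n_total == 0)
    stop("no centres inside the region: percentage undefined", call. = FALSE)
  proliferation_summary(n_total, sum(positive_flags & inside), ...)
}

#' Segment nuclei and score the labelled fraction
#'
#' Automates the manual count: nuclei are detected as 26-connected
#' components of the thresholded total channel (optionally after a
#' grey-scale closing), and a nucleus is positive when at least
#' `overlap_fraction` of its voxels lie in the thresholded positive
#' channel.
#'
#' @param total_channel,positive_channel Co-registered [voxel_grid()]s
#'   (all nuclei vs labelled nuclei).
#' @param region_mask Optional [seg_mask()]; nuclei are counted when their
#'   centroid voxel falls inside it.
#' @param cutoff Intensity cutoff: `"half_max"` (midpoint between minimum
#'   and maximum, per channel) or a number.
#' @param closing_radius Optional [close_nuclei()] SE half-width applied to
#'   both channels before thresholding.
#' @param min_voxels Components smaller than this are discarded as debris.
#' @param overlap_fraction Positivity rule, fraction of component volume.
#' @param ... Metadata passed to [proliferation_summary()].
#' @return A [proliferation_summary()] row with attribute `components`
#'   (per-nucleus size, centroid and positivity table).
#' @export
segment_and_count <- function(total_channel, positive_channel,
                              region_mask = NULL, cutoff = "half_max",
                              closing_radius = NULL, min_voxels = 4L,
                              overlap_fraction = 0.5, ...) {
  stopifnot(inherits(total_channel, "voxel_grid"),
            inherits(positive_channel, "voxel_grid"))
  if (!same_geometry(total_channel, positive_channel))
    stop("channels are not co-registered", call. = FALSE)
  if (max(total_channel$values) <= 0)
    stop("empty total channel", call. = FALSE)
  if (!is.null(closing_radius)) {
    total_channel <- close_nuclei(total_channel, closing_radius)
    positive_channel <- close_nuclei(positive_channel, closing_radius)
  }
  thr <- function(g) {
    cut <- if (identical(cutoff, "half_max"))
      (max(g$values) + min(g$values)) / 2 else as.numeric(cutoff)
    g$values >= cut & g$values > 0
  }
  tot_fg <- thr(total_channel)
  pos_fg <- thr(positive_channel)
  labels <- label_components(seg_mask(total_channel, tot_fg))
  n_comp <- attr(labels, "n_components")
  if (n_comp == 0) stop("no nuclei detected", call. = FALSE)

  lab_vec <- as.integer(labels)[as.logical(tot_fg)]
  sizes <- tabulate(lab_vec, nbins = n_comp)
  pos_sizes <- tabulate(as.integer(labels)[as.logical(tot_fg & pos_fg)],
                        nbins = n_comp)
  idx <- which(tot_fg, arr.ind = TRUE)
  cx <- vapply(seq_len(n_comp), function(l) mean(idx[lab_vec == l, 1]), 0)
  cy <- vapply(seq_len(n_comp), function(l) mean(idx[lab_vec == l, 2]), 0)
  cz <- vapply(seq_len(n_comp), function(l) mean(idx[lab_vec == l, 3]), 0)

  keep <- sizes >= min_voxels
  in_region <- rep(TRUE, n_comp)
  if (!is.null(region_mask)) {
    stopifnot(inherits(region_mask, "seg_mask"))
    d <- dim(region_mask$values)
    ci <- pmin(pmax(round(cbind(cx, cy, cz)), 1), rep(d, each = n_comp))
    in_region <- region_mask$values[ci]
  }
  use <- keep & in_region
  if (!any(use))
    stop("no nuclei inside the region: percentage undefined", call. = FALSE)
  positive <- pos_sizes / pmax(sizes, 1L) >= overlap_fraction

  out <- proliferation_summary(sum(use), sum(positive & use), ...)
  ax <- voxel_axes(total_channel)
  attr(out, "components") <- data.frame(
    size = sizes[use],
    x = ax$x[1] + (cx[use] - 1) * total_channel$spacing[1],
    y = ax$y[1] + (cy[use] - 1) * total_channel$spacing[2],
    z = ax$z[1] + (cz[use] - 1) * total_channel$spacing[3],
    positive = positive[use])
  out
}

#' Cross-condition proliferation vs apico-basal length table
#'
#' Collates per-(species, stage) summaries and reports the Spearman rank
#' correlation between the labelled-cell percentage and the mean
#' apico-basal length — the cross-species relationship between residual
#' proliferation and cell flattening.
#'
#' @param summaries A list of [proliferation_summary()] rows or an
#'   rbind-ed data.frame of them; at least 3 rows with both quantities.
#' @return List of class `prolif_table` with the collated `table`,
#'   `spearman_rho` (NA, with a warning, when a column is constant) and
#'   `n`.
#' @export
proliferation_vs_thickness_table <- function(summaries) {
  tab <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, summaries)
  ok <- complete.cases(tab[, c("percent_positive", "mean_ab_length_um")])
  if (sum(ok) < 3)
    stop("need >= 3 rows with both percentage and A-B length", call. = FALSE)
  x <- tab$percent_positive[ok]
  y <- tab$mean_ab_length_um[ok]
  rho <- if (sd(x) == 0 || sd(y) == 0) {
    warning("constant column: rank correlation undefined", call. = FALSE)
    NA_real_
  } else {
    cor(x, y, method = "spearman")
  }
  structure(list(table = tab, spearman_rho = rho, n = sum(ok)),
            class = "prolif_table")
}

#' @export
print.prolif_table <- function(x, ...) {
  cat(sprintf("<prolif_table> %d conditions, Spearman rho = %.3f\n",
              x$n, x$spearman_rho))
  print(x$table)
  invisible(x)
}
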