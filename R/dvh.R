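#' Construct a DVH curve object
#'
#' Usually produced by [compute_dvh()]; exposed so curves can be rebuilt
#' from files ([read_dvh_csv()]) or synthesized ([synthesize_dvh()]).
#'
#' The cumulative convention is "volume receiving at least d": the
#' cumulative value at bin edge k is 100 x (differential volume in bins
#' >= k) / total volume, so `cumulative` has one more element than
#' `differential` and ends at 0.
#'
#' @param bin_edges strictly increasing dose values in Gy, starting at 0.
#' @param differential absolute volume (cm^3) per bin; length
#'   `length(bin_edges) - 1`.
#' @param structure label of the structure the curve belongs to.
#' @return An object of class `dvh_curve` with fields `bin_edges`,
#'   `differential`, `cumulative` (percent), `total_volume` (cm^3) and
#'   `structure`.
#' @export
dvh_curve <- function(bin_edges, differential, structure = "structure") {
  bin_edges <- as.numeric(bin_edges)
  differential <- as.numeric(differential)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing with at least two values")
  }
  if (length(differential) != length(bin_edges) - 1L) {
    stop("differential must have one value per bin")
  }
  if (any(differential < 0)) stop("differential volumes must be non-negative")
  total <- sum(differential)
  if (total <= 0) stop(sprintf("structure '%s' has zero total volume", structure))
  cumulative <- 100 * c(rev(cumsum(rev(differential))), 0) / total
  structure(
    list(
      bin_edges = bin_edges, differential = differential,
      cumulative = cumulative, total_volume = total,
      structure = as.character(structure)[1]
    ),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> '%s': %.2f cm^3, %d bins over [0, %.3f] Gy\n",
    x$structure, x$total_volume, length(x$differential), max(x$bin_edges)
  ))
  invisible(x)
}

#' Compute a dose-volume histogram
#'
#' Bins the doses of the voxels inside a structure mask into a differential
#' histogram (absolute cm^3 per bin) and the matching cumulative curve
#' (percent of structure volume receiving at least each bin edge's dose).
#' Voxel membership is whole-voxel; bins cover `[0, max dose in structure]`.
#'
#' @param dose a [dose_grid()].
#' @param structure a non-empty [structure_mask()] on the same grid.
#' @param bin_width dose bin width in Gy (default 0.05 Gy, i.e. at most
#'   0.1 percent of a typical 60 Gy prescription).
#' @return A [dvh_curve()].
#' @examples
#' g <- dose_grid(array(c(1, 2, 3, 4), c(2, 2, 1)), spacing = c(10, 10, 10))
#' m <- structure_mask(array(TRUE, c(2, 2, 1)), "ptv")
#' d <- compute_dvh(g, m, bin_width = 0.5)
#' volume_at_dose(d, 2)  # 75: three of four voxels receive >= 2 Gy
#' @export
compute_dvh <- function(dose, structure, bin_width = 0.05) {
  check_geometry(dose, structure)
  bin_width <- as.numeric(bin_width)
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  d <- dose$values[structure$mask]
  dmax <- max(d)
  n_bins <- max(1L, ceiling(dmax / bin_width - 1e-9))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # top edge must cover the maximum; the hottest voxel goes into the last bin
  if (edges[n_bins + 1L] < dmax) {
    n_bins <- n_bins + 1L
    edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  dvh_curve(edges, counts * voxel_volume_cc(dose), structure$label)
}

#' Point dose metrics from voxel values
#'
#' Dmax, Dmean and Dmin taken directly from the voxel doses inside the mask
#' (never from the binned DVH, so they carry no binning error).
#'
#' @inheritParams compute_dvh
#' @return Named list `Dmax`, `Dmean`, `Dmin` in Gy.
#' @export
dose_point_metrics <- function(dose, structure) {
  check_geometry(dose, structure)
  d <- dose$values[structure$mask]
  list(Dmax = max(d), Dmean = mean(d), Dmin = min(d))
}

#' Volume receiving at least a given dose (VxGy)
#'
#' Reads the cumulative DVH at a query dose, linearly interpolating between
#' bin edges. Queries above the curve range return 0 percent.
#'
#' @param dvh a [dvh_curve()].
#' @param dose query dose(s) in Gy, each >= 0.
#' @return Volume percentage(s) in `[0, 100]`.
#' @export
volume_at_dose <- function(dvh, dose) {
  stopifnot(inherits(dvh, "dvh_curve"))
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose < 0)) stop("query dose must be >= 0")
  out <- stats::approx(
    dvh$bin_edges, dvh$cumulative, xout = dose,
    yleft = 100, yright = 0, ties = "ordered"
  )$y
  pmin(100, pmax(0, out))
}

#' Minimum dose to the hottest x percent (Dx)
#'
#' Inverts the cumulative DVH: the smallest dose d such that the volume
#' receiving at least d is <= `percent`, with linear interpolation on the
#' strictly decreasing segments of the curve. D1 is the near-maximum dose,
#' D99 the near-minimum.
#'
#' @param dvh a [dvh_curve()].
#' @param percent volume percentage(s), each in `(0, 100]`.
#' @return Dose(s) in Gy; monotone non-increasing in `percent`.
#' @export
dose_at_volume <- function(dvh, percent) {
  stopifnot(inherits(dvh, "dvh_curve"))
  percent <- as.numeric(percent)
  if (any(!is.finite(percent)) || any(percent <= 0) || any(percent > 100)) {
    stop("percent must lie in (0, 100]")
  }
  cum <- dvh$cumulative
  edges <- dvh$bin_edges
  vapply(percent, function(p) {
    j <- which(cum < p)[1]          # first edge strictly below the query
    if (is.na(j)) return(edges[length(edges)])
    if (j == 1L) return(edges[1])
    d0 <- edges[j - 1L]; d1 <- edges[j]
    c0 <- cum[j - 1L]; c1 <- cum[j]
    d0 + (c0 - p) / (c0 - c1) * (d1 - d0)
  }, numeric(1))
}

#' Mean dose implied by a differential DVH
#'
#' Bin-midpoint weighted mean; agrees with the voxel mean to within half a
#' bin width. Used where only a tabulated DVH is available.
#'
#' @param dvh a [dvh_curve()].
#' @return Mean dose in Gy.
#' @export
dvh_mean_dose <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  mids <- (dvh$bin_edges[-1] + dvh$bin_edges[-length(dvh$bin_edges)]) / 2
  sum(mids * dvh$differential) / dvh$total_volume
}
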