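# 3D box counting of whole arbors. Occupancy is judged on the densely
# resampled centerline: dendrite width (~1.4 um) lies below the fine-scale
# cut-off, so radius-aware voxelization would not change counts in the
# fitted range.

# all arbor segments resampled to a dense point cloud at the given spacing
arbor_point_cloud <- function(arbor, spacing) {
  seg <- arbor_segments(arbor)
  nd <- arbor$nodes
  if (nrow(seg) == 0L) {
    return(node_positions(arbor))
  }
  pts <- lapply(seq_len(nrow(seg)), function(i) {
    resample_polyline(rbind(c(seg$px[i], seg$py[i], seg$pz[i]),
                            c(seg$cx[i], seg$cy[i], seg$cz[i])), spacing)
  })
  unique(do.call(rbind, pts))
}

#' Side length of the smallest enclosing grid
#'
#' `L_grid` is the largest of the three side lengths of the axis-aligned
#' bounding box of the arbor: the smallest single box that encloses it.
#' Box sizes are reported normalized by `L_grid`.
#'
#' @param arbor an `arbor`
#' @return `L_grid` in micrometres
#' @export
grid_length <- function(arbor) {
  pts <- node_positions(arbor)
  max(apply(pts, 2L, function(v) diff(range(v))))
}

#' Count grid boxes occupied by an arbor
#'
#' The arbor is inserted into a 3D grid of cubes of side `L_box` anchored
#' at the minimum corner of its axis-aligned bounding box; a box counts as
#' occupied when at least one point of the densely resampled centerline
#' falls inside it.
#'
#' @param arbor an `arbor` with at least one node
#' @param L_box box side length (um, > 0)
#' @param spacing centerline resampling spacing (um); default `L_box / 4`
#' @return integer number of occupied boxes
#' @export
occupied_boxes <- function(arbor, L_box, spacing = L_box / 4) {
  if (L_box <= 0) stop("L_box must be positive")
  if (nrow(arbor$nodes) == 0L) stop("empty arbor")
  pts <- arbor_point_cloud(arbor, spacing)
  origin <- apply(pts, 2L, min)
  count_boxes(sweep(pts, 2L, origin), L_box)
}

# grid-cell count for points already shifted to a zero origin; points on
# the far boundary of the enclosing grid belong to the last cell
count_boxes <- function(shifted, L_box) {
  idx <- floor(shifted / L_box + 1e-12)
  ext <- apply(shifted, 2L, max)
  hi <- pmax(0, ceiling(ext / L_box - 1e-9) - 1)
  for (k in 1:3) idx[, k] <- pmin(idx[, k], hi[k])
  length(unique(idx[, 1L] + 1e4 * idx[, 2L] + 1e8 * idx[, 3L]))
}

#' Default box-size grid for arbor box counting
#'
#' Fifteen log-spaced box sizes from 4 um (the fine-scale cut-off shared
#' with the branch analyses) up to `L_grid / 4`.
#'
#' @param arbor an `arbor`
#' @param lo smallest box size (um)
#' @param n number of box sizes
#' @return numeric vector of box sizes, increasing
#' @export
default_box_grid <- function(arbor, lo = 4, n = 15) {
  hi <- grid_length(arbor) / 4
  if (hi <= lo) stop("arbor too small for the default box grid")
  log_spaced(lo, hi, n)
}

#' Box-counting scaling table for an arbor
#'
#' Counts occupied boxes over a grid of box sizes. The centerline is
#' resampled once at a quarter of the smallest box size and reused for all
#' sizes, so counts across scales are mutually consistent.
#'
#' @param arbor an `arbor`
#' @param box_grid increasing box sizes (um); default [default_box_grid()]
#' @return a `scaling_table` data frame with columns `scale` (L_box, um),
#'   `normalized_scale` (L_box / L_grid) and `count` (N_box); `L_grid` is
#'   attached as an attribute
#' @export
box_scaling <- function(arbor, box_grid = default_box_grid(arbor)) {
  if (any(box_grid <= 0)) stop("box sizes must be positive")
  if (is.unsorted(box_grid, strictly = TRUE)) {
    stop("box_grid must be strictly increasing")
  }
  spacing <- min(box_grid) / 4
  pts <- arbor_point_cloud(arbor, spacing)
  origin <- apply(pts, 2L, min)
  shifted <- sweep(pts, 2L, origin)
  counts <- vapply(box_grid, function(lb) count_boxes(shifted, lb),
                   numeric(1))
  lg <- grid_length(arbor)
  out <- data.frame(scale = box_grid, normalized_scale = box_grid / lg,
                    count = counts)
  attr(out, "scale_kind") <- "box"
  attr(out, "L_grid") <- lg
  class(out) <- c("scaling_table", "data.frame")
  out
}

#' Fit the arbor box-counting dimension D_A
#'
#' Fractal scaling follows the power law `N_box` proportional to
#' `L_box^-D_A`; ordinary least squares on (log10 L_box, log10 N_box)
#' yields `D_A` as the negated slope.
#'
#' @param table a `scaling_table` from [box_scaling()]
#' @param fit_range (min, max) box size in um; default: the full table
#' @return a `dimension_estimate` (`method = "D_A"`)
#' @export
fit_arbor_dimension <- function(table, fit_range = range(table$scale)) {
  fit_branch_dimension(table, fit_range = fit_range, method = "D_A")
}

#' Box-counting dimension of an arbor in one call
#'
#' @param arbor an `arbor`
#' @param box_grid box sizes (um)
#' @param fit_range fit range (um); default: the full grid
#' @return a `dimension_estimate` (`method = "D_A"`)
#' @export
arbor_dimension <- function(arbor, box_grid = default_box_grid(arbor),
                            fit_range = range(box_grid)) {
  fit_arbor_dimension(box_scaling(arbor, box_grid), fit_range)
}
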