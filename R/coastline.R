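#' Default ruler grid for branch coastline analysis
#'
#' Twenty log-spaced ruler lengths from 4 um to 40 um. The 4 um fine-scale
#' cut-off sits near the median reconstruction segment length, below which
#' rulers would detect the linear character of the cylindrical segments
#' rather than the meandering of the branch; the 40 um coarse cut-off gives
#' one order of magnitude of scaling on the log-log fit.
#'
#' @param lo,hi smallest and largest ruler length (um)
#' @param n number of ruler lengths
#' @return numeric vector of ruler lengths (um), increasing
#' @export
default_ruler_grid <- function(lo = 4, hi = 40, n = 20) log_spaced(lo, hi, n)

#' Orders of magnitude spanned by a scaling range
#'
#' Fractal scaling in branches is bounded below by the fine-scale cut-off
#' (segment size) and above by the branch size, so the capacity for
#' fractality of a 141 um branch analysed above a 4 um cut-off is
#' `log10(141/4)`, about 1.5 orders of magnitude.
#'
#' @param coarse upper scale (um)
#' @param fine lower scale (um)
#' @return orders of magnitude, `log10(coarse/fine)`
#' @export
scaling_range_orders <- function(coarse, fine) {
  stopifnot(coarse > 0, fine > 0)
  log10(coarse / fine)
}

#' Segment a branch with a fixed-length ruler
#'
#' Richardson divider (coastline) measurement generalized to a 3D
#' polyline. A spherical shell of radius `L_R` is centred on the branch end
#' nearest the soma; the first ruler ends where the branch crosses the
#' shell. The shell is then re-centred on that endpoint and the process
#' repeats. Parts of the branch already segmented are never revisited:
#' only crossings at arc length strictly beyond the current centre are
#' admissible, and among several admissible crossings the one with the
#' shortest path length along the branch is chosen. When the shell no
#' longer intersects the remaining branch, a final truncated ruler joins
#' the last endpoint to the tip and is counted as the fraction
#' `truncated_len / L_R` — e.g. 12 full rulers plus a 2 um remainder at
#' `L_R` = 10 um give `N` = 12.2.
#'
#' Sphere-polyline crossings are solved exactly per segment (a quadratic in
#' the segment parameter); a tangency (zero discriminant) counts as a
#' crossing.
#'
#' @param branch a `branch`
#' @param L_R ruler length in micrometres (> 0)
#' @return an object of class `ruler_segmentation`: list with `L_R`,
#'   `endpoints` (ordered matrix of ruler endpoints on the branch),
#'   `n_full` (number of full rulers), `truncated_len` (um, 0 if none),
#'   `N` (fractional ruler count) and `L_T` (sum of ruler lengths)
#' @export
segment_with_ruler <- function(branch, L_R) {
  if (!is.numeric(L_R) || length(L_R) != 1L || L_R <= 0) {
    stop("ruler length L_R must be a positive number")
  }
  pts <- branch$points
  cl <- branch$cum_len
  if (branch$L_B < 1e-9) stop("degenerate branch: path length below tolerance")
  eps <- 1e-9
  centre <- pts[1L, ]
  s_c <- 0
  endpoints <- list(centre)
  n_full <- 0L
  repeat {
    hit <- next_crossing(pts, cl, centre, s_c, L_R, eps)
    if (is.null(hit)) break
    centre <- hit$point
    s_c <- hit$s
    n_full <- n_full + 1L
    endpoints[[length(endpoints) + 1L]] <- centre
  }
  truncated_len <- 0
  if (s_c < branch$L_B - eps) {
    tip <- pts[nrow(pts), ]
    truncated_len <- vec_norm(tip - centre)
    endpoints[[length(endpoints) + 1L]] <- tip
  }
  out <- list(
    L_R = L_R,
    endpoints = do.call(rbind, endpoints),
    n_full = n_full,
    truncated_len = truncated_len,
    N = n_full + truncated_len / L_R,
    L_T = n_full * L_R + truncated_len
  )
  class(out) <- "ruler_segmentation"
  out
}

# First crossing of the sphere |x - centre| = L_R along the polyline at arc
# length strictly greater than s_c. Exact per-segment quadratic.
next_crossing <- function(pts, cl, centre, s_c, L_R, eps) {
  n_seg <- nrow(pts) - 1L
  start_seg <- max(1L, findInterval(s_c, cl, rightmost.closed = TRUE))
  if (start_seg > n_seg) return(NULL)
  for (i in start_seg:n_seg) {
    p <- pts[i, ]
    d <- pts[i + 1L, ] - p
    seg_len <- cl[i + 1L] - cl[i]
    a <- sum(d * d)
    w <- p - centre
    b <- 2 * sum(w * d)
    c_ <- sum(w * w) - L_R * L_R
    disc <- b * b - 4 * a * c_
    if (disc < 0) next
    sq <- sqrt(max(0, disc))
    for (t in sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))) {
      if (t < -eps || t > 1 + eps) next
      t_cl <- min(1, max(0, t))
      s <- cl[i] + t_cl * seg_len
      if (s > s_c + eps) {
        return(list(point = p + t_cl * d, s = s))
      }
    }
  }
  NULL
}

#' Build a ruler scaling table for one branch
#'
#' Runs [segment_with_ruler()] over a grid of ruler lengths and records the
#' fractional ruler count `N` at each, together with the normalized scale
#' `L_R / L_E` used for pooled fitting.
#'
#' @param branch a `branch`
#' @param ruler_grid increasing positive ruler lengths (um)
#' @return a `scaling_table` data frame with columns `scale` (um),
#'   `normalized_scale`, `count` and `sub_ruler` (flag: branch shorter than
#'   the ruler, count below 1)
#' @export
coastline_scaling <- function(branch, ruler_grid = default_ruler_grid()) {
  if (any(ruler_grid <= 0)) stop("ruler lengths must be positive")
  if (is.unsorted(ruler_grid, strictly = TRUE)) {
    stop("ruler_grid must be strictly increasing")
  }
  counts <- vapply(ruler_grid,
                   function(lr) segment_with_ruler(branch, lr)$N, numeric(1))
  out <- data.frame(scale = ruler_grid,
                    normalized_scale = ruler_grid / branch$L_E,
                    count = counts,
                    sub_ruler = counts < 1)
  attr(out, "scale_kind") <- "ruler"
  class(out) <- c("scaling_table", "data.frame")
  out
}

#' Dimension estimate container
#'
#' @param D fractal dimension
#' @param stderr standard error of `D`
#' @param slope fitted log-log slope
#' @param fit_range (min, max) scale in um actually used
#' @param n_points_fit number of table rows in the fit
#' @param method one of "D_BC", "D_BCN", "D_BT", "D_A"
#' @return an object of class `dimension_estimate`
#' @export
dimension_estimate <- function(D, stderr, slope, fit_range, n_points_fit,
                               method) {
  stopifnot(stderr >= 0 || is.na(stderr))
  out <- list(D = D, stderr = stderr, slope = slope,
              fit_range = fit_range, n_points_fit = n_points_fit,
              method = method)
  class(out) <- "dimension_estimate"
  out
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf("<%s> D = %.4f +/- %.4f  (slope %.4f, %d points, range %.3g-%.3g um)\n",
              x$method, x$D, x$stderr, x$slope, x$n_points_fit,
              x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Fit the coastline dimension of one branch
#'
#' Ordinary least squares on (log10 ruler length, log10 count) restricted
#' to `fit_range`; the branch coastline dimension `D_BC` is the negated
#' slope. Branches whose span cannot support at least three rulers in the
#' range are excluded (short-branch exclusion).
#'
#' @param table a `scaling_table` from [coastline_scaling()]
#' @param fit_range (min, max) scale in um; default 4-40 um (one order)
#' @param method tag stored on the estimate
#' @return a `dimension_estimate` with `D = -slope`
#' @export
fit_branch_dimension <- function(table, fit_range = c(4, 40),
                                 method = "D_BC") {
  sel <- table$scale >= fit_range[1L] - 1e-12 &
    table$scale <= fit_range[2L] + 1e-12
  if (sum(sel) < 3L) {
    stop("insufficient data: fewer than 3 scales inside the fit range; ",
         "branch excluded")
  }
  f <- loglog_fit(table$scale[sel], table$count[sel])
  dimension_estimate(D = -f$slope, stderr = f$stderr, slope = f$slope,
                     fit_range = range(table$scale[sel]),
                     n_points_fit = sum(sel), method = method)
}

#' Exclusion rule for short branches
#'
#' A branch is excluded from per-branch fitting when it cannot support the
#' full ruler range, i.e. its end-to-end length `L_E` is below the coarse
#' cut-off.
#'
#' @param branch a `branch`
#' @param fit_range (min, max) ruler range in um
#' @return logical: `TRUE` if the branch should be excluded
#' @export
branch_excluded <- function(branch, fit_range = c(4, 40)) {
  branch$L_E < fit_range[2L]
}

#' Pooled, normalized coastline dimension of a set of branches
#'
#' Normalizing the ruler length by each branch's end-to-end length `L_E`
#' puts branches of different sizes on a common axis; all (log10 L_R/L_E,
#' log10 N) points are pooled and fitted together over the normalized range
#' shared by every contributing branch, so no branch dominates the fine or
#' coarse scales. When the shared range exceeds `max_span` orders of
#' magnitude it is trimmed symmetrically (in log space) to that span.
#'
#' @param branches list of `branch` objects
#' @param ruler_grid ruler lengths (um) applied to every branch
#' @param fit_range absolute ruler range (um) for the short-branch
#'   exclusion rule
#' @param max_span maximum fitted span in orders of magnitude (default
#'   0.75)
#' @return a `dimension_estimate` (`method = "D_BCN"`); the pooled table is
#'   attached as attribute `"pooled_table"`
#' @export
pooled_normalized_dimension <- function(branches,
                                        ruler_grid = default_ruler_grid(),
                                        fit_range = c(4, 40),
                                        max_span = 0.75) {
  keep <- !vapply(branches, branch_excluded, logical(1),
                  fit_range = fit_range)
  branches <- branches[keep]
  if (length(branches) < 2L) {
    stop("need at least 2 branches after short-branch exclusion")
  }
  tables <- lapply(branches, coastline_scaling, ruler_grid = ruler_grid)
  spans <- vapply(tables, function(tb) range(tb$normalized_scale), numeric(2))
  lo <- max(spans[1L, ])
  hi <- min(spans[2L, ])
  if (hi <= lo) {
    stop("no shared normalized range; per-branch spans: ",
         paste(sprintf("[%.3g, %.3g]", spans[1L, ], spans[2L, ]),
               collapse = " "))
  }
  span <- log10(hi) - log10(lo)
  if (span > max_span) {
    mid <- (log10(hi) + log10(lo)) / 2
    lo <- 10^(mid - max_span / 2)
    hi <- 10^(mid + max_span / 2)
  }
  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    tb$branch_id <- i
    tb
  }))
  sel <- pooled$normalized_scale >= lo - 1e-12 &
    pooled$normalized_scale <= hi + 1e-12
  if (sum(sel) < 3L) stop("insufficient pooled data in the shared range")
  f <- loglog_fit(pooled$normalized_scale[sel], pooled$count[sel])
  est <- dimension_estimate(D = -f$slope, stderr = f$stderr, slope = f$slope,
                            fit_range = c(lo, hi),
                            n_points_fit = sum(sel), method = "D_BCN")
  attr(est, "pooled_table") <- pooled
  est
}

#' Per-branch coastline dimensions for an arbor
#'
#' Convenience wrapper: extracts branches, applies the short-branch
#' exclusion, and fits `D_BC` per branch over the default one-order range.
#'
#' @param arbor a soma-stripped `arbor`
#' @param ruler_grid ruler lengths (um)
#' @param fit_range (min, max) ruler range (um)
#' @return data frame: branch_id, L_B, L_E, D_BC, stderr, n_rulers_fit,
#'   excluded
#' @export
arbor_branch_dimensions <- function(arbor,
                                    ruler_grid = default_ruler_grid(),
                                    fit_range = c(4, 40)) {
  branches <- extract_branches(arbor)
  rows <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    excl <- branch_excluded(b, fit_range)
    if (excl) {
      return(data.frame(branch_id = i, L_B = b$L_B, L_E = b$L_E,
                        D_BC = NA_real_, stderr = NA_real_,
                        n_rulers_fit = 0L, excluded = TRUE))
    }
    est <- fit_branch_dimension(coastline_scaling(b, ruler_grid), fit_range)
    data.frame(branch_id = i, L_B = b$L_B, L_E = b$L_E, D_BC = est$D,
               stderr = est$stderr, n_rulers_fit = est$n_points_fit,
               excluded = FALSE)
  })
  do.call(rbind, rows)
}
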