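#' All-sub-path tortuosity records of a branch
#'
#' Tortuosity `T` of a path is the ratio of its curvilinear length `L_P`
#' (summed segment lengths) to the Euclidean distance `L_D` between its two
#' endpoints; `T >= 1`, with equality for a straight path. Every
#' vertex-to-vertex sub-path of the branch polyline contributes one record
#' (endpoints are not interpolated inside segments). Sibling branches share
#' their proximal sections, so records carry a canonical endpoint key used
#' by [deduplicate_paths()].
#'
#' @param branch a `branch` with at least 3 points
#' @param arbor_id identifier mixed into the dedup key so records from
#'   different arbors never collide
#' @return a `tortuosity_table` data frame with columns `start_node`,
#'   `end_node`, `L_P`, `L_D`, `T`, `dedup_key`
#' @export
tortuosity_table <- function(branch, arbor_id = "a") {
  pts <- branch$points
  n <- nrow(pts)
  if (n < 3L) stop("branch needs at least 3 points for sub-path tortuosity")
  ids <- branch$node_ids
  if (is.null(ids)) ids <- seq_len(n)
  cl <- branch$cum_len
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  L_P <- cl[j] - cl[i]
  L_D <- sqrt(rowSums((pts[j, , drop = FALSE] - pts[i, , drop = FALSE])^2))
  if (any(L_D <= 0)) {
    k <- which(L_D <= 0)[1L]
    stop("degenerate path: coincident endpoints (nodes ", ids[i[k]], ", ",
         ids[j[k]], ") with positive path length")
  }
  out <- data.frame(
    start_node = ids[i], end_node = ids[j],
    L_P = L_P, L_D = L_D, T = L_P / L_D,
    dedup_key = paste0(arbor_id, ":", pmin(ids[i], ids[j]), "-",
                       pmax(ids[i], ids[j]))
  )
  class(out) <- c("tortuosity_table", "data.frame")
  out
}

#' Remove duplicate sub-paths shared between branches
#'
#' Branches descending from the same bifurcation share their proximal
#' polyline, so sub-paths lying entirely in a shared section appear once
#' per descending branch. Records with the same canonical endpoint key are
#' collapsed to a single occurrence before fitting.
#'
#' @param tables a list of `tortuosity_table`s (or a single combined one)
#' @return a combined, deduplicated `tortuosity_table`
#' @export
deduplicate_paths <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  combined <- do.call(rbind, tables)
  out <- combined[!duplicated(combined$dedup_key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tortuosity_table", "data.frame")
  out
}

#' Deduplicated tortuosity records for a whole arbor
#'
#' @param arbor a soma-stripped `arbor`
#' @return a deduplicated `tortuosity_table` over all branches
#' @export
arbor_tortuosity <- function(arbor) {
  branches <- extract_branches(arbor)
  branches <- branches[vapply(branches, function(b) nrow(b$points) >= 3L,
                              logical(1))]
  if (length(branches) == 0L) stop("arbor has no branch with >= 3 points")
  deduplicate_paths(lapply(branches, tortuosity_table,
                           arbor_id = arbor$name))
}

#' Map a tortuosity scaling slope to a fractal dimension
#'
#' For tortuosity scaling `T` proportional to `L_P^S`, the branch fractal
#' dimension is `D_BT = 1 / (1 - S)`: `S = 0` (straight) gives `D = 1` and
#' `S -> 1` diverges towards space filling.
#'
#' @param S log-log slope of mean tortuosity versus path length (`S < 1`)
#' @return the tortuosity fractal dimension
#' @export
dimension_from_slope <- function(S) {
  if (any(S >= 1)) stop("divergent dimension: slope S must be < 1")
  1 / (1 - S)
}

#' Binned tortuosity fit yielding D_BT
#'
#' Individual (L_P, T) records are noisy, so they are binned (log-spaced in
#' `L_P`) over the fit range, the arithmetic mean `T` is taken per bin, and
#' ordinary least squares on (log10 bin centre, log10 mean T) yields the
#' slope `S`. `D_BT = 1/(1-S)`; its standard error follows from the delta
#' method as `D_BT^2 * stderr(S)`. The 4-40 um default range matches the
#' coastline analysis. Bins are equally weighted.
#'
#' @param table a `tortuosity_table`
#' @param fit_range (min, max) path length L_P in um
#' @param n_bins number of log-spaced bins
#' @return a `dimension_estimate` (`method = "D_BT"`) with the binned table
#'   attached as attribute `"binned"`
#' @export
binned_fit <- function(table, fit_range = c(4, 40), n_bins = 12) {
  stopifnot(n_bins >= 3)
  sel <- table$L_P >= fit_range[1L] & table$L_P <= fit_range[2L]
  if (!any(sel)) stop("insufficient data: no paths inside the fit range")
  edges <- 10^seq(log10(fit_range[1L]), log10(fit_range[2L]),
                  length.out = n_bins + 1L)
  lp <- table$L_P[sel]
  tt <- table$T[sel]
  bin <- findInterval(lp, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  centres <- sqrt(edges[-length(edges)] * edges[-1L])
  mean_t <- tapply(tt, factor(bin, levels = seq_len(n_bins)), mean)
  counts <- tapply(rep(1, length(bin)), factor(bin, levels = seq_len(n_bins)),
                   sum)
  nonempty <- !is.na(mean_t)
  if (sum(nonempty) < 3L) {
    stop("insufficient data: fewer than 3 non-empty bins in the fit range")
  }
  f <- loglog_fit(centres[nonempty], as.numeric(mean_t[nonempty]))
  S <- f$slope
  D <- dimension_from_slope(S)
  est <- dimension_estimate(D = D, stderr = D^2 * f$stderr, slope = S,
                            fit_range = fit_range,
                            n_points_fit = sum(nonempty), method = "D_BT")
  attr(est, "binned") <- data.frame(
    bin_centre = centres[nonempty],
    mean_T = as.numeric(mean_t[nonempty]),
    n_paths = as.integer(counts[nonempty])
  )
  est
}
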