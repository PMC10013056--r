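#' Decompose an arbor into local angle geometry
#'
#' Lossless local representation of a soma-stripped arbor: per node, the
#' incoming segment length, the bend angle (the weave angle `theta` at
#' continuation nodes, the fork angle `phi` at branch-point children) and a
#' torsion (azimuth) angle giving the orientation of the bending plane
#' about the incoming direction, measured in a frame parallel-transported
#' along the path. Stem roots keep their absolute position and each
#' root-child edge its absolute initial direction. Reconstructing with an
#' angle multiplier of 1 reproduces the original positions to within
#' 1e-6 um.
#'
#' @param arbor a soma-stripped `arbor` with no zero-length segments
#' @return an object of class `local_geometry`
#' @export
decompose_to_angles <- function(arbor) {
  nd <- arbor$nodes
  if (any(nd$type == 1L)) stop("decompose_to_angles expects a soma-stripped arbor")
  n <- nrow(nd)
  idx <- match(nd$parent, nd$id)
  pts <- node_positions(arbor)
  # topological order: parents before children
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i; d <- 0L
    while (!is.na(idx[j])) { j <- idx[j]; d <- d + 1L }
    depth[i] <- d
  }
  ord <- order(depth)
  seg_len <- rep(NA_real_, n)
  bend <- rep(NA_real_, n)
  torsion <- rep(NA_real_, n)
  init_dir <- matrix(NA_real_, n, 3L)
  tangent <- matrix(NA_real_, n, 3L)
  normal <- matrix(NA_real_, n, 3L)
  for (i in ord) {
    p <- idx[i]
    if (is.na(p)) next  # stem root: anchor only
    d <- pts[i, ] - pts[p, ]
    len <- vec_norm(d)
    if (len < 1e-12) {
      stop("degenerate geometry: zero-length segment into node ", nd$id[i])
    }
    seg_len[i] <- len
    t_c <- d / len
    if (is.na(idx[p])) {
      # first edge out of a stem root: absolute direction, fresh frame
      init_dir[i, ] <- t_c
      tangent[i, ] <- t_c
      normal[i, ] <- perp_vector(t_c)
      next
    }
    t_p <- tangent[p, ]
    n_p <- normal[p, ]
    b_p <- cross3(t_p, n_p)
    bend[i] <- angle_between(t_p, t_c)
    d_perp <- t_c - sum(t_c * t_p) * t_p
    if (vec_norm(d_perp) < 1e-12) {
      torsion[i] <- 0  # collinear (or reversed): bending axis undefined
    } else {
      torsion[i] <- atan2(sum(d_perp * b_p), sum(d_perp * n_p))
    }
    tangent[i, ] <- t_c
    normal[i, ] <- as.numeric(rotation_between(t_p, t_c) %*% n_p)
  }
  out <- list(
    ids = nd$id, parent = nd$parent, order = ord,
    seg_len = seg_len, bend = bend, torsion = torsion,
    init_dir = init_dir,
    root_pos = pts, # positions are only read for roots at reconstruction
    radius = nd$radius, type = nd$type,
    name = arbor$name, soma_centroid = arbor$soma_centroid
  )
  class(out) <- "local_geometry"
  out
}

#' Rebuild an arbor with all bend angles scaled by alpha
#'
#' Multiplies every weave and fork angle by a common factor `alpha` while
#' preserving all segment lengths and torsion angles, then rebuilds node
#' positions depth-first from each stem root so downstream geometry
#' inherits upstream rotations. `alpha = 1` is the identity; `alpha = 0`
#' straightens every branch; `alpha > 1` makes branches curl up (the
#' end-to-end distance `L_E` shrinks while the path length `L_B` is
#' conserved). Scaled angles are clipped just below pi; a warning reports
#' the clip count, also stored as attribute `"clip_count"`.
#'
#' @param geom a `local_geometry` from [decompose_to_angles()]
#' @param alpha non-negative angle multiplier; values outside `[0.5, 2]`
#'   trigger a range warning
#' @return a distorted `arbor`
#' @export
apply_angle_multiplier <- function(geom, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single non-negative number")
  }
  if (alpha < 0.5 || alpha > 2) {
    warning("alpha = ", alpha, " is outside the physically vetted range [0.5, 2]")
  }
  n <- length(geom$ids)
  idx <- match(geom$parent, geom$ids)
  pts <- matrix(NA_real_, n, 3L)
  tangent <- matrix(NA_real_, n, 3L)
  normal <- matrix(NA_real_, n, 3L)
  clip_count <- 0L
  cap <- pi - 1e-6
  for (i in geom$order) {
    p <- idx[i]
    if (is.na(p)) {
      pts[i, ] <- geom$root_pos[i, ]
      next
    }
    if (!any(is.na(geom$init_dir[i, ]))) {
      d <- geom$init_dir[i, ]
      pts[i, ] <- pts[p, ] + geom$seg_len[i] * d
      tangent[i, ] <- d
      normal[i, ] <- perp_vector(d)
      next
    }
    t_p <- tangent[p, ]
    n_p <- normal[p, ]
    b_p <- cross3(t_p, n_p)
    ang <- alpha * geom$bend[i]
    if (ang >= cap) {
      ang <- cap
      clip_count <- clip_count + 1L
    }
    psi <- geom$torsion[i]
    d <- cos(ang) * t_p + sin(ang) * (cos(psi) * n_p + sin(psi) * b_p)
    d <- d / vec_norm(d)
    pts[i, ] <- pts[p, ] + geom$seg_len[i] * d
    tangent[i, ] <- d
    normal[i, ] <- as.numeric(rotation_between(t_p, d) %*% n_p)
  }
  nodes <- data.frame(id = geom$ids, type = geom$type,
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      radius = geom$radius, parent = geom$parent)
  out <- arbor(nodes, name = paste0(geom$name, "_alpha", alpha),
               soma_centroid = geom$soma_centroid)
  if (clip_count > 0L) {
    warning(clip_count, " scaled angle(s) clipped below pi")
  }
  attr(out, "clip_count") <- clip_count
  out
}

#' Distort an arbor by an angle multiplier
#'
#' Convenience wrapper: decompose, scale, rebuild.
#'
#' @param arbor a soma-stripped `arbor`
#' @param alpha angle multiplier
#' @return the distorted `arbor`
#' @export
distort_arbor <- function(arbor, alpha) {
  apply_angle_multiplier(decompose_to_angles(arbor), alpha)
}

#' Report near-intersections between non-adjacent segments
#'
#' Lists pairs of cylindrical segments that do not share a node but come
#' closer than `clearance` (default: the sum of their radii, i.e. touching
#' cylinders). Used to verify that distorted arbors remain physically
#' reasonable ("branches rarely intersect"); intersections are reported,
#' never repaired.
#'
#' @param arbor an `arbor`
#' @param clearance minimum allowed centerline distance in um; `NULL` uses
#'   the per-pair sum of radii
#' @return an object of class `intersection_report`: list with `pairs`
#'   (data frame of offending segment pairs), `n_pairs_checked` and
#'   `fraction` (offending / checked)
#' @export
self_intersection_report <- function(arbor, clearance = NULL) {
  seg <- arbor_segments(arbor)
  ns <- nrow(seg)
  p1 <- as.matrix(seg[c("px", "py", "pz")])
  p2 <- as.matrix(seg[c("cx", "cy", "cz")])
  centers <- (p1 + p2) / 2
  half_len <- sqrt(rowSums((p2 - p1)^2)) / 2
  # node keys to skip segment pairs that share an endpoint
  nd <- arbor$nodes
  parent_of <- stats::setNames(nd$parent, nd$id)
  offenders <- list()
  checked <- 0L
  for (i in seq_len(max(0L, ns - 1L))) {
    j <- (i + 1L):ns
    cl_ij <- if (is.null(clearance)) seg$radius[i] + seg$radius[j] else
      rep(clearance, length(j))
    # prune by bounding spheres
    cd <- sqrt(rowSums((centers[j, , drop = FALSE] -
                          matrix(centers[i, ], length(j), 3L, byrow = TRUE))^2))
    cand <- j[cd <= cl_ij + half_len[i] + half_len[j]]
    checked <- checked + length(j)
    for (k in cand) {
      # skip pairs sharing a node (consecutive or sibling segments)
      a <- seg$child_id[i]; b <- seg$child_id[k]
      if (a == b || parent_of[[as.character(a)]] == b ||
          parent_of[[as.character(b)]] == a ||
          parent_of[[as.character(a)]] == parent_of[[as.character(b)]]) next
      cl_k <- if (is.null(clearance)) seg$radius[i] + seg$radius[k] else clearance
      d <- segment_segment_distance(p1[i, ], p2[i, ], p1[k, ], p2[k, ])
      if (d < cl_k) {
        offenders[[length(offenders) + 1L]] <-
          data.frame(seg_i = a, seg_j = b, distance = d, clearance = cl_k)
      }
    }
  }
  pairs <- if (length(offenders)) do.call(rbind, offenders) else
    data.frame(seg_i = integer(0), seg_j = integer(0),
               distance = numeric(0), clearance = numeric(0))
  out <- list(pairs = pairs, n_pairs_checked = checked,
              fraction = if (checked > 0L) nrow(pairs) / checked else 0)
  class(out) <- "intersection_report"
  out
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> %d offending pair(s) of %d checked (%.3g%%)\n",
              nrow(x$pairs), x$n_pairs_checked, 100 * x$fraction))
  invisible(x)
}
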