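#' Construct an arbor object
#'
#' An `arbor` is a rooted 3D tree (or forest) of cylindrical segments: the
#' standard representation of a traced neuron morphology. Nodes carry a
#' position in micrometres, a radius in micrometres and a parent link; soma
#' nodes are tagged by SWC type code 1. All analyses in this package operate
#' on the dendrite-only arbor produced by [strip_soma()].
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (parent id, `-1` for a root).
#' @param name identifier string for the arbor.
#' @param soma_centroid optional 3-vector; retained after soma stripping so
#'   the arbor radius can still be measured from the soma centre.
#' @return An object of class `arbor`.
#' @export
arbor <- function(nodes, name = "arbor", soma_centroid = NULL) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  rownames(nodes) <- NULL
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")])))) {
    stop("non-finite node positions")
  }
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0)) {
    stop("all radii must be positive and finite")
  }
  validate_topology(nodes)
  obj <- list(nodes = nodes, name = name, soma_centroid = soma_centroid)
  class(obj) <- "arbor"
  obj
}

# parent links must form a forest: every non-root parent exists, no cycles
validate_topology <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & is.na(idx))
  if (length(bad) > 0L) {
    stop("structural error: node ", nodes$id[bad[1L]],
         " references missing parent ", nodes$parent[bad[1L]])
  }
  n <- nrow(nodes)
  state <- integer(n) # 0 unvisited, 1 in progress, 2 done
  for (i in seq_len(n)) {
    j <- i
    path <- integer(0)
    while (j != 0L && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      p <- idx[j]
      j <- if (is.na(p)) 0L else p
    }
    if (j != 0L && state[j] == 1L) {
      stop("structural error: cycle through node ", nodes$id[j])
    }
    state[path] <- 2L
  }
  invisible(TRUE)
}

#' @export
print.arbor <- function(x, ...) {
  cat("<arbor> ", x$name, ": ", nrow(x$nodes), " nodes, ",
      length(soma_ids(x)), " soma, ", length(tip_ids(x)), " tips\n", sep = "")
  invisible(x)
}

#' Node ids tagged as soma
#' @param arbor an `arbor`
#' @return integer vector of soma node ids
#' @export
soma_ids <- function(arbor) arbor$nodes$id[arbor$nodes$type == 1L]

#' Tip (terminal) node ids: dendrite nodes with no children
#' @param arbor an `arbor`
#' @return integer vector of tip node ids
#' @export
tip_ids <- function(arbor) {
  nd <- arbor$nodes
  dend <- nd$type != 1L
  has_child <- nd$id %in% nd$parent[dend]
  nd$id[dend & !has_child]
}

node_positions <- function(arbor) {
  as.matrix(arbor$nodes[c("x", "y", "z")])
}

#' Arbor radius
#'
#' The arbor radius `R_A` is the maximum Euclidean distance from the soma
#' centroid to any dendrite node: a simple rotation-invariant measure of
#' arbor size (CA1 basal arbors have a median `R_A` around 100 um).
#'
#' @param arbor an `arbor` (soma-stripped arbors use the retained centroid)
#' @return radius in micrometres
#' @export
arbor_radius <- function(arbor) {
  ctr <- soma_centroid(arbor)
  dend <- arbor$nodes$type != 1L
  if (!any(dend)) stop("arbor has no dendrite nodes")
  pts <- node_positions(arbor)[dend, , drop = FALSE]
  sqrt(max(rowSums((pts - matrix(ctr, nrow(pts), 3L, byrow = TRUE))^2)))
}

soma_centroid <- function(arbor) {
  if (!is.null(arbor$soma_centroid)) return(arbor$soma_centroid)
  sid <- soma_ids(arbor)
  if (length(sid) == 0L) stop("arbor has no soma nodes and no stored centroid")
  colMeans(node_positions(arbor)[match(sid, arbor$nodes$id), , drop = FALSE])
}

#' Remove soma nodes, leaving only the dendritic arbor
#'
#' Soma nodes (SWC type 1) are dropped; each former soma child becomes the
#' root of its own stem, anchored at its original position. The soma
#' centroid is retained as metadata so [arbor_radius()] remains defined.
#'
#' @param arbor an `arbor` with at least one soma node and one dendrite node
#' @return a soma-stripped `arbor`
#' @export
strip_soma <- function(arbor) {
  nd <- arbor$nodes
  sid <- soma_ids(arbor)
  if (length(sid) == 0L) stop("arbor has no soma nodes")
  keep <- !(nd$id %in% sid)
  if (!any(keep)) stop("empty arbor: no dendrite nodes remain after soma removal")
  ctr <- soma_centroid(arbor)
  out <- nd[keep, , drop = FALSE]
  out$parent[out$parent %in% sid] <- -1L
  a <- arbor(out, name = arbor$name, soma_centroid = ctr)
  if (any(a$nodes$type == 1L)) stop("internal error: soma nodes remain")
  a
}

#' Construct a branch
#'
#' A branch is one soma-to-tip path through the arbor, stored as an ordered
#' polyline. `L_B` is its total path length and `L_E` the Euclidean
#' distance between its two ends; `L_E <= L_B` always, with equality only
#' for a perfectly straight branch.
#'
#' @param points n x 3 matrix of ordered positions (um), soma side first
#' @param node_ids optional integer ids matching the rows of `points`
#' @return an object of class `branch` with fields `points`, `node_ids`,
#'   `cum_len`, `L_B`, `L_E`
#' @export
branch <- function(points, node_ids = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L) {
    stop("branch needs an n x 3 matrix with n >= 2")
  }
  dimnames(points) <- NULL
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d == 0)) stop("branch has coincident consecutive points")
  cl <- unname(c(0, cumsum(d)))
  le <- vec_norm(points[nrow(points), ] - points[1L, ])
  if (le <= 0) stop("branch endpoints coincide")
  obj <- list(points = points, node_ids = node_ids, cum_len = cl,
              L_B = cl[length(cl)], L_E = le)
  class(obj) <- "branch"
  obj
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf("<branch> %d points, L_B = %.2f um, L_E = %.2f um\n",
              nrow(x$points), x$L_B, x$L_E))
  invisible(x)
}

#' Decompose an arbor into soma-to-tip branches
#'
#' Every path from a stem root to a terminal tip is one branch, so the
#' number of branches equals the number of tips. Branches descending from
#' the same bifurcation share their proximal sections; the tortuosity
#' analysis removes the resulting duplicate sub-paths
#' (see [deduplicate_paths()]).
#'
#' @param arbor a soma-stripped `arbor`
#' @return list of `branch` objects, one per tip
#' @export
extract_branches <- function(arbor) {
  nd <- arbor$nodes
  if (any(nd$type == 1L)) stop("extract_branches expects a soma-stripped arbor")
  idx <- match(nd$parent, nd$id)
  pts <- node_positions(arbor)
  tips <- tip_ids(arbor)
  lapply(tips, function(tid) {
    path <- integer(0)
    j <- match(tid, nd$id)
    while (!is.na(j)) {
      path <- c(j, path)
      j <- idx[j]
    }
    branch(pts[path, , drop = FALSE], node_ids = nd$id[path])
  })
}

#' Summarize branches as a table
#' @param branches list of `branch` objects from [extract_branches()]
#' @return data frame with branch_id, tip_node, L_B, L_E, n_points
#' @export
branch_table <- function(branches) {
  data.frame(
    branch_id = seq_along(branches),
    tip_node = vapply(branches, function(b) {
      if (is.null(b$node_ids)) NA_integer_ else b$node_ids[length(b$node_ids)]
    }, integer(1)),
    L_B = vapply(branches, function(b) b$L_B, numeric(1)),
    L_E = vapply(branches, function(b) b$L_E, numeric(1)),
    n_points = vapply(branches, function(b) nrow(b$points), integer(1))
  )
}

#' Measure weave and fork angles of an arbor
#'
#' The weave angle `theta` at an interior continuation node is the angle
#' between the incoming and outgoing segment directions. The fork angle
#' `phi` of each child at a branching node is the first weave angle after
#' the branch point: the angle between the segment arriving at the node and
#' the segment leaving towards that child. Multifurcations are allowed;
#' every child at a branching node gets a `phi`. Direction vectors use
#' adjacent node positions only (no smoothing).
#'
#' @param arbor a soma-stripped `arbor`
#' @return an object of class `angle_set`: a list with data frames
#'   `weave` (node_id, theta) and `fork` (node_id, child_id, phi),
#'   all angles in radians within `[0, pi)`
#' @export
measure_angles <- function(arbor) {
  nd <- arbor$nodes
  if (any(nd$type == 1L)) stop("measure_angles expects a soma-stripped arbor")
  idx <- match(nd$parent, nd$id)
  pts <- node_positions(arbor)
  children <- split(seq_len(nrow(nd)), factor(idx, levels = seq_len(nrow(nd))))
  weave <- list()
  fork <- list()
  for (i in seq_len(nrow(nd))) {
    pi_ <- idx[i]
    if (is.na(pi_)) next  # stem root: no incoming direction
    kids <- children[[i]]
    if (length(kids) == 0L) next  # tip
    vin <- pts[i, ] - pts[pi_, ]
    if (vec_norm(vin) < 1e-12) {
      stop("degenerate geometry: zero-length segment into node ", nd$id[i])
    }
    for (k in kids) {
      vout <- pts[k, ] - pts[i, ]
      if (vec_norm(vout) < 1e-12) {
        stop("degenerate geometry: zero-length segment into node ", nd$id[k])
      }
      ang <- angle_between(vin, vout)
      if (length(kids) == 1L) {
        weave[[length(weave) + 1L]] <- data.frame(node_id = nd$id[i], theta = ang)
      } else {
        fork[[length(fork) + 1L]] <-
          data.frame(node_id = nd$id[i], child_id = nd$id[k], phi = ang)
      }
    }
  }
  out <- list(
    weave = if (length(weave)) do.call(rbind, weave)
            else data.frame(node_id = integer(0), theta = numeric(0)),
    fork = if (length(fork)) do.call(rbind, fork)
           else data.frame(node_id = integer(0), child_id = integer(0),
                           phi = numeric(0))
  )
  class(out) <- "angle_set"
  out
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC: node id, type code, x, y, z (um), radius (um),
#' parent id (-1 for a root). Lines starting with `#` are comments. Soma
#' nodes are those with type code 1.
#'
#' @param path path to an SWC file
#' @param name arbor name; defaults to the file name without extension
#' @return an `arbor`
#' @export
read_swc <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("SWC file has no data lines: ", path)
  rows <- lapply(keep, function(ln) {
    fields <- strsplit(trimws(raw[ln]), "\\s+")[[1L]]
    if (length(fields) != 7L) {
      stop("parse error at line ", ln, ": expected 7 fields, got ",
           length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("parse error at line ", ln, ": non-numeric field")
    vals
  })
  m <- do.call(rbind, rows)
  nodes <- data.frame(id = m[, 1L], type = m[, 2L], x = m[, 3L], y = m[, 4L],
                      z = m[, 5L], radius = m[, 6L], parent = m[, 7L])
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  arbor(nodes, name = name)
}

#' Write an arbor to an SWC file
#'
#' Emits the standard 7-column format; output is deterministic for a given
#' arbor so written files round-trip through [read_swc()] exactly.
#'
#' @param arbor an `arbor`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_swc <- function(arbor, path) {
  nd <- arbor$nodes
  lines <- c(
    paste0("# ", arbor$name),
    "# id type x y z radius parent",
    sprintf("%d %d %.17g %.17g %.17g %.17g %d",
            nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text segment list as an arbor
#'
#' Companion format for morphologies exported as bare segment sets: a CSV
#' with header `parent_x,parent_y,parent_z,child_x,child_y,child_z,radius`,
#' one row per cylindrical segment, coordinates in micrometres. Segments
#' are stitched into a tree by matching shared endpoints; points that never
#' appear as a child are stem roots. The result is treated as already
#' soma-stripped, with the soma centroid placed at the root centroid.
#'
#' @param path path to the CSV file
#' @param name arbor name
#' @param tol coordinate matching tolerance in micrometres
#' @return a soma-stripped `arbor`
#' @export
read_segment_list <- function(path, name = NULL, tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  required <- c("parent_x", "parent_y", "parent_z",
                "child_x", "child_y", "child_z", "radius")
  if (!all(required %in% names(df))) {
    stop("segment list must have columns: ", paste(required, collapse = ", "))
  }
  key <- function(x, y, z) paste(round(x / tol), round(y / tol), round(z / tol))
  pk <- key(df$parent_x, df$parent_y, df$parent_z)
  ck <- key(df$child_x, df$child_y, df$child_z)
  all_keys <- unique(c(pk, ck))
  id_of <- stats::setNames(seq_along(all_keys), all_keys)
  coords <- rbind(as.matrix(df[c("parent_x", "parent_y", "parent_z")]),
                  as.matrix(df[c("child_x", "child_y", "child_z")]))
  pos <- coords[match(all_keys, c(pk, ck)), , drop = FALSE]
  parent <- rep(-1L, length(all_keys))
  radius <- rep(NA_real_, length(all_keys))
  for (r in seq_len(nrow(df))) {
    child <- id_of[[ck[r]]]
    if (parent[child] != -1L) {
      stop("structural error: point ", ck[r], " has two parents")
    }
    parent[child] <- id_of[[pk[r]]]
    radius[child] <- df$radius[r]
  }
  # roots inherit the radius of their first outgoing segment
  for (r in seq_len(nrow(df))) {
    p <- id_of[[pk[r]]]
    if (is.na(radius[p])) radius[p] <- df$radius[r]
  }
  nodes <- data.frame(id = seq_along(all_keys), type = 3L,
                      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                      radius = radius, parent = parent)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  roots <- nodes$parent == -1L
  ctr <- colMeans(pos[roots, , drop = FALSE])
  arbor(nodes, name = name, soma_centroid = ctr)
}

# Cylindrical segments of a (soma-stripped) arbor as a data frame:
# one row per child node with its parent position, child position and radius.
arbor_segments <- function(arbor) {
  nd <- arbor$nodes
  idx <- match(nd$parent, nd$id)
  has_parent <- !is.na(idx)
  pts <- node_positions(arbor)
  data.frame(
    child_id = nd$id[has_parent],
    px = pts[idx[has_parent], 1L], py = pts[idx[has_parent], 2L],
    pz = pts[idx[has_parent], 3L],
    cx = pts[has_parent, 1L], cy = pts[has_parent, 2L],
    cz = pts[has_parent, 3L],
    radius = nd$radius[has_parent]
  )
}
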