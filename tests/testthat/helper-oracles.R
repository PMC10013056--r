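# Independent oracles and small fixtures used across the suite.
# Every oracle deliberately takes a different computational route from the
# implementation it checks.

# --- fixtures ---------------------------------------------------------------

# single-cylinder arbor along +x
cylinder_arbor <- function(L = 10, r = 1) {
  arbor(data.frame(id = 1:2, type = 3L, x = c(0, L), y = 0, z = 0,
                   radius = r, parent = c(-1L, 1L)), name = "cyl")
}

# classic three-tip topology: root stem S -> B1, bifurcations at B1 and B2,
# tips E1-E3; the S -> B1 section is shared by all three branches
three_tip_arbor <- function() {
  nodes <- data.frame(
    id = 1:9,
    type = c(1L, rep(3L, 8)),
    x = c(0, 10, 20, 30, 40, 30, 40, 42, 30),
    y = c(0, 0, 0, 10, 15, -10, -12, -20, 12),
    z = 0,
    radius = c(6, rep(0.7, 8)),
    parent = c(-1L, 1L, 2L, 3L, 4L, 3L, 6L, 7L, 4L)
  )
  # id2 stem, id3 = B1 (children 4, 6), id4 = B2 (children 5, 9)
  # tips: 5? no: children(4) = {5, 9} -> B2 is node 4; tips are 5, 8, 9
  arbor(nodes, name = "three_tip")
}

# small soma + chain fixture written as an SWC text block
write_minimal_swc <- function(path) {
  writeLines(c(
    "# minimal",
    "1 1 0 0 0 5 -1",
    "2 3 10 0 0 1 1",
    "3 3 20 0 0 1 2"
  ), path)
  path
}

# rigid motion: fixed rotation + translation applied to an arbor
rigid_transform_arbor <- function(a, angle = 0.7, axis = c(1, 2, 2) / 3,
                                  shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  nd <- a$nodes
  p <- as.matrix(nd[c("x", "y", "z")]) %*% t(R)
  nd$x <- p[, 1] + shift[1]
  nd$y <- p[, 2] + shift[2]
  nd$z <- p[, 3] + shift[3]
  ctr <- a$soma_centroid
  if (!is.null(ctr)) ctr <- as.numeric(R %*% ctr) + shift
  arbor(nd, name = a$name, soma_centroid = ctr)
}

rigid_transform_branch <- function(b, angle = 0.7, axis = c(1, 2, 2) / 3,
                                   shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  branch(sweep(b$points %*% t(R), 2, -shift), node_ids = b$node_ids)
}

# --- ruler-marching oracle --------------------------------------------------

# dense-sampling divider oracle: march along the polyline in tiny arc-length
# steps, record the first point at distance L_R from the current centre
# (refined by bisection), and count the truncated remainder as a fraction.
oracle_ruler_count <- function(b, L_R, step = 1e-3) {
  pts <- b$points
  cl <- b$cum_len
  total <- b$L_B
  point_at <- function(s) {
    i <- findInterval(s, cl, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(cl) - 1L)
    f <- (s - cl[i]) / (cl[i + 1L] - cl[i])
    pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
  }
  s_grid <- unique(c(seq(0, total, by = step), total))
  P <- t(vapply(s_grid, point_at, numeric(3)))
  centre <- pts[1L, ]
  s_c <- 0
  n_full <- 0L
  repeat {
    d2 <- rowSums(sweep(P, 2L, centre)^2)
    beyond <- which(s_grid > s_c + 1e-12 & d2 >= L_R^2)
    if (length(beyond) == 0L) break
    j <- beyond[1L]
    lo <- max(s_c, s_grid[j - 1L])
    hi <- s_grid[j]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (sum((point_at(mid) - centre)^2) >= L_R^2) hi <- mid else lo <- mid
    }
    s_c <- (lo + hi) / 2
    centre <- point_at(s_c)
    n_full <- n_full + 1L
  }
  truncated <- if (s_c < total - 1e-9) {
    sqrt(sum((pts[nrow(pts), ] - centre)^2))
  } else 0
  n_full + truncated / L_R
}

# --- box-count oracle -------------------------------------------------------

# voxelization oracle: sample all segments at a fixed fine spacing, key each
# point by integer voxel triple (string keys, independent of the package's
# numeric hashing)
oracle_box_count <- function(a, L_box, spacing = 0.01) {
  nd <- a$nodes
  idx <- match(nd$parent, nd$id)
  pts_list <- list(as.matrix(nd[is.na(idx), c("x", "y", "z")]))
  for (i in which(!is.na(idx))) {
    p <- as.numeric(nd[idx[i], c("x", "y", "z")])
    q <- as.numeric(nd[i, c("x", "y", "z")])
    len <- sqrt(sum((q - p)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
    pts_list[[length(pts_list) + 1L]] <-
      cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]),
            p[3] + tt * (q[3] - p[3]))
  }
  pts <- do.call(rbind, pts_list)
  origin <- apply(pts, 2L, min)
  shifted <- sweep(pts, 2L, origin)
  v <- floor(shifted / L_box + 1e-12)
  hi <- pmax(0, ceiling(apply(shifted, 2L, max) / L_box - 1e-9) - 1)
  for (k in 1:3) v[, k] <- pmin(v[, k], hi[k])
  length(unique(paste(v[, 1], v[, 2], v[, 3])))
}

# --- convex hull oracle -----------------------------------------------------

# brute-force facet enumeration for small point sets in generic position:
# a triple is a hull facet iff all remaining points lie on one side
oracle_hull <- function(pts) {
  n <- nrow(pts)
  centroid <- colMeans(pts)
  area <- 0
  volume <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    nrm <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    s <- as.numeric(sweep(pts[-c(i, j, k), , drop = FALSE], 2L, a) %*% nrm)
    if (all(s < 0) || all(s > 0)) {
      area <- area + sqrt(sum(nrm^2)) / 2
      u <- a - centroid; v <- b - centroid; w <- c_ - centroid
      volume <- volume + abs(u[1] * (v[2] * w[3] - v[3] * w[2]) -
                               u[2] * (v[1] * w[3] - v[3] * w[1]) +
                               u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
    }
  }
  list(area = area, volume = volume)
}

# --- tree path enumeration oracle -------------------------------------------

# unique vertex-to-vertex sub-paths along soma-to-tip branches equal the
# ancestor-descendant pairs of the stripped forest: sum over nodes of depth
oracle_unique_path_count <- function(stripped) {
  nd <- stripped$nodes
  idx <- match(nd$parent, nd$id)
  sum(vapply(seq_len(nrow(nd)), function(i) {
    d <- 0L
    j <- idx[i]
    while (!is.na(j)) {
      d <- d + 1L
      j <- idx[j]
    }
    d
  }, integer(1)))
}
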