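# Incremental 3D convex hull. No pre-existing R dependency in this stack
# provides 3D hulls, so a standard incremental (beneath-beyond) algorithm
# is implemented here: seed a tetrahedron, then for each remaining point
# find the faces it can see, remove them, and stitch new faces along the
# horizon edges. Adequate for the point counts of traced morphologies
# (hundreds to thousands of nodes).

#' 3D convex hull of a point set
#'
#' @param pts n x 3 matrix of points (n >= 4, not all coplanar)
#' @return list with `faces` (m x 3 matrix of point indices, outward
#'   oriented), `area` (surface area) and `volume`
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("degenerate hull: need at least 4 points")
  scale <- max(1, max(abs(pts)))
  eps <- 1e-10 * scale
  seed <- hull_seed(pts, eps)
  if (is.null(seed)) stop("degenerate hull: points are coplanar or collinear")
  centroid <- colMeans(pts[seed, , drop = FALSE])
  faces <- list(c(seed[1L], seed[2L], seed[3L]),
                c(seed[1L], seed[2L], seed[4L]),
                c(seed[1L], seed[3L], seed[4L]),
                c(seed[2L], seed[3L], seed[4L]))
  faces <- lapply(faces, orient_face, pts = pts, interior = centroid)
  for (v in setdiff(seq_len(n), seed)) {
    vis <- vapply(faces, function(f) face_sees(pts, f, pts[v, ], eps),
                  logical(1))
    if (!any(vis)) next
    # horizon: edges shared by exactly one visible face
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(f[c(1L, 2L)], f[c(2L, 3L)], f[c(3L, 1L)])
    }))
    keys <- paste(pmin(edges[, 1L], edges[, 2L]),
                  pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[keys %in% names(which(table(keys) == 1L)), ,
                     drop = FALSE]
    faces <- faces[!vis]
    # the seed tetrahedron centroid stays strictly interior as the hull grows
    for (e in seq_len(nrow(horizon))) {
      faces[[length(faces) + 1L]] <-
        orient_face(c(horizon[e, ], v), pts, centroid)
    }
  }
  fm <- do.call(rbind, faces)
  area <- 0
  volume <- 0
  ref <- colMeans(pts)
  for (r in seq_len(nrow(fm))) {
    a <- pts[fm[r, 1L], ]; b <- pts[fm[r, 2L], ]; c_ <- pts[fm[r, 3L], ]
    cr <- cross3(b - a, c_ - a)
    area <- area + vec_norm(cr) / 2
    volume <- volume + sum(cross3(b - ref, c_ - ref) * (a - ref)) / 6
  }
  list(faces = fm, area = area, volume = abs(volume))
}

# four affinely independent points, or NULL
hull_seed <- function(pts, eps) {
  n <- nrow(pts)
  i1 <- 1L
  d <- sqrt(rowSums(sweep(pts, 2L, pts[i1, ])^2))
  i2 <- which.max(d)
  if (d[i2] < eps) return(NULL)
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(w[, 2L] * u[3L] - w[, 3L] * u[2L],
              w[, 3L] * u[1L] - w[, 1L] * u[3L],
              w[, 1L] * u[2L] - w[, 2L] * u[1L])
  d2 <- sqrt(rowSums(cr^2))
  i3 <- which.max(d2)
  if (d2[i3] < eps) return(NULL)
  nrm <- cross3(u, pts[i3, ] - pts[i1, ])
  d3 <- abs(as.numeric(w %*% nrm)) / vec_norm(nrm)
  i4 <- which.max(d3)
  if (d3[i4] < eps) return(NULL)
  c(i1, i2, i3, i4)
}

orient_face <- function(f, pts, interior) {
  nrm <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
  if (sum(nrm * (interior - pts[f[1L], ])) > 0) f[c(1L, 3L, 2L)] else f
}

face_sees <- function(pts, f, p, eps) {
  nrm <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
  sum(nrm * (p - pts[f[1L], ])) > eps * vec_norm(nrm)
}
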