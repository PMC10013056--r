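# Connectivity and cost metrics of an arbor:
#   P   view-averaged expanded profile area (connectivity proxy)
#   A_s dendrite surface area (operating-cost proxy)
#   V_m dendrite volume (building-cost proxy)
#   A_b, V_b convex-hull bounding area and volume (size normalizers)

#' Deterministic, near-uniform view directions (Fibonacci sphere)
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# centerline samples with per-point dilation radius (segment radius carried)
sampled_centerline <- function(arbor, spacing) {
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0L) stop("empty arbor: no segments")
  pts <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- resample_polyline(rbind(c(seg$px[i], seg$py[i], seg$pz[i]),
                                 c(seg$cx[i], seg$cy[i], seg$cz[i])), spacing)
    pts[[i]] <- cbind(s, seg$radius[i])
  }
  do.call(rbind, pts)
}

#' View-averaged expanded profile area
#'
#' Orthogonally projects the arbor onto a plane perpendicular to each view
#' direction, uniformly expands the projected silhouette by `expansion`
#' micrometres (accounting for spine growth around each dendrite), measures
#' the expanded profile area on a pixel raster, and averages over the
#' views. Views are deterministic Fibonacci-sphere directions; projection
#' areas are computed on a raster with disk dilation of radius
#' (segment radius + expansion) around the densely sampled centerline.
#'
#' @param arbor an `arbor`
#' @param expansion silhouette expansion in um (default 2)
#' @param n_views number of view directions (ignored when `directions`
#'   given)
#' @param pixel raster pixel size in um
#' @param directions optional m x 3 matrix of explicit view directions
#' @return mean profile area in um^2
#' @export
profile_area <- function(arbor, expansion = 2, n_views = 64, pixel = 0.5,
                         directions = NULL) {
  stopifnot(expansion >= 0, pixel > 0)
  if (is.null(directions)) {
    stopifnot(n_views >= 1)
    directions <- fibonacci_directions(n_views)
  }
  directions <- matrix(directions, ncol = 3L)
  samples <- sampled_centerline(arbor, spacing = pixel / 2)
  pts <- samples[, 1:3, drop = FALSE]
  dil <- samples[, 4L] + expansion
  # candidate disk offsets (in cells) per distinct dilation radius; a cell
  # is occupied when its centre lies within the radius of a sample point
  radii <- sort(unique(dil))
  offsets <- lapply(radii, function(r) {
    m <- ceiling(r / pixel) + 1L
    g <- expand.grid(dx = -m:m, dy = -m:m)
    keep <- (pmax(0, sqrt(g$dx^2 + g$dy^2) - sqrt(2)))^2 * pixel^2 <= r^2
    g[keep, , drop = FALSE]
  })
  rad_class <- match(dil, radii)
  areas <- apply(directions, 1L, function(u) {
    u <- unit_vec(u)
    e1 <- perp_vector(u)
    e2 <- cross3(u, e1)
    x <- as.numeric(pts %*% e1)
    y <- as.numeric(pts %*% e2)
    px <- floor(x / pixel)
    py <- floor(y / pixel)
    # offset of each sample point from its cell centre
    ax <- (px + 0.5) * pixel - x
    ay <- (py + 0.5) * pixel - y
    occ <- vector("list", length(radii))
    for (k in seq_along(radii)) {
      sel <- rad_class == k
      if (!any(sel)) next
      off <- offsets[[k]]
      d2 <- outer(ax[sel], off$dx * pixel, `+`)^2 +
        outer(ay[sel], off$dy * pixel, `+`)^2
      hit <- d2 <= radii[k]^2
      cx <- outer(px[sel], off$dx, `+`)[hit]
      cy <- outer(py[sel], off$dy, `+`)[hit]
      occ[[k]] <- unique(cx + 1e5 * cy)
    }
    length(unique(unlist(occ))) * pixel^2
  })
  mean(areas)
}

#' Dendrite surface area
#'
#' Tessellates the lateral surface of every cylindrical segment into
#' triangular faces, removes faces whose three corners all lie strictly
#' inside another segment's cylinder (junction overlap correction), and
#' sums the remaining face areas.
#'
#' @param arbor an `arbor`
#' @param n_theta circumferential facets after subdivision (default 32,
#'   i.e. a 16-facet prism subdivided once)
#' @param max_axial cap on axial subdivisions per segment
#' @return surface area in um^2
#' @export
dendrite_surface_area <- function(arbor, n_theta = 32, max_axial = 8) {
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0L) stop("empty arbor: no segments")
  p1 <- as.matrix(seg[c("px", "py", "pz")])
  p2 <- as.matrix(seg[c("cx", "cy", "cz")])
  lens <- sqrt(rowSums((p2 - p1)^2))
  verts <- list()
  tris <- list()   # each row: 3 vertex indices + owner segment
  offset <- 0L
  for (i in seq_len(nrow(seg))) {
    L <- lens[i]
    if (L < 1e-12) next
    axis <- (p2[i, ] - p1[i, ]) / L
    e1 <- perp_vector(axis)
    e2 <- cross3(axis, e1)
    r <- seg$radius[i]
    n_len <- max(2L, min(max_axial, ceiling(L / r)))
    th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
    ring <- outer(cos(th), e1) + outer(sin(th), e2)
    zs <- seq(0, L, length.out = n_len + 1L)
    v <- do.call(rbind, lapply(zs, function(z) {
      sweep(r * ring, 2L, p1[i, ] + z * axis, `+`)
    }))
    verts[[length(verts) + 1L]] <- v
    # quad (t, z) -> two triangles; vertex index = offset + z*n_theta + t
    tq <- expand.grid(t = seq_len(n_theta), z = seq_len(n_len))
    a <- offset + (tq$z - 1L) * n_theta + tq$t
    b <- offset + (tq$z - 1L) * n_theta + (tq$t %% n_theta) + 1L
    c_ <- a + n_theta
    d <- b + n_theta
    tris[[length(tris) + 1L]] <- cbind(rbind(cbind(a, b, c_),
                                             cbind(b, d, c_)), i)
    offset <- offset + nrow(v)
  }
  V <- do.call(rbind, verts)
  Tm <- do.call(rbind, tris)
  inside <- rep(FALSE, nrow(V))
  owner <- rep(which(lens >= 1e-12), vapply(verts, nrow, integer(1)))
  tol <- 1e-9
  for (s in seq_len(nrow(seg))) {
    L <- lens[s]
    if (L < 1e-12) next
    axis <- (p2[s, ] - p1[s, ]) / L
    r <- seg$radius[s]
    cand <- which(owner != s & !inside)
    if (length(cand) == 0L) next
    w <- sweep(V[cand, , drop = FALSE], 2L, p1[s, ])
    t <- as.numeric(w %*% axis)
    sel <- t > tol & t < L - tol
    if (!any(sel)) next
    radial2 <- rowSums(w[sel, , drop = FALSE]^2) - t[sel]^2
    hit <- radial2 < (r - tol)^2
    inside[cand[sel][hit]] <- TRUE
  }
  keep <- !(inside[Tm[, 1L]] & inside[Tm[, 2L]] & inside[Tm[, 3L]])
  tri_area <- function(rows) {
    a <- V[rows[, 1L], , drop = FALSE]
    b <- V[rows[, 2L], , drop = FALSE]
    c_ <- V[rows[, 3L], , drop = FALSE]
    u <- b - a; w <- c_ - a
    cr <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  tri_area(Tm[keep, 1:3, drop = FALSE])
}

#' Dendrite volume
#'
#' Sum of cylinder volumes `pi r^2 L` over all segments. Junction overlaps
#' are ignored (segment-wise model); with thin dendrites relative to their
#' lengths the approximation error is small.
#'
#' @param arbor an `arbor`
#' @return volume in um^3
#' @export
dendrite_volume <- function(arbor) {
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0L) stop("empty arbor: no segments")
  lens <- sqrt((seg$cx - seg$px)^2 + (seg$cy - seg$py)^2 +
                 (seg$cz - seg$pz)^2)
  sum(pi * seg$radius^2 * lens)
}

#' Bounding convex hull area and volume
#'
#' Convex hull of all node positions; `A_b` is its surface area and `V_b`
#' its volume.
#'
#' @param arbor an `arbor` with at least 4 non-coplanar nodes
#' @return list with `A_b` (um^2) and `V_b` (um^3)
#' @export
bounding_hull <- function(arbor) {
  h <- convex_hull_3d(node_positions(arbor))
  list(A_b = h$area, V_b = h$volume)
}

#' All connectivity/cost metrics for one arbor
#'
#' @param arbor an `arbor`
#' @param expansion profile expansion in um
#' @param n_views number of profile view directions
#' @param pixel profile raster pixel size in um
#' @return an object of class `arbor_metrics`: list with `P`, `A_s`,
#'   `V_m`, `A_b`, `V_b` and the normalized ratios `P_Ab`, `As_Ab`,
#'   `Vm_Vb`
#' @export
arbor_metrics <- function(arbor, expansion = 2, n_views = 64, pixel = 0.5) {
  hull <- bounding_hull(arbor)
  P <- profile_area(arbor, expansion = expansion, n_views = n_views,
                    pixel = pixel)
  A_s <- dendrite_surface_area(arbor)
  V_m <- dendrite_volume(arbor)
  out <- list(P = P, A_s = A_s, V_m = V_m, A_b = hull$A_b, V_b = hull$V_b,
              P_Ab = P / hull$A_b, As_Ab = A_s / hull$A_b,
              Vm_Vb = V_m / hull$V_b)
  class(out) <- "arbor_metrics"
  out
}

#' @export
print.arbor_metrics <- function(x, ...) {
  cat(sprintf(paste0("<arbor_metrics> P = %.1f um^2, A_s = %.1f um^2, ",
                     "V_m = %.1f um^3, A_b = %.1f um^2, V_b = %.1f um^3\n"),
              x$P, x$A_s, x$V_m, x$A_b, x$V_b))
  invisible(x)
}

#' Connectivity-cost balance curves across a distortion ensemble
#'
#' Fits each size-normalized metric (connectivity `P/A_b`, operating cost
#' `A_s/A_b`, building cost `V_m/V_b`) as a smooth quadratic in the arbor
#' dimension `D_A`, differentiates analytically, and returns the derivative
#' ratios
#' `R_PA = d(P/A_b)/dD_A / d(A_s/A_b)/dD_A` and
#' `R_PV = d(P/A_b)/dD_A / d(V_m/V_b)/dD_A`
#' on a `D_A` grid. Grid points where the denominator derivative is within
#' `singular_tol` of zero are masked (`NA`), never extrapolated.
#'
#' @param ensemble data frame with one row per ensemble condition (e.g.
#'   per angle multiplier): columns `D_A`, `P_Ab`, `As_Ab`, `Vm_Vb`
#' @param grid_n number of `D_A` evaluation points
#' @param singular_tol denominator magnitude below which the ratio is
#'   masked
#' @return an object of class `balance_curves`: list with `coefs`
#'   (quadratic coefficients per metric), `D_A` grid, `R_PA`, `R_PV` and
#'   `masked` flags
#' @export
balance_curves <- function(ensemble, grid_n = 50, singular_tol = 1e-8) {
  need <- c("D_A", "P_Ab", "As_Ab", "Vm_Vb")
  if (!all(need %in% names(ensemble))) {
    stop("ensemble must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(ensemble$D_A)) < 4L) {
    stop("need at least 4 distinct D_A values for a quadratic fit")
  }
  fit_one <- function(y) {
    unname(stats::coef(stats::lm(y ~ D_A + I(D_A^2), data = ensemble)))
  }
  coefs <- list(P_Ab = fit_one(ensemble$P_Ab),
                As_Ab = fit_one(ensemble$As_Ab),
                Vm_Vb = fit_one(ensemble$Vm_Vb))
  deriv <- function(co, d) co[2L] + 2 * co[3L] * d
  d_grid <- seq(min(ensemble$D_A), max(ensemble$D_A), length.out = grid_n)
  num <- deriv(coefs$P_Ab, d_grid)
  den_a <- deriv(coefs$As_Ab, d_grid)
  den_v <- deriv(coefs$Vm_Vb, d_grid)
  mask_a <- abs(den_a) < singular_tol
  mask_v <- abs(den_v) < singular_tol
  R_PA <- ifelse(mask_a, NA_real_, num / den_a)
  R_PV <- ifelse(mask_v, NA_real_, num / den_v)
  out <- list(coefs = coefs, D_A = d_grid, R_PA = R_PA, R_PV = R_PV,
              masked = list(R_PA = mask_a, R_PV = mask_v))
  class(out) <- "balance_curves"
  out
}
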