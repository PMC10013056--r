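# Internal geometry helpers shared across modules. All coordinates are in
# micrometres; angles in radians.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Angle in [0, pi] between two vectors; robust to rounding at the ends.
angle_between <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  acos(min(1, max(-1, ca)))
}

# Rotate vector v by angle ang about unit axis (Rodrigues).
rotate_about <- function(v, axis, ang) {
  k <- axis
  v * cos(ang) + cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
}

# Any unit vector perpendicular to unit vector t (deterministic choice).
perp_vector <- function(t) {
  ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(cross3(t, ref))
}

# Rotation matrix sending unit vector 'from' onto unit vector 'to' by the
# minimal rotation; identity when they coincide.
rotation_between <- function(from, to) {
  axis <- cross3(from, to)
  s <- vec_norm(axis)
  c_ <- sum(from * to)
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate by pi about any perpendicular axis
    axis <- perp_vector(from)
    s <- 0
  } else {
    axis <- axis / s
  }
  ang <- atan2(s, c_)
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Cumulative arc length along an n x 3 polyline matrix.
cumulative_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Resample a polyline at fixed arc-length spacing (keeps both endpoints).
resample_polyline <- function(pts, spacing) {
  stopifnot(spacing > 0)
  cl <- cumulative_arclength(pts)
  total <- cl[length(cl)]
  if (total == 0) return(pts[1L, , drop = FALSE])
  s <- seq(0, total, by = spacing)
  if (s[length(s)] < total) s <- c(s, total)
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg[seg >= length(cl)] <- length(cl) - 1L
  frac <- (s - cl[seg]) / (cl[seg + 1L] - cl[seg])
  pts[seg, , drop = FALSE] +
    (pts[seg + 1L, , drop = FALSE] - pts[seg, , drop = FALSE]) * frac
}

# log-spaced grid of n values between lo and hi (inclusive)
log_spaced <- function(lo, hi, n) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  10^seq(log10(lo), log10(hi), length.out = n)
}

# Ordinary least squares of log10(y) on log10(x); returns slope, its
# standard error and the intercept. Base-10 logs throughout.
loglog_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  lx <- log10(x)
  ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  # summary.lm warns on an exactly perfect fit (stderr 0); that case is
  # legitimate here (e.g. straight branches), so silence it
  co <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(co) >= 2L && ncol(co) >= 2L) co["lx", "Std. Error"] else NA_real_
  if (is.nan(se)) se <- 0
  list(slope = unname(stats::coef(fit)[["lx"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       stderr = unname(se))
}

# Minimum distance between two 3D segments p1-p2 and q1-q2.
segment_segment_distance <- function(p1, p2, q1, q2) {
  u <- p2 - p1
  v <- q2 - q1
  w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c_ <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c_ - b * b
  sc <- 0; tc <- 0
  if (D > 1e-14) {
    sc <- (b * e - c_ * d) / D
    tc <- (a * e - b * d) / D
  } else {
    sc <- 0
    tc <- if (c_ > 1e-14) e / c_ else 0
  }
  sc <- min(1, max(0, sc))
  # re-clamp tc for the clamped sc, then sc again (standard two-pass clamp)
  tc <- if (c_ > 1e-14) (e + sc * b) / c_ else 0
  tc <- min(1, max(0, tc))
  sc2 <- if (a > 1e-14) (b * tc - d) / a else 0
  sc2 <- min(1, max(0, sc2))
  vec_norm((p1 + sc2 * u) - (q1 + tc * v))
}
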