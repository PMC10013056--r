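test_that("profile area matches closed-form silhouettes", {
  seg <- cylinder_arbor(L = 20, r = 1)
  # perpendicular view: stadium of radius r + expansion
  expect_equal(profile_area(seg, expansion = 2, directions = c(0, 0, 1)),
               20 * 2 * 3 + pi * 3^2, tolerance = 0.02)
  # view along the axis: disk
  expect_equal(profile_area(seg, expansion = 2, directions = c(1, 0, 0)),
               pi * 3^2, tolerance = 0.02)
  # view average converges to capsule surface / 4 (mean projection)
  capsule <- 2 * pi * 3 * 20 + 4 * pi * 3^2
  expect_equal(profile_area(seg, expansion = 2, n_views = 128),
               capsule / 4, tolerance = 0.02)
})

test_that("profile area is monotone in the expansion", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 5,
                                                    target_tips = 6,
                                                    max_extent = 50)))
  areas <- vapply(c(0, 1, 2, 4), function(e) {
    profile_area(a, expansion = e, n_views = 8)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("dendrite surface area matches cylinder closed forms", {
  expect_equal(dendrite_surface_area(cylinder_arbor(10, 1)), 2 * pi * 10,
               tolerance = 0.01)
  # two disjoint cylinders: the areas add
  two <- arbor(data.frame(id = 1:4, type = 3L,
                          x = c(0, 10, 0, 10), y = c(0, 0, 50, 50), z = 0,
                          radius = 1, parent = c(-1L, 1L, -1L, 3L)),
               soma_centroid = c(0, 0, 0))
  expect_equal(dendrite_surface_area(two), 2 * (2 * pi * 10),
               tolerance = 0.01)
  # a thin cylinder fully inside a fat collinear one contributes ~nothing
  nested <- arbor(data.frame(id = 1:4, type = 3L,
                             x = c(0, 10, 2, 8), y = 0, z = 0,
                             radius = c(2, 2, 0.5, 0.5),
                             parent = c(-1L, 1L, -1L, 3L)),
                  soma_centroid = c(0, 0, 0))
  outer_only <- dendrite_surface_area(cylinder_arbor(10, 2))
  expect_equal(dendrite_surface_area(nested), outer_only, tolerance = 0.02)
})

test_that("dendrite volume sums cylinders and splitting conserves it", {
  expect_equal(dendrite_volume(cylinder_arbor(10, 1)), 10 * pi,
               tolerance = 1e-9)
  split2 <- arbor(data.frame(id = 1:3, type = 3L, x = c(0, 5, 10), y = 0,
                             z = 0, radius = 1, parent = c(-1L, 1L, 2L)),
                  soma_centroid = c(0, 0, 0))
  expect_equal(dendrite_volume(split2), 10 * pi, tolerance = 1e-9)
})

test_that("bounding hulls match closed forms and a brute-force oracle", {
  # unit cube corners (plus interior noise): A = 6, V = 1
  set.seed(1)
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
               matrix(runif(30, 0.2, 0.8), 10, 3))
  h <- convex_hull_3d(pts)
  expect_equal(h$area, 6, tolerance = 1e-9)
  expect_equal(h$volume, 1, tolerance = 1e-9)

  # regular tetrahedron of edge 1
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    (2 * sqrt(2))
  h2 <- convex_hull_3d(v)
  expect_equal(h2$area, sqrt(3), tolerance = 1e-9)
  expect_equal(h2$volume, 1 / (6 * sqrt(2)), tolerance = 1e-9)

  # random point sets against the facet-enumeration oracle
  for (s in 1:5) {
    set.seed(100 + s)
    p <- matrix(rnorm(36), 12, 3)
    h3 <- convex_hull_3d(p)
    o <- oracle_hull(p)
    expect_equal(h3$area, o$area, tolerance = 1e-9)
    expect_equal(h3$volume, o$volume, tolerance = 1e-9)
  }

  # degenerate (coplanar) input errors
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(convex_hull_3d(flat), "degenerate")
})

test_that("metrics are invariant under rigid motion", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 3,
                                                    target_tips = 6,
                                                    max_extent = 50)))
  b <- rigid_transform_arbor(a)
  expect_equal(dendrite_volume(b), dendrite_volume(a), tolerance = 1e-9)
  # tessellation frames rotate with the arbor, so facet areas shift at the
  # discretization level
  expect_equal(dendrite_surface_area(b), dendrite_surface_area(a),
               tolerance = 1e-3)
  ha <- bounding_hull(a)
  hb <- bounding_hull(b)
  expect_equal(hb$A_b, ha$A_b, tolerance = 1e-6)
  expect_equal(hb$V_b, ha$V_b, tolerance = 1e-6)
  # profile area within view-sampling error
  expect_equal(profile_area(b, n_views = 32), profile_area(a, n_views = 32),
               tolerance = 0.03)
})

test_that("arbor_metrics bundles all quantities with sane relations", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 6,
                                                    target_tips = 6,
                                                    max_extent = 50)))
  m <- arbor_metrics(a, n_views = 8)
  expect_true(all(unlist(m[c("P", "A_s", "V_m", "A_b", "V_b")]) > 0))
  expect_lt(m$V_m, m$V_b)
  expect_equal(m$P_Ab, m$P / m$A_b)
  expect_equal(m$As_Ab, m$A_s / m$A_b)
  expect_equal(m$Vm_Vb, m$V_m / m$V_b)
})

test_that("balance curves recover analytic derivative ratios", {
  d <- seq(1.1, 1.6, length.out = 7)
  lin <- data.frame(D_A = d, P_Ab = 2 * d, As_Ab = 4 * d, Vm_Vb = d)
  bc <- balance_curves(lin)
  expect_equal(bc$R_PA, rep(0.5, length(bc$D_A)), tolerance = 1e-8)
  expect_equal(bc$R_PV, rep(2, length(bc$D_A)), tolerance = 1e-8)

  # quadratic numerator with vertex inside the range: sign change there
  vertex <- 1.35
  quad <- data.frame(D_A = d, P_Ab = (d - vertex)^2, As_Ab = 4 * d,
                     Vm_Vb = d)
  bc2 <- balance_curves(quad, grid_n = 201)
  signs <- sign(bc2$R_PA)
  flip <- bc2$D_A[which(diff(signs) != 0)[1]]
  expect_equal(flip, vertex, tolerance = 0.01)

  # flat denominator is masked, not fabricated
  flat <- data.frame(D_A = d, P_Ab = 2 * d, As_Ab = 1, Vm_Vb = d)
  bc3 <- balance_curves(flat)
  expect_true(all(is.na(bc3$R_PA)))
  expect_true(all(is.finite(bc3$R_PV)))
  expect_error(balance_curves(lin[1:3, ]), "at least 4")
})
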