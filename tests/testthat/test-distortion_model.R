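test_that("angle decomposition round-trips arbors at alpha = 1", {
  for (s in 1:4) {
    a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = s,
                                                      target_tips = 10)))
    g <- decompose_to_angles(a)
    b <- apply_angle_multiplier(g, 1)
    expect_lt(max(abs(as.matrix(b$nodes[c("x", "y", "z")]) -
                        as.matrix(a$nodes[c("x", "y", "z")]))), 1e-6)
    expect_equal(b$nodes$radius, a$nodes$radius)
  }
})

test_that("decomposition handles straight and planar zigzag paths", {
  coll <- arbor(data.frame(id = 1:4, type = c(1L, rep(3L, 3)),
                           x = c(0, 1, 2, 3), y = 0, z = 0, radius = 1,
                           parent = c(-1L, 1L, 2L, 3L)))
  g <- decompose_to_angles(strip_soma(coll))
  expect_equal(g$bend[!is.na(g$bend)], 0)
  expect_equal(g$torsion[!is.na(g$torsion)], 0)

  zig <- arbor(data.frame(id = 1:6, type = c(1L, rep(3L, 5)),
                          x = c(-1, 0, 1, 2, 3, 4),
                          y = c(0, 0, 1, 0, 1, 0), z = 0, radius = 1,
                          parent = c(-1L, 1L, 2L, 3L, 4L, 5L)))
  gz <- decompose_to_angles(strip_soma(zig))
  bends <- gz$bend[!is.na(gz$bend)]
  expect_equal(bends, rep(pi / 2, 3), tolerance = 1e-12)
  tors <- gz$torsion[!is.na(gz$torsion)]
  # alternating bending sides: consecutive torsions are pi apart
  circ <- abs((diff(tors) + pi) %% (2 * pi) - pi)
  expect_equal(circ, rep(pi, length(circ)), tolerance = 1e-9)

  # zero-length segment is a degenerate-geometry error
  dup <- arbor(data.frame(id = 1:3, type = c(1L, 3L, 3L),
                          x = c(0, 1, 1), y = 0, z = 0, radius = 1,
                          parent = c(-1L, 1L, 2L)))
  expect_error(decompose_to_angles(strip_soma(dup)), "zero-length")
})

test_that("measured angles scale exactly with the multiplier", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 7,
                                                    target_tips = 8)))
  ang0 <- measure_angles(a)
  d <- distort_arbor(a, 1.5)
  ang1 <- measure_angles(d)
  m0 <- ang0$weave$theta[order(ang0$weave$node_id)]
  m1 <- ang1$weave$theta[order(ang1$weave$node_id)]
  expect_equal(m1, 1.5 * m0, tolerance = 1e-9)
  f0 <- ang0$fork[order(ang0$fork$child_id), ]
  f1 <- ang1$fork[order(ang1$fork$child_id), ]
  expect_equal(f1$phi, 1.5 * f0$phi, tolerance = 1e-9)
})

test_that("alpha = 0 straightens every branch and lengths are preserved", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 3,
                                                    target_tips = 8)))
  g <- decompose_to_angles(a)
  s <- suppressWarnings(apply_angle_multiplier(g, 0))
  tb <- branch_table(extract_branches(s))
  expect_equal(tb$L_E, tb$L_B, tolerance = 1e-9)

  # alpha = 2 curls branches: L_B conserved, L_E strictly decreases
  tb0 <- branch_table(extract_branches(a))
  c2 <- suppressWarnings(apply_angle_multiplier(g, 2))
  tb2 <- branch_table(extract_branches(c2))
  expect_equal(tb2$L_B, tb0$L_B, tolerance = 1e-9)
  expect_true(all(tb2$L_E < tb0$L_E))
})

test_that("out-of-range multipliers warn and scaled angles clip below pi", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 1,
                                                    target_tips = 6)))
  g <- decompose_to_angles(a)
  expect_warning(
    withCallingHandlers(
      apply_angle_multiplier(g, 3),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    "outside")
  # a sharply bent elbow forces clipping at alpha = 2
  elbow <- arbor(data.frame(id = 1:4, type = c(1L, rep(3L, 3)),
                            x = c(-1, 0, 1, 0.8), y = c(0, 0, 0, 0.2),
                            z = 0, radius = 1,
                            parent = c(-1L, 1L, 2L, 3L)))
  ge <- decompose_to_angles(strip_soma(elbow))
  expect_warning(out <- apply_angle_multiplier(ge, 2), "clipped")
  expect_gt(attr(out, "clip_count"), 0)
})

test_that("self-intersection reports count offending pairs only", {
  # two parallel stems 10 um apart: clean at 2 um clearance
  par2 <- arbor(data.frame(id = 1:4, type = 3L,
                           x = c(0, 20, 0, 20), y = c(0, 0, 10, 10), z = 0,
                           radius = 0.7, parent = c(-1L, 1L, -1L, 3L)),
                soma_centroid = c(0, 0, 0))
  expect_equal(nrow(self_intersection_report(par2, 2)$pairs), 0)

  # two crossing stems: exactly one offending pair
  cross <- arbor(data.frame(id = 1:4, type = 3L,
                            x = c(-10, 10, 0, 0), y = c(0, 0, -10, 10),
                            z = c(0, 0, 0.5, 0.5),
                            radius = 0.7, parent = c(-1L, 1L, -1L, 3L)),
                 soma_centroid = c(0, 0, 0))
  rep2 <- self_intersection_report(cross, 2)
  expect_equal(nrow(rep2$pairs), 1)

  # natural-statistics arbors rarely intersect across the alpha range
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 4)))
  g <- decompose_to_angles(a)
  for (al in c(0.5, 1, 2)) {
    d <- suppressWarnings(apply_angle_multiplier(g, al))
    expect_lt(self_intersection_report(d)$fraction, 0.01)
  }
})

test_that("dendrite volume is exactly invariant under distortion", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 2,
                                                    target_tips = 8)))
  v0 <- dendrite_volume(a)
  for (al in c(0.5, 1.5)) {
    expect_equal(dendrite_volume(distort_arbor(a, al)), v0,
                 tolerance = 1e-9)
  }
})
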