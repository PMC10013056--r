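test_that("SWC reading handles minimal files, types and units", {
  f <- withr::local_tempfile(fileext = ".swc")
  write_minimal_swc(f)
  a <- read_swc(f)
  expect_s3_class(a, "arbor")
  expect_equal(nrow(a$nodes), 3)
  expect_equal(soma_ids(a), 1L)
  expect_equal(tip_ids(a), 3L)
})

test_that("SWC structural and parse errors are reported precisely", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "5 3 1 0 0 1 99"), f)
  expect_error(read_swc(f), "missing parent 99")

  writeLines(c("1 1 0 0 0 5 -1", "2 3 x 0 0 1 1"), f)
  expect_error(read_swc(f), "line 2")

  writeLines(c("1 3 0 0 0 1 2", "2 3 1 0 0 1 1"), f)
  expect_error(read_swc(f), "cycle")

  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 1 9"), f)
  expect_error(read_swc(f), "7 fields")
})

test_that("write_swc round-trips arbors exactly and deterministically", {
  a <- make_synthetic_arbor(arbor_recipe(seed = 5))
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(a, f1)
  b <- read_swc(f1, name = a$name)
  expect_equal(b$nodes, a$nodes)
  write_swc(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("strip_soma removes exactly the soma and re-roots its children", {
  f <- withr::local_tempfile(fileext = ".swc")
  write_minimal_swc(f)
  d <- strip_soma(read_swc(f))
  expect_equal(nrow(d$nodes), 2)
  expect_equal(d$nodes$parent[d$nodes$id == 2L], -1L)
  expect_equal(unname(d$soma_centroid), c(0, 0, 0))

  # five soma children -> five root stems
  nodes <- data.frame(id = 1:11, type = c(1L, rep(3L, 10)),
                      x = c(0, rep(c(5, 10), 5)),
                      y = c(0, rep(1:5, each = 2)), z = 0, radius = 1,
                      parent = c(-1L, 1L, 2L, 1L, 4L, 1L, 6L, 1L, 8L, 1L, 10L))
  d5 <- strip_soma(arbor(nodes))
  expect_equal(sum(d5$nodes$parent == -1L), 5)

  # node count drops by exactly the soma node count
  a <- make_synthetic_arbor(arbor_recipe(seed = 2))
  n_soma <- length(soma_ids(a))
  expect_equal(nrow(strip_soma(a)$nodes), nrow(a$nodes) - n_soma)

  # soma-only arbor is an error
  soma_only <- arbor(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                radius = 5, parent = -1L))
  expect_error(strip_soma(soma_only), "empty arbor")
})

test_that("branch decomposition yields one branch per tip with shared sections", {
  d <- strip_soma(three_tip_arbor())
  br <- extract_branches(d)
  expect_length(br, 3)
  # the proximal stem section is shared by all three branches
  for (b in br) expect_equal(b$node_ids[1:2], c(2L, 3L))
  # geometry conservation: union of branch nodes is the dendrite node set
  expect_setequal(unique(unlist(lapply(br, function(b) b$node_ids))),
                  d$nodes$id)

  # unbranched path: one branch, L_B = sum of segment lengths
  chain <- arbor(data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                            x = c(0, 3, 3, 3), y = c(0, 0, 4, 4),
                            z = c(0, 0, 0, 2), radius = 1,
                            parent = c(-1L, 1L, 2L, 3L)))
  b1 <- extract_branches(strip_soma(chain))
  expect_length(b1, 1)
  expect_equal(b1[[1]]$L_B, 6)
  expect_equal(b1[[1]]$L_E, sqrt(16 + 4))

  # branch count equals tip count on random arbors
  for (s in 1:3) {
    a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = s,
                                                      target_tips = 12)))
    expect_length(extract_branches(a), length(tip_ids(a)))
  }
})

test_that("branches satisfy L_E <= L_B with equality only when straight", {
  for (s in 1:5) {
    a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = s,
                                                      target_tips = 8)))
    tb <- branch_table(extract_branches(a))
    expect_true(all(tb$L_E <= tb$L_B + 1e-9))
  }
  st <- make_straight_branch(10, 2)
  expect_equal(st$L_B, st$L_E)
})

test_that("weave and fork angles match elementary geometry", {
  # collinear path: theta = 0
  coll <- arbor(data.frame(id = 1:4, type = c(1L, rep(3L, 3)),
                           x = c(0, 1, 2, 3), y = 0, z = 0, radius = 1,
                           parent = c(-1L, 1L, 2L, 3L)))
  ang <- measure_angles(strip_soma(coll))
  expect_equal(ang$weave$theta, 0)

  # right-angle elbow (0,0,0)-(1,0,0)-(1,1,0): theta = pi/2
  ra <- arbor(data.frame(id = 1:4, type = c(1L, rep(3L, 3)),
                         x = c(-1, 0, 1, 1), y = c(0, 0, 0, 1), z = 0,
                         radius = 1, parent = c(-1L, 1L, 2L, 3L)))
  ang2 <- measure_angles(strip_soma(ra))
  expect_equal(ang2$weave$theta, pi / 2)

  # every bifurcation child gets a fork angle
  d <- strip_soma(three_tip_arbor())
  ang3 <- measure_angles(d)
  expect_equal(nrow(ang3$fork), 4)   # two branch points x two children
  expect_true(all(ang3$fork$phi >= 0 & ang3$fork$phi < pi))
  expect_true(all(ang3$weave$theta >= 0 & ang3$weave$theta < pi))
})

test_that("segment-list files load as soma-stripped arbors", {
  a <- strip_soma(make_synthetic_arbor(arbor_recipe(seed = 4,
                                                    target_tips = 6)))
  seg <- arborfract:::arbor_segments(a)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(parent_x = seg$px, parent_y = seg$py, parent_z = seg$pz,
               child_x = seg$cx, child_y = seg$cy, child_z = seg$cz,
               radius = seg$radius),
    f, row.names = FALSE)
  b <- read_segment_list(f)
  expect_equal(nrow(b$nodes), nrow(a$nodes))
  expect_equal(length(tip_ids(b)), length(tip_ids(a)))
  # same multiset of positions
  key <- function(x) paste(round(x$nodes$x, 6), round(x$nodes$y, 6),
                           round(x$nodes$z, 6))
  expect_setequal(key(b), key(a))
})

test_that("arbor radius is the farthest dendrite node from the soma centroid", {
  f <- withr::local_tempfile(fileext = ".swc")
  write_minimal_swc(f)
  a <- read_swc(f)
  expect_equal(arbor_radius(a), 20)
  expect_equal(arbor_radius(strip_soma(a)), 20)
})
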