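# Synthetic morphologies with the statistical structure of CA1 basal
# arbors: segment length median 2.4 um, dendrite radius 0.7 um (1.4 um
# width), ~32 soma-to-tip branches per arbor, branch path lengths around
# 141 um capped at a ~100 um radial extent, and gentle correlated weave
# giving branch dimensions slightly above 1.

# evaluate code under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' A perfectly straight branch
#'
#' The Euclidean limit: a collinear polyline with `L_B = L_E`, zero weave
#' angles everywhere, and fractal dimension exactly 1 under both branch
#' estimators.
#'
#' @param n_segments number of segments (>= 2)
#' @param seg_len segment length in um
#' @return a `branch`
#' @export
make_straight_branch <- function(n_segments, seg_len = 2.5) {
  stopifnot(n_segments >= 2, seg_len > 0)
  x <- seq(0, n_segments) * seg_len
  branch(cbind(x, 0, 0))
}

#' A correlated-random-walk weave branch
#'
#' Emulates the meander of natural dendrites: each step bends by
#' `|N(theta_mean, theta_mean/3)|` about a uniformly random torsion axis.
#' The default `theta_mean` of 0.25 rad is calibrated so that branch
#' fractal dimensions over the standard 4-40 um range land near the
#' natural value of 1.04 (pooled tortuosity dimensions in roughly
#' 1.02-1.08); `theta_mean -> 0` recovers the straight limit.
#'
#' @param n_segments number of segments
#' @param seg_len segment length (um)
#' @param theta_mean mean bend per step in radians, in (0, pi/4]
#' @param seed RNG seed (reproducible output; caller's RNG state is
#'   untouched)
#' @return a `branch`
#' @export
make_weave_branch <- function(n_segments, seg_len = 2.4, theta_mean = 0.25,
                              seed = 1) {
  stopifnot(n_segments >= 2, seg_len > 0,
            theta_mean > 0, theta_mean <= pi / 4)
  with_seed(seed, {
    pts <- matrix(0, n_segments + 1L, 3L)
    d <- c(1, 0, 0)
    for (i in seq_len(n_segments)) {
      pts[i + 1L, ] <- pts[i, ] + seg_len * d
      bend <- abs(stats::rnorm(1, theta_mean, theta_mean / 3))
      bend <- min(bend, pi - 1e-6)
      psi <- stats::runif(1, 0, 2 * pi)
      n_ <- perp_vector(d)
      axis <- cos(psi) * n_ + sin(psi) * cross3(d, n_)
      d <- unit_vec(rotate_about(d, axis, bend))
    }
    branch(pts)
  })
}

#' Recipe of generator parameters for a synthetic arbor
#'
#' Defaults emulate CA1 basal arbor statistics: median segment length
#' 2.4 um, dendrite width 1.4 um (radius 0.7 um), about 32 soma-to-tip
#' branches, branch path lengths drawn around 141 um confined to a
#' radial extent of about 100 um, and weave, fork and self-avoidance
#' angle scales that put branch dimensions near the natural value
#' (about 1.05 over the 4-40 um range).
#'
#' @param n_stems primary dendrites leaving the soma
#' @param target_tips target number of terminal tips (~branches)
#' @param seg_len median segment length (um; lognormal spread)
#' @param seg_len_sdlog lognormal sdlog of segment lengths
#' @param radius dendrite radius (um), constant per arbor
#' @param theta_mean mean weave bend per step (rad)
#' @param fork_angle mean fork half-opening at bifurcations (rad)
#' @param branch_len_mean,branch_len_sd target branch path length (um)
#' @param tropism radial tropism weight in `[0, 1)`: per-step pull of the
#'   growth direction towards the outward radial
#' @param repulsion self-avoidance weight: per-step deflection of the
#'   growth direction away from dendrite already placed within
#'   `repulsion_radius`; makes the natural (multiplier 1) condition the
#'   maximally spread one
#' @param repulsion_radius neighbourhood radius (um) for self-avoidance
#' @param max_extent radial growth cap from the soma (um)
#' @param soma_radius soma radius (um)
#' @param seed RNG seed
#' @return an object of class `arbor_recipe`
#' @export
arbor_recipe <- function(n_stems = 4, target_tips = 32, seg_len = 2.4,
                         seg_len_sdlog = 0.3, radius = 0.7,
                         theta_mean = 0.09, fork_angle = 0.6,
                         branch_len_mean = 141, branch_len_sd = 20,
                         tropism = 0.1, repulsion = 0.3,
                         repulsion_radius = 10, max_extent = 100,
                         soma_radius = 6, seed = 1) {
  stopifnot(n_stems >= 1, target_tips >= n_stems, seg_len > 0, radius > 0,
            theta_mean > 0, fork_angle > 0, branch_len_mean > 0,
            max_extent > 0, repulsion >= 0, repulsion_radius > 0)
  out <- as.list(environment())
  class(out) <- "arbor_recipe"
  out
}

#' Generate a synthetic soma-rooted arbor
#'
#' Stems leave the soma in well-spread directions and grow as correlated
#' random walks; the target tip count is partitioned over the stems and
#' each subtree bifurcates at random depths until its quota of tips is
#' reached. Paths terminate when they exhaust their drawn target length or
#' hit the radial extent cap. Output is reproducible from the recipe seed.
#'
#' @param recipe an `arbor_recipe`
#' @return an `arbor` (soma node included, type 1)
#' @export
make_synthetic_arbor <- function(recipe) {
  stopifnot(inherits(recipe, "arbor_recipe"))
  with_seed(recipe$seed, {
    rows <- list()
    placed <- matrix(NA_real_, 512L, 3L)  # node positions, grown on demand
    add_node <- function(type, pos, radius, parent) {
      id <- length(rows) + 1L
      rows[[id]] <<- data.frame(id = id, type = type, x = pos[1L],
                                y = pos[2L], z = pos[3L], radius = radius,
                                parent = parent)
      if (id > nrow(placed)) {
        placed <<- rbind(placed, matrix(NA_real_, nrow(placed), 3L))
      }
      placed[id, ] <<- pos
      id
    }
    soma_id <- add_node(1L, c(0, 0, 0), recipe$soma_radius, -1L)
    # tip quota per stem: as even as possible
    quota <- rep(recipe$target_tips %/% recipe$n_stems, recipe$n_stems)
    extra <- recipe$target_tips %% recipe$n_stems
    if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    # basal arbors occupy roughly a hemisphere below the soma (stratum
    # oriens side), so stem directions are well-spread but confined there
    stem_dirs <- fibonacci_directions(recipe$n_stems)
    stem_dirs[, 3L] <- -abs(stem_dirs[, 3L]) - 0.2
    stem_dirs <- stem_dirs / sqrt(rowSums(stem_dirs^2))

    step_len <- function() {
      stats::rlnorm(1, log(recipe$seg_len), recipe$seg_len_sdlog)
    }
    bend_dir <- function(d, bend) {
      psi <- stats::runif(1, 0, 2 * pi)
      n_ <- perp_vector(d)
      axis <- cos(psi) * n_ + sin(psi) * cross3(d, n_)
      unit_vec(rotate_about(d, axis, min(bend, pi - 1e-6)))
    }
    # one weave step. Growing dendrites self-avoid: the step direction is
    # deflected away from already-grown dendrite (excluding the path's own
    # recent nodes), with a mild radial tropism as in dendritic growth
    # models. Both deflections are recorded in the final geometry as weave
    # bends, so an angle multiplier other than 1 disrupts the avoidance:
    # branches then move closer together, the natural condition being the
    # maximally spread one. Near the radial cap the direction is steered
    # tangentially, so paths keep growing to their target length while the
    # arbor stays confined to its ~max_extent radius.
    advance <- function(pos, dir, recent) {
      dir <- bend_dir(dir, abs(stats::rnorm(1, recipe$theta_mean,
                                            recipe$theta_mean / 3)))
      if (recipe$repulsion > 0 && length(rows) > 1L) {
        others <- setdiff(2:length(rows), recent)  # node 1 is the soma
        if (length(others) > 0L) {
          q <- placed[others, , drop = FALSE]
          dv <- -sweep(q, 2L, pos)
          d2 <- rowSums(dv^2)
          near <- d2 < recipe$repulsion_radius^2 & d2 > 1e-12
          if (any(near)) {
            rep_vec <- colSums(dv[near, , drop = FALSE] / d2[near])
            rn <- vec_norm(rep_vec)
            if (rn > 1e-12) {
              dir <- unit_vec(dir + recipe$repulsion * rep_vec / rn)
            }
          }
        }
      }
      if (recipe$tropism > 0 && vec_norm(pos) > recipe$soma_radius) {
        dir <- unit_vec((1 - recipe$tropism) * dir +
                          recipe$tropism * unit_vec(pos))
      }
      len <- step_len()
      pos2 <- pos + len * dir
      if (vec_norm(pos2) > recipe$max_extent) {
        rhat <- unit_vec(pos)
        tang <- dir - sum(dir * rhat) * rhat
        dir <- if (vec_norm(tang) < 1e-9) {
          unit_vec(perp_vector(rhat))
        } else {
          unit_vec(tang)
        }
        pos2 <- pos + len * dir
      }
      list(pos = pos2, dir = dir, len = len)
    }

    # grow a subtree with `m` tips from (pos, dir), with `grown` path
    # length already behind it and `target_len` total to reach
    grow <- function(m, pos, dir, parent, grown, target_len, recent) {
      if (m > 1L) {
        # walk to a split point, then bifurcate the quota; proximal split
        # fractions mirror the bias of basal-arbor bifurcations towards
        # the soma and give realistic total dendritic length
        split_at <- grown + stats::runif(1, 0.05, 0.2) *
          max(recipe$seg_len, target_len - grown)
        while (grown < split_at) {
          st <- advance(pos, dir, recent)
          parent <- add_node(3L, st$pos, recipe$radius, parent)
          recent <- c(utils::tail(recent, 7L), parent)
          grown <- grown + st$len
          pos <- st$pos
          dir <- st$dir
        }
        m1 <- max(1L, stats::rbinom(1, m - 1L, 0.5))
        m2 <- m - m1
        # siblings fork to opposite sides of the parent direction: the
        # geometric self-avoidance that makes alpha = 1 the natural,
        # maximally spread condition
        psi0 <- stats::runif(1, 0, 2 * pi)
        n_ <- perp_vector(dir)
        b_ <- cross3(dir, n_)
        sides <- c(0, pi)
        for (k in 1:2) {
          part <- c(m1, m2)[k]
          phi <- abs(stats::rnorm(1, recipe$fork_angle,
                                  recipe$fork_angle / 3))
          axis <- cos(psi0 + sides[k]) * n_ + sin(psi0 + sides[k]) * b_
          d_child <- unit_vec(rotate_about(dir, axis, min(phi, pi - 1e-6)))
          tl <- max(grown + 10 * recipe$seg_len,
                    stats::rnorm(1, recipe$branch_len_mean,
                                 recipe$branch_len_sd))
          grow(part, pos, d_child, parent, grown, tl, recent)
        }
        return(invisible(NULL))
      }
      # terminal path
      while (grown < target_len) {
        st <- advance(pos, dir, recent)
        parent <- add_node(3L, st$pos, recipe$radius, parent)
        recent <- c(utils::tail(recent, 7L), parent)
        grown <- grown + st$len
        pos <- st$pos
        dir <- st$dir
      }
      invisible(NULL)
    }

    for (s in seq_len(recipe$n_stems)) {
      dir <- unit_vec(stem_dirs[s, ])
      pos <- recipe$soma_radius * dir
      stem_root <- add_node(3L, pos, recipe$radius, soma_id)
      tl <- max(20, stats::rnorm(1, recipe$branch_len_mean,
                                 recipe$branch_len_sd))
      grow(quota[s], pos, dir, stem_root, recipe$soma_radius, tl,
           recent = stem_root)
    }
    nodes <- do.call(rbind, rows)
    arbor(nodes, name = sprintf("synthetic_seed%d", recipe$seed))
  })
}

#' Deterministic H-tree arbor of known fractal dimension
#'
#' Classic planar H-tree embedded at z = 0: every bar spawns two
#' perpendicular children whose lengths shrink by `length_ratio` per
#' level. Its theoretical self-similarity dimension is
#' `D = log(2) / log(1 / length_ratio)`; e.g. `length_ratio = 2^(-1/1.5)`
#' gives `D = 1.5`. Useful as a known-dimension fixture for the
#' box-counting estimator.
#'
#' @param levels number of branching generations (>= 1)
#' @param length_ratio child/parent bar length, in (0, 1)
#' @param trunk_len trunk bar length (um)
#' @param n_sub subdivisions per bar (polyline resolution)
#' @return an `arbor` (soma node at the trunk base)
#' @export
make_h_tree <- function(levels, length_ratio, trunk_len = 100, n_sub = 1) {
  stopifnot(levels >= 1, length_ratio > 0, length_ratio < 1, trunk_len > 0,
            n_sub >= 1)
  rows <- list()
  add_node <- function(type, pos, radius, parent) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(id = id, type = type, x = pos[1L],
                              y = pos[2L], z = pos[3L], radius = radius,
                              parent = parent)
    id
  }
  soma_id <- add_node(1L, c(0, 0, 0), 2, -1L)
  add_bar <- function(from_id, from_pos, dir, len, level) {
    end <- from_pos + len * dir
    parent <- from_id
    for (k in seq_len(n_sub)) {
      p <- from_pos + (k / n_sub) * len * dir
      parent <- add_node(3L, p, 0.7, parent)
    }
    if (level < levels) {
      perp <- c(-dir[2L], dir[1L], 0)
      for (sgn in c(1, -1)) {
        add_bar(parent, end, sgn * perp, len * length_ratio, level + 1L)
      }
    }
    invisible(NULL)
  }
  add_bar(soma_id, c(0, 0, 0), c(0, 1, 0), trunk_len, 0L)
  arbor(do.call(rbind, rows),
        name = sprintf("htree_L%d_r%.3f", levels, length_ratio))
}

#' Theoretical H-tree dimension
#' @param length_ratio child/parent bar length ratio in (0, 1)
#' @return `log(2) / log(1 / length_ratio)`
#' @export
h_tree_dimension <- function(length_ratio) {
  stopifnot(length_ratio > 0, length_ratio < 1)
  log(2) / log(1 / length_ratio)
}
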