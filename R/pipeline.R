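# Directory-level orchestration of the analysis flows: per-branch and
# pooled branch dimensions over a set of SWC files, and the angle-
# multiplier distortion sweep with arbor dimension and connectivity/cost
# metrics. Analyses are blind to file naming; grouping metadata, if any,
# comes from the caller.

#' Analysis run configuration
#'
#' Defaults mirror the standard analysis parameters: branch fit range
#' 4-40 um (one order of magnitude), 20 log-spaced rulers, 12 tortuosity
#' bins, angle multipliers 0.5-2 in steps of 0.25, 2 um profile expansion.
#'
#' @param fit_range branch-scale fit range (um)
#' @param n_rulers rulers in the default grid
#' @param n_bins tortuosity bins
#' @param alphas angle-multiplier sweep values
#' @param n_views profile-area view directions
#' @param expansion profile expansion (um)
#' @param pixel profile raster pixel (um)
#' @param seed seed recorded in provenance (analyses are deterministic)
#' @return a `run_config` list
#' @export
run_config <- function(fit_range = c(4, 40), n_rulers = 20, n_bins = 12,
                       alphas = seq(0.5, 2, by = 0.25), n_views = 64,
                       expansion = 2, pixel = 0.5, seed = 1) {
  out <- as.list(environment())
  class(out) <- "run_config"
  out
}

read_arbor_dir <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.swc$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no SWC files to analyse")
  arbors <- list()
  for (p in paths) {
    a <- tryCatch(read_swc(p), error = function(e) {
      warning("skipping unreadable file ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(a)) arbors[[length(arbors) + 1L]] <- a
  }
  if (length(arbors) == 0L) stop("all input files were unreadable")
  arbors
}

provenance_record <- function(config, out_dir) {
  cfg <- unclass(config)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(js, tmp)
  rec <- list(
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("arborfract")),
    r_version = R.version.string
  )
  unlink(tmp)
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Branch fractal analysis over a set of arbors
#'
#' For every readable SWC file: strips the soma, fits the coastline
#' dimension `D_BC` of each branch (4-40 um, short branches excluded), the
#' pooled normalized dimension `D_BCN` per arbor, and a single pooled
#' tortuosity dimension `D_BT` over the deduplicated sub-paths of all
#' arbors. Writes `branch_dimensions.csv`, `arbor_dimensions.csv`,
#' `pooled_tortuosity.json` and `provenance.json` to `out_dir`; outputs
#' are byte-identical across reruns with the same inputs and config.
#'
#' @param paths directory or vector of SWC file paths
#' @param out_dir output directory (created if needed)
#' @param config a [run_config()]
#' @return invisibly, a list with `branch_table`, `arbor_table` and
#'   `pooled_D_BT`
#' @export
run_branch_analysis <- function(paths, out_dir, config = run_config()) {
  arbors <- read_arbor_dir(paths)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- log_spaced(config$fit_range[1L], config$fit_range[2L],
                     config$n_rulers)
  branch_rows <- list()
  arbor_rows <- list()
  tort_tables <- list()
  for (a in arbors) {
    message("analysing arbor ", a$name)
    d <- strip_soma(a)
    bt <- arbor_branch_dimensions(d, ruler_grid = grid,
                                  fit_range = config$fit_range)
    bt$arbor_id <- a$name
    branch_rows[[length(branch_rows) + 1L]] <- bt
    n_excl <- sum(bt$excluded)
    if (n_excl > 0L) {
      warning(n_excl, " short branch(es) excluded in ", a$name)
    }
    dbcn <- tryCatch(
      pooled_normalized_dimension(extract_branches(d), ruler_grid = grid,
                                  fit_range = config$fit_range),
      error = function(e) NULL)
    arbor_rows[[length(arbor_rows) + 1L]] <- data.frame(
      arbor_id = a$name,
      n_branches = nrow(bt),
      n_excluded = n_excl,
      mean_D_BC = mean(bt$D_BC, na.rm = TRUE),
      D_BCN = if (is.null(dbcn)) NA_real_ else dbcn$D,
      D_BCN_stderr = if (is.null(dbcn)) NA_real_ else dbcn$stderr
    )
    tort_tables[[length(tort_tables) + 1L]] <- arbor_tortuosity(d)
  }
  branch_table <- do.call(rbind, branch_rows)
  arbor_table <- do.call(rbind, arbor_rows)
  pooled <- deduplicate_paths(tort_tables)
  pooled_fit <- binned_fit(pooled, fit_range = config$fit_range,
                           n_bins = config$n_bins)
  utils::write.csv(branch_table,
                   file.path(out_dir, "branch_dimensions.csv"),
                   row.names = FALSE)
  utils::write.csv(arbor_table,
                   file.path(out_dir, "arbor_dimensions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(S = pooled_fit$slope, D_BT = pooled_fit$D,
         stderr = pooled_fit$stderr, fit_range = pooled_fit$fit_range,
         bins = attr(pooled_fit, "binned")),
    file.path(out_dir, "pooled_tortuosity.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  provenance_record(config, out_dir)
  invisible(list(branch_table = branch_table, arbor_table = arbor_table,
                 pooled_D_BT = pooled_fit))
}

#' Angle-multiplier distortion sweep
#'
#' For every arbor and every angle multiplier in `config$alphas`: distorts
#' the arbor, measures the box-counting dimension `D_A`, the mean branch
#' coastline dimension, and the connectivity/cost metrics; then fits the
#' balance curves `R_PA` and `R_PV` against `D_A` over the ensemble means.
#' Writes `distortion_ensemble.csv`, `balance_curves.json`, one SWC per
#' distorted arbor and `provenance.json` to `out_dir`.
#'
#' @param paths directory or vector of SWC file paths
#' @param out_dir output directory
#' @param config a [run_config()]
#' @param write_swc_files write the distorted morphologies as SWC files
#' @return invisibly, a list with `ensemble` (per arbor per alpha) and
#'   `balance` (a `balance_curves`, or `NULL` if too few alphas)
#' @export
run_distortion_sweep <- function(paths, out_dir, config = run_config(),
                                 write_swc_files = FALSE) {
  arbors <- read_arbor_dir(paths)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- log_spaced(config$fit_range[1L], config$fit_range[2L],
                     config$n_rulers)
  rows <- list()
  for (a in arbors) {
    d0 <- strip_soma(a)
    geom <- decompose_to_angles(d0)
    for (alpha in config$alphas) {
      message("arbor ", a$name, ", alpha = ", alpha)
      d <- withCallingHandlers(
        apply_angle_multiplier(geom, alpha),
        warning = function(w) invokeRestart("muffleWarning"))
      bt <- arbor_branch_dimensions(d, ruler_grid = grid,
                                    fit_range = config$fit_range)
      da <- arbor_dimension(d)
      met <- arbor_metrics(d, expansion = config$expansion,
                           n_views = config$n_views, pixel = config$pixel)
      xr <- self_intersection_report(d)
      if (write_swc_files) {
        write_swc(d, file.path(out_dir, paste0(d$name, ".swc")))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        arbor_id = a$name, alpha = alpha,
        D_A = da$D, mean_D_BC = mean(bt$D_BC, na.rm = TRUE),
        P = met$P, A_s = met$A_s, V_m = met$V_m,
        A_b = met$A_b, V_b = met$V_b,
        P_Ab = met$P_Ab, As_Ab = met$As_Ab, Vm_Vb = met$Vm_Vb,
        clip_count = attr(d, "clip_count"),
        intersection_fraction = xr$fraction
      )
    }
  }
  ensemble <- do.call(rbind, rows)
  utils::write.csv(ensemble, file.path(out_dir, "distortion_ensemble.csv"),
                   row.names = FALSE)
  means <- stats::aggregate(
    ensemble[c("D_A", "mean_D_BC", "P_Ab", "As_Ab", "Vm_Vb")],
    by = list(alpha = ensemble$alpha), FUN = mean)
  bal <- NULL
  if (length(unique(means$D_A)) >= 4L) {
    bal <- balance_curves(means)
    jsonlite::write_json(
      list(coefs = bal$coefs, D_A = bal$D_A, R_PA = bal$R_PA,
           R_PV = bal$R_PV),
      file.path(out_dir, "balance_curves.json"),
      auto_unbox = TRUE, digits = NA)
  }
  provenance_record(config, out_dir)
  invisible(list(ensemble = ensemble, alpha_means = means, balance = bal))
}
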