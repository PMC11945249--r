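# Pipeline orchestration: each cmd_* function is one workflow step writing
# tidy CSV outputs plus a JSON run manifest. The thin dispatcher in
# inst/cli/enzvec.R maps these to subcommands and exit codes (0 success,
# 1 data error, 2 configuration/schema error).

#' Write a run manifest
#'
#' Records timestamp, package version, seed, configuration hash, the
#' parameter values actually used, input/output paths and warnings, so
#' every output directory is traceable to one invocation.
#'
#' @param out_dir Output directory.
#' @param step Workflow step name.
#' @param seed Integer seed (or NA).
#' @param params Named list of parameter values in force.
#' @param files Named list of file paths written.
#' @param warnings Character vector of warnings raised.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, step, seed = NA, params = list(),
                           files = list(), warnings = character()) {
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(step = step,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package = "enzvec",
                   version = as.character(utils::packageVersion("enzvec")),
                   seed = seed,
                   config_hash = unname(tools::md5sum(tf)),
                   parameters = params, files = files,
                   warnings = warnings)
  unlink(tf)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.load_config <- function(config) {
  if (is.null(config)) return(gradient_config())
  if (inherits(config, "gradient_config")) return(config)
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    known <- names(formals(gradient_config))
    bad <- setdiff(names(raw), known)
    if (length(bad))
      ev_config_error(sprintf("unknown config field(s): %s",
                              paste(bad, collapse = ", ")))
    if (!is.null(raw$lakes_per_class))
      raw$lakes_per_class <- unlist(raw$lakes_per_class)
    if (!is.null(raw$sites_per_lake))
      raw$sites_per_lake <- lapply(raw$sites_per_lake, unlist)
    if (!is.null(raw$nutrient_trends))
      raw$nutrient_trends <- lapply(raw$nutrient_trends, unlist)
    return(do.call(gradient_config, raw))
  }
  if (is.list(config)) return(do.call(gradient_config, config))
  ev_config_error("'config' must be NULL, a path, a list or a gradient_config")
}

#' Simulate a cohort and its plates to disk
#'
#' @param config `NULL` (defaults), a JSON config path, or a
#'   [gradient_config()] (or plain list of its arguments).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param n_sites Optional cohort size override (see [generate_cohort()]).
#' @param with_plates Also write simulated noisy plates for the cohort.
#' @return Named list of file paths, invisibly.
#' @export
cmd_simulate <- function(config = NULL, seed = 1, out_dir = ".",
                         n_sites = NULL, with_plates = TRUE) {
  cfg <- .load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg, seed = seed, n_sites = n_sites)
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  files <- list(cohort = cohort_path)
  if (isTRUE(with_plates)) {
    qs <- stats::runif(nrow(cohort), cfg$quench_range[1], cfg$quench_range[2])
    plates <- simulate_plate(cohort[c("sample_id", ENZYMES)],
                             quench_q = qs, noise_sd = cfg$plate_noise_sd)
    plate_path <- file.path(out_dir, "plates.csv")
    utils::write.csv(plates, plate_path, row.names = FALSE)
    files$plates <- plate_path
  }
  write_manifest(out_dir, "simulate", seed = seed,
                 params = list(n_sites = n_sites %||% nrow(cohort),
                               anchor = cfg$anchor,
                               salinity_anchor = cfg$salinity_anchor,
                               r2_targets = cfg[c("r2_salinity_length",
                                                  "r2_salinity_angle",
                                                  "r2_soc_length_marginal",
                                                  "r2_soc_length_partial")],
                               mean_angle_deg = cfg$mean_angle_deg,
                               resample_count = attr(cohort, "resample_count")),
                 files = files)
  invisible(files)
}

#' Reduce a plate CSV to activities and QC
#'
#' @param plate_csv Long-format plate CSV path.
#' @param params An [assay_params()].
#' @param out_dir Output directory.
#' @param ... Passed to [plate_activity()] (QC thresholds).
#' @return Named list of file paths, invisibly.
#' @export
cmd_reduce <- function(plate_csv, params = assay_params(), out_dir = ".", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plate <- read_plate_table(plate_csv)
  warns <- character()
  res <- withCallingHandlers(
    reduce_plate_set(plate, params = params, ...),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  qc_path <- file.path(out_dir, "qc_report.csv")
  act_path <- file.path(out_dir, "activities.csv")
  utils::write.csv(res$qc, qc_path, row.names = FALSE)
  utils::write.csv(res$activities, act_path, row.names = FALSE)
  write_manifest(out_dir, "reduce", params = unclass(params),
                 files = list(qc = qc_path, activities = act_path),
                 warnings = warns)
  invisible(list(qc = qc_path, activities = act_path))
}

#' Compute the MML table from an activity CSV
#'
#' @param activity_csv Path to `sample_id,bg,cbh,nag,lap,ap` CSV.
#' @param out Output CSV path.
#' @param ... Passed to [mml_from_activities()].
#' @return The output path, invisibly.
#' @export
cmd_mml <- function(activity_csv, out = "mml.csv", ...) {
  acts <- read_activity_table(activity_csv)
  mml <- mml_from_activities(acts, ...)
  utils::write.csv(mml, out, row.names = FALSE)
  invisible(out)
}

#' Run the gradient analysis suite on a cohort table
#'
#' Reproduces the survey's inference chain on a cohort CSV (as written by
#' [cmd_simulate()], or any table with the same columns): log-log
#' regressions of the limitation metrics on salinity and pH, salinity-class
#' ANOVAs with compact letters, marginal and partial SOC regressions,
#' VIF-filtered three-block variance partitioning (pH + salinity /
#' nutrients / microbial diversity), and MRM of the limitation distance
#' matrix on predictor distance matrices.
#'
#' @param cohort_csv Cohort CSV path.
#' @param out_dir Output directory.
#' @param n_perm MRM permutations (default 999).
#' @param alpha ANOVA letter significance level (default 0.05).
#' @param seed Seed for the MRM permutations.
#' @return Named list of result file paths, invisibly; the parsed result
#'   objects are attached as attribute `results`.
#' @export
cmd_analyze <- function(cohort_csv, out_dir = ".", n_perm = 999,
                        alpha = 0.05, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  need <- c("sample_id", "salinity", "salinity_class", "ph", "soc",
            "vector_length", "vector_angle_deg")
  if (!all(need %in% names(co)))
    ev_data_error(sprintf("cohort table must have columns %s",
                          paste(need, collapse = ", ")))

  regs <- list(
    salinity_vs_length = loglinear_fit(co$salinity, co$vector_length),
    salinity_vs_angle  = loglinear_fit(co$salinity, co$vector_angle_deg),
    ph_vs_length       = loglinear_fit(co$ph, co$vector_length),
    ph_vs_angle        = loglinear_fit(co$ph, co$vector_angle_deg),
    length_vs_soc      = loglinear_fit(co$vector_length, co$soc),
    length_vs_soc_partial_salinity =
      partial_regression(co$soc, co$vector_length, co$salinity),
    length_vs_soc_partial_ph =
      partial_regression(co$soc, co$vector_length, co$ph))
  reg_df <- do.call(rbind, lapply(names(regs), function(nm) {
    r <- regs[[nm]]
    data.frame(model = nm, slope = r$slope, intercept = r$intercept,
               r2 = r$r2, adj_r2 = r$adj_r2, p_value = r$p_value, n = r$n)
  }))
  reg_path <- file.path(out_dir, "regression_results.csv")
  utils::write.csv(reg_df, reg_path, row.names = FALSE)

  anovas <- list(vector_length = class_anova(log(co$vector_length),
                                             co$salinity_class, alpha = alpha),
                 vector_angle = class_anova(log(co$vector_angle_deg),
                                            co$salinity_class, alpha = alpha))
  an_df <- do.call(rbind, lapply(names(anovas), function(nm) {
    a <- anovas[[nm]]
    data.frame(response = nm, class = names(a$letters),
               mean_ln = as.numeric(a$means[names(a$letters)]),
               letters = unname(a$letters),
               f = a$f, p = a$p)
  }))
  an_path <- file.path(out_dir, "anova_letters.csv")
  utils::write.csv(an_df, an_path, row.names = FALSE)

  # VPA blocks: pH+salinity / nutrients / diversity (VIF-filtered within block)
  blocks <- list(
    ph_salinity = co[intersect(c("ph", "salinity"), names(co))],
    nutrients = co[intersect(c("tn", "tp", "soc", "nh4", "no3", "no2", "dip",
                               "doc", "soc_tn", "soc_tp", "tn_tp", "water_tn",
                               "water_tp", "water_tn_tp", "water_chla"),
                             names(co))],
    diversity = co[intersect(c("bacterial_richness", "fungal_richness",
                               "bacterial_dca1", "fungal_dca1"), names(co))])
  blocks <- lapply(blocks, function(b) {
    b <- as.data.frame(lapply(b, function(col) as.numeric(scale(col))))
    if (ncol(b) >= 2) vif_filter(b)$retained else b
  })
  vpa_rows <- lapply(c(length = "vector_length", angle = "vector_angle_deg"),
                     function(resp) {
    vp <- variance_partition(log(co[[resp]]), blocks$ph_salinity,
                             blocks$nutrients, blocks$diversity,
                             block_names = names(blocks))
    data.frame(response = resp, fraction = names(vp$fractions),
               value = unname(vp$fractions))
  })
  vpa_path <- file.path(out_dir, "vpa_fractions.csv")
  utils::write.csv(do.call(rbind, vpa_rows), vpa_path, row.names = FALSE)

  # MRM: limitation profile distances vs predictor distances (z-scored)
  mml_d <- stats::dist(cbind(zscore(co$vector_length),
                             zscore(co$vector_angle_deg)))
  preds <- list(salinity = stats::dist(zscore(log(co$salinity))),
                ph = stats::dist(zscore(co$ph)),
                soc = stats::dist(zscore(log(co$soc))))
  mr <- mrm(mml_d, preds, n_perm = n_perm, seed = seed)
  mrm_df <- cbind(mr$coefficients, r2 = mr$r2, p_r2 = mr$p_r2,
                  n_perm = mr$n_perm)
  mrm_path <- file.path(out_dir, "mrm_results.csv")
  utils::write.csv(mrm_df, mrm_path, row.names = FALSE)

  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c(
    sprintf("enzvec analysis of %s (n = %d sites)", cohort_csv, nrow(co)),
    sprintf("salinity -> C limitation (vector length): adj R2 = %.3f (p = %.3g)",
            regs$salinity_vs_length$adj_r2, regs$salinity_vs_length$p_value),
    sprintf("salinity -> N/P limitation (vector angle): adj R2 = %.3f (p = %.3g)",
            regs$salinity_vs_angle$adj_r2, regs$salinity_vs_angle$p_value),
    sprintf("SOC ~ C limitation marginal: adj R2 = %.3f; partial | salinity: %.3f; partial | pH: %.3f",
            regs$length_vs_soc$adj_r2,
            regs$length_vs_soc_partial_salinity$adj_r2,
            regs$length_vs_soc_partial_ph$adj_r2),
    sprintf("mean vector angle: %.2f deg; %.1f%% of sites N-limited",
            mean(co$vector_angle_deg),
            100 * mean(co$vector_angle_deg < 45)),
    sprintf("MRM R2 = %.3f (p = %.3g, %d permutations)", mr$r2, mr$p_r2, n_perm))
  writeLines(lines, summary_path)

  files <- list(regressions = reg_path, anova = an_path, vpa = vpa_path,
                mrm = mrm_path, summary = summary_path)
  write_manifest(out_dir, "analyze", seed = seed,
                 params = list(n_perm = n_perm, alpha = alpha,
                               vif_threshold = 10,
                               log_base = "natural",
                               salinity_boundaries = c(0.5, 3, 20),
                               boundary_convention = "left-closed"),
                 files = files)
  res <- list(regressions = regs, anovas = anovas, mrm = mr)
  attr(files, "results") <- res
  invisible(files)
}
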