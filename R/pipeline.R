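# End-to-end orchestration: simulate -> detect -> cafseg -> apoptosis ->
# proximity, with per-stage outputs, a report and a checksummed manifest.

stage_dir <- function(out_dir, name) {
  p <- file.path(out_dir, name)
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
  p
}

#' Run the full tumor-on-chip analysis pipeline
#'
#' Executes every stage on one or more simulated conditions and writes all
#' stage outputs, a `report.md` aggregating the kinetics (plus a paired
#' condition comparison when exactly two conditions with matched videos are
#' run) and the kiss-of-life stratification, and finally `manifest.json`
#' with MD5 checksums of every produced file. Deterministic stages reproduce
#' identical checksums when re-run with the same configuration.
#'
#' @param config A [toc_config()] (or list / YAML / JSON path accepted by
#'   [validate_toc_config()]). Per-condition runs derive their seeds from
#'   `config$sim$seed`.
#' @param out_dir Output directory.
#' @param conditions Optional named list of simulation-parameter overrides,
#'   one entry per condition (e.g.
#'   `list(mono = list(rho = 1), co = list(rho = 0.5))`); `NULL` runs the
#'   single configured condition.
#' @param videos_per_condition Replicate videos per condition.
#' @return The manifest (list), invisibly; per-condition results in
#'   attribute `results`.
#' @export
run_toc_pipeline <- function(config, out_dir, conditions = NULL,
                             videos_per_condition = 1L) {
  cfg <- validate_toc_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conditions <- conditions %||% list(default = list())
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    abort("conditions must be a named list")

  all_kinetics <- list()
  all_kiss <- list()
  files <- character()
  stage <- "setup"
  run_one <- function(cond, rep_i, sim_over) {
    vcfg <- cfg
    vcfg$sim <- validate_sim_config(utils::modifyList(
      unclass(cfg$sim),
      c(sim_over, list(seed = cfg$sim$seed +
                         1000L * (match(cond, names(conditions)) - 1L) + rep_i - 1L))))
    vdir <- stage_dir(out_dir, sprintf("%s_v%d", cond, rep_i))

    stage <<- "simulate"
    video <- generate_toc_video(vcfg$sim)
    write_toc_video(video, vdir)

    stage <<- "detect"
    cells <- detect_tumor_cells(
      video$stack, pixel_size_um = vcfg$sim$pixel_size_um,
      neighborhood_fraction = vcfg$detect$neighborhood_fraction,
      sensitivity = vcfg$detect$sensitivity,
      persistence = vcfg$detect$persistence,
      min_area_px = vcfg$detect$min_area_px)
    tmask <- attr(cells, "tumor_mask")
    write_mask_tiff(tmask * 1, file.path(vdir, "tumor_mask.tif"))
    lab_img <- attr(cells, "label_image")
    readr::write_csv(
      mutate(select(cells, "label", "row", "col", "x_um", "y_um", "area_px",
                    "r_dilate", "touches_border")),
      file.path(vdir, "detected_cells.csv"))

    stage <<- "cafseg"
    cafs <- segment_cafs(
      video$stack, method = vcfg$cafseg$method,
      masks = if (vcfg$cafseg$method == "import") video$truth$caf_masks else NULL,
      tumor_mask = tmask,
      texture_window_px = vcfg$cafseg$texture_window_px,
      closing_radius_px = vcfg$cafseg$closing_radius_px,
      shrink_px = vcfg$cafseg$shrink_px,
      min_area_px = vcfg$cafseg$min_area_px,
      max_area_px = vcfg$cafseg$max_area_px,
      sensitivity = vcfg$cafseg$sensitivity,
      neighborhood_fraction = vcfg$cafseg$neighborhood_fraction)
    write_mask_tiff(cafs$masks, file.path(vdir, "caf_masks_detected.tif"))

    stage <<- "apoptosis"
    traces <- extract_green_traces(video$stack, cells)
    events <- call_apoptosis_events(traces, vcfg$apoptosis$k_sigma,
                                    vcfg$apoptosis$m_consec)
    kin <- kinetics_table(events, n_alive_t0 = nrow(cells),
                          duration_h = vcfg$sim$duration_h,
                          window_h = vcfg$apoptosis$window_h,
                          condition = cond, video = sprintf("v%d", rep_i))
    readr::write_csv(traces, file.path(vdir, "traces.csv"))
    readr::write_csv(events, file.path(vdir, "events.csv"))
    readr::write_csv(kin, file.path(vdir, "kinetics.csv"))

    stage <<- "proximity"
    prox <- proximity_records(cells, cafs,
                              contact_um = vcfg$proximity$contact_um,
                              iou_radius_um = vcfg$proximity$iou_radius_um)
    fates <- fate_table(cells, events, horizon_h = vcfg$proximity$horizon_h)
    readr::write_csv(prox, file.path(vdir, "proximity.csv"))
    readr::write_csv(fates, file.path(vdir, "fate.csv"))
    kiss <- tryCatch(
      withr::with_seed(vcfg$sim$seed + 500000L,
        stratify_by_fate(prox, fates,
                         early_window_h = vcfg$proximity$early_window_h,
                         exclude_border = vcfg$proximity$exclude_border,
                         n_perm = vcfg$proximity$n_perm)),
      error = function(e) NULL)   # a stratum may be empty in small runs
    if (!is.null(kiss))
      readr::write_csv(kiss$tests, file.path(vdir, "kiss_of_life.csv"))

    files <<- c(files, list.files(vdir, full.names = TRUE))
    list(kinetics = kin, kiss = kiss, cells = cells, events = events)
  }

  results <- list()
  for (cond in names(conditions)) {
    for (rep_i in seq_len(videos_per_condition)) {
      res <- tryCatch(run_one(cond, rep_i, conditions[[cond]]),
                      error = function(e)
                        abort(sprintf("pipeline failed at stage '%s': %s",
                                      stage, conditionMessage(e))))
      results[[sprintf("%s_v%d", cond, rep_i)]] <- res
      all_kinetics[[length(all_kinetics) + 1L]] <- res$kinetics
      if (!is.null(res$kiss))
        all_kiss[[length(all_kiss) + 1L]] <-
          mutate(res$kiss$tests, condition = cond, video = sprintf("v%d", rep_i))
    }
  }

  stage <- "report"
  kin_all <- bind_rows(all_kinetics)
  readr::write_csv(kin_all, file.path(out_dir, "kinetics_all.csv"))
  comparison <- NULL
  if (length(conditions) == 2L && videos_per_condition >= 3L) {
    nm <- names(conditions)
    comparison <- compare_conditions(
      filter(kin_all, .data$condition == nm[1L]),
      filter(kin_all, .data$condition == nm[2L]))
    readr::write_csv(comparison, file.path(out_dir, "stats.csv"))
  }
  report <- c(
    "# Tumor-on-chip pipeline report", "",
    sprintf("Conditions: %s; %d video(s) each.",
            paste(names(conditions), collapse = ", "), videos_per_condition),
    "", "## Survival by condition (mean over videos)", "",
    utils::capture.output(print(as.data.frame(
      kin_all %>% group_by(.data$condition, .data$t_n) %>%
        summarise(survival_pct = mean(.data$survival_pct),
                  rate_pct = mean(.data$rate_pct, na.rm = TRUE),
                  .groups = "drop")), digits = 4)))
  if (!is.null(comparison))
    report <- c(report, "", "## Paired Wilcoxon (condition 1 vs 2, survival)", "",
                utils::capture.output(print(as.data.frame(comparison), digits = 4)))
  if (length(all_kiss) > 0)
    report <- c(report, "", "## Kiss-of-life stratification", "",
                utils::capture.output(print(as.data.frame(bind_rows(all_kiss)),
                                            digits = 4)))
  writeLines(report, file.path(out_dir, "report.md"))

  files <- c(files, file.path(out_dir, "kinetics_all.csv"),
             file.path(out_dir, "report.md"),
             if (!is.null(comparison)) file.path(out_dir, "stats.csv"))
  files <- unique(normalizePath(files))
  manifest <- list(
    tool = "tocstamp",
    version = as.character(utils::packageVersion("tocstamp")),
    config_hash = unname(tools::md5sum(
      local({ tf <- tempfile(); config_to_json(cfg, tf); tf }))),
    seed = cfg$sim$seed,
    conditions = names(conditions),
    videos_per_condition = videos_per_condition,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = lapply(files, function(f)
      list(path = sub(paste0("^", normalizePath(out_dir), "/?"), "", f),
           md5 = md5_of_file(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Compare the file checksums of two pipeline runs
#'
#' @param dir_a,dir_b Output directories of two [run_toc_pipeline()] runs.
#' @return TRUE iff both manifests list identical files with identical MD5
#'   checksums.
#' @export
identical_run_checksums <- function(dir_a, dir_b) {
  rd <- function(d) {
    m <- jsonlite::read_json(file.path(d, "manifest.json"), simplifyVector = FALSE)
    x <- vapply(m$files, function(f) f$md5, character(1))
    names(x) <- vapply(m$files, function(f) f$path, character(1))
    x[order(names(x))]
  }
  identical(rd(dir_a), rd(dir_b))
}
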