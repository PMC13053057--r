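#' Simulation configuration for synthetic tumor-on-chip videos
#'
#' Defaults reproduce the acquisition geometry and coculture composition of
#' the chip experiments the generator emulates: a 3.5:1 cancer:CAF seeding
#' ratio, fluorescence frames every 30 minutes, transmission frames every
#' 5 minutes, and up to 72 hours of acquisition. Key names carry their units
#' (`*_um`, `*_h`, `*_min`, `*_px`).
#'
#' @param seed Integer RNG seed; mandatory, the single source of randomness
#'   for one video.
#' @param field_size_px Field size `c(rows, cols)` in pixels.
#' @param pixel_size_um Micrometres per pixel. Physical thresholds used
#'   downstream (18 um contacts, 82 um IOU disc) divide by this value.
#' @param duration_h Total acquisition span, hours.
#' @param dt_fluor_min Minutes between red/green frames.
#' @param dt_trans_min Minutes between transmission frames; must not exceed
#'   `dt_fluor_min`.
#' @param n_cancer,n_caf Cell counts. The default 100:29 keeps the 3.5:1
#'   seeding ratio at desk scale.
#' @param cancer_radius_um `c(mean, sd)` of cancer-cell disc radius.
#' @param caf_length_um,caf_width_um CAF capsule dimensions.
#' @param caf_step_um Persistent-random-walk step length per transmission
#'   frame.
#' @param caf_turn_sd Gaussian turning-angle s.d. per transmission frame
#'   (radians).
#' @param lambda0_per_h Baseline apoptosis hazard per hour (chemotherapy is
#'   modelled only through this rate).
#' @param rho Hazard multiplier applied to cells whose early-window minimum
#'   CAF distance falls below `d_prox_um`; `rho < 1` plants a protective
#'   proximity effect, `rho = 1` switches it off.
#' @param d_prox_um,w_early_h Proximity-hazard distance threshold and early
#'   window length.
#' @param green_rise_frames Fluorescence frames over which the caspase signal
#'   rises linearly to its plateau after an event; the signal is persistent
#'   thereafter.
#' @param green_plateau,red_intensity Peak intensities (uint16 counts).
#' @param trans_background,caf_contrast,caf_texture_sd Transmission-channel
#'   rendering: background level, multiplicative cell darkening, and per-pixel
#'   texture s.d. inside cells (the texture CAF segmentation keys on).
#' @param background,gradient_amp Fluorescence background level and amplitude
#'   of the smooth illumination gradient.
#' @param read_sd Gaussian read-noise s.d.
#' @param shot_scale Poisson shot-noise scaling (photons per intensity unit);
#'   `0` disables shot noise.
#' @return A validated list of class `toc_sim_config`.
#' @export
sim_config <- function(seed,
                       field_size_px = c(512L, 512L),
                       pixel_size_um = 1.3,
                       duration_h = 72,
                       dt_fluor_min = 30,
                       dt_trans_min = 5,
                       n_cancer = 100L,
                       n_caf = 29L,
                       cancer_radius_um = c(8, 1),
                       caf_length_um = 60,
                       caf_width_um = 15,
                       caf_step_um = 2,
                       caf_turn_sd = 0.4,
                       lambda0_per_h = 0.03,
                       rho = 1,
                       d_prox_um = 50,
                       w_early_h = 8,
                       green_rise_frames = 4L,
                       green_plateau = 3000,
                       red_intensity = 10000,
                       trans_background = 2000,
                       caf_contrast = 0.75,
                       caf_texture_sd = 300,
                       background = 500,
                       gradient_amp = 200,
                       read_sd = 50,
                       shot_scale = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (inherits(cfg, "toc_sim_config")) return(cfg)
  errs <- character()
  req <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  known <- names(formals(sim_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    errs <- c(errs, paste("unknown simulation keys:", paste(extra, collapse = ", ")))
  cfg <- utils::modifyList(as.list(formals(sim_config))[-1L], cfg[intersect(names(cfg), known)])
  for (k in names(cfg)) if (is.language(cfg[[k]])) cfg[[k]] <- eval(cfg[[k]])
  req(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed is mandatory and must be a single integer")
  req(length(cfg$field_size_px) == 2L && all(cfg$field_size_px >= 8),
      "field_size_px must be two values >= 8")
  req(cfg$pixel_size_um > 0, "pixel_size_um must be > 0")
  req(cfg$duration_h > 0, "duration_h must be > 0")
  req(cfg$dt_fluor_min > 0 && cfg$dt_trans_min > 0, "frame intervals must be > 0")
  req(cfg$dt_trans_min <= cfg$dt_fluor_min,
      "dt_trans_min must not exceed dt_fluor_min")
  req(cfg$n_cancer >= 1 && cfg$n_caf >= 0, "cell counts must be positive")
  req(length(cfg$cancer_radius_um) == 2L && cfg$cancer_radius_um[1L] > 0,
      "cancer_radius_um must be c(mean, sd) with mean > 0")
  req(cfg$caf_length_um > 0 && cfg$caf_width_um > 0 &&
        cfg$caf_width_um <= cfg$caf_length_um,
      "CAF capsule needs 0 < width <= length")
  req(cfg$caf_step_um >= 0 && cfg$caf_turn_sd >= 0, "CAF motility must be >= 0")
  req(cfg$lambda0_per_h >= 0, "lambda0_per_h must be >= 0")
  req(cfg$rho > 0, "rho must be > 0")
  req(cfg$d_prox_um > 0 && cfg$w_early_h > 0, "proximity hazard needs d_prox_um, w_early_h > 0")
  req(cfg$green_rise_frames >= 1, "green_rise_frames must be >= 1")
  req(all(c(cfg$green_plateau, cfg$red_intensity, cfg$trans_background) > 0),
      "intensities must be > 0")
  req(cfg$caf_contrast > 0 && cfg$caf_contrast <= 1, "caf_contrast must be in (0, 1]")
  req(all(c(cfg$caf_texture_sd, cfg$background, cfg$gradient_amp,
            cfg$read_sd, cfg$shot_scale) >= 0),
      "noise parameters must be >= 0")
  if (length(errs) > 0) abort(paste0("invalid simulation config:\n  - ",
                                     paste(errs, collapse = "\n  - ")))
  cfg$field_size_px <- as.integer(cfg$field_size_px)
  cfg$n_cancer <- as.integer(cfg$n_cancer)
  cfg$n_caf <- as.integer(cfg$n_caf)
  cfg$seed <- as.integer(cfg$seed)
  cfg$green_rise_frames <- as.integer(cfg$green_rise_frames)
  structure(cfg, class = "toc_sim_config")
}

pipeline_defaults <- function() {
  list(
    detect = list(neighborhood_fraction = 1 / 8, sensitivity = 0.05,
                  persistence = 0.95, min_area_px = 20L),
    cafseg = list(method = "classical", texture_window_px = 7L,
                  closing_radius_px = 2L, shrink_px = 3L,
                  min_area_px = 200L, max_area_px = 20000L, sensitivity = 0.5,
                  neighborhood_fraction = 0.25),
    apoptosis = list(k_sigma = 5, m_consec = 3L, window_h = 10),
    proximity = list(contact_um = 18, iou_radius_um = 82,
                     early_window_h = c(0, 8), horizon_h = NULL,
                     exclude_border = TRUE, n_perm = 999L)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a nested list (sections `sim`, `detect`, `cafseg`, `apoptosis`,
#' `proximity`) or a path to a YAML/JSON file. Missing analysis keys are
#' filled with the method defaults (95% persistence, 1/8 Bradley
#' neighborhood, 10-hour windows, 18 um contact threshold, 82 um IOU disc,
#' 0-8 h early window); unknown keys are rejected with an itemised error.
#' The operation is idempotent: `validate_toc_config(validate_toc_config(x))`
#' equals `validate_toc_config(x)`.
#'
#' @param config Nested list or file path.
#' @return A normalised list of class `toc_config`.
#' @export
validate_toc_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON file path")
  config <- unclass(config)
  defaults <- pipeline_defaults()
  known_sections <- c("sim", names(defaults))
  extra <- setdiff(names(config), known_sections)
  if (length(extra) > 0)
    abort(paste("unknown config sections:", paste(extra, collapse = ", ")))
  if (is.null(config$sim)) abort("config must contain a 'sim' section (incl. seed)")
  errs <- character()
  out <- list(sim = validate_sim_config(config$sim))
  for (sec in names(defaults)) {
    given <- config[[sec]] %||% list()
    bad <- setdiff(names(given), names(defaults[[sec]]))
    if (length(bad) > 0)
      errs <- c(errs, sprintf("unknown %s keys: %s", sec, paste(bad, collapse = ", ")))
    out[[sec]] <- utils::modifyList(defaults[[sec]], given)
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(out$detect$persistence > 0 && out$detect$persistence <= 1,
      "detect$persistence must be in (0, 1]")
  chk(out$detect$neighborhood_fraction > 0 && out$detect$neighborhood_fraction <= 1,
      "detect$neighborhood_fraction must be in (0, 1]")
  chk(out$detect$sensitivity >= 0, "detect$sensitivity must be >= 0")
  chk(out$detect$min_area_px >= 1, "detect$min_area_px must be >= 1")
  chk(out$cafseg$method %in% c("classical", "import"),
      "cafseg$method must be 'classical' or 'import'")
  chk(out$apoptosis$k_sigma > 0, "apoptosis$k_sigma must be > 0")
  chk(out$apoptosis$m_consec >= 1, "apoptosis$m_consec must be >= 1")
  chk(out$apoptosis$window_h > 0, "apoptosis$window_h must be > 0")
  chk(out$proximity$contact_um > 0, "proximity$contact_um must be > 0")
  chk(out$proximity$iou_radius_um > 0, "proximity$iou_radius_um must be > 0")
  chk(length(out$proximity$early_window_h) == 2L &&
        out$proximity$early_window_h[1L] < out$proximity$early_window_h[2L],
      "proximity$early_window_h must be an increasing interval")
  if (length(errs) > 0)
    abort(paste0("invalid config:\n  - ", paste(errs, collapse = "\n  - ")))
  if (is.null(out$proximity$horizon_h)) out$proximity$horizon_h <- out$sim$duration_h
  structure(out, class = "toc_config")
}

#' @rdname validate_toc_config
#' @param sim,detect,cafseg,apoptosis,proximity Section lists; see
#'   [sim_config()] and the pipeline defaults.
#' @export
toc_config <- function(sim, detect = list(), cafseg = list(),
                       apoptosis = list(), proximity = list()) {
  validate_toc_config(list(sim = sim, detect = detect, cafseg = cafseg,
                           apoptosis = apoptosis, proximity = proximity))
}

config_to_json <- function(config, path = NULL) {
  strip <- function(v) if (is.list(v)) lapply(unclass(v), strip) else v
  x <- strip(config)
  if (is.null(path)) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}
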