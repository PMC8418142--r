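#' Waveform CSV I/O
#'
#' Waveforms are exchanged as two-column CSV files with header
#' `time_s,value`, time strictly increasing, full double precision.
#'
#' @param path file path.
#' @param time,value waveform samples.
#' @return `read_waveform_csv` returns a data frame with columns `time_s`
#'   and `value`; `write_waveform_csv` returns `path` invisibly. Format
#'   errors name the first offending data row (header excluded).
#' @name waveform_csv
NULL

#' @rdname waveform_csv
#' @export
write_waveform_csv <- function(time, value, path) {
  stopifnot(length(time) == length(value))
  df <- data.frame(time_s = time, value = value)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname waveform_csv
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("no such waveform file: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("waveform format error in ", path,
                                          ": ", conditionMessage(e)))
  if (!all(c("time_s", "value") %in% names(df)) || nrow(df) == 0) {
    stop("waveform format error in ", path,
         ": expected non-empty CSV with header time_s,value")
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad) > 0) {
    stop("waveform format error in ", path, ": non-finite value at row ",
         bad[1])
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono) > 0) {
    stop("waveform format error in ", path,
         ": time not strictly increasing at row ", nonmono[1] + 1)
  }
  df
}

#' Serialise a network model to a YAML configuration
#'
#' Writes (or builds) the configuration list with blocks `heart`, `valve`,
#' `windkessel.{ubv,lbv,lpa,rpa,fen}` and `junction` (per-segment
#' radius/length, wall properties, pouch loss, endograft defaults), in the
#' internal g-mm-s units. A configuration written from the default model
#' reproduces the tabulated parameter values exactly.
#'
#' @param model a `network_model`.
#' @param path optional output path; when `NULL` the list is returned.
#' @return the configuration list, invisibly when written to file.
#' @export
write_model_config <- function(model, path = NULL) {
  stopifnot(inherits(model, "network_model"))
  h <- model$heart
  jn <- model$junction
  seg_block <- function(s) list(radius = s$radius, length = s$length,
                                wall_stiffness = s$wall_stiffness,
                                wall_thickness = s$wall_thickness)
  cfg <- list(
    heart = list(P_RA = h$P_RA, R_TV = h$R_TV, I_TV = h$I_TV,
                 C_AR = h$C_AR, I_AR = h$I_AR, V_rest = h$V_rest,
                 elastance = list(E_max = h$elastance$E_max,
                                  E_min = h$elastance$E_min,
                                  T = h$elastance$T,
                                  tau1_frac = h$elastance$tau1 / h$elastance$T,
                                  m1 = h$elastance$m1,
                                  tau2_frac = h$elastance$tau2 / h$elastance$T,
                                  m2 = h$elastance$m2)),
    valve = h$valve[c("A_ann", "p_open", "p_close", "K_vo", "K_vc",
                      "M_rg", "M_st", "l_eff", "rho", "K_s", "use_Ks")],
    windkessel = lapply(model[c("ubv", "lbv", "lpa", "rpa", "fen")],
                        function(w) w[c("R_p", "C", "R_d", "P_distal")]),
    junction = list(
      segments = lapply(jn$segments, seg_block),
      face_radius = as.list(sqrt(jn$face_areas / pi)),
      pouch_loss_R = jn$pouch_loss_R,
      fenestration_present = jn$fenestration_present),
    blood = list(rho = model$rho, mu = model$mu)
  )
  if (is.null(path)) return(cfg)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(cfg)
}

#' Read a network model from a YAML configuration
#'
#' @param path YAML file written by [write_model_config()] (or following
#'   the same schema).
#' @return a `network_model`.
#' @export
read_model_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  need <- c("heart", "valve", "windkessel", "junction", "blood")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("config error: missing block(s) ", paste(missing, collapse = ", "))
  }
  el <- cfg$heart$elastance
  heart <- heart_params(
    P_RA = cfg$heart$P_RA, R_TV = cfg$heart$R_TV, I_TV = cfg$heart$I_TV,
    C_AR = cfg$heart$C_AR, I_AR = cfg$heart$I_AR,
    V_rest = cfg$heart$V_rest,
    elastance = elastance_params(el$E_max, el$E_min, el$T, el$tau1_frac,
                                 el$m1, el$tau2_frac, el$m2),
    valve = do.call(valve_params, cfg$valve))
  wk <- lapply(cfg$windkessel, function(w) do.call(windkessel_params, w))
  segs <- cfg$junction$segments
  geometry <- lapply(segs, function(s) c(radius = s$radius,
                                         length = s$length))
  geometry$face_radius <- unlist(cfg$junction$face_radius)
  jn <- build_pre_junction(
    geometry = geometry,
    wall_stiffness = segs$ivc$wall_stiffness,
    wall_thickness = segs$ivc$wall_thickness,
    pouch_loss_R = cfg$junction$pouch_loss_R,
    mu = cfg$blood$mu, rho = cfg$blood$rho,
    fenestration_present = cfg$junction$fenestration_present)
  # honour per-segment wall properties when they differ from the IVC limb
  for (nm in names(jn$segments)) {
    s <- segs[[nm]]
    jn$segments[[nm]] <- tube_segment(nm, s$radius, s$length,
                                      s$wall_stiffness, s$wall_thickness,
                                      cfg$blood$mu, cfg$blood$rho)
  }
  jn$node_compliances <- junction_node_compliances(jn)
  network_model(heart = heart, ubv = wk$ubv, lbv = wk$lbv, lpa = wk$lpa,
                rpa = wk$rpa, fen = wk$fen, junction = jn,
                rho = cfg$blood$rho, mu = cfg$blood$mu)
}

provenance_stamp <- function(cfg_like, seed) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg_like, tmp, precision = 15)
  list(config_md5 = unname(tools::md5sum(tmp)), seed = seed,
       package_version = as.character(utils::packageVersion("fontanlpm")))
}

write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in colnames(sim$flows)) {
    if (f == "FEN" && !sim$model$junction$fenestration_present) next
    write_waveform_csv(sim$time, sim$flows[, f],
                       file.path(dir, paste0("flow_", f, ".csv")))
  }
  for (f in colnames(sim$pressures)) {
    if (f == "FEN" && !sim$model$junction$fenestration_present) next
    write_waveform_csv(sim$time, sim$pressures[, f],
                       file.path(dir, paste0("pressure_", f, ".csv")))
  }
  write_waveform_csv(sim$time, sim$volume, file.path(dir, "volume_RV.csv"))
  invisible(dir)
}

#' Run the full pre/post analysis pipeline
#'
#' The end-to-end arc of the analysis: generate (or accept) the clinical
#' targets, calibrate the pre-intervention model, simulate it, apply the
#' virtual endograft revision, simulate the post-intervention model, and
#' write the pre-versus-post comparison. All outputs land under `out_dir`:
#' `calib.json`, `pre/` and `post/` per-face waveform CSVs, and
#' `report.json` with the metrics, energy reports, comparison table and a
#' provenance stamp (config hash, seed, package version).
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the synthetic acquisition noise.
#' @param model ground-truth / initial `network_model`.
#' @param targets optional [calibration_targets()]; when `NULL` they are
#'   derived from a synthetic dataset generated from `model` with `seed`.
#' @param budget calibration evaluation budget; `0` skips calibration.
#' @param free free parameters for [calibrate()].
#' @param graft an [endograft_spec()] for the revision stage.
#' @param bsa body surface area, m^2.
#' @return invisibly, a list with `calibration`, `pre`, `post`
#'   (simulations), `comparison` (data frame) and `report` (list written
#'   to `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 42, model = default_network(),
                         targets = NULL, budget = 150,
                         free = c("R_lpa", "R_rpa", "C_lpa", "C_rpa",
                                  "pouch_loss_R", "C_junction"),
                         graft = endograft_spec(), bsa = 0.51) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(targets)) {
    ds <- generate_dataset(model, seed = seed, bsa = bsa)
    targets <- dataset_to_targets(ds)
  }
  calib <- NULL
  pre_model <- model
  if (budget > 0) {
    calib <- calibrate(model, targets, budget = budget, free = free,
                       bsa = bsa)
    pre_model <- calib$model
    jsonlite::write_json(
      list(scales = as.list(calib$scales),
           residuals_pct = as.list(calib$residuals$per_item),
           category_max_pct = as.list(calib$residuals$category_max),
           converged = calib$converged, iterations = calib$iterations,
           objective = calib$objective),
      file.path(out_dir, "calib.json"), auto_unbox = TRUE, digits = NA)
  }
  pre <- run_to_periodicity(pre_model)
  post_model <- pre_model
  post_model$junction <- apply_endograft(pre_model$junction, graft)
  post <- run_to_periodicity(post_model)
  write_sim_outputs(pre, file.path(out_dir, "pre"))
  write_sim_outputs(post, file.path(out_dir, "post"))
  pre_scal <- report_scalars(metrics_report(pre, bsa), energy_report(pre, bsa))
  post_scal <- report_scalars(metrics_report(post, bsa),
                              energy_report(post, bsa))
  comparison <- compare_models(pre_scal, post_scal)
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  report <- list(
    provenance = provenance_stamp(write_model_config(model), seed),
    pre = as.list(pre_scal), post = as.list(post_scal),
    comparison = comparison,
    more_efficient = isTRUE(attr(comparison, "more_efficient")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calibration = calib, pre = pre, post = post,
                 comparison = comparison, report = report))
}
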