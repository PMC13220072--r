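#' Read a run configuration (YAML or JSON)
#'
#' The configuration mirrors the physical setup: `artery` (either `mesh` +
#' `centerline` file paths, or an inline `fixture` block with [tube_spec()]
#' fields), `stent` (`length_mm`, `diameter_mm`, `crimped_radius_mm`,
#' `strut_thickness_mm`, `youngs_modulus_gpa`, `poisson`), `balloon`
#' (`pressure_atm`), `model` (`threshold_T`), `material` (`C10`..`C60`,
#' `lambda_res`, `nu`), `dynamics` (`gamma`, `alpha`, `beta`, `max_steps`,
#' `tol_disp`), `metrics` (`spacing`, `stations`), `output` (`dir`). All
#' lengths are in millimetres; missing fields take the package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file
#' @return a nested list (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stopf("unsupported config format '.%s' (use YAML or JSON)", ext)
  structure(cfg, class = c("run_config", "list"))
}

cfg_get <- function(cfg, ...) {
  out <- cfg
  for (k in c(...)) {
    if (is.null(out)) return(NULL)
    out <- out[[k]]
  }
  out
}

config_stent <- function(cfg) {
  stent_spec(
    length_mm = cfg_get(cfg, "stent", "length_mm") %||% 34,
    diameter_mm = cfg_get(cfg, "stent", "diameter_mm") %||% 2.15,
    crimped_radius_mm = cfg_get(cfg, "stent", "crimped_radius_mm") %||% 0.5,
    youngs_modulus_gpa = cfg_get(cfg, "stent", "youngs_modulus_gpa") %||% 233,
    poisson = cfg_get(cfg, "stent", "poisson") %||% 0.35,
    pressure_atm = cfg_get(cfg, "balloon", "pressure_atm") %||% 9,
    strut_thickness_mm = cfg_get(cfg, "stent", "strut_thickness_mm") %||% 0.08,
    threshold_T = cfg_get(cfg, "model", "threshold_T") %||% 0.01)
}

config_material <- function(cfg) {
  defaults <- c(C10 = 6.52e-3, C20 = 4.89e-2, C30 = 9.26e-3,
                C40 = 7.60e-1, C50 = -4.30e-1, C60 = 8.69e-2)
  co <- vapply(names(defaults), function(nm)
    cfg_get(cfg, "material", nm) %||% defaults[[nm]], numeric(1))
  artery_material(co,
                  lambda_res = cfg_get(cfg, "material", "lambda_res") %||% 1.4,
                  nu = cfg_get(cfg, "material", "nu") %||% 0.35)
}

config_dynamics <- function(cfg) {
  dynamics_config(
    gamma = cfg_get(cfg, "dynamics", "gamma") %||% 0.65,
    alpha = cfg_get(cfg, "dynamics", "alpha") %||% 0.01,
    beta = cfg_get(cfg, "dynamics", "beta") %||% 0.01,
    max_steps = cfg_get(cfg, "dynamics", "max_steps") %||% 5000L,
    tol_disp = cfg_get(cfg, "dynamics", "tol_disp") %||% 1e-5)
}

config_artery_geometry <- function(cfg) {
  fx <- cfg_get(cfg, "artery", "fixture")
  if (!is.null(fx)) {
    ts <- tube_spec(
      length = fx$length %||% 40, diameter = fx$diameter %||% 3,
      n_axial = fx$n_axial %||% 40, n_circ = fx$n_circ %||% 32,
      stenosis_severity = fx$stenosis_severity %||% 0,
      stenosis_center = fx$stenosis_center %||% ((fx$length %||% 40) / 2),
      stenosis_width = fx$stenosis_width %||% 3,
      curvature_radius = fx$curvature_radius %||% Inf,
      jitter = fx$jitter %||% 0, seed = fx$seed %||% 1L)
    gen <- if (is.finite(ts$curvature_radius)) make_curved_tube
           else if (ts$stenosis_severity > 0) make_stenotic_tube else make_tube
    out <- gen(ts)
    list(mesh = out$mesh, centerline = out$centerline)
  } else {
    mesh_path <- cfg_get(cfg, "artery", "mesh")
    cl_path <- cfg_get(cfg, "artery", "centerline")
    if (is.null(mesh_path) || is.null(cl_path))
      stopf("config must provide artery$mesh and artery$centerline paths, or an artery$fixture block")
    list(mesh = read_surface(mesh_path), centerline = read_centerline(cl_path))
  }
}

#' Run the full virtual-deployment pipeline
#'
#' Pre-process (orient surface outward, convert to the dual simplex mesh,
#' generate the crimped stent by inward centerline projection), main process
#' (damped explicit dynamics with contact-activated wall resistance) and
#' post-process (lumen diameter profiles, optional cross-sections, file
#' exports). Wall-clock time per phase is reported.
#'
#' @param cfg a `run_config` list (see [read_run_config()]); may also be a
#'   plain nested list built in code
#' @param out_dir output directory; overrides `output$dir` in the config.
#'   `NULL` (and no config entry) disables file output.
#' @return a `run_report` list: `converged`, `steps`, `first_contact_step`,
#'   `device` (k_stn, F_unit, F_rf, delta, chi, equilibrium diameter),
#'   `mld_initial`, `mld_final` (data.frames), `stations` (if requested),
#'   `timings_s` (pre/main/post), plus the deformed meshes and history
#' @export
sdm_simulate <- function(cfg, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  geom <- config_artery_geometry(cfg)
  spec <- config_stent(cfg)
  material <- config_material(cfg)
  dyn <- config_dynamics(cfg)

  tri <- orient_outward(geom$mesh, geom$centerline)
  artery_sm <- triangulation_to_simplex(tri)
  sb <- build_stent_mesh(artery_sm, geom$centerline, spec,
                         s0 = cfg_get(cfg, "stent", "s0"))
  t_pre <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  run <- sdm_run(artery_sm, sb, geom$centerline, spec, material, dyn)
  t_main <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  spacing <- cfg_get(cfg, "metrics", "spacing") %||% 0.5
  tri0 <- simplex_to_tri(artery_sm)
  tri1 <- simplex_to_tri(run$artery)
  mld0 <- mld_profile(tri0, geom$centerline, spacing)
  mld1 <- mld_profile(tri1, geom$centerline, spacing)
  stations <- cfg_get(cfg, "metrics", "stations")
  cs <- if (length(stations))
    data.frame(s = unlist(stations),
               initial = cross_section_diameters(tri0, geom$centerline, unlist(stations)),
               final = cross_section_diameters(tri1, geom$centerline, unlist(stations)))
  else NULL

  out_dir <- out_dir %||% cfg_get(cfg, "output", "dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(run$history, file.path(out_dir, "history.csv"), row.names = FALSE)
    write_surface(tri1, file.path(out_dir, "artery_deformed.stl"))
    write_surface(simplex_to_tri(run$stent), file.path(out_dir, "stent_deployed.stl"))
    write_simplex(run$artery, file.path(out_dir, "artery_deformed.ply"))
    utils::write.csv(mld1, file.path(out_dir, "mld_final.csv"), row.names = FALSE)
    utils::write.csv(mld0, file.path(out_dir, "mld_initial.csv"), row.names = FALSE)
  }
  t_post <- proc.time()[["elapsed"]] - t2

  report <- structure(list(
    converged = run$converged, steps = run$steps,
    first_contact_step = run$first_contact_step,
    device = list(k_stn = spec$k_stn, F_unit = spec$F_unit, F_rf = spec$F_rf,
                  delta = spec$delta, chi = spec$chi,
                  d_equilibrium = spec$d_equilibrium),
    mld_initial = mld0, mld_final = mld1, stations = cs,
    timings_s = list(pre = t_pre, main = t_main, post = t_post),
    history = run$history, stent = run$stent, artery = run$artery),
    class = "run_report")

  if (!is.null(out_dir)) {
    ser <- report[c("converged", "steps", "first_contact_step", "device")]
    ser$mld_initial <- mld0; ser$mld_final <- mld1
    if (!is.null(cs)) ser$stations <- cs
    jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("<run_report> %s in %d steps (first contact: %s)\n",
                     "  device: k_stn %.3f N/mm, F_rf %.2f N, chi %.4f, equilibrium %.3f mm\n",
                     "  MLD (final): min %.3f, max %.3f mm | timings pre/main/post: %.2f/%.2f/%.2f s\n"),
              if (x$converged) "converged" else "NOT converged", x$steps,
              ifelse(is.na(x$first_contact_step), "none", x$first_contact_step),
              x$device$k_stn, x$device$F_rf, x$device$chi, x$device$d_equilibrium,
              min(x$mld_final$mld), max(x$mld_final$mld),
              x$timings_s$pre, x$timings_s$main, x$timings_s$post))
  invisible(x)
}
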