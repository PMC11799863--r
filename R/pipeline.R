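#' Study configuration
#'
#' Bundles every knob of the in-silico study so a run is reproducible from
#' its config plus seed alone.
#'
#' @param n_knees_per_group Knees per group.
#' @param seed Master seed.
#' @param preset Tunnel prescription preset, see [default_tunnel_specs()].
#' @param noise_sd Post-operative surface noise (mm).
#' @param resolution_mm Femur polygonization resolution (mm).
#' @param error_model_path Optional YAML override for the error model.
#' @param displacement Rigid displacement bounds, list `max_angle_deg`,
#'   `max_trans_mm`.
#' @param icp_control List of [icp()] arguments.
#' @param min_wall_mm Collision threshold, see [check_convergence()].
#' @param quartile_convention,levene_center Statistical conventions.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_knees_per_group = 5, seed = 1L,
                         preset = "protocol", noise_sd = 0.79,
                         resolution_mm = 3, error_model_path = NULL,
                         displacement = list(max_angle_deg = 15,
                                             max_trans_mm = 8),
                         icp_control = list(), min_wall_mm = 0,
                         quartile_convention = "linear",
                         levene_center = "mean") {
  structure(
    list(n_knees_per_group = n_knees_per_group, seed = as.integer(seed),
         preset = preset, noise_sd = noise_sd,
         resolution_mm = resolution_mm,
         error_model_path = error_model_path, displacement = displacement,
         icp_control = icp_control, min_wall_mm = min_wall_mm,
         quartile_convention = quartile_convention,
         levene_center = levene_center),
    class = "study_config"
  )
}

#' Run the full in-silico study
#'
#' Executes every stage in order -- generate, plan, simulate execution
#' error, displace, register, measure, compare -- and writes a run
#' directory: `records.csv` (per-tunnel accuracy records),
#' `comparisons.csv` (the statistical comparison table),
#' `collisions.csv` (pairwise convergence reports of the planned tunnels,
#' per knee), `registration.json` (per-knee ICP summaries),
#' `config.json` (config echo), and `manifest.json`.
#'
#' @param config A [study_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with `records`, `comparisons`, `collisions`,
#'   and the output paths.
#' @export
run_study <- function(config = study_config(), outdir = tempfile("psirun")) {
  stopifnot(inherits(config, "study_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  model <- default_error_model(config$error_model_path)
  specs <- default_tunnel_specs(config$preset)

  records <- simulate_study(
    n_knees_per_group = config$n_knees_per_group, error_model = model,
    seed = config$seed, specs = specs, noise_sd = config$noise_sd,
    resolution_mm = config$resolution_mm,
    displacement = config$displacement, icp_control = config$icp_control
  )

  # collision reports on the planned trajectories, one femur per knee seed
  set.seed(config$seed)
  n_total <- 2L * config$n_knees_per_group
  knee_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  knee_ids <- unique(records$knee_id)
  collisions <- do.call(rbind, lapply(seq_len(n_total), function(k) {
    femur <- generate_femur(seed = knee_seeds[k],
                            resolution_mm = config$resolution_mm)
    planned <- plan_knee(femur, specs, knee_frames(femur))
    rep_k <- check_convergence(planned, config$min_wall_mm)
    rep_k$knee_id <- knee_ids[k]
    rep_k
  }))

  comparisons <- compare_study(records,
                               quartile_convention =
                                 config$quartile_convention,
                               levene_center = config$levene_center)

  regs <- attr(records, "registrations")
  reg_summary <- lapply(regs, function(r)
    list(mean_distance_mm = r$mean_distance_mm, iterations = r$iterations,
         converged = r$converged,
         transform = as_homogeneous(r$transform)))

  paths <- list(
    records = file.path(outdir, "records.csv"),
    comparisons = file.path(outdir, "comparisons.csv"),
    collisions = file.path(outdir, "collisions.csv"),
    registration = file.path(outdir, "registration.json"),
    config = file.path(outdir, "config.json"),
    manifest = file.path(outdir, "manifest.json")
  )
  rec_out <- records
  attr(rec_out, "registrations") <- NULL
  utils::write.csv(rec_out, paths$records, row.names = FALSE)
  utils::write.csv(as.data.frame(comparisons), paths$comparisons,
                   row.names = FALSE)
  utils::write.csv(collisions, paths$collisions, row.names = FALSE)
  jsonlite::write_json(reg_summary, paths$registration, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    list(package = "psitunnel",
         version = as.character(utils::packageVersion("psitunnel")),
         n_records = nrow(records),
         n_comparison_rows = nrow(comparisons),
         n_collisions = sum(collisions$collides)),
    paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(records = records, comparisons = comparisons,
                 collisions = collisions, paths = paths))
}
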