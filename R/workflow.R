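user_error <- function(...) {
  stop(structure(class = c("mirloops_user_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read and validate a run configuration
#'
#' Run configurations are YAML files (or equivalent named lists) holding
#' input paths, the focal gene, motif constraints, circuit parameter
#' overrides, the output directory and the seed. The seed is recorded in
#' every output manifest so runs are rerunnable bit-for-bit.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) user_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, out_dir = "mirloops_out", radius = 1L,
                   require_mirna = FALSE, log_level = "info")
  config <- utils::modifyList(defaults, config)
  config$seed <- as.integer(config$seed)
  structure(config, class = c("run_config", "list"))
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

write_manifest <- function(config, outputs, file = "manifest.json") {
  manifest <- list(
    package = "mirloops",
    version = as.character(utils::packageVersion("mirloops")),
    seed = config$seed,
    config = unclass(config),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(config$out_dir, file)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Assemble a focal regulatory network from configured inputs
#'
#' Runs the full assembly chain: merge the configured source networks
#' (each tagged with its provenance label), extract the focal ego
#' subnetwork, integrate miRNA-target records, and annotate known TFs.
#' Writes the result as GraphML and TSV along with a degree summary and a
#' run manifest.
#'
#' Config fields used: `networks` (list of `path`/`label`/optional
#' `dialect` entries), `focal`, `radius`, `mirna_targets` (optional TSV),
#' `tf_list` (optional one-symbol-per-line file), `out_dir`, `seed`.
#'
#' @param config Path or list accepted by [read_run_config()].
#' @return Invisibly, a list with the final `network` and output paths.
#' @export
run_build_network <- function(config) {
  config <- read_run_config(config)
  ensure_out_dir(config)
  if (is.null(config$networks) || !length(config$networks))
    user_error("config must list at least one input network")
  nets <- purrr::map(config$networks, function(nw) {
    if (!file.exists(nw$path)) user_error("network file not found: ", nw$path)
    read_edge_table(nw$path, dialect = nw$dialect,
                    name = nw$label %||% basename(nw$path))
  })
  labels <- purrr::map_chr(config$networks, function(nw)
    nw$label %||% basename(nw$path))
  net <- merge_networks(nets, labels, name = "full_network")
  log_msg(config, "merged ", length(nets), " network(s): ",
          nrow(net$nodes), " nodes, ", nrow(net$edges), " edges")

  if (!is.null(config$focal)) {
    focal <- normalize_symbol(config$focal)
    if (!focal %in% net$nodes$symbol)
      user_error("focal gene '", config$focal,
                 "' not present in the merged network")
    net <- extract_focal_subnetwork(net, focal, radius = config$radius)
    log_msg(config, "focal subnetwork around ", focal, ": ",
            nrow(net$nodes), " nodes")
  }
  if (!is.null(config$mirna_targets)) {
    if (!file.exists(config$mirna_targets))
      user_error("miRNA-target table not found: ", config$mirna_targets)
    tbl <- readr::read_tsv(config$mirna_targets, show_col_types = FALSE)
    net <- integrate_mirna_targets(net, tbl)
    log_msg(config, "integrated miRNA targets (",
            attr(net, "n_skipped"), " record(s) skipped)")
  }
  if (!is.null(config$tf_list)) {
    if (!file.exists(config$tf_list))
      user_error("TF list not found: ", config$tf_list)
    tfs <- readLines(config$tf_list, warn = FALSE)
    tfs <- trimws(tfs[nzchar(trimws(tfs)) & !startsWith(tfs, "#")])
    net <- suppressMessages(annotate_tfs(net, tfs))
  }

  paths <- list(
    graphml = file.path(config$out_dir, "network.graphml"),
    tsv = file.path(config$out_dir, "network.tsv"),
    degrees = file.path(config$out_dir, "degree_summary.tsv"))
  write_network(net, paths$graphml, "graphml")
  write_network(net, paths$tsv, "tsv")
  readr::write_tsv(degree_summary(net), paths$degrees)
  write_manifest(config, paths)
  invisible(list(network = net, paths = paths))
}

#' Enumerate and classify motifs in a configured network
#'
#' Reads the configured network file, enumerates feedforward and feedback
#' loops under the configured constraints, and writes the motif table,
#' census and manifest.
#'
#' Config fields used: `network` (path), `require_member`,
#' `require_mirna`, `out_dir`, `seed`.
#'
#' @inheritParams run_build_network
#' @return Invisibly, a list with `motifs`, `census` and output paths.
#' @export
run_find_motifs <- function(config) {
  config <- read_run_config(config)
  ensure_out_dir(config)
  if (is.null(config$network)) user_error("config must name a network file")
  if (!file.exists(config$network))
    user_error("network file not found: ", config$network)
  net <- read_edge_table(config$network)
  motifs <- dplyr::bind_rows(
    enumerate_ffls(net, config$require_member, config$require_mirna),
    enumerate_fbls(net, 3, config$require_member, config$require_mirna))
  census <- motif_census(net, config$require_member, config$require_mirna)
  paths <- list(motifs = file.path(config$out_dir, "motifs.tsv"),
                census = file.path(config$out_dir, "motif_census.tsv"))
  write_motif_table(motifs, paths$motifs)
  write_motif_table(census, paths$census)
  write_manifest(config, paths)
  log_msg(config, nrow(motifs), " motif instance(s) found")
  invisible(list(motifs = motifs, census = census, paths = paths))
}

scenario_names <- function() {
  c("input_functions", "leak_suppression", "ffl_delay_and", "ffl_delay_or",
    "fbl_bifurcation", "fbl_hysteresis")
}

scenario_defaults <- function(scenario) {
  path <- system.file("extdata", "scenarios", paste0(scenario, ".yaml"),
                      package = "mirloops")
  if (!nzchar(path)) user_error("unknown scenario: ", scenario)
  yaml::read_yaml(path)
}

#' Run a named dynamics scenario
#'
#' Scenarios bundle a circuit, a stimulus protocol and the metrics that
#' summarize its behaviour; defaults ship as YAML under
#' `inst/extdata/scenarios` and can be overridden via the config's
#' `scenario_params` (path to a YAML of overrides) or `params` (inline
#' list).
#'
#' \describe{
#'   \item{`input_functions`}{Linear/saturated/sigmoidal response and
#'     sensitivity curves plus rheostat phenotype calls along an MITF
#'     sweep.}
#'   \item{`leak_suppression`}{Leaky-transcript clearance with and without
#'     the miRNA degradation arm, and the AUC-vs-lambda curve.}
#'   \item{`ffl_delay_and`, `ffl_delay_or`}{Gate-dependent sign-sensitive
#'     delay and transient-pulse rejection of the feedforward circuit.}
#'   \item{`fbl_bifurcation`}{Fixed points across an ATF2-activity scan,
#'     folds, bistable window, reversibility verdict for the default and
#'     the basal-shifted (irreversible) parameterization.}
#'   \item{`fbl_hysteresis`}{Quasi-static up/down sweep with switching
#'     thresholds and a four-phase replay with phenotype calls.}
#' }
#'
#' @inheritParams run_build_network
#' @param scenario One of `scenario_names()`.
#' @return Invisibly, a list with the scenario `summary` (also written as
#'   JSON) and output paths.
#' @export
run_simulate <- function(config, scenario) {
  config <- read_run_config(config)
  scenario <- match.arg(scenario, scenario_names())
  ensure_out_dir(config)
  params <- scenario_defaults(scenario)
  if (!is.null(config$scenario_params)) {
    if (!file.exists(config$scenario_params))
      user_error("scenario parameter file not found: ",
                 config$scenario_params)
    params <- utils::modifyList(params, yaml::read_yaml(
      config$scenario_params))
  }
  if (!is.null(config$params))
    params <- utils::modifyList(params, config$params)

  out <- switch(scenario,
                input_functions = scenario_input_functions(config, params),
                leak_suppression = scenario_leak_suppression(config, params),
                ffl_delay_and = scenario_ffl_delay(config, params, "AND"),
                ffl_delay_or = scenario_ffl_delay(config, params, "OR"),
                fbl_bifurcation = scenario_fbl_bifurcation(config, params),
                fbl_hysteresis = scenario_fbl_hysteresis(config, params))
  summary_path <- file.path(config$out_dir,
                            paste0(scenario, "_summary.json"))
  jsonlite::write_json(out$summary, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$paths$summary <- summary_path
  write_manifest(config, out$paths,
                 file = paste0(scenario, "_manifest.json"))
  invisible(out)
}

scenario_input_functions <- function(config, p) {
  grid <- seq(0, p$sox10_max, length.out = p$n_grid)
  specs <- list(
    linear = input_function_spec("linear", a = p$a),
    saturated = input_function_spec("saturated", v_max = p$v_max,
                                    k_half = p$k_half),
    sigmoidal = input_function_spec("sigmoidal", v_max = p$v_max,
                                    k_half = p$k_half, hill_n = p$hill_n))
  curves <- purrr::imap_dfr(specs, function(sp, nm)
    tibble::tibble(model = nm, sox10 = grid,
                   mitf = input_response(sp, grid),
                   sensitivity = response_sensitivity(sp, grid)))
  map <- phenotype_map(boundaries = unlist(p$boundaries),
                       gray_width = p$gray_width)
  curves$phenotype <- classify_phenotype(curves$mitf, map)
  path <- file.path(config$out_dir, "input_functions.tsv")
  readr::write_tsv(curves, path)
  n <- p$hill_n
  summary <- list(
    sigmoidal_midpoint = input_response(specs$sigmoidal, p$k_half),
    sigmoidal_peak_sensitivity_at =
      p$k_half * ((n - 1) / (n + 1))^(1 / n),
    saturated_initial_sensitivity = p$v_max / p$k_half)
  list(summary = summary, paths = list(curves = path))
}

scenario_leak_suppression <- function(config, p) {
  fp <- do.call(ffl_params, p$ffl_params %||% list())
  cmp <- leaky_transcript_comparison(fp, lambda = p$lambda,
                                     hypoxia_time = p$hypoxia_time,
                                     t_end = p$t_end)
  curve <- leak_suppression_curve(fp, lambdas = seq(p$lambda_min,
                                                    p$lambda_max,
                                                    length.out = p$n_lambda),
                                  hypoxia_time = p$hypoxia_time,
                                  t_end = p$t_end)
  paths <- list(
    trajectories = file.path(config$out_dir, "leak_trajectories.tsv"),
    curve = file.path(config$out_dir, "leak_auc_curve.tsv"))
  readr::write_tsv(cmp$trajectories, paths$trajectories)
  readr::write_tsv(curve, paths$curve)
  m <- cmp$metrics
  auc_with <- m$auc[m$run == "with_mirna"]
  auc_without <- m$auc[m$run == "without_mirna"]
  list(summary = list(
    auc_with_mirna = auc_with, auc_without_mirna = auc_without,
    auc_ratio = auc_with / auc_without,
    t10_with_mirna = m$t10[m$run == "with_mirna"],
    t10_without_mirna = m$t10[m$run == "without_mirna"],
    auc_monotone_in_lambda = all(diff(curve$auc) < 0)),
    paths = paths)
}

scenario_ffl_delay <- function(config, p, gate) {
  fp <- do.call(ffl_params, p$ffl_params %||% list())
  model <- build_ffl_model(fp, gate = gate, logic_mode = "threshold")
  d <- ffl_delay_metrics(model, t_on = p$t_on, t_off = p$t_off,
                         t_end = p$t_end)
  pr <- pulse_rejection(model, pulse_durations = unlist(p$pulse_durations),
                        epsilon = p$epsilon)
  paths <- list(trajectory = file.path(
    config$out_dir, paste0("ffl_", tolower(gate), "_trajectory.tsv")))
  readr::write_tsv(tibble::as_tibble(d$trajectory), paths$trajectory)
  list(summary = list(
    gate = gate,
    off_delay_mitf = d$off_delay_mitf,
    off_delay_sox10 = d$off_delay_sox10,
    off_delay_difference = d$off_delay_difference,
    on_delay_mitf = d$on_delay_mitf,
    on_delay_sox10 = d$on_delay_sox10,
    on_delay_difference = d$on_delay_difference,
    pulse_epsilon = pr$epsilon,
    min_responding_pulse = pr$min_responding_duration,
    short_pulse_excursion = pr$results$excursion[1]),
    paths = paths)
}

#' Sign-sensitive delay metrics for a feedforward circuit
#'
#' Simulates an ON -> OFF -> ON signal protocol and measures, at each
#' step, the midpoint-crossing delay of MITF protein and of SOX10. The
#' AND gate delays MITF (relative to SOX10) after signal *removal*; the
#' OR gate after signal *onset*.
#'
#' @param model An FFL `circuit_model`.
#' @param t_on Time the signal is removed (end of initial ON phase).
#' @param t_off Time the signal resumes.
#' @param t_end End of simulation.
#' @return List with the trajectory and the four delays plus their
#'   OFF-step and ON-step differences (MITF minus SOX10).
#' @export
ffl_delay_metrics <- function(model, t_on = 12, t_off = 30, t_end = 45) {
  sig <- signal_profile(c(t_on, t_off), c(1, 0, 1))
  ss <- find_steady_states(model, input_value = 1, n_starts = 12, seed = 1)
  init <- as.numeric(ss[which.max(ss$MIR155), model$species])
  traj <- simulate_circuit(model, sig, t_end = t_end, initial_state = init,
                           n_out = 4501)
  off_m <- measure_response_delay(traj, "MITF_protein", t_on)
  off_s <- measure_response_delay(traj, "SOX10", t_on)
  on_m <- measure_response_delay(traj, "MITF_protein", t_off)
  on_s <- measure_response_delay(traj, "SOX10", t_off)
  list(trajectory = traj,
       off_delay_mitf = as.numeric(off_m),
       off_delay_sox10 = as.numeric(off_s),
       off_delay_difference = as.numeric(off_m) - as.numeric(off_s),
       on_delay_mitf = as.numeric(on_m),
       on_delay_sox10 = as.numeric(on_s),
       on_delay_difference = as.numeric(on_m) - as.numeric(on_s))
}

scenario_fbl_bifurcation <- function(config, p) {
  grid <- seq(p$atf2_min, p$atf2_max, by = p$atf2_step)
  fp <- do.call(fbl_params, p$fbl_params %||% list())
  model <- build_fbl_model(fp)
  bd <- scan_bifurcation(model, grid, physical_range = c(0, Inf),
                         seed = config$seed, parameter = "ATF2 activity")
  fp_irrev <- utils::modifyList(fp, list(atf2_basal = p$irreversible_basal))
  bd_irrev <- scan_bifurcation(build_fbl_model(fp_irrev), grid,
                               physical_range = c(0, Inf),
                               seed = config$seed,
                               parameter = "ATF2 activity")
  paths <- list(
    points = file.path(config$out_dir, "bifurcation_points.tsv"),
    points_irrev = file.path(config$out_dir,
                             "bifurcation_points_basal_shifted.tsv"))
  readr::write_tsv(tidy(bd), paths$points)
  readr::write_tsv(tidy(bd_irrev), paths$points_irrev)
  list(summary = list(
    n_folds = length(bd$folds),
    fold_left = if (length(bd$folds)) min(bd$folds) else NA,
    fold_right = if (length(bd$folds)) max(bd$folds) else NA,
    reversibility = bd$reversibility,
    basal_shifted_n_folds = length(bd_irrev$folds),
    basal_shifted_reversibility = bd_irrev$reversibility),
    paths = paths)
}

scenario_fbl_hysteresis <- function(config, p) {
  fp <- do.call(fbl_params, p$fbl_params %||% list())
  model <- build_fbl_model(fp)
  grid <- seq(p$atf2_min, p$atf2_max, by = p$atf2_step)
  hs <- hysteresis_sweep(model, grid, dwell = p$dwell)

  phases <- unlist(p$replay_levels)
  dur <- p$phase_duration
  sig <- signal_profile(dur * seq_len(length(phases) - 1), phases)
  ss <- find_steady_states(model, phases[1], n_starts = 12, seed = 1)
  init <- as.numeric(ss[which.max(ss$SOX10), model$species])
  traj <- simulate_circuit(model, sig, t_end = dur * length(phases),
                           initial_state = init)
  pmax_mitf <- fp$beta_p / fp$delta_p
  map <- melanoma_state_map(c(0, pmax_mitf))
  phases_tbl <- phase_report(traj, map)

  paths <- list(
    sweep = file.path(config$out_dir, "hysteresis_sweep.tsv"),
    replay = file.path(config$out_dir, "phase_replay.tsv"),
    phases = file.path(config$out_dir, "phase_report.tsv"))
  readr::write_tsv(hs$sweep, paths$sweep)
  readr::write_tsv(tibble::as_tibble(traj), paths$replay)
  readr::write_tsv(phases_tbl, paths$phases)
  list(summary = list(
    up_threshold = hs$up_threshold,
    down_threshold = hs$down_threshold,
    loop_width = hs$loop_width,
    phase_phenotypes = phases_tbl$phenotype),
    paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
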