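#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, preset to the reference
#' parameterization: edge width 1 cell, 100 hm^2 core threshold, dPC > 1,
#' 1500 m / 0.5 dispersal kernel, land-use/relief resistance scores with
#' 0.7/0.3 weights, 100 m corridor buffer, 30 m / 5000 m river-corridor
#' rules, 7 nodes, the per-class neighborhood weights, both transfer
#' matrices, 5-km rings (12 of them) and the ANN settings.
#'
#' @param seed Global seed; per-stage seeds are derived by fixed offsets so
#'   stages can be re-run in isolation.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synth = list(
      shape = c(200, 200), cell_size = 30,
      class_fractions = c(arable = 0.30, woodland = 0.30, grassland = 0.10,
                          water = 0.10, construction = 0.15, unused = 0.05),
      autocorrelation_range = 12,
      transition_matrix = NULL,  # NULL -> built-in urbanizing default
      steps = 2, epoch_interval = 10
    ),
    esp = list(
      edge_width = 1, core_min_area = 100, dpc_min = 1,
      distance_threshold = 1500, p_at_threshold = 0.5, kernel_mode = "kernel",
      al_mode = "patch_sum",
      water_min_area = 100, elongation_max = 10,
      corridor_buffer = 100, river_min_width = 30, river_min_length = 5000,
      n_corridors = 14, n_nodes = 7, node_max_dist = Inf
    ),
    resistance = RESISTANCE_DEFAULTS,
    sim = list(
      horizon_years = 12,
      neighborhood_weights = NEIGHBORHOOD_WEIGHTS,
      window = 3, max_iterations = 200, tolerance = 0,
      ann = list(fraction = 0.05, hidden_units = 12, maxit = 200)
    ),
    metrics = list(ring_width = 5000, n_rings = 12,
                   validation_fraction = 0.1)
  )
}

# Built-in per-step transition matrix for the synthetic epochs: a slowly
# urbanizing landscape (arable and grassland feed construction; classes are
# otherwise sticky).
default_transition_matrix <- function() {
  cls <- names(LU_CLASSES)
  M <- diag(6)
  dimnames(M) <- list(cls, cls)
  M["arable", "arable"] <- 0.88; M["arable", "construction"] <- 0.10
  M["arable", "grassland"] <- 0.02
  M["woodland", "woodland"] <- 0.97; M["woodland", "construction"] <- 0.02
  M["woodland", "grassland"] <- 0.01
  M["grassland", "grassland"] <- 0.90; M["grassland", "construction"] <- 0.06
  M["grassland", "arable"] <- 0.04
  M["water", "water"] <- 0.99; M["water", "construction"] <- 0.01
  M["unused", "unused"] <- 0.85; M["unused", "construction"] <- 0.10
  M["unused", "arable"] <- 0.05
  M
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override the defaults; everything else keeps its
#' default.
#'
#' @param path YAML file.
#' @param seed Fallback global seed.
#' @return Configuration list.
#' @export
load_config <- function(path, seed = 1) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(default_config(seed), user)
  if (!is.null(cfg$synth$class_fractions))
    cfg$synth$class_fractions <- unlist(cfg$synth$class_fractions)
  cfg
}

#' Generate the synthetic study system a config describes
#'
#' @param config Configuration list.
#' @return See [generate_study_system()].
#' @export
run_synth <- function(config) {
  sy <- config$synth
  M <- if (is.null(sy$transition_matrix)) default_transition_matrix()
       else as.matrix(sy$transition_matrix)
  spec <- landscape_spec(sy$shape, sy$cell_size, sy$class_fractions,
                         sy$autocorrelation_range, seed = config$seed + 11L)
  evo <- evolution_spec(M, steps = sy$steps, seed = config$seed + 12L)
  generate_study_system(spec, evo)
}

#' Construct the ecological security pattern
#'
#' Runs foreground extraction, MSPA, core selection, PC/dPC source selection
#' (plus large non-river water bodies), the resistance surface, least-cost
#' corridors between all source pairs, gravity ranking with a spanning
#' safety net, the 100 m corridor buffer, river corridors, and node
#' selection, then assembles the restricted-area pattern.
#'
#' @param landuse Base-epoch [land_grid].
#' @param relief Topographic-relief [cont_grid].
#' @param config Configuration list.
#' @param river_mask Optional [bin_mask] of the mapped river network.
#' @return List: `esp`, `sources`, `cores`, `nodes`, `dpc` (table),
#'   `gravity` (table), `corridors` (paths), `mspa`, `resistance`.
#' @export
run_esp <- function(landuse, relief, config = default_config(),
                    river_mask = NULL) {
  p <- config$esp
  fg <- make_foreground(landuse)
  if (!any(fg$bits)) {
    warning("no woodland/grassland foreground; ecological security pattern is empty")
    empty <- bin_mask(matrix(FALSE, nrow(landuse$codes), ncol(landuse$codes)),
                      landuse$cell_size, landuse$origin)
    return(list(esp = assemble_esp(empty, empty), sources = NULL, cores = NULL,
                nodes = NULL, dpc = NULL, gravity = NULL, corridors = list(),
                mspa = NULL, resistance = NULL))
  }
  ms <- classify_mspa(fg, edge_width = p$edge_width)
  cores <- extract_cores(ms, min_area = p$core_min_area)
  if (length(cores$patches) == 0)
    stop("no core patch above the area threshold; lower esp$core_min_area")
  graph <- build_connectivity_graph(cores, threshold = p$distance_threshold,
                                    p_thr = p$p_at_threshold,
                                    mode = p$kernel_mode, al_mode = p$al_mode,
                                    landscape_area =
                                      cells_to_hm2(sum(landuse$codes != landuse$nodata),
                                                   landuse$cell_size))
  dpc <- compute_dpc(graph)
  water <- patch_set_from_mask(landuse$codes == LU_CLASSES[["water"]],
                               landuse$cell_size, landuse$origin)
  sources <- select_sources(cores, dpc, water, dpc_min = p$dpc_min,
                            water_min_area = p$water_min_area,
                            elongation_max = p$elongation_max,
                            river_mask = river_mask)
  if (length(sources$patches) == 0)
    stop("no ecological source selected; relax esp thresholds")
  res <- build_resistance(landuse, relief, config$resistance)
  paths <- list()
  ns <- length(sources$patches)
  if (ns >= 2) {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      paths[[length(paths) + 1]] <-
        least_cost_path(res, sources$patches[[i]], sources$patches[[j]])
  }
  gravity <- if (length(paths)) gravity_matrix(paths, sources, res) else NULL
  selected <- if (length(paths))
    select_corridors(paths, gravity, rule = "top_k", k = p$n_corridors)
    else list()
  corr_mask <- buffer_paths(selected, p$corridor_buffer, fg)
  rivers <- river_corridors(bin_mask(landuse$codes == LU_CLASSES[["water"]],
                                     landuse$cell_size, landuse$origin),
                            min_width = p$river_min_width,
                            min_length = p$river_min_length)
  nodes <- select_nodes(cores, sources, n = p$n_nodes,
                        corridor_mask = corr_mask, max_dist = p$node_max_dist)
  esp <- assemble_esp(patch_set_mask(sources), corr_mask, rivers,
                      patch_set_mask(nodes))
  list(esp = esp, sources = sources, cores = cores, nodes = nodes, dpc = dpc,
       gravity = gravity, corridors = selected, mspa = ms, resistance = res)
}

#' Run one simulation track
#'
#' demand -> suitability -> allocation -> expansion metrics; when a held-out
#' later epoch is supplied the run is a hindcast and kappa validation is
#' reported against it.
#'
#' @param epochs List of >= 2 [land_grid]s (calibration pair = last two).
#' @param factors Driving-factor stack.
#' @param scenario "natural" or "ecological".
#' @param config Configuration list.
#' @param esp `esp` object (ecological scenario).
#' @param holdout Optional observed [land_grid] at the horizon for
#'   validation.
#' @return List: `grid`, `demand`, `matrix`, `metrics` (quadrant + ring
#'   tables), `validation` (or NULL).
#' @export
run_simulation <- function(epochs, factors, scenario = "natural",
                           config = default_config(), esp = NULL,
                           holdout = NULL) {
  s <- config$sim
  name <- match.arg(scenario, c("natural", "ecological"))
  restricted <- if (name == "ecological") {
    if (is.null(esp)) stop("ecological scenario requires an esp")
    esp$restricted
  } else NULL
  sc <- scenario_config(TRANSFER_MATRICES[[name]], restricted = restricted,
                        neighborhood_weights = s$neighborhood_weights,
                        window = s$window, max_iterations = s$max_iterations,
                        tolerance = s$tolerance, seed = config$seed + 31L)
  sim <- simulate_scenario(epochs, factors, scenario = sc,
                           horizon_years = s$horizon_years,
                           epoch_interval = config$synth$epoch_interval,
                           ann = s$ann, seed = config$seed + 21L)
  base <- epochs[[length(epochs)]]
  center <- center_of_gravity(base, "construction")
  zoning <- make_zonings(center, base, n_rings = config$metrics$n_rings,
                         ring_width = config$metrics$ring_width)
  years <- c(0, s$horizon_years)
  series <- stats::setNames(list(base, sim$grid), years)
  metrics <- list(
    quadrant = zonal_series(series, zoning, "construction", "quadrant"),
    ring = zonal_series(series, zoning, "construction", "ring")
  )
  validation <- if (!is.null(holdout))
    kappa_validate(holdout, sim$grid,
                   fraction = config$metrics$validation_fraction,
                   seed = config$seed + 41L)
  else NULL
  list(grid = sim$grid, demand = sim$demand, matrix = sim$matrix,
       metrics = metrics, validation = validation, scenario = name)
}

#' Run the full pipeline on a synthetic study system
#'
#' Generates the landscape sequence, constructs the ecological security
#' pattern, simulates both scenarios from the final epoch, and reports the
#' comparison. When `outdir` is given every artifact is written (ASCII
#' grids, CSV tables, corridor GeoJSON) together with a manifest of file
#' hashes.
#'
#' @param config Configuration list.
#' @param outdir Optional output directory.
#' @return List: `system`, `esp_result`, `natural`, `ecological`,
#'   `comparison` (data.frame), `manifest` (or NULL).
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  system <- run_synth(config)
  base <- system$epochs[[length(system$epochs)]]
  esp_res <- run_esp(base, system$relief, config)
  nat <- run_simulation(system$epochs, system$factors, "natural", config)
  eco <- run_simulation(system$epochs, system$factors, "ecological", config,
                        esp = esp_res$esp)
  cs <- base$cell_size
  area_constr <- function(g) cells_to_km2(sum(g$codes == LU_CLASSES[["construction"]]), cs)
  a0 <- area_constr(base)
  comparison <- do.call(rbind, lapply(list(natural = nat, ecological = eco),
    function(r) {
      a1 <- area_constr(r$grid)
      data.frame(scenario = r$scenario, construction_km2 = a1,
                 net_increase_km2 = a1 - a0,
                 ai = compute_ai(a0, a1, config$sim$horizon_years),
                 agr_pct = compute_agr(a0, a1, config$sim$horizon_years))
    }))
  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name, writer) {
      p <- file.path(outdir, name); writer(obj, p); p
    }
    files <- c(
      wr(base, "landuse_base.asc", write_ascii_grid),
      wr(esp_res$esp$restricted, "esp_restricted.asc", write_ascii_grid),
      wr(nat$grid, "sim_natural.asc", write_ascii_grid),
      wr(eco$grid, "sim_ecological.asc", write_ascii_grid)
    )
    if (!is.null(esp_res$dpc)) {
      p <- file.path(outdir, "dpc_table.csv")
      utils::write.csv(esp_res$dpc, p, row.names = FALSE); files <- c(files, p)
    }
    if (!is.null(esp_res$gravity)) {
      p <- file.path(outdir, "gravity_table.csv")
      utils::write.csv(esp_res$gravity, p, row.names = FALSE); files <- c(files, p)
    }
    if (length(esp_res$corridors)) {
      p <- file.path(outdir, "corridors.geojson")
      write_corridors_geojson(esp_res$corridors,
                              esp_res$gravity[attr(esp_res$corridors, "selected"), ],
                              base, p)
      files <- c(files, p)
    }
    p <- file.path(outdir, "scenario_comparison.csv")
    utils::write.csv(comparison, p, row.names = FALSE); files <- c(files, p)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  list(system = system, esp_result = esp_res, natural = nat, ecological = eco,
       comparison = comparison, manifest = manifest)
}
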