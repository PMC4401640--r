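# End-to-end pipeline: simulate -> (render/extract) -> flow -> polarity ->
# profile -> regression, with a YAML config and a machine-readable report.

#' Write analysis tables to CSV
#'
#' Helpers writing the package's standard flat files: the cells table
#' (positions, polarity, assignment, angle columns when present), the
#' per-segment flow table (`segment_id`, `Q`, `v`, `tau`, `dir_x`, `dir_y`,
#' `perfused`), and marker event tables.
#'
#' @param x object to write.
#' @param path output path.
#' @param net network (for mean flow directions).
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @param flow a flow solution from [wall_shear()].
#' @export
write_flow_csv <- function(flow, path, net = NULL) {
  fs <- flow$segments
  if (!is.null(flow$flow_dir)) {
    dirs <- t(vapply(flow$flow_dir, function(d) {
      if (all(is.na(d))) c(NA_real_, NA_real_) else colMeans(d, na.rm = TRUE)
    }, numeric(2)))
    fs$dir_x <- dirs[, 1]; fs$dir_y <- dirs[, 2]
  }
  write.csv(fs, path, row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1L,
    outdir = ".",
    generator = list(),          # overrides for gen_config()
    boundary = list(inlet_pressure = 60, outlet_pressure = 0,
                    viscosity = 3.5e-3),
    analysis = list(bin_width = 100, low_q = 0.25, coloc_dist = 10,
                    adjacency_dist = 20, n_perm = 1000,
                    lumen_cutoff = 0.5, max_assign_dist = 15),
    render = list(enabled = FALSE, use_masks = FALSE),
    input = list(network = NULL, cells = NULL, events = NULL)
  )
}

validate_run_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in c("generator", "boundary", "analysis", "render", "input")) {
    if (!is.null(config[[sec]]) && !is.list(config[[sec]])) {
      stop_config("config section '", sec, "' must be a mapping")
    }
  }
  gen_known <- names(formals(gen_config))
  bad <- setdiff(names(config$generator), gen_known)
  if (length(bad)) stop_config("unknown generator key(s): ", paste(bad, collapse = ", "))
  for (sec in c("boundary", "analysis", "render", "input")) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad)) {
      stop_config("unknown ", sec, " key(s): ", paste(bad, collapse = ", "))
    }
  }
  cfg <- modifyList(def, config)
  cfg
}

#' Run the whole analysis pipeline
#'
#' Orchestrates simulate -> (optional render + extract) -> flow -> polarity ->
#' profile -> regression on a synthetic retina (or on user-supplied network /
#' cells / events files), writes every artifact plus a JSON run report to
#' `outdir`, and returns the report. With `render$use_masks = TRUE` the
#' network used for analysis is re-extracted from the rendered masks instead
#' of taken from the generator, exercising the full image path.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Recognised sections: `seed`, `outdir`, `generator` (overrides for
#'   [gen_config()]), `boundary`, `analysis`, `render`, `input`. Unknown
#'   keys are rejected.
#' @param seed optional override of the config seed.
#' @param outdir optional override of the output directory.
#' @param quiet suppress progress messages.
#' @return The run report (list), invisibly. Headline metrics live under
#'   `$metrics`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  report <- list(config = config, tool_version = as.character(utils::packageVersion("polarflow")),
                 stages = list(), metrics = list())
  paths <- list()

  # --- simulate -----------------------------------------------------------
  t0 <- tic()
  gen_args <- config$generator
  gen_args$seed <- gen_args$seed %||% config$seed
  cfg <- do.call(gen_config, gen_args)
  if (!is.null(config$input$network)) {
    say("simulate", "skipped: network supplied at ", config$input$network)
    net <- read_network(config$input$network)
    truth <- NULL
    pre_flow <- NULL
    events <- if (!is.null(config$input$events)) read.csv(config$input$events) else
      data.frame(x = numeric(0), y = numeric(0))
    cells <- if (!is.null(config$input$cells)) read.csv(config$input$cells) else NULL
  } else {
    say("simulate", "generating synthetic retina (seed ", cfg$seed, ")")
    net0 <- generate_network(cfg)
    bc <- do.call(boundary_conditions,
                  c(list(inlets = net0$meta$inlets, outlets = net0$meta$outlets),
                    config$boundary))
    pre_flow <- solve_haemodynamics(net0, bc, config$analysis$lumen_cutoff)
    planted <- plant_regression_and_apoptosis(net0, cfg)
    net <- planted$network
    truth <- planted$truth
    events <- planted$events
    post_flow <- solve_haemodynamics(net, bc, config$analysis$lumen_cutoff)
    gen <- generate_cells(net, cfg, post_flow)
    cells <- gen$cells
    truth$polarity <- gen$truth
    paths$network <- file.path(config$outdir, "network.json")
    write_network(net, paths$network)
    paths$cells <- file.path(config$outdir, "cells.csv")
    write_cells_csv(cells, paths$cells)
    paths$events <- file.path(config$outdir, "events.csv")
    write.csv(events, paths$events, row.names = FALSE)
    paths$truth <- file.path(config$outdir, "truth.json")
    jsonlite::write_json(list(
      regression = truth$regression, apoptosis = truth$apoptosis,
      coloc_rate_planted = truth$coloc_rate_planted,
      n_detectable = truth$n_detectable),
      paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  t_all$simulate <- tic() - t0

  # --- render + extract (optional image path) -----------------------------
  t0 <- tic()
  analysis_net <- net
  if (isTRUE(config$render$enabled)) {
    say("render", "rasterizing channels at ", cfg$pixel_size, " um/px")
    stack <- render_masks(net, cells, cfg, events)
    paths$image <- file.path(config$outdir, "stack.tif")
    write_image_stack(stack, paths$image)
    if (isTRUE(config$render$use_masks)) {
      say("extract", "re-extracting network from rendered masks")
      sk <- skeletonize(stack$channels$matrix)
      ex <- build_graph(sk$skeleton, sk$distance, stack$pixel_size, stack$origin)
      analysis_net <- annotate_segments(ex, stack)
      # carry flow boundaries over: nearest extracted node to each generated
      # inlet/outlet position
      if (!is.null(net$meta$inlets)) {
        exy <- as.matrix(analysis_net$nodes[, c("x", "y")])
        near <- function(ids) {
          pts <- as.matrix(net$nodes[match(ids, net$nodes$id), c("x", "y")])
          analysis_net$nodes$id[nn_lookup(exy, pts)$index]
        }
        analysis_net$meta$inlets <- near(net$meta$inlets)
        analysis_net$meta$outlets <- near(net$meta$outlets)
      }
      paths$extracted <- file.path(config$outdir, "network_extracted.json")
      write_network(analysis_net, paths$extracted)
    }
  }
  t_all$extract <- tic() - t0

  # --- flow ---------------------------------------------------------------
  t0 <- tic()
  say("flow", "solving Poiseuille network flow")
  bc2 <- if (!is.null(analysis_net$meta$inlets)) {
    do.call(boundary_conditions,
            c(list(inlets = analysis_net$meta$inlets,
                   outlets = analysis_net$meta$outlets), config$boundary))
  } else {
    do.call(default_bc, c(list(net = analysis_net), config$boundary))
  }
  flow <- solve_haemodynamics(analysis_net, bc2, config$analysis$lumen_cutoff)
  paths$flow <- file.path(config$outdir, "flow.csv")
  write_flow_csv(flow, paths$flow)
  t_all$flow <- tic() - t0

  # --- polarity -----------------------------------------------------------
  t0 <- tic()
  say("polarity", "computing angle-to-flow statistics for ", nrow(cells), " cells")
  cells <- assign_to_segments(cells, analysis_net, config$analysis$max_assign_dist)
  cells <- angle_and_scalar(cells, analysis_net, flow)
  pstats <- region_stats(cells)
  sreg <- shear_regressions(cells, flow)
  paths$cells_aug <- file.path(config$outdir, "cells_annotated.csv")
  write_cells_csv(cells, paths$cells_aug)
  t_all$polarity <- tic() - t0

  # --- regression detection (needed by profile + misalignment) ------------
  t0 <- tic()
  counts_by_seg <- table(cells$segment_id)
  profiles <- detect_profiles(analysis_net, cell_counts = counts_by_seg,
                              continuity_threshold = 0.95,
                              disconnect_threshold = config$analysis$lumen_cutoff)
  coloc <- colocalize_apoptosis(profiles, analysis_net, events,
                                config$analysis$coloc_dist)
  rcounts <- regression_counts(profiles, analysis_net)
  assoc <- if (!is.null(pre_flow) && nrow(profiles) > 0) {
    low_flow_association(net, pre_flow, profiles,
                         low_q = config$analysis$low_q,
                         n_perm = config$analysis$n_perm, seed = config$seed)
  } else NULL
  mis <- if (nrow(profiles) > 0) {
    misalignment_near_regression(cells, analysis_net, flow, profiles,
                                 adjacency_dist = config$analysis$adjacency_dist,
                                 low_q = config$analysis$low_q,
                                 n_perm = config$analysis$n_perm,
                                 seed = config$seed)
  } else NULL
  paths$profiles <- file.path(config$outdir, "regression_profiles.csv")
  write.csv(coloc$profiles, paths$profiles, row.names = FALSE)
  t_all$regression <- tic() - t0

  # --- radial profile -----------------------------------------------------
  t0 <- tic()
  say("profile", "radial profiling at ", config$analysis$bin_width, " um bins")
  prof <- radial_profile(analysis_net, cells, flow, profiles,
                         optic_center = cfg$optic_center,
                         bin_width = config$analysis$bin_width)
  mdens <- marker_density(transform(events, marker = "caspase"),
                          analysis_net, cells = cells)
  paths$radial <- file.path(config$outdir, "radial_profile.csv")
  write.csv(as.data.frame(prof), paths$radial, row.names = FALSE)
  t_all$profile <- tic() - t0

  report$stages <- lapply(names(t_all), function(nm) {
    list(stage = nm, seconds = unname(t_all[[nm]]))
  })
  report$paths <- paths
  report$metrics <- list(
    n_cells = nrow(cells),
    n_segments = nrow(analysis_net$segments),
    against_flow_by_region = setNames(
      as.list(pstats$by_region$frac_against), pstats$by_region$region),
    scalar_product_gradients = sreg[sreg$region == "all", c("stratum", "gradient", "R", "n")],
    n_regression_profiles = coloc$n_profiles,
    colocalization_percentage = coloc$percentage,
    complement_percentage = coloc$complement_percentage,
    regression_per_100um2 = rcounts$per_100um2,
    apoptosis_events = nrow(events),
    low_flow_association = if (!is.null(assoc)) {
      list(odds_ratio = assoc$odds_ratio, direction = assoc$direction,
           p_value = assoc$p_value)
    } else NULL,
    misalignment = if (!is.null(mis)) {
      list(shear_magnitude_p = mis$shear$magnitude$p_value,
           adjacency_magnitude_p = mis$regression_adjacency$magnitude$p_value)
    } else NULL,
    radial_profile_summary = list(
      bins = nrow(prof),
      central_cell_density = prof$cell_density[1],
      peripheral_cell_density = prof$cell_density[max(1, nrow(prof) - 1)],
      central_mean_tau = prof$mean_tau[1]),
    marker_density = mdens
  )
  paths$report <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  report$paths <- paths
  say("done", "report written to ", paths$report)
  invisible(report)
}
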