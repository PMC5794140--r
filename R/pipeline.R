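#' Pipeline configuration
#'
#' One structured config drives the whole pipeline. Exactly one of the
#' `synthetic` / `real` blocks must be active: `synthetic` holds
#' [landscape_layout()] fields plus `noise_sd` and transect-sampling
#' settings; `real` holds file paths (season-band rasters, DEM, overlay
#' and point GeoJSON, optional serialized tree). The `classifier`,
#' `benefits` and `accuracy` blocks carry the tunables of those stages;
#' all have documented defaults. `default_pipeline_config()` returns the
#' synthetic default; configs load from YAML with
#' `read_pipeline_config()`.
#'
#' @param seed integer seed for every random stage.
#' @return a validated config list (class `sep_config`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  validate_pipeline_config(list(
    seed = as.integer(seed),
    synthetic = list(
      nrow = 200, ncol = 200, pixel = 30, n_villages = 6,
      noise_sd = 0.01,
      fractions = list(field = 0.50, shrubland = 0.20, depression = 0.06,
                       homestead = 0.03, water = 0.02, forest = 0.01,
                       urban = 0.01),
      n_transects = 27, length_m = 3000, spacing_m = 100, gps_noise_m = 5,
      calibration_fraction = 0.5
    ),
    classifier = list(m_threshold = 1.0,
                      class_order = c("water", "forest", "shrubland",
                                      "field", "bare_soil"),
                      use_overlays = TRUE),
    benefits = list(n_zones = 5, w_near = 1.2, w_far = 0.8,
                    zone_width_m = 500,
                    breakpoints = c(0.02, 0.10, 0.25, 0.40),
                    area_weights = c(0.8, 1.0, 1.2, 1.1, 0.9)),
    accuracy = list(buffer_m = 15)
  ))
}

#' @rdname default_pipeline_config
#' @param path YAML config path.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname default_pipeline_config
#' @param config a raw config list.
#' @export
validate_pipeline_config <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$real)
  if (has_syn == has_real) {
    stop("config must activate exactly one of the 'synthetic' and 'real' ",
         "input blocks")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (has_real) {
    paths <- c(unlist(config$real$bands), config$real$dem,
               config$real$overlays, config$real$points,
               config$real$villages, config$real$tree,
               config$real$patch_map)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("referenced input file(s) do not exist: ",
           paste(missing, collapse = ", "))
    }
  }
  for (blk in c("classifier", "benefits", "accuracy")) {
    if (is.null(config[[blk]])) config[[blk]] <- list()
  }
  defaults <- list(
    classifier = list(m_threshold = 1.0,
                      class_order = c("water", "forest", "shrubland",
                                      "field", "bare_soil"),
                      use_overlays = TRUE),
    benefits = list(n_zones = 5, w_near = 1.2, w_far = 0.8,
                    zone_width_m = 500,
                    breakpoints = c(0.02, 0.10, 0.25, 0.40),
                    area_weights = c(0.8, 1.0, 1.2, 1.1, 0.9)),
    accuracy = list(buffer_m = 15)
  )
  for (blk in names(defaults)) {
    for (key in names(defaults[[blk]])) {
      if (is.null(config[[blk]][[key]])) {
        config[[blk]][[key]] <- defaults[[blk]][[key]]
      }
    }
  }
  structure(config, class = c("sep_config", "list"))
}

# run expr, rethrowing any error prefixed with the pipeline stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: input preparation (synthetic generation or file
#' loading), derived-layer computation and calibration signatures, hybrid
#' classification, benefit mapping, and accuracy assessment; writes all
#' artifacts (patch map + legend, five benefit maps, heat map, serialized
#' tree, signature and per-village shrubland tables, accuracy report) plus
#' a provenance record (config hash, seed, package version) to
#' `output_dir`. Any stage error aborts with the stage name prefixed.
#' Deterministic for a fixed config and seed: re-running writes
#' byte-identical artifacts.
#'
#' @param config a pipeline config (see [default_pipeline_config()]).
#' @param output_dir directory for artifacts (created if needed); `NULL`
#'   skips writing and just returns results.
#' @return list with the main objects: `patch_map`, `truth` (synthetic
#'   runs), `signatures`, `tree`, `benefits`, `heat`, `report`, `paths`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  config <- validate_pipeline_config(unclass(config))
  seed <- as.integer(config$seed)

  # --- stage 1: inputs -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    prep <- with_stage("synthetic_landscape", {
      syn <- config$synthetic
      layout <- landscape_layout(
        nrow = syn$nrow %||% 200, ncol = syn$ncol %||% 200,
        pixel = syn$pixel %||% 30, n_villages = syn$n_villages %||% 6,
        fractions = unlist(syn$fractions))
      model <- spectral_signature_model(noise_sd = syn$noise_sd %||% 0.01)
      land <- generate_landscape(model, layout, seed = seed)
      points <- sample_transects(
        land$truth, n_transects = syn$n_transects %||% 27,
        length_m = syn$length_m %||% 3000,
        spacing_m = syn$spacing_m %||% 100,
        gps_noise_m = syn$gps_noise_m %||% 5, seed = seed + 1L,
        calibration_fraction = syn$calibration_fraction %||% 0.5)
      list(scene = land$scene, dem = land$dem, truth = land$truth,
           villages = land$truth$villages, points = points,
           overlays = land$truth$overlays)
    })
  } else {
    prep <- with_stage("load_inputs", {
      bands <- lapply(config$real$bands, read_ascii_grid)
      scene <- sep_scene(bands)
      dem <- if (!is.null(config$real$dem))
        read_ascii_grid(config$real$dem) else NULL
      overlays <- if (!is.null(config$real$overlays))
        read_polygons_geojson(config$real$overlays) else list()
      points <- read_points_geojson(config$real$points)
      villages <- if (!is.null(config$real$villages))
        read_points_geojson(config$real$villages) else NULL
      list(scene = scene, dem = dem, truth = NULL, villages = villages,
           points = points, overlays = overlays)
    })
  }

  # --- stage 2: derived layers and signatures --------------------------------
  idx <- with_stage("spectral_indices", {
    layers <- compute_indices(prep$scene, dem = prep$dem)
    signatures <- class_signatures(layers, prep$points)
    list(layers = layers, signatures = signatures)
  })

  # --- stage 3: hybrid classification ----------------------------------------
  clf <- with_stage("hybrid_classifier", {
    tree <- if (!is.null(config$real$tree)) {
      read_tree(config$real$tree)
    } else {
      derive_tree(idx$signatures,
                  class_order = config$classifier$class_order,
                  m_threshold = config$classifier$m_threshold)
    }
    overlays <- if (isTRUE(config$classifier$use_overlays))
      prep$overlays else list()
    spec <- classifier_spec(tree, overlays,
                            m_threshold = config$classifier$m_threshold)
    list(tree = tree, spec = spec,
         patch_map = classify(idx$layers, spec))
  })

  # --- stage 4: benefit mapping ----------------------------------------------
  ben <- with_stage("benefit_mapping", {
    table <- if (!is.null(config$benefits$score_table)) {
      score_table_from_config(config$benefits$score_table)
    } else default_score_table()
    if (is.null(prep$villages) || !nrow(prep$villages)) {
      stop("village points are required for territory weights")
    }
    terr <- voronoi_territories(prep$villages, clf$patch_map)
    hmask <- rast_like(clf$patch_map,
                       (!is.na(clf$patch_map$values)) *
                         (clf$patch_map$values == .CODE[["homestead"]]))
    dist_w <- homestead_distance_weights(
      hmask, n_zones = config$benefits$n_zones,
      w_near = config$benefits$w_near, w_far = config$benefits$w_far,
      zone_width_m = config$benefits$zone_width_m)
    area_w <- shrubland_area_weights(
      clf$patch_map, terr,
      breakpoints = config$benefits$breakpoints,
      weights = config$benefits$area_weights)
    maps <- benefit_maps(clf$patch_map, table, dist_w, area_w)
    list(table = table, territories = terr, dist_w = dist_w,
         area_w = area_w, maps = maps, heat = heat_map(maps))
  })

  # --- stage 5: accuracy assessment ------------------------------------------
  report <- with_stage("accuracy_assessment", {
    accuracy_report(clf$patch_map, prep$points,
                    buffer_m = config$accuracy$buffer_m)
  })

  paths <- NULL
  if (!is.null(output_dir)) {
    paths <- with_stage("write_artifacts", {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      p <- c()
      p["patch_map"] <- write_ascii_grid(
        clf$patch_map, file.path(output_dir, "patch_map.asc"))
      write_legend(file.path(output_dir, "patch_legend.tsv"))
      for (b in names(ben$maps)) {
        p[paste0("benefit_", b)] <- write_ascii_grid(
          ben$maps[[b]], file.path(output_dir, paste0("benefit_", b, ".asc")))
      }
      p["heat_map"] <- write_ascii_grid(
        ben$heat, file.path(output_dir, "heat_map.asc"))
      p["tree"] <- write_tree(clf$tree, file.path(output_dir, "tree.yaml"))
      p["signatures"] <- write_signatures(
        idx$signatures, file.path(output_dir, "signatures.tsv"))
      vs <- attr(ben$area_w, "village_stats")
      utils::write.table(vs, file.path(output_dir, "village_shrubland.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      p["village_shrubland"] <- file.path(output_dir,
                                          "village_shrubland.tsv")
      write_accuracy_report(report, output_dir)
      p["accuracy_report"] <- file.path(output_dir, "accuracy_report.json")
      jsonlite::write_json(list(
        config_hash = rlang::hash(unclass(config)),
        seed = seed,
        package_version = as.character(utils::packageVersion("sepatch")),
        class_codes = as.list(.CODE)
      ), file.path(output_dir, "provenance.json"), auto_unbox = TRUE,
      pretty = TRUE)
      p["provenance"] <- file.path(output_dir, "provenance.json")
      p
    })
  }

  list(patch_map = clf$patch_map, truth = prep$truth, points = prep$points,
       layers = idx$layers, signatures = idx$signatures, tree = clf$tree,
       territories = ben$territories, dist_w = ben$dist_w,
       area_w = ben$area_w, benefits = ben$maps, heat = ben$heat,
       report = report, paths = paths)
}

# build a benefit_score_table from a config block:
# scores: named list class -> 5 numbers (benefit_labels() order);
# distance_weighted / area_weighted: lists of [class, benefit] pairs
# (defaults from default_score_table() when omitted)
score_table_from_config <- function(blk) {
  def <- default_score_table()
  scores <- def$scores
  if (!is.null(blk$scores)) {
    for (cl in names(blk$scores)) {
      v <- as.numeric(unlist(blk$scores[[cl]]))
      if (length(v) != 5) {
        stop("score row for class '", cl, "' must have 5 values")
      }
      if (!cl %in% rownames(scores)) stop("unknown class in scores: ", cl)
      scores[cl, ] <- v
    }
  }
  pairs_to_mat <- function(pairs, base) {
    if (is.null(pairs)) return(base)
    m <- matrix(FALSE, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
    for (p in pairs) m[p[[1]], p[[2]]] <- TRUE
    m
  }
  benefit_score_table(scores,
                      pairs_to_mat(blk$distance_weighted,
                                   def$distance_weighted),
                      pairs_to_mat(blk$area_weighted, def$area_weighted))
}
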