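#' Point-in-polygon test (ray casting)
#'
#' @param x,y point coordinates (vectorized).
#' @param poly two-column matrix/data frame of polygon vertices.
#' @return logical vector; points exactly on an edge may fall either side.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly[, 1:2])
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

demo_class_codes <- c(forest = 1L, rubber = 2L, tea = 3L,
                      cultivated = 4L, builtup = 5L, water = 6L)

#' Write a ready-to-run synthetic demo dataset
#'
#' Generates a 4-epoch synthetic land-use sequence over an irregular study
#' area: a forest-dominated mosaic in which rubber and tea plantations expand
#' into forest (adjacency-biased conversion) and built-up land grows, so the
#' forest share strictly decreases across epochs. Writes per-epoch ASCII
#' grids, a GeoJSON boundary, and a YAML pipeline configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param n_rows,n_cols raster size (default 120 x 120 cells of 1 km).
#' @return the config file path, invisibly.
#' @export
make_demo_dataset <- function(out_dir, seed = 42, n_rows = 120, n_cols = 120) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- bind_rows(
    class_spec(1, 0.70, clumping = 2000),   # forest
    class_spec(2, 0.15, clumping = 500),    # rubber
    class_spec(3, 0.03, clumping = 200),    # tea
    class_spec(4, 0.07, clumping = 300),    # cultivated
    class_spec(5, 0.03, clumping = 100),    # built-up
    class_spec(6, 0.02, clumping = 100)     # water
  )
  rules <- bind_rows(
    transition_rule(1, 2, rate = 0.004, adjacency_bias = 40),  # forest -> rubber
    transition_rule(1, 3, rate = 0.002, adjacency_bias = 30),  # forest -> tea
    transition_rule(4, 5, rate = 0.010, adjacency_bias = 10)   # cultivated -> built-up
  )
  # irregular hexagon spanning the raster extent (vertices in fractions of
  # the grid span, so any raster size yields a consistent layout)
  boundary_frac <- rbind(
    c(0.04, 0.17), c(0.50, 0.02), c(0.96, 0.12),
    c(0.98, 0.79), c(0.58, 0.98), c(0.07, 0.83)
  )
  boundary <- cbind(boundary_frac[, 1] * n_cols * 1000,
                    boundary_frac[, 2] * n_rows * 1000)

  epochs <- c("1996", "2003", "2010", "2017")
  r <- generate_landuse_raster(n_rows, n_cols, specs, seed = seed,
                               cell_size = 1000)
  rasters <- list(r)
  for (i in 2:4)
    rasters[[i]] <- evolve_landuse(rasters[[i - 1]], rules, seed = seed + i)
  # mask to the study area
  pts <- raster_points(rasters[[1]])
  outside <- !points_in_polygon(pts$x, pts$y, boundary)
  for (i in seq_along(rasters)) {
    v <- rasters[[i]]$values
    v[cbind(pts$row[outside], pts$col[outside])] <- NA_integer_
    rasters[[i]]$values <- v
    rasters[[i]]$legend <- demo_class_codes
    write_ascii_grid(rasters[[i]],
                     file.path(out_dir, paste0("landuse_", epochs[i], ".asc")))
  }
  write_boundary_geojson(boundary, file.path(out_dir, "boundary.geojson"))
  config <- list(
    epochs = purrr::map2(epochs, epochs, function(lab, e)
      list(label = lab, raster = paste0("landuse_", e, ".asc"))),
    boundary = "boundary.geojson",
    cell_km = 10,
    disturbance_weights = list(a = 0.5, b = 0.3, c = 0.2),
    class_names = as.list(demo_class_codes),
    vulnerability = list(forest = 0.10, rubber = 0.28, tea = 0.24,
                         cultivated = 0.14, builtup = 0.05, water = 0.19),
    grade_scheme = list(breaks = c(0.042, 0.049, 0.056, 0.06), upper = 1),
    variogram_family = "exponential",
    weights_scheme = "rook",
    permutations = 199,
    alpha = 0.05,
    krige_grid_km = 5,
    forecast_horizons = c(1, 2),
    seed = seed
  )
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  required <- c("epochs", "boundary", "cell_km", "vulnerability")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    abort(paste0("config missing field(s): ", paste(missing, collapse = ", ")))
  for (e in cfg$epochs) {
    p <- file.path(cfg$base_dir, e$raster)
    if (!file.exists(p)) abort(paste0("raster not found: ", p))
  }
  if (!file.exists(file.path(cfg$base_dir, cfg$boundary)))
    abort("boundary file not found")
  cfg
}

#' Run the full landscape ecological security pipeline
#'
#' Stages, in dependency order: per-epoch landscape metrics (C, S, D, E, F,
#' R), fishnet construction, per-cell ERI and grading, variogram fitting and
#' ordinary kriging of the ERI point set, global and local Moran's I,
#' grade-transition matrices and grade-area proportions, gravity-center
#' migration, and (with >= 4 epochs) per-cell GM(1,1) forecasts. A stage
#' failure aborts with the stage name; warnings are collected into the
#' report. Identical config and seed give an identical report.
#'
#' @param config path to a YAML configuration (as written by
#'   [make_demo_dataset()]) or an equivalent list with `base_dir` set.
#' @return a `run_report` list of tables plus a `provenance` block (config
#'   hash, seed, package version) and collected `warnings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  warnings_log <- character(0)
  note <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  perms <- if (is.null(config$permutations)) 999L else config$permutations
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  family <- if (is.null(config$variogram_family)) "exponential"
            else config$variogram_family
  wscheme <- if (is.null(config$weights_scheme)) "rook" else config$weights_scheme
  scheme <- if (is.null(config$grade_scheme)) grade_scheme()
            else grade_scheme(breaks = as.numeric(config$grade_scheme$breaks),
                              upper = config$grade_scheme$upper)
  codes <- unlist(config$class_names)
  vul <- setNames(as.numeric(unlist(config$vulnerability)[names(codes)]),
                  as.character(codes))
  dw <- if (is.null(config$disturbance_weights)) disturbance_weights()
        else do.call(disturbance_weights, config$disturbance_weights)

  labels <- vapply(config$epochs, `[[`, "", "label")
  rasters <- note("ingest", {
    rs <- lapply(config$epochs, function(e)
      read_ascii_grid(file.path(config$base_dir, e$raster), legend = codes))
    setNames(rs, labels)
  })
  boundary <- note("ingest", {
    b <- read_boundary_geojson(file.path(config$base_dir, config$boundary))
    as.matrix(b)
  })

  metrics <- note("landscape_metrics",
                  metrics_table(rasters, weights = dw, vulnerability = vul))

  net <- note("fishnet", build_fishnet(boundary, cell_km = config$cell_km))

  grids <- note("risk_grid", {
    gs <- lapply(labels, function(ep) {
      loss <- metrics %>% filter(.data$epoch == ep)
      lv <- setNames(loss$R, as.character(loss$class_code))
      g <- compute_eri(net, rasters[[ep]], lv, epoch = ep)
      g$grade <- classify_grades(pmin(g$eri, scheme$upper), scheme)
      g
    })
    setNames(gs, labels)
  })

  grade_props <- note("risk_grid", {
    purrr::map_dfr(grids, function(g)
      grade_area_proportions(g$grade, g$area) %>%
        mutate(epoch = g$epoch[1]), .id = NULL)
  })

  variograms <- note("geostatistics", {
    purrr::map_dfr(labels, function(ep) {
      g <- grids[[ep]]
      emp <- empirical_variogram(tibble(x = g$x, y = g$y, value = g$eri))
      vm <- fit_variogram_model(emp, family = family)
      tidy(vm) %>% mutate(epoch = ep, .before = 1)
    })
  })

  surfaces <- note("geostatistics", {
    s <- attr(net, "cell_size_m")
    kkm <- if (is.null(config$krige_grid_km)) config$cell_km / 2
           else config$krige_grid_km
    step <- kkm * 1000
    org <- attr(net, "origin")
    xs <- seq(org[1] + step / 2, max(net$x), by = step)
    ys <- seq(org[2] + step / 2, max(net$y), by = step)
    targets <- tidyr::expand_grid(x = xs, y = ys)
    inside <- points_in_polygon(targets$x, targets$y, boundary)
    targets <- targets[inside, ]
    lapply(labels, function(ep) {
      g <- grids[[ep]]
      emp <- empirical_variogram(tibble(x = g$x, y = g$y, value = g$eri))
      vm <- fit_variogram_model(emp, family = family)
      ok <- ordinary_kriging(vm, tibble(x = g$x, y = g$y, value = g$eri),
                             targets)
      ok$grade <- classify_grades(pmin(pmax(ok$pred, 0), scheme$upper), scheme)
      ok
    }) %>% setNames(labels)
  })

  # weights built on the realized risk grid (cells without raster data were
  # dropped), which is shared by construction across epochs
  W <- note("spatial_autocorrelation",
            build_weights(grids[[labels[1]]], scheme = wscheme))
  moran_global <- note("spatial_autocorrelation", {
    purrr::map_dfr(labels, function(ep)
      tidy(global_morans_i(grids[[ep]]$eri, W, n_permutations = perms,
                           seed = seed)) %>%
        mutate(epoch = ep, .before = 1))
  })
  lisa <- note("spatial_autocorrelation", {
    lapply(labels, function(ep)
      local_morans_i(grids[[ep]]$eri, W, n_permutations = perms,
                     seed = seed, alpha = alpha)) %>% setNames(labels)
  })

  transitions <- note("risk_grid", {
    prs <- list()
    for (i in seq_len(length(labels) - 1)) {
      nm <- paste0(labels[i], "~", labels[i + 1])
      prs[[nm]] <- grade_transition_matrix(grids[[labels[i]]],
                                           grids[[labels[i + 1]]])
    }
    prs
  })

  gravity <- note("gravity", gravity_track(grids))

  forecasts <- NULL
  fq <- NULL
  if (!is.null(config$forecast_horizons)) {
    forecasts <- note("grey_model",
                      forecast_risk_grid(grids,
                                         horizons = unlist(config$forecast_horizons),
                                         scheme = scheme))
    fq <- note("grey_model", {
      purrr::map_dfr(forecasts, function(g)
        tibble(epoch = g$epoch[1],
               mean_r_squared = mean(g$r_squared, na.rm = TRUE),
               mean_rmse = mean(g$rmse, na.rm = TRUE)))
    })
    gravity <- note("gravity",
                    gravity_track(c(grids, forecasts)))
  }

  defaults <- list(seed = seed, permutations = perms, alpha = alpha,
                   variogram_family = family, weights_scheme = wscheme,
                   grade_breaks = scheme$breaks,
                   disturbance_weights = unname(dw))
  report <- list(
    class_metrics = metrics,
    fishnet = net,
    risk_grids = grids,
    grade_proportions = grade_props,
    variograms = variograms,
    kriged_surfaces = surfaces,
    moran_global = moran_global,
    lisa = lisa,
    transitions = transitions,
    gravity = gravity,
    forecasts = forecasts,
    forecast_quality = fq,
    warnings = warnings_log,
    provenance = list(
      config_hash = rlang::hash(config[setdiff(names(config), "base_dir")]),
      seed = seed,
      parameters = defaults,
      package_version = as.character(utils::packageVersion("landsecr"))
    )
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  epochs:", paste(names(x$risk_grids), collapse = ", "), "\n")
  cat("  fishnet cells:", nrow(x$fishnet), "\n")
  cat("  grade shares (%):\n")
  tab <- x$grade_proportions %>%
    tidyr::pivot_wider(id_cols = "epoch", names_from = "grade",
                       values_from = "pct")
  print(as.data.frame(tab), digits = 3, row.names = FALSE)
  cat("  global Moran's I:",
      paste(sprintf("%s=%.3f", x$moran_global$epoch, x$moran_global$I),
            collapse = ", "), "\n")
  if (!is.null(x$forecasts))
    cat("  forecast horizons:", paste(names(x$forecasts), collapse = ", "), "\n")
  cat("  provenance: seed", x$provenance$seed, "config",
      substr(x$provenance$config_hash, 1, 8), "\n")
  invisible(x)
}
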