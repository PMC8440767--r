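#' Pipeline run configuration
#'
#' Either a synthetic [scenario] or a set of input paths (stack manifest,
#' grove GeoJSON, agricultural mask, optional study-area mask) -- exactly
#' one of the two -- plus the analysis constants, every one of which
#' defaults to the standard procedure: 15 m grove buffer, 30 m rings out
#' to K = 17 (510 m), tau-b, complete 12-month windows, alpha = 0.05.
#'
#' @param scenario a [scenario], or `NULL` when real inputs are given.
#' @param stack_manifest,groves,agri_mask,study_area_mask input paths
#'   (used when `scenario` is `NULL`; `study_area_mask` optional).
#' @param period study period.
#' @param grove_buffer_m,ring_width,K spatial constants.
#' @param tau_convention `"b"` or `"a"`.
#' @param min_years,min_valid_in_window,min_points preprocessing/trend
#'   guards.
#' @param alpha,asym_distances,se_method spill-over inference settings.
#' @param crs_id CRS identifier for file-based inputs.
#' @param seed seed for any randomness (synthetic scenes).
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, stack_manifest = NULL, groves = NULL,
                       agri_mask = NULL, study_area_mask = NULL,
                       period = c("2000-01-01", "2019-12-31"),
                       grove_buffer_m = 15, ring_width = 30, K = 17,
                       tau_convention = c("b", "a"),
                       min_years = 3, min_valid_in_window = 12,
                       min_points = 24,
                       alpha = 0.05, asym_distances = c(450, 480, 510),
                       se_method = c("propagate", "fixed"),
                       crs_id = "EPSG:32637", seed = 1) {
  tau_convention <- match.arg(tau_convention)
  se_method <- match.arg(se_method)
  from_files <- !is.null(stack_manifest) || !is.null(groves) ||
    !is.null(agri_mask)
  if (is.null(scenario) && !from_files)
    stop("supply either a scenario or input paths")
  if (!is.null(scenario) && from_files)
    stop("supply a scenario or input paths, not both")
  if (from_files) {
    for (p in c(stack_manifest, groves, agri_mask, study_area_mask)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  stopifnot(grove_buffer_m >= 0, ring_width > 0, K >= 1, alpha > 0, alpha < 1)
  structure(list(scenario = scenario, stack_manifest = stack_manifest,
                 groves = groves, agri_mask = agri_mask,
                 study_area_mask = study_area_mask,
                 period = as.Date(period),
                 grove_buffer_m = grove_buffer_m, ring_width = ring_width,
                 K = as.integer(K), tau_convention = tau_convention,
                 min_years = min_years,
                 min_valid_in_window = min_valid_in_window,
                 min_points = min_points, alpha = alpha,
                 asym_distances = asym_distances, se_method = se_method,
                 crs_id = crs_id, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' generate/load -> composite -> decycle -> smooth -> per-pixel trend ->
#' classify -> spill-over fit, with all artifacts written to `out_dir`:
#' tau and trend-class maps, the classification map (with code table),
#' ring profile and test table, class distribution and bin-fraction
#' tables, a plain-text report, a machine-readable summary JSON, and a run
#' manifest. Deterministic for a fixed config and seed.
#'
#' @param config a [run_config].
#' @param out_dir output directory.
#' @param quiet suppress stage logging.
#' @return (invisibly) a list with the in-memory results: `trend`,
#'   `classification`, `fit`, `summary`, and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$scenario)) {
    say("stage simulate: seed %d", config$scenario$seed)
    scene <- stage("simulate", simulate_scene(config$scenario))
    stack <- scene$stack; groves <- scene$groves; mask <- scene$mask
  } else {
    say("stage load: %s", config$stack_manifest)
    stack <- stage("load", read_stack(config$stack_manifest,
                                      period = config$period,
                                      crs_id = config$crs_id))
    groves <- stage("load", read_groves(config$groves,
                                        crs_id = config$crs_id))
    agri <- stage("load", read_mask(config$agri_mask, stack$grid))
    study <- if (!is.null(config$study_area_mask))
      stage("load", read_mask(config$study_area_mask, stack$grid))
    else rep(TRUE, n_cells(stack$grid))
    mask <- stage("load", study_mask(stack$grid, agri & study, study))
  }
  grid <- stack$grid

  say("stage preprocess: %d layers -> monthly series", length(stack$dates))
  smoothed <- stage("preprocess",
                    preprocess_stack(stack, period = config$period,
                                     min_years = config$min_years,
                                     min_valid_in_window = config$min_valid_in_window))

  say("stage trend: %d pixels", n_cells(grid))
  trend <- stage("trend", trend_map(smoothed, min_points = config$min_points,
                                    convention = config$tau_convention))

  say("stage classify: %d grove polygons, K = %d", length(groves), config$K)
  gpx <- stage("classify", grove_pixels(groves, grid,
                                        buffer_m = config$grove_buffer_m))
  rings <- stage("classify", distance_rings(gpx, grid, K = config$K,
                                            ring_width = config$ring_width))
  classification <- stage("classify",
                          classify_pixels(gpx, rings, mask, K = config$K,
                                          ring_width = config$ring_width))
  say("stage classify: %d grove px, %d ring px, %d other-agri px",
      sum(classification$label == 1L),
      sum(classification$label > 1L & classification$label < 255L),
      sum(classification$label == 255L))

  say("stage spillover: asymptote at %s m",
      paste(config$asym_distances, collapse = "/"))
  fit <- stage("spillover",
               spillover_fit(trend, classification, alpha = config$alpha,
                             asym_distances = config$asym_distances,
                             se_method = config$se_method))

  paths <- write_artifacts(trend, classification, fit, config, out_dir)
  say("pipeline complete: %s", out_dir)
  invisible(list(trend = trend, classification = classification, fit = fit,
                 summary = report_summary(fit, trend, classification),
                 paths = paths))
}

write_artifacts <- function(trend, classification, fit, config, out_dir) {
  grid <- trend$grid
  p <- list()
  p$tau_map <- file.path(out_dir, "tau.asc")
  write_grid(trend$tau, grid, p$tau_map)
  p$class_map <- file.path(out_dir, "trend_class.asc")
  write_grid(as.integer(trend$class_label), grid, p$class_map, nodata = 0)
  p$classification_map <- file.path(out_dir, "classification.asc")
  write_grid(classification$label, grid, p$classification_map, nodata = -1)
  p$code_table <- file.path(out_dir, "classification_codes.tsv")
  utils::write.table(classification$code_table, p$code_table, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  p$ring_profile <- file.path(out_dir, "ring_profile.tsv")
  prof <- fit$profile
  # one row per configured distance class, grove first; rings with no
  # defined-tau pixels keep their row with n = 0 and an "omitted" marker
  tests <- fit$tests
  gi <- match(0, prof$distance_m)
  grove_row <- data.frame(label = "grove", distance_m = 0,
                          n = if (is.na(gi)) 0L else prof$n[gi],
                          mean_tau = if (is.na(gi)) NA_real_ else prof$mean_tau[gi],
                          se = if (is.na(gi)) NA_real_ else prof$se[gi],
                          delta = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, significant = NA,
                          note = if (is.na(gi)) "omitted" else "")
  ring_rows <- data.frame(label = tests$label, distance_m = tests$distance_m,
                          n = tests$n, mean_tau = tests$mean_tau,
                          se = prof$se[match(tests$distance_m, prof$distance_m)],
                          delta = tests$delta, statistic = tests$statistic,
                          p_value = tests$p_value,
                          significant = tests$significant,
                          note = ifelse(tests$testable, "", "omitted"))
  utils::write.table(format(rbind(grove_row, ring_rows), digits = 10),
                     p$ring_profile, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  summ <- report_summary(fit, trend, classification)
  p$class_distribution <- file.path(out_dir, "class_distribution.tsv")
  utils::write.table(summ$class_distribution, p$class_distribution,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  p$bin_fractions <- file.path(out_dir, "bin_fractions.tsv")
  utils::write.table(format(summ$bin_fractions, digits = 10),
                     p$bin_fractions, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  p$summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ$machine, p$summary_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  p$report <- file.path(out_dir, "report.txt")
  writeLines(summ$text, p$report)

  cfg <- config
  cfg$scenario <- if (!is.null(cfg$scenario)) unclass(cfg$scenario) else NULL
  manifest <- list(package = "greenspill",
                   version = as.character(utils::packageVersion("greenspill")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config = lapply(unclass(cfg), function(v)
                     if (inherits(v, "Date")) format(v) else v))
  p$run_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, p$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  p
}

#' Human- and machine-readable run summary
#'
#' Collates the per-class trend distributions, bin fractions, t-tests,
#' spill-over distance and area roll-up. Every number in the text report
#' is present in the machine-readable list.
#'
#' @param fit a [spillover_fit].
#' @param trend the [trend_map].
#' @param classification the [pixel_classes].
#' @return list with `text` (character vector), `machine` (nested list),
#'   `class_distribution` and `bin_fractions` data frames.
#' @export
report_summary <- function(fit, trend, classification) {
  cls <- list(grove = "grove", neighbour = "ring_1",
              other_agri = "other_agri")
  bins <- c("strong_browning", "moderate_browning",
            "moderate_greening", "strong_greening")
  if (is.null(trend) || is.null(classification)) cls <- list()
  dist_rows <- list(); bin_rows <- list()
  for (nm in names(cls)) {
    cells <- label_cells(classification, cls[[nm]])
    tau <- trend$tau[cells]
    ok <- !is.na(tau)
    lab <- trend$class_label[cells][ok]
    n <- sum(ok)
    dist_rows[[nm]] <- data.frame(
      class = nm, n_pixels = length(cells), n_defined = n,
      mean_tau = if (n) mean(tau[ok]) else NA_real_,
      median_tau = if (n) stats::median(tau[ok]) else NA_real_,
      area_ha = area_ha(classification, cls[[nm]]),
      stringsAsFactors = FALSE)
    fr <- if (n) as.numeric(table(lab)[bins]) / n else rep(NA_real_, 4)
    bin_rows[[nm]] <- data.frame(class = nm, bin = bins, fraction = fr,
                                 stringsAsFactors = FALSE)
  }
  class_distribution <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame()
  bin_fractions <- if (length(bin_rows)) do.call(rbind, bin_rows) else
    data.frame()

  machine <- list(
    greening_pct = lapply(fit$greening, function(g)
      list(strict = 100 * g$strict, inclusive = 100 * g$inclusive)),
    asymptote = fit$asymptote$asymptote,
    asymptote_se = fit$asymptote$se,
    spill_distance_m = fit$spill$spill_distance_m,
    background_distance_m = fit$spill$background_distance_m,
    censored = fit$spill$censored,
    areas_ha = fit$influence,
    ttests = fit$ttests[!vapply(fit$ttests, is.null, logical(1))],
    class_distribution = class_distribution,
    bin_fractions = bin_fractions,
    ring_tests = fit$tests)

  txt <- c(
    "== Grove greening spill-over report ==",
    sprintf("Greening fraction (tau > 0): grove %.2f%%, neighbour %.2f%%, other agricultural %.2f%%",
            100 * fit$greening$grove$strict,
            100 * fit$greening$neighbour$strict,
            100 * fit$greening$other_agri$strict),
    sprintf("Local background (asymptote) tau: %.4f (se %.4f)",
            fit$asymptote$asymptote, fit$asymptote$se),
    sprintf("Spill-over distance: %d m%s; background level reached at %d m",
            as.integer(fit$spill$spill_distance_m),
            if (fit$spill$censored) " (censored)" else "",
            as.integer(fit$spill$background_distance_m)),
    sprintf("Influenced area: groves %.2f ha + immediate %.2f ha + extended %.2f ha = %.2f ha",
            fit$influence$grove_ha, fit$influence$immediate_ha,
            fit$influence$extended_ha, fit$influence$total_ha))
  for (nm in names(fit$ttests)) {
    tt <- fit$ttests[[nm]]
    if (is.null(tt)) next
    txt <- c(txt, sprintf("t-test %s: t = %.3f, p = %.3g", nm, tt$t, tt$p))
  }
  list(text = txt, machine = machine,
       class_distribution = class_distribution,
       bin_fractions = bin_fractions)
}
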