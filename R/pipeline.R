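# End-to-end orchestration.  Every stage reads its inputs from files in
# `outdir` and writes its artifacts back there, so any single stage can be
# re-run from saved intermediates and reproduce the full-run artifact.

#' Pipeline configuration
#'
#' @param outdir output directory (created if missing).
#' @param simulate a [synthetic_city_config()] to generate inputs, or
#'   `NULL` to use pre-existing files in `outdir`
#'   (`blocks.geojson`, `incidents.csv`, `covariates.csv`,
#'   `facilities.csv`).
#' @param n_years number of years spanned by the incident stream; an
#'   explicit parameter, never inferred from the data.  Defaults to
#'   `length(simulate$years)` when simulating.
#' @param associated_dispositions study-relevant disposition codes.
#' @param jenks list: `k` (`"auto"` or integer), `k_range`, `gvf_target`.
#' @param ripley list: `n_radii`, `n_sims`, `alpha`.
#' @param lisa list: `n_permutations`, `alpha`, `snap`.
#' @param conditional list: `threshold`.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(outdir,
                            simulate = synthetic_city_config(),
                            n_years = NULL,
                            associated_dispositions = NULL,
                            jenks = list(k = "auto", k_range = 2:9,
                                         gvf_target = 0.85),
                            ripley = list(n_radii = 64L, n_sims = 999L,
                                          alpha = 0.01),
                            lisa = list(n_permutations = 9999L, alpha = 0.01,
                                        snap = 0),
                            conditional = list(threshold = 0.6),
                            seed = 1L) {
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "synthetic_city_config"))
    if (is.null(n_years)) n_years <- length(simulate$years)
    if (is.null(associated_dispositions))
      associated_dispositions <- simulate$associated_dispositions
  }
  if (is.null(n_years) || n_years <= 0)
    stop("n_years must be supplied and positive")
  if (is.null(associated_dispositions) ||
      length(associated_dispositions) == 0L)
    stop("associated_dispositions must be non-empty")
  stopifnot(ripley$alpha > 0, ripley$alpha < 1,
            lisa$alpha > 0, lisa$alpha < 1)
  structure(list(outdir = outdir, simulate = simulate, n_years = n_years,
                 associated_dispositions = associated_dispositions,
                 jenks = jenks, ripley = ripley, lisa = lisa,
                 conditional = conditional, seed = as.integer(seed)),
            class = "pipeline_config")
}

path_in <- function(outdir, name) file.path(outdir, name)

read_prepared_blocks <- function(outdir) {
  blocks <- read_blocks_geojson(path_in(outdir, "blocks.geojson"))
  project_blocks(blocks)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  city <- generate_synthetic_city(config$simulate)
  write_blocks_geojson(city$blocks, path_in(config$outdir, "blocks.geojson"))
  write.csv(city$covariates, path_in(config$outdir, "covariates.csv"),
            row.names = FALSE)
  write_incidents_csv(city$incidents, path_in(config$outdir, "incidents.csv"))
  write_facilities_csv(city$facilities,
                       path_in(config$outdir, "facilities.csv"))
  invisible(city)
}

#' @rdname run_pipeline
#' @export
stage_prepare <- function(config) {
  outdir <- config$outdir
  blocks <- read_prepared_blocks(outdir)
  records <- read_incidents_csv(path_in(outdir, "incidents.csv"))
  facilities <- read_facilities_csv(path_in(outdir, "facilities.csv"))
  # project geographic coordinates before containment filtering so that
  # window membership and the point pattern share one planar frame
  crs <- attr(records, "crs")
  if (identical(crs$kind, "wgs84")) {
    ok <- !is.na(records$x)
    xy <- utm_forward(records$x[ok], records$y[ok], blocks$crs$zone,
                      blocks$crs$north)
    records$x[ok] <- xy[, 1L]; records$y[ok] <- xy[, 2L]
    attr(records, "crs") <- blocks$crs
  }
  if (identical(attr(facilities, "crs")$kind, "wgs84")) {
    xy <- utm_forward(facilities$x, facilities$y, blocks$crs$zone,
                      blocks$crs$north)
    facilities$x <- xy[, 1L]; facilities$y <- xy[, 2L]
    attr(facilities, "crs") <- blocks$crs
  }
  flt <- filter_incidents(records, blocks$window,
                          config$associated_dispositions)
  counts <- assign_to_blocks(flt$retained, blocks)
  rates <- compute_rates(counts, blocks, config$n_years)
  fdist <- nearest_facility_distance(blocks, facilities)
  pattern <- project_points(flt$retained, blocks)
  write.csv(rates, path_in(outdir, "rates.csv"), row.names = FALSE)
  write.csv(fdist, path_in(outdir, "facility_distances.csv"),
            row.names = FALSE)
  write.csv(data.frame(x = pattern$x, y = pattern$y),
            path_in(outdir, "pattern.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(n_input = nrow(records)), unclass(flt$tally),
      list(excluded_zero_population = attr(rates, "excluded_blocks"))),
    path_in(outdir, "exclusions.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(tally = flt$tally, rates = rates, fdist = fdist,
                 pattern = pattern, n_input = nrow(records)))
}

#' @rdname run_pipeline
#' @export
stage_jenks <- function(config) {
  rates <- read.csv(path_in(config$outdir, "rates.csv"),
                    stringsAsFactors = FALSE)
  k <- config$jenks$k
  if (identical(k, "auto"))
    k <- select_k(rates$rate, k_range = config$jenks$k_range,
                  gvf_target = config$jenks$gvf_target)
  br <- jenks_breaks(rates$rate, k)
  write.csv(data.frame(block_id = rates$block_id, rate = rates$rate,
                       class = br$labels),
            path_in(config$outdir, "jenks_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(k = br$k, breaks = br$breaks, gvf = br$gvf),
                       path_in(config$outdir, "breaks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(br)
}

#' @rdname run_pipeline
#' @export
stage_ripley <- function(config) {
  blocks <- read_prepared_blocks(config$outdir)
  pts <- read.csv(path_in(config$outdir, "pattern.csv"))
  pattern <- point_pattern(pts$x, pts$y, blocks$window, crs = blocks$crs)
  radii <- default_radii(pattern$window, n = config$ripley$n_radii)
  kr <- csr_envelope(pattern, radii, n_sims = config$ripley$n_sims,
                     alpha = config$ripley$alpha,
                     seed = derive_seed(config$seed, "ripley"))
  write.csv(as.data.frame(kr), path_in(config$outdir, "kresult.csv"),
            row.names = FALSE)
  invisible(kr)
}

#' @rdname run_pipeline
#' @export
stage_lisa <- function(config) {
  blocks <- read_prepared_blocks(config$outdir)
  rates <- read.csv(path_in(config$outdir, "rates.csv"),
                    stringsAsFactors = FALSE)
  # restrict to analyzed blocks (those with rates) before building weights
  keep <- blocks$df$block_id %in% rates$block_id
  sub <- block_set(blocks$df[keep, , drop = FALSE],
                   blocks$geoms[blocks$df$block_id[keep]],
                   window = blocks$window, crs = blocks$crs)
  W <- queen_weights(sub, snap = config$lisa$snap)
  values <- stats::setNames(rates$rate, rates$block_id)
  res <- lisa_cluster(values, W,
                      n_permutations = config$lisa$n_permutations,
                      alpha = config$lisa$alpha,
                      seed = derive_seed(config$seed, "lisa"))
  write.csv(as.data.frame(res), path_in(config$outdir, "lisa.csv"),
            row.names = FALSE)
  write_weights(W, path_in(config$outdir, "weights.txt"))
  write_blocks_geojson(sub, path_in(config$outdir, "lisa_categories.geojson"),
                       covariates = data.frame(block_id = res$id,
                                               category = res$category,
                                               stringsAsFactors = FALSE))
  invisible(res)
}

#' @rdname run_pipeline
#' @export
stage_condmap <- function(config) {
  outdir <- config$outdir
  lisa <- read.csv(path_in(outdir, "lisa.csv"), stringsAsFactors = FALSE)
  covariates <- read.csv(path_in(outdir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  fdist <- read.csv(path_in(outdir, "facility_distances.csv"),
                    stringsAsFactors = FALSE)
  categories <- stats::setNames(lisa$category, lisa$id)
  cov_vars <- c("pct_male", "pct_poverty", "pct_bachelor", "income_percap",
                "crime_rate")
  cov <- covariates[match(names(categories), covariates$block_id), ]
  levels <- lapply(cov_vars, function(v)
    stats::setNames(median_split(cov[[v]]), names(categories)))
  names(levels) <- cov_vars
  pairs <- utils::combn(cov_vars, 2L, simplify = FALSE)
  tables <- lapply(pairs, function(pr)
    conditional_cluster_table(categories, levels[[pr[1L]]], levels[[pr[2L]]],
                              var_names = pr))
  for (tb in tables) {
    write.csv(tb$counts,
              path_in(outdir, sprintf("cond_%s_%s.csv", tb$pair[1L],
                                      tb$pair[2L])), row.names = FALSE)
  }
  retained <- screen_pairs(tables, threshold = config$conditional$threshold)
  profile <- spot_profile(categories, covariates)
  fcond <- facility_conditional(categories, fdist)
  write.csv(profile, path_in(outdir, "spot_profile.csv"), row.names = FALSE)
  write.csv(fcond, path_in(outdir, "facility_conditional.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(threshold = config$conditional$threshold,
         retained = lapply(retained, function(tb)
           list(pair = tb$pair,
                hot_fractions = lapply(tb$hot_fractions, as.list)))),
    path_in(outdir, "retained_pairs.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(tables = tables, retained = retained, profile = profile,
                 facility = fcond))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when configured), prepare, jenks, ripley, lisa and
#' condmap in order; every stage reads from and writes to
#' `config$outdir`, and a machine-readable run report is written to
#' `report.json`.  Any stage failure aborts with an error naming the
#' stage.  The report contains no timings or timestamps, so identical
#' configurations and seeds give byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return The run report (a list), invisibly classed `pipeline_report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, fn) {
    say("stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(config),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    say(sprintf("stage %s done (%.1fs)", name,
                proc.time()[["elapsed"]] - t0))
    out
  }
  if (!is.null(config$simulate)) run_stage("simulate", stage_simulate)
  prep <- run_stage("prepare", stage_prepare)
  br <- run_stage("jenks", stage_jenks)
  kr <- run_stage("ripley", stage_ripley)
  lr <- run_stage("lisa", stage_lisa)
  cm <- run_stage("condmap", stage_condmap)
  counts <- table(factor(lr$category, levels = LISA_LEVELS))
  report <- list(
    n_input_records = prep$n_input,
    exclusion_tally = unclass(prep$tally),
    n_blocks_analyzed = nrow(prep$rates),
    jenks = list(k = br$k, gvf = br$gvf, breaks = br$breaks),
    ripley = list(n_sims = attr(kr, "n_sims"), alpha = attr(kr, "alpha"),
                  n_radii = nrow(kr),
                  n_clustered = sum(kr$verdict == "clustered"),
                  global_verdict = if (all(kr$verdict == "clustered"))
                    "clustered" else if (all(kr$verdict == "random"))
                    "random" else if (all(kr$verdict == "dispersed"))
                    "dispersed" else "mixed"),
    lisa = list(n_permutations = attr(lr, "n_permutations"),
                alpha = attr(lr, "alpha"),
                counts = as.list(counts)),
    conditional = list(threshold = config$conditional$threshold,
                       retained_pairs = vapply(cm$retained, function(tb)
                         paste(tb$pair, collapse = "|"), character(1))),
    facility_conditional = cm$facility,
    seeds = list(master = config$seed,
                 ripley = derive_seed(config$seed, "ripley"),
                 lisa = derive_seed(config$seed, "lisa")),
    package_version = as.character(utils::packageVersion("odhotspot")))
  jsonlite::write_json(report, path_in(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(report, class = "pipeline_report"))
}
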