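#' Default pipeline run configuration
#'
#' A complete, serializable configuration exercising every stage on
#' synthetic data. Every default parameter actually used is echoed into the
#' run report, so a run is reproducible from its config and seed alone.
#'
#' @param seed integer seed driving every stage.
#' @return Nested list (a `RunConfig`).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      coloc = list(n_cells = 60L, true_positive_fraction = 0.3,
                   pattern = "membrane", pixel_size_um = 0.5),
      timelapse = list(n_cells = 100L, mean_speed_um_h = 39,
                       sd_speed = 10, interval_min = 30, n_frames = 5L),
      explant = list(n_litters = 4L, slices_per_litter = 2L,
                     cells_per_slice = 15L),
      counts = list(n_cells = 60L, n_genes = 6000L,
                    planted = list(low_features = 4L, high_features = 3L,
                                   high_mito = 3L))),
    coloc = list(threshold = 0.6, r_in = 2L, r_out = 2L, method = "otsu"),
    migrate = list(implant_center_um = c(0, 0), implant_radius_um = 500),
    stats = list(alpha = 0.05, outcomes = c("lateral", "radial")),
    qc = list(min_features = 200L, max_features = 5000L, max_mito = 0.25,
              mito_prefix = "mt-"))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (simulate, coloc, migrate, stats,
#' qc) from a config (list or path to a JSON file), writes each stage's
#' tables as CSV under `out_dir`, and writes a machine-readable JSON report
#' (`report.json`) with parameters, seeds, warnings and headline numbers.
#' A stage failure aborts the run with an error naming the stage; referenced
#' input paths are checked before any computation.
#'
#' @param config nested list or JSON file path; see [default_run_config()].
#' @param out_dir output directory (created if needed).
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed))
    stop("config must contain a `seed`", call. = FALSE)
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # upfront input validation: any configured "*_path" entry must exist
  flat <- unlist(config)
  for (nm in names(flat)[grepl("_path$", names(flat))])
    if (!file.exists(flat[[nm]]))
      stop("input path not found: ", flat[[nm]], call. = FALSE)

  warnings_log <- character()
  note <- function(w) warnings_log[[length(warnings_log) + 1L]] <<- w
  seed <- as.integer(config$seed)
  report <- list(package_version =
                   as.character(utils::packageVersion("astromigr")),
                 seed = seed, parameters = config, stages = list(),
                 warnings = character())
  run_stage <- function(name, fun) {
    withCallingHandlers(
      tryCatch(fun(), error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  sim <- list()
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim <- run_stage("simulate", function() {
      out <- list()
      if (!is.null(sc$coloc)) {
        tr <- coloc_truth(sc$coloc$n_cells, sc$coloc$true_positive_fraction,
                          sc$coloc$pattern,
                          sc$coloc$pixel_size_um %||% 0.5)
        out$coloc <- make_coloc_image(tr, seed = seed)
        write_image_tsv(out$coloc$mask, file.path(out_dir, "coloc_mask.tsv"))
        write_image_tsv(out$coloc$marker,
                        file.path(out_dir, "coloc_marker.tsv"))
        write.csv(out$coloc$truth, file.path(out_dir, "coloc_truth.csv"),
                  row.names = FALSE)
      }
      if (!is.null(sc$timelapse)) {
        out$timelapse <- do.call(make_timelapse,
                                 c(sc$timelapse, list(seed = seed + 1L)))
        write.csv(out$timelapse$tracks, file.path(out_dir, "tracks.csv"),
                  row.names = FALSE)
      }
      if (!is.null(sc$explant)) {
        des <- do.call(explant_design, sc$explant)
        out$explant <- make_explant_experiment(des, seed = seed + 2L)
        write.csv(out$explant$records, file.path(out_dir, "records.csv"),
                  row.names = FALSE)
        write.csv(out$explant$counts, file.path(out_dir, "counts.csv"),
                  row.names = FALSE)
      }
      if (!is.null(sc$counts)) {
        pl <- unlist(sc$counts$planted)
        out$qc_matrix <- make_count_matrix(
          n_cells = sc$counts$n_cells, n_genes = sc$counts$n_genes,
          planted = pl, seed = seed + 3L)
      }
      out
    })
    report$stages$simulate <- list(seeds = seed + 0:3,
                                   outputs = list.files(out_dir))
  }

  if (!is.null(config$coloc) && !is.null(sim$coloc)) {
    cc <- config$coloc
    res <- run_stage("coloc", function()
      score_coloc(sim$coloc$mask, sim$coloc$marker,
                  pattern = config$simulate$coloc$pattern,
                  threshold = cc$threshold %||% 0.6,
                  nuclei = sim$coloc$nuclei,
                  r_in = cc$r_in %||% 2L, r_out = cc$r_out %||% 2L,
                  method = cc$method %||% "otsu"))
    write.csv(res$table, file.path(out_dir, "coloc_scores.csv"),
              row.names = FALSE)
    report$stages$coloc <- list(
      region_kind = res$region_kind, threshold = res$threshold,
      n_cells = res$n_cells, percent_positive = res$percent_positive,
      true_fraction_pct =
        100 * config$simulate$coloc$true_positive_fraction)
  }

  if (!is.null(config$migrate) && !is.null(sim$explant)) {
    mg <- config$migrate
    res <- run_stage("migrate", function() {
      ann <- annotate_migration(sim$explant$records)
      write.csv(ann, file.path(out_dir, "migration_annotated.csv"),
                row.names = FALSE)
      ann
    })
    hl <- list(n_cells = nrow(res),
               mean_net_um = mean(res$net),
               mean_lateral_um = mean(res$lateral),
               mean_radial_um = mean(res$radial))
    if (!is.null(sim$timelapse))
      hl$mean_speed_um_h <-
        mean(track_speeds(sim$timelapse$tracks)$speed_um_h)
    report$stages$migrate <- hl
    sim$annotated <- res
  }

  if (!is.null(config$stats) && !is.null(sim$annotated)) {
    st <- config$stats
    res <- run_stage("stats", function() {
      out <- list()
      for (oc in (st$outcomes %||% c("lateral", "radial"))) {
        fit <- fit_migration_model(sim$annotated, oc)
        gate <- family_gate(fit, alpha = st$alpha %||% 0.05)
        write.csv(gate$families,
                  file.path(out_dir, paste0("gate_", oc, ".csv")),
                  row.names = FALSE)
        out[[oc]] <- gate
      }
      out
    })
    report$stages$stats <- lapply(res, function(g)
      list(families = g$families, alpha = g$alpha,
           n_gates_open = sum(g$families$gate_open)))
  }

  if (!is.null(config$qc) && !is.null(sim$qc_matrix)) {
    qc <- config$qc
    res <- run_stage("qc", function()
      qc_filter(sim$qc_matrix$matrix,
                min_features = qc$min_features %||% 200L,
                max_features = qc$max_features %||% 5000L,
                max_mito = qc$max_mito %||% 0.25,
                mito_prefix = qc$mito_prefix %||% "mt-"))
    write.csv(res$report, file.path(out_dir, "qc_report.csv"),
              row.names = FALSE)
    report$stages$qc <- as.list(res$summary)
  }

  report$warnings <- warnings_log
  write_report(report, file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and verify the machine-readable run report
#'
#' Serializes the report to JSON, checks the minimal schema (package
#' version, seed, parameters, stages, warnings) and verifies the file
#' round-trips losslessly for all numeric fields.
#'
#' @param report report list (at least one completed stage).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  need <- c("package_version", "seed", "parameters", "stages", "warnings")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("report schema violation; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(report$stages) == 0L)
    stop("report must contain at least one completed stage", call. = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  num0 <- unlist(report$stages)
  num0 <- suppressWarnings(as.numeric(num0[!is.na(suppressWarnings(
    as.numeric(num0)))]))
  num1 <- unlist(back$stages)
  num1 <- suppressWarnings(as.numeric(num1[!is.na(suppressWarnings(
    as.numeric(num1)))]))
  if (length(num0) != length(num1) ||
      (length(num0) && max(abs(num0 - num1)) > 0))
    stop("report did not round-trip losslessly", call. = FALSE)
  invisible(path)
}
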