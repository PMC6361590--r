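#' Run the end-to-end cluster-size analysis pipeline
#'
#' Executes simulate (or ingest) -> DBSCAN cluster -> per-cluster metrics
#' -> diameter filter -> size histogram -> self-consistent nucleation fit
#' -> thermodynamic summary, and returns a report bundle. All stages are
#' deterministic under the config seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, CSV intermediates and the
#'   JSON report are written there.
#' @param verbose log stage progress to stderr.
#' @return list (class `nucfit_report`) with `records`, `dist`, `curve`,
#'   `fit`, `params`, `report` (plain-list JSON-ready summary).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_nucfit(sprintf("stage '%s' failed [config %s]: %s", name,
                          format(config_hash(config)), conditionMessage(e)),
                  "nucfit_stage_error")
    })
  }

  maps <- stage("input", {
    if (!is.null(config$input_csv)) {
      log_msg("reading localizations from %s", config$input_csv)
      read_localizations(config$input_csv)
    } else {
      gen_args <- config$generator
      lapply(seq_len(config$n_cells), function(i) {
        cfg <- do.call(generator_config,
                       utils::modifyList(gen_args,
                                         list(seed = config$seed + i)))
        sizes <- sample_cluster_sizes(cfg)
        generate_localization_map(sizes, cfg,
                                  cell_id = sprintf("cell_%03d", i))
      })
    }
  })
  log_msg("%d cell(s)", length(maps))

  records <- stage("cluster", {
    recs <- lapply(maps, function(m)
      cluster_map(m, eps = config$eps, min_pts = config$min_pts))
    out <- do.call(rbind, recs)
    class(out) <- c("cluster_records", "data.frame")
    out
  })
  log_msg("%d clusters detected", nrow(records))

  filtered <- stage("filter",
                    suppressMessages(filter_clusters(records,
                                                     config$min_diameter)))
  log_msg("%d clusters retained (diameter >= %g nm)", nrow(filtered),
          config$min_diameter)

  dist <- stage("histogram", {
    n_vals <- filtered$n[filtered$n >= config$n_start]
    histogram_sizes(n_vals, delta_n = config$delta_n,
                    n_start = config$n_start)
  })

  fit <- stage("fit", self_consistent_fit(dist, rule = config$fit_rule))
  params <- stage("thermo", nucleation_parameters(fit))
  curve <- stage("offset", {
    cv <- empirical_free_energy(dist)
    apply_normalization_offset(cv, fit)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("nucfit")),
    config = unclass(config),
    config_hash = config_hash(config),
    n_cells = length(maps),
    n_clusters_detected = nrow(records),
    n_clusters_retained = nrow(filtered),
    fit = list(a = fit$a, b = fit$b, sem_a = fit$sem_a, sem_b = fit$sem_b,
               intercept = fit$intercept, n_lo = fit$n_lo, n_hi = fit$n_hi,
               iterations = fit$iterations,
               saturation_class = fit$saturation_class),
    thermo = if (params$saturation_class == "super") {
      list(n_c = params$n_c, R_c_nm = params$R_c,
           barrier_kBT = params$barrier,
           sem_Rc = params$sem_Rc, sem_barrier = params$sem_barrier)
    } else {
      list(saturation_class = "sub")
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cluster_table(filtered, file.path(out_dir, "clusters.csv"))
    write_distribution(dist, file.path(out_dir, "distribution.csv"), curve)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  structure(list(maps = maps, records = records, filtered = filtered,
                 dist = dist, curve = curve, fit = fit, params = params,
                 report = report),
            class = "nucfit_report")
}

#' @export
print.nucfit_report <- function(x, ...) {
  cat(sprintf("nucfit pipeline report: %d cells, %d clusters (%d retained)\n",
              x$report$n_cells, x$report$n_clusters_detected,
              x$report$n_clusters_retained))
  print(x$fit)
  invisible(x)
}
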