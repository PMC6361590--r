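#' Read and write localization tables
#'
#' Localization CSVs carry one row per detected single-molecule position
#' with header columns `cell_id`, `frame`, `x_nm`, `y_nm` (coordinates in
#' nm, origin at the field corner). Malformed rows (non-finite
#' coordinates, negative frames) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param field_size field of view in nm stored on the returned maps.
#' @return list of `localization_map`, one per `cell_id`.
#' @export
read_localizations <- function(path, field_size = 25000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "frame", "x_nm", "y_nm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_nucfit(paste("missing column(s):", paste(missing_cols, collapse = ", ")),
                "nucfit_schema_error")
  }
  if (nrow(df) == 0) {
    warning("empty localization file: returning no maps")
    return(list())
  }
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm) |
                 !is.finite(df$frame) | df$frame < 0)
  if (length(bad)) {
    stop_nucfit(sprintf("malformed row(s) at line(s): %s",
                        paste(bad + 1L, collapse = ", ")),  # +1 for header
                "nucfit_row_error")
  }
  lapply(split(df, df$cell_id), function(d) {
    structure(list(points = data.frame(frame = as.integer(d$frame),
                                       x_nm = d$x_nm, y_nm = d$y_nm),
                   field_size = field_size, cell_id = d$cell_id[1],
                   ground_truth = NULL),
              class = "localization_map")
  })
}

#' @rdname read_localizations
#' @param maps a `localization_map` or list of them.
#' @export
write_localizations <- function(maps, path) {
  if (inherits(maps, "localization_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    if (nrow(m$points) == 0) return(NULL)
    cbind(cell_id = m$cell_id, m$points)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(cell_id = character(0), frame = integer(0),
                     x_nm = numeric(0), y_nm = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read ground-truth cluster tables
#'
#' Columns: `cluster_id`, `x_nm`, `y_nm`, `R_nm`, `n_true`.
#' @param gt ground-truth data.frame (e.g. `map$ground_truth`).
#' @param path CSV path.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt[, c("cluster_id", "x_nm", "y_nm", "R_nm", "n_true")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster record table
#'
#' Columns: `cell_id`, `cluster_id`, `x_nm`, `y_nm`, `R_nm`, `diameter_nm`,
#' `count`, `n`.
#' @param records a `cluster_records` table.
#' @param path CSV path.
#' @export
write_cluster_table <- function(records, path) {
  out <- data.frame(cell_id = records$cell_id,
                    cluster_id = records$cluster_id,
                    x_nm = records$x_nm, y_nm = records$y_nm,
                    R_nm = records$R_nm, diameter_nm = records$diameter_nm,
                    count = records$localization_count, n = records$n)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a size-distribution / free-energy table
#'
#' Columns: `bin_center_n`, `count`, `P`, `dG_kBT` (NA on empty bins).
#' @param dist a `size_distribution`.
#' @param curve optional matching `free_energy_curve`.
#' @param path CSV path.
#' @export
write_distribution <- function(dist, path, curve = NULL) {
  dG <- rep(NA_real_, length(dist$bin_centers))
  if (!is.null(curve)) dG[match(curve$n, dist$bin_centers)] <- curve$dG
  utils::write.csv(data.frame(bin_center_n = dist$bin_centers,
                              count = dist$counts, P = dist$P,
                              dG_kBT = dG),
                   path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Round-trippable configuration for the end-to-end pipeline. Every
#' stochastic stage receives an explicit seed.
#'
#' @param generator list of [generator_config()] arguments (or NULL to
#'   ingest files instead).
#' @param n_cells number of synthetic cells to simulate.
#' @param input_csv optional localization CSV to ingest instead of
#'   simulating.
#' @param eps,min_pts,min_diameter clustering parameters (nm, count, nm).
#' @param delta_n,n_start histogram binning.
#' @param fit_rule "n" or "R" variant of the 80% range rule.
#' @param temperature_K,r1_nm thermodynamic conversion inputs.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), n_cells = 1L,
                            input_csv = NULL,
                            eps = 40, min_pts = 10, min_diameter = 50,
                            delta_n = 3e4, n_start = 1.5e4,
                            fit_rule = "n",
                            temperature_K = 310, r1_nm = 1,
                            seed = 1L) {
  structure(list(generator = generator, n_cells = as.integer(n_cells),
                 input_csv = input_csv,
                 eps = eps, min_pts = min_pts, min_diameter = min_diameter,
                 delta_n = delta_n, n_start = n_start, fit_rule = fit_rule,
                 temperature_K = temperature_K, r1_nm = r1_nm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration (JSON)
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

config_hash <- function(config) {
  # cheap stable hash of the serialized config (no digest dependency)
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * seq_along(utf8ToInt(as.character(s)))) %%
    .Machine$integer.max
}
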