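#' Write a functional dataset as curve + metadata CSV files
#'
#' The curve file has one row per observation and one column per grid
#' point, header = grid values; the metadata file carries individual_id,
#' time_index, segment_id and (when present) true_state. Plain CSV is used
#' because PSD-like curve matrices are small; paths ending in `.gz` are
#' compressed transparently.
#'
#' @param dataset an [functional_dataset].
#' @param curves_path,meta_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, curves_path, meta_path) {
  stopifnot(inherits(dataset, "fd_dataset"))
  # 17 significant digits round-trip IEEE doubles exactly
  cur <- as.data.frame(matrix(sprintf("%.17g", dataset$curves),
                              nrow(dataset$curves)))
  names(cur) <- format(dataset$grid, digits = 15, trim = TRUE,
                       scientific = FALSE)
  write.csv(cur, gz_conn(curves_path, "w"), row.names = FALSE,
            quote = FALSE)
  write.csv(dataset$meta, gz_conn(meta_path, "w"), row.names = FALSE)
  invisible(c(curves_path, meta_path))
}

gz_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else path
}

#' Read a functional dataset from curve + metadata CSV files
#'
#' Round-trips [write_dataset] output bit-for-bit for finite doubles. The
#' curve header must parse as a strictly increasing numeric grid; curve and
#' metadata rows must align 1:1; duplicated (individual, time) keys are
#' errors; unsorted rows are accepted, sorted, and flagged with a warning.
#'
#' @param curves_path,meta_path input CSV paths (gzip accepted).
#' @return An [functional_dataset].
#' @export
read_dataset <- function(curves_path, meta_path) {
  cur <- read.csv(curves_path, check.names = FALSE)
  grid <- suppressWarnings(as.numeric(names(cur)))
  if (anyNA(grid))
    stop("curve header does not parse as numeric grid points", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("curve header grid is not strictly increasing", call. = FALSE)
  meta <- read.csv(meta_path)
  if (nrow(meta) != nrow(cur))
    stop("metadata has ", nrow(meta), " rows but curves file has ", nrow(cur),
         call. = FALSE)
  functional_dataset(grid, as.matrix(cur), meta)
}

#' Serialise a fitted model to JSON
#'
#' Stores the initial distribution, transition matrix, centroid curves,
#' grid and emission regulariser, with full double precision.
#'
#' @param model an [fhmm_model].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fhmm_model"))
  obj <- list(n_states = model$n_states, init = model$init,
              trans = model$trans, centroids = model$centroids,
              grid = model$grid, epsilon = model$epsilon)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model serialised by [write_model_json]
#' @param path JSON path.
#' @return An [fhmm_model].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fhmm_model(obj$init, obj$trans, obj$centroids, obj$grid, obj$epsilon)
}

#' Write decoded paths as a tidy CSV
#'
#' @param paths list of `viterbi_path` objects.
#' @param path output CSV path.
#' @param time_indices optional list of per-individual time indices; default
#'   1..K.
#' @return Invisibly, `path`.
#' @export
write_paths_csv <- function(paths, path, time_indices = NULL) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    ti <- if (is.null(time_indices)) seq_along(p$states) else time_indices[[i]]
    data.frame(individual_id = p$individual_id, time_index = ti,
               state = p$states)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export the per-individual feature table for downstream regression
#'
#' One row per individual: occupancy dynamics (dominant state, number of
#' states visited, number of transitions, dominant-state time fraction),
#' a `mixed` flag for individuals below the dominance threshold (they still
#' receive scores for their dominant state), the per-individual mean scores
#' on the leading functional principal components of the dominant state's
#' FPCA model, and optional covariates. Rows are sorted by individual id so
#' the file is byte-identical regardless of input order.
#'
#' @param summaries list of `occupancy_summary` objects.
#' @param fpca_models named list of `fpca_model` objects, one per state
#'   label, each fitted to that state's curves.
#' @param score_tables named list (per state) of data frames from
#'   [individual_mean_scores] for that state's model.
#' @param threshold dominance threshold (default 0.8).
#' @param covariates optional data frame keyed by `individual_id`.
#' @param n_components leading components to export (default 5).
#' @return Data frame (the feature table).
#' @export
export_feature_table <- function(summaries, fpca_models, score_tables,
                                 threshold = 0.8, covariates = NULL,
                                 n_components = 5L) {
  occ <- occupancy_table(summaries)
  grp <- dominant_state_groups(summaries, threshold)
  C <- min(n_components,
           min(vapply(fpca_models, `[[`, 0L, "n_retained")))
  score_cols <- paste0("fpc_score_", seq_len(C))
  ft <- occ[, c("individual_id", "dominant_state", "n_states_visited",
                "n_transitions", "dominant_pct")]
  ft$mixed <- grp$groups[match(ft$individual_id, names(grp$groups))] == "mixed"
  for (cc in score_cols) ft[[cc]] <- NA_real_
  for (i in seq_len(nrow(ft))) {
    st <- as.character(ft$dominant_state[i])
    tab <- score_tables[[st]]
    if (is.null(tab)) next
    j <- match(ft$individual_id[i], tab$individual_id)
    if (!is.na(j)) ft[i, score_cols] <- tab[j, score_cols[score_cols %in% names(tab)]]
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"individual_id" %in% names(covariates))
      stop("covariates need an individual_id column", call. = FALSE)
    ft <- merge(ft, covariates, by = "individual_id", all.x = TRUE,
                sort = FALSE)
  }
  ft <- ft[order(ft$individual_id), , drop = FALSE]
  rownames(ft) <- NULL
  ft
}
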