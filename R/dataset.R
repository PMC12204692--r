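#' Functional dataset container
#'
#' Bundles a curve matrix (one row per functional observation, columns =
#' values on the shared grid) with observation metadata. Each individual's
#' rows, ordered by `time_index`, form one functional time series.
#'
#' @param grid strictly increasing numeric vector, length G.
#' @param curves numeric matrix, `n_obs` x G, finite values.
#' @param meta data frame with columns `individual_id`, `time_index` and
#'   optionally `segment_id`, `true_state`; one row per curve row.
#' @return An object of class `fd_dataset`: a list with elements `grid`,
#'   `curves`, `meta`. Rows are sorted by (individual_id, time_index).
#' @export
#' @examples
#' grid <- default_psd_grid()
#' curves <- matrix(rnorm(2 * length(grid)), 2)
#' meta <- data.frame(individual_id = "a", time_index = 1:2)
#' d <- functional_dataset(grid, curves, meta)
#' d
functional_dataset <- function(grid, curves, meta) {
  validate_grid(grid)
  curves <- as.matrix(curves)
  if (!is.numeric(curves) || anyNA(curves) || any(!is.finite(curves)))
    stop("curve values must be finite numbers", call. = FALSE)
  if (ncol(curves) != length(grid))
    stop("curve matrix has ", ncol(curves), " columns but the grid has ",
         length(grid), " points", call. = FALSE)
  meta <- as.data.frame(meta)
  req <- c("individual_id", "time_index")
  if (!all(req %in% names(meta)))
    stop("metadata must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != nrow(curves))
    stop("metadata has ", nrow(meta), " rows but the curve matrix has ",
         nrow(curves), call. = FALSE)
  if (!"segment_id" %in% names(meta)) meta$segment_id <- NA_integer_
  key <- paste(meta$individual_id, meta$time_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (individual_id, time_index) key: ",
         gsub("\r", ", t=", dup), call. = FALSE)
  }
  ord <- order(meta$individual_id, meta$time_index)
  if (any(ord != seq_along(ord))) {
    warning("observations were not sorted by (individual_id, time_index); sorting",
            call. = FALSE)
  }
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  curves <- curves[ord, , drop = FALSE]
  dimnames(curves) <- NULL
  structure(list(grid = as.numeric(grid), curves = curves, meta = meta),
            class = "fd_dataset")
}

#' @export
print.fd_dataset <- function(x, ...) {
  ids <- unique(x$meta$individual_id)
  cat("<fd_dataset> ", nrow(x$curves), " curves on ", length(x$grid),
      "-point grid [", format(min(x$grid)), ", ", format(max(x$grid)),
      "], ", length(ids), " individual(s)\n", sep = "")
  invisible(x)
}

#' Split a dataset into per-individual series
#'
#' @param dataset an `fd_dataset`.
#' @return Named list, one element per individual, each a list with
#'   `individual_id`, `curves` (K x G matrix ordered by time), `time_index`,
#'   `segment_id`.
#' @export
split_series <- function(dataset) {
  stopifnot(inherits(dataset, "fd_dataset"))
  idx <- split(seq_len(nrow(dataset$meta)), dataset$meta$individual_id)
  # preserve first-appearance order of individuals
  first <- vapply(idx, min, 0L)
  idx <- idx[order(first)]
  lapply(idx, function(i) {
    list(individual_id = dataset$meta$individual_id[i[1]],
         curves = dataset$curves[i, , drop = FALSE],
         time_index = dataset$meta$time_index[i],
         segment_id = dataset$meta$segment_id[i])
  })
}
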