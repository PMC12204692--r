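#' Resting-state recording paradigm specification
#'
#' Describes an alternating eyes-closed / eyes-open block structure sampled
#' at one functional observation (e.g. one PSD) per second, and the buffer
#' trimmed from each end of every eyes-closed block to avoid transition
#' contamination.
#'
#' @param blocks data frame or matrix with columns `condition`
#'   ("eyes_closed" / "eyes_open") and `duration` (seconds), in recording
#'   order.
#' @param buffer seconds trimmed from each end of every eyes-closed block
#'   (>= 0 and less than half the shortest eyes-closed block).
#' @return Object of class `paradigm_spec` with `blocks`, `buffer`,
#'   `total_duration`.
#' @export
paradigm_spec <- function(blocks, buffer = 0) {
  blocks <- as.data.frame(blocks)
  if (!all(c("condition", "duration") %in% names(blocks)))
    stop("blocks need columns `condition` and `duration`", call. = FALSE)
  blocks$duration <- as.numeric(blocks$duration)
  if (any(blocks$duration <= 0)) stop("durations must be positive", call. = FALSE)
  if (!all(blocks$condition %in% c("eyes_closed", "eyes_open")))
    stop("conditions must be 'eyes_closed' or 'eyes_open'", call. = FALSE)
  ec <- blocks$duration[blocks$condition == "eyes_closed"]
  if (length(ec) == 0L) stop("at least one eyes-closed block required",
                             call. = FALSE)
  if (buffer < 0 || buffer >= min(ec) / 2)
    stop("buffer must be >= 0 and less than half the shortest eyes-closed ",
         "block (", min(ec) / 2, " s)", call. = FALSE)
  structure(list(blocks = blocks, buffer = buffer,
                 total_duration = sum(blocks$duration)),
            class = "paradigm_spec")
}

#' The 5-minute alternating resting-state paradigm
#'
#' Five repetitions of 40 s eyes closed followed by 20 s eyes open
#' (300 s total, 200 s eyes closed), with a 2 s leading and trailing buffer
#' trimmed from each eyes-closed block.
#'
#' @param buffer trim in seconds (default 2).
#' @return A [paradigm_spec].
#' @export
#' @examples
#' segment_eyes_closed(resting_paradigm())$totals
resting_paradigm <- function(buffer = 2) {
  blocks <- data.frame(
    condition = rep(c("eyes_closed", "eyes_open"), 5),
    duration = rep(c(40, 20), 5))
  paradigm_spec(blocks, buffer = buffer)
}

#' Retained eyes-closed observation indices under buffer trimming
#'
#' With one observation per second, drops `buffer` seconds from each end of
#' every eyes-closed block and returns the surviving 1-based second indices
#' (into the full recording), grouped by segment.
#'
#' @param spec a [paradigm_spec].
#' @return List: `segments` (list of retained index vectors per eyes-closed
#'   block), `per_segment` (retained count per block), `totals` (named
#'   vector: `retained`, `untrimmed_eyes_closed`, `total_duration`).
#' @export
segment_eyes_closed <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  b <- spec$blocks
  starts <- cumsum(c(0, b$duration[-nrow(b)]))
  segments <- list()
  for (i in seq_len(nrow(b))) {
    if (b$condition[i] != "eyes_closed") next
    lo <- starts[i] + spec$buffer + 1
    hi <- starts[i] + b$duration[i] - spec$buffer
    segments[[length(segments) + 1L]] <- seq.int(lo, hi)
  }
  per_segment <- vapply(segments, length, 0L)
  untrimmed <- sum(b$duration[b$condition == "eyes_closed"])
  list(segments = segments, per_segment = per_segment,
       totals = c(retained = sum(per_segment),
                  untrimmed_eyes_closed = untrimmed,
                  total_duration = spec$total_duration))
}

#' Multitaper taper count from the time-half-bandwidth product
#'
#' The standard Slepian taper count `floor(2 * TW) - 1` for a multitaper
#' spectral estimate with time-half-bandwidth product TW.
#'
#' @param time_half_bandwidth_product TW (>= 1 so at least one taper exists).
#' @return Integer taper count.
#' @export
#' @examples
#' taper_count(2)  # 3
taper_count <- function(time_half_bandwidth_product) {
  tw <- time_half_bandwidth_product
  if (!is.numeric(tw) || length(tw) != 1L || tw < 1)
    stop("time-half-bandwidth product must be a scalar >= 1", call. = FALSE)
  as.integer(floor(2 * tw) - 1)
}
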