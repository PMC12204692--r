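#' Occupancy statistics for one decoded state path
#'
#' From a Viterbi-decoded state sequence, computes the number of distinct
#' states visited, the number of transitions (adjacent unequal pairs), the
#' proportion of time in each state (over all K steps), and the dominant
#' (most occupied) state. A dominance tie is broken toward the lowest label
#' and flagged.
#'
#' @param path a `viterbi_path` or a bare integer vector of labels in 1..N.
#' @param n_states total number of states N.
#' @return Object of class `occupancy_summary`: `individual_id`,
#'   `n_states_visited`, `n_transitions`, `state_proportions` (length N,
#'   sums to 1), `dominant_state`, `dominant_pct`, `dominant_tie`,
#'   `visited_set`, `length`.
#' @export
#' @examples
#' s <- summarise_path(c(1, 1, 2, 2, 1), n_states = 2)
#' s$n_transitions      # 2
#' s$state_proportions  # 0.6 0.4
summarise_path <- function(path, n_states) {
  states <- if (inherits(path, "viterbi_path")) path$states else as.integer(path)
  id <- if (inherits(path, "viterbi_path")) path$individual_id else NA_character_
  K <- length(states)
  if (K < 1L) stop("path must be nonempty", call. = FALSE)
  if (any(states < 1L | states > n_states))
    stop("state label outside 1..", n_states, call. = FALSE)
  counts <- tabulate(states, nbins = n_states)
  props <- counts / K
  dom <- which.max(props)  # ties -> lowest label
  tie <- sum(props == props[dom]) > 1L
  structure(list(individual_id = id,
                 n_states_visited = sum(counts > 0L),
                 n_transitions = sum(states[-1] != states[-K]),
                 state_proportions = props,
                 dominant_state = dom,
                 dominant_pct = props[dom],
                 dominant_tie = tie,
                 visited_set = which(counts > 0L),
                 length = K),
            class = "occupancy_summary")
}

#' Summarise every decoded path
#'
#' @param paths list of `viterbi_path` objects.
#' @param n_states total number of states.
#' @return List of [summarise_path] results, named by individual.
#' @export
summarise_paths <- function(paths, n_states) {
  out <- lapply(paths, summarise_path, n_states = n_states)
  names(out) <- vapply(paths, function(p)
    as.character(p$individual_id %||% NA_character_), "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Occupancy summaries as a data frame
#'
#' @param summaries list of `occupancy_summary` objects.
#' @return Data frame with one row per individual: id, dynamics statistics
#'   and one proportion column per state.
#' @export
occupancy_table <- function(summaries) {
  N <- length(summaries[[1]]$state_proportions)
  props <- do.call(rbind, lapply(summaries, `[[`, "state_proportions"))
  colnames(props) <- paste0("prop_state_", seq_len(N))
  data.frame(
    individual_id = vapply(summaries, function(s) as.character(s$individual_id), ""),
    n_states_visited = vapply(summaries, `[[`, 0L, "n_states_visited"),
    n_transitions = vapply(summaries, `[[`, 0L, "n_transitions"),
    dominant_state = vapply(summaries, `[[`, 0L, "dominant_state"),
    dominant_pct = vapply(summaries, `[[`, 0, "dominant_pct"),
    dominant_tie = vapply(summaries, `[[`, FALSE, "dominant_tie"),
    props,
    row.names = NULL)
}

#' Group individuals by dominant state
#'
#' An individual belongs to its dominant state's group when it spends at
#' least `threshold` of its decoded time there ("80% or more" is inclusive);
#' otherwise it is labelled `"mixed"`.
#'
#' @param summaries list of `occupancy_summary` objects.
#' @param threshold dominance threshold in (0, 1], default 0.8.
#' @return List: `groups` (character vector per individual: state label or
#'   "mixed"), `sizes` (table of group sizes).
#' @export
dominant_state_groups <- function(summaries, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  groups <- vapply(summaries, function(s) {
    if (s$dominant_pct >= threshold) as.character(s$dominant_state) else "mixed"
  }, "")
  names(groups) <- vapply(summaries, function(s) as.character(s$individual_id), "")
  list(groups = groups, sizes = table(groups))
}

#' Count individuals by the combination of states they visit
#'
#' Every individual contributes to exactly one nonempty subset of states --
#' the set it visits -- so the counts partition the individuals (the cells
#' of a Venn diagram over states). For N <= 4 all nonempty subsets are
#' listed, including zero-count ones.
#'
#' @param summaries list of `occupancy_summary` objects.
#' @param n_states total number of states.
#' @return Data frame: `subset` (sorted label string like "1+3"), `count`,
#'   `percent`.
#' @export
visited_combinations <- function(summaries, n_states) {
  key <- vapply(summaries, function(s)
    paste(sort(s$visited_set), collapse = "+"), "")
  tab <- table(key)
  if (n_states <= 4L) {
    all_subsets <- unlist(lapply(seq_len(n_states), function(m)
      apply(utils::combn(n_states, m), 2, paste, collapse = "+")))
    counts <- setNames(integer(length(all_subsets)), all_subsets)
    counts[names(tab)] <- as.integer(tab)
  } else {
    counts <- setNames(as.integer(tab), names(tab))
  }
  data.frame(subset = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(summaries),
             row.names = NULL)
}
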