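#' Default pipeline configuration
#'
#' @param seed master integer seed for all stochastic stages.
#' @param n_states number of latent states for the final model; `NULL`
#'   requires `init_centroids`.
#' @param smooth `"none"` (curves are already prepared, e.g. peak curves),
#'   or `"spectral"` to run the spectral parameteriser and feed its
#'   peak-only curves to the model.
#' @param n_models,subsample_fraction,states_per_model consensus
#'   initialisation settings (see [subsample_initialise]).
#' @param init `"subsample"` (consensus initialisation), `"kmeans"`
#'   (functional k-means on all curves), or `"file"` (use
#'   `init_centroids` verbatim and skip grouping).
#' @param init_centroids optional N x G matrix for `init = "file"`.
#' @param tol,max_iter final Baum-Welch controls.
#' @param dominance_threshold dominant-state grouping threshold.
#' @param fpca_penalty,fpca_threshold within-state FPCA settings.
#' @param n_score_components leading FPC scores exported per individual.
#' @return Named list of settings.
#' @export
pipeline_config <- function(seed, n_states = 4L, smooth = c("none", "spectral"),
                            n_models = 10L, subsample_fraction = 0.8,
                            states_per_model = 8L,
                            init = c("subsample", "kmeans", "file"),
                            init_centroids = NULL,
                            tol = 1e-6, max_iter = 200L,
                            dominance_threshold = 0.8,
                            fpca_penalty = 1e-4, fpca_threshold = 0.70,
                            n_score_components = 5L) {
  list(seed = as.integer(seed), n_states = n_states,
       smooth = match.arg(smooth), n_models = n_models,
       subsample_fraction = subsample_fraction,
       states_per_model = states_per_model, init = match.arg(init),
       init_centroids = init_centroids, tol = tol, max_iter = max_iter,
       dominance_threshold = dominance_threshold,
       fpca_penalty = fpca_penalty, fpca_threshold = fpca_threshold,
       n_score_components = n_score_components)
}

#' Run the full latent-state functional analysis pipeline
#'
#' Executes, in order: optional spectral smoothing; centroid initialisation
#' (consensus over subsampled fits, plain functional k-means, or
#' user-supplied centroids); Baum-Welch estimation; Viterbi decoding;
#' relabelling of states by decreasing allocation; per-individual occupancy
#' statistics, dominant-state grouping and visited-combination counts;
#' within-state FPCA; and the feature-table export. When `out_dir` is given
#' every artifact is written (model JSON, paths/occupancy/combination/
#' feature CSVs, per-state FPCA CSVs) together with a manifest recording
#' package version, every setting, the seed, the objective history and md5
#' hashes of the numeric artifacts, so a run is reconstructible from the
#' manifest alone.
#'
#' @param dataset an [functional_dataset] (or pass `curves_path`/`meta_path`).
#' @param config list from [pipeline_config].
#' @param out_dir optional output directory.
#' @param curves_path,meta_path CSV inputs, read when `dataset` is NULL.
#' @param quiet suppress stage messages.
#' @return List of artifacts: `model`, `fit`, `paths`, `summaries`,
#'   `groups`, `combinations`, `fpca` (per state), `feature_table`,
#'   `manifest`, and `smooth_report` when spectral smoothing ran.
#' @export
run_pipeline <- function(dataset = NULL, config, out_dir = NULL,
                         curves_path = NULL, meta_path = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[statefda] ", ...)
  t0 <- Sys.time()
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  if (is.null(dataset)) {
    if (is.null(curves_path) || is.null(meta_path))
      stop("supply `dataset` or both `curves_path` and `meta_path`",
           call. = FALSE)
    say("reading dataset")
    dataset <- read_dataset(curves_path, meta_path)
  }
  stopifnot(inherits(dataset, "fd_dataset"))
  done("read")

  smooth_report <- NULL
  if (config$smooth == "spectral") {
    say("spectral parameterisation of ", nrow(dataset$curves), " curves")
    batch <- fit_spectral_batch(dataset$curves, dataset$grid)
    smooth_report <- batch$report
    dataset <- functional_dataset(batch$grid, batch$peak_curves, dataset$meta)
    done("smooth")
  }

  N <- config$n_states
  if (config$init == "file") {
    if (is.null(config$init_centroids))
      stop("init = 'file' requires init_centroids", call. = FALSE)
    say("using supplied initial centroids; grouping skipped")
    init_cent <- as.matrix(config$init_centroids)
    N <- nrow(init_cent)
    pool <- NULL; grouping <- NULL
    done("init_file")
  } else if (config$init == "kmeans") {
    say("functional k-means initialisation")
    km <- functional_kmeans(dataset$curves, N, dataset$grid,
                            seed = config$seed)
    init_cent <- km$centroids
    pool <- NULL; grouping <- NULL
    done("init_kmeans")
  } else {
    say("consensus initialisation: ", config$n_models, " subsampled fits x ",
        config$states_per_model, " states")
    pool <- subsample_initialise(dataset, n_models = config$n_models,
                                 subsample_fraction = config$subsample_fraction,
                                 states_per_model = config$states_per_model,
                                 seed = config$seed)
    grouping <- group_centroids(pool, n_groups = N)
    init_cent <- grouping$centroids
    done("init_subsample")
  }

  say("Baum-Welch fit, N = ", N)
  init <- fhmm_model(rep(1 / N, N), matrix(1 / N, N, N), init_cent,
                     dataset$grid)
  fit <- baum_welch(dataset, init, tol = config$tol,
                    max_iter = config$max_iter)
  done("baum_welch")

  say("Viterbi decoding")
  paths <- decode_states(dataset, fit$model)
  rl <- relabel_states(fit$model, paths)
  model <- rl$model
  paths <- rl$paths
  done("viterbi_relabel")

  say("occupancy statistics")
  summaries <- summarise_paths(paths, N)
  groups <- dominant_state_groups(summaries, config$dominance_threshold)
  combos <- visited_combinations(summaries, N)
  done("occupancy")

  say("within-state FPCA")
  basis <- bspline_basis(dataset$grid)
  fpca_models <- list()
  score_tables <- list()
  for (s in seq_len(N)) {
    sub <- subset_by_state(dataset, paths, s)
    if (nrow(sub$curves) < 2L) {
      say("state ", s, " has <2 curves; FPCA skipped")
      next
    }
    m <- fit_fpca(sub$curves, basis, penalty = config$fpca_penalty,
                  state_label = s,
                  retention_threshold = config$fpca_threshold)
    fpca_models[[as.character(s)]] <- m
    score_tables[[as.character(s)]] <-
      individual_mean_scores(m, sub$provenance$individual_id,
                             config$n_score_components)
  }
  done("fpca")

  say("feature table export")
  feature_table <- export_feature_table(summaries, fpca_models, score_tables,
                                        threshold = config$dominance_threshold,
                                        n_components = config$n_score_components)
  done("features")

  manifest <- list(
    package = "statefda",
    version = as.character(utils::packageVersion("statefda")),
    seed = config$seed,
    settings = config[setdiff(names(config), "init_centroids")],
    n_individuals = length(unique(dataset$meta$individual_id)),
    n_observations = nrow(dataset$curves),
    n_states = N,
    allocations = rl$allocations,
    objective_history = fit$history,
    converged = fit$converged,
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  artifacts <- list(model = model, fit = fit, paths = paths,
                    summaries = summaries, groups = groups,
                    combinations = combos, fpca = fpca_models,
                    score_tables = score_tables,
                    feature_table = feature_table,
                    smooth_report = smooth_report,
                    pool = pool, grouping = grouping,
                    manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    write_model_json(model, fp("model.json"))
    write_paths_csv(paths, fp("paths.csv"))
    write.csv(occupancy_table(summaries), fp("occupancy.csv"),
              row.names = FALSE)
    write.csv(combos, fp("state_combinations.csv"), row.names = FALSE)
    write.csv(feature_table, fp("features.csv"), row.names = FALSE)
    for (s in names(fpca_models)) {
      m <- fpca_models[[s]]
      ef <- rbind(mean = m$mean_function, m$eigenfunctions)
      ef_df <- as.data.frame(ef)
      names(ef_df) <- format(m$grid, digits = 15, trim = TRUE)
      write.csv(cbind(fn = c("mean", paste0("phi_", seq_len(nrow(m$eigenfunctions)))),
                      ef_df),
                fp(paste0("fpca_state", s, "_functions.csv")),
                row.names = FALSE)
      write.csv(m$scree, fp(paste0("fpca_state", s, "_variance.csv")),
                row.names = FALSE)
    }
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$artifact_md5 <- as.list(tools::md5sum(files))
    names(manifest$artifact_md5) <- basename(files)
    artifacts$manifest <- manifest
    jsonlite::write_json(manifest, fp("manifest.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  artifacts
}
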