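#' Read and validate an experiment configuration
#'
#' Loads a YAML experiment manifest and validates every field against the
#' known schema; unknown keys are rejected so typos cannot silently change
#' an experiment. Missing keys take the documented defaults.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  defaults <- list(
    seed = 1L,
    classifier = "frnn",          # frnn | knn
    strategy = "probability",     # probability | actual_class | none
    k = 5L,
    window_size = 0L,
    insert_label_mode = "predicted",
    n_subjects = 45L,
    n_per_subject = 150L,
    n_features = 12L,
    client_subject = 1L,
    drift = 0.5,
    folds = 10L,
    run_folds = NULL,             # subset of folds to run (NULL = all)
    cfs = FALSE,
    block = 10L,
    channels = c("T5", "T6", "O1", "OZ", "O2"),
    pairs = list(c("O1", "OZ"), c("OZ", "O2")),
    bands = list(alpha = c(8, 13), beta = c(13, 30)),
    positive = "client",
    output_dir = "incfrnn_runs",
    input = NULL                  # optional descriptor table path (csv/arff)
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  stopifnot(cfg$classifier %in% c("frnn", "knn"),
            cfg$strategy %in% c("probability", "actual_class", "none"),
            cfg$insert_label_mode %in% c("predicted", "actual"))
  for (f in c("k", "window_size", "n_subjects", "n_per_subject",
              "n_features", "client_subject", "folds", "block", "seed")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop("config field '", f, "' must be a non-negative number", call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(cfg, class = "experiment_config")
}
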