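# Run configuration: one YAML file covering every tunable of the pipeline,
# validated against a closed schema (unknown keys are rejected so typos
# cannot silently fall back to defaults).

config_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(
      enabled = TRUE, n_metabolites = 283L, n_group_a = 8L, n_group_b = 7L,
      n_signatures = 5L, separation = 2.0, noise_sigma = 0.1,
      dirichlet_alpha = 0.1, n_sets = 10L, set_size = 15L,
      aligned_fraction = 0.5
    ),
    input = list(abundance = NULL, metadata = NULL, gmt = NULL),
    preprocess = list(impute = "half_min", scale = "row_mean"),
    nmf = list(
      rank_range = c(2L, 8L), n_restarts = 10L, max_iter = 2000L,
      tol = 1e-6, bootstrap_count = 20L, stability_threshold = 0.7
    ),
    clustering = list(metric = "correlation", linkage = "average",
                      n_clusters = "auto"),
    enrichment = list(assign_rule = "argmax_above_uniform", top_n = 25L),
    stats = list(test = "student", append_bh = FALSE)
  )
}

validate_config <- function(cfg) {
  with_name <- function(ok, key, msg) if (!ok) stop(sprintf("configuration error: `%s` %s", key, msg), call. = FALSE)
  rr <- cfg$nmf$rank_range
  with_name(is.numeric(rr) && length(rr) == 2 && all(rr >= 1) && rr[1] <= rr[2],
            "nmf.rank_range", "must be [min, max] with 1 <= min <= max")
  with_name(is.numeric(cfg$nmf$bootstrap_count) && cfg$nmf$bootstrap_count >= 2,
            "nmf.bootstrap_count", "must be >= 2")
  with_name(is.numeric(cfg$nmf$n_restarts) && cfg$nmf$n_restarts >= 1,
            "nmf.n_restarts", "must be >= 1")
  with_name(is.numeric(cfg$nmf$tol) && cfg$nmf$tol > 0, "nmf.tol", "must be > 0")
  with_name(is.numeric(cfg$nmf$stability_threshold) &&
              abs(cfg$nmf$stability_threshold) <= 1,
            "nmf.stability_threshold", "must be in [-1, 1]")
  with_name(cfg$preprocess$impute %in% c("half_min", "drop"),
            "preprocess.impute", "must be 'half_min' or 'drop'")
  with_name(cfg$preprocess$scale %in% c("row_mean", "none"),
            "preprocess.scale", "must be 'row_mean' or 'none'")
  with_name(cfg$clustering$metric %in% c("correlation", "cosine", "euclidean"),
            "clustering.metric", "must be correlation, cosine or euclidean")
  with_name(cfg$clustering$linkage %in% c("average", "complete"),
            "clustering.linkage", "must be 'average' or 'complete'")
  with_name(identical(cfg$clustering$n_clusters, "auto") ||
              (is.numeric(cfg$clustering$n_clusters) && cfg$clustering$n_clusters >= 2),
            "clustering.n_clusters", "must be 'auto' or an integer >= 2")
  with_name(cfg$enrichment$assign_rule %in% c("argmax_above_uniform", "top_n"),
            "enrichment.assign_rule", "must be 'argmax_above_uniform' or 'top_n'")
  with_name(cfg$stats$test %in% c("student", "welch"),
            "stats.test", "must be 'student' or 'welch'")
  with_name(is.numeric(cfg$seed) && cfg$seed >= 0 && cfg$seed < 2^31,
            "seed", "must be a nonnegative 32-bit integer")
  if (!isTRUE(cfg$simulate$enabled) && is.null(cfg$input$abundance)) {
    stop("configuration error: either `simulate.enabled: true` or `input.abundance` is required",
         call. = FALSE)
  }
  cfg
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("configuration error: unknown key `", full, "`", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration error: `", full, "` must be a mapping", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, overlays it on the documented defaults
#' (see `config_defaults`, echoed in the returned object), rejects unknown
#' keys, and validates ranges. An empty or missing-free file yields the full
#' default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list of class `metabosig_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration error: file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- validate_config(merge_config(config_defaults(), user))
  class(cfg) <- "metabosig_config"
  cfg
}
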