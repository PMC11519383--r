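# Configuration and batch pipeline.

.config_ranges <- list(
  preprocess = list(
    mode = c("a_plus_negb", "negb_only", "negb_minus_posa"),
    p_low = c(0, 100), p_high = c(0, 100),
    smooth_sigma = c(0, Inf), zero_floor = c(0, 1)
  ),
  alignment = list(
    r_min = c(0, 0.5), r_max = c(0, 0.5), n_bins = c(2, Inf)
  ),
  kinetics = list(
    fit_variable = c("area", "contraction_complement")
  )
)

#' Pipeline configuration
#'
#' Assembles and validates the full parameter set of the analysis chain.
#' Unknown keys are rejected so that typos never fall back silently to
#' defaults.
#'
#' @param preprocess list overriding `mode`, `p_low`, `p_high`,
#'   `smooth_sigma`, `zero_floor` (see [isolate_collagen()], [enhance()]).
#' @param alignment list overriding `r_min`, `r_max`, `n_bins`
#'   (see [angular_spectrum()]).
#' @param kinetics list overriding `fit_variable`
#'   (see [fit_one_phase_decay()]).
#' @param seed integer seed recorded for provenance of any simulation step.
#' @return a `pipeline_config` list with a `version` string attached.
#' @export
pipeline_config <- function(preprocess = list(), alignment = list(),
                            kinetics = list(), seed = 0L) {
  defaults <- list(
    preprocess = list(mode = "a_plus_negb", p_low = 1, p_high = 99,
                      smooth_sigma = 1, zero_floor = 0.1),
    alignment = list(r_min = 0.05, r_max = 0.45, n_bins = 180L),
    kinetics = list(fit_variable = "area")
  )
  user <- list(preprocess = preprocess, alignment = alignment,
               kinetics = kinetics)
  cfg <- defaults
  for (block in names(defaults)) {
    extra <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(extra)) {
      stop(sprintf("unknown config key(s) in [%s]: %s", block,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    cfg[[block]][names(user[[block]])] <- user[[block]]
    for (key in names(cfg[[block]])) {
      rng <- .config_ranges[[block]][[key]]
      val <- cfg[[block]][[key]]
      if (is.character(rng)) {
        if (!val %in% rng) {
          stop(sprintf("config %s.%s: '%s' not one of %s", block, key, val,
                       paste(rng, collapse = "/")), call. = FALSE)
        }
      } else if (!is.numeric(val) || val < rng[1] || val > rng[2]) {
        stop(sprintf("config %s.%s out of range [%g, %g]", block, key,
                     rng[1], rng[2]), call. = FALSE)
      }
    }
  }
  if (cfg$preprocess$p_low >= cfg$preprocess$p_high) {
    stop("config preprocess: p_low must be < p_high", call. = FALSE)
  }
  if (cfg$alignment$r_min >= cfg$alignment$r_max) {
    stop("config alignment: r_min must be < r_max", call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  cfg$version <- as.character(utils::packageVersion("fibralign"))
  structure(cfg, class = "pipeline_config")
}

#' Stable hash of a pipeline configuration
#'
#' @param config a [pipeline_config()] object.
#' @return character hash; changes whenever any config value changes.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys `preprocess`, `alignment`, `kinetics`, `seed` as in
#' [pipeline_config()]; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), c("preprocess", "alignment", "kinetics",
                                 "seed"))
  if (length(extra)) {
    stop(sprintf("unknown top-level config key(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  pipeline_config(
    preprocess = as.list(raw$preprocess),
    alignment = as.list(raw$alignment),
    kinetics = as.list(raw$kinetics),
    seed = if (is.null(raw$seed)) 0L else raw$seed
  )
}

#' Run the batch image-analysis pipeline over a manifest
#'
#' Analyses every image listed in the manifest, then runs the group
#' statistics the manifest supports: a paired t-test on each metric when
#' exactly two groups are paired within donors, and a Pearson correlation of
#' each metric with months since radiotherapy when that covariate is
#' present. An unreadable or degenerate image is recorded as a row-level
#' error and the pipeline continues; a malformed manifest aborts.
#'
#' @param manifest data.frame (or CSV path) with column `path` and optional
#'   `donor`, `group`, `months_since_rt`, `label`.
#' @param config a [pipeline_config()].
#' @return list with `results` (one row per image: manifest metadata plus
#'   `coefficient`, `dominant_orientation_deg`, `density`, `status`,
#'   `config_hash`), `stats` (data.frame of test summaries, possibly empty),
#'   and `log` (config snapshot, package version, per-image status).
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0 ||
      !"path" %in% names(manifest)) {
    stop("malformed manifest: need a non-empty table with a `path` column",
         call. = FALSE)
  }
  hash <- config_hash(config)

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$path[i]
    res <- if (!file.exists(path)) {
      simpleError(sprintf("[read] file not found: %s", path))
    } else {
      tryCatch(analyze_image(path, config), error = identity)
    }
    if (inherits(res, "error")) {
      data.frame(path = path, coefficient = NA_real_,
                 dominant_orientation_deg = NA_real_, density = NA_real_,
                 status = conditionMessage(res))
    } else {
      data.frame(path = path, coefficient = res$coefficient,
                 dominant_orientation_deg =
                   res$dominant_orientation * 180 / pi,
                 density = res$density, status = "ok")
    }
  })
  results <- do.call(rbind, rows)
  meta_cols <- setdiff(names(manifest), "path")
  for (col in meta_cols) results[[col]] <- manifest[[col]]
  results$config_hash <- hash
  results <- results[, c("path", meta_cols,
                         "coefficient", "dominant_orientation_deg",
                         "density", "status", "config_hash")]

  stats_rows <- list()
  ok <- results$status == "ok"
  if (all(c("donor", "group") %in% names(results))) {
    groups <- unique(results$group[ok])
    if (length(groups) == 2) {
      for (metric in c("coefficient", "density")) {
        wide <- stats::reshape(
          results[ok, c("donor", "group", metric)],
          idvar = "donor", timevar = "group", direction = "wide"
        )
        wide <- wide[stats::complete.cases(wide), , drop = FALSE]
        if (nrow(wide) >= 2) {
          pd <- tryCatch(
            paired_difference(wide[[paste0(metric, ".", groups[1])]],
                              wide[[paste0(metric, ".", groups[2])]]),
            error = identity
          )
          if (!inherits(pd, "error")) {
            stats_rows[[length(stats_rows) + 1]] <- data.frame(
              test = "paired_t", metric = metric,
              comparison = paste(groups, collapse = " vs "),
              statistic = pd$statistic, p_value = pd$p_value, n = pd$n,
              estimate = pd$mean_difference
            )
          }
        }
      }
    }
  }
  if ("months_since_rt" %in% names(results)) {
    for (metric in c("coefficient", "density")) {
      use <- ok & is.finite(results$months_since_rt)
      if (sum(use) >= 3) {
        ct <- tryCatch(
          correlation_with_time(results[[metric]][use],
                                results$months_since_rt[use]),
          error = identity
        )
        if (!inherits(ct, "error")) {
          stats_rows[[length(stats_rows) + 1]] <- data.frame(
            test = "pearson", metric = metric,
            comparison = "months_since_rt",
            statistic = ct$r, p_value = ct$p_value, n = ct$n,
            estimate = ct$r
          )
        }
      }
    }
  }
  stats_tbl <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame(test = character(), metric = character(),
               comparison = character(), statistic = numeric(),
               p_value = numeric(), n = integer(), estimate = numeric())

  list(
    results = results,
    stats = stats_tbl,
    log = list(
      config = unclass(config), config_hash = hash,
      version = as.character(utils::packageVersion("fibralign")),
      n_images = nrow(results), n_errors = sum(!ok),
      status = stats::setNames(results$status, results$path)
    )
  )
}
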