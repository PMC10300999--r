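# End-to-end orchestration: simulate -> preprocess -> features -> labels ->
# train -> evaluate, from one configuration list.

#' Extract per-view feature matrices for a cohort
#'
#' Preprocesses every view of every case (orientation, segmentation,
#' pectoral removal on MLO, ROI delineation, optional z-scoring) and runs the
#' 203-feature extractor on the requested ROI kind.
#'
#' @param cohort a `synthetic_cohort` (or list of `case_record`s in `cases`).
#' @param roi_kind "square", "retroareolar" or "whole".
#' @param normalized use the z-scored ROI track.
#' @param Ng grey levels for quantized families.
#' @param views view tags to process (default all four).
#' @return Named list (by view tag) of matrices, cases x 203, with case ids
#'   as row names.
#' @export
cohort_features <- function(cohort, roi_kind = "square", normalized = TRUE,
                            Ng = 32, views = view_tags()) {
  cases <- cohort$cases
  ids <- vapply(cases, `[[`, "", "case_id")
  reg <- feature_registry()
  out <- lapply(views, function(v) {
    m <- matrix(NA_real_, length(cases), nrow(reg),
                dimnames = list(ids, reg$name))
    for (i in seq_along(cases)) {
      pre <- preprocess_view(cases[[i]]$views[[v]], v, normalize = normalized)
      m[i, ] <- extract_all(pre$rois[[roi_kind]], Ng = Ng)
    }
    m
  })
  stats::setNames(out, views)
}

#' Difficulty labels for one basis from simulated responses
#'
#' Convenience wrapper: summarizes error proportions, splits tertiles and
#' returns the easy/difficult labels (median group dropped, as modelling
#' excludes it).
#'
#' @param responses reader responses.
#' @param truth case truth table (`case_id`, `cancer`).
#' @param basis error basis.
#' @param lesions lesion table (for the location basis).
#' @param radius correct-localization radius in pixels.
#' @return Named factor with levels easy/difficult.
#' @export
difficulty_labels <- function(responses, truth, basis, lesions = NULL,
                              radius = 250) {
  su <- summarize_errors(responses, truth, basis, lesions = lesions,
                         radius = radius)
  lab <- tertile_split(su)
  keep <- lab$tertile != "median"
  stats::setNames(factor(lab$tertile[keep], levels = c("easy", "difficult")),
                  lab$case_id[keep])
}

#' Run the full pipeline from one configuration
#'
#' Executes the enabled stages in order: cohort simulation, reader panel,
#' preprocessing + feature extraction, difficulty labelling, nested-CV
#' training and ROC evaluation, for each requested error basis. When
#' `out_dir` is given, artifacts (cohort PNGs/CSVs, features, labels,
#' predictions, metrics) are written there; a manifest with per-stage wall
#' times and a config hash is always returned.
#'
#' @param config list with elements `synthetic` (a [synthetic_config()]),
#'   and optionally `basis` (default "FP"), `roi_kind` ("square"),
#'   `normalized` (TRUE), `Ng` (32), `grid` (default the reduced grid
#'   `hyper_grid(100, 1, 5, c(16, 203))`), `threshold` (0.5), `n_boot`
#'   (2000), `seed` (the synthetic seed), `out_dir` (NULL).
#' @return Manifest list: `config_hash`, `timings`, and per-basis `results`
#'   (each with `labels`, `predictions`, `auc`, `ci`, `metrics`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config$synthetic, "synthetic_config"))
  basis <- config$basis %||% "FP"
  roi_kind <- config$roi_kind %||% "square"
  normalized <- config$normalized %||% TRUE
  Ng <- config$Ng %||% 32
  grid <- config$grid %||% hyper_grid(n_trees = 100, max_sample_fraction = 1,
                                      max_depth = 5,
                                      n_selected_features = c(16, 203))
  threshold <- config$threshold %||% 0.5
  n_boot <- config$n_boot %||% 2000
  seed <- config$seed %||% config$synthetic$seed
  out_dir <- config$out_dir

  timings <- c()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    r
  }

  cohort <- tick("simulate", generate_cohort(config$synthetic))
  responses <- tick("panel",
                    simulate_reader_panel(cohort$cases, cohort$truth,
                                          config$synthetic))
  if (!is.null(out_dir)) {
    write_cohort(cohort, responses, file.path(out_dir, "cohort"))
  }

  results <- list()
  for (b in basis) {
    labels <- tick(paste0("labels_", b),
                   difficulty_labels(responses, cohort$truth, b,
                                     lesions = cohort$lesions,
                                     radius = config$synthetic$loc_radius))
    views <- if (b == "FP") view_tags() else unique(unlist(
      lapply(cohort$cases[vapply(cohort$cases, `[[`, NA, "cancer")],
             select_views, basis = b)))
    feats <- tick(paste0("features_", b), {
      sub <- cohort
      sub$cases <- cohort$cases[
        vapply(cohort$cases, `[[`, "", "case_id") %in% names(labels)]
      cohort_features(sub, roi_kind = roi_kind, normalized = normalized,
                      Ng = Ng, views = views)
    })
    if (b != "FP") {
      # lesion-side views only: collapse the per-case view pair into CC/MLO
      # slots so all cases share model inputs
      feats <- lesion_side_features(feats, cohort$cases, names(labels), b)
    }
    cv <- tick(paste0("train_", b),
               nested_cv(feats, labels, grid = grid,
                         seed = substream_seed(seed, paste0("cv_", b))))
    scores <- cv$predictions$fused
    y <- cv$predictions$label == "difficult"
    res <- list(
      labels = labels,
      predictions = cv$predictions,
      chosen = cv$chosen,
      auc = auc(scores, y),
      ci = bootstrap_ci(scores, y, n_boot = n_boot,
                        seed = substream_seed(seed, paste0("ci_", b))),
      metrics = operating_metrics(scores, y, threshold)
    )
    results[[b]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(cv$predictions,
                       file.path(out_dir, sprintf("predictions_%s.csv", b)),
                       row.names = FALSE)
    }
  }

  manifest <- list(config_hash = config_hash(config),
                   timings = as.list(timings), results = results)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, timings = manifest$timings,
           auc = lapply(results, `[[`, "auc"),
           ci = lapply(results, function(r) unname(r$ci)),
           metrics = lapply(results, function(r) as.list(r$metrics))),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# For FN/location bases each cancer case contributes its two lesion-side
# views; map them onto generic CC / MLO model slots.
lesion_side_features <- function(feats, cases, ids, basis) {
  cases <- cases[vapply(cases, `[[`, "", "case_id") %in% ids]
  cc <- matrix(NA_real_, length(ids), ncol(feats[[1]]),
               dimnames = list(ids, colnames(feats[[1]])))
  mlo <- cc
  for (cs in cases) {
    vt <- select_views(cs, basis)
    cc[cs$case_id, ] <- feats[[vt[1]]][cs$case_id, ]
    mlo[cs$case_id, ] <- feats[[vt[2]]][cs$case_id, ]
  }
  list(CC = cc, MLO = mlo)
}
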