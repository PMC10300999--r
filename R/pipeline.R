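# Nested cross-validated random-forest classification of easy vs difficult
# cases per view, with embedded feature selection, exhaustive grid search and
# maximum-probability fusion of view models to the case level.

#' Random-forest hyperparameter grid
#'
#' Exhaustively enumerated grid: number of trees, maximum sampled fraction of
#' the training cases per tree, maximum tree depth, and the number of
#' features kept by embedded selection (203 = no selection).
#'
#' @param n_trees,max_sample_fraction,max_depth,n_selected_features candidate
#'   values.
#' @return Data frame with one row per grid cell.
#' @export
hyper_grid <- function(n_trees = c(50, 100, 500, 1000),
                       max_sample_fraction = c(0.10, 0.50, 1.00),
                       max_depth = c(1, 5, 10),
                       n_selected_features = c(8, 16, 32, 64, 203)) {
  expand.grid(n_trees = n_trees, max_sample_fraction = max_sample_fraction,
              max_depth = max_depth,
              n_selected_features = n_selected_features,
              KEEP.OUT.ATTRS = FALSE)
}

#' Case-level nested cross-validation plan
#'
#' Outer layer: leave-one-case-out. Inner layer: label-stratified k-fold
#' cross-validation repeated `repeats` times over the outer-training cases.
#' All views of a case always travel together (folds are assigned at case
#' level).
#'
#' @param labels factor of class labels named by case id.
#' @param inner_k inner folds (default 3).
#' @param repeats inner repeats (default 3).
#' @param seed integer seed.
#' @return A `fold_plan`: list with `case_ids`, `outer` (list: each with
#'   `test` case and `inner`, a list of `repeats * inner_k` splits, each a
#'   list of `train`/`validation` case-id vectors) and `seed`.
#' @export
fold_plan <- function(labels, inner_k = 3, repeats = 3, seed = 1) {
  stopifnot(!is.null(names(labels)))
  ids <- names(labels)
  outer <- lapply(seq_along(ids), function(i) {
    tr_ids <- ids[-i]
    tr_lab <- labels[-i]
    inner <- list()
    for (rep_i in seq_len(repeats)) {
      fold_of <- with_seed(
        substream_seed(seed, sprintf("inner_%s_rep%d", ids[i], rep_i)),
        stratified_fold_ids(tr_lab, inner_k)
      )
      for (k in seq_len(inner_k)) {
        inner[[length(inner) + 1]] <- list(
          train = tr_ids[fold_of != k],
          validation = tr_ids[fold_of == k]
        )
      }
    }
    list(test = ids[i], train = tr_ids, inner = inner)
  })
  structure(list(case_ids = ids, outer = outer, inner_k = inner_k,
                 repeats = repeats, seed = seed), class = "fold_plan")
}

# Random fold assignment with per-class balance; guarantees every fold has
# at least one case of each class whenever each class has >= k members.
stratified_fold_ids <- function(labels, k) {
  fold_of <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold_of
}

#' Views fed to the models for an error basis
#'
#' False-positive models see all four views (an FP can arise on either
#' breast); false-negative and localization models see only the two views of
#' the lesion side.
#'
#' @param case a `case_record` (or any list with `cancer` and `lesion$side`).
#' @param basis "FP", "FN" or "location".
#' @return Character vector of view tags.
#' @export
select_views <- function(case, basis = c("FP", "FN", "location")) {
  basis <- match.arg(basis)
  if (basis == "FP") return(view_tags())
  side <- case$lesion$side
  if (is.null(side) || !side %in% c("L", "R")) {
    stop_readiff("cancer case lacks a lesion side", "readiff_input_error")
  }
  paste0(side, c("CC", "MLO"))
}

#' Embedded random-forest feature selection
#'
#' Fits a forest on all features and keeps the `k` with the largest
#' mean-decrease-in-impurity importance; ties are broken by registry
#' (column) order.
#'
#' @param x feature matrix (cases x features).
#' @param y factor labels.
#' @param k number of features to keep.
#' @param n_trees,max_sample_fraction,max_depth forest parameters.
#' @param seed integer seed.
#' @return Integer vector of selected column indices, length `k`.
#' @export
embedded_select <- function(x, y, k, n_trees = 100, max_sample_fraction = 1,
                            max_depth = 5, seed = 1) {
  if (k < 1) stop_readiff("k must be >= 1", "readiff_input_error")
  k <- min(k, ncol(x))
  if (k == ncol(x)) return(seq_len(ncol(x)))
  fit <- fit_rf(x, y, n_trees, max_sample_fraction, max_depth, seed,
                importance = "impurity")
  imp <- fit$variable.importance
  sort(order(-imp, seq_along(imp))[seq_len(k)])
}

fit_rf <- function(x, y, n_trees, max_sample_fraction, max_depth, seed,
                   importance = "none") {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, sample.fraction = max_sample_fraction,
    max.depth = max_depth, probability = TRUE, importance = importance,
    min.node.size = 1,  # depth is the tuned complexity control
    num.threads = 1, seed = seed, respect.unordered.factors = "order"
  )
}

predict_rf <- function(fit, x, positive_class) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  pr <- stats::predict(fit, data = df, num.threads = 1)$predictions
  pr[, positive_class]
}

#' Maximum-probability fusion of view probabilities
#'
#' @param p numeric vector of per-view probabilities (>= 1).
#' @return The maximum.
#' @export
fuse_max <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop_readiff("no view probabilities to fuse",
                               "readiff_input_error")
  max(p)
}

#' Nested cross-validated view models with max-probability fusion
#'
#' For each outer leave-one-case-out fold and each view model: every grid
#' cell is scored by the mean view-level validation AUC over the inner
#' splits (embedded feature selection is refit inside every inner-training
#' set, so the held-out case never influences selection or tuning); the
#' winning cell is refit on the full outer-training set and applied to the
#' held-out case. Case-level predictions are the maximum over view
#' probabilities, pooled over all outer folds. With a single-cell grid the
#' inner search is skipped (plain leave-one-out with fixed hyperparameters).
#'
#' @param features named list (by view tag) of feature matrices with case ids
#'   as row names; all matrices must cover the labelled cases.
#' @param labels factor with levels `c("easy", "difficult")` named by case
#'   id.
#' @param grid data frame from [hyper_grid()].
#' @param plan a [fold_plan()]; built from `labels` and `seed` if NULL.
#' @param seed integer seed (used for forests, and the plan when not given).
#' @return List with `predictions` (data frame: `case_id`, one `p_<view>`
#'   column per view, `fused`, `label`), `chosen` (per-fold winning grid
#'   cells) and `plan`.
#' @export
nested_cv <- function(features, labels, grid = hyper_grid(), plan = NULL,
                      seed = 1) {
  stopifnot(is.list(features), length(features) >= 1)
  labels <- stats::setNames(factor(labels, levels = c("easy", "difficult")),
                            names(labels))
  if (length(labels) < 6 || length(unique(labels)) < 2) {
    stop_readiff("need >= 6 cases with both classes", "readiff_input_error")
  }
  if (is.null(plan)) plan <- fold_plan(labels, seed = seed)
  views <- names(features)
  for (v in views) {
    if (!all(names(labels) %in% rownames(features[[v]]))) {
      stop_readiff(sprintf("view %s is missing labelled cases", v),
                   "readiff_input_error")
    }
  }

  preds <- matrix(NA_real_, length(plan$case_ids), length(views),
                  dimnames = list(plan$case_ids, views))
  chosen <- list()

  for (fi in seq_along(plan$outer)) {
    fold <- plan$outer[[fi]]
    for (v in views) {
      xv <- features[[v]]
      if (nrow(grid) > 1) {
        cell_auc <- vapply(seq_len(nrow(grid)), function(gi) {
          g <- grid[gi, ]
          aucs <- vapply(seq_along(fold$inner), function(si) {
            sp <- fold$inner[[si]]
            inner_cell_auc(xv, labels, sp, g,
                           substream_seed(seed, sprintf("f%d_%s_g%d_s%d",
                                                        fi, v, gi, si)))
          }, 0)
          mean(aucs, na.rm = TRUE)
        }, 0)
        best <- which.max(cell_auc)
      } else best <- 1L
      g <- grid[best, ]
      chosen[[length(chosen) + 1]] <- cbind(
        data.frame(fold = fi, test_case = fold$test, view = v), g)

      sel_seed <- substream_seed(seed, sprintf("refit_f%d_%s", fi, v))
      keep <- embedded_select(xv[fold$train, , drop = FALSE],
                              labels[fold$train], g$n_selected_features,
                              g$n_trees, g$max_sample_fraction, g$max_depth,
                              seed = sel_seed)
      fit <- fit_rf(xv[fold$train, keep, drop = FALSE], labels[fold$train],
                    g$n_trees, g$max_sample_fraction, g$max_depth,
                    seed = sel_seed + 1L)
      preds[fold$test, v] <- predict_rf(
        fit, xv[fold$test, keep, drop = FALSE], "difficult")
    }
  }

  fused <- apply(preds, 1, function(p) fuse_max(p))
  out <- data.frame(case_id = plan$case_ids, preds, check.names = FALSE)
  names(out)[-1] <- paste0("p_", views)
  out$fused <- fused
  out$label <- labels[plan$case_ids]
  list(predictions = out, chosen = do.call(rbind, chosen), plan = plan)
}

inner_cell_auc <- function(xv, labels, split, g, seed) {
  ytr <- labels[split$train]
  if (length(unique(ytr)) < 2) return(NA_real_)
  keep <- embedded_select(xv[split$train, , drop = FALSE], ytr,
                          g$n_selected_features, g$n_trees,
                          g$max_sample_fraction, g$max_depth, seed = seed)
  fit <- fit_rf(xv[split$train, keep, drop = FALSE], ytr, g$n_trees,
                g$max_sample_fraction, g$max_depth, seed = seed + 1L)
  p <- predict_rf(fit, xv[split$validation, keep, drop = FALSE], "difficult")
  yva <- labels[split$validation]
  if (length(unique(yva)) < 2) return(NA_real_)
  auc(p, yva == "difficult")
}
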