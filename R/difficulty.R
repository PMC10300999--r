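# Reader-response scoring: per-case error proportions for the three error
# bases (FP on cancer-free cases, FN and localization on cancer cases) and
# tertile difficulty labels.

#' Dichotomize a suspicion rating
#'
#' Ratings use the 5-point RANZCR mammography scale; 1-2 are negative calls,
#' 3 and above positive.
#'
#' @param rating integer vector in 1..5.
#' @return Logical: positive call.
#' @export
rating_to_binary <- function(rating) {
  if (any(!rating %in% 1:5)) {
    stop_readiff("ratings must be integers in 1..5", "readiff_input_error")
  }
  rating >= 3
}

#' Is an annotation a correct localization?
#'
#' TRUE iff the Euclidean distance from the annotated point to the nearest
#' lesion *in the same view* is at most `radius` pixels (inclusive boundary).
#'
#' @param annotation list or vector with `view`, `x`, `y`.
#' @param lesions data frame with `view`, `x`, `y` (>= 1 row).
#' @param radius correct-localization radius in pixels.
#' @return Logical.
#' @export
localization_correct <- function(annotation, lesions, radius = 250) {
  ann <- as.list(annotation)
  if (is.null(ann$view) || is.na(ann$view)) {
    stop_readiff("annotation must carry a view tag", "readiff_input_error")
  }
  stopifnot(nrow(lesions) >= 1)
  same <- lesions$view == ann$view
  if (!any(same)) return(FALSE)
  d <- sqrt((lesions$x[same] - as.numeric(ann$x))^2 +
              (lesions$y[same] - as.numeric(ann$y))^2)
  min(d) <= radius
}

#' Per-case error proportions for one error basis
#'
#' FP errors are positive calls on cancer-free cases; FN errors negative
#' calls on cancer cases; localization errors are cancer-case readings with
#' no correct localization (covering both misses and mislocalized positive
#' calls when `denominator = "all"`; `denominator = "positives"` restricts
#' the location basis to readers who called the case positive). When a reader
#' has several rows for a case only the highest-rated one is used.
#'
#' @param responses data frame: `reader_id`, `case_id`, `rating`, `view`,
#'   `x`, `y`.
#' @param truth data frame: `case_id`, `cancer`.
#' @param basis one of "FP", "FN", "location".
#' @param lesions data frame `case_id`, `view`, `x`, `y` (required for the
#'   location basis).
#' @param radius correct-localization radius in pixels.
#' @param denominator for the location basis: "all" readers or only
#'   "positives".
#' @return Data frame: `case_id`, `basis`, `n_readers`, `n_errors`,
#'   `proportion`.
#' @export
summarize_errors <- function(responses, truth, basis = c("FP", "FN", "location"),
                             lesions = NULL, radius = 250,
                             denominator = c("all", "positives")) {
  basis <- match.arg(basis)
  denominator <- match.arg(denominator)
  stopifnot(all(c("reader_id", "case_id", "rating") %in% names(responses)))

  # keep each reader's highest-rated response per case
  o <- order(responses$reader_id, responses$case_id, -responses$rating)
  responses <- responses[o, ]
  responses <- responses[!duplicated(responses[c("reader_id", "case_id")]), ]

  readers <- sort(unique(responses$reader_id))
  want <- truth$case_id[if (basis == "FP") !truth$cancer else truth$cancer]
  if (!length(want)) {
    stop_readiff(sprintf("no cases with the right truth status for basis %s",
                         basis), "readiff_input_error")
  }
  full <- expand.grid(reader_id = readers, case_id = want,
                      stringsAsFactors = FALSE)
  key_have <- paste(responses$reader_id, responses$case_id)
  key_want <- paste(full$reader_id, full$case_id)
  missing <- setdiff(key_want, key_have)
  if (length(missing)) {
    stop_readiff(paste0("incomplete reader panel; missing reader x case: ",
                        paste(utils::head(missing, 10), collapse = ", "),
                        if (length(missing) > 10) " ..."),
                 "readiff_incomplete_panel_error")
  }
  res <- responses[responses$case_id %in% want, ]
  rating_to_binary(res$rating)  # validates range
  positive <- res$rating >= 3

  err <- switch(basis,
    FP = positive,
    FN = !positive,
    location = {
      if (is.null(lesions)) {
        stop_readiff("location basis requires a lesion table",
                     "readiff_input_error")
      }
      vapply(seq_len(nrow(res)), function(i) {
        if (!positive[i]) return(TRUE)  # a missed case cannot be localized
        les <- lesions[lesions$case_id == res$case_id[i], , drop = FALSE]
        if (!nrow(les)) return(TRUE)
        if (is.na(res$x[i]) || is.na(res$y[i])) return(TRUE)
        !localization_correct(list(view = res$view[i], x = res$x[i],
                                   y = res$y[i]), les, radius)
      }, TRUE)
    })

  if (basis == "location" && denominator == "positives") {
    res <- res[positive, ]; err <- err[positive]
  }
  n_err <- tapply(err, res$case_id, sum)
  n_rdr <- tapply(err, res$case_id, length)
  ids <- sort(unique(res$case_id))
  data.frame(case_id = ids, basis = basis,
             n_readers = as.integer(n_rdr[ids]),
             n_errors = as.integer(n_err[ids]),
             proportion = as.numeric(n_err[ids] / n_rdr[ids]),
             row.names = NULL)
}

#' Split cases into easy / median / difficult tertiles
#'
#' Cases are sorted by ascending error proportion, ties broken by case id
#' (lexicographic), and cut into three groups whose sizes differ by at most
#' one: the extra case goes to `easy` first, then `difficult`. Modelling
#' downstream uses only the easy and difficult groups.
#'
#' @param summaries output of [summarize_errors()] (>= 3 cases).
#' @return Data frame: `case_id`, `basis`, `tertile` (factor
#'   easy/median/difficult).
#' @export
tertile_split <- function(summaries) {
  n <- nrow(summaries)
  if (n < 3) stop_readiff("need at least 3 cases", "readiff_input_error")
  o <- order(summaries$proportion, summaries$case_id)
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(easy = base + (rem >= 1), median = base, difficult = base + (rem >= 2))
  tert <- rep(c("easy", "median", "difficult"), sizes)
  out <- data.frame(case_id = summaries$case_id[o],
                    basis = summaries$basis[o],
                    tertile = factor(tert, levels = c("easy", "median",
                                                      "difficult")))
  out[order(out$case_id), , drop = FALSE]
}
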