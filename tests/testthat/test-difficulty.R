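# Reader-error summarization and tertile difficulty labels.

test_that("rating dichotomization follows the 5-point scale", {
  expect_false(rating_to_binary(2))
  expect_true(rating_to_binary(3))
  expect_equal(rating_to_binary(c(1, 5)), c(FALSE, TRUE))
  expect_error(rating_to_binary(0), class = "readiff_input_error")
  expect_error(rating_to_binary(6), class = "readiff_input_error")
})

test_that("localization rule is inclusive at the radius and view-matched", {
  les <- data.frame(view = "LCC", x = 0, y = 0)
  expect_true(localization_correct(list(view = "LCC", x = 0, y = 0), les))
  expect_true(localization_correct(list(view = "LCC", x = 150, y = 200), les))
  expect_false(localization_correct(list(view = "LCC", x = 300, y = 400), les))
  expect_false(localization_correct(list(view = "LMLO", x = 0, y = 0), les))
  expect_error(localization_correct(list(x = 0, y = 0), les),
               class = "readiff_input_error")
})

make_responses <- function(ratings, case_id = "c1",
                           view = NA, x = NA, y = NA) {
  data.frame(reader_id = sprintf("r%d", seq_along(ratings)),
             case_id = case_id, rating = ratings, view = view, x = x, y = y)
}

test_that("error proportions match hand counts", {
  truth <- data.frame(case_id = "c1", cancer = FALSE)
  fp <- summarize_errors(make_responses(c(1, 2, 3, 5)), truth, "FP")
  expect_equal(fp$proportion, 0.5)
  expect_equal(fp$n_readers, 4L)

  truth_c <- data.frame(case_id = "c1", cancer = TRUE)
  les <- data.frame(case_id = "c1", view = "LCC", x = 100, y = 100)
  all_miss <- make_responses(c(1, 1, 1))
  expect_equal(summarize_errors(all_miss, truth_c, "FN")$proportion, 1)
  expect_equal(summarize_errors(all_miss, truth_c, "location",
                                lesions = les)$proportion, 1)

  # two positive readers: one localizes at distance 100, one at 400
  two <- data.frame(reader_id = c("r1", "r2"), case_id = "c1",
                    rating = c(4, 4), view = "LCC",
                    x = c(200, 500), y = c(100, 100))
  loc <- summarize_errors(two, truth_c, "location", lesions = les,
                          denominator = "positives")
  expect_equal(loc$n_readers, 2L)
  expect_equal(loc$proportion, 0.5)
  # with the all-readers denominator a negative call also counts as an error
  three <- rbind(two, data.frame(reader_id = "r3", case_id = "c1", rating = 1,
                                 view = NA, x = NA, y = NA))
  loc_all <- summarize_errors(three, truth_c, "location", lesions = les)
  expect_equal(loc_all$proportion, 2 / 3)
})

test_that("only the highest-rated annotation per reader is used", {
  truth <- data.frame(case_id = "c1", cancer = TRUE)
  les <- data.frame(case_id = "c1", view = "LCC", x = 0, y = 0)
  resp <- data.frame(reader_id = "r1", case_id = "c1", rating = c(3, 5),
                     view = "LCC", x = c(0, 1000), y = 0)
  out <- summarize_errors(resp, truth, "location", lesions = les)
  expect_equal(out$n_readers, 1L)
  expect_equal(out$proportion, 1)  # the rating-5 annotation is off-target
})

test_that("incomplete panels are rejected with offenders listed", {
  truth <- data.frame(case_id = c("c1", "c2"), cancer = FALSE)
  resp <- data.frame(reader_id = c("r1", "r1", "r2"),
                     case_id = c("c1", "c2", "c1"),
                     rating = c(1, 2, 3), view = NA, x = NA, y = NA)
  expect_error(summarize_errors(resp, truth, "FP"),
               regexp = "r2 c2", class = "readiff_incomplete_panel_error")
})

test_that("tertile split is rank-based, balanced and deterministic", {
  su <- data.frame(case_id = c("a", "b", "c"), basis = "FP",
                   n_readers = 4L, n_errors = c(0L, 2L, 4L),
                   proportion = c(0, 0.5, 1))
  lab <- tertile_split(su)
  expect_equal(as.character(lab$tertile[match(c("a", "b", "c"), lab$case_id)]),
               c("easy", "median", "difficult"))

  su9 <- data.frame(case_id = sprintf("c%02d", 1:9), basis = "FN",
                    n_readers = 10L, n_errors = 0L,
                    proportion = (1:9) / 10)
  lab9 <- tertile_split(su9[sample(9), ])  # input order must not matter
  expect_equal(as.vector(table(lab9$tertile)), c(3, 3, 3))
  expect_equal(as.character(lab9$tertile[match(sprintf("c%02d", 1:9),
                                               lab9$case_id)]),
               rep(c("easy", "median", "difficult"), each = 3))

  # all proportions equal: case-id order decides, sizes still balanced
  su_tie <- data.frame(case_id = sprintf("c%02d", 9:1), basis = "FP",
                       n_readers = 4L, n_errors = 2L, proportion = 0.5)
  lab_tie <- tertile_split(su_tie)
  expect_equal(as.vector(table(lab_tie$tertile)), c(3, 3, 3))
  expect_equal(as.character(lab_tie$tertile[match(sprintf("c%02d", 1:9),
                                                  lab_tie$case_id)]),
               rep(c("easy", "median", "difficult"), each = 3))

  # sizes differ by at most one for any n
  for (n in c(7, 20, 40)) {
    su_n <- data.frame(case_id = sprintf("c%03d", 1:n), basis = "FP",
                       n_readers = 10L, n_errors = 0L,
                       proportion = seq(0, 1, length.out = n))
    sz <- table(tertile_split(su_n)$tertile)
    expect_lte(max(sz) - min(sz), 1)
    expect_equal(sum(sz), n)
  }
  expect_error(tertile_split(su9[1:2, ]), class = "readiff_input_error")
})

test_that("difficult cases carry higher latent difficulty when coupling is strong", {
  stub <- stub_cohort(30, seed = 14)
  cfg <- synthetic_config(n_normal = 30, n_cancer = 1, n_readers = 20,
                          error_link_slope = 5, seed = 15)
  resp <- simulate_reader_panel(stub$cases, stub$truth, cfg)
  lab <- difficulty_labels(resp, stub$truth, "FP")
  d <- stub$truth$latent_difficulty[match(names(lab), stub$truth$case_id)]
  expect_gt(mean(d[lab == "difficult"]), mean(d[lab == "easy"]))
})
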