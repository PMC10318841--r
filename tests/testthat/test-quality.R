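max_record <- function() {
  list(study_id = "max", n_total = 800L, n_sites = 5L,
       cv_scheme = "nested_kfold", external_validation = "cross_country",
       sensitivity = 0.8, specificity = 0.8, balanced_accuracy = 0.8, auc = 0.8,
       data_claimed = TRUE, data_verified = TRUE,
       model_claimed = TRUE, model_verified = TRUE)
}

min_record <- function() {
  list(study_id = "min", n_total = 40L, n_sites = 1L,
       cv_scheme = "none", external_validation = "none",
       sensitivity = NULL, specificity = NULL, balanced_accuracy = NULL,
       auc = NULL, data_claimed = FALSE, data_verified = FALSE,
       model_claimed = FALSE, model_verified = FALSE)
}

test_that("rubric extremes score the maximum and the floor", {
  s_max <- score_study(max_record())
  expect_equal(s_max$total, 10)
  expect_equal(s_max$stars, 5)
  s_min <- score_study(min_record())
  expect_equal(s_min$total, 0)
  expect_equal(s_min$stars, 0.5) # floor of the star scale
})

test_that("a mid-quality record scores the hand-applied rubric total", {
  rec <- list(study_id = "mid", n_total = 150L, n_sites = 1L,   # item 1: 0
              cv_scheme = "LOOCV",                              # item 2: 1
              external_validation = "within_country",           # item 3: 1
              sensitivity = 0.7, specificity = 0.75,            # item 4: 1
              data_claimed = TRUE, data_verified = FALSE,       # item 5: 1
              model_claimed = FALSE, model_verified = FALSE)
  s <- score_study(rec)
  expect_equal(s$sample_representativeness, 0)
  expect_equal(s$cv_scheme, 1)
  expect_equal(s$external_validation, 1)
  expect_equal(s$reporting_transparency, 1)
  expect_equal(s$availability, 1)
  expect_equal(s$total, 4)
  expect_equal(s$stars, 2)
})

test_that("either large n or multiple sites earns the middle sample point", {
  base <- min_record()
  big <- modifyList(base, list(n_total = 250L))
  expect_equal(score_study(big)$sample_representativeness, 1)
  multi <- modifyList(base, list(n_sites = 3L))
  expect_equal(score_study(multi)$sample_representativeness, 1)
})

test_that("missing fields score the floor and are flagged, never an error", {
  rec <- list(study_id = "sparse", accuracy = 0.8)
  s <- score_study(rec)
  expect_equal(s$total, 0)
  expect_equal(s$n_not_reported, 5L)
})

test_that("reported_metrics string and per-metric columns agree", {
  a <- modifyList(min_record(), list(reported_metrics = "sensitivity;auc"))
  b <- modifyList(min_record(), list(sensitivity = 0.7, auc = 0.8))
  expect_equal(score_study(a)$reporting_transparency, 1)
  expect_equal(score_study(b)$reporting_transparency, 1)
})

cv_levels <- c("none", "LOOCV", "kfold", "nested_kfold", "other")

test_that("scoring is deterministic and monotone in single-field improvements", {
  expect_identical(score_study(max_record()), score_study(max_record()))
  ladders <- list(
    list(field = "cv_scheme", worse = "none", better = "LOOCV"),
    list(field = "cv_scheme", worse = "LOOCV", better = "nested_kfold"),
    list(field = "external_validation", worse = "none", better = "within_country"),
    list(field = "external_validation", worse = "within_country",
         better = "cross_country"),
    list(field = "n_total", worse = 150L, better = 400L),
    list(field = "n_sites", worse = 1L, better = 4L),
    list(field = "data_claimed", worse = FALSE, better = TRUE)
  )
  set.seed(21)
  for (i in 1:20) {
    rec <- list(study_id = "r",
                n_total = sample(c(50L, 400L), 1),
                n_sites = sample(c(1L, 3L), 1),
                cv_scheme = sample(cv_levels, 1),
                external_validation = sample(c("none", "within_country",
                                               "cross_country"), 1),
                sensitivity = if (runif(1) < 0.5) 0.7,
                auc = if (runif(1) < 0.5) 0.8,
                data_claimed = runif(1) < 0.5, data_verified = FALSE,
                model_claimed = FALSE, model_verified = FALSE)
    for (lad in ladders) {
      worse <- modifyList(rec, setNames(list(lad$worse), lad$field))
      better <- modifyList(rec, setNames(list(lad$better), lad$field))
      expect_gte(score_study(better)$total, score_study(worse)$total)
    }
    verified <- modifyList(rec, list(data_claimed = TRUE, data_verified = TRUE))
    claimed <- modifyList(rec, list(data_claimed = TRUE, data_verified = FALSE))
    expect_gte(score_study(verified)$total, score_study(claimed)$total)
  }
})

test_that("score_table summarizes by year and disorder with hand-checked means", {
  ev <- dplyr::bind_rows(
    tibble::as_tibble(max_record()) |> dplyr::mutate(year = 2020L, disorder = "SZ"),
    tibble::as_tibble(max_record()) |>
      dplyr::mutate(study_id = "max2", year = 2020L, disorder = "SZ"),
    tibble::as_tibble(min_record() |> purrr::compact()) |>
      dplyr::mutate(year = 2019L, disorder = "ASD")
  )
  qs <- score_table(ev)
  expect_equal(qs$scores$total, c(10, 10, 0))
  expect_equal(qs$by_year$mean_total[qs$by_year$year == 2020], 10)
  expect_equal(qs$by_year$mean_total[qs$by_year$year == 2019], 0)
  expect_equal(qs$by_disorder$mean_total[qs$by_disorder$disorder == "SZ"], 10)
  expect_equal(qs$low_quality_share, 1 / 3)
  expect_error(score_table(ev[0, ]), "empty")
})

test_that("identical max-quality records give zero-variance summaries", {
  ev <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::as_tibble(max_record()) |>
      dplyr::mutate(study_id = paste0("m", i), year = 2021L)
  }))
  qs <- score_table(ev)
  expect_equal(qs$mean_total, 10)
  expect_equal(var(qs$scores$total), 0)
})

test_that("adjudication flags only differences strictly above the threshold", {
  expect_false(adjudicate(7, 7))
  expect_true(adjudicate(4, 7))
  expect_false(adjudicate(5, 7)) # |diff| = 2 is tolerated
  a <- score_study(max_record()); b <- score_study(min_record())
  expect_error(adjudicate(a, b), "different studies")
  b2 <- b; b2$study_id <- a$study_id
  expect_true(adjudicate(a, b2))
})

test_that("a rubric without exactly five items is rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  bad <- jsonlite::read_json(system.file("extdata", "rubric_default.json",
                                         package = "metasample"),
                             simplifyVector = TRUE)
  bad$items <- lapply(bad$items, function(z) z[1:4])
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(default_rubric(path), "exactly 5")
})
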