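# staging of screens on the refined metabolic classification

test_that("criteria thresholds are exact at their boundaries", {
  # inclusive ">=" thresholds flag positive exactly at the cutoff;
  # the exclusive "<" HDL thresholds flag negative exactly at the cutoff
  base_f <- list(sex = "female", waist = 70, triglycerides = 100, hdl = 60,
                 sbp = 110, dbp = 70, glucose = 90)
  base_m <- utils::modifyList(base_f, list(sex = "male"))
  cases <- list(
    list(base_f, list(waist = 80), "central_obesity", TRUE),
    list(base_f, list(waist = 79.9), "central_obesity", FALSE),
    list(base_m, list(waist = 90), "central_obesity", TRUE),
    list(base_m, list(waist = 89.9), "central_obesity", FALSE),
    list(base_f, list(triglycerides = 150), "hypertriglyceridemia", TRUE),
    list(base_f, list(triglycerides = 149.9), "hypertriglyceridemia", FALSE),
    list(base_f, list(hdl = 50), "low_hdl", FALSE),
    list(base_f, list(hdl = 49.9), "low_hdl", TRUE),
    list(base_m, list(hdl = 40), "low_hdl", FALSE),
    list(base_m, list(hdl = 39.9), "low_hdl", TRUE),
    list(base_f, list(sbp = 130), "high_bp", TRUE),
    list(base_f, list(sbp = 129.9), "high_bp", FALSE),
    list(base_f, list(dbp = 85), "high_bp", TRUE),
    list(base_f, list(dbp = 84.9), "high_bp", FALSE),
    list(base_f, list(glucose = 100), "hyperglycemia", TRUE),
    list(base_f, list(glucose = 99.9), "hyperglycemia", FALSE)
  )
  for (cs in cases) {
    args <- utils::modifyList(cs[[1]], cs[[2]])
    cv <- do.call(evaluate_criteria, args)
    expect_identical(cv[[cs[[3]]]], cs[[4]],
                     info = paste(cs[[3]], deparse(cs[[2]])))
  }
})

test_that("worked boundary screens classify as expected", {
  cv <- evaluate_criteria("female", waist = 80.0, triglycerides = 149,
                          hdl = 50, sbp = 129, dbp = 84, glucose = 99)
  expect_identical(unlist(cv[c("central_obesity", "hypertriglyceridemia",
                               "low_hdl", "high_bp", "hyperglycemia")]),
                   c(central_obesity = TRUE, hypertriglyceridemia = FALSE,
                     low_hdl = FALSE, high_bp = FALSE, hyperglycemia = FALSE))
  expect_equal(cv$n_positive, 1)

  cv2 <- evaluate_criteria("male", waist = 89, triglycerides = 140, hdl = 45,
                           sbp = 120, dbp = 80, glucose = 90)
  expect_equal(cv2$n_positive, 0)
})

test_that("treatment history forces the covered criteria positive", {
  cv <- evaluate_criteria("female", waist = 75, triglycerides = 100, hdl = 60,
                          sbp = 110, dbp = 70, glucose = 85,
                          on_diabetes_treatment = TRUE)
  expect_true(cv$hyperglycemia)
  expect_equal(cv$n_positive, 1)

  cv <- evaluate_criteria("female", waist = 75, triglycerides = 100, hdl = 60,
                          sbp = 110, dbp = 70, glucose = 85,
                          on_hypertension_treatment = TRUE,
                          on_hyperlipidemia_treatment = TRUE)
  expect_true(cv$high_bp)
  expect_true(cv$hypertriglyceridemia)
  expect_false(cv$low_hdl)  # hyperlipidemia maps to triglycerides only
  expect_equal(cv$n_positive, 2)

  cv <- evaluate_criteria("female", waist = 75, triglycerides = 100, hdl = 60,
                          sbp = 110, dbp = 70, glucose = 85,
                          on_hyperlipidemia_treatment = TRUE,
                          hyperlipidemia_sets_low_hdl = TRUE)
  expect_true(cv$low_hdl)
})

test_that("missing biomarkers error by name unless covered or permissive", {
  expect_error(
    evaluate_criteria("female", waist = NA, triglycerides = 100, hdl = 60,
                      sbp = 110, dbp = 70, glucose = 85),
    "central_obesity")
  expect_error(
    evaluate_criteria("male", waist = 80, triglycerides = 100, hdl = 60,
                      sbp = NA, dbp = 70, glucose = 85),
    "high_bp")
  # treatment covers the missing measurement
  cv <- evaluate_criteria("male", waist = 80, triglycerides = 100, hdl = 60,
                          sbp = NA, dbp = NA, glucose = 85,
                          on_hypertension_treatment = TRUE)
  expect_true(cv$high_bp)
  # permissive mode flags instead of failing
  cv <- evaluate_criteria("female", waist = NA, triglycerides = 100, hdl = 60,
                          sbp = 110, dbp = 70, glucose = 85, permissive = TRUE)
  expect_true(cv$incomplete)
  expect_equal(cv$n_positive, 0)
})

test_that("staging is monotone in the number of positive criteria", {
  states <- classify_rmrc(0:5)
  expect_equal(unname(states), c(1L, 2L, 2L, 3L, 3L, 3L))
  expect_true(all(diff(states) >= 0))
  expect_identical(names(states), c("FMD", "MMD", "MMD", "MetS", "MetS", "MetS"))
})

test_that("synthetic biomarker cohorts round-trip to their generating states", {
  set.seed(42)
  states <- sample(1:3, 400, replace = TRUE, prob = c(0.36, 0.47, 0.17))
  sexes <- sample(c("male", "female"), 400, replace = TRUE)
  bio <- simulate_biomarkers(states, sexes)
  out <- classify_screens(bio)
  expect_identical(out$state, as.integer(states))
  expect_false(any(out$incomplete))
})

test_that("classify_screens maps columns and reports row numbers on errors", {
  df <- data.frame(sex = "female", wc = 85, triglycerides = 160, hdl = 45,
                   sbp = 135, dbp = 80, glucose = 101)
  out <- classify_screens(df, col_map = c(waist = "wc"))
  expect_equal(out$n_positive, 5L)
  expect_equal(out$state, 3L)
  expect_equal(out$state_label, "MetS")

  bad <- data.frame(sex = c("female", "female"),
                    waist = c(85, NA), triglycerides = 100, hdl = 60,
                    sbp = 110, dbp = 70, glucose = 85)
  expect_error(classify_screens(bad), "row 2")
  ok <- classify_screens(bad, permissive = TRUE)
  expect_identical(ok$incomplete, c(FALSE, TRUE))
})
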