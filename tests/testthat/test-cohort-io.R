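test_that("measurements round-trip through CSV unchanged", {
    m <- data.frame(participant_id = c("p1", "p1", "p2"),
                    biomarker = c("LDL", "LDL", "VITD"),
                    value = c(120.5, 112, 28.25),
                    draw_date = as.Date(c("2016-01-10", "2016-05-01",
                                          "2016-03-03")))
    tab <- measurementTable(m)
    f <- withr::local_tempfile(fileext = ".csv")
    pf <- withr::local_tempfile(fileext = ".csv")
    writeMeasurements(tab, f, pf)
    back <- readMeasurements(f, pf)
    got <- measurements(back)
    attr(got, "rejected") <- NULL
    expect_equal(got, measurements(tab))
    expect_equal(participants(back)$participant_id,
                 participants(tab)$participant_id)
})

test_that("malformed CSVs are rejected with precise diagnostics", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("participant_id,biomarker,draw_date",
                 "p1,LDL,2016-01-01"), f)
    expect_error(readMeasurements(f), "value")

    writeLines(c("participant_id,biomarker,value,draw_date",
                 "p1,LDL,120,2016-01-01",
                 "p1,LDL,abc,2016-02-01",
                 "p2,LDL,130,2016-01-01"), f)
    expect_warning(readMeasurements(f), "rejected")
    tab <- suppressWarnings(readMeasurements(f))
    expect_equal(nrow(measurements(tab)), 2L)
    rej <- attr(measurements(tab), "rejected")
    expect_equal(rej$row, 2L)
    expect_match(rej$reason, "value")

    writeLines(c("participant_id,biomarker,value,draw_date",
                 "p1,LDL,120,2016-01-01",
                 "p1,LDL,125,2016-01-01"), f)
    expect_error(readMeasurements(f), "duplicate")
})

test_that("MeasurementTable validity enforces its invariants", {
    m <- data.frame(participant_id = "p1", biomarker = "LDL",
                    value = Inf, draw_date = as.Date("2016-01-01"))
    expect_error(measurementTable(m), "finite")
    m$value <- 100
    p <- data.frame(participant_id = "p9", sex = "male",
                    age_years = 40, bmi_baseline = NA, bmi_followup = NA)
    expect_error(measurementTable(m, p), "unknown participant")
})

test_that("extractPairs selects baseline and gap-qualifying follow-up", {
    mk <- function(days, values) measurementTable(data.frame(
        participant_id = "p1", biomarker = "GLU", value = values,
        draw_date = as.Date("2016-01-01") + days))
    p <- extractPairs(mk(c(0, 90), c(100, 90)), min_gap_days = 30)
    expect_equal(nrow(p), 1L)
    expect_equal(p$delta, -10)
    expect_equal(nrow(extractPairs(mk(c(0, 10), c(100, 90)),
                                   min_gap_days = 30)), 0L)
    ## candidates at 20 and 45 days: earliest follow-up >= 30 d is day 45
    p <- extractPairs(mk(c(0, 20, 45), c(100, 97, 91)), min_gap_days = 30)
    expect_equal(as.numeric(p$followup_date - p$baseline_date), 45)
    expect_equal(p$followup_value, 91)
    ## latest strategy takes the last qualifying follow-up
    p <- extractPairs(mk(c(0, 40, 400), c(100, 95, 80)),
                      min_gap_days = 30, strategy = "latest")
    expect_equal(p$followup_value, 80)
})

test_that("extractPairs is invariant to input row order and exact on deltas", {
    set.seed(5)
    n <- 60
    m <- data.frame(
        participant_id = sample(sprintf("p%d", 1:8), n, replace = TRUE),
        biomarker = sample(c("LDL", "GLU", "VITD"), n, replace = TRUE),
        value = round(rnorm(n, 100, 20), 2),
        draw_date = as.Date("2016-01-01") + sample(0:400, n))
    m <- m[!duplicated(m[c("participant_id", "biomarker", "draw_date")]), ]
    tab1 <- measurementTable(m)
    tab2 <- measurementTable(m[sample(nrow(m)), ])
    p1 <- extractPairs(tab1)
    expect_identical(p1, extractPairs(tab2))
    expect_identical(p1$delta, p1$followup_value - p1$baseline_value)
})

test_that("bundled range rules transcribe the clinical thresholds", {
    rules <- loadRangeRules()
    r <- rangeRules(rules)
    expect_equal(nrow(r), 17L)
    ldl <- r[r$biomarker == "LDL", ]
    expect_equal(ldl$direction, "high")
    expect_equal(ldl$threshold_male, 130)
    expect_equal(ldl$threshold_female, 130)
    alt <- r[r$biomarker == "ALT", ]
    expect_equal(c(alt$threshold_male, alt$threshold_female), c(46, 29))
    vitd <- r[r$biomarker == "VITD", ]
    expect_equal(vitd$direction, "low")
    expect_equal(vitd$threshold_male, 30)
    expect_true(r$sex_stratified[r$biomarker == "TESTO"])
})

test_that("range-rule config errors carry the offending key", {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("LDL:", "  direction: sideways", "  threshold: 130"), f)
    expect_error(loadRangeRules(f), "LDL.*direction")
    writeLines(c("LDL:", "  direction: high", "  threshold: plenty"), f)
    expect_error(loadRangeRules(f), "LDL.*threshold")
})
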