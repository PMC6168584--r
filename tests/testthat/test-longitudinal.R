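partTab <- function(ids, sex) {
    data.frame(participant_id = ids, sex = sex,
               age_years = 40, bmi_baseline = NA_real_,
               bmi_followup = NA_real_, stringsAsFactors = FALSE)
}

test_that("out-of-range flags honour direction, strictness and sex", {
    rules <- loadRangeRules()
    pairs <- rbind(makePairs("p1", "VITD", 23.7, 33),
                   makePairs("p2", "LDL", 130, 120),
                   makePairs("p3", "ALT", 35, 30),
                   makePairs("p4", "ALT", 35, 30))
    parts <- partTab(c("p1", "p2", "p3", "p4"),
                     c("female", "male", "male", "female"))
    fl <- flagOutOfRange(pairs, rules, parts)
    expect_true(fl$out_of_range[fl$participant_id == "p1"])
    ## threshold is strict: LDL exactly 130 is in range
    expect_false(fl$out_of_range[fl$participant_id == "p2"])
    ## ALT 35: in range for a male (46), out for a female (29)
    expect_false(fl$out_of_range[fl$participant_id == "p3"])
    expect_true(fl$out_of_range[fl$participant_id == "p4"])
})

test_that("unknown sex excludes only sex-specific flagging", {
    rules <- loadRangeRules()
    pairs <- rbind(makePairs("p1", "ALT", 35, 30),
                   makePairs("p1", "LDL", 150, 140))
    parts <- partTab("p1", NA_character_)
    fl <- flagOutOfRange(pairs, rules, parts)
    expect_equal(fl$biomarker, "LDL")      # ALT row dropped
    expect_true(fl$out_of_range)
    expect_equal(attr(fl, "excluded")$biomarker, "ALT")
})

test_that("flagging is order-invariant", {
    set.seed(41)
    pairs <- makePairs(sprintf("p%d", 1:50), "LDL",
                       rnorm(50, 130, 20), rnorm(50, 125, 20))
    parts <- partTab(sprintf("p%d", 1:50),
                     sample(c("male", "female"), 50, TRUE))
    f1 <- flagOutOfRange(pairs, loadRangeRules(), parts)
    shuffled <- pairs[sample(nrow(pairs)), ]
    f2 <- flagOutOfRange(shuffled, loadRangeRules(), parts)
    f2 <- f2[order(match(f2$participant_id, f1$participant_id)), ]
    expect_equal(f1$out_of_range, f2$out_of_range)
})

test_that("seasonal model recovers a two-group mean difference exactly", {
    dates <- as.Date(c(rep("2016-02-15", 12), rep("2016-07-15", 12)))
    values <- c(rep(30, 12), rep(30 + 4.2, 12))
    m <- fitSeasonalModel(values, dates)
    expect_equal(m$offset_estimate, 4.2)
    expect_error(fitSeasonalModel(rep(30, 30),
                                  rep(as.Date("2016-01-15"), 30)),
                 "each season")
})

test_that("seasonal model recovers the planted summer offset on a cohort", {
    cfg <- syntheticConfig(
        data.frame(biomarker = "VITD", baseline_mean = 32,
                   baseline_sd = 8, delta_sd = 8, seasonal_offset = 2.5),
        n_participants = 2000, summer_fraction = 0.33, seed = 42)
    ch <- generateCohort(cfg)
    mm <- measurements(ch$table)
    m <- fitSeasonalModel(mm$value, mm$draw_date)
    expect_lt(abs(m$offset_estimate - 2.5), 0.3)
    rep <- validateTruth(ch$truth, seasonal = m)
    expect_lt(abs(rep$seasonal_error), 0.3)
})

test_that("seasonal adjustment shifts only summer values and cancels in-pair", {
    model <- list(biomarker = "VITD", summer_months = 6:9,
                  offset_estimate = 2.5)
    pairs <- makePairs("p1", "VITD", 28, 32.4,
                       baseline_date = as.Date("2016-01-10"),
                       followup_date = as.Date("2016-07-10"))
    adj <- applySeasonalAdjustment(pairs, model)
    expect_equal(adj$baseline_value, 28)        # winter untouched
    expect_equal(adj$followup_value, 29.9)
    expect_equal(adj$delta, 1.9)
    ## both tests in summer: delta unchanged
    pairs2 <- makePairs("p1", "VITD", 28, 35,
                        baseline_date = as.Date("2016-06-10"),
                        followup_date = as.Date("2016-08-10"))
    expect_equal(applySeasonalAdjustment(pairs2, model)$delta,
                 pairs2$delta)
    ## other biomarkers untouched
    pairs3 <- makePairs("p1", "LDL", 120, 110,
                        followup_date = as.Date("2016-07-10"))
    expect_equal(applySeasonalAdjustment(pairs3, model)$followup_value, 110)
})

test_that("signed-rank test matches exact references", {
    ## constant positive shift, n = 10: p = 2 / 2^10
    res <- wilcoxonSignedRank(1:10, 1:10 + 3)
    expect_equal(res$p, 2 / 1024)
    expect_equal(res$method, "exact")
    ## no change convention
    res0 <- wilcoxonSignedRank(1:5, 1:5)
    expect_equal(res0$p, 1)
    expect_match(res0$flag, "zero")
    ## n = 6, differences (+1,+2,+3,+4,+5,-6): W = 15, enumeration oracle
    b <- rep(0, 6); f <- c(1, 2, 3, 4, 5, -6)
    res6 <- wilcoxonSignedRank(b, f)
    expect_equal(res6$statistic, 15)
    expect_equal(res6$p, bruteSignRankP(b, f))
})

test_that("signed-rank exact path equals enumeration on random tied inputs", {
    set.seed(43)
    for (i in 1:60) {
        n <- sample(3:12, 1)
        b <- sample(0:6, n, replace = TRUE)
        f <- sample(0:6, n, replace = TRUE)
        if (all(f - b == 0)) next
        expect_equal(wilcoxonSignedRank(b, f)$p, bruteSignRankP(b, f))
    }
})

test_that("signed-rank normal path agrees with the reference implementation", {
    set.seed(44)
    for (i in 1:20) {
        b <- rnorm(60); f <- b + rnorm(60, 0.1)
        got <- wilcoxonSignedRank(b, f)
        expect_equal(got$method, "normal")
        ref <- wilcox.test(f, b, paired = TRUE, exact = FALSE,
                           correct = TRUE)
        expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
})

test_that("paired t-test matches the closed form and handles degeneracy", {
    d <- c(1, -1, 2, -2, 3)
    res <- pairedTTest(rep(0, 5), d)
    tt <- mean(d) / (sd(d) / sqrt(5))
    expect_equal(res$mean_change, mean(d))
    expect_equal(res$p, 2 * pt(-abs(tt), 4))
    res0 <- pairedTTest(1:5, 1:5)
    expect_equal(res0$p, 1)
    expect_match(res0$flag, "zero")
    expect_error(pairedTTest(1:5, 1:5 + 2), "degenerate")
    ## planted shift recovery
    set.seed(45)
    b <- rnorm(400, 25, 3)
    a <- b + rnorm(400, -0.25, 1)
    res <- pairedTTest(b, a)
    expect_lt(abs(res$mean_change + 0.25), 0.15)
})

test_that("change table enforces the minimum group size and direction", {
    rules <- loadRangeRules()
    set.seed(46)
    ## 30 out-of-range LDL participants improving, 19 out-of-range GLU
    ldl <- makePairs(sprintf("l%d", 1:40), "LDL",
                     c(rnorm(30, 150, 8), rnorm(10, 110, 5)),
                     c(rnorm(30, 138, 8), rnorm(10, 110, 5)))
    glu <- makePairs(sprintf("g%d", 1:19), "GLU",
                     rnorm(19, 110, 3), rnorm(19, 100, 3))
    pairs <- rbind(ldl, glu)
    parts <- partTab(unique(pairs$participant_id), "male")
    tab <- outOfRangeChangeTable(pairs, rules, parts, min_group = 20)
    expect_true("LDL" %in% tab$biomarker)
    expect_false("GLU" %in% tab$biomarker)
    om <- attr(tab, "omitted")
    expect_true("GLU" %in% om$biomarker)
    ldl_row <- tab[tab$biomarker == "LDL", ]
    expect_equal(ldl_row$improvement_direction, "decrease")
    expect_lt(ldl_row$p_value, 0.001)
    ## medians computed on exactly the tested (out-of-range) pairs
    oor <- ldl$baseline_value > 130
    expect_equal(ldl_row$baseline_median, median(ldl$baseline_value[oor]))
    expect_equal(ldl_row$n, sum(oor))
})

test_that("sex-stratified biomarkers are analysed per sex", {
    rules <- loadRangeRules()
    set.seed(47)
    ids <- sprintf("t%d", 1:60)
    pairs <- makePairs(ids, "TESTO", rnorm(60, 210, 15), rnorm(60, 300, 40))
    parts <- partTab(ids, rep(c("male", "female"), each = 30))
    tab <- outOfRangeChangeTable(pairs, rules, parts, min_group = 10)
    testo <- tab[tab$biomarker == "TESTO", ]
    ## female threshold is 0 (direction low): no female is out-of-range
    expect_equal(testo$stratum, "male")
    expect_equal(testo$threshold, 250)
})

test_that("null change data yield approximately uniform p-values", {
    set.seed(48)
    pvals <- replicate(400, {
        b <- rnorm(40); f <- b + rnorm(40)
        wilcoxonSignedRank(b, f)$p
    })
    ks <- suppressWarnings(ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
})
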