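test_that("the generator is a deterministic function of config and seed", {
    cfg <- syntheticPreset("tiny", seed = 11)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(measurements(a$table), measurements(b$table))
    expect_identical(a$choices, b$choices)
    expect_identical(a$truth, b$truth)
    c2 <- generateCohort(syntheticPreset("tiny", seed = 12))
    expect_false(identical(measurements(a$table),
                           measurements(c2$table)))
})

test_that("the generator does not disturb the caller's RNG stream", {
    set.seed(99); x1 <- runif(3)
    set.seed(99); invisible(generateCohort(syntheticPreset("tiny")))
    x2 <- runif(3)
    expect_identical(x1, x2)
})

test_that("an empty cohort is valid and empty", {
    cfg <- syntheticConfig("A", n_participants = 0)
    ch <- generateCohort(cfg)
    expect_equal(nrow(measurements(ch$table)), 0L)
    expect_equal(nrow(ch$choices), 0L)
})

test_that("a non-PSD implied correlation fails before any sampling", {
    expect_error(
        syntheticConfig(LETTERS[1:6],
                        blocks = list(b1 = c("A", "B", "C"),
                                      b2 = c("D", "E", "F")),
                        r_within = 0.1, r_between = 0.9),
        "positive semi-definite")
    expect_error(
        syntheticConfig(LETTERS[1:3],
                        panels = list(p1 = list(biomarkers = c("A", "B"),
                                                weight = 1))),
        "cover every biomarker")
})

test_that("panel-based missingness is honoured exactly", {
    cfg <- syntheticConfig(
        LETTERS[1:4],
        panels = list(p1 = list(biomarkers = c("A", "B"), weight = 0.5),
                      p2 = list(biomarkers = c("C", "D"), weight = 0.5)),
        n_participants = 60, seed = 13)
    ch <- generateCohort(cfg)
    mm <- measurements(ch$table)
    for (id in names(ch$truth$panel)) {
        want <- cfg@panels[[ch$truth$panel[id]]]$biomarkers
        expect_setequal(unique(mm$biomarker[mm$participant_id == id]),
                        want)
    }
    ## two dated measurements per covered biomarker, gap >= min gap
    cnt <- table(mm$participant_id, mm$biomarker)
    expect_true(all(cnt %in% c(0L, 2L)))
    pairs <- extractPairs(ch$table, min_gap_days = 30)
    expect_true(all(as.numeric(pairs$followup_date -
                               pairs$baseline_date) >= 30))
})

test_that("baseline marginals are calibrated to the spec", {
    cfg <- syntheticConfig(
        data.frame(biomarker = c("A", "B"), baseline_mean = c(100, 30),
                   baseline_sd = c(20, 5), delta_sd = c(10, 4),
                   seasonal_offset = 0),
        n_participants = 2000, seed = 14)
    ch <- generateCohort(cfg)
    mm <- measurements(ch$table)
    pairs <- extractPairs(ch$table)
    base <- pairs[pairs$biomarker == "A", "baseline_value"]
    expect_lt(abs(mean(base) - 100), 3 * 20 / sqrt(2000))
    expect_lt(abs(sd(base) - 20), 3 * 20 / sqrt(2 * 2000))
})

test_that("planted delta correlations appear at their Spearman-converted value", {
    ## 2 blocks of 3, Pearson 0.7 -> Spearman (6/pi) asin(0.35) ~= 0.683
    cfg <- syntheticConfig(LETTERS[1:6],
                           blocks = list(b1 = c("A", "B", "C"),
                                         b2 = c("D", "E", "F")),
                           r_within = 0.7, r_between = 0,
                           n_participants = 2000, seed = 15)
    ch <- generateCohort(cfg)
    e <- correlateAll(deltaMatrix(extractPairs(ch$table)))
    target <- spearmanFromPearson(0.7)
    expect_equal(target, (6 / pi) * asin(0.35))
    same_block <- with(ch$truth,
        blocks[e$biomarker_a] == blocks[e$biomarker_b] &
        blocks[e$biomarker_a] > 0)
    expect_true(all(abs(e$rho[same_block] - target) < 0.05))
    expect_true(all(abs(e$rho[!same_block]) < 0.1))
    rep <- validateTruth(ch$truth, entries = e)
    expect_lt(rep$correlation$mean_abs_error, 0.05)
})

test_that("planted correlation recovery holds over random block configs", {
    set.seed(16)
    for (i in 1:3) {
        r <- runif(1, 0.3, 0.8)
        cfg <- syntheticConfig(sprintf("B%02d", 1:8),
                               blocks = list(x = sprintf("B%02d", 1:4)),
                               r_within = r, n_participants = 2000,
                               seed = 160 + i)
        ch <- generateCohort(cfg)
        e <- correlateAll(deltaMatrix(extractPairs(ch$table)))
        rep <- validateTruth(ch$truth, entries = e)
        expect_lt(rep$correlation$max_abs_error, 0.08)
    }
})

test_that("intervention choices are boosted by out-of-range status", {
    iv <- data.frame(intervention_id = "vitd_supp", biomarker = "VITD",
                     shift = 8, base_rate = 0.1)
    cfg <- syntheticConfig(
        data.frame(biomarker = "VITD", baseline_mean = 30,
                   baseline_sd = 8, delta_sd = 8, seasonal_offset = 0),
        n_participants = 4000, intervention_effects = iv,
        choice_oor_boost = 1.5, seed = 17)
    ch <- generateCohort(cfg)
    pairs <- extractPairs(ch$table)
    fl <- flagOutOfRange(pairs, cfg@range_rules,
                         participants(ch$table))
    chose <- fl$participant_id %in% ch$choices$participant_id
    rate_oor <- mean(chose[fl$out_of_range])
    rate_in <- mean(chose[!fl$out_of_range])
    expect_gt(rate_oor, rate_in + 0.05)
    ## choosers' deltas carry the planted shift
    expect_gt(mean(fl$delta[chose]) - mean(fl$delta[!chose]), 4)
})

test_that("truth validation scores clusterings and flags foreign biomarkers", {
    truth <- list(blocks = c(A = 1L, B = 1L, C = 2L, D = 2L),
                  spearman_within = 0.68, spearman_between = 0,
                  seasonal_offsets = c(A = 0, B = 0, C = 0, D = 0),
                  intervention_effects = data.frame())
    perfect <- c(A = 5L, B = 5L, C = 9L, D = 9L)  # relabeled truth
    expect_equal(validateTruth(truth, clusters = perfect)$ari, 1)
    allsame <- c(A = 1L, B = 1L, C = 1L, D = 1L)
    expect_equal(validateTruth(truth, clusters = allsame)$ari, 0)
    bad <- data.frame(biomarker_a = "ZZ", biomarker_b = "A",
                      rho = 0.5, n = 10L, p = 0.1, q = 0.2)
    expect_error(validateTruth(truth, entries = bad), "absent")
})

test_that("null cohorts show no spurious correlation structure", {
    cfg <- syntheticConfig(sprintf("B%02d", 1:10), n_participants = 1000,
                           seed = 18)
    ch <- generateCohort(cfg)
    e <- correlateAll(deltaMatrix(extractPairs(ch$table)))
    expect_lt(mean(abs(e$rho)), 0.1)
})
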