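## Block-structured Pearson correlation matrix implied by a config:
## r_within inside a block, r_between across distinct blocks, zero for
## biomarkers outside any block.
.deltaCorrelationMatrix <- function(biomarkers, blocks, r_within,
                                    r_between) {
    m <- length(biomarkers)
    block_of <- setNames(rep(0L, m), biomarkers)
    for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
    R <- matrix(0, m, m, dimnames = list(biomarkers, biomarkers))
    same <- outer(block_of, block_of, "==") & block_of > 0
    both_blocked <- outer(block_of > 0, block_of > 0, "&")
    R[both_blocked & !same] <- r_between
    R[same] <- r_within
    diag(R) <- 1
    R
}

#' Expected Spearman correlation of a bivariate normal
#'
#' For deltas drawn from a bivariate normal with Pearson correlation `r`,
#' the population Spearman correlation is `(6 / pi) * asin(r / 2)`. The
#' generator plants Pearson correlations, so truth-recovery checks compare
#' estimated Spearman coefficients against this transform, not against `r`
#' itself.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @return the corresponding Spearman correlation(s).
#' @export
spearmanFromPearson <- function(r) (6 / pi) * asin(r / 2)

#' Construct a synthetic-cohort configuration
#'
#' Builds and validates a \linkS4class{SyntheticCohortConfig}. The implied
#' delta correlation matrix (blocks at `r_within`, cross-block `r_between`,
#' independence outside blocks) is checked for positive semi-definiteness
#' before any sampling.
#'
#' @param biomarkers data.frame with columns `biomarker`, `baseline_mean`,
#'   `baseline_sd`, `delta_sd`, `seasonal_offset`; or a character vector of
#'   codes (standard-normal baselines, unit delta SD, no seasonality).
#' @param blocks named list of character vectors (disjoint biomarker
#'   blocks).
#' @param r_within,r_between Pearson delta correlations within / between
#'   blocks.
#' @param panels named list of `list(biomarkers=, weight=)`; default one
#'   full panel.
#' @param n_participants cohort size.
#' @param summer_fraction probability a baseline draw date falls in a
#'   summer month (default 0.33, roughly the uniform-calendar value).
#' @param summer_months months treated as summer (default June-September).
#' @param gap_meanlog,gap_sdlog log-normal parameters of the extra
#'   test-retest gap in days beyond `min_gap_days` (default median 90,
#'   right-skewed).
#' @param min_gap_days minimum gap (default 30).
#' @param intervention_effects data.frame `intervention_id`, `biomarker`
#'   (`NA` for inert), `shift` (additive delta in choosers), optional
#'   `base_rate`.
#' @param choice_base_rate default per-intervention choice probability.
#' @param choice_oor_boost log-odds boost to choosing an intervention whose
#'   target biomarker is out of range at baseline.
#' @param range_rules \linkS4class{RangeRuleSet} used by the choice model.
#' @param year calendar year of baseline dates.
#' @param seed integer seed.
#' @return A validated `SyntheticCohortConfig`.
#' @export
syntheticConfig <- function(biomarkers, blocks = list(), r_within = 0,
                            r_between = 0, panels = NULL,
                            n_participants = 100, summer_fraction = 0.33,
                            summer_months = 6:9,
                            gap_meanlog = log(90), gap_sdlog = 0.6,
                            min_gap_days = 30,
                            intervention_effects = NULL,
                            choice_base_rate = 0.1,
                            choice_oor_boost = 1,
                            range_rules = NULL, year = 2016, seed = 1) {
    if (is.character(biomarkers))
        biomarkers <- data.frame(biomarker = biomarkers,
                                 baseline_mean = 0, baseline_sd = 1,
                                 delta_sd = 1, seasonal_offset = 0,
                                 stringsAsFactors = FALSE)
    if (is.null(panels))
        panels <- list(full = list(biomarkers = biomarkers$biomarker,
                                   weight = 1))
    if (is.null(intervention_effects))
        intervention_effects <- data.frame(intervention_id = character(),
                                           biomarker = character(),
                                           shift = numeric(),
                                           base_rate = numeric(),
                                           stringsAsFactors = FALSE)
    if (!"base_rate" %in% names(intervention_effects))
        intervention_effects$base_rate <- NA_real_
    if (is.null(range_rules))
        range_rules <- loadRangeRules()
    new("SyntheticCohortConfig",
        biomarkers = biomarkers, blocks = blocks,
        r_within = r_within, r_between = r_between, panels = panels,
        n_participants = as.integer(n_participants),
        summer_fraction = summer_fraction,
        summer_months = as.integer(summer_months),
        gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
        min_gap_days = min_gap_days,
        intervention_effects = intervention_effects,
        choice_base_rate = choice_base_rate,
        choice_oor_boost = choice_oor_boost,
        range_rules = range_rules,
        year = as.integer(year), seed = as.integer(seed))
}

## plausibility-level marginals for the 40-biomarker full panel
.fullCohortBiomarkers <- function() {
    spec <- rbind(
        c("VITD", 32, 8), c("LDL", 110, 30), c("CK", 160, 60),
        c("GLU", 90, 10), c("HDL", 55, 14), c("CHOL", 190, 35),
        c("ALT", 26, 9), c("TG", 110, 45), c("CORT", 14, 4.5),
        c("FERR", 100, 40), c("HSCRP", 2.2, 0.9), c("AST", 24, 8),
        c("TESTO", 500, 150), c("EOS", 160, 60), c("MCHC", 33.5, 1.1),
        c("SHBG", 40, 14), c("FTESTO", 70, 22), c("WBC", 6.5, 1.6),
        c("NEUT", 3.8, 1.2), c("LYMPH", 2.0, 0.6), c("MONO", 0.5, 0.15),
        c("BASO", 0.05, 0.02), c("RBC", 4.8, 0.4), c("HGB", 14.5, 1.3),
        c("HCT", 43, 3.5), c("MCV", 89, 4.5), c("MCH", 30, 2),
        c("PLT", 250, 55), c("RDW", 13.2, 0.9), c("SODIUM", 140, 2.2),
        c("POTASSIUM", 4.3, 0.35), c("CALCIUM", 9.5, 0.4),
        c("MAGNESIUM", 2.05, 0.18), c("B12", 550, 170),
        c("FOLATE", 15, 4.5), c("IRON", 100, 33), c("TIBC", 320, 45),
        c("TSAT", 30, 10), c("DHEAS", 200, 70), c("TSH", 1.8, 0.6))
    out <- data.frame(biomarker = spec[, 1],
                      baseline_mean = as.numeric(spec[, 2]),
                      baseline_sd = as.numeric(spec[, 3]),
                      stringsAsFactors = FALSE)
    out$delta_sd <- 0.8 * out$baseline_sd
    out$delta_sd[out$biomarker == "VITD"] <- 8
    out$seasonal_offset <- ifelse(out$biomarker == "VITD",
                                  loadSeasonalDefaults()$offset, 0)
    out
}

.fullCohortBlocks <- function() {
    list(lipids = c("LDL", "CHOL", "HDL", "TG"),
         liver_muscle = c("ALT", "AST", "CK", "MAGNESIUM"),
         inflammation = c("HSCRP", "WBC", "NEUT", "LYMPH", "MONO"),
         iron = c("FERR", "IRON", "TSAT", "TIBC"),
         red_cells = c("RBC", "HGB", "HCT", "MCV", "MCH", "MCHC"),
         hormones = c("TESTO", "FTESTO", "SHBG", "DHEAS"))
}

.fullCohortPanels <- function(bm) {
    cbc <- c("WBC", "NEUT", "LYMPH", "MONO", "BASO", "EOS", "RBC", "HGB",
             "HCT", "MCV", "MCH", "MCHC", "PLT", "RDW")
    lipid_met <- c("LDL", "HDL", "CHOL", "TG", "GLU", "VITD", "HSCRP")
    list(
        ultimate = list(biomarkers = bm, weight = 0.35),
        performance = list(
            biomarkers = unique(c(lipid_met, cbc, "ALT", "AST", "CK",
                                  "MAGNESIUM", "CORT", "TESTO", "VITD",
                                  "FERR", "IRON", "TSAT", "TIBC", "B12",
                                  "FOLATE")),
            weight = 0.2),
        vitality = list(
            biomarkers = c(lipid_met, "FERR", "B12", "FOLATE", "TSH",
                           "CORT", "DHEAS"),
            weight = 0.12),
        essentials = list(biomarkers = lipid_met, weight = 0.12),
        metabolism = list(
            biomarkers = c("GLU", "TG", "HDL", "LDL", "CHOL", "SODIUM",
                           "POTASSIUM", "CALCIUM", "MAGNESIUM"),
            weight = 0.08),
        blood_basics = list(biomarkers = cbc, weight = 0.08),
        hormone = list(
            biomarkers = c("TESTO", "FTESTO", "SHBG", "DHEAS", "CORT",
                           "TSH"),
            weight = 0.05))
}

.fullCohortInterventions <- function() {
    data.frame(
        intervention_id = c("oatmeal", "vitamin_d_supplement", "green_tea",
                            "fish_oil", "dairy", "exercise_program",
                            "multivitamin", "meditation", "sleep_hygiene",
                            "probiotics", "magnesium_supplement",
                            "b12_supplement"),
        biomarker = c("LDL", "VITD", "LDL", "TG", "LDL", NA, NA, NA, NA,
                      NA, "MAGNESIUM", "B12"),
        shift = c(-8, 8, -5, -15, -4, 0, 0, 0, 0, 0, 0.08, 60),
        base_rate = c(0.25, 0.2, 0.18, 0.15, 0.15, 0.12, 0.1, 0.08, 0.08,
                      0.06, 0.06, 0.05),
        stringsAsFactors = FALSE)
}

#' Built-in synthetic cohort presets
#'
#' `"full"`: 40 biomarkers with plausible clinical marginals, ~1000
#' participants, 7 overlapping panels, six correlated blocks
#' (`r_within = 0.5`), a 2.5-unit summer offset on vitamin D, and a dozen
#' interventions (five with planted delta shifts). `"tiny"`: 6 biomarkers
#' in two blocks (`r_within = 0.7`), 50 participants, one panel — runs the
#' full pipeline in seconds. `"null"`: the full panel with every
#' planted correlation, offset and intervention effect set to zero.
#'
#' @param name preset name.
#' @param seed integer seed stored in the config.
#' @return A \linkS4class{SyntheticCohortConfig}.
#' @export
syntheticPreset <- function(name = c("full", "tiny", "null"),
                            seed = 1) {
    if (!is.character(name) || !name[1] %in% c("full", "tiny", "null"))
        stop("unknown preset '", name[1],
             "'; available: full, tiny, null")
    name <- match.arg(name)
    if (name == "full") {
        bm <- .fullCohortBiomarkers()
        return(syntheticConfig(
            biomarkers = bm, blocks = .fullCohortBlocks(),
            r_within = 0.5, r_between = 0,
            panels = .fullCohortPanels(bm$biomarker),
            n_participants = 1000,
            intervention_effects = .fullCohortInterventions(),
            choice_base_rate = 0.1, choice_oor_boost = 1,
            seed = seed))
    }
    if (name == "null") {
        bm <- .fullCohortBiomarkers()
        bm$seasonal_offset <- 0
        iv <- .fullCohortInterventions()
        iv$shift <- 0
        return(syntheticConfig(
            biomarkers = bm, blocks = list(), r_within = 0, r_between = 0,
            panels = .fullCohortPanels(bm$biomarker),
            n_participants = 1000, intervention_effects = iv,
            choice_oor_boost = 0, seed = seed))
    }
    ## tiny: two 3-biomarker blocks, strong correlation, single panel
    bm <- .fullCohortBiomarkers()
    bm <- bm[bm$biomarker %in% c("VITD", "LDL", "CHOL", "TG", "ALT",
                                 "AST"), ]
    syntheticConfig(
        biomarkers = bm,
        blocks = list(lipids = c("LDL", "CHOL", "TG"),
                      liver = c("ALT", "AST")),
        r_within = 0.7, r_between = 0,
        n_participants = 50,
        intervention_effects = .fullCohortInterventions()[1:4, ],
        seed = seed)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort from a \linkS4class{SyntheticCohortConfig}: each
#' participant is assigned a panel; baselines are independent normals per
#' biomarker; deltas come from the block-structured multivariate normal;
#' intervention choices follow a logistic model boosted by baseline
#' out-of-range status, and chosen interventions add their planted shift to
#' the targeted biomarker's delta; measurements drawn in summer months gain
#' the biomarker's seasonal offset. Two dated measurements are emitted per
#' covered biomarker. The generator is a deterministic function of the
#' config (including its seed) and leaves the caller's RNG state untouched.
#'
#' @param config a `SyntheticCohortConfig`.
#' @return list with `table` (a \linkS4class{MeasurementTable}), `choices`
#'   (data.frame `participant_id`, `intervention_id`), and `truth` — a
#'   machine-readable record of everything planted: block labels, planted
#'   Pearson and implied Spearman correlations, seasonal offsets,
#'   intervention effects, and per-participant panel assignment.
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "SyntheticCohortConfig"))
    validObject(config)
    .withSeed(config@seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
    bm <- config@biomarkers
    n <- config@n_participants
    m <- nrow(bm)
    truth <- list(
        blocks = {
            lab <- setNames(rep(0L, m), bm$biomarker)
            for (b in seq_along(config@blocks))
                lab[config@blocks[[b]]] <- b
            lab
        },
        r_within = config@r_within, r_between = config@r_between,
        spearman_within = spearmanFromPearson(config@r_within),
        spearman_between = spearmanFromPearson(config@r_between),
        seasonal_offsets = setNames(bm$seasonal_offset, bm$biomarker),
        summer_months = config@summer_months,
        intervention_effects = config@intervention_effects,
        n_participants = n, seed = config@seed)
    if (n == 0L) {
        tab <- measurementTable(
            data.frame(participant_id = character(),
                       biomarker = character(), value = numeric(),
                       draw_date = as.Date(character())))
        truth$panel <- setNames(character(), character())
        return(list(table = tab,
                    choices = data.frame(participant_id = character(),
                                         intervention_id = character()),
                    truth = truth))
    }
    ids <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(runif(n) < 0.65, "male", "female")
    age <- pmax(18, round(rnorm(n, 42, 11)))
    bmi0 <- round(rnorm(n, ifelse(sex == "male", 25.2, 22.3), 3.2), 1)
    bmi1 <- round(bmi0 + rnorm(n, -0.2, 1.0), 1)
    participants <- data.frame(participant_id = ids, sex = sex,
                               age_years = age, bmi_baseline = bmi0,
                               bmi_followup = bmi1,
                               stringsAsFactors = FALSE)
    ## panels
    pw <- vapply(config@panels, `[[`, numeric(1), "weight")
    panel <- sample(names(config@panels), n, replace = TRUE,
                    prob = pw / sum(pw))
    truth$panel <- setNames(panel, ids)
    ## draw dates: baseline season chosen by summer_fraction, day uniform
    ## within season; follow-up = baseline + min gap + log-normal extra
    year0 <- as.Date(sprintf("%d-01-01", config@year))
    days <- seq(year0, by = "day", length.out = 365)
    in_summer <- .isSummer(days, config@summer_months)
    take_summer <- runif(n) < config@summer_fraction
    base_date <- as.Date(ifelse(
        take_summer,
        sample(days[in_summer], n, replace = TRUE),
        sample(days[!in_summer], n, replace = TRUE)),
        origin = "1970-01-01")
    gap <- config@min_gap_days +
        ceiling(rlnorm(n, config@gap_meanlog, config@gap_sdlog))
    fu_date <- base_date + gap
    ## core values
    base_core <- matrix(rnorm(n * m), n, m) %*%
        diag(bm$baseline_sd, m) +
        matrix(bm$baseline_mean, n, m, byrow = TRUE)
    R <- .deltaCorrelationMatrix(bm$biomarker, config@blocks,
                                 config@r_within, config@r_between)
    Sigma <- diag(bm$delta_sd, m) %*% R %*% diag(bm$delta_sd, m)
    delta_core <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = Sigma)
    if (n == 1L) delta_core <- matrix(delta_core, 1L, m)
    colnames(base_core) <- colnames(delta_core) <- bm$biomarker
    ## seasonal offsets on measured values
    seas <- matrix(bm$seasonal_offset, n, m, byrow = TRUE)
    base_meas <- base_core +
        seas * .isSummer(base_date, config@summer_months)
    ## out-of-range status of the measured baseline (per the range rules)
    rules <- config@range_rules@rules
    oor <- matrix(FALSE, n, m, dimnames = list(NULL, bm$biomarker))
    ri <- match(bm$biomarker, rules$biomarker)
    for (j in which(!is.na(ri))) {
        rr <- rules[ri[j], ]
        thr <- ifelse(sex == "female", rr$threshold_female,
                      rr$threshold_male)
        oor[, j] <- if (rr$direction == "high") base_meas[, j] > thr
                    else base_meas[, j] < thr
    }
    ## measured = panel coverage mask
    covered <- matrix(FALSE, n, m, dimnames = list(NULL, bm$biomarker))
    for (pn in names(config@panels))
        covered[panel == pn, config@panels[[pn]]$biomarkers] <- TRUE
    ## intervention choices: logistic in out-of-range status of the target
    iv <- config@intervention_effects
    choice <- matrix(FALSE, n, nrow(iv))
    if (nrow(iv)) {
        for (k in seq_len(nrow(iv))) {
            rate <- iv$base_rate[k]
            if (is.na(rate)) rate <- config@choice_base_rate
            boost <- if (!is.na(iv$biomarker[k]) &&
                         iv$biomarker[k] %in% bm$biomarker)
                config@choice_oor_boost *
                    (oor[, iv$biomarker[k]] &
                     covered[, iv$biomarker[k]])
            else 0
            pr <- stats::plogis(stats::qlogis(rate) + boost)
            choice[, k] <- runif(n) < pr
        }
    }
    ## intervention shifts land on the targeted biomarker's delta
    shift <- matrix(0, n, m, dimnames = list(NULL, bm$biomarker))
    if (nrow(iv)) {
        for (k in seq_len(nrow(iv))) {
            tgt <- iv$biomarker[k]
            if (!is.na(tgt) && tgt %in% bm$biomarker)
                shift[choice[, k], tgt] <- shift[choice[, k], tgt] +
                    iv$shift[k]
        }
    }
    fu_meas <- base_core + delta_core + shift +
        seas * .isSummer(fu_date, config@summer_months)
    ## long format, panel-masked
    idx <- which(covered, arr.ind = TRUE)
    meas <- rbind(
        data.frame(participant_id = ids[idx[, 1]],
                   biomarker = bm$biomarker[idx[, 2]],
                   value = base_meas[idx],
                   draw_date = base_date[idx[, 1]],
                   stringsAsFactors = FALSE),
        data.frame(participant_id = ids[idx[, 1]],
                   biomarker = bm$biomarker[idx[, 2]],
                   value = fu_meas[idx],
                   draw_date = fu_date[idx[, 1]],
                   stringsAsFactors = FALSE))
    choices <- if (nrow(iv) && any(choice)) {
        ci <- which(choice, arr.ind = TRUE)
        out <- data.frame(participant_id = ids[ci[, 1]],
                          intervention_id = iv$intervention_id[ci[, 2]],
                          stringsAsFactors = FALSE)
        out <- out[order(out$participant_id, out$intervention_id), ]
        rownames(out) <- NULL
        out
    } else data.frame(participant_id = character(),
                      intervention_id = character(),
                      stringsAsFactors = FALSE)
    list(table = measurementTable(meas, participants),
         choices = choices, truth = truth)
}

#' Score analysis outputs against the planted truth
#'
#' Compares downstream analysis results with the truth record emitted by
#' [generateCohort()]: planted-vs-estimated Spearman correlation error (the
#' planted Pearson values are converted with [spearmanFromPearson()]),
#' cluster recovery as the adjusted Rand index against the planted block
#' labels, seasonal-offset estimation error, and per-intervention detection
#' status (nominal `p_mc < 0.05` for interventions with a planted nonzero
#' shift).
#'
#' @param truth truth record from [generateCohort()].
#' @param entries optional correlation table from [correlateAll()].
#' @param clusters optional assignment from [dynamicTreeCut()].
#' @param seasonal optional model from [fitSeasonalModel()].
#' @param scan optional results from [interventionScan()].
#' @return list of recovery summaries (components present for the outputs
#'   supplied): `correlation` (mean/max absolute error, per-pair table),
#'   `ari`, `seasonal_error`, `interventions`.
#' @export
validateTruth <- function(truth, entries = NULL, clusters = NULL,
                          seasonal = NULL, scan = NULL) {
    stopifnot(is.list(truth), !is.null(truth$blocks))
    report <- list()
    if (!is.null(entries)) {
        unknown <- setdiff(unique(c(entries$biomarker_a,
                                    entries$biomarker_b)),
                           names(truth$blocks))
        if (length(unknown))
            stop("correlation table references biomarker(s) absent from ",
                 "the truth record: ", paste(unknown, collapse = ", "))
        ba <- truth$blocks[entries$biomarker_a]
        bb <- truth$blocks[entries$biomarker_b]
        expected <- ifelse(ba > 0 & ba == bb, truth$spearman_within,
                    ifelse(ba > 0 & bb > 0, truth$spearman_between, 0))
        err <- entries$rho - expected
        report$correlation <- list(
            mean_abs_error = mean(abs(err)),
            max_abs_error = max(abs(err)),
            table = data.frame(biomarker_a = entries$biomarker_a,
                               biomarker_b = entries$biomarker_b,
                               rho = entries$rho, expected = expected,
                               stringsAsFactors = FALSE))
    }
    if (!is.null(clusters)) {
        shared <- intersect(names(clusters), names(truth$blocks))
        if (!length(shared))
            stop("cluster assignment shares no biomarkers with the truth ",
                 "record")
        ## biomarkers outside any planted block are their own singletons
        ref <- truth$blocks[shared]
        singles <- ref == 0
        ref[singles] <- max(ref) + seq_len(sum(singles))
        report$ari <- mclust::adjustedRandIndex(as.integer(clusters[shared]),
                                                as.integer(ref))
    }
    if (!is.null(seasonal)) {
        planted <- truth$seasonal_offsets[seasonal$biomarker]
        if (is.na(planted))
            stop("seasonal model biomarker absent from the truth record: ",
                 seasonal$biomarker)
        report$seasonal_error <- unname(seasonal$offset_estimate - planted)
    }
    if (!is.null(scan)) {
        iv <- truth$intervention_effects
        active <- iv[!is.na(iv$biomarker) & iv$shift != 0, , drop = FALSE]
        hit <- merge(active, scan,
                     by.x = c("intervention_id", "biomarker"),
                     by.y = c("intervention_id", "biomarker"))
        report$interventions <- data.frame(
            intervention_id = hit$intervention_id,
            biomarker = hit$biomarker, shift = hit$shift,
            p_mc = hit$p_mc,
            detected = !is.na(hit$p_mc) & hit$p_mc < 0.05,
            stringsAsFactors = FALSE)
    }
    report
}
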