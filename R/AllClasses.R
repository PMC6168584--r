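#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats aggregate approx complete.cases cor hclust as.dist
#'   as.dendrogram is.leaf lm median pchisq pnorm pt quantile rbinom rlnorm
#'   rnorm runif sd setNames var coef qnorm
#' @importFrom utils read.csv write.csv head packageVersion
NULL

## Columns every measurement table must carry, in canonical order.
.MEASUREMENT_COLS <- c("participant_id", "biomarker", "value", "draw_date")
.PARTICIPANT_COLS <- c("participant_id", "sex", "age_years",
                       "bmi_baseline", "bmi_followup")

#' MeasurementTable: long-format longitudinal biomarker observations
#'
#' Container for a longitudinal biomarker cohort: one row of `measurements`
#' per (participant, biomarker, draw date) triple, plus a participant table
#' with demographics. Validity enforces finiteness of values, uniqueness of
#' the (participant, biomarker, date) key, and referential integrity of
#' participant identifiers.
#'
#' @slot measurements data.frame with columns `participant_id`, `biomarker`,
#'   `value` (numeric, native units), `draw_date` (`Date`).
#' @slot participants data.frame with columns `participant_id`, `sex`
#'   (`"male"`, `"female"` or `NA`), `age_years`, and optional
#'   `bmi_baseline` / `bmi_followup`.
#'
#' @seealso [readMeasurements()], [extractPairs()]
#' @export
setClass("MeasurementTable",
         representation(measurements = "data.frame",
                        participants = "data.frame"))

setValidity("MeasurementTable", function(object) {
    m <- object@measurements
    p <- object@participants
    msgs <- character()
    missing_cols <- setdiff(.MEASUREMENT_COLS, names(m))
    if (length(missing_cols))
        msgs <- c(msgs, paste("measurements missing column(s):",
                              paste(missing_cols, collapse = ", ")))
    if (!"participant_id" %in% names(p))
        msgs <- c(msgs, "participants missing column participant_id")
    if (length(msgs)) return(msgs)
    if (nrow(m)) {
        if (!is.numeric(m$value) || any(!is.finite(m$value)))
            msgs <- c(msgs, "measurement values must be finite numbers")
        if (!inherits(m$draw_date, "Date"))
            msgs <- c(msgs, "draw_date must be of class Date")
        key <- paste(m$participant_id, m$biomarker, m$draw_date, sep = "\r")
        if (anyDuplicated(key)) {
            dup <- which(duplicated(key))
            msgs <- c(msgs, paste0(
                "duplicate (participant, biomarker, draw_date) rows: ",
                paste(head(dup, 5L), collapse = ", "),
                if (length(dup) > 5L) " ..."))
        }
        unknown <- setdiff(unique(m$participant_id), p$participant_id)
        if (length(unknown))
            msgs <- c(msgs, paste0("measurements reference unknown participant(s): ",
                                   paste(head(unknown, 5L), collapse = ", ")))
    }
    if (nrow(p) && anyDuplicated(p$participant_id))
        msgs <- c(msgs, "participant_id must be unique in the participant table")
    if (nrow(p) && "sex" %in% names(p)) {
        bad <- !is.na(p$sex) & !p$sex %in% c("male", "female")
        if (any(bad))
            msgs <- c(msgs, "sex must be 'male', 'female' or NA")
    }
    if (length(msgs)) msgs else TRUE
})

#' RangeRuleSet: per-biomarker direction-of-risk thresholds
#'
#' Clinical reference-range rules. Each biomarker has one rule giving the
#' direction in which values are considered at risk (`"high"` or `"low"`) and
#' the threshold past which a value is out of range, possibly sex-specific.
#' Thresholds are strict: a value exactly at the threshold is in range.
#'
#' @slot rules data.frame with columns `biomarker`, `direction` ("high" or
#'   "low"), `threshold_male`, `threshold_female`, `units`,
#'   `sex_stratified` (logical: analyse this biomarker separately by sex).
#'
#' @seealso [loadRangeRules()], [flagOutOfRange()]
#' @export
setClass("RangeRuleSet", representation(rules = "data.frame"))

setValidity("RangeRuleSet", function(object) {
    r <- object@rules
    need <- c("biomarker", "direction", "threshold_male", "threshold_female",
              "units", "sex_stratified")
    missing_cols <- setdiff(need, names(r))
    if (length(missing_cols))
        return(paste("rules missing column(s):",
                     paste(missing_cols, collapse = ", ")))
    msgs <- character()
    if (anyDuplicated(r$biomarker))
        msgs <- c(msgs, "exactly one rule per biomarker is allowed")
    if (nrow(r) && !all(r$direction %in% c("high", "low")))
        msgs <- c(msgs, "direction must be 'high' or 'low'")
    if (nrow(r) && (!is.numeric(r$threshold_male) ||
                    !is.numeric(r$threshold_female) ||
                    any(!is.finite(r$threshold_male)) ||
                    any(!is.finite(r$threshold_female))))
        msgs <- c(msgs, "thresholds must be finite numbers")
    if (length(msgs)) msgs else TRUE
})

#' DeltaMatrix: biomarkers x participants matrix of longitudinal changes
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay,
#' `"delta"`, holds follow-up minus baseline changes: rows are biomarkers,
#' columns are participants, and an entry is `NA` exactly when the
#' participant has no quality-passing longitudinal pair for that biomarker
#' (panel-based missingness). Participant demographics travel in `colData`.
#'
#' @seealso [deltaMatrix()], [correlateAll()]
#' @export
setClass("DeltaMatrix", contains = "SummarizedExperiment")

setValidity("DeltaMatrix", function(object) {
    if (!"delta" %in% SummarizedExperiment::assayNames(object))
        return("DeltaMatrix requires an assay named 'delta'")
    a <- SummarizedExperiment::assay(object, "delta")
    if (!is.numeric(a))
        return("'delta' assay must be numeric")
    if (any(is.infinite(a)))
        return("'delta' assay must not contain infinite values")
    TRUE
})

#' CorrelationNetwork: significant biomarker-change correlations
#'
#' The biomarker-change correlation network: nodes are biomarkers (isolated
#' nodes are retained), edges are the pairwise Spearman correlation entries
#' whose Benjamini-Hochberg adjusted p-value is below `alpha`. Edge weight is
#' the signed correlation coefficient.
#'
#' @slot nodes character vector of biomarker codes.
#' @slot edges data.frame with columns `biomarker_a`, `biomarker_b`, `rho`,
#'   `n`, `p`, `q`.
#' @slot alpha numeric significance level applied to q-values.
#'
#' @seealso [buildNetwork()], [neighborhood()], [asIgraph()]
#' @export
setClass("CorrelationNetwork",
         representation(nodes = "character", edges = "data.frame",
                        alpha = "numeric"))

setValidity("CorrelationNetwork", function(object) {
    e <- object@edges
    need <- c("biomarker_a", "biomarker_b", "rho", "n", "p", "q")
    missing_cols <- setdiff(need, names(e))
    if (length(missing_cols))
        return(paste("edges missing column(s):",
                     paste(missing_cols, collapse = ", ")))
    msgs <- character()
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
        msgs <- c(msgs, "alpha must be a single value in (0, 1]")
    if (nrow(e)) {
        if (any(e$biomarker_a == e$biomarker_b))
            msgs <- c(msgs, "self-loops are not allowed")
        if (!all(c(e$biomarker_a, e$biomarker_b) %in% object@nodes))
            msgs <- c(msgs, "edge endpoints must be nodes")
        if (any(e$q >= object@alpha))
            msgs <- c(msgs, "all edges must satisfy q < alpha")
        if (any(abs(e$rho) > 1 + 1e-12))
            msgs <- c(msgs, "correlation coefficients must lie in [-1, 1]")
    }
    if (length(msgs)) msgs else TRUE
})

#' SyntheticCohortConfig: generative specification for a synthetic cohort
#'
#' Full specification of the synthetic-cohort generator: per-biomarker
#' baseline and change distributions, a block structure for delta
#' correlations, panel-based missingness, draw-date and seasonality model,
#' and intervention-choice effects. The implied delta correlation matrix is
#' validated to be positive semi-definite at construction, before any
#' sampling.
#'
#' @slot biomarkers data.frame: `biomarker`, `baseline_mean`, `baseline_sd`,
#'   `delta_sd`, `seasonal_offset` (additive shift applied to measurements
#'   drawn in summer months; 0 for non-seasonal biomarkers).
#' @slot blocks named list of character vectors partitioning a subset of the
#'   biomarkers into correlated blocks; biomarkers in no block have
#'   independent deltas.
#' @slot r_within,r_between numeric Pearson correlations of deltas within a
#'   block and between blocks.
#' @slot panels named list; each element is a list with `biomarkers`
#'   (character) and `weight` (sampling probability weight). Panels must
#'   jointly cover every biomarker.
#' @slot n_participants integer cohort size.
#' @slot summer_fraction numeric probability that a baseline draw date falls
#'   in a summer month (June-September).
#' @slot summer_months integer months treated as summer.
#' @slot gap_meanlog,gap_sdlog numeric log-normal parameters of the
#'   baseline-to-follow-up gap (days) added to `min_gap_days`.
#' @slot min_gap_days numeric minimum test-retest gap.
#' @slot intervention_effects data.frame: `intervention_id`, `biomarker`,
#'   `shift` (additive delta shift in choosers; biomarker NA for inert
#'   interventions).
#' @slot choice_base_rate numeric baseline probability of choosing each
#'   intervention.
#' @slot choice_oor_boost numeric log-odds increase in the choice probability
#'   when the targeted biomarker is out of range at baseline.
#' @slot range_rules RangeRuleSet used by the choice model.
#' @slot year integer calendar year over which baseline dates are drawn.
#' @slot seed integer random seed; the generator is a deterministic function
#'   of (config, seed).
#'
#' @seealso [syntheticConfig()], [syntheticPreset()], [generateCohort()]
#' @export
setClass("SyntheticCohortConfig",
         representation(biomarkers = "data.frame",
                        blocks = "list",
                        r_within = "numeric",
                        r_between = "numeric",
                        panels = "list",
                        n_participants = "integer",
                        summer_fraction = "numeric",
                        summer_months = "integer",
                        gap_meanlog = "numeric",
                        gap_sdlog = "numeric",
                        min_gap_days = "numeric",
                        intervention_effects = "data.frame",
                        choice_base_rate = "numeric",
                        choice_oor_boost = "numeric",
                        range_rules = "RangeRuleSet",
                        year = "integer",
                        seed = "integer"))

setValidity("SyntheticCohortConfig", function(object) {
    b <- object@biomarkers
    msgs <- character()
    need <- c("biomarker", "baseline_mean", "baseline_sd", "delta_sd",
              "seasonal_offset")
    missing_cols <- setdiff(need, names(b))
    if (length(missing_cols))
        return(paste("biomarkers missing column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(b$biomarker))
        msgs <- c(msgs, "biomarker codes must be unique")
    if (any(b$baseline_sd <= 0) || any(b$delta_sd <= 0))
        msgs <- c(msgs, "baseline_sd and delta_sd must be positive")
    blk <- unlist(object@blocks, use.names = FALSE)
    if (anyDuplicated(blk))
        msgs <- c(msgs, "blocks must be disjoint")
    if (length(setdiff(blk, b$biomarker)))
        msgs <- c(msgs, "blocks reference unknown biomarkers")
    if (abs(object@r_within) >= 1)
        msgs <- c(msgs, "r_within must lie in (-1, 1)")
    covered <- unique(unlist(lapply(object@panels, `[[`, "biomarkers")))
    if (length(setdiff(b$biomarker, covered)))
        msgs <- c(msgs, "panels must cover every biomarker at least once")
    if (length(setdiff(covered, b$biomarker)))
        msgs <- c(msgs, "panels reference unknown biomarkers")
    if (object@summer_fraction < 0 || object@summer_fraction > 1)
        msgs <- c(msgs, "summer_fraction must lie in [0, 1]")
    if (!length(msgs)) {
        R <- .deltaCorrelationMatrix(b$biomarker, object@blocks,
                                     object@r_within, object@r_between)
        ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8)
            msgs <- c(msgs, sprintf(
                "implied delta correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                min(ev)))
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "MeasurementTable", function(object) {
    cat("MeasurementTable:",
        nrow(object@measurements), "measurements,",
        length(unique(object@measurements$biomarker)), "biomarkers,",
        nrow(object@participants), "participants\n")
})

setMethod("show", "RangeRuleSet", function(object) {
    cat("RangeRuleSet with", nrow(object@rules), "rules\n")
    if (nrow(object@rules)) {
        sexed <- sum(object@rules$threshold_male != object@rules$threshold_female)
        cat("  sex-specific thresholds:", sexed, "\n")
    }
})

setMethod("show", "CorrelationNetwork", function(object) {
    cat("CorrelationNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges (q <", object@alpha, ")\n")
})

setMethod("show", "SyntheticCohortConfig", function(object) {
    cat("SyntheticCohortConfig:", nrow(object@biomarkers), "biomarkers,",
        object@n_participants, "participants,",
        length(object@blocks), "correlation blocks,",
        length(object@panels), "panels, seed", object@seed, "\n")
})
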