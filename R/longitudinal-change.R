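.isSummer <- function(dates, summer_months) {
    as.integer(format(dates, "%m")) %in% summer_months
}

#' Flag participants out of clinical range at baseline
#'
#' Applies the direction-of-risk rules: a baseline value is out of range when
#' it lies strictly past the threshold in the risk direction (`> threshold`
#' for direction `"high"`, `< threshold` for `"low"`), with the threshold
#' chosen by the participant's sex where thresholds are sex-specific.
#' Participants of unknown sex are excluded from flagging for sex-specific
#' rules only (logged in the `"excluded"` attribute) and retained elsewhere.
#'
#' @param pairs data.frame of longitudinal pairs (see [extractPairs()]).
#' @param rules a \linkS4class{RangeRuleSet}.
#' @param participants participant data.frame carrying `sex`.
#' @return `pairs` restricted to biomarkers covered by the rules, with added
#'   columns `sex`, `threshold` and logical `out_of_range`; attributes
#'   `"excluded"` (rows dropped for unknown sex under sex-specific rules)
#'   and `"uncovered"` (biomarkers with no rule).
#' @export
flagOutOfRange <- function(pairs, rules, participants) {
    stopifnot(is.data.frame(pairs), is(rules, "RangeRuleSet"))
    r <- rules@rules
    i <- match(pairs$biomarker, r$biomarker)
    uncovered <- unique(pairs$biomarker[is.na(i)])
    out <- pairs[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
    sex <- participants$sex[match(out$participant_id,
                                  participants$participant_id)]
    sex_specific <- r$threshold_male[i] != r$threshold_female[i]
    drop <- sex_specific & (is.na(sex) | !sex %in% c("male", "female"))
    excluded <- out[drop, c("participant_id", "biomarker"), drop = FALSE]
    out <- out[!drop, , drop = FALSE]
    i <- i[!drop]; sex <- sex[!drop]
    thr <- ifelse(!is.na(sex) & sex == "female",
                  r$threshold_female[i], r$threshold_male[i])
    out$sex <- sex
    out$threshold <- thr
    out$out_of_range <- ifelse(r$direction[i] == "high",
                               out$baseline_value > thr,
                               out$baseline_value < thr)
    rownames(out) <- NULL
    attr(out, "excluded") <- excluded
    attr(out, "uncovered") <- uncovered
    out
}

#' Load the default seasonal-adjustment configuration
#'
#' @param path YAML path, or `NULL` for the bundled default (vitamin D,
#'   summer = June-September, offset 2.5).
#' @return list with `biomarker`, `summer_months`, `offset`.
#' @export
loadSeasonalDefaults <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "seasonal_defaults.yaml",
                            package = "biodelta", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    list(biomarker = cfg$biomarker,
         summer_months = as.integer(cfg$summer_months),
         offset = as.numeric(cfg$offset))
}

#' Fit the seasonal (summer) offset model for one biomarker
#'
#' Regresses all of a biomarker's measurements (baseline and follow-up
#' pooled) on a binary summer indicator by ordinary least squares:
#' `value ~ intercept + summer`. The summer coefficient is the estimated
#' seasonal offset.
#'
#' @param values numeric measurement values (pooled across time points).
#' @param dates `Date` vector of the corresponding draw dates.
#' @param biomarker biomarker code recorded in the model.
#' @param summer_months integer months counted as summer (default
#'   June-September).
#' @param min_per_season minimum measurements required in each season
#'   (default 10).
#' @return list with `biomarker`, `summer_months`, `offset_estimate`,
#'   `n_summer`, `n_other`.
#' @export
fitSeasonalModel <- function(values, dates, biomarker = "VITD",
                             summer_months = 6:9, min_per_season = 10) {
    stopifnot(length(values) == length(dates), inherits(dates, "Date"))
    summer <- .isSummer(dates, summer_months)
    if (sum(summer) < min_per_season || sum(!summer) < min_per_season)
        stop("cannot fit seasonal model for ", biomarker, ": need at least ",
             min_per_season, " measurements in each season (have ",
             sum(summer), " summer, ", sum(!summer), " non-summer)")
    fit <- lm(values ~ summer)
    list(biomarker = biomarker,
         summer_months = as.integer(summer_months),
         offset_estimate = unname(coef(fit)["summerTRUE"]),
         n_summer = sum(summer), n_other = sum(!summer))
}

#' Apply a fitted seasonal adjustment to longitudinal pairs
#'
#' Subtracts the fitted summer offset from every baseline or follow-up value
#' of the model's biomarker whose draw date falls in a summer month, and
#' recomputes deltas. Non-summer values are never changed; when both tests
#' fall in summer the delta is unchanged (the offset cancels).
#'
#' @param pairs data.frame of longitudinal pairs.
#' @param model seasonal model from [fitSeasonalModel()].
#' @return the adjusted pairs data.frame.
#' @export
applySeasonalAdjustment <- function(pairs, model) {
    sel <- pairs$biomarker == model$biomarker
    bsum <- sel & .isSummer(pairs$baseline_date, model$summer_months)
    fsum <- sel & .isSummer(pairs$followup_date, model$summer_months)
    pairs$baseline_value[bsum] <- pairs$baseline_value[bsum] -
        model$offset_estimate
    pairs$followup_value[fsum] <- pairs$followup_value[fsum] -
        model$offset_estimate
    pairs$delta <- pairs$followup_value - pairs$baseline_value
    pairs
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test of baseline-to-follow-up change. Zero
#' differences are dropped before ranking (Wilcoxon's treatment; Pratt's
#' method, which ranks zeros before discarding them, is available via
#' `zeroes = "pratt"`). Absolute differences are ranked with average ties.
#' For effective sample sizes up to `exact_limit` the p-value is computed
#' from the exact sign-flip null distribution of the positive-rank sum,
#' conditional on the observed (possibly tied) ranks; beyond that, a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. If every difference is zero the result is "no change": `p = 1`,
#' flagged.
#'
#' @param baseline,followup paired numeric vectors of equal length.
#' @param exact_limit largest effective n for the exact distribution
#'   (default 25).
#' @param zeroes `"wilcox"` (drop zero differences, default) or `"pratt"`.
#' @return list with `statistic` (positive-rank sum W), `p`, `n_effective`,
#'   `method` (`"exact"`, `"normal"`, or `"degenerate"`), and `flag`.
#' @export
wilcoxonSignedRank <- function(baseline, followup, exact_limit = 25,
                               zeroes = c("wilcox", "pratt")) {
    stopifnot(length(baseline) == length(followup), length(baseline) >= 1)
    zeroes <- match.arg(zeroes)
    d <- followup - baseline
    d <- d[is.finite(d)]
    if (!length(d) || all(d == 0))
        return(list(statistic = 0, p = 1, n_effective = 0L,
                    method = "degenerate",
                    flag = "all differences zero: no change"))
    if (zeroes == "wilcox") {
        dnz <- d[d != 0]
        r <- rank(abs(dnz), ties.method = "average")
    } else {
        r_all <- rank(abs(d), ties.method = "average")
        dnz <- d[d != 0]
        r <- r_all[d != 0]
    }
    n <- length(dnz)
    W <- sum(r[dnz > 0])
    if (n <= exact_limit) {
        p <- .signRankExactP(W, r)
        method <- "exact"
    } else {
        mu <- sum(r) / 2
        sigma <- sqrt(sum(r^2) / 4)
        z <- (W - mu - 0.5 * sign(W - mu)) / sigma
        p <- min(1, 2 * pnorm(-abs(z)))
        method <- "normal"
    }
    list(statistic = W, p = p, n_effective = n, method = method,
         flag = NA_character_)
}

## Exact two-sided p for the signed-rank sum by dynamic programming over the
## doubled ranks (average ties make ranks half-integers; doubling restores
## integer support). Enumerates the same distribution as brute-force
## iteration over all 2^n sign patterns.
.signRankExactP <- function(W, r) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)   # index k  <->  doubled rank-sum k - 1
    counts[1L] <- 1
    for (v in r2) {
        shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
        counts <- counts + shifted
    }
    probs <- counts / 2^length(r2)
    w2 <- as.integer(round(2 * W))
    lower <- sum(probs[seq_len(w2 + 1L)])
    upper <- sum(probs[(w2 + 1L):(total + 1L)])
    min(1, 2 * min(lower, upper))
}

#' Paired t-test on before/after values
#'
#' Classical paired t-test (used for BMI change). Identical before/after
#' vectors return a flagged no-change result; zero variance of the
#' differences with a nonzero mean is a degenerate-input error.
#'
#' @param before,after paired numeric vectors.
#' @return list with `mean_change`, `p`, `n`, and `flag`.
#' @export
pairedTTest <- function(before, after) {
    stopifnot(length(before) == length(after))
    ok <- is.finite(before) & is.finite(after)
    before <- before[ok]; after <- after[ok]
    if (length(before) < 2) stop("need at least 2 complete pairs")
    d <- after - before
    if (all(d == 0))
        return(list(mean_change = 0, p = 1, n = length(d),
                    flag = "all differences zero: no change"))
    if (var(d) == 0)
        stop("degenerate input: differences have zero variance")
    tt <- stats::t.test(after, before, paired = TRUE)
    list(mean_change = unname(tt$estimate), p = tt$p.value,
         n = length(d), flag = NA_character_)
}

#' Baseline-to-follow-up change table
#'
#' For each biomarker covered by the range rules, tests the change from
#' baseline to follow-up with the Wilcoxon signed-rank test and reports
#' medians and IQRs of exactly the tested pairs. With
#' `group = "out_of_range"` (default) only participants whose baseline was
#' out of clinical range are tested, and biomarkers with fewer than
#' `min_group` such participants are omitted (listed in the `"omitted"`
#' attribute); `group = "all"` tests the full population. Biomarkers marked
#' `sex_stratified` in the rules are analysed separately by sex, each
#' stratum subject to `min_group`. P-values are not multiplicity-adjusted.
#' Seasonal adjustment, where designated, must be applied to `pairs`
#' beforehand (see [applySeasonalAdjustment()]).
#'
#' @param pairs data.frame of longitudinal pairs.
#' @param rules a \linkS4class{RangeRuleSet}.
#' @param participants participant data.frame carrying `sex`.
#' @param min_group minimum tested group size (default 20).
#' @param group `"out_of_range"` or `"all"`.
#' @return data.frame with one row per qualifying (biomarker, stratum):
#'   `biomarker`, `group`, `stratum`, `n`, `baseline_median`,
#'   `baseline_iqr`, `followup_median`, `followup_iqr`, `p_value`,
#'   `improvement_direction`, `threshold`; attribute `"omitted"` logs
#'   below-threshold groups.
#' @export
outOfRangeChangeTable <- function(pairs, rules, participants,
                                  min_group = 20,
                                  group = c("out_of_range", "all")) {
    group <- match.arg(group)
    flagged <- flagOutOfRange(pairs, rules, participants)
    r <- rules@rules
    rows <- list(); omitted <- list()
    for (k in seq_len(nrow(r))) {
        bm <- r$biomarker[k]
        sub <- flagged[flagged$biomarker == bm, , drop = FALSE]
        if (group == "out_of_range")
            sub <- sub[sub$out_of_range, , drop = FALSE]
        strata <- if (r$sex_stratified[k]) c("male", "female") else "pooled"
        for (st in strata) {
            ss <- if (st == "pooled") sub
                  else sub[!is.na(sub$sex) & sub$sex == st, , drop = FALSE]
            if (nrow(ss) < min_group) {
                omitted[[paste(bm, st)]] <- data.frame(
                    biomarker = bm, stratum = st, n = nrow(ss),
                    stringsAsFactors = FALSE)
                next
            }
            wt <- wilcoxonSignedRank(ss$baseline_value, ss$followup_value)
            rows[[paste(bm, st)]] <- data.frame(
                biomarker = bm, group = group, stratum = st, n = nrow(ss),
                baseline_median = median(ss$baseline_value),
                baseline_iqr = unname(diff(quantile(ss$baseline_value,
                                                    c(0.25, 0.75)))),
                followup_median = median(ss$followup_value),
                followup_iqr = unname(diff(quantile(ss$followup_value,
                                                    c(0.25, 0.75)))),
                p_value = wt$p,
                improvement_direction = if (r$direction[k] == "high")
                    "decrease" else "increase",
                threshold = if (st == "female") r$threshold_female[k]
                            else r$threshold_male[k],
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(biomarker = character(), group = character(),
                   stratum = character(), n = integer(),
                   baseline_median = numeric(), baseline_iqr = numeric(),
                   followup_median = numeric(), followup_iqr = numeric(),
                   p_value = numeric(), improvement_direction = character(),
                   threshold = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "omitted") <- if (length(omitted)) {
        om <- do.call(rbind, omitted); rownames(om) <- NULL; om
    } else data.frame(biomarker = character(), stratum = character(),
                      n = integer(), stringsAsFactors = FALSE)
    out
}

#' Write a change table to CSV
#'
#' @param table data.frame from [outOfRangeChangeTable()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeChangeTable <- function(table, path) {
    write.csv(table, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
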