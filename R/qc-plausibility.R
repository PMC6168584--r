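#' Derive plausibility limits from a reference sample
#'
#' Computes per-biomarker outer limits for acceptable values as percentiles
#' of a reference sample (default the 0.5 and 99.5 percentiles). The
#' percentile definition is linear interpolation between closest order
#' statistics (`quantile(type = 7)`), fixed and documented because
#' percentile conventions differ across ecosystems.
#'
#' Derivation is refused for a biomarker with fewer than `min_reference`
#' values, or whose derived limits are degenerate (lower == upper, e.g. a
#' constant reference sample); other biomarkers proceed, and refusals are
#' listed in the `"errors"` attribute of the result.
#'
#' @param reference_values named list: biomarker -> numeric vector of
#'   reference values.
#' @param lower_pct,upper_pct percentiles (0-100) used as outer limits.
#' @param min_reference minimum reference sample size per biomarker
#'   (default 200).
#' @return data.frame with columns `biomarker`, `lower`, `upper`, `source`
#'   (`"reference_sample"`); attribute `"errors"` is a data.frame of refused
#'   biomarkers and reasons.
#' @export
deriveLimits <- function(reference_values, lower_pct = 0.5,
                         upper_pct = 99.5, min_reference = 200) {
    stopifnot(is.list(reference_values), !is.null(names(reference_values)),
              lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
    rows <- list(); errs <- list()
    for (bm in names(reference_values)) {
        v <- reference_values[[bm]]
        v <- v[is.finite(v)]
        if (length(v) < min_reference) {
            errs[[bm]] <- sprintf(
                "only %d reference values (minimum %d)", length(v),
                min_reference)
            next
        }
        lims <- unname(quantile(v, probs = c(lower_pct, upper_pct) / 100,
                                type = 7, names = FALSE))
        if (!(lims[1] < lims[2])) {
            errs[[bm]] <- "degenerate limits (lower == upper)"
            next
        }
        rows[[bm]] <- data.frame(biomarker = bm, lower = lims[1],
                                 upper = lims[2],
                                 source = "reference_sample",
                                 stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(biomarker = character(), lower = numeric(),
                   upper = numeric(), source = character(),
                   stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "errors") <- if (length(errs))
        data.frame(biomarker = names(errs),
                   reason = unlist(errs, use.names = FALSE),
                   stringsAsFactors = FALSE)
    else data.frame(biomarker = character(), reason = character(),
                    stringsAsFactors = FALSE)
    out
}

#' Load plausibility limits from a config file
#'
#' Reads a YAML/JSON mapping `biomarker: {lower, upper}`. With no argument,
#' loads the bundled synthetic defaults (constructed from the synthetic
#' preset marginals; see the file header of
#' `extdata/plausibility_limits_synthetic.yaml`).
#'
#' @param path config path, or `NULL` for the bundled defaults.
#' @return data.frame with columns `biomarker`, `lower`, `upper`, `source`
#'   (`"config"`).
#' @export
loadLimits <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "plausibility_limits_synthetic.yaml",
                            package = "biodelta", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    rows <- lapply(names(cfg), function(bm) {
        lim <- cfg[[bm]]
        if (!is.numeric(lim$lower) || !is.numeric(lim$upper))
            stop("plausibility config error at '", bm,
                 "': lower and upper must be numeric")
        if (!(lim$lower < lim$upper))
            stop("plausibility config error at '", bm,
                 "': lower must be < upper")
        data.frame(biomarker = bm, lower = lim$lower, upper = lim$upper,
                   source = "config", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Apply plausibility limits to longitudinal pairs
#'
#' Removes a (participant, biomarker) pair when its baseline OR follow-up
#' value lies strictly outside that biomarker's `[lower, upper]` limits.
#' Limits are inclusive: a value exactly at a limit is retained. Removal is
#' always per (participant, biomarker) pair, never whole-participant.
#' Biomarkers with no limits pass through unfiltered, with a warning entry
#' in the report.
#'
#' @param pairs data.frame of longitudinal pairs from [extractPairs()].
#' @param limits data.frame from [deriveLimits()] or [loadLimits()].
#' @return list with `pairs` (the filtered data.frame) and `report` (one row
#'   per biomarker present: `biomarker`, `n_removed`, `n_retained`,
#'   `unfiltered` flag for biomarkers without limits).
#' @export
applyLimits <- function(pairs, limits) {
    stopifnot(is.data.frame(pairs), is.data.frame(limits))
    if (!nrow(pairs))
        return(list(pairs = pairs,
                    report = data.frame(biomarker = character(),
                                        n_removed = integer(),
                                        n_retained = integer(),
                                        unfiltered = logical())))
    i <- match(pairs$biomarker, limits$biomarker)
    has_limits <- !is.na(i)
    lo <- limits$lower[i]; hi <- limits$upper[i]
    out_of_limits <- has_limits &
        (pairs$baseline_value < lo | pairs$baseline_value > hi |
         pairs$followup_value < lo | pairs$followup_value > hi)
    missing_bm <- unique(pairs$biomarker[!has_limits])
    if (length(missing_bm))
        warning("no plausibility limits for biomarker(s): ",
                paste(missing_bm, collapse = ", "),
                "; passed through unfiltered")
    kept <- pairs[!out_of_limits, , drop = FALSE]
    rownames(kept) <- NULL
    bms <- sort(unique(pairs$biomarker))
    report <- data.frame(
        biomarker = bms,
        n_removed = as.integer(tapply(out_of_limits, pairs$biomarker,
                                      sum)[bms]),
        n_retained = as.integer(tapply(!out_of_limits, pairs$biomarker,
                                       sum)[bms]),
        unfiltered = bms %in% missing_bm,
        stringsAsFactors = FALSE)
    rownames(report) <- NULL
    list(pairs = kept, report = report)
}

#' Write a QC exclusion report to CSV
#'
#' @param report the `report` component returned by [applyLimits()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeExclusionReport <- function(report, path) {
    write.csv(report, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
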