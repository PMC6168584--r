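## evaluate expr under a local, restored RNG state when seed is given
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Improvement definitions from range rules
#'
#' Derives the per-biomarker improvement direction from the direction of
#' risk: improvement is a decrease for biomarkers whose risk is high, an
#' increase for those whose risk is low (e.g. any increase in vitamin D, any
#' decrease in LDL).
#'
#' @param rules a \linkS4class{RangeRuleSet}.
#' @param biomarkers biomarkers to include (default: all covered by the
#'   rules).
#' @return data.frame with columns `biomarker`, `improvement`.
#' @export
improvementDefinitions <- function(rules, biomarkers = NULL) {
    r <- rules@rules
    if (!is.null(biomarkers)) {
        unknown <- setdiff(biomarkers, r$biomarker)
        if (length(unknown))
            stop("no range rule for biomarker(s): ",
                 paste(unknown, collapse = ", "))
        r <- r[match(biomarkers, r$biomarker), , drop = FALSE]
    }
    data.frame(biomarker = r$biomarker,
               improvement = ifelse(r$direction == "high",
                                    "decrease", "increase"),
               stringsAsFactors = FALSE)
}

#' Per-participant improvement flags for one biomarker
#'
#' A participant improved when their delta is strictly in the improvement
#' direction; a delta of exactly zero is not improvement.
#'
#' @param pairs data.frame of longitudinal pairs (seasonally adjusted where
#'   designated).
#' @param biomarker biomarker code.
#' @param improvement `"increase"` or `"decrease"`.
#' @return named logical vector indexed by participant_id.
#' @export
improvementFlags <- function(pairs, biomarker,
                             improvement = c("increase", "decrease")) {
    improvement <- match.arg(improvement)
    sub <- pairs[pairs$biomarker == biomarker, , drop = FALSE]
    flags <- if (improvement == "increase") sub$delta > 0 else sub$delta < 0
    setNames(flags, sub$participant_id)
}

#' Pearson chi-square test of a 2x2 table with a Monte-Carlo p-value
#'
#' Classical Pearson chi-square statistic (no continuity correction) with a
#' Monte-Carlo p-value obtained by simulating tables with both margins fixed
#' (multivariate hypergeometric null, via [stats::r2dtable()]):
#' `p_mc = (1 + #(chi2_sim >= chi2_obs)) / (B + 1)`. The asymptotic
#' chi-square(1) p-value is reported alongside for cross-checking.
#'
#' @param table 2x2 integer matrix of counts; all row and column margins
#'   must be positive.
#' @param B number of simulated tables (default 10000).
#' @param seed optional integer seed; the simulation is deterministic given
#'   (table, B, seed) and the caller's RNG state is left untouched.
#' @return list with `chi2`, `p_mc`, `p_asymptotic`, `B`.
#' @export
chi2MonteCarlo <- function(table, B = 10000, seed = NULL) {
    table <- as.matrix(table)
    stopifnot(identical(dim(table), c(2L, 2L)), B >= 1)
    if (any(table < 0) || any(table != round(table)))
        stop("table must contain nonnegative integer counts")
    rs <- rowSums(table); cs <- colSums(table); N <- sum(table)
    if (any(rs == 0) || any(cs == 0))
        stop("untestable table: zero row or column margin")
    chi2_of <- function(a) {
        ## all four cells follow from a11 with fixed margins
        b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - cs[1] + a
        N * (a * d - b * c)^2 / (rs[1] * rs[2] * cs[1] * cs[2])
    }
    chi2 <- unname(chi2_of(table[1, 1]))
    sims <- .withSeed(seed, stats::r2dtable(B, rs, cs))
    a_sim <- vapply(sims, function(m) m[1, 1], numeric(1))
    chi2_sim <- chi2_of(a_sim)
    p_mc <- (1 + sum(chi2_sim >= chi2 - 1e-12)) / (B + 1)
    list(chi2 = chi2, p_mc = unname(p_mc),
         p_asymptotic = pchisq(chi2, df = 1, lower.tail = FALSE),
         B = as.integer(B))
}

#' Scan intervention choices against biomarker improvement
#'
#' For each biomarker in `definitions` and each of the `top_k` most
#' frequently chosen interventions (ties broken lexicographically),
#' cross-tabulates improvement against choice over the entire population
#' with a pair for that biomarker — participants with no recorded choices
#' count as not choosing every intervention — and tests the 2x2 table with
#' [chi2MonteCarlo()]. Benjamini-Hochberg adjustment is applied across the
#' scanned family; nominal (uncorrected `p_mc < 0.05`) flags are reported
#' separately.
#'
#' @param pairs data.frame of longitudinal pairs (seasonally adjusted where
#'   designated).
#' @param choices data.frame of (participant_id, intervention_id) choices.
#' @param definitions data.frame from [improvementDefinitions()].
#' @param top_k number of interventions to scan (default 10).
#' @param B Monte-Carlo replicates per test (default 10000).
#' @param seed integer seed; per-test seeds are derived deterministically.
#' @return data.frame with one row per (biomarker, intervention):
#'   contingency counts, `chi2`, `p_mc`, `p_asymptotic`, `q`, `nominal`,
#'   `untestable`.
#' @export
interventionScan <- function(pairs, choices, definitions, top_k = 10,
                             B = 10000, seed = 1) {
    stopifnot(is.data.frame(choices),
              all(c("participant_id", "intervention_id") %in%
                  names(choices)))
    freq <- table(choices$intervention_id)
    ivs <- names(freq)[order(-as.integer(freq), names(freq))]
    ivs <- utils::head(ivs, top_k)
    rows <- list(); test_i <- 0L
    for (k in seq_len(nrow(definitions))) {
        bm <- definitions$biomarker[k]
        sub <- pairs[pairs$biomarker == bm, , drop = FALSE]
        improved <- if (definitions$improvement[k] == "increase")
            sub$delta > 0 else sub$delta < 0
        for (iv in ivs) {
            test_i <- test_i + 1L
            chose <- sub$participant_id %in%
                choices$participant_id[choices$intervention_id == iv]
            tab <- matrix(c(sum(improved & chose), sum(improved & !chose),
                            sum(!improved & chose), sum(!improved & !chose)),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(improved = c("yes", "no"),
                                          chose = c("yes", "no")))
            res <- tryCatch(
                chi2MonteCarlo(tab, B = B,
                               seed = if (is.null(seed)) NULL
                                      else seed + test_i),
                error = function(e) NULL)
            rows[[paste(bm, iv)]] <- data.frame(
                biomarker = bm, intervention_id = iv,
                n_improved_chose = tab[1, 1],
                n_improved_not = tab[1, 2],
                n_notimproved_chose = tab[2, 1],
                n_notimproved_not = tab[2, 2],
                chi2 = if (is.null(res)) NA_real_ else res$chi2,
                p_mc = if (is.null(res)) NA_real_ else res$p_mc,
                p_asymptotic = if (is.null(res)) NA_real_
                               else res$p_asymptotic,
                untestable = is.null(res),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$q <- NA_real_
    tested <- !out$untestable
    if (any(tested)) out$q[tested] <- bhAdjust(out$p_mc[tested])
    out$nominal <- tested & out$p_mc < 0.05
    out
}

#' Write intervention-scan results to CSV
#'
#' @param scan data.frame from [interventionScan()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeInterventionScan <- function(scan, path) {
    write.csv(scan, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
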