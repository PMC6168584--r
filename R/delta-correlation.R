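#' Build a DeltaMatrix from longitudinal pairs
#'
#' Pivots QC-passing longitudinal pairs into a biomarkers x participants
#' change matrix (follow-up minus baseline), wrapped in a
#' \linkS4class{DeltaMatrix} (a `SummarizedExperiment`). An entry is `NA`
#' exactly when the participant has no pair for that biomarker. Participant
#' demographics, when supplied, are attached as `colData` for stratified
#' analyses.
#'
#' @param pairs data.frame from [extractPairs()] (optionally filtered by
#'   [applyLimits()] / seasonally adjusted).
#' @param participants optional participant data.frame (see
#'   [readParticipants()]).
#' @return A `DeltaMatrix`.
#' @export
deltaMatrix <- function(pairs, participants = NULL) {
    stopifnot(is.data.frame(pairs))
    bms <- sort(unique(pairs$biomarker))
    ids <- sort(unique(pairs$participant_id))
    mat <- matrix(NA_real_, nrow = length(bms), ncol = length(ids),
                  dimnames = list(bms, ids))
    mat[cbind(match(pairs$biomarker, bms),
              match(pairs$participant_id, ids))] <- pairs$delta
    cd <- if (!is.null(participants)) {
        p <- participants[match(ids, participants$participant_id), ,
                          drop = FALSE]
        rownames(p) <- ids
        S4Vectors::DataFrame(p)
    } else S4Vectors::DataFrame(row.names = ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(delta = mat), colData = cd)
    new("DeltaMatrix", se)
}

#' Pairwise-complete Spearman correlation test
#'
#' Spearman's rank correlation between two paired vectors, computed as the
#' Pearson correlation of average-tied ranks over the pairwise-complete
#' observations, with a two-sided p-value from the t approximation on
#' `n - 2` degrees of freedom. `|rho| = 1` yields `p = 0` by convention.
#' The pair is flagged untestable (rho and p `NA`) when fewer than `min_n`
#' complete observations remain or either vector has zero rank variance.
#'
#' @param x,y paired numeric vectors (may contain `NA`).
#' @param min_n minimum number of complete pairs (default 3).
#' @return list with `rho`, `p`, `n`, and logical `untestable`.
#' @export
spearmanPair <- function(x, y, min_n = 3) {
    stopifnot(length(x) == length(y), min_n >= 3)
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n)
        return(list(rho = NA_real_, p = NA_real_, n = n, untestable = TRUE))
    rx <- rank(x[ok], ties.method = "average")
    ry <- rank(y[ok], ties.method = "average")
    if (var(rx) == 0 || var(ry) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, untestable = TRUE))
    rho <- cor(rx, ry)
    list(rho = rho, p = .spearmanP(rho, n), n = n, untestable = FALSE)
}

## two-sided p from the t approximation; |rho| = 1 -> p = 0 by convention
.spearmanP <- function(rho, n) {
    p <- numeric(length(rho))
    sat <- abs(rho) >= 1 - 1e-14
    p[sat] <- 0
    if (any(!sat)) {
        r <- rho[!sat]
        tt <- r * sqrt((n[!sat] - 2) / (1 - r^2))
        p[!sat] <- 2 * pt(-abs(tt), n[!sat] - 2)
    }
    p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a family of p-values
#' (`q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back to input
#' order). A thin validating front end to [stats::p.adjust()].
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return numeric q-values in input order.
#' @export
bhAdjust <- function(pvals) {
    if (!length(pvals)) return(numeric())
    if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' All pairwise delta correlations with FDR control
#'
#' Runs the pairwise-complete Spearman test for every unordered pair of
#' biomarkers in a \linkS4class{DeltaMatrix}, then applies Benjamini-Hochberg
#' adjustment over exactly the family of tested pairs. Pairs with fewer than
#' `min_n` shared participants, or zero rank variance, are excluded from both
#' the output and the BH family and recorded in the `"untested"` attribute.
#'
#' With a 40-biomarker panel in which every pair is testable this yields the
#' full family of choose(40, 2) = 780 comparisons.
#'
#' @param deltas a `DeltaMatrix` (or plain participants-in-columns matrix).
#' @param min_n minimum pairwise-complete sample size (default 10).
#' @return data.frame with one row per tested pair: `biomarker_a`,
#'   `biomarker_b` (lexicographically ordered within a pair), `rho`, `n`,
#'   `p`, `q`; attribute `"untested"` lists excluded pairs with reasons.
#' @export
correlateAll <- function(deltas, min_n = 10) {
    X <- if (is(deltas, "DeltaMatrix")) t(deltaValues(deltas))
         else if (is.matrix(deltas)) deltas
         else stop("deltas must be a DeltaMatrix or a matrix")
    if (ncol(X) < 2) stop("need at least 2 biomarker columns")
    min_n <- max(3L, as.integer(min_n))
    bms <- colnames(X)
    ord <- order(bms)          # column-order invariance
    X <- X[, ord, drop = FALSE]
    bms <- bms[ord]
    m <- ncol(X)
    complete <- !anyNA(X)
    if (complete) {
        ranks <- apply(X, 2, rank, ties.method = "average")
        sds <- apply(ranks, 2, sd)
        testable_col <- sds > 0 & nrow(X) >= min_n
        R <- suppressWarnings(cor(ranks))
    }
    ia <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    ib <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
    rho <- n_pair <- numeric(length(ia))
    untestable <- logical(length(ia))
    reason <- character(length(ia))
    for (k in seq_along(ia)) {
        i <- ia[k]; j <- ib[k]
        if (complete) {
            n_pair[k] <- nrow(X)
            if (!testable_col[i] || !testable_col[j]) {
                untestable[k] <- TRUE
                reason[k] <- if (nrow(X) < min_n) "n below minimum"
                             else "zero rank variance"
            } else rho[k] <- R[i, j]
        } else {
            res <- spearmanPair(X[, i], X[, j], min_n = 3)
            n_pair[k] <- res$n
            if (res$n < min_n) {
                untestable[k] <- TRUE; reason[k] <- "n below minimum"
            } else if (res$untestable) {
                untestable[k] <- TRUE; reason[k] <- "zero rank variance"
            } else rho[k] <- res$rho
        }
    }
    keep <- !untestable
    out <- data.frame(biomarker_a = bms[ia[keep]],
                      biomarker_b = bms[ib[keep]],
                      rho = rho[keep],
                      n = as.integer(n_pair[keep]),
                      stringsAsFactors = FALSE)
    out$p <- .spearmanP(out$rho, out$n)
    out$q <- bhAdjust(out$p)
    rownames(out) <- NULL
    attr(out, "untested") <- data.frame(
        biomarker_a = bms[ia[!keep]], biomarker_b = bms[ib[!keep]],
        n = as.integer(n_pair[!keep]), reason = reason[!keep],
        stringsAsFactors = FALSE)
    out
}

#' Build the significant-edge correlation network
#'
#' Thresholds a correlation table at `q < alpha` to form the biomarker-change
#' network. Edge weight is the signed Spearman coefficient; isolated nodes
#' (biomarkers with no significant partner) are retained in the node set.
#'
#' @param entries correlation table from [correlateAll()].
#' @param alpha significance level on q-values (default 0.05).
#' @param nodes optional character vector of nodes; defaults to all
#'   biomarkers appearing in `entries`.
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
buildNetwork <- function(entries, alpha = 0.05, nodes = NULL) {
    stopifnot(is.data.frame(entries), "q" %in% names(entries))
    if (is.null(nodes))
        nodes <- sort(unique(c(entries$biomarker_a, entries$biomarker_b)))
    edges <- entries[entries$q < alpha, , drop = FALSE]
    rownames(edges) <- NULL
    new("CorrelationNetwork", nodes = nodes,
        edges = edges[, c("biomarker_a", "biomarker_b", "rho", "n",
                          "p", "q")],
        alpha = alpha)
}

#' Extract the neighborhood (star) of a focus biomarker
#'
#' Returns the induced star sub-network around one biomarker: the focus, its
#' significantly-correlated partners, and only the focus-incident edges.
#'
#' @param network a \linkS4class{CorrelationNetwork}.
#' @param focus biomarker code; must be a node of the network.
#' @return A `CorrelationNetwork` restricted to the star of `focus`.
#' @export
neighborhood <- function(network, focus) {
    stopifnot(is(network, "CorrelationNetwork"))
    if (!focus %in% network@nodes)
        stop("unknown biomarker: ", focus)
    e <- network@edges
    inc <- e$biomarker_a == focus | e$biomarker_b == focus
    e <- e[inc, , drop = FALSE]
    rownames(e) <- NULL
    new("CorrelationNetwork",
        nodes = unique(c(focus, e$biomarker_a, e$biomarker_b)),
        edges = e, alpha = network@alpha)
}

#' Compare correlation tables between a stratum and the full data
#'
#' Sensitivity analysis: Pearson correlation between the Spearman
#' coefficients of two correlation tables (e.g. full cohort vs a
#' time-filtered or sex-stratified subset), restricted to the pairs testable
#' in both.
#'
#' @param entries_full,entries_stratum correlation tables from
#'   [correlateAll()].
#' @return list with `r` (Pearson correlation of the aligned rho vectors)
#'   and `table` (the aligned per-pair data.frame with `rho_full`,
#'   `rho_stratum`).
#' @export
sensitivityCompare <- function(entries_full, entries_stratum) {
    key <- function(e) paste(e$biomarker_a, e$biomarker_b, sep = "\r")
    kf <- key(entries_full); ks <- key(entries_stratum)
    shared <- intersect(kf, ks)
    if (length(shared) < 3)
        stop("insufficient overlap: only ", length(shared),
             " pair(s) testable in both tables (need >= 3)")
    i <- match(shared, kf); j <- match(shared, ks)
    tab <- data.frame(biomarker_a = entries_full$biomarker_a[i],
                      biomarker_b = entries_full$biomarker_b[i],
                      rho_full = entries_full$rho[i],
                      rho_stratum = entries_stratum$rho[j],
                      stringsAsFactors = FALSE)
    list(r = cor(tab$rho_full, tab$rho_stratum), table = tab)
}

#' Export a correlation table or network
#'
#' `writeCorrelationTable()` writes the full per-pair table
#' (`biomarker_a,biomarker_b,rho,n,p,q`) as CSV. `writeEdgeList()` writes
#' the significant edges as a Cytoscape-loadable TSV. `writeGraphML()`
#' exports the network (with `weight = rho` edge attributes, plus an
#' optional `cluster` node attribute) as GraphML.
#'
#' @param entries correlation table from [correlateAll()].
#' @param network a \linkS4class{CorrelationNetwork}.
#' @param path output path.
#' @param clusters optional named vector (biomarker -> cluster label) from
#'   [dynamicTreeCut()], stored as a `cluster` node attribute.
#' @return `path`, invisibly.
#' @export
writeCorrelationTable <- function(entries, path) {
    write.csv(entries[, c("biomarker_a", "biomarker_b", "rho", "n",
                          "p", "q")],
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCorrelationTable
#' @export
writeEdgeList <- function(network, path) {
    stopifnot(is(network, "CorrelationNetwork"))
    e <- network@edges
    out <- data.frame(source = e$biomarker_a, target = e$biomarker_b,
                      weight = e$rho, q = e$q, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCorrelationTable
#' @export
writeGraphML <- function(network, path, clusters = NULL) {
    g <- asIgraph(network)
    if (!is.null(clusters))
        igraph::V(g)$cluster <-
            as.integer(clusters[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
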