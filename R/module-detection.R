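#' Correlation-derived distance matrix
#'
#' Converts a correlation table into the clustering distance
#' `d_ij = 1 - |rho_ij|` (zero diagonal). Pairs absent from the table
#' (untestable) are imputed with `rho = 0`, i.e. maximal distance, with a
#' warning, so the matrix is always complete.
#'
#' @param entries correlation table from [correlateAll()].
#' @param biomarkers optional character vector fixing the matrix dimension;
#'   defaults to all biomarkers in `entries`.
#' @return symmetric numeric matrix with dimnames.
#' @export
distanceFromCorrelations <- function(entries, biomarkers = NULL) {
    stopifnot(is.data.frame(entries))
    if (is.null(biomarkers))
        biomarkers <- sort(unique(c(entries$biomarker_a,
                                    entries$biomarker_b)))
    m <- length(biomarkers)
    D <- matrix(1, m, m, dimnames = list(biomarkers, biomarkers))
    diag(D) <- 0
    i <- match(entries$biomarker_a, biomarkers)
    j <- match(entries$biomarker_b, biomarkers)
    ok <- !is.na(i) & !is.na(j)
    D[cbind(i[ok], j[ok])] <- 1 - abs(entries$rho[ok])
    D[cbind(j[ok], i[ok])] <- 1 - abs(entries$rho[ok])
    n_missing <- m * (m - 1) / 2 - sum(ok)
    if (n_missing > 0)
        warning(n_missing, " biomarker pair(s) missing from the ",
                "correlation table; imputed with rho = 0 (distance 1)")
    D
}

#' Hierarchical clustering of biomarkers
#'
#' Agglomerative clustering of the `1 - |rho|` distance matrix. Leaves are
#' ordered lexicographically before agglomeration so the merge sequence is a
#' deterministic function of the distances alone (ties resolved by the
#' smallest-label pair), independent of input column order.
#'
#' @param d symmetric distance matrix from [distanceFromCorrelations()].
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return An [stats::hclust] dendrogram.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete",
                                               "single")) {
    linkage <- match.arg(linkage)
    if (!is.matrix(d) || nrow(d) != ncol(d) ||
        !isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
        stop("d must be a symmetric distance matrix")
    if (nrow(d) < 2) stop("need at least 2 biomarkers to cluster")
    ord <- order(rownames(d))
    d <- d[ord, ord]
    hclust(as.dist(d), method = linkage)
}

## all internal node heights of a dendrogram branch
.branchHeights <- function(d) {
    if (is.leaf(d)) return(numeric())
    c(attr(d, "height"),
      .branchHeights(d[[1L]]), .branchHeights(d[[2L]]))
}

#' Adaptive (dynamic) tree cut
#'
#' Decomposes a dendrogram into biomarker clusters without a single fixed
#' height cut:
#' \enumerate{
#'   \item merges above `cut_height_fraction` times the maximum merge height
#'     are removed (unless every merge lies above that line, in which case
#'     the tree is homogeneous at the top and stays whole);
#'   \item each remaining subtree is a candidate cluster;
#'   \item a candidate whose internal merge heights show a gap larger than
#'     `split_gap_fraction` times the branch's height range (taken from zero
#'     to its top merge) is split inside the largest such gap, recursively;
#'   \item clusters smaller than `min_cluster_size` are dissolved: each
#'     member joins the nearest retained cluster by average distance,
#'     provided that average distance does not exceed the cluster's own
#'     merge height; otherwise it is left unassigned (label 0).
#' }
#' Cluster labels are arbitrary (1 = largest); equality of assignments is
#' meaningful only up to label permutation. Exact replication of any
#' particular reference implementation's labels is not claimed; the method
#' is validated by recovery of planted block structure and by agreement with
#' a static cut in the clean-separation limit.
#'
#' @param dend an [stats::hclust] object from [hierarchicalCluster()].
#' @param d the distance matrix the dendrogram was built from.
#' @param min_cluster_size smallest retainable cluster (default 3).
#' @param cut_height_fraction top-merge removal line as a fraction of the
#'   maximum merge height (default 0.99).
#' @param split_gap_fraction fraction of a branch's height range that an
#'   internal height gap must exceed to split the branch (default 0.35).
#' @return named integer vector mapping biomarker to cluster label (0 =
#'   unassigned), with the parameters used in `attr(, "parameters")`.
#' @export
dynamicTreeCut <- function(dend, d, min_cluster_size = 3,
                           cut_height_fraction = 0.99,
                           split_gap_fraction = 0.35) {
    stopifnot(inherits(dend, "hclust"), is.matrix(d))
    if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
    leaves <- dend$labels
    if (!all(leaves %in% rownames(d)))
        stop("dendrogram leaves must match the distance matrix")
    dnd <- as.dendrogram(dend)
    H <- attr(dnd, "height")
    cutoff <- cut_height_fraction * H
    initial <- if (any(.branchHeights(dnd) <= cutoff))
        cut(dnd, h = cutoff)$lower else list(dnd)
    split_branch <- function(br) {
        hh <- .branchHeights(br)
        if (length(hh) >= 2) {
            shh <- sort(hh)
            gaps <- diff(shh)
            top <- shh[length(shh)]
            k <- which.max(gaps)
            if (top > 0 && gaps[k] > split_gap_fraction * top) {
                cut_at <- (shh[k] + shh[k + 1L]) / 2
                kids <- cut(br, h = cut_at)$lower
                return(unlist(lapply(kids, split_branch),
                              recursive = FALSE))
            }
        }
        list(br)
    }
    branches <- unlist(lapply(initial, split_branch), recursive = FALSE)
    members <- lapply(branches, labels)
    heights <- vapply(branches, function(b) {
        hh <- .branchHeights(b)
        if (length(hh)) max(hh) else 0
    }, numeric(1))
    sizes <- lengths(members)
    keep <- sizes >= min_cluster_size
    out <- setNames(integer(length(leaves)), sort(leaves))
    if (any(keep)) {
        keepers <- members[keep]
        keeper_h <- heights[keep]
        ## stable labels: largest first, ties by smallest member label
        ord <- order(-sizes[keep],
                     vapply(keepers, function(x) min(x), character(1)))
        keepers <- keepers[ord]; keeper_h <- keeper_h[ord]
        for (lab in seq_along(keepers)) out[keepers[[lab]]] <- lab
        ## dissolve small clusters member-by-member
        strays <- unlist(members[!keep], use.names = FALSE)
        for (s in strays) {
            avg <- vapply(keepers, function(mem) mean(d[s, mem]),
                          numeric(1))
            best <- which.min(avg)
            out[s] <- if (avg[best] <= keeper_h[best]) best else 0L
        }
    }
    attr(out, "parameters") <- list(
        linkage = dend$method, min_cluster_size = min_cluster_size,
        cut_height_fraction = cut_height_fraction,
        split_gap_fraction = split_gap_fraction)
    out
}

#' Write a cluster assignment to CSV
#'
#' @param clusters named integer vector from [dynamicTreeCut()].
#' @param path output CSV path (`biomarker,cluster_label`).
#' @return `path`, invisibly.
#' @export
writeClusterAssignment <- function(clusters, path) {
    write.csv(data.frame(biomarker = names(clusters),
                         cluster_label = as.integer(clusters)),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
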