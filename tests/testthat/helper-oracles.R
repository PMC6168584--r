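# Independent brute-force oracles used to validate the package's
# statistical primitives. These deliberately re-derive each quantity from
# its definition, not from the code path under test.

## Benjamini-Hochberg step-up, straight from the definition:
## q_(i) = min_{j >= i} m p_(j) / j, capped at 1, in input order.
bruteBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[ord] <- q
    out
}

## Exact two-sided signed-rank p by enumerating all 2^n sign patterns on the
## observed (average-tied) ranks of the nonzero |differences|.
bruteSignRankP <- function(baseline, followup) {
    d <- followup - baseline
    dnz <- d[d != 0]
    if (!length(dnz)) return(1)
    r <- rank(abs(dnz), ties.method = "average")
    W <- sum(r[dnz > 0])
    n <- length(r)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(signs %*% r)
    min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

## Spearman rho and t-approximation p via the rank-then-Pearson definition.
bruteSpearman <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    rx <- rank(x[ok], ties.method = "average")
    ry <- rank(y[ok], ties.method = "average")
    n <- sum(ok)
    rho <- cor(rx, ry)
    p <- if (abs(rho) >= 1 - 1e-14) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tt), n - 2)
    }
    list(rho = rho, p = p, n = n)
}

## quick builder for longitudinal-pair tables in tests
makePairs <- function(participant_id, biomarker, baseline, followup,
                      baseline_date = as.Date("2016-02-01"),
                      followup_date = as.Date("2016-08-01")) {
    data.frame(participant_id = as.character(participant_id),
               biomarker = biomarker,
               baseline_value = baseline, followup_value = followup,
               baseline_date = baseline_date,
               followup_date = followup_date,
               delta = followup - baseline,
               stringsAsFactors = FALSE)
}

## distance matrix with planted tight blocks, small deterministic jitter
blockDistance <- function(block_sizes, d_within = 0.3, d_between = 0.95,
                          jitter = 0.01, seed = 42) {
    m <- sum(block_sizes)
    lab <- rep(seq_along(block_sizes), block_sizes)
    D <- matrix(d_between, m, m)
    D[outer(lab, lab, "==")] <- d_within
    set.seed(seed)
    noise <- matrix(runif(m * m, -jitter, jitter), m, m)
    noise <- (noise + t(noise)) / 2
    D <- D + noise
    diag(D) <- 0
    nm <- sprintf("B%02d", seq_len(m))
    dimnames(D) <- list(nm, nm)
    attr(D, "blocks") <- setNames(lab, nm)
    D
}
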