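suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

## Brute-force weighted UniFrac: explicitly enumerates every branch's
## descendant tip set by recursion, independent of the package's
## postorder accumulation.
bruteUnifrac <- function(tree, a, b, normalized = TRUE) {
    ntip <- length(tree$tip.label)
    full <- function(v) {
        p <- setNames(rep(0, ntip), tree$tip.label)
        p[names(v)] <- v
        p / sum(p)
    }
    pa <- full(a); pb <- full(b)
    descTips <- function(node) {
        if (node <= ntip) return(tree$tip.label[node])
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        unlist(lapply(kids, descTips))
    }
    raw <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
        tips <- descTips(tree$edge[e, 2])
        A <- sum(pa[tips]); B <- sum(pb[tips])
        raw <- raw + tree$edge.length[e] * abs(A - B)
        den <- den + tree$edge.length[e] * (A + B)
    }
    if (normalized) raw / den else raw
}

## Exact two-sided Wilcoxon rank-sum p by full enumeration of all
## rank assignments (tie-free data only).
enumWilcoxonP <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sets <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(seq_len(n1 + n2)[sets], nrow = n1)) -
        n1 * (n1 + 1) / 2
    pl <- mean(w_all <= w_obs); pu <- mean(w_all >= w_obs)
    min(1, 2 * min(pl, pu))
}

## Small reusable synthetic fixtures.
smallFixture <- function(n = 30, seed = 11) {
    buildClassificationFixture(
        n, c(oral = 0.6, transient_extraoral = 0.2, unknown = 0.2),
        seed = seed)
}

namedGenomeLengths <- function(taxa) {
    setNames(taxa$genome_length, taxa$name)
}

## Euclidean distance matrix for random points, with sample names.
randomEuclidean <- function(n, d = 3, seed = 1) {
    set.seed(seed)
    pts <- matrix(rnorm(n * d), n, d)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    m
}
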