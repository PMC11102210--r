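#' Shannon-Weaver diversity index
#'
#' \code{H = -sum(p_i * ln(p_i))} over positive entries, with
#' \code{p_i = x_i / sum(x)}. Natural-log scale.
#'
#' @param abundances non-negative vector with at least one positive
#'   entry.
#' @return The index (0 for a single-species sample).
#' @examples
#' shannonWeaver(c(1, 1))  # ln 2
#' @export
shannonWeaver <- function(abundances) {
    x <- abundances[abundances > 0]
    if (!length(x)) stop("all-zero abundance vector")
    p <- x / sum(x)
    -sum(p * log(p))
}

#' Observed species richness
#'
#' Count of entries > 0; invariant to positive rescaling.
#'
#' @param abundances non-negative vector.
#' @return Integer count.
#' @export
observedRichness <- function(abundances) sum(abundances > 0)

#' Read a rooted phylogeny from newick
#'
#' Standard newick grammar (quoted labels allowed, multifurcations
#' supported). Missing branch lengths default to 1 with a warning, as
#' taxonomy-derived trees often omit them.
#'
#' @param path newick file path.
#' @return An \code{ape} \code{phylo} object with complete edge lengths.
#' @export
readNewickTree <- function(path) {
    tree <- ape::read.tree(path)
    ensureBranchLengths(tree)
}

ensureBranchLengths <- function(tree) {
    if (is.null(tree$edge.length)) {
        warning("tree has no branch lengths; defaulting all to 1")
        tree$edge.length <- rep(1, nrow(tree$edge))
    } else if (anyNA(tree$edge.length)) {
        warning("tree has missing branch lengths; defaulting them to 1")
        tree$edge.length[is.na(tree$edge.length)] <- 1
    }
    if (any(tree$edge.length < 0))
        stop("negative branch lengths are not allowed")
    tree
}

## Per-edge proportion of each sample's total descending through the
## edge's child node. mat: leaves x samples (rows named by tip labels,
## proportions or raw abundances). Returns edges x samples matrix
## aligned with tree$edge.
edgeProportions <- function(tree, mat) {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    cs <- colSums(mat)
    if (any(cs <= 0)) stop("each sample needs a positive total abundance")
    p <- sweep(mat, 2, cs, "/")
    node_w <- matrix(0, nnode, ncol(mat))
    node_w[seq_len(ntip), ] <- p[tree$tip.label, , drop = FALSE]
    ## children precede parents in postorder, so one sweep accumulates
    ord <- ape::postorder(tree)
    for (e in ord) {
        par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        node_w[par, ] <- node_w[par, ] + node_w[child, ]
    }
    node_w[tree$edge[, 2], , drop = FALSE]
}

checkTreeCoverage <- function(tree, taxa) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
        stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
}

#' Weighted UniFrac distance between two samples
#'
#' Raw weighted UniFrac is \code{sum_b l_b * |A_b - B_b|}, where
#' \code{A_b} and \code{B_b} are the proportions of each sample's total
#' abundance descending through branch \code{b}. The normalized variant
#' (default) divides by \code{sum_b l_b * (A_b + B_b)}, the
#' abundance-weighted maximum attainable distance, giving a value in
#' [0, 1].
#'
#' @param tree rooted \code{phylo} tree with branch lengths (see
#'   \code{\link{readNewickTree}}); multifurcations supported.
#' @param a,b named non-negative abundance vectors; every taxon name
#'   must be a tree tip, and each vector needs a positive total.
#' @param normalized divide by the weighted maximum (default TRUE).
#' @return The distance (scalar).
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' weightedUnifrac(tree, c(A = 1), c(B = 1), normalized = FALSE)  # 2
#' @export
weightedUnifrac <- function(tree, a, b, normalized = TRUE) {
    tree <- ensureBranchLengths(tree)
    checkTreeCoverage(tree, c(names(a), names(b)))
    mat <- matrix(0, length(tree$tip.label), 2,
                  dimnames = list(tree$tip.label, c("a", "b")))
    mat[names(a), 1] <- a
    mat[names(b), 2] <- b
    ep <- edgeProportions(tree, mat)
    raw <- sum(tree$edge.length * abs(ep[, 1] - ep[, 2]))
    if (!normalized) return(raw)
    denom <- sum(tree$edge.length * (ep[, 1] + ep[, 2]))
    if (denom == 0) 0 else raw / denom
}

#' Weighted UniFrac distance matrix over samples
#'
#' @param tree rooted \code{phylo} tree with branch lengths.
#' @param mat taxa x samples abundance matrix (rows named by tree tips).
#' @param normalized see \code{\link{weightedUnifrac}}.
#' @return Symmetric samples x samples distance matrix with zero
#'   diagonal.
#' @export
unifracMatrix <- function(tree, mat, normalized = TRUE) {
    tree <- ensureBranchLengths(tree)
    checkTreeCoverage(tree, rownames(mat))
    full <- matrix(0, length(tree$tip.label), ncol(mat),
                   dimnames = list(tree$tip.label, colnames(mat)))
    full[rownames(mat), ] <- mat
    ep <- edgeProportions(tree, full)
    n <- ncol(mat)
    d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
    len <- tree$edge.length
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
        raw <- sum(len * abs(ep[, i] - ep[, j]))
        d[i, j] <- d[j, i] <- if (normalized)
            raw / sum(len * (ep[, i] + ep[, j])) else raw
    }
    d
}

checkDistanceMatrix <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
        stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 0)) stop("distance matrix diagonal must be 0")
    d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of \code{-0.5 * d^2} followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which
#' arise for non-Euclidean distances, are reported but their axes are
#' dropped; proportions explained are computed over the positive
#' eigenvalues only.
#'
#' @param d symmetric distance matrix (zero diagonal) or \code{dist}.
#' @param k number of axes requested (>= 1); truncated with a warning if
#'   fewer positive axes exist.
#' @return An \linkS4class{OrdinationResult}.
#' @export
pcoaOrdination <- function(d, k = 2L) {
    stopifnot(k >= 1)
    d <- checkDistanceMatrix(d)
    n <- nrow(d)
    a <- -0.5 * d^2
    ctr <- a - matrix(rowMeans(a), n, n) -
        matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
    eig <- eigen(ctr, symmetric = TRUE)
    tol <- max(abs(eig$values)) * 1e-9
    pos <- which(eig$values > tol)
    if (k > length(pos)) {
        warning("only ", length(pos), " positive axes available; truncating")
        k <- length(pos)
    }
    keep <- pos[seq_len(k)]
    coords <- eig$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eig$values[keep]), length(keep))
    dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k)))
    new("OrdinationResult", coordinates = coords, eigenvalues = eig$values,
        proportionExplained = eig$values[keep] / sum(eig$values[pos]))
}

setMethod("show", "OrdinationResult", function(object) {
    cat("OrdinationResult:", nrow(object@coordinates), "samples x",
        ncol(object@coordinates), "axes\n")
    cat("  proportion explained:",
        paste(sprintf("%.1f%%", 100 * object@proportionExplained),
              collapse = ", "), "\n")
    nneg <- sum(object@eigenvalues < 0)
    if (nneg) cat("  (", nneg, "negative eigenvalues dropped )\n")
})

#' @rdname OrdinationResult-class
#' @param x an \code{OrdinationResult}.
#' @export
ordCoordinates <- function(x) x@coordinates

#' @rdname OrdinationResult-class
#' @export
ordEigenvalues <- function(x) x@eigenvalues

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F formulation): with total sum of squared
#' distances \code{SS_T = (1/N) sum_{i<j} d_ij^2} and within-group
#' \code{SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2},
#' \code{F = (SS_A / (k-1)) / (SS_W / (N-k))} where
#' \code{SS_A = SS_T - SS_W}. The p-value counts permutations of the
#' sample ordering whose F meets or exceeds the observed one:
#' \code{p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)}, so p is never
#' below \code{1/(n_perm + 1)}. Single-factor designs only.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param labels group label per sample; at least two groups, each with
#'   at least two samples.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutations (deterministic result).
#' @return A \linkS4class{PermanovaResult}.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
    d <- checkDistanceMatrix(d)
    labels <- as.character(labels)
    n <- nrow(d)
    stopifnot(length(labels) == n, n_perm >= 1)
    tab <- table(labels)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L))
        stop("every group needs >= 2 samples (offender: ",
             paste(names(tab)[tab < 2], collapse = ", "), ")")
    d2 <- d^2
    k <- length(tab)
    ss_t <- sum(d2) / (2 * n)
    groups <- split(seq_len(n), labels)
    ssw <- function(idx_list) sum(vapply(idx_list, function(idx)
        sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
    fstat <- function(idx_list) {
        w <- ssw(idx_list)
        ((ss_t - w) / (k - 1)) / (w / (n - k))
    }
    f_obs <- fstat(groups)
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        if (fstat(lapply(groups, function(idx) perm[idx])) >= f_obs)
            exceed <- exceed + 1L
    }
    w_obs <- ssw(groups)
    new("PermanovaResult", pseudoF = f_obs,
        pValue = (1 + exceed) / (1 + n_perm),
        nPermutations = as.integer(n_perm), seed = as.integer(seed),
        ssAmong = ss_t - w_obs, ssWithin = w_obs,
        dfAmong = as.integer(k - 1), dfWithin = as.integer(n - k))
}

setMethod("show", "PermanovaResult", function(object) {
    cat(sprintf(
        "PERMANOVA: pseudo-F(%d, %d) = %.4f, p = %.4g (%d permutations)\n",
        object@dfAmong, object@dfWithin, object@pseudoF, object@pValue,
        object@nPermutations))
})

#' @rdname PermanovaResult-class
#' @param x a \code{PermanovaResult}.
#' @export
pseudoF <- function(x) x@pseudoF

#' @rdname PermanovaResult-class
#' @export
pValue <- function(x) x@pValue

#' Read / write a square distance matrix as TSV
#'
#' Square TSV with a header row and a leading identifier column.
#'
#' @param path file path.
#' @return \code{readDistanceMatrix} returns the matrix.
#' @export
readDistanceMatrix <- function(path) {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    checkDistanceMatrix(as.matrix(df))
}

#' @rdname readDistanceMatrix
#' @param d distance matrix.
#' @export
writeDistanceMatrix <- function(d, path) {
    out <- data.frame(sample = rownames(d), formatNum(as.matrix(d)),
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
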