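test_that("Shannon-Weaver index matches direct summation", {
    expect_equal(shannonWeaver(c(5, 0, 0)), 0)
    expect_equal(shannonWeaver(c(1, 1)), log(2))
    x <- c(1, 2, 3)
    p <- x / sum(x)
    expect_equal(shannonWeaver(x), -sum(p * log(p)), tolerance = 1e-12)
    expect_error(shannonWeaver(c(0, 0)), "all-zero")
    ## cross-check against vegan on random vectors
    set.seed(5)
    for (i in 1:5) {
        v <- runif(20)
        expect_equal(shannonWeaver(v), unname(vegan::diversity(v)),
                     tolerance = 1e-12)
    }
    ## maximum ln S only at the uniform vector
    S <- 8
    expect_equal(shannonWeaver(rep(1, S)), log(S), tolerance = 1e-12)
    set.seed(6)
    for (i in 1:20) {
        v <- rep(1, S) + runif(S, 0.01, 0.5)
        expect_lt(shannonWeaver(v), log(S))
    }
})

test_that("observed richness counts positives and ignores scale", {
    expect_equal(observedRichness(c(0, 0)), 0)
    expect_equal(observedRichness(c(1, 0, 3)), 2)
    set.seed(7)
    v <- rbinom(30, 1, 0.5) * runif(30)
    expect_equal(observedRichness(v), observedRichness(10 * v))
})

test_that("weighted UniFrac reproduces the hand-enumerated tree value", {
    tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    expect_equal(weightedUnifrac(tree, c(A = 1), c(B = 1),
                                 normalized = FALSE), 2)
    expect_equal(weightedUnifrac(tree, c(A = 1), c(B = 1),
                                 normalized = TRUE), 0.5)
    expect_equal(weightedUnifrac(tree, c(A = 2, C = 1), c(A = 2, C = 1)), 0)
    expect_error(weightedUnifrac(tree, c(A = 1, Z = 1), c(B = 1)), "Z")
})

test_that("weighted UniFrac matches brute-force branch enumeration", {
    set.seed(41)
    for (i in 1:25) {
        tree <- ape::rtree(5)
        a <- setNames(runif(5, 0.1, 10), tree$tip.label)
        b <- setNames(runif(5, 0.1, 10), tree$tip.label)
        for (norm in c(TRUE, FALSE)) {
            expect_equal(weightedUnifrac(tree, a, b, normalized = norm),
                         bruteUnifrac(tree, a, b, normalized = norm),
                         tolerance = 1e-10)
        }
        ## metric sanity: symmetry, identity, non-negativity
        expect_equal(weightedUnifrac(tree, a, b), weightedUnifrac(tree, b, a))
        expect_equal(weightedUnifrac(tree, a, a), 0)
        expect_gte(weightedUnifrac(tree, a, b), 0)
    }
})

test_that("unifracMatrix agrees with phyloseq on a random community", {
    skip_if_not_installed("phyloseq")
    set.seed(43)
    tree <- ape::rtree(12)
    mat <- matrix(rpois(12 * 6, 20), 12, 6,
                  dimnames = list(tree$tip.label, paste0("s", 1:6)))
    mine <- unifracMatrix(tree, mat, normalized = TRUE)
    ps <- phyloseq::phyloseq(
        phyloseq::otu_table(mat, taxa_are_rows = TRUE),
        phyloseq::phy_tree(tree))
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                       normalized = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-8)
})

test_that("PCoA round-trips Euclidean distances and orders axes", {
    d <- randomEuclidean(6, d = 2, seed = 47)
    ord <- pcoaOrdination(d, k = 2)
    rec <- as.matrix(dist(ordCoordinates(ord)))
    expect_equal(unname(rec), unname(d), tolerance = 1e-9)
    ev <- ordEigenvalues(ord)
    expect_true(all(diff(ev) <= 1e-9))  # descending
    ## equidistant triangle -> pairwise coordinate distances all equal
    d3 <- matrix(1, 3, 3) - diag(3)
    dimnames(d3) <- list(letters[1:3], letters[1:3])
    ord3 <- pcoaOrdination(d3, k = 2)
    pw <- dist(ordCoordinates(ord3))
    expect_lt(max(pw) - min(pw), 1e-9)
    ## k beyond available positive axes truncates with a warning
    expect_warning(ord_big <- pcoaOrdination(d3, k = 5), "truncat")
    expect_lte(ncol(ordCoordinates(ord_big)), 2)
    expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2), k = 1),
                 "symmetric")
    ## agreement with cmdscale as an independent implementation
    cs <- stats::cmdscale(d, k = 2)
    expect_equal(abs(ordCoordinates(ord)), abs(unname(cs)),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PERMANOVA matches vegan's pseudo-F and behaves under separation", {
    d <- randomEuclidean(12, d = 3, seed = 53)
    labels <- rep(c("g1", "g2"), each = 6)
    res <- permanova(d, labels, n_perm = 199, seed = 1)
    ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                          data = data.frame(g = labels), permutations = 99)
    expect_equal(pseudoF(res), ref$F[1], tolerance = 1e-9)
    ## identical seed -> identical result
    res2 <- permanova(d, labels, n_perm = 199, seed = 1)
    expect_identical(pValue(res), pValue(res2))
    ## p floor at 1/(n_perm + 1)
    expect_gte(pValue(res), 1 / 200)
    ## far-separated groups reach the permutation floor
    set.seed(59)
    pts <- rbind(matrix(rnorm(12), 6, 2),
                 matrix(rnorm(12, mean = 10), 6, 2))
    dsep <- as.matrix(dist(pts))
    dimnames(dsep) <- list(paste0("s", 1:12), paste0("s", 1:12))
    sep <- permanova(dsep, labels, n_perm = 199, seed = 3)
    expect_equal(pValue(sep), 1 / 200)
    expect_error(permanova(d, c(rep("a", 11), "b"), n_perm = 9), "group")
})

test_that("newick reading defaults missing branch lengths with a warning", {
    path <- withr::local_tempfile(fileext = ".nwk")
    writeLines("((A,B),C);", path)
    expect_warning(tree <- readNewickTree(path), "branch length")
    expect_true(all(tree$edge.length == 1))
    ## multifurcating tree with lengths parses cleanly
    writeLines("((A:1,B:2,C:1):0.5,D:3);", path)
    tree2 <- readNewickTree(path)
    expect_equal(length(tree2$tip.label), 4)
    expect_equal(weightedUnifrac(tree2, c(A = 1), c(A = 1)), 0)
})

test_that("distance matrices round-trip through TSV", {
    d <- randomEuclidean(5, seed = 61)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDistanceMatrix(d, path)
    back <- readDistanceMatrix(path)
    expect_equal(back, d, tolerance = 1e-10)
})
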