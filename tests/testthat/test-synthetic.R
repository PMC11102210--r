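test_that("classification fixture matches the requested residency mix", {
    mix <- c(oral = 236, transient_extraoral = 228, unknown = 109) / 573
    fx <- buildClassificationFixture(574, mix, seed = 1)
    counts <- table(fx$classification$residency)
    expect_equal(unname(counts["oral"]), 236)
    expect_equal(unname(counts["transient_extraoral"]), 228)
    expect_equal(unname(counts["unknown"]), 110)

    one <- buildClassificationFixture(1, c(oral = 1), seed = 5)
    expect_equal(one$classification$residency, "oral")

    a <- buildClassificationFixture(10, c(oral = 0.5,
        transient_extraoral = 0.3, unknown = 0.2), seed = 7)
    b <- buildClassificationFixture(10, c(oral = 0.5,
        transient_extraoral = 0.3, unknown = 0.2), seed = 7)
    expect_identical(a, b)
    expect_equal(as.vector(table(a$classification$residency)[
        c("oral", "transient_extraoral", "unknown")]), c(5, 3, 2))

    expect_error(buildClassificationFixture(10, c(oral = -0.1,
        unknown = 1.1)), "non-negative")
    expect_true(all(fx$taxa$genome_length >= 1.5e6 &
                    fx$taxa$genome_length <= 6.5e6))
    nonoral <- fx$classification$residency != "oral"
    expect_true(all(fx$classification$categories[nonoral] == ""))
})

test_that("imposed category effects shift true counts by the stated factor", {
    fx <- smallFixture(40, seed = 3)
    fx$taxa$prevalence <- 1  # all present so geometric means are clean
    eff <- data.frame(arm = "T", visit = "week4", category = "gingivitis",
                      effect = -1.0)
    des <- studyDesign(fx$taxa, arms = c("C", "T"), effects = eff,
                       n_subjects_per_arm = 200L,
                       visits = "week4", read_depth = 1e4, seed = 21)
    sim <- simulateStudy(des)
    md <- studyMetadata(sim)
    gin <- vapply(strsplit(fx$taxa$categories, ";"), function(v)
        "gingivitis" %in% v, logical(1))
    expect_gt(sum(gin), 3)
    tc <- trueCounts(sim)
    gm <- function(arm) mean(log10(tc[gin, md$arm == arm]))
    expect_equal(gm("T") - gm("C"), -1.0, tolerance = 0.05)
    ## non-member taxa are untouched in expectation
    expect_equal(mean(log10(tc[!gin, md$arm == "T"])) -
                 mean(log10(tc[!gin, md$arm == "C"])), 0, tolerance = 0.05)
})

test_that("prevalence controls presence and zero prevalence means absence", {
    fx <- smallFixture(20, seed = 9)
    fx$taxa$prevalence[1] <- 0
    des <- studyDesign(fx$taxa, arms = "B", n_subjects_per_arm = 30L,
                       visits = "baseline", read_depth = 1e4, seed = 4)
    sim <- simulateStudy(des)
    expect_true(all(trueCounts(sim)[1, ] == 0))
    ## observed richness has binomial expectation sum(prevalence)
    rich <- colSums(trueCounts(sim) > 0)
    expected <- sum(fx$taxa$prevalence)
    se <- sqrt(sum(fx$taxa$prevalence * (1 - fx$taxa$prevalence)) /
               length(rich))
    expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("simulateStudy is deterministic and validly structured", {
    fx <- smallFixture(15, seed = 2)
    des <- studyDesign(fx$taxa, arms = c("B", "BF"),
                       n_subjects_per_arm = 3L,
                       visits = c("baseline", "week4"), read_depth = 1e4,
                       seed = 8)
    s1 <- simulateStudy(des)
    s2 <- simulateStudy(des)
    expect_identical(assay(relabund(s1)), assay(relabund(s2)))
    expect_identical(trueCounts(s1), trueCounts(s2))
    ## every relabund column sums to 1
    expect_true(all(abs(colSums(assay(relabund(s1))) - 1) < 1e-9))
    ## metadata covers every sample exactly once
    md <- studyMetadata(s1)
    expect_setequal(md$sample, colnames(assay(relabund(s1))))
    expect_false(anyDuplicated(md$sample) > 0)
    expect_error(studyDesign(fx$taxa, arms = "B",
        effects = data.frame(arm = "B", visit = "baseline",
                             category = "nonsense", effect = -1),
        visits = "baseline"), "category")
})

test_that("sequencing weights reads by cells times genome length", {
    man <- defaultSpikeInManifest()
    cells <- c(t1 = 1e6, t2 = 1e6)
    gl <- c(t1 = 4e6, t2 = 2e6)
    p <- spikeAndSequence(cells, gl, man, read_depth = 1e4, noise = FALSE)
    expect_equal(unname(p["t1"] / p["t2"]), 2)  # 2:1 read share, 4 vs 2 Mbp
    ## equal cells, equal genomes -> symmetric shares
    p2 <- spikeAndSequence(c(a = 5, b = 5), c(a = 3e6, b = 3e6), man,
                           read_depth = 1e4, noise = FALSE)
    expect_equal(unname(p2["a"]), unname(p2["b"]))
    ## Monte-Carlo mean agrees with the analytic expectation
    draws <- vapply(seq_len(300), function(i)
        spikeAndSequence(cells, gl, man, read_depth = 1e4, seed = i),
        numeric(5))
    expect_equal(rowMeans(draws)[names(p)], p, tolerance = 0.02)
    ## determinism and error cases
    expect_identical(
        spikeAndSequence(cells, gl, man, 1e4, seed = 42),
        spikeAndSequence(cells, gl, man, 1e4, seed = 42))
    expect_error(spikeAndSequence(c(t1 = 0, t2 = 0), gl, man, 1e4),
                 "empty community")
})

test_that("control share responds to cell doubling as mass balance dictates", {
    man <- defaultSpikeInManifest()
    cells <- c(x = 2e8, y = 1e8)  # community DNA well above spike-in mass
    gl <- c(x = 3e6, y = 4e6)
    p1 <- spikeAndSequence(cells, gl, man, 1e4, noise = FALSE)
    ## doubling cells AND control masses leaves everything unchanged
    man2 <- SpikeInManifest(controlNames(man), 2 * addedMasses(man),
                            man@controls$genome_length)
    p2 <- spikeAndSequence(2 * cells, gl, man2, 1e4, noise = FALSE)
    expect_equal(p1, p2, tolerance = 1e-12)
    ## doubling cells only roughly halves the control share
    p3 <- spikeAndSequence(2 * cells, gl, man, 1e4, noise = FALSE)
    ctl <- controlNames(man)
    ratio <- sum(p3[ctl]) / sum(p1[ctl])
    expect_gt(ratio, 0.45)
    expect_lt(ratio, 0.62)
    ## community shares are NOT unchanged in this direction: they rise by
    ## the (small) share the controls gave up
    comm <- setdiff(names(p1), ctl)
    expect_true(all(p3[comm] > p1[comm]))
    expect_equal(sum(p3[comm]) - sum(p1[comm]),
                 sum(p1[ctl]) - sum(p3[ctl]), tolerance = 1e-12)
})

test_that("study export writes readable plain-text artifacts", {
    fx <- smallFixture(10, seed = 6)
    des <- studyDesign(fx$taxa, arms = "B", n_subjects_per_arm = 2L,
                       visits = "baseline", read_depth = 1e4, seed = 1)
    sim <- simulateStudy(des)
    dir <- withr::local_tempdir()
    paths <- exportStudy(sim, dir)
    back <- readAbundanceTable(paths["relabund"])
    expect_equal(dim(back), dim(assay(relabund(sim))))
    md <- readStudyMetadata(paths["metadata"])
    expect_setequal(md$sample, colnames(back))
})
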