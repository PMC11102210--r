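test_that("calibration fitting matches closed-form least squares", {
    cv <- fitCalibration(c(0.01, 0.02, 0.04), c(1, 2, 4))
    expect_equal(cv@slope, 0.01, tolerance = 1e-12)
    expect_equal(cv@intercept, 0, tolerance = 1e-14)
    expect_equal(cv@rSquared, 1, tolerance = 1e-12)
    expect_true(cv@usable)

    ## flat line -> slope 0 -> unusable, but no error
    flat <- fitCalibration(c(0.02, 0.02), c(1, 2))
    expect_false(flat@usable)
    expect_error(dnaMassFromRelAbund(0.05, flat), "unusable")

    ## noisy points vs hand-computed OLS
    m <- c(1, 2, 4); r <- c(0.012, 0.019, 0.041)
    b1 <- sum((m - mean(m)) * (r - mean(r))) / sum((m - mean(m))^2)
    b0 <- mean(r) - b1 * mean(m)
    cv2 <- fitCalibration(r, m)
    expect_equal(cv2@slope, b1, tolerance = 1e-12)
    expect_equal(cv2@intercept, b0, tolerance = 1e-12)

    expect_error(fitCalibration(c(0.01, 0.02), c(2, 2)), "degenerate")
    ## zero-observed controls are kept as (mass, 0) points
    cv3 <- fitCalibration(c(0, 0.02, 0.04), c(1, 2, 4))
    expect_equal(cv3@nPoints, 3L)
})

test_that("mass prediction inverts the curve and clamps at zero", {
    cv <- fitCalibration(c(0.01, 0.02, 0.04), c(1, 2, 4))
    expect_equal(as.numeric(dnaMassFromRelAbund(0.05, cv)), 5,
                 tolerance = 1e-9)
    expect_equal(as.numeric(dnaMassFromRelAbund(cv@intercept, cv)), 0)
    cv2 <- fitCalibration(c(0.02, 0.03, 0.05), c(1, 2, 4))
    low <- dnaMassFromRelAbund(cv2@intercept - 0.01, cv2)
    expect_equal(as.numeric(low), 0)
    expect_true(attr(low, "clamped"))
})

test_that("CMU arithmetic follows mass / (genome length x bp weight)", {
    expect_equal(cmuFromMass(0, 2e6), 0)
    ## identity by construction: mass of exactly one 1-Mbp genome
    one_genome_ng <- 1e6 * 650 / 6.02214076e23 * 1e9
    expect_equal(cmuFromMass(one_genome_ng, 1e6), 1, tolerance = 1e-12)
    expect_equal(cmuFromMass(2, 2e6), (2e-9 * 6.02214076e23) / (2e6 * 650),
                 tolerance = 1e-12)
    expect_true(is.na(cmuFromMass(2, NA)))
})

test_that("quantifySample recovers truth on noise-free input", {
    fx <- smallFixture(25, seed = 13)
    gl <- namedGenomeLengths(fx$taxa)
    man <- defaultSpikeInManifest()
    set.seed(31)
    cells <- setNames(ifelse(runif(25) < 0.7, 10^runif(25, 3, 8), 0),
                      fx$taxa$name)
    col <- spikeAndSequence(cells, gl, man, 1e5, noise = FALSE)
    q <- quantifySample(col, man, gl)
    pres <- cells > 0
    expect_lt(max(abs(q$cmu[pres] - cells[pres]) / cells[pres]), 1e-6)
    expect_true(all(q$cmu[!pres] == 0))
    expect_equal(q$curve@rSquared, 1, tolerance = 1e-9)

    ## missing control is named in the error
    expect_error(quantifySample(col[-match("spikein_control_A", names(col))],
                                man, gl), "spikein_control_A")
    ## missing genome length -> unquantified, not dropped
    gl2 <- gl; gl2[3] <- NA
    q2 <- quantifySample(col, man, gl2)
    expect_true(names(gl)[3] %in% q2$unquantified)
    expect_true(is.na(q2$cmu[names(gl)[3]]))
    expect_equal(length(q2$cmu), 25L)
})

test_that("CMU scale equivariance and genome-size correction hold", {
    man <- defaultSpikeInManifest()
    gl <- c(t1 = 2e6, t2 = 4e6)
    cells <- c(t1 = 4e5, t2 = 2e5)  # equal DNA mass -> equal read share
    col <- spikeAndSequence(cells, gl, man, 1e5, noise = FALSE)
    expect_equal(unname(col["t1"]), unname(col["t2"]), tolerance = 1e-12)
    q <- quantifySample(col, man, gl)
    ## equal read share, genomes L vs 2L -> CMU ratio 2:1
    expect_equal(unname(q$cmu["t1"] / q$cmu["t2"]), 2, tolerance = 1e-9)
    ## scaling all control masses by c scales recovered CMU by c
    man3 <- SpikeInManifest(controlNames(man), 3 * addedMasses(man),
                            man@controls$genome_length)
    q3 <- quantifySample(col, man3, gl)
    expect_equal(q3$cmu, 3 * q$cmu, tolerance = 1e-9)
})

test_that("quantifySamples round-trips a whole simulated study", {
    fx <- smallFixture(30, seed = 17)
    des <- studyDesign(fx$taxa, arms = "B", n_subjects_per_arm = 6L,
                       visits = c("baseline", "week4"), read_depth = 1e5,
                       seed = 19)
    sim <- simulateStudy(des)
    cmu <- quantifySamples(relabund(sim), des@manifest)
    expect_s4_class(cmu, "CMUExperiment")
    expect_false(any(rowData(cmu)$is_control))
    tc <- trueCounts(sim)
    a <- cmuValues(cmu)[rownames(tc), colnames(tc)]
    pres <- tc > 0
    err <- abs(log10(a[pres] / tc[pres]))
    expect_lt(median(err), 0.1)
    rep <- calibrationReport(cmu)
    expect_equal(nrow(rep), ncol(a))
    expect_true(all(rep$usable))
    expect_true(all(rep$r_squared >= 0.99))
})

test_that("regression direction option changes the fit orientation", {
    r <- c(0.011, 0.022, 0.039); m <- c(1, 2, 4)
    fwd <- fitCalibration(r, m, direction = "relabund_on_mass")
    inv <- fitCalibration(r, m, direction = "mass_on_relabund")
    ## on exact data both orientations invert to the same masses
    exact <- fitCalibration(c(0.01, 0.02, 0.04), m)
    exact_inv <- fitCalibration(c(0.01, 0.02, 0.04), m,
                                direction = "mass_on_relabund")
    expect_equal(as.numeric(dnaMassFromRelAbund(0.03, exact)),
                 as.numeric(dnaMassFromRelAbund(0.03, exact_inv)),
                 tolerance = 1e-9)
    ## on noisy data they differ (distinct least-squares problems)
    expect_false(isTRUE(all.equal(
        as.numeric(dnaMassFromRelAbund(0.03, fwd)),
        as.numeric(dnaMassFromRelAbund(0.03, inv)))))
})
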