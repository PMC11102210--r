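#' @importFrom stats rbinom rnorm rmultinom runif rbeta setNames
NULL

## Physical constants used throughout quantification.
AVOGADRO <- 6.02214076e23   # molecules per mole
DEFAULT_W_BP <- 650         # g/mol per base pair, average dsDNA

## Deterministic 31-bit string hash; used to derive per-sample RNG
## sub-seeds from (subject, visit) so simulation output is independent
## of sample evaluation order.
stableHash <- function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
    as.integer(h)
}

subSeed <- function(master, sample_id) {
    as.integer((as.numeric(master) * 2654435 + stableHash(sample_id)) %%
               2147483647)
}

splitCategories <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
}

#' Build a classification fixture and matching taxon specifications
#'
#' Generates a species classification table (residency plus clinical
#' categories) whose residency-class counts match a requested mix, along
#' with per-taxon simulation parameters (genome length, log10 abundance
#' model, prevalence). Residency quotas use largest-remainder style
#' rounding in which the \code{"unknown"} class absorbs the rounding
#' residual; with the five-arm trial's study-level mix this reproduces
#' 236 oral / 228 transient / 110 unknown out of 574 candidate species.
#'
#' Oral taxa draw clinical categories independently at rates echoing the
#' study-level class ratios (commensal 158/236, gingivitis 67/236,
#' malodor 30/236, acidogenic 21/236); overlap between categories is
#' allowed, as observed in real plaque communities. Genome lengths are
#' uniform on 1.5--6.5 Mbp. Default prevalence is Beta-distributed per
#' residency class with means 0.51 (oral), 0.04 (transient) and 0.24
#' (unknown), so a 574-taxon community yields about 155 species per
#' sample of which about 120 are oral residents.
#'
#' @param n_species number of community species (>= 1).
#' @param class_mix named numeric vector of residency proportions over
#'   \code{c("oral", "transient_extraoral", "unknown")} (any subset),
#'   summing to 1.
#' @param seed integer seed; the fixture is deterministic given it.
#' @param category_rates named per-category Bernoulli rates for oral taxa.
#' @param prevalence_means named per-residency mean prevalence.
#' @param base_mean_range,base_sd_range ranges for the per-taxon log10
#'   abundance model (mean and SD of log10 cells when present).
#' @return A list with \code{classification} (data.frame: species,
#'   residency, categories, genome_length) and \code{taxa} (data.frame of
#'   full taxon specs for \code{\link{simulateStudy}}).
#' @examples
#' fx <- buildClassificationFixture(574,
#'     c(oral = 236, transient_extraoral = 228, unknown = 109) / 573,
#'     seed = 1)
#' table(fx$classification$residency)
#' @export
buildClassificationFixture <- function(n_species, class_mix, seed = 1L,
        category_rates = c(commensal = 158 / 236, gingivitis = 67 / 236,
                           malodor = 30 / 236, acidogenic = 21 / 236),
        prevalence_means = c(oral = 0.51, transient_extraoral = 0.04,
                             unknown = 0.24),
        base_mean_range = c(3, 7.5), base_sd_range = c(0.4, 1.0)) {
    stopifnot(n_species >= 1)
    if (any(class_mix < 0))
        stop("class_mix proportions must be non-negative")
    if (abs(sum(class_mix) - 1) > 1e-9)
        stop("class_mix proportions must sum to 1")
    if (!all(names(class_mix) %in% VALID_RESIDENCY))
        stop("unknown residency class in class_mix")

    quota <- class_mix * n_species
    counts <- setNames(integer(length(quota)), names(quota))
    if ("unknown" %in% names(quota) && length(quota) > 1L) {
        named <- setdiff(names(quota), "unknown")
        counts[named] <- round(quota[named])
        counts["unknown"] <- n_species - sum(counts[named])
        if (counts["unknown"] < 0)
            stop("class_mix rounding produced a negative 'unknown' count")
    } else {
        base <- floor(quota)
        left <- n_species - sum(base)
        if (left > 0) {
            rem <- quota - base
            take <- order(rem, decreasing = TRUE)[seq_len(left)]
            base[take] <- base[take] + 1
        }
        counts[] <- base
    }

    set.seed(seed)
    residency <- rep(names(counts), counts)
    n <- length(residency)
    species <- sprintf("Species_%03d", seq_len(n))
    genome_length <- round(runif(n, 1.5e6, 6.5e6))
    cats <- character(n)
    oral <- residency == "oral"
    for (cg in names(category_rates)) {
        hit <- oral & runif(n) < category_rates[[cg]]
        cats[hit] <- ifelse(nzchar(cats[hit]), paste(cats[hit], cg, sep = ";"),
                            cg)
    }
    prev_m <- prevalence_means[residency]
    k <- 6
    prevalence <- rbeta(n, k * prev_m, k * (1 - prev_m))
    taxa <- data.frame(
        name = species, genome_length = genome_length, residency = residency,
        categories = cats,
        base_log10_mean = runif(n, base_mean_range[1], base_mean_range[2]),
        base_log10_sd = runif(n, base_sd_range[1], base_sd_range[2]),
        prevalence = prevalence, stringsAsFactors = FALSE)
    classification <- taxa[, c("name", "residency", "categories",
                               "genome_length")]
    names(classification)[1] <- "species"
    rownames(classification) <- rownames(taxa) <- NULL
    list(classification = classification, taxa = taxa)
}

#' Construct a synthetic study design
#'
#' @param taxa taxon specification data.frame as produced by
#'   \code{\link{buildClassificationFixture}}.
#' @param arms character vector of unique arm labels.
#' @param effects data.frame with columns \code{arm}, \code{visit},
#'   \code{category}, \code{effect}: the log10 shift applied to taxa of
#'   that category in that arm at that visit (negative = reduction). A
#'   taxon carrying several affected categories receives the minimum
#'   (most negative) applicable effect.
#' @param n_subjects_per_arm subjects per arm.
#' @param visits ordered visit labels.
#' @param read_depth reads per sample for multinomial sequencing.
#' @param manifest \linkS4class{SpikeInManifest}.
#' @param seed master integer seed.
#' @return A \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(taxa, arms, effects = emptyEffects(),
                        n_subjects_per_arm = 50L,
                        visits = c("baseline", "week4", "week12"),
                        read_depth = 3.5e6,
                        manifest = defaultSpikeInManifest(), seed = 1L) {
    new("StudyDesign", taxa = taxa, arms = as.character(arms),
        effects = effects, nSubjectsPerArm = as.integer(n_subjects_per_arm),
        visits = as.character(visits), readDepth = as.integer(read_depth),
        manifest = manifest, seed = as.integer(seed))
}

#' @rdname studyDesign
#' @export
emptyEffects <- function() {
    data.frame(arm = character(), visit = character(),
               category = character(), effect = numeric(),
               stringsAsFactors = FALSE)
}

#' Default arm-by-visit category effects
#'
#' Log10 category effects for the five oral-care arms, derived from the
#' percent reductions the trial reported versus the brushing-and-flossing
#' control: for a reported reduction of p percent the imposed effect is
#' \code{log10(1 - p/100)}. Brushing (B) and brushing-plus-flossing (BF)
#' have no effect; the mouthrinse arms (BA, BZ, BFZ) reduce commensal,
#' gingivitis and malodor categories at week 4 and week 12.
#'
#' @return effects data.frame suitable for \code{\link{studyDesign}}.
#' @export
defaultArmEffects <- function() {
    pct <- rbind(
        c("BA",  "week4",  "commensal",  82.0),
        c("BA",  "week12", "commensal",  75.4),
        c("BA",  "week4",  "gingivitis", 93.6),
        c("BA",  "week12", "gingivitis", 91.3),
        c("BA",  "week4",  "malodor",    88.5),
        c("BA",  "week12", "malodor",    85.2),
        c("BZ",  "week4",  "commensal",  58.2),
        c("BZ",  "week12", "commensal",  46.6),
        c("BZ",  "week4",  "gingivitis", 85.8),
        c("BZ",  "week12", "gingivitis", 80.2),
        c("BZ",  "week4",  "malodor",    68.5),
        c("BFZ", "week4",  "commensal",  52.6),
        c("BFZ", "week4",  "gingivitis", 84.5),
        c("BFZ", "week12", "gingivitis", 75.9),
        c("BFZ", "week4",  "malodor",    60.7))
    data.frame(arm = pct[, 1], visit = pct[, 2], category = pct[, 3],
               effect = log10(1 - as.numeric(pct[, 4]) / 100),
               stringsAsFactors = FALSE)
}

#' Default full-scale study design
#'
#' Emulates the five-arm, three-visit gingivitis trial: 574 candidate
#' species with the study-level residency mix, 50 subjects per arm,
#' 3.5 million reads per sample, and the default mouthrinse effects.
#'
#' @param seed master seed.
#' @return A \linkS4class{StudyDesign}.
#' @export
defaultStudyDesign <- function(seed = 1L) {
    fx <- buildClassificationFixture(
        574, c(oral = 236, transient_extraoral = 228, unknown = 109) / 573,
        seed = seed)
    studyDesign(fx$taxa, arms = c("B", "BF", "BA", "BZ", "BFZ"),
                effects = defaultArmEffects(), n_subjects_per_arm = 50L,
                read_depth = 3.5e6, seed = seed)
}

## Effect applied to one taxon's categories at (arm, visit): the minimum
## (most negative) over applicable category effects, 0 when none apply.
effectFor <- function(categories, arm, visit, effects) {
    if (!nrow(effects) || !length(categories)) return(0)
    hit <- effects$arm == arm & effects$visit == visit &
        effects$category %in% categories
    if (!any(hit)) 0 else min(effects$effect[hit])
}

#' Spike a community and sequence it to relative abundances
#'
#' Converts one sample's true cell counts plus the spike-in controls into
#' an observed relative-abundance column. Expected read share of a
#' community taxon is proportional to \code{cells x genome_length}
#' (shotgun reads scale with DNA mass, not cell number); each control
#' contributes its added mass converted to base-pair equivalents via the
#' base-pair molecular weight. Reads are drawn multinomially at
#' \code{read_depth} and divided by the depth, so the returned column
#' sums to one.
#'
#' @param cells named non-negative vector of true cell counts.
#' @param genome_lengths named vector of community genome lengths (bp).
#' @param manifest \linkS4class{SpikeInManifest}; control names must be
#'   disjoint from the community taxa.
#' @param read_depth reads to draw (>= 1).
#' @param seed integer seed for the multinomial draw.
#' @param w_bp base-pair molecular weight, g/mol per bp.
#' @param noise if \code{FALSE}, return the expected (infinite-depth)
#'   proportions instead of a multinomial draw.
#' @return Named numeric vector of proportions over community taxa plus
#'   controls, summing to 1.
#' @export
spikeAndSequence <- function(cells, genome_lengths, manifest, read_depth,
                             seed = 1L, w_bp = DEFAULT_W_BP, noise = TRUE) {
    stopifnot(read_depth >= 1)
    taxa <- names(cells)
    if (is.null(taxa) || !identical(taxa, names(genome_lengths)))
        stop("cells and genome_lengths must share names")
    ctl <- manifest@controls
    if (any(ctl$name %in% taxa))
        stop("control taxa must be disjoint from community taxa")
    if (all(cells == 0))
        stop("empty community: all true cell counts are zero")
    comm_bp <- cells * genome_lengths
    ctl_bp <- ctl$added_mass_ng * 1e-9 * AVOGADRO / w_bp
    w <- c(comm_bp, setNames(ctl_bp, ctl$name))
    p <- w / sum(w)
    if (!noise) return(p)
    set.seed(seed)
    reads <- rmultinom(1, size = read_depth, prob = p)[, 1]
    reads / read_depth
}

#' Simulate a complete study
#'
#' For every subject-by-visit sample, each taxon is present with its
#' prevalence (independent Bernoulli draws); present taxa receive
#' \code{10^Normal(base_log10_mean + effect, base_log10_sd)} cells, where
#' the effect is the minimum applicable arm-by-visit category effect.
#' Each sample is then spiked and sequenced with
#' \code{\link{spikeAndSequence}}. Per-sample RNG sub-seeds are derived
#' by stable hashing of the sample identifier, so results do not depend
#' on evaluation order and are reproducible for a fixed design seed.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return A \linkS4class{SimulatedStudy}.
#' @examples
#' fx <- buildClassificationFixture(20, c(oral = 0.6, unknown = 0.4), seed = 2)
#' des <- studyDesign(fx$taxa, arms = "B", n_subjects_per_arm = 3L,
#'                    visits = "baseline", read_depth = 1e4, seed = 2)
#' sim <- simulateStudy(des)
#' dim(assay(relabund(sim)))
#' @export
simulateStudy <- function(design) {
    validObject(design)
    tx <- design@taxa
    cats <- splitCategories(tx$categories)
    grid <- expand.grid(subject = seq_len(design@nSubjectsPerArm),
                        arm = design@arms, visit = design@visits,
                        stringsAsFactors = FALSE)
    grid <- grid[order(match(grid$arm, design@arms), grid$subject,
                       match(grid$visit, design@visits)), ]
    subject <- sprintf("%s_S%02d", grid$arm, grid$subject)
    sample_id <- paste(subject, grid$visit, sep = "_")
    md <- data.frame(sample = sample_id, subject = subject, arm = grid$arm,
                     visit = grid$visit, stringsAsFactors = FALSE)
    rownames(md) <- NULL

    n_tx <- nrow(tx)
    true_counts <- matrix(0, n_tx, nrow(md),
                          dimnames = list(tx$name, md$sample))
    ctl_names <- design@manifest@controls$name
    relab <- matrix(0, n_tx + length(ctl_names), nrow(md),
                    dimnames = list(c(tx$name, ctl_names), md$sample))
    gl <- setNames(tx$genome_length, tx$name)

    for (j in seq_len(nrow(md))) {
        sid <- md$sample[j]
        set.seed(subSeed(design@seed, sid))
        present <- runif(n_tx) < tx$prevalence
        eff <- vapply(cats, effectFor, numeric(1),
                      arm = md$arm[j], visit = md$visit[j],
                      effects = design@effects)
        mu <- tx$base_log10_mean + eff
        cells <- ifelse(present, 10^rnorm(n_tx, mu, tx$base_log10_sd), 0)
        true_counts[, j] <- cells
        relab[, j] <- spikeAndSequence(
            setNames(cells, tx$name), gl, design@manifest, design@readDepth,
            seed = subSeed(design@seed + 1L, sid))
    }

    rd <- DataFrame(
        taxon = rownames(relab),
        is_control = rownames(relab) %in% ctl_names,
        genome_length = c(tx$genome_length,
                          design@manifest@controls$genome_length),
        residency = c(tx$residency, rep(NA_character_, length(ctl_names))),
        categories = c(tx$categories, rep("", length(ctl_names))))
    rae <- RelAbundExperiment(relab, rowData = rd, colData = md)
    new("SimulatedStudy", trueCounts = true_counts, relabund = rae,
        metadata = md,
        truthLog = list(seed = design@seed, effects = design@effects,
                        arms = design@arms, visits = design@visits,
                        n_subjects_per_arm = design@nSubjectsPerArm,
                        read_depth = design@readDepth))
}

#' @rdname SimulatedStudy-class
#' @param x a \code{SimulatedStudy}.
#' @export
relabund <- function(x) x@relabund

#' @rdname SimulatedStudy-class
#' @export
trueCounts <- function(x) x@trueCounts

#' @rdname SimulatedStudy-class
#' @export
studyMetadata <- function(x) x@metadata

#' @rdname SimulatedStudy-class
#' @export
truthLog <- function(x) x@truthLog

setMethod("show", "SimulatedStudy", function(object) {
    cat("SimulatedStudy:", nrow(object@trueCounts), "taxa x",
        ncol(object@trueCounts), "samples\n")
    cat("  arms:", paste(unique(object@metadata$arm), collapse = ", "), "\n")
    cat("  visits:", paste(unique(object@metadata$visit), collapse = ", "),
        "\n")
})

#' Construct a RelAbundExperiment
#'
#' @param relabund taxa x samples matrix of proportions; every column
#'   must sum to 1 within 1e-6.
#' @param rowData,colData optional annotations.
#' @return A \linkS4class{RelAbundExperiment}.
#' @export
RelAbundExperiment <- function(relabund, rowData = NULL, colData = NULL) {
    args <- list(assays = list(relabund = relabund))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    new("RelAbundExperiment", se)
}
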