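#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

VALID_RESIDENCY <- c("oral", "transient_extraoral", "unknown")
VALID_CATEGORIES <- c("commensal", "gingivitis", "malodor", "acidogenic")

#' Spike-in control manifest
#'
#' Describes the exogenous DNA controls added to each specimen before
#' extraction: control taxon name, added DNA mass in nanograms, and control
#' genome length in base pairs. The per-sample calibration curve is fitted
#' on these controls, so at least two controls with two distinct masses are
#' required.
#'
#' @slot controls data.frame with columns \code{name}, \code{added_mass_ng},
#'   \code{genome_length}.
#' @export
setClass("SpikeInManifest", representation(controls = "data.frame"))

setValidity("SpikeInManifest", function(object) {
    ctl <- object@controls
    msg <- character()
    need <- c("name", "added_mass_ng", "genome_length")
    if (!all(need %in% colnames(ctl)))
        return(paste("controls must have columns:", paste(need, collapse = ", ")))
    if (nrow(ctl) < 2L)
        msg <- c(msg, "at least 2 spike-in controls are required")
    if (anyDuplicated(ctl$name))
        msg <- c(msg, "control names must be unique")
    if (any(ctl$added_mass_ng <= 0))
        msg <- c(msg, "added masses must be > 0 ng")
    if (length(unique(ctl$added_mass_ng)) < 2L)
        msg <- c(msg, "at least 2 distinct added masses are required")
    if (any(ctl$genome_length < 1))
        msg <- c(msg, "control genome lengths must be >= 1 bp")
    if (length(msg)) msg else TRUE
})

#' Per-sample spike-in calibration curve
#'
#' Ordinary least-squares fit of observed control relative abundance on
#' added control DNA mass (ng). A curve with non-positive slope is flagged
#' unusable and cannot be inverted to predict masses.
#'
#' @slot sample sample identifier.
#' @slot slope relative abundance per ng.
#' @slot intercept relative abundance at zero added mass.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nPoints number of control points used.
#' @slot usable logical; FALSE when slope <= 0.
#' @slot direction \code{"relabund_on_mass"} (default; inverted for mass
#'   prediction) or \code{"mass_on_relabund"} (direct prediction).
#' @export
setClass("CalibrationCurve", representation(
    sample = "character", slope = "numeric", intercept = "numeric",
    rSquared = "numeric", nPoints = "integer", usable = "logical",
    direction = "character"))

setValidity("CalibrationCurve", function(object) {
    if (object@nPoints < 2L) return("a calibration curve needs >= 2 points")
    if (!(object@rSquared >= -1e-12 && object@rSquared <= 1 + 1e-12))
        return("R-squared must lie in [0, 1]")
    TRUE
})

#' Relative-abundance experiment
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' \code{"relabund"} holds per-sample species proportions (including any
#' spike-in control rows, flagged in \code{rowData(x)$is_control}). Every
#' sample column must sum to one.
#'
#' @export
setClass("RelAbundExperiment", contains = "SummarizedExperiment")

setValidity("RelAbundExperiment", function(object) {
    if (!"relabund" %in% assayNames(object))
        return("assay 'relabund' is required")
    a <- assay(object, "relabund")
    if (any(a < -1e-12)) return("relative abundances must be >= 0")
    if (ncol(a) > 0L) {
        cs <- colSums(a)
        if (any(abs(cs - 1) > 1e-6))
            return(sprintf("sample columns must sum to 1 (worst deviation %.3g)",
                           max(abs(cs - 1))))
    }
    TRUE
})

#' Absolute-abundance (CMU) experiment
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"cmu"} holds
#' absolute per-species abundances in calculated microbial units (cells).
#' Spike-in control rows are excluded. Calibration provenance (per-sample
#' curves, the base-pair molecular weight constant and the Avogadro
#' constant used) is stored in \code{metadata(x)}.
#'
#' @export
setClass("CMUExperiment", contains = "SummarizedExperiment")

setValidity("CMUExperiment", function(object) {
    if (!"cmu" %in% assayNames(object)) return("assay 'cmu' is required")
    a <- assay(object, "cmu")
    if (any(a[!is.na(a)] < 0)) return("CMU values must be >= 0")
    rd <- rowData(object)
    if ("is_control" %in% colnames(rd) && any(rd$is_control))
        return("spike-in control rows must be excluded from a CMUExperiment")
    TRUE
})

#' Synthetic study design
#'
#' Parameters for the synthetic study generator: taxon specifications,
#' treatment arms with per-category log10 effects per visit, subjects per
#' arm, ordered visits, sequencing depth, spike-in manifest, and master
#' seed.
#'
#' @slot taxa data.frame with columns \code{name}, \code{genome_length},
#'   \code{residency}, \code{categories} (semicolon-joined),
#'   \code{base_log10_mean}, \code{base_log10_sd}, \code{prevalence}.
#' @slot arms character vector of unique arm labels.
#' @slot effects data.frame with columns \code{arm}, \code{visit},
#'   \code{category}, \code{effect} (log10 shift, typically <= 0).
#' @slot nSubjectsPerArm integer.
#' @slot visits ordered character vector of visit labels.
#' @slot readDepth integer sequencing depth (reads per sample).
#' @slot manifest \linkS4class{SpikeInManifest}.
#' @slot seed integer master seed.
#' @export
setClass("StudyDesign", representation(
    taxa = "data.frame", arms = "character", effects = "data.frame",
    nSubjectsPerArm = "integer", visits = "character", readDepth = "integer",
    manifest = "SpikeInManifest", seed = "integer"))

setValidity("StudyDesign", function(object) {
    msg <- character()
    tx <- object@taxa
    need <- c("name", "genome_length", "residency", "categories",
              "base_log10_mean", "base_log10_sd", "prevalence")
    if (!all(need %in% colnames(tx)))
        return(paste("taxa must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tx$name)) msg <- c(msg, "taxon names must be unique")
    if (any(tx$genome_length < 1)) msg <- c(msg, "genome lengths must be >= 1 bp")
    if (!all(tx$residency %in% VALID_RESIDENCY))
        msg <- c(msg, "invalid residency value")
    if (any(tx$prevalence < 0 | tx$prevalence > 1))
        msg <- c(msg, "prevalence must lie in [0, 1]")
    if (any(tx$base_log10_sd < 0)) msg <- c(msg, "base_log10_sd must be >= 0")
    cats <- strsplit(tx$categories, ";", fixed = TRUE)
    nonoral <- tx$residency != "oral" & vapply(cats, function(x)
        any(nzchar(x)), logical(1))
    if (any(nonoral))
        msg <- c(msg, "only oral taxa may carry clinical categories")
    bad <- setdiff(unlist(cats), c(VALID_CATEGORIES, ""))
    if (length(bad))
        msg <- c(msg, paste("unknown categories:", paste(bad, collapse = ", ")))
    if (anyDuplicated(object@arms)) msg <- c(msg, "arm labels must be unique")
    ef <- object@effects
    if (nrow(ef)) {
        if (!all(c("arm", "visit", "category", "effect") %in% colnames(ef)))
            return("effects must have columns arm, visit, category, effect")
        if (!all(ef$category %in% VALID_CATEGORIES))
            msg <- c(msg, paste("effect references unknown category:",
                                paste(setdiff(ef$category, VALID_CATEGORIES),
                                      collapse = ", ")))
        if (!all(ef$arm %in% object@arms))
            msg <- c(msg, "effect references unknown arm")
        if (!all(ef$visit %in% object@visits))
            msg <- c(msg, "effect references unknown visit")
    }
    if (object@nSubjectsPerArm < 1L) msg <- c(msg, "need >= 1 subject per arm")
    if (object@readDepth < 1L) msg <- c(msg, "read depth must be > 0")
    if (length(msg)) msg else TRUE
})

#' Simulated study bundle
#'
#' Holds the generator's ground truth (true cell counts), the observed
#' relative-abundance experiment after spike-in and multinomial read
#' sampling, per-sample metadata, and a truth log recording the imposed
#' effects and seed.
#'
#' @slot trueCounts species x sample matrix of true cell counts.
#' @slot relabund \linkS4class{RelAbundExperiment} of observed proportions
#'   (community taxa plus spike-in control rows).
#' @slot metadata data.frame with columns \code{sample}, \code{subject},
#'   \code{arm}, \code{visit}.
#' @slot truthLog list recording design parameters and imposed effects.
#' @export
setClass("SimulatedStudy", representation(
    trueCounts = "matrix", relabund = "RelAbundExperiment",
    metadata = "data.frame", truthLog = "list"))

setValidity("SimulatedStudy", function(object) {
    msg <- character()
    if (any(object@trueCounts < 0)) msg <- c(msg, "true counts must be >= 0")
    sam <- colnames(object@relabund)
    if (!identical(sort(sam), sort(object@metadata$sample)) ||
        anyDuplicated(object@metadata$sample))
        msg <- c(msg, "metadata must cover every sample exactly once")
    if (length(msg)) msg else TRUE
})

#' Principal-coordinate ordination result
#'
#' @slot coordinates samples x axes matrix (axes ordered by descending
#'   eigenvalue; only positive-eigenvalue axes are retained).
#' @slot eigenvalues all eigenvalues, descending.
#' @slot proportionExplained per retained axis, computed over the positive
#'   eigenvalues.
#' @export
setClass("OrdinationResult", representation(
    coordinates = "matrix", eigenvalues = "numeric",
    proportionExplained = "numeric"))

#' PERMANOVA result
#'
#' One-factor permutational multivariate ANOVA on a distance matrix,
#' with the permutation p-value computed as
#' \code{(1 + # permuted F >= observed F) / (1 + n permutations)}.
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot pValue permutation p-value in (0, 1].
#' @slot nPermutations number of permutations.
#' @slot seed RNG seed used for the permutations.
#' @slot ssAmong,ssWithin among/within-group sums of squared distances.
#' @slot dfAmong,dfWithin degrees of freedom.
#' @export
setClass("PermanovaResult", representation(
    pseudoF = "numeric", pValue = "numeric", nPermutations = "integer",
    seed = "integer", ssAmong = "numeric", ssWithin = "numeric",
    dfAmong = "integer", dfWithin = "integer"))

setValidity("PermanovaResult", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("p-value must lie in (0, 1]")
    if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
        return("p-value cannot be below 1/(n_perm + 1)")
    TRUE
})
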