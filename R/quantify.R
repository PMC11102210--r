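#' Fit a per-sample spike-in calibration curve
#'
#' Ordinary least squares of observed control relative abundance on added
#' control DNA mass (the orientation written into the analysis methods);
#' the inverse orientation (mass on relative abundance) is selectable for
#' sensitivity analyses. The intercept absorbs background signal; a
#' through-origin fit is available via \code{intercept = FALSE}. A fitted
#' slope <= 0 flags the curve unusable rather than erroring, so a whole
#' study can be processed and failed samples reported.
#'
#' Controls observed at zero relative abundance are retained as
#' \code{(mass, 0)} points, not dropped.
#'
#' @param control_relabunds observed relative abundances of the controls.
#' @param added_masses added DNA masses (ng), same order; at least two
#'   distinct values.
#' @param sample sample identifier recorded in the curve.
#' @param intercept fit an intercept (default) or force through origin.
#' @param direction regression orientation, see Details.
#' @return A \linkS4class{CalibrationCurve}.
#' @examples
#' fitCalibration(c(0.01, 0.02, 0.04), c(1, 2, 4))
#' @export
fitCalibration <- function(control_relabunds, added_masses,
                           sample = NA_character_, intercept = TRUE,
                           direction = c("relabund_on_mass",
                                         "mass_on_relabund")) {
    direction <- match.arg(direction)
    y <- as.numeric(control_relabunds)
    m <- as.numeric(added_masses)
    if (length(y) != length(m) || length(y) < 2L)
        stop("need equal-length vectors with >= 2 points")
    if (length(unique(m)) < 2L)
        stop("degenerate calibration: fewer than 2 distinct added masses")
    if (direction == "mass_on_relabund") { tmp <- y; y <- m; m <- tmp }
    if (intercept) {
        fit <- stats::lm.fit(cbind(1, m), y)
        b0 <- unname(fit$coefficients[1]); b1 <- unname(fit$coefficients[2])
    } else {
        fit <- stats::lm.fit(cbind(m), y)
        b0 <- 0; b1 <- unname(fit$coefficients[1])
    }
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
    ## squash numerically-zero slopes from flat fits
    if (is.finite(b1) && abs(b1) < 100 * .Machine$double.eps) b1 <- 0
    new("CalibrationCurve", sample = as.character(sample), slope = b1,
        intercept = b0, rSquared = r2, nPoints = length(y),
        usable = is.finite(b1) && b1 > 0, direction = direction)
}

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve [%s]: slope %.4g, intercept %.4g, R^2 %.4f (%d points)%s\n",
        object@sample, object@slope, object@intercept, object@rSquared,
        object@nPoints, if (object@usable) "" else " [UNUSABLE]"))
})

#' Predict DNA mass from relative abundance
#'
#' Inverts (or applies, depending on the curve's orientation) the
#' calibration line. Negative predicted masses are clamped to zero; the
#' number of clamped values is attached as attribute \code{"clamped"}.
#'
#' @param r relative abundance(s).
#' @param curve a usable \linkS4class{CalibrationCurve}.
#' @return Predicted DNA mass(es) in ng, with attribute \code{"clamped"}
#'   (logical vector marking values clamped at 0).
#' @export
dnaMassFromRelAbund <- function(r, curve) {
    if (!curve@usable)
        stop("calibration curve is unusable (slope <= 0)")
    mass <- if (curve@direction == "relabund_on_mass")
        (r - curve@intercept) / curve@slope
    else
        curve@intercept + curve@slope * r
    clamped <- mass < 0
    mass[clamped] <- 0
    attr(mass, "clamped") <- clamped
    mass
}

#' Convert DNA mass to calculated microbial units
#'
#' CMU = (mass in grams x Avogadro's number) / (genome length x base-pair
#' molecular weight), i.e. the number of genome copies the DNA mass
#' corresponds to.
#'
#' @param mass DNA mass in ng (>= 0).
#' @param genome_length genome length in bp (>= 1); \code{NA} yields
#'   \code{NA} (taxon unquantified).
#' @param w_bp base-pair molecular weight, g/mol per bp (default 650,
#'   the standard average for double-stranded DNA).
#' @return CMU value(s) (cells).
#' @examples
#' cmuFromMass(2, 2e6)  # ~9.26e5 CMU
#' @export
cmuFromMass <- function(mass, genome_length, w_bp = DEFAULT_W_BP) {
    stopifnot(all(mass >= 0, na.rm = TRUE))
    (mass * 1e-9 * AVOGADRO) / (genome_length * w_bp)
}

#' Quantify one sample column
#'
#' Fits the spike-in calibration on the manifest's controls as observed
#' in the column, converts every non-control taxon's relative abundance
#' to DNA mass and then to CMU, and reports the curve, the number of
#' clamped (below-background) values, and any taxa left unquantified for
#' lack of a genome length.
#'
#' @param column named relative-abundance vector for one sample,
#'   including all manifest controls.
#' @param manifest \linkS4class{SpikeInManifest}.
#' @param genome_lengths named vector of genome lengths (bp) for the
#'   community taxa; missing or \code{NA} entries leave the taxon
#'   unquantified (\code{NA} CMU), never silently dropped.
#' @param sample sample identifier for provenance.
#' @param w_bp base-pair molecular weight (g/mol per bp).
#' @param intercept,direction passed to \code{\link{fitCalibration}}.
#' @return List with \code{cmu} (named vector over non-control taxa),
#'   \code{curve}, \code{clamp_count}, \code{unquantified} (taxon names).
#' @export
quantifySample <- function(column, manifest, genome_lengths,
                           sample = NA_character_, w_bp = DEFAULT_W_BP,
                           intercept = TRUE,
                           direction = "relabund_on_mass") {
    ctl <- manifest@controls
    missing_ctl <- setdiff(ctl$name, names(column))
    if (length(missing_ctl))
        stop("incomplete spike-in: control(s) missing from sample: ",
             paste(missing_ctl, collapse = ", "))
    curve <- fitCalibration(column[ctl$name], ctl$added_mass_ng,
                            sample = sample, intercept = intercept,
                            direction = direction)
    comm <- setdiff(names(column), ctl$name)
    gl <- genome_lengths[comm]
    mass <- dnaMassFromRelAbund(column[comm], curve)
    cmu <- cmuFromMass(as.numeric(mass), as.numeric(gl), w_bp = w_bp)
    names(cmu) <- comm
    unq <- comm[is.na(gl)]
    list(cmu = cmu, curve = curve,
         clamp_count = sum(attr(mass, "clamped")), unquantified = unq)
}

#' Quantify all samples of a relative-abundance experiment
#'
#' Applies \code{\link{quantifySample}} column by column and assembles a
#' \linkS4class{CMUExperiment}: control rows are dropped, row annotations
#' are carried over, and per-sample calibration provenance (curves, clamp
#' counts, constants) is stored in \code{metadata()}.
#'
#' @param x \linkS4class{RelAbundExperiment} whose
#'   \code{rowData(x)$genome_length} supplies community genome lengths
#'   and \code{rowData(x)$is_control} (if present) flags control rows
#'   in addition to the manifest names.
#' @param manifest \linkS4class{SpikeInManifest}.
#' @param w_bp,intercept,direction see \code{\link{quantifySample}}.
#' @return A \linkS4class{CMUExperiment}.
#' @rdname quantifySamples
#' @export
setMethod("quantifySamples", "RelAbundExperiment",
    function(x, manifest, w_bp = DEFAULT_W_BP, intercept = TRUE,
             direction = "relabund_on_mass") {
    a <- assay(x, "relabund")
    rd <- rowData(x)
    gl <- if ("genome_length" %in% colnames(rd))
        setNames(as.numeric(rd$genome_length), rownames(x))
    else stop("rowData(x)$genome_length is required for quantification")
    comm <- setdiff(rownames(a), manifest@controls$name)
    out <- matrix(NA_real_, length(comm), ncol(a),
                  dimnames = list(comm, colnames(a)))
    curves <- vector("list", ncol(a))
    clamp <- integer(ncol(a))
    unq <- character()
    for (j in seq_len(ncol(a))) {
        q <- quantifySample(a[, j], manifest, gl, sample = colnames(a)[j],
                            w_bp = w_bp, intercept = intercept,
                            direction = direction)
        out[, j] <- q$cmu[comm]
        curves[[j]] <- q$curve
        clamp[j] <- q$clamp_count
        unq <- union(unq, q$unquantified)
    }
    names(curves) <- colnames(a)
    se <- SummarizedExperiment(
        assays = list(cmu = out),
        rowData = rd[match(comm, rownames(x)), , drop = FALSE],
        colData = colData(x))
    metadata(se)$calibration <- curves
    metadata(se)$clamp_count <- setNames(clamp, colnames(a))
    metadata(se)$w_bp <- w_bp
    metadata(se)$avogadro <- AVOGADRO
    metadata(se)$unquantified <- unq
    new("CMUExperiment", se)
})

#' @rdname CMUExperiment-accessors
#' @param x a \linkS4class{CMUExperiment}.
#' @export
setMethod("cmuValues", "CMUExperiment", function(x) assay(x, "cmu"))

#' @rdname CMUExperiment-accessors
#' @export
setMethod("calibrationCurves", "CMUExperiment", function(x)
    metadata(x)$calibration)

#' Per-sample calibration report
#'
#' @param x a \linkS4class{CMUExperiment}.
#' @return data.frame with one row per sample: slope, intercept,
#'   R-squared, points used, usability flag, clamp count.
#' @export
calibrationReport <- function(x) {
    cv <- calibrationCurves(x)
    data.frame(
        sample = names(cv),
        slope = vapply(cv, slot, numeric(1), "slope"),
        intercept = vapply(cv, slot, numeric(1), "intercept"),
        r_squared = vapply(cv, slot, numeric(1), "rSquared"),
        n_points = vapply(cv, slot, integer(1), "nPoints"),
        usable = vapply(cv, slot, logical(1), "usable"),
        clamp_count = as.integer(metadata(x)$clamp_count),
        row.names = NULL, stringsAsFactors = FALSE)
}
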