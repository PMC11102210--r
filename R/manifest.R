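#' Construct a spike-in manifest
#'
#' @param name character vector of control taxon names.
#' @param added_mass_ng numeric vector of added DNA masses (ng), > 0, with
#'   at least two distinct values.
#' @param genome_length integer vector of control genome lengths (bp).
#' @return A \linkS4class{SpikeInManifest}.
#' @examples
#' SpikeInManifest(c("ctrl_lo", "ctrl_mid", "ctrl_hi"),
#'                 c(0.5, 2, 8), c(2e6, 3e6, 4e6))
#' @export
SpikeInManifest <- function(name, added_mass_ng, genome_length) {
    new("SpikeInManifest", controls = data.frame(
        name = as.character(name),
        added_mass_ng = as.numeric(added_mass_ng),
        genome_length = as.numeric(genome_length),
        stringsAsFactors = FALSE))
}

#' Default three-control spike-in manifest
#'
#' The composition of the commercial spike-in standard is not public, so
#' the default manifest uses three synthetic controls spanning a 16-fold
#' mass range with genome lengths typical of bacterial spike-in strains.
#'
#' @return A \linkS4class{SpikeInManifest} with three controls.
#' @export
defaultSpikeInManifest <- function() {
    SpikeInManifest(
        name = c("spikein_control_A", "spikein_control_B", "spikein_control_C"),
        added_mass_ng = c(0.5, 2, 8),
        genome_length = c(2.2e6, 3.5e6, 4.8e6))
}

#' @rdname SpikeInManifest-class
#' @param x a \code{SpikeInManifest}.
#' @export
setMethod("controlNames", "SpikeInManifest", function(x) x@controls$name)

#' @rdname SpikeInManifest-class
#' @export
setMethod("addedMasses", "SpikeInManifest", function(x) {
    stats::setNames(x@controls$added_mass_ng, x@controls$name)
})

#' @rdname SpikeInManifest-class
#' @export
setMethod("length", "SpikeInManifest", function(x) nrow(x@controls))

setMethod("show", "SpikeInManifest", function(object) {
    cat("SpikeInManifest with", nrow(object@controls), "controls\n")
    print(object@controls, row.names = FALSE)
})

#' Read / write a spike-in manifest
#'
#' TSV schema: columns \code{name}, \code{added_mass_ng},
#' \code{genome_length}; one control per row.
#'
#' @param path file path.
#' @return \code{readSpikeInManifest} returns a
#'   \linkS4class{SpikeInManifest}; \code{writeSpikeInManifest} returns
#'   \code{path} invisibly.
#' @export
readSpikeInManifest <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    SpikeInManifest(df$name, df$added_mass_ng, df$genome_length)
}

#' @rdname readSpikeInManifest
#' @param manifest a \linkS4class{SpikeInManifest}.
#' @export
writeSpikeInManifest <- function(manifest, path) {
    utils::write.table(manifest@controls, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
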