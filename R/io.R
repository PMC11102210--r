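## Numeric serialization at 12 significant digits so identical runs
## produce byte-identical output files.
formatNum <- function(x) {
    y <- formatC(x, digits = 12, format = "g")
    dim(y) <- dim(x)
    dimnames(y) <- dimnames(x)
    y
}

#' Read / write a taxa-by-sample abundance table as TSV
#'
#' Rows are taxa (first column \code{"taxon"}), remaining columns are
#' samples.
#'
#' @param path file path.
#' @return \code{readAbundanceTable} returns a numeric matrix with taxon
#'   rownames.
#' @export
readAbundanceTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1] != "taxon")
        stop("first column must be named 'taxon'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$taxon
    storage.mode(m) <- "double"
    m
}

#' @rdname readAbundanceTable
#' @param mat taxa x samples numeric matrix.
#' @export
writeAbundanceTable <- function(mat, path) {
    df <- data.frame(taxon = rownames(mat), formatNum(mat),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write per-sample metadata as TSV
#'
#' Columns \code{sample}, \code{subject}, \code{arm}, \code{visit}.
#'
#' @param path file path.
#' @return \code{readStudyMetadata} returns the metadata data.frame.
#' @export
readStudyMetadata <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "subject", "arm", "visit")
    if (!all(need %in% colnames(df)))
        stop("metadata needs columns: ", paste(need, collapse = ", "))
    df
}

#' @rdname readStudyMetadata
#' @param metadata metadata data.frame.
#' @export
writeStudyMetadata <- function(metadata, path) {
    utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export a simulated study to plain-text files
#'
#' Writes the observed relative abundances (taxa incl. controls x
#' samples, TSV), the sample metadata (TSV), and the truth log (JSON)
#' into a directory.
#'
#' @param sim a \linkS4class{SimulatedStudy}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
exportStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        relabund = file.path(dir, "relabund.tsv"),
        metadata = file.path(dir, "metadata.tsv"),
        truth = file.path(dir, "truth.json"))
    writeAbundanceTable(assay(relabund(sim), "relabund"), paths["relabund"])
    writeStudyMetadata(studyMetadata(sim), paths["metadata"])
    jsonlite::write_json(truthLog(sim), paths["truth"], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}
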