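#' Read / write a species classification table
#'
#' CSV schema: \code{species,residency,categories,genome_length} with
#' categories semicolon-joined (empty for none).
#'
#' @param path file path.
#' @return \code{readClassification} returns the classification
#'   data.frame.
#' @export
readClassification <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(categories = "character"))
    validateClassification(df)
    df
}

#' @rdname readClassification
#' @param classification classification data.frame.
#' @export
writeClassification <- function(classification, path) {
    utils::write.csv(classification, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

validateClassification <- function(classification) {
    need <- c("species", "residency", "categories")
    if (!all(need %in% colnames(classification)))
        stop("classification needs columns: ", paste(need, collapse = ", "))
    sp <- trimws(classification$species)
    if (anyDuplicated(sp))
        stop("duplicate species in classification table: ",
             paste(unique(sp[duplicated(sp)]), collapse = ", "))
    if (!all(classification$residency %in% VALID_RESIDENCY))
        stop("invalid residency value(s): ",
             paste(setdiff(classification$residency, VALID_RESIDENCY),
                   collapse = ", "))
    bad <- setdiff(unlist(splitCategories(classification$categories)),
                   VALID_CATEGORIES)
    if (length(bad))
        stop("invalid categories: ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' Annotate taxa with residency and clinical categories
#'
#' Exact string match after whitespace trimming; taxa absent from the
#' table are annotated \code{residency = "unknown"} with no categories.
#'
#' @param taxa character vector of taxon names.
#' @param classification classification data.frame (columns
#'   \code{species}, \code{residency}, \code{categories}); duplicate
#'   species are a validation error.
#' @return data.frame with one row per input taxon: \code{taxon},
#'   \code{residency}, \code{categories}, \code{matched}. The number of
#'   matched/unmatched taxa is attached as attribute \code{"report"}.
#' @examples
#' tab <- data.frame(species = "Veillonella parvula", residency = "oral",
#'                   categories = "commensal;malodor")
#' annotateSpecies(" Veillonella parvula ", tab)
#' @export
annotateSpecies <- function(taxa, classification) {
    validateClassification(classification)
    key <- trimws(classification$species)
    idx <- match(trimws(taxa), key)
    out <- data.frame(
        taxon = taxa,
        residency = ifelse(is.na(idx), "unknown",
                           classification$residency[idx]),
        categories = ifelse(is.na(idx), "", classification$categories[idx]),
        matched = !is.na(idx), stringsAsFactors = FALSE)
    attr(out, "report") <- c(matched = sum(out$matched),
                             unmatched = sum(!out$matched))
    out
}

categoryMembers <- function(taxa, classification, category) {
    ann <- annotateSpecies(taxa, classification)
    hit <- vapply(splitCategories(ann$categories),
                  function(v) category %in% v, logical(1))
    ann$taxon[hit]
}

#' Aggregate a clinical category per sample
#'
#' Per sample, the default aggregate is
#' \code{log10(1 + sum of CMU over member species)} — summed biomass on
#' the log scale, with samples lacking all members floored at 0. The
#' alternative reading, the mean of per-species \code{log10(1 + CMU)},
#' is available via \code{mode = "mean_log10"}.
#'
#' @param x \linkS4class{CMUExperiment}.
#' @param classification classification data.frame.
#' @param category one of \code{"commensal"}, \code{"gingivitis"},
#'   \code{"malodor"}, \code{"acidogenic"}.
#' @param mode \code{"log10_sum"} (default) or \code{"mean_log10"}.
#' @return data.frame with columns \code{sample}, \code{category},
#'   \code{value} (log10 CMU). A category with no member species warns
#'   and returns zero rows.
#' @rdname aggregateCategory
#' @export
setMethod("aggregateCategory", "CMUExperiment",
    function(x, classification, category,
             mode = c("log10_sum", "mean_log10")) {
    mode <- match.arg(mode)
    stopifnot(category %in% VALID_CATEGORIES)
    members <- categoryMembers(rownames(x), classification, category)
    if (!length(members)) {
        warning("category '", category, "' has no member species")
        return(data.frame(sample = character(), category = character(),
                          value = numeric(), stringsAsFactors = FALSE))
    }
    a <- cmuValues(x)[members, , drop = FALSE]
    a[is.na(a)] <- 0
    value <- if (mode == "log10_sum") log10(1 + colSums(a))
             else colMeans(log10(1 + a))
    data.frame(sample = colnames(x), category = category, value = value,
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Total oral bacterial abundance per sample
#'
#' \code{log10(1 + sum of CMU over oral-resident species)}; transient /
#' extraoral and unknown taxa are excluded, matching the usual "total
#' oral bacteria" summary.
#'
#' @param x \linkS4class{CMUExperiment}.
#' @param classification classification data.frame.
#' @return data.frame with columns \code{sample}, \code{value}.
#' @export
totalOralAbundance <- function(x, classification) {
    ann <- annotateSpecies(rownames(x), classification)
    a <- cmuValues(x)[ann$residency == "oral", , drop = FALSE]
    a[is.na(a)] <- 0
    data.frame(sample = colnames(x), value = log10(1 + colSums(a)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Richness by residency class and clinical category
#'
#' Per sample, the number of taxa observed (CMU > 0) in each residency
#' class and each clinical category; at the study level, the number of
#' distinct taxa ever observed per class across all samples.
#'
#' @param x \linkS4class{CMUExperiment}.
#' @param classification classification data.frame.
#' @return List with \code{per_sample} (data.frame: sample, richness,
#'   one column per residency class and category) and \code{study_level}
#'   (named vector of distinct-taxon totals, including \code{total}).
#' @rdname richnessByClass
#' @export
setMethod("richnessByClass", "CMUExperiment",
    function(x, classification) {
    ann <- annotateSpecies(rownames(x), classification)
    a <- cmuValues(x)
    a[is.na(a)] <- 0
    present <- a > 0
    cats <- splitCategories(ann$categories)
    groups <- c(
        setNames(lapply(VALID_RESIDENCY, function(r) ann$residency == r),
                 VALID_RESIDENCY),
        setNames(lapply(VALID_CATEGORIES, function(cg)
            vapply(cats, function(v) cg %in% v, logical(1))),
            VALID_CATEGORIES))
    per_sample <- data.frame(sample = colnames(x),
                             richness = colSums(present),
                             row.names = NULL, stringsAsFactors = FALSE)
    for (g in names(groups))
        per_sample[[g]] <- colSums(present[groups[[g]], , drop = FALSE])
    ever <- rowSums(present) > 0
    study <- c(total = sum(ever),
               vapply(groups, function(sel) sum(ever & sel), numeric(1)))
    list(per_sample = per_sample, study_level = study)
})
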