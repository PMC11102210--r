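#' Load and validate a study dataset from files
#'
#' Joins relative abundances, sample metadata, species classification
#' and the spike-in manifest into a validated
#' \linkS4class{RelAbundExperiment}, enumerating mismatches: samples
#' without metadata are a hard error, taxa without a genome length are a
#' soft warning (they remain but stay unquantified), and control taxa
#' are flagged in \code{rowData}.
#'
#' @param config list with paths \code{relabund}, \code{metadata},
#'   \code{classification}, \code{manifest}, and optionally \code{tree}.
#' @return List: \code{relabund}
#'   (\linkS4class{RelAbundExperiment}), \code{classification},
#'   \code{manifest}, \code{tree} (or NULL), \code{report} (consistency
#'   notes).
#' @export
loadDataset <- function(config) {
    for (p in c("relabund", "metadata", "classification", "manifest"))
        if (is.null(config[[p]]) || !file.exists(config[[p]]))
            stop("config path '", p, "' is missing or does not exist")
    mat <- readAbundanceTable(config$relabund)
    md <- readStudyMetadata(config$metadata)
    cls <- readClassification(config$classification)
    manifest <- readSpikeInManifest(config$manifest)
    if (anyDuplicated(md$sample))
        stop("duplicate sample(s) in metadata: ",
             paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
    missing_md <- setdiff(colnames(mat), md$sample)
    if (length(missing_md))
        stop("sample(s) missing metadata: ",
             paste(missing_md, collapse = ", "))
    md <- md[match(colnames(mat), md$sample), ]
    ctl <- manifest@controls
    ann <- annotateSpecies(rownames(mat), cls)
    gl <- cls$genome_length[match(trimws(rownames(mat)),
                                  trimws(cls$species))]
    is_ctl <- rownames(mat) %in% ctl$name
    gl[is_ctl] <- ctl$genome_length[match(rownames(mat)[is_ctl], ctl$name)]
    no_gl <- rownames(mat)[is.na(gl) & !is_ctl]
    if (length(no_gl))
        warning(length(no_gl),
                " taxa have no genome length and will stay unquantified")
    rd <- DataFrame(taxon = rownames(mat), is_control = is_ctl,
                    genome_length = gl, residency = ann$residency,
                    categories = ann$categories)
    rae <- RelAbundExperiment(mat, rowData = rd, colData = md)
    tree <- if (!is.null(config$tree)) readNewickTree(config$tree) else NULL
    report <- list(
        n_taxa = nrow(mat), n_samples = ncol(mat),
        n_controls = sum(is_ctl),
        unmatched_taxa = sum(!ann$matched & !is_ctl),
        taxa_without_genome_length = no_gl)
    list(relabund = rae, classification = cls, manifest = manifest,
         tree = tree, report = report)
}

pipelineDefaults <- function() {
    list(w_bp = DEFAULT_W_BP, regression_direction = "relabund_on_mass",
         aggregation_mode = "log10_sum", unifrac_normalized = TRUE,
         n_perm = 999L, seed = 1L, contrasts = NULL,
         compare_visit = NULL, compare_method = "wilcoxon", alpha = 0.05)
}

readRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        config <- if (grepl("\\.ya?ml$", config)) {
            if (!requireNamespace("yaml", quietly = TRUE))
                stop("the 'yaml' package is needed for YAML configs")
            yaml::read_yaml(config)
        } else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    cfg <- pipelineDefaults()
    cfg[names(config)] <- config
    cfg
}

#' Run the full quantitative microbiome pipeline
#'
#' simulate/load -> quantify -> aggregate -> diversity -> compare, with
#' every result written to \code{outdir} as plain-text tables (floats at
#' 12 significant digits) plus a JSON run manifest with a content hash
#' per output, so identical config and seed reproduce byte-identical
#' outputs.
#'
#' Outputs: \code{cmu.tsv}, \code{calibration.json},
#' \code{aggregates.tsv}, \code{alpha_diversity.tsv},
#' \code{distance_matrix.tsv} + \code{pcoa_coordinates.tsv} +
#' \code{permanova.json} (when a tree is supplied),
#' \code{comparisons.tsv} + \code{reductions.tsv} (when contrasts are
#' configured), \code{run_manifest.json}.
#'
#' @param config list or path to a JSON/YAML file: the input paths of
#'   \code{\link{loadDataset}} plus options \code{w_bp},
#'   \code{regression_direction}, \code{aggregation_mode},
#'   \code{unifrac_normalized}, \code{n_perm}, \code{seed},
#'   \code{contrasts} (list of \code{c(treatment, reference)} arm
#'   pairs), \code{compare_visit}, \code{compare_method}, \code{alpha}.
#' @param outdir output directory.
#' @return Invisibly, a list with all in-memory results.
#' @export
runPipeline <- function(config, outdir) {
    cfg <- readRunConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ds <- tryCatch(loadDataset(cfg), error = function(e)
        stop("stage 'load': ", conditionMessage(e), call. = FALSE))
    cmu <- tryCatch(
        quantifySamples(ds$relabund, ds$manifest, w_bp = cfg$w_bp,
                        direction = cfg$regression_direction),
        error = function(e)
            stop("stage 'quantify': ", conditionMessage(e), call. = FALSE))
    writeAbundanceTable(cmuValues(cmu), file.path(outdir, "cmu.tsv"))
    jsonlite::write_json(calibrationReport(cmu),
                         file.path(outdir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)

    agg <- do.call(rbind, lapply(VALID_CATEGORIES, function(cg)
        aggregateCategory(cmu, ds$classification, cg,
                          mode = cfg$aggregation_mode)))
    total <- totalOralAbundance(cmu, ds$classification)
    agg <- rbind(agg, data.frame(sample = total$sample,
                                 category = "total_oral",
                                 value = total$value))
    agg$value <- as.numeric(formatNum(agg$value))
    utils::write.table(
        data.frame(agg[1:2], value = formatNum(agg$value)),
        file.path(outdir, "aggregates.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    a <- cmuValues(cmu); a[is.na(a)] <- 0
    alpha_df <- data.frame(
        sample = colnames(a),
        shannon = apply(a, 2, function(v)
            if (any(v > 0)) shannonWeaver(v) else NA_real_),
        richness = apply(a, 2, observedRichness),
        row.names = NULL)
    utils::write.table(
        data.frame(sample = alpha_df$sample,
                   shannon = formatNum(alpha_df$shannon),
                   richness = alpha_df$richness),
        file.path(outdir, "alpha_diversity.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    dmat <- ord <- perm <- NULL
    if (!is.null(ds$tree)) {
        dmat <- tryCatch(
            unifracMatrix(ds$tree, a, normalized = cfg$unifrac_normalized),
            error = function(e)
                stop("stage 'diversity': ", conditionMessage(e),
                     call. = FALSE))
        writeDistanceMatrix(dmat, file.path(outdir, "distance_matrix.tsv"))
        ord <- pcoaOrdination(dmat, k = min(2L, ncol(dmat) - 1L))
        co <- ordCoordinates(ord)
        utils::write.table(
            data.frame(sample = rownames(co), formatNum(co)),
            file.path(outdir, "pcoa_coordinates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        arm <- colData(cmu)$arm
        if (length(unique(arm)) >= 2L && all(table(arm) >= 2L)) {
            perm <- permanova(dmat, arm, n_perm = cfg$n_perm,
                              seed = cfg$seed)
            jsonlite::write_json(
                list(pseudo_F = pseudoF(perm), p_value = pValue(perm),
                     n_permutations = perm@nPermutations, seed = perm@seed),
                file.path(outdir, "permanova.json"), auto_unbox = TRUE,
                digits = NA)
        }
    }

    cmp <- red <- NULL
    if (!is.null(cfg$contrasts)) {
        cd <- as.data.frame(colData(cmu))
        visit <- cfg$compare_visit
        if (is.null(visit)) visit <- cd$visit[nrow(cd)]
        sel <- cd$visit == visit
        cats <- unique(agg$category)
        vals <- t(vapply(cats, function(cg) {
            v <- agg$value[agg$category == cg]
            names(v) <- agg$sample[agg$category == cg]
            v[cd$sample[sel]]
        }, numeric(sum(sel))))
        rownames(vals) <- cats
        contrasts <- cfg$contrasts
        if (is.matrix(contrasts))
            contrasts <- split(contrasts, row(contrasts))
        cmp <- compareGroups(vals, cd$arm[sel], contrasts,
                             method = cfg$compare_method,
                             alpha = cfg$alpha)
        res <- cmp$results
        grp_mean <- function(cg, arm_label)
            mean(vals[cg, cd$arm[sel] == arm_label])
        red <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
            arms2 <- strsplit(res$contrast[i], " vs ", fixed = TRUE)[[1]]
            data.frame(metric = res$metric[i], contrast = res$contrast[i],
                       visit = visit,
                       reduction_pct = percentReduction(
                           grp_mean(res$metric[i], arms2[1]),
                           grp_mean(res$metric[i], arms2[2])),
                       p_value = res$p_value[i])
        }))
        utils::write.table(
            within(res, {
                statistic <- formatNum(statistic)
                estimate <- formatNum(estimate)
                p_value <- formatNum(p_value)
                p_adjusted <- formatNum(p_adjusted)
            }),
            file.path(outdir, "comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            within(red, {
                reduction_pct <- formatNum(reduction_pct)
                p_value <- formatNum(p_value)
            }),
            file.path(outdir, "reductions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    files <- setdiff(list.files(outdir), "run_manifest.json")
    manifest <- list(
        package = "cmuQuant",
        version = as.character(utils::packageVersion("cmuQuant")),
        seed = cfg$seed,
        config = cfg[setdiff(names(cfg), "contrasts")],
        contrasts = cfg$contrasts,
        outputs = lapply(stats::setNames(files, files), function(f)
            list(md5 = unname(tools::md5sum(file.path(outdir, f))))))
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(dataset = ds, cmu = cmu, aggregates = agg,
                   alpha = alpha_df, distance = dmat, ordination = ord,
                   permanova = perm, comparisons = cmp, reductions = red))
}

#' Recompute summaries from the transcribed trial fixtures
#'
#' The package bundles plain-text transcriptions of the baseline summary
#' tables of the five-arm gingivitis trial its generator emulates:
#' per-group clinical index means (MGI, TPI, EBI, PPD by region),
#' demographic counts, and the per-species healthy-vs-gingivitis log10
#' CMU means. This report recomputes, from those fixtures, the combined
#' cohort clinical means (via \code{\link{summarizeCohortMeans}}, the
#' gingivitis cohort pooling the five arms by n-weighted means), the
#' overall demographic proportions, and the per-species
#' gingivitis-minus-healthy differences next to the transcribed
#' difference column.
#'
#' @param extdata directory holding the fixture TSVs; defaults to the
#'   installed package's \code{extdata}.
#' @return List of data.frames: \code{clinical} (index, cohort, value),
#'   \code{demographics} (level, proportion_pct), \code{species}
#'   (species, computed and transcribed differences). Empty fixtures
#'   yield empty report components.
#' @export
baselineFixtureReport <- function(extdata = system.file("extdata",
                                                        package = "cmuQuant")) {
    ci <- utils::read.delim(file.path(extdata,
                                      "baseline_clinical_indices.tsv"))
    dm <- utils::read.delim(file.path(extdata, "baseline_demographics.tsv"))
    sp <- utils::read.delim(file.path(extdata,
                                      "baseline_species_log10cmu.tsv"))

    clinical <- if (nrow(ci)) {
        do.call(rbind, lapply(unique(ci$index), function(ix) {
            one <- function(groups, cohort) {
                wm <- ci[ci$index == ix & ci$region == "whole_mouth" &
                         ci$group %in% groups, ]
                ip <- ci[ci$index == ix & ci$region == "interproximal" &
                         ci$group %in% groups, ]
                ip <- ip[match(wm$group, ip$group), ]
                data.frame(index = ix, cohort = cohort,
                           value = summarizeCohortMeans(wm$mean, ip$mean,
                                                        n = wm$n))
            }
            rbind(one("Healthy", "healthy"),
                  one(c("B", "BF", "BA", "BZ", "BFZ"), "gingivitis"))
        }))
    } else data.frame(index = character(), cohort = character(),
                      value = numeric())

    demographics <- if (nrow(dm)) {
        tot <- sum(unique(dm[, c("group", "n")])$n)
        agg <- stats::aggregate(count ~ variable + level, dm, sum)
        data.frame(variable = agg$variable, level = agg$level,
                   proportion_pct = 100 * agg$count / tot)
    } else data.frame(variable = character(), level = character(),
                      proportion_pct = numeric())

    species <- if (nrow(sp)) {
        data.frame(species = sp$species,
                   computed_difference = sp$gingivitis_mean - sp$healthy_mean,
                   transcribed_difference = as.numeric(sp$difference),
                   p_printed = sp$p_printed)
    } else data.frame(species = character(), computed_difference = numeric(),
                      transcribed_difference = numeric(),
                      p_printed = character())

    list(clinical = clinical, demographics = demographics,
         species = species)
}
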