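#' Welch two-sample t-test contrast
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. When both samples have zero variance and equal means the
#' result is \code{t = 0, p = 1} by convention.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param label contrast label recorded in the result.
#' @return One-row data.frame: \code{contrast}, \code{method},
#'   \code{statistic}, \code{estimate} (mean(x) - mean(y)),
#'   \code{p_value}, \code{n_x}, \code{n_y}.
#' @export
welchT <- function(x, y, label = "x vs y") {
    stopifnot(length(x) >= 2, length(y) >= 2)
    est <- mean(x) - mean(y)
    if (stats::var(x) == 0 && stats::var(y) == 0 && est == 0) {
        stat <- 0; p <- 1
    } else {
        ht <- stats::t.test(x, y, var.equal = FALSE)
        stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(contrast = label, method = "welch", statistic = stat,
               estimate = est, p_value = p, n_x = length(x),
               n_y = length(y), stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum contrast
#'
#' Exact two-sided p-value by full enumeration of rank assignments when
#' \code{length(x) + length(y) <= 12} and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples, each of size >= 1.
#' @param label contrast label.
#' @return One-row data.frame as in \code{\link{welchT}} (statistic is
#'   the rank-sum W).
#' @export
wilcoxonRankSum <- function(x, y, label = "x vs y") {
    stopifnot(length(x) >= 1, length(y) >= 1)
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 12) && !ties
    ht <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(contrast = label, method = "wilcoxon",
               statistic = unname(ht$statistic),
               estimate = mean(x) - mean(y), p_value = ht$p.value,
               n_x = length(x), n_y = length(y), stringsAsFactors = FALSE)
}

#' Percent reduction from log10 group means
#'
#' \code{100 * (1 - 10^(mean_log10_treat - mean_log10_ctrl))}: the
#' percent by which the treated group's (geometric-mean) abundance falls
#' short of the control's. Negative values indicate an increase; the
#' result is always < 100.
#'
#' @param mean_log10_treat,mean_log10_ctrl group means on the log10
#'   scale.
#' @return Percent reduction.
#' @examples
#' percentReduction(7, 8)  # one log10 lower -> 90
#' @export
percentReduction <- function(mean_log10_treat, mean_log10_ctrl) {
    100 * (1 - 10^(mean_log10_treat - mean_log10_ctrl))
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution: with noncentrality
#' \code{ncp = delta / (sd * sqrt(2/n))} and \code{df = 2n - 2}, power
#' is \code{P(|T_ncp| > t_{1 - alpha/2, df})}. \code{alpha} is the total
#' two-sided significance level.
#'
#' @param n_per_group subjects per group.
#' @param delta true difference of means (index units).
#' @param sd common standard deviation (> 0).
#' @param alpha two-sided significance level in (0, 1).
#' @return Power in (0, 1).
#' @examples
#' tTestPower(50, 0.34, 0.43, alpha = 0.025)  # ~0.95
#' @export
tTestPower <- function(n_per_group, delta, sd, alpha = 0.05) {
    stopifnot(n_per_group >= 2, sd > 0, alpha > 0, alpha < 1)
    ncp <- abs(delta) / (sd * sqrt(2 / n_per_group))
    df <- 2 * n_per_group - 2
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Run contrasts of a per-sample metric between groups
#'
#' Applies the chosen two-sample test to each requested contrast. With a
#' metric matrix (rows = metrics), every metric is tested per contrast.
#' All results are returned together with a filtered view at the
#' significance threshold (default p <= 0.05, unadjusted, matching how
#' per-species differences are conventionally reported);
#' Benjamini-Hochberg adjustment is available via \code{adjust}.
#'
#' @param values numeric vector (one metric) or metrics x samples matrix.
#' @param groups group label per sample.
#' @param contrasts list of length-2 character vectors
#'   \code{c(treatment, reference)}.
#' @param method \code{"welch"} or \code{"wilcoxon"}.
#' @param alpha significance threshold for the filtered view.
#' @param adjust apply Benjamini-Hochberg across all p-values; the
#'   filtered view then uses adjusted p-values.
#' @return List with \code{results} (all contrasts) and \code{filtered}
#'   (rows with p <= alpha).
#' @export
compareGroups <- function(values, groups, contrasts,
                          method = c("welch", "wilcoxon"), alpha = 0.05,
                          adjust = FALSE) {
    method <- match.arg(method)
    test <- if (method == "welch") welchT else wilcoxonRankSum
    if (is.null(dim(values)))
        values <- matrix(values, 1, dimnames = list("metric", NULL))
    groups <- as.character(groups)
    stopifnot(ncol(values) == length(groups))
    rows <- list()
    for (ct in contrasts) {
        stopifnot(length(ct) == 2)
        sel_t <- groups == ct[1]; sel_r <- groups == ct[2]
        if (!any(sel_t) || !any(sel_r))
            stop("empty group in contrast '", ct[1], " vs ", ct[2], "'")
        for (m in rownames(values)) {
            res <- test(values[m, sel_t], values[m, sel_r],
                        label = paste(ct[1], "vs", ct[2]))
            res$metric <- m
            rows[[length(rows) + 1L]] <- res
        }
    }
    out <- do.call(rbind, rows)
    out <- out[, c("metric", "contrast", "method", "statistic", "estimate",
                   "p_value", "n_x", "n_y")]
    out$p_adjusted <- if (adjust) stats::p.adjust(out$p_value, "BH")
                      else out$p_value
    keep <- out$p_adjusted <= alpha
    list(results = out, filtered = out[keep, , drop = FALSE])
}

#' Combine whole-mouth and interproximal clinical index means
#'
#' The cohort summary for a clinical index (MGI, TPI, EBI, PPD) is the
#' arithmetic mean of the whole-mouth and interproximal means. A cohort
#' made of several groups (e.g. the pooled gingivitis arms) first
#' combines each region across groups by n-weighted mean.
#'
#' @param whole_mouth,interproximal per-group region means (equal
#'   length, no missing values).
#' @param n per-group sizes; required when more than one group is
#'   supplied.
#' @return The combined cohort mean.
#' @examples
#' summarizeCohortMeans(2.469, 2.715)  # healthy TPI -> 2.592
#' @export
summarizeCohortMeans <- function(whole_mouth, interproximal, n = NULL) {
    if (anyNA(whole_mouth) || anyNA(interproximal) ||
        !length(whole_mouth) || !length(interproximal))
        stop("both whole-mouth and interproximal means are required")
    stopifnot(length(whole_mouth) == length(interproximal))
    if (length(whole_mouth) > 1L) {
        if (is.null(n) || length(n) != length(whole_mouth))
            stop("per-group n is required for multi-group cohorts")
        wm <- sum(whole_mouth * n) / sum(n)
        ip <- sum(interproximal * n) / sum(n)
    } else {
        wm <- whole_mouth; ip <- interproximal
    }
    (wm + ip) / 2
}
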