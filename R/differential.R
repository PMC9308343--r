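#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over genes expressed in every sample,
#' of the ratio between that sample's count and the gene's geometric mean
#' across samples; factors are then rescaled to geometric mean 1.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of size factors.
#' @export
medianOfRatios <- function(counts) {
    counts <- as.matrix(counts)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) stop("no gene with nonzero counts in all samples")
    lg <- log(counts[pos, , drop = FALSE])
    gm <- rowMeans(lg)
    sf <- apply(exp(lg - gm), 2, median)
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin, validated wrapper around \code{p.adjust(method = "BH")}: monotone
#' step-up FDR values capped at 1. \code{NA} p-values propagate.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return FDR-adjusted values.
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

# Fit the mean-dispersion trend alpha(mu) = a0 + a1/mu by two rounds of
# least squares with outlier trimming; returns the evaluated trend.
fitDispersionTrend <- function(baseMean, alphaHat) {
    use <- baseMean > 1 & is.finite(alphaHat) & alphaHat > 1e-7
    if (sum(use) < 10) {
        a <- median(alphaHat[is.finite(alphaHat) & alphaHat > 0], na.rm = TRUE)
        if (!is.finite(a)) a <- 0.1
        return(rep(max(a, 1e-4), length(baseMean)))
    }
    x <- 1 / baseMean[use]; y <- alphaHat[use]
    for (it in 1:3) {
        fit <- stats::lm.fit(cbind(1, x), y)
        res <- y - fit$fitted.values
        s <- stats::mad(res)
        keep <- abs(res) <= 3 * max(s, 1e-8)
        x <- x[keep]; y <- y[keep]
        if (length(y) < 10) break
    }
    a0 <- max(fit$coefficients[1], 1e-4)
    a1 <- max(fit$coefficients[2], 0)
    pmax(a0 + a1 / baseMean, 1e-6)
}

#' Negative-binomial Wald test for two groups
#'
#' A documented simplified NB pipeline in the DESeq2 mould (median-of-ratios
#' normalization, moment dispersion estimates shrunk toward a fitted
#' mean-dispersion trend, Wald test on the log fold change) without
#' independent filtering, Cook's-distance outlier handling or LFC shrinkage.
#'
#' Per gene, the method-of-moments dispersion is estimated within each group
#' from the variance of normalized counts, combined across groups, and shrunk
#' in log space toward the trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} with a
#' weight that grows as the per-gene degrees of freedom shrink. The Wald
#' statistic compares group means of normalized counts on the log scale with
#' a 0.5 pseudocount; its variance follows the NB model
#' \eqn{Var(K) = \mu + \alpha \mu^2}:
#' \deqn{Var(\log \hat m_g) \approx \frac{1}{n_g^2} \sum_s \frac{1}{m_g s_s}
#'   + \frac{\alpha}{n_g}.}
#' P-values come from a moderated t reference with
#' \eqn{df = n_1 + n_2 - 2 + priorDf}, acknowledging that the shrunk
#' dispersion is better determined than the per-gene residual df alone
#' would suggest.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param group Two-level factor/character; the first level (for a
#'   character vector, the first value encountered) is the reference, e.g.
#'   wt; the log2 fold change is second over first.
#' @param sizeFactors Optional precomputed size factors.
#' @param priorDf Strength of the shrinkage toward the dispersion trend, in
#'   pseudo-degrees-of-freedom (default 10; the trend dominates for small
#'   designs).
#' @return A data.frame with columns \code{gene}, \code{baseMean},
#'   \code{log2fc}, \code{stat}, \code{pvalue}, \code{fdr}. Genes with zero
#'   counts throughout get \code{NA} statistics.
#' @export
nbWaldTest <- function(counts, group, sizeFactors = NULL, priorDf = 10) {
    counts <- as.matrix(counts)
    if (!is.factor(group)) group <- factor(group, levels = unique(group))
    if (nlevels(group) != 2L) stop("group must have exactly two levels")
    if (any(table(group) == 0L)) stop("a group has zero samples")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
    q <- sweep(counts, 2, sizeFactors, "/")
    g1 <- group == levels(group)[1]; g2 <- !g1
    n1 <- sum(g1); n2 <- sum(g2)
    m1 <- rowMeans(q[, g1, drop = FALSE])
    m2 <- rowMeans(q[, g2, drop = FALSE])
    baseMean <- rowMeans(q)

    rowVar <- function(x) {
        mu <- rowMeans(x)
        rowSums((x - mu)^2) / (ncol(x) - 1L)
    }
    momentAlpha <- function(cols, mu) {
        if (sum(cols) < 2L) return(rep(NA_real_, nrow(q)))
        v <- rowVar(q[, cols, drop = FALSE])
        shot <- mu * mean(1 / sizeFactors[cols])
        ifelse(mu > 0, (v - shot) / mu^2, NA_real_)
    }
    a1 <- momentAlpha(g1, m1); a2 <- momentAlpha(g2, m2)
    w1 <- ifelse(is.na(a1), 0, n1 - 1L); w2 <- ifelse(is.na(a2), 0, n2 - 1L)
    aHat <- ifelse(w1 + w2 > 0,
                   (ifelse(is.na(a1), 0, a1) * w1 + ifelse(is.na(a2), 0, a2) * w2) /
                       pmax(w1 + w2, 1),
                   NA_real_)
    aTrend <- fitDispersionTrend(baseMean, aHat)
    # shrink in log space; clamp the noisy moment estimate around the trend
    aClamp <- pmin(pmax(ifelse(is.na(aHat) | aHat <= 0, aTrend, aHat),
                        aTrend / 8), aTrend * 8)
    df <- n1 + n2 - 2L
    w <- priorDf / (priorDf + df)
    alpha <- exp(w * log(aTrend) + (1 - w) * log(aClamp))

    eps <- 0.5
    log2fc <- log2(m2 + eps) - log2(m1 + eps)
    vlog <- function(m, cols, n) {
        (1 / n^2) * rowSums(outer(1 / pmax(m, eps), 1 / sizeFactors[cols])) +
            alpha / n
    }
    V <- vlog(m1, g1, n1) + vlog(m2, g2, n2)
    stat <- (log(m2 + eps) - log(m1 + eps)) / sqrt(V)
    # moderated-t reference: the trend-shrunk dispersion contributes priorDf
    # pseudo-degrees-of-freedom on top of the residual df
    pvalue <- 2 * pt(-abs(stat), df = df + priorDf)
    zero <- baseMean == 0
    stat[zero] <- NA; pvalue[zero] <- NA; log2fc[zero] <- 0
    data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
               baseMean = baseMean, log2fc = log2fc, stat = stat,
               pvalue = pvalue, fdr = bhAdjust(pvalue),
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed genes
#'
#' Applies the FDR and fold-change thresholds (defaults FDR < 0.05 and
#' >= 1.5-fold) to a \code{\link{nbWaldTest}} result and removes genes on the
#' exclusion list (e.g. off-target deletion genes).
#'
#' @param res Result data.frame from \code{\link{nbWaldTest}}.
#' @param alpha FDR cutoff (default 0.05).
#' @param fcMin Minimal fold change (default 1.5, i.e. |log2fc| >= log2(1.5)).
#' @param exclude Character vector of gene ids to drop before calling.
#' @return A list: \code{records} (the input with a \code{direction} column,
#'   excluded genes removed), \code{up} and \code{down} gene-id vectors.
#' @export
callDegs <- function(res, alpha = 0.05, fcMin = 1.5, exclude = NULL) {
    if (!is.null(exclude)) res <- res[!res$gene %in% exclude, , drop = FALSE]
    lfcMin <- log2(fcMin)
    sig <- !is.na(res$fdr) & res$fdr < alpha
    direction <- rep("ns", nrow(res))
    direction[sig & res$log2fc >= lfcMin] <- "up"
    direction[sig & res$log2fc <= -lfcMin] <- "down"
    res$direction <- direction
    list(records = res,
         up = res$gene[direction == "up"],
         down = res$gene[direction == "down"])
}

#' Allele-specific differential expression
#'
#' Runs the NB Wald test independently on maternal and paternal exonic
#' counts of the same contrast, then removes genes whose estimated allelic
#' TPM stays below a floor (default 1) in every sample of that allele, and
#' genes whose allelic signal is masked (paternal X in male contrasts).
#'
#' @param matCounts,patCounts Integer matrices (genes x samples) of maternal
#'   and paternal exonic fragment counts.
#' @param group Two-level factor (reference first, e.g. wt then KO).
#' @param matTpm,patTpm Matching allelic TPM matrices used for the < 1 TPM
#'   post-filter.
#' @param minTpm Allelic TPM floor (default 1).
#' @param maskedGenes Optional gene ids to exclude from the paternal test.
#' @param alpha,fcMin,exclude Passed to \code{\link{callDegs}}.
#' @return A list with elements \code{maternal} and \code{paternal}, each a
#'   \code{\link{callDegs}} result.
#' @export
allelicDegPipeline <- function(matCounts, patCounts, group,
                               matTpm = NULL, patTpm = NULL, minTpm = 1,
                               maskedGenes = NULL,
                               alpha = 0.05, fcMin = 1.5, exclude = NULL) {
    runOne <- function(cnt, tpm, drop) {
        cnt <- as.matrix(cnt)
        keep <- rep(TRUE, nrow(cnt))
        if (!is.null(tpm)) keep <- keep & tpmFilter(tpm, minTpm = minTpm - 1e-12)
        if (!is.null(drop)) keep <- keep & !(rownames(cnt) %in% drop)
        res <- nbWaldTest(cnt[keep, , drop = FALSE], group)
        callDegs(res, alpha = alpha, fcMin = fcMin, exclude = exclude)
    }
    list(maternal = runOne(matCounts, matTpm, NULL),
         paternal = runOne(patCounts, patTpm, maskedGenes))
}

#' Classify allelic response groups A-F
#'
#' Downregulated allelic DEGs fall into group A (maternal allele only),
#' B (paternal only) or C (both alleles); upregulated DEGs into D (maternal),
#' E (paternal) or F (both). A gene can hold one down-group and one up-group
#' simultaneously (e.g. up maternally, down paternally).
#'
#' @param maternal,paternal \code{\link{callDegs}} results for the two
#'   alleles of one contrast (elements of
#'   \code{\link{allelicDegPipeline}}'s output).
#' @return A list: \code{labels} (data.frame gene / down_group / up_group for
#'   genes in any allelic DEG list) and \code{counts} (named integer vector
#'   over A..F plus \code{total_down} and \code{total_up}).
#' @export
classifyGroups <- function(maternal, paternal) {
    md <- maternal$down; pd <- paternal$down
    mu <- maternal$up; pu <- paternal$up
    genes <- sort(unique(c(md, pd, mu, pu)))
    down_group <- rep("none", length(genes))
    down_group[genes %in% md & !genes %in% pd] <- "A"
    down_group[genes %in% pd & !genes %in% md] <- "B"
    down_group[genes %in% md & genes %in% pd] <- "C"
    up_group <- rep("none", length(genes))
    up_group[genes %in% mu & !genes %in% pu] <- "D"
    up_group[genes %in% pu & !genes %in% mu] <- "E"
    up_group[genes %in% mu & genes %in% pu] <- "F"
    counts <- c(A = sum(down_group == "A"), B = sum(down_group == "B"),
                C = sum(down_group == "C"), D = sum(up_group == "D"),
                E = sum(up_group == "E"), F = sum(up_group == "F"))
    counts <- c(counts,
                total_down = unname(counts["A"] + counts["B"] + counts["C"]),
                total_up = unname(counts["D"] + counts["E"] + counts["F"]))
    list(labels = data.frame(gene = genes, down_group = down_group,
                             up_group = up_group, stringsAsFactors = FALSE),
         counts = counts)
}

#' Relaxed fold-change overlap between crosses
#'
#' Gene lists at a relaxed >= 1.25-fold change of mean TPM between KO and wt,
#' computed per cross and intersected, quantify how many expression changes
#' replicate across the reciprocal crosses even below the strict DEG
#' thresholds. Replicate-mean TPMs are floored at 0.5 before the ratio; the
#' > 1 TPM (any replicate) expression filter is applied per cross first.
#'
#' @param tpmWt,tpmKo Named lists (one element per cross, e.g. BC and CB) of
#'   TPM matrices (genes x replicates) for wt and KO samples.
#' @param fcMin Relaxed fold-change cutoff (default 1.25).
#' @param minTpm Expression-filter floor (default 1).
#' @return A list: \code{down} and \code{up} (gene ids changed in the same
#'   direction in every cross) and \code{perCross} (per-cross lists).
#' @export
relaxedFoldOverlap <- function(tpmWt, tpmKo, fcMin = 1.25, minTpm = 1) {
    stopifnot(identical(names(tpmWt), names(tpmKo)), length(tpmWt) >= 1)
    perCross <- lapply(names(tpmWt), function(cr) {
        w <- as.matrix(tpmWt[[cr]]); k <- as.matrix(tpmKo[[cr]])
        keep <- tpmFilter(cbind(w, k), minTpm)
        wm <- pmax(rowMeans(w)[keep], 0.5)
        km <- pmax(rowMeans(k)[keep], 0.5)
        g <- rownames(w)[keep]
        list(down = g[wm / km >= fcMin], up = g[km / wm >= fcMin])
    })
    names(perCross) <- names(tpmWt)
    list(down = Reduce(intersect, lapply(perCross, `[[`, "down")),
         up = Reduce(intersect, lapply(perCross, `[[`, "up")),
         perCross = perCross)
}
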