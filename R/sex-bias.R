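#' Call sex-biased genes in wild type
#'
#' A gene is sex-biased when its mean TPM differs at least \code{fold}-fold
#' between the sexes (means floored at 0.5 TPM) and a two-sided
#' two-sample Student t-test on the replicate TPM values gives
#' p <= \code{alpha}. Equal variances are assumed by default (Student's
#' test, as the definition is usually stated); Welch's correction is
#' available behind a flag.
#'
#' @param tpmF,tpmM TPM matrices (genes x replicates) for female and male wt
#'   samples; at least two replicates each. Apply \code{\link{tpmFilter}}
#'   beforehand.
#' @param fold Fold cutoff (default 2).
#' @param alpha p-value cutoff (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead.
#' @return A data.frame with \code{gene}, \code{mean_tpm_female},
#'   \code{mean_tpm_male}, \code{fold} (max/min ratio of pseudocounted
#'   means), \code{p_value} and \code{status_wt} in
#'   \{female-biased, male-biased, unbiased\}.
#' @export
callSexBiased <- function(tpmF, tpmM, fold = 2, alpha = 0.05, welch = FALSE) {
    tpmF <- as.matrix(tpmF); tpmM <- as.matrix(tpmM)
    stopifnot(nrow(tpmF) == nrow(tpmM))
    if (ncol(tpmF) < 2L || ncol(tpmM) < 2L)
        stop("need >= 2 replicates per sex for the t-test")
    mf <- rowMeans(tpmF); mm <- rowMeans(tpmM)
    # means floored at 0.5 TPM so ratios at zeros stay finite without
    # distorting well-expressed genes
    ratio <- pmax(mf, mm, 0.5) / pmax(pmin(mf, mm), 0.5)
    p <- vapply(seq_len(nrow(tpmF)), function(i) {
        x <- tpmF[i, ]; y <- tpmM[i, ]
        if (var(x) == 0 && var(y) == 0)
            return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
        t.test(x, y, var.equal = !welch)$p.value
    }, numeric(1))
    status <- rep("unbiased", nrow(tpmF))
    biased <- ratio >= fold & p <= alpha
    status[biased & mf > mm] <- "female-biased"
    status[biased & mm > mf] <- "male-biased"
    data.frame(gene = rownames(tpmF) %||% as.character(seq_len(nrow(tpmF))),
               mean_tpm_female = mf, mean_tpm_male = mm, fold = ratio,
               p_value = p, status_wt = status, stringsAsFactors = FALSE)
}

#' Loss of sex-biased expression after knockout
#'
#' A gene sex-biased in wt is "lost" when, after KO, the cross-sex ratio in
#' the direction of the wt bias drops below the fold cutoff: for a
#' female-biased gene the female-wt over male-KO mean ratio, and for a
#' male-biased gene the male-KO over female-wt ratio (the mirrored rule).
#' This criterion is fold-change-only, with no p-value.
#'
#' @param records Output of \code{\link{callSexBiased}}.
#' @param tpmFwt Female wt TPM matrix (same gene order as \code{records}).
#' @param tpmMko Male KO TPM matrix.
#' @param fold Fold cutoff (default 2).
#' @return \code{records} with a \code{status_ko} column: \code{lost} /
#'   \code{retained} for wt-biased genes, \code{NA} otherwise.
#' @export
lossAfterKo <- function(records, tpmFwt, tpmMko, fold = 2) {
    mf <- pmax(rowMeans(as.matrix(tpmFwt)), 0.5)
    mk <- pmax(rowMeans(as.matrix(tpmMko)), 0.5)
    stopifnot(length(mf) == nrow(records), length(mk) == nrow(records))
    status <- rep(NA_character_, nrow(records))
    fb <- records$status_wt == "female-biased"
    mb <- records$status_wt == "male-biased"
    status[fb] <- ifelse(mf[fb] / mk[fb] < fold, "lost", "retained")
    status[mb] <- ifelse(mk[mb] / mf[mb] < fold, "lost", "retained")
    records$status_ko <- status
    records
}

#' Gain of sex-biased expression after knockout
#'
#' Genes unbiased in wt gain a bias when the full sex-bias criterion
#' (>= fold difference AND t-test p <= alpha) holds for the post-KO
#' comparison of female wt against male KO replicates.
#'
#' @param records Output of \code{\link{lossAfterKo}} (or
#'   \code{\link{callSexBiased}}).
#' @param tpmFwt,tpmMko Replicate TPM matrices, same gene order.
#' @param fold,alpha,welch As in \code{\link{callSexBiased}}.
#' @return \code{records} with \code{status_ko} set to \code{gained_female}
#'   or \code{gained_male} for previously unbiased genes meeting the
#'   criterion.
#' @export
gainAfterKo <- function(records, tpmFwt, tpmMko, fold = 2, alpha = 0.05,
                        welch = FALSE) {
    post <- callSexBiased(tpmFwt, tpmMko, fold = fold, alpha = alpha,
                          welch = welch)
    unb <- records$status_wt == "unbiased"
    if (!"status_ko" %in% colnames(records))
        records$status_ko <- NA_character_
    records$status_ko[unb & post$status_wt == "female-biased"] <- "gained_female"
    records$status_ko[unb & post$status_wt == "male-biased"] <- "gained_male"
    records
}

#' Quantile normalization
#'
#' Forces every column of the matrix to share the same value distribution
#' (the per-rank mean across columns) while preserving within-column ranks;
#' ties receive the mean of the quantile values they span. Used before
#' comparing expression across datasets and promoter coverage across alleles
#' and cell lines. Delegates to \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param m Numeric matrix (features x samples), no missing values.
#' @return The normalized matrix; a single-column input is returned
#'   unchanged.
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m)) stop("quantile normalization requires complete data")
    if (ncol(m) < 2L) return(m)
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Call allelic bias in wild type
#'
#' A gene is allelically biased when one parental allele's mean TPM is at
#' least \code{fold} times the other's (means floored at 0.5). Masked genes
#' (paternal X in males) should be excluded upstream.
#'
#' @param tpmMat,tpmPat Maternal and paternal TPM matrices (genes x wt
#'   replicates).
#' @param fold Cutoff, default 2.
#' @return A data.frame with \code{gene}, \code{mean_tpm_maternal},
#'   \code{mean_tpm_paternal}, \code{biased_parent} in
#'   \{maternal, paternal, none\}.
#' @export
callAllelicBias <- function(tpmMat, tpmPat, fold = 2) {
    tpmMat <- as.matrix(tpmMat); tpmPat <- as.matrix(tpmPat)
    mm <- rowMeans(tpmMat); mp <- rowMeans(tpmPat)
    rm_ <- pmax(mm, 0.5) / pmax(mp, 0.5)
    biased <- rep("none", length(mm))
    biased[rm_ >= fold] <- "maternal"
    biased[rm_ <= 1 / fold] <- "paternal"
    data.frame(gene = rownames(tpmMat) %||% as.character(seq_along(mm)),
               mean_tpm_maternal = mm, mean_tpm_paternal = mp,
               biased_parent = biased, stringsAsFactors = FALSE)
}

# round half up at given digits (the presentation convention for percentages)
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Summarize sex-bias loss and gain
#'
#' Produces the wt / loss / gain contingency summary per sex plus totals,
#' with percentages recomputed from the counts in the same table
#' (loss or gain over the wt-biased count, rounded half-up to integers) and
#' the female/male wt ratio at one decimal.
#'
#' @param records Records carrying \code{status_wt} and \code{status_ko}
#'   (from \code{\link{lossAfterKo}} / \code{\link{gainAfterKo}}), or a
#'   data.frame of precomputed counts with columns \code{sex}, \code{n_wt},
#'   \code{n_lost} and optionally \code{n_gained}.
#' @return A list: \code{table} (rows female, male, total with counts and
#'   integer percentages) and \code{female_male_ratio}.
#' @export
sexBiasSummary <- function(records) {
    if (all(c("sex", "n_wt", "n_lost") %in% colnames(records))) {
        cnt <- records
        if (!"n_gained" %in% colnames(cnt)) cnt$n_gained <- NA_integer_
        fb <- cnt$n_wt[cnt$sex == "female"]; mb <- cnt$n_wt[cnt$sex == "male"]
        fl <- cnt$n_lost[cnt$sex == "female"]; ml <- cnt$n_lost[cnt$sex == "male"]
        fg <- cnt$n_gained[cnt$sex == "female"]; mg <- cnt$n_gained[cnt$sex == "male"]
    } else {
        fb <- sum(records$status_wt == "female-biased")
        mb <- sum(records$status_wt == "male-biased")
        fl <- sum(records$status_wt == "female-biased" &
                      records$status_ko %in% "lost")
        ml <- sum(records$status_wt == "male-biased" &
                      records$status_ko %in% "lost")
        fg <- sum(records$status_ko %in% "gained_female")
        mg <- sum(records$status_ko %in% "gained_male")
    }
    if (fb + mb == 0)
        return(list(table = data.frame(), female_male_ratio = NA_real_))
    pc <- function(a, b) if (is.na(a) || b == 0) NA_real_ else roundHalfUp(100 * a / b)
    tab <- data.frame(
        sex = c("female", "male", "total"),
        n_wt = c(fb, mb, fb + mb),
        n_lost = c(fl, ml, fl + ml),
        pct_lost = c(pc(fl, fb), pc(ml, mb), pc(fl + ml, fb + mb)),
        n_gained = c(fg, mg, fg + mg),
        pct_gained = c(pc(fg, fb), pc(mg, mb), pc(fg + mg, fb + mb)))
    list(table = tab,
         female_male_ratio = if (mb > 0) roundHalfUp(fb / mb, 1) else NA_real_)
}
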