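#' Transcripts per million over exon-union length
#'
#' Standard gene-level TPM: each gene's fragment count is divided by its
#' merged exon length in kilobases, and the resulting rates are scaled to sum
#' to one million per sample. The library size is the total over counted
#' genes, so every TPM column sums to exactly 1e6.
#'
#' @param counts Numeric matrix (genes x samples) or vector of fragment
#'   counts.
#' @param exonLengthBp Exon-union lengths in base pairs, one per gene.
#' @return Matrix (or vector) of TPM values.
#' @examples
#' computeTPM(c(g1 = 10, g2 = 10), c(1000, 2000))  # 666666.7, 333333.3
#' @export
computeTPM <- function(counts, exonLengthBp) {
    v <- is.null(dim(counts))
    m <- as.matrix(counts)
    stopifnot(nrow(m) == length(exonLengthBp), all(exonLengthBp > 0))
    rate <- m / (exonLengthBp / 1000)
    tot <- colSums(rate)
    if (any(tot == 0)) stop("all-zero counts: TPM undefined")
    out <- sweep(rate, 2, tot, "/") * 1e6
    if (v) out[, 1] else out
}

#' Raw and bias-adjusted allelic proportions
#'
#' The raw allele0 proportion is p0 = n0 / (n0 + n1). Because reads carrying
#' reference-strain bases map slightly better, p0 is systematically inflated;
#' dividing the allele1 count's weight by the genome-wide mapping ratio
#' corrects this: p0_adj = n0 / (n0 + r_m * n1). Genes with n0 + n1 = 0 carry
#' no allelic information and get \code{NA} in both proportions.
#'
#' @param n0,n1 Allele0 and allele1 counts (vectors or matrices of equal
#'   shape).
#' @param rm_ Mapping-bias ratio(s): a scalar, or one value per sample when
#'   the inputs are matrices.
#' @return A list with elements \code{p0} and \code{p0Adj}, same shape as the
#'   inputs.
#' @examples
#' allelicProportion(10, 10, 2)$p0Adj   # 1/3
#' @export
allelicProportion <- function(n0, n1, rm_) {
    stopifnot(all(rm_ > 0))
    if (!is.null(dim(n0)) && length(rm_) > 1L) {
        stopifnot(length(rm_) == ncol(n0))
        rmat <- matrix(rm_, nrow(n0), ncol(n0), byrow = TRUE)
    } else rmat <- rm_
    tot <- n0 + n1
    p0 <- ifelse(tot > 0, n0 / tot, NA_real_)
    p0Adj <- ifelse(tot > 0, n0 / (n0 + rmat * n1), NA_real_)
    list(p0 = p0, p0Adj = p0Adj)
}

#' Split diploid TPM into allelic TPM
#'
#' The diploid TPM is modelled as the sum of two haploid TPMs, split by the
#' adjusted allele0 proportion: TPM0 = p0_adj * TPM, TPM1 = (1 - p0_adj) * TPM.
#'
#' @param tpm Diploid TPM (vector or matrix).
#' @param p0Adj Adjusted allele0 proportion, same shape (NAs propagate).
#' @return List with elements \code{tpmA0} and \code{tpmA1}.
#' @export
decomposeTPM <- function(tpm, p0Adj) {
    stopifnot(all(is.na(p0Adj) | (p0Adj >= 0 & p0Adj <= 1)))
    list(tpmA0 = p0Adj * tpm, tpmA1 = (1 - p0Adj) * tpm)
}

#' Build the allelic expression decomposition for a count table
#'
#' Runs the whole per-sample quantification: diploid TPM from total exonic
#' counts, per-sample mapping-bias ratio from autosomal allele-specific
#' totals, adjusted allelic proportions, the allelic TPM split, the
#' maternal/paternal orientation given each sample's cross, and X-paternal
#' masking in male samples.
#'
#' @param ac An \code{\link[=AlleleCounts-class]{AlleleCounts}} with
#'   \code{chromClass} and \code{exonLength} row annotation and \code{cross}
#'   and \code{sex} column annotation.
#' @param rm_ Optional mapping-bias ratio(s) overriding the per-sample
#'   estimate (e.g. a pooled value).
#' @param maskX Mask paternal X-linked TPM to zero in male samples
#'   (default TRUE).
#' @return An \code{\link[=AllelicExpression-class]{AllelicExpression}}.
#' @export
allelicExpression <- function(ac, rm_ = NULL, maskX = TRUE) {
    stopifnot(is(ac, "AlleleCounts"))
    len <- rowData(ac)$exonLength
    if (is.null(len)) stop("AlleleCounts needs exonLength row annotation")
    if (is.null(rm_)) rm_ <- mappingBias(ac)$r_m
    tpm <- computeTPM(assay(ac, "total"), len)
    pr <- allelicProportion(assay(ac, "n0"), assay(ac, "n1"), rm_)
    dec <- decomposeTPM(tpm, pr$p0Adj)
    se <- SummarizedExperiment(
        assays = list(tpm = tpm, p0 = pr$p0, p0Adj = pr$p0Adj,
                      tpmA0 = dec$tpmA0, tpmA1 = dec$tpmA1,
                      tpmMat = dec$tpmA0, tpmPat = dec$tpmA1,
                      masked = matrix(FALSE, nrow(tpm), ncol(tpm),
                                      dimnames = dimnames(tpm))),
        rowData = rowData(ac), colData = colData(ac))
    ae <- orientAlleles(new("AllelicExpression", se))
    if (maskX) ae <- maskXPaternal(ae)
    ae
}

#' Orient allelic TPM to maternal/paternal
#'
#' The cross determines which strain allele is maternal: in BC
#' (BL6 mother x cast father) allele0 is maternal; in CB the orientation is
#' switched. Applying the orientation twice is a no-op because it always
#' starts from the strain-labelled assays.
#'
#' @param ae An \code{\link[=AllelicExpression-class]{AllelicExpression}}
#'   whose column data has a \code{cross} column with values "BC" or "CB".
#' @return The object with \code{tpmMat}/\code{tpmPat} assays set.
#' @export
orientAlleles <- function(ae) {
    stopifnot(is(ae, "AllelicExpression"))
    cross <- colData(ae)$cross
    if (is.null(cross)) {
        cross <- rep("BC", ncol(ae))  # strain-labelled == maternal-labelled
    }
    if (!all(cross %in% c("BC", "CB")))
        stop("unknown cross: ", paste(setdiff(cross, c("BC", "CB")), collapse = ", "))
    a0 <- assay(ae, "tpmA0"); a1 <- assay(ae, "tpmA1")
    cb <- cross == "CB"
    tm <- a0; tp <- a1
    tm[, cb] <- a1[, cb, drop = FALSE]
    tp[, cb] <- a0[, cb, drop = FALSE]
    assay(ae, "tpmMat") <- tm
    assay(ae, "tpmPat") <- tp
    ae
}

#' Mask paternal X-linked expression in males
#'
#' Male hybrid cells carry a single, maternal X, so any paternal X signal is
#' noise; it is zeroed and flagged. Female samples and autosomes are left
#' untouched.
#'
#' @param ae An \code{\link[=AllelicExpression-class]{AllelicExpression}}
#'   with \code{chromClass} row annotation and \code{sex} column annotation.
#' @return The masked object.
#' @export
maskXPaternal <- function(ae) {
    stopifnot(is(ae, "AllelicExpression"))
    sex <- colData(ae)$sex
    cls <- rowData(ae)$chromClass
    if (is.null(sex) || is.null(cls)) return(ae)
    xg <- cls == "X"
    male <- sex == "M"
    if (any(xg) && any(male)) {
        tp <- assay(ae, "tpmPat"); mk <- assay(ae, "masked")
        tp[xg, male] <- 0
        mk[xg, male] <- TRUE
        assay(ae, "tpmPat") <- tp
        assay(ae, "masked") <- mk
    }
    ae
}

#' Expression filter: above a TPM floor in at least one replicate
#'
#' @param tpm TPM matrix (genes x replicates).
#' @param minTpm Floor, default 1.
#' @return Logical vector: TRUE for genes with TPM > \code{minTpm} in at
#'   least one column.
#' @export
tpmFilter <- function(tpm, minTpm = 1) {
    apply(as.matrix(tpm) > minTpm, 1, any)
}
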