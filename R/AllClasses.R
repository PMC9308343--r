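#' Strain-distinguishing SNP index
#'
#' Holds biallelic single-nucleotide differences between the reference strain
#' (BL6, "allele0") and the alternate strain (cast, "allele1"), indexed for
#' fast interval queries. Positions are stored as width-1 \link[GenomicRanges]{GRanges}
#' (1-based, the Bioconductor convention); all text I/O and the
#' \code{\link{snpsInRegion}} query use 0-based half-open coordinates, and the
#' conversion happens only at those boundaries.
#'
#' @slot snps A width-1 \code{GRanges}, sorted, with metadata columns
#'   \code{ref} and \code{alt} (single upper-case bases, \code{ref != alt}).
#'
#' @seealso \code{\link{SnpIndex}}, \code{\link{readSnpTable}},
#'   \code{\link{buildPseudoGenome}}
#' @exportClass SnpIndex
setClass("SnpIndex", representation(snps = "GRanges"))

setValidity("SnpIndex", function(object) {
    gr <- object@snps
    msg <- character()
    if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "all SNP ranges must have width 1")
        m <- mcols(gr)
        if (!all(c("ref", "alt") %in% colnames(m)))
            msg <- c(msg, "metadata columns 'ref' and 'alt' are required")
        else {
            bases <- c("A", "C", "G", "T")
            if (!all(m$ref %in% bases) || !all(m$alt %in% bases))
                msg <- c(msg, "ref and alt must be single bases in {A,C,G,T}")
            if (any(m$ref == m$alt))
                msg <- c(msg, "ref and alt alleles must differ")
        }
        key <- paste(seqnames(gr), start(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos) entries")
        if (is.unsorted(gr))
            msg <- c(msg, "SNPs must be position-sorted")
    }
    if (length(msg)) msg else TRUE
})

#' Gene models with exon structure
#'
#' Per-gene exon sets plus the derived quantities the pipeline needs: the
#' merged exon-union length (for TPM), the transcription start site (for
#' promoter windows) and the chromosome class (autosome/X/Y, for mapping-bias
#' and masking rules).
#'
#' @slot exons A \code{GRangesList}, one element per gene, named by gene id.
#' @slot info A \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tss} (0-based position of the 5'-most
#'   transcribed base), \code{chromClass} (\code{"autosome"}, \code{"X"} or
#'   \code{"Y"}) and \code{exonLength} (merged exon-union length in bp).
#'
#' @seealso \code{\link{GeneModels}}, \code{\link{readGeneModels}},
#'   \code{\link{makePromoters}}
#' @exportClass GeneModels
setClass("GeneModels", representation(exons = "GRangesList", info = "DataFrame"))

setValidity("GeneModels", function(object) {
    msg <- character()
    if (length(object@exons) != nrow(object@info))
        msg <- c(msg, "exons and info must describe the same genes")
    need <- c("gene_id", "chrom", "strand", "tss", "chromClass", "exonLength")
    if (!all(need %in% colnames(object@info)))
        msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
    else {
        if (any(object@info$exonLength <= 0L))
            msg <- c(msg, "exon union length must be positive for every gene")
        if (!all(object@info$chromClass %in% c("autosome", "X", "Y")))
            msg <- c(msg, "chromClass must be autosome, X or Y")
        if (anyDuplicated(object@info$gene_id))
            msg <- c(msg, "duplicate gene ids")
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene allelic fragment counts
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one row per gene
#' and one column per sample, carrying four integer assays:
#' \code{n0} (allele0 = BL6 exonic fragments), \code{n1} (allele1 = cast),
#' \code{uncertain} (exonic fragments without SNP information) and
#' \code{total} (all exonic fragments). Column data holds the sample sheet
#' (\code{cross}, \code{sex}, \code{genotype}); row data holds gene
#' annotation (\code{chromClass}, \code{exonLength}).
#'
#' @seealso \code{\link{AlleleCounts}}, \code{\link{countGeneAlleles}},
#'   \code{\link{mappingBias}}, \code{\link{allelicExpression}}
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
    msg <- character()
    need <- c("n0", "n1", "uncertain", "total")
    if (!all(need %in% names(assays(object))))
        return(paste("assays required:", paste(need, collapse = ", ")))
    for (a in need) {
        x <- assay(object, a)
        if (any(x < 0) || any(x != round(x)))
            msg <- c(msg, paste0("assay '", a, "' must hold non-negative integers"))
    }
    if (!length(msg)) {
        if (any(assay(object, "n0") + assay(object, "n1") >
                assay(object, "total")))
            msg <- c(msg, "n0 + n1 must not exceed total exonic count")
    }
    if (length(msg)) msg else TRUE
})

#' Allelic expression decomposition
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with assays
#' \code{tpm} (diploid TPM), \code{p0} (raw allele0 proportion),
#' \code{p0Adj} (mapping-bias-adjusted proportion), \code{tpmA0}/\code{tpmA1}
#' (allelic TPM), \code{tpmMat}/\code{tpmPat} (cross-oriented maternal and
#' paternal TPM) and \code{masked} (TRUE where the paternal X copy of a male
#' sample was zeroed). Proportions are \code{NA} for genes without allelic
#' information in a sample.
#'
#' @seealso \code{\link{allelicExpression}}, \code{\link{orientAlleles}},
#'   \code{\link{maskXPaternal}}
#' @exportClass AllelicExpression
setClass("AllelicExpression", contains = "SummarizedExperiment")

setValidity("AllelicExpression", function(object) {
    need <- c("tpm", "p0", "p0Adj", "tpmA0", "tpmA1", "tpmMat", "tpmPat", "masked")
    if (!all(need %in% names(assays(object))))
        return(paste("assays required:", paste(need, collapse = ", ")))
    p <- assay(object, "p0Adj")
    ok <- is.na(p) | (p >= 0 & p <= 1)
    if (!all(ok))
        return("p0Adj must lie in [0, 1] (or be NA)")
    tpm <- assay(object, "tpm")
    s <- assay(object, "tpmA0") + assay(object, "tpmA1")
    bad <- !is.na(p) & abs(s - tpm) > 1e-6 * pmax(tpm, 1)
    if (any(bad))
        return("allelic TPM values must sum to the diploid TPM")
    TRUE
})

#' Synthetic F1-hybrid study configuration
#'
#' Describes one simulated study: the hybrid genome (chromosome count and
#' length, SNP density), the gene set, the sequencing process (depth, read and
#' fragment geometry, informative-read fraction, mapping bias), the
#' negative-binomial noise level, and the planted biology (allelic KO response
#' groups A-F, sex-biased genes with post-KO loss, imprinted genes). The seed
#' fully determines every simulated output.
#'
#' @seealso \code{\link{SimConfig}}, \code{\link{simulateReference}},
#'   \code{\link{simulateCounts}}
#' @exportClass SimConfig
setClass("SimConfig", representation(
    seed = "integer",
    nChromosomes = "integer",        # autosomes; one extra "chrX" is always added
    chromLength = "integer",
    nGenes = "integer",
    exonsPerGene = "integer",
    snpDensity = "numeric",          # per-bp Bernoulli rate
    informativeFraction = "numeric", # target fraction of exonic fragments overlapping a SNP
    readLength = "integer",
    fragmentMean = "numeric",
    fragmentSd = "numeric",
    depth = "numeric",               # expected exonic fragments per sample
    rTrue = "numeric",               # planted allele0 mapping bias
    nbDispersion = "numeric",
    groupFractions = "numeric",      # named A..F, fractions of genes per KO group
    groupEffect = "numeric",         # fold-change applied to the affected allele(s)
    sexBiasFractions = "numeric",    # named female, male
    sexBiasFold = "numeric",
    lossProbability = "numeric",     # P(a sex-biased gene loses its bias after KO)
    imprintedFraction = "numeric",
    imprintedF = "numeric",          # maternal fraction of imprinted genes
    nWt = "integer",                 # male wt replicates per cross
    nKo = "integer",                 # male KO replicates per cross
    nFemale = "integer"              # female wt replicates per cross
))

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- object@groupFractions
    if (!identical(sort(names(fr)), sort(c("A", "B", "C", "D", "E", "F"))))
        msg <- c(msg, "groupFractions must be named A..F")
    probs <- c(fr, object@sexBiasFractions, object@lossProbability,
               object@imprintedFraction, object@informativeFraction,
               object@snpDensity)
    if (any(probs < 0) || any(probs > 1))
        msg <- c(msg, "all fractions must lie in [0, 1]")
    if (sum(fr) + object@imprintedFraction > 1)
        msg <- c(msg, "group fractions plus imprinted fraction must sum to <= 1")
    if (!identical(sort(names(object@sexBiasFractions)), c("female", "male")))
        msg <- c(msg, "sexBiasFractions must be named female, male")
    if (object@snpDensity >= 1)
        msg <- c(msg, "snpDensity must be < 1")
    if (object@rTrue <= 0) msg <- c(msg, "rTrue must be positive")
    if (object@groupEffect <= 1) msg <- c(msg, "groupEffect must exceed 1")
    if (object@sexBiasFold <= 1) msg <- c(msg, "sexBiasFold must exceed 1")
    if (length(msg)) msg else TRUE
})
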