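#' Allele-assigned fragments
#'
#' Container tying each sequencing fragment (a read pair's outer template, or
#' a single-end read) to its allele call and to the aligned blocks of its
#' reads, so that exonic overlap can be computed at base resolution rather
#' than from the outer span.
#'
#' @slot frags A \code{GRanges} of fragment outer coordinates with metadata
#'   columns \code{qname} and \code{call}
#'   (allele0/allele1/uncertain/discard).
#' @slot blocks A \code{GRanges} of aligned blocks with metadata column
#'   \code{frag} (index into \code{frags}).
#' @exportClass AlleleFragments
setClass("AlleleFragments",
         representation(frags = "GRanges", blocks = "GRanges"))

setValidity("AlleleFragments", function(object) {
    msg <- character()
    if (!all(c("qname", "call") %in% colnames(mcols(object@frags))))
        msg <- c(msg, "frags needs mcols qname and call")
    if (!"frag" %in% colnames(mcols(object@blocks)))
        msg <- c(msg, "blocks needs mcols frag")
    else if (length(object@blocks) &&
             (max(mcols(object@blocks)$frag) > length(object@frags) ||
              min(mcols(object@blocks)$frag) < 1L))
        msg <- c(msg, "block fragment indices out of range")
    if (length(msg)) msg else TRUE
})

setMethod("length", "AlleleFragments", function(x) length(x@frags))

setMethod("show", "AlleleFragments", function(object) {
    tab <- table(factor(mcols(object@frags)$call,
                        levels = c("allele0", "allele1", "uncertain", "discard")))
    cat("AlleleFragments with", length(object), "fragments:",
        paste(names(tab), as.integer(tab), collapse = ", "), "\n")
})

setMethod("[", "AlleleFragments", function(x, i, j, ..., drop = FALSE) {
    idx <- seq_along(x@frags)[i]
    keepb <- mcols(x@blocks)$frag %in% idx
    b <- x@blocks[keepb]
    mcols(b)$frag <- match(mcols(b)$frag, idx)
    new("AlleleFragments", frags = x@frags[i], blocks = b)
})

#' Fragment accessors
#' @param x An \code{AlleleFragments} object.
#' @return \code{fragRanges}: outer fragment \code{GRanges};
#'   \code{fragBlocks}: aligned block \code{GRanges}; \code{fragCalls}:
#'   character vector of allele calls.
#' @name fragAccessors
NULL

#' @rdname fragAccessors
#' @export
fragRanges <- function(x) x@frags

#' @rdname fragAccessors
#' @export
fragBlocks <- function(x) x@blocks

#' @rdname fragAccessors
#' @export
fragCalls <- function(x) mcols(x@frags)$call

#' Read alignments from a SAM file
#'
#' Converts the SAM to BAM in a scratch directory with
#' \code{\link[Rsamtools]{asBam}} and loads it through
#' \code{\link[GenomicAlignments]{readGAlignments}}, keeping the fields the
#' allele classifier needs (name, flag, MAPQ, sequence, NH tag). Unmapped
#' records are dropped.
#'
#' @param path SAM file with header.
#' @return A \code{GAlignments} with metadata columns \code{qname},
#'   \code{flag}, \code{mapq}, \code{seq} and \code{NH}.
#' @export
readSamAlignments <- function(path) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "mapq", "seq"), tag = "NH",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    GenomicAlignments::readGAlignments(bam, param = param)
}

#' Filter alignments on uniqueness and mapping quality
#'
#' Keeps primary, non-supplementary alignments that map uniquely (NH tag
#' absent or 1) with MAPQ at or above the threshold (default 30), preserving
#' input order.
#'
#' @param aln A \code{GAlignments} from \code{\link{readSamAlignments}}.
#' @param mapqMin Minimum mapping quality (default 30).
#' @return The filtered \code{GAlignments}.
#' @export
filterAlignments <- function(aln, mapqMin = 30L) {
    stopifnot(mapqMin >= 0)
    m <- mcols(aln)
    secondary <- bitwAnd(m$flag, 256L) > 0L
    supp <- bitwAnd(m$flag, 2048L) > 0L
    nh <- if ("NH" %in% colnames(m)) m$NH else rep(NA_integer_, length(aln))
    unique_map <- is.na(nh) | nh == 1L
    keep <- !secondary & !supp & unique_map & !is.na(m$mapq) & m$mapq >= mapqMin
    aln[keep]
}

#' Classify reads by the SNP bases they cover
#'
#' For every SNP falling inside an aligned block of a read, the read base at
#' that reference position is compared against the two strain alleles. A read
#' whose covered SNP bases all match the reference (BL6) allele is
#' \code{allele0}; all matching the alternate (cast) allele, \code{allele1};
#' bases supporting both strains, \code{conflict}. SNP positions where the
#' read base matches neither allele (sequencing error) are ignored; a read
#' covering no SNP, or only ignored ones, is \code{uncertain}. Insertions,
#' deletions, splices and soft clips in the CIGAR are handled through the
#' block decomposition, so SNPs in skipped introns never vote.
#'
#' @param aln A filtered \code{GAlignments} with a \code{seq} metadata column.
#' @param snps A \code{\link[=SnpIndex-class]{SnpIndex}}.
#' @return A character vector (one call per alignment) with values
#'   \code{allele0}, \code{allele1}, \code{uncertain} or \code{conflict}.
#' @export
classifyReads <- function(aln, snps) {
    n <- length(aln)
    if (n == 0L) return(character(0))
    cig <- GenomicAlignments::cigar(aln)
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = c("M", "=", "X"))
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = c("M", "=", "X"))
    nb <- S4Vectors::elementNROWS(rr)
    alnIdx <- rep(seq_len(n), nb)
    rrf <- BiocGenerics::unlist(rr)
    qrf <- BiocGenerics::unlist(qr)
    absStart <- start(aln)[alnIdx] + start(rrf) - 1L
    blocks <- GRanges(rep(as.character(seqnames(aln)), nb),
                      IRanges(absStart, width = width(rrf)))
    sl <- seqlengths(snpRanges(snps))
    if (length(sl) && !anyNA(sl)) {
        lim <- sl[as.character(seqnames(blocks))]
        if (any(!is.na(lim) & end(blocks) > lim))
            stop("aligned block extends past chromosome end")
    }
    hits <- findOverlaps(blocks, snpRanges(snps))
    call <- rep("uncertain", n)
    if (length(hits)) {
        bi <- queryHits(hits); si <- subjectHits(hits)
        refpos <- start(snpRanges(snps))[si]
        qpos <- start(qrf)[bi] + (refpos - start(blocks)[bi])
        seqs <- as.character(mcols(aln)$seq)
        base <- toupper(substr(seqs[alnIdx[bi]], qpos, qpos))
        isRef <- base == mcols(snpRanges(snps))$ref[si]
        isAlt <- base == mcols(snpRanges(snps))$alt[si]
        ai <- alnIdx[bi]
        has0 <- tabulate(ai[isRef], nbins = n) > 0L
        has1 <- tabulate(ai[isAlt], nbins = n) > 0L
        call[has0 & !has1] <- "allele0"
        call[has1 & !has0] <- "allele1"
        call[has0 & has1] <- "conflict"
    }
    call
}

#' Combine the allele calls of a read pair
#'
#' Implements the pairing rule: if one end is allele-certain the fragment
#' takes that allele; two ends certain for different alleles, or any end in
#' conflict, discard the fragment; both ends uncertain, the fragment is
#' uncertain. Single-end fragments keep their own call (conflict becomes
#' discard).
#'
#' @param call1 Character vector of first-end calls.
#' @param call2 Second-end calls, or \code{NULL}/\code{NA} entries for
#'   single-end fragments.
#' @return Character vector of fragment calls:
#'   \code{allele0}, \code{allele1}, \code{uncertain} or \code{discard}.
#' @examples
#' assignFragment("allele0", "uncertain")  # "allele0"
#' assignFragment("allele0", "allele1")    # "discard"
#' @export
assignFragment <- function(call1, call2 = NULL) {
    if (is.null(call2)) call2 <- rep(NA_character_, length(call1))
    stopifnot(length(call1) == length(call2))
    out <- character(length(call1))
    for (i in seq_along(call1)) {
        a <- call1[i]; b <- call2[i]
        if (is.na(a) && !is.na(b)) { a <- b; b <- NA_character_ }
        if (is.na(b)) {
            out[i] <- if (a == "conflict") "discard" else a
        } else if (a == "conflict" || b == "conflict") {
            out[i] <- "discard"
        } else if (a == "uncertain") {
            out[i] <- b
        } else if (b == "uncertain" || b == a) {
            out[i] <- a
        } else {
            out[i] <- "discard"   # opposite certain alleles
        }
    }
    out
}

#' Pair classified alignments into fragments
#'
#' Groups alignments by read name (paired-end flag set), combines the two
#' ends' calls with \code{\link{assignFragment}}, and records the template's
#' outer coordinates (min start to max end) and the first end's strand.
#' Alignments whose mate is absent, and unpaired alignments, become
#' single-end fragments.
#'
#' @param aln A filtered \code{GAlignments} with \code{qname}, \code{flag}
#'   and \code{seq} metadata.
#' @param calls Per-alignment calls from \code{\link{classifyReads}}.
#' @return An \code{\link[=AlleleFragments-class]{AlleleFragments}} object.
#' @export
pairFragments <- function(aln, calls) {
    stopifnot(length(aln) == length(calls))
    m <- mcols(aln)
    paired <- bitwAnd(m$flag, 1L) > 0L
    isFirst <- bitwAnd(m$flag, 64L) > 0L
    revstr <- bitwAnd(m$flag, 16L) > 0L
    key <- ifelse(paired, m$qname, paste0(m$qname, "/", seq_along(aln)))
    grp <- match(key, unique(key))
    nfrag <- max(grp, 0L)
    ord <- order(grp, !isFirst)   # first mate first within each fragment
    gs <- grp[ord]
    firstOf <- ord[!duplicated(gs)]
    secondOf <- rep(NA_integer_, nfrag)
    dup2 <- ord[duplicated(gs)]
    secondOf[gs[duplicated(gs)]] <- dup2
    c1 <- calls[firstOf]
    c2 <- ifelse(is.na(secondOf), NA_character_, calls[secondOf])
    fcall <- assignFragment(c1, c2)
    st <- start(aln); en <- end(aln)
    outerS <- st[firstOf]; outerE <- en[firstOf]
    ok2 <- !is.na(secondOf)
    outerS[ok2] <- pmin(outerS[ok2], st[secondOf[ok2]])
    outerE[ok2] <- pmax(outerE[ok2], en[secondOf[ok2]])
    frags <- GRanges(as.character(seqnames(aln))[firstOf],
                     IRanges(outerS, outerE),
                     strand = ifelse(revstr[firstOf], "-", "+"),
                     qname = m$qname[firstOf], call = fcall)
    # aligned blocks of both ends, indexed by fragment
    cig <- GenomicAlignments::cigar(aln)
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = c("M", "=", "X"))
    nb <- S4Vectors::elementNROWS(rr)
    alnIdx <- rep(seq_along(aln), nb)
    rrf <- BiocGenerics::unlist(rr)
    blocks <- GRanges(as.character(seqnames(aln))[alnIdx],
                      IRanges(st[alnIdx] + start(rrf) - 1L, width = width(rrf)),
                      frag = grp[alnIdx])
    new("AlleleFragments", frags = frags, blocks = blocks)
}

#' Remove coordinate duplicates among fragments
#'
#' A stand-in for Picard MarkDuplicates: among fragments sharing identical
#' (chrom, outer start, outer end, strand), only the first encountered is
#' kept. Intended for ATAC/ChIP fragments; RNA-seq counting does not
#' deduplicate.
#'
#' @param x An \code{AlleleFragments} object.
#' @return The deduplicated \code{AlleleFragments}.
#' @export
dedupFragments <- function(x) {
    g <- x@frags
    key <- paste(seqnames(g), start(g), end(g), strand(g))
    x[!duplicated(key)]
}

#' Count allelic exonic fragments per gene
#'
#' A fragment contributes to a gene when at least one aligned base of either
#' read overlaps the gene's merged exon set; fragments touching exons of more
#' than one gene are dropped as ambiguous, and discarded fragments never
#' count. Each counted fragment increments \code{n0}, \code{n1} or
#' \code{uncertain} according to its allele call.
#'
#' @param x An \code{AlleleFragments} object.
#' @param models A \code{\link[=GeneModels-class]{GeneModels}}.
#' @param sampleId Column name for the resulting one-sample table.
#' @return An \code{\link[=AlleleCounts-class]{AlleleCounts}} with one column.
#' @export
countGeneAlleles <- function(x, models, sampleId = "sample1") {
    stopifnot(is(x, "AlleleFragments"), is(models, "GeneModels"))
    red <- reduce(geneExons(models))
    exu <- BiocGenerics::unlist(red)
    geneIdx <- rep(seq_along(red), S4Vectors::elementNROWS(red))
    keep <- mcols(x@frags)$call != "discard"
    fr <- x[keep]
    hits <- findOverlaps(fr@blocks, exu, ignore.strand = TRUE)
    fg <- unique(data.frame(frag = mcols(fr@blocks)$frag[queryHits(hits)],
                            gene = geneIdx[subjectHits(hits)]))
    multi <- unique(fg$frag[duplicated(fg$frag)])
    fg <- fg[!fg$frag %in% multi, , drop = FALSE]
    call <- mcols(fr@frags)$call[fg$frag]
    ng <- length(models)
    tal <- function(sel) tabulate(fg$gene[sel], nbins = ng)
    n0 <- tal(call == "allele0")
    n1 <- tal(call == "allele1")
    nu <- tal(call == "uncertain")
    AlleleCounts(n0 = matrix(n0, ncol = 1, dimnames = list(names(models), sampleId)),
                 n1 = matrix(n1, ncol = 1, dimnames = list(names(models), sampleId)),
                 uncertain = matrix(nu, ncol = 1, dimnames = list(names(models), sampleId)),
                 geneModels = models)
}

#' Construct an AlleleCounts table
#'
#' @param n0,n1,uncertain Integer matrices (genes x samples) of allele0
#'   (BL6), allele1 (cast) and allele-uncertain exonic fragment counts.
#' @param total Optional total exonic count matrix; defaults to the sum of
#'   the three classes.
#' @param geneModels Optional \code{GeneModels} supplying row annotation
#'   (\code{chromClass}, \code{exonLength}).
#' @param sampleData Optional \code{DataFrame}/data.frame sample sheet with
#'   columns such as \code{cross} (BC/CB), \code{sex} (M/F), \code{genotype}
#'   (wt/KO).
#' @return An \code{\link[=AlleleCounts-class]{AlleleCounts}}.
#' @export
AlleleCounts <- function(n0, n1, uncertain = NULL, total = NULL,
                         geneModels = NULL, sampleData = NULL) {
    n0 <- as.matrix(n0); n1 <- as.matrix(n1)
    if (is.null(uncertain)) uncertain <- matrix(0L, nrow(n0), ncol(n0),
                                                dimnames = dimnames(n0))
    uncertain <- as.matrix(uncertain)
    if (is.null(total)) total <- n0 + n1 + uncertain
    total <- as.matrix(total)
    rd <- NULL
    if (!is.null(geneModels)) {
        stopifnot(identical(rownames(n0), names(geneModels)))
        rd <- geneInfo(geneModels)
    }
    cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(n0))
          else DataFrame(sampleData, row.names = colnames(n0))
    se <- SummarizedExperiment(
        assays = list(n0 = n0, n1 = n1, uncertain = uncertain, total = total),
        colData = cd)
    if (!is.null(rd)) rowData(se) <- rd
    new("AlleleCounts", se)
}

#' Genome-wide strain mapping bias
#'
#' Computes, per sample, the ratio r_m = N_A0 / N_A1 of allele-specific
#' autosomal fragment totals (BL6 over cast). Reads mapping to the reference
#' strain's genome are slightly favored even after pseudo-genome
#' construction; this ratio is the correction factor applied to per-gene
#' allelic proportions. Autosomal genes only, so X-inactivation cannot
#' contaminate the estimate.
#'
#' @param ac An \code{\link[=AlleleCounts-class]{AlleleCounts}} whose row
#'   data carries \code{chromClass}.
#' @return A data.frame with columns \code{sample}, \code{N_A0},
#'   \code{N_A1}, \code{r_m}.
#' @export
mappingBias <- function(ac) {
    stopifnot(is(ac, "AlleleCounts"))
    cls <- rowData(ac)$chromClass
    if (is.null(cls)) stop("AlleleCounts needs chromClass row annotation")
    auto <- cls == "autosome"
    if (!any(auto)) stop("mapping bias undefined: no autosomal genes")
    N0 <- colSums(assay(ac, "n0")[auto, , drop = FALSE])
    N1 <- colSums(assay(ac, "n1")[auto, , drop = FALSE])
    if (any(N1 == 0)) stop("mapping bias undefined: no autosomal allele1 fragments")
    data.frame(sample = colnames(ac), N_A0 = N0, N_A1 = N1, r_m = N0 / N1,
               row.names = NULL)
}

#' Per-sample allele-assignment metrics
#'
#' @param x An \code{AlleleFragments} object.
#' @return A one-row data.frame with the fragment total, the fraction per
#'   allele call, and the discarded count.
#' @export
mappingMetrics <- function(x) {
    call <- fragCalls(x)
    n <- length(call)
    frac <- function(lab) if (n == 0L) 0 else sum(call == lab) / n
    data.frame(n_fragments = n,
               frac_allele0 = frac("allele0"),
               frac_allele1 = frac("allele1"),
               frac_uncertain = frac("uncertain"),
               n_discarded = sum(call == "discard"))
}
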