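#' Construct a SNP index
#'
#' Builds the position-indexed table of strain-distinguishing SNPs used for
#' pseudo-genome substitution and read classification. Input positions are
#' 0-based; they are converted once, here, to the 1-based \code{GRanges}
#' representation used internally.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based SNP positions.
#' @param ref Reference-strain (BL6) bases, single characters in A/C/G/T.
#' @param alt Alternate-strain (cast) bases.
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   when given, SNP positions are checked against it.
#'
#' @return A \code{\link[=SnpIndex-class]{SnpIndex}} object.
#'
#' @details Duplicate (chrom, pos) entries with identical alleles are
#' collapsed; duplicates with conflicting alleles are an error.
#'
#' @examples
#' si <- SnpIndex(c("chr1", "chr1"), c(4L, 9L), c("A", "G"), c("C", "T"))
#' length(si)
#' snpsInRegion(si, "chr1", 0, 6)
#' @export
SnpIndex <- function(chrom, pos, ref, alt, seqlengths = NULL) {
    stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
              length(alt) == length(pos))
    ref <- toupper(as.character(ref))
    alt <- toupper(as.character(alt))
    pos <- as.integer(pos)
    if (length(pos) && any(pos < 0L))
        stop("SNP positions must be >= 0 (0-based)")
    key <- paste(chrom, pos)
    if (anyDuplicated(key)) {
        allele_key <- paste(key, ref, alt)
        if (anyDuplicated(key[!duplicated(allele_key)]))
            stop("duplicate SNP positions with conflicting alleles")
        keep <- !duplicated(key)
        chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    }
    gr <- GRanges(chrom, IRanges(pos + 1L, width = 1L), ref = ref, alt = alt)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (!is.null(seqlengths)) {
        sl <- seqlengths[as.character(seqnames(gr))]
        if (anyNA(sl))
            stop("SNP on unknown chromosome: ",
                 paste(unique(setdiff(as.character(seqnames(gr)), names(seqlengths))),
                       collapse = ", "))
        if (any(start(gr) > sl))
            stop("SNP position beyond chromosome end")
        GenomeInfoDb::seqlengths(gr) <- seqlengths[seqlevels(gr)]
    }
    new("SnpIndex", snps = gr)
}

#' @describeIn SnpIndex Number of SNPs in the index.
#' @param x A \code{SnpIndex}.
#' @export
setMethod("length", "SnpIndex", function(x) length(x@snps))

#' Extract the SNP ranges
#'
#' @param x A \code{SnpIndex}.
#' @return The underlying width-1 \code{GRanges} (1-based) with \code{ref}
#'   and \code{alt} metadata columns.
#' @export
snpRanges <- function(x) {
    stopifnot(is(x, "SnpIndex"))
    x@snps
}

setMethod("show", "SnpIndex", function(object) {
    cat("SnpIndex with", length(object), "SNPs on",
        length(unique(as.character(seqnames(object@snps)))), "chromosome(s)\n")
    if (length(object))
        show(head(object@snps, 3))
})

#' Query SNPs overlapping an interval
#'
#' @param x A \code{SnpIndex}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, position-sorted; zero rows when no SNP falls in
#'   \code{[start, end)}.
#' @export
snpsInRegion <- function(x, chrom, start, end) {
    stopifnot(is(x, "SnpIndex"), end >= start)
    gr <- x@snps
    hit <- as.character(seqnames(gr)) == chrom &
        start(gr) >= start + 1L & start(gr) <= end   # 0-based [start,end) -> 1-based [start+1, end]
    g <- gr[hit]
    data.frame(chrom = as.character(seqnames(g)), pos = start(g) - 1L,
               ref = mcols(g)$ref, alt = mcols(g)$alt,
               stringsAsFactors = FALSE)
}
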