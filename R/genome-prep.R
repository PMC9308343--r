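#' Read and write genome FASTA
#'
#' Sequences are kept as \code{BStringSet} so that soft-masked (lower-case)
#' bases survive a round trip; substitution and classification treat case
#' insensitively.
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped).
#' @return A \code{BStringSet} named by the first word of each header.
#' @export
readFastaGenome <- function(path) {
    x <- readBStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

#' @rdname readFastaGenome
#' @param genome A \code{BStringSet} or \code{DNAStringSet}.
#' @export
writeFastaGenome <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}

#' Read a strain SNP table
#'
#' Accepts either a VCF (only CHROM/POS/REF/ALT are used; POS is 1-based) or
#' a tab-separated table. A headerless 4-column TSV is read as
#' (chrom, pos 1-based, ref, alt); a TSV whose header names a \code{pos0}
#' column is read 0-based (the normalized format \code{\link{writeSnpTable}}
#' emits). Indel and multiallelic records are skipped with a message giving
#' the count; only biallelic single-nucleotide substitutions enter the index.
#'
#' @param path VCF or TSV file.
#' @param seqlengths Optional named chromosome lengths for validation.
#' @return A \code{\link[=SnpIndex-class]{SnpIndex}}.
#' @export
readSnpTable <- function(path, seqlengths = NULL) {
    lines <- readLines(path)
    is_vcf <- grepl("\\.vcf$", path) || any(startsWith(lines, "##fileformat=VCF"))
    if (is_vcf) {
        body <- lines[!startsWith(lines, "#")]
        f <- strsplit(body, "\t")
        chrom <- vapply(f, `[`, "", 1L)
        pos1 <- as.integer(vapply(f, `[`, "", 2L))
        ref <- vapply(f, `[`, "", 4L)
        alt <- vapply(f, `[`, "", 5L)
    } else {
        has_header <- grepl("pos", tolower(lines[1]))
        if (has_header) {
            df <- read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character")
            chrom <- df$chrom
            pos1 <- if ("pos0" %in% colnames(df)) as.integer(df$pos0) + 1L
                    else as.integer(df[[2]])
            ref <- df$ref; alt <- df$alt
        } else {
            df <- read.table(path, header = FALSE, sep = "\t",
                             colClasses = "character")
            chrom <- df[[1]]; pos1 <- as.integer(df[[2]])
            ref <- df[[3]]; alt <- df[[4]]
        }
    }
    ok <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
        toupper(ref) %in% c("A", "C", "G", "T") &
        toupper(alt) %in% c("A", "C", "G", "T")
    if (any(!ok))
        message(sum(!ok), " non-SNP (indel/multiallelic/ambiguous) records skipped")
    SnpIndex(chrom[ok], pos1[ok] - 1L, ref[ok], alt[ok], seqlengths = seqlengths)
}

#' Write the normalized SNP table
#'
#' Emits the 0-based TSV (\code{chrom}, \code{pos0}, \code{ref}, \code{alt})
#' consumed by downstream stages.
#'
#' @param x A \code{SnpIndex}.
#' @param path Output path.
#' @export
writeSnpTable <- function(x, path) {
    gr <- snpRanges(x)
    df <- data.frame(chrom = as.character(seqnames(gr)), pos0 = start(gr) - 1L,
                     ref = mcols(gr)$ref, alt = mcols(gr)$alt)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Build the alternate-strain pseudo-genome
#'
#' Substitutes each SNP's alternate (cast) base into the reference (BL6)
#' sequence, yielding the "pseudo-cast" genome against which alternate-allele
#' reads map without mismatch. Every SNP's ref allele must match the
#' reference base at its position (case-insensitively); soft-mask case is
#' preserved in the output, and sequence lengths never change.
#'
#' @param genome A named \code{BStringSet}/\code{DNAStringSet} (reference).
#' @param snps A \code{\link[=SnpIndex-class]{SnpIndex}}.
#' @return Sequences of the same class, names and lengths with alternate
#'   bases substituted.
#' @examples
#' g <- Biostrings::BStringSet(c(chr1 = "AAAA"))
#' si <- SnpIndex("chr1", 1L, "A", "C")
#' as.character(buildPseudoGenome(g, si))  # "ACAA"
#' @export
buildPseudoGenome <- function(genome, snps) {
    stopifnot(is(snps, "SnpIndex"))
    gr <- snpRanges(snps)
    bad_chr <- setdiff(unique(as.character(seqnames(gr))), names(genome))
    if (length(bad_chr))
        stop("SNP on unknown chromosome: ", paste(bad_chr, collapse = ", "))
    out <- genome
    for (chr in unique(as.character(seqnames(gr)))) {
        g <- gr[seqnames(gr) == chr]
        if (max(start(g)) > length(genome[[chr]]))
            stop("SNP position beyond end of ", chr)
        cur <- as.character(Biostrings::extractAt(genome[[chr]],
                                                  IRanges(start(g), width = 1L)))
        if (any(toupper(cur) != mcols(g)$ref)) {
            i <- which(toupper(cur) != mcols(g)$ref)[1L]
            stop("reference mismatch at ", chr, ":", start(g)[i] - 1L,
                 " (0-based): expected ", mcols(g)$ref[i], ", found ", cur[i])
        }
        repl <- ifelse(cur == tolower(cur), tolower(mcols(g)$alt), mcols(g)$alt)
        out[[chr]] <- replaceAt(out[[chr]],
                                at = IRanges(start(g), width = 1L),
                                value = repl)
    }
    out
}
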