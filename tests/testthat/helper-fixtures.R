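suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# --- tiny hand-made fixtures -------------------------------------------------

toyGenome <- function() {
    BStringSet(c(chr1 = paste(rep("ACGT", 25), collapse = ""),   # 100 bp
                 chr2 = paste(rep("TTGCA", 20), collapse = "")))  # 100 bp
}

# write a SAM file from record vectors; returns the path
writeToySam <- function(records, chromLens = c(chr1 = 100L, chr2 = 100L)) {
    hdr <- c("@HD\tVN:1.6",
             paste0("@SQ\tSN:", names(chromLens), "\tLN:", chromLens))
    path <- tempfile(fileext = ".sam")
    writeLines(c(hdr, records), path)
    path
}

samRec <- function(qname, flag, chrom, pos, mapq, cigar, seq,
                   rnext = "*", pnext = 0, tlen = 0, nh = 1) {
    paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq, "*",
          paste0("NH:i:", nh), sep = "\t")
}

# two genes on chr1 (g1: exons 11-30 and 41-60; g2: exons 71-90), one on chrX
toyGenes <- function() {
    GeneModels(GRangesList(
        g1 = GRanges("chr1", IRanges(c(11, 41), c(30, 60)), strand = "+"),
        g2 = GRanges("chr1", IRanges(71, 90), strand = "-"),
        gx = GRanges("chrX", IRanges(11, 60), strand = "+")))
}

# AlleleFragments built directly from coordinate/call vectors (single blocks)
toyFragments <- function(chrom, start, end, call, strand = "+") {
    strand <- rep(strand, length.out = length(start))
    qn <- if (length(start)) paste0("q", seq_along(start)) else character(0)
    frags <- GRanges(chrom, IRanges(start, end), strand = strand,
                     qname = qn, call = call)
    blocks <- GRanges(chrom, IRanges(start, end), frag = seq_along(start))
    new("AlleleFragments", frags = frags, blocks = blocks)
}

# --- independent oracles -----------------------------------------------------

# Per-base read classifier working directly on SAM fields: walks the CIGAR
# itself, builds an explicit reference->query position map, and votes over
# every SNP the mapped bases cover. Independent of the package's block logic.
oracleClassifySam <- function(samPath, snpDf, mapqMin = 30) {
    lines <- readLines(samPath)
    lines <- lines[!startsWith(lines, "@")]
    byChrom <- split(snpDf, snpDf$chrom)
    out <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        flag <- as.integer(f[2])
        if (bitwAnd(flag, 4L) > 0L) next
        if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
        if (as.integer(f[5]) < mapqMin) next
        chrom <- f[3]; pos <- as.integer(f[4]); cigar <- f[6]; seq <- f[10]
        ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
        refpos <- pos; qpos <- 1L
        map <- integer(0)   # names: ref positions (1-based); values: query pos
        for (op in ops) {
            n <- as.integer(sub("[A-Z=]", "", op))
            t <- sub("\\d+", "", op)
            if (t %in% c("M", "=", "X")) {
                map[as.character(refpos:(refpos + n - 1L))] <- qpos:(qpos + n - 1L)
                refpos <- refpos + n; qpos <- qpos + n
            } else if (t %in% c("D", "N")) {
                refpos <- refpos + n
            } else if (t %in% c("I", "S")) {
                qpos <- qpos + n
            }
        }
        has0 <- FALSE; has1 <- FALSE
        sn <- byChrom[[chrom]]
        if (is.null(sn)) sn <- snpDf[0, ]
        sn <- sn[sn$pos + 1L >= pos & sn$pos + 1L < refpos, , drop = FALSE]
        for (k in seq_len(nrow(sn))) {
            qp <- map[as.character(sn$pos[k] + 1L)]
            if (is.na(qp)) next
            b <- toupper(substr(seq, qp, qp))
            if (b == sn$ref[k]) has0 <- TRUE
            else if (b == sn$alt[k]) has1 <- TRUE
        }
        call <- if (has0 && has1) "conflict"
                else if (has0) "allele0"
                else if (has1) "allele1"
                else "uncertain"
        out[[length(out) + 1L]] <- data.frame(qname = f[1], flag = flag,
                                              call = call,
                                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

# brute-force interval membership for SNP queries (0-based half-open)
oracleSnpQuery <- function(snpDf, chrom, qstart, qend) {
    hit <- snpDf$chrom == chrom & snpDf$pos >= qstart & snpDf$pos < qend
    d <- snpDf[hit, , drop = FALSE]
    d[order(d$pos), , drop = FALSE]
}
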