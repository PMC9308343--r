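#' Promoter windows around TSSs
#'
#' One symmetric window of \code{[tss - flank, tss + flank)} per gene
#' (default 2 kb each side), clipped at chromosome bounds when lengths are
#' known. The window is symmetric, so strand does not change it.
#'
#' @param models A \code{\link[=GeneModels-class]{GeneModels}}.
#' @param flank Half-width in bp (default 2000).
#' @param seqlengths Optional named chromosome lengths for clipping and
#'   validation.
#' @return A \code{GRanges} named by gene id with metadata columns
#'   \code{name} and \code{kind = "promoter"} (coordinates 1-based
#'   internally; exported BED would be 0-based).
#' @export
makePromoters <- function(models, flank = 2000L, seqlengths = NULL) {
    stopifnot(is(models, "GeneModels"))
    info <- geneInfo(models)
    s0 <- pmax(info$tss - flank, 0L)            # 0-based half-open
    e0 <- info$tss + flank
    if (!is.null(seqlengths)) {
        sl <- seqlengths[info$chrom]
        if (anyNA(sl)) stop("gene on chromosome without length")
        if (any(info$tss < 0L | info$tss >= sl))
            stop("TSS outside chromosome bounds")
        e0 <- pmin(e0, sl)
    }
    gr <- GRanges(info$chrom, IRanges(s0 + 1L, e0),
                  name = info$gene_id, kind = "promoter")
    names(gr) <- info$gene_id
    gr
}

#' Read a BED file of regions
#'
#' Minimal 3-6 column BED (0-based half-open) for custom region sets.
#'
#' @param path BED file.
#' @param kind Region kind label (default "custom").
#' @return A \code{GRanges} with \code{name} and \code{kind} columns.
#' @export
readBedRegions <- function(path, kind = "custom") {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    nm <- if (ncol(df) >= 4) df[[4]] else paste0("region", seq_len(nrow(df)))
    gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), name = nm, kind = kind)
    names(gr) <- nm
    gr
}

#' Allelic fragment coverage over regions
#'
#' Counts, per region and allele class, the fragments (outer template
#' intervals) overlapping the region by at least one base, and scales to
#' fragments per million assigned fragments in the sample. Regions may
#' overlap; a fragment is counted in every region it touches. The diploid
#' count is the sum over maternal, paternal and uncertain.
#'
#' @param frags Either an \code{\link[=AlleleFragments-class]{AlleleFragments}}
#'   (strain-labelled calls) or a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (1-based closed) and \code{allele}
#'   (maternal/paternal/uncertain).
#' @param regions \code{GRanges} from \code{\link{makePromoters}} or
#'   \code{\link{readBedRegions}}.
#' @param cross For \code{AlleleFragments} input: "BC" (allele0 maternal) or
#'   "CB" (allele1 maternal), used to orient the calls.
#' @param sample Sample label carried into the output.
#' @return A data.frame with columns \code{region}, \code{sample},
#'   \code{allele} (maternal/paternal/uncertain/diploid), \code{raw_count}
#'   and \code{depth_scaled}.
#' @export
regionCoverage <- function(frags, regions, cross = "BC", sample = "sample1") {
    if (is(frags, "AlleleFragments")) {
        g <- fragRanges(frags)
        call <- fragCalls(frags)
        keep <- call != "discard"
        g <- g[keep]; call <- call[keep]
        m0 <- if (cross == "BC") "maternal" else "paternal"
        m1 <- if (cross == "BC") "paternal" else "maternal"
        allele <- c(allele0 = m0, allele1 = m1, uncertain = "uncertain")[call]
    } else {
        g <- GRanges(frags$chrom, IRanges(frags$start, frags$end))
        allele <- frags$allele
    }
    total <- length(g)
    one <- function(sel) countOverlaps(regions, g[sel], ignore.strand = TRUE)
    alleles <- c("maternal", "paternal", "uncertain")
    counts <- lapply(alleles, function(a) one(allele == a))
    names(counts) <- alleles
    counts$diploid <- counts$maternal + counts$paternal + counts$uncertain
    scale <- if (total > 0) 1e6 / total else 0
    do.call(rbind, lapply(names(counts), function(a)
        data.frame(region = names(regions) %||% as.character(seq_along(regions)),
                   sample = sample, allele = a,
                   raw_count = as.integer(counts[[a]]),
                   depth_scaled = counts[[a]] * scale,
                   stringsAsFactors = FALSE)))
}

#' Normalize ChIP coverage by matched input
#'
#' Per region, the depth-scaled ChIP value is divided by the depth-scaled
#' input value, with a pseudocount on both to keep empty promoters finite:
#' (chip + pc) / (input + pc).
#'
#' @param chip,input Coverage data.frames from \code{\link{regionCoverage}},
#'   matched on (region, allele).
#' @param pseudocount Default 1 (on the depth-scaled values).
#' @return \code{chip} with an \code{input_normalized} column.
#' @export
inputNormalize <- function(chip, input, pseudocount = 1) {
    useSample <- "sample" %in% colnames(chip) && "sample" %in% colnames(input)
    key <- function(d) if (useSample) paste(d$region, d$allele, d$sample)
                       else paste(d$region, d$allele)
    idx <- match(key(chip), key(input))
    if (anyNA(idx)) stop("missing input coverage for some regions")
    chip$input_normalized <- (chip$depth_scaled + pseudocount) /
        (input$depth_scaled[idx] + pseudocount)
    chip
}

#' Quantile-normalize coverage across alleles and lines
#'
#' Arranges one value column per (allele, sample) group into a region x group
#' matrix and applies \code{\link{quantileNormalize}}, assuming promoter
#' coverage is similarly distributed between alleles and cell lines; every
#' group must cover the identical region set.
#'
#' @param records A coverage data.frame with columns \code{region},
#'   \code{sample}, \code{allele} and the value column.
#' @param value Which column to normalize (default \code{"depth_scaled"},
#'   use \code{"input_normalized"} for ChIP).
#' @return \code{records} with a \code{qn_value} column.
#' @export
qnAcross <- function(records, value = "depth_scaled") {
    grp <- paste(records$sample, records$allele, sep = "|")
    regions <- unique(records$region)
    groups <- unique(grp)
    m <- matrix(NA_real_, length(regions), length(groups),
                dimnames = list(regions, groups))
    idx <- cbind(match(records$region, regions), match(grp, groups))
    m[idx] <- records[[value]]
    if (anyNA(m)) stop("mismatched region sets across groups")
    qn <- quantileNormalize(m)
    records$qn_value <- qn[idx]
    records
}

#' Test a per-group coverage shift
#'
#' For the genes of one allelic response group, tests whether the per-gene
#' log2 KO/wt coverage ratios shift away from zero: a two-sided Wilcoxon
#' signed-rank test by default (robust to the heavy tails of coverage
#' ratios), or a one-sample t-test behind the flag.
#'
#' @param log2ratio Numeric vector of per-gene log2(KO/wt) values; at least
#'   5 genes.
#' @param test "wilcoxon" (default) or "t".
#' @return A list with \code{median}, \code{p_value}, \code{n}. With all
#'   ratios identical the Wilcoxon statistic is undefined: \code{p_value} is
#'   \code{NA} and \code{degenerate = TRUE} is flagged.
#' @export
groupShiftTest <- function(log2ratio, test = c("wilcoxon", "t")) {
    test <- match.arg(test)
    log2ratio <- log2ratio[is.finite(log2ratio)]
    if (length(log2ratio) < 5L) stop("need at least 5 genes in the group")
    med <- median(log2ratio)
    if (length(unique(log2ratio)) == 1L)
        return(list(median = med, p_value = NA_real_, n = length(log2ratio),
                    degenerate = TRUE))
    p <- if (test == "wilcoxon") {
        suppressWarnings(wilcox.test(log2ratio, mu = 0, exact = FALSE)$p.value)
    } else t.test(log2ratio, mu = 0)$p.value
    list(median = med, p_value = p, n = length(log2ratio), degenerate = FALSE)
}
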