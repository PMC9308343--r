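#' Construct gene models from exon sets
#'
#' @param exons A named \code{GRangesList}, one element per gene, holding that
#'   gene's exons (1-based GRanges). Strand is taken from the exons
#'   (one strand per gene).
#' @param chromClass Optional character vector (\code{"autosome"}, \code{"X"},
#'   \code{"Y"}) per gene; by default inferred from the chromosome name
#'   (\code{"chrX"}/\code{"X"} etc.).
#'
#' @details The TSS is the 5'-most transcribed base respecting strand
#' (plus strand: lowest exon start; minus strand: highest exon end), reported
#' 0-based. The exon-union length is the total width of the merged exon set
#' and must be positive.
#'
#' @return A \code{\link[=GeneModels-class]{GeneModels}} object.
#' @examples
#' ex <- GRangesList(g1 = GRanges("chr1", IRanges(c(11, 51), c(20, 70)), "+"))
#' gm <- GeneModels(ex)
#' exonLength(gm)  # 30
#' @export
GeneModels <- function(exons, chromClass = NULL) {
    stopifnot(is(exons, "GRangesList"), !is.null(names(exons)),
              !anyDuplicated(names(exons)))
    if (any(lengths(exons) == 0L))
        stop("gene with empty exon list: ",
             paste(names(exons)[lengths(exons) == 0L], collapse = ", "))
    chrom <- vapply(seq_along(exons), function(i)
        as.character(seqnames(exons[[i]])[1L]), character(1))
    str <- vapply(seq_along(exons), function(i)
        as.character(strand(exons[[i]])[1L]), character(1))
    str[!str %in% c("+", "-")] <- "+"
    red <- reduce(exons)
    exonLength <- sum(width(red))
    first <- min(start(red)); last <- max(end(red))
    tss <- ifelse(str == "+", first - 1L, last - 1L)   # 0-based 5'-most base
    if (is.null(chromClass)) {
        short <- sub("^chr", "", chrom)
        chromClass <- ifelse(short == "X", "X", ifelse(short == "Y", "Y", "autosome"))
    }
    info <- DataFrame(gene_id = names(exons), chrom = chrom, strand = str,
                      tss = as.integer(tss), chromClass = chromClass,
                      exonLength = as.integer(exonLength),
                      row.names = names(exons))
    new("GeneModels", exons = exons, info = info)
}

#' @describeIn GeneModels Number of genes.
#' @param x A \code{GeneModels}.
#' @export
setMethod("length", "GeneModels", function(x) length(x@exons))

setMethod("names", "GeneModels", function(x) names(x@exons))

setMethod("show", "GeneModels", function(object) {
    cls <- table(object@info$chromClass)
    cat("GeneModels with", length(object), "genes (",
        paste(names(cls), as.integer(cls), collapse = ", "), ")\n")
})

setMethod("[", "GeneModels", function(x, i, j, ..., drop = FALSE) {
    new("GeneModels", exons = x@exons[i], info = x@info[i, , drop = FALSE])
})

#' Gene model accessors
#'
#' @param x A \code{GeneModels} object.
#' @return \code{geneExons}: the \code{GRangesList} of exons; \code{geneInfo}:
#'   the per-gene annotation \code{DataFrame}; \code{exonLength}: named
#'   integer vector of merged exon-union lengths (bp); \code{geneTss}: named
#'   integer vector of 0-based TSS positions; \code{chromClass}: named
#'   character vector.
#' @name geneAccessors
NULL

#' @rdname geneAccessors
#' @export
geneExons <- function(x) x@exons

#' @rdname geneAccessors
#' @export
geneInfo <- function(x) x@info

#' @rdname geneAccessors
#' @export
exonLength <- function(x) setNames(x@info$exonLength, x@info$gene_id)

#' @rdname geneAccessors
#' @export
geneTss <- function(x) setNames(x@info$tss, x@info$gene_id)

#' @rdname geneAccessors
#' @export
chromClass <- function(x) setNames(x@info$chromClass, x@info$gene_id)

#' Read and write gene models as TSV
#'
#' The TSV has one row per gene with columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{exon_starts} (comma-separated, 0-based) and
#' \code{exon_ends} (comma-separated, exclusive) -- the BED12-style block
#' convention, 0-based half-open.
#'
#' @param path File path.
#' @return \code{readGeneModels} returns a \code{GeneModels};
#'   \code{writeGeneModels} writes one invisibly returning \code{path}.
#' @export
readGeneModels <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "exon_starts", "exon_ends")
    if (!all(need %in% colnames(df)))
        stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    ex <- lapply(seq_len(nrow(df)), function(i) {
        s <- as.integer(strsplit(df$exon_starts[i], ",")[[1]])
        e <- as.integer(strsplit(df$exon_ends[i], ",")[[1]])
        GRanges(df$chrom[i], IRanges(s + 1L, e), strand = df$strand[i])
    })
    names(ex) <- df$gene_id
    GeneModels(GRangesList(ex))
}

#' @rdname readGeneModels
#' @param x A \code{GeneModels} object.
#' @export
writeGeneModels <- function(x, path) {
    stopifnot(is(x, "GeneModels"))
    rows <- lapply(seq_along(x@exons), function(i) {
        g <- x@exons[[i]]
        data.frame(gene_id = names(x@exons)[i],
                   chrom = as.character(seqnames(g)[1L]),
                   strand = as.character(strand(g)[1L]),
                   exon_starts = paste(start(g) - 1L, collapse = ","),
                   exon_ends = paste(end(g), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
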