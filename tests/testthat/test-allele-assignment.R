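# chr1 of the toy genome is (ACGT)x25; SNPs below sit on known bases
toySnps <- function() {
    # 0-based pos 4 = 'A' (ref A -> alt G), pos 8 = 'A' (ref A -> alt T)
    SnpIndex(c("chr1", "chr1"), c(4L, 8L), c("A", "A"), c("G", "T"),
             seqlengths = c(chr1 = 100L, chr2 = 100L))
}

test_that("alignment filtering enforces MAPQ and uniqueness", {
    recs <- c(samRec("r1", 0, "chr1", 1, 30, "10M", paste(rep("A", 10), collapse = "")),
              samRec("r2", 0, "chr1", 1, 29, "10M", paste(rep("A", 10), collapse = "")),
              samRec("r3", 0, "chr1", 1, 40, "10M", paste(rep("A", 10), collapse = ""), nh = 2),
              samRec("r4", 256, "chr1", 1, 40, "10M", paste(rep("A", 10), collapse = "")))
    aln <- readSamAlignments(writeToySam(recs))
    kept <- filterAlignments(aln, 30)
    expect_equal(mcols(kept)$qname, "r1")
    expect_equal(length(filterAlignments(aln, 0)), 2L)  # multimappers and secondaries always drop
})

test_that("read classification votes over covered SNP bases", {
    # reads over pos0 4 (1-based 5): base at query offset depends on start
    mk <- function(qname, pos, seq, cigar = paste0(nchar(seq), "M"))
        samRec(qname, 0, "chr1", pos, 60, cigar, seq)
    recs <- c(
        mk("refRead", 3, "GTATG"),       # covers 5 with 'A' = ref -> allele0
        mk("altRead", 3, "GTGTG"),       # covers 5 with 'G' = alt -> allele1
        mk("noSnp", 21, "ACGT"),         # covers no SNP -> uncertain
        mk("errRead", 3, "GTCTG"),       # 'C' matches neither -> uncertain
        mk("mixRead", 3, "GTATGCTTC"),   # ref5 'A' (ref) + ref9 'T' (alt) -> conflict
        mk("bothAlt", 3, "GTGTGCTTC"),   # ref5 'G' (alt) + ref9 'T' (alt) -> allele1
        samRec("spliced", 0, "chr1", 3, 60, "2M4N3M", "GTGTC"))
    # spliced: blocks are ref 3-4 and 9-11; query covers SNP at ref 9 ('G'?):
    aln <- filterAlignments(readSamAlignments(writeToySam(recs)))
    calls <- setNames(classifyReads(aln, toySnps()), mcols(aln)$qname)
    expect_equal(unname(calls["refRead"]), "allele0")
    expect_equal(unname(calls["altRead"]), "allele1")
    expect_equal(unname(calls["noSnp"]), "uncertain")
    expect_equal(unname(calls["errRead"]), "uncertain")
    expect_equal(unname(calls["mixRead"]), "conflict")
    expect_equal(unname(calls["bothAlt"]), "allele1")
})

test_that("SNPs inside skipped introns do not vote", {
    # block 1 covers ref 1-4 (misses SNP at 5); N-gap spans ref 5-8 covering
    # both SNPs; block 2 covers ref 9-10 -> only SNP at ref pos 9 (0-based 8) votes
    rec <- samRec("spl", 0, "chr1", 1, 60, "4M4N2M", "ACGTTC")
    aln <- filterAlignments(readSamAlignments(writeToySam(rec)))
    expect_equal(classifyReads(aln, toySnps()), "allele1")  # base 'T' at ref 9 = alt
    # same read with a ref base at ref 9
    rec2 <- samRec("spl2", 0, "chr1", 1, 60, "4M4N2M", "ACGTAC")
    aln2 <- filterAlignments(readSamAlignments(writeToySam(rec2)))
    expect_equal(classifyReads(aln2, toySnps()), "allele0")
})

test_that("swapping ref and alt alleles swaps the calls exactly", {
    cfg <- SimConfig(seed = 5, nGenes = 24, chromLength = 50000L)
    ref <- simulateReference(cfg)
    gm <- simulateGenes(cfg, ref)
    sam <- tempfile(fileext = ".sam")
    simulateAlignments(cfg, ref$genome, ref$snps, gm, nFragments = 400,
                       samPath = sam, errorRate = 0.01)
    aln <- filterAlignments(readSamAlignments(sam))
    gr <- snpRanges(ref$snps)
    swapped <- SnpIndex(as.character(seqnames(gr)), start(gr) - 1L,
                        mcols(gr)$alt, mcols(gr)$ref)
    a <- classifyReads(aln, ref$snps)
    b <- classifyReads(aln, swapped)
    expect_equal(b[a == "allele0"], rep("allele1", sum(a == "allele0")))
    expect_equal(b[a == "allele1"], rep("allele0", sum(a == "allele1")))
    expect_equal(b[a %in% c("uncertain", "conflict")],
                 a[a %in% c("uncertain", "conflict")])
})

test_that("fragment assignment follows the paired-end rule exhaustively", {
    states <- c("allele0", "allele1", "uncertain", "conflict")
    grid <- expand.grid(a = states, b = states, stringsAsFactors = FALSE)
    got <- assignFragment(grid$a, grid$b)
    expected <- function(a, b) {
        if (a == "conflict" || b == "conflict") return("discard")
        if (a == "uncertain") return(b)
        if (b == "uncertain" || a == b) return(a)
        "discard"
    }
    expect_equal(got, mapply(expected, grid$a, grid$b, USE.NAMES = FALSE))
    # single-end
    expect_equal(assignFragment(states), c("allele0", "allele1", "uncertain", "discard"))
})

test_that("duplicate removal keys on outer coordinates and strand", {
    set.seed(3)
    n <- 90
    start <- sample(1:1000, n, replace = TRUE)
    fr <- toyFragments(rep("chr1", n), start, start + 99L,
                       sample(c("allele0", "allele1", "uncertain"), n, TRUE))
    # plant 10 duplicates of the first 10 fragments
    frdup <- toyFragments(rep("chr1", n + 10),
                          c(start, start[1:10]), c(start, start[1:10]) + 99L,
                          c(fragCalls(fr), fragCalls(fr)[1:10]))
    dd <- dedupFragments(frdup)
    expect_equal(length(dd), length(dedupFragments(fr)))
    # same start, different end -> both kept
    f2 <- toyFragments(c("chr1", "chr1"), c(5L, 5L), c(50L, 60L),
                       c("allele0", "allele0"))
    expect_equal(length(dedupFragments(f2)), 2L)
    # same coordinates, opposite strand -> both kept
    f3 <- toyFragments(c("chr1", "chr1"), c(5L, 5L), c(50L, 50L),
                       c("allele0", "allele0"), strand = c("+", "-"))
    expect_equal(length(dedupFragments(f3)), 2L)
})

test_that("gene counting uses exonic block overlap and drops ambiguity", {
    gm <- toyGenes()
    fr <- toyFragments(
        rep("chr1", 4),
        c(12L, 32L, 15L, 65L),
        c(25L, 38L, 45L, 75L),
        c("allele1", "allele0", "allele0", "uncertain"))
    # frag1 in g1 exon1 (allele1); frag2 intronic (32-38); frag3 spans intron but
    # overlaps g1 exons; frag4 overlaps g2 exon (65-75 vs 71-90)
    ac <- countGeneAlleles(fr, gm, "s")
    expect_equal(as.vector(assay(ac, "n1")[, 1]), c(1L, 0L, 0L))
    expect_equal(as.vector(assay(ac, "n0")[, 1]), c(1L, 0L, 0L))
    expect_equal(as.vector(assay(ac, "uncertain")[, 1]), c(0L, 1L, 0L))
    # a fragment overlapping exons of two genes counts for neither
    fr2 <- toyFragments("chr1", 55L, 75L, "allele0")
    ac2 <- countGeneAlleles(fr2, gm, "s")
    expect_true(all(assay(ac2, "total") == 0L))
    # discarded fragments never count
    fr3 <- toyFragments("chr1", 12L, 20L, "discard")
    expect_true(all(assay(countGeneAlleles(fr3, gm, "s"), "total") == 0L))
})

test_that("gene counts equal a brute-force tally on planted fragments", {
    set.seed(9)
    gm <- toyGenes()
    n <- 50
    start <- sample(1:90, n, replace = TRUE)
    end <- pmin(start + sample(5:30, n, replace = TRUE), 100L)
    call <- sample(c("allele0", "allele1", "uncertain", "discard"), n, TRUE)
    chrom <- sample(c("chr1", "chrX"), n, TRUE)
    fr <- toyFragments(chrom, start, end, call)
    ac <- countGeneAlleles(fr, gm, "s")
    # oracle: interval intersection against each gene's merged exons
    exons <- list(g1 = rbind(c(11, 30), c(41, 60)), g2 = rbind(c(71, 90)),
                  gx = rbind(c(11, 60)))
    chromOf <- c(g1 = "chr1", g2 = "chr1", gx = "chrX")
    for (g in names(exons)) {
        inGene <- vapply(seq_len(n), function(i) {
            chrom[i] == chromOf[g] &&
                any(start[i] <= exons[[g]][, 2] & end[i] >= exons[[g]][, 1])
        }, logical(1))
        # drop fragments also touching another gene's exons
        other <- setdiff(names(exons), g)
        amb <- vapply(seq_len(n), function(i) {
            any(vapply(other, function(o) {
                chrom[i] == chromOf[o] &&
                    any(start[i] <= exons[[o]][, 2] & end[i] >= exons[[o]][, 1])
            }, logical(1)))
        }, logical(1))
        use <- inGene & !amb & call != "discard"
        expect_equal(assay(ac, "n0")[g, 1], sum(use & call == "allele0"))
        expect_equal(assay(ac, "n1")[g, 1], sum(use & call == "allele1"))
        expect_equal(assay(ac, "uncertain")[g, 1], sum(use & call == "uncertain"))
    }
})

test_that("mapping bias is the autosomal allele-count ratio", {
    n0 <- matrix(c(60L, 50L, 40L), dimnames = list(c("g1", "g2", "gx"), "s"))
    n1 <- matrix(c(55L, 45L, 10L), dimnames = list(c("g1", "g2", "gx"), "s"))
    ac <- AlleleCounts(n0, n1, geneModels = toyGenes())
    mb <- mappingBias(ac)
    expect_equal(mb$N_A0, 110); expect_equal(mb$N_A1, 100)
    expect_equal(mb$r_m, 1.1)
    # equal totals give exactly 1
    ac2 <- AlleleCounts(n1, n1, geneModels = toyGenes())
    expect_equal(mappingBias(ac2)$r_m, 1)
    # X-only counts: bias undefined
    acx <- AlleleCounts(n0 * c(0L, 0L, 1L), n1 * c(0L, 0L, 1L),
                        geneModels = toyGenes())
    expect_error(mappingBias(acx), "undefined")
})

test_that("planted mapping bias is recovered from simulated counts", {
    # balanced genes only (no imprinting), enough genes that no single gene
    # dominates the autosomal totals
    cfg <- SimConfig(seed = 21, nGenes = 400, chromLength = 900000L,
                     depth = 3e5, rTrue = 1.3, imprintedFraction = 0)
    ref <- simulateReference(cfg)
    gm <- simulateGenes(cfg, ref)
    sim <- simulateCounts(cfg, gm)
    rm_ <- mappingBias(sim$ac)$r_m
    expect_lt(mean(abs(rm_ - 1.3) / 1.3), 0.05)
    expect_true(all(abs(rm_ - 1.3) / 1.3 < 0.1))
})

test_that("assignment metrics report call fractions", {
    fr <- toyFragments(rep("chr1", 10), 1:10, 11:20,
                       c("allele0", "allele1", rep("uncertain", 8)))
    m <- mappingMetrics(fr)
    expect_equal(m$frac_allele0, 0.1)
    expect_equal(m$frac_allele1, 0.1)
    expect_equal(m$frac_uncertain, 0.8)
    empty <- toyFragments(character(0), integer(0), integer(0), character(0))
    m0 <- mappingMetrics(empty)
    expect_equal(m0$n_fragments, 0)
    expect_equal(m0$frac_allele0, 0)
})
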