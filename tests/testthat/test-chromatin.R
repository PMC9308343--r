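test_that("promoter windows are symmetric, clipped and strand-free", {
    gm <- GeneModels(GRangesList(
        gplus = GRanges("chr1", IRanges(5001, 5400), strand = "+"),
        gminus = GRanges("chr1", IRanges(4601, 5000), strand = "-"),
        gedge = GRanges("chr1", IRanges(1001, 1400), strand = "+")))
    pr <- makePromoters(gm, flank = 2000, seqlengths = c(chr1 = 10000L))
    # tss 5000 (0-based) -> [3000, 7000) -> 1-based [3001, 7000]
    expect_equal(start(pr["gplus"]), 3001); expect_equal(end(pr["gplus"]), 7000)
    # minus-strand gene with tss at 0-based 4999 -> [2999, 6999)
    expect_equal(start(pr["gminus"]), 3000); expect_equal(end(pr["gminus"]), 6999)
    # clipped at the chromosome start: tss 1000 -> [0, 3000)
    expect_equal(start(pr["gedge"]), 1); expect_equal(end(pr["gedge"]), 3000)
    bad <- GeneModels(GRangesList(g = GRanges("chr1", IRanges(20001, 20010))))
    expect_error(makePromoters(bad, seqlengths = c(chr1 = 10000L)), "outside")
})

test_that("region coverage counts fragment overlaps per allele", {
    regions <- GRanges(c("chr1", "chr1"), IRanges(c(100, 250), c(300, 450)))
    names(regions) <- c("p1", "p2")
    fr <- data.frame(chrom = "chr1",
                     start = c(150, 260, 280, 500, 290),
                     end = c(200, 270, 320, 550, 460),
                     allele = c("maternal", "paternal", "maternal",
                                "maternal", "uncertain"))
    cov <- regionCoverage(fr, regions, sample = "s")
    get <- function(r, a) cov$raw_count[cov$region == r & cov$allele == a]
    expect_equal(get("p1", "maternal"), 2L)   # 150-200 and 280-320
    expect_equal(get("p1", "paternal"), 1L)
    expect_equal(get("p2", "maternal"), 1L)   # 280-320 spans both regions
    expect_equal(get("p2", "uncertain"), 1L)
    # additivity: diploid equals the sum of the three classes
    for (r in c("p1", "p2"))
        expect_equal(get(r, "diploid"),
                     get(r, "maternal") + get(r, "paternal") + get(r, "uncertain"))
    # depth scaling: per million assigned fragments
    expect_equal(cov$depth_scaled, cov$raw_count * 1e6 / 5)
    # brute-force overlap oracle on random data
    set.seed(12)
    st <- sample(1:1000, 200, TRUE)
    fr2 <- data.frame(chrom = "chr1", start = st, end = st + sample(20:80, 200, TRUE),
                      allele = sample(c("maternal", "paternal", "uncertain"), 200, TRUE))
    reg2 <- GRanges("chr1", IRanges(sample(1:900, 20), width = 150))
    names(reg2) <- paste0("r", 1:20)
    cov2 <- regionCoverage(fr2, reg2, sample = "s")
    for (i in sample(1:20, 8)) {
        for (a in c("maternal", "paternal")) {
            want <- sum(fr2$allele == a & fr2$start <= end(reg2)[i] &
                            fr2$end >= start(reg2)[i])
            expect_equal(cov2$raw_count[cov2$region == names(reg2)[i] &
                                            cov2$allele == a], want)
        }
    }
})

test_that("input normalization is a pseudocounted ratio", {
    chip <- data.frame(region = c("r1", "r2", "r3"), allele = "maternal",
                       depth_scaled = c(10, 0, 20))
    inp <- data.frame(region = c("r1", "r2", "r3"), allele = "maternal",
                      depth_scaled = c(10, 0, 10))
    out <- inputNormalize(chip, inp)
    expect_equal(out$input_normalized, c(1, 1, 21 / 11))
    expect_error(inputNormalize(chip, inp[1:2, ]), "missing input")
})

test_that("coverage QN equalizes allele and line distributions", {
    set.seed(14)
    rec <- expand.grid(region = paste0("r", 1:50),
                       sample = c("wt", "ko"), allele = c("maternal", "paternal"),
                       stringsAsFactors = FALSE)
    rec$depth_scaled <- rlnorm(nrow(rec), log(100), 0.5) *
        ifelse(rec$allele == "maternal", 2, 1)     # planted allele imbalance
    out <- qnAcross(rec)
    sp <- split(out$qn_value, paste(out$sample, out$allele))
    for (k in 2:length(sp)) expect_equal(sort(sp[[k]]), sort(sp[[1]]))
    # ranks preserved within each group
    g1 <- out[out$sample == "wt" & out$allele == "maternal", ]
    expect_equal(rank(g1$qn_value), rank(g1$depth_scaled))
    # mismatched region sets error
    expect_error(qnAcross(rec[-1, ]), "mismatched")
})

test_that("the group shift test detects planted ratio shifts", {
    set.seed(16)
    x <- rnorm(50, 1, 0.2)
    res <- groupShiftTest(x)
    expect_lt(res$p_value, 0.001)
    expect_gt(res$median, 0.8)
    # sign-flip symmetry
    resNeg <- groupShiftTest(-x)
    expect_equal(resNeg$median, -res$median)
    expect_equal(resNeg$p_value, res$p_value)
    # degenerate input flagged, not crashed
    resDeg <- groupShiftTest(rep(0, 10))
    expect_true(resDeg$degenerate)
    expect_true(is.na(resDeg$p_value))
    expect_error(groupShiftTest(c(0.1, 0.2)), "at least 5")
    # t-test variant agrees on direction
    expect_lt(groupShiftTest(x, test = "t")$p_value, 0.001)
})

test_that("simulated KO chromatin shifts appear only on affected alleles", {
    cfg <- SimConfig(seed = 43, nGenes = 300, chromLength = 800000L)
    ref <- simulateReference(cfg); gm <- simulateGenes(cfg, ref)
    sim <- simulateCounts(cfg, gm)
    chr <- simulateChromatin(cfg, gm, sim$truth)
    # input-normalize each sample, average lines, take log2 KO/wt per allele
    norm <- inputNormalize(chr$chip, chr$input)
    shift <- function(allele, genes) {
        d <- norm[norm$allele == allele & norm$region %in% genes, ]
        wt <- tapply(d$input_normalized[d$genotype == "wt"],
                     d$region[d$genotype == "wt"], mean)
        ko <- tapply(d$input_normalized[d$genotype == "KO"],
                     d$region[d$genotype == "KO"], mean)
        log2(ko[names(wt)] / wt)
    }
    gA <- sim$truth$gene[sim$truth$group == "A"]
    gE <- sim$truth$gene[sim$truth$group == "E"]
    resA <- groupShiftTest(shift("maternal", gA))
    resApat <- groupShiftTest(shift("paternal", gA))
    resE <- groupShiftTest(shift("maternal", gE))
    expect_lt(resA$p_value, 0.01)
    expect_gt(resA$median, 0.5)
    expect_gt(resApat$p_value, 0.01)   # paternal allele untouched for group A
    expect_gt(resE$p_value, 0.01)      # group E has no planted chip effect
})
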