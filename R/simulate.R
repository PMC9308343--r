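#' Construct a synthetic-study configuration
#'
#' Defaults emulate the hybrid ES-cell study design at desk scale: reciprocal
#' BC/CB crosses with two wt and three KO male clones plus two wt female
#' clones each; 75 bp reads at one million exonic fragments per sample;
#' roughly a fifth of exonic fragments SNP-informative with a mild reference
#' mapping bias (r = 1.2, matching the observed ~11% vs ~9% allelic read
#' split); negative-binomial noise typical of clonal ES lines (dispersion
#' 0.05); 4-fold knockout effects planted on single alleles or both (groups
#' A-F, 3% of genes each); female-biased genes outnumbering male-biased ones
#' 2.4-fold with a 3-fold expression gap and a 32% chance of losing the bias
#' after KO; and 1% imprinted genes at 95% maternal expression.
#'
#' @param seed Integer seed; fully determines all simulated output.
#' @param nChromosomes Number of autosomes (an X is always added).
#' @param chromLength Chromosome length in bp.
#' @param nGenes Genes to place across all chromosomes.
#' @param exonsPerGene Exons per gene.
#' @param snpDensity Per-bp probability of a strain SNP.
#' @param informativeFraction Target fraction of exonic fragments that carry
#'   SNP information.
#' @param readLength,fragmentMean,fragmentSd Read/fragment geometry (bp).
#' @param depth Expected exonic fragments per sample.
#' @param rTrue Planted allele0 (BL6) mapping-bias ratio.
#' @param nbDispersion NB dispersion (variance = mu + alpha mu^2).
#' @param groupFractions Named fractions of genes per KO response group A-F.
#' @param groupEffect Fold change applied to the affected allele(s) in KO.
#' @param sexBiasFractions Named fractions (female, male) of sex-biased genes.
#' @param sexBiasFold Expression fold between sexes for biased genes.
#' @param lossProbability Probability a sex-biased gene loses its bias in KO.
#' @param imprintedFraction,imprintedF Fraction of imprinted genes and their
#'   maternal expression fraction.
#' @param nWt,nKo,nFemale Replicates per cross: male wt, male KO, female wt.
#' @return A validated \code{\link[=SimConfig-class]{SimConfig}}.
#' @export
SimConfig <- function(seed = 1L, nChromosomes = 2L, chromLength = 1000000L,
                      nGenes = 400L, exonsPerGene = 4L, snpDensity = 0.007,
                      informativeFraction = 0.2, readLength = 75L,
                      fragmentMean = 250, fragmentSd = 30, depth = 1e6,
                      rTrue = 1.2, nbDispersion = 0.05,
                      groupFractions = c(A = 0.03, B = 0.03, C = 0.03,
                                         D = 0.03, E = 0.03, F = 0.03),
                      groupEffect = 4, sexBiasFractions = c(female = 0.08,
                                                           male = 0.034),
                      sexBiasFold = 3, lossProbability = 0.32,
                      imprintedFraction = 0.01, imprintedF = 0.95,
                      nWt = 2L, nKo = 3L, nFemale = 2L) {
    new("SimConfig", seed = as.integer(seed),
        nChromosomes = as.integer(nChromosomes),
        chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene), snpDensity = snpDensity,
        informativeFraction = informativeFraction,
        readLength = as.integer(readLength), fragmentMean = fragmentMean,
        fragmentSd = fragmentSd, depth = depth, rTrue = rTrue,
        nbDispersion = nbDispersion, groupFractions = groupFractions,
        groupEffect = groupEffect, sexBiasFractions = sexBiasFractions,
        sexBiasFold = sexBiasFold, lossProbability = lossProbability,
        imprintedFraction = imprintedFraction, imprintedF = imprintedF,
        nWt = as.integer(nWt), nKo = as.integer(nKo),
        nFemale = as.integer(nFemale))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|", object@nGenes, "genes on",
        object@nChromosomes, "autosome(s) + chrX |", object@depth,
        "fragments/sample | r_true", object@rTrue, "\n")
})

simChromNames <- function(cfg) c(paste0("chr", seq_len(cfg@nChromosomes)), "chrX")

#' Simulate the reference genome and strain SNPs
#'
#' Random uniform-base chromosomes (the configured autosomes plus chrX) and
#' Bernoulli-placed biallelic SNPs with the alternate base drawn from the
#' three non-reference bases.
#'
#' @param cfg A \code{\link{SimConfig}}.
#' @return A list: \code{genome} (\code{BStringSet}) and \code{snps}
#'   (\code{\link[=SnpIndex-class]{SnpIndex}} with seqlengths set).
#' @export
simulateReference <- function(cfg) {
    set.seed(cfg@seed)
    chroms <- simChromNames(cfg)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(chroms, function(ch)
        paste(sample(bases, cfg@chromLength, replace = TRUE), collapse = ""),
        character(1))
    genome <- BStringSet(seqs)
    chrom <- character(0); pos <- integer(0); ref <- character(0); alt <- character(0)
    for (ch in chroms) {
        p <- which(runif(cfg@chromLength) < cfg@snpDensity)
        if (!length(p)) next
        r <- substring(seqs[[ch]], p, p)
        a <- vapply(r, function(b) sample(setdiff(bases, b), 1L), character(1))
        chrom <- c(chrom, rep(ch, length(p)))
        pos <- c(pos, p - 1L); ref <- c(ref, r); alt <- c(alt, unname(a))
    }
    sl <- setNames(rep(cfg@chromLength, length(chroms)), chroms)
    list(genome = genome,
         snps = SnpIndex(chrom, pos, ref, alt, seqlengths = sl))
}

#' Simulate gene models
#'
#' Places non-overlapping multi-exon genes along every chromosome (including
#' chrX), alternating strands, with exon and intron sizes drawn uniformly
#' (120-300 bp exons, 100-400 bp introns) so each exon union comfortably
#' exceeds the read length.
#'
#' @param cfg A \code{\link{SimConfig}}.
#' @param reference Output of \code{\link{simulateReference}} (for
#'   chromosome names/lengths).
#' @return A \code{\link[=GeneModels-class]{GeneModels}}.
#' @export
simulateGenes <- function(cfg, reference) {
    set.seed(cfg@seed + 1L)
    chroms <- simChromNames(cfg)
    perChrom <- rep(floor(cfg@nGenes / length(chroms)), length(chroms))
    perChrom[1] <- perChrom[1] + cfg@nGenes - sum(perChrom)
    ex <- list(); gid <- 0L
    for (ci in seq_along(chroms)) {
        cursor <- 1L + sample(50:500, 1L)
        for (g in seq_len(perChrom[ci])) {
            starts <- integer(cfg@exonsPerGene); ends <- integer(cfg@exonsPerGene)
            p <- cursor
            for (e in seq_len(cfg@exonsPerGene)) {
                len <- sample(120:300, 1L)
                starts[e] <- p; ends[e] <- p + len - 1L
                p <- ends[e] + sample(100:400, 1L)
            }
            if (max(ends) > cfg@chromLength)
                stop("cannot place ", cfg@nGenes, " genes: chromosome too short")
            gid <- gid + 1L
            ex[[sprintf("g%04d", gid)]] <-
                GRanges(chroms[ci], IRanges(starts, ends),
                        strand = if (gid %% 2L) "+" else "-")
            cursor <- max(ends) + sample(200:800, 1L)
        }
    }
    GeneModels(GRangesList(ex))
}

# Build the sample sheet the default study design implies.
simSampleSheet <- function(cfg) {
    one <- function(cross) {
        data.frame(
            sample_id = c(sprintf("%s_F_wt_%d", cross, seq_len(cfg@nFemale)),
                          sprintf("%s_M_wt_%d", cross, seq_len(cfg@nWt)),
                          sprintf("%s_M_ko_%d", cross, seq_len(cfg@nKo))),
            cross = cross,
            sex = c(rep("F", cfg@nFemale), rep("M", cfg@nWt + cfg@nKo)),
            genotype = c(rep("wt", cfg@nFemale + cfg@nWt), rep("KO", cfg@nKo)),
            stringsAsFactors = FALSE)
    }
    rbind(one("BC"), one("CB"))
}

# Assign per-gene ground truth: maternal fraction, KO group, sex bias, loss.
simGeneTruth <- function(cfg, models) {
    ng <- length(models)
    cls <- chromClass(models)
    base <- rlnorm(ng, meanlog = 0, sdlog = 1)
    base <- base / sum(base)                      # relative expression
    f <- rep(0.5, ng)
    imprintable <- which(cls == "autosome")
    nImp <- round(cfg@imprintedFraction * ng)
    imp <- if (nImp > 0) sample(imprintable, min(nImp, length(imprintable))) else integer(0)
    f[imp] <- cfg@imprintedF
    group <- rep("none", ng)
    pool <- setdiff(which(cls == "autosome"), imp)
    pool <- sample(pool)
    k <- 0L
    for (g in names(cfg@groupFractions)) {
        n <- round(cfg@groupFractions[[g]] * ng)
        if (n > 0 && k + n <= length(pool)) {
            group[pool[(k + 1L):(k + n)]] <- g
            k <- k + n
        }
    }
    sexBias <- rep("none", ng)
    # sex-biased genes are drawn disjoint from the KO groups so each planted
    # effect can be recovered against a clean background
    pool2 <- sample(setdiff(which(cls == "autosome" & group == "none"), imp))
    nf <- round(cfg@sexBiasFractions[["female"]] * ng)
    nm <- round(cfg@sexBiasFractions[["male"]] * ng)
    if (nf + nm <= length(pool2)) {
        sexBias[pool2[seq_len(nf)]] <- "female"
        sexBias[pool2[nf + seq_len(nm)]] <- "male"
    }
    loss <- sexBias != "none" & runif(ng) < cfg@lossProbability
    data.frame(gene = names(models), chromClass = unname(cls),
               relExpr = base, f = f, imprinted = seq_len(ng) %in% imp,
               group = group, sexBias = sexBias, loss = loss,
               stringsAsFactors = FALSE)
}

# Expected maternal/paternal exonic fragment means for one sample.
simAllelicMeans <- function(cfg, truth, sex, genotype) {
    mu <- truth$relExpr * cfg@depth
    fb <- truth$sexBias == "female"; mb <- truth$sexBias == "male"
    if (sex == "F") mu[fb] <- mu[fb] * cfg@sexBiasFold
    if (sex == "M") mu[mb] <- mu[mb] * cfg@sexBiasFold
    f <- truth$f
    if (sex == "M") f[truth$chromClass == "X"] <- 1   # single, maternal X
    eMat <- rep(1, nrow(truth)); ePat <- rep(1, nrow(truth))
    if (genotype == "KO") {
        gr <- truth$group
        eMat[gr %in% c("A", "C")] <- 1 / cfg@groupEffect
        ePat[gr %in% c("B", "C")] <- 1 / cfg@groupEffect
        eMat[gr %in% c("D", "F")] <- cfg@groupEffect
        ePat[gr %in% c("E", "F")] <- cfg@groupEffect
        lossUp <- truth$loss & fb
        lossDn <- truth$loss & mb
        sc <- rep(1, nrow(truth))
        sc[lossUp] <- cfg@sexBiasFold       # rises to the female level
        sc[lossDn] <- 1 / cfg@sexBiasFold   # falls to the female level
        eMat <- eMat * sc; ePat <- ePat * sc
    }
    list(mat = mu * f * eMat, pat = mu * (1 - f) * ePat)
}

#' Simulate allelic count tables with ground truth
#'
#' Draws, for every sample of the default reciprocal-cross design, a per-gene
#' diploid exonic fragment total from the negative binomial (variance
#' mu + alpha mu^2), splits it binomially between the parental alleles
#' (oriented onto the strain axis by the sample's cross), and binomially
#' thins allele counts to the SNP-informative subset with the planted
#' allele0 mapping bias. KO effects hit the
#' allele(s) their group dictates; sex-biased genes differ between the sexes
#' and may lose the difference in KO; imprinted genes are maternally skewed;
#' the male X is maternal-only.
#'
#' @param cfg A \code{\link{SimConfig}}.
#' @param models Gene models from \code{\link{simulateGenes}}.
#' @return A list: \code{ac} (an
#'   \code{\link[=AlleleCounts-class]{AlleleCounts}} over all samples, with
#'   full allelic counts in metadata), \code{truth} (per-gene truth
#'   data.frame), \code{samples} (sample sheet), and \code{alleleMeans}
#'   (true per-sample maternal/paternal means).
#' @export
simulateCounts <- function(cfg, models) {
    set.seed(cfg@seed + 2L)
    truth <- simGeneTruth(cfg, models)
    samples <- simSampleSheet(cfg)
    ng <- nrow(truth); ns <- nrow(samples)
    size <- 1 / cfg@nbDispersion
    pi1 <- min(1, 2 * cfg@informativeFraction / (1 + cfg@rTrue))
    pi0 <- min(1, cfg@rTrue * pi1)
    n0 <- n1 <- nu <- tot <- a0m <- a1m <-
        matrix(0L, ng, ns, dimnames = list(truth$gene, samples$sample_id))
    matMean <- patMean <- matrix(0, ng, ns,
                                 dimnames = list(truth$gene, samples$sample_id))
    for (s in seq_len(ns)) {
        mm <- simAllelicMeans(cfg, truth, samples$sex[s], samples$genotype[s])
        matMean[, s] <- mm$mat; patMean[, s] <- mm$pat
        if (samples$cross[s] == "BC") { mu0 <- mm$mat; mu1 <- mm$pat }
        else { mu0 <- mm$pat; mu1 <- mm$mat }
        # clone-to-clone overdispersion acts on the diploid total; the
        # allelic split within a library is binomial read sampling
        tt <- rnbinom(ng, mu = mu0 + mu1, size = size)
        w <- ifelse(mu0 + mu1 > 0, mu0 / (mu0 + mu1), 0.5)
        a0 <- rbinom(ng, tt, w)
        a1 <- tt - a0
        i0 <- rbinom(ng, a0, pi0)
        i1 <- rbinom(ng, a1, pi1)
        n0[, s] <- i0; n1[, s] <- i1
        nu[, s] <- (a0 - i0) + (a1 - i1)
        tot[, s] <- a0 + a1
        a0m[, s] <- a0; a1m[, s] <- a1
    }
    ac <- AlleleCounts(n0, n1, uncertain = nu, total = tot,
                       geneModels = models, sampleData = samples)
    metadata(ac)$fullAllele0 <- a0m
    metadata(ac)$fullAllele1 <- a1m
    list(ac = ac, truth = truth, samples = samples,
         alleleMeans = list(mat = matMean, pat = patMean))
}

# transcript-coordinate interval -> genomic blocks over a gene's exons
# (exons in genomic order; returns matrix with cols start, width, 1-based)
txToBlocks <- function(exStarts, exWidths, txStart, len) {
    cum <- cumsum(exWidths)
    off <- c(0L, cum[-length(cum)])
    out <- NULL
    remaining <- len; p <- txStart   # 1-based transcript position
    while (remaining > 0L) {
        e <- which(p <= cum)[1L]
        inEx <- p - off[e]                       # 1-based offset within exon e
        take <- min(remaining, exWidths[e] - inEx + 1L)
        out <- rbind(out, c(exStarts[e] + inEx - 1L, take))
        remaining <- remaining - take
        p <- p + take
    }
    out
}

blocksToCigar <- function(blocks) {
    n <- nrow(blocks)
    parts <- character(0)
    for (i in seq_len(n)) {
        if (i > 1L) {
            gap <- blocks[i, 1] - (blocks[i - 1, 1] + blocks[i - 1, 2])
            if (gap > 0L) parts <- c(parts, paste0(gap, "N"))
        }
        parts <- c(parts, paste0(blocks[i, 2], "M"))
    }
    paste(parts, collapse = "")
}

#' Simulate paired-end alignments as SAM
#'
#' Samples fragments from the exon unions of the simulated genes, drawing
#' each fragment's haplotype (reference BL6 vs pseudo-cast) from the gene's
#' allele0 fraction, and emits a valid SAM file: spliced CIGARs across exon
#' junctions, proper-pair flags, NH tags, per-base sequencing errors,
#' planted coordinate duplicates and a configurable fraction of low-MAPQ
#' records. Sequences come from the generating haplotype, so a read over a
#' SNP carries that strain's base (up to sequencing error).
#'
#' @param cfg A \code{\link{SimConfig}}.
#' @param genome Reference \code{BStringSet} from
#'   \code{\link{simulateReference}}.
#' @param snps The \code{SnpIndex}.
#' @param models Gene models.
#' @param nFragments Number of fragments to simulate.
#' @param p0 Per-gene probability a fragment comes from allele0 (recycled;
#'   default 0.5 everywhere).
#' @param samPath Output SAM path.
#' @param errorRate Per-base substitution error rate (default 0.002).
#' @param dupRate Fraction of fragments re-emitted as coordinate duplicates
#'   (default 0).
#' @param lowMapqRate Fraction of fragments written with MAPQ 10 (default 0).
#' @param seedOffset Added to the config seed (use distinct offsets for
#'   distinct samples).
#' @return Invisibly, a data.frame of per-fragment truth: \code{qname},
#'   \code{gene}, \code{haplotype} (0/1), \code{duplicate}, \code{lowMapq}.
#' @export
simulateAlignments <- function(cfg, genome, snps, models, nFragments,
                               p0 = 0.5, samPath, errorRate = 0.002,
                               dupRate = 0, lowMapqRate = 0,
                               seedOffset = 10L) {
    set.seed(cfg@seed + seedOffset)
    pseudo <- buildPseudoGenome(genome, snps)
    haps <- list(toupper(as.character(genome)), toupper(as.character(pseudo)))
    info <- geneInfo(models)
    exl <- exonLength(models)
    rl <- cfg@readLength
    ok <- exl >= max(rl + 1L, 2L)
    geneIdx <- sample(which(ok), nFragments, replace = TRUE,
                      prob = exl[ok])
    p0 <- rep_len(p0, length(models))
    hap <- rbinom(nFragments, 1L, 1 - p0[geneIdx])   # 0 = BL6, 1 = cast
    red <- reduce(geneExons(models))
    bases <- c("A", "C", "G", "T")
    lines <- character(0)
    truth <- vector("list", nFragments)
    prev <- NULL
    qn <- 0L
    for (i in seq_len(nFragments)) {
        gi <- geneIdx[i]
        ex <- red[[gi]]
        exS <- start(ex); exW <- width(ex)
        chrom <- info$chrom[gi]
        L <- max(rl, min(exl[gi], round(rnorm(1, cfg@fragmentMean, cfg@fragmentSd))))
        t0 <- sample.int(exl[gi] - L + 1L, 1L)
        isDup <- !is.null(prev) && runif(1) < dupRate
        if (isDup) { gi <- prev$gi; chrom <- prev$chrom; L <- prev$L; t0 <- prev$t0
                     ex <- red[[gi]]; exS <- start(ex); exW <- width(ex) }
        prev <- list(gi = gi, chrom = chrom, L = L, t0 = t0)
        h <- hap[i] + 1L
        qn <- qn + 1L
        qname <- sprintf("frag%07d", qn)
        b1 <- txToBlocks(exS, exW, t0, rl)
        b2 <- txToBlocks(exS, exW, t0 + L - rl, rl)
        seqOf <- function(b) {
            s <- paste(substring(haps[[h]][[chrom]], b[, 1], b[, 1] + b[, 2] - 1L),
                       collapse = "")
            err <- which(runif(nchar(s)) < errorRate)
            if (length(err)) {
                ch <- strsplit(s, "")[[1]]
                ch[err] <- vapply(ch[err],
                                  function(x) sample(setdiff(bases, x), 1L), "")
                s <- paste(ch, collapse = "")
            }
            s
        }
        s1 <- seqOf(b1); s2 <- seqOf(b2)
        p1 <- b1[1, 1]; p2 <- b2[1, 1]
        end2 <- b2[nrow(b2), 1] + b2[nrow(b2), 2] - 1L
        tlen <- end2 - p1 + 1L
        mapq <- if (runif(1) < lowMapqRate) 10L else 60L
        lines <- c(lines,
                   paste(qname, 99L, chrom, p1, mapq, blocksToCigar(b1), "=",
                         p2, tlen, s1, "*", "NH:i:1", sep = "\t"),
                   paste(qname, 147L, chrom, p2, mapq, blocksToCigar(b2), "=",
                         p1, -tlen, s2, "*", "NH:i:1", sep = "\t"))
        truth[[i]] <- data.frame(qname = qname, gene = info$gene_id[gi],
                                 haplotype = hap[i], duplicate = isDup,
                                 lowMapq = mapq < 30L, stringsAsFactors = FALSE)
    }
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", names(genome), "\tLN:",
                    Biostrings::width(genome)))
    writeLines(c(hdr, lines), samPath)
    invisible(do.call(rbind, truth))
}

#' Simulate allelic promoter chromatin coverage
#'
#' Counts-level generator for ATAC and H3K27me3 ChIP with matched input:
#' per promoter and allele, NB-distributed fragment counts around a
#' log-normal baseline (input flat). In KO lines, genes in the allelic
#' downregulation groups gain H3K27me3 and lose accessibility on the
#' affected allele(s) (maternal for A, paternal for B, both for C); other
#' groups' promoters are untouched, mirroring the repressive-mark gain that
#' accompanies allele-specific silencing.
#'
#' @param cfg A \code{\link{SimConfig}}.
#' @param models Gene models.
#' @param truth Per-gene truth from \code{\link{simulateCounts}} (only the
#'   \code{group} column is used).
#' @param nWtLines,nKoLines Cell lines per genotype (default 2 each).
#' @param k27Gain H3K27me3 fold gain on the affected allele (default 3).
#' @param atacLoss Accessibility fold loss on the affected allele
#'   (default 2).
#' @param baseMean Mean promoter fragment count per allele (default 100).
#' @return A list of long-format coverage tables (\code{atac}, \code{chip},
#'   \code{input}; columns region/sample/allele/raw_count/depth_scaled plus
#'   \code{genotype}) and \code{truth}.
#' @export
simulateChromatin <- function(cfg, models, truth, nWtLines = 2L,
                              nKoLines = 2L, k27Gain = 3, atacLoss = 2,
                              baseMean = 100) {
    set.seed(cfg@seed + 3L)
    ng <- length(models)
    size <- 1 / cfg@nbDispersion
    baseAtac <- rlnorm(ng, log(baseMean), 0.4)
    baseChip <- rlnorm(ng, log(baseMean), 0.4)
    baseInput <- rep(baseMean, ng)
    samples <- c(sprintf("wt_%d", seq_len(nWtLines)),
                 sprintf("ko_%d", seq_len(nKoLines)))
    genotype <- rep(c("wt", "KO"), c(nWtLines, nKoLines))
    out <- list(atac = NULL, chip = NULL, input = NULL)
    for (s in seq_along(samples)) {
        effMat <- rep(1, ng); effPat <- rep(1, ng)
        if (genotype[s] == "KO") {
            effMat[truth$group %in% c("A", "C")] <- 1
            effPat[truth$group %in% c("B", "C")] <- 1
            # fold applied per assay below
        }
        for (assay in names(out)) {
            base <- switch(assay, atac = baseAtac, chip = baseChip,
                           input = baseInput)
            gM <- rep(1, ng); gP <- rep(1, ng)
            if (genotype[s] == "KO" && assay != "input") {
                fold <- if (assay == "chip") k27Gain else 1 / atacLoss
                gM[truth$group %in% c("A", "C")] <- fold
                gP[truth$group %in% c("B", "C")] <- fold
            }
            cm <- rnbinom(ng, mu = base * gM, size = size)
            cp <- rnbinom(ng, mu = base * gP, size = size)
            cu <- rnbinom(ng, mu = 0.3 * base, size = size)
            tot <- sum(cm) + sum(cp) + sum(cu)
            sc <- 1e6 / tot
            rec <- rbind(
                data.frame(region = truth$gene, sample = samples[s],
                           allele = "maternal", raw_count = cm,
                           depth_scaled = cm * sc),
                data.frame(region = truth$gene, sample = samples[s],
                           allele = "paternal", raw_count = cp,
                           depth_scaled = cp * sc),
                data.frame(region = truth$gene, sample = samples[s],
                           allele = "uncertain", raw_count = cu,
                           depth_scaled = cu * sc))
            rec$genotype <- genotype[s]
            out[[assay]] <- rbind(out[[assay]], rec)
        }
    }
    c(out, list(truth = truth))
}
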