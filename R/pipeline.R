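#' Summarize allelic response groups (the group-count accounting)
#'
#' From per-group DEG counts, reports group totals and the allele-specific
#' percentage: the share of allelic DEGs whose change is confined to a
#' single allele, (A + B) / (A + B + C) for the down set and
#' (D + E) / (D + E + F) for the up set, rounded half-up to an integer. The
#' percentages are always recomputed from the count fields present in the
#' same summary, never carried in.
#'
#' @param counts Named numeric vector with entries A..F (e.g. the
#'   \code{counts} element of \code{\link{classifyGroups}}).
#' @return A list: \code{counts} (A..F plus totals),
#'   \code{pct_allele_specific_down}, \code{pct_allele_specific_up}.
#' @examples
#' summarizeGroupTable(c(A = 109, B = 58, C = 27, D = 68, E = 71, F = 50))
#' @export
summarizeGroupTable <- function(counts) {
    stopifnot(all(c("A", "B", "C", "D", "E", "F") %in% names(counts)))
    dn <- counts[["A"]] + counts[["B"]] + counts[["C"]]
    up <- counts[["D"]] + counts[["E"]] + counts[["F"]]
    list(counts = c(counts[c("A", "B", "C", "D", "E", "F")],
                    total_down = dn, total_up = up),
         n_allele_specific_down = counts[["A"]] + counts[["B"]],
         n_allele_specific_up = counts[["D"]] + counts[["E"]],
         pct_allele_specific_down =
             if (dn > 0) roundHalfUp(100 * (counts[["A"]] + counts[["B"]]) / dn)
             else NA_real_,
         pct_allele_specific_up =
             if (up > 0) roundHalfUp(100 * (counts[["D"]] + counts[["E"]]) / up)
             else NA_real_)
}

#' Run the full hybrid analysis pipeline
#'
#' Orchestrates the stages on in-memory simulated inputs or on files:
#' allele counting per sample (from SAMs) or a ready
#' \code{\link[=AlleleCounts-class]{AlleleCounts}}, mapping bias, allelic
#' expression, diploid and allelic differential expression with group
#' classification per cross, and sex-bias accounting when female samples are
#' present. Writes stage TSVs and a JSON manifest into \code{outDir}.
#'
#' @param ac An \code{\link[=AlleleCounts-class]{AlleleCounts}} covering all
#'   samples, with \code{cross}/\code{sex}/\code{genotype} column data and
#'   gene annotation row data.
#' @param outDir Output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param alpha,fcMin,minTpm,sexFold Thresholds: FDR cutoff, DEG fold
#'   change, allelic TPM floor, sex-bias fold (defaults 0.05, 1.5, 1, 2).
#' @param exclude Gene ids excluded from DEG calling.
#' @return A list with elements \code{bias}, \code{expression}
#'   (\code{AllelicExpression}), per-cross \code{allelic} DEG results with
#'   \code{groups} and their summaries, \code{sexBias} records and summary
#'   per cross (when computable), and the output \code{manifest}.
#' @export
runPipeline <- function(ac, outDir = NULL, alpha = 0.05, fcMin = 1.5,
                        minTpm = 1, sexFold = 2, exclude = NULL) {
    stopifnot(is(ac, "AlleleCounts"))
    cd <- as.data.frame(colData(ac))
    need <- c("cross", "sex", "genotype")
    if (!all(need %in% colnames(cd)))
        stop("stage sample-sheet: colData needs ", paste(need, collapse = ", "))
    bias <- mappingBias(ac)
    ae <- allelicExpression(ac)
    res <- list(bias = bias, expression = ae, allelic = list(), sexBias = list())
    for (cr in unique(cd$cross)) {
        male <- cd$cross == cr & cd$sex == "M"
        wt <- male & cd$genotype == "wt"; ko <- male & cd$genotype == "KO"
        if (sum(wt) >= 2 && sum(ko) >= 2) {
            sel <- wt | ko
            group <- factor(ifelse(cd$genotype[sel] == "wt", "wt", "KO"),
                            levels = c("wt", "KO"))
            # allelic DE runs on the SNP-informative fragment counts,
            # oriented by the cross (BC: allele0 = maternal)
            n0 <- assay(ac, "n0")[, sel, drop = FALSE]
            n1 <- assay(ac, "n1")[, sel, drop = FALSE]
            if (cr == "BC") { matC <- n0; patC <- n1 }
            else { matC <- n1; patC <- n0 }
            matT <- assay(ae, "tpmMat")[, sel, drop = FALSE]
            patT <- assay(ae, "tpmPat")[, sel, drop = FALSE]
            masked <- rownames(ac)[rowSums(assay(ae, "masked")[, sel, drop = FALSE]) > 0]
            deg <- allelicDegPipeline(matC, patC, group, matT, patT,
                                      minTpm = minTpm, maskedGenes = masked,
                                      alpha = alpha, fcMin = fcMin,
                                      exclude = exclude)
            grp <- classifyGroups(deg$maternal, deg$paternal)
            res$allelic[[cr]] <- list(deg = deg, groups = grp,
                                      summary = summarizeGroupTable(grp$counts))
        }
        fem <- cd$cross == cr & cd$sex == "F" & cd$genotype == "wt"
        if (sum(fem) >= 2 && sum(wt) >= 2 && sum(ko) >= 2) {
            tpm <- assay(ae, "tpm")
            keep <- tpmFilter(tpm[, fem | wt | ko, drop = FALSE], minTpm)
            tf <- tpm[keep, fem, drop = FALSE]
            tw <- tpm[keep, wt, drop = FALSE]
            tk <- tpm[keep, ko, drop = FALSE]
            rec <- callSexBiased(tf, tw, fold = sexFold)
            rec <- lossAfterKo(rec, tf, tk, fold = sexFold)
            rec <- gainAfterKo(rec, tf, tk, fold = sexFold)
            res$sexBias[[cr]] <- list(records = rec,
                                      summary = sexBiasSummary(rec))
        }
    }
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        files <- character(0)
        wr <- function(df, name) {
            p <- file.path(outDir, name)
            write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
            files <<- c(files, name)
        }
        wr(bias, "mapping_bias.tsv")
        expr <- data.frame(gene = rep(rownames(ae), ncol(ae)),
                           sample = rep(colnames(ae), each = nrow(ae)),
                           tpm = as.vector(assay(ae, "tpm")),
                           p0 = as.vector(assay(ae, "p0")),
                           p0_adj = as.vector(assay(ae, "p0Adj")),
                           tpm_mat = as.vector(assay(ae, "tpmMat")),
                           tpm_pat = as.vector(assay(ae, "tpmPat")),
                           masked = as.vector(assay(ae, "masked")))
        wr(expr, "allelic_expression.tsv")
        for (cr in names(res$allelic)) {
            wr(res$allelic[[cr]]$groups$labels, paste0("groups_", cr, ".tsv"))
            s <- res$allelic[[cr]]$summary
            s$counts <- as.list(s$counts)
            jsonlite::write_json(s, file.path(outDir, paste0("groups_", cr, ".json")),
                                 auto_unbox = TRUE, digits = NA)
            files <- c(files, paste0("groups_", cr, ".json"))
        }
        for (cr in names(res$sexBias)) {
            wr(res$sexBias[[cr]]$records, paste0("sex_bias_", cr, ".tsv"))
        }
        manifest <- list(package = "hybridase",
                         version = as.character(utils::packageVersion("hybridase")),
                         n_genes = nrow(ac), n_samples = ncol(ac),
                         thresholds = list(alpha = alpha, fcMin = fcMin,
                                           minTpm = minTpm, sexFold = sexFold),
                         outputs = files)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE)
        res$manifest <- manifest
    }
    res
}
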