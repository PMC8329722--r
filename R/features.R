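# Per-gene 10D feature construction: top-5 GWAS p-values per gene (ascending,
# padded with 1) plus the eQTL p-values of the same SNPs (1 where unmapped).

#' Map SNPs to genes by genomic coordinates
#'
#' A SNP at 0-based position `pos` is assigned to every gene whose
#' (flank-extended) interval contains it: `start - flank <= pos < end + flank`
#' on the same chromosome. Overlap is computed with GenomicRanges. Genes
#' without SNPs are present in the result with empty tables.
#'
#' @param gwas GWAS `data.frame` (`variant_id`, `chrom`, `pos`, `pvalue`).
#' @param annotation Annotation `data.frame` (0-based half-open intervals);
#'   must be non-empty.
#' @param flank Cis-window extension in bp on each side of the gene body.
#' @return A named list (class `snp_gene_map`), one `data.frame`
#'   (`variant_id`, `pos`, `pvalue`) per gene_id.
#' @export
map_snps_to_genes <- function(gwas, annotation, flank = 0) {
  stopifnot(nrow(annotation) > 0, flank >= 0)
  shared <- intersect(unique(gwas$chrom), unique(annotation$chrom))
  if (nrow(gwas) > 0 && length(shared) == 0) {
    warning(sprintf(
      "no shared chromosomes between GWAS (%s) and annotation (%s)",
      paste(unique(gwas$chrom), collapse = ","),
      paste(unique(annotation$chrom), collapse = ",")))
  }
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = pmax(1, annotation$start - flank + 1),
                     end = annotation$end + flank))
  empty <- data.frame(variant_id = character(), pos = numeric(),
                      pvalue = numeric())
  out <- rep(list(empty), nrow(annotation))
  names(out) <- annotation$gene_id
  if (nrow(gwas) > 0) {
    snps <- GenomicRanges::GRanges(
      gwas$chrom, IRanges::IRanges(start = gwas$pos + 1, width = 1))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(snps, genes))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(q) > 0) {
      df <- data.frame(gene = annotation$gene_id[s],
                       variant_id = gwas$variant_id[q],
                       pos = gwas$pos[q], pvalue = gwas$pvalue[q])
      df <- df[order(df$pos, df$variant_id), , drop = FALSE]
      by_gene <- split(df[, c("variant_id", "pos", "pvalue")], df$gene)
      by_gene <- lapply(by_gene, function(d) {
        rownames(d) <- NULL
        d
      })
      out[names(by_gene)] <- by_gene
    }
  }
  structure(out, class = "snp_gene_map")
}

#' Phenotype-layer features: top-k GWAS p-values for one gene
#'
#' Returns the k smallest GWAS p-values among the gene's mapped SNPs in
#' ascending order; when fewer than k SNPs map, the remaining entries are
#' exactly 1 (read as "no association"). Ties in p-value are broken by
#' (position, variant_id), making the selection independent of input row
#' order.
#'
#' @param gene_id Gene identifier; must be present in `snp_map`.
#' @param snp_map A [map_snps_to_genes()] result.
#' @param k Number of SNPs to select (default 5).
#' @return A list: `gwas_part` (length-k numeric, ascending then padding),
#'   `selected_snps` (variant_ids, length <= k), `n_mapped_snps`.
#' @export
gwas_features <- function(gene_id, snp_map, k = 5) {
  if (!gene_id %in% names(snp_map)) {
    stop("gene_id not present in SNP-gene map: ", gene_id)
  }
  d <- snp_map[[gene_id]]
  o <- order(d$pvalue, d$pos, d$variant_id)
  sel <- head(o, k)
  part <- rep(1, k)
  if (length(sel) > 0) part[seq_along(sel)] <- d$pvalue[sel]
  list(gwas_part = part, selected_snps = d$variant_id[sel],
       n_mapped_snps = nrow(d))
}

#' Transcriptome-layer features: eQTL p-values of the selected SNPs
#'
#' For each selected SNP (index-aligned with the GWAS part), looks up its
#' eQTL p-value; a SNP without a matching eQTL record contributes exactly 1.
#' Under `match_mode = "pair"` the record must pair the SNP with this gene
#' (GTEx semantics); under `"snp_any_gene"` any record for the SNP counts.
#' Multiple matching records contribute their smallest p-value.
#'
#' @param gene_id Gene identifier (used in `"pair"` mode).
#' @param selected_snps Variant IDs from [gwas_features()] for this gene.
#' @param eqtl eQTL `data.frame` (`variant_id`, `gene_id`, `pvalue`).
#' @param match_mode `"pair"` (default) or `"snp_any_gene"`.
#' @param k Feature length (default 5).
#' @return Length-k numeric vector in (0, 1].
#' @export
eqtl_features <- function(gene_id, selected_snps, eqtl,
                          match_mode = c("pair", "snp_any_gene"), k = 5) {
  match_mode <- match.arg(match_mode)
  part <- rep(1, k)
  if (length(selected_snps) == 0 || nrow(eqtl) == 0) return(part)
  rel <- if (match_mode == "pair") {
    eqtl[eqtl$gene_id == gene_id, , drop = FALSE]
  } else {
    eqtl
  }
  for (i in seq_along(selected_snps)) {
    p <- rel$pvalue[rel$variant_id == selected_snps[i]]
    if (length(p) > 0) part[i] <- min(p)
  }
  part
}

#' Build the gene-by-feature matrix
#'
#' Assembles one 10D row per admissible gene: `P_p1..P_p5` (GWAS part,
#' ascending) then `P_T1..P_T5` (eQTL part, index-aligned to the same SNPs).
#' Only genes with at least one mapped SNP are admitted; excluded genes are
#' listed in `attr(, "excluded")`.
#'
#' @param annotation,gwas,eqtl Validated input data frames.
#' @param flank Cis-window in bp (see [map_snps_to_genes()]).
#' @param k SNPs per layer (default 5; the feature vector has length `2k`).
#' @param match_mode eQTL matching mode (see [eqtl_features()]).
#' @param scale `"pvalue"` (raw p-values, padding 1 — the default feature
#'   space) or `"neglog10"` (-log10 p, padding 0).
#' @return A `data.frame` with columns `gene_id`, `P_p1..P_p5`, `P_T1..P_T5`,
#'   `n_mapped_snps`, `selected_snps` (comma-separated variant IDs), plus
#'   attributes `excluded` (gene_ids with no mapped SNP) and `params`.
#' @export
build_feature_matrix <- function(annotation, gwas, eqtl, flank = 0, k = 5,
                                 match_mode = c("pair", "snp_any_gene"),
                                 scale = c("pvalue", "neglog10")) {
  match_mode <- match.arg(match_mode)
  scale <- match.arg(scale)
  snp_map <- map_snps_to_genes(gwas, annotation, flank = flank)
  rows <- vector("list", nrow(annotation))
  excluded <- character()
  for (i in seq_len(nrow(annotation))) {
    g <- annotation$gene_id[i]
    gw <- gwas_features(g, snp_map, k = k)
    if (gw$n_mapped_snps < 1) {
      excluded <- c(excluded, g)
      next
    }
    eq <- eqtl_features(g, gw$selected_snps, eqtl, match_mode = match_mode,
                        k = k)
    row <- data.frame(gene_id = g, t(gw$gwas_part), t(eq),
                      n_mapped_snps = gw$n_mapped_snps,
                      selected_snps = paste(gw$selected_snps, collapse = ","))
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("no gene has any mapped SNP; feature matrix would be empty")
  }
  fm <- do.call(rbind, rows)
  names(fm) <- c("gene_id", paste0("P_p", seq_len(k)),
                 paste0("P_T", seq_len(k)), "n_mapped_snps", "selected_snps")
  if (scale == "neglog10") {
    fcols <- c(paste0("P_p", seq_len(k)), paste0("P_T", seq_len(k)))
    fm[fcols] <- -log10(fm[fcols])
  }
  rownames(fm) <- NULL
  attr(fm, "excluded") <- excluded
  attr(fm, "params") <- list(flank = flank, k = k, match_mode = match_mode,
                             scale = scale)
  fm
}

#' @rdname build_feature_matrix
#' @param features A feature matrix from [build_feature_matrix()].
#' @param path Output file.
#' @export
write_feature_matrix <- function(features, path) {
  out <- features
  fcols <- intersect(names(out), feature_cols())
  out[fcols] <- lapply(out[fcols], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
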