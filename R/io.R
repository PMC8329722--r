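# Readers/writers for the five tab-delimited input formats, with p-value
# validation and coordinate normalization. Internal convention: 0-based
# half-open intervals, 0-based SNP positions.

read_table_checked <- function(path, required, column_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(unname(column_map[required]), names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path)
  }
  out <- df[, unname(column_map[required]), drop = FALSE]
  names(out) <- required
  if (nrow(out) == 0) warning("no data rows in ", path)
  out
}

# Drop rows with unparseable/out-of-range p-values (counted); clamp exact
# zeros to the smallest positive double rather than dropping them.
validate_pvalues <- function(df, context) {
  p <- suppressWarnings(as.numeric(df$pvalue))
  bad <- is.na(p) | p < 0 | p > 1
  if (any(bad)) {
    warning(sprintf("%s: dropped %d row(s) with invalid p-values",
                    context, sum(bad)))
  }
  df <- df[!bad, , drop = FALSE]
  p <- p[!bad]
  zero <- p == 0
  if (any(zero)) {
    warning(sprintf("%s: clamped %d zero p-value(s) to %.3g",
                    context, sum(zero), .Machine$double.xmin))
    p[zero] <- .Machine$double.xmin
  }
  df$pvalue <- p
  rownames(df) <- NULL
  attr(df, "n_dropped") <- sum(bad)
  df
}

#' Read GWAS summary statistics
#'
#' Expects a tab-delimited file with a header. Rows with unparseable or
#' out-of-range p-values are dropped (count in `attr(, "n_dropped")`, with a
#' warning); zero p-values are clamped to the smallest positive double.
#'
#' @param path File path (plain or gzip-compressed).
#' @param column_map Named character vector mapping the internal names
#'   `variant_id`, `chrom`, `pos`, `pvalue` to the file's column names, so
#'   GWAS-Catalog-style exports can be read without reformatting.
#' @param coords `"zero_based"` (the package's native dialect) or
#'   `"one_based"`; one-based positions are shifted to the internal 0-based
#'   convention.
#' @param p_ceiling Optional p-value ceiling; rows with `pvalue > p_ceiling`
#'   are filtered out after validation. Default `NULL` (no filtering).
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos`, `pvalue`.
#' @export
read_gwas <- function(path,
                      column_map = c(variant_id = "variant_id",
                                     chrom = "chrom", pos = "pos",
                                     pvalue = "pvalue"),
                      coords = c("zero_based", "one_based"),
                      p_ceiling = NULL) {
  coords <- match.arg(coords)
  df <- read_table_checked(path, c("variant_id", "chrom", "pos", "pvalue"),
                           column_map)
  df$pos <- suppressWarnings(as.numeric(df$pos))
  bad_pos <- is.na(df$pos) | df$pos < (if (coords == "one_based") 1 else 0)
  if (any(bad_pos)) {
    warning(sprintf("read_gwas: dropped %d row(s) with invalid positions",
                    sum(bad_pos)))
    df <- df[!bad_pos, , drop = FALSE]
  }
  if (coords == "one_based") df$pos <- df$pos - 1
  df <- validate_pvalues(df, "read_gwas")
  if (!is.null(p_ceiling)) df <- df[df$pvalue <= p_ceiling, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_gwas
#' @param records A GWAS `data.frame` in internal form.
#' @export
write_gwas <- function(records, path) {
  out <- records[, c("variant_id", "chrom", "pos", "pvalue")]
  out$pvalue <- fmt_num(out$pvalue)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tissue eQTL variant-gene associations
#'
#' GTEx-style significant-pair files: one row per variant-gene pair with a
#' nominal p-value. Same p-value validation as [read_gwas()].
#'
#' @inheritParams read_gwas
#' @param column_map Maps `variant_id`, `gene_id`, `pvalue` to file columns
#'   (default p-value column name is the GTEx `pval_nominal`).
#' @return A `data.frame` with columns `variant_id`, `gene_id`, `pvalue`.
#' @export
read_eqtl <- function(path,
                      column_map = c(variant_id = "variant_id",
                                     gene_id = "gene_id",
                                     pvalue = "pval_nominal")) {
  df <- read_table_checked(path, c("variant_id", "gene_id", "pvalue"),
                           column_map)
  validate_pvalues(df, "read_eqtl")
}

#' @rdname read_eqtl
#' @param records An eQTL `data.frame` in internal form.
#' @export
write_eqtl <- function(records, path) {
  out <- data.frame(variant_id = records$variant_id,
                    gene_id = records$gene_id,
                    pval_nominal = fmt_num(records$pvalue))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-disease association table
#'
#' DisGeNET-style: gene identifier plus a non-negative association score.
#' Rows with unparseable or negative scores are dropped with a warning.
#'
#' @inheritParams read_gwas
#' @param column_map Maps `gene_id` and `score` to the file's column names.
#' @return A `data.frame` with columns `gene_id`, `score`.
#' @export
read_gene_disease <- function(path,
                              column_map = c(gene_id = "gene_id",
                                             score = "score")) {
  df <- read_table_checked(path, c("gene_id", "score"), column_map)
  s <- suppressWarnings(as.numeric(df$score))
  bad <- is.na(s) | s < 0
  if (any(bad)) {
    warning(sprintf("read_gene_disease: dropped %d row(s) with invalid scores",
                    sum(bad)))
  }
  df <- df[!bad, , drop = FALSE]
  df$score <- s[!bad]
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_disease
#' @param records A gene-disease `data.frame`.
#' @export
write_gene_disease <- function(records, path) {
  out <- data.frame(gene_id = records$gene_id, score = fmt_num(records$score))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-gene network edge list
#'
#' HumanNet-style: two gene identifiers and a correlation score per row.
#' Self-edges are dropped with a warning.
#'
#' @inheritParams read_gwas
#' @param column_map Maps `gene_a`, `gene_b`, `score` to file columns.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `score`.
#' @export
read_network <- function(path,
                         column_map = c(gene_a = "gene_a", gene_b = "gene_b",
                                        score = "score")) {
  df <- read_table_checked(path, c("gene_a", "gene_b", "score"), column_map)
  df$score <- suppressWarnings(as.numeric(df$score))
  bad <- is.na(df$score)
  if (any(bad)) {
    warning(sprintf("read_network: dropped %d row(s) with invalid scores",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sprintf("read_network: dropped %d self-edge(s)", sum(self)))
    df <- df[!self, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_network
#' @param records A network edge-list `data.frame`.
#' @export
write_network <- function(records, path) {
  out <- data.frame(gene_a = records$gene_a, gene_b = records$gene_b,
                    score = fmt_num(records$score))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED or GTF
#'
#' BED is interpreted natively (0-based half-open). GTF (1-based inclusive)
#' is converted to the internal 0-based half-open convention; only `gene`
#' features are kept when a feature-type column is present. Duplicate gene
#' identifiers are an error.
#'
#' @param path File path (plain or gzip-compressed).
#' @param format `"bed"` or `"gtf"`; guessed from the extension by default.
#' @return A `data.frame` with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  gr <- rtracklayer::import(path, format = toupper(format))
  if (format == "gtf") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[as.character(gr$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    gene_id <- as.character(md$gene_id)
    symbol <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
              else gene_id
  } else {
    gene_id <- as.character(gr$name)
    symbol <- gene_id
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id(s) in annotation: ", paste(dup, collapse = ", "))
  }
  ann <- data.frame(gene_id = gene_id, symbol = symbol,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = as.numeric(GenomicRanges::start(gr)) - 1,
                    end = as.numeric(GenomicRanges::end(gr)))
  bad <- ann$start < 0 | ann$start >= ann$end
  if (any(bad)) stop("invalid gene interval(s): ",
                     paste(ann$gene_id[bad], collapse = ", "))
  rownames(ann) <- NULL
  ann
}

#' @rdname read_annotation
#' @param annotation An annotation `data.frame` in internal form.
#' @export
write_annotation <- function(annotation, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1, end = annotation$end))
  if (format == "bed") {
    gr$name <- annotation$gene_id
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$source <- "priogene"
    gr$type <- "gene"
    gr$gene_id <- annotation$gene_id
    gr$gene_name <- annotation$symbol
    rtracklayer::export(gr, path, format = "GTF")
  }
  invisible(path)
}

#' Referential-integrity report across the five inputs
#'
#' Checks that eQTL variants exist in the GWAS table, that eQTL and network
#' genes are annotated, that gene-disease entries map to annotated genes (by
#' gene_id or symbol), and that GWAS and annotation share chromosome names.
#' Nothing is modified; results are returned for inspection.
#'
#' @param gwas,eqtl,annotation,gene_disease,network Data frames in internal
#'   form (any may be `NULL` to skip its checks).
#' @return A list of named character vectors / count tables describing the
#'   inconsistencies found (empty elements mean a clean dataset).
#' @export
validate_dataset <- function(gwas = NULL, eqtl = NULL, annotation = NULL,
                             gene_disease = NULL, network = NULL) {
  report <- list()
  if (!is.null(eqtl) && !is.null(gwas)) {
    report$eqtl_variants_not_in_gwas <-
      sort(unique(setdiff(eqtl$variant_id, gwas$variant_id)))
  }
  if (!is.null(eqtl) && !is.null(annotation)) {
    report$eqtl_genes_not_annotated <-
      sort(unique(setdiff(eqtl$gene_id, annotation$gene_id)))
  }
  if (!is.null(gene_disease) && !is.null(annotation)) {
    known <- union(annotation$gene_id, annotation$symbol)
    report$gene_disease_unmapped <-
      sort(unique(setdiff(gene_disease$gene_id, known)))
  }
  if (!is.null(network) && !is.null(annotation)) {
    net_genes <- union(network$gene_a, network$gene_b)
    report$network_genes_not_annotated <-
      sort(unique(setdiff(net_genes, annotation$gene_id)))
  }
  if (!is.null(gwas) && !is.null(annotation)) {
    shared <- intersect(unique(gwas$chrom), unique(annotation$chrom))
    report$chromosomes <- list(
      gwas_only = sort(setdiff(unique(gwas$chrom), shared)),
      annotation_only = sort(setdiff(unique(annotation$chrom), shared)))
  }
  report
}

#' Map gene symbols to annotated gene identifiers
#'
#' Gene-disease tables often use symbols; this resolves them against the
#' annotation's `symbol` column (identifiers already present are kept).
#' Unmapped entries are reported in `attr(, "unmapped")`, not dropped
#' silently.
#'
#' @param ids Character vector of gene identifiers or symbols.
#' @param annotation Annotation `data.frame`.
#' @return Character vector of gene_ids (NA where unmapped), with the
#'   unmapped originals in `attr(, "unmapped")`.
#' @export
map_symbols <- function(ids, annotation) {
  out <- ifelse(ids %in% annotation$gene_id, ids,
                annotation$gene_id[match(ids, annotation$symbol)])
  attr(out, "unmapped") <- sort(unique(ids[is.na(out)]))
  out
}
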