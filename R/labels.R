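# Partition annotated genes into positive / negative / candidate sets from
# the gene-disease table and the gene-network correlation scores.

#' Build positive, negative, and candidate gene sets
#'
#' Positives are the annotated genes listed in the gene-disease table
#' (optionally above a minimum score); listing takes precedence over any
#' network evidence. Every other annotated gene gets a relevance score: the
#' maximum network correlation score over its edges to positive genes. Genes
#' with relevance below `score_threshold` are negatives; genes at or above
#' it are candidates. Genes with no edge to any positive are governed by
#' `isolated`: `"candidate"` (default; a gene the network says nothing about
#' is not a safe negative) or `"negative"` (relevance taken as 0).
#'
#' @param gene_disease Gene-disease `data.frame` (`gene_id`, `score`);
#'   symbols are resolved against the annotation.
#' @param network Network edge list (`gene_a`, `gene_b`, `score`).
#' @param annotation Annotation `data.frame`; only annotated genes are
#'   labeled.
#' @param score_threshold Relevance threshold separating negatives from
#'   candidates; must be > 0. Default 1.
#' @param isolated Policy for genes without edges to positives.
#' @param min_score Minimum gene-disease score for a gene to count as
#'   positive (default 0: any listed gene).
#' @return An object of class `label_sets`: list with `positives`,
#'   `negatives`, `candidates` (disjoint character vectors covering the
#'   annotated genes), `unannotated` (gene-disease entries that could not be
#'   mapped), and the parameters used.
#' @export
build_label_sets <- function(gene_disease, network, annotation,
                             score_threshold = 1.0,
                             isolated = c("candidate", "negative"),
                             min_score = 0) {
  isolated <- match.arg(isolated)
  stopifnot(score_threshold > 0)
  listed <- gene_disease$gene_id[gene_disease$score >= min_score]
  mapped <- map_symbols(unique(listed), annotation)
  unannotated <- attr(mapped, "unmapped")
  positives <- sort(unique(mapped[!is.na(mapped)]))
  if (length(positives) == 0) {
    stop("empty positive set: no gene-disease entry maps to the annotation; ",
         "training is impossible")
  }
  rest <- setdiff(annotation$gene_id, positives)
  # relevance of a non-positive gene = max score over its edges to positives
  relevance <- numeric(0)
  if (nrow(network) > 0) {
    a_pos <- network$gene_a %in% positives
    b_pos <- network$gene_b %in% positives
    touch <- data.frame(
      gene = c(network$gene_b[a_pos & !b_pos], network$gene_a[b_pos & !a_pos]),
      score = c(network$score[a_pos & !b_pos], network$score[b_pos & !a_pos]))
    touch <- touch[touch$gene %in% rest, , drop = FALSE]
    if (nrow(touch) > 0) {
      relevance <- tapply(touch$score, touch$gene, max)
    }
  }
  connected <- names(relevance)
  negatives <- sort(connected[relevance < score_threshold])
  candidates <- sort(setdiff(rest, negatives))
  if (isolated == "negative") {
    negatives <- sort(union(negatives, setdiff(rest, connected)))
    candidates <- sort(setdiff(candidates, negatives))
  }
  structure(list(positives = positives, negatives = negatives,
                 candidates = candidates,
                 unannotated = unannotated,
                 score_threshold = score_threshold, isolated = isolated,
                 min_score = min_score),
            class = "label_sets")
}

#' @export
print.label_sets <- function(x, ...) {
  cat(sprintf(
    "label_sets: %d positives, %d negatives, %d candidates (threshold %g, isolated -> %s)\n",
    length(x$positives), length(x$negatives), length(x$candidates),
    x$score_threshold, x$isolated))
  if (length(x$unannotated) > 0) {
    cat(sprintf("  %d gene-disease entr%s not in the annotation\n",
                length(x$unannotated),
                if (length(x$unannotated) == 1) "y" else "ies"))
  }
  invisible(x)
}

#' Write label sets as a two-column table
#'
#' @param labels A `label_sets` object.
#' @param path Output file: tab-delimited `gene_id`, `label`
#'   (positive/negative/candidate).
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_sets"))
  df <- data.frame(
    gene_id = c(labels$positives, labels$negatives, labels$candidates),
    label = rep(c("positive", "negative", "candidate"),
                c(length(labels$positives), length(labels$negatives),
                  length(labels$candidates))))
  df <- df[order(df$gene_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
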