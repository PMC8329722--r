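# Score candidate genes with the trained classifier and rank them.

#' Score and rank candidate genes
#'
#' Applies a trained [train_final()] model to the candidate genes' feature
#' rows and ranks them by decreasing positive-class probability, ties broken
#' by gene_id. Candidates without a feature row (no mapped SNP, so no 10D
#' vector exists) are reported as unscorable rather than silently scored.
#' The feature column order is checked against the one the model was trained
#' with; a mismatch is an error, never a silent misprediction.
#'
#' @param model A `gene_classifier` from [train_final()].
#' @param features Feature matrix from [build_feature_matrix()] (same
#'   construction parameters as at training time).
#' @param candidates Character vector of candidate gene_ids, or a
#'   `label_sets` object (its `candidates` element is used).
#' @return A `data.frame` of ranked genes: `rank` (1..n over scorable genes,
#'   NA for unscorable), `gene_id`, `score` (positive-class probability),
#'   `n_mapped_snps`, `selected_snps`, `scorable`.
#' @export
predict_candidates <- function(model, features, candidates) {
  stopifnot(inherits(model, "gene_classifier"))
  if (inherits(candidates, "label_sets")) candidates <- candidates$candidates
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) stop("empty candidate set: nothing to score")
  got <- names(features)[names(features) %in% feature_cols()]
  if (!identical(got, model$feature_cols)) {
    stop("feature columns do not match the model's training columns ",
         "(expected ", paste(model$feature_cols, collapse = ", "), ")")
  }
  idx <- match(candidates, features$gene_id)
  scorable <- !is.na(idx)
  out_unsc <- NULL
  if (any(!scorable)) {
    out_unsc <- data.frame(rank = NA_integer_,
                           gene_id = sort(candidates[!scorable]),
                           score = NA_real_, n_mapped_snps = 0L,
                           selected_snps = "", scorable = FALSE)
  }
  if (!any(scorable)) {
    warning("all candidates are unscorable (no mapped SNPs)")
    return(out_unsc)
  }
  rows <- features[idx[scorable], , drop = FALSE]
  X <- rows[, model$feature_cols, drop = FALSE]
  score <- predict_prob(model$spec, model$fit, X)
  o <- order(-score, rows$gene_id)
  out <- data.frame(rank = seq_along(o),
                    gene_id = rows$gene_id[o],
                    score = score[o],
                    n_mapped_snps = rows$n_mapped_snps[o],
                    selected_snps = rows$selected_snps[o],
                    scorable = TRUE)
  out <- rbind(out, out_unsc)
  rownames(out) <- NULL
  out
}

#' Call novel susceptibility genes from a ranking
#'
#' Selects scorable genes whose positive-class probability is at least
#' `threshold`. The threshold and the resulting count are recorded in
#' attributes so the selection is reproducible.
#'
#' @param ranked Output of [predict_candidates()].
#' @param threshold Probability cutoff in \[0, 1\]. Default 0.5.
#' @param top_n Alternative selection: keep the `top_n` best-ranked genes
#'   instead of thresholding (ignores `threshold` when given).
#' @return Character vector of gene_ids, with attributes `threshold`/`top_n`
#'   and `n_called`.
#' @export
call_novel_genes <- function(ranked, threshold = 0.5, top_n = NULL) {
  stopifnot(nrow(ranked) > 0)
  sc <- ranked[ranked$scorable, , drop = FALSE]
  if (!is.null(top_n)) {
    stopifnot(top_n >= 1)
    genes <- sc$gene_id[sc$rank <= top_n]
    attr(genes, "top_n") <- top_n
  } else {
    if (threshold < 0 || threshold > 1) {
      stop("threshold must be in [0, 1], got ", threshold)
    }
    genes <- sc$gene_id[sc$score >= threshold]
    attr(genes, "threshold") <- threshold
  }
  attr(genes, "n_called") <- length(genes)
  genes
}

#' Write a ranked candidate table
#'
#' @param ranked Output of [predict_candidates()].
#' @param path Output file (tab-delimited: rank, gene_id, score,
#'   n_mapped_snps, selected_snps, scorable).
#' @export
write_ranking <- function(ranked, path) {
  out <- ranked
  out$score <- ifelse(is.na(out$score), "NA", fmt_num(out$score))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full prioritization pipeline on in-memory tables
#'
#' Convenience wrapper: features -> labels -> final model -> candidate
#' ranking. Intended for synthetic or already-validated inputs; each stage
#' is also available separately.
#'
#' @param annotation,gwas,eqtl,gene_disease,network Input data frames in
#'   internal form (e.g. a [simulate_dataset()] or the readers' outputs).
#' @param spec A [classifier_spec()]; default random forest.
#' @param flank,match_mode Feature-construction options
#'   (see [build_feature_matrix()]).
#' @param score_threshold,isolated Label-construction options
#'   (see [build_label_sets()]).
#' @param seed Integer seed for model fitting.
#' @return List with `features`, `labels`, `model`, `ranked`.
#' @export
prioritize_genes <- function(annotation, gwas, eqtl, gene_disease, network,
                             spec = classifier_spec("random_forest"),
                             flank = 0, match_mode = "pair",
                             score_threshold = 1.0, isolated = "candidate",
                             seed = 1) {
  features <- build_feature_matrix(annotation, gwas, eqtl, flank = flank,
                                   match_mode = match_mode)
  labels <- build_label_sets(gene_disease, network, annotation,
                             score_threshold = score_threshold,
                             isolated = isolated)
  model <- train_final(features, labels, spec = spec, seed = seed)
  ranked <- predict_candidates(model, features, labels)
  list(features = features, labels = labels, model = model, ranked = ranked)
}
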