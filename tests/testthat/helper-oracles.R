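# Independent brute-force oracles and small random-instance builders.
# These deliberately avoid the package's implementation paths: mapping is a
# double loop, feature assembly is a literal sort/pad, AUC is exhaustive
# pair counting, and the label partition is a per-gene edge scan.

brute_map <- function(gwas, annotation, flank = 0) {
  out <- setNames(vector("list", nrow(annotation)), annotation$gene_id)
  for (g in seq_len(nrow(annotation))) {
    hits <- integer(0)
    for (s in seq_len(nrow(gwas))) {
      if (gwas$chrom[s] == annotation$chrom[g] &&
          gwas$pos[s] >= annotation$start[g] - flank &&
          gwas$pos[s] < annotation$end[g] + flank) {
        hits <- c(hits, s)
      }
    }
    out[[g]] <- gwas[hits, c("variant_id", "pos", "pvalue"), drop = FALSE]
  }
  out
}

# Literal restatement of the feature rules: ascending top-k GWAS p-values
# (ties by position then variant_id), pad with 1; eQTL p of the same SNPs,
# 1 where no record matches.
brute_feature_row <- function(gene, mapped, eqtl, k = 5,
                              match_mode = "pair") {
  d <- mapped[[gene]]
  o <- order(d$pvalue, d$pos, d$variant_id)
  sel <- d[o, , drop = FALSE][seq_len(min(k, nrow(d))), , drop = FALSE]
  gw <- c(sel$pvalue, rep(1, k - nrow(sel)))
  eq <- rep(1, k)
  for (i in seq_len(nrow(sel))) {
    if (match_mode == "pair") {
      m <- eqtl$pvalue[eqtl$variant_id == sel$variant_id[i] &
                       eqtl$gene_id == gene]
    } else {
      m <- eqtl$pvalue[eqtl$variant_id == sel$variant_id[i]]
    }
    if (length(m) > 0) eq[i] <- min(m)
  }
  c(gw, eq)
}

brute_feature_matrix <- function(annotation, gwas, eqtl, flank = 0, k = 5,
                                 match_mode = "pair") {
  mapped <- brute_map(gwas, annotation, flank)
  keep <- annotation$gene_id[vapply(mapped, nrow, integer(1)) >= 1]
  mat <- t(vapply(keep, brute_feature_row, numeric(2 * k),
                  mapped = mapped, eqtl = eqtl, k = k,
                  match_mode = match_mode))
  list(gene_id = keep, matrix = unname(mat),
       excluded = setdiff(annotation$gene_id, keep))
}

# AUC as the exhaustive Mann-Whitney statistic: over all positive-negative
# pairs, wins count 1, ties count 1/2.
brute_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  sp <- scores[y == 1]
  sn <- scores[y == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

brute_label_sets <- function(gene_disease, network, annotation,
                             threshold = 1, isolated = "candidate") {
  positives <- sort(intersect(unique(gene_disease$gene_id),
                              annotation$gene_id))
  neg <- cand <- character(0)
  for (g in setdiff(annotation$gene_id, positives)) {
    scores <- c(network$score[network$gene_a == g &
                              network$gene_b %in% positives],
                network$score[network$gene_b == g &
                              network$gene_a %in% positives])
    if (length(scores) == 0) {
      if (isolated == "negative") neg <- c(neg, g) else cand <- c(cand, g)
    } else if (max(scores) < threshold) {
      neg <- c(neg, g)
    } else {
      cand <- c(cand, g)
    }
  }
  list(positives = positives, negatives = sort(neg), candidates = sort(cand))
}

# Small random instance with overlapping genes, out-of-gene SNPs, deliberate
# p-value ties, and eQTL records for both matching and foreign genes.
random_instance <- function(seed, n_genes = 5, n_snps = 40) {
  set.seed(seed)
  start <- sample(0:500, n_genes)
  ann <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    symbol = sprintf("S%02d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    start = start, end = start + sample(50:200, n_genes, replace = TRUE))
  gwas <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(n_snps)),
    chrom = sample(c("chr1", "chr2"), n_snps, replace = TRUE),
    pos = sample(0:700, n_snps, replace = TRUE),
    pvalue = round(runif(n_snps), 2))  # rounding forces ties
  gwas$pvalue <- pmax(gwas$pvalue, 1e-6)
  n_eq <- max(1, rbinom(1, n_snps, 0.4))
  eqtl <- data.frame(
    variant_id = sample(gwas$variant_id, n_eq, replace = TRUE),
    gene_id = sample(ann$gene_id, n_eq, replace = TRUE),
    pvalue = pmax(round(runif(n_eq), 2), 1e-6))
  list(annotation = ann, gwas = gwas, eqtl = eqtl)
}

# Small planted-signal dataset for fast model tests.
small_sim <- function(seed = 7, n_genes = 200, n_causal = 60, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, n_causal = n_causal,
                              genome_length = 5e6, seed = seed, ...))
}

permuted_label_vector <- function(labels, seed) {
  y <- setNames(rep(c(1, 0), c(length(labels$positives),
                               length(labels$negatives))),
                c(labels$positives, labels$negatives))
  set.seed(seed)
  setNames(sample(unname(y)), names(y))
}
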