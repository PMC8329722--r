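#' Configuration for the synthetic summary-statistics simulator
#'
#' Defines the study conditions for a planted-truth simulation: genes placed
#' on a small synthetic genome, SNPs inside gene bodies, uniform null
#' p-values, and Beta(a, 1) enriched p-values (a < 1) for SNPs in causal
#' genes at the GWAS layer and, with probability `eqtl_signal_prob`, at the
#' eQTL layer. The defaults are the package's reference planted-signal
#' conditions used throughout its validation.
#'
#' @param n_genes Number of genes to place.
#' @param n_causal Number of causal (disease) genes among them.
#' @param genome_length Total genome length in base pairs (split evenly
#'   across `n_chrom` chromosomes).
#' @param gene_length_range Length-2 integer vector, min/max gene length (bp).
#' @param snps_per_gene_range Length-2 integer vector, min/max SNPs simulated
#'   per gene.
#' @param causal_beta_a Shape `a` of the Beta(a, 1) enriched p-value
#'   distribution, in (0, 1]; `a = 1` is the uniform null (no signal).
#' @param eqtl_signal_prob Probability that each of a causal gene's top-5
#'   GWAS SNPs carries an enriched eQTL association.
#' @param eqtl_background_prob Probability that any other in-gene SNP gets a
#'   null (uniform-p) eQTL pair with its host gene.
#' @param causal_known_frac Fraction of causal genes listed in the
#'   gene-disease table (the rest stay hidden and end up as candidates).
#' @param negative_fraction Fraction of non-causal genes given a network edge
#'   with score < 1 to a known positive, so the label stage recovers them as
#'   negatives; the rest receive a score >= 1 edge and become candidates.
#' @param network_density Probability of an additional noise edge between two
#'   non-positive genes (does not affect labels).
#' @param n_intergenic_snps Number of extra SNPs placed uniformly on the
#'   genome regardless of genes (null p-values).
#' @param allow_overlap Allow gene intervals to overlap. Default `FALSE`:
#'   genes are packed disjointly and an infeasible packing is an error.
#' @param n_chrom Number of chromosomes (`chr1`, `chr2`, ...).
#' @param seed Integer seed; all five outputs derive deterministic
#'   sub-streams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_causal = 400,
                       genome_length = 5e7,
                       gene_length_range = c(1000L, 5000L),
                       snps_per_gene_range = c(3L, 15L),
                       causal_beta_a = 0.1,
                       eqtl_signal_prob = 0.8,
                       eqtl_background_prob = 0.05,
                       causal_known_frac = 1,
                       negative_fraction = 0.3,
                       network_density = 5e-4,
                       n_intergenic_snps = 0,
                       allow_overlap = FALSE,
                       n_chrom = 1,
                       seed = 42) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_causal = as.integer(n_causal),
    genome_length = as.numeric(genome_length),
    gene_length_range = as.integer(gene_length_range),
    snps_per_gene_range = as.integer(snps_per_gene_range),
    causal_beta_a = causal_beta_a,
    eqtl_signal_prob = eqtl_signal_prob,
    eqtl_background_prob = eqtl_background_prob,
    causal_known_frac = causal_known_frac,
    negative_fraction = negative_fraction,
    network_density = network_density,
    n_intergenic_snps = as.integer(n_intergenic_snps),
    allow_overlap = isTRUE(allow_overlap),
    n_chrom = as.integer(n_chrom),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 0, cfg$n_causal >= 0, cfg$n_causal <= cfg$n_genes,
    cfg$genome_length > 0, cfg$n_chrom >= 1,
    length(cfg$gene_length_range) == 2,
    cfg$gene_length_range[1] >= 1,
    cfg$gene_length_range[1] <= cfg$gene_length_range[2],
    length(cfg$snps_per_gene_range) == 2,
    cfg$snps_per_gene_range[1] >= 0,
    cfg$snps_per_gene_range[1] <= cfg$snps_per_gene_range[2],
    cfg$causal_beta_a > 0, cfg$causal_beta_a <= 1
  )
  for (p in c("eqtl_signal_prob", "eqtl_background_prob", "causal_known_frac",
              "negative_fraction", "network_density")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("`%s` must be in [0, 1], got %g", p, cfg[[p]]))
    }
  }
  structure(cfg, class = "sim_config")
}

#' Place genes on the synthetic genome
#'
#' Genes are assigned to chromosomes round-robin and, unless
#' `allow_overlap = TRUE`, packed disjointly: random lengths are drawn first
#' and the remaining slack is distributed as random inter-gene gaps, so
#' intervals never overlap and always lie within the chromosome.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cols <- c("gene_id", "symbol", "chrom", "start", "end")
  if (config$n_genes == 0) {
    return(data.frame(gene_id = character(), symbol = character(),
                      chrom = character(), start = numeric(), end = numeric()))
  }
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_genes
  wid <- max(4L, nchar(as.character(n)))
  chrom_of <- sprintf("chr%d", ((seq_len(n) - 1) %% config$n_chrom) + 1)
  chrom_len <- floor(config$genome_length / config$n_chrom)
  lens <- sample_int_range(config$gene_length_range[1],
                           config$gene_length_range[2], n)
  start <- numeric(n)
  for (chr in unique(chrom_of)) {
    idx <- which(chrom_of == chr)
    total <- sum(lens[idx])
    if (!config$allow_overlap) {
      slack <- chrom_len - total
      if (slack < 0) {
        stop(sprintf(
          "cannot pack %d genes totalling %.0f bp into %s (%.0f bp); %s",
          length(idx), total, chr, chrom_len,
          "increase genome_length, reduce n_genes, or set allow_overlap = TRUE"))
      }
      gaps <- floor(sort(runif(length(idx), 0, slack)))
      start[idx] <- cumsum(c(0, lens[idx][-length(idx)])) + gaps
    } else {
      start[idx] <- floor(runif(length(idx), 0, pmax(1, chrom_len - lens[idx])))
    }
  }
  ann <- data.frame(
    gene_id = sprintf("gene_%0*d", wid, seq_len(n)),
    symbol = sprintf("SYM%0*d", wid, seq_len(n)),
    chrom = chrom_of,
    start = start,
    end = start + lens
  )
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), cols, drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Draw the planted truth: which genes are causal
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return A `planted_truth` list: `causal_genes`, `known_causal` (the subset
#'   listed in the gene-disease table, per `causal_known_frac`), and `seed`.
#' @export
simulate_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2))
  causal <- sort(sample(annotation$gene_id, config$n_causal))
  n_known <- round(config$causal_known_frac * length(causal))
  known <- sort(sample(causal, n_known))
  structure(list(causal_genes = causal, known_causal = known,
                 seed = config$seed),
            class = "planted_truth")
}

#' Simulate the GWAS summary-statistics table
#'
#' Each gene receives a number of SNPs drawn from `snps_per_gene_range`,
#' placed uniformly inside the gene body. SNPs in causal genes draw p-values
#' from Beta(a, 1) with `a = causal_beta_a`; all other SNPs (including
#' optional intergenic ones) draw from Uniform(0, 1).
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()]; must be non-empty.
#' @param truth Output of [simulate_truth()].
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos` (0-based),
#'   `pvalue`, sorted by position. The generating SNP-to-gene assignment is
#'   attached as `attr(, "snp_gene")` for provenance.
#' @export
simulate_gwas <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"), nrow(annotation) > 0)
  set.seed(sub_seed(config$seed, 3))
  n_per <- sample_int_range(config$snps_per_gene_range[1],
                            config$snps_per_gene_range[2], nrow(annotation))
  gene_idx <- rep(seq_len(nrow(annotation)), n_per)
  pos <- floor(runif(length(gene_idx),
                     annotation$start[gene_idx], annotation$end[gene_idx]))
  is_causal <- annotation$gene_id[gene_idx] %in% truth$causal_genes
  p <- numeric(length(gene_idx))
  p[is_causal] <- rbeta(sum(is_causal), config$causal_beta_a, 1)
  p[!is_causal] <- runif(sum(!is_causal))
  snp_gene <- annotation$gene_id[gene_idx]
  chrom <- annotation$chrom[gene_idx]
  if (config$n_intergenic_snps > 0) {
    m <- config$n_intergenic_snps
    chrom_len <- floor(config$genome_length / config$n_chrom)
    chr_i <- sample(config$n_chrom, m, replace = TRUE)
    pos <- c(pos, floor(runif(m, 0, chrom_len)))
    chrom <- c(chrom, sprintf("chr%d", chr_i))
    p <- c(p, runif(m))
    snp_gene <- c(snp_gene, rep(NA_character_, m))
  }
  p <- pmax(p, .Machine$double.xmin)
  o <- order(chrom, pos)
  gwas <- data.frame(
    variant_id = sprintf("rs%07d", seq_along(o)),
    chrom = chrom[o], pos = pos[o], pvalue = p[o]
  )
  attr(gwas, "snp_gene") <- data.frame(variant_id = gwas$variant_id,
                                       gene_id = snp_gene[o])
  gwas
}

#' Simulate the tissue eQTL variant-gene association table
#'
#' For each causal gene, its five smallest-p GWAS SNPs each receive an
#' enriched eQTL pair (p from Beta(a, 1)) with probability
#' `eqtl_signal_prob`. Every other in-gene SNP receives a null
#' (uniform-p) pair with its host gene with probability
#' `eqtl_background_prob`. Every emitted variant exists in the GWAS table.
#'
#' @param config A [sim_config()].
#' @param annotation,truth,gwas Outputs of the upstream simulators; `gwas`
#'   must come from [simulate_gwas()] under the same truth.
#' @return A `data.frame` with columns `variant_id`, `gene_id`, `pvalue`.
#' @export
simulate_eqtl <- function(config, annotation, truth, gwas) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 4))
  sg <- attr(gwas, "snp_gene")
  if (is.null(sg)) {
    m <- map_snps_to_genes(gwas, annotation, flank = 0)
    sg <- do.call(rbind, lapply(names(m), function(g) {
      if (nrow(m[[g]]) == 0) return(NULL)
      data.frame(variant_id = m[[g]]$variant_id, gene_id = g)
    }))
  }
  sg <- sg[!is.na(sg$gene_id), , drop = FALSE]
  sg$pvalue <- gwas$pvalue[match(sg$variant_id, gwas$variant_id)]
  top <- logical(nrow(sg))
  for (g in truth$causal_genes) {
    idx <- which(sg$gene_id == g)
    if (length(idx) == 0) next
    o <- idx[order(sg$pvalue[idx], sg$variant_id[idx])]
    top[head(o, 5L)] <- TRUE
  }
  keep_sig <- top & (runif(nrow(sg)) < config$eqtl_signal_prob)
  keep_bg <- !top & (runif(nrow(sg)) < config$eqtl_background_prob)
  p <- numeric(nrow(sg))
  p[keep_sig] <- rbeta(sum(keep_sig), config$causal_beta_a, 1)
  p[keep_bg] <- runif(sum(keep_bg))
  keep <- keep_sig | keep_bg
  eqtl <- data.frame(variant_id = sg$variant_id[keep],
                     gene_id = sg$gene_id[keep],
                     pvalue = pmax(p[keep], .Machine$double.xmin))
  eqtl <- eqtl[order(eqtl$variant_id, eqtl$gene_id), , drop = FALSE]
  rownames(eqtl) <- NULL
  eqtl
}

#' Simulate the gene-disease table and the gene network
#'
#' Known causal genes form the gene-disease table (scores ~ U(0.1, 1),
#' DisGeNET-like). Each other gene gets one edge to a random known positive:
#' with probability `negative_fraction` the edge score is drawn in (0, 1)
#' (so the label stage recovers the gene as a negative), otherwise in
#' \[1, 2.5\] (candidate). Hidden causal genes always receive a candidate
#' edge. Extra noise edges between non-positive genes are added at rate
#' `network_density`; they never touch positives, so labels are unaffected.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param truth Output of [simulate_truth()].
#' @return A list with `gene_disease` (`gene_id`, `score`) and `network`
#'   (`gene_a`, `gene_b`, `score`) data frames.
#' @export
simulate_labels_network <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 5))
  pos <- truth$known_causal
  gene_disease <- data.frame(gene_id = pos,
                             score = round(runif(length(pos), 0.1, 1), 6))
  others <- setdiff(annotation$gene_id, pos)
  if (length(pos) == 0 || length(others) == 0) {
    return(list(gene_disease = gene_disease,
                network = data.frame(gene_a = character(),
                                     gene_b = character(), score = numeric())))
  }
  hidden <- setdiff(truth$causal_genes, pos)
  is_neg <- runif(length(others)) < config$negative_fraction
  is_neg[others %in% hidden] <- FALSE
  score <- ifelse(is_neg, runif(length(others), 0.01, 0.99),
                  runif(length(others), 1.0, 2.5))
  net <- data.frame(gene_a = others,
                    gene_b = pos[sample.int(length(pos), length(others),
                                            replace = TRUE)],
                    score = round(score, 6))
  if (config$network_density > 0 && length(others) >= 2) {
    n_pairs <- choose(length(others), 2)
    n_noise <- rbinom(1, min(n_pairs, 1e6), config$network_density)
    if (n_noise > 0) {
      a <- sample(others, n_noise, replace = TRUE)
      b <- sample(others, n_noise, replace = TRUE)
      ok <- a != b
      noise <- data.frame(gene_a = a[ok], gene_b = b[ok],
                          score = round(runif(sum(ok), 0, 2), 6))
      net <- rbind(net, noise)
    }
  }
  net <- net[order(net$gene_a, net$gene_b, net$score), , drop = FALSE]
  rownames(net) <- NULL
  list(gene_disease = gene_disease, network = net)
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Runs all simulators in order and returns the five tables plus the truth.
#' Deterministic: the same config (including seed) always yields identical
#' tables.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `annotation`, `gwas`, `eqtl`,
#'   `gene_disease`, `network`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(config, annotation)
  gwas <- simulate_gwas(config, annotation, truth)
  eqtl <- simulate_eqtl(config, annotation, truth, gwas)
  ln <- simulate_labels_network(config, annotation, truth)
  structure(list(annotation = annotation, gwas = gwas, eqtl = eqtl,
                 gene_disease = ln$gene_disease, network = ln$network,
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits `genes.bed` (0-based half-open), `gwas.tsv`, `eqtl.tsv` (GTEx-style
#' `pval_nominal` column), `gene_disease.tsv`, `network.tsv`, and
#' `truth.json`. Numeric formatting is fixed so regeneration under the same
#' seed is byte-identical.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "genes.bed"),
             gwas = file.path(dir, "gwas.tsv"),
             eqtl = file.path(dir, "eqtl.tsv"),
             gene_disease = file.path(dir, "gene_disease.tsv"),
             network = file.path(dir, "network.tsv"),
             truth = file.path(dir, "truth.json"))
  write_annotation(sim$annotation, paths["annotation"], format = "bed")
  write_gwas(sim$gwas, paths["gwas"])
  write_eqtl(sim$eqtl, paths["eqtl"])
  write_gene_disease(sim$gene_disease, paths["gene_disease"])
  write_network(sim$network, paths["network"])
  jsonlite::write_json(
    list(causal_genes = sim$truth$causal_genes,
         known_causal = sim$truth$known_causal,
         seed = sim$config$seed),
    paths["truth"], pretty = TRUE)
  invisible(paths)
}
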