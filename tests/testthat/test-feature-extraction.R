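test_that("SNP-to-gene mapping follows half-open containment with flank", {
  ann <- data.frame(gene_id = "geneA", symbol = "A", chrom = "chr1",
                    start = 100, end = 200)
  gw <- function(pos) data.frame(variant_id = sprintf("rs%d", seq_along(pos)),
                                 chrom = "chr1", pos = pos,
                                 pvalue = rep(0.5, length(pos)))
  expect_identical(nrow(map_snps_to_genes(gw(150), ann)[["geneA"]]), 1L)
  expect_identical(nrow(map_snps_to_genes(gw(100), ann)[["geneA"]]), 1L)
  expect_identical(nrow(map_snps_to_genes(gw(200), ann)[["geneA"]]), 0L)
  expect_identical(nrow(map_snps_to_genes(gw(99), ann)[["geneA"]]), 0L)
  expect_identical(nrow(map_snps_to_genes(gw(c(99, 200)), ann,
                                          flank = 1)[["geneA"]]), 2L)
  expect_warning(
    map_snps_to_genes(data.frame(variant_id = "rs1", chrom = "chrX",
                                 pos = 150, pvalue = 0.5), ann),
    "no shared chromosomes")
})

test_that("mapping agrees with a brute-force double loop on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed, n_genes = 5, n_snps = 50)
    flank <- sample(c(0, 10, 50), 1)
    got <- map_snps_to_genes(inst$gwas, inst$annotation, flank = flank)
    ref <- brute_map(inst$gwas, inst$annotation, flank = flank)
    for (g in inst$annotation$gene_id) {
      expect_setequal(got[[g]]$variant_id, ref[[g]]$variant_id)
    }
  }
})

test_that("GWAS part is the ascending top five, padded with exact 1s", {
  ann <- data.frame(gene_id = "geneA", symbol = "A", chrom = "chr1",
                    start = 0, end = 1000)
  mk <- function(p) map_snps_to_genes(
    data.frame(variant_id = sprintf("rs%d", seq_along(p)), chrom = "chr1",
               pos = seq_along(p) * 10, pvalue = p), ann)

  got <- gwas_features("geneA", mk(c(.9, .2, .5, .01, .3, .7, .04)))
  expect_equal(got$gwas_part, c(.01, .04, .2, .3, .5))
  expect_identical(got$n_mapped_snps, 7L)

  got3 <- gwas_features("geneA", mk(c(.001, .01, .2)))
  expect_identical(got3$gwas_part, c(.001, .01, .2, 1, 1))
  expect_length(got3$selected_snps, 3)

  empty_map <- map_snps_to_genes(
    data.frame(variant_id = character(), chrom = character(),
               pos = numeric(), pvalue = numeric()), ann)
  got0 <- gwas_features("geneA", empty_map)
  expect_identical(got0$gwas_part, rep(1, 5))
  expect_identical(got0$n_mapped_snps, 0L)

  expect_error(gwas_features("nope", empty_map), "not present")

  # ties in p are broken by (position, variant_id): order-invariant
  tied <- data.frame(variant_id = c("rsB", "rsA"), chrom = "chr1",
                     pos = c(5, 5), pvalue = c(.1, .1))
  sel1 <- gwas_features("geneA", map_snps_to_genes(tied, ann))$selected_snps
  sel2 <- gwas_features("geneA",
                        map_snps_to_genes(tied[2:1, ], ann))$selected_snps
  expect_identical(sel1, sel2)
  expect_identical(sel1[1], "rsA")
})

test_that("eQTL part aligns to selected SNPs and pads missing lookups with 1", {
  eqtl <- data.frame(variant_id = sprintf("rs%d", 1:5), gene_id = "geneA",
                     pvalue = c(.01, .02, .03, .04, .05))
  sel <- sprintf("rs%d", 1:5)
  expect_equal(eqtl_features("geneA", sel, eqtl), c(.01, .02, .03, .04, .05))
  expect_identical(eqtl_features("geneA", sel, eqtl[0, ]), rep(1, 5))
  expect_identical(eqtl_features("geneA", character(0), eqtl), rep(1, 5))

  # record exists only for a different gene: pair mode pads, snp_any_gene uses it
  other <- data.frame(variant_id = "rs1", gene_id = "geneB", pvalue = .007)
  expect_identical(eqtl_features("geneA", "rs1", other,
                                 match_mode = "pair")[1], 1)
  expect_identical(eqtl_features("geneA", "rs1", other,
                                 match_mode = "snp_any_gene")[1], .007)

  # duplicate records for one pair contribute their minimum
  dup <- data.frame(variant_id = c("rs1", "rs1"), gene_id = "geneA",
                    pvalue = c(.5, .2))
  expect_identical(eqtl_features("geneA", "rs1", dup)[1], .2)
})

test_that("feature matrix admits only genes with mapped SNPs and is 10-dimensional", {
  ann <- data.frame(gene_id = sprintf("g%d", 1:6), symbol = sprintf("g%d", 1:6),
                    chrom = "chr1",
                    start = c(0, 100, 200, 300, 400, 500),
                    end = c(50, 150, 250, 350, 450, 550))
  gwas <- data.frame(variant_id = sprintf("rs%d", 1:8), chrom = "chr1",
                     pos = c(10, 20, 110, 210, 220, 230, 310, 410),
                     pvalue = (1:8) / 10)
  # g5 [400,450) has one SNP, g6 none; drop the g5 SNP too
  gwas <- gwas[gwas$pos != 410, ]
  fm <- build_feature_matrix(ann, gwas,
                             data.frame(variant_id = character(),
                                        gene_id = character(),
                                        pvalue = numeric()))
  expect_identical(nrow(fm), 4L)
  expect_setequal(attr(fm, "excluded"), c("g5", "g6"))
  expect_identical(names(fm)[2:11], c(paste0("P_p", 1:5), paste0("P_T", 1:5)))
  expect_error(
    build_feature_matrix(ann[6, ], gwas,
                         data.frame(variant_id = character(),
                                    gene_id = character(),
                                    pvalue = numeric())),
    "no gene has any mapped SNP")
})

test_that("feature matrix matches the brute-force oracle on a 200-gene fixture", {
  sim <- small_sim(seed = 41, n_genes = 200, n_causal = 50)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  ref <- brute_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  fcols <- c(paste0("P_p", 1:5), paste0("P_T", 1:5))
  expect_identical(fm$gene_id, ref$gene_id)
  expect_equal(unname(as.matrix(fm[, fcols])), ref$matrix)
})

test_that("extraction is invariant to input row order and monotone in new SNPs", {
  sim <- small_sim(seed = 43, n_genes = 50, n_causal = 10)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  set.seed(1)
  fm_perm <- build_feature_matrix(sim$annotation,
                                  sim$gwas[sample(nrow(sim$gwas)), ],
                                  sim$eqtl[sample(nrow(sim$eqtl)), ])
  expect_identical(fm, fm_perm)

  # adding a SNP smaller than the current max can only lower order statistics
  g <- fm$gene_id[1]
  row <- as.numeric(fm[1, paste0("P_p", 1:5)])
  ann_g <- sim$annotation[sim$annotation$gene_id == g, ]
  extra <- data.frame(variant_id = "rs_new", chrom = ann_g$chrom,
                      pos = ann_g$start, pvalue = max(row) / 2)
  fm2 <- build_feature_matrix(sim$annotation, rbind(sim$gwas, extra),
                              sim$eqtl)
  row2 <- as.numeric(fm2[fm2$gene_id == g, paste0("P_p", 1:5)])
  expect_true(all(row2 <= row))
})

test_that("the -log10 feature scale flips padding to 0", {
  sim <- small_sim(seed = 45, n_genes = 30, n_causal = 5,
                   snps_per_gene_range = c(0, 3))
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl,
                             scale = "neglog10")
  vals <- as.matrix(fm[, c(paste0("P_p", 1:5), paste0("P_T", 1:5))])
  expect_true(all(vals >= 0))
  short <- fm$n_mapped_snps < 5
  expect_true(any(short))
  expect_true(all(vals[cbind(which(short), 5)] == 0))
})
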