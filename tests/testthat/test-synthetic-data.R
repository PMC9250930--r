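test_that("the generator is fully deterministic under a fixed seed", {
  sc <- simulation_config(seed = 99, groups_per_subfamily = 5, n_snps = 30)
  a <- simulate_catalog(sc); b <- simulate_catalog(sc)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_identical(lapply(a$trees, ape::write.tree), lapply(b$trees, ape::write.tree))
  expect_identical(simulate_expression(a, sc)$expr, simulate_expression(b, sc)$expr)
  expect_identical(simulate_snps(a$genes, sc), simulate_snps(b$genes, sc))

  # a different seed gives different draws
  sc2 <- simulation_config(seed = 100, groups_per_subfamily = 5, n_snps = 30)
  expect_false(identical(simulate_catalog(sc2)$truth$category, a$truth$category))
})

test_that("forced compositions produce the promised group shapes", {
  one <- function(cat) simulation_config(
    seed = 3, subfamilies = "NPF1", groups_per_subfamily = 1,
    group_category_proportions =
      setNames(as.numeric(c("triad", "diad", "tetrad", "singleton") == cat),
               c("triad", "diad", "tetrad", "singleton")),
    un_singleton_fraction = 0)

  tri <- simulate_catalog(one("triad"))
  expect_equal(nrow(tri$genes), 3L)
  expect_setequal(tri$genes$subgenome, c("A", "B", "D"))
  expect_length(unique(tri$genes$chrom_group), 1L)
  expect_equal(sort(table(tri$genes$subgenome)), sort(table(c("A", "B", "D"))))

  tet <- simulate_catalog(one("tetrad"))
  expect_equal(nrow(tet$genes), 4L)
  cnt <- table(tet$genes$subgenome)
  expect_equal(sort(as.integer(cnt)), c(1L, 1L, 2L))
  # the duplicated copies are sister leaves and adjacent on the chromosome
  dup_sg <- names(cnt)[cnt == 2]
  dup <- tet$genes[tet$genes$subgenome == dup_sg, ]
  expect_lte(abs(dup$start[2] - dup$end[1]), 1e5 + 1)
  tr <- tet$trees[[1]]
  mrca <- ape::getMRCA(tr, dup$gene_id)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, dup$gene_id)
})

test_that("category frequencies follow the configured proportions", {
  sc <- simulation_config(seed = 1, subfamilies = "NPF5",
                          groups_per_subfamily = 200)
  sim <- simulate_catalog(sc)
  freq <- table(sim$truth$category[!duplicated(sim$truth$group)]) / 200
  p <- sc$group_category_proportions
  for (cat in names(p)) {
    f <- if (cat %in% names(freq)) freq[[cat]] else 0
    expect_lt(abs(f - p[[cat]]), 0.05)
  }
})

test_that("expression noise has the documented limits", {
  cen <- bias_centroids()
  # infinite concentration puts fractions exactly at the centroid
  expect_equal(triadkit:::rdirichlet_centroid(cen["Balanced", ], Inf),
               c(f_A = 1/3, f_B = 1/3, f_D = 1/3))
  # zero-noise dominant category: the other two homoeolog TPMs are exactly 0
  sc <- simulation_config(seed = 21, subfamilies = "NPF1", groups_per_subfamily = 4,
                          group_category_proportions = c(triad = 1, diad = 0,
                                                         tetrad = 0, singleton = 0),
                          bias_category_proportions = c(Balanced = 0, A_dominant = 1,
                                                        B_dominant = 0, D_dominant = 0,
                                                        A_suppressed = 0, B_suppressed = 0,
                                                        D_suppressed = 0),
                          specificity_proportions = c(ubiquitous = 1, root_specific = 0,
                                                      leaf_shoot_specific = 0,
                                                      spike_grain_specific = 0,
                                                      not_expressed = 0),
                          concentration = Inf)
  sim <- simulate_catalog(sc)
  ex <- simulate_expression(sim, sc)
  b_or_d <- ex$expr[grepl("\\.(B|D)1$", ex$expr$gene_id), ]
  expect_true(all(b_or_d$tpm == 0))
  a_only <- ex$expr[grepl("\\.A1$", ex$expr$gene_id), ]
  expect_true(all(a_only$tpm > 0))
})

test_that("planted bias categories are recovered through the classifier", {
  # moderately concentrated noise: recovery must reach 95%
  sc <- simulation_config(seed = 7, subfamilies = "NPF5", groups_per_subfamily = 125,
                          group_category_proportions = c(triad = 1, diad = 0,
                                                         tetrad = 0, singleton = 0),
                          specificity_proportions = c(ubiquitous = 1, root_specific = 0,
                                                      leaf_shoot_specific = 0,
                                                      spike_grain_specific = 0,
                                                      not_expressed = 0),
                          concentration = 200)
  sim <- simulate_catalog(sc)
  ex <- simulate_expression(sim, sc)
  truth <- ex$truth_bias  # 125 triads x 4 tissues = 500 planted draws
  expect_equal(nrow(truth), 500L)

  grp <- assign_group_ids(infer_homoeolog_groups(sim$trees[[1]], sim$genes))
  prof <- triad_expression_profiles(ex$expr, grp)
  first_gene <- tapply(sim$truth$gene_id, sim$truth$group, min)
  lookup <- setNames(grp$group_id,
                     vapply(grp$members, function(m) m$gene_id[1], ""))
  truth$group_id <- unname(lookup[first_gene[truth$group]])
  m <- merge(as.data.frame(prof), truth, by = c("group_id", "tissue"))
  expect_equal(nrow(m), 500L)
  rate <- mean(as.character(m$category.x) == m$category.y)
  expect_gte(rate, 0.95)
})

test_that("simulated SNP offsets reproduce the planted megabase distances", {
  gm <- quick_genes("g1", "1A", start = 12918698)
  sc <- simulation_config(seed = 4, n_snps = 0)
  # planting an offset of 1,601,059 bp must record 1.601059 Mb
  snp <- snp_markers("m", "1A", 12918698 + 1601059)
  expect_equal(distance_mb(snp$position, gm$start), 1.601059)

  sn <- simulate_snps(quick_genes(c("a", "b"), c("2A", "5D")),
                      simulation_config(seed = 12, n_snps = 40,
                                        snp_window_mix = 0.25))
  planted <- sn$truth[!is.na(sn$truth$gene_id), ]
  expect_equal(nrow(planted), 10L)
  expect_true(all(planted$distance_mb <= 15))
})
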