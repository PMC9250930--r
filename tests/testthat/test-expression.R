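triad_groups_for <- function(n, prefix = "tr") {
  specs <- lapply(seq_len(n), function(i) {
    data.frame(gene_id = paste0(prefix, i, c("A", "B", "D")),
               subgenome = c("A", "B", "D"), chrom_group = "1",
               start = i * 1000, stringsAsFactors = FALSE)
  })
  g <- triadkit:::new_homoeolog_groups(specs, "NPF1")
  assign_group_ids(g)
}

expr_for_triads <- function(tpm, tissue = "root", prefix = "tr") {
  # tpm: matrix n x 3 (A, B, D)
  n <- nrow(tpm)
  data.frame(gene_id = c(t(outer(seq_len(n), c("A", "B", "D"),
                                 function(i, s) paste0(prefix, i, s)))),
             tissue = tissue, stage = "seedling", cultivar = "CS",
             tpm = c(t(tpm)), stringsAsFactors = FALSE)
}

test_that("triad filtering applies the 1-TPM threshold to the tissue sum", {
  g <- triad_groups_for(3)
  tpm <- rbind(c(0.2, 0.3, 0.4),   # sum 0.9 -> excluded
               c(1, 0, 0),          # sum at threshold -> retained
               c(5, 4, 1))
  flt <- filter_triads(expr_for_triads(tpm), g)
  root <- flt[flt$tissue == "root", ]
  expect_equal(root$retained[match(paste0("TaNPF1-T", 1:3), root$group_id)],
               c(FALSE, TRUE, TRUE))

  # per-homoeolog variant: every member must pass individually
  flt2 <- filter_triads(expr_for_triads(tpm), g, per_homoeolog = TRUE)
  root2 <- flt2[flt2$tissue == "root", ]
  expect_equal(root2$retained[match(paste0("TaNPF1-T", 1:3), root2$group_id)],
               c(FALSE, FALSE, TRUE))

  # members without any record count as zero, with a note
  expect_message(
    flt3 <- filter_triads(expr_for_triads(tpm)[-1, ], g),
    "tr1A")
  expect_equal(flt3$tpm_A[flt3$group_id == "TaNPF1-T1" & flt3$tissue == "root"], 0)
})

test_that("normalization is exact arithmetic and rejects all-zero triads", {
  expect_equal(normalize_triad(10, 10, 10), data.frame(f_A = 1/3, f_B = 1/3, f_D = 1/3))
  expect_equal(normalize_triad(3, 0, 0), data.frame(f_A = 1, f_B = 0, f_D = 0))
  expect_equal(normalize_triad(5, 4, 1), data.frame(f_A = 0.5, f_B = 0.4, f_D = 0.1))
  expect_error(normalize_triad(0, 0, 0), "filter")
})

test_that("classification is nearest-centroid with the documented tie order", {
  cen <- bias_centroids()
  expect_equal(unname(rowSums(cen)), rep(1, 7))

  cl <- classify_triad(1/3, 1/3, 1/3)
  expect_equal(as.character(cl$category), "Balanced")
  expect_equal(cl$dist_Balanced, 0)

  cl2 <- classify_triad(1, 0, 0)
  expect_equal(as.character(cl2$category), "A_dominant")
  expect_equal(cl2$dist_A_dominant, 0)

  # brute-force check of the (0.5, 0.4, 0.1) example against all 7 distances
  f <- c(0.5, 0.4, 0.1)
  d_all <- apply(cen, 1, function(m) sqrt(sum((f - m)^2)))
  expect_equal(names(which.min(d_all)), "D_suppressed")
  expect_equal(as.character(classify_triad(0.5, 0.4, 0.1)$category), "D_suppressed")
})

test_that("classification is scale-invariant and permutation-equivariant", {
  set.seed(501)
  for (i in 1:50) {
    v <- stats::rgamma(3, 1) + 1e-6
    c0 <- as.character(classify_triad(v[1]/sum(v), v[2]/sum(v), v[3]/sum(v))$category)
    for (scale in c(0.01, 7, 1e4)) {
      w <- v * scale
      f <- normalize_triad(w[1], w[2], w[3])
      expect_equal(as.character(classify_triad(f$f_A, f$f_B, f$f_D)$category), c0)
    }
    # swapping A and B swaps the category's A/B role
    f <- v / sum(v)
    swapped <- as.character(classify_triad(f[2], f[1], f[3])$category)
    expect_equal(swapped, swap_bias_letter(c0, "A", "B"))
  }
})

test_that("per-tissue summaries report rounded percentages that sum to 100", {
  g <- triad_groups_for(54)
  cats <- rep(c("Balanced", "A_suppressed", "D_suppressed", "B_suppressed",
                "A_dominant", "B_dominant", "D_dominant"),
              c(30, 10, 6, 5, 1, 1, 1))
  cen <- bias_centroids()
  prof <- triad_expression_profiles(expr_for_triads(10 * cen[cats, ]), g)
  expect_equal(nrow(prof), 54L)
  expect_equal(as.character(prof$category), cats)

  s <- summarize_by_tissue(prof)
  expect_equal(s$n, 54L)
  expect_equal(s$Balanced, round(100 * 30 / 54, 1))  # the 55.6% arithmetic
  expect_equal(s$Balanced, 55.6)
  pc <- unlist(s[setdiff(names(s), c("tissue", "n"))])
  expect_lt(abs(sum(pc) - 100), 0.3)

  # conservation: category counts sum to retained triads
  expect_equal(sum(table(prof$category)), nrow(prof))

  one <- summarize_by_tissue(triad_expression_profiles(
    expr_for_triads(matrix(rep(c(3, 3, 3), 5), 5, byrow = TRUE)), triad_groups_for(5)))
  expect_equal(one$Balanced, 100)
})

test_that("tissue-specificity calls follow the threshold definition", {
  expr <- data.frame(
    gene_id = c("r", "r", "u", "u", "n"),
    tissue = c("root", "leaf_shoot", "root", "grain", "spike"),
    stage = "seedling", cultivar = "CS",
    tpm = c(5, 0.2, 2, 1.5, 0.4), stringsAsFactors = FALSE)
  calls <- call_tissue_specificity(expr)
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(unname(cls["r"]), "root_specific")
  expect_equal(unname(cls["u"]), "ubiquitous")
  expect_equal(unname(cls["n"]), "not_expressed")

  expect_warning(call_tissue_specificity(expr, gene_ids = c("r", "ghost")),
                 "ghost")
})

test_that("planted sub-threshold triads are excluded and bias recovered at zero noise", {
  sc <- simulation_config(seed = 1200, subfamilies = "NPF1",
                          groups_per_subfamily = 40,
                          group_category_proportions = c(triad = 1, diad = 0,
                                                         tetrad = 0, singleton = 0),
                          concentration = Inf)
  sim <- simulate_catalog(sc)
  ex <- simulate_expression(sim, sc)
  grp <- assign_group_ids(infer_homoeolog_groups(sim$trees[[1]], sim$genes))

  flt <- filter_triads(ex$expr, grp)
  prof <- triad_expression_profiles(ex$expr, grp)

  # map planted group labels to assigned group_ids via any member gene
  gid_of <- function(members) vapply(members, function(m) m$gene_id[1], "")
  lookup <- setNames(grp$group_id, gid_of(grp$members))
  truth <- ex$truth_bias
  first_gene <- tapply(sim$truth$gene_id, sim$truth$group, min)
  truth$group_id <- unname(lookup[first_gene[truth$group]])

  # every expressed (triad, tissue) classified exactly as planted
  m <- merge(as.data.frame(prof), truth, by = c("group_id", "tissue"))
  expect_gt(nrow(m), 0)
  expect_equal(as.character(m$category.x), m$category.y)

  # planted unexpressed (triad, tissue) pairs are exactly the excluded ones
  not_exp <- flt[!flt$retained, c("group_id", "tissue")]
  planted_on <- paste(truth$group_id, truth$tissue)
  expect_true(all(!(paste(not_exp$group_id, not_exp$tissue) %in% planted_on)))
  expect_equal(nrow(flt), nrow(not_exp) + nrow(prof))
})

test_that("planted tissue-specific genes are recovered exactly", {
  sc <- simulation_config(seed = 88, subfamilies = c("NPF5", "CLC"),
                          groups_per_subfamily = 15,
                          bias_category_proportions = c(Balanced = 1,
                                                        A_dominant = 0, B_dominant = 0,
                                                        D_dominant = 0, A_suppressed = 0,
                                                        B_suppressed = 0, D_suppressed = 0),
                          concentration = Inf)
  sim <- simulate_catalog(sc)
  ex <- simulate_expression(sim, sc)
  calls <- call_tissue_specificity(ex$expr)
  truth <- ex$truth_specificity
  got <- setNames(calls$class, calls$gene_id)[truth$gene_id]
  want <- sub("^(ubiquitous|not_expressed)$", "\\1", truth$class)
  expect_equal(unname(got), unname(want))
})
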