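test_that("GFF3 gene models map fields, exons and the Un sentinel", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "3A\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1;family=NPF;subfamily=NPF5",
    "3A\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1",
    "3A\tsrc\texon\t300\t500\t.\t+\t.\tParent=g1",
    "Un\tsrc\tgene\t10\t90\t.\t-\t.\tID=g2"
  ), gff)
  gm <- read_gene_models(gff)
  expect_s3_class(gm, "gene_models")
  expect_equal(nrow(gm), 2L)
  g1 <- gm[gm$gene_id == "g1", ]
  expect_equal(g1$chrom_group, "3")
  expect_equal(g1$subgenome, "A")
  expect_equal(nrow(g1$exons[[1]]), 2L)
  expect_equal(g1$subfamily, "NPF5")
  g2 <- gm[gm$gene_id == "g2", ]
  expect_equal(g2$subgenome, "Un")
  expect_equal(g2$chrom_group, "Un")
})

test_that("malformed coordinates fail with a line number; bad chromosomes skip", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "3A\tsrc\tgene\t500\t100\t.\t+\t.\tID=bad"
  ), gff)
  expect_error(read_gene_models(gff), "line 2")

  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "3A\tsrc\tgene\t100\t500\t.\t+\t.\tID=ok",
    "chr9Z\tsrc\tgene\t100\t500\t.\t+\t.\tID=odd"
  ), gff2)
  expect_warning(gm <- read_gene_models(gff2), "chr9Z")
  expect_equal(gm$gene_id, "ok")
})

test_that("gene models round-trip through GFF3 field-for-field", {
  set.seed(11)
  n <- 50
  chrom <- sample(c(paste0(rep(1:7, 2), c("A", "B", "D")), "Un"), n, replace = TRUE)
  start <- sort(sample(1e6:2e6, n))
  gm <- quick_genes(sprintf("g%02d", 1:n), chrom, start,
                    subfamily = "NPF5", n_exons = sample(1:4, n, replace = TRUE))
  path <- tempfile(fileext = ".gff3")
  write_gene_models(gm, path)
  back <- read_gene_models(path)
  back <- back[match(gm$gene_id, back$gene_id), ]
  for (col in c("gene_id", "chrom", "chrom_group", "subgenome", "start", "end",
                "strand", "family", "subfamily")) {
    expect_equal(unname(back[[col]]), unname(gm[[col]]), label = col)
  }
  for (i in seq_len(n)) {
    expect_equal(unname(back$exons[[i]]), unname(gm$exons[[i]]))
  }
})

test_that("expression and SNP tables validate their invariants", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttissue\tstage\tcultivar\ttpm",
               "g1\troot\tseedling\tCS\t5.0"), f)
  x <- read_expression_table(f)
  expect_equal(nrow(x), 1L)
  expect_equal(x$tpm, 5)

  writeLines(c("gene_id\ttissue\tstage\tcultivar\ttpm",
               "g1\troot\tseedling\tCS\t5.0",
               "g2\troot\tseedling\tCS\t-1"), f)
  expect_error(read_expression_table(f), "row.*3|g2")

  writeLines(c("gene_id\ttissue\tstage\tcultivar\ttpm",
               "g1\troot\tseedling\tCS\t5.0",
               "g1\troot\tseedling\tCS\t6.0"), f)
  expect_error(read_expression_table(f), "duplicated")

  s <- tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchromosome\tposition", "m1\t3B\t1234567"), s)
  snp <- read_snp_table(s)
  expect_equal(snp$chrom_group, "3")
  expect_equal(snp$subgenome, "B")
  write_snp_table(snp, s)
  expect_equal(read_snp_table(s), snp)
})

test_that("newick reading reconciles leaf labels against gene models", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((a,b),c);", f)
  tr <- read_trees(f)
  expect_length(tr, 1L)
  expect_length(tr[[1]]$tip.label, 3L)

  gm <- quick_genes(c("a", "b"), c("1A", "1B"))
  tr2 <- read_trees(f, gm)
  expect_equal(attr(tr2, "unmatched"), "c")
})

test_that("the packaged grouping catalogue matches its published totals", {
  ref <- read_reference_grouping()
  tab <- reference_gene_table(ref)
  expect_equal(length(unique(tab$name)), 412L)
  fam <- table(tab$family)
  expect_equal(as.integer(fam[c("NPF", "CLC", "SLAC", "NRT2")]),
               c(292L, 34L, 40L, 46L))

  r1 <- ref[ref$group_id == "TaNPF1-T1", ]
  expect_equal(r1$refseq_A, "TraesCS3A02G304400")
  expect_equal(r1$refseq_B, "TraesCS3B02G332100")
  expect_equal(r1$refseq_D, "TraesCS3D02G297600")
  expect_equal(c(r1$name_A, r1$name_B, r1$name_D),
               c("TaNPF1-3A1", "TaNPF1-3B1", "TaNPF1-3D1"))

  tt <- ref[ref$group_id == "TaNRT2-TT1", ]
  expect_equal(strsplit(tt$refseq_D, ";")[[1]],
               c("TraesCS6D02G038100", "TraesCS6D02G038000"))
  expect_equal(strsplit(tt$name_D, ";")[[1]],
               c("TaNRT2-6D11x", "TaNRT2-6D11y"))

  # re-parse is byte-stable
  expect_identical(ref, read_reference_grouping())
})

test_that("the packaged proximity panel parses one row per published SNP", {
  ref <- read_reference_proximity()
  expect_equal(nrow(ref), length(unique(ref$marker_id)))
  r <- ref[ref$marker_id == "AX94950355", ]
  expect_equal(r$chrom, "1A")
  expect_equal(r$position, 12918698)
  expect_equal(r$genes, "TaNPF6-1A1")
  expect_equal(r$gene_positions, "14519757")
  expect_equal(r$distances, "1.601059")

  r2 <- ref[ref$marker_id == "AX94561045", ]
  expect_equal(strsplit(r2$genes, ";")[[1]],
               c("TaNPF5-3B3-TaNPF5-3B10", "TaCLC-3B3"))
  expect_equal(r2$distances, "8.944145;12.954288")

  expect_identical(ref, read_reference_proximity())
})
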