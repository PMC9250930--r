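# Shared fixture builders; everything is generated in code.

# quick gene_models builder: chrom + start vectors, 10 kb genes
quick_genes <- function(ids, chrom, start = NULL, subfamily = NA, family = NA,
                        n_exons = 1L) {
  if (is.null(start)) start <- seq(1e6, by = 1e6, length.out = length(ids))
  end <- start + 9999
  exons <- Map(function(s, e, n) {
    if (n == 1) return(cbind(start = s, end = e))
    b <- round(seq(s, e, length.out = 2 * n))
    cbind(start = b[seq(1, 2 * n, 2)], end = b[seq(2, 2 * n, 2)])
  }, start, end, rep_len(n_exons, length(ids)))
  if (all(is.na(family)) && !all(is.na(subfamily))) {
    family <- family_of_subfamily(rep_len(subfamily, length(ids)))
  }
  gene_models(ids, chrom, start, end, exons = exons,
              family = family, subfamily = subfamily)
}

tree_of <- function(newick) ape::read.tree(text = newick)

# reference-derived gene models for one subfamily: chromosome comes from the
# RefSeq ID, start from its G-number (preserves positional order)
reference_subfamily_genes <- function(subfamily, ref = read_reference_grouping()) {
  tab <- reference_gene_table(ref)
  tab <- tab[tab$subfamily == subfamily, , drop = FALSE]
  chrom <- ifelse(grepl("^TraesCSU", tab$refseq_id), "Un",
                  substr(tab$refseq_id, 8, 9))
  start <- as.numeric(sub("^.*G(\\d+)$", "\\1", tab$refseq_id)) * 100
  list(genes = quick_genes(tab$refseq_id, chrom, start, subfamily = subfamily),
       tab = tab)
}

# newick in which every reference group is a clade (duplicated copies sisters)
reference_subfamily_tree <- function(subfamily, ref = read_reference_grouping()) {
  tab <- reference_gene_table(ref)
  tab <- tab[tab$subfamily == subfamily, , drop = FALSE]
  clades <- vapply(split(tab, tab$group_id), function(g) {
    by_sg <- split(g$refseq_id, g$subgenome)
    units <- vapply(by_sg, function(x)
      if (length(x) > 1) paste0("(", paste(x, collapse = ","), ")") else x, "")
    if (length(units) == 1) unname(units)
    else paste0("(", Reduce(function(a, b) paste0("(", a, ",", b, ")"),
                            unname(units)), ")")
  }, "")
  nwk <- paste0(Reduce(function(a, b) paste0("(", a, ",", b, ")"), clades), ";")
  tree_of(nwk)
}

# independent brute-force oracle: over all subsets of pairwise-disjoint valid
# clades, the maximum number of genes placed into multi-gene groups
oracle_max_grouped <- function(tree, genes) {
  gi <- match(tree$tip.label, genes$gene_id)
  sub <- genes$subgenome[gi]
  cg <- genes$chrom_group[gi]
  nt <- length(tree$tip.label)
  # clade tip sets by brute-force: all internal nodes via ape
  sets <- lapply(seq_len(tree$Nnode) + nt, function(nd) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    match(tips, tree$tip.label)
  })
  keys <- c(vapply(sets, function(t) paste(sort(t), collapse = ","), ""),
            vapply(seq_len(nt), function(i) as.character(i), ""))
  valid <- Filter(function(t) {
    n <- length(t)
    if (n < 2 || n > 4 || any(sub[t] == "Un")) return(FALSE)
    if (length(unique(cg[t])) != 1) return(FALSE)
    cnt <- table(factor(sub[t], levels = c("A", "B", "D")))
    if (n <= 3) return(all(cnt <= 1))
    if (!(sum(cnt == 2) == 1 && max(cnt) == 2)) return(FALSE)
    dup <- t[sub[t] == names(cnt)[cnt == 2]]
    paste(sort(dup), collapse = ",") %in% keys   # duplicated copies are sisters
  }, sets)
  best <- 0L
  recurse <- function(idx, used, total) {
    best <<- max(best, total)
    if (!length(idx)) return()
    for (j in seq_along(idx)) {
      t <- valid[[idx[j]]]
      if (!any(t %in% used)) {
        recurse(idx[-seq_len(j)], c(used, t), total + length(t))
      }
    }
  }
  recurse(seq_along(valid), integer(0), 0L)
  best
}

# swap the subgenome role letter in a bias category label ("Balanced" is fixed)
swap_bias_letter <- function(cat, x, y) {
  ifelse(cat == "Balanced", cat,
         paste0(chartr(paste0(x, y), paste0(y, x), substr(cat, 1, 1)),
                substring(cat, 2)))
}
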