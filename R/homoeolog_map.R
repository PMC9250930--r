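SUBGENOMES <- c("A", "B", "D")

new_homoeolog_groups <- function(members, subfamily, conflicts = character()) {
  # members: list of data.frames (gene_id, subgenome, chrom_group, start)
  category <- vapply(members, function(m) {
    cnt <- table(factor(m$subgenome[m$subgenome != "Un"], levels = SUBGENOMES))
    n <- nrow(m)
    if (n == 1) "singleton"
    else if (n == 4 && sum(cnt == 2) == 1) "tetrad"
    else if (n == 3 && all(cnt <= 1)) "triad"
    else if (n == 2 && all(cnt <= 1)) "diad"
    else stop("invalid member composition: ", paste(m$subgenome, collapse = ","))
  }, "")
  chrom_group <- vapply(members, function(m) {
    cg <- unique(m$chrom_group[m$subgenome != "Un"])
    if (length(cg) > 1) stop("members span chromosome groups: ", paste(cg, collapse = ","))
    if (length(cg) == 0) "Un" else cg
  }, "")
  out <- data.frame(
    subfamily = rep_len(subfamily, length(members)),
    family = family_of_subfamily(rep_len(subfamily, length(members))),
    chrom_group = chrom_group,
    category = category,
    n_members = vapply(members, nrow, 0L),
    stringsAsFactors = FALSE
  )
  out$composition <- vapply(members, composition_code, "")
  out$members <- members
  attr(out, "conflicts") <- conflicts
  class(out) <- c("homoeolog_groups", "data.frame")
  out
}

#' @export
print.homoeolog_groups <- function(x, ...) {
  cat("homoeolog_groups: ", nrow(x), " group(s), ", sum(x$n_members),
      " gene(s)\n", sep = "")
  print(table(x$category))
  invisible(x)
}

#' A:B:D composition code of a homoeolog group
#'
#' Counts of members per subgenome in fixed A, B, D order (e.g. a triad is
#' `"1:1:1"`, a tetrad with a duplicated D copy `"1:1:2"`). Members on
#' unplaced scaffolds are not part of the code; they are reported via the
#' `n_un` attribute-free convention of [tabulate_groups()].
#'
#' @param members either one row of a `homoeolog_groups` table's `members`
#'   list-column (a data.frame with a `subgenome` column) or a character
#'   vector of subgenome letters.
#' @return character scalar `"a:b:d"`.
#' @examples
#' composition_code(c("A", "B", "D"))
#' composition_code(c("A", "B", "D", "D"))
#' @export
composition_code <- function(members) {
  sg <- if (is.data.frame(members)) members$subgenome else as.character(members)
  cnt <- table(factor(sg[sg != "Un"], levels = SUBGENOMES))
  paste(as.integer(cnt), collapse = ":")
}

clade_tips <- function(tree) {
  # tip index sets for every internal node, by postorder accumulation
  nt <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(nt + 1):(nt + tree$Nnode)]
}

valid_group_leafset <- function(sub, cg) {
  # sub, cg: subgenome and chromosome group of each leaf in the clade
  n <- length(sub)
  if (n < 2 || n > 4) return(FALSE)
  if (any(sub == "Un")) return(FALSE)
  if (length(unique(cg)) != 1) return(NA)  # NA marks a chromosome-group conflict
  cnt <- table(factor(sub, levels = SUBGENOMES))
  if (n <= 3) all(cnt <= 1) else sum(cnt == 2) == 1 && max(cnt) == 2
}

#' Infer homoeolog groups from a subfamily gene tree
#'
#' Greedy extraction of minimal clades that look like homoeolog groups:
#' 2-4 leaves, at most one leaf per subgenome (two allowed only in the
#' four-leaf, tetrad case, and then only when the two copies are sister
#' leaves — tetrads model tandem duplication), all members on the same
#' chromosome group.
#' Overlapping candidate clades are resolved deterministically: prefer the
#' clade covering more distinct subgenomes, then the smaller clade, then the
#' lexicographically smallest member ID. Leaves left over become singletons;
#' genes on unplaced scaffolds ("Un") are always singletons. Bootstrap
#' support values, if present, are ignored.
#'
#' @param tree a `phylo` gene tree whose tip labels are gene IDs.
#' @param genes a [gene_models()] table covering (at least) the tree leaves,
#'   all from one subfamily.
#' @return A `homoeolog_groups` table (one row per group, with a `members`
#'   list-column). Clades rejected only because their members span
#'   chromosome groups are logged in the `"conflicts"` attribute.
#' @export
infer_homoeolog_groups <- function(tree, genes) {
  stopifnot(inherits(tree, "phylo"), inherits(genes, "gene_models"))
  missing <- setdiff(tree$tip.label, genes$gene_id)
  if (length(missing)) {
    stop("tree leaf label(s) without a gene model: ",
         paste(missing, collapse = ", "))
  }
  gi <- match(tree$tip.label, genes$gene_id)
  subf <- unique(genes$subfamily[gi])
  subf <- subf[!is.na(subf)]
  if (length(subf) > 1) {
    stop("tree mixes subfamilies: ", paste(subf, collapse = ", "))
  }
  if (length(subf) == 0) subf <- NA_character_
  sub <- genes$subgenome[gi]
  cg <- genes$chrom_group[gi]

  member_df <- function(tips) {
    idx <- gi[tips]
    m <- data.frame(gene_id = genes$gene_id[idx], subgenome = genes$subgenome[idx],
                    chrom_group = genes$chrom_group[idx], start = genes$start[idx],
                    stringsAsFactors = FALSE)
    m[order(m$gene_id), , drop = FALSE]
  }

  conflicts <- character()
  cand <- list()
  if (length(tree$tip.label) > 1) {
    all_clades <- clade_tips(tree)
    clade_keys <- vapply(all_clades, function(t) paste(sort(t), collapse = ","), "")
    is_cherry <- function(pair) paste(sort(pair), collapse = ",") %in% clade_keys
    for (tips in all_clades) {
      v <- valid_group_leafset(sub[tips], cg[tips])
      if (is.na(v)) {
        conflicts <- c(conflicts, paste(sort(tree$tip.label[tips]), collapse = "+"))
      } else if (v) {
        if (length(tips) == 4) {
          # tetrads model tandem duplication: the two same-subgenome copies
          # must be sister leaves
          cnt <- table(sub[tips])
          dup <- tips[sub[tips] == names(cnt)[cnt == 2]]
          if (!is_cherry(dup)) next
        }
        cand[[length(cand) + 1L]] <- tips
      }
    }
  }

  chosen <- list()
  while (length(cand)) {
    n_sub <- vapply(cand, function(t) length(unique(sub[t])), 0L)
    size <- lengths(cand)
    min_id <- vapply(cand, function(t) min(tree$tip.label[t]), "")
    best <- order(-n_sub, size, min_id)[1]
    pick <- cand[[best]]
    chosen[[length(chosen) + 1L]] <- pick
    cand <- cand[!vapply(cand, function(t) any(t %in% pick), TRUE)]
  }

  left <- setdiff(seq_along(tree$tip.label), unlist(chosen))
  members <- c(lapply(chosen, member_df), lapply(left, member_df))
  # canonical group order, independent of input leaf order
  ord <- order(vapply(members, function(m) m$gene_id[1], ""))
  new_homoeolog_groups(members[ord], subf, conflicts = sort(conflicts))
}

#' Build homoeolog groups from the packaged reference catalogue
#'
#' Converts the curated grouping table (see [read_reference_grouping()]) into
#' a `homoeolog_groups` object, keeping the published category labels.
#'
#' @param ref output of [read_reference_grouping()].
#' @param use_names use assigned gene names (`TRUE`) or RefSeq IDs (`FALSE`)
#'   as member `gene_id`s.
#' @return A `homoeolog_groups` table with an extra `group_id` column.
#' @export
groups_from_reference <- function(ref = read_reference_grouping(),
                                  use_names = FALSE) {
  tab <- reference_gene_table(ref)
  tab$chrom_group <- ifelse(tab$subgenome == "Un", "Un",
                            sub("^Ta[A-Za-z0-9]+-([1-7Un]+).*$", "\\1", tab$name))
  members <- lapply(split(tab, factor(tab$group_id, levels = ref$group_id)),
                    function(m) {
      data.frame(gene_id = if (use_names) m$name else m$refseq_id,
                 subgenome = m$subgenome,
                 chrom_group = m$chrom_group,
                 start = NA_real_, stringsAsFactors = FALSE)
    })
  category <- ref$category
  chrom_group <- vapply(members, function(m) {
    cg <- unique(m$chrom_group[m$subgenome != "Un"])
    if (length(cg) == 0) "Un" else if (length(cg) == 1) cg else paste(cg, collapse = "/")
  }, "")
  out <- data.frame(subfamily = ref$subfamily,
                    family = family_of_subfamily(ref$subfamily),
                    chrom_group = chrom_group,
                    category = category,
                    n_members = vapply(members, nrow, 0L),
                    stringsAsFactors = FALSE)
  out$composition <- vapply(members, composition_code, "")
  out$members <- unname(members)
  out$group_id <- ref$group_id
  class(out) <- c("homoeolog_groups", "data.frame")
  out
}

#' Tabulate homoeolog groups by family and composition
#'
#' Produces the per-family counts of triads, diads (by missing subgenome),
#' tetrads (by duplicated subgenome) and singletons, plus overall totals.
#' The member counts over all groups sum to the catalogue size.
#'
#' @param groups a `homoeolog_groups` table (possibly several subfamilies
#'   concatenated via `rbind`).
#' @return list with `by_family` (family x category counts), `by_composition`
#'   (family x composition counts), `category_totals`, `n_genes`, and
#'   `triad_gene_fraction` (per family, fraction of genes in 1:1:1 triads).
#' @export
tabulate_groups <- function(groups) {
  stopifnot(inherits(groups, "homoeolog_groups"))
  fam <- groups$family
  by_family <- as.data.frame.matrix(table(fam, factor(groups$category,
    levels = c("triad", "diad", "tetrad", "singleton"))))
  by_comp <- as.data.frame.matrix(table(fam, groups$composition))
  cat_tot <- table(factor(groups$category,
                          levels = c("triad", "diad", "tetrad", "singleton")))
  genes_per_fam <- tapply(groups$n_members, fam, sum)
  triad_genes <- tapply(ifelse(groups$category == "triad", groups$n_members, 0L),
                        fam, sum)
  list(by_family = by_family,
       by_composition = by_comp,
       category_totals = cat_tot,
       n_genes = sum(groups$n_members),
       triad_gene_fraction = triad_genes / genes_per_fam)
}

#' Export an ideogram track of grouped genes
#'
#' Plain TSV (chromosome, position, label) usable by external
#' chromosome-plotting tools.
#'
#' @param groups a `homoeolog_groups` table.
#' @param path output TSV path.
#' @export
write_ideogram_track <- function(groups, path) {
  mem <- do.call(rbind, groups$members)
  chrom <- ifelse(mem$subgenome == "Un", "Un", paste0(mem$chrom_group, mem$subgenome))
  out <- data.frame(chromosome = chrom, position = mem$start, label = mem$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
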