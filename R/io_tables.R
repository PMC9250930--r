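TISSUES <- c("root", "leaf_shoot", "spike", "grain")
STAGES <- c("seedling", "vegetative", "reproductive")

#' Read an expression table
#'
#' Tab-separated with header `gene_id, tissue, stage, cultivar, tpm`;
#' TPM values are stored on the linear scale (any log transform is applied
#' only when exporting matrices for plotting).
#'
#' @param path TSV file path.
#' @return data.frame of expression records, one per
#'   (gene, tissue, stage, cultivar).
#' @export
read_expression_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "tissue", "stage", "cultivar", "tpm")
  if (!all(need %in% names(x))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  x <- x[need]
  validate_expression(x)
}

validate_expression <- function(x) {
  bad <- which(!is.finite(x$tpm) | x$tpm < 0)
  if (length(bad)) {
    stop("negative or non-finite tpm at row(s) ", paste(bad, collapse = ", "),
         " (gene ", paste(unique(x$gene_id[bad]), collapse = ", "), ")")
  }
  key <- paste(x$gene_id, x$tissue, x$stage, x$cultivar)
  if (anyDuplicated(key)) {
    stop("duplicated (gene_id, tissue, stage, cultivar) record(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  bad_t <- setdiff(unique(x$tissue), TISSUES)
  if (length(bad_t)) stop("unknown tissue token(s): ", paste(bad_t, collapse = ", "))
  x
}

#' @rdname read_expression_table
#' @param expr data.frame of expression records.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP marker table
#'
#' Tab-separated with header `marker_id, chromosome, position` (1-based).
#'
#' @param path TSV file path.
#' @return data.frame with columns `marker_id`, `chrom`, `chrom_group`,
#'   `subgenome`, `position`.
#' @export
read_snp_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(x))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  snp_markers(x$marker_id, x$chromosome, x$position)
}

#' @rdname read_snp_table
#' @param marker_id,chromosome,position marker fields.
#' @export
snp_markers <- function(marker_id, chromosome, position) {
  ct <- parse_chrom_token(chromosome)
  if (anyNA(ct$chrom_group)) {
    stop("invalid chromosome token(s): ",
         paste(unique(chromosome[is.na(ct$chrom_group)]), collapse = ", "))
  }
  position <- as.numeric(position)
  if (any(!is.finite(position) | position < 1)) stop("SNP positions must be >= 1")
  data.frame(marker_id = as.character(marker_id), chrom = ct$chrom,
             chrom_group = ct$chrom_group, subgenome = ct$subgenome,
             position = position, stringsAsFactors = FALSE)
}

#' @rdname read_snp_table
#' @param snps SNP marker data.frame.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.frame(marker_id = snps$marker_id, chromosome = snps$chrom,
                    position = format(snps$position, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene trees from a Newick file
#'
#' One or more trees per file (one tree per subfamily). Leaf labels are
#' expected to match gene IDs; labels with no corresponding gene model are
#' reported in the `unmatched` attribute rather than failing.
#'
#' @param path Newick file.
#' @param genes optional `gene_models` table to reconcile leaf labels against.
#' @return A list of `phylo` objects; attribute `unmatched` lists leaf labels
#'   absent from `genes` (when `genes` is given).
#' @export
read_trees <- function(path, genes = NULL) {
  tr <- ape::read.tree(path)
  trees <- if (inherits(tr, "multiPhylo")) unclass(tr) else list(tr)
  trees <- lapply(trees, function(t) t)
  if (!is.null(genes)) {
    labels <- unlist(lapply(trees, function(t) t$tip.label))
    attr(trees, "unmatched") <- setdiff(labels, genes$gene_id)
  }
  trees
}

#' @rdname read_trees
#' @param trees list of `phylo` objects.
#' @export
write_trees <- function(trees, path) {
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, path)
  invisible(path)
}

ref_file <- function(name) {
  p <- system.file("extdata", name, package = "triadkit")
  if (p == "" || !file.exists(p)) {
    stop("packaged reference table '", name, "' is missing; broken installation")
  }
  p
}

#' Packaged reference catalogue of wheat nitrate-transporter groups and names
#'
#' The complete hand-transcribed grouping-and-naming catalogue of the 412
#' wheat nitrate-transporter genes (families NPF, NRT2, CLC, SLAC1/SLAH;
#' IWGSC RefSeq v2.0): one row per homoeolog group with per-subgenome
#' RefSeq IDs and assigned gene names. Multi-member cells (duplicated copies
#' within a subgenome, marked with x/y suffixes) are `;`-separated.
#'
#' @return A data.frame with columns `group_id`, `category`
#'   (triad/diad/tetrad/singleton), `subfamily`, `refseq_A/B/D/Un` and
#'   `name_A/B/D/Un`.
#' @examples
#' ref <- read_reference_grouping()
#' nrow(ref)
#' @export
read_reference_grouping <- function() {
  x <- utils::read.delim(ref_file("wheat_nt_grouping.tsv"),
                         stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(identical(names(x), c("group_id", "category", "subfamily",
                                  "refseq_A", "refseq_B", "refseq_D", "refseq_Un",
                                  "name_A", "name_B", "name_D", "name_Un")))
  for (sg in c("A", "B", "D", "Un")) {
    nr <- lengths(strsplit(x[[paste0("refseq_", sg)]], ";"))
    nn <- lengths(strsplit(x[[paste0("name_", sg)]], ";"))
    if (!all(nr == nn)) stop("member ID / name lists differ in length for subgenome ", sg)
  }
  x
}

#' Flatten the reference grouping catalogue to one row per gene
#'
#' @param ref output of [read_reference_grouping()] (default: read it).
#' @return data.frame with columns `group_id`, `category`, `subfamily`,
#'   `family`, `subgenome`, `refseq_id`, `name`.
#' @export
reference_gene_table <- function(ref = read_reference_grouping()) {
  rows <- lapply(c("A", "B", "D", "Un"), function(sg) {
    ids <- strsplit(ref[[paste0("refseq_", sg)]], ";")
    nms <- strsplit(ref[[paste0("name_", sg)]], ";")
    k <- lengths(ids)
    data.frame(group_id = rep(ref$group_id, k), category = rep(ref$category, k),
               subfamily = rep(ref$subfamily, k),
               subgenome = sg, refseq_id = unlist(ids), name = unlist(nms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$refseq_id != "", , drop = FALSE]
  out$family <- family_of_subfamily(out$subfamily)
  rownames(out) <- NULL
  out[order(match(out$group_id, ref$group_id), out$subgenome), ]
}

#' @rdname reference_gene_table
#' @param subfamily character vector of subfamily tokens (e.g. `"NPF5"`).
#' @export
family_of_subfamily <- function(subfamily) {
  fam <- sub("^(NPF|NRT2|CLC|SLAC).*$", "\\1", subfamily)
  fam[!fam %in% c("NPF", "NRT2", "CLC", "SLAC")] <- NA_character_
  fam
}

#' Packaged reference panel of NUE-associated SNPs near nitrate transporters
#'
#' A hand-transcribed panel of SNP markers associated with nitrogen-use
#' efficiency traits, each paired with the nearby nitrate-transporter gene(s),
#' the published representative gene position(s) and distance(s) in Mb.
#' Cluster rows keep their `a-b` range tokens (gene-name ranges and
#' position/distance intervals) exactly as published; use
#' [expand_gene_range()] to enumerate range members.
#'
#' @return A data.frame with columns `marker_id`, `chrom`, `chrom_group`,
#'   `subgenome`, `position` (numeric), and `;`-separated character columns
#'   `genes`, `gene_positions`, `distances` preserving the published strings.
#' @export
read_reference_proximity <- function() {
  x <- utils::read.delim(ref_file("nue_snp_proximity.tsv"),
                         colClasses = "character", comment.char = "#")
  ct <- parse_chrom_token(x$chromosome)
  data.frame(marker_id = x$marker_id, chrom = ct$chrom,
             chrom_group = ct$chrom_group, subgenome = ct$subgenome,
             position = as.numeric(x$position),
             genes = x$genes, gene_positions = x$gene_positions,
             distances = x$distances, stringsAsFactors = FALSE)
}
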