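#' Parse chromosome tokens of an allopolyploid assembly
#'
#' Chromosome names follow the hexaploid-wheat convention: a homoeologous
#' group digit 1-7 followed by a subgenome letter (A, B or D), e.g. `"3A"`,
#' or the sentinel `"Un"` for unplaced scaffolds. Anything else is rejected.
#'
#' @param chrom character vector of chromosome tokens.
#' @return A data.frame with columns `chrom`, `chrom_group` (character
#'   `"1"`..`"7"` or `"Un"`) and `subgenome` (`"A"`, `"B"`, `"D"` or `"Un"`).
#'   Invalid tokens yield `NA` in both derived columns.
#' @examples
#' parse_chrom_token(c("3A", "Un", "8Z"))
#' @export
parse_chrom_token <- function(chrom) {
  chrom <- as.character(chrom)
  ok <- grepl("^[1-7][ABD]$", chrom)
  un <- chrom == "Un"
  data.frame(
    chrom = chrom,
    chrom_group = ifelse(ok, substr(chrom, 1, 1), ifelse(un, "Un", NA_character_)),
    subgenome = ifelse(ok, substr(chrom, 2, 2), ifelse(un, "Un", NA_character_)),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene-model table
#'
#' The central container of the package: one row per annotated gene with its
#' chromosome-group / subgenome location, coordinates (1-based inclusive),
#' strand, exon structure and optional family/subfamily labels.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome tokens (see [parse_chrom_token()]).
#' @param start,end 1-based inclusive gene coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param exons list of two-column matrices (`start`, `end`), one per gene,
#'   sorted, non-overlapping and contained in `[start, end]`. Defaults to a
#'   single exon spanning the gene.
#' @param family,subfamily optional classification tokens (e.g. `"NPF"`,
#'   `"NPF5"`); `NA` when unknown.
#' @return A data.frame of class `"gene_models"`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+",
                        exons = NULL, family = NA_character_,
                        subfamily = NA_character_) {
  n <- length(gene_id)
  stopifnot(n > 0 || length(chrom) == 0)
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  ct <- parse_chrom_token(chrom)
  if (anyNA(ct$chrom_group)) {
    stop("invalid chromosome token(s): ",
         paste(unique(chrom[is.na(ct$chrom_group)]), collapse = ", "))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(end < start)
  if (length(bad)) {
    stop("end < start for gene(s): ", paste(gene_id[bad], collapse = ", "))
  }
  if (is.null(exons)) exons <- Map(function(s, e) cbind(start = s, end = e), start, end)
  stopifnot(length(exons) == n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    ex <- matrix(as.numeric(ex), ncol = 2, dimnames = list(NULL, c("start", "end")))
    if (nrow(ex) == 0) stop("gene ", gene_id[i], ": no exons")
    if (is.unsorted(ex[, "start"])) ex <- ex[order(ex[, "start"]), , drop = FALSE]
    if (any(ex[, "end"] < ex[, "start"])) stop("gene ", gene_id[i], ": exon end < start")
    if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"]))
      stop("gene ", gene_id[i], ": overlapping exons")
    if (ex[1, "start"] < start[i] || ex[nrow(ex), "end"] > end[i])
      stop("gene ", gene_id[i], ": exons outside gene body")
    exons[[i]] <- ex
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    chrom = ct$chrom, chrom_group = ct$chrom_group, subgenome = ct$subgenome,
    start = start, end = end,
    strand = as.character(rep_len(strand, n)),
    family = as.character(rep_len(family, n)),
    subfamily = as.character(rep_len(subfamily, n)),
    stringsAsFactors = FALSE
  )
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x), " gene(s) on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  shown <- utils::head(as.data.frame(x)[setdiff(names(x), "exons")], 10)
  shown$n_exons <- vapply(utils::head(x$exons, 10), nrow, 0L)
  print(shown)
  if (nrow(x) > 10) cat("... and ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}

#' Count introns of gene models
#'
#' The intron count of a gene is its exon count minus one; single-exon
#' ("intronless") genes therefore have zero introns.
#'
#' @param genes a `gene_models` table.
#' @return Integer vector named by `gene_id`.
#' @export
count_introns <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  n_ex <- vapply(genes$exons, nrow, 0L)
  if (any(n_ex == 0)) {
    stop("gene(s) without exons: ",
         paste(genes$gene_id[n_ex == 0], collapse = ", "))
  }
  stats::setNames(n_ex - 1L, genes$gene_id)
}

#' Read gene models from a GFF3 file
#'
#' Accepts GFF3 with `gene`, optional `mRNA` and `exon` features; exons are
#' attached to their gene through `Parent` linkage (directly or via an mRNA).
#' Family and subfamily labels are taken from `family=` / `subfamily=`
#' attributes when present.
#'
#' Records with a malformed coordinate (`end < start`) abort with the
#' offending line number; gene records on an unrecognized chromosome token
#' are skipped with a warning.
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  fields <- strsplit(raw[body], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 8)) {
    stop("malformed GFF3 record (fewer than 8 fields) at line ",
         body[which(nfield < 8)[1]])
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  bad <- which(!is.na(starts) & !is.na(ends) & ends < starts)
  if (length(bad)) {
    stop("malformed coordinate (end < start) at line ",
         paste(body[bad], collapse = ", "))
  }

  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))

  gi <- which(type == "gene")
  gene_chrom_ok <- grepl("^[1-7][ABD]$|^Un$", chrom[gi])
  if (any(!gene_chrom_ok)) {
    warning("skipping gene(s) on unrecognized chromosome token: ",
            paste(unique(chrom[gi][!gene_chrom_ok]), collapse = ", "))
    gi <- gi[gene_chrom_ok]
  }
  if (!length(gi)) return(gene_models(character(), character(), numeric(), numeric()))
  gene_ids <- as.character(md$ID[gi])

  # map feature ID -> owning gene (exons may point at an mRNA)
  parent_chr <- vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  owner <- stats::setNames(gene_ids, gene_ids)
  mi <- which(type == "mRNA")
  if (length(mi)) {
    m_owner <- owner[parent_chr[mi]]
    owner <- c(owner, stats::setNames(m_owner, as.character(md$ID[mi])))
  }
  ei <- which(type == "exon")
  exon_gene <- owner[parent_chr[ei]]
  exons <- lapply(gene_ids, function(g) {
    idx <- ei[!is.na(exon_gene) & exon_gene == g]
    if (!length(idx)) return(NULL)
    ex <- cbind(start = GenomicRanges::start(gr)[idx], end = GenomicRanges::end(gr)[idx])
    ex[order(ex[, "start"]), , drop = FALSE]
  })
  no_ex <- vapply(exons, is.null, TRUE)
  exons[no_ex] <- Map(function(s, e) cbind(start = s, end = e),
                      GenomicRanges::start(gr)[gi][no_ex], GenomicRanges::end(gr)[gi][no_ex])

  fam <- if ("family" %in% names(md)) as.character(md$family[gi]) else NA_character_
  subf <- if ("subfamily" %in% names(md)) as.character(md$subfamily[gi]) else NA_character_
  gene_models(
    gene_id = gene_ids,
    chrom = chrom[gi],
    start = GenomicRanges::start(gr)[gi],
    end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    exons = exons, family = fam, subfamily = subf
  )
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` feature per row plus its `exon` children (Parent-linked),
#' carrying `family`/`subfamily` attributes when set. [read_gene_models()] on
#' the result reproduces the input field-for-field.
#'
#' @param genes a `gene_models` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  n_ex <- vapply(genes$exons, nrow, 0L)
  ex_all <- do.call(rbind, genes$exons)
  strand_g <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  both <- GenomicRanges::GRanges(
    seqnames = c(genes$chrom, rep(genes$chrom, n_ex)),
    ranges = IRanges::IRanges(c(genes$start, ex_all[, "start"]),
                              c(genes$end, ex_all[, "end"])),
    strand = c(strand_g, rep(strand_g, n_ex))
  )
  ng <- nrow(genes)
  S4Vectors::mcols(both)$type <- c(rep("gene", ng), rep("exon", sum(n_ex)))
  S4Vectors::mcols(both)$ID <- c(genes$gene_id, rep(NA_character_, sum(n_ex)))
  S4Vectors::mcols(both)$Parent <- c(rep(NA_character_, ng),
                                     as.character(rep(genes$gene_id, n_ex)))
  if (!all(is.na(genes$family)))
    S4Vectors::mcols(both)$family <- c(genes$family, rep(NA_character_, sum(n_ex)))
  if (!all(is.na(genes$subfamily)))
    S4Vectors::mcols(both)$subfamily <- c(genes$subfamily, rep(NA_character_, sum(n_ex)))
  ord <- order(as.character(GenomicRanges::seqnames(both)), GenomicRanges::start(both),
               S4Vectors::mcols(both)$type != "gene")
  rtracklayer::export(both[ord], path, format = "gff3")
  invisible(path)
}
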