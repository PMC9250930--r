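#' SNP-to-gene distance in megabases
#'
#' `|gene_position - snp_position| / 1e6`, computed on raw 1-based integer
#' coordinates; exact at 6 printed decimals for any genomic coordinate.
#' When chromosomes are supplied they must match: a cross-chromosome
#' distance is an error, never a silently large number.
#'
#' @param snp_position,gene_position 1-based base coordinates (vectorized).
#' @param snp_chrom,gene_chrom optional chromosome tokens to cross-check.
#' @return numeric distances in Mb.
#' @examples
#' distance_mb(12918698, 14519757)
#' @export
distance_mb <- function(snp_position, gene_position,
                        snp_chrom = NULL, gene_chrom = NULL) {
  if (!is.null(snp_chrom) || !is.null(gene_chrom)) {
    if (is.null(snp_chrom) || is.null(gene_chrom) || any(snp_chrom != gene_chrom)) {
      bad <- which(is.null(snp_chrom) | is.null(gene_chrom) | snp_chrom != gene_chrom)
      stop("SNP and gene on different chromosomes (",
           paste(unique(paste0(snp_chrom[bad], " vs ", gene_chrom[bad])),
                 collapse = "; "), ")")
    }
  }
  abs(gene_position - snp_position) / 1e6
}

#' Find genes near SNP markers
#'
#' Reports every (SNP, gene) pair on the same chromosome whose distance is
#' within `window_mb` megabases. The representative gene coordinate is the
#' annotated gene start by default, or the nearest gene boundary
#' (`representative = "nearest_boundary"`). The window has no universal
#' biological definition; it is a required, logged parameter (the default
#' 15 Mb covers typical MTA-to-candidate reporting distances).
#'
#' @param snps SNP table (see [read_snp_table()]).
#' @param genes a [gene_models()] table, or a data.frame with columns
#'   `gene` (label), `chrom` and `position` for pre-tabulated positions.
#' @param window_mb maximum distance in Mb, default 15.
#' @param representative `"start"` or `"nearest_boundary"`.
#' @return data.frame of class `"proximity_hits"`: `marker_id`, `chrom`,
#'   `snp_position`, `gene`, `gene_position`, `distance_mb`, sorted by
#'   marker then distance. Attribute `"window_mb"` records the window.
#' @export
find_nearby_genes <- function(snps, genes, window_mb = 15,
                              representative = c("start", "nearest_boundary")) {
  representative <- match.arg(representative)
  if (inherits(genes, "gene_models")) {
    glab <- genes$gene_id
    gchrom <- genes$chrom
    gstart <- genes$start; gend <- genes$end
  } else {
    stopifnot(all(c("gene", "chrom", "position") %in% names(genes)))
    glab <- genes$gene; gchrom <- genes$chrom
    gstart <- genes$position; gend <- genes$position
  }
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    on_chrom <- which(gchrom == snps$chrom[i])
    if (!length(on_chrom)) return(NULL)
    pos <- if (representative == "start") gstart[on_chrom] else {
      p <- snps$position[i]
      ifelse(p < gstart[on_chrom], gstart[on_chrom],
             ifelse(p > gend[on_chrom], gend[on_chrom], p))
    }
    d <- distance_mb(snps$position[i], pos)
    keep <- d <= window_mb
    if (!any(keep)) return(NULL)
    data.frame(marker_id = snps$marker_id[i], chrom = snps$chrom[i],
               snp_position = snps$position[i], gene = glab[on_chrom][keep],
               gene_position = pos[keep], distance_mb = d[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(marker_id = character(), chrom = character(),
                      snp_position = numeric(), gene = character(),
                      gene_position = numeric(), distance_mb = numeric())
  }
  out <- out[order(out$marker_id, out$distance_mb, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_mb") <- window_mb
  class(out) <- c("proximity_hits", "data.frame")
  out
}

#' Expand a gene-name range token over consecutive serials
#'
#' Cluster hits are often reported as ranges like
#' `"TaNPF5-3B3-TaNPF5-3B10"` (hyphen, en- or em-dash): both endpoints must
#' share subfamily, chromosome group and subgenome, and the range expands
#' over the consecutive serial integers. Non-range tokens pass through
#' unchanged.
#'
#' @param tokens character vector of gene names or range tokens.
#' @param prefix species prefix, default `"Ta"`.
#' @return character vector of expanded gene names.
#' @examples
#' expand_gene_range("TaNPF5-3B3-TaNPF5-3B10")
#' @export
expand_gene_range <- function(tokens, prefix = "Ta") {
  out <- lapply(tokens, function(tok) {
    tok <- gsub("–|—", "-", trimws(tok))
    parts <- strsplit(tok, paste0("-\\s*(?=", prefix, ")"), perl = TRUE)[[1]]
    if (length(parts) == 2) {
      p <- parse_gene_name(trimws(parts), prefix = prefix)
      if (!anyNA(p$serial) && p$subfamily[1] == p$subfamily[2] &&
          p$chrom_group[1] == p$chrom_group[2] &&
          p$subgenome[1] == p$subgenome[2] && p$chrom_group[1] != "Un") {
        s <- seq(p$serial[1], p$serial[2])
        return(paste0(prefix, p$subfamily[1], "-", p$chrom_group[1],
                      p$subgenome[1], s))
      }
      warning("range token endpoints do not align, kept verbatim: ", tok)
    }
    tok
  })
  unlist(out)
}

#' Summarize proximity hits
#'
#' Distinct-entity counts over a hit table: number of distinct SNPs with at
#' least one nearby gene, number of distinct genes (gene-range tokens are
#' expanded over consecutive serials first) and the per-family partition of
#' those genes.
#'
#' @param hits either a `"proximity_hits"` table from [find_nearby_genes()]
#'   or the packaged panel from [read_reference_proximity()] (whose `genes`
#'   column is `;`-separated and may contain range tokens).
#' @param prefix species prefix used when parsing names, default `"Ta"`.
#' @return list with `n_snps`, `n_genes`, `genes` (the distinct expanded
#'   names) and `per_family` (named counts; unparseable tokens fall under
#'   `"other"`).
#' @export
summarize_hits <- function(hits, prefix = "Ta") {
  if ("genes" %in% names(hits) && !"gene" %in% names(hits)) {
    tokens <- unlist(strsplit(hits$genes, ";"))
    markers <- hits$marker_id
  } else {
    tokens <- hits$gene
    markers <- unique(hits$marker_id)
  }
  expanded <- unique(expand_gene_range(trimws(tokens), prefix = prefix))
  # family from the name prefix; tolerant of typographic tokens lacking the
  # canonical dash (e.g. "TaNPF4B1") so the per-family partition stays usable
  fam <- family_of_subfamily(sub(paste0("^", prefix), "", expanded))
  fam[is.na(fam)] <- "other"
  list(n_snps = length(unique(markers)),
       n_genes = length(expanded),
       genes = sort(expanded),
       per_family = table(fam))
}

#' Export SNP windows as BED intervals
#'
#' Writes 0-based half-open intervals of `window_mb` Mb around each SNP for
#' genome-browser use.
#'
#' @param snps SNP table.
#' @param path output BED path.
#' @param window_mb half-width of the interval in Mb.
#' @export
write_snp_windows_bed <- function(snps, path, window_mb = 15) {
  half <- window_mb * 1e6
  out <- data.frame(chrom = snps$chrom,
                    start = format(pmax(0, snps$position - 1 - half),
                                   scientific = FALSE, trim = TRUE),
                    end = format(snps$position + half, scientific = FALSE, trim = TRUE),
                    name = snps$marker_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
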