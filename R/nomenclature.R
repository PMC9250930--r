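CATEGORY_LETTER <- c(triad = "T", diad = "D", singleton = "S", tetrad = "TT")

group_sort_key <- function(groups) {
  # canonical group order: chromosome group (Un last), then leftmost member
  # position, then smallest member ID
  cg <- groups$chrom_group
  cg_num <- suppressWarnings(as.integer(cg))
  cg_num[is.na(cg_num)] <- 99L  # "Un" sorts last
  min_start <- vapply(groups$members, function(m) {
    s <- suppressWarnings(min(m$start, na.rm = TRUE))
    if (!is.finite(s)) Inf else s
  }, 0)
  min_id <- vapply(groups$members, function(m) min(m$gene_id), "")
  order(groups$subfamily, cg_num, min_start, min_id)
}

#' Assign group identifiers
#'
#' Group IDs follow the `<prefix><subfamily>-<letter><ordinal>` pattern with
#' letter T (triad), D (diad), S (singleton) or TT (tetrad). Ordinals count
#' per (subfamily, category), starting at 1, in canonical order: chromosome
#' group (unplaced last), then leftmost member position, then smallest member
#' ID — so the numbering never depends on input order.
#'
#' @param groups a `homoeolog_groups` table.
#' @param prefix species prefix, default `"Ta"`.
#' @return the input with a `group_id` column added (and rows in canonical
#'   order).
#' @export
assign_group_ids <- function(groups, prefix = "Ta") {
  stopifnot(inherits(groups, "homoeolog_groups"))
  ord <- group_sort_key(groups)
  groups <- groups[ord, , drop = FALSE]
  letter <- CATEGORY_LETTER[groups$category]
  key <- paste(groups$subfamily, letter)
  ordinal <- stats::ave(seq_along(key), key, FUN = seq_along)
  groups$group_id <- paste0(prefix, groups$subfamily, "-", letter, ordinal)
  class(groups) <- c("homoeolog_groups", "data.frame")
  rownames(groups) <- NULL
  groups
}

#' Assign subgenome-aware gene names
#'
#' Every gene gets a name `<prefix><subfamily>-<chrom group><subgenome
#' letter><serial>`, e.g. `TaNPF1-3A1`. Homoeologs within a group share the
#' serial and differ only in the subgenome letter; serial counters run per
#' (subfamily, chromosome group) and are shared across subgenomes, so a
#' group missing a subgenome still advances the counter for the groups after
#' it. Duplicated copies within one subgenome get suffixes `x`, `y` in order
#' of ascending start position. Genes on unplaced scaffolds are named
#' `<prefix><subfamily>-Un<serial>` from a per-subfamily "Un" counter.
#'
#' @param groups a `homoeolog_groups` table with `group_id` assigned (see
#'   [assign_group_ids()]).
#' @param prefix species prefix, default `"Ta"`.
#' @return data.frame `gene_id`, `name`, `group_id`, `subgenome`. Fails if
#'   two genes would render the same name.
#' @export
assign_gene_names <- function(groups, prefix = "Ta") {
  stopifnot(inherits(groups, "homoeolog_groups"))
  if (is.null(groups$group_id)) groups <- assign_group_ids(groups, prefix = prefix)
  ord <- group_sort_key(groups)
  groups <- groups[ord, , drop = FALSE]

  serial <- new.env(parent = emptyenv())
  next_serial <- function(key) {
    v <- get0(key, envir = serial, ifnotfound = 0L) + 1L
    assign(key, v, envir = serial)
    v
  }
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    m <- groups$members[[i]]
    subf <- groups$subfamily[i]
    non_un <- m[m$subgenome != "Un", , drop = FALSE]
    nm <- character(0); ids <- character(0); sg_out <- character(0)
    if (nrow(non_un)) {
      cg <- unique(non_un$chrom_group)
      if (length(cg) > 1) {
        stop("group ", groups$group_id[i], " spans chromosome groups: ",
             paste(cg, collapse = ","))
      }
      s <- next_serial(paste(subf, cg))
      for (sg in intersect(c(SUBGENOMES), unique(non_un$subgenome))) {
        mm <- non_un[non_un$subgenome == sg, , drop = FALSE]
        mm <- mm[order(mm$start, mm$gene_id), , drop = FALSE]
        suffix <- if (nrow(mm) > 1) c("x", "y", "z")[seq_len(nrow(mm))] else ""
        nm <- c(nm, paste0(prefix, subf, "-", cg, sg, s, suffix))
        ids <- c(ids, mm$gene_id)
        sg_out <- c(sg_out, mm$subgenome)
      }
    }
    un <- m[m$subgenome == "Un", , drop = FALSE]
    if (nrow(un)) {
      un <- un[order(un$start, un$gene_id), , drop = FALSE]
      for (k in seq_len(nrow(un))) {
        s <- next_serial(paste(subf, "Un"))
        nm <- c(nm, paste0(prefix, subf, "-Un", s))
        ids <- c(ids, un$gene_id[k])
        sg_out <- c(sg_out, "Un")
      }
    }
    rows[[i]] <- data.frame(gene_id = ids, name = nm,
                            group_id = groups$group_id[i], subgenome = sg_out,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$name)) {
    stop("gene name collision: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         " (genes ",
         paste(out$gene_id[out$name %in% out$name[duplicated(out$name)]],
               collapse = ", "), ")")
  }
  out
}

#' Parse a rendered gene name into its parts
#'
#' @param name character vector of names like `"TaNPF5-3B10x"` or
#'   `"TaNRT2-Un1"`.
#' @param prefix species prefix, default `"Ta"`.
#' @return data.frame `name`, `subfamily`, `chrom_group`, `subgenome`,
#'   `serial`, `copy_suffix` (`NA` where a token does not parse).
#' @export
parse_gene_name <- function(name, prefix = "Ta") {
  pat <- paste0("^", prefix, "([A-Za-z0-9]+)-(?:([1-7])([ABD])|(Un))([0-9]+)([xyz]?)$")
  m <- regmatches(name, regexec(pat, name))
  part <- function(k) vapply(m, function(g) if (length(g)) g[k] else NA_character_, "")
  sub_g <- ifelse(part(5) == "Un", "Un", part(4))
  data.frame(name = name, subfamily = part(2),
             chrom_group = ifelse(part(5) == "Un", "Un", part(3)),
             subgenome = sub_g,
             serial = suppressWarnings(as.integer(part(6))),
             copy_suffix = ifelse(part(7) == "", NA_character_, part(7)),
             stringsAsFactors = FALSE)
}

#' Write the gene-name map as TSV
#'
#' @param names_map output of [assign_gene_names()].
#' @param path output file.
#' @export
write_name_map <- function(names_map, path) {
  utils::write.table(names_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
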