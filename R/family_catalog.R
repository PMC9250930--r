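#' Construct a candidate-hit table
#'
#' One row per candidate gene from an evidence stream: either retrieval by
#' conserved-domain identifier (`"domain_retrieval"`) or an HMM profile
#' search (`"profile_search"`). Both searches run upstream of this package;
#' their output is consumed here as plain tables.
#'
#' @param gene_id candidate gene identifiers.
#' @param evidence `"domain_retrieval"` or `"profile_search"`.
#' @param confidence `"high"` or `"low"`.
#' @param canonical_id for splice variants, the canonical gene the transcript
#'   belongs to; `NA` otherwise.
#' @return data.frame of class `"candidate_hits"`.
#' @export
candidate_hits <- function(gene_id, evidence, confidence = "high",
                           canonical_id = NA_character_) {
  if (any(!nzchar(gene_id))) stop("empty gene_id in candidate hits")
  evidence <- match.arg(evidence, c("domain_retrieval", "profile_search"),
                        several.ok = TRUE)
  stopifnot(all(confidence %in% c("high", "low")))
  out <- data.frame(gene_id = as.character(gene_id),
                    evidence = rep_len(evidence, length(gene_id)),
                    confidence = rep_len(confidence, length(gene_id)),
                    canonical_id = rep_len(as.character(canonical_id), length(gene_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_hits", "data.frame")
  out
}

#' Read / write candidate hits as TSV
#'
#' Header: `gene_id, evidence, confidence, canonical_id` (empty canonical_id
#' means "not a splice variant").
#'
#' @param path TSV file path.
#' @return [candidate_hits()] table.
#' @export
read_candidate_hits <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = c("NA", ""))
  candidate_hits(x$gene_id, x$evidence, x$confidence, x$canonical_id)
}

#' @rdname read_candidate_hits
#' @param hits candidate-hit table.
#' @export
write_candidate_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Merge two candidate-evidence streams
#'
#' Set union on `gene_id` of the domain-retrieval and profile-search hits.
#' A gene found by both streams is flagged dual-evidence in the `sources`
#' column and keeps the better (high beats low) confidence call.
#'
#' @param domain_hits,profile_hits [candidate_hits()] tables.
#' @return data.frame with one row per distinct gene: `gene_id`, `confidence`,
#'   `canonical_id`, `sources` (comma-joined), `dual_evidence` (logical).
#' @export
merge_evidence <- function(domain_hits, profile_hits) {
  all_hits <- rbind(as.data.frame(domain_hits), as.data.frame(profile_hits))
  split_hits <- split(all_hits, all_hits$gene_id)
  rows <- lapply(split_hits, function(h) {
    canon <- unique(h$canonical_id[!is.na(h$canonical_id)])
    if (length(canon) > 1) {
      stop("conflicting splice-variant annotations for gene ", h$gene_id[1],
           ": ", paste(canon, collapse = " vs "))
    }
    src <- sort(unique(h$evidence))
    data.frame(gene_id = h$gene_id[1],
               confidence = if (any(h$confidence == "high")) "high" else "low",
               canonical_id = if (length(canon)) canon else NA_character_,
               sources = paste(src, collapse = ","),
               dual_evidence = length(src) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Curate merged candidates into the final gene catalogue
#'
#' Reproduces the catalogue-curation rules: low-confidence candidates are
#' removed, duplicate hits collapsed (by gene ID), splice variants collapsed
#' onto their canonical gene (transcript suffixes `.1`, `.2`, ... are also
#' stripped), and candidates without an annotated gene model are excluded and
#' reported. Curation is idempotent.
#'
#' @param candidates output of [merge_evidence()] (or a [candidate_hits()]
#'   table).
#' @param genes a [gene_models()] table supplying coordinates and
#'   family/subfamily labels for the retained genes.
#' @return An object of class `"gene_catalog"`: list with `genes` (the
#'   curated `gene_models` subset), `provenance` (per-gene evidence) and
#'   `dropped` (a report of what was removed and why).
#' @export
curate <- function(candidates, genes) {
  stopifnot(inherits(genes, "gene_models"))
  cand <- as.data.frame(candidates)
  if (!"sources" %in% names(cand)) cand$sources <- cand$evidence
  dropped <- data.frame(gene_id = character(), reason = character(),
                        stringsAsFactors = FALSE)

  low <- cand$confidence != "high"
  if (any(low)) {
    dropped <- rbind(dropped, data.frame(gene_id = cand$gene_id[low],
                                         reason = "low_confidence"))
    cand <- cand[!low, , drop = FALSE]
  }

  # splice-variant collapse: explicit canonical_id first, then transcript suffix
  target <- ifelse(!is.na(cand$canonical_id), cand$canonical_id,
                   sub("\\.\\d+$", "", cand$gene_id))
  variant <- target != cand$gene_id
  if (any(variant)) {
    dropped <- rbind(dropped, data.frame(gene_id = cand$gene_id[variant],
                                         reason = paste0("splice_variant_of:", target[variant])))
  }
  cand$gene_id <- target

  dup <- duplicated(cand$gene_id)
  if (any(dup)) {
    dropped <- rbind(dropped, data.frame(gene_id = cand$gene_id[dup],
                                         reason = "duplicate"))
    # keep dual-evidence provenance of all copies
    src <- tapply(cand$sources, cand$gene_id, function(s)
      paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ","))
    cand <- cand[!dup, , drop = FALSE]
    cand$sources <- unname(src[cand$gene_id])
  }

  no_model <- !(cand$gene_id %in% genes$gene_id)
  if (any(no_model)) {
    dropped <- rbind(dropped, data.frame(gene_id = cand$gene_id[no_model],
                                         reason = "no_gene_model"))
    cand <- cand[!no_model, , drop = FALSE]
  }

  keep <- genes[match(cand$gene_id, genes$gene_id), , drop = FALSE]
  class(keep) <- c("gene_models", "data.frame")
  rownames(keep) <- NULL
  if (nrow(keep) == 0) warning("curated catalogue is empty")
  if (anyNA(keep$family)) {
    stop("curated gene(s) without a family label: ",
         paste(utils::head(keep$gene_id[is.na(keep$family)], 5), collapse = ", "))
  }
  structure(list(genes = keep,
                 provenance = data.frame(gene_id = cand$gene_id,
                                         sources = cand$sources,
                                         stringsAsFactors = FALSE),
                 dropped = dropped),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog: ", nrow(x$genes), " curated gene(s), ",
      nrow(x$dropped), " dropped candidate(s)\n", sep = "")
  print(count_by_family(x)$family)
  invisible(x)
}

#' Tabulate a catalogue by family and subfamily
#'
#' Counts partition the catalogue: subfamily counts sum to family counts,
#' which sum to the catalogue size.
#'
#' @param catalog a `"gene_catalog"` (or a bare `gene_models` table).
#' @return list with data.frames `family` (`family`, `n`) and `subfamily`
#'   (`family`, `subfamily`, `n`), plus `total`.
#' @export
count_by_family <- function(catalog) {
  genes <- if (inherits(catalog, "gene_catalog")) catalog$genes else catalog
  if (nrow(genes) == 0) {
    return(list(family = data.frame(family = character(), n = integer()),
                subfamily = data.frame(family = character(), subfamily = character(),
                                       n = integer()),
                total = 0L))
  }
  fam <- table(factor(genes$family, levels = sort(unique(genes$family))))
  subf <- stats::aggregate(list(n = genes$gene_id),
                           by = list(family = genes$family, subfamily = genes$subfamily),
                           FUN = length)
  subf <- subf[order(subf$family, subf$subfamily), , drop = FALSE]
  rownames(subf) <- NULL
  list(family = data.frame(family = names(fam), n = as.integer(fam),
                           stringsAsFactors = FALSE),
       subfamily = subf,
       total = nrow(genes))
}
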