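BIAS_CATEGORIES <- c("Balanced", "A_dominant", "B_dominant", "D_dominant",
                     "A_suppressed", "B_suppressed", "D_suppressed")

#' Centroids of the seven homoeolog expression-bias categories
#'
#' Coordinates on the 2-simplex of normalized (fA, fB, fD) fractions:
#' Balanced sits at (1/3, 1/3, 1/3); a dominant category concentrates all
#' expression in one subgenome; a suppressed category zeroes one subgenome
#' and splits the remainder equally between the other two. Triads are
#' assigned to the category whose centroid is nearest in Euclidean distance.
#'
#' @return 7 x 3 numeric matrix (rows: categories; columns: f_A, f_B, f_D),
#'   each row summing to 1.
#' @export
bias_centroids <- function() {
  m <- rbind(
    Balanced     = c(1, 1, 1) / 3,
    A_dominant   = c(1, 0, 0),
    B_dominant   = c(0, 1, 0),
    D_dominant   = c(0, 0, 1),
    A_suppressed = c(0, 1, 1) / 2,
    B_suppressed = c(1, 0, 1) / 2,
    D_suppressed = c(1, 1, 0) / 2
  )
  colnames(m) <- c("f_A", "f_B", "f_D")
  m
}

#' Normalize a triad's TPM triple to simplex fractions
#'
#' @param tpm_A,tpm_B,tpm_D non-negative TPM values (vectorized).
#' @return data.frame with columns `f_A`, `f_B`, `f_D` summing to 1 row-wise.
#'   All-zero triples are an error: they must be removed by
#'   [filter_triads()] before normalization.
#' @examples
#' normalize_triad(5, 4, 1)
#' @export
normalize_triad <- function(tpm_A, tpm_B, tpm_D) {
  if (any(tpm_A < 0 | tpm_B < 0 | tpm_D < 0)) stop("negative tpm")
  s <- tpm_A + tpm_B + tpm_D
  if (any(s == 0)) {
    stop("all-zero triad(s) at position(s) ", paste(which(s == 0), collapse = ", "),
         "; filter before normalizing")
  }
  data.frame(f_A = tpm_A / s, f_B = tpm_B / s, f_D = tpm_D / s)
}

#' Classify a triad's homoeolog-bias category
#'
#' Nearest-centroid classification on the simplex: the Euclidean distance to
#' each of the seven category centroids is computed and the smallest wins.
#' Ties break in the fixed order Balanced, A/B/D dominant, A/B/D suppressed.
#'
#' @param f_A,f_B,f_D normalized fractions summing to 1 (vectorized).
#' @return data.frame with `category` (factor over the seven levels) and one
#'   distance column per centroid (`dist_Balanced`, `dist_A_dominant`, ...).
#' @examples
#' classify_triad(0.5, 0.4, 0.1)$category
#' @export
classify_triad <- function(f_A, f_B, f_D) {
  s <- f_A + f_B + f_D
  if (any(abs(s - 1) > 1e-6)) stop("fractions must sum to 1")
  fm <- cbind(f_A, f_B, f_D)
  cen <- bias_centroids()
  d <- vapply(seq_len(nrow(cen)), function(k)
    sqrt(rowSums((fm - matrix(cen[k, ], nrow(fm), 3, byrow = TRUE))^2)),
    numeric(nrow(fm)))
  d <- matrix(d, ncol = nrow(cen),
              dimnames = list(NULL, paste0("dist_", rownames(cen))))
  cat_idx <- apply(d, 1, which.min)  # ties: first index = fixed category order
  out <- data.frame(category = factor(BIAS_CATEGORIES[cat_idx],
                                      levels = BIAS_CATEGORIES))
  cbind(out, as.data.frame(d))
}

triad_member_map <- function(groups) {
  tri <- groups[groups$category == "triad", , drop = FALSE]
  tri <- tri[vapply(tri$members, function(m) !any(m$subgenome == "Un"), TRUE), ,
             drop = FALSE]
  if (!nrow(tri)) return(NULL)
  ids <- vapply(seq_len(nrow(tri)), function(i) {
    m <- tri$members[[i]]
    paste(m$gene_id[match(SUBGENOMES, m$subgenome)], collapse = "\r")
  }, "")
  mat <- do.call(rbind, strsplit(ids, "\r", fixed = TRUE))
  colnames(mat) <- SUBGENOMES
  gid <- if (!is.null(tri$group_id)) tri$group_id else
    paste0(tri$subfamily, ":", mat[, "A"])
  data.frame(group_id = gid, gene_A = mat[, "A"], gene_B = mat[, "B"],
             gene_D = mat[, "D"], subfamily = tri$subfamily,
             stringsAsFactors = FALSE)
}

tissue_tpm <- function(expr, gene_ids, aggregate = max) {
  # per (gene, tissue) aggregate over stages and cultivars; absent -> 0
  sub <- expr[expr$gene_id %in% gene_ids, , drop = FALSE]
  out <- matrix(0, length(gene_ids), length(TISSUES),
                dimnames = list(gene_ids, TISSUES))
  if (nrow(sub)) {
    agg <- stats::aggregate(list(tpm = sub$tpm),
                            by = list(gene_id = sub$gene_id, tissue = sub$tissue),
                            FUN = aggregate)
    out[cbind(match(agg$gene_id, gene_ids), match(agg$tissue, TISSUES))] <- agg$tpm
  }
  out
}

#' Filter triads on total expression per tissue
#'
#' A (triad, tissue) pair is retained iff the summed TPM of the three
#' homoeologs reaches `threshold_tpm` in that tissue (stage/cultivar
#' replicates are aggregated by maximum first). With
#' `per_homoeolog = TRUE` each homoeolog must individually reach the
#' threshold instead (sensitivity analysis). Triad members with no
#' expression record at all count as 0 TPM.
#'
#' @param expr expression records (see [read_expression_table()]).
#' @param groups a `homoeolog_groups` table; only 1:1:1 triads are profiled.
#' @param threshold_tpm detection threshold in TPM units, default 1.
#' @param per_homoeolog apply the threshold per homoeolog instead of to the
#'   triad sum.
#' @return data.frame with one row per (triad, tissue): `group_id`, `tissue`,
#'   `tpm_A/B/D`, `retained`.
#' @export
filter_triads <- function(expr, groups, threshold_tpm = 1, per_homoeolog = FALSE) {
  map <- triad_member_map(groups)
  if (is.null(map)) {
    return(data.frame(group_id = character(), tissue = character(),
                      tpm_A = numeric(), tpm_B = numeric(), tpm_D = numeric(),
                      retained = logical()))
  }
  all_ids <- unique(c(map$gene_A, map$gene_B, map$gene_D))
  no_rec <- setdiff(all_ids, unique(expr$gene_id))
  if (length(no_rec)) {
    message("triad member(s) with no expression record, treated as 0 tpm: ",
            paste(utils::head(no_rec, 5), collapse = ", "),
            if (length(no_rec) > 5) " ..." else "")
  }
  tm <- tissue_tpm(expr, all_ids)
  out <- do.call(rbind, lapply(TISSUES, function(ti) {
    data.frame(group_id = map$group_id, tissue = ti,
               tpm_A = tm[map$gene_A, ti], tpm_B = tm[map$gene_B, ti],
               tpm_D = tm[map$gene_D, ti], stringsAsFactors = FALSE)
  }))
  out$retained <- if (per_homoeolog) {
    out$tpm_A >= threshold_tpm & out$tpm_B >= threshold_tpm & out$tpm_D >= threshold_tpm
  } else {
    out$tpm_A + out$tpm_B + out$tpm_D >= threshold_tpm
  }
  rownames(out) <- NULL
  out
}

#' Compute classified triad expression profiles
#'
#' The full triad pipeline: aggregate TPM per tissue, apply the detection
#' filter, normalize to simplex fractions and classify against the seven
#' bias-category centroids.
#'
#' @inheritParams filter_triads
#' @return data.frame of class `"triad_profiles"`: one row per retained
#'   (triad, tissue) with TPMs, fractions, category and centroid distances.
#' @export
triad_expression_profiles <- function(expr, groups, threshold_tpm = 1,
                                      per_homoeolog = FALSE) {
  flt <- filter_triads(expr, groups, threshold_tpm, per_homoeolog)
  keep <- flt[flt$retained, , drop = FALSE]
  if (nrow(keep)) {
    fr <- normalize_triad(keep$tpm_A, keep$tpm_B, keep$tpm_D)
    cl <- classify_triad(fr$f_A, fr$f_B, fr$f_D)
    out <- cbind(keep[c("group_id", "tissue", "tpm_A", "tpm_B", "tpm_D")], fr, cl)
  } else {
    out <- cbind(keep[c("group_id", "tissue", "tpm_A", "tpm_B", "tpm_D")],
                 f_A = numeric(0), f_B = numeric(0), f_D = numeric(0),
                 category = factor(character(), levels = BIAS_CATEGORIES))
  }
  rownames(out) <- NULL
  class(out) <- c("triad_profiles", "data.frame")
  out
}

#' @export
print.triad_profiles <- function(x, ...) {
  cat("triad_profiles: ", nrow(x), " (triad, tissue) profile(s)\n", sep = "")
  print(table(x$tissue, x$category))
  invisible(x)
}

#' Summarize bias categories per tissue
#'
#' @param profiles a `"triad_profiles"` table.
#' @param digits decimal places for the percentage columns (default 1,
#'   matching the conventional reporting style).
#' @return data.frame: one row per tissue with `n` (triads expressed) and a
#'   percentage column per category; percentages sum to 100 within rounding.
#' @export
summarize_by_tissue <- function(profiles, digits = 1) {
  out <- do.call(rbind, lapply(split(profiles, profiles$tissue), function(p) {
    n <- nrow(p)
    pc <- if (n) 100 * table(p$category) / n else
      table(factor(character(), levels = BIAS_CATEGORIES)) * 0
    df <- data.frame(tissue = p$tissue[1] %||% NA_character_, n = n)
    cbind(df, as.data.frame.matrix(t(round(as.matrix(pc), digits))))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

TISSUE_CLASSES <- list(root = "root", leaf_shoot = "leaf_shoot",
                       spike_grain = c("spike", "grain"))

#' Call tissue-specific expression per gene
#'
#' Genes are classed over three tissue classes — root, leaf/shoot and
#' spike/grain — pooling stages and cultivars by maximum TPM:
#' `not_expressed` when the maximum TPM is below the threshold everywhere;
#' `<class>_specific` when the threshold is reached in exactly one class;
#' `ubiquitous` otherwise.
#'
#' @param expr expression records.
#' @param gene_ids genes to call (default: all genes present in `expr`).
#' @param expressed_threshold TPM threshold, default 1.
#' @return data.frame `gene_id`, `class`, and the per-class maximum TPM
#'   (`max_root`, `max_leaf_shoot`, `max_spike_grain`).
#' @export
call_tissue_specificity <- function(expr, gene_ids = NULL, expressed_threshold = 1) {
  if (is.null(gene_ids)) gene_ids <- sort(unique(expr$gene_id))
  missing <- setdiff(gene_ids, unique(expr$gene_id))
  if (length(missing)) {
    warning("gene(s) with no expression record called not_expressed: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ..." else "")
  }
  tm <- tissue_tpm(expr, gene_ids)
  cls_max <- vapply(TISSUE_CLASSES, function(tt)
    apply(tm[, tt, drop = FALSE], 1, max), numeric(length(gene_ids)))
  cls_max <- matrix(cls_max, ncol = length(TISSUE_CLASSES),
                    dimnames = list(gene_ids, names(TISSUE_CLASSES)))
  on <- cls_max >= expressed_threshold
  n_on <- rowSums(on)
  class_out <- ifelse(n_on == 0, "not_expressed",
                ifelse(n_on > 1, "ubiquitous",
                       paste0(names(TISSUE_CLASSES)[apply(on, 1, which.max)],
                              "_specific")))
  data.frame(gene_id = gene_ids, class = class_out,
             max_root = cls_max[, "root"], max_leaf_shoot = cls_max[, "leaf_shoot"],
             max_spike_grain = cls_max[, "spike_grain"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a log2(TPM + 1) gene x sample matrix for heatmaps
#'
#' @param expr expression records.
#' @param path output TSV path.
#' @return the matrix, invisibly.
#' @export
write_log2_matrix <- function(expr, path) {
  sample_id <- paste(expr$tissue, expr$stage, expr$cultivar, sep = ".")
  genes <- sort(unique(expr$gene_id)); samples <- sort(unique(sample_id))
  m <- matrix(0, length(genes), length(samples), dimnames = list(genes, samples))
  m[cbind(match(expr$gene_id, genes), match(sample_id, samples))] <- expr$tpm
  m <- log2(m + 1)
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
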