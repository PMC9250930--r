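#' Configuration for the synthetic polyploid generator
#'
#' Bundles every tunable of the simulator. Defaults describe a hexaploid
#' (A/B/D) genome with 7 chromosome groups whose homoeolog-group category mix
#' follows the wheat nitrate-transporter catalogue (103 triads : 26 diads :
#' 2 tetrads : 48 singletons), whose triads are mostly balanced in expression
#' (60% balanced, remainder spread over the six biased categories), and whose
#' expressed-gene fractions mirror the published family-level tissue calls.
#'
#' @param seed integer master seed; every stage derives its own stream from
#'   it (see Details).
#' @param subfamilies subfamily tokens to simulate; subfamilies whose family
#'   is NRT2 get intronless (single-exon) gene models.
#' @param groups_per_subfamily homoeolog groups per subfamily.
#' @param group_category_proportions probabilities over
#'   triad/diad/tetrad/singleton (normalized internally).
#' @param un_singleton_fraction fraction of singletons placed on unplaced
#'   scaffolds ("Un").
#' @param bias_category_proportions probabilities over the seven expression
#'   bias categories (see [bias_centroids()]).
#' @param specificity_proportions probabilities over the five
#'   tissue-specificity classes.
#' @param concentration Dirichlet concentration around bias centroids;
#'   `Inf` is the exact zero-noise limit.
#' @param tpm_log_mean,tpm_log_sd log-normal parameters of expressed TPM
#'   magnitudes.
#' @param threshold_tpm detection threshold the generator plants around.
#' @param n_snps number of SNP markers to simulate.
#' @param snp_window_mix fraction of SNPs planted within `window_mb` of a
#'   gene; the rest are placed outside the window.
#' @param window_mb proximity window in Mb.
#' @param chrom_length_bp simulated chromosome length in bp.
#' @param exon_range integer range of exon counts for multi-exon families.
#'
#' @details A single integer seed governs all draws: stage `k` of
#'   (catalog, expression, snps) seeds R's RNG with
#'   `(seed * 97 + k * 1009) mod (2^31 - 1)`, so stages are reproducible in
#'   isolation and identical config + seed gives byte-identical output.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              subfamilies = c("NPF5", "NRT2", "CLC", "SLAC"),
                              groups_per_subfamily = 12,
                              group_category_proportions = c(triad = 103, diad = 26,
                                                             tetrad = 2, singleton = 48),
                              un_singleton_fraction = 9 / 48,
                              bias_category_proportions = c(Balanced = 0.60,
                                                            A_dominant = 0.4 / 6,
                                                            B_dominant = 0.4 / 6,
                                                            D_dominant = 0.4 / 6,
                                                            A_suppressed = 0.4 / 6,
                                                            B_suppressed = 0.4 / 6,
                                                            D_suppressed = 0.4 / 6),
                              specificity_proportions = c(ubiquitous = 0.56,
                                                          root_specific = 0.05,
                                                          leaf_shoot_specific = 0.03,
                                                          spike_grain_specific = 0.04,
                                                          not_expressed = 0.32),
                              concentration = 200,
                              tpm_log_mean = log(10), tpm_log_sd = 1,
                              threshold_tpm = 1,
                              n_snps = 100, snp_window_mix = 0.5, window_mb = 15,
                              chrom_length_bp = 6e8,
                              exon_range = c(2L, 8L)) {
  stopifnot(length(seed) == 1, is.finite(seed))
  check_prop <- function(p, levels) {
    stopifnot(setequal(names(p), levels), all(p >= 0), sum(p) > 0)
    p[levels] / sum(p)
  }
  group_category_proportions <- check_prop(group_category_proportions,
                                           c("triad", "diad", "tetrad", "singleton"))
  bias_category_proportions <- check_prop(bias_category_proportions, BIAS_CATEGORIES)
  specificity_proportions <- check_prop(specificity_proportions,
                                        c("ubiquitous", "root_specific",
                                          "leaf_shoot_specific",
                                          "spike_grain_specific", "not_expressed"))
  stopifnot(concentration > 0, tpm_log_sd >= 0, threshold_tpm > 0,
            n_snps >= 0, snp_window_mix >= 0, snp_window_mix <= 1,
            window_mb > 0, chrom_length_bp > 2e6)
  structure(list(seed = as.integer(seed), subfamilies = subfamilies,
                 groups_per_subfamily = groups_per_subfamily,
                 group_category_proportions = group_category_proportions,
                 un_singleton_fraction = un_singleton_fraction,
                 bias_category_proportions = bias_category_proportions,
                 specificity_proportions = specificity_proportions,
                 concentration = concentration,
                 tpm_log_mean = tpm_log_mean, tpm_log_sd = tpm_log_sd,
                 threshold_tpm = threshold_tpm,
                 n_snps = n_snps, snp_window_mix = snp_window_mix,
                 window_mb = window_mb, chrom_length_bp = chrom_length_bp,
                 exon_range = as.integer(exon_range)),
            class = "simulation_config")
}

split_seed <- function(config, stream) {
  k <- match(stream, c("catalog", "expression", "snps"))
  as.integer((as.numeric(config$seed) * 97 + k * 1009) %% (2^31 - 1))
}

make_exons <- function(start, end, n) {
  # n non-overlapping exons spanning [start, end]
  len <- end - start + 1
  if (n == 1 || len < 2 * n) return(cbind(start = start, end = end))
  cuts <- sort(sample(seq_len(len - 1), 2 * (n - 1)))
  bounds <- c(start, start + cuts, end)
  ex_start <- bounds[seq(1, 2 * n - 1, by = 2)]
  ex_end <- bounds[seq(2, 2 * n, by = 2)]
  ex_end[n] <- end
  cbind(start = ex_start, end = ex_end)
}

#' Simulate a polyploid gene-family catalogue with known groups
#'
#' Generates gene models on a 3-subgenome (A/B/D, plus "Un") genome with 7
#' chromosome groups, homoeolog groups drawn from the configured
#' triad/diad/tetrad/singleton mix, and one gene tree per subfamily in which
#' every planted group is a clade (tetrad copies as sister leaves; the two
#' copies sit within 100 kb on their subgenome, emulating tandem
#' duplication). Deterministic under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `"synthetic_catalog"`: `genes` (a [gene_models()]
#'   table), `trees` (named list of `phylo`, one per subfamily) and `truth`
#'   (data.frame: gene_id, subfamily, group, category, subgenome,
#'   chrom_group, start).
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(split_seed(config, "catalog"))
  cats <- names(config$group_category_proportions)
  rows <- list(); clades <- list()
  for (subf in config$subfamilies) {
    fam <- family_of_subfamily(subf)
    single_exon <- identical(fam, "NRT2")
    clades[[subf]] <- character(0)
    for (g in seq_len(config$groups_per_subfamily)) {
      category <- sample(cats, 1, prob = config$group_category_proportions)
      cg <- sample(1:7, 1)
      base <- round(stats::runif(1, 1e6, config$chrom_length_bp - 2e6))
      sgs <- switch(category,
        triad = SUBGENOMES,
        diad = sort(sample(SUBGENOMES, 2)),
        tetrad = SUBGENOMES,
        singleton = if (stats::runif(1) < config$un_singleton_fraction) "Un"
                    else sample(SUBGENOMES, 1))
      dup_sg <- if (category == "tetrad") sample(SUBGENOMES, 1) else NA
      members <- data.frame(subgenome = sgs, copy = 1L, stringsAsFactors = FALSE)
      if (!is.na(dup_sg)) {
        members <- rbind(members, data.frame(subgenome = dup_sg, copy = 2L))
      }
      members <- members[order(members$subgenome, members$copy), , drop = FALSE]
      for (k in seq_len(nrow(members))) {
        sg <- members$subgenome[k]
        jitter <- round(stats::runif(1, -5e5, 5e5))
        start <- max(1, base + jitter)
        if (members$copy[k] == 2L) {
          prev <- rows[[length(rows)]]
          start <- prev$start + prev$end - prev$start + 1 +
            round(stats::runif(1, 1e3, 1e5))  # adjacent tandem copy
        }
        len <- round(stats::runif(1, 1000, 25000))
        n_ex <- if (single_exon) 1L else
          sample(seq(config$exon_range[1], config$exon_range[2]), 1)
        gid <- sprintf("SYN%s.G%02d.%s%d", subf, g, sg, members$copy[k])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = if (sg == "Un") "Un" else paste0(cg, sg),
          start = start, end = start + len - 1,
          strand = sample(c("+", "-"), 1), n_ex = n_ex,
          family = fam, subfamily = subf, group = paste0(subf, ".G", g),
          category = category, stringsAsFactors = FALSE)
      }
      ids <- vapply(rows[(length(rows) - nrow(members) + 1):length(rows)],
                    function(r) r$gene_id, "")
      clades[[subf]] <- c(clades[[subf]], group_clade_newick(ids, members$subgenome))
    }
  }
  tab <- do.call(rbind, rows)
  genes <- gene_models(tab$gene_id, tab$chrom, tab$start, tab$end, tab$strand,
                       exons = Map(make_exons, tab$start, tab$end, tab$n_ex),
                       family = tab$family, subfamily = tab$subfamily)
  trees <- lapply(clades, function(cl) {
    nwk <- if (length(cl) == 1 && !grepl("\\(", cl)) paste0("(", cl, ");")
           else paste0(Reduce(function(a, b) paste0("(", a, ",", b, ")"), cl), ";")
    ape::read.tree(text = nwk)
  })
  ct <- parse_chrom_token(tab$chrom)
  truth <- data.frame(gene_id = tab$gene_id, subfamily = tab$subfamily,
                      group = tab$group, category = tab$category,
                      subgenome = ct$subgenome, chrom_group = ct$chrom_group,
                      start = tab$start, stringsAsFactors = FALSE)
  structure(list(genes = genes, trees = trees, truth = truth),
            class = "synthetic_catalog")
}

group_clade_newick <- function(ids, subgenomes) {
  # triad ((A,B),D); tetrad with duplicated copies as sisters
  by_sg <- split(ids, subgenomes)
  units <- vapply(by_sg, function(x)
    if (length(x) > 1) paste0("(", paste(x, collapse = ","), ")") else x, "")
  if (length(units) == 1) return(unname(units))
  paste0("(", Reduce(function(a, b) paste0("(", a, ",", b, ")"), unname(units)), ")")
}

#' @export
print.synthetic_catalog <- function(x, ...) {
  cat("synthetic_catalog: ", nrow(x$genes), " gene(s), ",
      length(unique(x$truth$group)), " planted group(s), ",
      length(x$trees), " subfamily tree(s)\n", sep = "")
  print(table(x$truth$subfamily, x$truth$category))
  invisible(x)
}

rdirichlet_centroid <- function(centroid, concentration, smoothing = 1e-2) {
  if (!is.finite(concentration)) return(centroid)  # zero-noise limit
  x <- stats::rgamma(length(centroid), shape = concentration * centroid + smoothing)
  x / sum(x)
}

#' Simulate expression records with planted bias and specificity
#'
#' Each planted group first draws a tissue-specificity class (which tissues
#' it is expressed in at all). In each expressed tissue a triad draws a bias
#' category, homoeolog fractions around that category's centroid (Dirichlet
#' with the configured concentration; `Inf` gives the centroid exactly) and
#' a total magnitude of `3 * threshold + LogNormal`; members of non-triad
#' groups draw independent magnitudes of `threshold + LogNormal`. In
#' unexpressed tissues every member draws below `threshold / 6`, so even a
#' triad sum stays under the detection threshold. One record is emitted per
#' (gene, tissue, stage, cultivar); replicates within a tissue share the
#' tissue-level draw.
#'
#' @param sim a `"synthetic_catalog"` from [simulate_catalog()].
#' @param config the same [simulation_config()].
#' @param cultivars cultivar labels, default `c("CS", "AZ")`.
#' @return list: `expr` (expression records), `truth_bias` (data.frame
#'   group x tissue planted category for triads), `truth_specificity`
#'   (per-gene planted class).
#' @export
simulate_expression <- function(sim, config, cultivars = c("CS", "AZ")) {
  stopifnot(inherits(sim, "synthetic_catalog"), inherits(config, "simulation_config"))
  set.seed(split_seed(config, "expression"))
  cen <- bias_centroids()
  thr <- config$threshold_tpm
  groups <- split(sim$truth, sim$truth$group)

  expr <- list(); bias <- list(); spec <- list()
  for (gname in sort(names(groups))) {
    g <- groups[[gname]]
    cls <- sample(names(config$specificity_proportions), 1,
                  prob = config$specificity_proportions)
    tissues_on <- switch(cls, ubiquitous = TISSUES, root_specific = "root",
                         leaf_shoot_specific = "leaf_shoot",
                         spike_grain_specific = c("spike", "grain"),
                         not_expressed = character(0))
    spec[[gname]] <- data.frame(gene_id = g$gene_id, class = cls,
                                stringsAsFactors = FALSE)
    is_triad <- g$category[1] == "triad" && !any(g$subgenome == "Un")
    for (ti in TISSUES) {
      if (ti %in% tissues_on) {
        if (is_triad) {
          category <- sample(BIAS_CATEGORIES, 1,
                             prob = config$bias_category_proportions)
          f <- rdirichlet_centroid(cen[category, ], config$concentration)
          total <- 3 * thr + stats::rlnorm(1, config$tpm_log_mean, config$tpm_log_sd)
          tpm <- total * f[match(g$subgenome, SUBGENOMES)]
          bias[[length(bias) + 1L]] <- data.frame(group = gname, tissue = ti,
                                                  category = category,
                                                  stringsAsFactors = FALSE)
        } else {
          tpm <- thr + stats::rlnorm(nrow(g), config$tpm_log_mean, config$tpm_log_sd)
        }
      } else {
        tpm <- stats::runif(nrow(g), 0, thr / 6)
      }
      reps <- expand.grid(stage = STAGES, cultivar = cultivars,
                          stringsAsFactors = FALSE)
      expr[[length(expr) + 1L]] <- data.frame(
        gene_id = rep(g$gene_id, nrow(reps)), tissue = ti,
        stage = rep(reps$stage, each = nrow(g)),
        cultivar = rep(reps$cultivar, each = nrow(g)),
        tpm = rep(tpm, nrow(reps)), stringsAsFactors = FALSE)
    }
  }
  list(expr = validate_expression(do.call(rbind, c(expr, list(make.row.names = FALSE)))),
       truth_bias = do.call(rbind, bias),
       truth_specificity = do.call(rbind, c(unname(spec), list(make.row.names = FALSE))))
}

#' Simulate SNP markers at controlled distances from genes
#'
#' A configured fraction of markers is planted at a known offset (uniform
#' within the window) from a randomly chosen placed gene's start; the
#' remainder are background markers placed so that no gene lies within the
#' window (rejection sampling). True planted distances are recorded in Mb.
#'
#' @param genes a [gene_models()] table (e.g. from [simulate_catalog()]).
#' @param config a [simulation_config()].
#' @return list: `snps` (SNP table) and `truth` (data.frame marker_id,
#'   gene_id, distance_mb; `NA` gene for background markers).
#' @export
simulate_snps <- function(genes, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(config, "simulation_config"))
  if (nrow(genes) == 0) stop("no genes to place SNPs against")
  set.seed(split_seed(config, "snps"))
  placed <- genes[genes$chrom != "Un", , drop = FALSE]
  n_in <- round(config$n_snps * config$snp_window_mix)
  half <- config$window_mb * 1e6
  rows <- list(); truth <- list()
  for (i in seq_len(config$n_snps)) {
    mid <- sprintf("SYNSNP%04d", i)
    if (i <= n_in) {
      gidx <- sample(nrow(placed), 1)
      offset <- round(stats::runif(1, 0, half)) * sample(c(-1, 1), 1)
      pos <- max(1, placed$start[gidx] + offset)
      rows[[i]] <- data.frame(marker_id = mid, chrom = placed$chrom[gidx],
                              position = pos, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(marker_id = mid, gene_id = placed$gene_id[gidx],
                               distance_mb = abs(pos - placed$start[gidx]) / 1e6,
                               stringsAsFactors = FALSE)
    } else {
      for (try in 1:200) {
        chrom <- sample(unique(placed$chrom), 1)
        pos <- round(stats::runif(1, 1, config$chrom_length_bp))
        on_chrom <- placed[placed$chrom == chrom, , drop = FALSE]
        if (all(abs(on_chrom$start - pos) > half)) break
        if (try == 200) stop("could not place a background SNP outside the window")
      }
      rows[[i]] <- data.frame(marker_id = mid, chrom = chrom, position = pos,
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(marker_id = mid, gene_id = NA_character_,
                               distance_mb = NA_real_, stringsAsFactors = FALSE)
    }
  }
  snp_tab <- do.call(rbind, rows)
  list(snps = snp_markers(snp_tab$marker_id, snp_tab$chrom, snp_tab$position),
       truth = do.call(rbind, truth))
}
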