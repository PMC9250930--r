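#' Read and validate a pipeline configuration
#'
#' A single declarative YAML file: input paths, numeric parameters
#' (`threshold_tpm`, `window_mb`), `species_prefix`, `seed` and `output_dir`.
#' Referenced input paths must exist at validation time; numeric parameters
#' must be positive.
#'
#' @param path YAML file, or a named list of overrides.
#' @param overrides named list of parameters that win over the file (the
#'   command-line layer passes flag values here).
#' @return list of class `"pipeline_config"` with every resolved parameter.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(threshold_tpm = 1, window_mb = 15, species_prefix = "Ta",
              seed = 1, output_dir = "triadkit_out")
  if (is.list(path)) {
    cfg[names(path)] <- path
  } else if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    cfg[names(y)] <- y
  }
  cfg[names(overrides)] <- overrides
  for (p in c("threshold_tpm", "window_mb", "seed")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) stop(p, " must be a positive number")
  }
  for (key in c("gff", "trees", "expression", "snps", "domain_hits", "profile_hits")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("configured input does not exist: ", key, " = ", cfg[[key]])
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(...) message("[triadkit] ", ...)

artifact <- function(cfg, name) file.path(cfg$output_dir, name)

require_artifact <- function(cfg, name, produced_by) {
  p <- artifact(cfg, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "': run stage '", produced_by, "' first")
  }
  p
}

write_manifest <- function(cfg, stage, inputs, params, outputs) {
  man <- list(stage = stage,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              parameters = params,
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))),
              outputs = lapply(outputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))))
  yaml::write_yaml(man, artifact(cfg, paste0(stage, "_manifest.yaml")))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic genome + trees + expression + SNPs with
#' truth sidecars), `catalog` (merge evidence streams and curate),
#' `groups` (tree-based homoeolog grouping), `name` (group IDs and gene
#' names), `express` (triad bias profiles and per-tissue summaries),
#' `specificity` (tissue-specificity calls), `proximity` (SNP-to-gene
#' hits; with `fixture = TRUE` it re-derives the packaged reference panel's
#' distances instead), `report` (roll-up counts). Each stage writes its
#' outputs plus a manifest (inputs, parameters, md5 checksums) into
#' `output_dir`; every resolved parameter is logged.
#'
#' @param name stage name.
#' @param config a `"pipeline_config"` (or list / YAML path accepted by
#'   [read_pipeline_config()]).
#' @param fixture for `proximity`: use the packaged reference panel.
#' @return invisibly, a list of written artifact paths.
#' @export
run_stage <- function(name, config, fixture = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log("stage ", name, ": threshold_tpm=", cfg$threshold_tpm,
               " window_mb=", cfg$window_mb, " prefix=", cfg$species_prefix,
               " seed=", cfg$seed, " output_dir=", cfg$output_dir)
  paths <- switch(name,
    simulate = stage_simulate(cfg),
    catalog = stage_catalog(cfg),
    groups = stage_groups(cfg),
    name = stage_name(cfg),
    express = stage_express(cfg),
    specificity = stage_specificity(cfg),
    proximity = stage_proximity(cfg, fixture),
    report = stage_report(cfg),
    stop("unknown stage: ", name)
  )
  invisible(paths)
}

#' @rdname run_stage
#' @param stages stage names, run in order.
#' @export
run_pipeline <- function(config, stages = c("simulate", "groups", "name",
                                            "express", "specificity", "proximity",
                                            "report")) {
  for (s in stages) run_stage(s, config)
  invisible(config)
}

stage_simulate <- function(cfg) {
  sc <- simulation_config(seed = cfg$seed, threshold_tpm = cfg$threshold_tpm,
                          window_mb = cfg$window_mb)
  sim <- simulate_catalog(sc)
  ex <- simulate_expression(sim, sc)
  sn <- simulate_snps(sim$genes, sc)
  out <- c(gff = artifact(cfg, "genes.gff3"), trees = artifact(cfg, "trees.nwk"),
           expression = artifact(cfg, "expression.tsv"),
           snps = artifact(cfg, "snps.tsv"),
           truth_groups = artifact(cfg, "truth_groups.tsv"),
           truth_bias = artifact(cfg, "truth_bias.tsv"),
           truth_specificity = artifact(cfg, "truth_specificity.tsv"),
           truth_snps = artifact(cfg, "truth_snps.tsv"))
  write_gene_models(sim$genes, out["gff"])
  write_trees(sim$trees, out["trees"])
  write_expression_table(ex$expr, out["expression"])
  write_snp_table(sn$snps, out["snps"])
  for (nm in c("truth_groups", "truth_bias", "truth_specificity", "truth_snps")) {
    tab <- switch(nm, truth_groups = sim$truth, truth_bias = ex$truth_bias,
                  truth_specificity = ex$truth_specificity, truth_snps = sn$truth)
    utils::write.table(tab, out[nm], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(cfg, "simulate", character(), cfg[c("seed", "threshold_tpm", "window_mb")],
                 as.list(out))
  out
}

stage_catalog <- function(cfg) {
  if (is.null(cfg$domain_hits) || is.null(cfg$profile_hits)) {
    stop("stage 'catalog' needs config entries domain_hits and profile_hits")
  }
  gff <- cfg$gff %||% require_artifact(cfg, "genes.gff3", "simulate")
  genes <- read_gene_models(gff)
  merged <- merge_evidence(read_candidate_hits(cfg$domain_hits),
                           read_candidate_hits(cfg$profile_hits))
  cat <- curate(merged, genes)
  out <- c(catalog = artifact(cfg, "catalog.tsv"),
           dropped = artifact(cfg, "catalog_dropped.tsv"))
  tab <- as.data.frame(cat$genes)[c("gene_id", "chrom", "start", "end",
                                    "family", "subfamily")]
  tab$sources <- cat$provenance$sources[match(tab$gene_id, cat$provenance$gene_id)]
  utils::write.table(tab, out["catalog"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cat$dropped, out["dropped"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(cfg, "catalog", list(cfg$domain_hits, cfg$profile_hits, gff),
                 list(), as.list(out))
  out
}

stage_groups <- function(cfg) {
  gff <- cfg$gff %||% require_artifact(cfg, "genes.gff3", "simulate")
  trees_path <- cfg$trees %||% require_artifact(cfg, "trees.nwk", "simulate")
  genes <- read_gene_models(gff)
  trees <- read_trees(trees_path, genes)
  groups <- do.call(rbind, lapply(trees, infer_homoeolog_groups, genes = genes))
  class(groups) <- c("homoeolog_groups", "data.frame")
  out <- c(groups = artifact(cfg, "groups.tsv"),
           ideogram = artifact(cfg, "ideogram_track.tsv"))
  write_groups_tsv(groups, out["groups"])
  write_ideogram_track(groups, out["ideogram"])
  write_manifest(cfg, "groups", list(gff, trees_path), list(), as.list(out))
  out
}

stage_name <- function(cfg) {
  groups <- read_groups_tsv(require_artifact(cfg, "groups.tsv", "groups"))
  named <- assign_group_ids(groups, prefix = cfg$species_prefix)
  nm <- assign_gene_names(named, prefix = cfg$species_prefix)
  out <- c(names = artifact(cfg, "names.tsv"))
  write_name_map(nm, out["names"])
  write_manifest(cfg, "name", list(artifact(cfg, "groups.tsv")),
                 list(species_prefix = cfg$species_prefix), as.list(out))
  out
}

stage_express <- function(cfg) {
  expr <- read_expression_table(cfg$expression %||%
                                  require_artifact(cfg, "expression.tsv", "simulate"))
  groups <- read_groups_tsv(require_artifact(cfg, "groups.tsv", "groups"))
  groups <- assign_group_ids(groups, prefix = cfg$species_prefix)
  prof <- triad_expression_profiles(expr, groups, threshold_tpm = cfg$threshold_tpm)
  out <- c(profiles = artifact(cfg, "triad_profiles.tsv"),
           summary = artifact(cfg, "tissue_summary.tsv"),
           log2 = artifact(cfg, "log2_matrix.tsv"))
  utils::write.table(as.data.frame(prof), out["profiles"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summarize_by_tissue(prof), out["summary"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_log2_matrix(expr, out["log2"])
  write_manifest(cfg, "express", list(), list(threshold_tpm = cfg$threshold_tpm),
                 as.list(out))
  out
}

stage_specificity <- function(cfg) {
  expr <- read_expression_table(cfg$expression %||%
                                  require_artifact(cfg, "expression.tsv", "simulate"))
  calls <- call_tissue_specificity(expr, expressed_threshold = cfg$threshold_tpm)
  out <- c(specificity = artifact(cfg, "specificity.tsv"))
  utils::write.table(calls, out["specificity"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(cfg, "specificity", list(),
                 list(expressed_threshold = cfg$threshold_tpm), as.list(out))
  out
}

stage_proximity <- function(cfg, fixture = FALSE) {
  out <- c(hits = artifact(cfg, "proximity_hits.tsv"),
           summary = artifact(cfg, "proximity_summary.tsv"),
           bed = artifact(cfg, "snp_windows.bed"))
  if (fixture) {
    ref <- read_reference_proximity()
    hits <- reference_panel_hits(ref)
    utils::write.table(hits, out["hits"], sep = "\t", quote = FALSE, row.names = FALSE)
    s <- summarize_hits(ref, prefix = cfg$species_prefix)
    snps <- ref[c("marker_id", "chrom", "position")]
  } else {
    snps_tab <- read_snp_table(cfg$snps %||% require_artifact(cfg, "snps.tsv", "simulate"))
    genes <- read_gene_models(cfg$gff %||% require_artifact(cfg, "genes.gff3", "simulate"))
    hits <- find_nearby_genes(snps_tab, genes, window_mb = cfg$window_mb)
    utils::write.table(as.data.frame(hits), out["hits"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    s <- summarize_hits(hits, prefix = cfg$species_prefix)
    snps <- snps_tab
  }
  utils::write.table(
    data.frame(metric = c("n_snps", "n_genes", paste0("genes_", names(s$per_family))),
               value = c(s$n_snps, s$n_genes, as.integer(s$per_family))),
    out["summary"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_snp_windows_bed(snps, out["bed"], window_mb = cfg$window_mb)
  write_manifest(cfg, "proximity", list(),
                 list(window_mb = cfg$window_mb, fixture = fixture), as.list(out))
  out
}

stage_report <- function(cfg) {
  files <- list.files(cfg$output_dir, pattern = "\\.(tsv|gff3|nwk|bed)$",
                      full.names = TRUE)
  out <- c(report = artifact(cfg, "report.tsv"))
  utils::write.table(
    data.frame(artifact = basename(files), md5 = unname(tools::md5sum(files)),
               bytes = file.size(files)),
    out["report"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "report", as.list(files), list(), as.list(out))
  out
}

#' Re-derive the packaged proximity panel's distances
#'
#' Feeds the published SNP and representative gene positions back through
#' [distance_mb()], one row per (SNP, printed gene position).
#'
#' @param ref output of [read_reference_proximity()].
#' @return data.frame `marker_id`, `chrom`, `snp_position`, `gene_position`,
#'   `distance_mb` (recomputed, full precision).
#' @export
reference_panel_hits <- function(ref = read_reference_proximity()) {
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    pos <- as.numeric(strsplit(ref$gene_positions[i], ";")[[1]])
    data.frame(marker_id = ref$marker_id[i], chrom = ref$chrom[i],
               snp_position = ref$position[i], gene_position = pos,
               distance_mb = distance_mb(ref$position[i], pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_groups_tsv <- function(groups, path) {
  mem_str <- vapply(groups$members, function(m)
    paste(paste0(m$gene_id, "|", m$subgenome, "|", m$chrom_group, "|", m$start),
          collapse = ";"), "")
  out <- data.frame(group_id = groups$group_id %||% NA_character_,
                    subfamily = groups$subfamily, family = groups$family,
                    chrom_group = groups$chrom_group, category = groups$category,
                    composition = groups$composition, n_members = groups$n_members,
                    members = mem_str)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_groups_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  members <- lapply(strsplit(x$members, ";"), function(parts) {
    f <- do.call(rbind, strsplit(parts, "|", fixed = TRUE))
    data.frame(gene_id = f[, 1], subgenome = f[, 2], chrom_group = f[, 3],
               start = suppressWarnings(as.numeric(f[, 4])),
               stringsAsFactors = FALSE)
  })
  out <- x[setdiff(names(x), "members")]
  out$members <- members
  class(out) <- c("homoeolog_groups", "data.frame")
  out
}
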