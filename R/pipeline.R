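#' Pipeline configuration
#'
#' Collects every knob of the full analysis in one object so a run is
#' reproducible from its manifest. Inputs are either a simulation
#' (`sim` given) or file paths (`genome_paths`, `cds_paths`, `hits_path`,
#' `tree_path`).
#'
#' @param reference reference species name.
#' @param sim optional [sim_params()] object: simulate the inputs.
#' @param genome_paths named character vector of GFF3/BED files per
#'   species (ignored when `sim` is given).
#' @param cds_paths named character vector of CDS FASTA files per species.
#' @param hits_path 12-column homology table file.
#' @param tree_path Newick species tree (branch lengths in My).
#' @param max_evalue,top_n hit filtering, see [filter_hits()].
#' @param chain a [chain_params()] object.
#' @param ortholog_max,paralog_min,paralog_max Ks class boundaries, see
#'   [classify_block()].
#' @param clock_rate substitutions/site/year for [ks_to_time()]; the
#'   default is arbitrary and should be calibrated for real data.
#' @param window_bp retention window width.
#' @param tandem_max_gap see [find_tandem()].
#' @param reported_lengths named numeric: declared genome lengths for
#'   tandem densities; default genome length in Mb.
#' @param family_lists optional named list (per species) with elements
#'   `domain` and `homology`: gene-id vectors or one-id-per-line files for
#'   the two-evidence family call. For simulated input the tagged-family
#'   truth is used when absent.
#' @param outdir output directory, or `NULL` for an in-memory run.
#' @param seed seed for permutation tests (and the simulation when `sim`
#'   carries no seed of its own).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(reference = "ref", sim = NULL,
                            genome_paths = NULL, cds_paths = NULL,
                            hits_path = NULL, tree_path = NULL,
                            max_evalue = 1e-5, top_n = 5L,
                            chain = chain_params(),
                            ortholog_max = 0.3, paralog_min = 0.4,
                            paralog_max = 0.9,
                            clock_rate = 6.5e-9,
                            window_bp = 1e6, tandem_max_gap = 5L,
                            reported_lengths = NULL,
                            family_lists = NULL,
                            outdir = NULL, seed = 1L) {
  structure(list(reference = reference, sim = sim,
                 genome_paths = genome_paths, cds_paths = cds_paths,
                 hits_path = hits_path, tree_path = tree_path,
                 max_evalue = max_evalue, top_n = top_n, chain = chain,
                 ortholog_max = ortholog_max, paralog_min = paralog_min,
                 paralog_max = paralog_max, clock_rate = clock_rate,
                 window_bp = window_bp, tandem_max_gap = tandem_max_gap,
                 reported_lengths = reported_lengths,
                 family_lists = family_lists,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_gene_list <- function(x) {
  if (length(x) == 1 && is.character(x) && file.exists(x)) readLines(x) else as.character(x)
}

# chain + significance + per-anchor Ks + classification for one comparison
compare_genomes <- function(hits, genome_a, genome_b, cds_all, cfg) {
  ids_a <- genome_a$id; ids_b <- genome_b$id
  same <- identical(genome_species(genome_a), genome_species(genome_b))
  sub <- hits[(hits$query %in% ids_a & hits$subject %in% ids_b) |
                (hits$query %in% ids_b & hits$subject %in% ids_a), , drop = FALSE]
  sub <- filter_hits(sub, cfg$max_evalue, cfg$top_n)
  anchors <- build_anchors(sub, genome_a, genome_b)
  res <- chain_blocks(anchors, cfg$chain)
  if (nrow(res$blocks)) {
    key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
    n_per_pair <- table(key)
    na <- table(genome_a$chrom); nb <- table(genome_b$chrom)
    res$blocks$p_value <- vapply(seq_len(nrow(res$blocks)), function(k) {
      b <- res$blocks[k, ]
      block_significance(b, as.integer(na[b$chrom_a]), as.integer(nb[b$chrom_b]),
                         as.integer(n_per_pair[paste(b$chrom_a, b$chrom_b, sep = "\r")]))
    }, numeric(1))
    ks <- ng86_pairs(res$anchors[, c("gene_a", "gene_b")], cds_all)
    res$anchors$dS <- ks$dS
    res$anchors$dN <- ks$dN
    bks <- vapply(split(ks$dS, res$anchors$block_id),
                  function(v) block_ks(v)$ks, numeric(1))
    res$blocks$ks <- unname(bks[res$blocks$block_id])
    res$blocks$class <- classify_block(res$blocks$ks, cfg$ortholog_max,
                                       cfg$paralog_min, cfg$paralog_max)
  } else {
    res$blocks$ks <- numeric(0)
    res$blocks$class <- character(0)
    res$anchors$dS <- numeric(0)
    res$anchors$dN <- numeric(0)
  }
  res
}

#' Run the full fractionation analysis pipeline
#'
#' Stages: input (simulate or read), hit filtering, collinear block
#' detection (self-comparisons for every species plus reference-anchored
#' cross comparisons), NG86 Ks and block classification, alignment-table
#' construction, loss accounting (per-chromosome retention, ordinal trend,
#' subgenome partition, Dollo branch assignment and branch rates), tandem
#' clusters, and family enrichment. Identical configurations (including
#' seeds) yield identical outputs; when `outdir` is set every stage table
#' is written as TSV next to a JSON manifest.
#'
#' @param config a [pipeline_config()] object.
#' @return list of class `"synfrac_run"` with elements `genomes`, `hits`,
#'   `self_comparisons`, `ref_comparisons`, `block_summary`, `table`,
#'   `retention`, `ordinal_trends`, `subgenomes`, `branch_report`,
#'   `tandem`, `enrichment`, `manifest` (and `sim` for simulated input).
#' @export
run_pipeline <- function(config = pipeline_config(sim = sim_params())) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "synfrac",
                   version = as.character(utils::packageVersion("synfrac")),
                   seed = config$seed, stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
  }

  # --- stage 1: inputs ----------------------------------------------------
  sim <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_genomes(config$sim)
    genomes <- sim$genomes
    cds_all <- unlist(unname(sim$cds))
    hits <- sim$hits
    tree <- sim$tree
  } else {
    if (is.null(config$genome_paths) || is.null(config$hits_path))
      stop("[input] either sim or genome_paths + hits_path are required")
    genomes <- lapply(names(config$genome_paths), function(sp)
      read_gene_positions(config$genome_paths[[sp]], sp))
    names(genomes) <- names(config$genome_paths)
    cds_all <- character(0)
    if (!is.null(config$cds_paths)) {
      for (sp in names(config$cds_paths)) {
        s <- Biostrings::readDNAStringSet(config$cds_paths[[sp]])
        cds_all <- c(cds_all, stats::setNames(as.character(s), names(s)))
      }
    }
    hits <- read_homology_table(config$hits_path)
    tree <- if (!is.null(config$tree_path)) ape::read.tree(config$tree_path) else NULL
  }
  if (!config$reference %in% names(genomes))
    stop("[input] reference species ", config$reference, " not among genomes")
  reference <- genomes[[config$reference]]
  others <- setdiff(sort(names(genomes)), config$reference)
  stage("input", list(species = names(genomes),
                      genes = vapply(genomes, nrow, integer(1)),
                      hit_rows = nrow(hits)))

  # --- stages 2-4: blocks + Ks ---------------------------------------------
  self_cmp <- lapply(names(genomes), function(sp)
    compare_genomes(hits, genomes[[sp]], genomes[[sp]], cds_all, config))
  names(self_cmp) <- names(genomes)
  ref_cmp <- lapply(others, function(sp)
    compare_genomes(hits, reference, genomes[[sp]], cds_all, config))
  names(ref_cmp) <- others
  all_blocks <- rbind(do.call(rbind, lapply(self_cmp, `[[`, "blocks")),
                      do.call(rbind, lapply(ref_cmp, `[[`, "blocks")))
  rownames(all_blocks) <- NULL
  block_summary <- block_stats(all_blocks)
  stage("blocks", list(n_blocks = nrow(all_blocks),
                       n_anchors = sum(all_blocks$n_anchors)))
  stage("ks", list(n_anchor_ks = sum(vapply(c(self_cmp, ref_cmp),
                                            function(x) nrow(x$anchors), integer(1)))))

  # --- stage 5: alignment table -------------------------------------------
  comparisons <- c(stats::setNames(list(self_cmp[[config$reference]]), config$reference),
                   ref_cmp)
  tab <- build_table(reference, comparisons)
  stage("table", list(rows = nrow(tab), columns = names(tab)))

  # --- stage 6: loss accounting -------------------------------------------
  retention <- lapply(others, function(sp)
    chromosome_loss(tab, sp, reference, config$window_bp))
  names(retention) <- others
  ordinal_trends <- lapply(retention, function(p)
    ordinal_trend(p, seed = config$seed))
  subgenomes <- split_subgenomes(tab, comparisons[[config$reference]], others)
  branch_report <- NULL
  if (!is.null(tree)) {
    patterns <- presence_patterns(tab)
    counts <- dollo_assign(patterns, tree, reference_species = config$reference)
    branch_report <- branch_rates(counts, tree)
  }
  stage("loss", list(
    mean_loss = vapply(retention, function(p)
      mean(p$per_chromosome$loss_fraction, na.rm = TRUE), numeric(1)),
    dollo_total = if (!is.null(branch_report)) sum(branch_report$losses) else NA))

  # --- stage 7: tandem ----------------------------------------------------
  tandem <- lapply(names(genomes), function(sp) {
    g <- genomes[[sp]]
    sub <- hits[hits$query %in% g$id & hits$subject %in% g$id, , drop = FALSE]
    sub <- filter_hits(sub, config$max_evalue, top_n = 1000L)
    cl <- find_tandem(g, sub, config$tandem_max_gap)
    len <- if (!is.null(config$reported_lengths) && sp %in% names(config$reported_lengths))
      config$reported_lengths[[sp]] else attr(g, "genome_length") / 1e6
    list(clusters = cl, stats = tandem_stats(cl, g, len))
  })
  names(tandem) <- names(genomes)
  stage("tandem", list(n_tandem = vapply(tandem, function(t) t$stats$n_tandem,
                                         numeric(1))))

  # --- stage 8: enrichment ------------------------------------------------
  enrichment <- NULL
  fam_sets <- NULL
  if (!is.null(config$family_lists)) {
    fam_sets <- lapply(config$family_lists, function(fl)
      family_intersect(read_gene_list(fl$domain), read_gene_list(fl$homology)))
  } else if (!is.null(sim)) {
    lm <- sim$truth$leaf_meta
    fam_genes <- lm$gene_id[lm$family %in% sim$truth$tagged_families]
    fam_sets <- lapply(names(genomes), function(sp)
      fam_genes[fam_genes %in% genomes[[sp]]$id])
    names(fam_sets) <- names(genomes)
  }
  if (!is.null(fam_sets)) {
    enrichment <- do.call(rbind, lapply(names(fam_sets), function(sp) {
      g <- genomes[[sp]]
      tan <- tandem[[sp]]$clusters$gene_id
      fam <- intersect(fam_sets[[sp]], g$id)
      ct <- table_from_counts(nrow(g), length(tan), length(fam),
                              length(intersect(tan, fam)))
      r <- yates_chi2(ct)
      data.frame(species = sp, n_genes = nrow(g), n_tandem = length(tan),
                 n_family = length(fam), n_both = ct$a,
                 statistic = r$statistic, p = r$p, direction = r$direction)
    }))
    rownames(enrichment) <- NULL
  }
  stage("enrichment", list(rows = if (is.null(enrichment)) 0L else nrow(enrichment)))

  run <- structure(list(genomes = genomes, hits = hits, sim = sim,
                        self_comparisons = self_cmp, ref_comparisons = ref_cmp,
                        block_summary = block_summary, table = tab,
                        retention = retention, ordinal_trends = ordinal_trends,
                        subgenomes = subgenomes, branch_report = branch_report,
                        tandem = tandem, enrichment = enrichment,
                        config = config, manifest = manifest),
                   class = "synfrac_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' @export
print.synfrac_run <- function(x, ...) {
  cat(sprintf("<synfrac run> %d genomes, %d blocks, table %d x %d\n",
              length(x$genomes),
              sum(vapply(c(x$self_comparisons, x$ref_comparisons),
                         function(c) nrow(c$blocks), integer(1))),
              nrow(x$table), ncol(x$table)))
  invisible(x)
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

# write every stage table plus the JSON manifest
write_run <- function(run, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create ", outdir)
  all_blocks <- do.call(rbind, c(lapply(run$self_comparisons, `[[`, "blocks"),
                                 lapply(run$ref_comparisons, `[[`, "blocks")))
  all_anchors <- do.call(rbind, c(lapply(run$self_comparisons, `[[`, "anchors"),
                                  lapply(run$ref_comparisons, `[[`, "anchors")))
  write_tsv(all_blocks, file.path(outdir, "blocks.tsv"), "synfrac collinear blocks")
  write_tsv(all_anchors, file.path(outdir, "anchors.tsv"), "synfrac block anchors")
  write_tsv(run$block_summary, file.path(outdir, "block_summary.tsv"),
            "collinear genes per block by species pair")
  write_table(run$table, file.path(outdir, "alignment_table.tsv"))
  ret <- do.call(rbind, lapply(run$retention, function(p)
    cbind(species = p$species, p$per_chromosome)))
  win <- do.call(rbind, lapply(run$retention, function(p)
    cbind(species = p$species, p$per_window)))
  write_tsv(ret, file.path(outdir, "retention.tsv"), "per-chromosome retention")
  write_tsv(win, file.path(outdir, "windows.tsv"), "windowed retention")
  if (!is.null(run$branch_report))
    write_tsv(run$branch_report, file.path(outdir, "branch_report.tsv"),
              "Dollo loss counts and rates per branch")
  tan <- do.call(rbind, lapply(names(run$tandem), function(sp)
    cbind(species = sp, run$tandem[[sp]]$clusters)))
  write_tsv(tan, file.path(outdir, "tandem_clusters.tsv"),
            paste0("tandem clusters (max_gap = ",
                   run$config$tandem_max_gap, ")"))
  if (!is.null(run$enrichment))
    write_tsv(run$enrichment, file.path(outdir, "enrichment.tsv"),
              "tandem x family association")
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
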