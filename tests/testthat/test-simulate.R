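# small, fast parameter sets for structural checks
tiny_params <- function(...) {
  sim_params(genes_per_chromosome = 12, codon_length = 5,
             per_branch_loss_rate = 2, inversion_rate = 0.5,
             tandem_birth_rate = 1, seed = 21, ...)
}

test_that("the ancestor has the configured chromosomes and clean CDS", {
  set.seed(1)
  anc <- simulate_ancestor(sim_params(seed = 1, genes_per_chromosome = 10,
                                      codon_length = 30))
  expect_equal(length(unique(anc$meta$chrom)), 7L)
  expect_equal(nrow(anc$meta), 70L)
  # no internal stops anywhere
  cds <- do.call(paste0, lapply(seq_len(ncol(anc$seqs)), function(j) anc$seqs[, j]))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds)))
  expect_false(any(grepl("\\*", aa)))
  # empty is valid
  set.seed(1)
  anc0 <- simulate_ancestor(sim_params(seed = 1, genes_per_chromosome = 0))
  expect_equal(nrow(anc0$meta), 0L)
})

test_that("WGD doubles every gene and default fusions leave 12 chromosomes", {
  set.seed(2)
  anc <- simulate_ancestor(sim_params(seed = 2, genes_per_chromosome = 8,
                                      codon_length = 4))
  no_fusion <- apply_wgd_and_fusions(anc, sim_params(seed = 2, fusion_plan = data.frame()))
  expect_equal(length(unique(no_fusion$meta$chrom)), 14L)
  expect_equal(nrow(no_fusion$paralog_pairs), nrow(anc$meta))
  expect_true(all(no_fusion$paralog_pairs$gene_a %in% no_fusion$meta$id))
  expect_true(all(no_fusion$paralog_pairs$gene_b %in% no_fusion$meta$id))
  fused <- apply_wgd_and_fusions(anc, sim_params(seed = 2))
  expect_equal(length(unique(fused$meta$chrom)), 12L)
  expect_error(apply_wgd_and_fusions(anc, sim_params(
    seed = 2, fusion_plan = data.frame(target = "c9a", source = "c1a", at = NA))),
    "unknown chromosome")
})

test_that("nested fusion shifts the host genes beyond the insertion point", {
  set.seed(3)
  anc <- simulate_ancestor(sim_params(seed = 3, genes_per_chromosome = 6,
                                      codon_length = 4))
  k <- 2L
  fused <- apply_wgd_and_fusions(anc, sim_params(
    seed = 3, fusion_plan = data.frame(target = "c1a", source = "c2a", at = k)))
  host <- fused$meta[fused$meta$chrom == "1", ]
  # order: first k host genes, then the 6 source genes, then the rest
  expect_equal(grepl("a$", host$id), rep(TRUE, 12))
  src_block <- host$id[(k + 1):(k + 6)]
  expect_true(all(sub("a$", "", src_block) %in%
                    anc$meta$id[anc$meta$chrom == "c2"]))
  tail_block <- host$id[(k + 7):12]
  expect_true(all(sub("a$", "", tail_block) %in%
                    anc$meta$id[anc$meta$chrom == "c1"]))
})

test_that("zero rates leave every leaf identical to the root", {
  p <- sim_params(genes_per_chromosome = 10, codon_length = 6,
                  per_branch_loss_rate = 0, inversion_rate = 0,
                  tandem_birth_rate = 0, clock_rate = 1e-30, wgd_ds = 0,
                  seed = 4)
  sim <- simulate_genomes(p)
  expect_equal(nrow(sim$truth$loss_events), 0L)
  expect_equal(nrow(sim$truth$inversion_events), 0L)
  expect_equal(nrow(sim$truth$tandem_events), 0L)
  root_ids <- sim$truth$root_meta$id
  for (sp in names(sim$genomes)) {
    expect_equal(sub(paste0("^", sp, "_"), "", sim$genomes[[sp]]$id),
                 root_ids, info = sp)
    expect_equal(length(unique(sim$cds[[sp]])), length(unique(
      sim$cds$ref)), info = sp)
  }
  # all sequences byte-identical across species
  expect_identical(unname(sim$cds$spA), unname(sim$cds$ref))
})

test_that("loss confined to one terminal branch leaves the others untouched", {
  p <- sim_params(genes_per_chromosome = 10, codon_length = 6,
                  per_branch_loss_rate = c(spA = 30), inversion_rate = 0,
                  tandem_birth_rate = 0, clock_rate = 1e-30, wgd_ds = 0,
                  seed = 5)
  sim <- simulate_genomes(p)
  expect_true(all(sim$truth$loss_events$branch == "spA"))
  expect_lt(nrow(sim$genomes$spA), nrow(sim$genomes$ref))
  expect_equal(nrow(sim$genomes$spB), nrow(sim$truth$root_meta))
  expect_equal(nrow(sim$genomes$ref), nrow(sim$truth$root_meta))
})

test_that("identical parameters reproduce byte-identical simulations", {
  s1 <- simulate_genomes(tiny_params())
  s2 <- simulate_genomes(tiny_params())
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$truth$loss_events, s2$truth$loss_events)
})

test_that("realized loss counts respect Poisson sampling bounds", {
  rate <- 20; dur <- 2  # spA terminal branch: expectation ~ rate*dur*mult
  counts <- vapply(1:12, function(s) {
    sim <- simulate_genomes(sim_params(
      genes_per_chromosome = 150, codon_length = 4,
      per_branch_loss_rate = c(spA = rate),
      per_chromosome_loss_multiplier = rep(1, 12),
      inversion_rate = 0, tandem_birth_rate = 0, clock_rate = 1e-30,
      wgd_ds = 0, seed = 100 + s))
    sum(sim$truth$loss_events$branch == "spA")
  }, numeric(1))
  expectation <- rate * dur
  expect_lt(abs(mean(counts) - expectation),
            3 * sqrt(expectation / length(counts)))
})

test_that("gene conservation holds at every leaf", {
  sim <- simulate_genomes(tiny_params())
  tree <- sim$tree
  labs <- c(tree$tip.label, tree$node.label)
  path_branches <- function(tip) {
    node <- which(labs == tip); out <- character(0)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      out <- c(out, labs[node]); node <- tree$edge[e, 1]
    }
    out
  }
  for (sp in names(sim$genomes)) {
    branches <- path_branches(sp)
    losses <- sum(sim$truth$loss_events$branch %in% branches)
    gains <- sum(sim$truth$tandem_events$n_copies[
      sim$truth$tandem_events$branch %in% branches])
    expect_equal(nrow(sim$genomes[[sp]]) + losses,
                 nrow(sim$truth$root_meta) + gains, info = sp)
  }
})

test_that("fixtures re-emit identically and list every expected file", {
  sim <- simulate_genomes(tiny_params())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  set.seed(99); emit_fixture(sim, d1)
  set.seed(99); emit_fixture(sim, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_true(all(c("homology.tsv", "tree.nwk", "ref.gff3", "ref.cds.fasta",
                    "spA.gff3", "truth/losses.tsv", "truth/families.tsv") %in% files))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  h1 <- vapply(files, function(f) unname(tools::md5sum(file.path(d1, f))), character(1))
  h2 <- vapply(files, function(f) unname(tools::md5sum(file.path(d2, f))), character(1))
  expect_equal(h1, h2)
})

test_that("with no noise the homology table matches the true family pairs", {
  sim <- simulate_genomes(tiny_params(noise_hits = 0))
  lm <- sim$truth$leaf_meta
  fam <- setNames(lm$family, lm$gene_id)
  expect_true(all(fam[sim$hits$query] == fam[sim$hits$subject]))
  # every surviving cross-genome ortholog pair is present
  n_expected <- sum(vapply(split(lm$gene_id, lm$family),
                           function(g) choose(length(g), 2), numeric(1)))
  expect_equal(nrow(sim$hits) / 2, n_expected)
})

test_that("realized dS tracks the target at 0.1, 0.3 and 0.6", {
  set.seed(31)
  anc <- simulate_ancestor(sim_params(n_ancestral_chromosomes = 1,
                                      genes_per_chromosome = 100,
                                      codon_length = 500, seed = 31))
  cds <- do.call(paste0, lapply(seq_len(ncol(anc$seqs)), function(j) anc$seqs[, j]))
  ids <- paste0("g", seq_along(cds))
  for (target in c(0.1, 0.3, 0.6)) {
    div <- diverge_cds(cds, target, omega_n = 0.1)
    est <- ng86_pairs(data.frame(gene_a = ids, gene_b = paste0("d", ids)),
                      setNames(c(cds, div), c(ids, paste0("d", ids))))
    expect_lt(abs(mean(est$dS) - target), 0.05)
  }
})
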