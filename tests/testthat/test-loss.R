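toy_loss_setup <- function() {
  ref <- as_genome(data.frame(id = paste0("r", 1:10),
                              chrom = rep(c("chr1", "chr2"), each = 5),
                              start = rep(c(1e5, 6e5, 1.2e6, 1.9e6, 2.4e6), 2),
                              end = rep(c(1e5, 6e5, 1.2e6, 1.9e6, 2.4e6), 2) + 1000),
                   species = "ref")
  tab <- make_table(ref$id,
                    "spA.ortholog" = c("a1", NA, "a3", NA, "a5",
                                       "a6", NA, "a8", NA, "a10"))
  list(ref = ref, tab = tab)
}

test_that("chromosome loss fractions count absent ortholog cells", {
  s <- toy_loss_setup()
  prof <- chromosome_loss(s$tab, "spA", s$ref)
  expect_equal(prof$per_chromosome$loss_fraction, c(0.4, 0.4))
  expect_equal(prof$per_chromosome$n_retained, c(3L, 3L))
  # conservation: lost + retained = reference genes; lost = ABSENT cells
  expect_equal(sum(prof$per_chromosome$n_ref - prof$per_chromosome$n_retained),
               sum(is.na(s$tab[["spA.ortholog"]])))
  full <- s$tab
  full[["spA.ortholog"]] <- paste0("a", 1:10)
  prof0 <- chromosome_loss(full, "spA", s$ref)
  expect_equal(prof0$per_chromosome$loss_fraction, c(0, 0))
})

test_that("retention windows are half-open 1-Mb bins on reference coordinates", {
  s <- toy_loss_setup()
  prof <- chromosome_loss(s$tab, "spA", s$ref)
  w1 <- prof$per_window[prof$per_window$chrom == "chr1", ]
  # genes at 100 kb and 600 kb fall in window 0; 1.2 and 1.9 Mb in window 1
  expect_equal(w1$window, c(0, 1, 2))
  expect_equal(w1$n_ref, c(2L, 2L, 1L))
  expect_equal(w1$retained_fraction, c(0.5, 0.5, 1))
})

test_that("the ordinal trend statistic hits its analytic extremes", {
  inc <- data.frame(chrom_ordinal = 1:6, loss_fraction = seq(0.2, 0.7, 0.1))
  expect_equal(ordinal_trend(inc, n_perm = 200)$rho, 1)
  dec <- data.frame(chrom_ordinal = 1:6, loss_fraction = seq(0.7, 0.2, -0.1))
  expect_equal(ordinal_trend(dec, n_perm = 200)$rho, -1)
  flat <- data.frame(chrom_ordinal = 1:6, loss_fraction = rep(0.4, 6))
  r <- ordinal_trend(flat)
  expect_equal(r$rho, 0)
  expect_equal(r$p_value, 1)
  expect_error(ordinal_trend(data.frame(chrom_ordinal = 1:2,
                                        loss_fraction = c(0.1, 0.2))),
               "at least 3")
})

test_that("the permutation p-value matches exact enumeration at 5 chromosomes", {
  y <- c(0.31, 0.28, 0.44, 0.39, 0.52)
  df <- data.frame(chrom_ordinal = 1:5, loss_fraction = y)
  got <- ordinal_trend(df, n_perm = 20000, seed = 2)
  rho_obs <- cor(1:5, y, method = "spearman")
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rhos <- vapply(perms(y), function(p) cor(1:5, p, method = "spearman"),
                 numeric(1))
  p_exact <- mean(rhos >= rho_obs - 1e-12)
  expect_lt(abs(got$p_value - p_exact), 0.02)
})

test_that("subgenome partition prefers retention then lower ordinal", {
  ref <- as_genome(data.frame(id = paste0("r", 1:20),
                              chrom = rep(c("chr3", "chr7"), each = 10),
                              start = rep(seq(1e5, 1e6, by = 1e5), 2),
                              end = rep(seq(1e5, 1e6, by = 1e5), 2) + 10),
                   species = "ref")
  ref_paralogs <- list(
    blocks = data.frame(block_id = c("p1", "p2"), species_a = "ref",
                        species_b = "ref", chrom_a = "chr3", chrom_b = "chr7",
                        orientation = "+", n_anchors = 5, score = 100,
                        p_value = 1e-4, ks = 0.6, class = "gct_paralog"),
    anchors = data.frame(block_id = rep(c("p1", "p2"), each = 5),
                         gene_a = paste0("r", 1:10),
                         gene_b = paste0("r", 11:20)))
  # block p1: side a retains 4/5, side b retains 1/5 -> a is "more"
  # block p2: tie 3 vs 3 -> chr3 (lower ordinal) wins
  spA <- rep(NA_character_, 20)
  spA[c(1, 2, 3, 4, 11)] <- "x"                    # p1 genes
  spA[c(6, 7, 8, 16, 17, 18)] <- "y"               # p2 genes
  tab <- make_table(ref$id, "spA.ortholog" = spA)
  res <- split_subgenomes(tab, ref_paralogs)
  asg <- res$assignments
  expect_equal(asg$more_side, c("a", "a"))
  expect_equal(asg$chrom_more, c("chr3", "chr3"))
  expect_equal(asg$retained_a[1], 4L)
  expect_equal(asg$retained_b[1], 1L)
  cs <- res$chromosome_summary
  expect_equal(cs$loss_fraction[cs$chrom == "chr3" & cs$subgenome == "more"],
               1 - 7 / 10)
})

test_that("fully lost region pairs are excluded and counted", {
  ref <- as_genome(data.frame(id = paste0("r", 1:4), chrom = rep(c("c1", "c2"), each = 2),
                              start = rep(c(1, 100), 2), end = rep(c(50, 150), 2)),
                   species = "ref")
  ref_paralogs <- list(
    blocks = data.frame(block_id = "p1", species_a = "ref", species_b = "ref",
                        chrom_a = "c1", chrom_b = "c2", orientation = "+",
                        n_anchors = 2, score = 50, p_value = 0.01,
                        ks = 0.55, class = "gct_paralog"),
    anchors = data.frame(block_id = "p1", gene_a = c("r1", "r2"),
                         gene_b = c("r3", "r4")))
  tab <- make_table(ref$id, "spA.ortholog" = rep(NA_character_, 4))
  res <- split_subgenomes(tab, ref_paralogs)
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(res$n_excluded, 1L)
})

dollo_tree <- function() {
  ape::read.tree(text = "(((spA:2,spB:2)AB:28,spC:30)oryza:5,ref:35)root;")
}

test_that("Dollo assignment places textbook losses on the expected branches", {
  tr <- dollo_tree()
  pat <- rbind(allgone = c(spA = FALSE, spB = FALSE, spC = FALSE),
               onlyA = c(spA = FALSE, spB = TRUE, spC = TRUE),
               sisters = c(spA = FALSE, spB = FALSE, spC = TRUE),
               keep = c(spA = TRUE, spB = TRUE, spC = TRUE))
  res <- dollo_assign(pat, tr, reference_species = "ref")
  got <- setNames(res$losses, res$branch)
  expect_equal(got[["oryza"]], 1)  # absent in every ingroup leaf
  expect_equal(got[["spA"]], 1)    # absent only in A
  expect_equal(got[["AB"]], 1)     # absent in the sister pair
  expect_equal(sum(res$losses), 3)
})

test_that("Dollo equals exhaustive minimal-branch search on an 8-leaf tree", {
  tr <- ape::read.tree(text = paste0(
    "((((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1):2,R:4);"))
  sp <- LETTERS[1:8]
  labs <- c(tr$tip.label, paste0("n", seq_len(tr$Nnode)))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 8)))
  colnames(patterns) <- sp
  res_total <- dollo_assign(patterns, tr, reference_species = "R")
  oracle <- oracle_dollo_setup(tr)
  oracle_total <- setNames(numeric(nrow(tr$edge)), labs[tr$edge[, 2]])
  for (r in seq_len(nrow(patterns))) {
    present <- logical(length(tr$tip.label))
    present[match(sp, tr$tip.label)] <- patterns[r, ]
    present[match("R", tr$tip.label)] <- TRUE
    o <- oracle(present)
    if (o$size > 0) {
      ch <- labs[tr$edge[o$edges, 2]]
      oracle_total[ch] <- oracle_total[ch] + 1
    }
  }
  got <- setNames(res_total$losses, res_total$branch)
  expect_equal(got[names(oracle_total)], oracle_total)
})

test_that("genes absent from the reference are skipped", {
  tr <- dollo_tree()
  pat <- cbind(ref = c(TRUE, FALSE),
               spA = c(FALSE, FALSE), spB = c(TRUE, FALSE), spC = c(TRUE, TRUE))
  expect_message(res <- dollo_assign(pat, tr, reference_species = "ref"),
                 "skipped")
  expect_equal(sum(res$losses), 1)  # only the attested gene's spA loss
})

test_that("branch rates reproduce the printed loss-rate arithmetic", {
  counts <- data.frame(branch = c("stem", "pre", "jing", "rufi"),
                       losses = c(7354, 417, 2193, 1229))
  rates <- branch_rates(counts, c(stem = 5, pre = 0.36, jing = 1, rufi = 1))
  expect_equal(rates$rate[1], 1470.8)
  expect_equal(round(rates$rate[2]), 1158)
  expect_equal(rate_excess(rates$rate[3], rates$rate[4]), 78.4)
  expect_warning(z <- branch_rates(data.frame(branch = "x", losses = 5),
                                   c(x = 0)), "zero-duration")
  expect_true(is.na(z$rate))
})
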