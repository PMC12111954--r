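test_that("one-to-one hits become anchors on a single chromosome pair", {
  ga <- small_genome(10, species = "A")
  gb <- small_genome(10, species = "B")
  hits <- do.call(rbind, Map(hit_row, ga$id, gb$id))
  anch <- build_anchors(filter_hits(hits), ga, gb)
  expect_equal(nrow(anch), 10L)
  expect_equal(unique(paste(anch$chrom_a, anch$chrom_b)), "chr1 chr1")
  expect_equal(sort(anch$rank_a), 0:9)
})

test_that("self-comparison drops the trivial diagonal and keeps one pair copy", {
  g <- small_genome(6, species = "A")
  hits <- rbind(hit_row(g$id[1], g$id[1]),
                hit_row(g$id[2], g$id[5], bitscore = 100),
                hit_row(g$id[5], g$id[2], bitscore = 180))
  anch <- build_anchors(hits, g, g)
  expect_equal(nrow(anch), 1L)
  expect_equal(anch$score, 180)  # max over the two directions
  expect_equal(anch$rank_a, 1L)  # normalized to the upper triangle
  expect_equal(anch$rank_b, 4L)
})

test_that("bidirectional cross-genome rows collapse to one anchor with max score", {
  ga <- small_genome(4, species = "A")
  gb <- small_genome(4, species = "B")
  hits <- rbind(hit_row(ga$id[2], gb$id[3], bitscore = 120),
                hit_row(gb$id[3], ga$id[2], bitscore = 150))
  anch <- build_anchors(hits, ga, gb)
  expect_equal(nrow(anch), 1L)
  expect_equal(anch$score, 150)
})

test_that("a perfect diagonal chains into one forward block", {
  anch <- make_anchors(0:9, 0:9)
  res <- chain_blocks(anch, chain_params(min_anchors = 3))
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "+")
  expect_equal(res$blocks$n_anchors, 10L)
  expect_equal(nrow(res$anchors), 10L)
})

test_that("an inverted middle segment splits into +/-/+ blocks of 3, 4, 3", {
  rank_b <- c(0, 1, 2, 6, 5, 4, 3, 7, 8, 9)
  anch <- make_anchors(0:9, rank_b)
  res <- chain_blocks(anch, chain_params(min_anchors = 3))
  expect_equal(nrow(res$blocks), 3L)
  sizes <- res$blocks$n_anchors[order(res$blocks$rank_a_min)]
  orients <- res$blocks$orientation[order(res$blocks$rank_a_min)]
  expect_equal(sizes, c(3L, 4L, 3L))
  expect_equal(orients, c("+", "-", "+"))
})

test_that("empty anchor sets give empty block lists", {
  res <- chain_blocks(make_anchors(integer(0), integer(0)))
  expect_equal(nrow(res$blocks), 0L)
  expect_equal(nrow(res$anchors), 0L)
})

test_that("chains are strictly monotone and anchors belong to one block", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 60
    anch <- make_anchors(sample(0:80, n, replace = FALSE),
                         sample(0:80, n, replace = FALSE))
    res <- chain_blocks(anch, chain_params(min_anchors = 3))
    if (!nrow(res$anchors)) next
    expect_false(any(duplicated(res$anchors[, c("gene_a", "gene_b")])))
    for (b in split(res$anchors, res$anchors$block_id)) {
      o <- order(b$rank_a)
      expect_true(all(diff(b$rank_a[o]) > 0))
      d <- diff(b$rank_b[o])
      expect_true(all(d > 0) || all(d < 0))
    }
  }
})

test_that("raising min_anchors never increases the block count", {
  set.seed(23)
  anch <- make_anchors(sample(0:50, 40), sample(0:50, 40))
  counts <- vapply(c(2, 3, 5, 8), function(m)
    nrow(chain_blocks(anch, chain_params(min_anchors = m))$blocks), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the DP equals brute-force best-chain enumeration on small sets", {
  set.seed(29)
  params <- chain_params(min_anchors = 2, max_gap = 10, gap_penalty = 5,
                         anchor_score = 10)
  for (n in c(6, 8, 10, 12)) {
    for (rep in 1:3) {
      anch <- make_anchors(sample(0:14, n), sample(0:14, n))
      oracle <- oracle_best_chain(anch, params)
      res <- chain_blocks(anch, params)
      # the first extracted chain is the globally best one
      got <- if (nrow(res$blocks)) max(res$blocks$score) else -Inf
      if (is.finite(oracle) && oracle >= 2 * 10 - 0) {
        expect_equal(got, oracle, info = sprintf("n=%d rep=%d", n, rep))
      } else {
        expect_true(got <= oracle)
      }
    }
  }
})

test_that("block significance separates real diagonals from noise", {
  diag_block <- data.frame(n_anchors = 10L, rank_a_min = 0, rank_a_max = 9,
                           rank_b_min = 0, rank_b_max = 9)
  expect_lt(block_significance(diag_block, 100, 100, 10), 1e-6)
  small_block <- data.frame(n_anchors = 2L, rank_a_min = 0, rank_a_max = 40,
                            rank_b_min = 0, rank_b_max = 40)
  expect_gt(block_significance(small_block, 50, 50, 200), 0.9)
  degen <- data.frame(n_anchors = 4L, rank_a_min = 5, rank_a_max = 5,
                      rank_b_min = 0, rank_b_max = 9)
  expect_equal(block_significance(degen, 50, 50, 20), 1)
  expect_error(block_significance(data.frame(n_anchors = integer(0)), 10, 10, 5),
               "empty")
})

test_that("the closed significance form brackets the Monte-Carlo oracle", {
  set.seed(37)
  blk <- data.frame(n_anchors = 3L, rank_a_min = 0, rank_a_max = 3,
                    rank_b_min = 0, rank_b_max = 3)
  p_closed <- block_significance(blk, 20, 20, 8)
  p_mc <- oracle_mc_block_p(3, 8, 4, 4, 20, 20, nsim = 20000)
  expect_gte(p_closed, p_mc)          # conservative
  expect_lte(p_closed, 5 * p_mc)      # but within a small factor
})

test_that("block summary arithmetic matches its definition", {
  expect_equal(genes_per_block(7914, 348), 22.74)
  expect_true(is.na(genes_per_block(0, 0)))
  anch <- make_anchors(0:4, 0:4)
  res <- chain_blocks(anch, chain_params(min_anchors = 3))
  st <- block_stats(res$blocks)
  expect_equal(st$n_genes, 5L)        # 5 anchor pairs = 5 collinear genes
  expect_equal(st$genes_per_block, 5)
})
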