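#' Chaining parameters for collinear block detection
#'
#' Chains are scored as the sum of anchor scores minus a gap penalty for
#' every *anchor* of the chromosome pair that the chain skips over (anchors
#' of the original set whose rank falls strictly inside the gap between
#' consecutive chain anchors, counted on each axis). Penalizing skipped
#' anchors rather than raw rank gaps keeps chains intact across
#' fractionation gaps - lost genes leave rank holes but no conflicting
#' homology signal - while still splitting chains at inversions, where
#' skipped anchors of the opposite orientation accumulate. `max_gap` is a
#' hard cap on the rank gap bridged in either coordinate.
#'
#' @param min_anchors minimum anchors per reported block.
#' @param max_gap maximum intervening ranks between consecutive anchors.
#' @param gap_penalty score subtracted per skipped anchor; the default
#'   (6, against an anchor score of 10) makes it cheaper to close a chain
#'   at an inverted segment than to leapfrog it.
#' @param anchor_score per-anchor score: a constant, or a function of the
#'   hit bit score.
#' @return list of class `"chain_params"`.
#' @export
chain_params <- function(min_anchors = 5L, max_gap = 25L, gap_penalty = 6,
                         anchor_score = 10) {
  stopifnot(min_anchors >= 2, max_gap >= 1, gap_penalty >= 0)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 gap_penalty = gap_penalty, anchor_score = anchor_score),
            class = "chain_params")
}

#' Build anchor pairs from filtered homology hits
#'
#' Resolves hits to gene-rank coordinates in the two genomes. Hits in
#' either direction (A-queries against B and vice versa) collapse to a
#' single anchor keeping the best bit score. For a self-comparison
#' (`genome_a` identical to `genome_b`) the trivial diagonal is excluded
#' and unordered pairs are kept once (upper triangle of the dot plot).
#'
#' @param hits filtered hits, see [filter_hits()].
#' @param genome_a,genome_b genome objects.
#' @return data.frame of anchors: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `score`, with attribute `species` (length 2).
#' @export
build_anchors <- function(hits, genome_a, genome_b) {
  same <- identical(genome_species(genome_a), genome_species(genome_b))
  ia <- match(hits$query, genome_a$id); sb <- match(hits$subject, genome_b$id)
  fwd <- !is.na(ia) & !is.na(sb)
  anch <- data.frame(gene_a = hits$query[fwd], gene_b = hits$subject[fwd],
                     score = hits$bitscore[fwd],
                     .ia = ia[fwd], .ib = sb[fwd])
  if (!same) {
    ib <- match(hits$query, genome_b$id); sa <- match(hits$subject, genome_a$id)
    rev <- !is.na(ib) & !is.na(sa) & !fwd
    anch <- rbind(anch, data.frame(gene_a = hits$subject[rev],
                                   gene_b = hits$query[rev],
                                   score = hits$bitscore[rev],
                                   .ia = sa[rev], .ib = ib[rev]))
    n_bad <- sum(!fwd & !rev)
  } else {
    n_bad <- sum(!fwd)
  }
  if (n_bad > 0) warning(n_bad, " hit(s) with unresolvable gene ids skipped")
  anch <- anch[anch$gene_a != anch$gene_b, , drop = FALSE]
  anch$chrom_a <- genome_a$chrom[anch$.ia]; anch$rank_a <- genome_a$rank[anch$.ia]
  anch$chrom_b <- genome_b$chrom[anch$.ib]; anch$rank_b <- genome_b$rank[anch$.ib]
  if (same && nrow(anch)) {
    oa <- genome_a$chrom_ordinal[anch$.ia]; ob <- genome_b$chrom_ordinal[anch$.ib]
    flip <- (oa > ob) | (oa == ob & anch$rank_a > anch$rank_b)
    anch[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      anch[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
  }
  anch <- anch[order(anch$gene_a, anch$gene_b, -anch$score), , drop = FALSE]
  anch <- anch[!duplicated(anch[, c("gene_a", "gene_b")]), , drop = FALSE]
  anch <- anch[, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                   "rank_a", "rank_b", "score")]
  rownames(anch) <- NULL
  attr(anch, "species") <- c(genome_species(genome_a), genome_species(genome_b))
  anch
}

anchor_scores <- function(bits, anchor_score) {
  if (is.function(anchor_score)) anchor_score(bits) else rep(anchor_score, length(bits))
}

# number of values of `sorted` strictly between lo and hi (integer ranks)
count_between <- function(sorted, lo, hi) {
  findInterval(hi - 1L, sorted) - findInterval(lo, sorted)
}

# single best chain (max score) among `active` anchors for one orientation;
# skip penalties are computed against the original rank multisets sa0/sb0
best_chain_dp <- function(ra, rb, sc, sa0, sb0, params, orientation) {
  n <- length(ra)
  if (!n) return(NULL)
  rb_eff <- if (orientation == "+") rb else -rb
  o <- order(ra, rb_eff)
  ra <- ra[o]; rb <- rb[o]; rb_eff <- rb_eff[o]; sc <- sc[o]
  dp <- sc
  prev <- rep(0L, n)
  g <- params$gap_penalty; mg <- params$max_gap
  for (i in seq_len(n)) {
    lo <- findInterval(ra[i] - mg - 2L, ra) + 1L   # ra[j] >= ra[i]-mg-1
    js <- seq.int(lo, i - 1L)
    if (!length(js)) next
    ok <- ra[js] < ra[i] & rb_eff[js] < rb_eff[i] & abs(rb[i] - rb[js]) <= mg + 1L
    js <- js[ok]
    if (!length(js)) next
    skipA <- count_between(sa0, ra[js], ra[i])
    skipB <- if (orientation == "+") count_between(sb0, rb[js], rb[i])
             else count_between(sb0, rb[i], rb[js])
    cand <- dp[js] - g * (skipA + skipB)
    best <- which.max(cand)
    if (cand[best] > 0) {
      dp[i] <- sc[i] + cand[best]
      prev[i] <- js[best]
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  i <- end
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  list(idx = o[chain], score = dp[end], orientation = orientation)
}

#' Chain anchors into collinear blocks
#'
#' For every chromosome pair, repeatedly extracts the highest-scoring chain
#' (strictly monotone in both rank coordinates; ascending in `rank_b` for
#' orientation `+`, descending for `-`) by sparse dynamic programming,
#' removes its anchors, and repeats until the best remaining chain is
#' shorter than `min_anchors`. Each anchor therefore belongs to at most one
#' block.
#'
#' @param anchors data.frame from [build_anchors()].
#' @param params a [chain_params()] object.
#' @return list with `blocks` (block_id, species/chromosome pair,
#'   orientation, n_anchors, score, rank envelope, p_value placeholder)
#'   and `anchors` (per-anchor rows tagged with block_id).
#' @export
chain_blocks <- function(anchors, params = chain_params()) {
  species <- attr(anchors, "species")
  if (is.null(species)) species <- c(NA_character_, NA_character_)
  empty <- list(blocks = data.frame(block_id = character(), species_a = character(),
                                    species_b = character(), chrom_a = character(),
                                    chrom_b = character(), orientation = character(),
                                    n_anchors = integer(), score = numeric(),
                                    rank_a_min = integer(), rank_a_max = integer(),
                                    rank_b_min = integer(), rank_b_max = integer(),
                                    p_value = numeric()),
                anchors = data.frame(block_id = character(), gene_a = character(),
                                     gene_b = character(), rank_a = integer(),
                                     rank_b = integer(), score = numeric()))
  if (!nrow(anchors)) return(empty)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  blocks <- list(); banchors <- list()
  for (cp in sort(unique(key))) {
    sub <- anchors[key == cp, , drop = FALSE]
    sa0 <- sort(sub$rank_a); sb0 <- sort(sub$rank_b)
    sc <- anchor_scores(sub$score, params$anchor_score)
    active <- seq_len(nrow(sub))
    counter <- 0L
    repeat {
      if (length(active) < params$min_anchors) break
      cands <- lapply(c("+", "-"), function(orient)
        best_chain_dp(sub$rank_a[active], sub$rank_b[active], sc[active],
                      sa0, sb0, params, orient))
      scores <- vapply(cands, function(x) if (is.null(x)) -Inf else x$score, numeric(1))
      best <- cands[[which.max(scores)]]
      if (is.null(best) || length(best$idx) < params$min_anchors || best$score <= 0) break
      counter <- counter + 1L
      idx <- active[best$idx]
      bid <- sprintf("%s.%s.%s.%s.%03d", species[1], species[2],
                     sub$chrom_a[1], sub$chrom_b[1], counter)
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = bid, species_a = species[1], species_b = species[2],
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = best$orientation, n_anchors = length(idx),
        score = best$score,
        rank_a_min = min(sub$rank_a[idx]), rank_a_max = max(sub$rank_a[idx]),
        rank_b_min = min(sub$rank_b[idx]), rank_b_max = max(sub$rank_b[idx]),
        p_value = NA_real_)
      banchors[[length(banchors) + 1L]] <- data.frame(
        block_id = bid, gene_a = sub$gene_a[idx], gene_b = sub$gene_b[idx],
        rank_a = sub$rank_a[idx], rank_b = sub$rank_b[idx], score = sub$score[idx])
      active <- setdiff(active, idx)
    }
  }
  if (!length(blocks)) return(empty)
  out <- list(blocks = do.call(rbind, blocks), anchors = do.call(rbind, banchors))
  rownames(out$blocks) <- rownames(out$anchors) <- NULL
  stopifnot(all(vapply(split(out$anchors, out$anchors$block_id), function(a) {
    o <- order(a$rank_a)
    all(diff(a$rank_a[o]) > 0) && (all(diff(a$rank_b[o]) > 0) || all(diff(a$rank_b[o]) < 0))
  }, logical(1))))
  out
}

#' Significance of a collinear block
#'
#' Closed approximation to the probability of observing at least
#' `n_anchors` co-monotone anchors inside the block's rank envelope when
#' `n_anchors_total` anchors fall uniformly at random on the
#' `n_a x n_b` rank grid of the chromosome pair: with
#' `lambda = C(n_total, m) p_cell^m 2/m!` the expected number of
#' co-monotone m-subsets in the envelope (`p_cell` the envelope area
#' fraction), `p = 1 - exp(-lambda)`. Degenerate envelopes (a single rank
#' on either axis) give `p = 1`.
#'
#' @param block one row of the `blocks` table from [chain_blocks()].
#' @param n_a,n_b gene counts of the two chromosomes.
#' @param n_anchors_total anchors observed on the chromosome pair.
#' @return p-value in `(0, 1]`.
#' @export
block_significance <- function(block, n_a, n_b, n_anchors_total) {
  stopifnot(n_a > 0, n_b > 0, n_anchors_total > 0)
  m <- block$n_anchors
  if (is.null(m) || !length(m) || m < 1) stop("empty block")
  ra <- block$rank_a_max - block$rank_a_min + 1
  rb <- block$rank_b_max - block$rank_b_min + 1
  if (ra <= 1 || rb <= 1) return(1)
  p_cell <- min(1, (ra / n_a) * (rb / n_b))
  log_lambda <- lchoose(n_anchors_total, m) + m * log(p_cell) + log(2) - lfactorial(m)
  -expm1(-exp(log_lambda))
}

#' Average collinear genes per block
#'
#' The fractionation summary statistic: each anchor is one collinear gene
#' pair, so a genome's "gene number" is the anchor total.
#'
#' @param n_genes total collinear genes (anchor pairs).
#' @param n_blocks number of blocks.
#' @return genes per block, rounded to 2 decimals (`NA` when no blocks).
#' @export
genes_per_block <- function(n_genes, n_blocks) {
  ifelse(n_blocks > 0, round(n_genes / n_blocks, 2), NA_real_)
}

#' Summarize blocks per species pair
#'
#' @param blocks the `blocks` table from [chain_blocks()] (tables from
#'   several comparisons can be `rbind`-ed first).
#' @return data.frame with `species_a`, `species_b`, `n_genes` (anchor
#'   pairs), `n_blocks` and `genes_per_block`.
#' @export
block_stats <- function(blocks) {
  if (!nrow(blocks))
    return(data.frame(species_a = character(), species_b = character(),
                      n_genes = integer(), n_blocks = integer(),
                      genes_per_block = numeric()))
  key <- paste(blocks$species_a, blocks$species_b, sep = "\r")
  agg <- lapply(split(blocks, key), function(b)
    data.frame(species_a = b$species_a[1], species_b = b$species_b[1],
               n_genes = sum(b$n_anchors), n_blocks = nrow(b),
               genes_per_block = genes_per_block(sum(b$n_anchors), nrow(b))))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
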