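# Independent oracles used to validate the package implementations.
# These are deliberately naive (enumeration / brute force) and share no
# code with the functions they check.

# best single chain by exhaustive subset enumeration, scored like
# chain_params(): sum of anchor scores minus gap_penalty per anchor of the
# full set skipped (strictly inside the gap) on either rank axis, with a
# hard max_gap on both axes
oracle_best_chain <- function(anchors, params) {
  n <- nrow(anchors)
  stopifnot(n <= 15)
  sa0 <- sort(anchors$rank_a)
  sb0 <- sort(anchors$rank_b)
  score_chain <- function(idx, orient) {
    ra <- anchors$rank_a[idx]; rb <- anchors$rank_b[idx]
    o <- order(ra)
    ra <- ra[o]; rb <- rb[o]
    if (any(diff(ra) <= 0)) return(-Inf)
    if (orient == "+" && any(diff(rb) <= 0)) return(-Inf)
    if (orient == "-" && any(diff(rb) >= 0)) return(-Inf)
    if (length(ra) > 1) {
      if (any(diff(ra) - 1 > params$max_gap)) return(-Inf)
      if (any(abs(diff(rb)) - 1 > params$max_gap)) return(-Inf)
    }
    sc <- length(idx) * params$anchor_score
    if (length(ra) > 1) {
      for (k in seq_len(length(ra) - 1)) {
        skipA <- sum(sa0 > ra[k] & sa0 < ra[k + 1])
        skipB <- sum(sb0 > min(rb[k], rb[k + 1]) & sb0 < max(rb[k], rb[k + 1]))
        sc <- sc - params$gap_penalty * (skipA + skipB)
      }
    }
    sc
  }
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    best <- max(best, score_chain(idx, "+"), score_chain(idx, "-"))
  }
  best
}

# brute-force minimal-branch-loss search under single-origin parsimony.
# Returns a function(present_tips) -> list(size, edges); tip sets are
# encoded as bitmasks and branch subsets enumerated by increasing size.
oracle_dollo_setup <- function(tree, max_size = 6L) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  n_edge <- nrow(edge)
  below_mask <- vapply(seq_len(n_edge), function(e) {
    node <- edge[e, 2]
    if (node <= n_tip) return(bitwShiftL(1L, node - 1L))
    desc <- node
    repeat {
      kids <- edge[edge[, 1] %in% desc, 2]
      new <- setdiff(kids, desc)
      if (!length(new)) break
      desc <- c(desc, new)
    }
    tips <- desc[desc <= n_tip]
    Reduce(bitwOr, bitwShiftL(1L, tips - 1L))
  }, integer(1))
  combos <- lapply(seq_len(max_size), function(k)
    utils::combn(n_edge, k, simplify = FALSE))
  function(present_tips) {
    absent_mask <- Reduce(bitwOr, bitwShiftL(1L, which(!present_tips) - 1L), 0L)
    present_mask <- Reduce(bitwOr, bitwShiftL(1L, which(present_tips) - 1L), 0L)
    if (absent_mask == 0L) return(list(size = 0L, edges = integer(0)))
    for (size in seq_len(max_size)) {
      for (comb in combos[[size]]) {
        covered <- Reduce(bitwOr, below_mask[comb])
        if (bitwAnd(covered, absent_mask) == absent_mask &&
            bitwAnd(covered, present_mask) == 0L)
          return(list(size = size, edges = comb))
      }
    }
    stop("no explanation found within max_size")
  }
}

# connected components of tandem links by naive transitive closure
oracle_tandem_components <- function(edges) {
  nodes <- unique(c(edges$a, edges$b))
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      ca <- comp[edges$a[k]]; cb <- comp[edges$b[k]]
      if (ca != cb) { comp[comp == max(ca, cb)] <- min(ca, cb); changed <- TRUE }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# longest strictly increasing (in b) subsequence length for points sorted
# by a; used by the Monte-Carlo significance oracle
oracle_lis <- function(ra, rb) {
  o <- order(ra, rb)
  rb <- rb[o]
  best <- integer(0)
  for (v in rb) {
    i <- findInterval(v - 1L, best) + 1L
    best[i] <- v
  }
  length(best)
}

oracle_mc_block_p <- function(m, n_tot, ra_env, rb_env, n_a, n_b, nsim = 20000) {
  hit <- 0
  for (s in seq_len(nsim)) {
    xa <- sample.int(n_a, n_tot, replace = TRUE)
    xb <- sample.int(n_b, n_tot, replace = TRUE)
    inenv <- xa <= ra_env & xb <= rb_env
    if (sum(inenv) < m) next
    if (max(oracle_lis(xa[inenv], xb[inenv]),
            oracle_lis(xa[inenv], -xb[inenv])) >= m) hit <- hit + 1
  }
  hit / nsim
}

# small helper: data.frame of anchors with an attached species attribute
make_anchors <- function(rank_a, rank_b, chrom_a = "1", chrom_b = "1",
                         score = 100, species = c("A", "B")) {
  n <- length(rank_a)
  df <- data.frame(gene_a = sprintf("a%d", seq_len(n)),
                   gene_b = sprintf("b%d", seq_len(n)),
                   chrom_a = rep_len(chrom_a, n), chrom_b = rep_len(chrom_b, n),
                   rank_a = rank_a, rank_b = rank_b,
                   score = rep_len(score, n))
  attr(df, "species") <- species
  df
}

# small alignment-table fixture builder
make_table <- function(ref_ids, ...) {
  cols <- list(...)
  structure(data.frame(ref = ref_ids, cols, check.names = FALSE,
                       stringsAsFactors = FALSE),
            class = c("alignment_table", "data.frame"))
}

small_genome <- function(n = 10, chrom = "chr1", species = "toy", spacing = 1000) {
  as_genome(data.frame(id = sprintf("%s_g%02d", species, seq_len(n)),
                       chrom = chrom,
                       start = (seq_len(n) - 1) * spacing + 1,
                       end = (seq_len(n) - 1) * spacing + 500),
            species = species)
}

hit_row <- function(query, subject, evalue = 1e-50, bitscore = 200, pident = 90) {
  data.frame(query = query, subject = subject, pident = pident, length = 300L,
             mismatch = 10L, gapopen = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 300L, evalue = evalue, bitscore = bitscore,
             self_hit = query == subject)
}
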