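#' Parameters for the genome-evolution simulator
#'
#' The simulator emulates the history the analysis assumes: a 7-chromosome
#' ancestral genome, one whole-genome duplication (WGD), nested chromosome
#' fusions reducing 14 chromosomes to 12, branch-specific duplicate-biased
#' gene loss whose intensity ramps with chromosome ordinal, rank-interval
#' inversions that break collinearity, tandem duplication bursts, and codon
#' sequences diverged to prescribed synonymous distances.
#'
#' @param n_ancestral_chromosomes chromosomes before the WGD.
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param gene_spacing_bp base-pair spacing between gene starts.
#' @param codon_length codons per gene.
#' @param fusion_plan data.frame with columns `target`, `source` and `at`
#'   (0-based rank in the target where the source chromosome nests;
#'   `NA` = middle). Post-WGD labels are `c<k>a` / `c<k>b`. The default
#'   nests `c6a` into `c2a` and `c7b` into `c3b`, reducing 14 to 12.
#' @param tree rooted binary tree: `ape` phylo or Newick string with branch
#'   lengths in My. Internal nodes should be labelled (labels name
#'   branches); the default has an outgroup `ref` used as reference.
#' @param per_branch_loss_rate genes lost per My: single number or vector
#'   named by branch (= child node/tip label).
#' @param per_chromosome_loss_multiplier multiplier per chromosome ordinal,
#'   or `NULL` for a linear ramp 0.7 to 1.4 across ordinals (the
#'   ordinal-trend scenario); use `rep(1, 12)` for a flat null.
#' @param singleton_loss_fraction fraction of loss events drawn from genes
#'   whose WGD partner is already gone (the rest hit two-copy families,
#'   mirroring post-polyploidy fractionation).
#' @param subgenome_bias relative loss weight of copy-"b" homoeologs
#'   (1 = unbiased; 2 reproduces a dominance scenario).
#' @param inversion_rate expected inversion events per branch.
#' @param tandem_birth_rate expected tandem duplication events per branch.
#' @param tandem_copy_lambda extra copies per event are `1 + rpois(lambda)`.
#' @param tandem_ds synonymous divergence applied to a tandem copy at birth.
#' @param clock_rate synonymous substitutions/site/year used to convert
#'   branch durations into synonymous distances.
#' @param clock_multiplier per-species multiplier applied on terminal
#'   branches (named vector; lineages with faster molecular clocks).
#' @param wgd_ds target synonymous distance between surviving WGD paralog
#'   copies at the leaves (the paleo-duplication Ks peak).
#' @param omega_n,omega_s relative substitution pressure at nonsynonymous
#'   (codon positions 1-2) versus synonymous (fourfold third) sites.
#' @param family_fraction fraction of ancestral genes tagged as members of
#'   a fast-turnover gene family (tandem-prone, for enrichment tests).
#' @param family_tandem_weight sampling weight of tagged genes as tandem
#'   event parents.
#' @param noise_hits spurious random rows added per genome pair in the
#'   synthetic homology table.
#' @param seed integer seed; one pseudo-random stream drives the whole run.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_ancestral_chromosomes = 7L,
                       genes_per_chromosome = 360L,
                       gene_spacing_bp = 10000L,
                       codon_length = 100L,
                       fusion_plan = NULL,
                       tree = "(((spA:2,spB:2)AB:28,spC:30)oryza:5,ref:35)root;",
                       per_branch_loss_rate = c(oryza = 150, AB = 30, spC = 30,
                                                spA = 270, spB = 150, ref = 25),
                       per_chromosome_loss_multiplier = NULL,
                       singleton_loss_fraction = 0.1,
                       subgenome_bias = 1,
                       inversion_rate = 1,
                       tandem_birth_rate = 10,
                       tandem_copy_lambda = 1,
                       tandem_ds = 0.05,
                       clock_rate = 3.5e-9,
                       clock_multiplier = NULL,
                       wgd_ds = 0.6,
                       omega_n = 0.1, omega_s = 0.9,
                       family_fraction = 0.05,
                       family_tandem_weight = 8,
                       noise_hits = 0L,
                       seed = 1L) {
  if (is.null(fusion_plan))
    fusion_plan <- data.frame(target = c("c2a", "c3b"), source = c("c6a", "c7b"),
                              at = NA_integer_)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree),
            inversion_rate >= 0, tandem_birth_rate >= 0,
            singleton_loss_fraction >= 0, singleton_loss_fraction <= 1,
            all(per_branch_loss_rate >= 0), clock_rate > 0)
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  structure(list(n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 gene_spacing_bp = as.integer(gene_spacing_bp),
                 codon_length = as.integer(codon_length),
                 fusion_plan = fusion_plan, tree = tree,
                 per_branch_loss_rate = per_branch_loss_rate,
                 per_chromosome_loss_multiplier = per_chromosome_loss_multiplier,
                 singleton_loss_fraction = singleton_loss_fraction,
                 subgenome_bias = subgenome_bias,
                 inversion_rate = inversion_rate,
                 tandem_birth_rate = tandem_birth_rate,
                 tandem_copy_lambda = tandem_copy_lambda,
                 tandem_ds = tandem_ds,
                 clock_rate = clock_rate, clock_multiplier = clock_multiplier,
                 wgd_ds = wgd_ds, omega_n = omega_n, omega_s = omega_s,
                 family_fraction = family_fraction,
                 family_tandem_weight = family_tandem_weight,
                 noise_hits = as.integer(noise_hits), seed = as.integer(seed)),
            class = "sim_params")
}

# sample() that never falls into the 1:x trap on length-1 numeric vectors
safe_sample <- function(x, size, prob = NULL) {
  if (length(x) == 1) return(rep(x, min(size, 1)))
  sample(x, size, prob = prob)
}

SIM_NTS <- c("A", "C", "G", "T")
# fourfold-degenerate codon families (Val, Ala, Gly, Thr, Pro, Ser): every
# third position is fully synonymous and no single change yields a stop
# from the ancestral state, so target dS is realized exactly at third sites
SIM_PREFIXES <- c("GT", "GC", "GG", "AC", "CC", "TC")

#' Simulate the pre-duplication ancestral genome
#'
#' Genes are laid out at regular spacing on `n_ancestral_chromosomes`
#' chromosomes (`c1`, `c2`, ...); each gene receives a random in-frame CDS
#' drawn from fourfold-degenerate codon families (no internal stops).
#'
#' @param params a [sim_params()] object. The caller is responsible for
#'   seeding ([simulate_genomes()] seeds once for the whole run).
#' @return list with `meta` (gene table), `seqs` (nucleotide matrix, one
#'   row per gene) and `params`.
#' @export
simulate_ancestor <- function(params) {
  n_chr <- params$n_ancestral_chromosomes
  n_per <- params$genes_per_chromosome
  n <- n_chr * n_per
  ids <- sprintf("g%05d", seq_len(max(n, 1)))[seq_len(n)]
  meta <- data.frame(id = ids,
                     chrom = rep(paste0("c", seq_len(n_chr)), each = n_per),
                     family = ids, copy = rep("anc", n),
                     tandem = rep(FALSE, n),
                     birth_cum = rep(NA_real_, n), stringsAsFactors = FALSE)
  L <- 3L * params$codon_length
  seqs <- matrix("", nrow = n, ncol = L, dimnames = list(ids, NULL))
  if (n > 0 && L > 0) {
    pre <- sample(SIM_PREFIXES, n * params$codon_length, replace = TRUE)
    seqs[, seq(1, L, 3)] <- matrix(substr(pre, 1, 1), nrow = n)
    seqs[, seq(2, L, 3)] <- matrix(substr(pre, 2, 2), nrow = n)
    seqs[, seq(3, L, 3)] <- matrix(sample(SIM_NTS, n * params$codon_length,
                                          replace = TRUE), nrow = n)
  }
  list(meta = meta, seqs = seqs, params = params)
}

# Jukes-Cantor evolution of selected columns by synonymous distance d:
# each site changes with probability (3/4)(1 - exp(-4d/3)) to a uniformly
# chosen different nucleotide.
jc_evolve_cols <- function(seqs, cols, d) {
  if (d <= 0 || !length(cols) || !nrow(seqs)) return(seqs)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  block <- seqs[, cols, drop = FALSE]
  hit <- which(stats::runif(length(block)) < p)
  if (length(hit)) {
    old <- match(block[hit], SIM_NTS)
    block[hit] <- SIM_NTS[((old - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    seqs[, cols] <- block
  }
  seqs
}

# revert any codon that became a stop (possible only after nonsynonymous
# changes moved a codon out of its ancestral family)
fix_stops <- function(seqs, before) {
  if (!nrow(seqs)) return(seqs)
  n_codon <- ncol(seqs) / 3L
  for (k in seq_len(n_codon)) {
    j <- 3L * (k - 1L)
    c1 <- seqs[, j + 1L]; c2 <- seqs[, j + 2L]; c3 <- seqs[, j + 3L]
    bad <- c1 == "T" & ((c2 == "A" & c3 %in% c("A", "G")) | (c2 == "G" & c3 == "A"))
    if (any(bad)) seqs[bad, (j + 1L):(j + 3L)] <- before[bad, (j + 1L):(j + 3L)]
  }
  seqs
}

#' Apply a synonymous divergence to coding sequences
#'
#' Third codon positions evolve under Jukes-Cantor to the requested
#' synonymous distance; first and second positions evolve at
#' `omega_n / omega_s` of that distance (stop-creating draws are reverted).
#' Useful for building sequence pairs with known dS.
#'
#' @param cds character vector of in-frame coding sequences.
#' @param ds target synonymous distance.
#' @param omega_n,omega_s relative nonsynonymous/synonymous pressure
#'   (set `omega_n = 0` for purely synonymous divergence).
#' @return character vector of diverged sequences.
#' @export
diverge_cds <- function(cds, ds, omega_n = 0, omega_s = 0.9) {
  mats <- do.call(rbind, lapply(strsplit(toupper(cds), ""), identity))
  before <- mats
  L <- ncol(mats)
  third <- seq(3, L, 3)
  mats <- jc_evolve_cols(mats, third, ds)
  if (omega_n > 0)
    mats <- jc_evolve_cols(mats, setdiff(seq_len(L), third), ds * omega_n / omega_s)
  mats <- fix_stops(mats, before)
  unname(do.call(paste0, lapply(seq_len(L), function(j) mats[, j])))
}

#' Duplicate the ancestral genome and apply chromosome fusions
#'
#' Every gene is duplicated onto a homoeologous chromosome (`c<k>a` and
#' `c<k>b`); the fusion plan then nests source chromosomes into targets,
#' after which chromosomes are relabelled `1..n` by descending gene count
#' (fused neo-chromosomes receive the small ordinal numbers).
#'
#' @param ancestor result of [simulate_ancestor()].
#' @param params a [sim_params()] object.
#' @return list with `meta`, `seqs`, `paralog_pairs` (WGD pairing truth)
#'   and `chrom_map` (pre-fusion label to final ordinal label).
#' @export
apply_wgd_and_fusions <- function(ancestor, params) {
  meta <- ancestor$meta
  seqs <- ancestor$seqs
  ma <- meta; mb <- meta
  ma$id <- paste0(meta$id, "a"); ma$chrom <- paste0(meta$chrom, "a"); ma$copy <- "a"
  mb$id <- paste0(meta$id, "b"); mb$chrom <- paste0(meta$chrom, "b"); mb$copy <- "b"
  meta2 <- rbind(ma, mb)
  seqs2 <- rbind(seqs, seqs)
  rownames(seqs2) <- meta2$id
  paralog_pairs <- data.frame(gene_a = ma$id, gene_b = mb$id, family = meta$family)

  chroms <- split(seq_len(nrow(meta2)), meta2$chrom)
  fp <- params$fusion_plan
  if (!is.null(fp) && nrow(fp)) {
    for (k in seq_len(nrow(fp))) {
      tgt <- fp$target[k]; src <- fp$source[k]
      if (!tgt %in% names(chroms) || !src %in% names(chroms))
        stop("fusion plan references unknown chromosome: ", tgt, "/", src)
      at <- fp$at[k]
      tv <- chroms[[tgt]]
      if (is.na(at)) at <- floor(length(tv) / 2)
      at <- max(0L, min(length(tv), as.integer(at)))
      chroms[[tgt]] <- append(tv, chroms[[src]], after = at)
      chroms[[src]] <- NULL
    }
  }
  sizes <- lengths(chroms)
  new_order <- order(-sizes, names(chroms))
  chroms <- chroms[new_order]
  chrom_map <- stats::setNames(as.character(seq_along(chroms)), names(chroms))
  idx <- unlist(chroms, use.names = FALSE)
  meta2 <- meta2[idx, , drop = FALSE]
  # fused source genes inherit the label of their host chromosome
  meta2$chrom <- rep(unname(chrom_map), lengths(chroms))
  rownames(meta2) <- NULL
  seqs2 <- seqs2[meta2$id, , drop = FALSE]
  list(meta = meta2, seqs = seqs2, paralog_pairs = paralog_pairs,
       chrom_map = chrom_map)
}

branch_table <- function(tree) {
  labs <- c(tree$tip.label, tree$node.label)
  data.frame(parent = labs[tree$edge[, 1]], child = labs[tree$edge[, 2]],
             child_num = tree$edge[, 2], length = tree$edge.length,
             is_tip = tree$edge[, 2] <= length(tree$tip.label))
}

branch_rate <- function(rates, branch) {
  if (length(rates) == 1 && is.null(names(rates))) return(unname(rates))
  if (branch %in% names(rates)) return(unname(rates[branch]))
  0
}

chrom_multiplier <- function(params, n_chrom) {
  m <- params$per_chromosome_loss_multiplier
  if (is.null(m)) m <- seq(0.7, 1.4, length.out = n_chrom)
  if (length(m) < n_chrom) m <- rep_len(m, n_chrom)
  m
}

#' Evolve the post-WGD genome along a species tree
#'
#' Along each branch, in fixed event order: (1) gene losses, Poisson with
#' mean `rate x duration`, drawn with probability
#' `1 - singleton_loss_fraction` from two-copy families, weighted by the
#' per-chromosome ordinal multiplier and the copy-b subgenome bias;
#' (2) inversions reversing a random rank interval; (3) tandem duplication
#' events inserting adjacent near-copies; (4) nucleotide substitutions
#' realizing the branch's synonymous distance
#' (`clock_rate x duration`). Ground truth logs every event.
#'
#' @param root result of [apply_wgd_and_fusions()].
#' @param params a [sim_params()] object.
#' @return list with `genomes` (named list of [as_genome()] objects),
#'   `cds` (named list of named CDS vectors) and `truth`.
#' @export
evolve_along_tree <- function(root, params) {
  tree <- params$tree
  bt <- branch_table(tree)
  n_chrom <- length(unique(root$meta$chrom))
  mult <- chrom_multiplier(params, n_chrom)
  tagged <- tagged_families(root, params)

  truth <- new.env(parent = emptyenv())
  truth$losses <- list(); truth$inversions <- list(); truth$tandems <- list()
  truth$branch_ds <- numeric(0)
  truth$leaf_meta <- list()
  tandem_counter <- new.env(parent = emptyenv()); tandem_counter$n <- 0L

  evolve_branch <- function(state, branch, duration, is_tip) {
    meta <- state$meta; seqs <- state$seqs
    rate <- branch_rate(params$per_branch_loss_rate, branch)

    # --- losses -----------------------------------------------------------
    n_loss <- stats::rpois(1, rate * duration)
    if (n_loss > 0 && nrow(meta) > 0) {
      cm <- mult[chrom_ordinals(unique(meta$chrom))[meta$chrom]]
      w <- cm * ifelse(meta$copy == "b", params$subgenome_bias, 1)
      fam_copy <- paste(meta$family, meta$copy)
      other <- paste(meta$family, ifelse(meta$copy == "a", "b", "a"))
      dup <- other %in% fam_copy
      n_dup_want <- stats::rbinom(1, n_loss, 1 - params$singleton_loss_fraction)
      pick <- integer(0)
      dup_idx <- which(dup); sing_idx <- which(!dup)
      n_dup <- min(n_dup_want, length(dup_idx))
      n_sing <- min(n_loss - n_dup, length(sing_idx))
      if (n_dup > 0) pick <- c(pick, safe_sample(dup_idx, n_dup, prob = w[dup_idx]))
      if (n_sing > 0) pick <- c(pick, safe_sample(sing_idx, n_sing, prob = w[sing_idx]))
      if (length(pick)) {
        truth$losses[[length(truth$losses) + 1L]] <-
          data.frame(branch = branch, gene = meta$id[pick],
                     family = meta$family[pick], copy = meta$copy[pick],
                     chrom = meta$chrom[pick])
        emptied <- setdiff(unique(meta$chrom), unique(meta$chrom[-pick]))
        if (length(emptied))
          warning("loss emptied chromosome(s) ", paste(emptied, collapse = ","),
                  " on branch ", branch)
        meta <- meta[-pick, , drop = FALSE]
        seqs <- seqs[meta$id, , drop = FALSE]
      }
    }

    # --- inversions -------------------------------------------------------
    n_inv <- stats::rpois(1, params$inversion_rate)
    if (n_inv > 0 && nrow(meta) > 1) {
      for (k in seq_len(n_inv)) {
        ch <- sample(unique(meta$chrom), 1)
        pos <- which(meta$chrom == ch)
        if (length(pos) < 2) next
        ij <- sort(sample(seq_along(pos), 2))
        seg <- pos[ij[1]:ij[2]]
        new_order <- seq_len(nrow(meta))
        new_order[seg] <- rev(seg)
        meta <- meta[new_order, , drop = FALSE]
        truth$inversions[[length(truth$inversions) + 1L]] <-
          data.frame(branch = branch, chrom = ch,
                     rank_lo = ij[1] - 1L, rank_hi = ij[2] - 1L)
      }
      seqs <- seqs[meta$id, , drop = FALSE]
    }

    # --- tandem bursts ----------------------------------------------------
    n_tan <- stats::rpois(1, params$tandem_birth_rate)
    if (n_tan > 0 && nrow(meta) > 0) {
      wfam <- ifelse(meta$family %in% tagged, params$family_tandem_weight, 1)
      parents <- sample(seq_len(nrow(meta)), min(n_tan, nrow(meta)), prob = wfam)
      new_rows <- list(); new_seq_parent <- character(0)
      for (p in parents) {
        m <- 1L + stats::rpois(1, params$tandem_copy_lambda)
        tandem_counter$n <- tandem_counter$n + 1L
        ids_new <- sprintf("%s.t%04d.%d", meta$id[p], tandem_counter$n, seq_len(m))
        nr <- meta[rep(p, m), , drop = FALSE]
        nr$id <- ids_new; nr$tandem <- TRUE; nr$birth_cum <- state$cum_ds
        new_rows[[length(new_rows) + 1L]] <- cbind(nr, after = p)
        new_seq_parent <- c(new_seq_parent, rep(meta$id[p], m))
        truth$tandems[[length(truth$tandems) + 1L]] <-
          data.frame(branch = branch, parent = meta$id[p], n_copies = m)
      }
      nr <- do.call(rbind, new_rows)
      # insert after parents, preserving order (process from bottom up)
      nr <- nr[order(-nr$after), , drop = FALSE]
      add_seqs <- seqs[new_seq_parent, , drop = FALSE]
      rownames(add_seqs) <- unlist(lapply(new_rows, function(x) x$id))
      if (params$tandem_ds > 0) {
        before <- add_seqs
        third <- seq(3, ncol(add_seqs), 3)
        add_seqs <- jc_evolve_cols(add_seqs, third, params$tandem_ds)
        add_seqs <- fix_stops(add_seqs, before)
      }
      for (k in seq_len(nrow(nr))) {
        at <- nr$after[k]
        meta <- rbind(meta[seq_len(at), , drop = FALSE],
                      nr[k, setdiff(names(nr), "after"), drop = FALSE],
                      if (at < nrow(meta)) meta[(at + 1L):nrow(meta), , drop = FALSE])
      }
      rownames(meta) <- NULL
      seqs <- rbind(seqs, add_seqs)[meta$id, , drop = FALSE]
    }

    # --- substitutions ----------------------------------------------------
    cmult <- 1
    if (is_tip && !is.null(params$clock_multiplier) && branch %in% names(params$clock_multiplier))
      cmult <- params$clock_multiplier[[branch]]
    d <- params$clock_rate * duration * 1e6 * cmult
    truth$branch_ds[branch] <- d
    if (d > 0 && nrow(seqs) > 0) {
      before <- seqs
      third <- seq(3, ncol(seqs), 3)
      seqs <- jc_evolve_cols(seqs, third, d)
      if (params$omega_n > 0)
        seqs <- jc_evolve_cols(seqs, setdiff(seq_len(ncol(seqs)), third),
                               d * params$omega_n / params$omega_s)
      seqs <- fix_stops(seqs, before)
    }
    list(meta = meta, seqs = seqs, cum_ds = state$cum_ds + d)
  }

  walk <- function(node_num, state) {
    kids <- bt[bt$child_num > 0 & bt$parent == c(tree$tip.label, tree$node.label)[node_num], , drop = FALSE]
    kids <- kids[order(kids$child), , drop = FALSE]  # deterministic order
    for (k in seq_len(nrow(kids))) {
      child <- kids$child[k]
      st <- evolve_branch(state, child, kids$length[k], kids$is_tip[k])
      if (kids$is_tip[k]) {
        m <- st$meta
        m$species <- child
        m$cum_ds <- st$cum_ds
        truth$leaf_meta[[child]] <- m
        truth$leaf_seqs[[child]] <- st$seqs
      } else {
        walk(kids$child_num[k], st)
      }
    }
  }
  truth$leaf_seqs <- list()
  root_state <- list(meta = root$meta, seqs = root$seqs, cum_ds = 0)
  walk(length(tree$tip.label) + 1L, root_state)

  finalize_leaf <- function(sp) {
    m <- truth$leaf_meta[[sp]]
    g <- data.frame(id = paste(sp, m$id, sep = "_"), chrom = m$chrom,
                    start = NA_integer_, end = NA_integer_, strand = "+")
    pos <- stats::ave(seq_len(nrow(m)), m$chrom, FUN = seq_along)
    g$start <- (pos - 1L) * params$gene_spacing_bp + 1L
    g$end <- g$start + 3L * params$codon_length - 1L
    genome <- as_genome(g, species = sp)
    sq <- truth$leaf_seqs[[sp]]
    cds <- do.call(paste0, lapply(seq_len(ncol(sq)), function(j) sq[, j]))
    names(cds) <- paste(sp, rownames(sq), sep = "_")
    list(genome = genome, cds = cds)
  }
  leaves <- sort(tree$tip.label)
  fin <- lapply(leaves, finalize_leaf)
  names(fin) <- leaves

  leaf_meta <- do.call(rbind, lapply(leaves, function(sp) {
    m <- truth$leaf_meta[[sp]]
    data.frame(species = sp, gene_id = paste(sp, m$id, sep = "_"),
               lineage_id = m$id, family = m$family, copy = m$copy,
               tandem = m$tandem, birth_cum = m$birth_cum, chrom = m$chrom,
               cum_ds = m$cum_ds)
  }))
  rownames(leaf_meta) <- NULL

  truth_out <- list(
    loss_events = if (length(truth$losses)) do.call(rbind, truth$losses) else
      data.frame(branch = character(), gene = character(), family = character(),
                 copy = character(), chrom = character()),
    inversion_events = if (length(truth$inversions)) do.call(rbind, truth$inversions) else
      data.frame(branch = character(), chrom = character(),
                 rank_lo = integer(), rank_hi = integer()),
    tandem_events = if (length(truth$tandems)) do.call(rbind, truth$tandems) else
      data.frame(branch = character(), parent = character(), n_copies = integer()),
    branch_ds = truth$branch_ds,
    leaf_meta = leaf_meta,
    root_meta = root$meta,
    paralog_pairs = root$paralog_pairs,
    tagged_families = tagged,
    tree = tree)
  list(genomes = lapply(fin, `[[`, "genome"),
       cds = lapply(fin, `[[`, "cds"),
       truth = truth_out)
}

tagged_families <- function(root, params) {
  fams <- unique(root$meta$family)
  n_tag <- round(params$family_fraction * length(fams))
  if (n_tag <= 0) return(character(0))
  sample(fams, n_tag)
}

# species-pair synonymous path distance (sum of branch ds over the paths
# from each leaf up to their most recent common ancestor)
species_path_ds <- function(tree, branch_ds) {
  labs <- c(tree$tip.label, tree$node.label)
  n_tip <- length(tree$tip.label)
  depth_to_root <- function(tip) {
    path <- character(0)
    node <- which(labs == tip)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      path <- c(path, labs[node])
      node <- tree$edge[e, 1]
    }
    path
  }
  paths <- lapply(tree$tip.label, depth_to_root)
  names(paths) <- tree$tip.label
  out <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  full <- vapply(paths, function(p) sum(branch_ds[p]), numeric(1))
  for (i in seq_len(n_tip)) for (j in seq_len(n_tip)) {
    if (i == j) next
    shared <- intersect(paths[[i]], paths[[j]])
    out[i, j] <- full[i] + full[j] - 2 * sum(branch_ds[shared])
  }
  list(pair = out, full = full)
}

#' True pairwise synonymous distances for simulated genes
#'
#' Additive ground-truth dS between two leaf genes of one family: the
#' synonymous path distance through the tree, plus the WGD offset when the
#' two genes descend from different duplication copies, plus tandem birth
#' offsets. Tandem-involved pairs are additive approximations (each tandem
#' member contributes its birth offset plus twice the distance accumulated
#' since birth).
#'
#' @param sim a [simulate_genomes()] result.
#' @param gene_a,gene_b leaf gene ids (equal-length vectors).
#' @return numeric vector of distances.
#' @export
true_ds <- function(sim, gene_a, gene_b) {
  tr <- sim$truth
  meta <- tr$leaf_meta
  rownames(meta) <- meta$gene_id
  a <- meta[gene_a, ]; b <- meta[gene_b, ]
  sp <- species_path_ds(tr$tree, tr$branch_ds)
  wgd_offset <- attr(sim, "wgd_offset")
  ds <- numeric(length(gene_a))
  same_copy <- a$copy == b$copy
  ds[same_copy] <- sp$pair[cbind(a$species[same_copy], b$species[same_copy])]
  if (any(!same_copy))
    ds[!same_copy] <- wgd_offset + sp$full[a$species[!same_copy]] +
      sp$full[b$species[!same_copy]]
  tan_extra <- function(m) ifelse(m$tandem,
                                  sim$params$tandem_ds + 2 * (m$cum_ds - m$birth_cum),
                                  0)
  ds + tan_extra(a) + tan_extra(b)
}

# synthetic all-vs-all homology table from the true gene families
sim_homology <- function(genomes_meta, sim_ds_fun, params, tree) {
  species <- sort(unique(genomes_meta$species))
  rows <- list()
  for (i in seq_along(species)) for (j in i:length(species)) {
    mx <- genomes_meta[genomes_meta$species == species[i], c("gene_id", "family")]
    my <- genomes_meta[genomes_meta$species == species[j], c("gene_id", "family")]
    mm <- merge(mx, my, by = "family", suffixes = c("_a", "_b"))
    mm <- mm[mm$gene_id_a != mm$gene_id_b, , drop = FALSE]
    if (i == j) mm <- mm[mm$gene_id_a < mm$gene_id_b, , drop = FALSE]
    if (!nrow(mm)) next
    rows[[length(rows) + 1L]] <- mm[, c("gene_id_a", "gene_id_b")]
  }
  pairs <- do.call(rbind, rows)
  ds <- sim_ds_fun(pairs$gene_id_a, pairs$gene_id_b)
  aln_len <- 3 * params$codon_length
  pident <- pmax(35, round(100 * exp(-0.7 * ds), 1))
  bitscore <- round(2 * aln_len * pident / 100, 1)
  hits <- data.frame(query = c(pairs$gene_id_a, pairs$gene_id_b),
                     subject = c(pairs$gene_id_b, pairs$gene_id_a),
                     pident = rep(pident, 2), length = aln_len,
                     mismatch = rep(round(aln_len * (1 - pident / 100)), 2),
                     gapopen = 0L, qstart = 1L, qend = aln_len,
                     sstart = 1L, send = aln_len,
                     evalue = rep(10^-pmin(180, bitscore / 3), 2),
                     bitscore = rep(bitscore, 2))
  if (params$noise_hits > 0) {
    ids <- genomes_meta$gene_id
    n_pairs <- params$noise_hits * choose(length(species) + 1, 2)
    qa <- sample(ids, n_pairs, replace = TRUE)
    sa <- sample(ids, n_pairs, replace = TRUE)
    keep <- qa != sa
    noise <- data.frame(query = qa[keep], subject = sa[keep],
                        pident = round(stats::runif(sum(keep), 30, 60), 1),
                        length = round(aln_len * stats::runif(sum(keep), 0.2, 0.6)),
                        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
                        sstart = 1L, send = 1L,
                        evalue = 10^stats::runif(sum(keep), -20, -6),
                        bitscore = round(stats::runif(sum(keep), 50, 120), 1))
    noise$mismatch <- as.integer(round(noise$length * 0.4))
    hits <- rbind(hits, noise)
  }
  hits$self_hit <- hits$query == hits$subject
  rownames(hits) <- NULL
  hits
}

#' Run the full genome-evolution simulation
#'
#' Seeds one pseudo-random stream, simulates the ancestor, applies the WGD
#' and fusion plan, evolves genomes along the tree and synthesizes the
#' all-vs-all homology table from the true families. The WGD sequence
#' offset is chosen so that surviving duplicate pairs reach `wgd_ds` at the
#' leaves.
#'
#' @param params a [sim_params()] object.
#' @return object of class `"synfrac_sim"`: list with `genomes`, `cds`,
#'   `hits`, `tree`, `truth`, `params`.
#' @export
simulate_genomes <- function(params = sim_params()) {
  set.seed(params$seed)
  anc <- simulate_ancestor(params)
  root <- apply_wgd_and_fusions(anc, params)

  # diverge the two WGD copies so leaf paralog pairs hit the target Ks
  height <- max(ape::node.depth.edgelength(params$tree)[seq_along(params$tree$tip.label)])
  wgd_offset <- max(0, params$wgd_ds - 2 * params$clock_rate * height * 1e6)
  if (wgd_offset > 0) {
    b_rows <- root$meta$copy == "b"
    sq <- root$seqs[b_rows, , drop = FALSE]
    before <- sq
    sq <- jc_evolve_cols(sq, seq(3, ncol(sq), 3), wgd_offset)
    if (params$omega_n > 0)
      sq <- jc_evolve_cols(sq, setdiff(seq_len(ncol(sq)), seq(3, ncol(sq), 3)),
                           wgd_offset * params$omega_n / params$omega_s)
    sq <- fix_stops(sq, before)
    root$seqs[b_rows, ] <- sq
  }

  ev <- evolve_along_tree(root, params)
  sim <- structure(list(genomes = ev$genomes, cds = ev$cds,
                        hits = NULL, tree = params$tree,
                        truth = ev$truth, params = params),
                   class = "synfrac_sim")
  attr(sim, "wgd_offset") <- wgd_offset
  sim$hits <- sim_homology(ev$truth$leaf_meta,
                           function(a, b) true_ds(sim, a, b), params, params$tree)
  sim
}

#' @export
print.synfrac_sim <- function(x, ...) {
  cat(sprintf("<synfrac simulation> %d species, %d homology rows, seed %d\n",
              length(x$genomes), nrow(x$hits), x$params$seed))
  for (sp in names(x$genomes))
    cat(sprintf("  %s: %d genes\n", sp, nrow(x$genomes[[sp]])))
  invisible(x)
}

#' Write a simulation to disk as standard-format fixture files
#'
#' Emits one GFF3 and one FASTA per species, the 12-column homology table,
#' the Newick tree, two noisy family-evidence gene lists per species
#' (for the two-evidence intersection workflow), and ground-truth TSVs
#' under `truth/`.
#'
#' @param sim a [simulate_genomes()] result.
#' @param outdir output directory (created if needed).
#' @param family_dropout per-list probability that a true family gene is
#'   missing from an evidence list.
#' @return named character vector of written paths, invisibly.
#' @export
emit_fixture <- function(sim, outdir, family_dropout = 0.05) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create ", outdir)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  paths <- character(0)
  for (sp in names(sim$genomes)) {
    p_gff <- file.path(outdir, paste0(sp, ".gff3"))
    write_gene_positions(sim$genomes[[sp]], p_gff)
    p_fa <- file.path(outdir, paste0(sp, ".cds.fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds[[sp]]), p_fa)
    paths <- c(paths, p_gff, p_fa)
  }
  p_hits <- file.path(outdir, "homology.tsv")
  utils::write.table(sim$hits[, setdiff(names(sim$hits), "self_hit")],
                     p_hits, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  p_tree <- file.path(outdir, "tree.nwk")
  ape::write.tree(sim$tree, p_tree)
  paths <- c(paths, p_hits, p_tree)

  lm <- sim$truth$leaf_meta
  fam_genes <- lm$gene_id[lm$family %in% sim$truth$tagged_families]
  for (sp in names(sim$genomes)) {
    g <- fam_genes[startsWith(fam_genes, paste0(sp, "_"))]
    for (ev in c("domain_hits", "homology_family")) {
      keep <- stats::runif(length(g)) >= family_dropout
      p <- file.path(outdir, sprintf("%s.%s.txt", sp, ev))
      writeLines(g[keep], p)
      paths <- c(paths, p)
    }
  }
  tw <- function(df, name) {
    p <- file.path(outdir, "truth", name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths,
             tw(sim$truth$loss_events, "losses.tsv"),
             tw(sim$truth$inversion_events, "inversions.tsv"),
             tw(sim$truth$tandem_events, "tandem.tsv"),
             tw(sim$truth$leaf_meta, "families.tsv"),
             tw(data.frame(branch = names(sim$truth$branch_ds),
                           ds = unname(sim$truth$branch_ds)), "branches.tsv"))
  invisible(paths)
}
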