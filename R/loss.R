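#' Per-chromosome and windowed gene loss for one species
#'
#' Loss is defined operationally as the absence of a collinear ortholog:
#' a reference gene whose ortholog cell for `species` is empty counts as
#' lost, even if a non-collinear homolog survives elsewhere. Windowed
#' retention uses half-open windows `[k*w, (k+1)*w)` on reference base-pair
#' coordinates with step equal to the window width.
#'
#' @param table alignment table from [build_table()].
#' @param species species whose ortholog column is scored.
#' @param reference the reference genome (row order must match the table).
#' @param window_bp window width in base pairs (default 1 Mb).
#' @return list of class `"retention_profile"`: `species`,
#'   `per_chromosome` (chrom, chrom_ordinal, n_ref, n_retained,
#'   loss_fraction) and `per_window` (chrom, window, start, n_ref,
#'   retained_fraction).
#' @export
chromosome_loss <- function(table, species, reference, window_bp = 1e6) {
  col <- paste0(species, ".ortholog")
  if (!col %in% names(table)) stop("no ortholog column for ", species)
  stopifnot(nrow(table) == nrow(reference),
            all(table$ref == reference$id))
  present <- !is.na(table[[col]])
  chroms <- unique(reference$chrom)
  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    i <- reference$chrom == ch
    n <- sum(i)
    data.frame(chrom = ch, chrom_ordinal = reference$chrom_ordinal[i][1],
               n_ref = n, n_retained = sum(present[i]),
               loss_fraction = if (n > 0) 1 - sum(present[i]) / n else NA_real_)
  }))
  win <- (reference$start - 1) %/% window_bp
  key <- paste(reference$chrom, win, sep = "\r")
  per_window <- do.call(rbind, lapply(split(seq_len(nrow(reference)), key), function(i) {
    data.frame(chrom = reference$chrom[i[1]], window = win[i[1]],
               start = win[i[1]] * window_bp, n_ref = length(i),
               retained_fraction = mean(present[i]))
  }))
  per_window <- per_window[order(per_window$chrom, per_window$window), ]
  rownames(per_chrom) <- rownames(per_window) <- NULL
  structure(list(species = species, per_chromosome = per_chrom,
                 per_window = per_window, window_bp = window_bp),
            class = "retention_profile")
}

#' @export
print.retention_profile <- function(x, ...) {
  cat(sprintf("<retention profile> %s: mean loss %.1f%% over %d chromosomes\n",
              x$species, 100 * mean(x$per_chromosome$loss_fraction, na.rm = TRUE),
              nrow(x$per_chromosome)))
  invisible(x)
}

#' Ordinal trend of chromosome loss rates
#'
#' Tests the association between chromosome ordinal number and loss
#' fraction with a Spearman rank correlation and a seeded permutation
#' p-value (a made-explicit version of the qualitative claim that
#' smaller-numbered chromosomes lose fewer genes).
#'
#' @param profile a [chromosome_loss()] profile, or a data.frame with
#'   `chrom_ordinal` and `loss_fraction`.
#' @param n_perm number of permutations.
#' @param alternative `"greater"` (loss increases with ordinal, default),
#'   `"less"`, or `"two.sided"`.
#' @param seed seed for the permutation stream.
#' @return list with `rho`, `p_value`, `n`, `alternative`, `n_perm`.
#' @export
ordinal_trend <- function(profile, n_perm = 10000L,
                          alternative = c("greater", "less", "two.sided"),
                          seed = 1L) {
  alternative <- match.arg(alternative)
  df <- if (inherits(profile, "retention_profile")) profile$per_chromosome else profile
  df <- df[!is.na(df$loss_fraction), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 chromosomes with defined loss fractions")
  x <- df$chrom_ordinal; y <- df$loss_fraction
  if (length(unique(y)) == 1)
    return(list(rho = 0, p_value = 1, n = length(y),
                alternative = alternative, n_perm = 0L))
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm, stats::cor(x, sample(y), method = "spearman"))
  p <- switch(alternative,
              greater = (1 + sum(perm >= rho - 1e-12)) / (n_perm + 1),
              less = (1 + sum(perm <= rho + 1e-12)) / (n_perm + 1),
              two.sided = (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1))
  list(rho = rho, p_value = p, n = length(y),
       alternative = alternative, n_perm = n_perm)
}

#' Partition duplicated regions into retention subgenomes
#'
#' Each paleo-duplication block of the reference pairs two homoeologous
#' reference regions. For every species, the side whose genes kept more
#' collinear orthologs is assigned to `subgenome_more`, the other to
#' `subgenome_fewer` (ties go to the side on the lower-ordinal
#' chromosome). Regions in which both sides lost every gene are excluded
#' and counted.
#'
#' @param table alignment table.
#' @param ref_paralogs the reference self-comparison (list with `blocks`
#'   carrying a `class` column and `anchors`), whose `gct_paralog` blocks
#'   define the region pairing.
#' @param species species to partition (default: every ortholog column).
#' @return list with `assignments` (per block x species) and
#'   `chromosome_summary` (per species x chromosome x subgenome loss
#'   fractions), plus `n_excluded`.
#' @export
split_subgenomes <- function(table, ref_paralogs, species = NULL) {
  if (is.null(species)) {
    cols <- grep("\\.ortholog$", names(table), value = TRUE)
    species <- sub("\\.ortholog$", "", cols)
  }
  bl <- ref_paralogs$blocks
  bl <- bl[bl$class == "gct_paralog", , drop = FALSE]
  an <- ref_paralogs$anchors
  assignments <- list()
  n_excluded <- 0L
  ords <- chrom_ordinals(sort(unique(c(bl$chrom_a, bl$chrom_b))))
  for (k in seq_len(nrow(bl))) {
    a <- an[an$block_id == bl$block_id[k], , drop = FALSE]
    ia <- match(a$gene_a, table$ref)
    ib <- match(a$gene_b, table$ref)
    for (sp in species) {
      col <- table[[paste0(sp, ".ortholog")]]
      ra <- sum(!is.na(col[ia]), na.rm = TRUE)
      rb <- sum(!is.na(col[ib]), na.rm = TRUE)
      if (ra + rb == 0) { n_excluded <- n_excluded + 1L; next }
      more_is_a <- if (ra != rb) ra > rb else
        ords[bl$chrom_a[k]] <= ords[bl$chrom_b[k]]
      assignments[[length(assignments) + 1L]] <- data.frame(
        block_id = bl$block_id[k], species = sp,
        chrom_a = bl$chrom_a[k], chrom_b = bl$chrom_b[k],
        n_anchors = nrow(a), retained_a = ra, retained_b = rb,
        more_side = if (more_is_a) "a" else "b",
        chrom_more = if (more_is_a) bl$chrom_a[k] else bl$chrom_b[k],
        chrom_fewer = if (more_is_a) bl$chrom_b[k] else bl$chrom_a[k])
    }
  }
  assignments <- if (length(assignments)) do.call(rbind, assignments) else
    data.frame(block_id = character(), species = character(),
               chrom_a = character(), chrom_b = character(),
               n_anchors = integer(), retained_a = integer(),
               retained_b = integer(), more_side = character(),
               chrom_more = character(), chrom_fewer = character())
  rownames(assignments) <- NULL

  summ <- list()
  if (nrow(assignments)) {
    long <- rbind(
      data.frame(species = assignments$species, chrom = assignments$chrom_more,
                 subgenome = "more", n_ref = assignments$n_anchors,
                 n_ret = pmax(assignments$retained_a, assignments$retained_b)),
      data.frame(species = assignments$species, chrom = assignments$chrom_fewer,
                 subgenome = "fewer", n_ref = assignments$n_anchors,
                 n_ret = pmin(assignments$retained_a, assignments$retained_b)))
    key <- paste(long$species, long$chrom, long$subgenome, sep = "\r")
    summ <- do.call(rbind, lapply(split(long, key), function(d)
      data.frame(species = d$species[1], chrom = d$chrom[1],
                 subgenome = d$subgenome[1], n_ref = sum(d$n_ref),
                 n_retained = sum(d$n_ret),
                 loss_fraction = 1 - sum(d$n_ret) / sum(d$n_ref))))
    rownames(summ) <- NULL
  }
  list(assignments = assignments, chromosome_summary = summ,
       n_excluded = n_excluded)
}

#' Assign gene losses to tree branches by Dollo parsimony
#'
#' Each reference-attested gene is assumed present at the root (single
#' origin); the minimal explanation of its absences is one loss on the stem
#' of every maximal all-absent clade. The reference species acts as an
#' always-present outgroup: if it appears among the tree's tips it is
#' treated as retaining every gene (each table row attests ancestral
#' presence).
#'
#' @param patterns logical presence matrix from [presence_patterns()].
#' @param tree rooted `phylo`; tips must cover the pattern species (tips
#'   other than the reference that carry no pattern column are dropped).
#' @param reference_species name of the reference tip, or `NULL`.
#' @return data.frame with one row per branch (named by child node or
#'   tip): `branch`, `losses`. Branches never hit keep zero counts.
#' @export
dollo_assign <- function(patterns, tree, reference_species = NULL) {
  species <- colnames(patterns)
  if (!is.null(reference_species) && reference_species %in% species) {
    keep <- patterns[, reference_species]
    if (!all(keep)) message(sum(!keep), " gene(s) absent in the reference skipped")
    patterns <- patterns[keep, setdiff(species, reference_species), drop = FALSE]
    species <- colnames(patterns)
  }
  extra <- setdiff(tree$tip.label, c(species, reference_species))
  if (length(extra)) tree <- ape::keep.tip(tree, setdiff(tree$tip.label, extra))
  if (!all(species %in% tree$tip.label))
    stop("tree is missing tips: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  labs <- c(tree$tip.label, tree$node.label)
  n_tip <- length(tree$tip.label)
  edge <- tree$edge

  # collapse identical patterns; counts multiply at the end
  key <- apply(patterns, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(key)
  uniq <- do.call(rbind, strsplit(names(tab), ""))
  storage.mode(uniq) <- "integer"
  colnames(uniq) <- species

  counts <- stats::setNames(numeric(nrow(edge)), labs[edge[, 2]])
  ref_present <- !is.null(reference_species) && reference_species %in% tree$tip.label

  for (r in seq_len(nrow(uniq))) {
    present_tip <- logical(n_tip)
    present_tip[match(species, tree$tip.label)] <- uniq[r, ] == 1L
    if (ref_present) present_tip[match(reference_species, tree$tip.label)] <- TRUE
    all_absent <- c(!present_tip, rep(NA, tree$Nnode))
    for (e in ape::postorder(tree)) {
      par <- edge[e, 1]; child <- edge[e, 2]
      if (is.na(all_absent[par])) all_absent[par] <- TRUE
      all_absent[par] <- all_absent[par] && all_absent[child]
    }
    # a loss sits on every edge whose clade is all-absent but whose
    # parent's clade is not (maximal all-absent clades)
    loss_edges <- which(all_absent[edge[, 2]] & !all_absent[edge[, 1]])
    if (length(loss_edges))
      counts[loss_edges] <- counts[loss_edges] + as.numeric(tab[r])
  }
  data.frame(branch = labs[edge[, 2]], losses = unname(counts[labs[edge[, 2]]]),
             row.names = NULL)
}

#' Convert branch loss counts into loss rates
#'
#' @param counts data.frame with `branch` and `losses` (from
#'   [dollo_assign()]).
#' @param durations branch durations in My: a named numeric vector, or a
#'   `phylo` whose edge lengths are used (named by child node/tip).
#' @return data.frame `branch`, `losses`, `duration_my`, `rate`
#'   (genes/My; `NA` with a warning for zero durations).
#' @export
branch_rates <- function(counts, durations) {
  if (inherits(durations, "phylo")) {
    tr <- durations
    if (is.null(tr$node.label) || any(tr$node.label == ""))
      tr$node.label <- paste0("n", seq_len(tr$Nnode))
    labs <- c(tr$tip.label, tr$node.label)
    durations <- stats::setNames(tr$edge.length, labs[tr$edge[, 2]])
  }
  d <- unname(durations[counts$branch])
  if (any(!is.na(d) & d <= 0)) {
    warning("zero-duration branch(es); rate set to NA")
    d[d <= 0] <- NA
  }
  data.frame(branch = counts$branch, losses = counts$losses,
             duration_my = d, rate = counts$losses / d)
}

#' Percent excess of one loss rate over another
#'
#' `(rate1 - rate2) / rate2 * 100`, rounded to one decimal.
#'
#' @param rate1,rate2 loss rates (genes/My).
#' @return percent excess.
#' @export
rate_excess <- function(rate1, rate2) round((rate1 - rate2) / rate2 * 100, 1)
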