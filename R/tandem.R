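#' Detect tandem gene clusters
#'
#' Two genes are tandem-linked when they are homologous, lie on the same
#' chromosome, and are separated by at most `max_gap` intervening genes
#' (`|rank difference| - 1 <= max_gap`). Clusters are the connected
#' components of this link graph (transitive closure), so a chain
#' A~B, B~C forms one cluster without a direct A~C hit. Singletons are
#' discarded. There is no single field-standard definition of "tandem";
#' the `max_gap = 5` default is a common convention and is echoed in every
#' report.
#'
#' @param genome genome object.
#' @param hits filtered intra-species homology hits.
#' @param max_gap maximum intervening genes between linked members.
#' @return data.frame of cluster members: `cluster_id`, `chrom`, `gene_id`,
#'   `rank`, with attributes `species` and `max_gap`.
#' @export
find_tandem <- function(genome, hits, max_gap = 5L) {
  ia <- match(hits$query, genome$id)
  ib <- match(hits$subject, genome$id)
  ok <- !is.na(ia) & !is.na(ib) & hits$query != hits$subject &
    genome$chrom[ia] == genome$chrom[ib] &
    abs(genome$rank[ia] - genome$rank[ib]) - 1L <= max_gap
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      gene_id = character(), rank = integer())
  attr(empty, "species") <- genome_species(genome)
  attr(empty, "max_gap") <- max_gap
  if (!any(ok)) return(empty)
  g <- igraph::graph_from_edgelist(cbind(hits$query[ok], hits$subject[ok]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  members <- data.frame(gene_id = names(comp$membership),
                        comp = unname(comp$membership))
  members <- members[!duplicated(members$gene_id), , drop = FALSE]
  keep <- members$comp %in% which(comp$csize >= 2)
  members <- members[keep, , drop = FALSE]
  gi <- match(members$gene_id, genome$id)
  out <- data.frame(cluster_id = sprintf("%s.tc%04d", genome_species(genome),
                                         match(members$comp, sort(unique(members$comp)))),
                    chrom = genome$chrom[gi], gene_id = members$gene_id,
                    rank = genome$rank[gi])
  out <- out[order(out$cluster_id, out$rank), ]
  rownames(out) <- NULL
  attr(out, "species") <- genome_species(genome)
  attr(out, "max_gap") <- max_gap
  out
}

#' Tandem summary statistics
#'
#' Total tandem genes, their share of annotated genes, density per
#' declared length unit, and per-chromosome proportions. The density
#' denominator is the caller-declared genome length so that published
#' ratio arithmetic can be reproduced whatever its units.
#'
#' @param clusters [find_tandem()] result.
#' @param genome genome object (for annotated gene totals).
#' @param reported_length declared genome length, in the caller's units.
#' @return list with `n_tandem`, `percent_of_genes`, `density`
#'   (rounded to integer), `per_chromosome` (chrom, n_tandem, proportion),
#'   `max_gap`.
#' @export
tandem_stats <- function(clusters, genome, reported_length) {
  stopifnot(reported_length > 0)
  n_tan <- nrow(clusters)
  n_genes <- nrow(genome)
  per_chrom <- if (n_tan > 0) {
    cnt <- table(clusters$chrom)
    data.frame(chrom = names(cnt), n_tandem = as.integer(cnt),
               proportion = as.numeric(cnt) / n_tan)
  } else {
    data.frame(chrom = character(), n_tandem = integer(), proportion = numeric())
  }
  list(n_tandem = n_tan,
       percent_of_genes = if (n_genes > 0) 100 * n_tan / n_genes else NA_real_,
       density = round(n_tan / reported_length),
       per_chromosome = per_chrom,
       max_gap = attr(clusters, "max_gap"))
}
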