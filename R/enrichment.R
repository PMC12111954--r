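#' Two-evidence gene family call
#'
#' Intersects a domain-scan hit set with a homology-search hit set; genes
#' supported by both lines of evidence are the inferred family members
#' (the intersection rule used for NBS-LRR disease-resistance gene calls).
#'
#' @param domain_hits,homology_hits character vectors of gene ids from the
#'   same species' gene universe.
#' @return character vector of genes present in both sets.
#' @export
family_intersect <- function(domain_hits, homology_hits) {
  intersect(unique(domain_hits), unique(homology_hits))
}

#' Build a 2x2 contingency table from margin counts
#'
#' For testing the association between two gene properties (e.g. being
#' tandem and belonging to a gene family): `a` genes have both, `b` only
#' the first, `c` only the second, `d` neither.
#'
#' @param n_genes annotated genes in the genome.
#' @param n_tandem genes with the first property.
#' @param n_family genes with the second property.
#' @param n_both genes with both.
#' @return list of class `"contingency_2x2"` with `a`, `b`, `c`, `d`.
#' @export
table_from_counts <- function(n_genes, n_tandem, n_family, n_both) {
  if (n_both > min(n_tandem, n_family) || n_tandem + n_family - n_both > n_genes)
    stop("inconsistent margins")
  structure(list(a = n_both, b = n_tandem - n_both, c = n_family - n_both,
                 d = n_genes - n_tandem - n_family + n_both),
            class = "contingency_2x2")
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' `statistic = N (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with the upper-tail chi-squared probability (1 df) evaluated in
#' log-space so that p-values far below 1e-300 remain representable.
#' A zero margin yields statistic 0 and p = 1 with a warning.
#'
#' @param tab a [table_from_counts()] table (or any list with `a`-`d`).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list of class `"enrichment_result"`: `statistic`, `df`, `p`,
#'   `expected_a`, `direction` (`"over"`/`"under"`).
#' @export
yates_chi2 <- function(tab, correct = TRUE) {
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c <- as.numeric(tab$c); d <- as.numeric(tab$d)
  stopifnot(all(c(a, b, c, d) >= 0))
  N <- a + b + c + d
  if (N <= 0) stop("empty table")
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  expected_a <- m1 * m3 / N
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) {
    warning("zero margin; test undefined")
    return(structure(list(statistic = 0, df = 1L, p = 1,
                          expected_a = expected_a,
                          direction = "over"),
                     class = "enrichment_result"))
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - N / 2)
  statistic <- N * dev^2 / (m1 * m2 * m3 * m4)
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  structure(list(statistic = statistic, df = 1L, p = p,
                 expected_a = expected_a,
                 direction = if (a >= expected_a) "over" else "under"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<chi2> statistic=%.4g p=%.3g (%s-represented; expected a=%.1f)\n",
              x$statistic, x$p, x$direction, x$expected_a))
  invisible(x)
}

#' Over-representation analysis against a category annotation
#'
#' For each category, a 2x2 association test between target membership
#' and category membership over the gene universe, with Benjamini-
#' Hochberg multiple-testing correction and the category's share of the
#' target set. Uses the same corrected chi-squared machinery as
#' [yates_chi2()] by default; Fisher's exact test is available.
#'
#' @param target_set character vector of gene ids (subset of `universe`).
#' @param annotation data.frame with columns `gene` and `category`.
#' @param universe character vector of gene ids.
#' @param method `"chisq"` (Yates-corrected, default) or `"fisher"`.
#' @return data.frame: `category`, `a`, `b`, `c`, `d`, `statistic`, `p`,
#'   `p_adj`, `direction`, `target_share` (fraction of the target set in
#'   the category).
#' @export
ora <- function(target_set, annotation, universe,
                method = c("chisq", "fisher")) {
  method <- match.arg(method)
  target_set <- unique(target_set)
  universe <- unique(universe)
  if (!length(target_set)) stop("empty target set")
  if (!all(target_set %in% universe)) stop("target set not contained in universe")
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  cats <- split(annotation$gene, annotation$category)
  skipped <- setdiff(unique(annotation$category), names(cats))
  if (length(skipped)) message(length(skipped), " categories absent from universe skipped")
  rows <- lapply(names(cats), function(cat) {
    members <- unique(cats[[cat]])
    a <- length(intersect(target_set, members))
    b <- length(target_set) - a
    c <- length(members) - a
    d <- length(universe) - a - b - c
    if (method == "chisq") {
      r <- yates_chi2(list(a = a, b = b, c = c, d = d))
      stat <- r$statistic; p <- r$p; dir <- r$direction
    } else {
      f <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
      stat <- NA_real_; p <- f$p.value
      dir <- if (f$estimate >= 1) "over" else "under"
    }
    data.frame(category = cat, a = a, b = b, c = c, d = d,
               statistic = stat, p = p, direction = dir,
               target_share = a / length(target_set))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), c("category", "a", "b", "c", "d", "statistic",
                             "p", "p_adj", "direction", "target_share")]
  rownames(out) <- NULL
  out
}
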