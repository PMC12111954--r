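#' @importFrom Biostrings GENETIC_CODE
NULL

# Codon bookkeeping for the Nei-Gojobori (1986) estimator, built once per
# session. Synonymous site fractions count mutations to stop codons as
# nonsynonymous so that S + N = 3 * n_codons holds exactly; multi-hit codon
# differences are averaged over all orderings of single-step pathways,
# excluding pathways that pass through a stop codon (classic NG86; when
# every pathway is stop-routed, all pathways are used as a fallback).
ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$SdM)) return(ng86_env)
  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE)[, 3:1],
                  1, paste0, collapse = "")
  aa <- Biostrings::GENETIC_CODE[codons]
  is_stop <- aa == "*"
  n <- length(codons)
  idx <- stats::setNames(seq_len(n), codons)

  neighbours <- function(codon, pos) {
    out <- character(3)
    k <- 0
    for (nt in nts) {
      if (substr(codon, pos, pos) == nt) next
      k <- k + 1
      out[k] <- `substr<-`(codon, pos, pos, nt)
    }
    out
  }

  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    if (is_stop[i]) { syn_sites[i] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      nb <- neighbours(codons[i], pos)
      s <- s + sum(aa[nb] == aa[i] & aa[nb] != "*") / 3
    }
    syn_sites[i] <- s
  }

  # pathway-averaged (Sd, Nd) contribution for every ordered codon pair
  SdM <- matrix(0, n, n, dimnames = list(codons, codons))
  NdM <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || is_stop[i] || is_stop[j]) next
      diffpos <- which(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      perms <- perms_of(diffpos)
      syn_tot <- 0; non_tot <- 0; n_valid <- 0
      syn_all <- 0; non_all <- 0
      for (p in seq_len(nrow(perms))) {
        cur <- codons[i]
        syn <- 0; non <- 0; valid <- TRUE
        for (pos in perms[p, ]) {
          nxt <- `substr<-`(cur, pos, pos, substr(codons[j], pos, pos))
          if (aa[nxt] == "*") valid <- FALSE
          if (aa[nxt] == aa[cur]) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        syn_all <- syn_all + syn; non_all <- non_all + non
        if (valid) { syn_tot <- syn_tot + syn; non_tot <- non_tot + non; n_valid <- n_valid + 1 }
      }
      if (n_valid > 0) {
        SdM[i, j] <- syn_tot / n_valid
        NdM[i, j] <- non_tot / n_valid
      } else {
        SdM[i, j] <- syn_all / nrow(perms)
        NdM[i, j] <- non_all / nrow(perms)
      }
    }
  }
  ng86_env$codons <- codons
  ng86_env$idx <- idx
  ng86_env$aa <- aa
  ng86_env$is_stop <- is_stop
  ng86_env$syn_sites <- syn_sites
  ng86_env$SdM <- SdM
  ng86_env$NdM <- NdM
  ng86_env
}

perms_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (k in seq_along(x)) {
    rest <- perms_of(x[-k])
    out <- rbind(out, cbind(x[k], rest))
  }
  out
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pair two coding sequences codon-by-codon
#'
#' Builds the gap-free codon alignment the NG86 estimator consumes.
#' Equal-length in-frame sequences are paired positionally; unequal lengths
#' require a supplied protein alignment (two equal-length aligned amino
#' acid strings with `-` gaps) used to thread codons. Columns containing a
#' gap, a stop codon, or a non-ACGT base are dropped and counted.
#'
#' @param cds_a,cds_b nucleotide coding sequences (character scalars).
#' @param protein_alignment optional character vector of two aligned
#'   protein strings.
#' @return object of class `"codon_alignment"`: a list with `codons_a`,
#'   `codons_b`, `n_codons` and `n_dropped`.
#' @export
make_codon_alignment <- function(cds_a, cds_b, protein_alignment = NULL) {
  if (is.null(protein_alignment)) {
    if (nchar(cds_a) != nchar(cds_b))
      stop("sequences of unequal length require a protein alignment")
    ca <- split_codons(cds_a)
    cb <- split_codons(cds_b)
  } else {
    stopifnot(length(protein_alignment) == 2,
              nchar(protein_alignment[1]) == nchar(protein_alignment[2]))
    ca0 <- split_codons(cds_a)
    cb0 <- split_codons(cds_b)
    pa <- strsplit(protein_alignment[1], "")[[1]]
    pb <- strsplit(protein_alignment[2], "")[[1]]
    ia <- cumsum(pa != "-")
    ib <- cumsum(pb != "-")
    both <- pa != "-" & pb != "-"
    ca <- ca0[ia[both]]
    cb <- cb0[ib[both]]
  }
  tab <- ng86_tables()
  known <- ca %in% tab$codons & cb %in% tab$codons
  ca <- ca[known]; cb <- cb[known]
  keep <- !(tab$is_stop[tab$idx[ca]] | tab$is_stop[tab$idx[cb]])
  n_dropped <- sum(!known) + sum(!keep)
  ca <- ca[keep]; cb <- cb[keep]
  structure(list(codons_a = ca, codons_b = cb,
                 n_codons = length(ca), n_dropped = n_dropped),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous distances
#'
#' Computes per-codon synonymous site fractions from the universal genetic
#' code (averaged across the two sequences), pathway-averaged synonymous and
#' nonsynonymous difference counts, and Jukes-Cantor-corrected distances
#' `dS = -(3/4) log(1 - (4/3) pS)` (and analogously `dN`). A distance
#' saturates (reported `NA`, `defined = FALSE` for `dS`) when its proportion
#' reaches 3/4.
#'
#' @param aln a [make_codon_alignment()] object.
#' @return list of class `"ks_value"`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `n_codons`, `defined` (whether `dS` is defined).
#' @examples
#' a <- strrep("GGT", 10)
#' b <- paste0(strrep("GGC", 1), strrep("GGT", 9))
#' ng86(make_codon_alignment(a, b))$dS
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons < 1) stop("empty codon alignment")
  tab <- ng86_tables()
  ia <- tab$idx[aln$codons_a]
  ib <- tab$idx[aln$codons_b]
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * aln$n_codons - S
  Sd <- sum(tab$SdM[cbind(ia, ib)])
  Nd <- sum(tab$NdM[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = jc(pS), dN = jc(pN), n_codons = aln$n_codons,
                 defined = pS < 0.75),
            class = "ks_value")
}

#' @export
print.ks_value <- function(x, ...) {
  cat(sprintf("<ks> dS=%s dN=%s (S=%.2f N=%.2f, %d codons)\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              x$S, x$N, x$n_codons))
  invisible(x)
}

#' NG86 distances for many gene pairs
#'
#' Batch interface used by the pipeline: equal-length in-frame pairs only
#' (codon indices are cached per gene).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param cds named character vector of coding sequences.
#' @return `pairs` with appended columns `S`, `N`, `Sd`, `Nd`, `dS`, `dN`.
#' @export
ng86_pairs <- function(pairs, cds) {
  tab <- ng86_tables()
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(genes, names(cds))
  if (length(missing)) stop("no CDS for: ", paste(utils::head(missing, 3), collapse = ", "))
  codon_idx <- lapply(cds[genes], function(s) unname(tab$idx[split_codons(s)]))
  ka <- match(pairs$gene_a, genes)
  kb <- match(pairs$gene_b, genes)
  n <- nrow(pairs)
  S <- Sd <- Nd <- numeric(n)
  nc <- integer(n)
  for (k in seq_len(n)) {
    ia <- codon_idx[[ka[k]]]
    ib <- codon_idx[[kb[k]]]
    m <- min(length(ia), length(ib))
    ia <- ia[seq_len(m)]; ib <- ib[seq_len(m)]
    ok <- !(tab$is_stop[ia] | tab$is_stop[ib])
    ia <- ia[ok]; ib <- ib[ok]
    nc[k] <- length(ia)
    S[k] <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
    Sd[k] <- sum(tab$SdM[cbind(ia, ib)])
    Nd[k] <- sum(tab$NdM[cbind(ia, ib)])
  }
  N <- 3 * nc - S
  pS <- ifelse(S > 0, Sd / S, 0)
  pN <- ifelse(N > 0, Nd / N, 0)
  pairs$S <- S; pairs$N <- N; pairs$Sd <- Sd; pairs$Nd <- Nd
  pairs$dS <- ifelse(pS < 0.75, -0.75 * log(1 - 4 * pS / 3), NA_real_)
  pairs$dN <- ifelse(pN < 0.75, -0.75 * log(1 - 4 * pN / 3), NA_real_)
  pairs
}

#' Block-level Ks
#'
#' The block Ks is the median of the defined anchor dS values, robust to
#' anchor outliers from misassigned tandem copies.
#'
#' @param anchor_ds numeric vector of anchor dS values (may contain `NA`).
#' @return list with `ks` (`NA` when no anchor is defined) and
#'   `n_undefined`.
#' @export
block_ks <- function(anchor_ds) {
  defined <- anchor_ds[!is.na(anchor_ds)]
  list(ks = if (length(defined)) stats::median(defined) else NA_real_,
       n_undefined = sum(is.na(anchor_ds)))
}

#' Classify a block by its Ks
#'
#' Blocks with Ks below `ortholog_max` (default 0.3) are orthologous;
#' blocks inside the paleo-duplication window (default 0.4-0.9, around the
#' ~0.6 peak of the grass-common tetraploidization) are `gct_paralog`;
#' everything else, including `NA`, is `unclassified`.
#'
#' @param ks numeric vector of block Ks values.
#' @param ortholog_max,paralog_min,paralog_max class boundaries
#'   (`0 < ortholog_max <= paralog_min <= paralog_max`).
#' @return character vector in `{"ortholog", "gct_paralog", "unclassified"}`.
#' @export
classify_block <- function(ks, ortholog_max = 0.3, paralog_min = 0.4,
                           paralog_max = 0.9) {
  stopifnot(ortholog_max > 0, ortholog_max <= paralog_min, paralog_min <= paralog_max)
  out <- rep("unclassified", length(ks))
  out[!is.na(ks) & ks < ortholog_max] <- "ortholog"
  out[!is.na(ks) & ks >= paralog_min & ks <= paralog_max] <- "gct_paralog"
  out
}

#' Convert a synonymous distance to a divergence time
#'
#' `T = Ks / (2 * clock_rate)`, reported in million years. The clock rate
#' (substitutions per synonymous site per year) has no universally agreed
#' value and must be calibrated by the user; the package default used by
#' the pipeline is arbitrary and documented as such.
#'
#' @param ks synonymous distance(s).
#' @param clock_rate substitutions/site/year, `> 0`.
#' @return time in My (`NA` where `ks` is `NA`).
#' @export
ks_to_time <- function(ks, clock_rate) {
  stopifnot(clock_rate > 0)
  ks / (2 * clock_rate) / 1e6
}

#' Rescale per-species Ks distributions onto a reference clock
#'
#' Locates the shared-event mode of each species' Ks distribution by kernel
#' density maximum and multiplies each set by
#' `mode(reference) / mode(species)`, so that a lineage with a faster
#' molecular clock is shrunk onto the reference scale.
#'
#' @param ks_sets named list of numeric Ks vectors.
#' @param reference_species name of the reference set.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return list with `scaled` (rescaled sets), `scale_factors` and `modes`.
#' @export
rate_correct <- function(ks_sets, reference_species, bw = "nrd0") {
  stopifnot(reference_species %in% names(ks_sets))
  modes <- vapply(names(ks_sets), function(sp) {
    x <- ks_sets[[sp]]
    x <- x[is.finite(x)]
    if (!length(x)) stop("empty Ks set for ", sp)
    d <- stats::density(x, bw = bw)
    peaks <- which(diff(sign(diff(d$y))) == -2) + 1
    if (length(peaks) >= 2) {
      ys <- sort(d$y[peaks], decreasing = TRUE)
      if (ys[2] >= 0.9 * ys[1])
        warning("ambiguous Ks modes for ", sp, "; using the largest")
    }
    d$x[which.max(d$y)]
  }, numeric(1))
  scale_factors <- modes[[reference_species]] / modes
  scaled <- Map(function(x, f) x * f, ks_sets, scale_factors[names(ks_sets)])
  list(scaled = scaled, scale_factors = scale_factors, modes = modes)
}
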