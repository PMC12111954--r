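#' Read an all-vs-all homology table (BLAST outfmt 6)
#'
#' Parses the standard 12-column tabular format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Malformed rows (wrong column count, non-numeric
#' e-value or bit score) are dropped with a single summarising warning.
#'
#' @param path tab-separated file; lines starting with `#` are ignored.
#' @return data.frame with columns `query`, `subject`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore` and logical `self_hit`.
#' @export
read_homology_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  m <- do.call(rbind, fields[ok])
  hits <- data.frame(query = m[, 1], subject = m[, 2],
                     pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                     mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                     qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                     sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                     evalue = suppressWarnings(as.numeric(m[, 11])),
                     bitscore = suppressWarnings(as.numeric(m[, 12])))
  bad_num <- is.na(hits$evalue) | is.na(hits$bitscore) | hits$evalue < 0
  n_bad <- sum(!ok) + sum(bad_num)
  if (n_bad > 0)
    warning(sprintf("%d malformed row(s) dropped from %s", n_bad, path))
  hits <- hits[!bad_num, , drop = FALSE]
  hits$self_hit <- hits$query == hits$subject
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             self_hit = logical())
}

#' Filter homology hits
#'
#' Removes self-hits, applies the e-value ceiling (the homology-search
#' threshold used for the ancient-duplicate searches, default 1e-5), and
#' keeps at most `top_n` hits per query by descending bit score. The
#' operation is idempotent.
#'
#' @param hits data.frame as from [read_homology_table()].
#' @param max_evalue keep hits with `evalue <= max_evalue`.
#' @param top_n per-query cap on retained hits; ties broken by subject id
#'   for determinism.
#' @return filtered hits data.frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, top_n = 5L) {
  stopifnot(max_evalue > 0, top_n >= 1)
  hits <- hits[hits$query != hits$subject & hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  o <- order(hits$query, -hits$bitscore, hits$subject)
  hits <- hits[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along) <= top_n
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
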