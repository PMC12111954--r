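#' Build the reference-anchored multi-genome alignment table
#'
#' The central data structure of the analysis: one row per reference gene
#' (in chromosome-then-rank order), one column per (species, homology
#' class). Ortholog cells are filled from the highest-scoring
#' ortholog-class block whose anchors cover the reference gene; the
#' reference's own paleo-duplication (GCT) blocks fill the
#' `ref.paralog_copy*` columns; each other species' GCT-class blocks
#' against the reference fill that species' paralog columns (block-level
#' evidence only). Empty cells are `NA` internally and a dot on disk.
#' Cell conflicts are resolved by block score, then anchor count, then
#' block id; within a column a partner gene id is used at most once
#' (injectivity), again by the same priority.
#'
#' @param reference the reference genome object.
#' @param comparisons named list of classified comparison results, one per
#'   species. Each element is a list with `blocks` (including a `class`
#'   column, see [classify_block()]) and `anchors`, with the reference on
#'   the `gene_a` side. The element named after the reference species must
#'   be its self-comparison (used for the paralog copy columns).
#' @return data.frame of class `"alignment_table"`: column `ref` plus
#'   `<species>.ortholog`, `ref.paralog_copy1`, `ref.paralog_copy2` and
#'   `<species>.paralog_copy1/2` columns.
#' @export
build_table <- function(reference, comparisons) {
  ref_sp <- genome_species(reference)
  others <- setdiff(names(comparisons), ref_sp)
  tab <- data.frame(ref = reference$id, stringsAsFactors = FALSE)

  candidates <- function(cmp, classes) {
    bl <- cmp$blocks[cmp$blocks$class %in% classes, , drop = FALSE]
    if (is.null(bl) || !nrow(bl)) return(NULL)
    an <- cmp$anchors[cmp$anchors$block_id %in% bl$block_id, , drop = FALSE]
    m <- match(an$block_id, bl$block_id)
    data.frame(gene = an$gene_a, partner = an$gene_b,
               partner_chrom = bl$chrom_b[m], block_score = bl$score[m],
               block_anchors = bl$n_anchors[m], block_id = an$block_id)
  }

  pick_best <- function(cand, k = 1L) {
    # per reference gene keep the k top candidates from distinct blocks
    if (is.null(cand) || !nrow(cand)) return(NULL)
    o <- order(cand$gene, -cand$block_score, -cand$block_anchors, cand$block_id)
    cand <- cand[o, , drop = FALSE]
    cand <- cand[!duplicated(cand[, c("gene", "block_id")]), , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(cand)), cand$gene, FUN = seq_along) <= k
    cand[keep, , drop = FALSE]
  }

  enforce_injectivity <- function(cand) {
    if (is.null(cand) || !nrow(cand)) return(cand)
    o <- order(-cand$block_score, -cand$block_anchors, cand$block_id, cand$gene)
    cand <- cand[o, , drop = FALSE]
    dup <- duplicated(cand$partner)
    if (any(dup)) message(sum(dup), " conflicting cell(s) cleared for column injectivity")
    cand[!dup, , drop = FALSE]
  }

  fill_column <- function(cand) {
    out <- rep(NA_character_, nrow(tab))
    if (!is.null(cand) && nrow(cand))
      out[match(cand$gene, tab$ref)] <- cand$partner
    out
  }

  for (sp in others) {
    cand <- pick_best(candidates(comparisons[[sp]], "ortholog"), 1L)
    tab[[paste0(sp, ".ortholog")]] <- fill_column(enforce_injectivity(cand))
  }

  paralog_columns <- function(cmp, self = FALSE) {
    cand <- candidates(cmp, "gct_paralog")
    if (self && !is.null(cand) && nrow(cand)) {
      # self-comparison anchors are stored once per unordered pair; a
      # reference gene can sit on either side
      swapped <- cand
      swapped$gene <- cand$partner; swapped$partner <- cand$gene
      bl <- cmp$blocks
      swapped$partner_chrom <- bl$chrom_a[match(swapped$block_id, bl$block_id)]
      cand <- rbind(cand, swapped)
    }
    cand <- pick_best(cand, 2L)
    if (is.null(cand) || !nrow(cand))
      return(list(copy1 = rep(NA_character_, nrow(tab)),
                  copy2 = rep(NA_character_, nrow(tab))))
    ords <- chrom_ordinals(sort(unique(cand$partner_chrom)))
    cand$partner_ord <- ords[cand$partner_chrom]
    # copy1 = the partner on the lower-ordinal chromosome
    o <- order(cand$gene, cand$partner_ord, -cand$block_score, cand$block_id)
    cand <- cand[o, , drop = FALSE]
    slot <- stats::ave(seq_len(nrow(cand)), cand$gene, FUN = seq_along)
    list(copy1 = fill_column(enforce_injectivity(cand[slot == 1L, , drop = FALSE])),
         copy2 = fill_column(enforce_injectivity(cand[slot == 2L, , drop = FALSE])))
  }

  if (ref_sp %in% names(comparisons)) {
    pc <- paralog_columns(comparisons[[ref_sp]], self = TRUE)
    tab[["ref.paralog_copy1"]] <- pc$copy1
    tab[["ref.paralog_copy2"]] <- pc$copy2
  }
  for (sp in others) {
    pc <- paralog_columns(comparisons[[sp]])
    tab[[paste0(sp, ".paralog_copy1")]] <- pc$copy1
    tab[[paste0(sp, ".paralog_copy2")]] <- pc$copy2
  }
  structure(tab, class = c("alignment_table", "data.frame"),
            ref_species = ref_sp)
}

#' Presence/absence patterns from an alignment table
#'
#' @param table an [build_table()] alignment table.
#' @param class homology class of the columns to scan (default
#'   `"ortholog"`).
#' @return logical matrix, one row per reference gene, one column per
#'   species; `TRUE` where the cell is filled.
#' @export
presence_patterns <- function(table, class = "ortholog") {
  cols <- grep(paste0("\\.", class, "$"), names(table), value = TRUE)
  if (class == "ortholog") cols <- setdiff(cols, "ref.ortholog")
  m <- !is.na(as.matrix(table[, cols, drop = FALSE]))
  colnames(m) <- sub(paste0("\\.", class, ".*$"), "", cols)
  rownames(m) <- table$ref
  m
}

#' Write an alignment table as TSV (dot = absent)
#'
#' @param table alignment table.
#' @param path output file; a commented header line records the column
#'   layout.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  out <- as.data.frame(table)
  out[is.na(out)] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synfrac alignment table: %d rows, columns = %s",
                     nrow(out), paste(names(out), collapse = ",")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment table written by [write_table()]
#'
#' @param path TSV file.
#' @return alignment table (dots decoded to `NA`).
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(fields))) > 1) stop("ragged alignment table: ", path)
  header <- fields[[1]]
  if (length(fields) == 1) {
    tab <- as.data.frame(matrix(character(0), 0, length(header),
                                dimnames = list(NULL, header)))
  } else {
    m <- do.call(rbind, fields[-1])
    colnames(m) <- header
    tab <- as.data.frame(m, stringsAsFactors = FALSE)
  }
  tab[tab == "."] <- NA
  structure(tab, class = c("alignment_table", "data.frame"))
}
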