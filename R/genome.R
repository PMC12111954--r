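#' Construct a genome object from a gene table
#'
#' A genome is a plain `data.frame` of genes carrying the coordinate system
#' everything downstream relies on: base-pair spans for windowed statistics
#' and a 0-based `rank` (gene order along each chromosome, sorted by start)
#' that is the coordinate used for collinearity chaining. Coordinates are
#' 1-based inclusive throughout the package; BED input is converted at the
#' reading boundary.
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand` (defaults to `"+"`).
#' @param species single species name attached to the genome.
#' @param genome_length optional genome length in base pairs; when `NULL`,
#'   the sum of per-chromosome extents (max end per chromosome) is used.
#' @return A `data.frame` of class `"genome"` with columns `id`, `chrom`,
#'   `chrom_ordinal`, `start`, `end`, `strand`, `rank`, sorted by chromosome
#'   then start, with attributes `species` and `genome_length`.
#' @examples
#' g <- as_genome(data.frame(id = c("a", "b"), chrom = "chr1",
#'                           start = c(500, 100), end = c(600, 200)),
#'                species = "demo")
#' g$rank  # 0 for the gene starting at 100, 1 for the one at 500
#' @export
as_genome <- function(genes, species, genome_length = NULL) {
  stopifnot(is.data.frame(genes), all(c("id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) > 0 && anyDuplicated(genes$id))
    stop("duplicate gene IDs: ", paste(unique(genes$id[duplicated(genes$id)])[1:3], collapse = ", "))
  if (nrow(genes) > 0 && any(genes$start > genes$end))
    stop("gene with start > end")
  if (is.null(genes$strand)) genes$strand <- "+"
  genes$chrom <- as.character(genes$chrom)
  genes$id <- as.character(genes$id)
  chroms <- unique(genes$chrom)
  ord <- chrom_ordinals(chroms)
  genes$chrom_ordinal <- ord[genes$chrom]
  o <- order(genes$chrom_ordinal, genes$chrom, genes$start)
  if (is.unsorted(o)) message("gene table for ", species, " was unsorted; sorting by chromosome and start")
  genes <- genes[o, , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chrom, FUN = seq_along) - 1L
  genes <- genes[, c("id", "chrom", "chrom_ordinal", "start", "end", "strand", "rank")]
  rownames(genes) <- NULL
  if (is.null(genome_length)) {
    genome_length <- if (nrow(genes)) sum(tapply(genes$end, genes$chrom, max)) else 0
  }
  structure(genes, species = species, genome_length = as.numeric(genome_length),
            class = c("genome", "data.frame"))
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes on %d chromosomes (%.2f Mb)\n",
              attr(x, "species"), nrow(x), length(unique(x$chrom)),
              attr(x, "genome_length") / 1e6))
  invisible(x)
}

#' Species name of a genome
#' @param genome a genome object.
#' @return character scalar.
#' @export
genome_species <- function(genome) attr(genome, "species")

# Map chromosome labels to ordinal numbers. Numeric suffixes win ("chr3",
# "Os07", "12" all parse); otherwise ordinals fall back to encounter order.
chrom_ordinals <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[^0-9]*", "", labels)))
  if (any(is.na(num)) || anyDuplicated(num[!is.na(num)])) {
    message("non-numeric or ambiguous chromosome labels; using file order as ordinals")
    num <- seq_along(labels)
  }
  stats::setNames(num, labels)
}

#' Read gene positions from GFF3 or BED into a genome
#'
#' GFF3 features of type "gene" (all records when no type column or no gene
#' features are present) are used; BED intervals (0-based half-open) are
#' converted to the package's 1-based inclusive convention by the importer.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param species species name to attach.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param genome_length optional declared genome length in bp.
#' @return a [as_genome()] genome object.
#' @export
read_gene_positions <- function(path, species,
                                format = c("auto", "gff3", "bed"),
                                genome_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed")) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if (!is.null(md$type) && any(md$type == "gene")) gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
    id <- if (!is.null(md$ID)) as.character(md$ID) else as.character(md$Name)
  } else {
    id <- as.character(md$name)
  }
  if (anyNA(id)) stop("records without an ID in ", path)
  genes <- data.frame(id = id,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)))
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  as_genome(genes, species, genome_length)
}

#' Write a genome's gene positions as GFF3
#'
#' Round-trips with [read_gene_positions()] on `(id, chrom, start, end,
#' strand)`.
#'
#' @param genome genome object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$chrom,
    ranges = IRanges::IRanges(start = genome$start, end = genome$end),
    strand = genome$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genome$id
  S4Vectors::mcols(gr)$source <- "synfrac"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
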