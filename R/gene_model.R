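#' Construct a gene model
#'
#' A `GeneModel` is the unit every downstream analysis consumes: one
#' annotated protein-coding gene on one contig, with its exons stored in
#' transcription order. Coordinates are held internally as 0-based,
#' half-open intervals; all file I/O converts to and from each format's own
#' convention (GFF3 and GenBank are 1-based inclusive).
#'
#' @param gene_id Gene identifier, unique within a genome set.
#' @param contig_id Identifier of the contig the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons A `data.frame` with columns `start` and `end` (0-based,
#'   half-open, genomic). Rows may be given in any order; they are sorted
#'   into transcription order (reverse genomic order on the minus strand)
#'   and assigned consecutive ranks from 1.
#' @param role One of `"hop"`, `"fus"` or `"other"` — the gene's role in the
#'   pair analysis.
#' @param species Optional species name carried through reports.
#'
#' @return An object of class `GeneModel`: a list with fields `gene_id`,
#'   `contig_id`, `strand`, `exons` (columns `start`, `end`, `rank`),
#'   `role`, `species`.
#' @examples
#' gene_model("g1", "c1", "+", data.frame(start = 0, end = 30), role = "hop")
#' @export
gene_model <- function(gene_id, contig_id, strand, exons,
                       role = c("other", "hop", "fus"), species = NA_character_) {
  role <- match.arg(role)
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for gene ", gene_id)
  }
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) stop("gene ", gene_id, " has no exons")
  if (any(exons$start < 0) || any(exons$end <= exons$start)) {
    stop("gene ", gene_id, ": exon intervals must satisfy 0 <= start < end")
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("gene ", gene_id, ": overlapping exons within one gene")
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  exons$rank <- seq_len(nrow(exons))
  rownames(exons) <- NULL
  structure(
    list(gene_id = gene_id, contig_id = contig_id, strand = strand,
         exons = exons, role = role, species = species),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s [%s] on %s(%s): %d exon(s), span %d-%d\n",
              x$gene_id, x$role, x$contig_id, x$strand,
              nrow(x$exons), gene_span(x)[1L] + 1L, gene_span(x)[2L]))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param gene A `GeneModel`.
#' @return Integer vector `c(start, end)` in internal 0-based, half-open
#'   coordinates, covering all exons.
#' @export
gene_span <- function(gene) {
  c(min(gene$exons$start), max(gene$exons$end))
}

## fetch one contig sequence as a plain upper-case character string
contig_seq <- function(genome, contig_id) {
  if (!contig_id %in% names(genome)) {
    stop("contig '", contig_id, "' not present in genome")
  }
  as.character(genome[[contig_id]])
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the exon sequences in transcription order; on the minus
#' strand each exon is reverse-complemented first, so the result is always
#' given 5' to 3' in transcript space. All phase and codon logic in the
#' package operates on this materialized CDS, which removes strand special
#' cases downstream.
#'
#' @param gene A `GeneModel`.
#' @param genome A named `DNAStringSet` (as returned by [read_genome()]).
#' @return A character string with the spliced CDS.
#' @export
spliced_cds <- function(gene, genome) {
  seq <- contig_seq(genome, gene$contig_id)
  if (max(gene$exons$end) > nchar(seq)) {
    stop("gene ", gene$gene_id, ": exon outside contig ", gene$contig_id,
         " bounds (contig length ", nchar(seq), ")")
  }
  pieces <- substring(seq, gene$exons$start + 1L, gene$exons$end)
  if (gene$strand == "-") pieces <- vapply(pieces, revcomp, character(1L))
  paste0(pieces, collapse = "")
}

#' Translate a nucleotide string
#'
#' Thin wrapper around [Biostrings::translate()] that tolerates ambiguous
#' bases (translated as `X`) and optionally strips a terminal stop.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param drop_stop Drop one trailing `*` if present (default `TRUE`).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, drop_stop = TRUE) {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  if (drop_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
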