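#' Assign intron phases and split codons
#'
#' The phase of an intron is defined positionally: it is the number of
#' nucleotides by which the splice junction is offset from the nearest
#' upstream codon boundary of the spliced CDS. Phase-0 introns fall between
#' two codons, phase-1 introns split a codon after its first nucleotide,
#' phase-2 introns after its second. The phase is computed here as the
#' cumulative spliced coding length upstream of each junction modulo 3 —
#' annotation "phase" columns are deliberately ignored.
#'
#' @param gene A complete-CDS `GeneModel` (total exon length divisible by 3).
#' @param genome Named `DNAStringSet` with the gene's contig.
#' @return A `data.frame` with one row per intron: `gene_id`, `ordinal`,
#'   `roman` (e.g. `"I_h"`, subscript from the gene role), genomic `start`,
#'   `end` (internal 0-based half-open), `length`, `phase`, `donor`,
#'   `acceptor` (2-mers read in transcript orientation) and `split_codon`
#'   (`"X|YZ"` / `"XY|Z"` for phases 1-2, `""` for phase 0). Zero rows for a
#'   single-exon gene.
#' @examples
#' \dontrun{
#' introns <- assign_intron_phases(gene, genome)
#' }
#' @export
assign_intron_phases <- function(gene, genome) {
  seq <- contig_seq(genome, gene$contig_id)
  cds <- spliced_cds(gene, genome)
  if (nchar(cds) %% 3L != 0L) {
    stop("incomplete CDS: gene ", gene$gene_id, " spliced length ",
         nchar(cds), " not divisible by 3")
  }
  n_ex <- nrow(gene$exons)
  if (n_ex < 2L) return(empty_intron_table())
  ex <- gene$exons # transcription order
  exon_len <- ex$end - ex$start
  cum <- cumsum(exon_len)
  rows <- vector("list", n_ex - 1L)
  for (k in seq_len(n_ex - 1L)) {
    if (gene$strand == "+") {
      istart <- ex$end[k]
      iend <- ex$start[k + 1L]
      if (iend <= istart) stop("zero-length intron in gene ", gene$gene_id,
                               " after exon rank ", k)
      iseq <- substr(seq, istart + 1L, iend)
    } else {
      istart <- ex$end[k + 1L]
      iend <- ex$start[k]
      if (iend <= istart) stop("zero-length intron in gene ", gene$gene_id,
                               " after exon rank ", k)
      iseq <- revcomp(substr(seq, istart + 1L, iend))
    }
    phase <- cum[k] %% 3L
    rows[[k]] <- data.frame(
      gene_id = gene$gene_id,
      ordinal = k,
      roman = roman_ordinal(k, gene$role),
      start = istart, end = iend, length = iend - istart,
      phase = phase,
      cum_upstream = cum[k],
      donor = substr(iseq, 1L, 2L),
      acceptor = substr(iseq, nchar(iseq) - 1L, nchar(iseq)),
      split_codon = if (phase == 0L) "" else
        split_codon_at(cds, cum[k], phase),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

empty_intron_table <- function() {
  data.frame(gene_id = character(), ordinal = integer(), roman = character(),
             start = integer(), end = integer(), length = integer(),
             phase = integer(), cum_upstream = integer(), donor = character(),
             acceptor = character(), split_codon = character(),
             stringsAsFactors = FALSE)
}

## "I_h", "II_f", ... ordinal in transcription order, subscript from role
roman_ordinal <- function(ordinal, role) {
  sub <- switch(role, hop = "h", fus = "f", "g")
  paste0(as.character(utils::as.roman(ordinal)), "_", sub)
}

split_codon_at <- function(cds, cum_upstream, phase) {
  codon_start <- cum_upstream - phase + 1L # 1-based start of split codon
  codon <- substr(cds, codon_start, codon_start + 2L)
  paste0(substr(codon, 1L, phase), "|", substr(codon, phase + 1L, 3L))
}

#' Report the codon interrupted by a phase-1 or phase-2 intron
#'
#' @param intron One row of the table from [assign_intron_phases()] (or any
#'   list with `phase` and `split_codon`).
#' @param spliced_cds Optional spliced CDS; when given together with a `cum`
#'   attribute-free intron row the stored `split_codon` is returned, the CDS
#'   is only used for validation.
#' @param rna Render RNA-style (`T` printed as `U`), mirroring the
#'   conventional G|AU notation; default `FALSE` (DNA alphabet).
#' @return The interrupted codon with `|` at the splice position, e.g.
#'   `"G|AT"` for a phase-1 intron splitting an Asp codon.
#' @export
split_codon <- function(intron, spliced_cds = NULL, rna = FALSE) {
  if (intron$phase == 0L) {
    stop("split_codon() called on a phase-0 intron (ordinal ",
         intron$ordinal, "); phase-0 introns fall between codons")
  }
  out <- intron$split_codon
  if (rna) out <- chartr("T", "U", out)
  out
}

#' Classify splice-site dinucleotides
#'
#' Canonical spliceosomal introns start with `GT` and end with `AG`; a
#' minor class uses a `GC` donor. Anything else is reported as
#' non-canonical — a finding about the annotation, never an error.
#'
#' @param introns Intron table from [assign_intron_phases()].
#' @return The table with an added `splice_verdict` column taking values
#'   `canonical`, `gc_donor` or `noncanonical`.
#' @export
validate_splice_sites <- function(introns) {
  verdict <- rep("noncanonical", nrow(introns))
  verdict[introns$donor == "GT" & introns$acceptor == "AG"] <- "canonical"
  verdict[introns$donor == "GC" & introns$acceptor == "AG"] <- "gc_donor"
  introns$splice_verdict <- verdict
  introns
}

#' Enumerate recombinable (symmetric) exon modules
#'
#' A recombinable module is a run of exons flanked by two boundaries of the
#' same intron phase — classically phase-0, where excision or duplication
#' of the module leaves the reading frame intact. Every contiguous exon run
#' whose two flanking phases agree is enumerated (so both minimal and
#' maximal symmetric runs appear). Under `terminal_phase_policy = "phase0"`
#' the CDS start and stop behave as phase-0 boundaries, so 5'-terminal
#' modules bounded by the start codon and a phase-0 intron count as
#' recombinable; under `"excluded"` only internal intron boundaries are
#' considered.
#'
#' @param introns Intron table from [assign_intron_phases()], or a bare
#'   integer vector of phases.
#' @param n_exons Number of exons; must equal number of introns + 1.
#' @param terminal_phase_policy `"phase0"` (default) or `"excluded"`.
#' @return A `data.frame` with columns `first_exon_rank`, `last_exon_rank`,
#'   `flanking_phase`, `symmetric` (always `TRUE`), sorted by
#'   (`first_exon_rank`, `last_exon_rank`).
#' @export
find_recombinable_modules <- function(introns, n_exons,
                                      terminal_phase_policy = c("phase0", "excluded")) {
  terminal_phase_policy <- match.arg(terminal_phase_policy)
  phases <- if (is.data.frame(introns)) introns$phase else as.integer(introns)
  if (length(phases) + 1L != n_exons) {
    stop("inconsistent counts: ", length(phases), " introns with ",
         n_exons, " exons")
  }
  ## boundary b[i] sits upstream of exon i+1; b[0] = CDS start, b[n] = stop
  b_phase <- c(0L, phases, 0L)
  b_internal <- c(FALSE, rep(TRUE, length(phases)), FALSE)
  keep <- if (terminal_phase_policy == "phase0") rep(TRUE, length(b_phase)) else b_internal
  idx <- which(keep)
  rows <- list()
  for (a in idx) {
    for (b in idx[idx > a]) {
      if (b_phase[a] == b_phase[b]) {
        rows[[length(rows) + 1L]] <- data.frame(
          first_exon_rank = a, last_exon_rank = b - 1L,
          flanking_phase = b_phase[a], symmetric = TRUE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(first_exon_rank = integer(), last_exon_rank = integer(),
                      flanking_phase = integer(), symmetric = logical()))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$first_exon_rank, out$last_exon_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the transit-peptide intron of a chl-fus gene
#'
#' In all chl-fus genes examined the first intron is phase-1 and separates
#' the exon encoding the chloroplast transit peptide from the mature
#' protein. This helper returns the ordinal of the first intron when its
#' phase is 1, and `NA` (with a diagnostic attribute) otherwise.
#'
#' @param introns Intron table from [assign_intron_phases()] for a
#'   fus-tagged gene.
#' @return Ordinal `1L` when the first intron is phase-1, else `NA_integer_`
#'   with attribute `"diagnostic"` explaining why.
#' @export
find_transit_peptide_intron <- function(introns) {
  if (nrow(introns) == 0L) {
    return(structure(NA_integer_, diagnostic = "gene has no introns"))
  }
  if (introns$phase[1L] == 1L) return(1L)
  structure(NA_integer_,
            diagnostic = paste0("first intron is phase-", introns$phase[1L],
                                ", not phase-1"))
}

#' Propose a hidden in-frame intron in an over-long predicted protein
#'
#' When a predicted protein exceeds its cross-species reference length, an
#' intron may have gone unannotated because it is in frame with a short 5'
#' exon (no stop codons, length divisible by 3), so the translation simply
#' reads through it. This scans the CDS for an interval of exactly the
#' excess length, bounded by a spliceosomal donor (`GT` or `GC`) and
#' acceptor (`AG`), whose removal restores a stop-free protein of the
#' reference length, and returns the 5'-most candidate.
#'
#' @param gene A `GeneModel` whose translation exceeds the reference.
#' @param genome Named `DNAStringSet`.
#' @param reference_protein_length Reference protein length in amino acids
#'   (excluding the stop).
#' @return A list `list(start, end, length)` with transcript-space 0-based
#'   half-open coordinates of the proposed intron (genomic for a
#'   single-exon plus-strand gene), plus an attribute `"alternatives"`
#'   holding starts of any further satisfying intervals; `NULL` when the
#'   protein already matches the reference or no interval qualifies.
#' @export
propose_hidden_intron <- function(gene, genome, reference_protein_length) {
  cds <- spliced_cds(gene, genome)
  prot <- translate_cds(cds)
  excess_aa <- nchar(prot) - reference_protein_length
  if (excess_aa < 10L) return(NULL)
  excess_nt <- 3L * excess_aa
  n <- nchar(cds)
  hits <- integer()
  for (p in 0L:(n - excess_nt)) {
    donor <- substr(cds, p + 1L, p + 2L)
    if (donor != "GT" && donor != "GC") next
    if (substr(cds, p + excess_nt - 1L, p + excess_nt) != "AG") next
    reduced <- paste0(substr(cds, 1L, p), substr(cds, p + excess_nt + 1L, n))
    red_prot <- suppressWarnings(translate_cds(reduced))
    if (nchar(red_prot) == reference_protein_length &&
        !grepl("\\*", red_prot)) {
      hits <- c(hits, p)
    }
  }
  if (!length(hits)) return(NULL)
  structure(list(start = hits[1L], end = hits[1L] + excess_nt,
                 length = excess_nt),
            alternatives = hits[-1L])
}
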