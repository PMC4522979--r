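#' Load a structure-class decision table
#'
#' Exon-intron topologies are classed by an ordered rule table: each rule
#' names a label, the gene role it applies to, an intron count (a scalar or
#' an inclusive `[min, max]` range) and an optional exact phase signature.
#' Rules are evaluated in order and the first match wins; unmatched genes
#' are labelled `"unclassified"`. The shipped default encodes the named
#' hop classes h1-h6 and chl-fus classes f1-f5 together with the combined
#' gene-arrangement letters A-J; the table lives in an editable JSON file
#' so either reading of ambiguous class definitions can be pinned by the
#' user.
#'
#' @param path Path to a JSON class table; default is the table shipped in
#'   `inst/extdata/structure_classes.json`.
#' @return A list with elements `hop`, `fus` (lists of rules) and
#'   `arrangements` (decision table for letters A-J).
#' @export
load_class_table <- function(path = system.file("extdata", "structure_classes.json",
                                                package = "hopfus")) {
  tab <- jsonlite::read_json(path)
  for (role in c("hop", "fus")) {
    labels <- vapply(tab[[role]], function(r) r$label, character(1L))
    if (anyDuplicated(labels)) stop("duplicate labels in class table: ", role)
  }
  tab
}

#' Classify the exon-intron structure of one gene
#'
#' @param introns Intron table from [assign_intron_phases()] or a bare
#'   integer vector of phases.
#' @param role `"hop"` or `"fus"`.
#' @param table Class table from [load_class_table()].
#' @return A single label, e.g. `"h5"` or `"f4"`; `"unclassified"` when no
#'   rule matches.
#' @export
classify_gene_structure <- function(introns, role = c("hop", "fus"),
                                    table = load_class_table()) {
  role <- match.arg(role)
  phases <- if (is.data.frame(introns)) introns$phase else as.integer(introns)
  n <- length(phases)
  for (rule in table[[role]]) {
    cnt <- unlist(rule$intron_count)
    count_ok <- if (length(cnt) == 2L) n >= cnt[1L] && n <= cnt[2L] else n == cnt
    if (!count_ok) next
    if (!is.null(rule$phase_signature)) {
      sig <- as.integer(unlist(rule$phase_signature))
      if (length(sig) != n || any(sig != phases)) next
    }
    return(rule$label)
  }
  "unclassified"
}

#' Assign the combined gene-arrangement letter of a species
#'
#' The joint classification (letters A-J) combines the pair's
#' microcolinearity category (I-III) with the structure classes of the two
#' genes; the decision table is part of the class-table config.
#'
#' @param pair A `GenePairArrangement` row (or anything with a
#'   `colinearity_category` field), or a bare category string.
#' @param hop_label,fus_label Structure labels from
#'   [classify_gene_structure()].
#' @param table Class table from [load_class_table()].
#' @return A single letter `"A"`..`"J"`, or `"unassigned"` (with a
#'   `"diagnostic"` attribute) for combinations outside the table.
#' @export
assign_arrangement_category <- function(pair, hop_label, fus_label,
                                        table = load_class_table()) {
  category <- if (is.character(pair)) pair else
    as.character(pair$colinearity_category[1L])
  for (rule in table$arrangements) {
    if (rule$category == category && rule$hop == hop_label &&
        rule$fus == fus_label) {
      return(rule$letter)
    }
  }
  structure("unassigned",
            diagnostic = sprintf("no rule for (%s, %s, %s)",
                                 category, hop_label, fus_label))
}

#' Map intron positions onto a protein multiple alignment
#'
#' To compare intron positions across species, each intron is anchored to
#' an alignment column of the species' row: phase-1 and phase-2 introns to
#' the column of the residue whose codon they split, phase-0 introns to the
#' column of the residue immediately downstream of the junction (one fixed
#' convention, applied everywhere). Gap columns are skipped when counting
#' residues.
#'
#' @param introns Intron table from [assign_intron_phases()].
#' @param protein Ungapped protein sequence of the gene (translation of the
#'   spliced CDS, stop removed).
#' @param msa Named character vector or `AAStringSet` of aligned rows.
#' @param species Name of this gene's row in `msa`.
#' @return A `data.frame` with columns `species`, `intron_ordinal`, `phase`,
#'   `alignment_column`.
#' @export
map_introns_to_alignment <- function(introns, protein, msa, species) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (!species %in% names(msa)) stop("no MSA row named ", species)
  row <- msa[[species]]
  ungapped <- gsub("-", "", row)
  if (ungapped != protein) {
    diff <- which(strsplit(ungapped, "")[[1L]] != strsplit(protein, "")[[1L]])
    at <- if (length(diff)) diff[1L] else min(nchar(ungapped), nchar(protein)) + 1L
    stop("MSA row for ", species, " does not match the translated CDS ",
         "(first difference at residue ", at, ")")
  }
  chars <- strsplit(row, "")[[1L]]
  res_col <- which(chars != "-") # alignment column of each residue
  if (nrow(introns) == 0L) {
    return(data.frame(species = character(), intron_ordinal = integer(),
                      phase = integer(), alignment_column = integer()))
  }
  ## phase-0: residue downstream of the junction; phase-1/2: residue whose
  ## codon is split. Both reduce to cum %/% 3 + 1.
  cum <- introns_cumulative_nt(introns)
  residue <- cum %/% 3L + 1L
  if (any(residue > length(res_col))) {
    stop("intron maps beyond the end of the protein for ", species)
  }
  data.frame(species = species, intron_ordinal = introns$ordinal,
             phase = introns$phase, alignment_column = res_col[residue],
             stringsAsFactors = FALSE)
}

## recover cumulative upstream coding length per intron from phases is not
## possible; use the stored split position implicitly: the intron table
## carries genomic coordinates, so cumulative length is reconstructed from
## exon lengths embedded in consecutive intron bounds. For robustness the
## table from assign_intron_phases() stores enough: phase + ordinal are not
## sufficient, so we re-derive from the strand-ordered gaps.
introns_cumulative_nt <- function(introns) {
  if (!is.null(introns$cum_upstream)) return(introns$cum_upstream)
  stop("intron table lacks the cum_upstream column; ",
       "use assign_intron_phases() output")
}

#' Pairwise shared-intron-position matrix
#'
#' Two introns in two species are "shared" when they map to alignment
#' columns within `column_tolerance` of each other and have equal phase.
#' Matching is one-to-one (greedy in column order).
#'
#' @param positions `data.frame` from [map_introns_to_alignment()] rows
#'   bound over species (all on one MSA).
#' @param column_tolerance Maximum column distance for a match (default 0:
#'   strict identity of mapped columns).
#' @return A symmetric species-by-species integer matrix of shared intron
#'   counts; the diagonal holds each species' own intron count.
#' @export
shared_position_matrix <- function(positions, column_tolerance = 0L) {
  sp <- unique(positions$species)
  m <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) {
    for (j in seq_len(i)) {
      a <- positions[positions$species == sp[i], , drop = FALSE]
      b <- positions[positions$species == sp[j], , drop = FALSE]
      m[i, j] <- m[j, i] <- count_shared_introns(a, b, column_tolerance)
    }
  }
  m
}

count_shared_introns <- function(a, b, tol) {
  a <- a[order(a$alignment_column), , drop = FALSE]
  b <- b[order(b$alignment_column), , drop = FALSE]
  used <- rep(FALSE, nrow(b))
  n <- 0L
  for (i in seq_len(nrow(a))) {
    cand <- which(!used & b$phase == a$phase[i] &
                    abs(b$alignment_column - a$alignment_column[i]) <= tol)
    if (length(cand)) {
      used[cand[1L]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

#' Count class membership across species
#'
#' @param labels Named character vector mapping species to structure label
#'   (one role at a time).
#' @return A `data.frame` with columns `label` and `n`, sorted by
#'   decreasing `n`.
#' @export
count_class_membership <- function(labels) {
  if (length(labels) == 0L) return(data.frame(label = character(), n = integer()))
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(label = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
}

#' Count maximal tandem repetitions of a protein motif
#'
#' @param protein Amino-acid string.
#' @param motif Amino-acid motif, length >= 4.
#' @return The maximal number of consecutive, non-overlapping exact copies
#'   of `motif` found anywhere in `protein` (0 when absent).
#' @examples
#' count_tandem_motif(strrep("VPEVEKKLEPEPEP", 3), "VPEVEKKLEPEPEP")
#' @export
count_tandem_motif <- function(protein, motif) {
  if (nchar(motif) < 4L) stop("motif must be at least 4 residues")
  pat <- paste0("(?:", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", motif), ")+")
  m <- gregexpr(pat, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(0L)
  max(attr(m, "match.length")) %/% nchar(motif)
}
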