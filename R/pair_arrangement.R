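#' Classify the microsynteny and microcolinearity of a hop/fus gene pair
#'
#' Microsynteny means the two genes reside on the same contig; micro-
#' colinearity refines this by orientation. Three categories are used:
#' \describe{
#'   \item{I}{genes on different contigs (not syntenic, not colinear);}
#'   \item{II}{syntenic but rearranged — in the classical case chl-fus
#'     sits just upstream of hop and both are transcribed in the same
#'     direction (a local inversion); any other syntenic, non-convergent
#'     layout (e.g. divergent transcription) is also classed II;}
#'   \item{III}{colinear in convergent transcription, 3' ends facing —
#'     the ancestral-looking and most frequent arrangement.}
#' }
#' Orientation is determined purely from strands and relative order of the
#' annotated spans. The result is pair-intrinsic: argument order does not
#' matter (roles are read from the models' `role` tags).
#'
#' @param gene_a,gene_b The two `GeneModel`s of one species, one tagged
#'   `hop` and one tagged `fus`.
#' @param features Optional `data.frame` of annotated non-gene features
#'   (columns `contig_id`, `start`, `end`, `id`; internal coordinates);
#'   features falling inside the intergenic region are listed in
#'   `inserted_features` but never change the category.
#' @param species Species label carried into the result (defaults to the
#'   models' `species` field).
#' @return A one-row `data.frame` of class `GenePairArrangement` with
#'   columns `species`, `syntenic`, `orientation` (`convergent`,
#'   `divergent`, `tandem_same_strand`, `non_syntenic`),
#'   `colinearity_category` (`I`/`II`/`III`), `igr_start`, `igr_end`,
#'   `igr_length`, `overlap_bp`, `inserted_features` (comma-separated IDs),
#'   `hop_id`, `fus_id`, `hop_contig`, `fus_contig`.
#' @export
classify_pair <- function(gene_a, gene_b, features = NULL, species = NULL) {
  roles <- c(gene_a$role, gene_b$role)
  if (!setequal(roles, c("hop", "fus"))) {
    stop("classify_pair needs one hop-tagged and one fus-tagged gene, got: ",
         paste(roles, collapse = ", "))
  }
  hop <- if (gene_a$role == "hop") gene_a else gene_b
  fus <- if (gene_a$role == "fus") gene_a else gene_b
  if (is.null(species)) {
    species <- if (!is.na(hop$species)) hop$species else hop$gene_id
  }
  syntenic <- identical(hop$contig_id, fus$contig_id)
  if (!syntenic) {
    return(pair_row(species, hop, fus, syntenic = FALSE,
                    orientation = "non_syntenic", category = "I",
                    igr_start = NA_integer_, igr_end = NA_integer_,
                    igr_length = NA_integer_, overlap_bp = 0L,
                    inserted = character()))
  }
  hs <- gene_span(hop); fs <- gene_span(fus)
  ov <- min(hs[2L], fs[2L]) - max(hs[1L], fs[1L])
  if (ov > 0.5 * min(hs[2L] - hs[1L], fs[2L] - fs[1L])) {
    stop("annotation conflict: hop and fus spans overlap over >50% of a gene",
         " in species ", species)
  }
  left <- if (hs[1L] <= fs[1L]) hop else fus
  right <- if (hs[1L] <= fs[1L]) fus else hop
  orientation <- if (left$strand == right$strand) {
    "tandem_same_strand"
  } else if (left$strand == "+") "convergent" else "divergent"
  category <- if (orientation == "convergent") "III" else "II"
  igr_start <- gene_span(left)[2L]
  igr_end <- gene_span(right)[1L]
  overlap <- max(0L, igr_start - igr_end)
  igr_len <- max(0L, igr_end - igr_start)
  if (overlap > 0L) { igr_start <- igr_end <- NA_integer_ }
  inserted <- character()
  if (!is.null(features) && nrow(features) > 0L && igr_len > 0L) {
    inside <- features$contig_id == hop$contig_id &
      features$start >= igr_start & features$end <= igr_end
    inserted <- as.character(features$id[inside])
  }
  pair_row(species, hop, fus, syntenic = TRUE, orientation = orientation,
           category = category, igr_start = igr_start, igr_end = igr_end,
           igr_length = igr_len, overlap_bp = overlap, inserted = inserted)
}

pair_row <- function(species, hop, fus, syntenic, orientation, category,
                     igr_start, igr_end, igr_length, overlap_bp, inserted) {
  out <- data.frame(
    species = species, syntenic = syntenic, orientation = orientation,
    colinearity_category = category,
    igr_start = igr_start, igr_end = igr_end, igr_length = igr_length,
    overlap_bp = overlap_bp,
    inserted_features = paste(inserted, collapse = ","),
    hop_id = hop$gene_id, fus_id = fus$gene_id,
    hop_contig = hop$contig_id, fus_contig = fus$contig_id,
    stringsAsFactors = FALSE)
  class(out) <- c("GenePairArrangement", class(out))
  out
}

#' Extract the intergenic region of a syntenic pair
#'
#' Returns the sequence strictly between the two genes' outermost annotated
#' exon boundaries, i.e. between annotated CDS/exon extremes rather than
#' transcript 3' ends. When the genes abut or overlap the IGR is the empty
#' string and `overlap_bp` in the arrangement records the extent.
#'
#' @param pair A `GenePairArrangement` row from [classify_pair()].
#' @param genome Named `DNAStringSet`.
#' @return Nucleotide string (possibly `""`).
#' @export
extract_igr <- function(pair, genome) {
  if (!pair$syntenic[1L]) stop("non-syntenic pair has no intergenic region")
  if (is.na(pair$igr_start[1L]) || pair$igr_length[1L] == 0L) return("")
  seq <- contig_seq(genome, pair$hop_contig[1L])
  substr(seq, pair$igr_start[1L] + 1L, pair$igr_end[1L])
}

#' Summarize gene-pair arrangements across species
#'
#' @param pairs A `data.frame` of arrangements (rbind of [classify_pair()]
#'   rows), one per species.
#' @return A list with `n_species`, `n_syntenic`, `pct_syntenic`,
#'   `category_counts` (named integer vector over I/II/III),
#'   `orientation_counts`, and `pct_category` (percentages rounded to the
#'   nearest integer).
#' @export
summarize_arrangements <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(list(n_species = 0L, n_syntenic = 0L, pct_syntenic = 0L,
                category_counts = c(I = 0L, II = 0L, III = 0L),
                orientation_counts = integer(),
                pct_category = c(I = 0L, II = 0L, III = 0L)))
  }
  if (anyDuplicated(pairs$species)) {
    stop("duplicate species in arrangement table: ",
         paste(unique(pairs$species[duplicated(pairs$species)]), collapse = ", "))
  }
  n <- nrow(pairs)
  n_syn <- sum(pairs$syntenic)
  cats <- factor(pairs$colinearity_category, levels = c("I", "II", "III"))
  cat_counts <- table(cats)
  list(
    n_species = n,
    n_syntenic = n_syn,
    pct_syntenic = as.integer(round(100 * n_syn / n)),
    category_counts = stats::setNames(as.integer(cat_counts), names(cat_counts)),
    orientation_counts = table(pairs$orientation),
    pct_category = stats::setNames(as.integer(round(100 * as.integer(cat_counts) / n)),
                                   names(cat_counts)))
}
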