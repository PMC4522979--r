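#' Read annotated non-gene features from a GFF3 file
#'
#' Returns features other than gene/mRNA/exon/CDS (e.g. `repeat_region`,
#' `pseudogene` rows marking intergenic inserts) in internal coordinates.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return `data.frame` with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `type`, `id`.
#' @export
read_annotation_features <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[!df$type %in% c("gene", "mRNA", "exon", "CDS"), , drop = FALSE]
  data.frame(contig_id = as.character(df$seqnames), start = df$start - 1L,
             end = df$end, type = as.character(df$type),
             id = if ("ID" %in% names(df)) as.character(df$ID)
                  else rep(NA_character_, nrow(df)),
             stringsAsFactors = FALSE)
}

#' Run the full gene-pair analysis on a fixture directory
#'
#' Reads `genome.fa` and `genes.gff3` from `dir` (the layout written by
#' [generate_fixture()]), then per species: classifies the pair
#' arrangement, assigns intron phases to both genes, classes the
#' exon-intron structures, assigns the combined arrangement letter and
#' locates the transit-peptide intron of the chl-fus gene. Everything is
#' recomputed from the sequence and annotation files — never from any
#' manifest.
#'
#' @param dir Fixture directory, or a list with `genome` and `gff3` paths.
#' @param class_table Class table from [load_class_table()].
#' @return A list with `pairs` (arrangement `data.frame`, one row per
#'   species), `classes` (`data.frame`: species, labels, letter, intron
#'   counts, transit intron ordinal), `introns` (combined intron table
#'   with a `role` column) and `genome`/`genes` for reuse.
#' @export
analyze_fixture <- function(dir, class_table = load_class_table()) {
  paths <- if (is.list(dir)) dir else
    list(genome = file.path(dir, "genome.fa"),
         gff3 = file.path(dir, "genes.gff3"))
  genome <- read_genome(paths$genome)
  genes <- read_gene_models(paths$gff3, genome)
  features <- read_annotation_features(paths$gff3)
  species <- vapply(genes, function(g)
    if (!is.na(g$species)) g$species else sub("_(hop|fus)$", "", g$gene_id),
    character(1L))
  pairs <- NULL
  classes <- NULL
  introns <- NULL
  for (sp in unique(species)) {
    own <- genes[species == sp]
    roles <- vapply(own, function(g) g$role, character(1L))
    if (!all(c("hop", "fus") %in% roles)) {
      warning("species ", sp, " lacks a complete hop/fus pair; skipped")
      next
    }
    hop <- own[[which(roles == "hop")[1L]]]
    fus <- own[[which(roles == "fus")[1L]]]
    pair <- classify_pair(hop, fus, features = features, species = sp)
    ih <- assign_intron_phases(hop, genome)
    iff <- assign_intron_phases(fus, genome)
    hop_label <- classify_gene_structure(ih, "hop", class_table)
    fus_label <- classify_gene_structure(iff, "fus", class_table)
    letter <- assign_arrangement_category(pair, hop_label, fus_label,
                                          class_table)
    transit <- find_transit_peptide_intron(iff)
    pairs <- rbind(pairs, pair)
    classes <- rbind(classes, data.frame(
      species = sp, hop_label = hop_label, fus_label = fus_label,
      arrangement_letter = as.character(letter),
      hop_introns = nrow(ih), fus_introns = nrow(iff),
      hop_phases = paste(ih$phase, collapse = ","),
      fus_phases = paste(iff$phase, collapse = ","),
      transit_intron_ordinal = as.integer(transit),
      stringsAsFactors = FALSE))
    if (nrow(ih)) introns <- rbind(introns, cbind(ih, role = "hop",
                                                  species = sp))
    if (nrow(iff)) introns <- rbind(introns, cbind(iff, role = "fus",
                                                   species = sp))
  }
  rownames(pairs) <- rownames(classes) <- NULL
  list(pairs = pairs, classes = classes, introns = introns,
       genome = genome, genes = genes)
}

#' Summarize a fixture analysis
#'
#' @param analysis Result of [analyze_fixture()].
#' @return A list with the headline numbers of the comparative analysis:
#'   species and synteny counts (with percentages rounded to the nearest
#'   integer), microcolinearity category counts, structure class counts
#'   for both genes, arrangement-letter counts and the number of chl-fus
#'   genes whose first intron is the phase-1 transit-peptide intron.
#' @export
summarize_analysis <- function(analysis) {
  arr <- summarize_arrangements(analysis$pairs)
  cls <- analysis$classes
  hop_counts <- count_class_membership(
    stats::setNames(cls$hop_label, cls$species))
  fus_counts <- count_class_membership(
    stats::setNames(cls$fus_label, cls$species))
  letters <- count_class_membership(
    stats::setNames(cls$arrangement_letter, cls$species))
  c(arr, list(
    hop_class_counts = hop_counts,
    fus_class_counts = fus_counts,
    arrangement_letter_counts = letters,
    n_fus_with_transit_intron = sum(!is.na(cls$transit_intron_ordinal) &
                                      cls$transit_intron_ordinal == 1L)))
}

#' Generate the builtin fixture and summarize it in one call
#'
#' @param dir Working directory for the generated files.
#' @param seed Generator seed.
#' @return The summary list of [summarize_analysis()].
#' @export
summarize_fixture <- function(dir = tempfile("hopfus_fixture"), seed = 1L) {
  generate_fixture(dir, builtin_fixture_table(),
                   generator_config(seed = seed))
  summarize_analysis(analyze_fixture(dir))
}
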