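## Synthetic genome fixtures: deterministic generation of hop/chl-fus gene
## pairs with prescribed intron counts, phases, arrangements and intergenic
## content, plus a ground-truth manifest for parameter-recovery tests.

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  setdiff(all64, STOP_CODONS)
}

## one deterministic codon per amino acid, for reverse-translating motifs
AA_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Parse a comma-joined phase string
#'
#' Fixture tables store intron phase vectors as compact comma-joined
#' strings (e.g. `"0,1,0,2,0,0"`); this expands one to an integer vector.
#'
#' @param x A phase string; `""` or `NA` give `integer(0)`.
#' @return Integer vector of phases.
#' @export
phases_vec <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(integer())
  as.integer(strsplit(x, ",")[[1L]])
}

#' Generator configuration
#'
#' Bundles the tunable parameters of the synthetic-genome generator. The
#' defaults encode the study conditions the fixtures emulate: realistic
#' protein sizes for the two genes (Hop ~545 aa, cEF-G precursor ~775 aa
#' including a 50-aa transit peptide), plant-typical intron lengths and a
#' canonical GT..AG splice dialect.
#'
#' @param seed Integer seed; identical (table, seed) pairs produce
#'   byte-identical fixture files.
#' @param intron_length_range Intron lengths are drawn uniformly from this
#'   range (bp).
#' @param igr_length_range Intergenic-region lengths for the random-pair
#'   generator (the builtin table fixes its own lengths).
#' @param splice_dialect `"gt_ag_only"` (default) or `"allow_gc_donor"`
#'   (each intron has a 15% chance of a GC donor).
#' @param hop_aa,fus_aa Protein lengths in amino acids (stop excluded).
#' @param transit_aa Length of the chl-fus transit-peptide exon in codons;
#'   the first fus intron always interrupts the codon after it (phase 1).
#' @param flank Plain spacer sequence placed before and after genes (bp).
#' @return A list of class `hopfus_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             intron_length_range = c(80L, 400L),
                             igr_length_range = c(800L, 3000L),
                             splice_dialect = c("gt_ag_only", "allow_gc_donor"),
                             hop_aa = 545L, fus_aa = 775L, transit_aa = 50L,
                             flank = 200L) {
  splice_dialect <- match.arg(splice_dialect)
  stopifnot(all(intron_length_range > 0L), all(igr_length_range > 0L))
  structure(list(seed = as.integer(seed),
                 intron_length_range = as.integer(intron_length_range),
                 igr_length_range = as.integer(igr_length_range),
                 splice_dialect = splice_dialect,
                 hop_aa = as.integer(hop_aa), fus_aa = as.integer(fus_aa),
                 transit_aa = as.integer(transit_aa),
                 flank = as.integer(flank)),
            class = "hopfus_generator_config")
}

#' The builtin 53-species fixture table
#'
#' One row per species, transcribing the published per-species intron
#' counts and the per-family microsynteny statements into an explicit
#' specification the generator can realize: intron phase vectors for both
#' genes, gene-pair arrangement, intergenic-region length and planted
#' intergenic inserts. Every chl-fus phase vector starts with 1 (the
#' transit-peptide intron). The three non-syntenic Fabaceae are fixed
#' deterministically as Cajanus, Cicer and Lupinus; intergenic lengths
#' other than the two documented extremes (188 bp and 38523 bp) default to
#' 1500 bp, raised above 10 kb for the four species carrying decayed
#' retroelement-like insertions.
#'
#' @return A 53-row `data.frame`; see the package vignette for the column
#'   semantics.
#' @export
builtin_fixture_table <- function() {
  h5 <- "0,1,0,2,0,0" # dominant angiosperm hop form
  f4 <- "1,0,0"       # dominant angiosperm chl-fus form
  row <- function(species, family, clade, hop_phases, fus_phases,
                  orientation = "convergent", igr_length = 1500L,
                  igr_inserts = "", hop_c1 = NA_integer_, motif_copies = 1L) {
    syntenic <- orientation != "non_syntenic"
    data.frame(
      species = species, family = family, clade = clade,
      hop_introns = length(phases_vec(hop_phases)),
      fus_introns = length(phases_vec(fus_phases)),
      hop_phases = hop_phases, fus_phases = fus_phases,
      syntenic = syntenic, orientation = orientation,
      colinearity_category = if (!syntenic) "I" else
        if (orientation == "convergent") "III" else "II",
      igr_length = if (syntenic) igr_length else NA_integer_,
      igr_inserts = igr_inserts, hop_c1 = hop_c1,
      motif_copies = motif_copies, stringsAsFactors = FALSE)
  }
  crein_hop <- "0,0,0,1,0,0,0,2,0,0,2,0" # 9 of 12 phase-0
  crein_fus <- "1,0,0,0,0,0,0,0,0"
  land8 <- "0,0,1,0,0,2,0,0"
  tab <- rbind(
    row("Micromonas_sp_RCC299", "Mamiellaceae", "chlorophyta",
        "0", "1", "non_syntenic", hop_c1 = 18L),
    row("Ostreococcus_lucimarinus", "Mamiellaceae", "chlorophyta",
        "", "1", "non_syntenic"),
    row("Ostreococcus_tauri", "Mamiellaceae", "chlorophyta",
        "", "1", "non_syntenic"),
    row("Chlamydomonas_reinhardtii", "Chlamydomonadaceae", "chlorophyta",
        crein_hop, crein_fus, "non_syntenic"),
    row("Physcomitrella_patens", "Funariaceae", "gymnosperm",
        land8, "1,0,0,0,0,0", "non_syntenic"),
    row("Picea_abies", "Pinaceae", "gymnosperm",
        land8, f4, "non_syntenic"),
    row("Ensete_ventricosum", "Musaceae", "monocot", h5, f4, "non_syntenic"),
    row("Brachypodium_distachyon", "Poaceae", "monocot", h5, f4),
    row("Oryza_glaberrima", "Poaceae", "monocot", h5, f4,
        igr_inserts = "tir"),
    row("Oryza_sativa", "Poaceae", "monocot", h5, f4, igr_inserts = "tir"),
    row("Setaria_italica", "Poaceae", "monocot", h5, f4),
    row("Sorghum_bicolor", "Poaceae", "monocot", h5, f4),
    row("Zea_mays", "Poaceae", "monocot", h5, f4),
    row("Elaeis_guineensis", "Arecaceae", "monocot", h5, f4,
        igr_length = 12000L, igr_inserts = "interrupted_orf"),
    row("Phoenix_dactylifera", "Arecaceae", "monocot", h5, f4,
        igr_length = 11000L, igr_inserts = "interrupted_orf"),
    row("Citrullus_lanatus", "Cucurbitaceae", "dicot", h5, f4, "non_syntenic"),
    row("Cucumis_melo", "Cucurbitaceae", "dicot", h5, f4, "non_syntenic"),
    row("Cucumis_sativus", "Cucurbitaceae", "dicot", h5, f4, "non_syntenic"),
    row("Cannabis_sativa", "Cannabaceae", "dicot", h5, f4),
    row("Morus_notabilis", "Moraceae", "dicot", h5, f4,
        igr_length = 10000L, igr_inserts = "interrupted_orf"),
    row("Fragaria_vesca", "Rosaceae", "dicot", h5, f4),
    row("Malus_domestica", "Rosaceae", "dicot", h5, f4),
    row("Prunus_mume", "Rosaceae", "dicot", h5, f4),
    row("Prunus_persica", "Rosaceae", "dicot", h5, f4),
    row("Pyrus_bretschneideri", "Rosaceae", "dicot", h5, f4),
    row("Cajanus_cajan", "Fabaceae", "dicot", h5, f4, "non_syntenic"),
    row("Cicer_arietinum", "Fabaceae", "dicot", h5, f4, "non_syntenic"),
    row("Glycine_max", "Fabaceae", "dicot", h5, f4),
    row("Lupinus_angustifolius", "Fabaceae", "dicot", h5, f4, "non_syntenic"),
    row("Medicago_truncatula", "Fabaceae", "dicot", h5, f4,
        igr_inserts = "direct_repeat"),
    row("Hevea_brasiliensis", "Euphorbiaceae", "dicot", h5, f4),
    row("Jatropha_curcas", "Euphorbiaceae", "dicot", h5, f4),
    row("Ricinus_communis", "Euphorbiaceae", "dicot", h5, f4),
    row("Linum_usitatissimum", "Linaceae", "dicot", h5, f4,
        igr_length = 38523L, igr_inserts = "interrupted_orf"),
    row("Populus_trichocarpa", "Salicaceae", "dicot", h5, f4),
    row("Gossypium_raimondii", "Malvaceae", "dicot", h5, f4,
        "tandem_same_strand"),
    row("Theobroma_cacao", "Malvaceae", "dicot", h5, f4,
        "tandem_same_strand"),
    row("Aethionema_arabicum", "Brassicaceae", "dicot", "0,1,0,2,0", f4),
    row("Arabidopsis_lyrata", "Brassicaceae", "dicot", h5, f4),
    row("Arabidopsis_thaliana", "Brassicaceae", "dicot", h5, f4),
    row("Brassica_rapa", "Brassicaceae", "dicot", h5, "1,0"),
    row("Capsella_rubella", "Brassicaceae", "dicot", h5, f4),
    row("Eutrema_parvulum", "Brassicaceae", "dicot", h5, f4),
    row("Eutrema_salsugineum", "Brassicaceae", "dicot", h5, f4),
    row("Leavenworthia_alabamica", "Brassicaceae", "dicot", h5, f4,
        igr_length = 188L, motif_copies = 3L),
    row("Sisymbrium_irio", "Brassicaceae", "dicot", h5, f4),
    row("Carica_papaya", "Caricaceae", "dicot", h5, f4),
    row("Citrus_sinensis", "Rutaceae", "dicot", h5, f4),
    row("Vitis_vinifera", "Vitaceae", "dicot", h5, f4),
    row("Nicotiana_sylvestris", "Solanaceae", "dicot", h5, f4),
    row("Nicotiana_tomentosiformis", "Solanaceae", "dicot", h5, f4),
    row("Solanum_lycopersicum", "Solanaceae", "dicot", h5, f4),
    row("Solanum_tuberosum", "Solanaceae", "dicot", h5, f4))
  rownames(tab) <- NULL
  tab
}

## build a CDS (character string, ATG..stop) for one gene, with the codons
## needed by downstream checks forced deterministically
make_cds <- function(n_aa, role, clade, config, motif_copies = 1L,
                     prefix_aa = NULL) {
  codons <- c("ATG", sample(sense_codons(), n_aa - 1L, replace = TRUE), "TAA")
  if (!is.null(prefix_aa)) {
    codons[seq_len(nchar(prefix_aa))] <- AA_CODON[strsplit(prefix_aa, "")[[1L]]]
  }
  if (role == "fus") {
    ## codon split by the transit-peptide intron: G|A N in land plants and
    ## C. reinhardtii-like forms, G|C N in the basal chlorophytes
    codons[config$transit_aa + 1L] <-
      if (clade == "chlorophyta") "GCT" else "GAT"
  }
  if (role == "hop" && motif_copies >= 1L && n_aa >= 260L) {
    motif <- "VPEVEKKLEPEPEP"
    aa <- strsplit(strrep(motif, motif_copies), "")[[1L]]
    codons[200L + seq_along(aa) - 1L] <- AA_CODON[aa]
  }
  paste0(codons, collapse = "")
}

## cumulative spliced positions of the introns (nt upstream of each
## junction), realizing the requested phases
intron_cum_positions <- function(cds_len, phases, role, config,
                                 c1_override = NA_integer_) {
  k <- length(phases)
  if (k == 0L) return(integer())
  cums <- integer(k)
  if (role == "fus") {
    cums[1L] <- 3L * config$transit_aa + phases[1L]
    if (k > 1L) {
      for (i in 2L:k) {
        base <- cums[1L] + (i - 1L) * (cds_len - 9L - cums[1L]) / k
        cums[i] <- 3L * (floor(base) %/% 3L) + phases[i]
      }
    }
  } else {
    for (i in seq_len(k)) {
      base <- i * (cds_len - 9L) / (k + 1L)
      cums[i] <- 3L * (floor(base) %/% 3L) + phases[i]
    }
    if (!is.na(c1_override)) cums[1L] <- c1_override + phases[1L]
  }
  if (any(cums < 3L) || any(cums > cds_len - 6L) || any(diff(cums) < 3L)) {
    stop("phases unrealizable with exon length constraints (",
         k, " introns in a ", cds_len, " nt CDS)")
  }
  cums
}

## interleave exons and generated introns; returns the gene sequence on the
## transcript strand plus gene-local exon intervals (0-based half-open)
build_gene_parts <- function(cds, cums, config, intron_lengths = NULL) {
  k <- length(cums)
  bounds_lo <- c(0L, cums)
  bounds_hi <- c(cums, nchar(cds))
  exon_seqs <- substring(cds, bounds_lo + 1L, bounds_hi)
  if (is.null(intron_lengths)) {
    r <- config$intron_length_range
    intron_lengths <- if (k) sample(seq(r[1L], r[2L]), k, replace = TRUE)
                      else integer()
  }
  intron_seqs <- vapply(intron_lengths, function(len) {
    donor <- if (config$splice_dialect == "allow_gc_donor" &&
                 stats::runif(1L) < 0.15) "GC" else "GT"
    paste0(donor, random_dna(len - 4L), "AG")
  }, character(1L))
  gseq <- exon_seqs[1L]
  exons <- data.frame(start = 0L, end = nchar(exon_seqs[1L]))
  for (i in seq_len(k)) {
    gseq <- paste0(gseq, intron_seqs[i], exon_seqs[i + 1L])
    st <- nchar(gseq) - nchar(exon_seqs[i + 1L])
    exons <- rbind(exons, data.frame(start = st, end = nchar(gseq)))
  }
  list(gseq = gseq, exons_local = exons)
}

## map gene-local exons to genomic coordinates at `offset`, reverse-
## complementing the segment for minus-strand placement
place_gene <- function(parts, strand, offset) {
  glen <- nchar(parts$gseq)
  if (strand == "+") {
    segment <- parts$gseq
    exons <- data.frame(start = offset + parts$exons_local$start,
                        end = offset + parts$exons_local$end)
  } else {
    segment <- revcomp(parts$gseq)
    exons <- data.frame(start = offset + glen - parts$exons_local$end,
                        end = offset + glen - parts$exons_local$start)
  }
  list(segment = segment, exons = exons)
}

## intergenic region with optional planted instability signatures;
## returns the sequence and a table of planted features (IGR-local 0-based)
build_igr <- function(len, inserts) {
  seq <- random_dna(len)
  feats <- data.frame(start = integer(), end = integer(), type = character(),
                      insert = character(), stringsAsFactors = FALSE)
  put <- function(seq, at, piece) {
    paste0(substr(seq, 1L, at), piece,
           substr(seq, at + nchar(piece) + 1L, nchar(seq)))
  }
  for (ins in inserts) {
    if (ins == "tir" && len >= 400L) {
      arm <- random_dna(14L)
      seq <- put(seq, 100L, arm)
      seq <- put(seq, 300L, revcomp(arm))
      feats <- rbind(feats, data.frame(start = 100L, end = 314L,
                                       type = "repeat_region", insert = ins))
    } else if (ins == "direct_repeat" && len >= 500L) {
      arm <- paste0("CACTA", random_dna(9L))
      seq <- put(seq, 200L, arm)
      seq <- put(seq, 380L, arm)
      feats <- rbind(feats, data.frame(start = 200L, end = 394L,
                                       type = "repeat_region", insert = ins))
    } else if (ins == "interrupted_orf" && len >= 4000L) {
      guard <- function() paste0("TAA", paste0(sample(sense_codons(), 3L,
                                                      replace = TRUE),
                                               collapse = ""), "TAA")
      span <- paste0("ATG",
                     paste0(sample(sense_codons(), 29L, replace = TRUE),
                            collapse = ""))
      for (b in seq_len(12L)) {
        span <- paste0(span, "TAA",
                       paste0(sample(sense_codons(), 30L, replace = TRUE),
                              collapse = ""))
      }
      span <- paste0(span, "TAA")
      block <- paste0(guard(), span, guard())
      seq <- put(seq, 2000L, block)
      feats <- rbind(feats, data.frame(start = 2000L,
                                       end = 2000L + nchar(block),
                                       type = "pseudogene", insert = ins))
    }
  }
  list(seq = seq, features = feats)
}

#' Generate one synthetic species genome
#'
#' Realizes one fixture row: hop and chl-fus gene models with exactly the
#' requested intron counts and phases, canonical splice sites, the
#' requested pair arrangement and an intergenic region of the requested
#' length with any planted inserts. Consumes the session RNG; seed it (or
#' use [generate_fixture()], which seeds from its config) for determinism.
#'
#' @param spec One row of a fixture table (see [builtin_fixture_table()]).
#' @param config A [generator_config()].
#' @return A list with `contigs` (named character vector), `genes` (list of
#'   two `GeneModel`s), `proteins` (named character vector), `features`
#'   (`data.frame` of planted insert features, genomic coordinates) and
#'   `truth` (the realized specification, for manifests).
#' @export
generate_genome <- function(spec, config = generator_config()) {
  spec <- as.list(spec)
  sp <- spec$species
  hop_phases <- phases_vec(spec$hop_phases)
  fus_phases <- phases_vec(spec$fus_phases)
  if (length(fus_phases) && fus_phases[1L] != 1L) {
    stop("chl-fus phase vectors must start with the phase-1 ",
         "transit-peptide intron (species ", sp, ")")
  }
  motif_copies <- if (!is.null(spec$motif_copies) && !is.na(spec$motif_copies))
    spec$motif_copies else 1L
  hop_c1 <- if (!is.null(spec$hop_c1)) spec$hop_c1 else NA_integer_
  prefix <- if (!is.na(hop_c1)) "MADEHK" else NULL

  hop_cds <- make_cds(config$hop_aa, "hop", spec$clade, config,
                      motif_copies = motif_copies, prefix_aa = prefix)
  fus_cds <- make_cds(config$fus_aa, "fus", spec$clade, config)
  hop_cums <- intron_cum_positions(nchar(hop_cds), hop_phases, "hop", config,
                                   c1_override = hop_c1)
  fus_cums <- intron_cum_positions(nchar(fus_cds), fus_phases, "fus", config)
  hop_parts <- build_gene_parts(hop_cds, hop_cums, config)
  fus_parts <- build_gene_parts(fus_cds, fus_cums, config)

  fl <- config$flank
  contigs <- character()
  features <- data.frame(contig_id = character(), start = integer(),
                         end = integer(), type = character(),
                         id = character(), stringsAsFactors = FALSE)
  orientation <- spec$orientation
  if (orientation == "non_syntenic") {
    c1 <- paste0(sp, "_c1"); c2 <- paste0(sp, "_c2")
    hop_pl <- place_gene(hop_parts, "+", fl)
    fus_pl <- place_gene(fus_parts, "+", fl)
    contigs[c1] <- paste0(random_dna(fl), hop_pl$segment, random_dna(fl))
    contigs[c2] <- paste0(random_dna(fl), fus_pl$segment, random_dna(fl))
    hop_gene <- gene_model(paste0(sp, "_hop"), c1, "+", hop_pl$exons,
                           role = "hop", species = sp)
    fus_gene <- gene_model(paste0(sp, "_fus"), c2, "+", fus_pl$exons,
                           role = "fus", species = sp)
  } else {
    c1 <- paste0(sp, "_c1")
    igr <- build_igr(spec$igr_length,
                     setdiff(strsplit(spec$igr_inserts, ",")[[1L]], ""))
    layout <- switch(orientation,
      convergent = list(first = "hop", s1 = "+", s2 = "-"),
      divergent = list(first = "hop", s1 = "-", s2 = "+"),
      tandem_same_strand = list(first = "fus", s1 = "+", s2 = "+"),
      stop("unknown orientation: ", orientation))
    p1 <- if (layout$first == "hop") hop_parts else fus_parts
    p2 <- if (layout$first == "hop") fus_parts else hop_parts
    pl1 <- place_gene(p1, layout$s1, fl)
    igr_off <- fl + nchar(p1$gseq)
    pl2 <- place_gene(p2, layout$s2, igr_off + spec$igr_length)
    contigs[c1] <- paste0(random_dna(fl), pl1$segment, igr$seq, pl2$segment,
                          random_dna(fl))
    hop_pl <- if (layout$first == "hop") pl1 else pl2
    fus_pl <- if (layout$first == "hop") pl2 else pl1
    hop_gene <- gene_model(paste0(sp, "_hop"), c1,
                           if (layout$first == "hop") layout$s1 else layout$s2,
                           hop_pl$exons, role = "hop", species = sp)
    fus_gene <- gene_model(paste0(sp, "_fus"), c1,
                           if (layout$first == "hop") layout$s2 else layout$s1,
                           fus_pl$exons, role = "fus", species = sp)
    if (nrow(igr$features)) {
      features <- rbind(features, data.frame(
        contig_id = c1, start = igr_off + igr$features$start,
        end = igr_off + igr$features$end, type = igr$features$type,
        id = paste0(sp, "_", igr$features$insert,
                    seq_len(nrow(igr$features))),
        stringsAsFactors = FALSE))
    }
  }
  proteins <- c(translate_cds(hop_cds), translate_cds(fus_cds))
  names(proteins) <- c(paste0(sp, "_hop"), paste0(sp, "_fus"))
  list(contigs = contigs, genes = list(hop = hop_gene, fus = fus_gene),
       proteins = proteins, features = features,
       truth = list(species = sp,
                    family = if (!is.null(spec$family)) spec$family else NA,
                    clade = spec$clade,
                    syntenic = orientation != "non_syntenic",
                    orientation = orientation,
                    colinearity_category = spec$colinearity_category,
                    hop_introns = length(hop_phases),
                    fus_introns = length(fus_phases),
                    hop_phases = hop_phases, fus_phases = fus_phases,
                    igr_length = spec$igr_length,
                    igr_inserts = spec$igr_inserts,
                    hop_id = paste0(sp, "_hop"),
                    fus_id = paste0(sp, "_fus")))
}

#' Generate a complete fixture set on disk
#'
#' Writes `genome.fa`, `genes.gff3`, `proteins.faa` and a ground-truth
#' `manifest.json` for every species of a fixture table. Deterministic:
#' the same (table, config seed) produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param table Fixture table; default [builtin_fixture_table()].
#' @param config A [generator_config()].
#' @return Invisibly, a list with the four file paths and the manifest.
#' @export
generate_fixture <- function(dir, table = builtin_fixture_table(),
                             config = generator_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  contigs <- character()
  genes <- list()
  proteins <- character()
  features <- NULL
  manifest <- list()
  for (i in seq_len(nrow(table))) {
    g <- generate_genome(table[i, ], config)
    contigs <- c(contigs, g$contigs)
    genes <- c(genes, g$genes)
    proteins <- c(proteins, g$proteins)
    features <- rbind(features, g$features)
    manifest[[g$truth$species]] <- g$truth
  }
  paths <- list(genome = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "genes.gff3"),
                proteins = file.path(dir, "proteins.faa"),
                manifest = file.path(dir, "manifest.json"))
  write_genome(Biostrings::DNAStringSet(contigs), paths$genome)
  write_gene_models(genes, paths$gff3, extra_features = features)
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, paths$proteins, width = 70L)
  write_report(manifest, paths$manifest, format = "json")
  invisible(c(paths, list(manifest_data = manifest)))
}

#' Generate randomized gene-pair fixtures for property tests
#'
#' Draws `n_species` random specifications — intron counts, phase vectors
#' (the first chl-fus intron is always phase-1), arrangement and
#' intergenic length — realizes them as genomes and writes the ground
#' truth alongside, for parameter-recovery testing.
#'
#' @param dir Output directory.
#' @param n_species Number of random species (>= 1).
#' @param config A [generator_config()].
#' @return Invisibly, as [generate_fixture()].
#' @export
generate_random_pairs <- function(dir, n_species,
                                  config = generator_config()) {
  stopifnot(n_species >= 1L)
  set.seed(config$seed)
  orientations <- c("convergent", "divergent", "tandem_same_strand",
                    "non_syntenic")
  rows <- lapply(seq_len(n_species), function(i) {
    k_hop <- sample(0:8, 1L)
    k_fus <- sample(1:6, 1L)
    ori <- sample(orientations, 1L)
    data.frame(
      species = sprintf("sp%03d", i), family = "synthetic", clade = "dicot",
      hop_introns = k_hop, fus_introns = k_fus,
      hop_phases = paste(sample(0:2, k_hop, replace = TRUE), collapse = ","),
      fus_phases = paste(c(1L, sample(0:2, k_fus - 1L, replace = TRUE)),
                         collapse = ","),
      syntenic = ori != "non_syntenic", orientation = ori,
      colinearity_category = if (ori == "non_syntenic") "I" else
        if (ori == "convergent") "III" else "II",
      igr_length = if (ori == "non_syntenic") NA_integer_ else
        sample(seq(config$igr_length_range[1L], config$igr_length_range[2L]),
               1L),
      igr_inserts = "", hop_c1 = NA_integer_, motif_copies = 1L,
      stringsAsFactors = FALSE)
  })
  generate_fixture(dir, do.call(rbind, rows), config)
}

#' Build a gene directly from exon and intron sequences
#'
#' Low-level constructor for worked examples and surrogate records: lays
#' the given exon and intron sequences on a plus-strand contig and returns
#' both the genome and the `GeneModel`.
#'
#' @param exon_seqs Character vector of exon sequences (transcription
#'   order).
#' @param intron_seqs Character vector of intron sequences (length one
#'   less than `exon_seqs`).
#' @param gene_id,role,species Passed to [gene_model()].
#' @param flank Plain flanking sequence added on both sides (default
#'   `"ACGT"` repeated 5 times).
#' @return A list with `genome` (named `DNAStringSet`) and `gene`.
#' @export
synth_gene_from_exons <- function(exon_seqs, intron_seqs, gene_id = "g1",
                                  role = "other", species = NA_character_,
                                  flank = strrep("ACGT", 5L)) {
  stopifnot(length(intron_seqs) == length(exon_seqs) - 1L)
  seq <- flank
  exons <- NULL
  for (i in seq_along(exon_seqs)) {
    st <- nchar(seq)
    seq <- paste0(seq, exon_seqs[i])
    exons <- rbind(exons, data.frame(start = st, end = nchar(seq)))
    if (i < length(exon_seqs)) seq <- paste0(seq, intron_seqs[i])
  }
  seq <- paste0(seq, flank)
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- paste0(gene_id, "_contig")
  list(genome = genome,
       gene = gene_model(gene_id, paste0(gene_id, "_contig"), "+", exons,
                         role = role, species = species))
}

#' Generate a hidden-intron test gene
#'
#' Builds a single-exon gene whose CDS retains an in-frame, stop-free
#' intron (bounded by GT..AG) after a given codon, emulating an
#' over-predicted protein in which an unannotated intron reads through —
#' plus the reference (intron-free) protein for comparison.
#'
#' @param n_aa Reference protein length (default 300).
#' @param extra_aa Length of the retained in-frame insertion in codons
#'   (default 71).
#' @param after_codon Codon after which the intron sits (default 6).
#' @return A list with `genome`, `gene` (single-exon `GeneModel`),
#'   `reference_length` (aa), and `intron` (transcript-space 0-based
#'   half-open interval of the retained intron).
#' @export
synth_hidden_intron_gene <- function(n_aa = 300L, extra_aa = 71L,
                                     after_codon = 6L) {
  codons <- c(AA_CODON[strsplit("MADEHK", "")[[1L]]],
              sample(sense_codons(), n_aa - 6L, replace = TRUE), "TAA")
  p0 <- 3L * after_codon
  excess_nt <- 3L * extra_aa
  repeat {
    intron_codons <- sample(sense_codons(), extra_aa, replace = TRUE)
    intron_codons[1L] <- "GTT"                # GT donor
    intron_codons[extra_aa] <- "CAG"          # AG acceptor
    cds <- paste0(paste0(codons[seq_len(after_codon)], collapse = ""),
                  paste0(intron_codons, collapse = ""),
                  paste0(codons[(after_codon + 1L):length(codons)],
                         collapse = ""))
    ## the planted interval must be the 5'-most donor..acceptor candidate:
    ## no earlier position may offer both a GT/GC donor and an AG acceptor
    earlier <- vapply(seq_len(p0) - 1L, function(p) {
      substr(cds, p + 1L, p + 2L) %in% c("GT", "GC") &&
        substr(cds, p + excess_nt - 1L, p + excess_nt) == "AG"
    }, logical(1L))
    if (!any(earlier)) break
  }
  built <- synth_gene_from_exons(cds, character(), gene_id = "hidden",
                                 role = "hop")
  list(genome = built$genome, gene = built$gene, reference_length = n_aa,
       intron = list(start = 3L * after_codon,
                     end = 3L * after_codon + 3L * extra_aa))
}
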