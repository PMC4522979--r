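#' Read a genome FASTA
#'
#' Reads nucleotide FASTA into a named `DNAStringSet`. Sequences are
#' uppercased and RNA-style `U` is mapped to `T`, so downstream codon logic
#' only ever sees the DNA alphabet.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per contig.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  raw <- Biostrings::readBStringSet(fasta_path)
  if (length(raw) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate contig IDs in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "U", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome FASTA
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "XStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation into `GeneModel` objects. Gene intervals are
#' taken from `CDS` features (falling back to `exon` when a transcript has
#' no CDS rows), linked to their gene through the `Parent` chain. GFF3
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; the GFF3 `phase` column is ignored — intron phases
#' are recomputed positionally by [assign_intron_phases()].
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome Optional named `DNAStringSet`; when supplied, exon bounds
#'   are validated against contig lengths.
#' @param role_attr Name of the GFF3 attribute carrying the gene role
#'   (`hop`/`fus`); default `"role"`.
#' @return A named list of `GeneModel` objects (names are gene IDs).
#' @export
read_gene_models <- function(gff3_path, genome = NULL, role_attr = "role") {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(
    if (is.list(df$Parent) || methods::is(df$Parent, "List")) df$Parent
    else as.list(df$Parent),
    function(p) if (length(p)) as.character(p[[1L]]) else NA_character_,
    character(1L))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", gff3_path)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  parts <- df[df$type %in% c("CDS", "exon"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx_ids <- mrna$ID[!is.na(mrna$Parent) & mrna$Parent == g$ID]
    own <- parts[parts$Parent %in% c(g$ID, tx_ids), , drop = FALSE]
    use <- own[own$type == "CDS", , drop = FALSE]
    if (nrow(use) == 0L) use <- own[own$type == "exon", , drop = FALSE]
    if (nrow(use) == 0L) stop("gene ", g$ID, " has no CDS or exon features")
    exons <- data.frame(start = use$start - 1L, end = use$end)
    role <- if (role_attr %in% names(g) && !is.na(g[[role_attr]])) {
      as.character(g[[role_attr]])
    } else "other"
    if (!role %in% c("hop", "fus")) role <- "other"
    sp <- if ("species" %in% names(g) && !is.na(g$species)) {
      as.character(g$species)
    } else NA_character_
    gm <- gene_model(as.character(g$ID), as.character(g$seqnames),
                     as.character(g$strand), exons, role = role, species = sp)
    if (!is.null(genome)) {
      if (!gm$contig_id %in% names(genome)) {
        stop("gene ", gm$gene_id, ": contig ", gm$contig_id, " not in genome")
      }
      if (max(gm$exons$end) > Biostrings::width(genome)[
            match(gm$contig_id, names(genome))]) {
        stop("gene ", gm$gene_id, ": exon outside contig ", gm$contig_id,
             " bounds")
      }
    }
    out[[gm$gene_id]] <- gm
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / exon / CDS rows per gene, with the gene role and
#' species recorded as attributes; inverse of [read_gene_models()].
#'
#' @param genes List of `GeneModel` objects.
#' @param path Output GFF3 path.
#' @param extra_features Optional `data.frame` of additional features
#'   (columns `contig_id`, `start`, `end` in internal 0-based half-open
#'   coordinates, `type`, `id`) — used for annotated intergenic inserts.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, extra_features = NULL) {
  rows <- list()
  for (g in genes) {
    ## GFF3 CDS phase: offset to the next codon start, from cumulative
    ## coding length upstream of each exon in transcription order
    tx_ex <- g$exons
    cum_before <- c(0L, cumsum(tx_ex$end - tx_ex$start))[seq_len(nrow(tx_ex))]
    tx_ex$cds_phase <- (3L - cum_before %% 3L) %% 3L
    ex <- tx_ex[order(tx_ex$start), , drop = FALSE]
    span <- gene_span(g)
    tx <- paste0(g$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$contig_id, start = span[1L] + 1L, end = span[2L],
      strand = g$strand,
      type = c("gene", "mRNA"), ID = c(g$gene_id, tx),
      Parent = c(NA, g$gene_id), phase = NA_integer_,
      role = c(g$role, NA), species = c(g$species, NA),
      stringsAsFactors = FALSE)
    for (tp in c("exon", "CDS")) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = g$contig_id, start = ex$start + 1L, end = ex$end,
        strand = g$strand, type = tp,
        ID = paste0(tx, ".", tolower(tp), seq_len(nrow(ex))),
        Parent = tx,
        phase = if (tp == "CDS") ex$cds_phase else NA_integer_,
        role = NA, species = NA, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(extra_features) && nrow(extra_features) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = extra_features$contig_id, start = extra_features$start + 1L,
      end = extra_features$end, strand = "+", type = extra_features$type,
      ID = extra_features$id, Parent = NA, phase = NA_integer_, role = NA,
      species = NA, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$role <- df$role
  S4Vectors::mcols(gr)$species <- df$species
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a single-gene GenBank flat file
#'
#' Minimal reader for GenBank records carrying one `CDS` feature with a
#' `join()` of exon spans (optionally wrapped in `complement()`), plus the
#' `ORIGIN` sequence block. Fuzzy coordinates (`<`/`>`) are rejected.
#'
#' @param gb_path Path to a GenBank flat file.
#' @return A list with `contig` (named `DNAStringSet` of length 1) and
#'   `gene` (a `GeneModel`).
#' @export
read_genbank_gene <- function(gb_path) {
  lines <- readLines(gb_path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  acc <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else "record"
  ## CDS location may continue over several lines
  cds_i <- grep("^\\s{5}CDS\\s", lines)
  if (!length(cds_i)) stop("no CDS feature in ", gb_path)
  loc <- sub("^\\s{5}CDS\\s+", "", lines[cds_i[1L]])
  j <- cds_i[1L] + 1L
  while (j <= length(lines) && grepl("^\\s{21}[^/]", lines[j])) {
    loc <- paste0(loc, trimws(lines[j]))
    j <- j + 1L
  }
  if (grepl("[<>]", loc)) {
    stop("CDS with fuzzy coordinates in ", gb_path, ": ", loc)
  }
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  spans <- strsplit(loc, ",")[[1L]]
  m <- regmatches(spans, regexec("^(\\d+)\\.\\.(\\d+)$", spans))
  if (any(lengths(m) != 3L)) stop("unparseable CDS location in ", gb_path)
  starts <- as.integer(vapply(m, `[`, character(1L), 2L))
  ends <- as.integer(vapply(m, `[`, character(1L), 3L))
  ## ORIGIN block
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN block in ", gb_path)
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  seq <- chartr("U", "T", seq)
  contig <- Biostrings::DNAStringSet(seq)
  names(contig) <- acc
  gene <- gene_model(paste0(acc, ".cds"), acc, strand,
                     data.frame(start = starts - 1L, end = ends),
                     role = "other")
  list(contig = contig, gene = gene)
}

#' Write a single-gene GenBank flat file
#'
#' Writes the minimal record structure [read_genbank_gene()] understands;
#' mainly used for round-trip tests and synthetic surrogate records.
#'
#' @param gene A `GeneModel`.
#' @param genome Named `DNAStringSet` holding the gene's contig.
#' @param path Output path.
#' @param accession Accession string for the LOCUS line (default: contig id).
#' @return `path`, invisibly.
#' @export
write_genbank_gene <- function(gene, genome, path, accession = gene$contig_id) {
  seq <- tolower(contig_seq(genome, gene$contig_id))
  ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
  spans <- paste0(ex$start + 1L, "..", ex$end, collapse = ",")
  loc <- if (nrow(ex) > 1L) paste0("join(", spans, ")") else spans
  if (gene$strand == "-") loc <- paste0("complement(", loc, ")")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   PLN",
                     accession, nchar(seq)), con)
  writeLines(sprintf("DEFINITION  synthetic record for %s.", gene$gene_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(seq)), con)
  writeLines(paste0("     CDS             ", loc), con)
  writeLines(sprintf("                     /gene=\"%s\"", gene$gene_id), con)
  writeLines("ORIGIN", con)
  for (i in seq(1L, nchar(seq), by = 60L)) {
    chunk <- substr(seq, i, min(i + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a pipeline report
#'
#' Serializes a `data.frame` (TSV) or any list/data.frame (JSON) with
#' deterministic column and key order, so identical inputs always produce
#' byte-identical files.
#'
#' @param results A `data.frame` (for TSV) or list (for JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "tsv") {
    if (!is.data.frame(results)) results <- as.data.frame(results)
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
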