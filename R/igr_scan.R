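#' Scan an intergenic region for (interrupted) open reading frames
#'
#' Performs a six-frame scan. Plain ORFs are ATG-to-stop spans of at least
#' `min_aa` codons. In addition, interrupted reading frames — the signature
#' of decaying insertions such as pararetrovirus pseudogenes — are detected
#' by chaining consecutive in-frame stop-free stretches of at least
#' `min_fragment_aa` codons that are separated only by stop codons; the
#' chained span is reported once, with the number of internal stops. A span
#' is flagged as pseudogene-like when its internal stop count reaches
#' `stop_threshold`.
#'
#' @param igr Nucleotide string. `N` codons translate to `X` and never
#'   start or qualify a hit.
#' @param min_aa Minimum reported length in amino acids (default 50).
#' @param min_fragment_aa Minimum stop-free stretch length for chaining
#'   (default 30); stretches shorter than this break a chain.
#' @param stop_threshold Internal stops at which `pseudogene_flag` is set
#'   (default 3).
#' @return A `data.frame` with columns `frame` (+1..+3, -1..-3), `start`,
#'   `end` (IGR-local, 1-based, on the forward strand), `aa_length`,
#'   `internal_stops`, `pseudogene_flag`.
#' @export
scan_orfs <- function(igr, min_aa = 50L, min_fragment_aa = 30L,
                      stop_threshold = 3L) {
  empty <- data.frame(frame = integer(), start = integer(), end = integer(),
                      aa_length = integer(), internal_stops = integer(),
                      pseudogene_flag = logical())
  L <- nchar(igr)
  if (L < 3L * min_aa) return(empty)
  out <- list()
  for (sense in c(1L, -1L)) {
    s <- if (sense == 1L) toupper(igr) else revcomp(igr)
    for (off in 0L:2L) {
      n_cod <- (nchar(s) - off) %/% 3L
      if (n_cod < min_aa) next
      sub <- substr(s, off + 1L, off + 3L * n_cod)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      hits <- orf_spans(aa, min_aa, min_fragment_aa)
      for (h in hits) {
        s_start <- off + 3L * (h$q_start - 1L) + 1L
        s_end <- off + 3L * h$q_end
        if (sense == 1L) {
          start <- s_start; end <- s_end
        } else {
          start <- L - s_end + 1L; end <- L - s_start + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = sense * (off + 1L), start = start, end = end,
          aa_length = h$aa_length, internal_stops = h$stops,
          pseudogene_flag = h$stops >= stop_threshold)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## chain stop-free stretches of a frame translation into ORF spans
orf_spans <- function(aa, min_aa, min_fragment_aa) {
  chars <- strsplit(aa, "")[[1L]]
  n <- length(chars)
  is_stop <- chars == "*"
  ## fragment boundaries: runs of non-stop
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  frag <- data.frame(start = starts[!r$values], end = ends[!r$values])
  if (!nrow(frag)) return(list())
  frag$len <- frag$end - frag$start + 1L
  frag$qual <- frag$len >= min_fragment_aa
  ## chains: maximal runs of consecutive qualifying fragments
  hits <- list()
  i <- 1L
  while (i <= nrow(frag)) {
    if (!frag$qual[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= nrow(frag) && frag$qual[j + 1L]) j <- j + 1L
    q_lo <- frag$start[i]; q_hi <- frag$end[j]
    span_chars <- chars[q_lo:q_hi]
    m_rel <- which(span_chars == "M")
    if (length(m_rel)) {
      q_start <- q_lo + m_rel[1L] - 1L
      inner <- chars[q_start:q_hi]
      stops <- sum(inner == "*")
      aa_len <- sum(inner != "*")
      q_end <- q_hi
      ## include the terminal stop codon when present
      if (q_hi + 1L <= n && is_stop[q_hi + 1L]) q_end <- q_hi + 1L
      if (aa_len >= min_aa) {
        hits[[length(hits) + 1L]] <- list(q_start = q_start, q_end = q_end,
                                          aa_length = aa_len, stops = stops)
      }
    }
    i <- j + 1L
  }
  hits
}

#' Find MITE-like terminal inverted repeats in an intergenic region
#'
#' Reports maximal pairs of arms in which the second arm is the reverse
#' complement of the first up to `max_mismatch` substitutions, separated by
#' at most `max_spacer` bp — the structure of miniature inverted-repeat
#' transposable elements. A hit is maximal when no valid hit with the same
#' arm-pairing diagonal strictly contains it; arm ends always match, arms
#' never overlap, and `N` never matches anything.
#'
#' @param igr Nucleotide string.
#' @param min_arm Minimum arm length in bp (>= 8; default 10).
#' @param max_mismatch Maximum substitutions between arms (default 1).
#' @param max_spacer Maximum distance between arms in bp (default 1000).
#' @param max_arm Largest arm considered (default 2000); bounds the search.
#' @return `data.frame` with columns `kind`, `arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end` (IGR-local, 1-based inclusive), `arm_length`,
#'   `mismatches`, `spacer`, sorted by (`arm1_start`, `arm2_start`).
#' @export
find_inverted_repeats <- function(igr, min_arm = 10L, max_mismatch = 1L,
                                  max_spacer = 1000L, max_arm = 2000L) {
  if (min_arm < 8L) stop("min_arm must be >= 8")
  res <- scan_repeats_cpp(toupper(igr), as.integer(min_arm),
                          as.integer(max_mismatch), as.integer(max_spacer),
                          as.integer(max_arm), TRUE)
  finish_repeat_table(res, "inverted", igr)
}

#' Find CACTA-like direct repeats in an intergenic region
#'
#' As [find_inverted_repeats()], with arm equality instead of reverse
#' complementarity. Hits whose first arm begins with the pentamer `CACTA`
#' are flagged `cacta_like`, after the terminal structure of CACTA-family
#' DNA transposons.
#'
#' @inheritParams find_inverted_repeats
#' @return As [find_inverted_repeats()], plus a logical `cacta_like`
#'   column.
#' @export
find_direct_repeats <- function(igr, min_arm = 10L, max_mismatch = 1L,
                                max_spacer = 1000L, max_arm = 2000L) {
  if (min_arm < 8L) stop("min_arm must be >= 8")
  res <- scan_repeats_cpp(toupper(igr), as.integer(min_arm),
                          as.integer(max_mismatch), as.integer(max_spacer),
                          as.integer(max_arm), FALSE)
  res <- finish_repeat_table(res, "direct", igr)
  res$cacta_like <- if (nrow(res)) {
    substring(toupper(igr), res$arm1_start, res$arm1_start + 4L) == "CACTA"
  } else logical(0)
  res
}

finish_repeat_table <- function(res, kind, igr) {
  res <- as.data.frame(res)
  res$kind <- rep(kind, nrow(res))
  res <- res[order(res$arm1_start, res$arm2_start),
             c("kind", "arm1_start", "arm1_end", "arm2_start", "arm2_end",
               "arm_length", "mismatches", "spacer"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect 3' UTR overlap between convergent cDNA sets
#'
#' When the transcribed 3' ends of the two convergent genes run past each
#' other, the intergenic region is missing in the strict (transcript)
#' sense even though the coding annotations do not overlap. Given cDNA
#' alignments for each gene (as `GeneModel`s on one contig), this reports
#' the maximal 3'-end overlap over all cDNA combinations.
#'
#' @param hop_cdnas,fus_cdnas Lists of `GeneModel`s for the cDNAs of each
#'   gene, on one contig, in convergent orientation.
#' @return A list `list(overlap_bp, igr_missing)` where `igr_missing` is
#'   `TRUE` iff `overlap_bp > 0`.
#' @export
detect_utr_overlap <- function(hop_cdnas, fus_cdnas) {
  all_cdnas <- c(hop_cdnas, fus_cdnas)
  contigs <- unique(vapply(all_cdnas, function(g) g$contig_id, character(1L)))
  if (length(contigs) != 1L) {
    stop("cDNAs on different contigs: ", paste(contigs, collapse = ", "))
  }
  pos3 <- function(g) if (g$strand == "+") gene_span(g)[2L] else gene_span(g)[1L]
  hop3 <- vapply(hop_cdnas, pos3, numeric(1L))
  fus3 <- vapply(fus_cdnas, pos3, numeric(1L))
  hop_plus <- hop_cdnas[[1L]]$strand == "+"
  ov <- if (hop_plus) outer(hop3, fus3, `-`) else outer(fus3, hop3, `-`)
  overlap <- max(0L, as.integer(max(ov)))
  list(overlap_bp = overlap, igr_missing = overlap > 0L)
}

#' Estimate a deletion between two homologous intergenic regions
#'
#' Anchored at a shared 5' prefix, reports where the two sequences diverge
#' and the size difference beyond that point — the signature of a
#' chromosomal deletion in one copy. Requires a common prefix of at least
#' `anchor` bases; the deletion size is exact when the flanks are unique
#' (a shared suffix spans the remainder), an estimate otherwise.
#'
#' @param igr_a,igr_b Nucleotide strings.
#' @param anchor Minimum shared 5' prefix (default 20 bp).
#' @return A list `list(divergence_point, deleted_bp_estimate)` with an
#'   attribute `"clean"` set to `TRUE` when prefix + suffix anchors cover
#'   the shorter sequence entirely.
#' @export
compare_igr_deletion <- function(igr_a, igr_b, anchor = 20L) {
  a <- strsplit(toupper(igr_a), "")[[1L]]
  b <- strsplit(toupper(igr_b), "")[[1L]]
  k <- min(length(a), length(b))
  if (k == 0L) stop("not comparable: empty sequence")
  pre_mismatch <- which(a[seq_len(k)] != b[seq_len(k)])
  lcp <- if (length(pre_mismatch)) pre_mismatch[1L] - 1L else k
  if (lcp < anchor) {
    stop("not comparable: common prefix of ", lcp, " bp is shorter than the ",
         anchor, " bp anchor")
  }
  suf_mismatch <- which(rev(a)[seq_len(k)] != rev(b)[seq_len(k)])
  lcs <- if (length(suf_mismatch)) suf_mismatch[1L] - 1L else k
  structure(
    list(divergence_point = lcp,
         deleted_bp_estimate = abs(length(a) - length(b))),
    clean = (lcp + lcs) >= k)
}
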