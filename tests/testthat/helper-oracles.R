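## Shared builders and independent brute-force oracles used across tests.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

rnd_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rnd_cds <- function(n_aa) {
  paste0(c("ATG", sample(SENSE_CODONS, n_aa - 1L, TRUE), "TAA"),
         collapse = "")
}

## random multi-exon gene on either strand, with the exon length layout
## returned so the oracle can work from first principles
rnd_gene <- function(n_exons = sample(2:10, 1L), strand = sample(c("+", "-"), 1L),
                     n_aa = 120L) {
  cds <- rnd_cds(n_aa)
  L <- nchar(cds)
  ## n_exons - 1 distinct cut points, at least 3 nt apart
  repeat {
    cuts <- sort(sample(seq(3L, L - 3L), n_exons - 1L))
    if (n_exons == 1L || all(diff(cuts) >= 3L)) break
  }
  exon_seqs <- substring(cds, c(0L, cuts) + 1L, c(cuts, L))
  intron_seqs <- vapply(seq_len(n_exons - 1L), function(i)
    paste0("GT", rnd_dna(sample(10:60, 1L)), "AG"), character(1L))
  tx <- exon_seqs[1L]
  exons_local <- data.frame(start = 0L, end = nchar(exon_seqs[1L]))
  for (i in seq_along(intron_seqs)) {
    tx <- paste0(tx, intron_seqs[i], exon_seqs[i + 1L])
    exons_local <- rbind(exons_local,
                         data.frame(start = nchar(tx) - nchar(exon_seqs[i + 1L]),
                                    end = nchar(tx)))
  }
  flank <- rnd_dna(15L)
  if (strand == "+") {
    contig <- paste0(flank, tx, flank)
    exons <- exons_local + nchar(flank)
  } else {
    contig <- paste0(flank, hopfus::revcomp(tx), flank)
    glen <- nchar(tx)
    exons <- data.frame(start = nchar(flank) + glen - exons_local$end,
                        end = nchar(flank) + glen - exons_local$start)
  }
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "c1"
  list(gene = gene_model("g", "c1", strand, exons, role = "hop"),
       genome = genome, cds = cds, cuts = cuts,
       intron_seqs = intron_seqs)
}

## oracle: splice the CDS and count full codons before each junction
oracle_phases <- function(cuts) {
  vapply(cuts, function(cum) cum - 3L * (cum %/% 3L), integer(1L))
}

## oracle for recombinable modules: enumerate all contiguous exon runs and
## keep those whose two flanking boundary phases agree
oracle_modules <- function(phases, n_exons, policy = "phase0") {
  boundary_phase <- function(b) { # b in 0..n_exons; NA when excluded
    if (b == 0L || b == n_exons) {
      if (policy == "phase0") 0L else NA_integer_
    } else phases[b]
  }
  rows <- list()
  for (a in seq_len(n_exons)) {
    for (b in a:n_exons) {
      up <- boundary_phase(a - 1L)
      dn <- boundary_phase(b)
      if (!is.na(up) && !is.na(dn) && up == dn) {
        rows[[length(rows) + 1L]] <- data.frame(
          first_exon_rank = a, last_exon_rank = b, flanking_phase = up,
          symmetric = TRUE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(first_exon_rank = integer(), last_exon_rank = integer(),
                      flanking_phase = integer(), symmetric = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$first_exon_rank, out$last_exon_rank), , drop = FALSE]
}

## brute-force repeat oracle: enumerate every valid (arm1, arm2, len) and
## drop hits contained in another valid hit on the same pairing diagonal
oracle_repeats <- function(seq, min_arm, max_mismatch, max_spacer, max_arm,
                           inverted) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  if (!inverted) {
    for (i in seq_len(n)) {
      j_hi <- min(n, i + max_arm + max_spacer)
      if (i + min_arm > j_hi) next
      for (j in seq(i + min_arm, j_hi)) {
        maxlen <- min(j - i, max_arm, n - j + 1L)
        if (maxlen < min_arm) next
        t_idx <- seq_len(maxlen)
        bad <- !ok[i + t_idx - 1L] | !ok[j + t_idx - 1L]
        mis <- s[i + t_idx - 1L] != s[j + t_idx - 1L]
        first_bad <- if (any(bad)) which(bad)[1L] - 1L else maxlen
        if (first_bad < min_arm) next
        cmis <- cumsum(mis[seq_len(first_bad)])
        lenmin <- max(min_arm, (j - i) - max_spacer)
        if (lenmin > first_bad) next
        for (len in seq(lenmin, first_bad)) {
          if (cmis[len] > max_mismatch) next
          if (mis[1L] || mis[len]) next
          hits[[length(hits) + 1L]] <- c(i, i + len - 1L, j, j + len - 1L,
                                         len, cmis[len], (j - i) - len)
        }
      }
    }
  } else {
    for (i in seq_len(n)) {
      emax <- min(n, i + 2L * max_arm + max_spacer - 1L)
      e0 <- i + 2L * min_arm - 1L
      if (e0 > n) next
      for (e in seq(e0, emax)) {
        span <- e - i + 1L
        maxlen <- min(span %/% 2L, max_arm)
        if (maxlen < min_arm) next
        t_idx <- seq_len(maxlen)
        a <- s[i + t_idx - 1L]
        b <- s[e - t_idx + 1L]
        bad <- !ok[i + t_idx - 1L] | !ok[e - t_idx + 1L]
        mis <- a != unname(compl[b])
        first_bad <- if (any(bad)) which(bad)[1L] - 1L else maxlen
        if (first_bad < min_arm) next
        cmis <- cumsum(mis[seq_len(first_bad)])
        lenmin <- max(min_arm, ceiling((span - max_spacer) / 2))
        if (lenmin > first_bad) next
        for (len in seq(lenmin, first_bad)) {
          if (cmis[len] > max_mismatch) next
          if (mis[1L] || mis[len]) next
          hits[[length(hits) + 1L]] <- c(i, i + len - 1L, e - len + 1L, e,
                                         len, cmis[len], span - 2L * len)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      arm_length = integer(), mismatches = integer(),
                      spacer = integer()))
  }
  m <- do.call(rbind, hits)
  df <- data.frame(arm1_start = m[, 1L], arm1_end = m[, 2L],
                   arm2_start = m[, 3L], arm2_end = m[, 4L],
                   arm_length = m[, 5L], mismatches = m[, 6L],
                   spacer = m[, 7L])
  diag_key <- if (!inverted) df$arm2_start - df$arm1_start
              else df$arm1_start + df$arm2_end
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    same <- which(diag_key == diag_key[r])
    for (q in same) {
      if (q == r) next
      if (df$arm1_start[q] <= df$arm1_start[r] &&
          df$arm1_end[q] >= df$arm1_end[r] &&
          (df$arm1_start[q] < df$arm1_start[r] ||
           df$arm1_end[q] > df$arm1_end[r])) {
        keep[r] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$arm1_start, df$arm2_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

repeat_cols <- c("arm1_start", "arm1_end", "arm2_start", "arm2_end",
                 "arm_length", "mismatches", "spacer")

## flood-fill oracle for HCA clusters over the explicit adjacency graph
oracle_clusters <- function(protein, hydrophobic = HCA_HYDROPHOBIC) {
  chars <- strsplit(toupper(protein), "")[[1L]]
  hyd <- which(chars %in% hydrophobic)
  if (!length(hyd)) return(list())
  edges <- NULL
  for (i in hyd) {
    for (d in c(1L, 3L, 4L)) {
      j <- i + d
      if (!(j %in% hyd)) next
      if (d > 1L && any(chars[(i + 1L):(j - 1L)] == "P")) next
      edges <- rbind(edges, c(match(i, hyd), match(j, hyd)))
    }
  }
  g <- igraph::make_empty_graph(n = length(hyd), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  unname(lapply(split(hyd, comp), sort))
}

## random protein with tunable hydrophobic content
rnd_protein <- function(n, p_hyd = 0.35, p_pro = 0.05) {
  pool_h <- HCA_HYDROPHOBIC
  pool_o <- setdiff(LETTERS[LETTERS %in% c("A", "C", "D", "E", "G", "H", "K",
                                           "N", "Q", "R", "S", "T")], "")
  draw <- function() {
    u <- stats::runif(1L)
    if (u < p_pro) "P" else if (u < p_pro + p_hyd) sample(pool_h, 1L)
    else sample(pool_o, 1L)
  }
  paste0(vapply(seq_len(n), function(i) draw(), character(1L)), collapse = "")
}

cluster_sets <- function(clusters) {
  unname(lapply(clusters, function(cl) sort(cl$member_indices)))
}

sort_sets <- function(sets) sets[order(vapply(sets, `[`, numeric(1L), 1L))]
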