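intron20 <- function() paste0("GT", strrep("CTCA", 5L), "AG")

two_exon <- function(e1, e2, intron = intron20(), role = "other") {
  synth_gene_from_exons(c(e1, e2), intron, role = role)
}

test_that("the three canonical junction examples classify as phases 0/1/2", {
  ## junction between two complete codons -> phase 0
  b0 <- two_exon("ATGGGCCAG", "GTCACGTAA")
  i0 <- assign_intron_phases(b0$gene, b0$genome)
  expect_identical(i0$phase, 0L)
  expect_identical(i0$split_codon, "")
  ## junction after the first nucleotide of a codon -> phase 1
  b1 <- two_exon("ATGCCAG", "GTCACTAA")
  i1 <- assign_intron_phases(b1$gene, b1$genome)
  expect_identical(i1$phase, 1L)
  expect_identical(i1$split_codon, "G|GT")
  ## junction after the second nucleotide -> phase 2
  b2 <- two_exon("ATGGGCAG", "GTCATAA")
  i2 <- assign_intron_phases(b2$gene, b2$genome)
  expect_identical(i2$phase, 2L)
  expect_identical(i2$split_codon, "AG|G")
})

test_that("phase assignment matches the splice-and-count oracle", {
  set.seed(42)
  for (rep in 1:200) {
    g <- rnd_gene()
    got <- assign_intron_phases(g$gene, g$genome)
    expect_identical(got$phase, oracle_phases(g$cuts))
    expect_identical(got$ordinal, seq_along(g$cuts))
    ## donor/acceptor read in transcript orientation
    expect_true(all(got$donor == "GT"), info = g$gene$strand)
    expect_true(all(got$acceptor == "AG"))
    ## intron lengths recovered from genomic coordinates
    expect_identical(got$length, nchar(g$intron_seqs))
    ## chained phase identity: phase_k = (phase_{k-1} + exon_k length) mod 3
    if (nrow(got) > 1L) {
      cums <- c(0L, g$cuts)
      exon_len <- diff(cums)
      expect_identical(got$phase[-1L],
                       (got$phase[-nrow(got)] + exon_len[-1L]) %% 3L)
    }
  }
})

test_that("phase assignment rejects incomplete and degenerate models", {
  b <- synth_gene_from_exons(c("ATGCC", "AGTTAA"), intron20()) # 11 nt
  expect_error(assign_intron_phases(b$gene, b$genome), "incomplete CDS")
  expect_error(split_codon(list(phase = 0L, ordinal = 1L)), "phase-0")
})

test_that("split codons render in DNA or RNA alphabet", {
  b1 <- two_exon("ATGG", "ATTAA")
  i1 <- assign_intron_phases(b1$gene, b1$genome)
  expect_identical(i1$split_codon, "G|AT")
  expect_identical(split_codon(i1[1, ]), "G|AT")
  expect_identical(split_codon(i1[1, ], rna = TRUE), "G|AU")
  b2 <- two_exon("ATGG", "CCTAA")
  expect_identical(assign_intron_phases(b2$gene, b2$genome)$split_codon,
                   "G|CC")
})

test_that("splice verdicts separate canonical, GC-donor and aberrant sites", {
  b_gt <- two_exon("ATGGGC", "GTCTAA")
  v <- validate_splice_sites(assign_intron_phases(b_gt$gene, b_gt$genome))
  expect_identical(v$splice_verdict, "canonical")
  b_gc <- two_exon("ATGGGC", "GTCTAA",
                   intron = paste0("GC", strrep("CTCA", 5L), "AG"))
  v2 <- validate_splice_sites(assign_intron_phases(b_gc$gene, b_gc$genome))
  expect_identical(v2$splice_verdict, "gc_donor")
  b_nc <- two_exon("ATGGGC", "GTCTAA",
                   intron = paste0("AT", strrep("CTCA", 5L), "AC"))
  v3 <- validate_splice_sites(assign_intron_phases(b_nc$gene, b_nc$genome))
  expect_identical(v3$splice_verdict, "noncanonical")
})

test_that("recombinable-module enumeration matches the run oracle", {
  ## worked cases
  expect_identical(nrow(find_recombinable_modules(c(0L, 0L, 0L), 4L)), 10L)
  expect_identical(nrow(find_recombinable_modules(c(0L, 0L, 0L), 4L,
                                                  "excluded")), 3L)
  m <- find_recombinable_modules(c(1L, 2L), 3L)
  expect_identical(nrow(m), 1L)
  expect_identical(m$first_exon_rank, 1L)
  expect_identical(m$last_exon_rank, 3L)
  expect_error(find_recombinable_modules(c(0L, 1L), 4L), "inconsistent")
  ## property: agreement with independent enumeration over exon runs
  set.seed(5)
  for (rep in 1:200) {
    n_ex <- sample(1:9, 1L)
    phases <- sample(0:2, n_ex - 1L, replace = TRUE)
    for (pol in c("phase0", "excluded")) {
      got <- find_recombinable_modules(phases, n_ex, pol)
      want <- oracle_modules(phases, n_ex, pol)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste(pol, paste(phases, collapse = ",")))
    }
  }
})

test_that("an intron-rich chlorophyte-like gene yields a phase-0 module over the 5' domain unit", {
  ## phases transcribed from the intron-rich hop form: I..VI bound a
  ## complete TPR-DP-Ch.AA unit between phase-0 boundaries
  phases <- c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 2L, 0L, 0L, 2L, 0L)
  mods <- find_recombinable_modules(phases, 13L)
  expect_true(any(mods$first_exon_rank == 2L & mods$last_exon_rank == 6L &
                    mods$flanking_phase == 0L))
})

test_that("excising a symmetric phase-0 module preserves the reading frame", {
  set.seed(8)
  for (rep in 1:50) {
    g <- rnd_gene(n_exons = sample(3:8, 1L))
    introns <- assign_intron_phases(g$gene, g$genome)
    mods <- find_recombinable_modules(introns, nrow(g$gene$exons))
    mods <- mods[mods$flanking_phase == 0L, , drop = FALSE]
    cums <- c(0L, g$cuts, nchar(g$cds))
    for (r in seq_len(nrow(mods))) {
      a <- mods$first_exon_rank[r]; b <- mods$last_exon_rank[r]
      removed_len <- cums[b + 1L] - cums[a]
      expect_identical(removed_len %% 3L, 0L)
      rest <- paste0(substr(g$cds, 1L, cums[a]),
                     substr(g$cds, cums[b + 1L] + 1L, nchar(g$cds)))
      expect_identical(nchar(rest) %% 3L, 0L)
    }
  }
})

test_that("the transit-peptide intron is the phase-1 first intron", {
  expect_identical(find_transit_peptide_intron(
    data.frame(ordinal = 1:3, phase = c(1L, 0L, 0L))), 1L)
  none <- find_transit_peptide_intron(
    data.frame(ordinal = 1:2, phase = c(0L, 0L)))
  expect_true(is.na(none))
  expect_match(attr(none, "diagnostic"), "phase-0")
  expect_true(is.na(find_transit_peptide_intron(empty <- data.frame(
    ordinal = integer(), phase = integer()))))
})

test_that("a retained in-frame intron is recovered from an over-long protein", {
  set.seed(21)
  for (rep in 1:10) {
    h <- synth_hidden_intron_gene(n_aa = 300L, extra_aa = 71L,
                                  after_codon = 6L)
    cand <- propose_hidden_intron(h$gene, h$genome, h$reference_length)
    expect_identical(cand$start, h$intron$start)
    expect_identical(cand$end, h$intron$end)
    expect_identical(cand$length, 213L)
  }
  ## a gene already matching the reference length proposes nothing
  g <- rnd_gene(n_exons = 2L, n_aa = 100L)
  expect_null(propose_hidden_intron(g$gene, g$genome, 100L))
})
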