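test_that("a clean planted ORF is reported without internal stops", {
  set.seed(41)
  orf <- paste0("ATG", paste0(sample(SENSE_CODONS, 119L, TRUE), collapse = ""),
                "TAA")
  igr <- paste0(rnd_dna(60L), orf, rnd_dna(60L))
  hits <- scan_orfs(igr, min_aa = 100L)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$aa_length, 120L)
  expect_identical(hits$internal_stops, 0L)
  expect_false(hits$pseudogene_flag)
  expect_identical(hits$start, 61L)
  expect_identical(hits$end, 60L + nchar(orf))
})

test_that("an interrupted reading frame merges across its stop codons", {
  set.seed(43)
  span <- paste0("ATG", paste0(sample(SENSE_CODONS, 29L, TRUE), collapse = ""))
  for (b in 1:12) {
    span <- paste0(span, "TAA",
                   paste0(sample(SENSE_CODONS, 30L, TRUE), collapse = ""))
  }
  span <- paste0(span, "TAA")
  guard <- function() paste0("TAA", paste0(sample(SENSE_CODONS, 3L, TRUE),
                                           collapse = ""), "TAA")
  igr <- paste0(rnd_dna(51L), guard(), span, guard(), rnd_dna(51L))
  hits <- scan_orfs(igr, min_aa = 100L)
  ## the planted span is recovered with all 12 engineered stops merged
  ## (other frames may chain by chance; they are not the planted span)
  planted <- hits[hits$internal_stops == 12L, , drop = FALSE]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$aa_length, 390L)
  expect_true(planted$pseudogene_flag)
  expect_identical(planted$start, 67L) # the planted ATG: 51 flank + 15 guard
  expect_identical(planted$frame, 1L)
})

test_that("degenerate and short intergenic regions yield no ORFs", {
  expect_identical(nrow(scan_orfs(strrep("N", 600L))), 0L)
  expect_identical(nrow(scan_orfs("ATGTAA", min_aa = 50L)), 0L)
})

test_that("six-frame scanning mirrors under reverse complement", {
  set.seed(47)
  for (rep in 1:5) {
    igr <- paste0(rnd_dna(100L),
                  "ATG", paste0(sample(SENSE_CODONS, 70L, TRUE),
                                collapse = ""), "TAA",
                  rnd_dna(100L))
    fwd <- scan_orfs(igr, min_aa = 60L)
    rev <- scan_orfs(revcomp(igr), min_aa = 60L)
    L <- nchar(igr)
    mirrored <- data.frame(frame = -rev$frame,
                           start = L - rev$end + 1L, end = L - rev$start + 1L,
                           aa_length = rev$aa_length,
                           internal_stops = rev$internal_stops,
                           pseudogene_flag = rev$pseudogene_flag)
    mirrored <- mirrored[order(mirrored$start, mirrored$frame), , drop = FALSE]
    rownames(mirrored) <- NULL
    ## frame labels depend on length offsets; compare label-free content
    expect_identical(mirrored[, -1L], fwd[, -1L])
  }
})

test_that("planted terminal inverted repeats are recovered exactly", {
  set.seed(53)
  arm <- rnd_dna(12L)
  igr <- paste0(rnd_dna(100L), arm, rnd_dna(200L), revcomp(arm),
                rnd_dna(100L))
  hits <- find_inverted_repeats(igr, min_arm = 10L, max_mismatch = 0L)
  ## maximal hits may extend a base or two into matching flank by chance
  planted <- hits[hits$arm1_start <= 101L & hits$arm1_end >= 112L &
                    hits$arm2_start <= 313L & hits$arm2_end >= 324L, ,
                  drop = FALSE]
  expect_identical(nrow(planted), 1L)
  expect_gte(planted$arm_length, 12L)
  expect_identical(planted$mismatches, 0L)
  expect_lte(planted$spacer, 200L)
  ## one substitution in the second arm is tolerated at max_mismatch 1
  arm2 <- revcomp(arm)
  substr(arm2, 6L, 6L) <- setdiff(c("A", "C", "G", "T"),
                                  substr(arm2, 6L, 6L))[1L]
  igr2 <- paste0(rnd_dna(100L), arm, rnd_dna(200L), arm2, rnd_dna(100L))
  h2 <- find_inverted_repeats(igr2, min_arm = 10L, max_mismatch = 1L)
  p2 <- h2[h2$arm1_start <= 101L & h2$arm1_end >= 112L, , drop = FALSE]
  expect_gte(nrow(p2), 1L)
  expect_true(any(p2$mismatches == 1L))
  expect_error(find_inverted_repeats(igr, min_arm = 6L), ">= 8")
})

test_that("planted direct repeats are recovered and CACTA arms flagged", {
  set.seed(59)
  arm <- paste0("CACTA", rnd_dna(9L))
  igr <- paste0(rnd_dna(100L), arm, rnd_dna(60L), arm, rnd_dna(100L))
  hits <- find_direct_repeats(igr, min_arm = 10L)
  planted <- hits[hits$arm1_start == 101L, , drop = FALSE]
  expect_identical(nrow(planted), 1L)
  expect_gte(planted$arm_length, 14L)
  expect_true(planted$cacta_like)
  expect_false(any(hits$cacta_like[hits$arm1_start != 101L]))
})

test_that("both repeat finders match the brute-force oracle", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(40:70, 1L)
    seqc <- rnd_dna(n)
    if (rep %% 2L == 0L) { # plant something half the time
      arm <- rnd_dna(sample(8:12, 1L))
      at <- sample(1:10, 1L)
      piece <- if (rep %% 4L == 0L) revcomp(arm) else arm
      seqc <- paste0(substr(seqc, 1L, at), arm,
                     substr(seqc, at + 1L, at + 15L), piece,
                     substr(seqc, at + 16L, n))
    }
    for (inv in c(TRUE, FALSE)) {
      got <- if (inv) find_inverted_repeats(seqc, 8L, 1L, 40L, 30L)
             else find_direct_repeats(seqc, 8L, 1L, 40L, 30L)
      want <- oracle_repeats(seqc, 8L, 1L, 40L, 30L, inv)
      expect_identical(got[, repeat_cols], want[, repeat_cols],
                       info = paste(inv, seqc))
    }
  }
})

test_that("repeat detection is strand-consistent", {
  set.seed(67)
  for (rep in 1:10) {
    seqc <- paste0(rnd_dna(30L), rnd_dna(10L), rnd_dna(30L))
    for (inv in c(TRUE, FALSE)) {
      fwd <- oracle_repeats(seqc, 8L, 1L, 60L, 30L, inv)
      got_rc <- if (inv) find_inverted_repeats(revcomp(seqc), 8L, 1L, 60L, 30L)
                else find_direct_repeats(revcomp(seqc), 8L, 1L, 60L, 30L)
      want_rc <- oracle_repeats(revcomp(seqc), 8L, 1L, 60L, 30L, inv)
      expect_identical(got_rc[, repeat_cols], want_rc[, repeat_cols])
      ## mirror image: same number of repeats on either strand
      expect_identical(nrow(got_rc), nrow(fwd))
    }
  }
})

test_that("3' UTR overlap is detected from convergent cDNA ends", {
  cd <- function(id, start, end, strand, contig = "c1") {
    gene_model(id, contig, strand, data.frame(start = start, end = end),
               role = "other")
  }
  ## ends 1000 apart: no overlap
  r <- detect_utr_overlap(list(cd("h1", 1000L, 4000L, "+")),
                          list(cd("f1", 5000L, 8000L, "-")))
  expect_identical(r$overlap_bp, 0L)
  expect_false(r$igr_missing)
  ## hop cDNA running to 5100 past a fus cDNA ending at 5020 -> 80 bp
  r2 <- detect_utr_overlap(list(cd("h1", 1000L, 5100L, "+"),
                                cd("h2", 1000L, 4900L, "+")),
                           list(cd("f1", 5020L, 8000L, "-"),
                                cd("f2", 5500L, 8000L, "-")))
  expect_identical(r2$overlap_bp, 80L)
  expect_true(r2$igr_missing)
  expect_error(detect_utr_overlap(list(cd("h1", 1L, 10L, "+")),
                                  list(cd("f1", 1L, 10L, "-", "c2"))),
               "different contigs")
})

test_that("IGR deletions are located and sized against a shared anchor", {
  set.seed(71)
  a <- rnd_dna(1500L)
  expect_identical(compare_igr_deletion(a, a)$deleted_bp_estimate, 0L)
  expect_identical(compare_igr_deletion(a, a)$divergence_point, 1500L)
  ## 680 bp excised 123 nt downstream of the anchor start
  b <- paste0(substr(a, 1L, 123L), substr(a, 804L, 1500L))
  r <- compare_igr_deletion(a, b)
  expect_identical(r$divergence_point, 123L)
  expect_identical(r$deleted_bp_estimate, 680L)
  expect_true(attr(r, "clean"))
  ## random planted deletions recovered when flanks are unique
  for (rep in 1:25) {
    x <- rnd_dna(800L)
    at <- sample(50:300, 1L)
    dl <- sample(50:400, 1L)
    y <- paste0(substr(x, 1L, at), substr(x, at + dl + 1L, 800L))
    r2 <- compare_igr_deletion(x, y)
    expect_identical(r2$deleted_bp_estimate, dl)
    expect_lte(r2$divergence_point - at, 12L) # chance prefix extension only
  }
  expect_error(compare_igr_deletion(rnd_dna(100L), rnd_dna(100L)),
               "not comparable")
})
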