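test_that("the builtin fixture table encodes the study conditions", {
  tab <- builtin_fixture_table()
  expect_identical(nrow(tab), 53L)
  expect_identical(anyDuplicated(tab$species), 0L)
  expect_identical(sum(tab$syntenic), 40L)
  expect_identical(sum(tab$colinearity_category == "III"), 38L)
  expect_identical(sum(tab$colinearity_category == "II"), 2L)
  expect_identical(sum(tab$hop_introns == 6L), 46L)
  ## count consistency and the universal transit-peptide intron
  for (i in seq_len(nrow(tab))) {
    expect_identical(length(phases_vec(tab$hop_phases[i])),
                     tab$hop_introns[i])
    fp <- phases_vec(tab$fus_phases[i])
    expect_identical(length(fp), tab$fus_introns[i])
    expect_identical(fp[1L], 1L)
  }
  expect_identical(tab$igr_length[tab$species == "Leavenworthia_alabamica"],
                   188L)
  expect_identical(tab$igr_length[tab$species == "Linum_usitatissimum"],
                   38523L)
  expect_true(all(is.na(tab$igr_length[!tab$syntenic])))
})

test_that("generated genes re-analyze to their specification", {
  set.seed(201)
  cfg <- generator_config(seed = 201)
  tab <- builtin_fixture_table()
  picks <- c("Chlamydomonas_reinhardtii", "Micromonas_sp_RCC299",
             "Gossypium_raimondii", "Brassica_rapa", "Glycine_max")
  for (sp in picks) {
    g <- generate_genome(tab[tab$species == sp, ], cfg)
    genome <- Biostrings::DNAStringSet(g$contigs)
    ih <- assign_intron_phases(g$genes$hop, genome)
    iff <- assign_intron_phases(g$genes$fus, genome)
    expect_identical(ih$phase, g$truth$hop_phases, info = sp)
    expect_identical(iff$phase, g$truth$fus_phases, info = sp)
    pair <- classify_pair(g$genes$hop, g$genes$fus)
    expect_identical(pair$orientation, g$truth$orientation, info = sp)
    expect_identical(pair$colinearity_category,
                     g$truth$colinearity_category, info = sp)
    ## generated proteins match the translated gene models
    expect_identical(unname(g$proteins[g$truth$hop_id]),
                     translate_cds(spliced_cds(g$genes$hop, genome)))
    ## canonical splice sites throughout under the default dialect
    expect_true(all(validate_splice_sites(ih)$splice_verdict == "canonical"))
  }
})

test_that("non-syntenic specifications emit two contigs", {
  cfg <- generator_config(seed = 7)
  tab <- builtin_fixture_table()
  set.seed(7)
  g <- generate_genome(tab[tab$species == "Ensete_ventricosum", ], cfg)
  expect_length(g$contigs, 2L)
  set.seed(7)
  g2 <- generate_genome(tab[tab$species == "Vitis_vinifera", ], cfg)
  expect_length(g2$contigs, 1L)
})

test_that("specified intergenic lengths and inserts are realized", {
  cfg <- generator_config(seed = 11)
  tab <- builtin_fixture_table()
  set.seed(11)
  g <- generate_genome(tab[tab$species == "Leavenworthia_alabamica", ], cfg)
  genome <- Biostrings::DNAStringSet(g$contigs)
  pair <- classify_pair(g$genes$hop, g$genes$fus)
  expect_identical(pair$igr_length, 188L)
  expect_identical(nchar(extract_igr(pair, genome)), 188L)
  ## the motif planted three-fold in this species' Hop
  expect_identical(count_tandem_motif(unname(g$proteins[g$truth$hop_id]),
                                      "VPEVEKKLEPEPEP"), 3L)
  set.seed(11)
  g2 <- generate_genome(tab[tab$species == "Glycine_max", ], cfg)
  expect_identical(count_tandem_motif(unname(g2$proteins[paste0(
    "Glycine_max_hop")]), "VPEVEKKLEPEPEP"), 1L)
  ## MITE-like arms planted in the Oryza intergenic region are found again
  set.seed(11)
  g3 <- generate_genome(tab[tab$species == "Oryza_sativa", ], cfg)
  genome3 <- Biostrings::DNAStringSet(g3$contigs)
  igr <- extract_igr(classify_pair(g3$genes$hop, g3$genes$fus), genome3)
  tirs <- find_inverted_repeats(igr, min_arm = 10L, max_mismatch = 0L)
  expect_true(any(tirs$arm1_start == 101L & tirs$arm_length >= 14L))
  expect_identical(nrow(g3$features), 1L)
  ## CACTA-like direct repeat planted in the Medicago intergenic region
  set.seed(11)
  g4 <- generate_genome(tab[tab$species == "Medicago_truncatula", ], cfg)
  genome4 <- Biostrings::DNAStringSet(g4$contigs)
  igr4 <- extract_igr(classify_pair(g4$genes$hop, g4$genes$fus), genome4)
  dr <- find_direct_repeats(igr4, min_arm = 10L, max_mismatch = 0L)
  expect_true(any(dr$cacta_like & dr$arm1_start == 201L))
})

test_that("fixture generation is byte-deterministic under a fixed seed", {
  tab <- builtin_fixture_table()[c(1, 28, 41), ]
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  generate_fixture(d1, tab, generator_config(seed = 42))
  generate_fixture(d2, tab, generator_config(seed = 42))
  for (f in c("genome.fa", "genes.gff3", "proteins.faa", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  ## and a different seed changes the sequence
  d3 <- tempfile("det3")
  generate_fixture(d3, tab, generator_config(seed = 43))
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("fixture files round-trip losslessly through the readers", {
  tab <- builtin_fixture_table()[c(5, 36, 45), ]
  d <- tempfile("rt")
  fx <- generate_fixture(d, tab, generator_config(seed = 13))
  genome <- read_genome(fx$genome)
  genes <- read_gene_models(fx$gff3, genome)
  expect_length(genes, 6L)
  ## coordinate round trip: write -> read -> write is identity
  gff2 <- tempfile(fileext = ".gff3")
  write_gene_models(genes, gff2,
                    extra_features = read_annotation_features(fx$gff3))
  expect_identical(readLines(gff2), readLines(fx$gff3))
  ## genome write -> read round trip
  fa2 <- tempfile(fileext = ".fa")
  write_genome(genome, fa2)
  expect_identical(as.character(read_genome(fa2)), as.character(genome))
})

test_that("the GC-donor dialect produces gc_donor verdicts when requested", {
  d <- tempfile("gc")
  generate_random_pairs(d, 6L,
                        generator_config(seed = 5,
                                         splice_dialect = "allow_gc_donor"))
  a <- analyze_fixture(d)
  verdicts <- validate_splice_sites(a$introns)$splice_verdict
  expect_true(any(verdicts == "gc_donor"))
  expect_true(all(verdicts %in% c("canonical", "gc_donor")))
})

test_that("random gene pairs are recovered from their manifest", {
  d <- tempfile("rp")
  fx <- generate_random_pairs(d, 12L, generator_config(seed = 31))
  a <- analyze_fixture(d)
  man <- fx$manifest_data
  expect_identical(nrow(a$pairs), 12L)
  for (sp in names(man)) {
    p <- a$pairs[a$pairs$species == sp, ]
    cl <- a$classes[a$classes$species == sp, ]
    expect_identical(p$orientation, man[[sp]]$orientation, info = sp)
    expect_identical(p$colinearity_category,
                     man[[sp]]$colinearity_category, info = sp)
    expect_identical(phases_vec(cl$hop_phases),
                     as.integer(man[[sp]]$hop_phases), info = sp)
    expect_identical(phases_vec(cl$fus_phases),
                     as.integer(man[[sp]]$fus_phases), info = sp)
  }
})
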