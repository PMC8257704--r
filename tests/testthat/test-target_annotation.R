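m133 <- mature_mirna("mmu-miR-133a-3p", MIR133A)

test_that("find_target_sites types canonical loci against the hand oracle", {
  # 7mer-m8: rc(seed 2-8) = GGACCAA at [3,10)
  s <- find_target_sites(nucleotide_sequence("CUAGGACCAACUA", "g1"), m133)
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 3L)
  expect_identical(s$end, 10L)
  expect_identical(s$site_type, "7mer-m8")
  expect_identical(s$site_seq, "GGACCAA")

  # appending an A opposite miRNA position 1 upgrades the locus to 8mer
  s8 <- find_target_sites(nucleotide_sequence("CUAGGACCAAACUA", "g1"), m133)
  expect_identical(nrow(s8), 1L)
  expect_identical(s8$site_type, "8mer")
  expect_identical(c(s8$start, s8$end), c(3L, 11L))

  # no seed complement at all
  expect_identical(
    nrow(find_target_sites(nucleotide_sequence("AGUCUUAAGUCUUA", "g1"), m133)),
    0L)
})

test_that("weaker site types are reported only when min_site_type admits them", {
  # anchor GACCAA without the m8 G and without a 3' A -> 6mer only
  u6 <- nucleotide_sequence("CUAGACCAACUA", "g6")
  expect_identical(nrow(find_target_sites(u6, m133)), 0L)  # default 7mer-m8
  s6 <- find_target_sites(u6, m133, min_site_type = "6mer")
  expect_identical(s6$site_type, "6mer")
  expect_identical(c(s6$start, s6$end), c(3L, 9L))

  # anchor + 3' A, no m8 base -> 7mer-A1
  u7 <- nucleotide_sequence("CUAGACCAAACUA", "g7")
  s7 <- find_target_sites(u7, m133, min_site_type = "7mer-A1")
  expect_identical(s7$site_type, "7mer-A1")
  expect_identical(c(s7$start, s7$end), c(3L, 10L))
  expect_identical(nrow(find_target_sites(u7, m133)), 0L)

  # raising the floor filters monotonically
  u <- nucleotide_sequence("CUAGGACCAAACUAGACCAAC", "gm")
  n_by_floor <- vapply(c("6mer", "7mer-A1", "7mer-m8", "8mer"),
                       function(t) nrow(find_target_sites(u, m133,
                                                          min_site_type = t)),
                       integer(1))
  expect_true(all(diff(n_by_floor) <= 0))
})

test_that("annotate_genes applies the conjunction rule under both overlap modes", {
  utr_site <- "CUAGGACCAACUA"           # site [3,10) contains GGACC
  ann <- annotate_genes(c(gA = utr_site), m133, m6a_gene_set = "gA")
  expect_true(ann$is_target & ann$m6a_in_gene_set & ann$ggach_in_utr)
  expect_true(ann$m6a_modified_target)
  expect_true(ann$motif_overlaps_site)
  ann_strict <- annotate_genes(c(gA = utr_site), m133, "gA",
                               strict_site_overlap = TRUE)
  expect_true(ann_strict$m6a_modified_target)

  # same gene not in the m6A set: conjunction fails
  ann2 <- annotate_genes(c(gA = utr_site), m133, m6a_gene_set = character(0))
  expect_false(ann2$m6a_modified_target)
})

test_that("strict site overlap separates distal motifs from in-site motifs", {
  # a miRNA whose site text contains no GGACH, with a distal planted motif
  mir <- clean_site_mirna()
  utr <- paste0("CUA", "AAUCGAU", "CUACGUACUA", "GGACA", "CGUAC")
  ann_def <- annotate_genes(c(gB = utr), mir, "gB")
  ann_str <- annotate_genes(c(gB = utr), mir, "gB",
                            strict_site_overlap = TRUE)
  expect_true(ann_def$is_target & ann_def$ggach_in_utr)
  expect_false(ann_def$motif_overlaps_site)
  expect_true(ann_def$m6a_modified_target)    # default rule
  expect_false(ann_str$m6a_modified_target)   # strict rule
  # strict classification is a subset of the default classification
  expect_true(all(!ann_str$m6a_modified_target | ann_def$m6a_modified_target))
})

test_that("duplicate gene ids are rejected; absent m6A ids only message", {
  u <- list(nucleotide_sequence("ACGUACGUA", "g1"),
            nucleotide_sequence("ACGUACGUA", "g1"))
  expect_error(annotate_genes(u, m133, character(0)), "duplicate")
  expect_message(
    annotate_genes(c(g1 = "ACGUACGUA"), m133, c("g1", "ghost")),
    "absent")
})

test_that("planted synthetic genomes are classified back exactly", {
  cfg <- sim_config(rng_seed = 5, n_genes = 120, utr_length_mean = 120)
  cat_out <- gen_mirna_catalogue(cfg)
  mirna <- cat_out$mirnas[[which(cat_out$truth$match_class == "FULL")[1]]]
  g <- gen_utr_genome(cfg, mirna)
  ann <- annotate_genes(g$utrs, mirna, g$m6a_genes)
  expect_identical(ann$is_target, g$truth$is_target)
  expect_identical(ann$m6a_in_gene_set, g$truth$m6a_in_gene_set)
  expect_identical(ann$ggach_in_utr, g$truth$ggach_in_utr)
  expect_identical(ann$m6a_modified_target, g$truth$m6a_modified_target)
  # the GGACH-in-UTR count filter is exact against the planted count
  expect_identical(sum(ann$ggach_in_utr), sum(g$truth$ggach_in_utr))
  # strict mode: planted motifs of targets lie inside sites (GGACH-class
  # miRNA), so the strict classification matches the default one
  ann_str <- annotate_genes(g$utrs, mirna, g$m6a_genes,
                            strict_site_overlap = TRUE)
  expect_identical(ann_str$m6a_modified_target, ann$m6a_modified_target)
})
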