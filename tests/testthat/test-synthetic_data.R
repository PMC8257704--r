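test_that("sim_config validates its parameter space", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_target = 1.2), "probabilities")
  expect_error(sim_config(n_mirnas = 5, n_full_match = 4, n_partial_match = 3),
               "exceed")
  expect_error(sim_config(score_sd = 0), "score_sd")
  expect_error(sim_config(n_stages = 1), "n_stages")
})

test_that("planted catalogue classes are recovered exactly and reproducibly", {
  cfg <- sim_config(rng_seed = 7, n_mirnas = 40, n_full_match = 3,
                    n_partial_match = 5)
  out <- gen_mirna_catalogue(cfg)
  scr <- screen_catalogue(out$mirnas)
  expect_identical(as.character(scr$match_class), out$truth$match_class)
  cnt <- attr(scr, "counts")
  expect_identical(unname(cnt[c("n_full", "n_partial", "n_none")]),
                   c(3L, 5L, 32L))
  # clean catalogue
  clean <- gen_mirna_catalogue(sim_config(rng_seed = 3, n_mirnas = 15,
                                          n_full_match = 0,
                                          n_partial_match = 0))
  expect_true(all(screen_catalogue(clean$mirnas)$match_class == "NONE"))
  # determinism: same cfg, same seed -> identical sequences
  again <- gen_mirna_catalogue(cfg)
  expect_identical(
    vapply(out$mirnas, function(m) m$sequence$residues, character(1)),
    vapply(again$mirnas, function(m) m$sequence$residues, character(1)))
})

test_that("genome planting respects the conditional m6A probabilities", {
  mirna <- gen_mirna_catalogue(sim_config(rng_seed = 2, n_mirnas = 3,
                                          n_full_match = 1,
                                          n_partial_match = 0))
  full <- mirna$mirnas[[which(mirna$truth$match_class == "FULL")]]
  g0 <- gen_utr_genome(sim_config(rng_seed = 2, n_genes = 60,
                                  utr_length_mean = 100,
                                  p_m6a_given_target = 0,
                                  p_m6a_given_nontarget = 0), full)
  expect_identical(sum(g0$truth$m6a_modified_target), 0L)
  expect_identical(length(g0$m6a_genes), 0L)
  # peaks cover planted motif intervals of listed genes only
  g1 <- gen_utr_genome(sim_config(rng_seed = 4, n_genes = 50,
                                  utr_length_mean = 100), full)
  expect_true(all(g1$peaks$gene_id %in% g1$m6a_genes))
  expect_true(all(g1$peaks$end - g1$peaks$start == 5L))
})

test_that("score generation is seeded and shifts the modified stratum", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:400),
                      is_target = TRUE,
                      m6a_modified_target = rep(c(TRUE, FALSE), each = 200))
  cfg <- sim_config(rng_seed = 9, score_delta_m6a = 1, score_sd = 1)
  s1 <- gen_scores(cfg, truth)
  s2 <- gen_scores(cfg, truth)
  expect_identical(s1, s2)
  expect_gt(mean(s1$score[1:200]), mean(s1$score[201:400]))
  cmp <- compare_scores(s1$score[1:200], s1$score[201:400])
  expect_lt(cmp$p_two_sided, 1e-6)
})

test_that("timecourse planting interacts with the fold-change threshold", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:300),
                      is_target = rep(c(TRUE, FALSE), c(200, 100)),
                      m6a_modified_target = rep(c(TRUE, FALSE, FALSE),
                                                each = 100))
  cfg <- sim_config(rng_seed = 6, fold_change_magnitude = 4)
  tc <- gen_timecourse(cfg, truth)
  calls <- call_regulation(tc$matrix, "P23", fc_threshold = 1.5)
  expect_identical(as.character(calls$call), tc$truth$regulation)
  # magnitude below the caller's threshold: everything reads UNCHANGED
  tc_low <- gen_timecourse(sim_config(rng_seed = 6,
                                      fold_change_magnitude = 1.1,
                                      unchanged_jitter = 1.05), truth)
  calls_low <- call_regulation(tc_low$matrix, "P23", fc_threshold = 1.5)
  expect_true(all(calls_low$call == "UNCHANGED"))
  # f_down = 1 in both strata exercises the infinite-ratio branch
  tc_all <- gen_timecourse(sim_config(rng_seed = 6, f_down_m6a = 1,
                                      f_down_non_m6a = 1), truth)
  calls_all <- call_regulation(tc_all$matrix, "P23")
  s <- summarize_ratios(calls_all[truth$is_target, ])
  expect_true(s$ratio_infinite)
})

test_that("simulate_all writes a byte-stable, self-consistent input set", {
  cfg <- sim_config(rng_seed = 11, n_genes = 40, utr_length_mean = 80,
                    n_mirnas = 12, n_full_match = 1, n_partial_match = 2)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  sim1 <- simulate_all(cfg, d1)
  simulate_all(cfg, d2)
  for (f in c("mirnas.fasta", "utrs.fasta", "m6a_genes.tsv", "m6a_peaks.bed",
              "scores.tsv", "matrix.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # emitted files re-derive the planted flags exactly
  utrs <- read_fasta(sim1$paths$utrs)
  m6a <- read_tsv(sim1$paths$m6a_genes)$gene_id
  ann <- annotate_genes(utrs, sim1$screen_mirna, m6a)
  expect_identical(ann$m6a_modified_target,
                   sim1$genome$truth$m6a_modified_target)
})
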