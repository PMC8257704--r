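.toy_matrix <- function(vals, stages = c("P1", "P23")) {
  m <- matrix(vals, ncol = length(stages),
              dimnames = list(sprintf("g%02d", seq_len(length(vals) %/%
                                                         length(stages))),
                              stages))
  stage_matrix(m, reference_stage = stages[1])
}

test_that("stage matrices validate labels, finiteness and the reference", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("P1", "P23")))
  expect_s3_class(stage_matrix(m, "P1"), "stage_matrix")
  expect_error(stage_matrix(m, "P99"), "reference")
  expect_error(stage_matrix(unname(m), "P1"), "names")
  m2 <- m; m2[1] <- -1
  expect_error(stage_matrix(m2, "P1"), "non-negative")
  expect_error(stage_matrix(matrix(1:4, 2,
                                   dimnames = list(c("a", "a"),
                                                   c("P1", "P23"))), "P1"),
               "duplicate")
})

test_that("regulation calls follow the symmetric log2 threshold", {
  sm <- .toy_matrix(c(10, 10, 8, 5, 10, 8))  # refs 10,10,8; cmps 5,10,8
  calls <- call_regulation(sm, "P23", fc_threshold = 1.5)
  expect_equal(calls$log2_ratio, c(-1, 0, 0))
  expect_identical(as.character(calls$call), c("DOWN", "UNCHANGED", "UNCHANGED"))
  # sign-only calling: no UNCHANGED except exact ties
  calls1 <- call_regulation(sm, "P23", fc_threshold = 1)
  expect_identical(as.character(calls1$call), c("DOWN", "UNCHANGED", "UNCHANGED"))
  set.seed(51)
  rnd <- .toy_matrix(exp(rnorm(40)))
  c_rnd <- call_regulation(rnd, "P23", fc_threshold = 1)
  ties <- rnd$values[, 1] == rnd$values[, 2]
  expect_identical(c_rnd$call == "UNCHANGED", unname(ties))
  expect_error(call_regulation(sm, "P1"), "differ")
  expect_error(call_regulation(sm, "nope"), "stage")
})

test_that("zero reference abundance is flagged, not propagated", {
  sm <- .toy_matrix(c(0, 10, 5, 5))
  expect_message(calls <- call_regulation(sm, "P23"), "zero reference")
  expect_false(calls$computable[1])
  expect_true(is.na(calls$call[1]))
  # a pseudocount restores computability
  calls_pc <- call_regulation(sm, "P23", pseudocount = 1)
  expect_true(all(calls_pc$computable))
  # counts are conserved
  s <- summarize_ratios(calls)
  expect_identical(s$n_down + s$n_up + s$n_unchanged + s$n_not_computable,
                   nrow(calls))
})

test_that("raising the fold-change threshold weakly shrinks both call sets", {
  set.seed(52)
  sm <- .toy_matrix(exp(rnorm(200)))
  thresholds <- c(1, 1.2, 1.5, 2, 3)
  n_down <- n_up <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    s <- summarize_ratios(call_regulation(sm, "P23",
                                          fc_threshold = thresholds[i]))
    n_down[i] <- s$n_down; n_up[i] <- s$n_up
  }
  expect_true(all(diff(n_down) <= 0))
  expect_true(all(diff(n_up) <= 0))
})

.calls_from_counts <- function(n_down, n_up, prefix = "g") {
  n <- n_down + n_up
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             log2_ratio = rep(c(-2, 2), c(n_down, n_up)),
             call = factor(rep(c("DOWN", "UP"), c(n_down, n_up)),
                           levels = c("DOWN", "UP", "UNCHANGED")),
             computable = TRUE, stringsAsFactors = FALSE)
}

test_that("ratio summaries and fold differences follow the count arithmetic", {
  a <- .calls_from_counts(25, 4, "a")
  b <- .calls_from_counts(8, 4, "b")
  cmp <- summarize_ratios(a, b)
  expect_equal(cmp$set_a$down_up_ratio, 6.25)
  expect_equal(cmp$set_b$down_up_ratio, 2)
  expect_equal(cmp$fold_difference, 3.125)
  # identical call lists give fold 1
  expect_equal(summarize_ratios(a, a)$fold_difference, 1)
  # an all-down set flags the ratio infinite and the fold not computable
  inf <- summarize_ratios(.calls_from_counts(5, 0), b)
  expect_true(inf$set_a$ratio_infinite)
  expect_false(inf$fold_computable)
  expect_true(is.na(inf$fold_difference))
})

test_that("stratified percentages use down/(down+up) at 2 decimals", {
  a <- .calls_from_counts(25, 4, "m")          # the m6A stratum
  b <- .calls_from_counts(10, 10, "u")         # the unmodified stratum
  calls <- rbind(a, b)
  status <- setNames(c(rep(TRUE, 29), rep(FALSE, 20)), calls$gene_id)
  s <- summarize_ratios(calls, m6a_status = status)
  expect_equal(s$stratified$m6a$pct_down, 86.21)    # 25/29 rendered half-up
  expect_equal(s$stratified$non_m6a$pct_down, 50)
  expect_equal(s$stratified$m6a$pct_up, 13.79)
  # UNCHANGED genes do not enter the two-category percentage
  un <- data.frame(gene_id = "z001", log2_ratio = 0,
                   call = factor("UNCHANGED",
                                 levels = c("DOWN", "UP", "UNCHANGED")),
                   computable = TRUE, stringsAsFactors = FALSE)
  s2 <- summarize_ratios(rbind(calls, un),
                         m6a_status = c(status, z001 = TRUE))
  expect_equal(s2$stratified$m6a$pct_down, 86.21)
})
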