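# Stage 3: gene-set overlap (Venn) summaries and two-group comparison
# of enrichment scores between m6A-modified and unmodified targets.

#' Round half-up at a fixed number of decimals
#'
#' Percentages are rendered half-up at 2 decimals (the convention of
#' the figures this pipeline reproduces); base `round()` rounds half to
#' even and is not used for rendering.
#' @param x numeric; @param digits integer.
#' @keywords internal
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Gene-set overlap summary
#'
#' Exact counts of two gene sets and their intersection, plus the
#' directional percentage of `set_a` members that fall in `set_b`,
#' rendered half-up at 2 decimals.
#'
#' @param set_a,set_b Character vectors of gene ids (de-duplicated
#'   internally).  `set_a` must be non-empty: it is the percentage
#'   denominator.
#' @param a_name,b_name Display names.
#' @return Object of class `overlap_summary`: list with `n_a`, `n_b`,
#'   `n_intersection`, `pct_a_in_b` (2-decimal rendering) and
#'   `pct_exact`.
#' @examples
#' overlap(paste0("g", 1:894), paste0("g", 1:270))$pct_a_in_b  # 30.20
#' @export
overlap <- function(set_a, set_b, a_name = "set_a", b_name = "set_b") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a))
    stop("`set_a` is empty: overlap percentage is undefined", call. = FALSE)
  n_int <- length(intersect(set_a, set_b))
  pct <- 100 * n_int / length(set_a)
  structure(list(set_a_name = a_name, set_b_name = b_name,
                 n_a = length(set_a), n_b = length(set_b),
                 n_intersection = n_int,
                 pct_a_in_b = round_half_up(pct, 2L),
                 pct_exact = pct),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap: |%s| = %d, |%s| = %d, intersection = %d (%.2f%% of %s)\n",
              x$set_a_name, x$n_a, x$set_b_name, x$n_b,
              x$n_intersection, x$pct_a_in_b, x$set_a_name))
  invisible(x)
}

#' Two-sample comparison of enrichment scores
#'
#' Unpaired two-tailed two-sample t test.  The default is the classical
#' pooled-variance Student test (df = n1 + n2 - 2); `variant =
#' "welch"` uses the Welch-Satterthwaite correction, appropriate when
#' the strata are heteroscedastic.  The degenerate all-identical case
#' (zero variance in both groups, equal means) is defined as t = 0,
#' p = 1; zero variance in both groups with *different* means yields an
#' infinite t and p = 0.
#'
#' @param scores_group1,scores_group2 Numeric vectors, each of length
#'   >= 2, finite.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return Object of class `group_comparison`: list with `n1`, `n2`,
#'   `mean1`, `mean2`, `t_stat`, `df`, `p_two_sided`, `variant`.  The
#'   sign of `t_stat` follows `mean1 - mean2`.
#' @examples
#' compare_scores(c(2.1, 2.9, 3.0, 2.5), c(1.0, 1.4, 1.2, 0.9))
#' @export
compare_scores <- function(scores_group1, scores_group2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(scores_group1); y <- as.numeric(scores_group2)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs n >= 2 scores", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("scores must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (m1 == m2) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m1 - m2) * Inf; p <- 0
    }
    df <- n1 + n2 - 2
  } else {
    fit <- stats::t.test(x, y, var.equal = (variant == "pooled"),
                         alternative = "two.sided")
    t_stat <- unname(fit$statistic)
    df <- unname(fit$parameter)
    p <- fit$p.value
  }
  structure(list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                 t_stat = t_stat, df = df, p_two_sided = p,
                 variant = variant),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-sample t test (%s): n = %d vs %d, means %.4g vs %.4g\n  t = %.4g, df = %.4g, two-sided p = %.4g\n",
    x$variant, x$n1, x$n2, x$mean1, x$mean2, x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Overlap and score comparison stratified by m6A status
#'
#' The composite per-miRNA report: the Venn-style overlap of the
#' miRNA's target genes with the m6A-modified gene universe, and the
#' two-group comparison of enrichment scores between m6A-modified and
#' unmodified targets.  Genes without a score are excluded from the
#' comparison (but not from the overlap); if either stratum retains
#' fewer than 2 scored genes the comparison is flagged not-computable
#' rather than an error.
#'
#' @param annotations A `gene_annotation` data.frame (from
#'   [annotate_genes()]).
#' @param scores Named numeric vector of per-gene enrichment scores
#'   (possibly partial).  Names not present in `annotations` are
#'   ignored with a message.
#' @param variant t-test variant, see [compare_scores()].
#' @return Object of class `overlap_report`: list with elements
#'   `overlap` (an `overlap_summary`: targets vs m6A-modified genes),
#'   `comparison` (a `group_comparison` or `NULL`),
#'   `comparison_computable`, `table` (per-gene data.frame) and
#'   `n_unscored_targets`.
#' @export
stratified_overlap_report <- function(annotations, scores,
                                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(annotations))
  scores <- unlist(scores)
  if (is.null(names(scores)) && length(scores))
    stop("`scores` must be named by gene_id", call. = FALSE)
  extra <- setdiff(names(scores), annotations$gene_id)
  if (length(extra))
    message(length(extra), " scored gene(s) absent from annotations; ignored")

  targets <- annotations$gene_id[annotations$is_target]
  if (!length(targets))
    stop("no target genes in the annotation table", call. = FALSE)
  m6a_genes <- annotations$gene_id[annotations$m6a_in_gene_set &
                                   annotations$ggach_in_utr]
  ov <- overlap(targets, m6a_genes,
                a_name = paste0(attr(annotations, "mirna") %||% "miRNA",
                                " targets"),
                b_name = "m6A-modified genes")

  tab <- annotations[annotations$is_target,
                     c("gene_id", "m6a_modified_target"), drop = FALSE]
  tab$score <- unname(scores[tab$gene_id])
  s_mod <- tab$score[tab$m6a_modified_target & !is.na(tab$score)]
  s_unmod <- tab$score[!tab$m6a_modified_target & !is.na(tab$score)]
  computable <- length(s_mod) >= 2L && length(s_unmod) >= 2L
  cmp <- if (computable) compare_scores(s_mod, s_unmod, variant = variant)
         else NULL
  structure(list(overlap = ov, comparison = cmp,
                 comparison_computable = computable,
                 table = tab,
                 n_unscored_targets = sum(is.na(tab$score))),
            class = "overlap_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.overlap_report <- function(x, ...) {
  print(x$overlap)
  if (x$comparison_computable) {
    cat("Enrichment scores, m6A-modified vs unmodified targets:\n")
    print(x$comparison)
  } else {
    cat("Score comparison not computable (a stratum has < 2 scored genes)\n")
  }
  if (x$n_unscored_targets)
    cat(sprintf("  (%d target gene(s) without a score excluded from the comparison)\n",
                x$n_unscored_targets))
  invisible(x)
}
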