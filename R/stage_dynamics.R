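# Stage 4: classify target genes as down-/up-regulated between two
# stages, compute down:up ratios per target set, and stratify the
# down-regulated fraction by m6A status.

#' Construct a gene x stage abundance matrix
#'
#' @param values Numeric matrix, genes in rows, stages in columns, with
#'   full dimnames.  All values must be finite and >= 0.
#' @param reference_stage Column label of the reference stage (e.g.
#'   `"P1"` for a developmental series, `"Sham"` for a surgery model).
#' @return Object of class `stage_matrix`: list with `values`,
#'   `gene_ids`, `stage_labels`, `reference_stage`.
#' @export
stage_matrix <- function(values, reference_stage) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene row names and stage column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene labels", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate stage labels", call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  if (!reference_stage %in% colnames(values))
    stop(sprintf("reference stage '%s' not among stage labels",
                 reference_stage), call. = FALSE)
  structure(list(values = values,
                 gene_ids = rownames(values),
                 stage_labels = colnames(values),
                 reference_stage = reference_stage),
            class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat(sprintf("<stage_matrix> %d genes x %d stages (%s), reference %s\n",
              length(x$gene_ids), length(x$stage_labels),
              paste(x$stage_labels, collapse = ", "), x$reference_stage))
  invisible(x)
}

#' Call per-gene regulation between two stages
#'
#' Computes `log2((v_cmp + pseudocount) / (v_ref + pseudocount))` per
#' gene and applies a symmetric fold-change threshold: `DOWN` when the
#' log-ratio is <= -log2(fc_threshold), `UP` when >= +log2(fc_threshold),
#' else `UNCHANGED`.  With `fc_threshold = 1` the call is sign-only and
#' exact ties (log-ratio 0) are `UNCHANGED`.  A gene with zero
#' reference abundance and zero pseudocount has no defined ratio; it is
#' flagged not-computable and excluded from downstream counts.
#'
#' @param matrix A `stage_matrix`.
#' @param comparison_stage Stage label, distinct from the reference.
#' @param fc_threshold Linear fold-change threshold >= 1 (default 1.5).
#' @param pseudocount Non-negative offset added to both stages
#'   (default 0).
#' @return data.frame of class `regulation_calls` with columns
#'   `gene_id`, `log2_ratio`, `call` (factor DOWN/UP/UNCHANGED, `NA`
#'   when not computable) and `computable`.
#' @examples
#' m <- stage_matrix(matrix(c(10, 10, 5, 10), 2,
#'                   dimnames = list(c("g1", "g2"), c("P1", "P23"))), "P1")
#' call_regulation(m, "P23", fc_threshold = 1.5)
#' @export
call_regulation <- function(matrix, comparison_stage, fc_threshold = 1.5,
                            pseudocount = 0) {
  stopifnot(inherits(matrix, "stage_matrix"))
  if (!comparison_stage %in% matrix$stage_labels)
    stop(sprintf("comparison stage '%s' not among stage labels",
                 comparison_stage), call. = FALSE)
  if (comparison_stage == matrix$reference_stage)
    stop("comparison stage must differ from the reference stage",
         call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)

  v_ref <- matrix$values[, matrix$reference_stage] + pseudocount
  v_cmp <- matrix$values[, comparison_stage] + pseudocount
  computable <- v_ref > 0
  if (any(!computable))
    message(sum(!computable),
            " gene(s) with zero reference abundance and zero pseudocount",
            " excluded from regulation calls")
  lr <- ifelse(computable, log2(v_cmp / v_ref), NA_real_)
  t <- log2(fc_threshold)
  call <- rep(NA_character_, length(lr))
  idx <- which(computable)
  if (t == 0) {
    call[idx] <- ifelse(lr[idx] < 0, "DOWN",
                        ifelse(lr[idx] > 0, "UP", "UNCHANGED"))
  } else {
    call[idx] <- ifelse(lr[idx] <= -t, "DOWN",
                        ifelse(lr[idx] >= t, "UP", "UNCHANGED"))
  }
  out <- data.frame(gene_id = matrix$gene_ids, log2_ratio = lr,
                    call = factor(call, levels = c("DOWN", "UP", "UNCHANGED")),
                    computable = computable,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparison_stage") <- comparison_stage
  attr(out, "reference_stage") <- matrix$reference_stage
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("regulation_calls", "data.frame")
  out
}

.one_ratio_summary <- function(calls, m6a_status = NULL) {
  cc <- calls[calls$computable, , drop = FALSE]
  n_down <- sum(cc$call == "DOWN")
  n_up <- sum(cc$call == "UP")
  n_unchanged <- sum(cc$call == "UNCHANGED")
  ratio <- if (n_up == 0) Inf else n_down / n_up
  strat <- NULL
  if (!is.null(m6a_status)) {
    st <- as.logical(m6a_status[cc$gene_id])
    strat <- lapply(c(m6a = TRUE, non_m6a = FALSE), function(flag) {
      sub <- cc[!is.na(st) & st == flag, , drop = FALSE]
      d <- sum(sub$call == "DOWN"); u <- sum(sub$call == "UP")
      list(n_down = d, n_up = u,
           pct_down = if (d + u > 0) round_half_up(100 * d / (d + u), 2L)
                      else NA_real_,
           pct_up = if (d + u > 0) round_half_up(100 * u / (d + u), 2L)
                    else NA_real_)
    })
  }
  structure(list(n_down = n_down, n_up = n_up, n_unchanged = n_unchanged,
                 n_not_computable = sum(!calls$computable),
                 down_up_ratio = ratio, ratio_infinite = n_up == 0,
                 stratified = strat),
            class = "ratio_summary")
}

#' Summarize down:up regulation ratios, optionally for two target sets
#'
#' For each call list: counts of DOWN/UP/UNCHANGED genes, the down:up
#' ratio (flagged infinite when no gene is up-regulated), and — when an
#' m6A status map is given — the percentage of down- (and up-)
#' regulated genes within each m6A stratum, computed over DOWN + UP
#' only (UNCHANGED genes are excluded from the two-category
#' percentage).  When a second call list is supplied the ratio of the
#' two down:up ratios (set A over set B) is reported as
#' `fold_difference`; it is not computable when either ratio is
#' infinite.
#'
#' @param calls_set_a Regulation calls for target set A (e.g. the
#'   miR-133a targets), from [call_regulation()].
#' @param calls_set_b Optional calls for a comparison set (e.g. the
#'   miR-499 targets).
#' @param m6a_status Optional named logical vector
#'   (gene_id -> m6A-modified flag) used for stratification.
#' @return A `ratio_summary` when `calls_set_b` is `NULL`; otherwise a
#'   `ratio_comparison`: list with `set_a`, `set_b`, `fold_difference`
#'   and `fold_computable`.
#' @examples
#' # 25 down / 4 up in one stratum renders pct_down 86.21
#' @export
summarize_ratios <- function(calls_set_a, calls_set_b = NULL,
                             m6a_status = NULL) {
  stopifnot(is.data.frame(calls_set_a), nrow(calls_set_a) > 0)
  a <- .one_ratio_summary(calls_set_a, m6a_status)
  if (is.null(calls_set_b)) return(a)
  stopifnot(is.data.frame(calls_set_b), nrow(calls_set_b) > 0)
  b <- .one_ratio_summary(calls_set_b, m6a_status)
  computable <- !a$ratio_infinite && !b$ratio_infinite && b$down_up_ratio > 0
  structure(list(set_a = a, set_b = b,
                 fold_difference = if (computable)
                   a$down_up_ratio / b$down_up_ratio else NA_real_,
                 fold_computable = computable),
            class = "ratio_comparison")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("Regulation summary: %d down, %d up, %d unchanged (%d not computable)\n",
              x$n_down, x$n_up, x$n_unchanged, x$n_not_computable))
  if (x$ratio_infinite) cat("  down:up ratio infinite (no up-regulated gene)\n")
  else cat(sprintf("  down:up ratio = %.4g\n", x$down_up_ratio))
  if (!is.null(x$stratified)) {
    cat(sprintf("  pct down (of down+up): m6A-modified %.2f%%, unmodified %.2f%%\n",
                x$stratified$m6a$pct_down, x$stratified$non_m6a$pct_down))
  }
  invisible(x)
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat("Set A: "); print(x$set_a)
  cat("Set B: "); print(x$set_b)
  if (x$fold_computable)
    cat(sprintf("Fold difference of down:up ratios (A/B) = %.4g\n",
                x$fold_difference))
  else cat("Fold difference not computable (infinite or zero ratio)\n")
  invisible(x)
}
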