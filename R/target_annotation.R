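# Stage 2: locate canonical seed-match target sites in 3'UTRs and
# classify each target gene by m6A status.

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

.site_rank <- function(type) match(type, SITE_TYPES)

#' Find canonical miRNA seed-match sites in a 3'UTR
#'
#' Sites are anchored on an exact Watson-Crick match between the UTR
#' and the reverse complement of the seed "core" (mature positions 2-7
#' under the default span).  Each anchor is then typed by the canonical
#' taxonomy: `6mer` (core match only), `7mer-m8` (core plus a match to
#' mature position 8, extending the site one base 5' in the UTR),
#' `7mer-A1` (core plus an `A` in the UTR opposite mature position 1,
#' one base 3' of the core), and `8mer` (both).  Every anchor is
#' reported once with its strongest type; nested weaker matches at the
#' same locus are not duplicated.
#'
#' @param utr A `nucleotide_sequence` (its `id` is taken as the gene
#'   id) or a character scalar.
#' @param mirna A `mature_mirna`.
#' @param min_site_type Weakest type to report, one of
#'   `"6mer" < "7mer-A1" < "7mer-m8" < "8mer"`.  Default `"7mer-m8"`.
#' @return data.frame with columns `gene_id`, `mirna_name`, `start`,
#'   `end` (0-based half-open UTR offsets of the seed-paired region,
#'   so 6/7/8 nt wide by type), `site_type` and `site_seq`, sorted by
#'   `start`.  Zero rows when no qualifying site exists.
#' @examples
#' m133 <- mature_mirna("mmu-miR-133a-3p", "UUUGGUCCCCUUCAACCAGCUG")
#' find_target_sites(nucleotide_sequence("CUAGGACCAACUA", "g1"), m133)
#' @export
find_target_sites <- function(utr, mirna, min_site_type = "7mer-m8") {
  stopifnot(inherits(mirna, "mature_mirna"))
  min_site_type <- match.arg(min_site_type, SITE_TYPES)
  res <- .residues(utr)
  gene_id <- if (inherits(utr, "nucleotide_sequence")) utr$id else ""
  span <- mirna$seed_span
  mat <- mirna$sequence$residues

  core <- substr(mat, span[1L], span[2L] - 1L)        # positions 2..7
  anchor <- reverse_complement(core)                  # UTR-strand 6-mer
  m8_base <- unname(.RNA_COMPLEMENT[substr(mat, span[2L], span[2L])])
  w <- nchar(anchor)
  L <- nchar(res)

  empty <- data.frame(gene_id = character(), mirna_name = character(),
                      start = integer(), end = integer(),
                      site_type = character(), site_seq = character(),
                      stringsAsFactors = FALSE)
  if (w > L) return(empty)

  # exact anchor matches, overlapping allowed
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(anchor, substr(res, from, L), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + hit - 1L)
    from <- from + hit  # next search one past this anchor start
    if (from > L - w + 1L) break
  }
  if (!length(starts)) return(empty)

  rows <- lapply(starts, function(s1) {           # s1: 1-based anchor start
    x <- s1 - 1L                                  # 0-based
    has_m8 <- x >= 1L && substr(res, x, x) == m8_base
    has_a1 <- (x + w) < L && substr(res, x + w + 1L, x + w + 1L) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer";    st <- x - 1L; en <- x + w + 1L
    } else if (has_m8) {
      type <- "7mer-m8"; st <- x - 1L; en <- x + w
    } else if (has_a1) {
      type <- "7mer-A1"; st <- x;      en <- x + w + 1L
    } else {
      type <- "6mer";    st <- x;      en <- x + w
    }
    data.frame(gene_id = gene_id, mirna_name = mirna$name,
               start = st, end = en, site_type = type,
               site_seq = substr(res, st + 1L, en),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[.site_rank(out$site_type) >= .site_rank(min_site_type), ,
             drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate genes by miRNA targeting and m6A status
#'
#' Applies the two-step m6A filter to every 3'UTR: a gene is an
#' "m6A-modified target" when it (i) carries at least one seed-match
#' site of the miRNA at or above `min_site_type`, (ii) belongs to the
#' supplied m6A gene set (e.g. from m6A-RIP-seq), and (iii) contains
#' the m6A consensus motif in its UTR.  With
#' `strict_site_overlap = TRUE` the motif must additionally intersect a
#' target-site interval (half-open interval intersection), the stricter
#' reading in which the methylated adenosine lies inside the target
#' sequence itself.
#'
#' @param utrs List of `nucleotide_sequence` objects or a named
#'   character vector (names = gene ids).  Duplicate gene ids are
#'   rejected.
#' @param mirna A `mature_mirna`.
#' @param m6a_gene_set Character vector of gene ids called m6A-modified
#'   upstream.  Ids absent from `utrs` are counted and reported via a
#'   message, not an error.
#' @param motif m6A consensus motif; default `"GGACH"`.
#' @param strict_site_overlap Logical; default `FALSE`.
#' @param min_site_type Passed to [find_target_sites()].
#' @return data.frame of class `gene_annotation`, one row per UTR, with
#'   logical columns `is_target`, `m6a_in_gene_set`, `ggach_in_utr`,
#'   `motif_overlaps_site`, `m6a_modified_target` plus `n_sites`.
#'   The per-gene site table is attached as attribute `sites`.
#' @export
annotate_genes <- function(utrs, mirna, m6a_gene_set,
                           motif = "GGACH", strict_site_overlap = FALSE,
                           min_site_type = "7mer-m8") {
  if (is.character(utrs)) {
    if (is.null(names(utrs)) || any(!nzchar(names(utrs))))
      stop("character `utrs` must be named by gene id", call. = FALSE)
    utrs <- mapply(nucleotide_sequence, utrs, id = names(utrs),
                   SIMPLIFY = FALSE)
  }
  stopifnot(all(vapply(utrs, inherits, logical(1), "nucleotide_sequence")))
  ids <- vapply(utrs, function(u) u$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in UTR set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  motif <- .as_motif(motif)
  m6a_gene_set <- unique(as.character(m6a_gene_set))
  missing_m6a <- setdiff(m6a_gene_set, ids)
  if (length(missing_m6a))
    message(length(missing_m6a),
            " m6A gene-set id(s) absent from the UTR set; ignored")

  all_sites <- vector("list", length(utrs))
  rows <- vector("list", length(utrs))
  for (i in seq_along(utrs)) {
    u <- utrs[[i]]
    sites <- find_target_sites(u, mirna, min_site_type = min_site_type)
    hits <- scan_motif(u, motif)
    overlaps <- FALSE
    if (nrow(sites) && nrow(hits)) {
      for (j in seq_len(nrow(hits))) {
        if (any(hits$start[j] < sites$end & sites$start < hits$end[j])) {
          overlaps <- TRUE; break
        }
      }
    }
    is_target <- nrow(sites) > 0L
    in_set <- u$id %in% m6a_gene_set
    ggach <- nrow(hits) > 0L
    rows[[i]] <- data.frame(
      gene_id = u$id, is_target = is_target, n_sites = nrow(sites),
      m6a_in_gene_set = in_set, ggach_in_utr = ggach,
      motif_overlaps_site = overlaps,
      m6a_modified_target = is_target && in_set && ggach &&
        (!strict_site_overlap || overlaps),
      stringsAsFactors = FALSE)
    all_sites[[i]] <- sites
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            sites = do.call(rbind, all_sites),
            mirna = mirna$name,
            motif = motif$pattern,
            strict_site_overlap = strict_site_overlap,
            n_m6a_ids_missing = length(missing_m6a),
            class = c("gene_annotation", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "Gene annotation for %s (motif %s%s): %d genes, %d targets, %d m6A-modified targets\n",
    attr(x, "mirna"), attr(x, "motif"),
    if (attr(x, "strict_site_overlap")) ", strict site overlap" else "",
    nrow(x), sum(x$is_target), sum(x$m6a_modified_target)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
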