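# Stage 1: screen a miRNA catalogue for seeds whose complementary
# target-site sequence contains an m6A consensus motif.

#' Construct a mature miRNA record
#'
#' @param name miRNA name, e.g. `"mmu-miR-133a-3p"`.
#' @param sequence Mature sequence, 5'->3' (`nucleotide_sequence` or
#'   character).
#' @param seed_span Integer pair, 1-based inclusive positions of the
#'   seed on the mature strand.  The default `c(2, 8)` is the canonical
#'   7-nt seed; position 1 is excluded from seed pairing by convention,
#'   so the span must start at >= 2.
#' @return Object of class `mature_mirna`.
#' @examples
#' mature_mirna("mmu-miR-133a-3p", "UUUGGUCCCCUUCAACCAGCUG")
#' @export
mature_mirna <- function(name, sequence, seed_span = c(2L, 8L)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("miRNA `name` must be a non-empty string", call. = FALSE)
  seq <- if (inherits(sequence, "nucleotide_sequence")) sequence
         else nucleotide_sequence(sequence, id = name)
  seed_span <- as.integer(seed_span)
  if (length(seed_span) != 2L || any(is.na(seed_span)) ||
      seed_span[1L] > seed_span[2L])
    stop("`seed_span` must be an increasing pair of 1-based positions",
         call. = FALSE)
  if (seed_span[1L] < 2L)
    stop("seed_span must start at position >= 2 (position 1 does not pair)",
         call. = FALSE)
  if (nchar(seq$residues) < seed_span[2L])
    stop(sprintf("miRNA '%s' is shorter (%d nt) than its seed span end (%d)",
                 name, nchar(seq$residues), seed_span[2L]), call. = FALSE)
  structure(list(name = name, sequence = seq, seed_span = seed_span),
            class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s  %s  seed[%d-%d]=%s\n", x$name,
              x$sequence$residues, x$seed_span[1], x$seed_span[2],
              extract_seed(x)$residues))
  invisible(x)
}

#' Extract the seed region of a mature miRNA
#'
#' Returns the subsequence at the 1-based inclusive `seed_span` of the
#' mature strand, 5'->3'.
#'
#' @param mirna A `mature_mirna`.
#' @return A `nucleotide_sequence` holding the seed.
#' @examples
#' m <- mature_mirna("mmu-miR-133a-3p", "UUUGGUCCCCUUCAACCAGCUG")
#' extract_seed(m)$residues  # "UUGGUCC"
#' @export
extract_seed <- function(mirna) {
  stopifnot(inherits(mirna, "mature_mirna"))
  nucleotide_sequence(
    substr(mirna$sequence$residues, mirna$seed_span[1L], mirna$seed_span[2L]),
    id = paste0(mirna$name, "_seed"))
}

.classify_seed_site <- function(site_seq, relaxed, stringent,
                                n_matches_all = FALSE) {
  hits_s <- scan_motif(site_seq, stringent, n_matches_all = n_matches_all)
  if (nrow(hits_s))
    return(list(class = "FULL", hits = hits_s))
  hits_r <- scan_motif(site_seq, relaxed, n_matches_all = n_matches_all)
  if (nrow(hits_r))
    return(list(class = "PARTIAL", hits = hits_r))
  list(class = "NONE",
       hits = hits_s)  # zero-row frame
}

#' Screen a miRNA catalogue for m6A-motif complementarity
#'
#' For each miRNA the seed is extracted and reverse-complemented to the
#' mRNA-strand target-site sequence; that site sequence is scanned for
#' the stringent motif (GGACH by default) and, failing that, the
#' relaxed motif (RRACH).  A miRNA is classed `FULL` when the stringent
#' motif occurs as a contiguous window inside the site sequence,
#' `PARTIAL` when only the relaxed motif does, and `NONE` otherwise.
#' Because every GGACH match is an RRACH match, `FULL` implies the
#' relaxed condition also holds.
#'
#' @param mirnas List of `mature_mirna` objects (duplicate names are
#'   rejected: reporting would be ambiguous).
#' @param relaxed,stringent Motifs (`degenerate_motif` or pattern
#'   strings); defaults `"RRACH"` and `"GGACH"`.
#' @param n_matches_all Passed to [scan_motif()].
#' @return A data.frame of class `seed_screen`, one row per miRNA in
#'   input order, with columns `mirna`, `seed`, `site_sequence`,
#'   `match_class` (factor NONE/PARTIAL/FULL) and `motif_hits`
#'   (semicolon-joined `start:matched_text` of the hits that determined
#'   the class).  Summary counts are attached as attribute `counts`.
#' @examples
#' cat133 <- mature_mirna("mmu-miR-133a-3p", "UUUGGUCCCCUUCAACCAGCUG")
#' cat499 <- mature_mirna("mmu-miR-499-5p",  "UUAAGACUUGCAGUGAUGUUU")
#' screen_catalogue(list(cat133, cat499))
#' @export
screen_catalogue <- function(mirnas, relaxed = "RRACH", stringent = "GGACH",
                             n_matches_all = FALSE) {
  if (!length(mirnas)) stop("empty miRNA catalogue", call. = FALSE)
  if (inherits(mirnas, "mature_mirna")) mirnas <- list(mirnas)
  stopifnot(all(vapply(mirnas, inherits, logical(1), "mature_mirna")))
  nms <- vapply(mirnas, function(m) m$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate miRNA name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  relaxed <- .as_motif(relaxed); stringent <- .as_motif(stringent)

  rows <- lapply(mirnas, function(m) {
    seed <- extract_seed(m)
    site <- reverse_complement(seed)
    cl <- .classify_seed_site(site, relaxed, stringent, n_matches_all)
    data.frame(
      mirna = m$name, seed = seed$residues, site_sequence = site$residues,
      match_class = cl$class,
      motif_hits = if (nrow(cl$hits))
        paste(sprintf("%d:%s", cl$hits$start, cl$hits$matched_text),
              collapse = ";") else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$match_class <- factor(out$match_class,
                            levels = c("NONE", "PARTIAL", "FULL"))
  counts <- table(out$match_class)
  structure(out,
            counts = c(n_none = unname(counts["NONE"]),
                       n_partial = unname(counts["PARTIAL"]),
                       n_full = unname(counts["FULL"])),
            relaxed = relaxed$pattern, stringent = stringent$pattern,
            class = c("seed_screen", "data.frame"))
}

#' @export
print.seed_screen <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Seed/m6A-motif screen of %d miRNAs (relaxed %s, stringent %s)\n",
              nrow(x), attr(x, "relaxed"), attr(x, "stringent")))
  cat(sprintf("  FULL: %d   PARTIAL: %d   NONE: %d\n",
              cnt["n_full"], cnt["n_partial"], cnt["n_none"]))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
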