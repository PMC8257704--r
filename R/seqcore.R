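# Nucleotide alphabet handling, reverse complementation and
# IUPAC-degenerate motif matching: the primitive layer every other
# module builds on.  Internal alphabet is RNA (U); DNA input is mapped
# on construction.  All coordinates are 0-based, half-open.

#' IUPAC expansion sets
#'
#' Each IUPAC one-letter code mapped to the set of unambiguous RNA
#' residues it stands for (`R` = purine \{A,G\}, `H` = not-G \{A,C,U\},
#' and so on).
#' @keywords internal
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

# Watson-Crick complement extended over the ambiguity codes.
.RNA_COMPLEMENT <- c(
  A = "U", C = "G", G = "C", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Construct a normalized nucleotide sequence
#'
#' Normalizes a raw nucleotide string to the internal RNA alphabet:
#' case is folded to upper, `T` is mapped to `U`, and every residue is
#' checked against the IUPAC code table.  The declared alphabet is
#' recorded so DNA provenance is not lost.
#'
#' @param raw Character scalar, the sequence (letters only).
#' @param id Character scalar label (default `""`).
#' @param alphabet `"RNA"` or `"DNA"`; controls nothing beyond the
#'   recorded provenance because `T` is always accepted and mapped.
#' @return An object of class `nucleotide_sequence`: a list with
#'   elements `id`, `residues` (normalized string) and `alphabet`.
#' @examples
#' nucleotide_sequence("ggacu")$residues        # "GGACU"
#' nucleotide_sequence("GGACT", alphabet = "DNA")$residues  # "GGACU"
#' @export
nucleotide_sequence <- function(raw, id = "", alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single character string", call. = FALSE)
  res <- chartr("t", "u", toupper(raw))
  res <- chartr("T", "U", res)
  if (nchar(res) < 1L)
    stop("empty sequence rejected", if (nzchar(id)) paste0(" (id '", id, "')"),
         call. = FALSE)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_EXPANSION))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d (0-based) in sequence '%s'",
                 chars[bad[1L]], bad[1L] - 1L, id), call. = FALSE)
  }
  structure(list(id = as.character(id), residues = res, alphabet = alphabet),
            class = "nucleotide_sequence")
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  cat(sprintf("<nucleotide_sequence> %s (%d nt, from %s)\n  %s\n",
              if (nzchar(x$id)) x$id else "<unnamed>",
              nchar(x$residues), x$alphabet,
              if (nchar(x$residues) > 60)
                paste0(substr(x$residues, 1, 57), "...")
              else x$residues))
  invisible(x)
}

# Coerce character / nucleotide_sequence inputs to a plain residue string.
.residues <- function(x) {
  if (inherits(x, "nucleotide_sequence")) return(x$residues)
  if (is.character(x) && length(x) == 1L)
    return(nucleotide_sequence(x)$residues)
  stop("expected a nucleotide_sequence or a single character string",
       call. = FALSE)
}

#' Reverse complement of an RNA sequence
#'
#' Standard Watson-Crick complement (A-U, G-C), extended over IUPAC
#' ambiguity codes, followed by reversal.  The operation is an
#' involution and preserves length.
#'
#' @param x A `nucleotide_sequence` or character scalar.
#' @return Same type as the input (a `nucleotide_sequence` keeps its id
#'   with a `_rc` suffix; a character scalar comes back as character).
#' @examples
#' reverse_complement("GGACU")    # "AGUCC"
#' reverse_complement("UUGGUCC")  # "GGACCAA"
#' @export
reverse_complement <- function(x) {
  res <- .residues(x)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  rc <- paste(rev(unname(.RNA_COMPLEMENT[chars])), collapse = "")
  if (inherits(x, "nucleotide_sequence"))
    nucleotide_sequence(rc, id = if (nzchar(x$id)) paste0(x$id, "_rc") else "",
                        alphabet = x$alphabet)
  else rc
}

#' Construct a degenerate IUPAC motif
#'
#' @param pattern Character scalar over the IUPAC codes
#'   (A,C,G,U/T,R,Y,S,W,K,M,B,D,H,V,N).  `T` is mapped to `U`.
#' @return Object of class `degenerate_motif` with elements `pattern`
#'   and `length`.
#' @examples
#' degenerate_motif("RRACH")  # the m6A consensus
#' degenerate_motif("GGACH")  # its strongest form
#' @export
degenerate_motif <- function(pattern) {
  res <- chartr("Tt", "Uu", toupper(pattern))
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L) stop("empty motif pattern", call. = FALSE)
  bad <- which(!chars %in% names(IUPAC_EXPANSION))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d (0-based) in motif '%s'",
                 chars[bad[1L]], bad[1L] - 1L, pattern), call. = FALSE)
  structure(list(pattern = res, length = length(chars)),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s (%d nt)\n", x$pattern, x$length))
  invisible(x)
}

.as_motif <- function(x) {
  if (inherits(x, "degenerate_motif")) x else degenerate_motif(x)
}

#' Scan a sequence for a degenerate motif
#'
#' Slides the motif across the sequence and reports every (possibly
#' overlapping) window where each residue lies in the IUPAC expansion
#' set of the corresponding motif symbol.  An `N` in the *sequence*
#' matches nothing by default (conservative: an undetermined base is
#' never evidence for a motif); set `n_matches_all = TRUE` for the
#' permissive IUPAC reading.
#'
#' @param x A `nucleotide_sequence` or character scalar.
#' @param motif A `degenerate_motif` or pattern string.
#' @param n_matches_all Logical; should `N` residues in the sequence
#'   match every motif position?
#' @return A data.frame of motif hits with columns `sequence_id`,
#'   `start`, `end` (0-based, half-open) and `matched_text`, sorted by
#'   `start`.  Zero rows when there is no hit or the motif is longer
#'   than the sequence.
#' @examples
#' scan_motif("GGACCAA", "GGACH")     # one hit at [0,5)
#' scan_motif("GGACAGGACU", "GGACH")  # hits at [0,5) and [5,10)
#' @export
scan_motif <- function(x, motif, n_matches_all = FALSE) {
  res <- .residues(x)
  motif <- .as_motif(motif)
  id <- if (inherits(x, "nucleotide_sequence")) x$id else ""
  L <- nchar(res)
  m <- motif$length
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      stringsAsFactors = FALSE)
  if (m > L) return(empty)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  pat <- strsplit(motif$pattern, "", fixed = TRUE)[[1L]]
  k <- L - m + 1L
  ok <- rep(TRUE, k)
  for (i in seq_len(m)) {
    window_chars <- chars[i:(i + k - 1L)]
    hit_i <- window_chars %in% IUPAC_EXPANSION[[pat[i]]]
    if (n_matches_all) hit_i <- hit_i | window_chars == "N"
    ok <- ok & hit_i
    if (!any(ok)) return(empty)
  }
  starts <- which(ok) - 1L
  data.frame(sequence_id = id, start = starts, end = starts + m,
             matched_text = substring(res, starts + 1L, starts + m),
             stringsAsFactors = FALSE)
}
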