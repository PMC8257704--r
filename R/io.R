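# Format readers/writers and the umbrella pipeline runner that chains
# screen -> targets -> overlap -> dynamics into one reproducible run.
# TSV (tab-separated, header row, '#' comments) is the tabular dialect
# throughout; BED intervals are 0-based half-open with the gene id in
# the chrom column (UTR-relative coordinates).

#' Read a FASTA file of nucleotide sequences
#'
#' Wraps [Biostrings::readBStringSet()]; headers are parsed to the
#' first whitespace as ids, order is preserved, duplicate ids are
#' rejected and every sequence is normalized to the internal RNA
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Declared alphabet of the file, `"RNA"` or `"DNA"`.
#' @return List of `nucleotide_sequence` objects.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mapply(function(s, id) nucleotide_sequence(s, id = id, alphabet = alphabet),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector or list of `nucleotide_sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1),
                                  "nucleotide_sequence")))
    seqs <- stats::setNames(vapply(seqs, function(s) s$residues,
                                   character(1)),
                            vapply(seqs, function(s) s$id, character(1)))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named for FASTA output", call. = FALSE)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a tab-separated table (header row, '#' comments)
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table (header row)
#' @param df data.frame; @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED file of UTR-relative intervals
#'
#' At least three tab-separated columns (gene id, start, end), 0-based
#' half-open.  Extra columns are preserved opaquely.  Lines starting
#' with `#`, `track` or `browser` are skipped.  Invalid intervals
#' (`start >= end` or `start < 0`) are rejected with the offending line
#' number.
#'
#' @param path Input path.
#' @return data.frame with columns `gene_id`, `start`, `end` and any
#'   extra columns (`V4`, ...).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines))
  if (!length(keep))
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (k in seq_along(keep)) {
    f <- fields[[k]]
    i <- keep[k]
    if (length(f) < 3L)
      stop(sprintf("BED line %d of '%s': fewer than 3 columns", i, path),
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("BED line %d of '%s': non-integer coordinates", i, path),
           call. = FALSE)
    if (start < 0L || start >= end)
      stop(sprintf(
        "BED line %d of '%s': invalid interval [%d, %d) (need 0 <= start < end)",
        i, path, start, end), call. = FALSE)
  }
  ncol_max <- max(lengths(fields))
  out <- data.frame(
    gene_id = vapply(fields, `[`, character(1), 1L),
    start = as.integer(vapply(fields, `[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  if (ncol_max > 3L)
    for (j in 4:ncol_max)
      out[[paste0("V", j)]] <- vapply(fields, function(f)
        if (length(f) >= j) f[j] else NA_character_, character(1))
  out
}

#' Write UTR-relative intervals to BED
#' @param df data.frame with `gene_id`, `start`, `end` (+ extras).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(df)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full screen -> targets -> overlap -> dynamics pipeline
#'
#' Chains the four analysis stages on files produced upstream (or by
#' [simulate_all()]).  Stages whose inputs are absent are skipped with
#' a warning rather than failing the run; completion state per stage is
#' recorded in `MANIFEST.tsv` and the configuration is copied alongside
#' the outputs for provenance.
#'
#' @param config Named list of paths and options:
#'   \describe{
#'     \item{mirnas}{miRNA FASTA (required).}
#'     \item{utrs}{3'UTR FASTA (required).}
#'     \item{m6a_genes}{TSV gene list (required; column `gene_id` or a
#'       single unnamed column).}
#'     \item{scores}{optional score TSV (`gene_id`, `score`).}
#'     \item{matrix}{optional stage-matrix TSV (first column gene id).}
#'     \item{mirna_name}{which screened miRNA drives target annotation;
#'       default the first FULL-class hit, else the first miRNA.}
#'     \item{relaxed, stringent}{motif strings; defaults RRACH, GGACH.}
#'     \item{seed_span}{default `c(2, 8)`.}
#'     \item{min_site_type, strict_site_overlap}{site filter options.}
#'     \item{fc_threshold, pseudocount}{regulation-call options.}
#'     \item{reference_stage, comparison_stages}{stage selection;
#'       default first column and all remaining columns.}
#'     \item{variant}{t-test variant, `"pooled"` or `"welch"`.}
#'     \item{highlight}{`"down"` (development) or `"up"` (e.g.
#'       TAC-vs-Sham), which category the summary emphasises.}
#'     \item{outdir}{output directory (required).}
#'   }
#' @return Invisibly, a list of class `pipeline_run` with elements
#'   `screen`, `annotations`, `overlap_report`, `dynamics`, `summary`
#'   (the merged summary also written as JSON) and `manifest`.
#' @export
run_pipeline <- function(config) {
  required <- c("mirnas", "utrs", "m6a_genes", "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing required entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(
    list(relaxed = "RRACH", stringent = "GGACH", seed_span = c(2L, 8L),
         min_site_type = "7mer-m8", strict_site_overlap = FALSE,
         fc_threshold = 1.5, pseudocount = 0, variant = "pooled",
         highlight = "down", mirna_name = NULL, scores = NULL,
         matrix = NULL, reference_stage = NULL, comparison_stages = NULL),
    config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, state) manifest[[stage]] <<- state

  ## stage 1: screen
  mirna_seqs <- read_fasta(cfg$mirnas)
  mirnas <- lapply(mirna_seqs, function(s)
    mature_mirna(s$id, s, seed_span = cfg$seed_span))
  screen <- screen_catalogue(mirnas, relaxed = cfg$relaxed,
                             stringent = cfg$stringent)
  write_tsv(as.data.frame(screen), file.path(cfg$outdir, "screen.tsv"))
  note("screen", "done")

  ## stage 2: targets
  pick_name <- cfg$mirna_name
  if (is.null(pick_name)) {
    full <- which(screen$match_class == "FULL")
    pick_name <- screen$mirna[if (length(full)) full[1L] else 1L]
  }
  idx <- match(pick_name, screen$mirna)
  if (is.na(idx)) stop("miRNA '", pick_name, "' not in the catalogue",
                       call. = FALSE)
  mirna <- mirnas[[idx]]
  utrs <- read_fasta(cfg$utrs)
  m6a_tab <- read_tsv(cfg$m6a_genes)
  m6a_genes <- as.character(m6a_tab[[1L]])
  ann <- annotate_genes(utrs, mirna, m6a_genes,
                        motif = cfg$stringent,
                        strict_site_overlap = cfg$strict_site_overlap,
                        min_site_type = cfg$min_site_type)
  write_tsv(cbind(as.data.frame(ann)[1],
                  data.frame(lapply(as.data.frame(ann)[-1], as.integer))),
            file.path(cfg$outdir, "annotations.tsv"))
  sites <- attr(ann, "sites")
  if (!is.null(sites) && nrow(sites))
    write_bed(data.frame(gene_id = sites$gene_id, start = sites$start,
                         end = sites$end,
                         name = paste(sites$mirna_name, sites$site_type,
                                      sep = "|")),
              file.path(cfg$outdir, "sites.bed"))
  note("targets", "done")

  ## stage 3: overlap + score comparison
  report <- NULL
  if (!is.null(cfg$scores) && file.exists(cfg$scores)) {
    sc <- read_tsv(cfg$scores)
    scores <- stats::setNames(as.numeric(sc[[2L]]), as.character(sc[[1L]]))
    report <- stratified_overlap_report(ann, scores, variant = cfg$variant)
    note("overlap", "done")
  } else {
    warning("scores file missing; overlap stage skipped", call. = FALSE)
    note("overlap", "skipped")
  }

  ## stage 4: dynamics
  dynamics <- NULL
  if (!is.null(cfg$matrix) && file.exists(cfg$matrix)) {
    mt <- read_tsv(cfg$matrix)
    vals <- as.matrix(mt[, -1L, drop = FALSE])
    rownames(vals) <- as.character(mt[[1L]])
    ref <- cfg$reference_stage %||% colnames(vals)[1L]
    cmp_stages <- cfg$comparison_stages %||% setdiff(colnames(vals), ref)
    sm <- stage_matrix(vals, reference_stage = ref)
    m6a_status <- stats::setNames(ann$m6a_modified_target, ann$gene_id)
    target_ids <- ann$gene_id[ann$is_target]
    dynamics <- lapply(cmp_stages, function(st) {
      calls <- call_regulation(sm, st, fc_threshold = cfg$fc_threshold,
                               pseudocount = cfg$pseudocount)
      tcalls <- calls[calls$gene_id %in% target_ids, , drop = FALSE]
      list(stage = st, calls = calls,
           summary = summarize_ratios(tcalls, m6a_status = m6a_status))
    })
    names(dynamics) <- cmp_stages
    all_calls <- do.call(rbind, lapply(dynamics, function(d)
      cbind(stage = d$stage, d$calls)))
    write_tsv(all_calls, file.path(cfg$outdir, "regulation_calls.tsv"))
    note("dynamics", "done")
  } else {
    if (!is.null(cfg$matrix))
      warning("matrix file missing; dynamics stage skipped", call. = FALSE)
    note("dynamics", "skipped")
  }

  ## merged summary + provenance
  counts <- attr(screen, "counts")
  summary <- list(
    screen = list(n_mirnas = nrow(screen),
                  n_full = unname(counts["n_full"]),
                  n_partial = unname(counts["n_partial"]),
                  n_none = unname(counts["n_none"]),
                  screened_mirna = pick_name),
    annotation = list(n_genes = nrow(ann),
                      n_targets = sum(ann$is_target),
                      n_m6a_gene_set = sum(ann$m6a_in_gene_set),
                      n_ggach_in_utr = sum(ann$ggach_in_utr),
                      n_m6a_modified_targets = sum(ann$m6a_modified_target)),
    overlap = if (!is.null(report)) list(
      n_targets = report$overlap$n_a,
      n_m6a_modified = report$overlap$n_b,
      n_intersection = report$overlap$n_intersection,
      pct_targets_m6a = report$overlap$pct_a_in_b,
      comparison = if (report$comparison_computable)
        unclass(report$comparison) else NULL),
    dynamics = if (!is.null(dynamics)) lapply(dynamics, function(d) {
      s <- d$summary
      list(stage = d$stage, n_down = s$n_down, n_up = s$n_up,
           n_unchanged = s$n_unchanged,
           down_up_ratio = if (is.finite(s$down_up_ratio))
             s$down_up_ratio else NULL,
           ratio_infinite = s$ratio_infinite,
           pct_down_m6a = s$stratified$m6a$pct_down,
           pct_down_non_m6a = s$stratified$non_m6a$pct_down,
           pct_up_m6a = s$stratified$m6a$pct_up,
           pct_up_non_m6a = s$stratified$non_m6a$pct_up,
           highlight = cfg$highlight)
    }))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(data.frame(stage = names(manifest),
                       state = unlist(manifest)),
            file.path(cfg$outdir, "MANIFEST.tsv"))

  invisible(structure(list(screen = screen, annotations = ann,
                           overlap_report = report, dynamics = dynamics,
                           summary = summary, manifest = manifest,
                           outdir = cfg$outdir),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("m6A/miRNA interplay pipeline run ->", x$outdir, "\n")
  cat(sprintf("  screen: %d miRNAs (%d FULL / %d PARTIAL / %d NONE)\n",
              x$summary$screen$n_mirnas, x$summary$screen$n_full,
              x$summary$screen$n_partial, x$summary$screen$n_none))
  cat(sprintf("  annotation (%s): %d genes, %d targets, %d m6A-modified targets\n",
              x$summary$screen$screened_mirna,
              x$summary$annotation$n_genes, x$summary$annotation$n_targets,
              x$summary$annotation$n_m6a_modified_targets))
  if (!is.null(x$overlap_report)) print(x$overlap_report)
  if (!is.null(x$dynamics))
    for (d in x$dynamics) {
      cat(sprintf("  dynamics [%s vs reference]: ", d$stage))
      print(d$summary)
    }
  invisible(x)
}
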