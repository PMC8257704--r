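# Synthetic inputs with planted ground truth.  Background sequence is
# rejection-sampled to exclude accidental seed sites and m6A motifs,
# so the planted discrete truth (match classes, target/m6A flags,
# regulation calls) is exact, not probabilistic.
#
# All generators are pure functions of (cfg, rng_seed): each seeds its
# own stream (Mersenne-Twister, inversion normals, rejection sampling
# for `sample()`) from rng_seed plus a fixed per-generator offset, so
# outputs are byte-identical across runs and platforms.

.set_rng <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generators.  The defaults emulate
#' the study conditions this pipeline targets: a 139-miRNA cardiac
#' catalogue with 1 stringent (GGACH) and 9 relaxed-only (RRACH) seed
#' matches; a genome whose target fraction and m6A-conditional rates
#' reproduce a ~30% m6A-modified-target overlap; a unit-SD enrichment
#' score shift for m6A-modified targets; and a two-stage time course in
#' which 86.2% of m6A-modified targets versus 72.3% of unmodified
#' targets are down-regulated.
#'
#' @param rng_seed Integer seed (< 2^31 - 16).
#' @param n_mirnas,n_full_match,n_partial_match Catalogue size and
#'   planted seed-match counts (`full + partial <= n_mirnas`).
#' @param mature_length Mature miRNA length (nt), default 22.
#' @param n_genes Number of genes / 3'UTRs, default 3000.
#' @param utr_length_mean Mean 3'UTR length (nt), Poisson-distributed
#'   with a floor of 40 nt; default 200.
#' @param p_target Probability a gene carries a planted target site.
#' @param p_m6a_given_target,p_m6a_given_nontarget Probability a
#'   (non-)target gene is in the m6A gene set (and receives a planted
#'   GGACH motif).
#' @param score_mean_base,score_delta_m6a,score_sd Normal enrichment
#'   score model: mean `base + delta * [m6A-modified]`, SD `score_sd`.
#' @param n_stages Number of stages in the time course (>= 2; the
#'   first is the reference).
#' @param f_down_m6a,f_down_non_m6a Probability a (non-)m6A-modified
#'   target gene is planted DOWN (else UP).
#' @param fold_change_magnitude Linear fold applied to regulated genes.
#' @param unchanged_jitter Non-regulated genes vary within
#'   `[1/jitter, jitter]` fold of the reference; must stay below any
#'   fold-change threshold used downstream for the planted truth to be
#'   exact.  Default 1.2.
#' @param gc_content Background base composition knob (fraction G+C),
#'   default 0.5 (uniform).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(rng_seed = 1L,
                       n_mirnas = 139L, n_full_match = 1L,
                       n_partial_match = 9L, mature_length = 22L,
                       n_genes = 3000L, utr_length_mean = 200L,
                       p_target = 0.3, p_m6a_given_target = 0.302,
                       p_m6a_given_nontarget = 0.25,
                       score_mean_base = 1, score_delta_m6a = 1,
                       score_sd = 1,
                       n_stages = 2L,
                       f_down_m6a = 0.862, f_down_non_m6a = 0.723,
                       fold_change_magnitude = 4,
                       unchanged_jitter = 1.2,
                       gc_content = 0.5) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_mirnas = as.integer(n_mirnas),
              n_full_match = as.integer(n_full_match),
              n_partial_match = as.integer(n_partial_match),
              mature_length = as.integer(mature_length),
              n_genes = as.integer(n_genes),
              utr_length_mean = as.integer(utr_length_mean),
              p_target = p_target,
              p_m6a_given_target = p_m6a_given_target,
              p_m6a_given_nontarget = p_m6a_given_nontarget,
              score_mean_base = score_mean_base,
              score_delta_m6a = score_delta_m6a,
              score_sd = score_sd,
              n_stages = as.integer(n_stages),
              f_down_m6a = f_down_m6a, f_down_non_m6a = f_down_non_m6a,
              fold_change_magnitude = fold_change_magnitude,
              unchanged_jitter = unchanged_jitter,
              gc_content = gc_content)
  probs <- c(cfg$p_target, cfg$p_m6a_given_target, cfg$p_m6a_given_nontarget,
             cfg$f_down_m6a, cfg$f_down_non_m6a)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_full_match + cfg$n_partial_match > cfg$n_mirnas)
    stop("n_full_match + n_partial_match must not exceed n_mirnas",
         call. = FALSE)
  if (cfg$score_sd <= 0) stop("score_sd must be > 0", call. = FALSE)
  if (cfg$n_stages < 2L) stop("n_stages must be >= 2", call. = FALSE)
  if (cfg$mature_length < 8L) stop("mature_length must be >= 8", call. = FALSE)
  if (cfg$fold_change_magnitude <= 0 || cfg$unchanged_jitter < 1)
    stop("fold_change_magnitude must be > 0 and unchanged_jitter >= 1",
         call. = FALSE)
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("gc_content must lie in (0, 1)", call. = FALSE)
  if (cfg$rng_seed >= .Machine$integer.max - 16L)
    stop("rng_seed too large", call. = FALSE)
  structure(cfg, class = "sim_config")
}

.base_probs <- function(cfg) {
  gc <- cfg$gc_content
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
}

.rand_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Random sequence free of every pattern in `forbidden` (IUPAC strings).
# Offending windows are locally resampled; bounded restarts.
.clean_random_seq <- function(len, forbidden, probs, max_iter = 60L,
                              max_restart = 25L) {
  for (r in seq_len(max_restart)) {
    chars <- .rand_bases(len, probs)
    for (it in seq_len(max_iter)) {
      s <- paste(chars, collapse = "")
      bad <- integer(0)
      for (pat in forbidden) {
        h <- scan_motif(s, pat)
        if (nrow(h))
          bad <- c(bad, unlist(lapply(seq_len(nrow(h)),
                                      function(j) (h$start[j] + 1L):h$end[j])))
      }
      if (!length(bad)) return(s)
      bad <- unique(bad)
      chars[bad] <- .rand_bases(length(bad), probs)
    }
  }
  stop("could not construct a clean background sequence; ",
       "lower utr_length_mean or revisit the forbidden patterns",
       call. = FALSE)
}

# Splice `insert` into `s` replacing bases at 0-based offset `at`.
.splice <- function(s, insert, at) {
  paste0(substr(s, 1L, at), insert,
         substr(s, at + nchar(insert) + 1L, nchar(s)))
}

#' Generate a miRNA catalogue with planted seed-match classes
#'
#' Constructs `n_full_match` miRNAs whose seed reverse complement
#' contains the stringent motif (GGACH), `n_partial_match` with a
#' relaxed-only (RRACH, not GGACH) match, and the remainder
#' rejection-sampled to contain neither.  Class labels are shuffled
#' over catalogue positions.
#'
#' @param cfg A `sim_config`.
#' @return List with `mirnas` (list of `mature_mirna`) and `truth`
#'   (data.frame `name`, `match_class`).
#' @export
gen_mirna_catalogue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .set_rng(cfg$rng_seed + 1L)
  probs <- .base_probs(cfg)
  n <- cfg$n_mirnas
  classes <- sample(c(rep("FULL", cfg$n_full_match),
                      rep("PARTIAL", cfg$n_partial_match),
                      rep("NONE", n - cfg$n_full_match - cfg$n_partial_match)))
  h_set <- c("A", "C", "U")
  rr_set <- c("AA", "AG", "GA")  # purine pairs other than GG

  make_site <- function(class) {
    for (attempt in 1:10000) {
      site <- .rand_bases(7L, probs)
      if (class == "FULL") {
        off <- sample(0:2, 1L)
        site[off + 1:5] <- c("G", "G", "A", "C", sample(h_set, 1L))
        return(paste(site, collapse = ""))
      }
      s <- paste(site, collapse = "")
      if (class == "PARTIAL") {
        off <- sample(0:2, 1L)
        rr <- strsplit(sample(rr_set, 1L), "")[[1L]]
        site[off + 1:5] <- c(rr, "A", "C", sample(h_set, 1L))
        s <- paste(site, collapse = "")
        if (nrow(scan_motif(s, "GGACH")) == 0L) return(s)
      } else {
        if (nrow(scan_motif(s, "RRACH")) == 0L) return(s)
      }
    }
    stop("failed to construct a planted seed site after bounded attempts",
         call. = FALSE)
  }

  mirnas <- vector("list", n)
  for (i in seq_len(n)) {
    site <- make_site(classes[i])
    seed <- reverse_complement(site)
    mature <- paste0(paste(.rand_bases(1L, probs), collapse = ""), seed,
                     paste(.rand_bases(cfg$mature_length - 8L, probs),
                           collapse = ""))
    mirnas[[i]] <- mature_mirna(sprintf("syn-miR-%03d", i), mature)
  }
  list(mirnas = mirnas,
       truth = data.frame(name = vapply(mirnas, function(m) m$name,
                                        character(1)),
                          match_class = classes, stringsAsFactors = FALSE))
}

#' Generate a synthetic 3'UTR genome with planted sites and m6A status
#'
#' Each gene is independently a target (one planted 7mer-m8 site for
#' `mirna`) with probability `p_target`, and is listed in the m6A gene
#' set with the status-conditional probability.  Listed genes carry a
#' GGACH motif: planted into free background, or already present when
#' the target site of a GGACH-class miRNA itself contains the motif
#' (as the miR-133a site GGACCAA does).  Background sequence is
#' rejection-screened against accidental sites and motifs, and every
#' assembled UTR is verified against the package's own scanners, so
#' the emitted truth table is exact.
#'
#' @param cfg A `sim_config`.
#' @param mirna The screened `mature_mirna` whose sites are planted.
#' @return List with `utrs` (list of `nucleotide_sequence`),
#'   `m6a_genes` (character), `peaks` (data.frame gene_id/start/end,
#'   0-based half-open, UTR-relative) and `truth` (per-gene
#'   data.frame).
#' @export
gen_utr_genome <- function(cfg, mirna) {
  stopifnot(inherits(cfg, "sim_config"), inherits(mirna, "mature_mirna"))
  .set_rng(cfg$rng_seed + 2L)
  probs <- .base_probs(cfg)
  site7 <- reverse_complement(extract_seed(mirna))$residues
  site_ggach <- scan_motif(site7, "GGACH")
  site_has_motif <- nrow(site_ggach) > 0L
  forbidden <- list("GGACH", site7)
  motif_text <- function() paste0("GGAC", sample(c("A", "C", "U"), 1L))

  n <- cfg$n_genes
  lens <- pmax(40L, stats::rpois(n, cfg$utr_length_mean))
  is_target <- stats::runif(n) < cfg$p_target
  m6a_listed <- stats::runif(n) <
    ifelse(is_target, cfg$p_m6a_given_target, cfg$p_m6a_given_nontarget)

  utrs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- sprintf("gene_%05d", i)
    L <- lens[i]
    for (attempt in 1:100) {
      s <- .clean_random_seq(L, forbidden, probs)
      site_start <- NA_integer_
      motif_start <- NA_integer_
      if (is_target[i]) {
        site_start <- sample.int(L - 7L + 1L, 1L) - 1L
        s <- .splice(s, site7, site_start)
      }
      if (m6a_listed[i] && is_target[i] && site_has_motif) {
        # motif already inside the planted site; record its interval
        motif_start <- site_start + site_ggach$start[1L]
      } else if (m6a_listed[i]) {
        # plant into background, clear of the site interval
        free <- setdiff(0:(L - 5L),
                        if (is_target[i])
                          max(0L, site_start - 4L):(site_start + 6L)
                        else integer(0))
        if (!length(free)) next
        motif_start <- free[sample.int(length(free), 1L)]
        s <- .splice(s, motif_text(), motif_start)
      }
      # verify assembled sequence against the planted truth
      sites <- find_target_sites(nucleotide_sequence(s, gid), mirna,
                                 min_site_type = "7mer-m8")
      if ((nrow(sites) > 0L) != is_target[i]) next
      ggach_expected <- m6a_listed[i] || (is_target[i] && site_has_motif)
      hits <- scan_motif(s, "GGACH")
      if ((nrow(hits) > 0L) != ggach_expected) next
      if (ggach_expected && m6a_listed[i] && !is.na(motif_start) &&
          !any(hits$start == motif_start)) next
      utrs[[i]] <- nucleotide_sequence(s, gid)
      truth[[i]] <- data.frame(
        gene_id = gid, is_target = is_target[i],
        m6a_in_gene_set = m6a_listed[i], ggach_in_utr = ggach_expected,
        m6a_modified_target = is_target[i] && m6a_listed[i] && ggach_expected,
        site_start = site_start, site_end = site_start + 7L,
        motif_start = motif_start, motif_end = motif_start + 5L,
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(utrs[[i]]))
      stop("failed to assemble a truth-consistent UTR after bounded attempts",
           call. = FALSE)
  }
  truth <- do.call(rbind, truth)
  peaks <- truth[truth$m6a_in_gene_set & !is.na(truth$motif_start),
                 c("gene_id", "motif_start", "motif_end")]
  names(peaks) <- c("gene_id", "start", "end")
  rownames(peaks) <- NULL
  list(utrs = utrs, m6a_genes = truth$gene_id[truth$m6a_in_gene_set],
       peaks = peaks, truth = truth)
}

#' Generate per-gene enrichment scores
#'
#' Scores for target genes only (emulating a RISC/AGO2 pull-down score
#' table), drawn Normal(score_mean_base + score_delta_m6a *
#' \[m6A-modified\], score_sd).
#'
#' @param cfg A `sim_config`.
#' @param truth Per-gene truth from [gen_utr_genome()].
#' @return data.frame `gene_id`, `score` (targets only).
#' @export
gen_scores <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  .set_rng(cfg$rng_seed + 3L)
  t <- truth[truth$is_target, , drop = FALSE]
  data.frame(gene_id = t$gene_id,
             score = stats::rnorm(
               nrow(t),
               mean = cfg$score_mean_base +
                 cfg$score_delta_m6a * as.numeric(t$m6a_modified_target),
               sd = cfg$score_sd),
             stringsAsFactors = FALSE)
}

#' Generate a stage-wise abundance matrix with planted regulation
#'
#' Reference-stage abundances are lognormal; each target gene is
#' planted DOWN with the m6A-status-conditional probability (else UP),
#' and its comparison-stage abundance is the reference scaled by
#' 1/fold or fold exactly.  Non-target genes (and, implicitly,
#' unchanged genes) jitter within `[1/unchanged_jitter,
#' unchanged_jitter]` fold, so any downstream fold-change threshold in
#' `(unchanged_jitter, fold_change_magnitude)` recovers the planted
#' calls exactly.
#'
#' @param cfg A `sim_config`.
#' @param truth Per-gene truth from [gen_utr_genome()].
#' @return List with `matrix` (a `stage_matrix`, reference = first
#'   stage) and `truth` (data.frame `gene_id`, `regulation` in
#'   DOWN/UP/UNCHANGED).
#' @export
gen_timecourse <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  .set_rng(cfg$rng_seed + 4L)
  n <- nrow(truth)
  labels <- if (cfg$n_stages == 2L) c("P1", "P23")
            else c("P1", sprintf("S%d", 2:cfg$n_stages))
  f_down <- ifelse(truth$m6a_modified_target, cfg$f_down_m6a,
                   cfg$f_down_non_m6a)
  reg <- ifelse(!truth$is_target, "UNCHANGED",
                ifelse(stats::runif(n) < f_down, "DOWN", "UP"))
  ref <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.5)
  vals <- matrix(0, n, cfg$n_stages,
                 dimnames = list(truth$gene_id, labels))
  vals[, 1L] <- ref
  fcm <- cfg$fold_change_magnitude
  for (j in 2:cfg$n_stages) {
    jitter <- exp(stats::runif(n, -log(cfg$unchanged_jitter),
                               log(cfg$unchanged_jitter)))
    vals[, j] <- ifelse(reg == "DOWN", ref / fcm,
                        ifelse(reg == "UP", ref * fcm, ref * jitter))
  }
  list(matrix = stage_matrix(vals, reference_stage = labels[1L]),
       truth = data.frame(gene_id = truth$gene_id, regulation = reg,
                          stringsAsFactors = FALSE))
}

#' Generate and write a complete synthetic input set
#'
#' Runs all generators and writes `mirnas.fasta`, `utrs.fasta`,
#' `m6a_genes.tsv`, `m6a_peaks.bed`, `scores.tsv`, `matrix.tsv` and
#' `truth.json` into `outdir`.  The genome is planted for the first
#' FULL-class miRNA of the catalogue (the miR-133a analogue); if the
#' configuration plants none, the first miRNA is used.
#'
#' @param cfg A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all generated objects and `paths`.
#' @export
simulate_all <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cat_out <- gen_mirna_catalogue(cfg)
  full_idx <- which(cat_out$truth$match_class == "FULL")
  pick <- if (length(full_idx)) full_idx[1L] else 1L
  mirna <- cat_out$mirnas[[pick]]
  genome <- gen_utr_genome(cfg, mirna)
  scores <- gen_scores(cfg, genome$truth)
  tc <- gen_timecourse(cfg, genome$truth)

  paths <- list(
    mirnas = file.path(outdir, "mirnas.fasta"),
    utrs = file.path(outdir, "utrs.fasta"),
    m6a_genes = file.path(outdir, "m6a_genes.tsv"),
    m6a_peaks = file.path(outdir, "m6a_peaks.bed"),
    scores = file.path(outdir, "scores.tsv"),
    matrix = file.path(outdir, "matrix.tsv"),
    truth = file.path(outdir, "truth.json"))

  write_fasta(stats::setNames(
    vapply(cat_out$mirnas, function(m) m$sequence$residues, character(1)),
    cat_out$truth$name), paths$mirnas)
  write_fasta(stats::setNames(
    vapply(genome$utrs, function(u) u$residues, character(1)),
    vapply(genome$utrs, function(u) u$id, character(1))), paths$utrs)
  write_tsv(data.frame(gene_id = genome$m6a_genes), paths$m6a_genes)
  write_bed(genome$peaks, paths$m6a_peaks)
  write_tsv(scores, paths$scores)
  mat_df <- data.frame(gene_id = rownames(tc$matrix$values),
                       tc$matrix$values, check.names = FALSE)
  write_tsv(mat_df, paths$matrix)
  jsonlite::write_json(
    list(config = unclass(cfg),
         screen_mirna = mirna$name,
         mirnas = cat_out$truth,
         genes = genome$truth,
         regulation = tc$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(cfg = cfg, mirnas = cat_out$mirnas,
                 mirna_truth = cat_out$truth, screen_mirna = mirna,
                 genome = genome, scores = scores, timecourse = tc,
                 paths = paths))
}
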