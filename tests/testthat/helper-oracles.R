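# Independent oracles and fixture builders shared across test files.
# These deliberately re-derive the primitives (expansion table,
# complement map, window checks) from first principles rather than
# calling the package internals they check.

# canonical mature sequences, 5'->3'
MIR133A <- "UUUGGUCCCCUUCAACCAGCUG"   # mmu-miR-133a-3p
MIR499  <- "UUAAGACUUGCAGUGAUGUUU"    # mmu-miR-499-5p

oracle_iupac <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

# naive window-by-window motif checker (regex-free)
oracle_scan <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  starts <- integer(0)
  if (length(p) > length(s)) return(starts)
  for (i in 0:(length(s) - length(p))) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j] %in% oracle_iupac[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

# complement-then-reverse oracle
oracle_revcomp <- function(seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# textbook two-sample t formulas, independent of stats::t.test
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# a miRNA whose target site contains neither RRACH nor GGACH
# (site = reverse complement of its 2-8 seed)
clean_site_mirna <- function(name = "syn-clean") {
  site <- "AAUCGAU"                       # no purine-purine-A-C window
  seed <- oracle_revcomp(site)            # AUCGAUU
  mature_mirna(name, paste0("G", seed, "ACGUACGUACGUAC"))
}
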