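# Internal helpers shared across modules.

# IUPAC degenerate nucleotide codes -> the set of plain bases each covers.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# base-set (sorted, collapsed) -> degenerate code
IUPAC_FROM_SET <- local({
  x <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), character(1))
  stats::setNames(names(x), unname(x))
})

# 15x15 logical matrix: do two IUPAC codes share at least one plain base?
IUPAC_COMPAT <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (a in IUPAC_LETTERS) for (b in IUPAC_LETTERS) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  }
  m
})

iupac_regex <- "^[ACGTRYSWKMBDHVN-]*$"

# Normalize raw sequence text: uppercase, RNA U -> T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# 0-based half-open substring extraction (BED-style coordinates).
# substring() so that vectorised start/end against a single subject works.
subseq0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Round half away from zero (presentation rounding for percentages).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Substitute bases at random positions, always to a different base.
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Shared k-mer presence between two sequences (seeding prefilter).
shares_kmer <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(FALSE)
  ka <- unique(substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L))
  length(intersect(ka, kb)) > 0L
}

# Substitution matrix over A,C,G,T,N for pairwiseAlignment: exact matches score
# `match`, everything else (including N against anything) scores `mismatch`.
acgtn_matrix <- function(match, mismatch) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters5, letters5))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# Map degenerate letters (anything not A/C/G/T/-) to N for alignment scoring.
to_acgtn <- function(x) {
  gsub("[^ACGTN-]", "N", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
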