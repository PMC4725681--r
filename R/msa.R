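new_msa <- function(id, aligned) {
  aligned <- toupper(aligned)
  w <- unique(nchar(aligned))
  if (length(w) > 1) {
    stop("ragged alignment: rows have differing lengths (",
         paste(sort(w), collapse = ", "), ")", call. = FALSE)
  }
  out <- tibble::tibble(id = as.character(id), aligned = aligned)
  class(out) <- c("dna_msa", class(out))
  attr(out, "n_columns") <- if (length(w)) w else 0L
  out
}

#' Number of columns in an alignment
#' @param aln A `dna_msa` object.
#' @return Integer column count.
#' @export
msa_ncol <- function(aln) {
  attr(aln, "n_columns") %||% unique(nchar(aln$aligned))
}

#' Multiple alignment by center-star progressive alignment
#'
#' The center is the sequence with the highest summed pairwise k-mer
#' similarity to the others (ties go to the earliest); every other sequence is
#' globally aligned to it (Needleman-Wunsch, affine gaps) and the pairwise
#' alignments are merged under the usual once-a-gap-always-a-gap rule. The
#' result is deterministic given the input order. Alignment quality is not
#' benchmarked against Clustal/MAFFT; externally computed alignments can be
#' loaded with [load_msa()] instead.
#'
#' @param seqs Sequence table with at least two rows.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (defaults +1, -1, -4, -1). A gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param k Word length for center selection (default 6).
#' @return A `dna_msa`: tibble of (`id`, `aligned`) rows of identical length;
#'   removing `-` from each row recovers the input sequence exactly.
#' @export
build_msa <- function(seqs, match = 1, mismatch = -1, gap_open = -4,
                      gap_extend = -1, k = 6L) {
  if (nrow(seqs) < 2L) stop("build_msa needs at least 2 sequences", call. = FALSE)
  orig <- seqs$sequence
  mapped <- to_acgtn(orig)
  n <- length(mapped)

  kmers <- lapply(mapped, function(s) {
    ns <- nchar(s)
    if (ns < k) return(character())
    unique(substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L))
  })
  sim <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n)[-i],
               function(j) length(intersect(kmers[[i]], kmers[[j]])), numeric(1)))
  }, numeric(1))
  center <- which.max(sim)  # ties -> first

  mat <- acgtn_matrix(match, mismatch)
  c_seq <- mapped[[center]]
  lc <- nchar(c_seq)
  others <- setdiff(seq_len(n), center)

  # Per other sequence: gapped pattern string + insertion counts after each
  # center position (index j+1 holds insertions after center position j,
  # j = 0 meaning before the first center base).
  pair <- lapply(others, function(i) {
    al <- Biostrings::pairwiseAlignment(
      mapped[[i]], c_seq, type = "global", substitutionMatrix = mat,
      gapOpening = -gap_open, gapExtension = -gap_extend
    )
    gp <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    gs <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ins <- integer(lc + 1L)
    seg <- vector("list", lc + 1L)
    for (s in seq_along(seg)) seg[[s]] <- character()
    anchor <- character(lc)
    pos <- 0L
    for (t in seq_along(gs)) {
      if (gs[t] == "-") {
        ins[pos + 1L] <- ins[pos + 1L] + 1L
        seg[[pos + 1L]] <- c(seg[[pos + 1L]], gp[t])
      } else {
        pos <- pos + 1L
        anchor[pos] <- gp[t]
      }
    }
    list(ins = ins, seg = seg, anchor = anchor)
  })

  m_ins <- integer(lc + 1L)
  for (p in pair) m_ins <- pmax(m_ins, p$ins)

  pad <- function(chars, width) {
    c(chars, rep("-", width - length(chars)))
  }
  center_chars <- strsplit(c_seq, "")[[1]]
  build_row <- function(anchor, seg) {
    out <- pad(seg[[1L]], m_ins[1L])
    for (j in seq_len(lc)) {
      out <- c(out, anchor[j], pad(seg[[j + 1L]], m_ins[j + 1L]))
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  rows[center] <- build_row(center_chars,
                            c(list(character()), rep(list(character()), lc)))
  for (idx in seq_along(others)) {
    rows[others[idx]] <- build_row(pair[[idx]]$anchor, pair[[idx]]$seg)
  }

  # Restore original letters (degenerates were mapped to N for scoring only).
  rows <- vapply(seq_len(n), function(i) {
    chars <- strsplit(rows[i], "")[[1]]
    chars[chars != "-"] <- strsplit(orig[i], "")[[1]]
    paste(chars, collapse = "")
  }, character(1))

  aln <- new_msa(seqs$id, rows)
  stopifnot(identical(gsub("-", "", aln$aligned), orig))
  aln
}

#' Load a multiple alignment from aligned FASTA or Clustal format
#'
#' The format is detected from the first line (`CLUSTAL` header vs `>`).
#' Ragged rows raise a format error.
#'
#' @param path Path to the alignment file.
#' @return A `dna_msa` object.
#' @export
load_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)[1] %||% ""
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)[-1L]
    ids <- character()
    parts <- list()
    for (ln in lines) {
      if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next  # blank/consensus line
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 2L) next
      chunk <- f[2]
      if (!(f[1] %in% ids)) {
        ids <- c(ids, f[1])
        parts[[f[1]]] <- character()
      }
      parts[[f[1]]] <- c(parts[[f[1]]], chunk)
    }
    if (length(ids) == 0) stop("no alignment rows in '", path, "'", call. = FALSE)
    new_msa(ids, vapply(parts[ids], paste, character(1), collapse = ""))
  } else {
    x <- Biostrings::readBStringSet(path)
    new_msa(sub("\\s.*$", "", names(x)), as.character(x))
  }
}

#' Per-column conservation profile of an alignment
#'
#' Tallies A/C/G/T/N/gap per column (letters outside that alphabet count as
#' N). Gaps are counted in the denominator of `majority_fraction`, so an
#' indel anywhere penalises conservation; the majority base is taken over
#' A,C,G,T,N with ties broken in that fixed order.
#'
#' @param aln A `dna_msa` object (at least one row).
#' @return A `conservation_profile` tibble, one row per column: `column`
#'   (0-based), counts `a`, `c`, `g`, `t`, `n`, `gap`, plus `n_rows`,
#'   `majority_base`, `majority_fraction`, `gap_fraction`.
#' @export
conservation_profile <- function(aln) {
  stopifnot(nrow(aln) >= 1L)
  nc <- msa_ncol(aln)
  chars <- matrix(unlist(strsplit(aln$aligned, "")), nrow = nrow(aln),
                  ncol = nc, byrow = TRUE)
  chars[!(chars %in% c("A", "C", "G", "T", "N", "-"))] <- "N"
  counts <- vapply(c("A", "C", "G", "T", "N", "-"),
                   function(sym) .colSums(chars == sym, nrow(aln), nc),
                   numeric(nc))
  counts <- matrix(counts, ncol = 6L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N", "-")))
  base_counts <- counts[, 1:5, drop = FALSE]
  maj_idx <- max.col(base_counts, ties.method = "first")
  maj <- c("A", "C", "G", "T", "N")[maj_idx]
  n_rows <- nrow(aln)
  out <- tibble::tibble(
    column = seq_len(nc) - 1L,
    a = as.vector(counts[, "A"]), c = as.vector(counts[, "C"]),
    g = as.vector(counts[, "G"]), t = as.vector(counts[, "T"]),
    n = as.vector(counts[, "N"]), gap = as.vector(counts[, "-"]),
    n_rows = n_rows,
    majority_base = maj,
    majority_fraction =
      as.vector(base_counts[cbind(seq_len(nc), maj_idx)]) / n_rows,
    gap_fraction = as.vector(counts[, "-"]) / n_rows
  )
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Consensus sequence from a conservation profile
#'
#' In `strict` mode each column contributes its majority base; columns where
#' gaps outnumber the majority base are omitted. In `iupac` mode each column
#' contributes the degenerate code covering every base whose frequency is at
#' least `minor_threshold` (falling back to the majority base when no base
#' reaches the threshold).
#'
#' @param profile A `conservation_profile`.
#' @param mode `"strict"` or `"iupac"`.
#' @param minor_threshold Minimum base frequency to enter the degenerate code
#'   (default 0.25).
#' @return A single consensus string.
#' @export
consensus_sequence <- function(profile, mode = c("strict", "iupac"),
                               minor_threshold = 0.25) {
  mode <- match.arg(mode)
  keep <- profile$gap <= pmax(profile$a, profile$c, profile$g, profile$t,
                              profile$n)
  p <- profile[keep, , drop = FALSE]
  if (mode == "strict") return(paste(p$majority_base, collapse = ""))
  freq <- cbind(A = p$a, C = p$c, G = p$g, T = p$t) / p$n_rows
  code <- vapply(seq_len(nrow(p)), function(i) {
    set <- colnames(freq)[freq[i, ] >= minor_threshold]
    if (length(set) == 0) return(p$majority_base[i])
    IUPAC_FROM_SET[[paste(sort(set), collapse = "")]]
  }, character(1))
  paste(code, collapse = "")
}

#' Export a conservation profile as TSV (sequence-logo data)
#'
#' @param profile A `conservation_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}
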