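#' Scoring parameters for local homology search
#'
#' Simple +1/-2 scheme with affine gaps; a gap of length L costs
#' `gap_open + L * gap_extend`. No E-value statistics are computed, a raw
#' score threshold is used instead.
#'
#' @param word_size Seed word length for the k-mer prefilter (default 11).
#' @param match,mismatch Per-column scores (defaults +1 / -2).
#' @param gap_open,gap_extend Gap penalties, negative (defaults -5 / -2).
#' @param min_score Minimum alignment score to report a hit (default 40).
#' @return A named list of parameters.
#' @export
align_params <- function(word_size = 11L, match = 1, mismatch = -2,
                         gap_open = -5, gap_extend = -2, min_score = 40) {
  stopifnot(word_size >= 1, gap_open <= 0, gap_extend <= 0)
  list(word_size = as.integer(word_size), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, min_score = min_score)
}

# Coerce a one-row sequence table / named or bare character to (id, sequence).
as_seq_entry <- function(x, default_id) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id[[1]], sequence = x$sequence[[1]])
  } else {
    list(id = names(x) %||% default_id, sequence = normalize_seq(unname(x)))
  }
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    strand = character(), score = numeric(), identity = numeric()
  )
}

#' Local alignment search between two sequences
#'
#' Finds maximal local alignments (Smith-Waterman) of the query against both
#' strands of the subject, reporting every hit scoring at least
#' `params$min_score`. Multiple hits are recovered by greedily masking the
#' subject span of each accepted alignment and re-searching. A shared-word
#' prefilter of length `params$word_size` must pass before any dynamic
#' programming is attempted. All intervals are 0-based half-open on the
#' forward strand; identity is computed over aligned columns with gaps
#' counted as mismatches.
#'
#' @param query,subject One-row sequence tables (or bare character strings).
#' @param params See [align_params()].
#' @return A tibble of hits sorted by descending score, ties broken by
#'   (`subject_id`, `s_start`): columns `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `score`, `identity`.
#' @export
local_align_search <- function(query, subject, params = align_params()) {
  q <- as_seq_entry(query, "query")
  s <- as_seq_entry(subject, "subject")
  if (nchar(q$sequence) == 0 || nchar(s$sequence) == 0) {
    stop("query and subject must be non-empty", call. = FALSE)
  }
  qseq <- to_acgtn(q$sequence)
  qrc <- reverse_complement(qseq)
  sseq <- to_acgtn(s$sequence)
  k <- params$word_size
  if (!shares_kmer(qseq, sseq, k) && !shares_kmer(qrc, sseq, k)) {
    return(empty_hits())
  }
  mat <- acgtn_matrix(params$match, params$mismatch)
  qlen <- nchar(qseq)
  masked <- sseq
  hits <- list()
  for (iter in seq_len(200L)) {
    best <- NULL
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") qseq else qrc
      al <- Biostrings::pairwiseAlignment(
        pat, masked, type = "local", substitutionMatrix = mat,
        gapOpening = -params$gap_open, gapExtension = -params$gap_extend
      )
      sc <- BiocGenerics::score(al)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && strand == "+" && best$strand == "-")) {
        best <- list(al = al, score = sc, strand = strand)
      }
    }
    if (best$score < params$min_score) break
    al <- best$al
    ps <- BiocGenerics::start(Biostrings::pattern(al))
    pe <- BiocGenerics::end(Biostrings::pattern(al))
    ss <- BiocGenerics::start(Biostrings::subject(al))
    se <- BiocGenerics::end(Biostrings::subject(al))
    gp <- as.character(Biostrings::alignedPattern(al))
    gs <- as.character(Biostrings::alignedSubject(al))
    cp <- strsplit(gp, "")[[1]]
    cs <- strsplit(gs, "")[[1]]
    identity <- sum(cp == cs & cp != "-") / length(cp)
    if (best$strand == "+") {
      q_int <- c(ps - 1L, pe)
    } else {
      q_int <- c(qlen - pe, qlen - ps + 1L)
    }
    hits[[length(hits) + 1L]] <- tibble::tibble(
      query_id = q$id, subject_id = s$id,
      q_start = q_int[1], q_end = q_int[2],
      s_start = ss - 1L, s_end = se,
      strand = best$strand, score = best$score, identity = identity
    )
    substr(masked, ss, se) <- strrep("N", se - ss + 1L)
  }
  if (length(hits) == 0) return(empty_hits())
  out <- dplyr::bind_rows(hits)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$subject_id, .data$s_start)
}

# Search a query against every record of a genome table; pooled, re-sorted.
search_collection <- function(query, genome, params) {
  res <- purrr::map(seq_len(nrow(genome)), function(i) {
    local_align_search(query, genome[i, ], params)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty_hits())
  dplyr::arrange(out, dplyr::desc(.data$score), .data$subject_id, .data$s_start)
}

#' Screen seed sequences against two anchor genomes
#'
#' A seed is retained only if it has at least one hit in *both* anchors; the
#' intent is one dicot and one monocot anchor so that surviving seeds are not
#' clade-biased. Input order is preserved.
#'
#' @param seeds Sequence table of seed sequences.
#' @param anchor_a,anchor_b Sequence tables (one or more records each).
#' @param params See [align_params()].
#' @return A tibble with two rows per retained seed (its best hit per anchor):
#'   columns `seed_id`, `anchor` (`"A"`/`"B"`), `subject_id`, `s_start`,
#'   `s_end`, `strand`, `score`, `identity`.
#' @export
screen_seeds <- function(seeds, anchor_a, anchor_b, params = align_params()) {
  rows <- purrr::map(seq_len(nrow(seeds)), function(i) {
    seed <- seeds[i, ]
    ha <- search_collection(seed, anchor_a, params)
    hb <- search_collection(seed, anchor_b, params)
    if (nrow(ha) == 0 || nrow(hb) == 0) return(NULL)
    dplyr::bind_rows(
      dplyr::mutate(ha[1, ], anchor = "A", .after = "query_id"),
      dplyr::mutate(hb[1, ], anchor = "B", .after = "query_id")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      seed_id = character(), anchor = character(), subject_id = character(),
      s_start = integer(), s_end = integer(), strand = character(),
      score = numeric(), identity = numeric()
    ))
  }
  dplyr::select(dplyr::rename(out, seed_id = "query_id"),
                "seed_id", "anchor", "subject_id", "s_start", "s_end",
                "strand", "score", "identity")
}

#' Extend a homology hit into a candidate region
#'
#' Widens the subject interval of a hit by `flank` bases on each side, clipped
#' to the genome bounds, and extracts the region sequence. Minus-strand hits
#' are reverse-complemented so every region reads in seed orientation.
#'
#' @param hit One-row tibble with `query_id`, `subject_id`, `s_start`,
#'   `s_end`, `strand` (as returned by [local_align_search()]).
#' @param genome One-row sequence table the hit refers to.
#' @param flank Non-negative flank width in bases (default 200).
#' @return One-row tibble: `source_seed_id`, `genome_id`, `start`, `end`
#'   (0-based half-open), `sequence`.
#' @export
extend_hit <- function(hit, genome, flank = 200L) {
  stopifnot(nrow(hit) == 1L, flank >= 0L)
  g <- as_seq_entry(genome, "genome")
  if (!identical(hit$subject_id[[1]], g$id)) {
    stop("hit does not refer to this genome ('", hit$subject_id[[1]],
         "' vs '", g$id, "')", call. = FALSE)
  }
  len <- nchar(g$sequence)
  start <- max(0L, hit$s_start[[1]] - as.integer(flank))
  end <- min(len, hit$s_end[[1]] + as.integer(flank))
  seq <- subseq0(g$sequence, start, end)
  if (identical(hit$strand[[1]], "-")) seq <- reverse_complement(seq)
  tibble::tibble(
    source_seed_id = hit$query_id[[1]], genome_id = g$id,
    start = start, end = end, sequence = seq
  )
}
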