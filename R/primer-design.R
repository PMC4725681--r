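#' Base-26 triplet names for primer pairs
#'
#' Primer pairs within a conserved region are numbered `aaa`, `aab`, ...,
#' incrementing the rightmost letter first with carries (so index 26 is
#' `aba`). The inverse is [triplet_index()].
#'
#' @param index Non-negative integer(s) below 17576 (26^3).
#' @return Character vector of 3-letter lowercase names.
#' @export
triplet_name <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 0L | index >= 17576L)) {
    stop("triplet index must be in [0, 17575]", call. = FALSE)
  }
  paste0(letters[index %/% 676L + 1L],
         letters[(index %/% 26L) %% 26L + 1L],
         letters[index %% 26L + 1L])
}

#' @rdname triplet_name
#' @param name Character vector of 3-letter lowercase names.
#' @return For `triplet_index`, the integer index of each name.
#' @export
triplet_index <- function(name) {
  if (any(!grepl("^[a-z]{3}$", name))) {
    stop("triplet names are exactly three lowercase letters", call. = FALSE)
  }
  chars <- matrix(match(unlist(strsplit(name, "")), letters) - 1L,
                  ncol = 3L, byrow = TRUE)
  as.integer(chars[, 1] * 676L + chars[, 2] * 26L + chars[, 3])
}

#' Find conserved 20-column windows in a conservation profile
#'
#' A window qualifies when every one of its columns has
#' `majority_fraction >= min_conservation` and
#' `gap_fraction <= max_gap_fraction`. All qualifying start columns are
#' returned in ascending order. The defaults (0.90 conservation, zero gaps)
#' encode the requirement that primers must anneal across species and that
#' indels inside a binding site shift annealing.
#'
#' @param profile A `conservation_profile`.
#' @param window Window width in columns (design constant, default 20).
#' @param min_conservation Minimum per-column majority fraction (default 0.90).
#' @param max_gap_fraction Maximum per-column gap fraction (default 0).
#' @return A tibble of windows: `start`, `end` (0-based half-open columns),
#'   `min_conservation`, `max_gap_fraction`, `consensus` (strict consensus
#'   20-mer of the window).
#' @export
find_conserved_windows <- function(profile, window = 20L,
                                   min_conservation = 0.90,
                                   max_gap_fraction = 0) {
  nc <- nrow(profile)
  if (nc < window) {
    stop("profile shorter than the window width", call. = FALSE)
  }
  ok <- profile$majority_fraction >= min_conservation &
    profile$gap_fraction <= max_gap_fraction
  run <- stats::filter(as.numeric(ok), rep(1, window), sides = 1)
  starts <- which(!is.na(run) & run == window) - window  # 0-based
  rows <- purrr::map(starts, function(s) {
    cols <- profile[(s + 1L):(s + window), ]
    tibble::tibble(
      start = s, end = s + window,
      min_conservation = min(cols$majority_fraction),
      max_gap_fraction = max(cols$gap_fraction),
      consensus = paste(cols$majority_base, collapse = "")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(start = integer(), end = integer(),
                          min_conservation = numeric(),
                          max_gap_fraction = numeric(), consensus = character())
  }
  out
}

#' Enumerate candidate primer pairs from conserved windows
#'
#' Every combination of an upstream and a non-overlapping downstream window
#' whose implied amplicon length (downstream end minus upstream start,
#' primer-inclusive) falls within `[amplicon_min, amplicon_max]` yields one
#' pair. The forward primer is the strict consensus of the upstream window;
#' the reverse primer is the reverse complement of the strict consensus of the
#' downstream window (windows are taken on the profile's forward orientation
#' only). Pairs are ordered by (upstream start, downstream start) and named
#' `<seed_label>-<triplet>` with consecutive triplets starting at `aaa`.
#'
#' @param windows Window tibble from [find_conserved_windows()].
#' @param seed_label Label of the source conserved region (e.g. a seed id).
#' @param amplicon_min,amplicon_max Design bounds on the primer-inclusive
#'   amplicon length (defaults 100 and 350).
#' @return A tibble of pairs: `name`, `forward`, `reverse`, `amplicon_min`,
#'   `amplicon_max`, `upstream_start`, `downstream_start`, `implied_amplicon`.
#' @export
enumerate_primer_pairs <- function(windows, seed_label,
                                   amplicon_min = 100L, amplicon_max = 350L) {
  stopifnot(amplicon_min <= amplicon_max)
  empty <- tibble::tibble(
    name = character(), forward = character(), reverse = character(),
    amplicon_min = integer(), amplicon_max = integer(),
    upstream_start = integer(), downstream_start = integer(),
    implied_amplicon = integer()
  )
  if (nrow(windows) < 2L) return(empty)
  grid <- tidyr::expand_grid(u = seq_len(nrow(windows)),
                             d = seq_len(nrow(windows)))
  u_start <- windows$start[grid$u]
  u_end <- windows$end[grid$u]
  d_start <- windows$start[grid$d]
  d_end <- windows$end[grid$d]
  implied <- d_end - u_start
  keep <- d_start >= u_end & implied >= amplicon_min & implied <= amplicon_max
  grid <- grid[keep, ]
  if (nrow(grid) == 0) return(empty)
  ord <- order(windows$start[grid$u], windows$start[grid$d])
  grid <- grid[ord, ]
  tibble::tibble(
    name = paste0(seed_label, "-", triplet_name(seq_len(nrow(grid)) - 1L)),
    forward = windows$consensus[grid$u],
    reverse = reverse_complement(windows$consensus[grid$d]),
    amplicon_min = as.integer(amplicon_min),
    amplicon_max = as.integer(amplicon_max),
    upstream_start = windows$start[grid$u],
    downstream_start = windows$start[grid$d],
    implied_amplicon = as.integer(windows$end[grid$d] - windows$start[grid$u])
  )
}

#' Construct a single primer pair record
#'
#' Convenience constructor for downstream operations that take one pair.
#'
#' @param name Pair name (e.g. `"23579-aaa"`).
#' @param forward,reverse Primer sequences, 5' to 3' (IUPAC letters allowed).
#' @param amplicon_min,amplicon_max Design bounds (defaults 100, 350).
#' @return A one-row primer-pair tibble.
#' @export
primer_pair <- function(name, forward, reverse,
                        amplicon_min = 100L, amplicon_max = 350L) {
  forward <- normalize_seq(forward)
  reverse <- normalize_seq(reverse)
  stopifnot(grepl(iupac_regex, forward), grepl(iupac_regex, reverse))
  tibble::tibble(
    name = name, forward = forward, reverse = reverse,
    amplicon_min = as.integer(amplicon_min),
    amplicon_max = as.integer(amplicon_max)
  )
}

#' Write primer pairs as TSV or FASTA
#'
#' The FASTA dialect emits two records per pair with ids `<name>-F` and
#' `<name>-R`.
#'
#' @param pairs Primer-pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname write_primer_tsv
#' @export
write_primer_fasta <- function(pairs, path) {
  ids <- as.vector(rbind(paste0(pairs$name, "-F"), paste0(pairs$name, "-R")))
  seqs <- as.vector(rbind(pairs$forward, pairs$reverse))
  write_fasta(seq_tbl(ids, seqs), path)
}
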