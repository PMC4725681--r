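# Fit a primer against a candidate region by unit-cost global alignment
# (IUPAC-compatible columns cost 0). Returns total errors split into
# substitutions and gaps along one optimal path (diagonal preferred).
primer_fit <- function(primer, region) {
  p <- strsplit(primer, "")[[1]]
  r <- strsplit(region, "")[[1]]
  m <- length(p); n <- length(r)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  compat <- IUPAC_COMPAT
  for (i in seq_len(m)) {
    pi <- p[i]
    for (j in seq_len(n)) {
      sub <- if (compat[pi, r[j]]) 0L else 1L
      D[i + 1L, j + 1L] <- min(D[i, j] + sub, D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  # backtrack, preferring diagonal moves
  i <- m; j <- n; n_sub <- 0L; n_gap <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sub <- if (compat[p[i], r[j]]) 0L else 1L
      if (D[i + 1L, j + 1L] == D[i, j] + sub) {
        n_sub <- n_sub + sub; i <- i - 1L; j <- j - 1L; next
      }
    }
    if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      n_gap <- n_gap + 1L; i <- i - 1L
    } else {
      n_gap <- n_gap + 1L; j <- j - 1L
    }
  }
  list(errors = D[m + 1L, n + 1L], n_mismatches = n_sub, n_gaps = n_gap)
}

# Collapse overlapping same-strand placements to the one with fewest errors
# (ties: leftmost, then narrowest). Single-site reporting, as e-PCR does.
collapse_sites <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- dplyr::arrange(sites, .data$start, .data$end)
  grp <- integer(nrow(sites))
  g <- 1L; grp[1] <- 1L; max_end <- sites$end[1]
  for (i in seq_len(nrow(sites))[-1]) {
    if (sites$start[i] < max_end) {
      grp[i] <- g
      max_end <- max(max_end, sites$end[i])
    } else {
      g <- g + 1L; grp[i] <- g; max_end <- sites$end[i]
    }
  }
  sites$.grp <- grp
  out <- sites |>
    dplyr::group_by(.data$.grp) |>
    dplyr::arrange(.data$total_errors, .data$start, .data$end - .data$start,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  dplyr::select(dplyr::arrange(out, .data$start), -".grp")
}

#' Find approximate primer annealing sites on both strands
#'
#' Reports every forward-strand interval where a semi-global alignment of the
#' primer (or, for minus-strand sites, of its reverse complement) has at most
#' `max_errors` mismatches plus gaps. IUPAC degeneracy in the primer matches
#' compatible subject bases at zero cost; ambiguity codes in the subject are
#' treated as literal. Overlapping candidate placements are collapsed to the
#' placement with fewest errors (ties to the leftmost).
#'
#' @param primer Primer sequence (IUPAC letters allowed, length >= 10).
#' @param subject One-row sequence table or a bare character string.
#' @param max_errors Per-primer error budget (mismatches + gaps).
#' @return A tibble sorted by `start`: `subject_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `n_mismatches`, `n_gaps`,
#'   `total_errors`.
#' @export
find_primer_sites <- function(primer, subject, max_errors = 2L) {
  primer <- normalize_seq(primer)
  if (nchar(primer) < 10L) stop("primer must be at least 10 bases", call. = FALSE)
  s <- as_seq_entry(subject, "subject")
  sseq <- s$sequence
  max_errors <- as.integer(max_errors)
  fixed <- c(pattern = FALSE, subject = TRUE)

  scan_strand <- function(pat, strand) {
    subj <- Biostrings::DNAString(sseq)
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), subj,
      max.mismatch = max_errors, with.indels = max_errors > 0L, fixed = fixed
    )
    if (length(hits) == 0L) {
      return(tibble::tibble(subject_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            n_mismatches = integer(), n_gaps = integer(),
                            total_errors = integer()))
    }
    vs <- BiocGenerics::start(hits)
    ve <- BiocGenerics::end(hits)
    # the match engine supplies candidate neighbourhoods; make each placement
    # canonical by re-evaluating every window of length len +/- max_errors
    # around the candidate and keeping the fewest-error one (ties: leftmost,
    # then narrowest) -- the same rule collapse_sites applies across sites
    plen <- nchar(pat)
    slen <- nchar(sseq)
    refined <- purrr::map(seq_along(vs), function(i) {
      best <- NULL
      for (st in max(1L, vs[i] - max_errors):(vs[i] + max_errors)) {
        for (w in max(1L, plen - max_errors):(plen + max_errors)) {
          if (st + w - 1L > slen) next
          fit <- primer_fit(pat, substr(sseq, st, st + w - 1L))
          if (fit$errors > max_errors) next
          cand <- list(start = st - 1L, end = st + w - 1L, fit = fit)
          if (is.null(best) || fit$errors < best$fit$errors ||
              (fit$errors == best$fit$errors &&
                 (cand$start < best$start ||
                    (cand$start == best$start &&
                       (cand$end - cand$start) < (best$end - best$start))))) {
            best <- cand
          }
        }
      }
      best
    })
    refined <- refined[!vapply(refined, is.null, logical(1))]
    if (length(refined) == 0L) {
      return(tibble::tibble(subject_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            n_mismatches = integer(), n_gaps = integer(),
                            total_errors = integer()))
    }
    out <- tibble::tibble(
      subject_id = s$id,
      start = purrr::map_int(refined, ~ as.integer(.x$start)),
      end = purrr::map_int(refined, ~ as.integer(.x$end)),
      strand = strand,
      n_mismatches = purrr::map_int(refined,
                                    ~ as.integer(.x$fit$n_mismatches)),
      n_gaps = purrr::map_int(refined, ~ as.integer(.x$fit$n_gaps)),
      total_errors = purrr::map_int(refined, ~ as.integer(.x$fit$errors))
    )
    collapse_sites(dplyr::distinct(out))
  }

  out <- dplyr::bind_rows(
    scan_strand(primer, "+"),
    scan_strand(reverse_complement(primer), "-")
  )
  dplyr::arrange(out, .data$start, .data$end, .data$strand)
}

#' Predict PCR amplicons of a primer pair on a subject sequence
#'
#' Combines forward-primer sites with downstream reverse-complemented
#' reverse-primer sites (and the mirror-image products initiated on the minus
#' strand) into predicted products whose primer-inclusive length falls within
#' `[size_min, size_max]`. The `inner_sequence` always reads
#' forward-primer-first with both primer spans removed. Two error presets
#' mirror common scans: `"per_primer"` caps each primer's mismatches + gaps at
#' `per_primer_max` (database scans); `"total"` caps their sum at `total_max`
#' (genome scans).
#'
#' @param pair One-row primer-pair tibble (see [primer_pair()]).
#' @param subject One-row sequence table or a bare character string.
#' @param error_mode `"per_primer"` or `"total"`.
#' @param per_primer_max,total_max Error budgets (defaults 2 and 4).
#' @param size_min,size_max Primer-inclusive product length bounds
#'   (defaults 50 and 1000; the 100-350 design bounds apply at design time,
#'   not when scanning).
#' @return A tibble sorted by `start`: `subject_id`, `start`, `end`, `strand`,
#'   `length_with_primers`, `inner_sequence`, `forward_errors`,
#'   `reverse_errors`, `total_errors`. Deduplicated on the product interval.
#' @export
predict_amplicons <- function(pair, subject,
                              error_mode = c("per_primer", "total"),
                              per_primer_max = 2L, total_max = 4L,
                              size_min = 50L, size_max = 1000L) {
  error_mode <- match.arg(error_mode)
  stopifnot(nrow(pair) == 1L)
  s <- as_seq_entry(subject, "subject")
  budget <- if (error_mode == "per_primer") per_primer_max else total_max
  fs <- find_primer_sites(pair$forward[[1]], s$sequence, budget)
  rs <- find_primer_sites(pair$reverse[[1]], s$sequence, budget)

  combine <- function(up, down, strand) {
    if (nrow(up) == 0L || nrow(down) == 0L) return(NULL)
    grid <- tidyr::expand_grid(u = seq_len(nrow(up)), d = seq_len(nrow(down)))
    st <- up$start[grid$u]; en <- down$end[grid$d]
    len <- en - st
    ok <- down$start[grid$d] >= up$end[grid$u] &
      len >= size_min & len <= size_max
    grid <- grid[ok, ]
    if (nrow(grid) == 0L) return(NULL)
    if (strand == "+") {
      inner <- subseq0(s$sequence, up$end[grid$u], down$start[grid$d])
      f_err <- up$total_errors[grid$u]; r_err <- down$total_errors[grid$d]
    } else {
      inner <- reverse_complement(
        subseq0(s$sequence, up$end[grid$u], down$start[grid$d]))
      f_err <- down$total_errors[grid$d]; r_err <- up$total_errors[grid$u]
    }
    tibble::tibble(
      subject_id = s$id,
      start = up$start[grid$u], end = down$end[grid$d], strand = strand,
      length_with_primers = as.integer(down$end[grid$d] - up$start[grid$u]),
      inner_sequence = inner,
      forward_errors = f_err, reverse_errors = r_err,
      total_errors = f_err + r_err
    )
  }

  out <- dplyr::bind_rows(
    combine(fs[fs$strand == "+", ], rs[rs$strand == "-", ], "+"),
    combine(rs[rs$strand == "+", ], fs[fs$strand == "-", ], "-")
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(
      subject_id = character(), start = integer(), end = integer(),
      strand = character(), length_with_primers = integer(),
      inner_sequence = character(), forward_errors = integer(),
      reverse_errors = integer(), total_errors = integer()
    ))
  }
  if (error_mode == "per_primer") {
    out <- out[out$forward_errors <= per_primer_max &
                 out$reverse_errors <= per_primer_max, ]
  } else {
    out <- out[out$total_errors <= total_max, ]
  }
  out <- out |>
    dplyr::arrange(.data$total_errors, .data$strand) |>
    dplyr::distinct(.data$subject_id, .data$start, .data$end,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$start, .data$end)
  out
}

#' Construct a reference amplicon set
#'
#' `build_reference_set()` predicts amplicons of a primer pair across a
#' taxon-labelled sequence collection and keeps their inner sequences (primer
#' spans removed) labelled with the source species; `reference_set()` wraps an
#' existing record table. Records lacking a `species_taxid` are skipped with a
#' warning. Duplicate (inner sequence, taxid, source id) rows are collapsed.
#'
#' @param records For `build_reference_set`, a sequence table with
#'   `species_taxid` set; for `reference_set`, a tibble with columns
#'   `inner_sequence`, `species_taxid`, `source`, `source_id`.
#' @param pair One-row primer-pair tibble.
#' @param source Provenance label, `"genome"` or `"database"`.
#' @param ... Passed on to [predict_amplicons()].
#' @return A `reference_set` object.
#' @export
build_reference_set <- function(records, pair, source = "genome", ...) {
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    if (is.na(rec$species_taxid)) {
      warning("record '", rec$id, "' lacks a species_taxid; skipped",
              call. = FALSE)
      return(NULL)
    }
    amps <- predict_amplicons(pair, rec, ...)
    if (nrow(amps) == 0L) return(NULL)
    tibble::tibble(
      inner_sequence = amps$inner_sequence,
      species_taxid = rec$species_taxid,
      source = source,
      source_id = sprintf("%s:%d-%d", rec$id, amps$start, amps$end)
    )
  })
  reference_set(dplyr::bind_rows(rows))
}

#' @rdname build_reference_set
#' @export
reference_set <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- tibble::tibble(inner_sequence = character(),
                              species_taxid = integer(),
                              source = character(), source_id = character())
  }
  stopifnot(all(c("inner_sequence", "species_taxid", "source", "source_id")
                %in% names(records)))
  records <- dplyr::distinct(
    records, .data$inner_sequence, .data$species_taxid, .data$source,
    .data$source_id
  )
  structure(list(records = records), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", nrow(x$records), " records, ",
      dplyr::n_distinct(x$records$species_taxid), " species, ",
      dplyr::n_distinct(x$records$inner_sequence), " distinct inner sequences\n",
      sep = "")
  invisible(x)
}

#' Index of a reference set: inner sequence -> species set
#'
#' Rebuilt from the records on each call, so it is always consistent.
#'
#' @param refset A `reference_set`.
#' @return A tibble: `inner_sequence`, `taxids` (list column), `n_species`.
#' @export
ref_index <- function(refset) {
  refset$records |>
    dplyr::group_by(.data$inner_sequence) |>
    dplyr::summarise(taxids = list(sort(unique(.data$species_taxid))),
                     n_species = dplyr::n_distinct(.data$species_taxid),
                     .groups = "drop")
}

#' Count species-diagnostic amplicon sequences
#'
#' An inner sequence is diagnostic when it is observed in exactly one species
#' across the reference set; a species counts when it owns at least one
#' diagnostic sequence.
#'
#' @param refset A `reference_set`.
#' @return A tibble `species_taxid`, `n_diagnostic` (one row per species with
#'   at least one diagnostic sequence, so `nrow()` is the species tally).
#' @export
diagnostic_species_count <- function(refset) {
  idx <- ref_index(refset)
  diag <- idx[idx$n_species == 1L, ]
  if (nrow(diag) == 0L) {
    return(tibble::tibble(species_taxid = integer(), n_diagnostic = integer()))
  }
  tibble::tibble(species_taxid = purrr::map_int(diag$taxids, 1L)) |>
    dplyr::count(.data$species_taxid, name = "n_diagnostic")
}

#' Tally diagnostic species by taxonomy division
#'
#' Each species holding at least one diagnostic amplicon contributes one count
#' to its division (Plants, Invertebrates, Vertebrates, or other).
#'
#' @param refset A `reference_set`.
#' @param taxonomy A `taxonomy` object.
#' @return A tibble `division`, `n_species` with rows for all four labels.
#' @export
tally_divisions <- function(refset, taxonomy) {
  species <- diagnostic_species_count(refset)$species_taxid
  labels <- c("Plants", "Invertebrates", "Vertebrates", "other")
  div <- vapply(species, function(tx) {
    d <- tryCatch(division_of(taxonomy, tx), error = function(e) NA_character_)
    if (is.na(d)) {
      warning("taxid ", tx, " not resolvable; counted under 'other'",
              call. = FALSE)
      return("other")
    }
    if (d %in% labels) d else "other"
  }, character(1))
  tibble::tibble(division = factor(div, levels = labels)) |>
    dplyr::count(.data$division, name = "n_species", .drop = FALSE) |>
    dplyr::mutate(division = as.character(.data$division))
}

#' Serialize / load a reference set
#'
#' FASTA ids follow `<source>:<source_id>:<n>` with the species carried as a
#' `taxid=<int>` description token; the index TSV mirrors [ref_index()].
#'
#' @param refset A `reference_set`.
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_reference_fasta()` returns a
#'   `reference_set`.
#' @export
write_reference_fasta <- function(refset, path) {
  rec <- refset$records
  ids <- sprintf("%s:%s:%d", rec$source, rec$source_id, seq_len(nrow(rec)))
  write_fasta(seq_tbl(ids, rec$inner_sequence,
                      species_taxid = rec$species_taxid), path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- read_fasta(path)
  if (nrow(x) == 0L) return(reference_set(NULL))
  parts <- strsplit(x$id, ":")
  reference_set(tibble::tibble(
    inner_sequence = x$sequence,
    species_taxid = x$species_taxid,
    source = purrr::map_chr(parts, 1L),
    source_id = purrr::map_chr(parts, function(p) {
      paste(p[2:(length(p) - 1L)], collapse = ":")
    })
  ))
}

#' @rdname write_reference_fasta
#' @export
write_reference_index_tsv <- function(refset, path) {
  idx <- ref_index(refset)
  idx$taxids <- purrr::map_chr(idx$taxids, paste, collapse = ",")
  readr::write_tsv(idx, path)
  invisible(path)
}
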