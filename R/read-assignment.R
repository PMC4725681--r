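#' Define a multiplex-identifier (MID) scheme
#'
#' One row per sample with the MID carried by the forward and reverse fusion
#' primers (10-mers in the original design, e.g. MID1 `ACGAGTGCGT`, MID2
#' `ACGCTCGACA`). All MIDs must have the same length and every pair of
#' distinct MID sequences must differ at two or more positions; duplicate
#' sample labels or duplicate (forward, reverse) MID combinations are a
#' configuration error.
#'
#' @param sample Character vector of sample labels.
#' @param mid_f,mid_r Forward and reverse MID sequences per sample.
#' @return A `mid_scheme` tibble.
#' @export
mid_scheme <- function(sample, mid_f, mid_r = mid_f) {
  out <- tibble::tibble(sample = as.character(sample),
                        mid_f = normalize_seq(mid_f),
                        mid_r = normalize_seq(mid_r))
  if (anyDuplicated(out$sample)) {
    stop("duplicate sample labels in MID scheme", call. = FALSE)
  }
  if (anyDuplicated(paste(out$mid_f, out$mid_r))) {
    stop("duplicate (forward, reverse) MID combination in scheme",
         call. = FALSE)
  }
  mids <- unique(c(out$mid_f, out$mid_r))
  if (length(unique(nchar(mids))) > 1L) {
    stop("all MIDs in a scheme must have the same length", call. = FALSE)
  }
  if (length(mids) > 1L) {
    cmb <- utils::combn(mids, 2L)
    d <- apply(cmb, 2L, function(p) hamming(p[1], p[2]))
    if (any(d < 2L)) {
      stop("MIDs '", cmb[1, which(d < 2L)[1]], "' and '",
           cmb[2, which(d < 2L)[1]],
           "' differ at fewer than 2 positions", call. = FALSE)
    }
  }
  class(out) <- c("mid_scheme", class(out))
  out
}

#' Demultiplex reads by their 5' MID
#'
#' A read is routed to the unique sample whose forward or reverse MID matches
#' the read's 5' prefix within `max_mid_mismatches` substitutions (exact by
#' default); the MID prefix is removed from routed reads. Reads matching no
#' sample, or more than one, stay in the unassigned bin with their sequence
#' intact. Every read lands in exactly one bin.
#'
#' @param reads A sequence table.
#' @param scheme A [mid_scheme()].
#' @param max_mid_mismatches Substitution budget for the MID match (default 0).
#' @return A tibble with one row per input read: `id`, `sample`
#'   (`NA` for unassigned), `sequence` (MID-stripped when assigned).
#' @export
demultiplex <- function(reads, scheme, max_mid_mismatches = 0L) {
  stopifnot(inherits(scheme, "mid_scheme"))
  L <- nchar(scheme$mid_f[1])
  n <- nrow(reads)
  if (n == 0L) {
    return(tibble::tibble(id = character(), sample = character(),
                          sequence = character()))
  }
  prefix <- substr(reads$sequence, 1L, L)
  mids <- unique(c(scheme$mid_f, scheme$mid_r))
  dist <- matrix(0L, n, length(mids), dimnames = list(NULL, mids))
  for (m in mids) {
    mm <- integer(n)
    for (k in seq_len(L)) {
      mm <- mm + (substr(prefix, k, k) != substr(m, k, k))
    }
    dist[, m] <- mm
  }
  dist[nchar(prefix) < L, ] <- L  # too short to carry a MID
  n_match <- integer(n)
  assigned <- rep(NA_character_, n)
  for (i in seq_len(nrow(scheme))) {
    hit <- dist[, scheme$mid_f[i]] <= max_mid_mismatches |
      dist[, scheme$mid_r[i]] <= max_mid_mismatches
    n_match <- n_match + hit
    assigned[hit] <- scheme$sample[i]
  }
  assigned[n_match != 1L] <- NA_character_
  out_seq <- ifelse(is.na(assigned), reads$sequence,
                    substr(reads$sequence, L + 1L, nchar(reads$sequence)))
  tibble::tibble(id = reads$id, sample = assigned, sequence = out_seq)
}

# Anchored 5' fit of a (possibly degenerate) primer against a read prefix:
# minimal mismatches+gaps over prefix lengths in [m - max_e, m + max_e].
# Returns errors and the read position where the primer span ends.
prefix_fit <- function(primer, read, max_e) {
  p <- strsplit(primer, "")[[1]]
  m <- length(p)
  cap <- min(nchar(read), m + max_e)
  r <- strsplit(substr(read, 1L, cap), "")[[1]]
  ridx <- match(r, IUPAC_LETTERS)
  prev <- 0:cap
  for (i in seq_len(m)) {
    cur <- numeric(cap + 1L)
    cur[1] <- i
    compat_row <- IUPAC_COMPAT[p[i], ]
    for (j in seq_len(cap)) {
      sub <- if (!is.na(ridx[j]) && compat_row[ridx[j]]) 0L else 1L
      cur[j + 1L] <- min(prev[j] + sub, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  ends <- max(0L, m - max_e):cap
  costs <- prev[ends + 1L]
  best <- which(costs == min(costs))
  # prefer the end closest to the primer length, then the longer span
  pick <- best[order(abs(ends[best] - m), -ends[best])][1]
  list(errors = as.integer(costs[pick]), end = ends[pick])
}

revstr <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Anchored 3' fit: same contract as prefix_fit but from the read's 3' end.
suffix_fit <- function(primer, read, max_e) {
  prefix_fit(revstr(primer), revstr(read), max_e)
}

#' Orient reads by their 5' primer and trim primer spans
#'
#' Bidirectional amplicon sequencing yields reads starting with either the
#' forward or the reverse primer. A read beginning (within
#' `max_trim_errors`, semi-global) with the forward primer keeps its
#' orientation; one beginning with the reverse primer is reverse-complemented
#' into forward orientation. The matched 5' primer span is always removed;
#' the opposite primer span is removed best-effort when it is found within
#' budget at the other end (a short read without it is kept, not rejected).
#' Reads matching neither primer at the 5' end are rejected.
#'
#' @param reads A sequence table (MID already removed).
#' @param pair One-row primer-pair tibble.
#' @param max_trim_errors Mismatch+gap budget per primer match (default 2).
#' @return A tibble, one row per input read: `id`, `sequence` (the inner
#'   sequence for trimmed reads, the original for rejected ones),
#'   `orientation` (`"+"`, `"-"`, or `NA`), `status`
#'   (`"trimmed"` / `"rejected"`).
#' @export
orient_and_trim <- function(reads, pair, max_trim_errors = 2L) {
  stopifnot(nrow(pair) == 1L)
  fwd <- pair$forward[[1]]
  rev <- pair$reverse[[1]]
  rc_rev <- reverse_complement(rev)
  n <- nrow(reads)
  out_seq <- reads$sequence
  orientation <- rep(NA_character_, n)
  status <- rep("rejected", n)

  trim_tail <- function(seqs) {
    # best-effort removal of the reverse-complemented reverse primer at 3'
    exact <- endsWith(seqs, rc_rev)
    seqs[exact] <- substr(seqs[exact], 1L,
                          nchar(seqs[exact]) - nchar(rc_rev))
    todo <- which(!exact & nchar(seqs) >= nchar(rc_rev) - max_trim_errors)
    for (i in todo) {
      f <- suffix_fit(rc_rev, seqs[i], max_trim_errors)
      if (f$errors <= max_trim_errors) {
        seqs[i] <- substr(seqs[i], 1L, nchar(seqs[i]) - f$end)
      }
    }
    seqs
  }

  f_exact <- startsWith(reads$sequence, fwd)
  r_exact <- !f_exact & startsWith(reads$sequence, rev)
  # forward exact path
  if (any(f_exact)) {
    orientation[f_exact] <- "+"
    status[f_exact] <- "trimmed"
    out_seq[f_exact] <- trim_tail(substr(reads$sequence[f_exact],
                                         nchar(fwd) + 1L,
                                         nchar(reads$sequence[f_exact])))
  }
  # reverse exact path: trim the reverse primer, flip, then trim the forward
  if (any(r_exact)) {
    rest <- substr(reads$sequence[r_exact], nchar(rev) + 1L,
                   nchar(reads$sequence[r_exact]))
    flipped <- reverse_complement(rest)
    exact_f <- startsWith(flipped, fwd)
    flipped[exact_f] <- substr(flipped[exact_f], nchar(fwd) + 1L,
                               nchar(flipped[exact_f]))
    for (k in which(!exact_f)) {
      f <- prefix_fit(fwd, flipped[k], max_trim_errors)
      if (f$errors <= max_trim_errors) {
        flipped[k] <- substr(flipped[k], f$end + 1L, nchar(flipped[k]))
      }
    }
    orientation[r_exact] <- "-"
    status[r_exact] <- "trimmed"
    out_seq[r_exact] <- flipped
  }
  # approximate path for everything else
  todo <- which(!f_exact & !r_exact)
  for (i in todo) {
    sq <- reads$sequence[i]
    ff <- prefix_fit(fwd, sq, max_trim_errors)
    fr <- prefix_fit(rev, sq, max_trim_errors)
    if (ff$errors <= max_trim_errors && ff$errors <= fr$errors) {
      inner <- substr(sq, ff$end + 1L, nchar(sq))
      out_seq[i] <- trim_tail(inner)
      orientation[i] <- "+"
      status[i] <- "trimmed"
    } else if (fr$errors <= max_trim_errors) {
      flipped <- reverse_complement(substr(sq, fr$end + 1L, nchar(sq)))
      f2 <- prefix_fit(fwd, flipped, max_trim_errors)
      if (f2$errors <= max_trim_errors) {
        flipped <- substr(flipped, f2$end + 1L, nchar(flipped))
      }
      out_seq[i] <- flipped
      orientation[i] <- "-"
      status[i] <- "trimmed"
    }
  }
  tibble::tibble(id = reads$id, sequence = out_seq,
                 orientation = orientation, status = status)
}

#' Cluster reads with references at full-length 100% identity
#'
#' Clusters are the equivalence classes of exact, full-length string identity
#' over the union of inner reads and reference inner sequences (the cd-hit
#' `-c 1.0 -aL 1 -aS 1` semantics: a single base difference, or a length
#' difference, separates clusters). Each cluster is categorised as `mixed`
#' (reads and references), `reads_only`, or `refs_only`.
#'
#' @param inner_reads A tibble with `id` and `sequence` columns (e.g. the
#'   trimmed rows from [orient_and_trim()]).
#' @param refset A `reference_set`.
#' @return A tibble of clusters: `representative` (the shared sequence),
#'   `n_reads`, `n_refs`, `category`, and list columns `read_ids`,
#'   `ref_taxids`, `ref_source_ids`.
#' @export
cluster_exact <- function(inner_reads, refset) {
  reads_g <- inner_reads |>
    dplyr::group_by(representative = .data$sequence) |>
    dplyr::summarise(read_ids = list(.data$id), n_reads = dplyr::n(),
                     .groups = "drop")
  refs_g <- refset$records |>
    dplyr::group_by(representative = .data$inner_sequence) |>
    dplyr::summarise(ref_taxids = list(.data$species_taxid),
                     ref_source_ids = list(.data$source_id),
                     n_refs = dplyr::n(), .groups = "drop")
  out <- dplyr::full_join(reads_g, refs_g, by = "representative")
  out$n_reads[is.na(out$n_reads)] <- 0L
  out$n_refs[is.na(out$n_refs)] <- 0L
  out$read_ids <- purrr::map(out$read_ids, ~ .x %||% character())
  out$ref_taxids <- purrr::map(out$ref_taxids, ~ .x %||% integer())
  out$ref_source_ids <- purrr::map(out$ref_source_ids, ~ .x %||% character())
  out$category <- dplyr::case_when(
    out$n_reads > 0L & out$n_refs > 0L ~ "mixed",
    out$n_reads > 0L ~ "reads_only",
    TRUE ~ "refs_only"
  )
  dplyr::arrange(out, dplyr::desc(.data$n_reads), .data$representative)
}

#' Conclude clusters taxonomically and assemble a report
#'
#' Mixed clusters with references from a single species conclude that
#' species; with several species, the conclusion is their lowest common
#' ancestor. Reads-only clusters have no conclusion and count as unassigned;
#' refs-only clusters are excluded from the ranked table but retained in the
#' totals. The ranked table is ordered by descending read count, ties broken
#' by the representative sequence.
#'
#' @param clusters Cluster tibble from [cluster_exact()].
#' @param taxonomy A `taxonomy` resolving every reference taxid.
#' @param n_input,n_demuxed Optional upstream totals (raw reads in, reads
#'   surviving demultiplexing) to carry into the report.
#' @return A `cluster_report`: list with `clusters` (the ranked mixed
#'   clusters, numbered), `reads_only`, `refs_only`, and `totals`.
#' @export
conclude_clusters <- function(clusters, taxonomy, n_input = NULL,
                              n_demuxed = NULL) {
  mixed <- clusters[clusters$category == "mixed", ]
  reads_only <- clusters[clusters$category == "reads_only", ]
  refs_only <- clusters[clusters$category == "refs_only", ]
  if (nrow(mixed) > 0L) {
    concl <- purrr::map_int(mixed$ref_taxids, function(tx) {
      tx <- unique(tx)
      if (length(tx) == 1L) tx else
        as.integer(lowest_common_ancestor(taxonomy, tx))
    })
    mixed$conclusion_taxid <- concl
    mixed$conclusion_name <- tax_name(taxonomy, concl)
    mixed$conclusion_rank <- tax_rank(taxonomy, concl)
  } else {
    mixed$conclusion_taxid <- integer()
    mixed$conclusion_name <- character()
    mixed$conclusion_rank <- character()
  }
  mixed <- dplyr::arrange(mixed, dplyr::desc(.data$n_reads),
                          .data$representative)
  mixed$cluster <- seq_len(nrow(mixed))
  mixed <- dplyr::relocate(mixed, "cluster")
  assigned <- sum(mixed$n_reads)
  unassigned <- sum(reads_only$n_reads)
  trimmed <- assigned + unassigned
  totals <- list(
    reads_in = as.integer(n_input %||% n_demuxed %||% trimmed),
    demuxed = as.integer(n_demuxed %||% trimmed),
    trimmed = as.integer(trimmed),
    assigned = as.integer(assigned),
    unassigned = as.integer(unassigned)
  )
  structure(list(clusters = mixed, reads_only = reads_only,
                 refs_only = refs_only, totals = totals),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  t <- x$totals
  cat("<cluster_report> ", nrow(x$clusters), " mixed clusters | reads: ",
      t$reads_in, " in, ", t$assigned, " assigned, ", t$unassigned,
      " unassigned\n", sep = "")
  if (nrow(x$clusters) > 0L) {
    show <- utils::head(x$clusters, 10L)
    print(dplyr::select(show, "cluster", "n_reads", "n_refs",
                        "conclusion_name"))
  }
  invisible(x)
}

#' Aggregate a cluster report per concluded taxon
#'
#' Each concluded cluster contributes its reads to exactly one taxonomy node
#' (its conclusion); the lineage string is included for rendering along a
#' taxonomy line. Direct counts are reported, so `sum(n_reads)` equals the
#' report's assigned total.
#'
#' @param report A `cluster_report`.
#' @param taxonomy The `taxonomy` used to conclude it.
#' @return A tibble: `taxid`, `name`, `rank`, `n_clusters`, `n_reads`,
#'   `lineage` (root -> node, `;`-separated names).
#' @export
taxonomy_summary <- function(report, taxonomy) {
  cl <- report$clusters
  if (nrow(cl) == 0L) {
    return(tibble::tibble(taxid = integer(), name = character(),
                          rank = character(), n_clusters = integer(),
                          n_reads = integer(), lineage = character()))
  }
  out <- cl |>
    dplyr::group_by(taxid = .data$conclusion_taxid) |>
    dplyr::summarise(n_clusters = dplyr::n(), n_reads = sum(.data$n_reads),
                     .groups = "drop")
  out$name <- tax_name(taxonomy, out$taxid)
  out$rank <- tax_rank(taxonomy, out$taxid)
  out$lineage <- vapply(out$taxid, function(tx) {
    paste(rev(lineage(taxonomy, tx)$name), collapse = ";")
  }, character(1))
  dplyr::arrange(dplyr::relocate(out, "taxid", "name", "rank"),
                 dplyr::desc(.data$n_reads))
}

#' Run the full read-assignment stage
#'
#' Convenience wrapper chaining [demultiplex()] (optional),
#' [orient_and_trim()], [cluster_exact()] and [conclude_clusters()], with
#' read-count totals threaded through every stage.
#'
#' @param reads A sequence table of raw reads.
#' @param pair One-row primer-pair tibble.
#' @param refset A `reference_set`.
#' @param taxonomy A `taxonomy`.
#' @param scheme Optional [mid_scheme()]; when given, only reads routed to
#'   `sample` are analysed.
#' @param sample Sample label to keep after demultiplexing (defaults to the
#'   scheme's first sample).
#' @param max_mid_mismatches,max_trim_errors Stage budgets (defaults 0 and 2).
#' @return A `cluster_report`.
#' @export
assign_reads <- function(reads, pair, refset, taxonomy, scheme = NULL,
                         sample = NULL, max_mid_mismatches = 0L,
                         max_trim_errors = 2L) {
  n_input <- nrow(reads)
  if (!is.null(scheme)) {
    dm <- demultiplex(reads, scheme, max_mid_mismatches)
    sample <- sample %||% scheme$sample[1]
    reads <- dm[!is.na(dm$sample) & dm$sample == sample,
                c("id", "sequence")]
  }
  n_demuxed <- nrow(reads)
  trimmed <- orient_and_trim(reads, pair, max_trim_errors)
  inner <- trimmed[trimmed$status == "trimmed", c("id", "sequence")]
  clusters <- cluster_exact(inner, refset)
  conclude_clusters(clusters, taxonomy, n_input = n_input,
                    n_demuxed = n_demuxed)
}

#' Write / read a cluster report as TSV
#'
#' The ranked table mirrors the columns of a barcode cluster report (cluster,
#' read and reference counts, reference species, conclusion); totals travel
#' as `#total <key>=<value>` comment lines.
#'
#' @param report A `cluster_report`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_cluster_report()` returns a
#'   `cluster_report` (ranked clusters and totals only).
#' @export
write_cluster_report <- function(report, path) {
  cl <- report$clusters
  flat <- tibble::tibble(
    cluster = cl$cluster,
    n_reads = cl$n_reads,
    n_refs = cl$n_refs,
    ref_taxids = purrr::map_chr(cl$ref_taxids, paste, collapse = ","),
    ref_source_ids = purrr::map_chr(cl$ref_source_ids, paste, collapse = ","),
    conclusion_taxid = cl$conclusion_taxid,
    conclusion_name = cl$conclusion_name,
    conclusion_rank = cl$conclusion_rank,
    representative = cl$representative
  )
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(report$totals)) {
    writeLines(sprintf("#total %s=%d", k, report$totals[[k]]), con)
  }
  writeLines(paste(names(flat), collapse = "\t"), con)
  if (nrow(flat) > 0L) {
    writeLines(do.call(paste, c(as.list(flat), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tot_lines <- grep("^#total ", lines, value = TRUE)
  totals <- list()
  for (ln in tot_lines) {
    kv <- strsplit(sub("^#total ", "", ln), "=")[[1]]
    totals[[kv[1]]] <- as.integer(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           colClasses = "character")
  cl <- tibble::tibble(
    cluster = as.integer(tab$cluster),
    representative = tab$representative,
    read_ids = purrr::map(as.integer(tab$n_reads), ~ character()),
    n_reads = as.integer(tab$n_reads),
    ref_taxids = purrr::map(strsplit(tab$ref_taxids, ","), as.integer),
    ref_source_ids = strsplit(tab$ref_source_ids, ","),
    n_refs = as.integer(tab$n_refs),
    category = "mixed",
    conclusion_taxid = as.integer(tab$conclusion_taxid),
    conclusion_name = tab$conclusion_name,
    conclusion_rank = tab$conclusion_rank
  )
  structure(list(clusters = cl,
                 reads_only = cl[0, setdiff(names(cl), c("cluster",
                   "conclusion_taxid", "conclusion_name", "conclusion_rank"))],
                 refs_only = cl[0, ],
                 totals = totals),
            class = "cluster_report")
}
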