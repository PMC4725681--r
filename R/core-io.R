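#' Build a sequence table
#'
#' Sequence collections are plain tibbles with one row per record, so they can
#' be filtered, joined and summarised with ordinary dplyr verbs. This helper
#' builds one from vectors, normalising sequences to uppercase DNA (RNA `U` is
#' mapped to `T`).
#'
#' @param id Character vector of record identifiers (non-empty tokens).
#' @param sequence Character vector of nucleotide sequences (IUPAC letters).
#' @param description Free-text description per record (default `""`).
#' @param species_taxid Optional integer NCBI-style taxon id per record.
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `species_taxid`.
#' @export
seq_tbl <- function(id, sequence, description = "", species_taxid = NA_integer_) {
  id <- as.character(id)
  if (any(is.na(id) | id == "" | grepl("\\s", id))) {
    stop("sequence ids must be non-empty tokens without whitespace", call. = FALSE)
  }
  sequence <- normalize_seq(as.character(sequence))
  bad <- !grepl(iupac_regex, sequence)
  if (any(bad)) {
    stop("non-IUPAC character in sequence for id '", id[which(bad)[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(
    id = id,
    description = rep_len(as.character(description), length(id)),
    sequence = sequence,
    species_taxid = rep_len(as.integer(species_taxid), length(id))
  )
}

# Pull "taxid=<int>" out of a description string; NA when absent.
parse_taxid_token <- function(description) {
  m <- regmatches(description, regexpr("taxid=\\d+", description))
  out <- rep(NA_integer_, length(description))
  hit <- lengths(regmatches(description, gregexpr("taxid=\\d+", description))) > 0
  out[hit] <- as.integer(sub("taxid=", "", m))
  out
}

# Pre-scan a FASTA file so parse errors can name the offending line.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(invisible(lines))
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      if (!grepl("^>\\S", ln)) {
        stop("malformed FASTA header at line ", i, " of '", path, "'",
             call. = FALSE)
      }
      seen_header <- TRUE
    } else if (nzchar(trimws(ln))) {
      if (!seen_header) {
        stop("sequence data before first FASTA header at line ", i, " of '",
             path, "'", call. = FALSE)
      }
      if (!grepl(iupac_regex, normalize_seq(trimws(ln)))) {
        stop("non-IUPAC character at line ", i, " of '", path, "'",
             call. = FALSE)
      }
    }
  }
  invisible(lines)
}

#' Read a FASTA file into a sequence table
#'
#' One row per `>` record, in file order. Sequences are uppercased and RNA `U`
#' is normalised to `T`. A `taxid=<int>` token anywhere in the description is
#' parsed into the `species_taxid` column. Malformed headers or non-IUPAC
#' characters raise an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A sequence table (see [seq_tbl()]); zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  validate_fasta_lines(path)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    return(seq_tbl(character(), character()))
  }
  x <- Biostrings::readBStringSet(path)
  full <- names(x) %||% character()
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  out <- seq_tbl(id, as.character(x), description = desc)
  out$species_taxid <- parse_taxid_token(out$description)
  out
}

#' Read sequencing reads (FASTA or FASTQ)
#'
#' FASTQ quality lines are discarded; the format is auto-detected from the
#' first character of the file (`@` for FASTQ, `>` for FASTA).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return A sequence table.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  first <- substr(readLines(path, n = 1L, warn = FALSE)[1] %||% "", 1L, 1L)
  if (identical(first, "@")) {
    x <- Biostrings::readBStringSet(path, format = "fastq")
    full <- names(x) %||% character()
    seq_tbl(sub("\\s.*$", "", full), as.character(x),
            description = ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), ""))
  } else {
    read_fasta(path)
  }
}

#' Write a sequence table to FASTA
#'
#' Records with a `species_taxid` but no `taxid=` token in their description
#' get one appended, so taxon labels survive the round trip. Duplicate ids are
#' reported with a warning but still written.
#'
#' @param records A sequence table.
#' @param path Output file path.
#' @param line_width Positive integer, bases per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  if (nrow(records) > 0 && anyDuplicated(records$id)) {
    warning("duplicate sequence ids written to '", path, "'", call. = FALSE)
  }
  desc <- records$description %||% rep("", nrow(records))
  desc[is.na(desc)] <- ""
  taxid <- records$species_taxid %||% rep(NA_integer_, nrow(records))
  add <- !is.na(taxid) & !grepl("taxid=\\d+", desc)
  desc[add] <- trimws(paste(desc[add], paste0("taxid=", taxid[add])))
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  x <- Biostrings::BStringSet(stats::setNames(records$sequence, header))
  Biostrings::writeXStringSet(x, filepath = path, width = line_width)
  invisible(path)
}

#' Attach taxon ids from a sidecar TSV
#'
#' Accepts the two-column dialect `seq_id<TAB>taxid` (no header required; a
#' header line with non-numeric second field is skipped).
#'
#' @param records A sequence table.
#' @param path Path to the two-column TSV.
#' @return `records` with `species_taxid` filled from the map.
#' @export
attach_taxids <- function(records, path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", col.names = c("id", "taxid"))
  tab <- tab[grepl("^\\d+$", tab$taxid), , drop = FALSE]
  idx <- match(records$id, tab$id)
  hit <- !is.na(idx)
  records$species_taxid[hit] <- as.integer(tab$taxid[idx[hit]])
  records
}

#' Reverse complement of nucleotide sequences
#'
#' Honours IUPAC degeneracy (R<->Y, S<->S, W<->W, K<->M, N<->N) and preserves
#' gap characters. Vectorised over its input.
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  bad <- !grepl(iupac_regex, seq)
  if (any(bad)) {
    stop("non-IUPAC character in sequence: '", seq[which(bad)[1]], "'",
         call. = FALSE)
  }
  out <- character(length(seq))
  nz <- nzchar(seq)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz]))
    )
  }
  out
}
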