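#' C-value table (1C genome mass per species)
#'
#' @param species_taxid Integer taxids.
#' @param c_pg Strictly positive 1C genome masses in picograms.
#' @param name Optional species names.
#' @return A `cvalue_table` tibble.
#' @export
cvalue_table <- function(species_taxid, c_pg, name = NA_character_) {
  c_pg <- as.numeric(c_pg)
  if (any(is.na(c_pg) | c_pg <= 0)) {
    stop("C-values must be strictly positive", call. = FALSE)
  }
  out <- tibble::tibble(species_taxid = as.integer(species_taxid),
                        name = rep_len(as.character(name),
                                       length(species_taxid)),
                        c_pg = c_pg)
  class(out) <- c("cvalue_table", class(out))
  out
}

#' Read / write a C-value TSV (`taxid`, `name`, `c_pg`)
#' @param path File path.
#' @return A `cvalue_table`.
#' @export
read_cvalues <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  cvalue_table(tab$taxid, tab$c_pg, tab$name)
}

#' @rdname read_cvalues
#' @param cvalues A `cvalue_table`.
#' @export
write_cvalues <- function(cvalues, path) {
  readr::write_tsv(tibble::tibble(taxid = cvalues$species_taxid,
                                  name = cvalues$name,
                                  c_pg = cvalues$c_pg), path)
  invisible(path)
}

#' Select the marker reference for a species from a pure-sample report
#'
#' Among mixed clusters whose reference set is exactly one record of the
#' given species, returns the source id of the cluster with the most reads
#' (ties go to the first cluster in report order). Copy numbers and PCR
#' efficiency vary between loci, so a single well-amplifying, species-specific
#' locus is used as the quantification marker rather than summing all
#' clusters.
#'
#' @param pure_report A `cluster_report` from a pure sample of the species.
#' @param species Taxid of the species.
#' @return The marker reference `source_id` (character scalar).
#' @export
select_marker_reference <- function(pure_report, species) {
  cl <- pure_report$clusters
  ok <- cl$n_refs == 1L &
    purrr::map_lgl(cl$ref_taxids, ~ length(.x) == 1L &&
                     .x[[1]] == as.integer(species))
  cand <- cl[ok, ]
  if (nrow(cand) == 0L) {
    stop("no species-specific marker for taxid ", species, call. = FALSE)
  }
  cand <- cand[order(-cand$n_reads, cand$cluster), ]
  cand$ref_source_ids[[1]][[1]]
}

#' Quantify a species mixture from marker-cluster read counts
#'
#' For each species, the raw count is the read count of the mixture cluster
#' containing that species' marker reference (0 when absent). Counts are
#' corrected multiplicatively by the species' 1C genome mass
#' (`corrected = raw_reads * c_pg`, a picogram-weighted read mass: reads are
#' proportional to template copies and mass to copies times genome mass), and
#' converted to percentages of the corrected total, rounded half-up to one
#' decimal.
#'
#' @param mix_report A `cluster_report` from the mixed sample.
#' @param markers Mapping species -> marker reference id: a tibble with
#'   `species_taxid` and `source_id`, or a named character vector (names are
#'   taxids).
#' @param cvalues A `cvalue_table` covering every marker species.
#' @return A `quant_result` tibble: `species_taxid`, `name`, `marker_id`,
#'   `raw_reads`, `c_pg`, `corrected`, `percent`. Percentages sum to
#'   100 +/- 0.1 after rounding.
#' @export
quantify_mixture <- function(mix_report, markers, cvalues) {
  if (is.character(markers)) {
    markers <- tibble::tibble(species_taxid = as.integer(names(markers)),
                              source_id = unname(markers))
  }
  missing <- setdiff(markers$species_taxid, cvalues$species_taxid)
  if (length(missing) > 0L) {
    stop("no C-value for marker species ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cl <- mix_report$clusters
  raw <- vapply(markers$source_id, function(sid) {
    hit <- purrr::map_lgl(cl$ref_source_ids, ~ sid %in% .x)
    if (!any(hit)) 0L else as.integer(cl$n_reads[which(hit)[1]])
  }, integer(1), USE.NAMES = FALSE)
  ci <- match(markers$species_taxid, cvalues$species_taxid)
  corrected <- raw * cvalues$c_pg[ci]
  total <- sum(corrected)
  percent <- if (total > 0) round_half_up(100 * corrected / total, 1L)
             else rep(NA_real_, length(corrected))
  out <- tibble::tibble(
    species_taxid = markers$species_taxid,
    name = cvalues$name[ci],
    marker_id = markers$source_id,
    raw_reads = raw,
    c_pg = cvalues$c_pg[ci],
    corrected = corrected,
    percent = percent
  )
  class(out) <- c("quant_result", class(out))
  out
}

#' Write a quantification result as TSV
#' @param result A `quant_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path)
  invisible(path)
}
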