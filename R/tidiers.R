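#' Tidy a cluster report
#'
#' Flattens the ranked clusters into one row per cluster with reference
#' taxids collapsed to a comma-separated string.
#'
#' @param x A `cluster_report`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.cluster_report <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    cluster = cl$cluster,
    n_reads = cl$n_reads,
    n_refs = cl$n_refs,
    ref_taxids = purrr::map_chr(cl$ref_taxids, paste, collapse = ","),
    conclusion_taxid = cl$conclusion_taxid,
    conclusion_name = cl$conclusion_name,
    conclusion_rank = cl$conclusion_rank
  )
}

#' @rdname tidy.cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::as_tibble(x$totals)
}

#' Tidy a reference set
#'
#' @param x A `reference_set`.
#' @param ... Ignored.
#' @return The record tibble (`tidy`) or a one-row summary (`glance`) with
#'   record, species, distinct-sequence and diagnostic-species counts.
#' @export
tidy.reference_set <- function(x, ...) {
  x$records
}

#' @rdname tidy.reference_set
#' @export
glance.reference_set <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_species = dplyr::n_distinct(x$records$species_taxid),
    n_sequences = dplyr::n_distinct(x$records$inner_sequence),
    n_diagnostic_species = nrow(diagnostic_species_count(x))
  )
}

#' @rdname tidy.cluster_report
#' @export
glance.quant_result <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    total_raw_reads = sum(x$raw_reads),
    total_corrected = sum(x$corrected),
    percent_sum = sum(x$percent)
  )
}
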