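#' Pipeline configuration
#'
#' Central home of the pipeline constants: 20-base primer windows, a design
#' amplicon range of 100-350 bases, a per-primer annealing error budget of 2
#' (database scans) or a total budget of 4 across both primers (genome
#' scans), scan size bounds of 50-1000, a minimum per-column conservation of
#' 0.90 with zero gap tolerance inside windows, a 200-base seed-extension
#' flank, exact MID matching and a primer-trim budget of 2. Two named presets
#' switch the in-silico PCR error mode: `"genome-scan"` (total budget) and
#' `"db-scan"` (per-primer budget).
#'
#' @param preset Optional preset name (`"genome-scan"` or `"db-scan"`).
#' @param ... Named overrides of individual fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = NULL, ...) {
  cfg <- list(
    window = 20L,
    amplicon_min = 100L, amplicon_max = 350L,
    per_primer_max = 2L, total_max = 4L,
    error_mode = "per_primer",
    size_min = 50L, size_max = 1000L,
    min_conservation = 0.90, max_gap_fraction = 0,
    flank = 200L,
    max_mid_mismatches = 0L, max_trim_errors = 2L,
    seed = 1L
  )
  if (!is.null(preset)) {
    cfg$error_mode <- switch(preset,
      "genome-scan" = "total",
      "db-scan" = "per_primer",
      stop("unknown preset '", preset, "'", call. = FALSE)
    )
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$amplicon_min <= cfg$amplicon_max,
            cfg$size_min <= cfg$size_max,
            cfg$per_primer_max >= 0L, cfg$total_max >= 0L,
            cfg$max_mid_mismatches >= 0L, cfg$max_trim_errors >= 0L)
  structure(cfg, class = "pipeline_config")
}
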