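# Shared fixture builders (all generated in code; no stored data).

# A cluster report shaped like a pure-maize barcode run: the top cluster has
# two reference reads, the runner-up a single reference backed by record
# AI677436, mirroring the structure used for marker selection.
make_pure_maize_report <- function() {
  tax <- nucbarcode::poaceae_taxonomy()
  inner1 <- strrep("ACGT", 10)
  inner2 <- strrep("GGCA", 10)
  inner3 <- strrep("TTGC", 10)
  refs <- nucbarcode::reference_set(tibble::tibble(
    inner_sequence = c(inner1, inner1, inner2, inner3),
    species_taxid = c(4577L, 4577L, 4577L, 4577L),
    source = c("genome", "genome", "database", "genome"),
    source_id = c("zm_chr5:100-294", "zm_chr2:40-234", "AI677436",
                  "zm_chr1:10-204")
  ))
  reads <- tibble::tibble(
    id = sprintf("r%05d", seq_len(6602 + 3652 + 2806)),
    sequence = c(rep(inner1, 6602), rep(inner2, 3652), rep(inner3, 2806))
  )
  clusters <- nucbarcode::cluster_exact(reads, refs)
  nucbarcode::conclude_clusters(clusters, tax)
}

# A mixture report carrying one marker cluster per species with prescribed
# read counts (used to replay printed quantification tables).
make_marker_report <- function(raw_soy, raw_maize,
                               soy_marker = "gm_chr1:3082442-3082595",
                               maize_marker = "AI677436") {
  tax <- nucbarcode::poaceae_taxonomy()
  inner_soy <- strrep("AACG", 10)
  inner_maize <- strrep("GTTC", 10)
  refs <- nucbarcode::reference_set(tibble::tibble(
    inner_sequence = c(inner_soy, inner_maize),
    species_taxid = c(3847L, 4577L),
    source = c("genome", "database"),
    source_id = c(soy_marker, maize_marker)
  ))
  reads <- tibble::tibble(
    id = sprintf("r%05d", seq_len(raw_soy + raw_maize)),
    sequence = c(rep(inner_soy, raw_soy), rep(inner_maize, raw_maize))
  )
  clusters <- nucbarcode::cluster_exact(reads, refs)
  nucbarcode::conclude_clusters(clusters, tax)
}

maize_soy_cvalues <- function() {
  nucbarcode::cvalue_table(c(3847L, 4577L), c(1.13, 2.73),
                           c("Glycine max", "Zea mays"))
}

# Small two-species simulation universe reused by end-to-end tests.
make_sim_universe <- function(seed = 2, genome_length = 6000L) {
  species <- tibble::tibble(taxid = c(4577L, 3847L),
                            name = c("Zea mays", "Glycine max"))
  sim <- nucbarcode::simulate_genomes(species, genome_length = genome_length,
                                      seed = seed)
  list(
    sim = sim,
    pair = nucbarcode::primer_pair("sim-aaa", sim$locus$forward,
                                   sim$locus$reverse),
    cv = maize_soy_cvalues(),
    mids = nucbarcode::mid_scheme("S1", "ACGAGTGCGT", "ACGCTCGACA"),
    tax = nucbarcode::poaceae_taxonomy()
  )
}
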