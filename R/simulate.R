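#' Fixed fixture taxonomy with standard grass and legume lineages
#'
#' Encodes the standard lineages of Zea mays, Triticum aestivum, Panicum
#' virgatum, Oryza sativa/brachyantha (Poaceae), Glycine max/soja (Fabaceae),
#' Fragaria x ananassa (Rosaceae), plus a vertebrate (Homo sapiens) and an
#' invertebrate (Aedes aegypti) branch, using real NCBI taxids. Useful as a
#' hermetic stand-in for the NCBI taxonomy in worked examples and tests.
#'
#' @return A `taxonomy` object.
#' @export
poaceae_taxonomy <- function() {
  nodes <- tibble::tribble(
    ~taxid, ~parent, ~rank, ~name, ~division,
    1L, 1L, "no rank", "root", "",
    2759L, 1L, "superkingdom", "Eukaryota", "",
    33090L, 2759L, "kingdom", "Viridiplantae", "Plants",
    35493L, 33090L, "phylum", "Streptophyta", "",
    3398L, 35493L, "class", "Magnoliopsida", "",
    38820L, 3398L, "order", "Poales", "",
    4479L, 38820L, "family", "Poaceae", "",
    4575L, 4479L, "genus", "Zea", "",
    4577L, 4575L, "species", "Zea mays", "",
    4564L, 4479L, "genus", "Triticum", "",
    4565L, 4564L, "species", "Triticum aestivum", "",
    4539L, 4479L, "genus", "Panicum", "",
    38727L, 4539L, "species", "Panicum virgatum", "",
    4527L, 4479L, "genus", "Oryza", "",
    4530L, 4527L, "species", "Oryza sativa", "",
    4533L, 4527L, "species", "Oryza brachyantha", "",
    72025L, 3398L, "order", "Fabales", "",
    3803L, 72025L, "family", "Fabaceae", "",
    3846L, 3803L, "genus", "Glycine", "",
    3847L, 3846L, "species", "Glycine max", "",
    3848L, 3846L, "species", "Glycine soja", "",
    3744L, 3398L, "order", "Rosales", "",
    3745L, 3744L, "family", "Rosaceae", "",
    3746L, 3745L, "genus", "Fragaria", "",
    3747L, 3746L, "species", "Fragaria x ananassa", "",
    33208L, 2759L, "kingdom", "Metazoa", "",
    7742L, 33208L, "clade", "Vertebrata", "Vertebrates",
    9606L, 7742L, "species", "Homo sapiens", "",
    6656L, 33208L, "phylum", "Arthropoda", "Invertebrates",
    7159L, 6656L, "species", "Aedes aegypti", ""
  )
  new_taxonomy(nodes)
}

#' Simulate a random rooted taxonomy
#'
#' Builds a random tree with ranked internal nodes (division, family, genus)
#' and division labels, plus the species leaves. Deterministic per seed.
#'
#' @param seed Integer random seed.
#' @param n_species Number of species leaves (>= 1).
#' @param divisions Division labels to draw from.
#' @return A list: `taxonomy` (a `taxonomy` object) and `species` (tibble
#'   `taxid`, `name`, `division`).
#' @export
simulate_taxonomy <- function(seed = 1L, n_species = 8L,
                              divisions = c("Plants", "Invertebrates",
                                            "Vertebrates")) {
  stopifnot(n_species >= 1L)
  withr::local_seed(seed)
  rows <- list(tibble::tibble(taxid = 1L, parent = 1L, rank = "no rank",
                              name = "root", division = ""))
  nxt <- 100L
  new_id <- function() {
    id <- nxt
    nxt <<- nxt + 1L
    id
  }
  div_ids <- integer(length(divisions))
  for (k in seq_along(divisions)) {
    div_ids[k] <- new_id()
    rows[[length(rows) + 1L]] <- tibble::tibble(
      taxid = div_ids[k], parent = 1L, rank = "kingdom",
      name = paste0("Kingdom_", divisions[k]), division = divisions[k])
  }
  sp_div <- sort(sample.int(length(divisions), n_species, replace = TRUE))
  species <- list()
  for (k in unique(sp_div)) {
    n_k <- sum(sp_div == k)
    n_fam <- max(1L, ceiling(n_k / 4L))
    fam_ids <- integer(n_fam)
    gen_of_fam <- vector("list", n_fam)
    for (f in seq_len(n_fam)) {
      fam_ids[f] <- new_id()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        taxid = fam_ids[f], parent = div_ids[k], rank = "family",
        name = sprintf("Family_%d", fam_ids[f]), division = "")
      gen_of_fam[[f]] <- integer()
    }
    for (s in seq_len(n_k)) {
      f <- sample.int(n_fam, 1L)
      # reuse an existing genus half the time, to give LCA some work
      if (length(gen_of_fam[[f]]) > 0L && stats::runif(1) < 0.5) {
        gf <- gen_of_fam[[f]]
        g <- gf[sample.int(length(gf), 1L)]
      } else {
        g <- new_id()
        gen_of_fam[[f]] <- c(gen_of_fam[[f]], g)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          taxid = g, parent = fam_ids[f], rank = "genus",
          name = sprintf("Genus_%d", g), division = "")
      }
      sp <- new_id()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        taxid = sp, parent = g, rank = "species",
        name = sprintf("Species_%d", sp), division = "")
      species[[length(species) + 1L]] <- tibble::tibble(
        taxid = sp, name = sprintf("Species_%d", sp),
        division = divisions[k])
    }
  }
  list(taxonomy = new_taxonomy(dplyr::bind_rows(rows)),
       species = dplyr::bind_rows(species))
}

#' Model of a planted barcode locus
#'
#' Describes the multi-copy conserved locus planted into simulated genomes:
#' two flanking 20-mer primer sites around a variable inner region. The
#' default architecture (20 + 154 + 20 bases) implies a 194-bp product. The
#' default primer sequences are the experimentally validated pair
#' 5'-TCCTTCTGGATGTTGTAGTC-3' / 5'-AAGATGCAGATCTTCGTGAA-3'.
#'
#' @param forward,reverse Primer 20-mers (the reverse primer as written 5'-3',
#'   i.e. its reverse complement flanks the inner region on the plus strand).
#' @param inner_length Inner-region length in bases (default 154).
#' @param copies Locus copies per genome (default 2).
#' @param species_divergence Substitution rate applied to the inner region
#'   per species (default 0.05).
#' @param copy_divergence Substitution rate between copies within a genome
#'   (default 0.01).
#' @param primer_divergence Substitution rate inside the primer sites
#'   (default 0: sites are exact).
#' @return A `locus_model` list.
#' @export
locus_model <- function(forward = "TCCTTCTGGATGTTGTAGTC",
                        reverse = "AAGATGCAGATCTTCGTGAA",
                        inner_length = 154L, copies = 2L,
                        species_divergence = 0.05, copy_divergence = 0.01,
                        primer_divergence = 0) {
  forward <- normalize_seq(forward)
  reverse <- normalize_seq(reverse)
  stopifnot(copies >= 1L, inner_length >= 1L)
  structure(list(forward = forward, reverse = reverse,
                 inner_length = as.integer(inner_length),
                 copies = as.integer(copies),
                 species_divergence = species_divergence,
                 copy_divergence = copy_divergence,
                 primer_divergence = primer_divergence,
                 implied_amplicon = nchar(forward) + as.integer(inner_length) +
                   nchar(reverse)),
            class = "locus_model")
}

mutate_bases_n <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(seq = paste(chars, collapse = ""), n = length(hit))
}

#' Simulate genomes with planted multi-copy barcode loci
#'
#' Each genome is a random background into which `locus$copies`
#' non-overlapping copies of the locus cassette (forward primer + inner +
#' reverse complement of the reverse primer) are planted on random strands.
#' Inner regions diverge between species and between copies at the model's
#' stated rates; primer sites are exact unless `primer_divergence` is set.
#' Everything planted is recorded in the ledger.
#'
#' @param species Tibble of species leaves with `taxid` and `name` columns
#'   (e.g. from [simulate_taxonomy()]).
#' @param locus A [locus_model()].
#' @param genome_length Genome length in bases (must exceed the packed
#'   cassette length).
#' @param seed Integer random seed.
#' @return A list: `genomes` (sequence table), `ledger` (tibble `genome_id`,
#'   `species_taxid`, `copy`, `start`, `end`, `strand`, `inner_sequence`),
#'   `locus` (the model).
#' @export
simulate_genomes <- function(species, locus = locus_model(),
                             genome_length = 10000L, seed = 1L) {
  cass_len <- locus$implied_amplicon
  if (genome_length <= locus$copies * cass_len) {
    stop("infeasible packing: genome_length must exceed copies * (",
         cass_len, ")", call. = FALSE)
  }
  withr::local_seed(seed)
  anc <- rand_dna(locus$inner_length)
  genomes <- list()
  ledger <- list()
  for (i in seq_len(nrow(species))) {
    gid <- gsub("\\s+", "_", species$name[i])
    sp_inner <- mutate_bases(anc, locus$species_divergence)
    bg <- rand_dna(genome_length)
    placed <- matrix(numeric(0), ncol = 2L)
    seen_inner <- character()
    for (cp in seq_len(locus$copies)) {
      inner <- mutate_bases(sp_inner, locus$copy_divergence)
      if (locus$copy_divergence > 0) {
        # copies within a genome are distinguishable loci; redraw collisions
        for (try in seq_len(100L)) {
          if (!(inner %in% seen_inner)) break
          inner <- mutate_bases(sp_inner, locus$copy_divergence)
        }
      }
      seen_inner <- c(seen_inner, inner)
      fwd <- mutate_bases(locus$forward, locus$primer_divergence)
      rev <- mutate_bases(locus$reverse, locus$primer_divergence)
      cassette <- paste0(fwd, inner, reverse_complement(rev))
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") cassette else reverse_complement(cassette)
      ok <- FALSE
      for (try in seq_len(500L)) {
        start <- sample.int(genome_length - cass_len + 1L, 1L) - 1L
        end <- start + cass_len
        if (nrow(placed) == 0L ||
            all(end <= placed[, 1] | start >= placed[, 2])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible packing: could not place locus copies",
                    call. = FALSE)
      placed <- rbind(placed, c(start, end))
      substr(bg, start + 1L, end) <- planted
      ledger[[length(ledger) + 1L]] <- tibble::tibble(
        genome_id = gid, species_taxid = as.integer(species$taxid[i]),
        copy = cp, start = start, end = end, strand = strand,
        inner_sequence = inner
      )
    }
    genomes[[i]] <- seq_tbl(gid, bg, species_taxid = species$taxid[i])
  }
  list(genomes = dplyr::bind_rows(genomes),
       ledger = dplyr::bind_rows(ledger), locus = locus)
}

#' Simulate amplicon reads from a DNA mixture
#'
#' Reads are drawn per species with probability proportional to
#' `weight / C-value` (template copies per unit mass), uniformly across that
#' species' planted locus copies. Each read carries a fusion-primer layout:
#' forward-oriented reads are `MID_f + forward + inner + revcomp(reverse)`,
#' and the half sequenced from the other end are
#' `MID_r + reverse + revcomp(inner) + revcomp(forward)`. Substitution errors
#' are applied at `error_rate` per base over the whole read (homopolymer
#' indels are omitted by default: under full-length exact clustering an indel
#' read is unassigned by construction, so the substitution model exercises
#' the pipeline's logic rather than the instrument).
#'
#' @param sim Result of [simulate_genomes()].
#' @param mixture Named numeric vector of weight fractions summing to 1
#'   (names are species taxids).
#' @param cvalues A `cvalue_table` covering the mixture species.
#' @param mids A [mid_scheme()].
#' @param sample Scheme sample label to emit (default: first row).
#' @param n_reads Number of reads (default 10000).
#' @param error_rate Per-base substitution rate (default 0.01).
#' @param seed Integer random seed.
#' @param pair Optional primer pair; defaults to the simulation's locus
#'   primers under the name `"sim-aaa"`.
#' @return A list: `reads` (sequence table) and `ledger` (tibble `read_id`,
#'   `species_taxid`, `genome_id`, `copy`, `orientation`, `mid`, `n_errors`,
#'   `true_inner`).
#' @export
simulate_reads <- function(sim, mixture, cvalues, mids, sample = NULL,
                           n_reads = 10000L, error_rate = 0.01, seed = 1L,
                           pair = NULL) {
  stopifnot(n_reads >= 1L)
  if (abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  taxids <- as.integer(names(mixture))
  missing <- setdiff(taxids, sim$ledger$species_taxid)
  if (length(missing) > 0L) {
    stop("species ", paste(missing, collapse = ", "),
         " absent from the genome ledger", call. = FALSE)
  }
  pair <- pair %||% primer_pair("sim-aaa", sim$locus$forward,
                                sim$locus$reverse)
  withr::local_seed(seed)
  ci <- match(taxids, cvalues$species_taxid)
  if (anyNA(ci)) stop("C-value missing for a mixture species", call. = FALSE)
  prob <- unname(mixture) / cvalues$c_pg[ci]
  prob <- prob / sum(prob)
  sp_draw <- taxids[sample.int(length(taxids), n_reads, replace = TRUE,
                               prob = prob)]
  row <- if (is.null(sample)) mids[1, ] else mids[mids$sample == sample, ]
  stopifnot(nrow(row) == 1L)
  fwd <- pair$forward[[1]]
  rev <- pair$reverse[[1]]
  rc_rev <- reverse_complement(rev)
  rc_fwd <- reverse_complement(fwd)
  rc_inner <- reverse_complement(sim$ledger$inner_sequence)
  by_sp <- split(seq_len(nrow(sim$ledger)), sim$ledger$species_taxid)
  pick <- integer(n_reads)
  for (tx in taxids) {
    idx <- which(sp_draw == tx)
    rows_sp <- by_sp[[as.character(tx)]]
    pick[idx] <- rows_sp[sample.int(length(rows_sp), length(idx),
                                    replace = TRUE)]
  }
  forward_read <- stats::runif(n_reads) < 0.5
  raw <- ifelse(forward_read,
                paste0(row$mid_f, fwd, sim$ledger$inner_sequence[pick],
                       rc_rev),
                paste0(row$mid_r, rev, rc_inner[pick], rc_fwd))
  lens <- nchar(raw)
  n_errors <- integer(n_reads)
  if (error_rate > 0) {
    if (length(unique(lens)) == 1L) {
      # constant read length: mutate all reads as one character matrix
      L <- lens[1]
      m <- matrix(unlist(strsplit(raw, "")), nrow = n_reads, ncol = L,
                  byrow = TRUE)
      mask <- matrix(stats::runif(n_reads * L) < error_rate, n_reads, L)
      hits <- which(mask)
      if (length(hits) > 0L) {
        bases <- c("A", "C", "G", "T")
        alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                     c("A", "C", "T"), c("A", "C", "G"))
        cur <- match(m[hits], bases)
        m[hits] <- alt[cbind(cur, sample.int(3L, length(hits),
                                             replace = TRUE))]
      }
      raw <- apply(m, 1L, paste, collapse = "")
      n_errors <- as.integer(rowSums(mask))
    } else {
      for (r in seq_len(n_reads)) {
        mut <- mutate_bases_n(raw[r], error_rate)
        raw[r] <- mut$seq
        n_errors[r] <- mut$n
      }
    }
  }
  ledger <- tibble::tibble(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    species_taxid = sp_draw,
    genome_id = sim$ledger$genome_id[pick],
    copy = sim$ledger$copy[pick],
    orientation = ifelse(forward_read, "+", "-"),
    mid = ifelse(forward_read, row$mid_f, row$mid_r),
    n_errors = n_errors,
    true_inner = sim$ledger$inner_sequence[pick]
  )
  list(reads = seq_tbl(ledger$read_id, raw), ledger = ledger)
}

#' Write a taxonomy as a lineage TSV
#'
#' The 5-column dialect read back by [load_taxonomy()].
#'
#' @param tax A `taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  readr::write_tsv(tibble::as_tibble(tax), path)
  invisible(path)
}

#' Write a MID scheme as TSV
#' @param scheme A `mid_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mid_tsv <- function(scheme, path) {
  readr::write_tsv(tibble::as_tibble(scheme), path)
  invisible(path)
}

#' @rdname write_mid_tsv
#' @export
read_mid_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  mid_scheme(tab$sample, tab$mid_f, tab$mid_r)
}
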