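plant <- function(subject, pos0, what) {
  # overwrite subject at 0-based pos0
  substr(subject, pos0 + 1, pos0 + nchar(what)) <- what
  subject
}

test_that("an exact planted site is found once with zero errors", {
  withr::local_seed(29)
  primer <- rand_seq(20)
  subj <- plant(rand_seq(1000), 100, primer)
  sites <- find_primer_sites(primer, subj, max_errors = 0)
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$start, sites$end), c(100L, 120L))
  expect_equal(sites$strand, "+")
  expect_equal(sites$total_errors, 0L)
})

test_that("substituted sites obey the error budget", {
  withr::local_seed(30)
  primer <- rand_seq(20)
  mutated <- primer
  for (p in c(5, 15)) {
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mutated, p, p))[1]
  }
  subj <- plant(rand_seq(1000), 400, mutated)
  s2 <- find_primer_sites(primer, subj, max_errors = 2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$n_mismatches, 2L)
  expect_equal(s2$n_gaps, 0L)
  s1 <- find_primer_sites(primer, subj, max_errors = 1)
  expect_equal(nrow(s1), 0L)
})

test_that("IUPAC degeneracy in the primer matches at zero cost", {
  subj <- paste0(strrep("T", 50), "ACGTACGTACGTACGTACGA", strrep("T", 50))
  primer <- "ACGTACGTACGTACGTACGR"  # R covers the trailing A
  sites <- find_primer_sites(primer, subj, max_errors = 0)
  sites <- sites[sites$strand == "+", ]
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$total_errors, 0L)
})

test_that("site calls equal the window edit-distance oracle", {
  withr::local_seed(31)
  for (trial in 1:4) {
    primer <- rand_seq(20)
    subj <- rand_seq(2000)
    # plant sites: exact, 2-sub, 1-del, and a minus-strand copy
    mut2 <- primer
    for (p in c(3, 12)) {
      substr(mut2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mut2, p, p))[1]
    }
    del1 <- paste0(substr(primer, 1, 9), substr(primer, 11, 20))
    subj <- plant(subj, 100, primer)
    subj <- plant(subj, 600, mut2)
    subj <- plant(subj, 1200, del1)
    subj <- plant(subj, 1700, revcomp_chr(primer))
    got <- find_primer_sites(primer, subj, max_errors = 2)
    want <- oracle_primer_sites(primer, subj, 2)
    expect_equal(nrow(got), nrow(want), info = paste("trial", trial))
    expect_equal(got$start, want$start, info = paste("trial", trial))
    expect_equal(got$end, want$end, info = paste("trial", trial))
    expect_equal(got$strand, want$strand, info = paste("trial", trial))
    expect_equal(got$total_errors, want$total_errors,
                 info = paste("trial", trial))
  }
})

make_locus_subject <- function(fwd, rev, inner, lead = 100, tail = 100) {
  paste0(rand_seq(lead), fwd, inner, revcomp_chr(rev), rand_seq(tail))
}

test_that("a planted locus yields one amplicon of the designed size", {
  withr::local_seed(37)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  subj <- make_locus_subject(fwd, rev, rand_seq(154))
  amps <- predict_amplicons(pair, subj, per_primer_max = 0)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length_with_primers, 194L)
  expect_equal(nchar(amps$inner_sequence), 154L)
  expect_equal(amps$start, 100L)
  expect_equal(amps$end, 294L)
})

test_that("amplicon prediction is strand-symmetric", {
  withr::local_seed(38)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  subj <- paste0(make_locus_subject(fwd, rev, rand_seq(154)),
                 make_locus_subject(fwd, rev, rand_seq(120), lead = 30))
  a <- predict_amplicons(pair, subj, per_primer_max = 0)
  b <- predict_amplicons(pair, revcomp_chr(subj), per_primer_max = 0)
  expect_equal(sort(a$inner_sequence), sort(b$inner_sequence))
  expect_equal(sort(a$length_with_primers), sort(b$length_with_primers))
})

test_that("the size filter drops short products", {
  withr::local_seed(39)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  # loci spaced so cross-locus products exceed the size maximum
  subj <- paste0(
    make_locus_subject(fwd, rev, rand_seq(154), lead = 50, tail = 450),
    make_locus_subject(fwd, rev, rand_seq(0), lead = 450, tail = 450),  # 40 bp
    make_locus_subject(fwd, rev, rand_seq(200), lead = 450, tail = 50)
  )
  amps <- predict_amplicons(pair, subj, per_primer_max = 0, size_min = 50)
  expect_equal(nrow(amps), 2L)
  expect_setequal(amps$length_with_primers, c(194L, 240L))
})

test_that("with budget 0 predictions equal a substring-search construction", {
  withr::local_seed(41)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  inners <- replicate(3, rand_seq(sample(80:200, 1)))
  subj <- paste(vapply(inners, function(i)
    make_locus_subject(fwd, rev, i, lead = 60, tail = 60), character(1)),
    collapse = "")
  amps <- predict_amplicons(pair, subj, per_primer_max = 0)
  # independent construction: locate literal primer flanks with gregexpr
  f_pos <- as.integer(gregexpr(fwd, subj, fixed = TRUE)[[1]]) - 1L
  r_pos <- as.integer(gregexpr(revcomp_chr(rev), subj, fixed = TRUE)[[1]]) - 1L
  want <- list()
  for (f in f_pos) for (r in r_pos) {
    len <- r + 20L - f
    if (r >= f + 20L && len >= 50L && len <= 1000L) {
      want[[length(want) + 1L]] <-
        c(start = f, end = r + 20L, len = len)
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want[, "start"]), , drop = FALSE]
  expect_equal(amps$start, unname(want[, "start"]))
  expect_equal(amps$end, unname(want[, "end"]))
  expect_equal(amps$inner_sequence,
               substring(subj, want[, "start"] + 21L, want[, "end"] - 20L))
})

test_that("raising the error budget never removes a prediction", {
  withr::local_seed(43)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  mut <- fwd
  substr(mut, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(mut, 7, 7))[1]
  subj <- paste0(make_locus_subject(fwd, rev, rand_seq(154)),
                 make_locus_subject(mut, rev, rand_seq(100), lead = 30))
  keys <- function(x) paste(x$start, x$end)
  prev <- predict_amplicons(pair, subj, error_mode = "total", total_max = 0)
  # the substituted-forward-primer locus is only predictable at budget >= 1
  has_mut_locus <- function(x) any(x$forward_errors > 0)
  expect_false(has_mut_locus(prev))
  for (b in 1:4) {
    cur <- predict_amplicons(pair, subj, error_mode = "total", total_max = b)
    expect_true(all(keys(prev) %in% keys(cur)), info = paste("budget", b))
    prev <- cur
  }
  expect_true(has_mut_locus(prev))
})

test_that("reference sets collapse duplicates and index species", {
  withr::local_seed(47)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  inners <- replicate(3, rand_seq(154))
  genomes <- seq_tbl(
    c("g1", "g2", "g3"),
    vapply(inners, function(i) make_locus_subject(fwd, rev, i), character(1)),
    species_taxid = c(4577L, 3847L, 4530L)
  )
  refset <- build_reference_set(genomes, pair, error_mode = "total")
  expect_equal(nrow(refset$records), 3L)
  idx <- ref_index(refset)
  expect_equal(nrow(idx), 3L)
  expect_true(all(idx$n_species == 1L))
  expect_setequal(idx$inner_sequence, inners)

  # shared sequence between two species -> one key with a 2-species set
  shared <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "AAAA", "CCCC"),
    species_taxid = c(4577L, 4565L, 3847L),
    source = "genome", source_id = c("a", "b", "c")
  ))
  idx2 <- ref_index(shared)
  expect_equal(idx2$n_species[idx2$inner_sequence == "AAAA"], 2L)

  # a record without a taxid is skipped with a warning
  g2 <- genomes
  g2$species_taxid[2] <- NA
  expect_warning(r2 <- build_reference_set(g2, pair, error_mode = "total"),
                 "skipped")
  expect_equal(nrow(r2$records), 2L)
})

test_that("reference sets round-trip through FASTA", {
  refs <- reference_set(tibble::tibble(
    inner_sequence = c("ACGTACGT", "GGGGCCCC"),
    species_taxid = c(4577L, 3847L),
    source = c("genome", "database"),
    source_id = c("zm_chr5:100-294", "AI677436")
  ))
  tf <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(refs, tf)
  back <- read_reference_fasta(tf)
  expect_equal(back$records, refs$records)
})

test_that("diagnostic species are counted by uniqueness of inner sequences", {
  distinct <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "CCCC", "GGGG"),
    species_taxid = c(1L, 2L, 3L) + 100L,
    source = "genome", source_id = c("a", "b", "c")
  ))
  expect_equal(nrow(diagnostic_species_count(distinct)), 3L)

  shared_only <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "AAAA"),
    species_taxid = c(101L, 102L),
    source = "genome", source_id = c("a", "b")
  ))
  expect_equal(nrow(diagnostic_species_count(shared_only)), 0L)

  withr::local_seed(43)
  # random set vs a brute-force recount over the index
  recs <- tibble::tibble(
    inner_sequence = sample(replicate(12, rand_seq(8)), 40, replace = TRUE),
    species_taxid = sample(101:106, 40, replace = TRUE),
    source = "genome",
    source_id = sprintf("s%02d", 1:40)
  )
  refset <- reference_set(recs)
  got <- diagnostic_species_count(refset)
  by_seq <- split(recs$species_taxid, recs$inner_sequence)
  diag_seqs <- names(by_seq)[vapply(by_seq, function(x)
    length(unique(x)) == 1L, logical(1))]
  want <- table(vapply(by_seq[diag_seqs], `[`, integer(1), 1L))
  expect_equal(nrow(got), length(want))
  expect_equal(got$n_diagnostic[order(got$species_taxid)],
               as.integer(want[order(as.integer(names(want)))]))
})

test_that("division tallies follow the taxonomy", {
  tax <- poaceae_taxonomy()
  refs <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "CCCC", "GGGG"),
    species_taxid = c(4577L, 3847L, 9606L),
    source = "genome", source_id = c("a", "b", "c")
  ))
  t <- tally_divisions(refs, tax)
  expect_equal(t$n_species[t$division == "Plants"], 2L)
  expect_equal(t$n_species[t$division == "Vertebrates"], 1L)
  expect_equal(t$n_species[t$division == "Invertebrates"], 0L)

  empty <- reference_set(NULL)
  expect_true(all(tally_divisions(empty, tax)$n_species == 0L))

  stray <- reference_set(tibble::tibble(
    inner_sequence = "TTTT", species_taxid = 99999L,
    source = "genome", source_id = "x"
  ))
  expect_warning(t2 <- tally_divisions(stray, tax), "other")
  expect_equal(t2$n_species[t2$division == "other"], 1L)
})
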