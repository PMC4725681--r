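MID1 <- "ACGAGTGCGT"
MID2 <- "ACGCTCGACA"

test_that("mid_scheme validates distances and duplicates", {
  expect_s3_class(mid_scheme("S1", MID1, MID2), "mid_scheme")
  expect_error(mid_scheme(c("S1", "S1"), c(MID1, MID2)), "duplicate sample")
  expect_error(mid_scheme(c("S1", "S2"), c(MID1, MID1), c(MID2, MID2)),
               "duplicate \\(forward")
  near <- sub("T$", "A", MID1)  # one substitution away from MID1
  expect_error(mid_scheme(c("S1", "S2"), c(MID1, near)), "fewer than 2")
})

test_that("reads are routed by their 5' MID and stripped", {
  scheme <- mid_scheme(c("S1", "S2"), c(MID1, MID2))
  reads <- seq_tbl(c("r1", "r2", "r3"),
                   c(paste0(MID1, "AAAA"), paste0(MID2, "CCCC"),
                     paste0("TTTTTTTTTT", "GGGG")))
  dm <- demultiplex(reads, scheme)
  expect_equal(dm$sample, c("S1", "S2", NA))
  expect_equal(dm$sequence[1:2], c("AAAA", "CCCC"))
  expect_equal(dm$sequence[3], reads$sequence[3])  # unassigned kept intact
})

test_that("demultiplex routing matches a 1000-read construction ledger", {
  withr::local_seed(61)
  scheme <- mid_scheme(c("S1", "S2"), c(MID1, MID2), c(MID2, MID1))
  # S1: forward MID1 / reverse MID2; S2 the converse -> every MID prefix is
  # ambiguous between samples unless the scheme distinguishes by position?
  # It cannot: both samples carry both MIDs, so all reads are ambiguous.
  reads <- seq_tbl("x", paste0(MID1, "ACGT"))
  expect_true(is.na(demultiplex(reads, scheme)$sample))

  scheme <- mid_scheme(c("S1", "S2"), c(MID1, MID2))
  truth <- sample(c("S1", "S2", NA), 1000, replace = TRUE)
  payload <- replicate(1000, rand_seq(30))
  prefix <- ifelse(is.na(truth), strrep("G", 10),
                   ifelse(truth == "S1", MID1, MID2))
  reads <- seq_tbl(sprintf("r%04d", 1:1000), paste0(prefix, payload))
  dm <- demultiplex(reads, scheme)
  expect_equal(dm$sample, truth)
  expect_equal(nrow(dm), 1000L)
  expect_equal(dm$sequence[!is.na(truth)], payload[!is.na(truth)])
  # one-mismatch prefixes only route under a relaxed budget
  mut <- paste0(sub("^A", "C", MID1), payload[1])
  one <- seq_tbl("m", mut)
  expect_true(is.na(demultiplex(one, scheme, 0)$sample))
  expect_equal(demultiplex(one, scheme, 1)$sample, "S1")
})

test_that("orient_and_trim recovers inners from both read orientations", {
  withr::local_seed(63)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  inner <- rand_seq(154)
  fwd_read <- paste0(fwd, inner, revcomp_chr(rev))
  rev_read <- paste0(rev, revcomp_chr(inner), revcomp_chr(fwd))
  out <- orient_and_trim(seq_tbl(c("f", "r"), c(fwd_read, rev_read)), pair)
  expect_equal(out$status, c("trimmed", "trimmed"))
  expect_equal(out$orientation, c("+", "-"))
  expect_equal(out$sequence, c(inner, inner))
})

test_that("trimming tolerates primer errors up to the budget", {
  withr::local_seed(67)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  n <- 50L
  inners <- replicate(n, rand_seq(154))
  reads <- character(n)
  n_err <- integer(n)
  for (i in seq_len(n)) {
    f <- fwd
    k <- sample(0:2, 1)
    n_err[i] <- k
    for (p in sample(1:20, k)) {
      substr(f, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(f, p, p)), 1)
    }
    reads[i] <- paste0(f, inners[i], revcomp_chr(rev))
  }
  out <- orient_and_trim(seq_tbl(sprintf("r%02d", 1:n), reads), pair,
                         max_trim_errors = 2)
  expect_true(all(out$status == "trimmed"))
  expect_equal(out$sequence, inners)

  # 3 errors at budget 2 -> rejected
  f3 <- fwd
  for (p in c(2, 9, 17)) {
    substr(f3, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(f3, p, p)), 1)
  }
  bad <- seq_tbl("bad", paste0(f3, inners[1], revcomp_chr(rev)))
  expect_equal(orient_and_trim(bad, pair, max_trim_errors = 2)$status,
               "rejected")
})

test_that("a missing 3' primer does not reject a read", {
  withr::local_seed(68)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  pair <- primer_pair("t-aaa", fwd, rev)
  short <- paste0(fwd, rand_seq(60))  # read ends before the reverse primer
  out <- orient_and_trim(seq_tbl("s", short), pair)
  expect_equal(out$status, "trimmed")
  expect_equal(nchar(out$sequence), 60L)
})

test_that("exact clustering equals the group-by oracle at scale", {
  withr::local_seed(71)
  pool <- replicate(300, rand_seq(sample(30:40, 1)))
  seqs <- sample(pool, 10000, replace = TRUE)
  ids <- sprintf("r%05d", seq_along(seqs))
  n_ref <- 200L
  ref_seqs <- c(sample(pool, n_ref - 50), replicate(50, rand_seq(35)))
  refs <- reference_set(tibble::tibble(
    inner_sequence = ref_seqs,
    species_taxid = sample(101:110, n_ref, replace = TRUE),
    source = "genome",
    source_id = sprintf("ref%03d", seq_len(n_ref))
  ))
  clusters <- cluster_exact(tibble::tibble(id = ids, sequence = seqs), refs)
  # oracle partition over the union
  want <- oracle_partition(c(ids, refs$records$source_id),
                           c(seqs, refs$records$inner_sequence))
  got <- stats::setNames(
    lapply(seq_len(nrow(clusters)), function(i) {
      sort(c(clusters$read_ids[[i]], clusters$ref_source_ids[[i]]))
    }),
    clusters$representative
  )
  got <- got[order(names(got))]
  expect_equal(got, want)
  # categories consistent with counts
  expect_true(all((clusters$n_reads > 0 & clusters$n_refs > 0) ==
                    (clusters$category == "mixed")))
  # permutation invariance up to documented ordering
  perm <- sample(seq_along(seqs))
  clusters2 <- cluster_exact(tibble::tibble(id = ids[perm],
                                            sequence = seqs[perm]), refs)
  expect_equal(clusters2$representative, clusters$representative)
  expect_equal(clusters2$n_reads, clusters$n_reads)
})

test_that("one base difference separates clusters at 100% identity", {
  refs <- reference_set(tibble::tibble(
    inner_sequence = "ACGTACGTAC", species_taxid = 4577L,
    source = "genome", source_id = "zm:1"
  ))
  reads <- tibble::tibble(id = c("r1", "r2", "r3"),
                          sequence = c("ACGTACGTAC", "ACGTACGTAC",
                                       "ACGTACGTAT"))
  cl <- cluster_exact(reads, refs)
  expect_equal(sort(cl$category), c("mixed", "reads_only"))
  expect_equal(cl$n_reads[cl$category == "mixed"], 2L)
  expect_equal(cl$n_refs[cl$category == "mixed"], 1L)
})

test_that("cluster conclusions use the species or their LCA", {
  tax <- poaceae_taxonomy()
  refs <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "CCCC", "CCCC", "GGGG"),
    species_taxid = c(4577L, 4565L, 4577L, 4577L),
    source = "genome",
    source_id = c("zm:1", "ta:1", "zm:2", "zm:3")
  ))
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:12),
    sequence = c(rep("AAAA", 6), rep("CCCC", 4), rep("GGGG", 1), "TTTT")
  )
  report <- conclude_clusters(cluster_exact(reads, refs), tax)
  cl <- report$clusters
  expect_equal(cl$conclusion_name[cl$representative == "AAAA"], "Zea mays")
  expect_equal(cl$conclusion_name[cl$representative == "CCCC"], "Poaceae")
  expect_equal(cl$conclusion_rank[cl$representative == "CCCC"], "family")
  # ranked by reads, descending
  expect_equal(cl$n_reads, sort(cl$n_reads, decreasing = TRUE))
  expect_equal(report$totals$assigned, 11L)
  expect_equal(report$totals$unassigned, 1L)
  expect_equal(report$totals$trimmed, 12L)
})

test_that("counts are conserved through every stage", {
  withr::local_seed(73)
  u <- make_sim_universe(seed = 73)
  refset <- build_reference_set(u$sim$genomes, u$pair, error_mode = "total")
  rd <- simulate_reads(u$sim, c("4577" = 0.5, "3847" = 0.5), u$cv, u$mids,
                       n_reads = 800, error_rate = 0.02, seed = 74)
  dm <- demultiplex(rd$reads, u$mids)
  expect_equal(sum(!is.na(dm$sample)) + sum(is.na(dm$sample)), 800L)
  kept <- dm[!is.na(dm$sample), c("id", "sequence")]
  tr <- orient_and_trim(kept, u$pair)
  expect_equal(nrow(tr), nrow(kept))
  report <- assign_reads(rd$reads, u$pair, refset, u$tax, scheme = u$mids)
  t <- report$totals
  expect_equal(t$reads_in, 800L)
  expect_equal(t$assigned + t$unassigned, t$trimmed)
  expect_lte(t$trimmed, t$demuxed)
  expect_lte(t$demuxed, t$reads_in)
})

test_that("taxonomy_summary conserves assigned reads across taxa", {
  tax <- poaceae_taxonomy()
  refs <- reference_set(tibble::tibble(
    inner_sequence = c("AAAA", "CCCC", "CCCC"),
    species_taxid = c(4577L, 4565L, 4577L),
    source = "genome", source_id = c("zm:1", "ta:1", "zm:2")
  ))
  reads <- tibble::tibble(id = sprintf("r%02d", 1:10),
                          sequence = c(rep("AAAA", 7), rep("CCCC", 3)))
  report <- conclude_clusters(cluster_exact(reads, refs), tax)
  s <- taxonomy_summary(report, tax)
  expect_equal(sum(s$n_reads), report$totals$assigned)
  expect_equal(s$n_reads[s$name == "Zea mays"], 7L)
  expect_equal(s$n_clusters[s$name == "Poaceae"], 1L)
  expect_match(s$lineage[s$name == "Zea mays"], "root;.*Poaceae;Zea;Zea mays")
})

test_that("pure-sample conclusions never leave the source lineage", {
  u <- make_sim_universe(seed = 99)
  refset <- build_reference_set(u$sim$genomes, u$pair, error_mode = "total")
  zea_lineage <- lineage(u$tax, 4577L)$taxid
  for (seed in 100:119) {
    rd <- simulate_reads(u$sim, c("4577" = 1), u$cv, u$mids, n_reads = 250,
                         error_rate = 0.01, seed = seed)
    report <- assign_reads(rd$reads, u$pair, refset, u$tax, scheme = u$mids)
    expect_true(all(report$clusters$conclusion_taxid %in% zea_lineage),
                info = paste("seed", seed))
  }
})

test_that("cluster reports round-trip through TSV", {
  report <- make_marker_report(2688, 442)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(report, tf)
  back <- read_cluster_report(tf)
  expect_equal(back$totals, report$totals)
  expect_equal(back$clusters$n_reads, report$clusters$n_reads)
  expect_equal(back$clusters$ref_source_ids, report$clusters$ref_source_ids)
  expect_equal(back$clusters$conclusion_name, report$clusters$conclusion_name)
})
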