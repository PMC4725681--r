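# Independent brute-force oracles. These deliberately re-derive results with
# plain dynamic programming / enumeration, sharing no code with the package's
# implementation paths.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp_chr <- function(x) {
  # independent per-base complement + reverse
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", "-" = "-")
  vapply(x, function(s) {
    paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Affine-gap Smith-Waterman (Gotoh) with origin propagation: returns the best
# local alignment as list(score, q_start, q_end, s_start, s_end), 0-based
# half-open, or NULL if the best score is 0.
oracle_sw <- function(q, s, match = 1, mismatch = -2, gap_open = -5,
                      gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  open <- -(gap_open + gap_extend)  # cost of a length-1 gap
  ext <- -gap_extend
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)  # gap consuming subject
  F <- matrix(-Inf, m + 1L, n + 1L)  # gap consuming query
  OH <- matrix(0L, m + 1L, n + 1L)   # encoded origin (i * (n+2) + j)
  OE <- matrix(0L, m + 1L, n + 1L)
  OF <- matrix(0L, m + 1L, n + 1L)
  enc <- function(i, j) i * (n + 2L) + j
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, E[i + 1L, j] - ext)
      OE[i + 1L, j + 1L] <- if (H[i + 1L, j] - open >= E[i + 1L, j] - ext)
        OH[i + 1L, j] else OE[i + 1L, j]
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, F[i, j + 1L] - ext)
      OF[i + 1L, j + 1L] <- if (H[i, j + 1L] - open >= F[i, j + 1L] - ext)
        OH[i, j + 1L] else OF[i, j + 1L]
      sub <- if (qc[i] == sc[j] && qc[i] != "N") match else mismatch
      diag <- H[i, j] + sub
      odiag <- if (H[i, j] > 0) OH[i, j] else enc(i - 1L, j - 1L)
      val <- max(0, diag, E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- val
      OH[i + 1L, j + 1L] <- if (val == 0) enc(i, j)
        else if (val == diag) odiag
        else if (val == E[i + 1L, j + 1L]) OE[i + 1L, j + 1L]
        else OF[i + 1L, j + 1L]
      if (val > best) {
        best <- val; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) return(NULL)
  o <- OH[bi + 1L, bj + 1L]
  oi <- o %/% (n + 2L); oj <- o %% (n + 2L)
  list(score = best, q_start = oi, q_end = bi, s_start = oj, s_end = bj)
}

# Greedy multi-hit protocol around the DP oracle: report the best alignment on
# either strand, mask its subject span, repeat while score >= min_score.
oracle_local_hits <- function(q, s, params) {
  qrc <- revcomp_chr(q)
  qlen <- nchar(q)
  masked <- s
  hits <- list()
  repeat {
    a_p <- oracle_sw(q, masked, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
    a_m <- oracle_sw(qrc, masked, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
    sp <- if (is.null(a_p)) -Inf else a_p$score
    sm <- if (is.null(a_m)) -Inf else a_m$score
    if (max(sp, sm) < params$min_score) break
    if (sp >= sm) {
      a <- a_p; strand <- "+"
      qi <- c(a$q_start, a$q_end)
    } else {
      a <- a_m; strand <- "-"
      qi <- c(qlen - a$q_end, qlen - a$q_start)
    }
    hits[[length(hits) + 1L]] <- data.frame(
      q_start = qi[1], q_end = qi[2], s_start = a$s_start, s_end = a$s_end,
      strand = strand, score = a$score
    )
    substr(masked, a$s_start + 1L, a$s_end) <-
      strrep("N", a$s_end - a$s_start)
  }
  if (length(hits) == 0L) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(-out$score, out$s_start), , drop = FALSE]
}

# Window-scan oracle for approximate primer sites: evaluate the edit distance
# of the primer against every window of length len +/- max_e on both strands
# (utils::adist), then collapse overlapping placements per strand to the
# fewest-error one (ties: leftmost, then narrowest).
oracle_primer_sites <- function(primer, subject, max_e) {
  plen <- nchar(primer)
  slen <- nchar(subject)
  scan <- function(pat, strand) {
    rows <- list()
    for (w in max(1L, plen - max_e):(plen + max_e)) {
      if (w > slen) next
      starts <- 0:(slen - w)
      wins <- substring(subject, starts + 1L, starts + w)
      d <- as.integer(utils::adist(pat, wins))
      keep <- which(d <= max_e)
      if (length(keep) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[keep], end = starts[keep] + w,
          strand = strand, total_errors = d[keep]
        )
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), total_errors = integer()))
    }
    x <- do.call(rbind, rows)
    x <- x[order(x$start, x$end), , drop = FALSE]
    # group transitively-overlapping intervals, keep the group optimum
    grp <- integer(nrow(x)); g <- 1L; grp[1] <- 1L; max_end <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] < max_end) {
        grp[i] <- g; max_end <- max(max_end, x$end[i])
      } else {
        g <- g + 1L; grp[i] <- g; max_end <- x$end[i]
      }
    }
    out <- lapply(split(x, grp), function(gx) {
      gx <- gx[order(gx$total_errors, gx$start, gx$end - gx$start), ,
               drop = FALSE]
      gx[1, , drop = FALSE]
    })
    do.call(rbind, out)
  }
  out <- rbind(scan(primer, "+"), scan(revcomp_chr(primer), "-"))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Partition oracle for exact clustering: split ids by sequence.
oracle_partition <- function(ids, seqs) {
  p <- split(ids, seqs)
  lapply(p[order(names(p))], sort)
}

# LCA oracle: intersect full ancestor-or-self sets, take the deepest member.
oracle_lca <- function(tax, taxids) {
  parent <- stats::setNames(tax$parent, tax$taxid)
  path_of <- function(tx) {
    p <- tx
    while (parent[[as.character(tx)]] != tx) {
      tx <- parent[[as.character(tx)]]
      p <- c(p, tx)
    }
    p
  }
  paths <- lapply(taxids, path_of)
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(tx) length(path_of(tx)), numeric(1))
  common[which.max(depth)]
}

# Equivalence check between implementation hits and oracle hits: the greedy
# multi-hit protocol must find the same number of alignments with identical
# scores and strands; intervals must coincide up to zero-scoring end segments
# (co-optimal alignments can include or trim score-neutral flanks), so they
# are required to overlap by at least 80% of the shorter interval.
expect_hits_equiv <- function(got, want, info = NULL) {
  testthat::expect_equal(nrow(got), nrow(want), info = info)
  if (nrow(got) == 0L) return(invisible())
  testthat::expect_equal(got$score, want$score, info = info)
  testthat::expect_equal(got$strand, want$strand, info = info)
  for (i in seq_len(nrow(got))) {
    ov <- min(got$s_end[i], want$s_end[i]) -
      max(got$s_start[i], want$s_start[i])
    shorter <- min(got$s_end[i] - got$s_start[i],
                   want$s_end[i] - want$s_start[i])
    testthat::expect_gte(ov, 0.8 * shorter)
    ovq <- min(got$q_end[i], want$q_end[i]) -
      max(got$q_start[i], want$q_start[i])
    shq <- min(got$q_end[i] - got$q_start[i],
               want$q_end[i] - want$q_start[i])
    testthat::expect_gte(ovq, 0.8 * shq)
  }
  invisible()
}
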