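schema <- scoring_schema()

test_that("non-overlapping mates keep the initial score everywhere", {
  p <- mk_pair(pos1 = 100L, pos2 = 280L, len = 50L)
  sp <- score_pair(p, schema)
  expect_identical(sp$read1, rep(6L, 50L))
  expect_identical(sp$read2, rep(6L, 50L))
})

test_that("overlap agreement and disagreement adjust scores", {
  # fully overlapping identical mates, all Q30 -> agree bonus everywhere
  seqs <- cycle_n("ACGT", 50L)
  p <- mk_pair(pos1 = 100L, pos2 = 100L, len = 50L, seq1 = seqs,
               seq2 = seqs)
  sp <- score_pair(p, schema)
  expect_identical(sp$read1, rep(8L, 50L))
  expect_identical(sp$read2, rep(8L, 50L))

  # one disagreeing position: C(Q30) vs G(Q10) -> keep 3 / drop 0
  s2 <- seqs
  substr(s2, 10L, 10L) <- "G"
  q2 <- rep(30L, 50L)
  q2[10L] <- 10L
  p2 <- mk_pair(pos1 = 100L, pos2 = 100L, len = 50L, seq1 = seqs,
                seq2 = s2, quals2 = q2)
  sp2 <- score_pair(p2, schema)
  expect_identical(sp2$read1[10L], 3L)
  expect_identical(sp2$read2[10L], 0L)
  expect_identical(sp2$read1[-10L], rep(8L, 49L))

  # equal qualities on disagreement drop both
  p3 <- mk_pair(pos1 = 100L, pos2 = 100L, len = 50L, seq1 = seqs,
                seq2 = s2)
  sp3 <- score_pair(p3, schema)
  expect_identical(sp3$read1[10L], 0L)
  expect_identical(sp3$read2[10L], 0L)
})

test_that("partial mate overlap only rescores the shared interval", {
  p <- mk_pair(pos1 = 100L, pos2 = 130L, len = 50L,
               seq1 = bases_n("A", 50L), seq2 = bases_n("A", 50L))
  sp <- score_pair(p, schema)
  expect_identical(sp$read1, c(rep(6L, 30L), rep(8L, 20L)))
  expect_identical(sp$read2, c(rep(8L, 20L), rep(6L, 30L)))
})

mk_cluster <- function(members) {
  consensr:::new_umi_cluster(members[[1]]$key, "", members, c(0L, 0L))
}

test_that("cluster scores are per-pair sums over A/C/G/T", {
  mk <- function(q) mk_pair(q, pos1 = 100L, pos2 = 280L, len = 50L,
                            seq1 = bases_n("A", 50L))
  sm <- score_cluster(mk_cluster(list(mk("a"), mk("b"), mk("c"))), schema)
  expect_identical(unname(sm$read1$scores["A", 1L]), 18L)
  expect_identical(sum(sm$read1$scores[c("C", "G", "T"), ]), 0L)

  p_c <- mk_pair("d", pos1 = 100L, pos2 = 280L, len = 50L,
                 seq1 = bases_n("C", 50L))
  sm2 <- score_cluster(mk_cluster(list(mk("a"), mk("b"), p_c)), schema)
  expect_identical(unname(sm2$read1$scores["A", 5L]), 12L)
  expect_identical(unname(sm2$read1$scores["C", 5L]), 6L)

  one <- mk_pair("solo", pos1 = 100L, pos2 = 130L, len = 50L,
                 seq1 = bases_n("G", 50L), seq2 = bases_n("G", 50L))
  sm3 <- score_cluster(mk_cluster(list(one)), schema)
  sp <- score_pair(one, schema)
  expect_identical(as.integer(sm3$read1$scores["G", ]), sp$read1)
  expect_identical(as.integer(sm3$read2$scores["G", ]), sp$read2)
})

test_that("score conservation holds column by column", {
  set.seed(21)
  for (i in 1:20) {
    rc <- random_cluster(sample(2:6, 1L), L = 20L, err = 0.1)
    sm <- score_cluster(rc$cluster, schema)
    members <- rc$cluster$members[sm$included]
    for (mate in c("read1", "read2")) {
      expected <- Reduce(`+`, lapply(members, function(p) {
        sp <- score_pair(p, schema)[[mate]]
        sp[strsplit(p[[mate]]$seq, "")[[1]] == "N"] <- 0L
        sp
      }))
      expect_identical(as.integer(colSums(sm[[mate]]$scores)), expected)
    }
  }
})

test_that("members with a non-template CIGAR are excluded, not realigned", {
  a <- mk_pair("a", pos1 = 100L, pos2 = 180L, len = 50L)
  b <- mk_pair("b", pos1 = 100L, pos2 = 180L, len = 50L,
               cigar1 = "5S45M")
  sm <- score_cluster(mk_cluster(list(a, b)), schema)
  expect_identical(sm$n_excluded, 1L)
  expect_identical(as.integer(sm$read1$scores["A", 1L]), 6L)
})

test_that("consensus base calls follow the dominant/reference/low rules", {
  s <- c(A = 18, C = 0, G = 0, T = 0)
  q <- c(A = 35, C = 0, G = 0, T = 0)
  call <- call_consensus_base(s, q, ref_base = "C", schema = schema)
  expect_identical(call$base, "A")
  expect_identical(call$qual, 35L)

  # no dominant base but high-quality reference concordance
  call2 <- call_consensus_base(c(A = 6, C = 6, G = 0, T = 0),
                               c(A = 20, C = 35, G = 0, T = 0),
                               ref_base = "C", schema = schema)
  expect_identical(call2$base, "C")
  expect_identical(call2$qual, 15L)

  # all covering reads low-quality -> reference
  call3 <- call_consensus_base(c(T = 6, G = 6, A = 0, C = 0),
                               c(T = 5, G = 5, A = 0, C = 0),
                               ref_base = "A", schema = schema)
  expect_identical(call3$base, "A")
  expect_identical(call3$qual, 15L)

  # low-quality but dominant still wins (rule order)
  call4 <- call_consensus_base(c(T = 12, A = 0, C = 0, G = 0),
                               c(T = 5, A = 0, C = 0, G = 0),
                               ref_base = "A", schema = schema)
  expect_identical(call4$base, "T")

  # unresolved column: highest score at Q2, reference wins ties
  call5 <- call_consensus_base(c(A = 6, C = 6, G = 0, T = 0),
                               c(A = 25, C = 25, G = 0, T = 0),
                               ref_base = "C", schema = schema)
  expect_identical(call5$base, "C")
  expect_identical(call5$qual, 2L)

  # scoreless column falls back to the reference at Q2
  call6 <- call_consensus_base(c(A = 0, C = 0, G = 0, T = 0),
                               c(A = 0, C = 0, G = 0, T = 0),
                               ref_base = "G", schema = schema)
  expect_identical(call6$base, "G")
  expect_identical(call6$qual, 2L)
})

test_that("a lone error among duplicates is outvoted by the consensus", {
  ref <- mk_ref(cycle_n("ACGT", 1000L))
  truth1 <- ref_subseq(ref, "simchr1", 100L, 150L)
  truth2 <- ref_subseq(ref, "simchr1", 180L, 230L)
  clean <- function(q) mk_pair(q, pos1 = 100L, pos2 = 180L, len = 50L,
                               seq1 = truth1, seq2 = truth2)
  bad_seq <- truth1
  substr(bad_seq, 25L, 25L) <- if (substr(truth1, 25, 25) == "A") "C" else "A"
  bad <- mk_pair("zz", pos1 = 100L, pos2 = 180L, len = 50L,
                 seq1 = bad_seq, seq2 = truth2)
  cl <- mk_cluster(list(clean("a"), clean("b"), clean("c"), clean("d"), bad))
  cons <- build_consensus_pair(cl, ref, schema)
  expect_identical(cons$read1$seq, truth1)
  expect_identical(cons$read2$seq, truth2)
  expect_identical(cons$supporting_pairs, 5L)
})

test_that("a single clean pair passes through consensus unchanged", {
  ref <- mk_ref(cycle_n("ACGT", 1000L))
  p <- mk_pair("solo", pos1 = 100L, pos2 = 180L, len = 50L,
               seq1 = ref_subseq(ref, "simchr1", 100L, 150L),
               seq2 = ref_subseq(ref, "simchr1", 180L, 230L))
  cons <- build_consensus_pair(mk_cluster(list(p)), ref, schema)
  expect_identical(cons$read1$seq, p$read1$seq)
  expect_identical(cons$read2$seq, p$read2$seq)
})

test_that("a true variant shared by all duplicates survives consensus", {
  ref <- mk_ref(cycle_n("ACGT", 1000L))
  variant_seq <- ref_subseq(ref, "simchr1", 100L, 150L)
  substr(variant_seq, 20L, 20L) <-
    if (substr(variant_seq, 20, 20) == "T") "G" else "T"
  members <- lapply(letters[1:4], function(q)
    mk_pair(q, pos1 = 100L, pos2 = 180L, len = 50L, seq1 = variant_seq,
            seq2 = ref_subseq(ref, "simchr1", 180L, 230L)))
  cons <- build_consensus_pair(mk_cluster(members), ref, schema)
  expect_identical(cons$read1$seq, variant_seq)
})

test_that("template selection favours MAPQ then name", {
  ref <- mk_ref(cycle_n("ACGT", 1000L))
  lo <- mk_pair("zzz", pos1 = 100L, pos2 = 180L, len = 50L, mapq = 20L)
  hi <- mk_pair("aaa", pos1 = 100L, pos2 = 181L, len = 50L, mapq = 60L)
  expect_identical(consensr:::select_template(list(lo, hi)), 2L)
  tie <- mk_pair("bbb", pos1 = 100L, pos2 = 182L, len = 50L, mapq = 60L)
  expect_identical(consensr:::select_template(list(tie, hi)), 2L)
})

test_that("consensus equals the brute-force score-table oracle", {
  set.seed(77)
  for (i in 1:40) {
    rc <- random_cluster(sample(1:6, 1L), L = sample(8:20, 1L),
                         err = 0.08, overlap = sample(c(TRUE, FALSE), 1L))
    got <- build_consensus_pair(rc$cluster, rc$ref, schema)
    want <- oracle_consensus(rc$cluster$members, rc$ref, schema)
    expect_identical(got$read1$seq, want$read1$seq)
    expect_identical(got$read2$seq, want$read2$seq)
    expect_identical(got$read1$quals, as.integer(want$read1$quals))
    expect_identical(got$read2$quals, as.integer(want$read2$quals))
  }
})

test_that("adding an agreeing member never changes the called sequence", {
  set.seed(31)
  for (i in 1:15) {
    rc <- random_cluster(sample(2:5, 1L), L = 15L, err = 0.05,
                         overlap = FALSE)
    cons <- build_consensus_pair(rc$cluster, rc$ref, schema)
    tpl <- rc$cluster$members[[consensr:::select_template(rc$cluster$members)]]
    agreeing <- mk_pair("zzzagree", pos1 = tpl$read1$ref_start,
                        pos2 = tpl$read2$ref_start, len = nchar(cons$read1$seq),
                        seq1 = cons$read1$seq, seq2 = cons$read2$seq,
                        quals1 = 36L, quals2 = 36L)
    grown <- mk_cluster(c(rc$cluster$members, list(agreeing)))
    cons2 <- build_consensus_pair(grown, rc$ref, schema)
    expect_identical(cons2$read1$seq, cons$read1$seq)
    expect_identical(cons2$read2$seq, cons$read2$seq)
  }
})

test_that("consensus suppresses random errors on duplicated clusters", {
  set.seed(2024)
  n_trials <- 1000L
  improved <- 0L
  L <- 150L
  for (i in seq_len(n_trials)) {
    rc <- random_cluster(sample(3:6, 1L), L = L, err = 0.01,
                         overlap = FALSE)
    cons <- build_consensus_pair(rc$cluster, rc$ref, schema)
    raw_mm <- sum(vapply(rc$cluster$members, function(p) {
      sum(strsplit(p$read1$seq, "")[[1]] != strsplit(rc$truth1, "")[[1]]) +
        sum(strsplit(p$read2$seq, "")[[1]] != strsplit(rc$truth2, "")[[1]])
    }, numeric(1)))
    raw_rate <- raw_mm / (length(rc$cluster$members) * 2L * L)
    cons_mm <- sum(strsplit(cons$read1$seq, "")[[1]] !=
                     strsplit(rc$truth1, "")[[1]]) +
      sum(strsplit(cons$read2$seq, "")[[1]] != strsplit(rc$truth2, "")[[1]])
    cons_rate <- cons_mm / (2L * L)
    if (cons_rate < raw_rate) improved <- improved + 1L
  }
  expect_gte(improved / n_trials, 0.99)
})
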