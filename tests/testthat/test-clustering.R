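test_that("fragment keys follow reference-consuming CIGAR arithmetic", {
  p <- mk_pair(pos1 = 100L, pos2 = 180L, len = 50L)
  expect_identical(p$key$left_pos, 100L)
  expect_identical(p$key$right_pos, 229L)
  # soft clips consume no reference: 5S45M@100 ends at 144, 50M@160 at 209
  p2 <- mk_pair(pos1 = 100L, pos2 = 160L, len = 50L, cigar1 = "5S45M")
  expect_identical(p2$key$left_pos, 100L)
  expect_identical(p2$key$right_pos, 209L)
  p3 <- mk_pair(pos1 = 100L, pos2 = 100L, len = 50L)
  expect_identical(p3$key$right_pos, 149L)
})

test_that("UMIs are recovered from read names", {
  expect_identical(extract_umi("A00001:8:read123:ATGC_GCAA"), "ATGC_GCAA")
  expect_identical(extract_umi("read123"), "")
  expect_identical(extract_umi("read123:UMI_TTAA"), "TTAA")
  expect_identical(extract_umi("read123:notaumi"), "")
  expect_identical(extract_umi("r+TTAA", delimiter = "+"), "TTAA")
})

test_that("canonical form unifies reciprocal dual UMIs", {
  expect_identical(canonical_umi("GCAA_ATGC")$umi, "ATGC_GCAA")
  expect_identical(canonical_umi("GCAA_ATGC")$orientation, "ba")
  expect_identical(canonical_umi("ATGC_GCAA")$umi, "ATGC_GCAA")
  expect_identical(canonical_umi("ATGC_GCAA")$orientation, "ab")
  expect_identical(canonical_umi("TTTT")$umi, "TTTT")
  expect_error(canonical_umi("A_B_C"), "malformed")
})

test_that("canonicalization is idempotent and symmetric", {
  set.seed(11)
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), 4, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N"), 4, TRUE), collapse = "")
    ab <- canonical_umi(paste0(a, "_", b))$umi
    ba <- canonical_umi(paste0(b, "_", a))$umi
    expect_identical(ab, ba)
    expect_identical(canonical_umi(ab)$umi, ab)
  }
})

test_that("UMI distance handles singles, duals and the swapped alignment", {
  expect_identical(umi_distance("ATGC", "ATGA"), 1)
  expect_identical(umi_distance("ATGC_GCAA", "ATGC_GCAA"), 0)
  expect_identical(umi_distance("ATGC_GCAA", "GCAA_ATGA"), 1)
  expect_identical(umi_distance("ATGC", "ATGCA"), Inf)
  expect_identical(umi_distance("ATGC", "ATGC_GCAA"), Inf)
  expect_identical(umi_distance("NNNN", "ATGC"), 4)
})

mk_umi_pairs <- function(umis) {
  lapply(seq_along(umis), function(i) {
    mk_pair(sprintf("u%03d", i), pos1 = 100L, pos2 = 180L, len = 50L,
            umi = umis[i])
  })
}

test_that("greedy UMI clustering merges within tolerance, seeds first", {
  cl <- cluster_by_umi(mk_umi_pairs(c("ATGC", "ATGC", "ATGC", "ATGA")))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$canonical_umi, "ATGC")
  expect_length(cl[[1]]$members, 4L)

  cl2 <- cluster_by_umi(mk_umi_pairs(c("AAAA", "AAAA", "TTTT", "TTTT")))
  expect_length(cl2, 2L)

  cl3 <- cluster_by_umi(mk_umi_pairs(c("ATGC_GCAA", "GCAA_ATGC")))
  expect_length(cl3, 1L)
  expect_identical(cl3[[1]]$strand_counts, c(1L, 1L))
})

test_that("non-UMI mode forms one cluster; mixed presence is fatal", {
  cl <- cluster_by_umi(mk_umi_pairs(c("", "", "")))
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 3L)
  expect_identical(cl[[1]]$strand_counts, c(0L, 0L))
  expect_error(cluster_by_umi(mk_umi_pairs(c("ATGC", ""))),
               "inconsistent UMI presence")
})

test_that("tolerance 0 clustering matches exact canonical grouping", {
  set.seed(5)
  schema0 <- scoring_schema(umi_tolerance = 0L)
  for (i in 1:20) {
    umis <- replicate(sample(3:30, 1L), paste(
      sample(c("A", "C", "G", "T"), 4, TRUE), collapse = ""))
    cl <- cluster_by_umi(mk_umi_pairs(umis), schema0)
    canon <- sapply(umis, function(u) canonical_umi(u)$umi)
    expect_identical(length(cl), length(unique(canon)))
    sizes <- sort(sapply(cl, function(c) length(c$members)))
    expect_identical(sizes, sort(as.integer(table(canon))), ignore_attr = TRUE)
  }
})

test_that("tolerance 1 clustering matches the greedy brute-force oracle", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(2:50, 1L)
    len <- sample(3:8, 1L)
    umis <- replicate(n, paste(
      sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
    cl <- cluster_by_umi(mk_umi_pairs(umis))
    canon <- sapply(umis, function(u) canonical_umi(u)$umi)
    oracle <- oracle_cluster_umis(canon, 1L)
    expect_identical(sapply(cl, `[[`, "canonical_umi"), oracle$seeds,
                     ignore_attr = TRUE)
    for (j in seq_along(cl)) {
      member_canon <- sapply(cl[[j]]$members,
                             function(p) canonical_umi(p$umi)$umi)
      expect_setequal(unique(member_canon),
                      names(oracle$assign)[oracle$assign == j])
    }
  }
})

test_that("clustering partitions its input", {
  set.seed(3)
  umis <- replicate(40, paste(sample(c("A", "C"), 4, TRUE), collapse = ""))
  pairs <- mk_umi_pairs(umis)
  cl <- cluster_by_umi(pairs)
  all_names <- unlist(lapply(cl, function(c)
    sapply(c$members, function(p) p$read1$qname)))
  expect_setequal(all_names, sapply(pairs, function(p) p$read1$qname))
  expect_identical(anyDuplicated(all_names), 0L)
})

test_that("supporting-reads filter compares against the threshold", {
  one <- cluster_by_umi(mk_umi_pairs("ATGC"))[[1]]
  expect_true(passes_filter(one, scoring_schema()))
  expect_false(passes_filter(one, scoring_schema(min_supporting_reads = 2)))
  two <- cluster_by_umi(mk_umi_pairs(c("ATGC", "ATGC")))[[1]]
  expect_true(passes_filter(two, scoring_schema(min_supporting_reads = 2)))
})
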