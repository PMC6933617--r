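## UMI extraction, canonicalization and tolerance-based clustering.
## Dual (duplex) UMIs are written A_B; reads sequenced from the opposite
## strand of the same fragment carry B_A, and both forms must land in one
## cluster.

#' Extract a UMI from a read name
#'
#' UMI-aware preprocessors move the molecular barcode into the read name as
#' its last `delimiter`-separated field (dual UMIs joined by `"_"`, e.g.
#' `"A00001:8:read123:ATGC_GCAA"`). Returns the empty string when no UMI is
#' present, which switches that read to non-UMI mode.
#'
#' @param query_name Read name.
#' @param delimiter Character separating the UMI from the rest of the name
#'   (default `":"`).
#' @param prefix Optional prefix stripped from the UMI tail (default
#'   `"UMI_"`).
#' @return The UMI string, or `""` if the name carries none.
#' @examples
#' extract_umi("A00001:8:read123:ATGC_GCAA")
#' extract_umi("read123")
#' extract_umi("read123:UMI_TTAA")
#' @export
extract_umi <- function(query_name, delimiter = ":", prefix = "UMI_") {
  parts <- strsplit(query_name, delimiter, fixed = TRUE)[[1]]
  if (length(parts) < 2L) return("")
  tail <- parts[length(parts)]
  if (nzchar(prefix) && startsWith(tail, prefix)) {
    tail <- substring(tail, nchar(prefix) + 1L)
  }
  if (!nzchar(tail) || !grepl("^[ACGTN_]+$", tail)) return("")
  tail
}

#' Canonicalize a (possibly dual) UMI
#'
#' Single UMIs are returned unchanged. A dual UMI `"A_B"` maps to the
#' lexicographic minimum of `"A_B"` and `"B_A"`, so the two reciprocal
#' orientations — reads derived from the two strands of one original DNA
#' fragment — share a single clustering key. The orientation records whether
#' the input already was the canonical form (`"ab"`) or the reciprocal
#' (`"ba"`).
#'
#' @param umi Non-empty UMI string; dual UMIs use `"_"` as strand separator.
#' @return A list with `umi` (canonical string) and `orientation` (`"ab"` or
#'   `"ba"`; single UMIs are always `"ab"`).
#' @examples
#' canonical_umi("GCAA_ATGC")$umi   # "ATGC_GCAA"
#' canonical_umi("TTTT")$umi        # unchanged
#' @export
canonical_umi <- function(umi) {
  parts <- strsplit(umi, "_", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    return(list(umi = umi, orientation = "ab"))
  }
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop(sprintf("malformed UMI '%s': expected at most one '_' separator", umi))
  }
  swapped <- paste0(parts[2], "_", parts[1])
  if (umi <= swapped) {
    list(umi = umi, orientation = "ab")
  } else {
    list(umi = swapped, orientation = "ba")
  }
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Distance between two canonical UMIs
#'
#' Single UMIs: Hamming distance (`Inf` on length mismatch). Dual UMIs: the
#' minimum, over the direct and the swapped part alignment, of the summed
#' part-wise Hamming distances. N bases count as mismatches.
#'
#' @param u1,u2 Canonical UMI strings.
#' @return Integer distance, or `Inf` when the UMIs are structurally
#'   incomparable.
#' @examples
#' umi_distance("ATGC", "ATGA")            # 1
#' umi_distance("ATGC_GCAA", "GCAA_ATGA")  # 1 (swapped alignment)
#' @export
umi_distance <- function(u1, u2) {
  p1 <- strsplit(u1, "_", fixed = TRUE)[[1]]
  p2 <- strsplit(u2, "_", fixed = TRUE)[[1]]
  if (length(p1) != length(p2)) return(Inf)
  if (length(p1) == 1L) return(as.numeric(hamming(u1, u2)))
  as.numeric(min(hamming(p1[1], p2[1]) + hamming(p1[2], p2[2]),
                 hamming(p1[1], p2[2]) + hamming(p1[2], p2[1])))
}

#' Cluster read pairs sharing one fragment key by UMI
#'
#' Canonical UMIs are ranked by descending member count (ties broken
#' lexicographically); each UMI in rank order joins the first existing
#' cluster whose *seed* UMI lies within `schema$umi_tolerance`, else seeds a
#' new cluster. Merging is greedy and non-transitive: distance is always
#' measured to the seed, so unrelated UMIs cannot chain together through
#' intermediates. In non-UMI mode (all UMIs empty) all pairs form one
#' cluster.
#'
#' @param pairs List of `read_pair` objects sharing one fragment key.
#' @param schema A [scoring_schema()].
#' @return A list of `umi_cluster` objects (fields `key`, `canonical_umi`,
#'   `members`, `strand_counts`), ordered by seed rank.
#' @export
cluster_by_umi <- function(pairs, schema = scoring_schema()) {
  stopifnot(length(pairs) >= 1L)
  key <- pairs[[1]]$key
  umis <- vapply(pairs, function(p) p$umi, character(1))
  has <- nzchar(umis)
  if (!any(has)) {
    return(list(new_umi_cluster(key, "", pairs, c(0L, 0L))))
  }
  if (!all(has)) {
    stop("inconsistent UMI presence: some read pairs carry UMIs and some do not")
  }
  canon <- lapply(umis, canonical_umi)
  cu <- vapply(canon, `[[`, character(1), "umi")
  orient <- vapply(canon, `[[`, character(1), "orientation")
  counts <- table(cu)
  ord <- order(-as.integer(counts), names(counts))
  ranked <- names(counts)[ord]
  seeds <- character(0)
  assignment <- integer(length(ranked))
  for (i in seq_along(ranked)) {
    hit <- 0L
    for (j in seq_along(seeds)) {
      if (umi_distance(ranked[i], seeds[j]) <= schema$umi_tolerance) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      seeds <- c(seeds, ranked[i])
      hit <- length(seeds)
    }
    assignment[i] <- hit
  }
  lapply(seq_along(seeds), function(j) {
    in_cluster <- cu %in% ranked[assignment == j]
    dual <- grepl("_", seeds[j], fixed = TRUE)
    sc <- if (dual) {
      c(sum(orient[in_cluster] == "ab"), sum(orient[in_cluster] == "ba"))
    } else {
      c(0L, 0L)
    }
    new_umi_cluster(key, seeds[j], pairs[in_cluster], as.integer(sc))
  })
}

new_umi_cluster <- function(key, canonical_umi, members, strand_counts) {
  structure(
    list(key = key, canonical_umi = canonical_umi, members = members,
         strand_counts = strand_counts),
    class = "umi_cluster")
}

#' @export
print.umi_cluster <- function(x, ...) {
  cat(sprintf("<umi_cluster %s:%d-%d UMI='%s' members=%d strands=%d/%d>\n",
              x$key$chrom, x$key$left_pos, x$key$right_pos,
              x$canonical_umi, length(x$members),
              x$strand_counts[1], x$strand_counts[2]))
  invisible(x)
}

#' Supporting-reads cluster filter
#'
#' A cluster passes when its member count reaches the configured threshold.
#' The default threshold of 1 keeps everything; raising it to 2 discards
#' fragments seen without any PCR duplicate, which is recommended for
#' ultra-deep sequencing.
#'
#' @param cluster A `umi_cluster`.
#' @param schema A [scoring_schema()].
#' @return Logical.
#' @export
passes_filter <- function(cluster, schema = scoring_schema()) {
  length(cluster$members) >= schema$min_supporting_reads
}
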