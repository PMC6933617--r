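## Consensus generation: per-pair mate-overlap base scoring, per-cluster
## score summation over A/C/G/T, and reference-aware consensus calling.

BASES <- c("A", "C", "G", "T")

#' Score the bases of one read pair
#'
#' Every base starts at `schema$initial_score`. Over the reference interval
#' covered by both mates (M/=/X-aligned positions only), agreement raises
#' both bases to `agree_bonus`; on disagreement the strictly higher-quality
#' base keeps `disagree_keep` and the other drops to `disagree_drop` (a
#' quality tie drops both). Bases outside the overlap keep the initial
#' score, so a lone non-overlapping pair contributes `initial_score`
#' everywhere.
#'
#' @param pair A `read_pair` with both mates mapped.
#' @param schema A [scoring_schema()].
#' @return List with integer score vectors `read1` and `read2`, one entry
#'   per query base.
#' @export
score_pair <- function(pair, schema = scoring_schema()) {
  r1 <- pair$read1
  r2 <- pair$read2
  if (is.null(r1) || is.null(r2)) {
    stop("orphan read pair: both mates are required for pair scoring")
  }
  s1 <- rep(schema$initial_score, nchar(r1$seq))
  s2 <- rep(schema$initial_score, nchar(r2$seq))
  m1 <- aligned_query_map(r1)
  m2 <- aligned_query_map(r2)
  shared <- intersect(m1$rpos, m2$rpos)
  if (length(shared)) {
    i1 <- m1$qpos[match(shared, m1$rpos)]
    i2 <- m2$qpos[match(shared, m2$rpos)]
    b1 <- substring(r1$seq, i1, i1)
    b2 <- substring(r2$seq, i2, i2)
    q1 <- r1$quals[i1]
    q2 <- r2$quals[i2]
    agree <- b1 == b2
    s1[i1[agree]] <- schema$agree_bonus
    s2[i2[agree]] <- schema$agree_bonus
    d <- !agree
    s1[i1[d & q1 > q2]] <- schema$disagree_keep
    s2[i2[d & q1 > q2]] <- schema$disagree_drop
    s1[i1[d & q2 > q1]] <- schema$disagree_drop
    s2[i2[d & q2 > q1]] <- schema$disagree_keep
    s1[i1[d & q1 == q2]] <- schema$disagree_drop
    s2[i2[d & q1 == q2]] <- schema$disagree_drop
  }
  list(read1 = s1, read2 = s2)
}

## template = member with highest summed mate MAPQ; tie -> lexicographically
## smallest query name
select_template <- function(members) {
  mapq <- vapply(members, function(p) p$read1$mapq + p$read2$mapq, numeric(1))
  nm <- vapply(members, function(p) p$read1$qname, character(1))
  order(-mapq, nm)[1]
}

member_matches_template <- function(member, template) {
  identical(member$read1$ref_start, template$read1$ref_start) &&
    identical(member$read1$cigar, template$read1$cigar) &&
    identical(member$read2$ref_start, template$read2$ref_start) &&
    identical(member$read2$cigar, template$read2$cigar)
}

#' Sum per-pair base scores over a cluster
#'
#' For every template query position, the scores from [score_pair()] of all
#' included members are summed per base (A/C/G/T); the per-base maximum
#' observed Phred quality and a coverage count are recorded alongside. N
#' bases contribute no score. Members whose per-mate CIGAR or position
#' differs from the template's are excluded from scoring (no realignment)
#' and counted in `n_excluded`.
#'
#' @param cluster A `umi_cluster`.
#' @param schema A [scoring_schema()].
#' @param template_idx Index of the template member; defaults to the member
#'   with the highest summed mate MAPQ (ties: smallest query name).
#' @return A `score_matrix`: list with `key`, `template_idx`, `included`
#'   (logical per member), `n_excluded`, and per mate (`read1`, `read2`) a
#'   list of `scores` (4 x L integer matrix, rows A/C/G/T), `maxq` (4 x L),
#'   `obs` (4 x L logical: base seen at position), `coverage` (length-L
#'   integer).
#' @export
score_cluster <- function(cluster, schema = scoring_schema(),
                          template_idx = NULL) {
  members <- cluster$members
  if (is.null(template_idx)) template_idx <- select_template(members)
  template <- members[[template_idx]]
  included <- vapply(members, member_matches_template, logical(1),
                     template = template)
  if (!any(included)) {
    stop("degenerate cluster: every member excluded by CIGAR mismatch")
  }
  mates <- list()
  for (mate in c("read1", "read2")) {
    L <- nchar(template[[mate]]$seq)
    scores <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
    maxq <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
    obs <- matrix(FALSE, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
    coverage <- integer(L)
    for (i in which(included)) {
      p <- members[[i]]
      sp <- score_pair(p, schema)
      r <- p[[mate]]
      rows <- match(strsplit(r$seq, "")[[1]], BASES)  # N -> NA
      ok <- !is.na(rows)
      lin <- rows[ok] + 4L * (which(ok) - 1L)
      scores[lin] <- scores[lin] + sp[[mate]][ok]
      maxq[lin] <- pmax(maxq[lin], r$quals[ok])
      obs[lin] <- TRUE
      coverage <- coverage + 1L
    }
    mates[[mate]] <- list(scores = scores, maxq = maxq, obs = obs,
                          coverage = coverage)
  }
  structure(
    list(key = cluster$key, template_idx = template_idx,
         included = included, n_excluded = sum(!included),
         read1 = mates$read1, read2 = mates$read2),
    class = "score_matrix")
}

## vectorized consensus call over all columns of one mate.
## refbases: character vector length L, NA where no reference base exists
## (insertion / soft-clip columns, where reference fallback is disabled).
call_columns <- function(sm_mate, refbases, schema) {
  scores <- sm_mate$scores
  maxq <- sm_mate$maxq
  obs <- sm_mate$obs
  L <- ncol(scores)
  if (L == 0L) {
    return(list(bases = character(0), quals = integer(0),
                ref_corrected = integer(0)))
  }
  s_tot <- colSums(scores)
  s_max <- pmax(scores[1, ], scores[2, ], scores[3, ], scores[4, ])
  n_max <- colSums(scores == rep(s_max, each = 4L))
  top <- max.col(t(scores), ties.method = "first")  # alphabetical on ties
  ref_row <- match(refbases, BASES)
  has_ref <- !is.na(ref_row)
  ref_lin <- ifelse(has_ref, ref_row + 4L * (seq_len(L) - 1L), 1L)

  bases <- character(L)
  quals <- integer(L)

  zero <- s_tot == 0L
  a <- !zero & (s_max >= schema$dominant_fraction * s_tot) & n_max == 1L
  colq <- pmax(maxq[1, ], maxq[2, ], maxq[3, ], maxq[4, ])
  anyobs <- obs[1, ] | obs[2, ] | obs[3, ] | obs[4, ]
  ref_high <- has_ref & obs[ref_lin] & maxq[ref_lin] >= schema$high_qual
  all_low <- anyobs & colq < schema$moderate_qual
  b <- !zero & !a & has_ref & (ref_high | all_low)
  cc <- !zero & !a & !b

  if (any(a)) {
    ia <- which(a)
    bases[ia] <- BASES[top[ia]]
    quals[ia] <- maxq[cbind(top[ia], ia)]
  }
  if (any(b)) {
    bases[b] <- refbases[b]
    quals[b] <- schema$moderate_qual
  }
  if (any(cc)) {
    ic <- which(cc)
    ref_tied <- has_ref[ic] & scores[ref_lin[ic]] == s_max[ic]
    pick <- ifelse(ref_tied, ref_row[ic], top[ic])
    bases[ic] <- BASES[pick]
    quals[ic] <- 2L
  }
  if (any(zero)) {
    iz <- which(zero)
    bases[iz] <- ifelse(has_ref[iz], refbases[iz], "N")
    quals[iz] <- 2L
  }
  list(bases = bases, quals = quals,
       ref_corrected = which(b & BASES[top] != refbases))
}

#' Call one consensus base
#'
#' Scalar form of the per-column consensus rule. With `S_tot` the summed
#' score over bases and `S_max` the top base's score: (a) a unique top base
#' holding at least `dominant_fraction` of `S_tot` is called with the
#' maximum Phred observed among its carriers; (b) otherwise the reference
#' base is called at `moderate_qual` when some read carries it at Phred >=
#' `high_qual`, or when every covering base is below `moderate_qual`; (c)
#' otherwise the highest-scoring base is called at Phred 2 (ties: the
#' reference base if tied, else alphabetical). A scoreless column yields the
#' reference base at Phred 2.
#'
#' @param scores Named numeric vector of summed scores for A/C/G/T.
#' @param max_quals Named numeric vector: maximum observed Phred per base.
#' @param ref_base Reference base at this position, or `NA` where none
#'   exists (insertion/soft-clip columns; disables reference fallback).
#' @param schema A [scoring_schema()].
#' @param observed Logical per base: was the base seen at all (defaults to
#'   `scores > 0 | max_quals > 0`).
#' @return List with `base` and `qual`.
#' @examples
#' call_consensus_base(c(A = 18, C = 0, G = 0, T = 0),
#'                     c(A = 35, C = 0, G = 0, T = 0), ref_base = "C")
#' @export
call_consensus_base <- function(scores, max_quals, ref_base = NA,
                                schema = scoring_schema(),
                                observed = NULL) {
  scores <- scores[BASES]
  scores[is.na(scores)] <- 0
  max_quals <- max_quals[BASES]
  max_quals <- ifelse(is.na(max_quals), 0, max_quals)
  if (is.null(observed)) observed <- scores > 0 | max_quals > 0
  sm <- list(scores = matrix(as.integer(scores), ncol = 1,
                             dimnames = list(BASES, NULL)),
             maxq = matrix(as.integer(max_quals), ncol = 1,
                           dimnames = list(BASES, NULL)),
             obs = matrix(as.logical(observed[BASES]), ncol = 1,
                          dimnames = list(BASES, NULL)))
  out <- call_columns(sm, as.character(ref_base), schema)
  list(base = out$bases, qual = out$quals)
}

#' Merge a cluster into one consensus read pair
#'
#' The template is the member pair with the highest summed mate MAPQ (ties
#' broken by query name); its names, flags, positions and CIGARs carry over
#' to the output. Every M/=/X-aligned query position is called through the
#' consensus rule against the reference; insertion and soft-clipped
#' positions, having no reference base, use the dominant-or-highest-score
#' rule only. The consensus records carry the supporting pair count in the
#' `sp:i` tag and (for dual UMIs) the two strand-orientation counts in
#' `fs:i`/`rs:i`.
#'
#' @param cluster A `umi_cluster` that passed the supporting-reads filter.
#' @param ref A `ref_genome` from [load_reference()].
#' @param schema A [scoring_schema()].
#' @return A `consensus_read`: list with `read1`/`read2` (consensus
#'   `aligned_read`s), `supporting_pairs`, `strand_counts`,
#'   `ref_corrected` (per mate, query positions where the reference
#'   overrode read evidence) and `n_excluded`.
#' @export
build_consensus_pair <- function(cluster, ref, schema = scoring_schema()) {
  members <- cluster$members
  template_idx <- select_template(members)
  template <- members[[template_idx]]
  sm <- tryCatch(
    score_cluster(cluster, schema, template_idx = template_idx),
    error = function(e) NULL)
  if (is.null(sm)) {
    # degenerate cluster: emit the template pair unchanged
    return(structure(
      list(read1 = template$read1, read2 = template$read2,
           supporting_pairs = 1L, strand_counts = cluster$strand_counts,
           ref_corrected = list(read1 = integer(0), read2 = integer(0)),
           n_excluded = length(members) - 1L),
      class = "consensus_read"))
  }
  out <- list()
  ref_corrected <- list()
  for (mate in c("read1", "read2")) {
    tr <- template[[mate]]
    L <- nchar(tr$seq)
    refbases <- rep(NA_character_, L)
    qmap <- aligned_query_map(tr)
    if (length(qmap$qpos)) {
      span0 <- min(qmap$rpos)
      chars <- strsplit(ref_subseq(ref, tr$chrom, span0,
                                   max(qmap$rpos) + 1L), "")[[1]]
      refbases[qmap$qpos] <- chars[qmap$rpos - span0 + 1L]
    }
    call <- call_columns(sm[[mate]], refbases, schema)
    cons <- tr
    cons$seq <- paste(call$bases, collapse = "")
    cons$quals <- call$quals
    cons$mapq <- as.integer(max(vapply(members[sm$included],
                                       function(p) p[[mate]]$mapq,
                                       numeric(1))))
    cons$tags <- c(sprintf("sp:i:%d", length(members)),
                   if (sum(cluster$strand_counts) > 0L) {
                     c(sprintf("fs:i:%d", cluster$strand_counts[1]),
                       sprintf("rs:i:%d", cluster$strand_counts[2]))
                   })
    cons$line <- NULL  # force fresh serialization
    out[[mate]] <- cons
    ref_corrected[[mate]] <- call$ref_corrected
  }
  structure(
    list(read1 = out$read1, read2 = out$read2,
         supporting_pairs = length(members),
         strand_counts = cluster$strand_counts,
         ref_corrected = ref_corrected,
         n_excluded = sm$n_excluded),
    class = "consensus_read")
}

#' @export
print.consensus_read <- function(x, ...) {
  cat(sprintf("<consensus_read %s %s:%d support=%d excluded=%d>\n",
              x$read1$qname, x$read1$chrom, x$read1$ref_start,
              x$supporting_pairs, x$n_excluded))
  invisible(x)
}
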