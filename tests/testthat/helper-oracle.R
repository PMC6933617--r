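# Independent brute-force oracles. These re-derive the scoring and
# consensus rules with naive explicit loops and no shared code with the
# package internals, so agreement is a genuine two-route check.

# reference positions covered by M/=/X ops of one read, one by one
oracle_covered <- function(read) {
  out <- list()
  q <- 1L
  r <- read$ref_start
  cig <- consensr:::parse_cigar(read$cigar)
  for (i in seq_along(cig$ops)) {
    for (k in seq_len(cig$lens[i])) {
      op <- cig$ops[i]
      if (op %in% c("M", "=", "X")) {
        out[[length(out) + 1L]] <- c(q = q, r = r)
        q <- q + 1L
        r <- r + 1L
      } else if (op %in% c("I", "S")) {
        q <- q + 1L
      } else if (op %in% c("D", "N")) {
        r <- r + 1L
      }
    }
  }
  out
}

# per-mate base scores of one pair, scalar loops only
oracle_score_pair <- function(pair, schema) {
  s1 <- rep(schema$initial_score, nchar(pair$read1$seq))
  s2 <- rep(schema$initial_score, nchar(pair$read2$seq))
  cov1 <- oracle_covered(pair$read1)
  cov2 <- oracle_covered(pair$read2)
  for (a in cov1) {
    for (b in cov2) {
      if (a["r"] != b["r"]) next
      b1 <- substr(pair$read1$seq, a["q"], a["q"])
      b2 <- substr(pair$read2$seq, b["q"], b["q"])
      q1 <- pair$read1$quals[a["q"]]
      q2 <- pair$read2$quals[b["q"]]
      if (b1 == b2) {
        s1[a["q"]] <- schema$agree_bonus
        s2[b["q"]] <- schema$agree_bonus
      } else if (q1 > q2) {
        s1[a["q"]] <- schema$disagree_keep
        s2[b["q"]] <- schema$disagree_drop
      } else if (q2 > q1) {
        s1[a["q"]] <- schema$disagree_drop
        s2[b["q"]] <- schema$disagree_keep
      } else {
        s1[a["q"]] <- schema$disagree_drop
        s2[b["q"]] <- schema$disagree_drop
      }
    }
  }
  list(read1 = s1, read2 = s2)
}

oracle_call <- function(score, maxq, obs, refb, schema) {
  bases <- c("A", "C", "G", "T")
  s_tot <- sum(score)
  if (s_tot == 0) {
    return(list(base = if (is.na(refb)) "N" else refb, qual = 2L))
  }
  s_max <- max(score)
  winners <- bases[score == s_max]
  if (length(winners) == 1L && s_max / s_tot >= schema$dominant_fraction) {
    return(list(base = winners, qual = maxq[[winners]]))
  }
  if (!is.na(refb)) {
    ref_high <- obs[[refb]] && maxq[[refb]] >= schema$high_qual
    all_low <- any(obs) && max(maxq[obs]) < schema$moderate_qual
    if (ref_high || all_low) {
      return(list(base = refb, qual = schema$moderate_qual))
    }
  }
  pick <- if (!is.na(refb) && refb %in% winners) refb else winners[1]
  list(base = pick, qual = 2L)
}

# full naive consensus: materializes the per-position score table
oracle_consensus <- function(members, ref, schema) {
  bases <- c("A", "C", "G", "T")
  mapqs <- sapply(members, function(p) p$read1$mapq + p$read2$mapq)
  nms <- sapply(members, function(p) p$read1$qname)
  best <- which(mapqs == max(mapqs))
  tpl_i <- best[order(nms[best])][1]
  tpl <- members[[tpl_i]]
  same_shape <- function(p) {
    p$read1$ref_start == tpl$read1$ref_start &&
      p$read1$cigar == tpl$read1$cigar &&
      p$read2$ref_start == tpl$read2$ref_start &&
      p$read2$cigar == tpl$read2$cigar
  }
  included <- members[sapply(members, same_shape)]
  pair_scores <- lapply(included, oracle_score_pair, schema = schema)
  out <- list()
  for (mate in c("read1", "read2")) {
    L <- nchar(tpl[[mate]]$seq)
    refb <- rep(NA_character_, L)
    for (cov in oracle_covered(tpl[[mate]])) {
      refb[cov["q"]] <- ref_base(ref, tpl[[mate]]$chrom, cov["r"])
    }
    seq_out <- character(L)
    qual_out <- integer(L)
    for (pos in seq_len(L)) {
      score <- stats::setNames(rep(0, 4), bases)
      maxq <- stats::setNames(rep(0, 4), bases)
      obs <- stats::setNames(rep(FALSE, 4), bases)
      for (k in seq_along(included)) {
        p <- included[[k]]
        sp <- pair_scores[[k]]
        b <- substr(p[[mate]]$seq, pos, pos)
        if (!b %in% bases) next
        score[[b]] <- score[[b]] + sp[[mate]][pos]
        maxq[[b]] <- max(maxq[[b]], p[[mate]]$quals[pos])
        obs[[b]] <- TRUE
      }
      call <- oracle_call(score, maxq, obs, refb[pos], schema)
      seq_out[pos] <- call$base
      qual_out[pos] <- call$qual
    }
    out[[mate]] <- list(seq = paste(seq_out, collapse = ""),
                        quals = qual_out)
  }
  out
}

# greedy seed-based UMI clustering, re-derived with explicit loops
oracle_cluster_umis <- function(canonical_umis, tolerance) {
  naive_dist <- function(u1, u2) {
    p1 <- strsplit(u1, "_")[[1]]
    p2 <- strsplit(u2, "_")[[1]]
    if (length(p1) != length(p2)) return(Inf)
    hd <- function(a, b) {
      if (nchar(a) != nchar(b)) return(Inf)
      d <- 0
      for (i in seq_len(nchar(a))) {
        if (substr(a, i, i) != substr(b, i, i)) d <- d + 1
      }
      d
    }
    if (length(p1) == 1L) return(hd(u1, u2))
    min(hd(p1[1], p2[1]) + hd(p1[2], p2[2]),
        hd(p1[1], p2[2]) + hd(p1[2], p2[1]))
  }
  tab <- table(canonical_umis)
  ranked <- names(tab)[order(-as.integer(tab), names(tab))]
  seeds <- character(0)
  assign <- stats::setNames(integer(length(ranked)), ranked)
  for (u in ranked) {
    placed <- FALSE
    for (j in seq_along(seeds)) {
      if (naive_dist(u, seeds[j]) <= tolerance) {
        assign[[u]] <- j
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, u)
      assign[[u]] <- length(seeds)
    }
  }
  list(seeds = seeds, assign = assign)
}
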