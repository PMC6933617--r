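# In-code fixture builders shared across test files.

# single aligned read with uniform or per-base qualities
mk_read <- function(qname, chrom = "simchr1", pos0 = 100L, cigar = "50M",
                    seq = NULL, quals = 30L, flag = 99L, mapq = 60L,
                    umi = "", chrom_idx = 1L, rnext = "=", pnext = 0L,
                    tlen = 0L) {
  qlen <- consensr:::cigar_query_len(consensr:::parse_cigar(cigar))
  if (is.null(seq)) seq <- paste(rep("A", qlen), collapse = "")
  if (length(quals) == 1L) quals <- rep(quals, nchar(seq))
  aligned_read(qname = qname, flag = flag, chrom = chrom, ref_start = pos0,
               mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
               tlen = tlen, seq = seq, quals = quals, umi = umi,
               chrom_idx = chrom_idx)
}

# proper FR pair: read1 forward at pos1, read2 reverse at pos2
mk_pair <- function(qname = "p1", chrom = "simchr1", pos1 = 100L,
                    pos2 = 180L, len = 50L, seq1 = NULL, seq2 = NULL,
                    quals1 = 30L, quals2 = 30L, mapq = 60L, umi = "",
                    cigar1 = NULL, cigar2 = NULL) {
  if (is.null(cigar1)) cigar1 <- sprintf("%dM", len)
  if (is.null(cigar2)) cigar2 <- sprintf("%dM", len)
  r1 <- mk_read(qname, chrom, pos1, cigar1, seq1, quals1, flag = 99L,
                mapq = mapq, umi = umi)
  r2 <- mk_read(qname, chrom, pos2, cigar2, seq2, quals2, flag = 147L,
                mapq = mapq, umi = umi)
  read_pair(r1, r2)
}

# reference genome built from literal sequence strings
mk_ref <- function(...) {
  seqs <- toupper(c(...))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("simchr", seq_along(seqs))
  }
  structure(list(seqs = seqs, lengths = nchar(seqs)), class = "ref_genome")
}

# repeat a base / cycle a string to length n
bases_n <- function(base, n) paste(rep(base, n), collapse = "")
cycle_n <- function(s, n) {
  paste(rep_len(strsplit(s, "")[[1]], n), collapse = "")
}

# write a SAM file from record field lists; returns path
write_sam <- function(records, path = tempfile(fileext = ".sam"),
                      chroms = c(simchr1 = 100000L),
                      sort_order = "coordinate") {
  header <- c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, mapq = 60L,
                       cigar = "4M", rnext = "*", pnext = 0L, tlen = 0L,
                       seq = "ACGT", qual = NULL) {
  if (is.null(qual)) {
    qual <- if (seq == "*") "*" else paste(rep("I", nchar(seq)), collapse = "")
  }
  paste(qname, flag, chrom, pos1, mapq, cigar, rnext, pnext, tlen, seq,
        qual, sep = "\t")
}

# random read pair cluster for property tests: n members, read length L,
# substitution errors at err on a shared true fragment
random_cluster <- function(n, L = 20L, err = 0.05, overlap = TRUE,
                           chrom_seq = NULL, umi = "") {
  flen <- if (overlap) round(L * 1.5) else 3L * L
  if (is.null(chrom_seq)) {
    chrom_seq <- paste(sample(c("A", "C", "G", "T"), max(400L, 3L * L + 50L),
                              replace = TRUE), collapse = "")
  }
  ref <- mk_ref(chrom_seq)
  start <- sample.int(nchar(chrom_seq) - flen, 1L) - 1L
  frag <- ref_subseq(ref, "simchr1", start, start + flen)
  truth1 <- substr(frag, 1L, L)
  truth2 <- substr(frag, flen - L + 1L, flen)
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    for (i in which(stats::runif(length(ch)) < err)) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }
  members <- lapply(seq_len(n), function(d) {
    mk_pair(qname = sprintf("rc%03d", d), pos1 = start,
            pos2 = start + flen - L, len = L,
            seq1 = mutate(truth1), seq2 = mutate(truth2),
            quals1 = sample(c(36L, 11L), L, replace = TRUE,
                            prob = c(0.9, 0.1)),
            quals2 = sample(c(36L, 11L), L, replace = TRUE,
                            prob = c(0.9, 0.1)),
            umi = umi)
  })
  cluster <- consensr:::new_umi_cluster(members[[1]]$key, umi, members,
                                        c(0L, 0L))
  list(cluster = cluster, ref = ref, truth1 = truth1, truth2 = truth2)
}
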