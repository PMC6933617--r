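## Ground-truthed synthetic fixtures: random reference, cfDNA-like fragment
## lengths (~167 bp peak), per-fragment UMIs (single or dual), PCR duplicate
## multiplicities, per-base substitution errors under a two-level Phred
## quality model, and a coordinate-sorted SAM/BAM fixture with a JSON
## ground-truth sidecar.

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Generate a random reference genome
#'
#' @param n_chroms Number of chromosomes.
#' @param length Length of each chromosome (>= 1).
#' @param seed Optional RNG seed (reproducible output when set).
#' @return A `ref_genome` whose sequences are i.i.d. uniform A/C/G/T;
#'   chromosomes are named `simchr1`, `simchr2`, ...
#' @export
make_reference <- function(n_chroms = 1L, length = 100000L, seed = NULL) {
  if (length < 1L) stop("chromosome length must be >= 1")
  if (n_chroms < 1L) stop("n_chroms must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i) random_dna(length),
                 character(1))
  names(seqs) <- paste0("simchr", seq_len(n_chroms))
  structure(list(seqs = seqs, lengths = nchar(seqs)), class = "ref_genome")
}

#' Draw cfDNA-like fragment intervals
#'
#' Fragment lengths are normal with the cell-free DNA peak of ~167 bp as
#' the default mean, clipped below at `read_len` (so a read never runs off
#' its fragment) and above at the chromosome length; start positions are
#' uniform.
#'
#' @param n Number of fragments (>= 0).
#' @param reference A `ref_genome`.
#' @param mean_len,sd_len Fragment length distribution (defaults 167, 10).
#' @param read_len Sequencing read length (lower clip; default 100).
#' @param seed Optional RNG seed.
#' @param unique_keys Reject duplicated (chrom, start, end) triples so
#'   every fragment owns a distinct position key (default TRUE).
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open),
#'   `len`.
#' @export
draw_fragments <- function(n, reference, mean_len = 167L, sd_len = 10L,
                           read_len = 100L, seed = NULL,
                           unique_keys = TRUE) {
  if (n < 0L) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), len = integer(0)))
  }
  chroms <- names(reference$seqs)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), len = integer(0))
  attempts <- 0L
  while (nrow(out) < n) {
    need <- n - nrow(out)
    chrom <- sample(chroms, need, replace = TRUE)
    clen <- reference$lengths[chrom]
    len <- pmin(pmax(round(stats::rnorm(need, mean_len, sd_len)),
                     read_len), clen)
    start <- floor(stats::runif(need) * (clen - len + 1))
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + len), len = as.integer(len))
    out <- rbind(out, cand)
    if (unique_keys) {
      out <- out[!duplicated(out[, c("chrom", "start", "end")]), ,
                 drop = FALSE]
    }
    attempts <- attempts + 1L
    if (attempts > 100L) stop("cannot draw enough unique fragment keys")
  }
  rownames(out) <- NULL
  out[seq_len(n), , drop = FALSE]
}

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < error_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

draw_quals <- function(n, qual_model) {
  ifelse(stats::runif(n) < qual_model$low_fraction,
         qual_model$low, qual_model$high)
}

#' Amplify one fragment and sequence its duplicates
#'
#' Emulates PCR overrepresentation followed by paired-end sequencing: the
#' duplicate count is `1 + Poisson(dup_mean - 1)` (every fragment is
#' observed at least once); each duplicate yields a proper FR read pair
#' with all-M CIGARs, i.i.d. substitution errors at `error_rate`, and
#' qualities drawn from the two-level `qual_model`. In dual-UMI mode every
#' second duplicate carries the reciprocal `B_A` orientation in its name,
#' mimicking reads sequenced from the opposite strand of the fragment.
#'
#' @param fragment One row of [draw_fragments()] output (list or
#'   single-row data.frame with `chrom`, `start`, `end`).
#' @param reference A `ref_genome`.
#' @param frag_id Integer fragment id used in read names.
#' @param umi `""` for non-UMI mode, a single UMI string, or a dual UMI
#'   `"A_B"`.
#' @param dup_mean Expected duplicate count (>= 1).
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param read_len Read length.
#' @param qual_model List with `high`, `low` (Phred values) and
#'   `low_fraction`.
#' @param chrom_idx Chromosome rank for the reads.
#' @param variant Optional list `(pos0, alt)` planting a substitution on
#'   the fragment template, so every duplicate carries it (a true
#'   variant, as opposed to random errors).
#' @return List with `reads` (unsorted `aligned_read`s) and `truth`
#'   (error-free read sequences plus metadata).
#' @export
amplify_and_sequence <- function(fragment, reference, frag_id, umi = "",
                                 dup_mean = 4, error_rate = 0.005,
                                 read_len = 100L,
                                 qual_model = list(high = 36L, low = 11L,
                                                   low_fraction = 0.05),
                                 chrom_idx = 1L, variant = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (dup_mean < 1) stop("dup_mean must be >= 1")
  chrom <- fragment$chrom
  frag_seq <- ref_subseq(reference, chrom, fragment$start, fragment$end)
  if (!is.null(variant)) {
    substr(frag_seq, variant$pos0 + 1L, variant$pos0 + 1L) <- variant$alt
  }
  flen <- nchar(frag_seq)
  stopifnot(flen >= read_len)
  truth_seq1 <- substr(frag_seq, 1L, read_len)
  truth_seq2_fwd <- substr(frag_seq, flen - read_len + 1L, flen)
  pos1 <- fragment$start
  pos2 <- fragment$end - read_len
  n_dup <- 1L + stats::rpois(1L, dup_mean - 1)
  dual <- grepl("_", umi, fixed = TRUE)
  reads <- vector("list", 2L * n_dup)
  for (d in seq_len(n_dup)) {
    umi_name <- umi
    if (dual && d %% 2L == 0L) {
      parts <- strsplit(umi, "_", fixed = TRUE)[[1]]
      umi_name <- paste0(parts[2], "_", parts[1])
    }
    qname <- sprintf("sim%06d.%d%s", frag_id, d,
                     if (nzchar(umi)) paste0(":", umi_name) else "")
    seq1 <- apply_errors(truth_seq1, error_rate)
    seq2 <- apply_errors(truth_seq2_fwd, error_rate)
    tlen <- fragment$end - fragment$start
    reads[[2L * d - 1L]] <- aligned_read(
      qname = qname, flag = 99L, chrom = chrom, ref_start = pos1,
      mapq = 60L, cigar = sprintf("%dM", read_len), rnext = "=",
      pnext = pos2, tlen = tlen, seq = seq1,
      quals = draw_quals(read_len, qual_model), umi = umi_name,
      chrom_idx = chrom_idx)
    reads[[2L * d]] <- aligned_read(
      qname = qname, flag = 147L, chrom = chrom, ref_start = pos2,
      mapq = 60L, cigar = sprintf("%dM", read_len), rnext = "=",
      pnext = pos1, tlen = -tlen, seq = seq2,
      quals = draw_quals(read_len, qual_model), umi = umi_name,
      chrom_idx = chrom_idx)
  }
  truth <- list(
    id = sprintf("sim%06d", frag_id), chrom = chrom,
    start = fragment$start, end = fragment$end,
    umi = umi, n_duplicates = n_dup,
    seq1 = truth_seq1, seq2 = truth_seq2_fwd,
    variant = if (is.null(variant)) NULL else
      list(chrom = chrom, pos0 = fragment$start + variant$pos0,
           alt = variant$alt))
  list(reads = reads, truth = truth)
}

#' Write a coordinate-sorted fixture
#'
#' @param reads List of `aligned_read`s (any order).
#' @param reference A `ref_genome`.
#' @param sam_path Output alignment path (`.sam`, or `.bam` to convert and
#'   index through Rsamtools).
#' @param fasta_path Output reference path (a `.fai` index is written
#'   alongside).
#' @return List of written paths (`alignment`, `fasta`), invisibly.
#' @export
write_fixture <- function(reads, reference, sam_path, fasta_path) {
  set <- Biostrings::DNAStringSet(reference$seqs)
  Biostrings::writeXStringSet(set, fasta_path, width = 70L)
  Rsamtools::indexFa(fasta_path)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference$seqs), reference$lengths),
    "@PG\tID:consensr-simulate\tPN:consensr")
  lines <- character(0)
  if (length(reads)) {
    rank <- vapply(reads, function(r) key_rank(r$chrom_idx, r$ref_start),
                   numeric(1))
    reads <- reads[order(rank)]
    lines <- vapply(reads, sam_line, character(1), verbatim = FALSE)
  }
  out <- sam_path
  is_bam <- grepl("\\.bam$", sam_path, ignore.case = TRUE)
  txt <- if (is_bam) tempfile(fileext = ".sam") else sam_path
  writeLines(c(header, lines), txt)
  if (is_bam) {
    Rsamtools::asBam(txt, sub("\\.bam$", "", sam_path),
                     overwrite = TRUE, indexDestination = TRUE)
    unlink(txt)
  }
  invisible(list(alignment = out, fasta = fasta_path))
}

#' Simulate a complete ground-truthed fixture
#'
#' Convenience wrapper: random reference, fragments, amplification and
#' sequencing, sorted fixture files and a JSON ground-truth sidecar.
#'
#' @param out_prefix Path prefix; writes `<prefix>.sam` (or `.bam`),
#'   `<prefix>.fasta` (+`.fai`) and `<prefix>.truth.json`.
#' @param n_fragments Number of original DNA fragments.
#' @param dup_mean Expected PCR duplicate count per fragment (default 4).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param umi_mode `"none"`, `"single"` or `"dual"`.
#' @param seed RNG seed (fixture is deterministic given the seed).
#' @param read_len,mean_len,sd_len Read and fragment-length parameters
#'   (defaults 100, 167, 10).
#' @param ref_len,n_chroms Reference size (defaults 100000, 1).
#' @param umi_len Length of each UMI half (default 8 single, 4+4 dual).
#' @param qual_model Two-level Phred model (default Q36 with 5% Q11).
#' @param variant_fragment Index of one fragment to receive a planted true
#'   variant (NULL for none).
#' @param bam Write BAM instead of SAM (default FALSE).
#' @return List with `alignment`, `fasta`, `truth_path`, `truth`
#'   (list per fragment) and `fragments`.
#' @export
simulate_fixture <- function(out_prefix, n_fragments, dup_mean = 4,
                             error_rate = 0.005,
                             umi_mode = c("none", "single", "dual"),
                             seed = 1L, read_len = 100L, mean_len = 167L,
                             sd_len = 10L, ref_len = 100000L,
                             n_chroms = 1L, umi_len = NULL,
                             qual_model = list(high = 36L, low = 11L,
                                               low_fraction = 0.05),
                             variant_fragment = NULL, bam = FALSE) {
  umi_mode <- match.arg(umi_mode)
  set.seed(seed)
  reference <- make_reference(n_chroms, ref_len)
  fragments <- draw_fragments(n_fragments, reference, mean_len, sd_len,
                              read_len)
  if (is.null(umi_len)) umi_len <- if (umi_mode == "dual") 4L else 8L
  chrom_ranks <- stats::setNames(seq_along(reference$seqs),
                                 names(reference$seqs))
  reads <- list()
  truth <- vector("list", n_fragments)
  for (i in seq_len(n_fragments)) {
    umi <- switch(umi_mode,
                  none = "",
                  single = random_dna(umi_len),
                  dual = paste0(random_dna(umi_len), "_",
                                random_dna(umi_len)))
    variant <- NULL
    if (!is.null(variant_fragment) && i == variant_fragment) {
      pos0 <- sample.int(read_len, 1L) - 1L  # inside read1
      ref_b <- substr(ref_subseq(reference, fragments$chrom[i],
                                 fragments$start[i] + pos0,
                                 fragments$start[i] + pos0 + 1L), 1L, 1L)
      variant <- list(pos0 = pos0, alt = sample(setdiff(BASES, ref_b), 1L))
    }
    sim <- amplify_and_sequence(
      fragments[i, ], reference, i, umi = umi, dup_mean = dup_mean,
      error_rate = error_rate, read_len = read_len,
      qual_model = qual_model,
      chrom_idx = chrom_ranks[[fragments$chrom[i]]], variant = variant)
    reads <- c(reads, sim$reads)
    truth[[i]] <- sim$truth
  }
  aln_path <- paste0(out_prefix, if (bam) ".bam" else ".sam")
  fasta_path <- paste0(out_prefix, ".fasta")
  write_fixture(reads, reference, aln_path, fasta_path)
  truth_path <- paste0(out_prefix, ".truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  list(alignment = aln_path, fasta = fasta_path, truth_path = truth_path,
       truth = truth, fragments = fragments)
}
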