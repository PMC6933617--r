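## Reference genome and capture-region inputs.

#' Load a reference genome FASTA
#'
#' @param path FASTA path.
#' @return A `ref_genome` object: uppercase sequences addressable with
#'   [ref_base()] and [ref_subseq()].
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop(sprintf("reference FASTA not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # first word of defline
  structure(list(seqs = seqs, lengths = nchar(seqs)), class = "ref_genome")
}

ref_check_chrom <- function(ref, chrom) {
  if (!chrom %in% names(ref$seqs)) {
    stop(sprintf("chromosome '%s' not present in the reference FASTA", chrom))
  }
}

#' Single reference base
#'
#' @param ref A `ref_genome`.
#' @param chrom Chromosome name.
#' @param pos0 0-based position.
#' @return One uppercase base.
#' @export
ref_base <- function(ref, chrom, pos0) {
  ref_check_chrom(ref, chrom)
  if (pos0 < 0L || pos0 >= ref$lengths[[chrom]]) {
    stop(sprintf("position %d outside %s (length %d)",
                 pos0, chrom, ref$lengths[[chrom]]))
  }
  substr(ref$seqs[[chrom]], pos0 + 1L, pos0 + 1L)
}

#' Reference subsequence (0-based, half-open)
#'
#' @param ref A `ref_genome`.
#' @param chrom Chromosome name.
#' @param start0,end0 Half-open 0-based interval.
#' @return Uppercase subsequence string.
#' @export
ref_subseq <- function(ref, chrom, start0, end0) {
  ref_check_chrom(ref, chrom)
  if (start0 < 0L || end0 > ref$lengths[[chrom]] || end0 < start0) {
    stop(sprintf("interval [%d,%d) outside %s (length %d)",
                 start0, end0, chrom, ref$lengths[[chrom]]))
  }
  substr(ref$seqs[[chrom]], start0 + 1L, end0)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome %d sequence(s), %s bases>\n",
              length(x$seqs), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Load capture regions from a BED file
#'
#' Reads 3+ column tab-separated BED; `track`, `browser` and `#` comment
#' lines are skipped. Regions are returned 0-based half-open, sorted by
#' (chromosome, start).
#'
#' @param path BED path.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
load_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("BED parse error at line %d: fewer than 3 columns", i))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("BED parse error at line %d: non-numeric coordinates", i))
    }
    if (end <= start) {
      stop(sprintf("BED parse error at line %d: end (%d) <= start (%d)",
                   i, end, start))
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1], start = start, end = end, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  bed <- do.call(rbind, out)
  bed[order(bed$chrom, bed$start), , drop = FALSE]
}
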