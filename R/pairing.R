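## Mate joining and position keys. A fragment key is the (chromosome,
## leftmost, rightmost) aligned coordinate triple of a read pair — the
## position-clustering key. Coordinates are 0-based; right_pos is the
## inclusive last aligned reference base.

#' Fragment key of a mapped read pair
#'
#' @param pair A `read_pair` with both mates mapped on one chromosome, or
#'   two `aligned_read`s via `read1`/`read2`.
#' @return A `fragment_key`: list with `chrom`, `left_pos`, `right_pos`,
#'   `chrom_idx`.
#' @examples
#' # mates 50M@100 and 50M@180 (0-based) give key (chr1, 100, 229)
#' @export
fragment_key <- function(pair) {
  r1 <- pair$read1
  r2 <- pair$read2
  stopifnot(identical(r1$chrom, r2$chrom))
  structure(
    list(chrom = r1$chrom,
         left_pos = min(r1$ref_start, r2$ref_start),
         right_pos = max(r1$ref_end, r2$ref_end) - 1L,
         chrom_idx = r1$chrom_idx),
    class = "fragment_key")
}

## total order consistent with BAM coordinate sort, encoded as one double
## (exact: chrom_idx and positions are both far below 2^26 and 2^31)
key_rank <- function(chrom_idx, pos) {
  as.numeric(chrom_idx) * 2^32 + as.numeric(pos)
}

#' @export
format.fragment_key <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, x$left_pos, x$right_pos)
}

#' @export
print.fragment_key <- function(x, ...) {
  cat(sprintf("<fragment_key %s>\n", format(x)))
  invisible(x)
}

#' Join two mates into a read pair
#'
#' @param read1,read2 The two primary alignments of one template (in either
#'   order; stored so that `read1` is the mate flagged as first-in-pair when
#'   that flag is usable, else the leftmost).
#' @return A `read_pair` with fields `read1`, `read2`, `key`, `umi`.
#' @export
read_pair <- function(read1, read2) {
  if (!identical(read1$qname, read2$qname)) {
    stop("mates must share a query name")
  }
  if (read1$is_read2 && read2$is_read1) {
    tmp <- read1; read1 <- read2; read2 <- tmp
  }
  umi <- read1$umi
  if (!identical(read1$umi, read2$umi)) {
    stop(sprintf("read '%s': mates disagree on UMI ('%s' vs '%s')",
                 read1$qname, read1$umi, read2$umi))
  }
  p <- list(read1 = read1, read2 = read2, umi = umi)
  p$key <- fragment_key(p)
  structure(p, class = "read_pair")
}

pairable <- function(r) {
  r$is_paired && !r$is_unmapped && !r$mate_unmapped &&
    !r$is_secondary && !r$is_supplementary &&
    (r$rnext == "=" || identical(r$rnext, r$chrom))
}

#' Join mates across a coordinate-sorted read stream
#'
#' Two primary mapped mates with equal name on the same chromosome become
#' one `read_pair`, emitted when the second mate arrives. Secondary,
#' supplementary and unmapped records, and orphans (mate unmapped, on
#' another chromosome, or never seen) pass through unchanged. Orphaned reads
#' are never merged into consensus.
#'
#' @param reads List of `aligned_read` in coordinate order.
#' @return List with `pairs` (read pairs in completion order),
#'   `passthrough` (records emitted unchanged, in input order) and
#'   `orphans` (count of paired reads whose mate never arrived).
#' @export
pair_reads <- function(reads) {
  st <- new_pair_state()
  pairs <- list()
  passthrough <- list()
  for (r in reads) {
    out <- pair_state_push(st, r)
    pairs <- c(pairs, out$pairs)
    passthrough <- c(passthrough, out$passthrough)
  }
  out <- pair_state_flush(st)
  list(pairs = pairs,
       passthrough = c(passthrough, out$passthrough),
       orphans = st$orphans)
}

## incremental mate-joining state machine used by pair_reads and the
## streaming pipeline; buffers first-seen mates per chromosome
new_pair_state <- function() {
  e <- new.env(parent = emptyenv())
  e$pending <- new.env(parent = emptyenv())  # qname -> aligned_read
  e$chrom <- NULL
  e$orphans <- 0L
  e
}

pair_state_push <- function(st, r) {
  pairs <- list()
  passthrough <- list()
  if (!is.null(st$chrom) && !identical(r$chrom, st$chrom)) {
    fl <- pair_state_flush(st)
    passthrough <- fl$passthrough
  }
  st$chrom <- r$chrom
  if (!pairable(r)) {
    # paired primary mapped reads that can never be joined (mate unmapped
    # or on another chromosome) are orphans; the rest is plain passthrough
    if (r$is_paired && !r$is_unmapped && !r$is_secondary &&
        !r$is_supplementary) {
      st$orphans <- st$orphans + 1L
    }
    passthrough <- c(passthrough, list(r))
  } else {
    mate <- st$pending[[r$qname]]
    if (is.null(mate)) {
      assign(r$qname, r, envir = st$pending)
    } else if (is.logical(mate)) {
      stop(sprintf("duplicate primary alignment for read '%s'", r$qname))
    } else {
      pairs <- list(read_pair(mate, r))
      assign(r$qname, TRUE, envir = st$pending)  # sentinel: pair closed
    }
  }
  list(pairs = pairs, passthrough = passthrough)
}

pair_state_flush <- function(st) {
  nm <- ls(st$pending)
  left <- lapply(nm, function(q) st$pending[[q]])
  left <- left[!vapply(left, is.logical, logical(1))]
  if (length(left)) {
    ord <- order(vapply(left, function(r) key_rank(r$chrom_idx, r$ref_start),
                        numeric(1)))
    left <- left[ord]
    st$orphans <- st$orphans + length(left)
  }
  rm(list = nm, envir = st$pending)
  list(passthrough = left)
}

## minimum position of any buffered first-seen mate (Inf when none); open
## pairs can only add records at or after this position
pair_state_min_pos <- function(st) {
  nm <- ls(st$pending)
  vals <- Inf
  for (q in nm) {
    r <- st$pending[[q]]
    if (!is.logical(r)) vals <- min(vals, key_rank(r$chrom_idx, r$ref_start))
  }
  vals
}
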