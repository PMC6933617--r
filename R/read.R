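## SAM/BAM record handling. Internal coordinates are 0-based; half-open for
## ranges. SAM text emission converts back to 1-based.

CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string such as `"5S45M"`, or `"*"`.
#' @return A list with integer vector `lens` and character vector `ops`
#'   (empty for `"*"`).
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(list(lens = integer(0), ops = character(0)))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop(sprintf("malformed CIGAR string: '%s'", cigar))
  }
  list(
    lens = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    ops = sub("^[0-9]+", "", toks)
  )
}

cigar_query_len <- function(cig) {
  sum(cig$lens[cig$ops %in% CIGAR_QUERY_OPS])
}

cigar_ref_len <- function(cig) {
  sum(cig$lens[cig$ops %in% CIGAR_REF_OPS])
}

#' Construct an aligned read
#'
#' One SAM record held in memory: sequence, qualities, parsed CIGAR, decoded
#' flags and the UMI (if any) recovered from the read name. Constructor
#' validates the SAM invariants: sequence and quality lengths agree and the
#' query-consuming CIGAR length equals the sequence length.
#'
#' @param qname Query (template) name.
#' @param flag Integer SAM flag.
#' @param chrom Reference name (`"*"` for unplaced unmapped reads).
#' @param ref_start 0-based leftmost aligned reference position (-1 for
#'   unplaced reads).
#' @param mapq Mapping quality 0-255.
#' @param cigar CIGAR string.
#' @param rnext,pnext,tlen Mate reference name (`"="` allowed), 0-based mate
#'   position, template length.
#' @param seq Read sequence over `A,C,G,T,N` (or `"*"`).
#' @param quals Integer vector of Phred qualities (0-93), one per base.
#' @param tags Character vector of raw SAM tag fields (kept verbatim).
#' @param umi UMI string recovered from the read name ("" for none).
#' @param chrom_idx Integer rank of `chrom` in the header (for ordering).
#' @return An object of class `aligned_read`.
#' @export
aligned_read <- function(qname, flag, chrom, ref_start, mapq, cigar,
                         rnext = "*", pnext = -1L, tlen = 0L,
                         seq = "*", quals = integer(0),
                         tags = character(0), umi = "", chrom_idx = NA_integer_) {
  flag <- as.integer(flag)
  cig <- parse_cigar(cigar)
  r <- list(
    qname = qname,
    flag = flag,
    chrom = chrom,
    ref_start = as.integer(ref_start),
    mapq = as.integer(mapq),
    cigar = cigar,
    cig = cig,
    rnext = rnext,
    pnext = as.integer(pnext),
    tlen = as.integer(tlen),
    seq = seq,
    quals = as.integer(quals),
    tags = tags,
    umi = umi,
    chrom_idx = as.integer(chrom_idx),
    is_paired = bitwAnd(flag, 1L) != 0L,
    is_unmapped = bitwAnd(flag, 4L) != 0L,
    mate_unmapped = bitwAnd(flag, 8L) != 0L,
    is_reverse = bitwAnd(flag, 16L) != 0L,
    is_read1 = bitwAnd(flag, 64L) != 0L,
    is_read2 = bitwAnd(flag, 128L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_supplementary = bitwAnd(flag, 2048L) != 0L
  )
  if (seq != "*") {
    if (nchar(seq) != length(quals)) {
      stop(sprintf("read '%s': sequence length %d != quality length %d",
                   qname, nchar(seq), length(quals)))
    }
    if (length(quals) && (min(quals) < 0L || max(quals) > 93L)) {
      stop(sprintf("read '%s': Phred qualities outside [0, 93]", qname))
    }
    qlen <- cigar_query_len(cig)
    if (length(cig$ops) && qlen != nchar(seq)) {
      stop(sprintf(
        "read '%s': CIGAR query length %d != sequence length %d",
        qname, qlen, nchar(seq)))
    }
  }
  r$ref_end <- if (r$is_unmapped) r$ref_start else r$ref_start + cigar_ref_len(cig)
  if (!r$is_unmapped && length(cig$ops) && r$ref_end <= r$ref_start) {
    stop(sprintf("read '%s': mapped read consumes no reference", qname))
  }
  structure(r, class = "aligned_read")
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read %s %s:%d %s flag=%d%s>\n",
              x$qname, x$chrom, x$ref_start, x$cigar, x$flag,
              if (nzchar(x$umi)) paste0(" UMI=", x$umi) else ""))
  invisible(x)
}

phred_from_string <- function(qual) {
  if (qual == "*") return(integer(0))
  utf8ToInt(qual) - 33L
}

phred_to_string <- function(quals) {
  if (length(quals) == 0L) return("*")
  intToUtf8(pmin(pmax(quals, 0L), 93L) + 33L)
}

parse_sam_line <- function(line, chrom_ranks, umi_delim = ":",
                           umi_prefix = "UMI_") {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) {
    stop(sprintf("SAM record with %d fields (11 required): %s",
                 length(f), substr(line, 1, 60)))
  }
  chrom <- f[3]
  r <- aligned_read(
    qname = f[1],
    flag = as.integer(f[2]),
    chrom = chrom,
    ref_start = as.integer(f[4]) - 1L,
    mapq = as.integer(f[5]),
    cigar = f[6],
    rnext = f[7],
    pnext = as.integer(f[8]) - 1L,
    tlen = as.integer(f[9]),
    seq = f[10],
    quals = phred_from_string(f[11]),
    tags = if (length(f) > 11L) f[12:length(f)] else character(0),
    umi = extract_umi(f[1], delimiter = umi_delim, prefix = umi_prefix),
    chrom_idx = if (chrom == "*") NA_integer_ else chrom_ranks[[chrom]]
  )
  r$line <- line  # verbatim for byte-equivalent passthrough
  r
}

#' Serialize an aligned read to one SAM text line
#'
#' Passthrough records retain their original line byte-for-byte; records
#' built in memory are formatted from fields (positions converted to
#' 1-based).
#'
#' @param read An `aligned_read`.
#' @param verbatim Use the stored input line if present (default TRUE).
#' @return A single character string without trailing newline.
#' @export
sam_line <- function(read, verbatim = TRUE) {
  if (verbatim && !is.null(read$line)) return(read$line)
  paste(c(read$qname, read$flag, read$chrom, read$ref_start + 1L,
          read$mapq, read$cigar, read$rnext, read$pnext + 1L, read$tlen,
          read$seq, phred_to_string(read$quals), read$tags),
        collapse = "\t")
}

parse_sam_header <- function(lines) {
  hd <- grep("^@HD", lines, value = TRUE)
  sort_order <- "unknown"
  if (length(hd)) {
    so <- regmatches(hd[1], regexpr("SO:[^\t]+", hd[1]))
    if (length(so)) sort_order <- sub("^SO:", "", so)
  }
  sq <- grep("^@SQ", lines, value = TRUE)
  chroms <- integer(0)
  if (length(sq)) {
    sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
    ln <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
    chroms <- stats::setNames(ln, sn)
  }
  list(chroms = chroms, sort_order = sort_order, text = lines)
}

#' Open a coordinate-sorted SAM/BAM alignment file
#'
#' Reads the whole file into memory as `aligned_read` records, in file
#' order. BAM input is converted through `Rsamtools::asSam()`; SAM text is
#' parsed directly. The header must declare `SO:coordinate` and records must
#' be coordinate-sorted; violations are fatal.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param umi_delim Character separating the UMI from the rest of the read
#'   name (default `":"`).
#' @param umi_prefix Optional prefix stripped from the UMI (default
#'   `"UMI_"`).
#' @return A list with `header` (list: `chroms` named integer vector of
#'   lengths, `sort_order`, `text`) and `reads` (list of `aligned_read`).
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000",
#'   paste("r1", 0, "chr1", 101, 60, "4M", "*", 0, 0, "ACGT", "IIII",
#'         sep = "\t")), sam)
#' aln <- read_alignments(sam)
#' aln$header$chroms
#' @export
read_alignments <- function(path, umi_delim = ":", umi_prefix = "UMI_") {
  if (!file.exists(path)) {
    stop(sprintf("alignment file not found: %s", path))
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam), add = TRUE)
    Rsamtools::asSam(path, sub("\\.sam$", "", sam), overwrite = TRUE)
    path <- sam
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  header <- parse_sam_header(lines[is_header])
  if (!identical(header$sort_order, "coordinate")) {
    stop(sprintf(
      "input must be coordinate-sorted (header SO tag is '%s', 'coordinate' required)",
      header$sort_order))
  }
  body <- lines[!is_header]
  ranks <- as.list(seq_along(header$chroms))
  names(ranks) <- names(header$chroms)
  reads <- vector("list", length(body))
  last_idx <- -Inf
  last_pos <- -Inf
  for (i in seq_along(body)) {
    r <- parse_sam_line(body[i], ranks, umi_delim, umi_prefix)
    if (!r$is_unmapped && !is.na(r$chrom_idx)) {
      if (r$chrom_idx < last_idx ||
          (r$chrom_idx == last_idx && r$ref_start < last_pos)) {
        stop(sprintf(
          "unsorted input: record '%s' at %s:%d follows position %d",
          r$qname, r$chrom, r$ref_start + 1L, as.integer(last_pos) + 1L))
      }
      last_idx <- r$chrom_idx
      last_pos <- r$ref_start
    }
    reads[[i]] <- r
  }
  list(header = header, reads = reads)
}

## map of aligned query positions (1-based qpos) to reference positions
## (0-based rpos) over M/=/X ops only
aligned_query_map <- function(read) {
  ops <- read$cig$ops
  lens <- read$cig$lens
  qpos <- integer(0)
  rpos <- integer(0)
  q <- 1L
  r <- read$ref_start
  for (i in seq_along(ops)) {
    op <- ops[i]
    len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, q:(q + len - 1L))
      rpos <- c(rpos, r:(r + len - 1L))
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  list(qpos = qpos, rpos = rpos)
}
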