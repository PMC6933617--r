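## Pre/post run statistics: read and base counters, reference-mismatch
## counts, coverage bins, BED region depths, duplication histogram.

#' Create a run-statistics accumulator
#'
#' @param chroms Named integer vector of chromosome lengths (from
#'   `read_alignments()$header$chroms`).
#' @param bin_width Width of genome-scale coverage bins in bases
#'   (default 10000).
#' @param bed Optional data.frame of capture regions from [load_bed()].
#' @return A `run_stats` environment updated in place by
#'   [accumulate_read()] and [record_cluster()].
#' @export
run_stats <- function(chroms, bin_width = 10000L, bed = NULL) {
  e <- new.env(parent = emptyenv())
  e$chroms <- chroms
  e$bin_width <- as.integer(bin_width)
  e$bed <- bed
  for (phase in c("pre", "post")) {
    p <- new.env(parent = emptyenv())
    p$total_reads <- 0
    p$mapped_reads <- 0
    p$total_bases <- 0
    p$aligned_bases <- 0
    p$mismatched_bases <- 0
    p$coverage <- lapply(chroms, function(len) {
      integer(max(1L, ceiling(len / bin_width)))
    })
    p$bed_bases <- if (!is.null(bed)) numeric(nrow(bed)) else numeric(0)
    e[[phase]] <- p
  }
  e$histogram <- integer(0)      # names: cluster size
  e$clusters_total <- 0
  e$clusters_passing <- 0
  e$pairs_pre <- 0
  e$orphans <- 0
  e$excluded_members <- 0
  structure(e, class = "run_stats")
}

#' Accumulate one read into the statistics
#'
#' Counts reads and bases; for mapped reads, compares every M/=/X-aligned
#' base against the reference to count mismatches, and adds aligned bases
#' into the genome-scale coverage bins and any overlapping BED region.
#'
#' @param stats A [run_stats()] accumulator.
#' @param read An `aligned_read`.
#' @param ref A `ref_genome` (may be `NULL` to skip mismatch counting).
#' @param phase `"pre"` (input) or `"post"` (output).
#' @return The accumulator, invisibly.
#' @export
accumulate_read <- function(stats, read, ref, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  p <- stats[[phase]]
  p$total_reads <- p$total_reads + 1
  nb <- if (read$seq == "*") 0L else nchar(read$seq)
  p$total_bases <- p$total_bases + nb
  if (read$is_unmapped || is.na(read$chrom_idx)) return(invisible(stats))
  p$mapped_reads <- p$mapped_reads + 1
  bw <- stats$bin_width
  cov <- p$coverage[[read$chrom]]
  bed <- stats$bed
  q <- 1L
  r <- read$ref_start
  for (i in seq_along(read$cig$ops)) {
    op <- read$cig$ops[i]
    len <- read$cig$lens[i]
    if (op %in% c("M", "=", "X")) {
      p$aligned_bases <- p$aligned_bases + len
      if (!is.null(ref)) {
        seg <- strsplit(substring(read$seq, q, q + len - 1L), "")[[1]]
        refseg <- strsplit(ref_subseq(ref, read$chrom, r, r + len), "")[[1]]
        p$mismatched_bases <- p$mismatched_bases + sum(seg != refseg)
      }
      pos <- r:(r + len - 1L)
      bins <- pmin(pos %/% bw + 1L, length(cov))
      tab <- table(bins)
      cov[as.integer(names(tab))] <- cov[as.integer(names(tab))] +
        as.integer(tab)
      if (!is.null(bed) && nrow(bed)) {
        on_chrom <- which(bed$chrom == read$chrom)
        for (j in on_chrom) {
          ov <- min(bed$end[j], r + len) - max(bed$start[j], r)
          if (ov > 0) p$bed_bases[j] <- p$bed_bases[j] + ov
        }
      }
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  p$coverage[[read$chrom]] <- cov
  invisible(stats)
}

#' Record one position/UMI cluster
#'
#' @param stats A [run_stats()] accumulator.
#' @param cluster_size Number of read pairs in the cluster (>= 1).
#' @param passed Did the cluster pass the supporting-reads filter?
#' @return The accumulator, invisibly.
#' @export
record_cluster <- function(stats, cluster_size, passed) {
  stopifnot(cluster_size >= 1)
  key <- as.character(cluster_size)
  cur <- stats$histogram[key]
  stats$histogram[key] <- if (is.na(cur)) 1L else cur + 1L
  stats$clusters_total <- stats$clusters_total + 1
  stats$clusters_passing <- stats$clusters_passing + as.integer(passed)
  invisible(stats)
}

rate_or_null <- function(num, den) {
  if (is.null(den) || den == 0) NULL else num / den
}

phase_summary <- function(p, genome_len, bed) {
  out <- list(
    total_reads = p$total_reads,
    mapped_reads = p$mapped_reads,
    total_bases = p$total_bases,
    aligned_bases = p$aligned_bases,
    mismatched_bases = p$mismatched_bases,
    mismatch_rate = rate_or_null(p$mismatched_bases, p$aligned_bases),
    mean_depth = rate_or_null(p$aligned_bases, genome_len)
  )
  out
}

#' Finalize statistics into the report model
#'
#' @param stats A [run_stats()] accumulator after the run.
#' @param options Optional named list of run options echoed into the
#'   report.
#' @return The report model: a named list with `summary`,
#'   `pre_filtering`, `post_filtering`, `duplication_histogram`,
#'   `coverage`, optional `bed_regions`, `options` and `version`,
#'   ready for [write_json_report()] / [write_html_report()]. Undefined
#'   rates are `NULL` (serialized as JSON null), never `NaN`.
#' @export
finalize_stats <- function(stats, options = list()) {
  genome_len <- sum(as.numeric(stats$chroms))
  pre <- phase_summary(stats$pre, genome_len, stats$bed)
  post <- phase_summary(stats$post, genome_len, stats$bed)
  hist_sizes <- sort(as.integer(names(stats$histogram)))
  histogram <- as.list(stats$histogram[as.character(hist_sizes)])
  names(histogram) <- as.character(hist_sizes)
  mapping_rate <- if (stats$pre$total_reads == 0) 0 else
    stats$pre$mapped_reads / stats$pre$total_reads
  model <- list(
    summary = list(
      mapping_rate = mapping_rate,
      duplication_rate = if (stats$pairs_pre == 0) NULL else
        1 - stats$clusters_total / stats$pairs_pre,
      passing_filter_rate = rate_or_null(stats$clusters_passing,
                                         stats$clusters_total),
      read_pairs_in = stats$pairs_pre,
      clusters_total = stats$clusters_total,
      clusters_passing = stats$clusters_passing,
      orphan_reads = stats$orphans,
      cigar_excluded_members = stats$excluded_members
    ),
    pre_filtering = pre,
    post_filtering = post,
    duplication_histogram = histogram,
    coverage = list(
      bin_width = stats$bin_width,
      chromosomes = lapply(names(stats$chroms), function(ch) {
        list(name = ch, length = stats$chroms[[ch]],
             pre = as.integer(stats$pre$coverage[[ch]]),
             post = as.integer(stats$post$coverage[[ch]]))
      })
    ),
    options = options,
    version = as.character(utils::packageVersion("consensr"))
  )
  if (!is.null(stats$bed) && nrow(stats$bed)) {
    model$bed_regions <- lapply(seq_len(nrow(stats$bed)), function(j) {
      w <- stats$bed$end[j] - stats$bed$start[j]
      list(chrom = stats$bed$chrom[j],
           start = stats$bed$start[j],
           end = stats$bed$end[j],
           mean_depth_pre = stats$pre$bed_bases[j] / w,
           mean_depth_post = stats$post$bed_bases[j] / w)
    })
  }
  model
}
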