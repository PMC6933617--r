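## Single-pass pipeline: stream records once, join mates, release position
## groups as soon as no member can still arrive, cluster by UMI, filter,
## build consensus pairs, and drain everything through the watermarked
## sorted writer. No temporary files and no re-sort.

#' Run the consensus pipeline
#'
#' Reads a coordinate-sorted SAM/BAM, clusters read pairs by mapping
#' position and (when present in read names) UMI, filters clusters by
#' supporting-read count, merges each passing cluster into one
#' error-suppressed consensus read pair using the reference genome, and
#' writes a coordinate-sorted output plus optional JSON/HTML reports.
#' Unmapped, secondary, supplementary and orphaned records pass through
#' unchanged.
#'
#' @param input Coordinate-sorted SAM/BAM path.
#' @param output Output SAM path (`.bam` to emit sorted, indexed BAM).
#' @param reference Reference FASTA path, or a `ref_genome` object.
#' @param bed Optional BED path of capture regions.
#' @param json,html Optional report output paths.
#' @param schema A [scoring_schema()].
#' @param umi_delim,umi_prefix Read-name UMI conventions (defaults `":"`,
#'   `"UMI_"`).
#' @param coverage_bin Genome-scale coverage bin width (default 10000).
#' @param verbose Log counts to stderr (default TRUE).
#' @return Invisibly, a list with `report` (the model from
#'   [finalize_stats()]) and `counts` (pairs in, clusters, passing,
#'   consensus pairs out, passthrough records, orphans).
#' @export
run_consensus <- function(input, output, reference, bed = NULL,
                          json = NULL, html = NULL,
                          schema = scoring_schema(),
                          umi_delim = ":", umi_prefix = "UMI_",
                          coverage_bin = 10000L, verbose = TRUE) {
  ref <- if (inherits(reference, "ref_genome")) reference
         else load_reference(reference)
  aln <- read_alignments(input, umi_delim = umi_delim,
                         umi_prefix = umi_prefix)
  missing_chroms <- setdiff(names(aln$header$chroms), names(ref$seqs))
  if (length(missing_chroms)) {
    stop(sprintf(
      "chromosome(s) present in the alignment header but absent from the reference FASTA: %s",
      paste(missing_chroms, collapse = ", ")))
  }
  bed_regions <- if (!is.null(bed)) load_bed(bed) else NULL
  stats <- run_stats(aln$header$chroms, bin_width = coverage_bin,
                     bed = bed_regions)

  out_is_bam <- grepl("\\.bam$", output, ignore.case = TRUE)
  sam_out <- if (out_is_bam) tempfile(fileext = ".sam") else output
  header_out <- c(aln$header$text,
                  sprintf("@PG\tID:consensr\tPN:consensr\tVN:%s",
                          utils::packageVersion("consensr")))
  writer <- new_sorted_writer(sam_out, header_out)
  pair_st <- new_pair_state()
  group_st <- new_group_state()
  counts <- list(pairs_in = 0L, clusters = 0L, passing = 0L,
                 consensus_out = 0L, passthrough = 0L, orphans = 0L)

  emit_passthrough <- function(r) {
    counts$passthrough <<- counts$passthrough + 1L
    accumulate_read(stats, r, ref, "post")
    writer_insert(writer, r$chrom_idx, r$ref_start, sam_line(r))
  }
  process_group <- function(group) {
    clusters <- cluster_by_umi(group$pairs, schema)
    for (cl in clusters) {
      ok <- passes_filter(cl, schema)
      record_cluster(stats, length(cl$members), ok)
      counts$clusters <<- counts$clusters + 1L
      if (!ok) next
      counts$passing <<- counts$passing + 1L
      cons <- build_consensus_pair(cl, ref, schema)
      stats$excluded_members <- stats$excluded_members + cons$n_excluded
      for (mate in c("read1", "read2")) {
        cr <- cons[[mate]]
        accumulate_read(stats, cr, ref, "post")
        writer_insert(writer, cr$chrom_idx, cr$ref_start,
                      sam_line(cr, verbatim = FALSE))
      }
      counts$consensus_out <<- counts$consensus_out + 1L
    }
  }

  for (r in aln$reads) {
    accumulate_read(stats, r, ref, "pre")
    step <- pair_state_push(pair_st, r)
    for (pt in step$passthrough) emit_passthrough(pt)
    for (p in step$pairs) {
      counts$pairs_in <- counts$pairs_in + 1L
      stats$pairs_pre <- stats$pairs_pre + 1L
      done <- group_state_push(group_st, p)
      for (g in done) process_group(g)
    }
    watermark <- min(group_state_min_left(group_st),
                     pair_state_min_pos(pair_st))
    writer_advance(writer, watermark)
  }
  fl <- pair_state_flush(pair_st)
  for (pt in fl$passthrough) emit_passthrough(pt)
  counts$orphans <- pair_st$orphans
  stats$orphans <- pair_st$orphans
  for (g in group_state_flush(group_st)) process_group(g)
  writer_close(writer)
  if (out_is_bam) {
    Rsamtools::asBam(sam_out, sub("\\.bam$", "", output),
                     overwrite = TRUE, indexDestination = TRUE)
    unlink(sam_out)
  }

  opts <- list(
    input = input, output = output,
    initial_score = schema$initial_score,
    agree_bonus = schema$agree_bonus,
    disagree_keep = schema$disagree_keep,
    disagree_drop = schema$disagree_drop,
    high_qual = schema$high_qual,
    moderate_qual = schema$moderate_qual,
    dominant_fraction = schema$dominant_fraction,
    min_supporting_reads = schema$min_supporting_reads,
    umi_tolerance = schema$umi_tolerance,
    coverage_bin = as.integer(coverage_bin))
  model <- finalize_stats(stats, options = opts)
  if (!is.null(json)) write_json_report(model, json)
  if (!is.null(html)) write_html_report(model, html)
  if (verbose) {
    message(sprintf(
      "consensr: %d pairs in, %d clusters (%d passing), %d consensus pairs out, %d passthrough records, %d orphans",
      counts$pairs_in, counts$clusters, counts$passing,
      counts$consensus_out, counts$passthrough, counts$orphans))
    if (counts$passing == 0L && counts$pairs_in > 0L) {
      message("consensr: warning: no cluster passed the supporting-reads filter; output contains no consensus reads")
    }
  }
  invisible(list(report = model, counts = counts))
}
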