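#' Scoring schema for consensus generation
#'
#' Bundles every tunable parameter of the clustering / scoring / consensus
#' pipeline. Each base of a read pair starts with `initial_score`; where the
#' two mates of a pair overlap on the reference, agreement raises both bases
#' to `agree_bonus`, while disagreement lets the higher-quality base keep
#' `disagree_keep` and drops the other to `disagree_drop`. Per-cluster summed
#' scores then drive consensus calling: a base owning at least
#' `dominant_fraction` of a column's total score is called outright;
#' otherwise the reference base is used when some read matches it at Phred >=
#' `high_qual` or when every covering base is below `moderate_qual`.
#'
#' @param initial_score Integer score initially assigned to every base
#'   (default 6).
#' @param agree_bonus Score both mates receive where overlapped bases agree
#'   (default 8).
#' @param disagree_keep Score kept by the higher-quality base on overlap
#'   disagreement (default 3).
#' @param disagree_drop Score given to the losing base on disagreement, and
#'   to both bases on a quality tie (default 0).
#' @param high_qual Phred threshold above which a reference-concordant base
#'   triggers reference fallback (default 30).
#' @param moderate_qual Phred threshold under which a column counts as
#'   all-low-quality; also the quality assigned to reference-fallback calls
#'   (default 15).
#' @param dominant_fraction Fraction of a column's total score the top base
#'   must reach to be called dominant; must exceed 0.5 (default 0.8).
#' @param min_supporting_reads Minimum read pairs a cluster needs to emit a
#'   consensus read (default 1, i.e. no filtering; 2 is recommended for
#'   ultra-deep data so that singleton fragments without PCR duplicates are
#'   discarded).
#' @param umi_tolerance Maximum per-UMI mismatch count for two UMIs to join
#'   one cluster (default 1).
#'
#' @return An object of class `scoring_schema` (a named list).
#' @examples
#' scoring_schema()
#' scoring_schema(min_supporting_reads = 2)
#' @export
scoring_schema <- function(initial_score = 6L,
                           agree_bonus = 8L,
                           disagree_keep = 3L,
                           disagree_drop = 0L,
                           high_qual = 30L,
                           moderate_qual = 15L,
                           dominant_fraction = 0.8,
                           min_supporting_reads = 1L,
                           umi_tolerance = 1L) {
  s <- list(
    initial_score = as.integer(initial_score),
    agree_bonus = as.integer(agree_bonus),
    disagree_keep = as.integer(disagree_keep),
    disagree_drop = as.integer(disagree_drop),
    high_qual = as.integer(high_qual),
    moderate_qual = as.integer(moderate_qual),
    dominant_fraction = as.numeric(dominant_fraction),
    min_supporting_reads = as.integer(min_supporting_reads),
    umi_tolerance = as.integer(umi_tolerance)
  )
  if (s$initial_score <= 0L) stop("initial_score must be > 0")
  if (s$high_qual < s$moderate_qual) {
    stop("high_qual must be >= moderate_qual")
  }
  if (!(s$dominant_fraction > 0.5 && s$dominant_fraction <= 1)) {
    stop("dominant_fraction must be in (0.5, 1]")
  }
  if (s$min_supporting_reads < 1L) stop("min_supporting_reads must be >= 1")
  if (s$umi_tolerance < 0L) stop("umi_tolerance must be >= 0")
  structure(s, class = "scoring_schema")
}

#' @export
print.scoring_schema <- function(x, ...) {
  cat("Consensus scoring schema\n")
  cat(sprintf("  initial score        : %d\n", x$initial_score))
  cat(sprintf("  agree bonus          : %d\n", x$agree_bonus))
  cat(sprintf("  disagree keep / drop : %d / %d\n",
              x$disagree_keep, x$disagree_drop))
  cat(sprintf("  high / moderate qual : Q%d / Q%d\n",
              x$high_qual, x$moderate_qual))
  cat(sprintf("  dominant fraction    : %g\n", x$dominant_fraction))
  cat(sprintf("  min supporting reads : %d\n", x$min_supporting_reads))
  cat(sprintf("  UMI tolerance        : %d\n", x$umi_tolerance))
  invisible(x)
}
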