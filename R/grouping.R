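## Processing-while-reading: position groups are released as soon as no
## further member can arrive, and finished records drain through a
## position-sorted output queue gated by a watermark, so the output stays
## coordinate-sorted without a second sort pass.

#' Create an empty position-group state
#'
#' Holds the open `[chrom]:[left_pos]:[right_pos]` groups of read pairs
#' still awaiting possible members.
#'
#' @return A group-state environment for [group_state_push()] /
#'   [group_state_flush()].
#' @export
new_group_state <- function() {
  e <- new.env(parent = emptyenv())
  e$groups <- list()   # id -> list(key, pairs)
  e
}

group_id <- function(key) {
  sprintf("%09d:%012d:%012d", key$chrom_idx, key$left_pos, key$right_pos)
}

#' Add a read pair; release groups that can no longer grow
#'
#' Because pairs complete in coordinate order of their left positions, any
#' open group whose chromosome precedes the incoming pair's, or whose
#' `right_pos` is smaller than the incoming `left_pos`, can never gain
#' another member and is released for consensus processing.
#'
#' @param state A group state from [new_group_state()].
#' @param pair Incoming `read_pair` (pairs must arrive ordered by
#'   (chromosome, left position)).
#' @return List of completed groups, each a list with `key` and `pairs`,
#'   in coordinate order.
#' @export
group_state_push <- function(state, pair) {
  done <- release_groups(state, pair$key$chrom_idx, pair$key$left_pos)
  id <- group_id(pair$key)
  g <- state$groups[[id]]
  if (is.null(g)) {
    state$groups[[id]] <- list(key = pair$key, pairs = list(pair))
  } else {
    g$pairs <- c(g$pairs, list(pair))
    state$groups[[id]] <- g
  }
  done
}

release_groups <- function(state, chrom_idx, left_pos) {
  if (length(state$groups) == 0L) return(list())
  keys <- lapply(state$groups, `[[`, "key")
  complete <- vapply(keys, function(k) {
    k$chrom_idx < chrom_idx ||
      (k$chrom_idx == chrom_idx && k$right_pos < left_pos)
  }, logical(1))
  if (!any(complete)) return(list())
  ids <- names(state$groups)[complete]
  ids <- ids[order(ids)]  # group ids sort in coordinate order
  done <- state$groups[ids]
  state$groups[ids] <- NULL
  unname(done)
}

#' Release all remaining groups (end of stream)
#'
#' @param state A group state.
#' @return All open groups in coordinate order; the state becomes empty.
#' @export
group_state_flush <- function(state) {
  if (length(state$groups) == 0L) return(list())
  done <- state$groups[order(names(state$groups))]
  state$groups <- list()
  unname(done)
}

## minimum left position over open groups as a key_rank (Inf when none)
group_state_min_left <- function(state) {
  if (length(state$groups) == 0L) return(Inf)
  min(vapply(state$groups, function(g) {
    key_rank(g$key$chrom_idx, g$key$left_pos)
  }, numeric(1)))
}

#' Create a position-sorted output writer
#'
#' Buffers SAM lines keyed by position and writes them once the watermark —
#' the least position any still-unfinished record could take — has moved
#' past them. Unplaced unmapped records are appended after all placed ones.
#'
#' @param path Output SAM path, or `NULL` to collect lines in memory.
#' @param header_lines Character vector of header lines written first.
#' @return A writer environment for [writer_insert()], [writer_advance()]
#'   and [writer_close()].
#' @export
new_sorted_writer <- function(path = NULL, header_lines = character(0)) {
  e <- new.env(parent = emptyenv())
  e$path <- path
  e$con <- NULL
  e$lines <- character(0)
  e$queue_rank <- numeric(0)
  e$queue_serial <- numeric(0)
  e$queue_lines <- character(0)
  e$serial <- 0
  e$last_written <- -Inf
  e$unmapped <- character(0)
  if (!is.null(path)) {
    e$con <- file(path, open = "wt")
  }
  if (length(header_lines)) writer_emit(e, header_lines)
  e
}

writer_emit <- function(w, lines) {
  if (length(lines) == 0L) return(invisible())
  if (is.null(w$con)) {
    w$lines <- c(w$lines, lines)
  } else {
    writeLines(lines, w$con)
  }
  invisible()
}

#' Queue one record for sorted output
#'
#' @param writer A writer from [new_sorted_writer()].
#' @param chrom_idx Chromosome rank in the header (NA for unplaced
#'   unmapped records, which are appended at the end of the file).
#' @param pos 0-based position of the record.
#' @param line Serialized SAM line.
#' @return The writer, invisibly. Inserting below the last written position
#'   is a fatal internal-ordering error.
#' @export
writer_insert <- function(writer, chrom_idx, pos, line) {
  if (is.na(chrom_idx)) {
    writer$unmapped <- c(writer$unmapped, line)
    return(invisible(writer))
  }
  rank <- key_rank(chrom_idx, pos)
  if (rank < writer$last_written) {
    stop(sprintf(
      "internal ordering error: record at rank %.0f inserted after rank %.0f was written",
      rank, writer$last_written))
  }
  writer$serial <- writer$serial + 1
  writer$queue_rank <- c(writer$queue_rank, rank)
  writer$queue_serial <- c(writer$queue_serial, writer$serial)
  writer$queue_lines <- c(writer$queue_lines, line)
  invisible(writer)
}

#' Write all queued records below a watermark
#'
#' @param writer A writer.
#' @param watermark_rank Numeric rank (see `key_rank`); every queued record
#'   with rank strictly below it is flushed in (rank, insertion) order.
#'   `Inf` drains the whole queue.
#' @return The writer, invisibly.
#' @export
writer_advance <- function(writer, watermark_rank) {
  if (length(writer$queue_rank) == 0L) return(invisible(writer))
  ready <- writer$queue_rank < watermark_rank
  if (any(ready)) {
    ord <- order(writer$queue_rank[ready], writer$queue_serial[ready])
    lines <- writer$queue_lines[ready][ord]
    writer_emit(writer, lines)
    writer$last_written <- max(writer$queue_rank[ready])
    writer$queue_rank <- writer$queue_rank[!ready]
    writer$queue_serial <- writer$queue_serial[!ready]
    writer$queue_lines <- writer$queue_lines[!ready]
  }
  invisible(writer)
}

#' Drain the queue and close the output
#'
#' @param writer A writer.
#' @return Character vector of all lines when the writer collects in
#'   memory, else `NULL` (file written and closed), invisibly.
#' @export
writer_close <- function(writer) {
  writer_advance(writer, Inf)
  writer_emit(writer, writer$unmapped)
  writer$unmapped <- character(0)
  if (!is.null(writer$con)) {
    close(writer$con)
    writer$con <- NULL
    invisible(NULL)
  } else {
    invisible(writer$lines)
  }
}
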