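#' Score every database sequence against a query
#'
#' Streams each set's interlaced codes through the compiled lane engine:
#' the `lanes` lanes of a set advance in lock-step over consecutive
#' `subset_length` windows, exactly as a half-warp consumes the layout, and
#' each lane keeps only a single H column, a D column, a running E value
#' and the upper-left H carry. Terminators emit the finished sequence's
#' maximum score and reset the lane; PAD codes are inert. Scores are
#' independent of the `lanes`/`subset_length` configuration and of where a
#' sequence was placed, and equal the full-matrix [sw_score_oracle()].
#'
#' @param db a [pack_database()] or [read_packed()] result.
#' @param query query as residue string or encoded vector.
#' @param scheme a [scoring_scheme()].
#' @return data frame of hits in original database order: `seq_id`,
#'   `score`, `saturated`, `db_order`, plus the record description columns
#'   when available.
#' @export
search_packed <- function(db, query, scheme) {
  stopifnot(inherits(db, "packed_db"))
  if (db$alphabet_size != 23L) {
    stop(swlane_error("domain", sprintf(
      "database alphabet size %d does not match the engine's 23-letter alphabet",
      db$alphabet_size)))
  }
  profile <- build_query_profile(query, scheme)
  idx <- db$index
  out_score <- integer(nrow(idx))
  out_sat <- logical(nrow(idx))
  for (s in seq_along(db$sets)) {
    rows <- which(idx$set == s)
    rows <- rows[order(idx$lane[rows], idx$offset[rows])]
    counts <- tabulate(idx$lane[rows], nbins = db$lanes)
    res <- cpp_scan_set(db$sets[[s]], db$lanes, db$subset_length,
                        profile$table, open_cost(scheme),
                        scheme$gap_extend, counts)
    # emitted per lane in stream order; map back through the sorted rows
    out_score[rows] <- res$scores
    out_sat[rows] <- res$saturated
  }
  data.frame(seq_id = idx$seq_id, score = out_score, saturated = out_sat,
             db_order = idx$db_order,
             stringsAsFactors = FALSE)[order(idx$db_order), , drop = FALSE] ->
    hits
  rownames(hits) <- NULL
  hits
}

#' Select the top-scoring hits
#'
#' Highest scores first; ties are broken by database rank ascending (the
#' sequence's position in the original input). Twenty hits by default;
#' asking for more than the database holds returns everything.
#'
#' @param hits data frame from [search_packed()].
#' @param n number of hits to keep (default 20).
#' @return the selected rows, in rank order, with a `rank` column prepended.
#' @export
top_hits <- function(hits, n = 20L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) {
    stop(swlane_error("usage", "n must be a non-negative count"))
  }
  ord <- order(-hits$score, hits$db_order)
  sel <- hits[utils::head(ord, n), , drop = FALSE]
  if (nrow(sel)) sel <- cbind(rank = seq_len(nrow(sel)), sel)
  else sel <- cbind(rank = integer(0), sel)
  rownames(sel) <- NULL
  sel
}

#' Export top hits as a FASTA database
#'
#' Writes the selected sequences, in hit order, to a new FASTA file whose
#' headers carry the id, the original description and the score. The file
#' is meant for downstream full (traceback) alignment with a conventional
#' local-alignment tool, which the score-only engine deliberately skips.
#'
#' @param hits ranked hits from [top_hits()].
#' @param records the record store the database was packed from.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_top_fasta <- function(hits, records, path) {
  records <- as_records(records)
  if (nrow(hits) == 0L) {
    write_fasta(records[integer(0), , drop = FALSE], path)
    return(invisible(path))
  }
  pos <- hits$db_order
  if (is.null(pos) || anyNA(pos) || any(pos < 1L | pos > nrow(records)) ||
      !identical(records$id[pos], hits$seq_id)) {
    stop(swlane_error("consistency",
                      "hit ids do not resolve to the supplied record store"))
  }
  out <- records[pos, , drop = FALSE]
  out$description <- trimws(paste(out$description,
                                  sprintf("score=%d", hits$score)))
  write_fasta(out, path)
}

#' Write / read a hit report TSV
#'
#' @param hits ranked hits from [top_hits()].
#' @param records record store supplying descriptions.
#' @param path output TSV path (columns `rank`, `seq_id`, `score`,
#'   `description`).
#' @return `write_hits_tsv()` returns `path` invisibly; `read_hits_tsv()`
#'   the parsed report.
#' @export
write_hits_tsv <- function(hits, records, path) {
  records <- as_records(records)
  df <- data.frame(rank = hits$rank, seq_id = hits$seq_id,
                   score = hits$score,
                   description = records$description[hits$db_order],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = c("integer", "character", "integer",
                                   "character"),
                    stringsAsFactors = FALSE)
}
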