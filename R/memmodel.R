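ALLOWED_TRANSACTIONS <- c(32L, 64L, 128L)

#' Model memory transactions for a half-warp access
#'
#' A group of `threads` lock-step lanes each accesses `payload_bytes`. When
#' the values sit at scattered addresses, every lane issues its own
#' transaction of the smallest supported size (32 bytes) that covers its
#' payload. When the addresses are contiguous, the device covers the whole
#' `threads * payload_bytes` block with the minimal set of 32/64/128-byte
#' transactions.
#'
#' @param payload_bytes bytes of useful data per thread (2, 4 or 8).
#' @param pattern `"scattered"` or `"contiguous"`.
#' @param threads lanes per half-warp (default 16).
#' @return list with `transactions` (vector of transaction sizes in bytes),
#'   `count`, `bytes` (their total), `payload` (useful bytes) and
#'   `wasted_bytes`.
#' @examples
#' transaction_size(4, "scattered", 16)   # 16 x 32-byte accesses
#' transaction_size(4, "contiguous", 16)  # one 64-byte load
#' transaction_size(8, "contiguous", 16)  # one 128-byte load
#' @export
transaction_size <- function(payload_bytes, pattern = c("scattered",
                                                        "contiguous"),
                             threads = 16L) {
  pattern <- match.arg(pattern)
  payload_bytes <- as.integer(payload_bytes)
  threads <- as.integer(threads)
  if (payload_bytes > 128L) {
    stop(swlane_error("usage", "payloads above 128 bytes are unsupported"))
  }
  if (payload_bytes < 1L || threads < 1L) {
    stop(swlane_error("usage", "payload_bytes and threads must be >= 1"))
  }
  if (pattern == "scattered") {
    size <- ALLOWED_TRANSACTIONS[ALLOWED_TRANSACTIONS >= payload_bytes][1L]
    tx <- rep(size, threads)
  } else {
    total <- payload_bytes * threads
    tx <- integer(0)
    remaining <- as.integer(ceiling(total / 32L) * 32L)
    for (size in rev(ALLOWED_TRANSACTIONS)) {
      tx <- c(tx, rep(size, remaining %/% size))
      remaining <- remaining %% size
    }
  }
  payload <- payload_bytes * threads
  list(transactions = tx, count = length(tx), bytes = sum(tx),
       payload = payload, wasted_bytes = sum(tx) - payload)
}

#' Bandwidth wasted by uncoalesced half-warp accesses
#'
#' Each of `threads` lanes fetching a scattered `payload_bytes` value pays
#' for a full minimum-size transaction; the waste is
#' `(transaction - payload) * threads`. Sixteen scattered 4-byte accesses
#' waste `(32 - 4) * 16 = 448` bytes.
#'
#' @inheritParams transaction_size
#' @return wasted bytes (integer).
#' @export
coalescing_waste <- function(payload_bytes, threads = 16L) {
  transaction_size(payload_bytes, "scattered", threads)$wasted_bytes
}

#' The temporary-data bandwidth optimization ladder
#'
#' Every inner-loop iteration of the streaming engine reads and writes two
#' temporary values per lane (the H score and the D gap value), four
#' accesses in total. The ladder reports, per half-warp per iteration, the
#' cost of that traffic at each optimization stage:
#'
#' * rung 0 — baseline: 4-byte values at scattered addresses; 4 accesses x
#'   16 threads = 64 transactions of 32 bytes, 2048 bytes of traffic.
#' * rung 1 — 16-bit values interlaced by thread: each access coalesces
#'   into one 32-byte transaction per half-warp; 4 transactions, 128 bytes.
#' * rung 2 — H and D interlaced into one structure: one read and one
#'   write of 16 x 2 x 2 = 64 payload bytes each; 2 transactions of
#'   64 bytes.
#' * rung 3 — two iterations interlaced: one 128-byte read and write per
#'   two iterations, i.e. 1 transaction per iteration; the largest
#'   supported access size.
#'
#' The final rung moves 16 times less data than the baseline and issues 1
#' instead of 64 transactions per iteration.
#'
#' @param threads lanes per half-warp (default 16).
#' @return data frame with one row per rung: `rung`, `description`,
#'   `value_bytes`, `bytes_per_iteration`, `transactions_per_iteration`,
#'   `payload_bytes`, `wasted_bytes`, `ratio_vs_baseline`.
#' @export
temp_scheme_ladder <- function(threads = 16L) {
  threads <- as.integer(threads)
  accesses <- 4L  # read+write of H and of D
  base <- transaction_size(4L, "scattered", threads)
  r0 <- list(bytes = base$bytes * accesses, tx = base$count * accesses,
             payload = base$payload * accesses,
             waste = base$wasted_bytes * accesses)
  c1 <- transaction_size(2L, "contiguous", threads)
  r1 <- list(bytes = c1$bytes * accesses, tx = c1$count * accesses,
             payload = c1$payload * accesses, waste = c1$wasted_bytes * accesses)
  c2 <- transaction_size(4L, "contiguous", threads)  # H+D struct, 2 accesses
  r2 <- list(bytes = c2$bytes * 2L, tx = c2$count * 2L,
             payload = c2$payload * 2L, waste = c2$wasted_bytes * 2L)
  c3 <- transaction_size(8L, "contiguous", threads)  # 2 iterations in one go
  r3 <- list(bytes = c3$bytes, tx = c3$count, payload = c3$payload,
             waste = c3$wasted_bytes)                # per iteration: /2 * 2
  rungs <- list(r0, r1, r2, r3)
  df <- data.frame(
    rung = 0:3,
    description = c(
      "baseline: scattered 4-byte temporaries",
      "16-bit temporaries, interlaced by thread (coalesced 32-byte)",
      "H and D interlaced into one structure (64-byte accesses)",
      "two iterations interlaced (128-byte access every second iteration)"),
    value_bytes = c(4L, 2L, 2L, 2L),
    bytes_per_iteration = vapply(rungs, `[[`, 0L, "bytes"),
    transactions_per_iteration = vapply(rungs, `[[`, 0L, "tx"),
    payload_bytes = vapply(rungs, `[[`, 0L, "payload"),
    wasted_bytes = vapply(rungs, `[[`, 0L, "waste"),
    stringsAsFactors = FALSE)
  df$ratio_vs_baseline <- df$bytes_per_iteration[1L] / df$bytes_per_iteration
  df
}

#' How many query-profile columns fit in a cache
#'
#' A profile column holds one score per alphabet letter at `entry_bytes`
#' each, so a cache of `cache_bytes` holds
#' `floor(cache_bytes / (alphabet * entry_bytes))` columns — with the
#' default 8 KB cache, 23-letter alphabet and 1-byte entries, 356 columns.
#' Queries longer than this bound overflow the cache and start missing.
#'
#' @param cache_bytes cache size in bytes (default `8 * 1024`).
#' @param alphabet scored letters per column (default 23).
#' @param entry_bytes bytes per profile entry (default 1).
#' @return maximum number of whole profile columns (integer).
#' @examples
#' cache_column_capacity()  # 356
#' @export
cache_column_capacity <- function(cache_bytes = 8L * 1024L, alphabet = 23L,
                                  entry_bytes = 1L) {
  if (any(c(cache_bytes, alphabet, entry_bytes) < 1L)) {
    stop(swlane_error("usage", "all arguments must be >= 1"))
  }
  as.integer(floor(cache_bytes / (alphabet * entry_bytes)))
}

#' Workload balance of a packed database
#'
#' Every lane of a set sweeps the same number of stream positions, so a
#' set's per-lane work is `stream_length * query_length` matrix cells. In
#' equal mode all sets share one stream length and the balance ratio
#' (max over mean of per-set stream lengths) is exactly 1; in set-local
#' mode it grows with the database's length skew, quantifying the idle time
#' a skewed layout leaves on short-sequence sets.
#'
#' @param db a [pack_database()] result.
#' @param query_length query length in residues.
#' @return list with `stream_lengths`, `cells_per_lane`, `total_cells`,
#'   `pad_fraction`, `balance_ratio`.
#' @export
workload_report <- function(db, query_length) {
  stopifnot(inherits(db, "packed_db"))
  query_length <- as.integer(query_length)
  if (query_length < 1L) {
    stop(swlane_error("usage", "query_length must be >= 1"))
  }
  pad_count <- sum(vapply(db$sets, function(s) sum(s == PAD), 0L))
  total_codes <- sum(lengths(db$sets))
  lens <- db$stream_lengths
  list(stream_lengths = lens,
       cells_per_lane = lens * query_length,
       total_cells = sum(lens) * db$lanes * query_length,
       pad_fraction = pad_count / total_codes,
       balance_ratio = max(lens) / mean(lens))
}

#' Write the memory-model report
#'
#' Emits the optimization ladder and the workload balance of a packed
#' database as a TSV (machine-readable) plus a short human-readable
#' summary, including whether the query's profile fits the modeled cache.
#'
#' @param db a packed database.
#' @param query_length query length in residues.
#' @param path output TSV path; the text summary goes to `<path>.txt`.
#' @param cache_bytes modeled profile cache size (default 8 KB).
#' @return the report list, invisibly.
#' @export
write_memreport <- function(db, query_length, path,
                            cache_bytes = 8L * 1024L) {
  ladder <- temp_scheme_ladder(db$lanes)
  wl <- workload_report(db, query_length)
  capacity <- cache_column_capacity(cache_bytes, db$alphabet_size, 1L)
  fits <- query_length <= capacity
  utils::write.table(ladder, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_lines <- c(
    sprintf("lanes\t%d", db$lanes),
    sprintf("sets\t%d", length(db$sets)),
    sprintf("balance_ratio\t%.6f", wl$balance_ratio),
    sprintf("pad_fraction\t%.6f", wl$pad_fraction),
    sprintf("total_cells\t%.0f", wl$total_cells),
    sprintf("bandwidth_ratio_final\t%.1f",
            ladder$ratio_vs_baseline[nrow(ladder)]),
    sprintf("profile_cache_columns\t%d", capacity),
    sprintf("query_profile_fits_cache\t%s", ifelse(fits, "yes", "no")))
  writeLines(summary_lines, paste0(path, ".txt"))
  invisible(list(ladder = ladder, workload = wl, cache_columns = capacity,
                 query_fits_cache = fits))
}
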