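PACKED_MAGIC <- "DOPA"
PACKED_VERSION <- 1L

#' Write / read a packed database
#'
#' The on-disk layout is little-endian binary: magic `"DOPA"` (4 bytes),
#' then single bytes for format version, alphabet size, lanes, subset
#' length and mode (0 = equal, 1 = set-local), then `target_length` and the
#' set count as unsigned 32-bit integers, then per set its per-group stream
#' length (u32) followed by the interlaced codes, one byte each. The
#' sequence index travels in a plain TSV sidecar at `<path>.idx` with
#' columns `seq_id`, `set`, `lane`, `offset`, `length`, `db_order`.
#'
#' @param db a [pack_database()] result.
#' @param path output path; the index sidecar is written next to it.
#' @return `write_packed()` returns `path` invisibly; `read_packed()`
#'   returns the reconstructed `packed_db`.
#' @export
write_packed <- function(db, path) {
  stopifnot(inherits(db, "packed_db"))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop(swlane_error("usage", sprintf("cannot write %s: %s", path,
                                       conditionMessage(e))))
  })
  on.exit(close(con))
  writeBin(charToRaw(PACKED_MAGIC), con)
  writeBin(as.raw(c(db$version, db$alphabet_size, db$lanes,
                    db$subset_length, if (db$mode == "equal") 0L else 1L)),
           con)
  writeBin(as.integer(c(db$target_length, length(db$sets))), con,
           size = 4L, endian = "little")
  for (s in seq_along(db$sets)) {
    writeBin(as.integer(db$stream_lengths[s]), con, size = 4L,
             endian = "little")
    writeBin(as.raw(db$sets[[s]]), con)
  }
  utils::write.table(db$index, paste0(path, ".idx"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_packed
#' @export
read_packed <- function(path) {
  if (!file.exists(path)) {
    stop(swlane_error("usage", sprintf("packed database not found: %s", path)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  need <- function(x, n, what) {
    if (length(x) < n) {
      stop(swlane_error("format", sprintf(
        "truncated packed database %s: %s missing", path, what)))
    }
    x
  }
  magic <- need(readBin(con, "raw", 4L), 4L, "magic")
  if (!identical(rawToChar(magic), PACKED_MAGIC)) {
    stop(swlane_error("format", sprintf(
      "bad magic in %s: not a packed database", path)))
  }
  hdr <- as.integer(need(readBin(con, "raw", 5L), 5L, "header"))
  if (hdr[1L] != PACKED_VERSION) {
    stop(swlane_error("format", sprintf(
      "unsupported format version %d in %s (reader supports version %d)",
      hdr[1L], path, PACKED_VERSION)))
  }
  words <- need(readBin(con, "integer", 2L, size = 4L, endian = "little"),
                2L, "target length / set count")
  n_sets <- words[2L]
  sets <- vector("list", n_sets)
  stream_lengths <- integer(n_sets)
  for (s in seq_len(n_sets)) {
    stream_lengths[s] <- need(
      readBin(con, "integer", 1L, size = 4L, endian = "little"),
      1L, sprintf("stream length of set %d", s))
    n_codes <- stream_lengths[s] * hdr[3L]
    sets[[s]] <- as.integer(need(readBin(con, "raw", n_codes), n_codes,
                                 sprintf("codes of set %d", s)))
  }
  idx_path <- paste0(path, ".idx")
  if (!file.exists(idx_path)) {
    stop(swlane_error("format", sprintf("index sidecar missing: %s", idx_path)))
  }
  index <- utils::read.table(
    idx_path, sep = "\t", header = TRUE, quote = "",
    colClasses = c("character", rep("integer", 5L)),
    stringsAsFactors = FALSE)
  structure(
    list(version = hdr[1L], alphabet_size = hdr[2L], lanes = hdr[3L],
         subset_length = hdr[4L],
         mode = if (hdr[5L] == 0L) "equal" else "set-local",
         target_length = words[1L], sets = sets,
         stream_lengths = stream_lengths, index = index,
         residue_total = sum(index$length)),
    class = "packed_db")
}
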