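#' Sort records by decreasing sequence length
#'
#' Stable descending length sort, so neighboring lanes receive sequences of
#' similar length and ties keep their input order. Sorting is the first
#' conversion step: it minimizes the length spread within each 16-sequence
#' batch and thus the time lock-step lanes wait for each other.
#'
#' @param records records data frame (see [read_fasta()]).
#' @return the same data frame, rows reordered.
#' @export
sort_by_length <- function(records) {
  records <- as_records(records)
  records[order(-nchar(records$residues)), , drop = FALSE]
}

#' Pack a protein database into the lane-interlaced layout
#'
#' Converts records into the packed layout a lock-step engine consumes:
#'
#' 1. *Sort* by decreasing length.
#' 2. *Concatenate*: batches of `lanes` sequences seed the sequence groups
#'    of a new sequence set; shorter leftover sequences are appended to
#'    groups where they fit, separated by `SEQ_TERM`, each group ending in
#'    one `GROUP_TERM`.
#' 3. *Equalize*: in `"equal"` mode every group across the whole database
#'    gets the same capacity, the length of the longest database sequence,
#'    so all lanes everywhere do identical work; in `"set-local"` mode a
#'    set's capacity is its own longest (first-seeded) sequence, the
#'    pre-equalization behavior whose imbalance [workload_report()]
#'    quantifies.
#' 4. *Interlace*: each set's group streams are stored as alternating
#'    `subset_length`-character subsets (see [interlace()]) so the `lanes`
#'    lock-step readers touch contiguous memory.
#'
#' Group filling is greedy best-fit-decreasing: each group repeatedly takes
#' the longest unplaced sequence that still fits its remaining capacity
#' (a sequence of length L plus its terminator costs L + 1 codes of the
#' group's `target + 1` total). A final partial set is completed with all-PAD
#' groups so every set has exactly `lanes` lanes. Streams are padded with
#' `PAD` to a multiple of `subset_length`.
#'
#' @param records records data frame; must be non-empty.
#' @param lanes number of lock-step lanes per set (default 16, the
#'   half-warp width).
#' @param subset_length characters per lane per interlaced subset
#'   (default 8).
#' @param mode `"equal"` (one global capacity) or `"set-local"`.
#' @param target_length optional explicit group capacity; it is an error
#'   for any sequence to exceed it.
#' @return object of class `"packed_db"`: header fields (`version`,
#'   `alphabet_size`, `lanes`, `subset_length`, `mode`, `target_length`),
#'   `sets` (list of interlaced integer code vectors), `stream_lengths`
#'   (per-set padded per-group length), `index` (data frame `seq_id`, `set`,
#'   `lane`, `offset`, `length`, `db_order`) and `residue_total`.
#' @export
pack_database <- function(records, lanes = 16L, subset_length = 8L,
                          mode = c("equal", "set-local"),
                          target_length = NULL) {
  mode <- match.arg(mode)
  records <- as_records(records)
  lanes <- as.integer(lanes)
  subset_length <- as.integer(subset_length)
  if (nrow(records) == 0L) {
    stop(swlane_error("usage", "no sequences: cannot pack an empty database"))
  }
  if (lanes < 1L || subset_length < 1L) {
    stop(swlane_error("usage", "lanes and subset_length must be >= 1"))
  }
  codes <- lapply(records$residues, encode_sequence)
  lens <- lengths(codes)
  global_target <- if (is.null(target_length)) max(lens)
                   else as.integer(target_length)
  if (any(lens > global_target)) {
    stop(swlane_error("usage", sprintf(
      "sequence '%s' (length %d) exceeds target length %d; increase target_length",
      records$id[which.max(lens)], max(lens), global_target)))
  }

  order_desc <- order(-lens)            # stable: ties keep input order
  pool <- order_desc                    # indexes into records, longest first
  sets <- list()                        # per set: list of member index vectors
  set_targets <- integer(0)
  while (length(pool) > 0L) {
    n_seed <- min(lanes, length(pool))
    seeds <- pool[seq_len(n_seed)]
    pool <- pool[-seq_len(n_seed)]
    target <- if (mode == "equal") global_target else lens[seeds[1L]]
    groups <- as.list(seeds)
    if (n_seed < lanes) groups <- c(groups, rep(list(integer(0)), lanes - n_seed))
    remaining <- target - ifelse(lengths(groups) > 0L,
                                 vapply(groups, function(g) lens[g[1L]], 0L), target + 1L)
    # empty trailing groups stay empty (all PAD): capacity -1 admits nothing,
    # keeping the partial final set's fill deterministic
    for (g in seq_len(lanes)) {
      while (length(pool) > 0L) {
        fit <- which(lens[pool] + 1L <= remaining[g])
        if (length(fit) == 0L) break
        take <- fit[1L]                 # pool is sorted: first fit = longest fit
        groups[[g]] <- c(groups[[g]], pool[take])
        remaining[g] <- remaining[g] - (lens[pool[take]] + 1L)
        pool <- pool[-take]
      }
    }
    sets[[length(sets) + 1L]] <- groups
    set_targets[length(sets)] <- target
  }

  # materialize group streams, build index, interlace
  idx <- vector("list", length(sets))
  out_sets <- vector("list", length(sets))
  stream_lengths <- integer(length(sets))
  for (s in seq_along(sets)) {
    target <- set_targets[s]
    padded <- ceiling((target + 1L) / subset_length) * subset_length
    stream_lengths[s] <- padded
    streams <- matrix(PAD, nrow = padded, ncol = lanes)
    rows <- list()
    for (g in seq_len(lanes)) {
      members <- sets[[s]][[g]]
      if (length(members) == 0L) next
      pos <- 1L
      for (k in seq_along(members)) {
        ri <- members[k]
        L <- lens[ri]
        streams[pos:(pos + L - 1L), g] <- codes[[ri]]
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = records$id[ri], set = s, lane = g, offset = pos,
          length = L, db_order = ri, stringsAsFactors = FALSE)
        pos <- pos + L
        streams[pos, g] <- if (k < length(members)) SEQ_TERM else GROUP_TERM
        pos <- pos + 1L
      }
    }
    idx[[s]] <- do.call(rbind, rows)
    out_sets[[s]] <- interlace(streams, subset_length)
  }

  structure(
    list(version = 1L, alphabet_size = 23L, lanes = lanes,
         subset_length = subset_length, mode = mode,
         target_length = global_target, sets = out_sets,
         stream_lengths = stream_lengths,
         index = do.call(rbind, idx), residue_total = sum(lens)),
    class = "packed_db")
}

#' @export
print.packed_db <- function(x, ...) {
  cat(sprintf(
    "packed database: %d sequences, %d residues, %d set(s) of %d lanes (subset %d, %s mode, target %d)\n",
    nrow(x$index), x$residue_total, length(x$sets), x$lanes,
    x$subset_length, x$mode, x$target_length))
  invisible(x)
}

#' Interlace / deinterlace a sequence set's lane streams
#'
#' `interlace()` rewrites `lanes` equal-length streams as consecutive
#' subsets: `subset_length` codes of lane 1, then of lane 2, ... then of
#' lane `lanes`, then the next window, so `lanes` lock-step readers each
#' loading `subset_length` bytes touch one contiguous block (with 16 lanes
#' and 8-byte subsets, a 128-byte block). `deinterlace()` is the exact
#' inverse.
#'
#' @param streams integer matrix, one column per lane, equal-length columns
#'   whose length is a multiple of `subset_length`.
#' @param stream interlaced integer vector.
#' @param lanes,subset_length layout parameters.
#' @return `interlace()`: integer vector of length `lanes * nrow(streams)`;
#'   `deinterlace()`: the lane-column matrix back.
#' @examples
#' s <- matrix(c(1:4, 5:8), ncol = 2)
#' interlace(s, 2)                  # 1 2 5 6 3 4 7 8
#' deinterlace(interlace(s, 2), 2, 2)
#' @export
interlace <- function(streams, subset_length) {
  if (!is.matrix(streams)) streams <- matrix(streams, ncol = 1L)
  subset_length <- as.integer(subset_length)
  n <- nrow(streams)
  if (n %% subset_length != 0L) {
    stop(swlane_error("consistency",
                      "stream length must be a multiple of subset_length"))
  }
  if (n == 0L) return(integer(0))
  a <- array(as.integer(streams), dim = c(subset_length, n %/% subset_length,
                                          ncol(streams)))
  as.integer(aperm(a, c(1L, 3L, 2L)))
}

#' @rdname interlace
#' @export
deinterlace <- function(stream, lanes, subset_length) {
  lanes <- as.integer(lanes)
  subset_length <- as.integer(subset_length)
  n <- length(stream)
  if (n %% (lanes * subset_length) != 0L) {
    stop(swlane_error("format", sprintf(
      "interlaced stream length %d is not divisible by lanes x subset_length = %d",
      n, lanes * subset_length)))
  }
  if (n == 0L) return(matrix(integer(0), nrow = 0L, ncol = lanes))
  a <- array(as.integer(stream), dim = c(subset_length, lanes,
                                         n %/% (lanes * subset_length)))
  matrix(as.integer(aperm(a, c(1L, 3L, 2L))), ncol = lanes)
}

# split one deinterlaced lane stream into member code vectors
split_group_stream <- function(column) {
  members <- list()
  start <- 1L
  for (p in seq_along(column)) {
    code <- column[p]
    if (code == SEQ_TERM || code == GROUP_TERM) {
      members[[length(members) + 1L]] <- column[seq(start, p - 1L)]
      start <- p + 1L
      if (code == GROUP_TERM) break
    }
  }
  members
}

#' Verify that a packed database reproduces its input records
#'
#' Deinterlaces every set, splits each lane stream at its terminators, and
#' checks (a) that the recovered encoded sequences equal the encoded input
#' records as a multiset and (b) that every index entry points at exactly
#' its record's codes. Also reports residue totals, the PAD overhead
#' fraction and per-set stream lengths.
#'
#' @param records the records the database was built from.
#' @param db a [pack_database()] result.
#' @return list with `ok`, `n_sequences`, `residue_total`, `pad_fraction`,
#'   `stream_lengths` and, on failure, `first_mismatch` (a sequence id).
#' @export
verify_roundtrip <- function(records, db) {
  records <- as_records(records)
  recovered <- character(0)
  pad_count <- 0L
  lane_cols <- vector("list", length(db$sets))
  for (s in seq_along(db$sets)) {
    cols <- deinterlace(db$sets[[s]], db$lanes, db$subset_length)
    lane_cols[[s]] <- cols
    pad_count <- pad_count + sum(cols == PAD)
    for (g in seq_len(ncol(cols))) {
      members <- split_group_stream(cols[, g])
      recovered <- c(recovered,
                     vapply(members, function(m) paste(m, collapse = ","),
                            character(1)))
    }
  }
  original <- vapply(lapply(records$residues, encode_sequence),
                     function(m) paste(m, collapse = ","), character(1))
  multiset_ok <- identical(sort(recovered), sort(original))

  first_mismatch <- NULL
  for (r in seq_len(nrow(db$index))) {
    e <- db$index[r, ]
    got <- lane_cols[[e$set]][seq(e$offset, e$offset + e$length - 1L), e$lane]
    want <- encode_sequence(records$residues[e$db_order])
    if (!identical(as.integer(got), as.integer(want))) {
      first_mismatch <- e$seq_id
      break
    }
  }
  total_codes <- sum(lengths(db$sets))
  list(ok = multiset_ok && is.null(first_mismatch),
       n_sequences = nrow(db$index),
       residue_total = db$residue_total,
       pad_fraction = pad_count / total_codes,
       stream_lengths = db$stream_lengths,
       first_mismatch = first_mismatch)
}
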