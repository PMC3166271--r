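#' Affine-gap scoring scheme
#'
#' Bundles a substitution matrix with affine gap penalties. A gap of length
#' `k` costs `gap_open + (k - 1) * gap_extend` under the default
#' `first_gap = "open"` convention (the first gap residue pays the opening
#' penalty only). The alternative `"open+extend"` convention charges
#' `gap_open + gap_extend` for the first gap residue, i.e. a gap of length
#' `k` costs `gap_open + k * gap_extend`, matching the FASTA-suite tools.
#' Both are exact Gotoh recurrences; only the opening charge differs.
#'
#' @param matrix 23x23 integer substitution matrix (see
#'   [read_substitution_matrix()]); defaults to the bundled BLOSUM62.
#' @param gap_open positive gap opening penalty (default 10).
#' @param gap_extend positive gap extension penalty (default 2); must not
#'   exceed `gap_open` (affine regime: extending is cheaper than opening).
#' @param first_gap gap-opening convention, `"open"` or `"open+extend"`.
#' @return object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 10L,
                           gap_extend = 2L,
                           first_gap = c("open", "open+extend")) {
  first_gap <- match.arg(first_gap)
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || is.na(gap_extend) ||
      gap_open < gap_extend || gap_extend < 0L) {
    stop(swlane_error(
      "usage", "need gap_open >= gap_extend >= 0 (affine gap regime)"))
  }
  if (!is.matrix(matrix) || !identical(dim(matrix), c(23L, 23L))) {
    stop(swlane_error("usage", "matrix must be a 23x23 substitution matrix"))
  }
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         first_gap = first_gap),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: %s, gap open %d / extend %d (%s convention)\n",
              attr(x$matrix, "name") %||% "custom matrix",
              x$gap_open, x$gap_extend, x$first_gap))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effective opening charge for the first gap residue
open_cost <- function(scheme) {
  if (scheme$first_gap == "open") scheme$gap_open
  else scheme$gap_open + scheme$gap_extend
}

# accept either an encoded integer vector or a residue string
as_codes <- function(x) {
  if (is.character(x)) return(encode_sequence(x))
  x <- as.integer(x)
  if (length(x) && (anyNA(x) || any(x < 0L | x > 22L))) {
    stop(swlane_error(
      "domain", "encoded sequence contains codes outside the residue range 0..22"))
  }
  x
}

#' Build a query profile
#'
#' Reindexes the substitution matrix by query position: column `j` of the
#' profile holds the 23 scores of the query's j-th residue against every
#' alphabet letter, so a database residue code selects a profile row
#' directly and no query lookup is needed during the inner loop. Entries are
#' one signed byte each, so a query of M residues occupies `23 * M` bytes;
#' [cache_column_capacity()] turns a cache size into the longest query whose
#' profile fits.
#'
#' @param query query as residue string or encoded integer vector (codes
#'   0..22; control codes are rejected).
#' @param scheme a [scoring_scheme()].
#' @return object of class `"query_profile"`: list with `query` (codes),
#'   `table` (M x 23 integer matrix) and `bytes` (profile footprint).
#' @export
build_query_profile <- function(query, scheme) {
  codes <- as_codes(query)
  if (length(codes) == 0L) {
    stop(swlane_error("usage", "query must be non-empty"))
  }
  table <- scheme$matrix[codes + 1L, , drop = FALSE]
  rownames(table) <- NULL
  structure(
    list(query = codes, table = table, bytes = length(table)),
    class = "query_profile")
}

#' Full-matrix Smith-Waterman score (scalar oracle)
#'
#' Computes the optimal local alignment score with affine gaps by filling
#' the complete H/E/D dynamic-programming matrices with zero boundary
#' conditions and taking the maximum over all cells. This is the reference
#' implementation the streaming lane engine is checked against; it keeps
#' every matrix cell and shares no state machinery with the engine.
#' Scores saturate at the 16-bit maximum (65535) instead of wrapping.
#'
#' @param a,b sequences as residue strings or encoded integer vectors.
#' @param scheme a [scoring_scheme()].
#' @return integer score (>= 0), with attribute `saturated` (logical).
#' @examples
#' sw_score_oracle("AW", "AW", scoring_scheme())  # 15
#' @export
sw_score_oracle <- function(a, b, scheme) {
  a <- as_codes(a)
  b <- as_codes(b)
  res <- cpp_sw_full_matrix(a, b, scheme$matrix, open_cost(scheme),
                            scheme$gap_extend)
  structure(res$score, saturated = res$saturated)
}

#' Streaming lane state for one packed-database lane
#'
#' The lane engine keeps, per lane, only what one database position needs:
#' the previous position's H column and D column (length M, 16-bit,
#' saturating), the running E value and upper-left H carry of the current
#' sweep, and the best score seen since the last sequence start. Feeding a
#' residue performs one column update; feeding `SEQ_TERM` or `GROUP_TERM`
#' emits the finished sequence's maximum score and zeroes the state;
#' feeding `PAD` is a no-op. `lane_state()` creates a fresh zeroed state.
#'
#' This R-level stepper is the readable reference for the engine's inner
#' loop; [search_packed()] runs the same recurrence in compiled code.
#'
#' @param profile a [build_query_profile()] result.
#' @param state a lane state created by `lane_state()`.
#' @param code one stream code: residue 0..22, `SEQ_TERM`, `GROUP_TERM` or
#'   `PAD`.
#' @param scheme the [scoring_scheme()] the profile was built from.
#' @return `lane_advance()` returns a list with the updated `state` and
#'   `emitted` (`NULL`, or a list with `score` and `saturated` when a
#'   terminator finished a sequence).
#' @export
lane_state <- function(profile) {
  m <- length(profile$query)
  structure(
    list(H_col = integer(m), D_col = integer(m), best = 0L,
         saturated = FALSE, M = m),
    class = "lane_state")
}

#' @rdname lane_state
#' @export
lane_advance <- function(state, code, profile, scheme) {
  code <- as.integer(code)
  if (code == PAD) return(list(state = state, emitted = NULL))
  if (code == SEQ_TERM || code == GROUP_TERM) {
    emitted <- list(score = state$best, saturated = state$saturated)
    fresh <- lane_state(profile)
    return(list(state = fresh, emitted = emitted))
  }
  if (code < 0L || code > 22L) {
    stop(swlane_error("domain", sprintf("invalid stream code %d", code)))
  }
  alpha <- open_cost(scheme)
  beta <- scheme$gap_extend
  H <- state$H_col
  D <- state$D_col
  prof <- profile$table
  e <- 0L
  h_diag <- 0L   # H(previous position, j-1)
  h_left <- 0L   # H(current position, j-1)
  best <- state$best
  saturated <- state$saturated
  for (j in seq_len(state$M)) {
    d <- max(H[j] - alpha, D[j] - beta, 0L)
    e <- max(h_left - alpha, e - beta, 0L)
    h <- max(0L, h_diag + prof[j, code + 1L], e, d)
    if (h > 65535L) {
      h <- 65535L
      saturated <- TRUE
    }
    h_diag <- H[j]
    H[j] <- h
    D[j] <- d
    h_left <- h
    if (h > best) best <- h
  }
  state$H_col <- H
  state$D_col <- D
  state$best <- best
  state$saturated <- saturated
  list(state = state, emitted = NULL)
}
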