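#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout: `#` comment lines, a header row of
#' alphabet letters, then one labeled row of integer scores per letter.
#' Columns are reordered into the package's fixed 23-letter alphabet order
#' (see [aa_alphabet()]); any `*` (stop) row/column is ignored. The matrix
#' must be symmetric and every score must fit a signed byte, since profile
#' entries are stored one byte per score.
#'
#' @param path path to a matrix file, e.g. the bundled BLOSUM62 fixture.
#' @param name matrix name to record; defaults to the file name.
#' @return 23x23 integer matrix with dimnames in alphabet order and a
#'   `"name"` attribute.
#' @examples
#' m <- blosum62()
#' m["A", "A"]  # 4
#' m["W", "W"]  # 11
#' @export
read_substitution_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(swlane_error("usage", sprintf("matrix file not found: %s", path)))
  }
  tab <- tryCatch(
    utils::read.table(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(swlane_error("format", sprintf(
        "cannot parse substitution matrix %s: %s", path, conditionMessage(e))))
    })
  m <- as.matrix(tab)
  missing <- setdiff(AA_LETTERS, intersect(rownames(m), colnames(m)))
  if (length(missing)) {
    stop(swlane_error("format", sprintf(
      "substitution matrix %s lacks required letters: %s",
      path, paste(missing, collapse = ", "))))
  }
  m <- m[AA_LETTERS, AA_LETTERS]
  if (!is.numeric(m) || anyNA(m) || any(m != round(m))) {
    stop(swlane_error("format", sprintf(
      "substitution matrix %s contains non-integer scores", path)))
  }
  storage.mode(m) <- "integer"
  if (!identical(m, t(m))) {
    stop(swlane_error("format", sprintf(
      "substitution matrix %s is not symmetric", path)))
  }
  if (any(m < -128L) || any(m > 127L)) {
    stop(swlane_error("format", sprintf(
      "substitution matrix %s has scores outside the signed 8-bit range", path)))
  }
  attr(m, "name") <- if (is.null(name)) basename(path) else name
  m
}

#' @rdname read_substitution_matrix
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "swlane"),
    name = "BLOSUM62")
}
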