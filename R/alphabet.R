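#' The 23-letter protein alphabet and stream control codes
#'
#' Residues are encoded as integer indexes into a fixed 23-symbol protein
#' alphabet: the 20 standard amino acids followed by the ambiguity symbols
#' B (Asx), Z (Glx) and X (unknown). A substitution profile column therefore
#' holds exactly 23 scores. Three control codes live above the alphabet and
#' never collide with residue codes: `SEQ_TERM` (23) separates concatenated
#' sequences within a lane and tells the engine to start a new alignment,
#' `GROUP_TERM` (24) ends a lane's workload, and `PAD` (25) is inert filler
#' used to equalize lane stream lengths.
#'
#' @return `aa_alphabet()` returns the 23 alphabet letters in encoding order.
#' @examples
#' aa_alphabet()
#' encode_sequence("ACDX")
#' @export
aa_alphabet <- function() AA_LETTERS

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

#' @rdname aa_alphabet
#' @format `SEQ_TERM`, `GROUP_TERM` and `PAD` are integer scalars 23, 24, 25.
#' @export
SEQ_TERM <- 23L

#' @rdname aa_alphabet
#' @export
GROUP_TERM <- 24L

#' @rdname aa_alphabet
#' @export
PAD <- 25L

# 256-entry byte lookup: letter -> code, anything unknown -> code of 'X' (22)
.encode_lut <- local({
  lut <- rep(22L, 256L)
  codes <- utf8ToInt(paste(AA_LETTERS, collapse = ""))
  lut[codes + 1L] <- seq_along(AA_LETTERS) - 1L
  lut[utf8ToInt(paste(tolower(AA_LETTERS), collapse = "")) + 1L] <-
    seq_along(AA_LETTERS) - 1L
  lut
})

#' Encode residues as integer alphabet indexes
#'
#' Total on arbitrary strings: letters outside the 23-letter alphabet
#' (selenocysteine U, pyrrolysine O, J, `*`, ...) map to the code of `X`, so
#' they score as unknown residues rather than failing. Case-insensitive.
#'
#' @param residues single character string of residues.
#' @return integer vector of codes in `0:22`, one per input character.
#' @seealso [decode_sequence()]
#' @export
encode_sequence <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) return(integer(0))
  .encode_lut[as.integer(charToRaw(residues)) + 1L]
}

#' Decode integer alphabet indexes back to residues
#'
#' Inverse of [encode_sequence()] on the 23-letter alphabet. Control codes
#' (`SEQ_TERM`, `GROUP_TERM`, `PAD`) are not residues and raise a domain
#' error.
#'
#' @param codes integer vector of codes in `0:22`.
#' @return single character string of residues.
#' @export
decode_sequence <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) && (anyNA(codes) || any(codes < 0L | codes > 22L))) {
    stop(swlane_error(
      "domain", sprintf(
        "codes outside residue range 0..22 (first offender: %s); control codes are not residues",
        codes[which(codes < 0L | codes > 22L | is.na(codes))[1L]])))
  }
  paste(AA_LETTERS[codes + 1L], collapse = "")
}

# classed conditions: kind in "usage", "format", "consistency", "domain"
swlane_error <- function(kind, message) {
  structure(
    class = c(paste0("swlane_", kind, "_error"), "swlane_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1)))
}
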