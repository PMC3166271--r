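#' Read a protein FASTA file
#'
#' Records are returned as a data frame with one row per sequence. The
#' identifier is the first whitespace-delimited token of the header line and
#' the description is the remainder. Multi-line bodies are joined and
#' lowercase residues are uppercased.
#'
#' @param path path to a FASTA file.
#' @return data frame with character columns `id`, `description`, `residues`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 example", "ACD", "EF"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(swlane_error("usage", sprintf("FASTA file not found: %s", path)))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop(swlane_error("format", sprintf(
        "malformed FASTA %s: %s", path, conditionMessage(e))))
    })
  if (length(set) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      residues = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  if (any(!nzchar(residues))) {
    stop(swlane_error("format", sprintf(
      "empty sequence body for record '%s' in %s",
      id[!nzchar(residues)][1L], path)))
  }
  data.frame(id = id, description = description, residues = residues,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to a FASTA file
#'
#' Sequence bodies are wrapped at 60 columns. An empty record set writes an
#' empty file.
#'
#' @param records data frame with columns `id`, `description`, `residues`
#'   (as returned by [read_fasta()] or [generate_synthetic_db()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_records(records)
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- trimws(paste(records$id, records$description))
  tryCatch(
    Biostrings::writeXStringSet(set, path, width = 60L),
    error = function(e) {
      stop(swlane_error("usage", sprintf(
        "cannot write FASTA %s: %s", path, conditionMessage(e))))
    })
  invisible(path)
}

# validate/coerce a records data frame
as_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "description", "residues") %in% names(records))) {
    stop(swlane_error(
      "usage", "records must be a data frame with columns id, description, residues"))
  }
  if (any(grepl("\\s", records$id))) {
    stop(swlane_error("usage", "record ids must not contain whitespace"))
  }
  records
}

#' Write or read the description sidecar
#'
#' Sequence descriptions are kept in a plain TSV sidecar (columns `id`,
#' `description`, `length`) next to the packed database rather than inside
#' it, so the search engine never carries header text.
#'
#' @param records records data frame.
#' @param path sidecar path.
#' @return `write_descriptions()` returns `path` invisibly;
#'   `read_descriptions()` returns the sidecar as a data frame.
#' @export
write_descriptions <- function(records, path) {
  records <- as_records(records)
  df <- data.frame(id = records$id, description = records$description,
                   length = nchar(records$residues))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptions
#' @export
read_descriptions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = c("character", "character", "integer"),
                    stringsAsFactors = FALSE)
}
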