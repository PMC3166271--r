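# independent local-alignment score via Biostrings (convention mapping:
# Biostrings charges gapOpening + k * gapExtension for a gap of length k)
bios_local_score <- function(a, b, scheme) {
  go <- if (scheme$first_gap == "open") scheme$gap_open - scheme$gap_extend
        else scheme$gap_open
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$matrix, gapOpening = go,
    gapExtension = scheme$gap_extend, scoreOnly = TRUE))
}

random_protein <- function(len) {
  paste(sample(aa_alphabet()[1:20], len, replace = TRUE), collapse = "")
}

random_records <- function(n, min_len = 1L, max_len = 60L) {
  lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
  data.frame(
    id = sprintf("r%04d", seq_len(n)),
    description = sprintf("random length %d", lens),
    residues = vapply(lens, random_protein, character(1)),
    stringsAsFactors = FALSE)
}

oracle_scores <- function(query, records, scheme) {
  vapply(records$residues,
         function(s) as.integer(sw_score_oracle(query, s, scheme)),
         0L, USE.NAMES = FALSE)
}

engine_scores <- function(db, query, scheme) {
  hits <- search_packed(db, query, scheme)
  hits$score[order(hits$db_order)]
}
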