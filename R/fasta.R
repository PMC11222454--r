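#' Read mature miRNA sequences from FASTA
#'
#' miRBase-dialect FASTA (headers like `>rno-miR-21-5p ...`): the id is the
#' header token before the first whitespace; wrapped sequence lines are
#' concatenated; sequences are uppercased with the U/T alphabet preserved as
#' read. Empty sequences and duplicate headers are errors.
#'
#' @param path FASTA file path.
#' @return named character vector, id -> sequence.
#' @export
read_mature_fasta <- function(path) {
  if (!file.exists(path)) stop_configuration(sprintf("missing FASTA: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_parse(sprintf("cannot parse FASTA %s: %s",
                                                         path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop_parse(sprintf("empty sequence for '%s' in %s", ids[!nzchar(seqs)][1], path))
  }
  if (anyDuplicated(ids))
    stop_parse(sprintf("duplicate FASTA header '%s' in %s",
                       ids[duplicated(ids)][1], path))
  setNames(unname(seqs), ids)
}
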