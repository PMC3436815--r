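#' Read a FASTA file into a tibble
#'
#' @param path path to a (plain-text) FASTA file.
#' @return A tibble with columns `id` (first word of the header),
#'   `description` (remainder of the header, `""` if none) and `seq`
#'   (uppercase sequence).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  tibble(id = id, description = desc,
         seq = toupper(as.character(unname(set))))
}

#' Write sequence records to FASTA
#'
#' Writes 60-column-wrapped FASTA.  Records round-trip through
#' [read_fasta()].
#'
#' @param records a data frame with columns `id` and `seq` (and optionally
#'   `description`), or a named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(id = names(records), seq = unname(records))
  }
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate record id(s): ",
                 records$id[duplicated(records$id)][1]))
  }
  set <- Biostrings::DNAStringSet(records$seq)
  desc <- records[["description"]] %||% rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
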