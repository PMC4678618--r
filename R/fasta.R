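#' Read and write FASTA as a tibble
#'
#' Sequences are the currency of the whole pipeline and are carried as plain
#' tibbles with one row per record: `id` (first whitespace-delimited token of
#' the header), `description` (remainder of the header, possibly empty) and
#' `seq` (uppercase residues). Parsing is delegated to Biostrings, so wrapped
#' and unwrapped records and CRLF line endings are all accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble(id = id, description = desc,
         seq = toupper(as.character(unname(x))))
}

#' @rdname read_fasta
#' @param seqs A tibble with columns `id` and `seq` (and optionally
#'   `description`), or a named character vector.
#' @param width Line-wrap width for output.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_tbl(seqs)
  hdr <- ifelse(nzchar(seqs$description),
                paste(seqs$id, seqs$description), seqs$id)
  x <- Biostrings::BStringSet(setNames(seqs$seq, hdr))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Coerce the accepted sequence representations to the canonical tibble.
as_seq_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(tibble(id = ids, description = "", seq = toupper(unname(x))))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  out <- as_tibble(x)
  if (!"description" %in% names(out)) out$description <- ""
  out$seq <- toupper(out$seq)
  if (anyDuplicated(out$id)) stop("sequence ids must be unique", call. = FALSE)
  out[, c("id", "description", setdiff(names(out), c("id", "description")))]
}

# Single sequence from a seq tibble / character scalar.
as_seq_chr <- function(x) {
  if (is.character(x) && length(x) == 1L) return(toupper(unname(x)))
  tb <- as_seq_tbl(x)
  if (nrow(tb) != 1L) stop("expected a single sequence", call. = FALSE)
  tb$seq
}
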