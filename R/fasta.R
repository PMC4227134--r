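#' DNA alphabet
#'
#' @return Character vector `c("A","C","G","T")`.
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' Read a FASTA file into a dataset tibble
#'
#' Sequences are uppercased and validated against the declared alphabet;
#' the record id is the first whitespace-delimited token of the header.
#' Record order is preserved. The method is alphabet-independent, so any
#' user-declared alphabet (e.g. amino acids) is accepted.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Character vector of allowed letters (default DNA).
#' @param on_invalid What to do with records containing letters outside the
#'   alphabet: `"error"` (default) or `"skip"` the record.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet(),
                       on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ds <- tibble::tibble(
    id = vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L),
    seq = unname(toupper(as.character(set)))
  )
  bad <- !valid_letters(ds$seq, alphabet)
  if (any(bad)) {
    if (on_invalid == "error")
      stop("record(s) with letters outside the alphabet: ",
           paste(ds$id[bad], collapse = ", "), call. = FALSE)
    ds <- ds[!bad, ]
    if (nrow(ds) == 0L)
      stop("all records contained letters outside the alphabet", call. = FALSE)
  }
  if (anyDuplicated(ds$id))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  ds
}

#' Write a dataset tibble to a FASTA file
#'
#' @param dataset Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  dataset <- as_dataset(dataset, min_n = 1L)
  set <- Biostrings::BStringSet(setNames(dataset$seq, dataset$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

valid_letters <- function(seqs, alphabet) {
  pat <- paste0("^[", paste(alphabet, collapse = ""), "]*$")
  grepl(pat, seqs)
}

# Normalise user input (tibble/data.frame with id+seq, or named character
# vector) into the canonical dataset tibble and validate it.
as_dataset <- function(dataset, min_n = 2L, alphabet = NULL) {
  if (is.character(dataset)) {
    ids <- names(dataset)
    if (is.null(ids)) ids <- paste0("seq", seq_along(dataset))
    dataset <- tibble::tibble(id = ids, seq = unname(dataset))
  }
  if (!is.data.frame(dataset) || !all(c("id", "seq") %in% names(dataset)))
    stop("dataset must be a data frame with columns `id` and `seq`",
         call. = FALSE)
  dataset <- tibble::as_tibble(dataset[, c("id", "seq")])
  dataset$id <- as.character(dataset$id)
  dataset$seq <- toupper(as.character(dataset$seq))
  if (nrow(dataset) < min_n)
    stop(sprintf("at least %d sequences are required (got %d)",
                 min_n, nrow(dataset)), call. = FALSE)
  if (any(nchar(dataset$seq) < 1L))
    stop("empty sequences are not allowed", call. = FALSE)
  if (anyDuplicated(dataset$id))
    stop("sequence ids must be unique", call. = FALSE)
  if (!is.null(alphabet) && !all(valid_letters(dataset$seq, alphabet)))
    stop("sequences contain letters outside the declared alphabet",
         call. = FALSE)
  dataset
}
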