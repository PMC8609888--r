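AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a protein sequence record
#'
#' A record holds one protein sequence together with its identifier and a
#' species label. Residues must come from the 20-letter amino-acid alphabet
#' plus \code{X} (unknown); gap characters are rejected.
#'
#' @param id Non-empty unique identifier.
#' @param species Species label (free text, used for per-species operations).
#' @param residues Amino-acid string, length >= 1.
#' @return A list of class \code{tlr_record} with fields \code{id},
#'   \code{species}, \code{residues}.
#' @examples
#' r <- seq_record("tlr1", "G. oculata", "MKLLVLLLAGX")
#' @export
seq_record <- function(id, species, residues) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a string")
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("'residues' must have length >= 1")
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), c(AA20, "X"))
  if (length(bad))
    stop("invalid residue characters: ", paste(bad, collapse = ", "))
  structure(list(id = id, species = as.character(species),
                 residues = residues),
            class = "tlr_record")
}

#' @export
print.tlr_record <- function(x, ...) {
  cat(sprintf("<tlr_record %s [%s], %d aa>\n", x$id, x$species,
              nchar(x$residues)))
  invisible(x)
}

# Accept either a tlr_record or a plain list/one-row data.frame with the
# same fields; always returns a validated tlr_record.
as_record <- function(x) {
  if (inherits(x, "tlr_record")) return(x)
  if (is.data.frame(x) && nrow(x) == 1L)
    return(seq_record(x$id, x$species, x$residues))
  if (is.list(x) && !is.null(x$residues))
    return(seq_record(if (is.null(x$id)) "seq" else x$id,
                      if (is.null(x$species)) NA_character_ else x$species,
                      x$residues))
  stop("cannot interpret input as a sequence record")
}

#' Build a record set from vectors
#'
#' @param id,species,residues Parallel character vectors.
#' @return A data.frame with columns \code{id}, \code{species},
#'   \code{residues}; ids must be unique.
#' @export
record_set <- function(id, species, residues) {
  if (anyDuplicated(id)) stop("record ids must be unique within a dataset")
  df <- data.frame(id = as.character(id), species = as.character(species),
                   residues = toupper(as.character(residues)),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) as_record(df[i, ])  # validate
  df
}

#' Read a protein FASTA into a record set
#'
#' Headers are parsed as \code{"id species=<name>"}; a sample sheet (TSV with
#' columns \code{id} and \code{species}) overrides or supplies species labels.
#'
#' @param path FASTA file of protein sequences.
#' @param sample_sheet Optional path to a TSV with columns \code{id},
#'   \code{species}.
#' @return A record-set data.frame (see \code{\link{record_set}}).
#' @export
read_proteome_fasta <- function(path, sample_sheet = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  species <- rep(NA_character_, length(ids))
  m <- regmatches(headers, regexpr("species=\\S+", headers))
  has <- grepl("species=", headers)
  species[has] <- sub("^species=", "", m)
  if (!is.null(sample_sheet)) {
    sh <- read.delim(sample_sheet, stringsAsFactors = FALSE)
    if (!all(c("id", "species") %in% names(sh)))
      stop("sample sheet needs columns 'id' and 'species'")
    idx <- match(ids, sh$id)
    species[!is.na(idx)] <- sh$species[idx[!is.na(idx)]]
  }
  record_set(ids, species, as.character(ss))
}

#' Write a record set to FASTA
#'
#' @param records Record-set data.frame.
#' @param path Output file.
#' @export
write_proteome_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(setNames(
    records$residues,
    ifelse(is.na(records$species), records$id,
           paste0(records$id, " species=", records$species))))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
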