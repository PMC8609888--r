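# ---- receptor calling -------------------------------------------------------

#' Call the receptor category of an architecture
#'
#' A sequence is a TLR iff it carries a TIR domain, a transmembrane segment
#' and at least one LRR repeat. Otherwise it falls into a TLR-like or empty
#' category.
#'
#' @param arch A \code{tlr_architecture}.
#' @return A list with \code{seq_id} and \code{category}, one of
#'   \code{"TLR"}, \code{"TIR_ONLY"}, \code{"LRR_ONLY"},
#'   \code{"TIR_LRR_NO_TM"}, \code{"NONE"}.
#' @export
call_receptor <- function(arch) {
  stopifnot(inherits(arch, "tlr_architecture"))
  category <-
    if (arch$has_tir && arch$has_tm && arch$n_lrr >= 1L) "TLR"
    else if (arch$has_tir && arch$n_lrr >= 1L) "TIR_LRR_NO_TM"
    else if (arch$has_tir) "TIR_ONLY"
    else if (arch$n_lrr >= 1L) "LRR_ONLY"
    else "NONE"
  list(seq_id = arch$seq_id, category = category)
}

# ---- pairwise identity ------------------------------------------------------

.identity_submat <- function() {
  if (!is.null(.pkg_cache$submat)) return(.pkg_cache$submat)
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- matrix(-1, 21, 21, dimnames = list(alpha, alpha))
  diag(m) <- 2
  m["X", ] <- 0; m[, "X"] <- 0
  .pkg_cache$submat <- m
  m
}

#' Global-alignment identity between two protein sequences
#'
#' Needleman--Wunsch global alignment (match 2, mismatch -1, affine gaps:
#' opening 10, extension 0.5); identity is the number of identical aligned
#' residue pairs divided by the length of the shorter sequence, so a perfect
#' substring scores 1. Symmetric in its arguments.
#'
#' @param a,b Sequence records or residue strings.
#' @return Identity in [0, 1].
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (is.character(a) && length(a) == 1L) toupper(a) else as_record(a)$residues
  sb <- if (is.character(b) && length(b) == 1L) toupper(b) else as_record(b)$residues
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = .identity_submat(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  Biostrings::nmatch(pa) / min(nchar(sa), nchar(sb))
}

# full identity matrix for a set of sequences (vectorized over rows)
identity_matrix <- function(residues) {
  k <- length(residues)
  idm <- diag(1, k)
  if (k < 2L) return(idm)
  lens <- nchar(residues)
  for (i in seq_len(k - 1L)) {
    js <- (i + 1L):k
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(residues[js]),
      Biostrings::AAString(residues[i]),
      substitutionMatrix = .identity_submat(),
      gapOpening = 10, gapExtension = 0.5, type = "global")
    idm[i, js] <- idm[js, i] <-
      Biostrings::nmatch(pa) / pmin(lens[js], lens[i])
  }
  idm
}

# ---- redundancy collapse ----------------------------------------------------

#' Collapse same-species redundant sequences
#'
#' Within each species, sequences whose pairwise identity strictly exceeds
#' \code{threshold} are linked; single-linkage connected components are
#' treated as one gene (polymorphisms or isoforms) and only one
#' representative is kept: the longest sequence, ties broken by the
#' lexicographically smallest id. Cross-species pairs are never collapsed.
#'
#' @param records Record-set data.frame.
#' @param threshold Identity threshold; comparison is strict (\code{>}).
#' @return List with \code{kept} (record-set of representatives) and
#'   \code{clusters} (data.frame: representative, member, identity_to_rep,
#'   species).
#' @export
collapse_redundant <- function(records, threshold = 0.90) {
  if (!nrow(records))
    return(list(kept = records,
                clusters = data.frame(representative = character(),
                                      member = character(),
                                      identity_to_rep = numeric(),
                                      species = character())))
  if (any(is.na(records$species)))
    stop("all records need a species label for redundancy collapse")
  kept_idx <- integer(0)
  cl_rows <- list()
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    idm <- identity_matrix(records$residues[idx])
    if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      if (idm[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    for (cc in unique(comp)) {
      mem <- idx[comp == cc]
      lens <- nchar(records$residues[mem])
      ids <- records$id[mem]
      rep_i <- mem[order(-lens, ids)][1L]
      kept_idx <- c(kept_idx, rep_i)
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        representative = records$id[rep_i], member = records$id[mem],
        identity_to_rep = idm[match(mem, idx), match(rep_i, idx)],
        species = sp, stringsAsFactors = FALSE)
    }
  }
  kept <- records[sort(kept_idx), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, clusters = do.call(rbind, cl_rows))
}

# ---- survey -----------------------------------------------------------------

#' Survey a proteome for TLRs, per species
#'
#' Annotates every record, applies the TLR calling rule, collapses
#' same-species redundancy among the called TLRs (identity > threshold), and
#' classifies the kept TLRs into scc/mcc/NC.
#'
#' @param records Record-set data.frame with species labels.
#' @param identity_threshold Collapse threshold (strict).
#' @param archs Optional pre-computed list of architectures keyed by id.
#' @return A data.frame (one row per species): \code{species}, \code{n_tlr},
#'   \code{n_scc}, \code{n_mcc}, \code{n_nc}, \code{tlr_ids} (comma-joined).
#'   Attributes \code{calls} (per-sequence category table), \code{clusters}
#'   (collapse report) and \code{types} (per-TLR typing table) carry the
#'   details.
#' @export
survey_proteome <- function(records, identity_threshold = 0.90,
                            archs = NULL) {
  empty <- data.frame(species = character(), n_tlr = integer(),
                      n_scc = integer(), n_mcc = integer(),
                      n_nc = integer(), tlr_ids = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  if (is.null(archs)) archs <- annotate_set(records)
  calls <- data.frame(
    seq_id = records$id, species = records$species,
    category = vapply(archs[records$id],
                      function(a) call_receptor(a)$category, character(1)),
    stringsAsFactors = FALSE)
  tlr <- records[calls$category == "TLR", , drop = FALSE]
  coll <- collapse_redundant(tlr, threshold = identity_threshold)
  kept <- coll$kept
  types <- if (nrow(kept)) data.frame(
    seq_id = kept$id, species = kept$species,
    tlr_type = vapply(kept$id, function(i)
      classify_type(archs[[i]])$tlr_type, character(1)),
    stringsAsFactors = FALSE)
  else data.frame(seq_id = character(), species = character(),
                  tlr_type = character(), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(sort(unique(records$species)), function(sp) {
    ty <- types[types$species == sp, , drop = FALSE]
    data.frame(species = sp, n_tlr = nrow(ty),
               n_scc = sum(ty$tlr_type == "scc"),
               n_mcc = sum(ty$tlr_type == "mcc"),
               n_nc = sum(ty$tlr_type == "NC"),
               tlr_ids = paste(sort(ty$seq_id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  attr(out, "clusters") <- coll$clusters
  attr(out, "types") <- types
  out
}

#' Write the survey table as TSV
#'
#' @param survey Result of \code{\link{survey_proteome}}.
#' @param path Output TSV.
#' @export
write_survey_tsv <- function(survey, path) {
  write.table(survey, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
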