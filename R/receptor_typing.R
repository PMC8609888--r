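#' Classify a TLR as V-type/scc, P-type/mcc or NC
#'
#' P-type/mcc receptors carry two or more LRRCT caps (often an LRRNT as
#' well); V-type/scc receptors carry exactly one LRRCT, located next to the
#' membrane, operationalized here as the cap ending within
#' \code{membrane_proximal_window} residues of the transmembrane start.
#' Fragments (\code{complete = FALSE}), receptors with no detectable LRRCT,
#' and receptors whose single LRRCT is not membrane-proximal cannot be
#' classified (NC): a detection failure must not masquerade as a type. The
#' LRRNT is recorded but never decisive.
#'
#' @param arch A \code{tlr_architecture} that satisfies the TLR calling rule
#'   (TIR + TM + at least one LRR); anything else is an error.
#' @param membrane_proximal_window Maximum distance (residues) between the
#'   LRRCT end and the TM start for the cap to count as membrane-proximal.
#' @return List with \code{seq_id}, \code{tlr_type} (\code{"scc"},
#'   \code{"mcc"} or \code{"NC"}), \code{n_lrrct}, \code{has_lrrnt}.
#' @export
classify_type <- function(arch, membrane_proximal_window = 60L) {
  stopifnot(inherits(arch, "tlr_architecture"))
  if (!(arch$has_tir && arch$has_tm && arch$n_lrr >= 1L))
    stop("classify_type expects a called TLR architecture (TIR + TM + LRR)")
  tlr_type <-
    if (arch$n_lrrct >= 2L) "mcc"
    else if (!arch$complete || arch$n_lrrct == 0L) "NC"
    else {
      ct <- arch$hits[arch$hits$kind == "LRRCT", , drop = FALSE]
      tm <- arch$hits[arch$hits$kind == "TM", , drop = FALSE]
      gap <- tm$start[1L] - ct$end[1L]
      if (gap >= 0L && gap <= membrane_proximal_window) "scc" else "NC"
    }
  list(seq_id = arch$seq_id, tlr_type = tlr_type,
       n_lrrct = arch$n_lrrct, has_lrrnt = arch$has_lrrnt)
}

#' Type every called TLR in an annotated set
#'
#' @param archs List of architectures (only those passing the TLR rule are
#'   typed).
#' @param ... Passed to \code{\link{classify_type}}.
#' @return data.frame: seq_id, tlr_type, n_lrrct, has_lrrnt.
#' @export
classify_set <- function(archs, ...) {
  is_tlr <- vapply(archs, function(a)
    a$has_tir && a$has_tm && a$n_lrr >= 1L, logical(1))
  rows <- lapply(archs[is_tlr], function(a) {
    t <- classify_type(a, ...)
    data.frame(seq_id = t$seq_id, tlr_type = t$tlr_type,
               n_lrrct = t$n_lrrct, has_lrrnt = t$has_lrrnt,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(seq_id = character(), tlr_type = character(),
                  n_lrrct = integer(), has_lrrnt = logical())
  rownames(out) <- NULL
  out
}
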