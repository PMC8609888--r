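# ---- containers -------------------------------------------------------------

#' Create a gene-by-stage count matrix
#'
#' @param counts Non-negative numeric matrix, genes x stages.
#' @param eff_length Positive effective lengths: a matrix of the same shape,
#'   or a per-gene vector recycled across stages.
#' @param stage_order Optional character vector fixing the stage order.
#' @return List of class \code{count_matrix}: \code{counts},
#'   \code{eff_length} (matrix), \code{stages}, \code{genes}.
#' @export
count_matrix <- function(counts, eff_length, stage_order = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (is.null(dim(eff_length)))
    eff_length <- matrix(eff_length, nrow = nrow(counts),
                         ncol = ncol(counts),
                         dimnames = dimnames(counts))
  eff_length <- as.matrix(eff_length)
  if (!all(dim(eff_length) == dim(counts)))
    stop("eff_length shape does not match counts")
  if (any(eff_length <= 0)) stop("effective lengths must be positive")
  if (!is.null(stage_order)) {
    if (!setequal(stage_order, colnames(counts)))
      stop("stage_order does not match count matrix columns")
    counts <- counts[, stage_order, drop = FALSE]
    eff_length <- eff_length[, stage_order, drop = FALSE]
  }
  if (ncol(counts) < 2L)
    stop("at least 2 stages are required for cross-stage normalization")
  structure(list(counts = counts, eff_length = eff_length,
                 stages = colnames(counts), genes = rownames(counts)),
            class = "count_matrix")
}

#' Read a long-format counts TSV
#'
#' Expected columns: \code{gene}, \code{stage}, \code{count},
#' \code{eff_length}. A sample sheet TSV with a \code{stage} column fixes the
#' stage order (and optionally a \code{replicate_group} column groups stages
#' for averaging).
#'
#' @param path Counts TSV.
#' @param sample_sheet Optional sample-sheet TSV.
#' @return A \code{count_matrix}; replicate groups, when present, are
#'   attached as attribute \code{replicate_groups}.
#' @export
read_counts_tsv <- function(path, sample_sheet = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "stage", "count", "eff_length")
  if (!all(need %in% names(df)))
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  genes <- unique(df$gene); stages <- unique(df$stage)
  cm <- matrix(0, length(genes), length(stages),
               dimnames = list(genes, stages))
  el <- cm + 1
  cm[cbind(df$gene, df$stage)] <- df$count
  el[cbind(df$gene, df$stage)] <- df$eff_length
  groups <- NULL
  if (!is.null(sample_sheet)) {
    sh <- read.delim(sample_sheet, stringsAsFactors = FALSE)
    if (!"stage" %in% names(sh)) stop("sample sheet needs a 'stage' column")
    stages <- sh$stage
    if ("replicate_group" %in% names(sh))
      groups <- setNames(sh$replicate_group, sh$stage)
  }
  m <- count_matrix(cm, el, stage_order = stages)
  attr(m, "replicate_groups") <- groups
  m
}

# ---- TPM --------------------------------------------------------------------

#' Transcripts-per-million from counts and effective lengths
#'
#' Per stage: \code{rate = count / eff_length}; \code{TPM = 1e6 * rate /
#' sum(rate)}. Every stage column sums to one million.
#'
#' @param m A \code{count_matrix}.
#' @return Numeric genes-x-stages TPM matrix.
#' @export
tpm_from_counts <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  rate <- m$counts / m$eff_length
  tot <- colSums(rate)
  zero <- which(tot == 0)
  if (length(zero))
    stop("stage(s) with all-zero counts: ",
         paste(m$stages[zero], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

# ---- TMM --------------------------------------------------------------------

#' Trimmed-mean-of-M-values scaling factors across stages
#'
#' Standard TMM scheme applied to the TPM table: the reference stage is the
#' one whose upper-quartile expression is closest to the mean upper quartile
#' (unless given); genes zero in either sample are excluded; log2-ratios (M)
#' are trimmed by 30\% on each tail and average abundances (A) by 5\% on each
#' tail; the factor is the precision-weighted mean of the kept M-values, and
#' the factors are rescaled to geometric mean 1.
#'
#' @param tpm Genes-x-stages TPM (or any positive abundance) matrix.
#' @param ref_stage Optional reference column (name or index).
#' @param logratio_trim,abundance_trim Tail trim fractions.
#' @return Named numeric vector of per-stage scaling factors (divide each
#'   stage column by its factor to normalize).
#' @export
tmm_factors <- function(tpm, ref_stage = NULL, logratio_trim = 0.3,
                        abundance_trim = 0.05) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2L) stop("TMM needs at least 2 stages")
  N <- colSums(tpm)
  uq <- vapply(seq_len(ncol(tpm)), function(k)
    quantile(tpm[, k] / N[k], 0.75, names = FALSE), numeric(1))
  r <- if (is.null(ref_stage)) which.min(abs(uq - mean(uq)))
       else if (is.character(ref_stage)) match(ref_stage, colnames(tpm))
       else as.integer(ref_stage)
  if (is.na(r)) stop("unknown reference stage")
  f <- vapply(seq_len(ncol(tpm)), function(k) {
    if (k == r) return(1)
    ok <- tpm[, k] > 0 & tpm[, r] > 0
    if (!any(ok)) return(1)
    yk <- tpm[ok, k]; yr <- tpm[ok, r]
    # the input is already within-sample normalized (TPM), so M compares
    # the values directly; any residual column-sum difference is exactly
    # the cross-sample effect TMM is meant to absorb
    M <- log2(yk / yr)
    Aval <- 0.5 * log2((yk / N[k]) * (yr / N[r]))
    if (all(abs(M) < 1e-10)) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(Aval, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    w <- (N[k] - yk[keep]) / (N[k] * yk[keep]) +
         (N[r] - yr[keep]) / (N[r] * yr[keep])
    2^(sum(M[keep] / w) / sum(1 / w))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(tpm))
}

#' TPM + cross-stage TMM normalization
#'
#' Computes TPM per stage, then divides each stage column by its TMM scaling
#' factor. When \code{replicate_groups} maps stages to groups, the normalized
#' values of each group's stages are averaged afterwards.
#'
#' @param m A \code{count_matrix}.
#' @param replicate_groups Optional named vector stage -> group label.
#' @param ... Passed to \code{\link{tmm_factors}}.
#' @return Genes-x-stages normalized expression matrix ("TMM units": TPM
#'   scale after cross-stage scaling), with the factors attached as attribute
#'   \code{tmm_factors}.
#' @export
normalize_expression <- function(m, replicate_groups = NULL, ...) {
  tpm <- tpm_from_counts(m)
  f <- tmm_factors(tpm, ...)
  e <- sweep(tpm, 2, f, "/")
  if (is.null(replicate_groups))
    replicate_groups <- attr(m, "replicate_groups")
  if (!is.null(replicate_groups)) {
    grp <- replicate_groups[colnames(e)]
    glev <- unique(grp)
    e <- vapply(glev, function(g)
      rowMeans(e[, grp == g, drop = FALSE]), numeric(nrow(e)))
    colnames(e) <- glev
  }
  attr(e, "tmm_factors") <- f
  e
}

# ---- expression calls -------------------------------------------------------

#' Call expressed/silent per stage and assign temporal classes
#'
#' A gene is expressed at a stage iff its normalized value is at least
#' \code{threshold} (inclusive). Temporal classes: \code{throughout}
#' (expressed at every stage), \code{not_detected} (at none),
#' \code{windowed} (at some but not all); for windowed genes the expressed
#' window's contiguity is reported but not required.
#'
#' @param e Normalized expression matrix (genes x stages).
#' @param threshold Detection threshold, compared inclusively.
#' @return data.frame of class \code{expression_calls}: \code{gene},
#'   \code{temporal_class}, \code{n_expressed}, \code{contiguous}; the
#'   per-stage logical matrix is attached as attribute \code{expressed}.
#' @export
call_expressed <- function(e, threshold = 0.15) {
  e <- as.matrix(e)
  ex <- e >= threshold
  n_st <- ncol(e)
  n_ex <- rowSums(ex)
  cls <- ifelse(n_ex == 0L, "not_detected",
                ifelse(n_ex == n_st, "throughout", "windowed"))
  contiguous <- vapply(seq_len(nrow(ex)), function(i) {
    w <- which(ex[i, ])
    length(w) <= 1L || all(diff(w) == 1L)
  }, logical(1))
  out <- data.frame(gene = rownames(e), temporal_class = cls,
                    n_expressed = as.integer(n_ex), contiguous = contiguous,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "expressed") <- ex
  attr(out, "threshold") <- threshold
  class(out) <- c("expression_calls", class(out))
  out
}

#' Summarize expression calls
#'
#' @param calls Result of \code{\link{call_expressed}}.
#' @return Named integer vector: \code{n_genes}, \code{n_expressed_anywhere},
#'   \code{n_throughout}, \code{n_windowed}, \code{n_not_detected}.
#' @export
summarize_survey <- function(calls) {
  cls <- calls$temporal_class
  c(n_genes = length(cls),
    n_expressed_anywhere = sum(cls != "not_detected"),
    n_throughout = sum(cls == "throughout"),
    n_windowed = sum(cls == "windowed"),
    n_not_detected = sum(cls == "not_detected"))
}

#' Write normalized values and calls in long format
#'
#' Heatmap-ready long table: gene, stage, value, expressed.
#'
#' @param e Normalized matrix.
#' @param calls Result of \code{\link{call_expressed}} on \code{e}.
#' @param path Output TSV.
#' @export
write_expression_tsv <- function(e, calls, path) {
  ex <- attr(calls, "expressed")
  long <- data.frame(
    gene = rep(rownames(e), times = ncol(e)),
    stage = rep(colnames(e), each = nrow(e)),
    value = as.vector(e),
    expressed = as.vector(ex), stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
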