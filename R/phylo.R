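# ---- alignment container ----------------------------------------------------

#' Create a protein alignment
#'
#' Rows are gapped residue strings of equal length; the gap character is
#' \code{"-"}. Columns are indexed 1-based.
#'
#' @param ids Row identifiers (unique).
#' @param seqs Gapped residue strings, equal length.
#' @return List of class \code{tlr_alignment} with \code{ids}, \code{seqs},
#'   \code{n_cols}.
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("alignment row ids must be unique")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all alignment rows must have equal length")
  structure(list(ids = ids, seqs = seqs, n_cols = w),
            class = "tlr_alignment")
}

#' @export
print.tlr_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d columns>\n", length(x$ids), x$n_cols))
  invisible(x)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

aln_from_matrix <- function(m) {
  alignment(rownames(m), apply(m, 1, paste, collapse = ""))
}

#' Read an aligned FASTA
#' @param path Aligned FASTA file.
#' @return A \code{tlr_alignment}.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  alignment(sub("\\s.*$", "", names(ss)), as.character(ss))
}

#' Write an alignment to FASTA
#' @param aln Alignment.
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(aln$seqs, aln$ids)), path)
  invisible(path)
}

keep_columns <- function(aln, cols) {
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  aln_from_matrix(m)
}

# map: for one alignment row, alignment column of each residue position
residue_columns <- function(gapped) {
  which(strsplit(gapped, "")[[1]] != "-")
}

# ---- trimming and masking ---------------------------------------------------

#' Extract the core LRR--TM--TIR column block
#'
#' Deterministic surrogate for a manual alignment trim: for every row, the
#' column of the start of its membrane-proximal LRR (the LRR hit closest
#' upstream of the TM) and the column of its last TIR residue are located;
#' the contiguous block from the median start column to the median end column
#' (medians across rows, rounded down) is kept.
#'
#' @param aln Alignment whose rows are ungapped versions of annotated
#'   sequences.
#' @param archs Named list of architectures (by row id), each with TM and TIR
#'   hits; a missing or TM/TIR-less architecture is an error.
#' @return The trimmed \code{tlr_alignment}.
#' @export
extract_core_columns <- function(aln, archs) {
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(aln$ids)) {
    id <- aln$ids[i]
    a <- archs[[id]]
    if (is.null(a)) stop("no architecture for row '", id, "'")
    if (!a$has_tm || !a$has_tir)
      stop("architecture of '", id, "' lacks a TM or TIR hit")
    cols <- residue_columns(aln$seqs[i])
    tm <- a$hits[a$hits$kind == "TM", , drop = FALSE][1L, ]
    tir <- a$hits[a$hits$kind == "TIR", , drop = FALSE][1L, ]
    lrr <- a$hits[a$hits$kind == "LRR" & a$hits$end < tm$start, ,
                  drop = FALSE]
    if (!nrow(lrr)) stop("no LRR upstream of the TM for row '", id, "'")
    prox <- lrr[which.max(lrr$start), ]
    starts <- c(starts, cols[prox$start])
    ends <- c(ends, cols[min(tir$end, length(cols))])
  }
  from <- floor(median(starts)); to <- floor(median(ends))
  keep_columns(aln, from:to)
}

#' Gap-driven automatic column trimming (gappyout scheme)
#'
#' Computes the per-column gap fraction, sorts the distinct values, places
#' the cutoff at the steepest break of the sorted gap-fraction curve (the
#' largest jump between consecutive distinct values), and removes columns
#' whose gap fraction exceeds the cutoff. Retained columns keep their order.
#'
#' @param aln Alignment with at least 3 columns.
#' @return Trimmed alignment; removing every column is an error.
#' @export
trim_gappyout <- function(aln) {
  if (aln$n_cols < 3L) stop("alignment needs at least 3 columns")
  m <- aln_matrix(aln)
  gf <- colMeans(m == "-")
  v <- sort(unique(gf))
  cutoff <- if (length(v) == 1L) v else {
    jumps <- diff(v)
    v[which.max(jumps)]
  }
  keep <- which(gf <= cutoff)
  if (!length(keep)) stop("gappyout removed every column (degenerate alignment)")
  keep_columns(aln, keep)
}

#' Remove an inclusive column range
#'
#' @param aln Alignment.
#' @param start,end 1-based inclusive column range to remove.
#' @return Alignment with \code{end - start + 1} fewer columns.
#' @export
mask_region <- function(aln, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > aln$n_cols || start > end)
    stop("column range out of bounds: ", start, "..", end,
         " on ", aln$n_cols, " columns")
  keep_columns(aln, setdiff(seq_len(aln$n_cols), start:end))
}

#' Detect which rows carry an insertion in a column window
#'
#' A row is a carrier when at least \code{min_nongap} of the columns
#' \code{start..end} hold non-gap residues.
#'
#' @param aln Alignment.
#' @param start,end 1-based inclusive column window.
#' @param min_nongap Minimum number of non-gap residues in the window.
#' @return Named logical vector over row ids.
#' @export
detect_insertion <- function(aln, start, end, min_nongap = 5L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > aln$n_cols || start > end)
    stop("column range out of bounds")
  m <- aln_matrix(aln)[, start:end, drop = FALSE]
  setNames(rowSums(m != "-") >= min_nongap, aln$ids)
}

# ---- tree building and rooting ----------------------------------------------

#' Pairwise p-distances of an alignment
#'
#' Proportion of differing residues among columns that are non-gap in both
#' rows (pairwise deletion).
#'
#' @param aln Alignment.
#' @return A symmetric distance matrix.
#' @export
p_distances <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop("rows '", aln$ids[i], "' and '", aln$ids[j],
                       "' share no ungapped columns")
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree from an alignment (test-scale tree builder)
#'
#' Neighbor joining on pairwise p-distances. This is the package's
#' deterministic desk-scale substitute for external maximum-likelihood
#' inference; see the methods vignette for the documented external ML
#' commands.
#'
#' @param aln Alignment with at least 3 rows, or a distance matrix.
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
build_nj_tree <- function(aln) {
  d <- if (inherits(aln, "tlr_alignment")) {
    if (length(aln$ids) < 3L) stop("need at least 3 rows to build a tree")
    p_distances(aln)
  } else {
    d <- as.matrix(aln)
    if (nrow(d) < 3L) stop("need at least 3 taxa to build a tree")
    d
  }
  ape::nj(as.dist(d))
}

tip_set <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_set, tree = tree))
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup tips from the rest.
#' The outgroup must form a clade of the unrooted tree; otherwise the
#' offending tips are reported.
#'
#' @param tree An \code{ape::phylo} tree (rooted representation is ignored).
#' @param outgroup_tips Character vector of outgroup tip labels.
#' @return A rooted \code{ape::phylo} tree. Node labels (supports) are
#'   re-attached edge-wise so they stay with the bipartition they annotate.
#' @export
root_with_outgroup <- function(tree, outgroup_tips) {
  outgroup_tips <- unique(as.character(outgroup_tips))
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing))
    stop("outgroup tips not in tree: ", paste(missing, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup_tips)
  if (!length(ingroup)) stop("outgroup cannot contain every tip")
  # monophyly in the unrooted sense: orient from an ingroup tip, then the
  # outgroup must be a clade
  if (length(outgroup_tips) > 1L) {
    probe <- ape::root(tree, outgroup = ingroup[1L], resolve.root = TRUE,
                       edgelabel = TRUE)
    mrca <- ape::getMRCA(probe, outgroup_tips)
    desc <- tip_set(probe, mrca)
    extra <- setdiff(desc, outgroup_tips)
    if (length(extra))
      stop("outgroup is not monophyletic; clade also contains: ",
           paste(sort(extra), collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE,
            edgelabel = TRUE)
}

# ---- clade assignment -------------------------------------------------------

node_support <- function(tree, default_support = 100) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) return(rep(default_support, nnode))
  sup <- suppressWarnings(as.numeric(lab))
  sup[is.na(sup)] <- default_support
  sup
}

#' Assign gene-tree tips to anchored clades
#'
#' For each label, the assignment looks for the largest clade of the rooted
#' tree that (i) contains all of that label's anchor tips, (ii) contains no
#' other label's anchors, and (iii) has stem support strictly greater than
#' \code{support_min}. Tips of that clade receive the label; anchor tips
#' always keep their own label; every other tip is \code{"unassigned"}.
#' Outgroup tips are excluded from the assignment.
#'
#' @param tree Rooted \code{ape::phylo} with bootstrap-style node labels on
#'   the 0--100 scale (missing labels are treated as \code{default_support}).
#' @param anchors Named list: label -> character vector of anchor tips.
#' @param support_min Support threshold (strict \code{>}).
#' @param outgroup Tips to exclude entirely.
#' @param default_support Support assumed for unlabeled nodes.
#' @return List of class \code{clade_assignment}: \code{assignment} (named
#'   character vector tip -> label), \code{counts} (per-label tip counts,
#'   including \code{unassigned}).
#' @export
assign_clades <- function(tree, anchors, support_min = 60,
                          outgroup = character(), default_support = 100) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see root_with_outgroup)")
  labs <- names(anchors)
  if (is.null(labs) || any(!nzchar(labs))) stop("anchors must be a named list")
  all_anchor <- unlist(anchors)
  missing <- setdiff(all_anchor, tree$tip.label)
  if (length(missing))
    stop("anchor tips not in tree: ", paste(missing, collapse = ", "))
  if (length(intersect(all_anchor, outgroup)))
    stop("anchors may not include outgroup tips")
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tips_of <- lapply(nodes, tip_set, tree = tree)
  sup <- node_support(tree, default_support)
  root_node <- ntip + 1L
  sup[1L] <- default_support  # the root has no stem edge

  # anchor consistency: the minimal clade spanning one label's anchors must
  # not contain another label's anchors
  for (a in labs) {
    span <- if (length(anchors[[a]]) > 1L)
      tips_of[[ape::getMRCA(tree, anchors[[a]]) - ntip]]
    else anchors[[a]]
    for (b in setdiff(labs, a)) {
      hit <- intersect(span, anchors[[b]])
      if (length(hit))
        stop("anchors inconsistent with tree: minimal clade of '", a,
             "' contains anchors of '", b, "': ",
             paste(sort(hit), collapse = ", "))
    }
  }

  assignment <- setNames(rep("unassigned", ntip), tree$tip.label)
  for (a in labs) {
    other <- setdiff(all_anchor, anchors[[a]])
    ok <- vapply(seq_along(nodes), function(k) {
      ts <- tips_of[[k]]
      all(anchors[[a]] %in% ts) && !length(intersect(other, ts)) &&
        sup[k] > support_min
    }, logical(1))
    assignment[anchors[[a]]] <- a
    if (any(ok)) {
      sizes <- lengths(tips_of)
      best <- which(ok)[which.max(sizes[ok])]
      members <- setdiff(tips_of[[best]], outgroup)
      assignment[members] <- a
    }
  }
  assignment <- assignment[setdiff(tree$tip.label, outgroup)]
  counts <- table(factor(assignment, levels = c(labs, "unassigned")))
  structure(list(assignment = assignment,
                 counts = as.integer(counts),
                 labels = names(counts)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("<clade assignment>\n")
  print(setNames(x$counts, x$labels))
  invisible(x)
}

#' Write a clade assignment as TSV
#' @param ca A \code{clade_assignment}.
#' @param path Output TSV.
#' @export
write_clades_tsv <- function(ca, path) {
  write.table(data.frame(tip = names(ca$assignment), clade = ca$assignment),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
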