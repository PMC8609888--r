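# Independent oracles used across the suite. Each one deliberately takes a
# different computational route than the package implementation it checks.

# ---- exhaustive global-alignment oracle (affine gaps) -----------------------
# Enumerates every global alignment of a and b (short sequences only),
# scores with match 2 / mismatch -1 / gap opening 10 / extension 0.5
# (penalty for a gap of length L: opening + L * extension, matching
# Biostrings::pairwiseAlignment), and returns the optimal score plus the
# set of identity values achieved by co-optimal alignments.
oracle_align <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf; best$idents <- integer(0)
  go <- function(i, j, score, nid, last) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score) { best$score <- score; best$idents <- nid }
      else if (score == best$score) best$idents <- union(best$idents, nid)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) 2 else -1
      go(i + 1L, j + 1L, score + s, nid + (a[i] == b[j]), "m")
    }
    if (i <= length(a)) {
      pen <- if (identical(last, "da")) 0.5 else 10.5
      go(i + 1L, j, score - pen, nid, "da")
    }
    if (j <= length(b)) {
      pen <- if (identical(last, "db")) 0.5 else 10.5
      go(i, j + 1L, score - pen, nid, "db")
    }
  }
  go(1L, 1L, 0, 0L, "m")
  list(score = best$score,
       identities = best$idents / min(length(a), length(b)))
}

# ---- transitive-closure clustering oracle -----------------------------------
# Single-linkage components from an identity matrix via boolean matrix
# powering (different machinery from the union-find in the package).
oracle_components <- function(idm, threshold) {
  adj <- idm > threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(nrow(adj))
  cid <- 0L
  for (i in seq_len(nrow(adj))) if (!comp[i]) {
    cid <- cid + 1L
    comp[reach[i, ]] <- cid
  }
  comp
}

# ---- brute-force Dollo oracle -----------------------------------------------
# Descendant node list of a node (excluding itself)
.desc_nodes <- function(tree, g) {
  r <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == g, 2]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    r <- c(r, v)
    stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  r
}

.desc_tips <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(v)
  d <- .desc_nodes(tree, v)
  d[d <= ntip]
}

# Minimal loss count: enumerate loss-edge subsets by increasing size for a
# given gain (or over every valid gain when gain is NULL). A tip is present
# iff no chosen loss node lies on its path from the gain, which is checked
# against a precomputed tip x node ancestry matrix. Exponential but fine at
# <= 12 leaves.
oracle_dollo_losses <- function(tree, presence, gain = NULL) {
  ntip <- length(tree$tip.label)
  pres <- as.logical(if (is.null(names(presence))) presence
                     else presence[tree$tip.label])
  present_tips <- which(pres)
  gains <- if (!is.null(gain)) gain
  else Filter(function(v) all(present_tips %in% .desc_tips(tree, v)),
              seq_len(ntip + tree$Nnode))
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  best <- Inf
  for (g in gains) {
    cand <- if (g <= ntip) integer(0) else .desc_nodes(tree, g)
    below <- .desc_tips(tree, g)
    # anc[t, j]: candidate node cand[j] lies on the path gain -> tip t
    anc <- matrix(FALSE, ntip, length(cand))
    for (t in below) {
      v <- t
      while (v != g) { anc[t, match(v, cand)] <- TRUE; v <- parent_of[v] }
    }
    target <- pres
    feasible_tip <- function(sel) {
      state <- logical(ntip)
      state[below] <- !apply(anc[, sel, drop = FALSE], 1, any)[below]
      identical(unname(state), unname(target))
    }
    for (k in 0:length(cand)) {
      if (k >= best) break
      sets <- if (k == 0L) list(integer(0))
      else asplit(combn(seq_along(cand), k), 2)
      hit <- FALSE
      for (s in sets) {
        if (feasible_tip(s)) { best <- min(best, k); hit <- TRUE; break }
      }
      if (hit) break
    }
  }
  best
}

# ---- gappyout cutoff-scan oracle --------------------------------------------
# Scans every possible cutoff and keeps the one maximizing the separation
# between consecutive distinct gap-fraction levels.
oracle_gappyout_removed <- function(gap_fractions) {
  v <- sort(unique(gap_fractions))
  if (length(v) == 1L) return(integer(0))
  cut <- v[which.max(diff(v))]
  which(gap_fractions > cut)
}

# ---- misc helpers -----------------------------------------------------------
random_protein <- function(n,
                           alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# mutate exactly k positions of a sequence (substitutions only)
mutate_seq <- function(s, k) {
  res <- strsplit(s, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos <- sample(length(res), k)
  for (p in pos) res[p] <- sample(setdiff(aa, res[p]), 1)
  paste(res, collapse = "")
}

# a rooted gene tree + labels used by the hypothesis-ranking tests:
# cnidarian TLR tips nested inside clade alpha, gamma sister to beta.
demo_gene_tree <- function() {
  nwk <- paste0(
    "(MyD88_out,((((cn1,cn2)95,(al1,al2)90)92,al3)88,",
    "(((be1,be2)91,be3)87,((ga1,ga2)93,ga3)89)86)99)root;")
  tree <- ape::read.tree(text = nwk)
  clades <- c(cn1 = "alpha", cn2 = "alpha", al1 = "alpha", al2 = "alpha",
              al3 = "alpha", be1 = "beta", be2 = "beta", be3 = "beta",
              ga1 = "gamma", ga2 = "gamma", ga3 = "gamma",
              MyD88_out = "unassigned")
  taxa <- c(cn1 = "Cnidaria", cn2 = "Cnidaria", al1 = "Annelida",
            al2 = "Mollusca", al3 = "Priapulida", be1 = "Craniata",
            be2 = "Echinodermata", be3 = "Annelida", ga1 = "Annelida",
            ga2 = "Brachiopoda", ga3 = "Phoronida",
            MyD88_out = "Craniata")
  list(tree = tree, clades = clades, taxa = taxa)
}
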