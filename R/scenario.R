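# ---- species tree fixture ---------------------------------------------------

#' The fixed metazoan species tree
#'
#' A rooted topology over 22 metazoan groups (Cnidaria, Xenacoelomorpha and
#' the main protostome and deuterostome lineages) with named internal nodes
#' (Planulozoa, Bilateria, Nephrozoa, Protostomia, Ecdysozoa, Spiralia,
#' Trochozoa, Deuterostomia, ...). Alternative topologies can be supplied to
#' every function that takes a species tree by reading any newick with named
#' internal nodes.
#'
#' @return An \code{ape::phylo} tree.
#' @export
metazoan_species_tree <- function() {
  if (!is.null(.pkg_cache$sp_tree)) return(.pkg_cache$sp_tree)
  path <- system.file("extdata", "species_tree_metazoa.nwk",
                      package = "tollscan")
  tr <- ape::read.tree(path)
  .pkg_cache$sp_tree <- tr
  tr
}

# resolve a node given by tip label, internal node label, or number
node_id <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > length(tree$tip.label) + tree$Nnode)
      stop("node number out of range: ", node)
    return(node)
  }
  ntip <- length(tree$tip.label)
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(node, tree$node.label)
  if (!is.na(j)) return(ntip + j)
  stop("no node named '", node, "' in the tree")
}

node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label[node - ntip]
  if (!is.null(lab) && nzchar(lab)) lab else paste0("node", node)
}

children_of <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# ---- presence matrix --------------------------------------------------------

TLR_CHARACTERS <- c("Calpha", "Cbeta", "Cgamma")

#' Build the taxon-by-clade presence matrix
#'
#' A cell is TRUE iff at least one of the taxon's TLRs carries that clade
#' label. Taxa of the species tree with no assigned TLRs get an all-FALSE row
#' (absence of detection).
#'
#' @param clade_table data.frame with columns \code{seq_id}, \code{species}
#'   and \code{clade} (values \code{alpha}/\code{beta}/\code{gamma}; anything
#'   else, e.g. \code{unassigned}, is ignored).
#' @param tree Species tree (default: \code{\link{metazoan_species_tree}}).
#' @param taxon_map Optional named vector mapping species labels to species
#'   tree tips; by default species labels are used as taxa directly.
#' @return Logical matrix, rows = tree tips, columns \code{Calpha},
#'   \code{Cbeta}, \code{Cgamma}.
#' @export
build_presence_matrix <- function(clade_table,
                                  tree = metazoan_species_tree(),
                                  taxon_map = NULL) {
  taxa <- as.character(clade_table$species)
  if (!is.null(taxon_map)) {
    mapped <- taxon_map[taxa]
    taxa <- ifelse(is.na(mapped), taxa, mapped)
  }
  unknown <- setdiff(unique(taxa), tree$tip.label)
  if (length(unknown))
    stop("taxa absent from the species tree: ",
         paste(sort(unknown), collapse = ", "))
  pm <- matrix(FALSE, nrow = length(tree$tip.label),
               ncol = length(TLR_CHARACTERS),
               dimnames = list(tree$tip.label, TLR_CHARACTERS))
  key <- c(alpha = "Calpha", beta = "Cbeta", gamma = "Cgamma")
  for (i in seq_len(nrow(clade_table))) {
    ch <- key[as.character(clade_table$clade[i])]
    if (!is.na(ch)) pm[taxa[i], ch] <- TRUE
  }
  pm
}

#' A representative metazoan presence/absence pattern of the three clades
#'
#' Encodes the qualitative distribution of the three TLR clades across the
#' fixture taxa: clade alpha in cnidarians and most protostomes, clade beta
#' in deuterostomes plus some protostomes, clade gamma confined to trochozoan
#' groups (absent in nemerteans), and total TLR absence in xenacoelomorphs,
#' platyhelminths, gastrotrichs, micrognathozoans and cycliophorans.
#'
#' @return Logical matrix as in \code{\link{build_presence_matrix}}.
#' @export
demo_presence_matrix <- function() {
  tr <- metazoan_species_tree()
  pm <- matrix(FALSE, nrow = length(tr$tip.label), ncol = 3,
               dimnames = list(tr$tip.label, TLR_CHARACTERS))
  alpha <- c("Cnidaria", "Bryozoa", "Annelida", "Mollusca", "Brachiopoda",
             "Nemertea", "Phoronida", "Rotifera", "Priapulida", "Tardigrada",
             "Nematoda", "Loricifera", "Arthropoda")
  beta <- c("Annelida", "Mollusca", "Brachiopoda", "Nemertea", "Phoronida",
            "Onychophora", "Arthropoda", "Tunicata", "Echinodermata",
            "Craniata")
  gamma <- c("Annelida", "Mollusca", "Brachiopoda", "Phoronida")
  pm[alpha, "Calpha"] <- TRUE
  pm[beta, "Cbeta"] <- TRUE
  pm[gamma, "Cgamma"] <- TRUE
  pm
}

# ---- Dollo reconstruction ---------------------------------------------------

# minimal losses below a fixed gain node: edges (u,v) below the gain whose
# child subtree contains no presence while the parent subtree does. When the
# gain subtree holds no presence at all the gene dies immediately (1 loss).
losses_below <- function(tree, gain, presence) {
  ntip <- length(tree$tip.label)
  stopifnot(length(presence) == ntip)
  pres_sub <- function(v) {
    if (v <= ntip) return(presence[v])
    any(vapply(children_of(tree, v), pres_sub, logical(1)))
  }
  if (gain <= ntip) return(if (presence[gain]) integer(0) else gain)
  if (!pres_sub(gain)) return(gain)  # loss on the gain lineage itself
  losses <- integer(0)
  walk <- function(u) {
    for (v in children_of(tree, u)) {
      if (!pres_sub(v)) losses <<- c(losses, v)
      else if (v > ntip) walk(v)
    }
  }
  walk(gain)
  losses
}

as_presence_vec <- function(tree, column) {
  if (is.null(names(column))) {
    stopifnot(length(column) == length(tree$tip.label))
    return(as.logical(column))
  }
  miss <- setdiff(tree$tip.label, names(column))
  if (length(miss))
    stop("presence column misses taxa: ", paste(miss, collapse = ", "))
  as.logical(column[tree$tip.label])
}

#' Dollo reconstruction of one presence/absence character
#'
#' Places the single gain at the most recent common ancestor of all
#' presence taxa (or at a supplied constrained node) and finds the unique
#' minimal set of loss edges explaining every absence below the gain.
#'
#' @param tree Species tree (\code{ape::phylo} with named internal nodes).
#' @param presence Logical vector named by tree tips (or in tip order).
#' @param gain Optional constrained gain node (name or number); must be
#'   ancestral to every presence taxon.
#' @return List of class \code{dollo_events}: \code{gain} (node name),
#'   \code{gain_node} (number), \code{losses} (data.frame: edge child node
#'   name/number), \code{n_losses}, \code{total_events} (gain + losses).
#' @export
dollo_reconstruct <- function(tree, presence, gain = NULL) {
  pres <- as_presence_vec(tree, presence)
  if (!any(pres)) stop("character is absent from every taxon")
  ntip <- length(tree$tip.label)
  present_tips <- which(pres)
  g <- if (is.null(gain)) {
    if (length(present_tips) == 1L) present_tips
    else ape::getMRCA(tree, present_tips)
  } else {
    g <- node_id(tree, gain)
    covered <- if (g <= ntip) tree$tip.label[g] else tip_set(tree, g)
    out <- setdiff(tree$tip.label[present_tips], covered)
    if (length(out))
      stop("gain node not ancestral to presence taxa: ",
           paste(out, collapse = ", "))
    g
  }
  loss_nodes <- losses_below(tree, g, pres)
  losses <- data.frame(
    node = vapply(loss_nodes, node_name, character(1), tree = tree),
    node_id = as.integer(loss_nodes), stringsAsFactors = FALSE)
  structure(list(gain = node_name(tree, g), gain_node = g, losses = losses,
                 n_losses = nrow(losses),
                 total_events = 1L + nrow(losses)),
            class = "dollo_events")
}

#' @export
print.dollo_events <- function(x, ...) {
  cat(sprintf("<Dollo events: gain at %s, %d loss(es)%s>\n", x$gain,
              x$n_losses,
              if (x$n_losses) paste0(" on ",
                                     paste(x$losses$node, collapse = ", "))
              else ""))
  invisible(x)
}

#' Implied loss count for a forced gain placement
#'
#' @inheritParams dollo_reconstruct
#' @param gain Node (name or number) at which the gain is forced; must be
#'   ancestral to every presence taxon.
#' @return Integer loss count.
#' @export
score_gain_placement <- function(tree, presence, gain) {
  dollo_reconstruct(tree, presence, gain = gain)$n_losses
}

#' Reconstruct all three clade characters
#'
#' @param pm Presence matrix from \code{\link{build_presence_matrix}}.
#' @param tree Species tree.
#' @param gains Optional named list/vector of constrained gain nodes per
#'   character.
#' @return Named list of \code{dollo_events} per character column.
#' @export
dollo_reconstruct_all <- function(pm, tree = metazoan_species_tree(),
                                  gains = NULL) {
  out <- lapply(colnames(pm), function(ch)
    dollo_reconstruct(tree, pm[, ch],
                      gain = if (!is.null(gains)) gains[[ch]] else NULL))
  names(out) <- colnames(pm)
  out
}

#' Write an event map as TSV
#'
#' One row per character: character, gain node, comma-joined loss edges
#' (identified by the child node of each edge), total events.
#'
#' @param events Named list of \code{dollo_events}.
#' @param path Output TSV.
#' @export
write_event_map_tsv <- function(events, path) {
  df <- do.call(rbind, lapply(names(events), function(ch) {
    e <- events[[ch]]
    data.frame(character = ch, gain = e$gain,
               losses = paste(e$losses$node, collapse = ","),
               total_events = e$total_events, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Text rendering of a gain/loss-annotated species tree
#'
#' @param events Named list of \code{dollo_events}.
#' @param tree Species tree.
#' @return Character vector of lines (also printed invisibly by cat-ing).
#' @export
format_event_map <- function(events, tree = metazoan_species_tree()) {
  lines <- c("Gain/loss reconstruction on the species tree:")
  for (ch in names(events)) {
    e <- events[[ch]]
    lines <- c(lines,
               sprintf("  %s: gained at %s; lost on %d edge(s)%s",
                       ch, e$gain, e$n_losses,
                       if (e$n_losses)
                         paste0(" (below: ",
                                paste(e$losses$node, collapse = ", "), ")")
                       else ""))
  }
  lines
}

# ---- hypothesis ranking -----------------------------------------------------

# does the span (minimal clade) of 'outer' tips contain all 'inner' tips?
nested_within <- function(tree, inner, outer) {
  if (!length(inner) || length(outer) < 2L) return(FALSE)
  span <- tip_set(tree, ape::getMRCA(tree, outer))
  all(inner %in% span)
}

#' Rank the TLR duplication scenarios
#'
#' Enumerates the scenario families: hypothesis 1A (a single ancestral TLR in
#' the planulozoan ancestor, duplicating into the clade-alpha and
#' clade-beta/gamma genes in the nephrozoan ancestor) versus 1B (both genes
#' already in the planulozoan ancestor, the beta/gamma gene lost in
#' cnidarians); and hypothesis 2A/2B/2C (the beta/gamma duplication in the
#' nephrozoan, spiralian or trochozoan ancestor respectively). Each of the six
#' combinations is scored by its total implied events (gene origins +
#' duplications + Dollo losses); each hypothesis id is also checked for
#' consistency with the assigned gene-tree topology: 1B requires the
#' cnidarian TLRs to nest within clade alpha (1A requires the opposite),
#' and 2B/2C require clade gamma to nest within clade beta's span (2A
#' requires beta and gamma to be non-nested sister groups).
#'
#' @param pm Presence matrix (taxa x Calpha/Cbeta/Cgamma).
#' @param tree Species tree with internal nodes named Planulozoa, Nephrozoa,
#'   Spiralia, Trochozoa.
#' @param gene_tree Rooted gene tree (\code{ape::phylo}).
#' @param gene_clades Named vector tip -> clade label (\code{alpha},
#'   \code{beta}, \code{gamma}, other = unplaced), or a
#'   \code{clade_assignment}.
#' @param gene_taxa Named vector tip -> species-tree taxon (used to find the
#'   cnidarian gene-tree tips).
#' @return data.frame of class \code{hypothesis_ranking}: \code{id},
#'   \code{family}, \code{events} (minimal total events over combinations
#'   containing the hypothesis), \code{gene_tree_consistent}, ordered with
#'   consistent hypotheses first, then ascending events. Attribute
#'   \code{combinations} holds the six combination scores.
#' @export
rank_hypotheses <- function(pm, tree = metazoan_species_tree(), gene_tree,
                            gene_clades, gene_taxa) {
  if (inherits(gene_clades, "clade_assignment"))
    gene_clades <- gene_clades$assignment
  A <- as_presence_vec(tree, pm[, "Calpha"])
  B <- as_presence_vec(tree, pm[, "Cbeta"])
  G <- as_presence_vec(tree, pm[, "Cgamma"])
  BG <- B | G
  ANY <- A | BG
  ntip <- length(tree$tip.label)
  stips <- function(name) tip_set(tree, node_id(tree, name))
  force_true <- function(col, taxa) {
    col[match(taxa, tree$tip.label)] <- TRUE
    col
  }
  lb <- function(gain_name, col)
    length(losses_below(tree, node_id(tree, gain_name), col))
  d2_node <- c(`2A` = "Nephrozoa", `2B` = "Spiralia", `2C` = "Trochozoa")

  combos <- expand.grid(h1 = c("1A", "1B"), h2 = c("2A", "2B", "2C"),
                        stringsAsFactors = FALSE)
  combos$events <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    h1 <- combos$h1[i]; h2 <- combos$h2[i]
    d2 <- d2_node[h2]
    ev <- 0L
    if (h1 == "1B") {
      ev <- ev + 2L  # origin + alpha/(beta-gamma) duplication, pre-Planulozoa
      ev <- ev + lb("Planulozoa", A)
      ev <- ev + lb("Planulozoa", force_true(BG, stips(d2)))
    } else {
      ev <- ev + 2L  # origin at Planulozoa + duplication at Nephrozoa
      ev <- ev + lb("Planulozoa", force_true(ANY, stips("Nephrozoa")))
      ev <- ev + lb("Nephrozoa", A)
      ev <- ev + lb("Nephrozoa", force_true(BG, stips(d2)))
    }
    ev <- ev + 1L  # beta/gamma duplication at the d2 node
    ev <- ev + lb(d2, B)
    ev <- ev + lb(d2, G)
    combos$events[i] <- ev
  }

  # gene-tree consistency
  a_tips <- names(gene_clades)[gene_clades == "alpha"]
  b_tips <- names(gene_clades)[gene_clades == "beta"]
  g_tips <- names(gene_clades)[gene_clades == "gamma"]
  cn_tips <- names(gene_taxa)[gene_taxa == "Cnidaria"]
  cn_tips <- intersect(cn_tips, gene_tree$tip.label)
  cn_in_alpha <- length(cn_tips) > 0 &&
    nested_within(gene_tree, cn_tips, a_tips)
  g_in_b <- nested_within(gene_tree, g_tips, b_tips)
  b_in_g <- nested_within(gene_tree, b_tips, g_tips)
  consistent <- c(`1A` = if (length(cn_tips)) !cn_in_alpha else TRUE,
                  `1B` = if (length(cn_tips)) cn_in_alpha else TRUE,
                  `2A` = !g_in_b && !b_in_g,
                  `2B` = g_in_b,
                  `2C` = g_in_b)

  ids <- c("1A", "1B", "2A", "2B", "2C")
  out <- data.frame(
    id = ids,
    family = c(1L, 1L, 2L, 2L, 2L),
    events = vapply(ids, function(id)
      min(combos$events[combos$h1 == id | combos$h2 == id]), integer(1)),
    gene_tree_consistent = consistent[ids],
    stringsAsFactors = FALSE)
  out <- out[order(-out$gene_tree_consistent, out$events, out$id), ]
  rownames(out) <- NULL
  attr(out, "combinations") <- combos
  class(out) <- c("hypothesis_ranking", class(out))
  out
}

#' Write a hypothesis ranking as TSV
#' @param ranking Result of \code{\link{rank_hypotheses}}.
#' @param path Output TSV.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
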