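# ---- seeded RNG helper ------------------------------------------------------

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ---- sequence building blocks ----------------------------------------------

# canonical 24-aa LRR unit; positions 1,4,6,9,11 are the conserved
# LxxLxLxxNxL anchors, the remainder is motif-neutral and non-hydrophobic
LRR_UNIT_TEMPLATE <- "LKSLDLSSNQLTAGAFEHVPTRVD"
LRR_ANCHOR_POS <- c(1L, 4L, 6L, 9L, 11L)

# cap modules: four cysteines with canonical spacing, motif-neutral otherwise
LRRCT_TEMPLATE <- "PSCANCSSHEPQPMNDKAFEGCTRC"
LRRNT_TEMPLATE <- "GACSPHNCDSRSPENTKGLNACEHC"

TM_ALPHABET <- c("L", "I", "V", "F", "A", "M")
# polar filler: no Cys (would seed cap clusters), no Leu-class residues
# (would seed LRR anchors), hydropathy below the TM threshold
FILLER_ALPHABET <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T")
NOISE_ALPHABET <- setdiff(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), "C")

rand_filler <- function(n) paste(sample(FILLER_ALPHABET, n, replace = TRUE),
                                 collapse = "")

rand_tm <- function(n = 23L) paste(sample(TM_ALPHABET, n, replace = TRUE,
                                          prob = c(.35, .2, .2, .1, .1, .05)),
                                   collapse = "")

sample_tir_segment <- function() {
  prof <- tir_profile()
  alpha <- colnames(prof$freq)[1:20]
  paste(vapply(seq_len(prof$len), function(j)
    sample(alpha, 1L, prob = prof$freq[j, 1:20]), character(1)),
    collapse = "")
}

noisy_lrr_unit <- function(len, noise) {
  u <- strsplit(LRR_UNIT_TEMPLATE, "")[[1]]
  if (len < 24L) u <- u[1:len]
  if (len > 24L) u <- c(u, sample(FILLER_ALPHABET, len - 24L, replace = TRUE))
  if (noise > 0) {
    mut <- setdiff(seq_along(u), LRR_ANCHOR_POS)
    hit <- mut[runif(length(mut)) < noise]
    if (length(hit))
      u[hit] <- sample(setdiff(NOISE_ALPHABET, c("L", "I", "V", "F", "M")),
                       length(hit), replace = TRUE)
  }
  paste(u, collapse = "")
}

# ---- TLR generator ----------------------------------------------------------

#' Generate one synthetic TLR with known architecture
#'
#' Concatenates: an N-terminal polar pad, an optional LRRNT cap (mcc only,
#' probability 0.7), \code{n_lrr} canonical LRR units (length
#' \code{lrr_unit_len}, per-position substitution noise outside the conserved
#' anchors), one (scc) or 2--3 (mcc) LRRCT caps placed per the type
#' definition, a 10-residue juxtamembrane spacer, a 23-residue hydrophobic
#' transmembrane segment, a polar linker, a TIR segment sampled from the
#' bundled seed profile, and a C-terminal pad. All planted coordinates are
#' recorded in the ground truth.
#'
#' @param type \code{"scc"} or \code{"mcc"}.
#' @param n_lrr Number of LRR units (>= 1; mcc needs >= 2 to split across
#'   cap-delimited arrays).
#' @param seed Integer seed (deterministic output).
#' @param noise Per-position substitution probability inside LRR units.
#' @param lrr_unit_len LRR unit length (22--26).
#' @param id,species Record labels.
#' @param fragment When TRUE the N-terminal pad is removed and the sequence
#'   starts inside the first domain, producing an incomplete record.
#' @return List with \code{record} (a \code{\link{seq_record}}) and
#'   \code{truth} (planted type, domain coordinate table, seed).
#' @export
make_tlr_sequence <- function(type = c("scc", "mcc"), n_lrr = 8L, seed = NULL,
                              noise = 0.05, lrr_unit_len = 24L,
                              id = paste0("tlr_", type[1]),
                              species = "synthetic_sp", fragment = FALSE) {
  type <- match.arg(type)
  if (n_lrr < 1L) stop("n_lrr must be >= 1")
  if (lrr_unit_len < 22L || lrr_unit_len > 26L)
    stop("lrr_unit_len must be within 22..26")
  with_seed(seed, {
    parts <- character(0)
    hits <- domain_hits()
    pos <- 0L
    add <- function(segment, kind = NA) {
      parts[[length(parts) + 1L]] <<- segment
      st <- pos + 1L; en <- pos + nchar(segment)
      pos <<- en
      if (!is.na(kind)) {
        # caps: the detectable signal is the first-to-last cysteine span
        if (kind %in% c("LRRNT", "LRRCT")) st <- st + 2L
        hits <<- rbind(hits, domain_hits(kind, st, en, NA_real_))
      }
      invisible(NULL)
    }
    if (!fragment) add(rand_filler(15L))
    n_caps <- if (type == "scc") 1L else sample(2:3, 1L)
    if (type == "mcc" && n_lrr < n_caps) n_caps <- max(2L, n_lrr)
    if (type == "mcc" && n_lrr < 2L)
      stop("mcc needs n_lrr >= 2 (one unit per cap-delimited array)")
    has_nt <- type == "mcc" && runif(1) < 0.7
    if (has_nt) add(LRRNT_TEMPLATE, "LRRNT")
    # split units into n_caps arrays (scc: one array)
    sizes <- if (n_caps == 1L) n_lrr else {
      base <- rep(n_lrr %/% n_caps, n_caps)
      extra <- n_lrr %% n_caps
      if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      base
    }
    for (a in seq_along(sizes)) {
      for (u in seq_len(sizes[a]))
        add(noisy_lrr_unit(lrr_unit_len, noise), "LRR")
      add(LRRCT_TEMPLATE, "LRRCT")
    }
    add(rand_filler(10L))
    add(rand_tm(23L), "TM")
    add(rand_filler(15L))
    add(sample_tir_segment(), "TIR")
    add(rand_filler(15L))
    record <- seq_record(id, species, paste(parts, collapse = ""))
    truth <- list(id = id, type = type, n_lrr = as.integer(n_lrr),
                  n_lrrct = n_caps, has_lrrnt = has_nt,
                  fragment = fragment, hits = hits, seed = seed)
    list(record = record, truth = truth)
  })
}

#' Generate a background protein without TLR-related signals
#'
#' Uniform 20-letter composition; regions that would trigger the LRR or
#' transmembrane detectors by chance are resampled so the planted truth
#' (no domains) holds. The TIR profile score is deliberately NOT screened,
#' so these sequences remain a fair background set for calibrating the TIR
#' false-positive rate.
#'
#' @param len Sequence length.
#' @param id,species Record labels.
#' @return A \code{\link{seq_record}}.
#' @export
make_background_protein <- function(len = 300L, id = "bg", species = "synthetic_sp") {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (try in 1:50) {
    res <- paste(sample(alpha, len, replace = TRUE), collapse = "")
    rec <- seq_record(id, species, res)
    if (nrow(find_transmembrane(rec))) next
    if (nrow(find_lrr_repeats(rec))) next
    return(rec)
  }
  stop("could not generate a clean background protein")
}

make_tlr_like <- function(kind = c("tir_only", "lrr_only"), id, species,
                          n_lrr = 6L, noise = 0) {
  kind <- match.arg(kind)
  if (kind == "tir_only") {
    res <- paste0(rand_filler(30L), sample_tir_segment(), rand_filler(30L))
  } else {
    units <- vapply(seq_len(n_lrr), function(i) noisy_lrr_unit(24L, noise),
                    character(1))
    res <- paste0(rand_filler(30L), paste(units, collapse = ""),
                  rand_filler(30L))
  }
  seq_record(id, species, res)
}

#' Generate a proteome with planted receptors and ground truth
#'
#' Mixes planted TLRs (alternating scc/mcc), TIR-only and LRR-only decoys,
#' clean background proteins, and isoform pairs: for each pair one planted
#' TLR is duplicated and mutated (substitutions only, outside the critical
#' anchors) to a target identity so the redundancy collapse has work to do.
#'
#' @param n_tlr,n_tir_only,n_lrr_only,n_background Counts of each class.
#' @param isoform_pairs Number of TLRs to duplicate as isoforms.
#' @param seed Integer seed.
#' @param species Species label applied to every record.
#' @param noise LRR noise passed to \code{\link{make_tlr_sequence}}.
#' @param target_identity Identity aimed for by isoform mutation.
#' @return List with \code{records} (record-set data.frame) and \code{truth}
#'   (data.frame: id, category, tlr_type, cluster; plus per-TLR coordinate
#'   tables in attribute \code{hits}).
#' @export
make_proteome <- function(n_tlr = 3L, n_tir_only = 2L, n_lrr_only = 2L,
                          n_background = 10L, isoform_pairs = 0L,
                          seed = NULL, species = "synthetic_sp", noise = 0,
                          target_identity = 0.95) {
  stopifnot(n_tlr >= 0, n_tir_only >= 0, n_lrr_only >= 0, n_background >= 0,
            isoform_pairs <= n_tlr)
  with_seed(seed, {
    recs <- list(); rows <- list(); hits <- list()
    addrow <- function(id, category, tlr_type, cluster)
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, category = category, tlr_type = tlr_type,
        cluster = cluster, stringsAsFactors = FALSE)
    tlrs <- list()
    for (i in seq_len(n_tlr)) {
      ty <- if (i %% 2L == 1L) "scc" else "mcc"
      sim <- make_tlr_sequence(ty, n_lrr = if (ty == "scc") 8L else 6L,
                               noise = noise,
                               id = sprintf("tlr%02d", i), species = species)
      tlrs[[i]] <- sim
      recs[[length(recs) + 1L]] <- sim$record
      hits[[sim$record$id]] <- sim$truth$hits
      addrow(sim$record$id, "TLR", sim$truth$type, sim$record$id)
    }
    for (i in seq_len(isoform_pairs)) {
      base <- tlrs[[i]]
      res <- strsplit(base$record$residues, "")[[1]]
      protected <- unlist(lapply(seq_len(nrow(base$truth$hits)), function(k) {
        h <- base$truth$hits[k, ]
        if (h$kind %in% c("TM", "LRRCT", "LRRNT")) seq(h$start, h$end)
        else if (h$kind == "LRR")
          h$start - 1L + LRR_ANCHOR_POS
        else integer(0)
      }))
      mutable <- setdiff(seq_along(res), protected)
      k <- round((1 - target_identity) * length(res))
      mut <- sample(mutable, min(k, length(mutable)))
      for (p in mut)
        res[p] <- sample(setdiff(NOISE_ALPHABET, res[p]), 1L)
      iso_id <- paste0(base$record$id, "_iso")
      recs[[length(recs) + 1L]] <-
        seq_record(iso_id, species, paste(res, collapse = ""))
      addrow(iso_id, "TLR", base$truth$type, base$record$id)
    }
    for (i in seq_len(n_tir_only)) {
      r <- make_tlr_like("tir_only", sprintf("tironly%02d", i), species)
      recs[[length(recs) + 1L]] <- r
      addrow(r$id, "TIR_ONLY", NA_character_, r$id)
    }
    for (i in seq_len(n_lrr_only)) {
      r <- make_tlr_like("lrr_only", sprintf("lrronly%02d", i), species)
      recs[[length(recs) + 1L]] <- r
      addrow(r$id, "LRR_ONLY", NA_character_, r$id)
    }
    for (i in seq_len(n_background)) {
      r <- make_background_protein(sample(200:500, 1L),
                                   sprintf("bg%03d", i), species)
      recs[[length(recs) + 1L]] <- r
      addrow(r$id, "NONE", NA_character_, r$id)
    }
    records <- record_set(vapply(recs, `[[`, character(1), "id"),
                          vapply(recs, `[[`, character(1), "species"),
                          vapply(recs, `[[`, character(1), "residues"))
    truth <- do.call(rbind, rows)
    attr(truth, "hits") <- hits
    list(records = records, truth = truth, seed = seed)
  })
}

# ---- clade-evolution simulator ----------------------------------------------

#' Gain node presets for the named duplication scenarios
#'
#' @param h1 \code{"1A"} or \code{"1B"} (both imply the clade-alpha gene by
#'   the planulozoan ancestor; they differ in gene-tree expectations, not in
#'   the leaf pattern).
#' @param h2 \code{"2A"}, \code{"2B"} or \code{"2C"}: the beta/gamma split at
#'   Nephrozoa, Spiralia or Trochozoa.
#' @return Named character vector: character -> gain node name.
#' @export
scenario_gains <- function(h1 = "1B", h2 = "2A") {
  d2 <- c(`2A` = "Nephrozoa", `2B` = "Spiralia", `2C` = "Trochozoa")[h2]
  c(Calpha = "Planulozoa", Cbeta = unname(d2), Cgamma = unname(d2))
}

#' Simulate presence/absence evolution of the clade characters
#'
#' Each character is gained once (at a supplied or random internal node) and
#' then lost independently on descendant edges with probability
#' \code{loss_rate}; lost lineages never regain the character (Dollo).
#'
#' @param tree Species tree.
#' @param characters Character names (matrix columns).
#' @param loss_rate Per-edge loss probability in [0, 1).
#' @param seed Integer seed.
#' @param gains Optional named vector character -> gain node name; missing
#'   entries get a random internal gain node.
#' @param forced_losses Optional named list character -> node names whose
#'   stem edge is forced to lose the character (for deterministic layouts).
#' @return List with \code{matrix} (tips x characters logical) and
#'   \code{truth} (per character: gain node and realized loss edges).
#' @export
simulate_clade_evolution <- function(tree = metazoan_species_tree(),
                                     characters = TLR_CHARACTERS,
                                     loss_rate = 0.1, seed = NULL,
                                     gains = NULL, forced_losses = NULL) {
  if (loss_rate < 0 || loss_rate >= 1) stop("loss_rate must be in [0, 1)")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    pm <- matrix(FALSE, ntip, length(characters),
                 dimnames = list(tree$tip.label, characters))
    truth <- list()
    for (ch in characters) {
      g <- if (!is.null(gains) && !is.na(gains[ch])) node_id(tree, gains[ch])
           else ntip + sample(tree$Nnode, 1L)
      forced <- if (!is.null(forced_losses) && ch %in% names(forced_losses))
        vapply(forced_losses[[ch]], node_id, integer(1), tree = tree)
      else integer(0)
      losses <- integer(0)
      state <- logical(ntip)
      walk <- function(v, alive) {
        lost <- alive && (v %in% forced || runif(1) < loss_rate)
        if (lost && alive) losses <<- c(losses, v)
        alive <- alive && !lost
        if (v <= ntip) state[v] <<- alive
        else for (k in children_of(tree, v)) walk(k, alive)
      }
      if (g <= ntip) state[g] <- TRUE
      else for (k in children_of(tree, g)) walk(k, TRUE)
      pm[, ch] <- state
      truth[[ch]] <- list(gain = node_name(tree, g), gain_node = g,
                          loss_nodes = vapply(losses, node_name, character(1),
                                              tree = tree))
    }
    list(matrix = pm, truth = truth, seed = seed)
  })
}

# ---- alignment simulator ----------------------------------------------------

#' Simulate an alignment with a planted insertion window
#'
#' Carrier rows hold residues across the whole window; non-carriers are fully
#' gapped there. Outside the window every row derives from a common sampled
#' consensus with substitution noise and random gaps.
#'
#' @param n_carriers,n_noncarriers Row counts.
#' @param n_cols Alignment width.
#' @param window Integer pair c(start, end), 1-based inclusive.
#' @param seed Integer seed.
#' @param gap_fraction Per-cell gap probability outside the window.
#' @param sub_rate Per-cell substitution probability outside the window.
#' @return List with \code{aln} (a \code{tlr_alignment}) and \code{truth}
#'   (carrier ids).
#' @export
simulate_alignment_with_insertion <- function(n_carriers = 10L,
                                              n_noncarriers = 5L,
                                              n_cols = 400L,
                                              window = c(349L, 354L),
                                              seed = NULL,
                                              gap_fraction = 0.05,
                                              sub_rate = 0.1) {
  stopifnot(length(window) == 2L, window[1] >= 1L, window[2] <= n_cols,
            window[1] <= window[2])
  with_seed(seed, {
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    consensus <- sample(alpha, n_cols, replace = TRUE)
    n <- n_carriers + n_noncarriers
    ids <- sprintf("row%02d", seq_len(n))
    carriers <- ids[seq_len(n_carriers)]
    win <- window[1]:window[2]
    rows <- vapply(seq_len(n), function(i) {
      r <- consensus
      sub <- runif(n_cols) < sub_rate
      r[sub] <- sample(alpha, sum(sub), replace = TRUE)
      gap <- runif(n_cols) < gap_fraction
      gap[win] <- FALSE
      r[gap] <- "-"
      if (i > n_carriers) r[win] <- "-"
      paste(r, collapse = "")
    }, character(1))
    list(aln = alignment(ids, rows), truth = list(carriers = carriers),
         seed = seed)
  })
}

# ---- expression simulator ---------------------------------------------------

#' Simulate a stage-by-gene count matrix with planted expression classes
#'
#' Target genes are planted as \code{throughout} (expressed at every stage),
#' \code{windowed} (expressed in a contiguous random window) or \code{silent}.
#' Counts are negative-binomial on top of a pool of background genes;
#' per-stage library sizes vary up to \code{libsize_fold}. The generator then
#' enforces its own statement: realized TPM of an expressed gene-stage is at
#' least \code{threshold * margin} and of a silent gene-stage at most
#' \code{threshold / margin} (counts are minimally adjusted when a draw
#' crosses the line), so the planted temporal classes are guaranteed to be
#' recoverable whenever margin-cleared data are analyzed.
#'
#' @param n_genes Number of target genes (ignored when
#'   \code{expressed_profiles} is a full specification).
#' @param stages Stage names (>= 2).
#' @param expressed_profiles Either a named list
#'   \code{list(throughout=, windowed=, silent=)} of class counts (summing to
#'   \code{n_genes}), or a named list gene -> logical vector over stages.
#' @param libsize_fold Maximum fold-variation of per-stage library size.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion.
#' @param margin Multiplicative clearance around the threshold.
#' @param threshold Detection threshold the margins refer to.
#' @param n_background Background gene count.
#' @return List with \code{m} (a \code{\link{count_matrix}}) and \code{truth}
#'   (per-gene intended class and expressed-stage pattern).
#' @export
simulate_expression <- function(n_genes = 12L,
                                stages = sprintf("S%02d", 1:19),
                                expressed_profiles = NULL,
                                libsize_fold = 3, seed = NULL,
                                dispersion = 0.1, margin = 2,
                                threshold = 0.15, n_background = 100L) {
  if (libsize_fold < 1) stop("libsize_fold must be >= 1")
  n_st <- length(stages)
  if (n_st < 2L) stop("need at least 2 stages")
  with_seed(seed, {
    # resolve planted patterns
    if (is.null(expressed_profiles))
      expressed_profiles <- list(
        throughout = max(1L, round(n_genes / 3)),
        windowed = max(1L, round(n_genes / 3)),
        silent = n_genes - max(1L, round(n_genes / 3)) * 2L)
    patterns <- list()
    if (all(names(expressed_profiles) %in%
            c("throughout", "windowed", "silent")) &&
        all(vapply(expressed_profiles, length, integer(1)) == 1L)) {
      gi <- 0L
      for (cls in names(expressed_profiles)) {
        for (i in seq_len(expressed_profiles[[cls]])) {
          gi <- gi + 1L
          pat <- switch(cls,
            throughout = rep(TRUE, n_st),
            silent = rep(FALSE, n_st),
            windowed = {
              w <- sort(sample(n_st, 2L))
              if (w[1] == 1L && w[2] == n_st) w[2] <- n_st - 1L
              p <- rep(FALSE, n_st); p[w[1]:w[2]] <- TRUE; p
            })
          patterns[[sprintf("gene%02d", gi)]] <- pat
        }
      }
    } else {
      patterns <- lapply(expressed_profiles, function(p) {
        stopifnot(length(p) == n_st)
        as.logical(p)
      })
      if (is.null(names(patterns)))
        names(patterns) <- sprintf("gene%02d", seq_along(patterns))
    }
    genes <- names(patterns)
    bg <- sprintf("bg%03d", seq_len(n_background))
    all_genes <- c(genes, bg)
    len <- setNames(c(rep(2000, length(genes)), rep(500, n_background)),
                    all_genes)
    bg_rate <- runif(n_background, 0.5, 2)
    # target TPM levels: 2x headroom beyond the enforced margin
    v_on <- threshold * margin * 2
    v_off <- threshold / (margin * 2)
    depth <- round(3e5 * exp(runif(n_st, -log(libsize_fold) / 2,
                                   log(libsize_fold) / 2)))
    counts <- matrix(0, length(all_genes), n_st,
                     dimnames = list(all_genes, stages))
    elen <- matrix(len[all_genes], length(all_genes), n_st,
                   dimnames = list(all_genes, stages))
    sum_bg_rate <- sum(bg_rate)
    read_w_bg <- sum(bg_rate * 500)
    for (s in seq_len(n_st)) {
      counts[bg, s] <- rnbinom(n_background, mu = depth[s] * bg_rate * 500 /
                                 (read_w_bg), size = 1 / dispersion)
      for (g in genes) {
        v <- if (patterns[[g]][s]) v_on else v_off
        rate <- v / 1e6 * sum_bg_rate
        mu <- depth[s] * rate * len[g] / read_w_bg
        counts[g, s] <- rnbinom(1L, mu = mu, size = 1 / dispersion)
      }
      # enforce the stated margins on realized TPM (iterate: the targets are
      # a tiny share of the column, so this converges immediately)
      for (it in 1:5) {
        rate_col <- counts[, s] / elen[, s]
        tot <- sum(rate_col)
        tpmc <- 1e6 * rate_col / tot
        bad <- FALSE
        for (g in genes) {
          if (patterns[[g]][s] && tpmc[g] < threshold * margin * 1.2) {
            counts[g, s] <- ceiling(threshold * margin * 1.25 / 1e6 *
                                      tot * len[g])
            bad <- TRUE
          } else if (!patterns[[g]][s] &&
                     tpmc[g] > threshold / (margin * 1.2)) {
            counts[g, s] <- floor(threshold / (margin * 1.25) / 1e6 *
                                    tot * len[g])
            bad <- TRUE
          }
        }
        if (!bad) break
      }
    }
    cls <- vapply(patterns, function(p)
      if (all(p)) "throughout" else if (!any(p)) "not_detected"
      else "windowed", character(1))
    truth <- list(genes = genes,
                  class = setNames(cls, genes),
                  pattern = patterns)
    list(m = count_matrix(counts, elen), truth = truth, seed = seed)
  })
}

#' Serialize ground truth next to a generated dataset
#'
#' @param truth Any generator's \code{truth} component.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
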