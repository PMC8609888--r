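test_that("extract_core_columns keeps the LRR-to-TIR block", {
  sim <- make_tlr_sequence("scc", n_lrr = 8, seed = 1, noise = 0)
  ids <- c("r1", "r2", "r3")
  aln <- alignment(ids, rep(sim$record$residues, 3))
  arch <- annotate_architecture(sim$record)
  archs <- setNames(lapply(ids, function(i) { a <- arch; a$seq_id <- i; a }),
                    ids)
  core <- extract_core_columns(aln, archs)
  lrr <- arch$hits[arch$hits$kind == "LRR", ]
  tm <- arch$hits[arch$hits$kind == "TM", ]
  tir <- arch$hits[arch$hits$kind == "TIR", ]
  prox_start <- max(lrr$start[lrr$end < tm$start])
  expect_equal(core$n_cols, tir$end - prox_start + 1L)
  # idempotent on its own output (architectures re-annotated on the core)
  core_rec <- seq_record("c1", "sp", core$seqs[1])
  core_arch <- annotate_architecture(core_rec)
  expect_true(core_arch$has_tm && core_arch$has_tir)

  # a row lacking a TIR is a precondition failure
  archs_bad <- archs
  archs_bad$r2$has_tir <- FALSE
  expect_error(extract_core_columns(aln, archs_bad), "TIR")
  expect_error(extract_core_columns(aln, archs[1:2]), "architecture")
})

test_that("trim_gappyout removes the gappy column block and nothing else", {
  set.seed(3)
  clean <- replicate(10, random_protein(100))
  aln <- alignment(sprintf("s%02d", 1:10), clean)
  expect_equal(trim_gappyout(aln)$n_cols, 100L)  # gap-free: unchanged

  # 80 clean columns, 20 columns at 90% gaps
  m <- tollscan:::aln_matrix(aln)
  gappy_cols <- sample(100, 20)
  for (j in gappy_cols) m[sample(10, 9), j] <- "-"
  aln2 <- tollscan:::aln_from_matrix(m)
  gf <- colMeans(m == "-")
  removed_oracle <- oracle_gappyout_removed(gf)
  expect_setequal(removed_oracle, gappy_cols)
  trimmed <- trim_gappyout(aln2)
  expect_equal(trimmed$n_cols, 80L)
  # projection property: retained columns identical and in order
  kept <- setdiff(seq_len(100), gappy_cols)
  expect_equal(tollscan:::aln_matrix(trimmed),
               m[, kept], ignore_attr = TRUE)

  # a single fully gapped column among clean ones is removed
  m3 <- tollscan:::aln_matrix(aln)
  m3[, 50] <- "-"
  expect_equal(trim_gappyout(tollscan:::aln_from_matrix(m3))$n_cols, 99L)
})

test_that("mask_region removes exactly the inclusive range", {
  set.seed(4)
  aln <- alignment(c("a", "b"), replicate(2, random_protein(375)))
  expect_equal(mask_region(aln, 349, 354)$n_cols, 375L - 6L)
  expect_equal(mask_region(aln, 150, 220)$n_cols, 304L)
  m1 <- mask_region(aln, 1, 1)
  expect_equal(m1$n_cols, 374L)
  expect_equal(substr(m1$seqs[1], 1, 10), substr(aln$seqs[1], 2, 11))
  expect_error(mask_region(aln, 370, 380), "out of bounds")
  expect_error(mask_region(aln, 0, 5), "out of bounds")
})

test_that("detect_insertion flags carriers and is monotone in min_nongap", {
  sim <- simulate_alignment_with_insertion(10, 5, 400, c(349, 354), seed = 5)
  carriers <- detect_insertion(sim$aln, 349, 354)
  expect_setequal(names(carriers)[carriers], sim$truth$carriers)
  # fully gapped window rows are FALSE
  expect_false(any(carriers[setdiff(names(carriers), sim$truth$carriers)]))
  # monotone: raising min_nongap never flips FALSE -> TRUE
  for (k in 1:6) {
    lo <- detect_insertion(sim$aln, 349, 354, min_nongap = k)
    hi <- detect_insertion(sim$aln, 349, 354, min_nongap = k + 1L)
    expect_true(all(lo | !hi))
  }
})

test_that("neighbor joining recovers additive topologies", {
  # explicit 4-taxon additive matrix satisfying the four-point condition:
  # ((A,B),(C,D)) with internal edge 2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3          # 1 + 2
  d["C", "D"] <- d["D", "C"] <- 5          # 2 + 3
  d["A", "C"] <- d["C", "A"] <- 1 + 2 + 2  # via internal edge
  d["A", "D"] <- d["D", "A"] <- 1 + 2 + 3
  d["B", "C"] <- d["C", "B"] <- 2 + 2 + 2
  d["B", "D"] <- d["D", "B"] <- 2 + 2 + 3
  tr <- build_nj_tree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want))[1], 0)

  # random additive matrices from simulated trees, up to 12 taxa
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    sim_tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(sim_tr)
    rec <- build_nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(sim_tr))[1], 0)
  }

  expect_error(build_nj_tree(d[1:2, 1:2]), "3")
  # 3 taxa: the unique unrooted topology
  tr3 <- build_nj_tree(d[1:3, 1:3])
  expect_equal(length(tr3$tip.label), 3L)
})

test_that("p-distances ignore columns gapped in either row", {
  aln <- alignment(c("a", "b"), c("AC-DE", "ACQD-"))
  d <- p_distances(aln)
  expect_equal(d["a", "b"], 0)  # comparable columns 1,2,4 all equal
  aln2 <- alignment(c("a", "b"), c("ACADE", "ACQDE"))
  expect_equal(p_distances(aln2)["a", "b"], 0.2)
})

test_that("root_with_outgroup places and validates the root", {
  tr <- ape::read.tree(text = "(((t1,t2),t3),(og1,og2),t4);")
  rooted <- root_with_outgroup(tr, c("og1", "og2"))
  expect_true(ape::is.rooted(rooted))
  kids <- tollscan:::children_of(rooted, length(rooted$tip.label) + 1L)
  sides <- lapply(kids, tollscan:::tip_set, tree = rooted)
  expect_true(any(vapply(sides, function(s)
    setequal(s, c("og1", "og2")), logical(1))))

  # single-tip outgroup
  tr2 <- ape::read.tree(text = "((t1,t2),(t3,t4),og);")
  expect_true(ape::is.rooted(root_with_outgroup(tr2, "og")))

  # split outgroup is rejected with the offending tips listed
  tr3 <- ape::read.tree(text = "((og1,t1),(og2,t2),t3);")
  expect_error(root_with_outgroup(tr3, c("og1", "og2")), "monophyletic")
  expect_error(root_with_outgroup(tr, c("og1", "nope")), "not in tree")
})

test_that("assign_clades honours anchors, support and the strict threshold", {
  # three supported clades: alpha (a1..a3), beta (b1..b3), gamma (g1..g3)
  nwk <- paste0("(og,((a1,(a2,a3)90)95,((b1,(b2,b3)80)85,",
                "((g1,g2)70,g3)75)65)99)root;")
  tr <- ape::read.tree(text = nwk)
  anchors <- list(alpha = c("a1", "a2"), beta = c("b1", "b2"),
                  gamma = c("g1", "g2"))
  ca <- assign_clades(tr, anchors, support_min = 60, outgroup = "og")
  expect_equal(unname(ca$assignment[c("a3", "b3", "g3")]),
               c("alpha", "beta", "gamma"))
  expect_false("og" %in% names(ca$assignment))
  expect_equal(sum(ca$assignment == "unassigned"), 0L)

  # stem support exactly at the threshold: non-anchor tips stay unassigned
  nwk2 <- "(og,((a1,(a2,a3)90)60,(b1,b2)95)99)root;"
  tr2 <- ape::read.tree(text = nwk2)
  ca2 <- assign_clades(tr2, list(alpha = c("a1", "a2"), beta = c("b1", "b2")),
                       support_min = 60, outgroup = "og")
  expect_equal(unname(ca2$assignment["a3"]), "unassigned")
  expect_equal(unname(ca2$assignment["a1"]), "alpha")  # anchors keep labels

  # a tip attached between the clades' stems stays unassigned
  nwk3 <- "(og,(stray,((a1,a2)90,(b1,b2)90)80)99)root;"
  tr3 <- ape::read.tree(text = nwk3)
  ca3 <- assign_clades(tr3, list(alpha = c("a1", "a2"), beta = c("b1", "b2")),
                       support_min = 60, outgroup = "og")
  expect_equal(unname(ca3$assignment["stray"]), "unassigned")

  # interleaved anchors are inconsistent with the tree
  expect_error(
    assign_clades(tr3, list(alpha = c("a1", "b1"), beta = c("a2", "b2")),
                  outgroup = "og"),
    "inconsistent")
})

test_that("assign_clades is invariant to tip rotations", {
  nwk <- "(og,((a1,(a2,a3)90)95,(b1,(b2,b3)80)85)99)root;"
  tr <- ape::read.tree(text = nwk)
  anchors <- list(alpha = c("a1", "a2"), beta = c("b1", "b2"))
  ca1 <- assign_clades(tr, anchors, outgroup = "og")
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  ca2 <- assign_clades(tr_rot, anchors, outgroup = "og")
  expect_equal(ca1$assignment[sort(names(ca1$assignment))],
               ca2$assignment[sort(names(ca2$assignment))])
})
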