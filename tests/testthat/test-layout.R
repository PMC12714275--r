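test_that("post-order y assignment matches hand-computed means", {
  b <- build_backbone(net_cherry(), "combining")
  y <- assign_y(b)
  expect_equal(unname(y[c(2, 3, 1)]), c(0, 1, 0.5))
  # caterpillar ((a,b),c)
  net <- parse_extended_newick("((a,b),c);")[[1]]
  b <- build_backbone(net, "combining")
  yc <- assign_y(b, "children")
  yl <- assign_y(b, "leaves")
  expect_equal(unname(yc[net$root]), 1.25)   # mean(0.5, 2)
  expect_equal(unname(yl[net$root]), 1.0)    # mean(0, 1, 2)
  # leaves get pairwise distinct integers
  lv <- net$taxa
  expect_setequal(yc[lv], 0:2)
})

test_that("y assignment agrees with the independent recursive oracle", {
  for (s in 1:10) {
    net <- random_network(sample(4:12, 1), sample(0:3, 1), seed = 700 + s)
    b <- build_backbone(net, "combining")
    for (m in c("children", "leaves"))
      expect_equal(assign_y(b, m), oracle_y(b, m),
                   info = paste("seed", 700 + s, m))
  }
})

test_that("depths are maximum edge counts from the root", {
  net <- net_cherry()
  d <- compute_depths(net)
  expect_equal(unname(d[c(1, 2, 3)]), c(0, 1, 1))
  dia <- net_diamond()
  d <- compute_depths(dia)
  expect_equal(unname(d[4]), 2)  # max over the two paths
  chain <- phylo_network(data.frame(from = 1:5, to = 2:6),
                         taxa = c(a = 6L), root = 1L)
  # chain has through nodes; depths still well defined
  expect_equal(unname(compute_depths(chain)[6]), 5)
})

test_that("transfer-depth adjustment raises sources and propagates", {
  # transfer edge (2,6) with d(2)=1 < d(6)=3; subtree of 2 shifts
  net <- phylo_network(
    data.frame(from = c(1, 2, 1, 4, 5, 2, 6),
               to   = c(2, 3, 4, 5, 6, 6, 7),
               acceptor = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)),
    taxa = c(a = 3L, b = 7L), root = 1L)
  d0 <- compute_depths(net)
  expect_equal(unname(d0[1:7]), c(0, 1, 2, 1, 2, 3, 4))
  d <- adjust_transfer_depths(net, d0)
  expect_equal(unname(d[1:7]), c(0, 3, 4, 1, 2, 3, 4))
  # no transfer edges: identity
  tr <- random_network(6, 0, seed = 2)
  d1 <- compute_depths(tr)
  expect_identical(adjust_transfer_depths(tr, d1), d1)
})

test_that("transfer-depth fixpoint equals the constraint-repair oracle", {
  set.seed(5)
  for (s in 1:10) {
    net <- random_network(sample(6:14, 1), sample(1:3, 1), seed = 800 + s,
                          acceptors = TRUE)
    d0 <- compute_depths(net)
    d <- adjust_transfer_depths(net, d0)
    expect_equal(d, oracle_depth_fixpoint(net, d0),
                 info = paste("seed", 800 + s))
    kinds <- phynetdraw:::edge_kinds(net)
    trf <- which(kinds == "transfer")
    expect_true(all(d[net$edges$from[trf]] >= d[net$edges$to[trf]]))
  }
})

test_that("phylogram x honors weights exactly and offsets combining nodes", {
  net <- phylo_network(data.frame(from = c(1, 1), to = c(2, 3),
                                  weight = c(2.5, 1)),
                       taxa = c(a = 2L, b = 3L), root = 1L)
  x <- assign_x_phylogram(net)
  expect_equal(unname(x[2]), 2.5)
  # combining node: max of parents + delta
  dia <- net_diamond()
  dia$edges$weight <- c(1, 3, 2, NA, 1)  # weights on tree edges; 3->4 retic
  dia$edges$weight[3] <- 2               # 2->4 reticulate too (both retic)
  # both in-edges of 4 are reticulate: no weight needed on them
  dia$edges$weight <- c(1, 3, NA, NA, 1)
  x <- assign_x_phylogram(dia, delta = 0.1)
  expect_equal(unname(x[4]), 3.1)
  expect_equal(unname(x[5]), 4.1)
  # missing weight on a tree edge errors with the edge named
  bad <- net_cherry()
  expect_error(assign_x_phylogram(bad), "missing weight.*1 -> 2")
})

test_that("all-zero weights collapse tree nodes to 0, reticulations to delta", {
  net <- net_retic_example()
  net$edges$weight <- 0
  x <- assign_x_phylogram(net, delta = 0.25)
  r <- net$nodes[vapply(net$nodes, function(v)
    sum(net$edges$to == v) >= 2, logical(1))]
  treeish <- setdiff(net$nodes, c(r, net$taxa[["b"]]))
  expect_true(all(x[treeish] == 0))
  expect_equal(unname(x[r]), 0.25)
  expect_equal(unname(x[net$taxa[["b"]]]), 0.25)
})

test_that("late layout pushes internal nodes leafward, keeping edge order", {
  # balanced tree: unchanged
  bal <- parse_extended_newick("((a,b),(c,d));")[[1]]
  d <- as.numeric(compute_depths(bal))
  expect_equal(apply_late_layout(bal, d), d)
  # unbalanced caterpillar: leaves right-aligned, edges stay monotone
  cat5 <- parse_extended_newick("((((a,b),c),d),e);")[[1]]
  d0 <- as.numeric(compute_depths(cat5))
  dl <- apply_late_layout(cat5, d0)
  expect_true(all(dl[cat5$edges$from] < dl[cat5$edges$to]))
  expect_true(all(dl[cat5$taxa] == max(d0, na.rm = TRUE)))
  # a reticulation whose depth is boosted by a deep second parent pulls
  # its rootward ancestors toward the leaves
  net <- phylo_network(
    data.frame(from = c(1, 2, 1, 4, 4, 6, 2, 6, 8),
               to   = c(2, 3, 4, 5, 6, 7, 8, 8, 9)),
    taxa = c(a = 3L, b = 5L, c = 7L, d = 9L), root = 1L)
  d0 <- as.numeric(compute_depths(net))
  dl <- apply_late_layout(net, d0)
  expect_true(all(dl[net$edges$from] < dl[net$edges$to]))
  expect_gt(dl[2], d0[2])
  # late + phylogram is rejected
  net <- random_network(5, 0, seed = 1)
  expect_error(layout_network(net, style = "phylogram", timing = "late"),
               "late")
})

test_that("equalized spacing interpolates unlabeled leaves", {
  # no unlabeled leaves: identical to assign_y on leaves
  net <- random_network(6, 0, seed = 4)
  b <- build_backbone(net, "combining")
  expect_equal(equalize_leaf_spacing(b, net), assign_y(b))
  # labeled,unlabeled,labeled -> 0, 0.5, 1 and 0,1/3,2/3,1 patterns
  netu <- net_with_unlabeled_leaves(8, seed = 31)
  bu <- build_backbone(netu, "combining")
  yu <- equalize_leaf_spacing(bu, netu)
  lv <- yu[netu$taxa]
  expect_setequal(lv, 0:(length(netu$taxa) - 1))
  po <- phynetdraw:::backbone_postorder(bu)
  leaf_seq <- po[vapply(po, function(v) length(bu$children[[v]]) == 0,
                        logical(1))]
  ys <- yu[leaf_seq]
  expect_true(all(diff(ys) > 0))          # traversal order preserved
  for (u in bu$unlabeled_leaves) {
    i <- match(u, leaf_seq)
    expect_false(yu[u] %in% 0:(length(netu$taxa) - 1))
  }
})

test_that("explicit unlabeled-run positions match the interpolation rule", {
  # build a backbone with leaf pattern L U U L by hand
  net <- parse_extended_newick(
    "((a,(x1)#H1,(x2)#H2),(#H1,#H2),b);")[[1]]
  # donor node (#H1,#H2) loses both children -> unlabeled leaf
  b <- build_backbone(net, "combining")
  y <- equalize_leaf_spacing(b, net)
  expect_setequal(y[net$taxa], 0:(length(net$taxa) - 1))
  u <- b$unlabeled_leaves
  expect_true(all(y[u] > min(y[net$taxa]) - 1 &
                  y[u] < max(y[net$taxa]) + 1))
  expect_true(all(abs(y[u] - round(y[u])) > 1e-9))
})

test_that("circular transform maps y to angles over H", {
  net <- parse_extended_newick("((a,b),c);")[[1]]
  lay <- layout_network(net, circular = TRUE, optimize = FALSE)
  expect_equal(lay$H, 4)
  cc <- lay$circular
  ang <- cc$angle[match(net$taxa, cc$node)]
  expect_equal(sort(ang), c(0, 90, 180))
  expect_true(all(cc$angle >= 0 & cc$angle < 360))
  # inverse transform recovers y
  m <- layout_maps(lay)
  expect_equal(cc$angle * lay$H / 360, m$y[cc$node], tolerance = 1e-12)
  expect_error(circular_coords(c(0, 1), c(0, 1), H = 0), "positive")
})

test_that("tree cladograms are planar and reticulation-free", {
  for (s in 1:10) {
    net <- random_network(sample(4:20, 1), 0, seed = 1100 + s)
    lay <- layout_network(net)
    expect_equal(lay$displacement, 0)
    m <- layout_maps(lay)
    expect_equal(count_edge_crossings(m$x, m$y, net$edges[, 1:2]), 0,
                 info = paste("seed", 1100 + s))
    expect_equal(unname(m$x[net$root]), 0)
    expect_true(all(m$x[lay$xy$node] >= 0))
  }
})
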