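test_that("binarize thresholds luminance and rejects empty images", {
  expect_error(binarize(matrix(1, 5, 5)), "no drawable content")
  m <- matrix(1, 5, 5); m[3, ] <- 0
  fg <- binarize(m)
  expect_equal(which(fg, arr.ind = TRUE)[, 1], rep(3L, 5),
               ignore_attr = TRUE)
  # antialiased pixels at 0.5 luminance are included at threshold 0.6
  m2 <- matrix(1, 5, 5); m2[3, 2:4] <- 0; m2[2, 2:4] <- 0.5
  fg2 <- binarize(m2, threshold = 0.6)
  expect_true(all(fg2[2, 2:4]))
  expect_false(any(fg2[1, ]))
  # logical masks pass through unchanged
  expect_identical(binarize(fg2), fg2)
})

test_that("skeletonization thins a bar to a unit-width line", {
  bar <- matrix(FALSE, 9, 40)
  bar[4:6, 2:39] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(colSums(sk[, 4:37]) == 1))        # unit width
  expect_gte(sum(sk), 34)                           # length preserved
                                                    # (ends erode <= 2 px)
  # idempotent on a single pixel
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_identical(skeletonize(px), px)
  # plus-shaped blob keeps exactly one 4-way junction
  plus <- matrix(FALSE, 21, 21)
  plus[9:13, 2:20] <- TRUE
  plus[2:20, 9:13] <- TRUE
  skp <- skeletonize(plus)
  nd <- detect_nodes(skp)
  expect_equal(sum(nd$nodes$type == "junction"), 1)
})

test_that("node detection counts endpoints and junctions by neighbor mask", {
  img <- matrix(FALSE, 20, 20)
  img <- draw_px_line(img, 3, 10, 17, 10)
  nd <- detect_nodes(img)
  expect_equal(sum(nd$nodes$type == "endpoint"), 2)
  expect_equal(sum(nd$nodes$type == "junction"), 0)
  # T shape
  img2 <- matrix(FALSE, 20, 20)
  img2 <- draw_px_line(img2, 3, 5, 17, 5)
  img2 <- draw_px_line(img2, 10, 5, 10, 17)
  nd2 <- detect_nodes(img2)
  expect_equal(sum(nd2$nodes$type == "endpoint"), 3)
  expect_equal(sum(nd2$nodes$type == "junction"), 1)
  # X shape: 4 endpoints, one (crossing) junction cluster
  img3 <- matrix(FALSE, 21, 21)
  img3 <- draw_px_line(img3, 3, 3, 19, 19)
  img3 <- draw_px_line(img3, 3, 19, 19, 3)
  nd3 <- detect_nodes(img3)
  expect_equal(sum(nd3$nodes$type == "endpoint"), 4)
  expect_equal(sum(nd3$nodes$type == "junction"), 1)
})

test_that("path tracing partitions the skeleton", {
  img <- matrix(FALSE, 20, 20)
  img <- draw_px_line(img, 3, 10, 17, 10)
  nd <- detect_nodes(img)
  p <- trace_paths(img, nd)
  expect_length(p, 1)
  # T: 3 paths meeting at the junction
  img2 <- matrix(FALSE, 20, 20)
  img2 <- draw_px_line(img2, 3, 5, 17, 5)
  img2 <- draw_px_line(img2, 10, 5, 10, 17)
  nd2 <- detect_nodes(img2)
  p2 <- trace_paths(img2, nd2)
  expect_length(p2, 3)
  # pixel partition: every skeleton pixel is in exactly one path interior
  # or one node cluster
  interior <- sum(vapply(p2, function(q) nrow(q$pixels) - 2L, integer(1)))
  expect_equal(interior + sum(nd2$nodemap > 0), sum(img2))
  # two disjoint lines: 2 paths, 4 endpoint nodes
  img3 <- matrix(FALSE, 20, 20)
  img3 <- draw_px_line(img3, 2, 3, 18, 3)
  img3 <- draw_px_line(img3, 2, 15, 18, 15)
  nd3 <- detect_nodes(img3)
  expect_equal(nrow(nd3$nodes), 4)
  expect_length(trace_paths(img3, nd3), 2)
})

test_that("label-box filtering removes fully covered paths only", {
  img <- matrix(FALSE, 20, 30)
  img <- draw_px_line(img, 3, 5, 12, 5)     # inside box
  img <- draw_px_line(img, 3, 15, 25, 15)   # crosses the box boundary
  nd <- detect_nodes(img)
  p <- trace_paths(img, nd)
  box <- data.frame(x0 = 1, y0 = 1, x1 = 14, y1 = 18)
  kept <- filter_label_paths(p, box)
  expect_length(kept, 1)
  expect_identical(filter_label_paths(p, NULL), p)
  expect_length(filter_label_paths(p, box[0, ]), 2)
})

test_that("assembly round-trips a rendered 3-leaf tree", {
  net <- parse_extended_newick("((a,b),c);")[[1]]
  lay <- layout_network(net, optimize = FALSE)
  fx <- render_raster_fixture(lay)
  cap <- capture_network(fx$raster, fx$root, labels = fx$labels)
  expect_equal(cap$orientation, "left_right")
  expect_length(cap$unresolved_paths, 0)
  clean <- remove_through_nodes(cap$network)
  expect_true(network_isomorphic(clean, net))
  # with nothing unresolved, the cleaned capture is a valid network
  expect_equal(nrow(validate_network(clean)), 0)
})

test_that("assembly round-trips a network with one reticulation", {
  net <- net_retic_example()
  lay <- layout_network(net, sa = sa_config(seed = 1))
  fx <- render_raster_fixture(lay)
  cap <- capture_network(fx$raster, fx$root, labels = fx$labels)
  expect_true(network_isomorphic(remove_through_nodes(cap$network), net))
})

test_that("a triangle leaves exactly one path unresolved", {
  tri <- triangle_raster()
  cap <- capture_network(tri$img, tri$root)
  expect_length(cap$unresolved_paths, 1)
  expect_equal(nrow(cap$network$edges), 2)
})

test_that("a root far from the drawing is rejected", {
  img <- matrix(FALSE, 20, 20)
  img <- draw_px_line(img, 3, 10, 17, 10)
  expect_error(capture_network(img, c(1, 1), tolerance = 3), "farther")
})

test_that("capture is deterministic for a fixed image and root", {
  net <- random_network(7, 1, seed = 33)
  lay <- layout_network(net, sa = sa_config(seed = 1))
  fx <- render_raster_fixture(lay)
  c1 <- capture_network(fx$raster, fx$root, labels = fx$labels)
  c2 <- capture_network(fx$raster, fx$root, labels = fx$labels)
  expect_identical(c1$network$edges, c2$network$edges)
  expect_identical(c1$network$taxa, c2$network$taxa)
})

test_that("through-node removal contracts chains and sums weights", {
  chain <- phylo_network(data.frame(from = c(1, 2), to = c(2, 3),
                                    weight = c(1.5, 2.0)),
                         taxa = c(a = 3L), root = 1L)
  out <- remove_through_nodes(chain)
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$weight, 3.5)
  expect_equal(out$edges$to, 3)
  # no through nodes: identity on the edge set
  net <- net_cherry()
  expect_identical(remove_through_nodes(net)$edges, net$edges)
})

test_that("crossing replacement pairs edges by direction", {
  # X junction: in from NW and SW, out to SE and NE
  net <- phylo_network(
    data.frame(from = c(1, 1, 2, 3, 5, 5, 4, 6),
               to   = c(2, 3, 5, 5, 4, 6, 7, 8)),
    taxa = c(a = 7L, b = 8L), root = 1L)
  pos <- data.frame(node = 1:8,
                    x = c(0, 1, 1, 3, 2, 3, 4, 4),
                    y = c(2, 1, 3, 1, 2, 3, 1, 3))
  out <- replace_with_crossing(net, 5, pos)
  expect_false(5 %in% c(out$edges$from, out$edges$to))
  # NW in-edge (from node 2, going down-right) continues to SE (node 6)
  expect_true(any(out$edges$from == 2 & out$edges$to == 6))
  expect_true(any(out$edges$from == 3 & out$edges$to == 4))
  expect_error(replace_with_crossing(net, 2, pos), "in-degree 2")
})

test_that("node merging keeps labels and connectivity", {
  # broken stroke: two endpoint nodes merged into one
  net <- phylo_network(data.frame(from = c(1, 2, 1), to = c(2, 3, 4)),
                       taxa = c(a = 3L, b = 4L), root = 1L)
  out <- merge_nodes(net, c(2, 4))
  expect_equal(length(out$nodes), 3)
  expect_true(is.finite(out$root))
  expect_identical(merge_nodes(net, 2), net)
  # merging two taxa violates the bijection
  expect_error(merge_nodes(net, c(3, 4)), "bijection")
  # merging the root with a child that has other parents is refused
  net2 <- net_diamond()
  expect_error(merge_nodes(net2, c(1, 4)), "incoming edge")
})
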