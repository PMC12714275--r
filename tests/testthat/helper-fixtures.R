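# Small fixture builders used across test files.

# diamond: root -> x, root -> y, x -> v, y -> v, v -> leaf
net_diamond <- function() {
  phylo_network(
    data.frame(from = c(1, 1, 2, 3, 4), to = c(2, 3, 4, 4, 5)),
    taxa = c(a = 5L), root = 1L)
}

# root with two labeled leaves (minimal valid network)
net_cherry <- function() {
  phylo_network(data.frame(from = c(1, 1), to = c(2, 3)),
                taxa = c(a = 2L, b = 3L), root = 1L)
}

# the running reticulation example: ((a,(b)#H1),(#H1,c));
net_retic_example <- function(acceptor_on_c_side = FALSE) {
  txt <- if (acceptor_on_c_side) "((a,(b)#H1),(##H1,c));"
         else "((a,(b)#H1),(#H1,c));"
  parse_extended_newick(txt)[[1]]
}

# draw a 1-px line into a logical matrix (x = col, y = row)
draw_px_line <- function(img, x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1
  img[cbind(round(seq(y0, y1, length.out = n)),
            round(seq(x0, x1, length.out = n)))] <- TRUE
  img
}

# triangle (closed curve) with the root corner on the left and a vertical
# far side; used for the unresolved-path behavior of capture
triangle_raster <- function() {
  img <- matrix(FALSE, 90, 90)
  img <- draw_px_line(img, 10, 45, 60, 10)
  img <- draw_px_line(img, 10, 45, 60, 80)
  img <- draw_px_line(img, 60, 10, 60, 80)
  list(img = img, root = c(10, 45))
}

# random tree/network plus a donor node whose children are all reticulate,
# so its backbone tree has unlabeled leaves
net_with_unlabeled_leaves <- function(n = 8, seed = 1) {
  net <- random_network(n, 0, seed = seed)
  ed <- net$edges
  maxid <- max(net$nodes)
  donor <- maxid + 1L
  # subdivide two distinct non-root edges; their new midpoints become
  # reticulate children of the donor
  cand <- which(ed$from != net$root)
  es <- sample(cand, 2)
  mids <- c(maxid + 2L, maxid + 3L)
  for (i in 1:2) {
    e <- es[i]
    old_to <- ed$to[e]
    ed$to[e] <- mids[i]
    ed <- rbind(ed, data.frame(from = mids[i], to = old_to,
                               weight = NA_real_, acceptor = FALSE))
    ed <- rbind(ed, data.frame(from = donor, to = mids[i],
                               weight = NA_real_, acceptor = FALSE))
  }
  ed <- rbind(ed, data.frame(from = net$root, to = donor,
                             weight = NA_real_, acceptor = FALSE))
  phylo_network(ed[, c("from", "to")], taxa = net$taxa, root = net$root)
}

# layout coordinates as id-indexed vectors
layout_maps <- function(lay) {
  maxid <- max(lay$net$nodes)
  xx <- rep(NA_real_, maxid); yy <- rep(NA_real_, maxid)
  xx[lay$xy$node] <- lay$xy$x
  yy[lay$xy$node] <- lay$xy$y
  list(x = xx, y = yy)
}
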