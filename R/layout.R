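## Coordinate assignment.
##
## Throughout, coordinate maps are numeric vectors indexed by node id
## (length max(id), NA at unused indices): y increases downward (or
## clockwise), x increases from the root toward the leaves, origin at the
## root.

#' Assign y-coordinates on the backbone tree
#'
#' Performs a post-order traversal of the backbone tree under its current
#' child order. The i-th leaf visited receives y = i (0-based); each internal
#' node receives the mean of its children's y (`mode = "children"`) or the
#' mean of its B-subtree leaves' y (`mode = "leaves"`).
#'
#' @param b a `backbone_tree`
#' @param mode averaging mode for internal nodes
#' @return numeric vector indexed by node id
#' @export
assign_y <- function(b, mode = c("children", "leaves")) {
  mode <- match.arg(mode)
  maxid <- length(b$children)
  y <- rep(NA_real_, maxid)
  lsum <- rep(0, maxid); lcnt <- rep(0L, maxid)
  po <- backbone_postorder(b)
  i <- 0L
  for (v in po) {
    kids <- b$children[[v]]
    if (length(kids) == 0) {
      y[v] <- i; lsum[v] <- i; lcnt[v] <- 1L
      i <- i + 1L
    } else {
      lsum[v] <- sum(lsum[kids]); lcnt[v] <- sum(lcnt[kids])
      y[v] <- if (mode == "children") mean(y[kids]) else lsum[v] / lcnt[v]
    }
  }
  y
}

#' Node depths in the network
#'
#' The depth d(v) is the maximum number of edges on any directed path from
#' the root to v; the cladogram uses x(v) = d(v).
#'
#' @param net a `phylo_network`
#' @return integer vector indexed by node id
#' @export
compute_depths <- function(net) {
  maxid <- max(net$nodes)
  d <- rep(NA_integer_, maxid)
  pa <- net_parents(net)
  ord <- topo_order(net)
  if (!attr(ord, "acyclic")) stop("network contains a directed cycle")
  for (v in ord) {
    p <- pa[[v]]
    d[v] <- if (length(p) == 0) 0L else max(d[p]) + 1L
  }
  d
}

#' Adjust depths for transfer edges
#'
#' Encourages the source and target of every transfer edge to share the same
#' x-coordinate in the transfer cladogram: whenever a transfer edge (v, w)
#' has d(v) < d(w), d(v) is raised to d(w); consistency along tree and
#' transfer-acceptor edges (d(child) >= d(parent) + 1) is then restored, and
#' the two steps are repeated until a fixed point is reached or a pass cap is
#' hit. A fixed point exists whenever the network is time-consistent (no
#' transfer runs from a lineage into its own backbone descendants); when the
#' cap is hit the current best-effort map is returned with a warning.
#'
#' @param net a `phylo_network`
#' @param d depth map from [compute_depths()]
#' @param max_passes pass cap (default: number of nodes + 2)
#' @return adjusted integer depth map indexed by node id
#' @export
adjust_transfer_depths <- function(net, d,
                                   max_passes = length(net$nodes) + 2L) {
  kinds <- edge_kinds(net)
  tr <- which(kinds == "transfer")
  if (length(tr) == 0) return(d)
  keep <- which(kinds %in% c("tree", "transfer_acceptor"))
  ord <- topo_order(net)
  e_from <- net$edges$from; e_to <- net$edges$to
  pa_keep <- rep(list(integer()), max(net$nodes))
  sp <- split(e_from[keep], e_to[keep])
  pa_keep[as.integer(names(sp))] <- lapply(sp, as.integer)

  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (e in tr) {
      v <- e_from[e]; w <- e_to[e]
      if (d[v] < d[w]) { d[v] <- d[w]; changed <- TRUE }
    }
    for (v in ord) {
      p <- pa_keep[[v]]
      if (length(p)) {
        m <- max(d[p]) + 1L
        if (d[v] < m) { d[v] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  if (any(d[e_from[tr]] < d[e_to[tr]]))
    warning("transfer-depth constraints not satisfiable (time-inconsistent ",
            "transfers); returning best-effort depths")
  d
}

#' Phylogram x-coordinates
#'
#' Assigns x(root) = 0 and processes nodes so that all parents precede their
#' children. A tree or transfer node v with (unique) tree or
#' transfer-acceptor in-edge e = (u, v) receives x(v) = x(u) + w(e). A
#' combining reticulate node receives max over parents' x, plus delta, a
#' small fixed offset that keeps reticulate edges running left-to-right.
#'
#' @param net a `phylo_network` whose tree and transfer-acceptor edges all
#'   carry weights
#' @param delta offset for combining nodes; default 0.02 times the maximal
#'   root-to-node distance along tree/acceptor edges (floor 1e-6)
#' @return numeric vector indexed by node id
#' @export
assign_x_phylogram <- function(net, delta = NULL) {
  kinds <- edge_kinds(net)
  main <- kinds %in% c("tree", "transfer_acceptor")
  if (any(main & is.na(net$edges$weight))) {
    bad <- net$edges[main & is.na(net$edges$weight), ][1, ]
    stop(sprintf("missing weight on tree/acceptor edge %d -> %d",
                 bad$from, bad$to))
  }
  compute <- function(delta) {
    maxid <- max(net$nodes)
    x <- rep(NA_real_, maxid)
    ord <- topo_order(net)
    for (v in ord) {
      ein <- which(net$edges$to == v)
      if (length(ein) == 0) { x[v] <- 0; next }
      em <- ein[main[ein]]
      if (length(em) == 1) {
        x[v] <- x[net$edges$from[em]] + net$edges$weight[em]
      } else if (length(em) == 0) {
        x[v] <- max(x[net$edges$from[ein]]) + delta
      } else stop("node ", v, " has several tree/acceptor in-edges")
    }
    x
  }
  if (is.null(delta)) {
    x0 <- compute(0)
    delta <- max(0.02 * max(x0, na.rm = TRUE), 1e-6)
  }
  compute(delta)
}

#' Late (leafward) cladogram layout
#'
#' Pushes nodes toward the leaves: leaves are right-aligned at the maximal
#' depth, and every non-leaf v then receives, in reverse topological order,
#' x(v) = min over out-edges (v, w) of x(w), minus 1. Every edge still runs
#' strictly left-to-right (source before target).
#'
#' @param net a `phylo_network`
#' @param x cladogram x-map (from [compute_depths()], possibly transfer
#'   adjusted)
#' @return numeric vector indexed by node id
#' @export
apply_late_layout <- function(net, x) {
  ch <- net_children(net)
  xmax <- max(x, na.rm = TRUE)
  ord <- rev(topo_order(net))
  for (v in ord) {
    kids <- ch[[v]]
    x[v] <- if (length(kids)) min(x[kids]) - 1 else xmax
  }
  x
}

#' Equalized leaf spacing
#'
#' Re-runs the post-order traversal of the backbone tree, assigning integer
#' y-values 0, 1, ..., |X|-1 to the labeled leaves in traversal order. Each
#' maximal run of m unlabeled backbone leaves between labeled neighbors at
#' integers k and k+1 receives k + j/(m+1), j = 1..m; runs before the first
#' (after the last) labeled leaf extend outward by the same fractional
#' steps. Internal y-values are recomputed with the chosen averaging mode.
#' The relative leaf order of the traversal is preserved exactly.
#'
#' @param b a `backbone_tree` (with its final, e.g. optimized, child order)
#' @param net the underlying `phylo_network`
#' @param mode averaging mode for internal nodes
#' @return numeric vector indexed by node id
#' @export
equalize_leaf_spacing <- function(b, net, mode = c("children", "leaves")) {
  mode <- match.arg(mode)
  po <- backbone_postorder(b)
  leaf_seq <- po[vapply(po, function(v) length(b$children[[v]]) == 0,
                        logical(1))]
  labeled <- leaf_seq %in% net$taxa
  K <- sum(labeled)
  pos <- numeric(length(leaf_seq))
  if (K == 0) {
    pos <- seq_along(leaf_seq) - 1
  } else {
    lab_idx <- which(labeled)
    pos[lab_idx] <- seq_len(K) - 1
    runs <- split(which(!labeled),
                  cumsum(labeled)[which(!labeled)])
    for (nm in names(runs)) {
      run <- runs[[nm]]
      m <- length(run)
      nlab_before <- as.integer(nm)
      if (nlab_before == 0) {                    # before first labeled leaf
        pos[run] <- -((m:1)) / (m + 1)
      } else if (nlab_before == K) {             # after last labeled leaf
        pos[run] <- (K - 1) + (1:m) / (m + 1)
      } else {
        k <- nlab_before - 1
        pos[run] <- k + (1:m) / (m + 1)
      }
    }
  }
  maxid <- length(b$children)
  y <- rep(NA_real_, maxid)
  y[leaf_seq] <- pos
  lsum <- rep(0, maxid); lcnt <- rep(0L, maxid)
  for (v in po) {
    kids <- b$children[[v]]
    if (length(kids) == 0) { lsum[v] <- y[v]; lcnt[v] <- 1L }
    else {
      lsum[v] <- sum(lsum[kids]); lcnt[v] <- sum(lcnt[kids])
      y[v] <- if (mode == "children") mean(y[kids]) else lsum[v] / lcnt[v]
    }
  }
  y
}

#' Circular transform
#'
#' Converts a linear layout into a circular one: angle(v) = y(v) / H * 360
#' degrees and radius(v) = x(v) + r0, where H is the number of backbone
#' leaves plus 1 and r0 a root offset keeping the root off the center point.
#'
#' @param y,x coordinate maps indexed by node id
#' @param H circle divisor (from the backbone tree)
#' @param r0 root radius offset (drawing units)
#' @return data frame `node`, `radius`, `angle` (degrees in \[0, 360))
#' @export
circular_coords <- function(y, x, H, r0 = 1) {
  if (H <= 0) stop("H must be positive")
  nodes <- which(!is.na(y))
  ang <- (y[nodes] / H * 360) %% 360
  data.frame(node = nodes, radius = x[nodes] + r0, angle = ang)
}

#' Compute a full network layout
#'
#' End-to-end driver: builds the backbone tree for the requested view,
#' optionally optimizes child orders to minimize reticulate displacement,
#' assigns y (post-order averaging, optionally with equalized leaf spacing)
#' and x (depths for cladograms, with transfer adjustment in the transfer
#' view and an optional late variant; edge weights for phylograms), and
#' optionally adds circular coordinates.
#'
#' @param net a valid `phylo_network`
#' @param view `"combining"` or `"transfer"`
#' @param style `"cladogram"` (ignore weights) or `"phylogram"` (use them)
#' @param timing `"early"` (nodes rootward) or `"late"` (nodes leafward;
#'   cladograms only)
#' @param mode averaging mode for internal y
#' @param optimize run [optimize_child_orders()]
#' @param sa simulated-annealing schedule, see [sa_config()]
#' @param circular also compute circular coordinates (and optimize the
#'   circular displacement)
#' @param equalize apply [equalize_leaf_spacing()] after optimization
#' @param delta phylogram offset for combining nodes (see
#'   [assign_x_phylogram()])
#' @param r0 circular root radius offset
#' @param passes optimization pass cap, see [optimize_child_orders()]
#' @return an object of class `phynet_layout`: `net`, `backbone`, `xy`
#'   (data frame `node`, `x`, `y`), `circular` (or `NULL`), `view`, `style`,
#'   `timing`, `H`, `displacement` (final linear reticulate displacement),
#'   `circular_displacement` (when circular)
#' @export
layout_network <- function(net, view = c("combining", "transfer"),
                           style = c("cladogram", "phylogram"),
                           timing = c("early", "late"),
                           mode = c("children", "leaves"),
                           optimize = TRUE, sa = sa_config(),
                           circular = FALSE, equalize = TRUE,
                           delta = NULL, r0 = 1, passes = 10L) {
  view <- match.arg(view); style <- match.arg(style)
  timing <- match.arg(timing); mode <- match.arg(mode)
  if (style == "phylogram" && timing == "late")
    stop("the late layout is defined for cladograms only")

  b <- build_backbone(net, view)
  if (optimize)
    b <- optimize_child_orders(net, b,
                               cost = if (circular) "circular" else "linear",
                               sa = sa, mode = mode, passes = passes)
  y <- if (equalize) equalize_leaf_spacing(b, net, mode) else assign_y(b, mode)

  if (style == "cladogram") {
    x <- compute_depths(net)
    if (view == "transfer") x <- adjust_transfer_depths(net, x)
    x <- as.numeric(x)
    if (timing == "late") x <- apply_late_layout(net, x)
  } else {
    x <- assign_x_phylogram(net, delta = delta)
  }
  x <- x - x[net$root]   # root at the origin even after a late push

  redges <- rd_edge_set(net, b)
  disp <- reticulate_displacement(y, redges)
  circ <- NULL; cdisp <- NULL
  if (circular) {
    circ <- circular_coords(y, x, b$H, r0 = r0)
    cdisp <- circular_displacement(y, redges, b$H)
  }
  structure(list(
    net = net, backbone = b,
    xy = data.frame(node = net$nodes, x = x[net$nodes], y = y[net$nodes]),
    circular = circ, view = view, style = style, timing = timing,
    H = b$H, displacement = disp, circular_displacement = cdisp),
    class = "phynet_layout")
}

#' @export
print.phynet_layout <- function(x, ...) {
  cat(sprintf("Network layout: %s %s (%s), %d nodes%s\n",
              x$view, x$style, x$timing, nrow(x$xy),
              if (!is.null(x$circular)) ", circular" else ""))
  cat(sprintf("Reticulate displacement: %g%s\n", x$displacement,
              if (!is.null(x$circular_displacement))
                sprintf(" (circular cost %g)", x$circular_displacement)
              else ""))
  invisible(x)
}

#' Plot a network layout
#'
#' Draws tree and transfer-acceptor edges as right-angled two-segment paths
#' and the remaining reticulate/transfer edges as curves, with taxon labels
#' at the leaves. Circular layouts are drawn with arc + radial segments.
#'
#' @param x a `phynet_layout`
#' @param edge_col,retic_col colors for main and reticulate edges
#' @param cex label size
#' @param ... passed to [graphics::plot.default()]
#' @export
plot.phynet_layout <- function(x, edge_col = "grey20", retic_col = "#c0392b",
                               cex = 0.8, ...) {
  net <- x$net
  kinds <- edge_kinds(net)
  inb <- interaction(x$backbone$edges$from, x$backbone$edges$to)
  main_edge <- kinds %in% c("tree", "transfer_acceptor")
  if (is.null(x$circular)) {
    px <- stats::setNames(x$xy$x, x$xy$node)
    py <- stats::setNames(x$xy$y, x$xy$node)
    graphics::plot(NA, xlim = range(x$xy$x) + c(0, diff(range(x$xy$x)) * .2),
                   ylim = rev(range(x$xy$y)), axes = FALSE,
                   xlab = "", ylab = "", ...)
    for (i in seq_len(nrow(net$edges))) {
      u <- as.character(net$edges$from[i]); v <- as.character(net$edges$to[i])
      if (main_edge[i]) {
        graphics::lines(c(px[u], px[u], px[v]), c(py[u], py[v], py[v]),
                        col = edge_col)
      } else {
        graphics::xspline(c(px[u], (px[u] + px[v]) / 2, px[v]),
                          c(py[u], py[u], py[v]), shape = c(0, 1, 0),
                          border = retic_col, lty = 2, open = TRUE)
      }
    }
    lv <- net$taxa
    graphics::text(px[as.character(lv)], py[as.character(lv)],
                   labels = names(lv), pos = 4, cex = cex)
  } else {
    cc <- x$circular
    th <- cc$angle * pi / 180
    cx <- cc$radius * cos(th); cy <- cc$radius * sin(th)
    pos <- data.frame(node = cc$node, px = cx, py = cy,
                      r = cc$radius, th = th)
    rownames(pos) <- pos$node
    lim <- max(cc$radius) * 1.25
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(lim, -lim),
                   axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
    for (i in seq_len(nrow(net$edges))) {
      u <- as.character(net$edges$from[i]); v <- as.character(net$edges$to[i])
      tu <- pos[u, "th"]; tv <- pos[v, "th"]
      ru <- pos[u, "r"]; rv <- pos[v, "r"]
      tt <- seq(tu, tv, length.out = 24)
      if (main_edge[i]) {
        graphics::lines(c(ru * cos(tt), rv * cos(tv)),
                        c(ru * sin(tt), rv * sin(tv)), col = edge_col)
      } else {
        graphics::lines(c(ru * cos(tu), rv * cos(tv)),
                        c(ru * sin(tu), rv * sin(tv)),
                        col = retic_col, lty = 2)
      }
    }
    lv <- as.character(net$taxa)
    graphics::text(pos[lv, "px"] * 1.06, pos[lv, "py"] * 1.06,
                   labels = names(net$taxa), cex = cex)
  }
  invisible(x)
}

#' Count crossings among right-angled edge paths
#'
#' Diagnostic used to verify planarity contracts: each selected edge
#' (v, w) is drawn as the two-segment path (x(v), y(v)) -> (x(v), y(w)) ->
#' (x(w), y(w)); the function counts pairs of edges whose paths intersect
#' at a point other than a shared endpoint (a common network node).
#'
#' @param x,y coordinate maps indexed by node id
#' @param edges two-column matrix/data frame of edges to test
#' @return number of crossing edge pairs
#' @export
count_edge_crossings <- function(x, y, edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  m <- nrow(edges)
  if (m < 2) return(0L)
  eps <- 1e-9
  # two axis-aligned segments per edge: vertical then horizontal
  v <- edges[, 1]; w <- edges[, 2]
  sx1 <- c(x[v], x[v]); sy1 <- c(y[v], y[w])
  sx2 <- c(x[v], x[w]); sy2 <- c(y[w], y[w])
  xlo <- pmin(sx1, sx2); xhi <- pmax(sx1, sx2)
  ylo <- pmin(sy1, sy2); yhi <- pmax(sy1, sy2)
  eidx <- c(seq_len(m), seq_len(m))
  n <- 2L * m
  oxl <- outer(xlo, xlo, pmax); oxh <- outer(xhi, xhi, pmin)
  oyl <- outer(ylo, ylo, pmax); oyh <- outer(yhi, yhi, pmin)
  has_ov <- oxl <= oxh + eps & oyl <= oyh + eps
  nondegen <- (oxh - oxl > eps) | (oyh - oyl > eps)
  # a degenerate (single-point) intersection is allowed only at the
  # coordinates of a node shared by the two edges
  ef <- edges[eidx, 1]; et <- edges[eidx, 2]
  XF <- matrix(x[ef], n, n); YF <- matrix(y[ef], n, n)
  XT <- matrix(x[et], n, n); YT <- matrix(y[et], n, n)
  shareF <- outer(ef, ef, "==") | outer(ef, et, "==")
  shareT <- outer(et, ef, "==") | outer(et, et, "==")
  allowed <- (shareF & abs(oxl - XF) < eps & abs(oyl - YF) < eps) |
             (shareT & abs(oxl - XT) < eps & abs(oyl - YT) < eps)
  bad <- has_ov & (nondegen | !allowed)
  bad[outer(eidx, eidx, "==")] <- FALSE        # same edge: free to touch
  bad[lower.tri(bad, diag = TRUE)] <- FALSE
  if (!any(bad)) return(0L)
  ii <- row(bad)[bad]; jj <- col(bad)[bad]
  nrow(unique(cbind(pmin(eidx[ii], eidx[jj]), pmax(eidx[ii], eidx[jj]))))
}
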