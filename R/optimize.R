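#' Simulated-annealing schedule
#'
#' Container for the annealing parameters used by child-order optimization:
#' start temperature 1000, end temperature 0.01, 1000 iterations per
#' temperature step, cooling rate 0.95. The temperature is multiplied by the
#' cooling rate after each block of iterations until it drops below the end
#' temperature.
#'
#' @param start_temperature,end_temperature temperature range (start > end)
#' @param iterations_per_step Metropolis iterations per temperature step
#' @param cooling_rate multiplicative cooling factor in (0, 1)
#' @param seed optional integer seed; when given, the optimizer seeds R's
#'   RNG once per call so results are reproducible
#' @return an object of class `sa_config`
#' @export
sa_config <- function(start_temperature = 1000, end_temperature = 0.01,
                      iterations_per_step = 1000, cooling_rate = 0.95,
                      seed = NULL) {
  stopifnot(cooling_rate > 0, cooling_rate < 1,
            end_temperature < start_temperature, end_temperature > 0,
            iterations_per_step >= 1)
  structure(list(start_temperature = start_temperature,
                 end_temperature = end_temperature,
                 iterations_per_step = as.integer(iterations_per_step),
                 cooling_rate = cooling_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sa_config")
}

#' Reticulate displacement of a drawing
#'
#' The total reticulate displacement is the sum of |y(v) - y(w)| over the
#' displacement edge set R (reticulate edges, excluding transfer-acceptor
#' edges). `circular_displacement()` is the circular variant in which each
#' edge costs min(|dy|, H - |dy|), accounting for the shorter way around the
#' circle; H is the number of backbone leaves plus 1.
#'
#' @param y y-coordinate map indexed by node id
#' @param edges two-column matrix/data frame of displacement edges
#' @param H circle divisor (positive)
#' @return non-negative number (0 for an empty edge set)
#' @export
reticulate_displacement <- function(y, edges) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) return(0)
  sum(abs(y[edges[, 1]] - y[edges[, 2]]))
}

#' @rdname reticulate_displacement
#' @export
circular_displacement <- function(y, edges, H) {
  if (H <= 0) stop("H must be positive")
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) return(0)
  d <- abs(y[edges[, 1]] - y[edges[, 2]])
  sum(pmin(d, H - d))
}

#' Displacement edge set of a network
#'
#' The edges whose y-extent the optimizer minimizes: reticulate edges,
#' excluding transfer-acceptor edges and excluding any original edge that
#' coincides with the backbone edge into its target (such an edge is drawn
#' as the node's main attachment, exactly like an acceptor edge; this also
#' makes the displacement of a star reduction equal the minimum linear
#' arrangement cost, see [minla_to_network()]).
#'
#' @param net a `phylo_network`
#' @param b its `backbone_tree`
#' @return two-column integer matrix (`from`, `to`)
#' @export
rd_edge_set <- function(net, b) {
  if (nrow(net$edges) == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to"))))
  kinds <- edge_kinds(net)
  keep <- kinds %in% c("reticulate", "transfer")
  inb <- paste(net$edges$from, net$edges$to) %in%
    paste(b$edges$from, b$edges$to)
  keep <- keep & !inb
  cbind(from = net$edges$from[keep], to = net$edges$to[keep])
}

#' Simulated annealing over child orders
#'
#' Generic Metropolis annealer over permutations: the neighbor move is a
#' uniform random transposition of two elements; a worse order is accepted
#' with probability exp(-dcost / T); after each block of
#' `iterations_per_step` proposals the temperature is multiplied by the
#' cooling rate, until it falls below the end temperature. Returns the best
#' order evaluated. Deterministic for a fixed `sa$seed`.
#'
#' This reference implementation accepts an arbitrary cost function;
#' [optimize_child_orders()] runs the same schedule through a compiled
#' kernel specialized to the displacement objective.
#'
#' @param children vector (length >= 2) to reorder
#' @param cost_fn function mapping an order to a numeric cost
#' @param sa an [sa_config()]
#' @return reordered `children`
#' @export
simulated_annealing_order <- function(children, cost_fn, sa = sa_config()) {
  k <- length(children)
  if (k < 2) stop("need at least two children")
  if (!is.null(sa$seed)) set.seed(sa$seed)
  cur <- children
  ccur <- cost_fn(cur)
  best <- cur; cbest <- ccur
  temp <- sa$start_temperature
  while (temp >= sa$end_temperature) {
    for (it in seq_len(sa$iterations_per_step)) {
      ij <- sample.int(k, 2L)
      cand <- cur
      cand[ij[1]] <- cur[ij[2]]; cand[ij[2]] <- cur[ij[1]]
      cc <- cost_fn(cand)
      if (cc < cbest) { cbest <- cc; best <- cand }
      d <- cc - ccur
      if (d <= 0 || stats::runif(1) < exp(-d / temp)) {
        cur <- cand; ccur <- cc
      }
    }
    temp <- temp * sa$cooling_rate
  }
  best
}

#' Optimize backbone child orders to minimize reticulate displacement
#'
#' Visits every branching node of the backbone tree in pre-order (this is a
#' superset of the lowest-stable-ancestor anchors of the reticulations;
#' under children-mean averaging a reorder anywhere can shift ancestor
#' y-values, so all branching nodes participate) and selects a permutation
#' of its children minimizing the total (linear or circular) displacement,
#' recomputing the full y-assignment for each candidate. Nodes with at most
#' `exhaustive_threshold` children are searched exhaustively; larger nodes
#' are searched by simulated annealing over pairwise swaps with the `sa`
#' schedule. The pre-order pass repeats until it yields no further strict
#' improvement (at most `passes` times), after which an exact pairwise
#' refinement jointly re-optimizes two nodes at a time — escaping the local
#' optima of single-node coordinate descent, which cannot realize
#' simultaneous reorders; on small instances this reliably reaches the
#' global joint optimum. The final displacement never exceeds the initial
#' one.
#'
#' @param net a valid `phylo_network`
#' @param b its `backbone_tree` (built for the requested view)
#' @param cost `"linear"` or `"circular"` displacement
#' @param sa an [sa_config()]; `sa$seed`, when set, seeds the RNG once for
#'   the whole call
#' @param mode averaging mode used for candidate y-assignments
#' @param exhaustive_threshold maximum child count searched exhaustively
#' @param passes cap on repeated pre-order passes
#' @return `b` with optimized child order and a `displacement` field
#' @export
optimize_child_orders <- function(net, b, cost = c("linear", "circular"),
                                  sa = sa_config(),
                                  mode = c("children", "leaves"),
                                  exhaustive_threshold = 8L,
                                  passes = 10L) {
  cost <- match.arg(cost); mode <- match.arg(mode)
  redges <- rd_edge_set(net, b)
  if (nrow(redges) == 0) {
    b$displacement <- 0
    return(b)
  }
  if (!is.null(sa$seed)) set.seed(sa$seed)

  ids <- b$nodes
  idx <- integer(max(ids)); idx[ids] <- seq_along(ids)
  kidsc <- lapply(ids, function(v) idx[b$children[[v]]])
  cnt <- integer(length(ids))
  for (v in backbone_postorder(b)) {
    kids <- b$children[[v]]
    cnt[idx[v]] <- if (length(kids) == 0) 1L else sum(cnt[idx[kids]])
  }
  prec <- idx[backbone_preorder(b)]
  rec <- cbind(idx[redges[, 1]], idx[redges[, 2]])
  mode01 <- if (mode == "children") 0L else 1L
  circ <- cost == "circular"

  # Every multi-child node is visited, not only the LSA anchors of the
  # reticulations: with children-mean averaging, reordering any branching
  # node shifts the y of its ancestors and can therefore lower the
  # displacement, and restricting the search to LSA nodes demonstrably
  # misses joint optima on small networks.
  pre_ids <- backbone_preorder(b)
  targets <- pre_ids[vapply(pre_ids, function(v)
    length(b$children[[v]]) >= 2, logical(1))]

  total <- eval_order_cost_cpp(kidsc, cnt, prec, rec, mode01, circ,
                               as.numeric(b$H))
  for (outer in seq_len(passes)) {
    # single-node sweeps (pre-order) until they stall
    for (pass in seq_len(passes)) {
      improved <- FALSE
      for (v in targets) {
        vi <- idx[v]
        k <- length(kidsc[[vi]])
        method <- if (k <= exhaustive_threshold) 0L else 1L
        res <- order_search_cpp(kidsc, cnt, prec, vi, rec, mode01, circ,
                                as.numeric(b$H), method,
                                sa$start_temperature, sa$end_temperature,
                                sa$iterations_per_step, sa$cooling_rate)
        if (res$cost < total - 1e-9) improved <- TRUE
        if (res$cost <= total) {
          kidsc[[vi]] <- res$order
          total <- res$cost
        }
      }
      if (!improved) break
    }
    # exact pairwise refinement: simultaneous reorders of two nodes that
    # single-node moves cannot realize; cheap for the typical binary nodes
    ks <- vapply(targets, function(v) length(kidsc[[idx[v]]]), integer(1))
    small <- targets[ks <= exhaustive_threshold]
    kf <- factorial(vapply(small, function(v)
      length(kidsc[[idx[v]]]), integer(1)))
    improved2 <- FALSE
    budget <- 2e6
    if (length(small) >= 2) {
      for (i in seq_len(length(small) - 1)) {
        for (j in (i + 1):length(small)) {
          work <- kf[i] * kf[j]
          if (work > budget) next
          budget <- budget - work
          res <- pair_search_cpp(kidsc, cnt, prec,
                                 idx[small[i]], idx[small[j]], rec,
                                 mode01, circ, as.numeric(b$H))
          if (res$cost < total - 1e-9) {
            kidsc[[idx[small[i]]]] <- res$order_a
            kidsc[[idx[small[j]]]] <- res$order_b
            total <- res$cost
            improved2 <- TRUE
          }
        }
      }
    }
    if (!improved2) break
  }

  for (v in targets) b$children[[v]] <- ids[kidsc[[idx[v]]]]
  b$displacement <- total
  b
}

#' Reduce a minimum linear arrangement instance to a layout instance
#'
#' Given an undirected graph G = (V, E), builds the rooted phylogenetic
#' network of the MinLA reduction: a root with a tree edge to every original
#' vertex (these edges make up the backbone star) and a pendant labeled leaf
#' below each vertex (keeping the taxon bijection and avoiding through
#' nodes); each undirected edge becomes one directed reticulate edge (from
#' the lower-indexed vertex; |dy| is symmetric, so the direction is
#' immaterial). The reticulate displacement of a leaf order equals the
#' MinLA cost of the corresponding arrangement f (f = leaf rank + 1).
#'
#' @param g list with `vertices` (character names, or a single integer
#'   count) and `edges` (two-column matrix of vertex indices; may be empty)
#' @return list with `network` (a `phylo_network`) and `backbone` (its
#'   combining-view `backbone_tree`, a star below the root)
#' @export
minla_to_network <- function(g) {
  verts <- g$vertices
  if (length(verts) == 1 && is.numeric(verts))
    verts <- paste0("v", seq_len(verts))
  n <- length(verts)
  stopifnot(n >= 1)
  em <- g$edges
  if (is.null(em) || NROW(em) == 0) {
    em <- matrix(integer(), 0, 2)
  } else {
    em <- as.matrix(em)[, 1:2, drop = FALSE]
    em <- t(apply(em, 1, sort))
    em <- unique(em)
    stopifnot(all(em >= 1 & em <= n), all(em[, 1] != em[, 2]))
  }
  root <- 1L
  vid <- 1L + seq_len(n)          # original vertices
  touched <- sort(unique(c(em)))  # vertices with at least one G-edge
  # vertices incident to a G-edge get a pendant labeled leaf (they are
  # internal in the network); isolated vertices are labeled leaves directly,
  # which avoids through nodes
  lid <- integer(n)
  lid[touched] <- 1L + n + seq_along(touched)
  lid[-touched] <- vid[-touched]
  if (length(touched) == 0) lid <- vid
  ed <- rbind(
    data.frame(from = root, to = vid),
    if (length(touched))
      data.frame(from = vid[touched], to = lid[touched]),
    if (nrow(em)) data.frame(from = vid[em[, 1]], to = vid[em[, 2]])
  )
  net <- phylo_network(ed, taxa = stats::setNames(lid, verts), root = root)
  list(network = net, backbone = build_backbone(net, "combining"))
}
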