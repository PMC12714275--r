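## Topology clean-up operations for captured (or edited) networks.

#' Remove through nodes
#'
#' Contracts every node of in-degree 1 and out-degree 1, merging its two
#' incident edges into one; weights are summed when present (an edge with
#' no weight contributes nothing, two absent weights stay absent), and a
#' transfer-acceptor flag on either edge is kept. A contraction that would
#' create a parallel edge is skipped with a warning.
#'
#' @param net a `phylo_network`
#' @return a `phylo_network` without through nodes
#' @export
remove_through_nodes <- function(net) {
  ed <- net$edges
  repeat {
    maxid <- max(net$nodes)
    indeg <- tabulate(ed$to, nbins = maxid)
    outdeg <- tabulate(ed$from, nbins = maxid)
    thr <- net$nodes[indeg[net$nodes] == 1 & outdeg[net$nodes] == 1]
    thr <- setdiff(thr, c(net$root, net$taxa))
    done <- TRUE
    for (v in thr) {
      ein <- which(ed$to == v); eout <- which(ed$from == v)
      if (length(ein) != 1 || length(eout) != 1) next  # stale after edits
      u <- ed$from[ein]; w <- ed$to[eout]
      if (any(ed$from == u & ed$to == w)) {
        warning("skipping contraction of node ", v,
                ": edge ", u, " -> ", w, " already exists")
        next
      }
      wt <- if (is.na(ed$weight[ein]) && is.na(ed$weight[eout])) NA_real_
            else sum(ed$weight[ein], ed$weight[eout], na.rm = TRUE)
      ed$to[ein] <- w
      ed$weight[ein] <- wt
      ed$acceptor[ein] <- ed$acceptor[ein] | ed$acceptor[eout]
      ed <- ed[-eout, , drop = FALSE]
      done <- FALSE
      break  # recompute degrees after each contraction
    }
    if (done) break
  }
  keep <- sort(unique(c(ed$from, ed$to, net$root, net$taxa)))
  nl <- net$node_labels[names(net$node_labels) %in% as.character(keep)]
  phylo_network(ed, taxa = net$taxa, root = net$root,
                node_labels = if (length(nl)) nl else NULL)
}

#' Replace a degree-2/2 node by crossing edges
#'
#' A node with in-degree 2 and out-degree 2 usually arises when two straight
#' strokes cross in a captured figure. The node is removed and each incoming
#' edge is paired with the outgoing edge most collinear with it (judged from
#' the node positions), yielding two independent edges; weights are summed.
#' Ties are broken deterministically by edge order.
#'
#' @param net a `phylo_network`
#' @param v node id with in-degree 2 and out-degree 2
#' @param positions data frame `node`, `x`, `y` with pixel/drawing
#'   coordinates (e.g. from a `capture_result`)
#' @return a `phylo_network` without `v`
#' @export
replace_with_crossing <- function(net, v, positions) {
  v <- as.integer(v)
  if (!(v %in% net$nodes)) stop("no such node: ", v)
  ed <- net$edges
  ein <- which(ed$to == v); eout <- which(ed$from == v)
  if (length(ein) != 2 || length(eout) != 2)
    stop("node ", v, " does not have in-degree 2 and out-degree 2")
  pos <- function(id) {
    i <- match(id, positions$node)
    if (is.na(i)) stop("no position for node ", id)
    c(positions$x[i], positions$y[i])
  }
  pv <- pos(v)
  din <- lapply(ed$from[ein], function(u) { d <- pv - pos(u); d / sqrt(sum(d^2)) })
  dout <- lapply(ed$to[eout], function(w) { d <- pos(w) - pv; d / sqrt(sum(d^2)) })
  # pairing maximizing summed direction agreement; tie-break: identity pairing
  s_id <- sum(din[[1]] * dout[[1]]) + sum(din[[2]] * dout[[2]])
  s_sw <- sum(din[[1]] * dout[[2]]) + sum(din[[2]] * dout[[1]])
  pair <- if (s_sw > s_id + 1e-9) c(2L, 1L) else c(1L, 2L)
  addw <- function(a, b) if (is.na(a) && is.na(b)) NA_real_ else sum(a, b, na.rm = TRUE)
  for (i in 1:2) {
    eo <- eout[pair[i]]
    ed$to[ein[i]] <- ed$to[eo]
    ed$weight[ein[i]] <- addw(ed$weight[ein[i]], ed$weight[eo])
    ed$acceptor[ein[i]] <- FALSE
  }
  ed <- ed[-eout, , drop = FALSE]
  phylo_network(ed, taxa = net$taxa, root = net$root,
                node_labels = net$node_labels)
}

#' Merge a set of nodes into one
#'
#' The nodes in `S` collapse into a single node (the smallest id in `S`)
#' that inherits all external edges (deduplicated, self-loops discarded)
#' and the union of labels; merging two different taxa is rejected (the
#' taxon map must stay a bijection), as is a merge that would give the root
#' an incoming edge.
#'
#' @param net a `phylo_network`
#' @param S node ids to merge (singleton is the identity)
#' @return a `phylo_network`
#' @export
merge_nodes <- function(net, S) {
  S <- sort(unique(as.integer(S)))
  if (length(S) == 0) stop("S must be non-empty")
  if (!all(S %in% net$nodes)) stop("unknown node id(s) in S")
  if (length(S) == 1) return(net)
  tx_in <- names(net$taxa)[net$taxa %in% S]
  if (length(tx_in) > 1)
    stop("cannot merge two taxa (", paste(tx_in, collapse = ", "),
         "): taxon labeling must remain a bijection")
  m <- S[1]
  ed <- net$edges
  ext_into <- any(ed$to %in% S & !(ed$from %in% S))
  if (net$root %in% S && ext_into)
    stop("merge would give the root an incoming edge")
  ed$from[ed$from %in% S] <- m
  ed$to[ed$to %in% S] <- m
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  ed <- ed[!duplicated(ed[, c("from", "to")]), , drop = FALSE]
  taxa <- net$taxa
  taxa[taxa %in% S] <- m
  root <- if (net$root %in% S) m else net$root
  nl <- net$node_labels
  if (!is.null(nl)) {
    keepnm <- setdiff(names(nl), as.character(setdiff(S, m)))
    nl <- nl[keepnm]
    if (!length(nl)) nl <- NULL
  }
  phylo_network(ed, taxa = taxa, root = root, node_labels = nl)
}
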