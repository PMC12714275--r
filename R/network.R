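#' Construct a rooted phylogenetic network
#'
#' A rooted phylogenetic network is a directed acyclic graph with a single
#' root (the unique in-degree-0 node), whose leaves (out-degree-0 nodes) are
#' in bijection with a taxon set. Nodes with in-degree >= 2 are reticulate
#' nodes; one of their incoming edges may be flagged as the transfer-acceptor
#' edge, in which case the node is displayed as a transfer (e.g. HGT) event
#' rather than a combining (e.g. hybridization) event.
#'
#' The constructor performs only structural checks (ids resolve, no parallel
#' edges, taxon labels unique and non-empty); semantic rules (acyclicity,
#' single root, taxon bijection, no through nodes, ...) are checked by
#' [validate_network()], which reports violations as data rather than
#' throwing, so that partially built or captured networks can be inspected.
#'
#' @param edges two-column matrix or data frame of directed edges
#'   (`from`, `to`), positive integer node ids. Optional columns `weight`
#'   (non-negative edge length, `NA` when absent) and `acceptor` (logical,
#'   transfer-acceptor flag).
#' @param taxa named integer vector mapping taxon labels to leaf node ids.
#' @param root root node id; inferred as the unique in-degree-0 node when
#'   `NULL`.
#' @param node_labels optional named character vector (names are node ids) of
#'   display labels for internal nodes; these are not taxa.
#' @return an object of class `phylo_network` with fields `nodes`, `edges`
#'   (data frame `from`, `to`, `weight`, `acceptor`), `root`, `taxa`,
#'   `node_labels`.
#' @seealso [validate_network()], [classify_node()], [classify_edge()],
#'   [parse_extended_newick()]
#' @export
phylo_network <- function(edges, taxa = integer(), root = NULL,
                          node_labels = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("'edges' needs at least columns from, to")
  if (nrow(edges) == 0) {
    edges <- data.frame(from = integer(), to = integer())
  }
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (anyNA(edges$from) || anyNA(edges$to))
    stop("edge endpoints must be integer node ids")
  if (is.null(edges$weight)) edges$weight <- NA_real_
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.na(edges$weight) & edges$weight < 0))
    stop("edge weights must be non-negative")
  if (is.null(edges$acceptor)) edges$acceptor <- FALSE
  edges$acceptor <- as.logical(edges$acceptor)
  edges$acceptor[is.na(edges$acceptor)] <- FALSE
  edges <- edges[, c("from", "to", "weight", "acceptor")]
  if (anyDuplicated(edges[, c("from", "to")]))
    stop("parallel edges are not allowed")
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed")

  taxa <- unlist(taxa)
  if (length(taxa)) {
    storage.mode(taxa) <- "integer"
    if (is.null(names(taxa)) || any(!nzchar(names(taxa))))
      stop("taxon labels must be non-empty strings")
    if (anyDuplicated(names(taxa)))
      stop("duplicate taxon labels")
    if (anyDuplicated(taxa))
      stop("two taxa mapped to the same node")
  } else {
    taxa <- stats::setNames(integer(), character())
  }

  nodes <- sort(unique(c(edges$from, edges$to, taxa,
                         if (!is.null(root)) as.integer(root))))
  if (length(nodes) == 0) stop("network has no nodes")
  if (any(nodes < 1)) stop("node ids must be positive integers")
  if (length(taxa) && !all(taxa %in% nodes))
    stop("taxa refer to unknown node ids")

  if (is.null(root)) {
    indeg <- tabulate(edges$to, nbins = max(nodes))
    r <- nodes[indeg[nodes] == 0]
    if (length(r) != 1)
      stop("root cannot be inferred: ", length(r), " in-degree-0 nodes")
    root <- r
  }
  root <- as.integer(root)
  if (!(root %in% nodes)) stop("root is not a node of the network")

  if (!is.null(node_labels)) {
    node_labels <- stats::setNames(as.character(node_labels),
                                   names(node_labels))
  }

  structure(list(nodes = nodes, edges = edges, root = root, taxa = taxa,
                 node_labels = node_labels),
            class = "phylo_network")
}

#' @export
print.phylo_network <- function(x, ...) {
  nr <- sum(node_in_degree(x)[x$nodes] >= 2)
  cat(sprintf(
    "Rooted phylogenetic network: %d nodes, %d edges, %d taxa, %d reticulation%s\n",
    length(x$nodes), nrow(x$edges), length(x$taxa), nr,
    if (nr == 1) "" else "s"))
  if (length(x$taxa))
    cat("Taxa:", paste(utils::head(names(x$taxa), 8), collapse = ", "),
        if (length(x$taxa) > 8) "..." else "", "\n")
  v <- validate_network(x)
  if (nrow(v) == 0) cat("Valid network.\n")
  else cat(nrow(v), "validation violation(s); see validate_network().\n")
  invisible(x)
}

## ---- internal degree / adjacency helpers -------------------------------

node_in_degree <- function(net) {
  n <- max(net$nodes)
  tabulate(net$edges$to, nbins = n)
}

node_out_degree <- function(net) {
  n <- max(net$nodes)
  tabulate(net$edges$from, nbins = n)
}

# children[[id]] / parents[[id]] as integer vectors (edge order preserved)
net_children <- function(net) {
  n <- max(net$nodes)
  out <- rep(list(integer()), n)
  if (nrow(net$edges)) {
    sp <- split(net$edges$to, net$edges$from)
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

net_parents <- function(net) {
  n <- max(net$nodes)
  out <- rep(list(integer()), n)
  if (nrow(net$edges)) {
    sp <- split(net$edges$from, net$edges$to)
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

#' Leaves of a network
#'
#' Nodes of out-degree zero, in increasing id order.
#' @param net a `phylo_network`
#' @return integer vector of node ids
#' @export
network_leaves <- function(net) {
  outdeg <- node_out_degree(net)
  net$nodes[outdeg[net$nodes] == 0]
}

# Kahn topological sort; attr "acyclic" FALSE when a cycle blocks completion,
# in which case the returned order omits the nodes on/below cycles.
topo_order <- function(net) {
  n <- max(net$nodes)
  indeg <- node_in_degree(net)
  present <- logical(n); present[net$nodes] <- TRUE
  ch <- net_children(net)
  queue <- net$nodes[indeg[net$nodes] == 0]
  ord <- integer(0)
  indeg <- indeg  # local copy mutated below
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (w in ch[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  structure(ord, acyclic = length(ord) == length(net$nodes))
}

## ---- classification -----------------------------------------------------

#' Classify a node as tree or reticulate
#'
#' A node is a tree node if its in-degree is at most 1, and a reticulate
#' node otherwise.
#'
#' @param net a `phylo_network`
#' @param v node id
#' @return `"tree"` or `"reticulate"`
#' @export
classify_node <- function(net, v) {
  v <- as.integer(v)
  if (length(v) != 1 || !(v %in% net$nodes))
    stop("unknown node id: ", v)
  if (node_in_degree(net)[v] <= 1) "tree" else "reticulate"
}

#' Classify an edge
#'
#' An edge is a tree edge if its target is a tree node. Edges into a
#' reticulate node are reticulate edges; if one incoming edge of the node is
#' flagged as transfer-acceptor, that edge is classified
#' `"transfer_acceptor"` and its siblings `"transfer"`.
#'
#' @param net a `phylo_network`
#' @param from,to endpoints of an existing edge
#' @return one of `"tree"`, `"reticulate"`, `"transfer_acceptor"`,
#'   `"transfer"`
#' @export
classify_edge <- function(net, from, to) {
  i <- which(net$edges$from == from & net$edges$to == to)
  if (length(i) != 1) stop("no such edge: ", from, " -> ", to)
  edge_kinds(net)[i]
}

# vectorized per-edge kinds, in edge-table order
edge_kinds <- function(net) {
  if (nrow(net$edges) == 0) return(character())
  indeg <- node_in_degree(net)
  tgt_retic <- indeg[net$edges$to] >= 2
  if (any(net$edges$acceptor & !tgt_retic))
    stop("acceptor flag on edge into a tree node: ",
         paste(with(net$edges[net$edges$acceptor & !tgt_retic, ],
                    paste0(from, "->", to)), collapse = ", "))
  kind <- ifelse(tgt_retic, "reticulate", "tree")
  flagged_nodes <- unique(net$edges$to[net$edges$acceptor])
  transfer_tgt <- net$edges$to %in% flagged_nodes
  kind[transfer_tgt] <- ifelse(net$edges$acceptor[transfer_tgt],
                               "transfer_acceptor", "transfer")
  kind
}

## ---- validation ---------------------------------------------------------

#' Validate a rooted phylogenetic network
#'
#' Checks the defining properties of a rooted phylogenetic network and
#' returns each violation as a row of a data frame (rule name, offending
#' node/edge, message). An empty result means the network is valid. The rules:
#' acyclicity; exactly one in-degree-0 node which is the stored root;
#' connectivity from the root; bijection between taxa and leaves; no through
#' nodes (in-degree 1 and out-degree 1); leaf in-degree at most 1; at most
#' one incoming acceptor-flagged edge per node, only on nodes of in-degree
#' at least 2.
#'
#' @param net a `phylo_network`
#' @return data frame with columns `rule`, `id`, `message` (zero rows when
#'   valid)
#' @export
validate_network <- function(net) {
  bad <- list()
  add <- function(rule, id, message)
    bad[[length(bad) + 1]] <<- data.frame(rule = rule, id = as.character(id),
                                          message = message)

  ord <- topo_order(net)
  if (!attr(ord, "acyclic")) {
    cyc <- setdiff(net$nodes, ord)
    add("acyclicity", paste(cyc, collapse = ","),
        "directed cycle involving these nodes")
  }

  indeg <- node_in_degree(net)
  outdeg <- node_out_degree(net)
  roots <- net$nodes[indeg[net$nodes] == 0]
  if (length(roots) != 1)
    add("single-root", paste(roots, collapse = ","),
        sprintf("%d nodes have in-degree 0", length(roots)))
  if (!(net$root %in% roots))
    add("root-mismatch", net$root,
        "stored root is not the unique in-degree-0 node")

  # connectivity from root
  ch <- net_children(net)
  seen <- logical(max(net$nodes))
  queue <- net$root; seen[net$root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in ch[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  unreach <- net$nodes[!seen[net$nodes]]
  if (length(unreach))
    add("connectivity", paste(unreach, collapse = ","),
        "nodes not reachable from the root")

  lv <- network_leaves(net)
  unlabeled <- setdiff(lv, net$taxa)
  if (length(unlabeled))
    add("taxa-bijection", paste(unlabeled, collapse = ","),
        "unlabeled leaves")
  nonleaf_taxa <- net$taxa[!(net$taxa %in% lv)]
  if (length(nonleaf_taxa))
    add("taxa-bijection", paste(nonleaf_taxa, collapse = ","),
        "taxa mapped to non-leaf nodes")

  through <- net$nodes[indeg[net$nodes] == 1 & outdeg[net$nodes] == 1]
  for (v in through) add("through-node", v, "in-degree 1 and out-degree 1")

  badleaf <- lv[indeg[lv] > 1]
  for (v in badleaf) add("leaf-indegree", v, "leaf with in-degree > 1")

  if (any(net$edges$acceptor)) {
    acc <- net$edges[net$edges$acceptor, ]
    cnt <- table(acc$to)
    for (v in names(cnt)[cnt > 1])
      add("acceptor", v, "more than one incoming transfer-acceptor edge")
    single <- as.integer(names(cnt))
    for (v in single[indeg[single] < 2])
      add("acceptor", v, "acceptor flag on edge into a tree node")
  }

  if (length(bad)) do.call(rbind, bad)
  else data.frame(rule = character(), id = character(), message = character())
}

#' @rdname validate_network
#' @export
is_valid_network <- function(net) nrow(validate_network(net)) == 0

## ---- igraph bridge and isomorphism --------------------------------------

# igraph with vertex attribute "id" mapping back to network node ids
as_igraph_net <- function(net) {
  idx <- match(net$nodes, net$nodes)  # 1..V
  from <- match(net$edges$from, net$nodes)
  to <- match(net$edges$to, net$nodes)
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = TRUE)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$id <- net$nodes
  g
}

#' Test two networks for labeled isomorphism
#'
#' Two rooted phylogenetic networks are considered equal when there is a
#' directed-graph isomorphism between them that maps the root to the root,
#' each taxon's leaf to the leaf of the same taxon, and preserves
#' transfer-acceptor flags (and, optionally, edge weights). Uses the VF2
#' algorithm with vertex and edge colors.
#'
#' @param a,b `phylo_network` objects
#' @param weights also require edge weights to match (`NA` matches `NA`)
#' @return logical
#' @export
network_isomorphic <- function(a, b, weights = FALSE) {
  if (length(a$nodes) != length(b$nodes) || nrow(a$edges) != nrow(b$edges) ||
      length(a$taxa) != length(b$taxa))
    return(FALSE)
  labs <- sort(names(a$taxa))
  if (!identical(labs, sort(names(b$taxa)))) return(FALSE)

  vcol <- function(net) {
    col <- integer(length(net$nodes))           # 0 = unlabeled internal
    col[match(net$taxa[labs], net$nodes)] <- seq_along(labs)
    col[match(net$root, net$nodes)] <- length(labs) + 1L  # root is never a taxon here
    col
  }
  # a labeled root (single-taxon network) keeps its taxon color
  vcol_a <- vcol(a); vcol_b <- vcol(b)

  ecol <- function(net, dict) {
    col <- as.integer(net$edges$acceptor)
    if (weights) {
      w <- net$edges$weight
      wi <- match(round(w, 12), dict)
      wi[is.na(wi)] <- 0L
      col <- col + 2L * wi
    }
    col + 1L
  }
  dict <- if (weights)
    sort(unique(round(c(a$edges$weight, b$edges$weight), 12))) else NULL

  igraph::isomorphic(as_igraph_net(a), as_igraph_net(b), method = "vf2",
                     vertex.color1 = vcol_a, vertex.color2 = vcol_b,
                     edge.color1 = ecol(a, dict), edge.color2 = ecol(b, dict))
}
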