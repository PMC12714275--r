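#' Lowest stable ancestor
#'
#' The lowest stable ancestor LSA(v) is the last node (other than `v`
#' itself) that lies on every directed path from the root to `v` —
#' equivalently, the immediate dominator of `v` in the DAG rooted at the
#' network's root. For a tree node with a single parent this is that parent.
#'
#' @param net a valid `phylo_network`
#' @param v node id, not the root
#' @return node id of LSA(v)
#' @export
lowest_stable_ancestor <- function(net, v) {
  v <- as.integer(v)
  if (!(v %in% net$nodes)) stop("unknown node id: ", v)
  if (v == net$root) stop("the root has no lowest stable ancestor")
  dom <- network_idom(net)
  u <- dom[match(v, net$nodes)]
  if (is.na(u)) stop("node ", v, " is not reachable from the root")
  u
}

# immediate dominators for all nodes, as ids aligned with net$nodes
# (NA for the root / unreachable nodes)
network_idom <- function(net) {
  g <- as_igraph_net(net)
  ridx <- match(net$root, net$nodes)
  dom <- igraph::dominator_tree(g, root = ridx)$dom
  dom <- as.numeric(dom)
  dom[dom < 1 | is.na(dom)] <- NA
  ids <- rep(NA_integer_, length(net$nodes))
  ok <- !is.na(dom)
  ids[ok] <- net$nodes[dom[ok]]
  ids
}

#' Build the backbone tree of a network
#'
#' The backbone tree B spans every node of the network. In the combining
#' view, each reticulate node v loses all incoming edges and is re-attached
#' below its lowest stable ancestor. In the transfer view, a reticulate node
#' with a designated transfer-acceptor edge keeps only that edge (a transfer
#' node without an acceptor flag falls back to combining treatment). Former
#' parents that lose all their children become unlabeled leaves of B.
#'
#' The per-node child order of B determines the y-coordinates of the layout;
#' the default order sorts children by the smallest taxon label in their
#' B-subtree (ties by node id) and is the deterministic starting point for
#' [optimize_child_orders()].
#'
#' @param net a valid `phylo_network`
#' @param view `"combining"` or `"transfer"`
#' @return an object of class `backbone_tree`: fields `root`, `nodes`,
#'   `edges` (with `rerouted` flag), `children` (ordered child lists, indexed
#'   by node id), `parent`, `leaves`, `unlabeled_leaves`, `H` (number of
#'   B-leaves plus 1), `lsa` (LSA per reticulate node), `lsa_nodes`
#'   (nodes that are the LSA of at least one reticulate node), `view`,
#'   `taxa`.
#' @export
build_backbone <- function(net, view = c("combining", "transfer")) {
  view <- match.arg(view)
  viol <- validate_network(net)
  if (nrow(viol))
    stop("network does not validate (", paste(unique(viol$rule),
                                              collapse = ", "), ")")
  indeg <- node_in_degree(net)
  retic <- net$nodes[indeg[net$nodes] >= 2]
  idom <- network_idom(net)
  lsa <- stats::setNames(idom[match(retic, net$nodes)], retic)

  ed <- net$edges
  ed$rerouted <- FALSE
  for (v in retic) {
    ein <- which(ed$to == v)
    if (view == "transfer" && any(ed$acceptor[ein])) {
      drop <- ein[!ed$acceptor[ein]]
      if (length(drop)) ed <- ed[-drop, , drop = FALSE]
    } else {
      u <- lsa[[as.character(v)]]
      ed <- ed[ed$to != v, , drop = FALSE]
      ed <- rbind(ed, data.frame(from = u, to = v, weight = NA_real_,
                                 acceptor = FALSE, rerouted = TRUE))
    }
  }
  stopifnot(nrow(ed) == length(net$nodes) - 1L)

  maxid <- max(net$nodes)
  children <- rep(list(integer()), maxid)
  sp <- split(ed$to, ed$from)
  children[as.integer(names(sp))] <- lapply(sp, as.integer)
  parent <- rep(NA_integer_, maxid)
  parent[ed$to] <- ed$from

  outdeg <- tabulate(ed$from, nbins = maxid)
  bleaves <- net$nodes[outdeg[net$nodes] == 0]
  unlabeled <- setdiff(bleaves, net$taxa)

  b <- structure(list(
    root = net$root, nodes = net$nodes, edges = ed,
    children = children, parent = parent,
    leaves = bleaves, unlabeled_leaves = unlabeled,
    H = length(bleaves) + 1L,
    lsa = lsa, lsa_nodes = sort(unique(unname(lsa))),
    view = view, taxa = net$taxa), class = "backbone_tree")
  b$children <- default_child_order(b)
  b
}

# children sorted by smallest taxon label in their B-subtree; subtrees
# without any labeled leaf sort last; ties broken by node id
default_child_order <- function(b) {
  maxid <- length(b$children)
  minlab <- rep(NA_character_, maxid)
  lab_of <- stats::setNames(names(b$taxa), as.character(b$taxa))
  po <- backbone_postorder(b)
  for (v in po) {
    kids <- b$children[[v]]
    if (length(kids) == 0) {
      key <- as.character(v)
      if (key %in% names(lab_of)) minlab[v] <- lab_of[[key]]
    } else {
      labs <- minlab[kids]
      labs <- labs[!is.na(labs)]
      if (length(labs)) minlab[v] <- min(labs)
    }
  }
  ch <- b$children
  for (v in b$nodes) {
    kids <- ch[[v]]
    if (length(kids) > 1) {
      key <- minlab[kids]
      ch[[v]] <- kids[order(is.na(key), key, kids)]
    }
  }
  ch
}

# post-order node sequence honoring the current child order
backbone_postorder <- function(b) {
  out <- integer(length(b$nodes)); k <- 0L
  st_node <- b$root; st_exp <- FALSE
  while (length(st_node)) {
    i <- length(st_node)
    v <- st_node[i]; e <- st_exp[i]
    st_node <- st_node[-i]; st_exp <- st_exp[-i]
    if (e) { k <- k + 1L; out[k] <- v }
    else {
      st_node <- c(st_node, v); st_exp <- c(st_exp, TRUE)
      kids <- b$children[[v]]
      if (length(kids)) {
        st_node <- c(st_node, rev(kids))
        st_exp <- c(st_exp, rep(FALSE, length(kids)))
      }
    }
  }
  out
}

# pre-order node sequence (parents before children)
backbone_preorder <- function(b) {
  out <- integer(length(b$nodes)); k <- 0L
  st <- b$root
  while (length(st)) {
    i <- length(st); v <- st[i]; st <- st[-i]
    k <- k + 1L; out[k] <- v
    kids <- b$children[[v]]
    if (length(kids)) st <- c(st, rev(kids))
  }
  out
}

#' @export
print.backbone_tree <- function(x, ...) {
  cat(sprintf(
    "Backbone tree (%s view): %d nodes, %d leaves (%d unlabeled), H = %d\n",
    x$view, length(x$nodes), length(x$leaves), length(x$unlabeled_leaves),
    x$H))
  if (length(x$lsa))
    cat("Rerouting anchors (LSA nodes):",
        paste(x$lsa_nodes, collapse = ", "), "\n")
  invisible(x)
}
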