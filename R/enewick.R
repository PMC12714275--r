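## Extended Newick I/O.
##
## Reticulate nodes are written with a shared tag (#H1, #LGT1, #R1 or bare
## #1): every occurrence of the tag contributes a parent edge, and the single
## occurrence carrying a subtree contributes the node's children. A '##'
## occurrence marks that parent edge as the transfer-acceptor edge. ':len'
## suffixes carry edge weights; '[...]' comment blocks are skipped.

#' Parse extended Newick text
#'
#' Parses one or more ';'-terminated extended Newick statements into rooted
#' phylogenetic networks. Reticulation tags occurring k >= 2 times merge into
#' one reticulate node with k parents; a `##` occurrence flags that incoming
#' edge as the transfer-acceptor edge; `:len` suffixes populate edge weights.
#' Through nodes produced by parsing (single-child nestings) are contracted,
#' summing any weights. Internal node names are kept as display labels, not
#' taxa.
#'
#' @param text character scalar (or vector, concatenated with newlines)
#'   containing at least one statement
#' @return list of `phylo_network` objects, one per statement
#' @export
parse_extended_newick <- function(text) {
  text <- paste(text, collapse = "\n")
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pos <- 1L

  perr <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg),
                             call. = FALSE)
  skip <- function() {
    repeat {
      while (pos <= n && ch[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
      if (pos <= n && ch[pos] == "[") {
        while (pos <= n && ch[pos] != "]") pos <<- pos + 1L
        if (pos > n) perr("unclosed '[' comment")
        pos <<- pos + 1L
      } else break
    }
  }
  peek <- function() if (pos <= n) ch[pos] else ""

  delims <- c("(", ")", ",", ";", ":", "#", "[", "'",
              " ", "\t", "\n", "\r")
  read_name <- function() {
    skip()
    if (peek() == "'") {
      pos <<- pos + 1L
      out <- character()
      repeat {
        if (pos > n) perr("unterminated quoted label")
        if (ch[pos] == "'") {
          if (pos + 1L <= n && ch[pos + 1L] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, ch[pos]); pos <<- pos + 1L }
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= n && !(ch[pos] %in% delims)) pos <<- pos + 1L
      if (pos > start) paste(ch[start:(pos - 1)], collapse = "") else ""
    }
  }
  read_suffix <- function() {
    name <- read_name()
    tag <- NULL; acceptor <- FALSE; len <- NA_real_
    skip()
    if (peek() == "#") {
      pos <<- pos + 1L
      if (peek() == "#") { acceptor <- TRUE; pos <<- pos + 1L }
      start <- pos
      while (pos <= n && grepl("[A-Za-z0-9_]", ch[pos])) pos <<- pos + 1L
      tag <- if (pos > start) paste(ch[start:(pos - 1)], collapse = "") else ""
      if (!nzchar(tag)) perr("empty reticulation tag after '#'")
    }
    skip()
    if (peek() == ":") {
      pos <<- pos + 1L; skip()
      start <- pos
      while (pos <= n && grepl("[-+0-9.eE]", ch[pos])) pos <<- pos + 1L
      num <- if (pos > start) paste(ch[start:(pos - 1)], collapse = "") else ""
      len <- suppressWarnings(as.numeric(num))
      if (is.na(len)) perr("malformed branch length")
    }
    list(name = name, tag = tag, acceptor = acceptor, length = len)
  }
  parse_clade <- function() {
    skip()
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_clade()
        skip()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        perr("expected ',' or ')'")
      }
    }
    c(list(children = children), read_suffix())
  }

  networks <- list()
  repeat {
    skip()
    if (pos > n) break
    occ <- parse_clade()
    skip()
    if (peek() != ";") perr("expected ';' at end of statement")
    pos <- pos + 1L
    networks[[length(networks) + 1L]] <- occurrences_to_network(occ)
  }
  if (length(networks) == 0) stop("no ';'-terminated statement found")
  networks
}

# Convert one parsed occurrence tree into a phylo_network
occurrences_to_network <- function(root_occ) {
  env <- new.env(parent = emptyenv())
  env$next_id <- 0L
  env$from <- integer(); env$to <- integer()
  env$weight <- numeric(); env$acceptor <- logical()
  env$tag_node <- list()      # tag -> node id
  env$tag_count <- list()     # tag -> occurrence count
  env$tag_owner <- list()     # tag -> TRUE once a subtree-bearing occurrence seen
  env$tag_acc <- list()       # tag -> count of '##' occurrences
  env$tag_name <- list()
  env$leaf_name <- list()     # node id -> taxon label (leaves)
  env$int_name <- list()      # node id -> display label

  new_id <- function() { env$next_id <- env$next_id + 1L; env$next_id }

  visit <- function(occ, parent) {
    if (!is.null(occ$tag)) {
      tg <- occ$tag
      if (is.null(parent))
        stop("parse error: reticulation tag '", tg, "' at statement root",
             call. = FALSE)
      if (is.null(env$tag_node[[tg]])) {
        env$tag_node[[tg]] <- new_id()
        env$tag_count[[tg]] <- 0L
        env$tag_acc[[tg]] <- 0L
      }
      v <- env$tag_node[[tg]]
      env$tag_count[[tg]] <- env$tag_count[[tg]] + 1L
      if (occ$acceptor) {
        env$tag_acc[[tg]] <- env$tag_acc[[tg]] + 1L
        if (env$tag_acc[[tg]] > 1)
          stop("parse error: two '##' occurrences of tag '", tg, "'",
               call. = FALSE)
      }
      if (nzchar(occ$name) && is.null(env$tag_name[[tg]]))
        env$tag_name[[tg]] <- occ$name
      if (length(occ$children)) {
        if (isTRUE(env$tag_owner[[tg]]))
          stop("parse error: tag '", tg, "' carries two subtrees",
               call. = FALSE)
        env$tag_owner[[tg]] <- TRUE
        for (childocc in occ$children) visit(childocc, v)
      }
    } else {
      v <- new_id()
      if (length(occ$children)) {
        if (nzchar(occ$name)) env$int_name[[as.character(v)]] <- occ$name
        for (childocc in occ$children) visit(childocc, v)
      } else {
        if (nzchar(occ$name)) env$leaf_name[[as.character(v)]] <- occ$name
      }
    }
    if (!is.null(parent)) {
      env$from <- c(env$from, parent); env$to <- c(env$to, v)
      env$weight <- c(env$weight, occ$length)
      env$acceptor <- c(env$acceptor, isTRUE(occ$acceptor))
    }
    v
  }
  root <- visit(root_occ, NULL)

  once <- names(env$tag_count)[unlist(env$tag_count) < 2]
  if (length(once))
    stop("parse error: reticulation tag(s) used only once: ",
         paste(once, collapse = ", "), call. = FALSE)
  # tagged leaves (no subtree-bearing occurrence) take their tag name as label
  for (tg in names(env$tag_node)) {
    if (!isTRUE(env$tag_owner[[tg]]) && !is.null(env$tag_name[[tg]]))
      env$leaf_name[[as.character(env$tag_node[[tg]])]] <- env$tag_name[[tg]]
    else if (isTRUE(env$tag_owner[[tg]]) && !is.null(env$tag_name[[tg]]))
      env$int_name[[as.character(env$tag_node[[tg]])]] <- env$tag_name[[tg]]
  }

  ed <- data.frame(from = env$from, to = env$to,
                   weight = env$weight, acceptor = env$acceptor)

  # contract through nodes (in-degree 1, out-degree 1) created by nesting
  repeat {
    indeg <- tabulate(ed$to, nbins = env$next_id)
    outdeg <- tabulate(ed$from, nbins = env$next_id)
    thr <- which(indeg == 1 & outdeg == 1)
    thr <- setdiff(thr, root)
    if (!length(thr)) break
    v <- thr[1]
    ein <- which(ed$to == v); eout <- which(ed$from == v)
    w_in <- ed$weight[ein]; w_out <- ed$weight[eout]
    w <- if (is.na(w_in) && is.na(w_out)) NA_real_ else sum(w_in, w_out, na.rm = TRUE)
    ed$to[ein] <- ed$to[eout]
    ed$weight[ein] <- w
    ed$acceptor[ein] <- ed$acceptor[ein] | ed$acceptor[eout]
    ed <- ed[-eout, ]
  }

  taxa_ids <- as.integer(names(env$leaf_name))
  taxa <- stats::setNames(taxa_ids, unlist(env$leaf_name))
  nl <- if (length(env$int_name)) unlist(env$int_name) else NULL
  net <- phylo_network(ed, taxa = taxa, root = root, node_labels = nl)
  if (!attr(topo_order(net), "acyclic"))
    stop("parse error: reticulation tags induce a directed cycle",
         call. = FALSE)
  net
}

#' Write a network as extended Newick
#'
#' Serializes a validated network. For every reticulate node, the first
#' parent reached in a depth-first traversal from the root (children in
#' increasing node-id order) carries the inline subtree occurrence; the other
#' parents emit tag references. Transfer-acceptor edges are re-emitted with
#' `##`. The output re-parses to an isomorphic network.
#'
#' @param net a valid `phylo_network`
#' @param include_weights emit `:len` for edges whose weight is present
#' @return a single character string ending in ";"
#' @export
write_extended_newick <- function(net, include_weights = TRUE) {
  viol <- validate_network(net)
  if (nrow(viol))
    stop("cannot write invalid network (", nrow(viol), " violation(s): ",
         paste(unique(viol$rule), collapse = ", "), ")")

  ch <- net_children(net)
  ch <- lapply(ch, sort)
  indeg <- node_in_degree(net)
  retic <- net$nodes[indeg[net$nodes] >= 2]

  # inline parent = first parent on a DFS from the root, ties by child id
  inline_parent <- integer(0); tag_no <- integer(0)
  counter <- 0L
  seen <- logical(max(net$nodes))
  dfs <- function(v) {
    for (w in ch[[v]]) {
      if (indeg[w] >= 2 && is.na(inline_parent[as.character(w)])) {
        inline_parent[as.character(w)] <<- v
        counter <<- counter + 1L
        tag_no[as.character(w)] <<- counter
      }
      if (!seen[w]) { seen[w] <<- TRUE; dfs(w) }
    }
  }
  inline_parent <- stats::setNames(rep(NA_integer_, length(retic)),
                                   as.character(retic))
  tag_no <- stats::setNames(rep(NA_integer_, length(retic)),
                            as.character(retic))
  seen[net$root] <- TRUE
  dfs(net$root)

  taxon_of <- stats::setNames(names(net$taxa), as.character(net$taxa))
  quote_label <- function(x) {
    if (grepl("[][ \t\n\r(),:;#']", x))
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    else x
  }
  fmt_len <- function(w) {
    if (is.na(w) || !include_weights) ""
    else paste0(":", sprintf("%.17g", w))  # round-trips doubles exactly
  }
  edge_w <- function(u, v)
    net$edges$weight[net$edges$from == u & net$edges$to == v]
  edge_acc <- function(u, v)
    net$edges$acceptor[net$edges$from == u & net$edges$to == v]

  emit <- function(v, parent) {
    isretic <- indeg[v] >= 2
    tagpart <- ""
    key <- as.character(v)
    name <- if (key %in% names(taxon_of)) quote_label(taxon_of[[key]])
    else if (!is.null(net$node_labels) && key %in% names(net$node_labels))
      quote_label(net$node_labels[[key]])
    else ""
    lenpart <- if (is.null(parent)) "" else fmt_len(edge_w(parent, v))
    if (isretic) {
      hash <- if (!is.null(parent) && edge_acc(parent, v)) "##" else "#"
      tagpart <- paste0(hash, "H", tag_no[[as.character(v)]])
      if (is.null(parent) || inline_parent[[as.character(v)]] != parent)
        return(paste0(name, tagpart, lenpart))
    }
    if (length(ch[[v]]) == 0)
      return(paste0(name, tagpart, lenpart))
    inner <- vapply(ch[[v]], emit, character(1), parent = v)
    paste0("(", paste(inner, collapse = ","), ")", name, tagpart, lenpart)
  }
  paste0(emit(net$root, NULL), ";")
}

#' Read / write extended Newick files
#'
#' `read_extended_newick()` parses every statement in a file;
#' `write_extended_newick_file()` writes one or more networks, one statement
#' per line (UTF-8).
#'
#' @param path file path
#' @param nets a `phylo_network` or list of them
#' @param include_weights passed to [write_extended_newick()]
#' @return a list of `phylo_network` objects (read); `path`, invisibly (write)
#' @export
read_extended_newick <- function(path) {
  parse_extended_newick(readLines(path, warn = FALSE))
}

#' @rdname read_extended_newick
#' @export
write_extended_newick_file <- function(nets, path, include_weights = TRUE) {
  if (inherits(nets, "phylo_network")) nets <- list(nets)
  writeLines(vapply(nets, write_extended_newick, character(1),
                    include_weights = include_weights), path)
  invisible(path)
}
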