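# Independent oracles used to cross-check the package's algorithms.
# These deliberately use naive path-enumeration / full-enumeration
# implementations, kept separate from the code paths they verify.

# all directed root->v paths by DFS (node id sequences)
all_root_paths <- function(net, v) {
  ch <- split(net$edges$to, net$edges$from)
  out <- list()
  walk <- function(u, acc) {
    if (u == v) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (w in ch[[as.character(u)]]) walk(w, c(acc, w))
  }
  walk(net$root, net$root)
  out
}

# LSA by brute force: intersect the node sets of all root->v paths and take
# the last common node before v on any of them
oracle_lsa <- function(net, v) {
  ps <- all_root_paths(net, v)
  common <- Reduce(intersect, ps)
  common <- setdiff(common, v)
  p1 <- ps[[1]]
  common[which.max(match(common, p1))]
}

# independent recursive y-assignment on a backbone tree (0-based leaves,
# children mean or descendant-leaf mean)
oracle_y <- function(b, mode = "children") {
  y <- rep(NA_real_, length(b$children))
  counter <- 0L
  rec <- function(v) {
    kids <- b$children[[v]]
    if (length(kids) == 0) {
      y[v] <<- counter
      counter <<- counter + 1L
      return(c(y[v], 1))
    }
    res <- vapply(kids, rec, numeric(2))
    y[v] <<- if (mode == "children") mean(y[kids])
             else sum(res[1, ] * res[2, ]) / sum(res[2, ])
    c(sum(res[1, ] * res[2, ]) / sum(res[2, ]), sum(res[2, ]))
  }
  rec(b$root)
  y
}

# displacement edge set computed independently of rd_edge_set()
oracle_rd_edges <- function(net, b) {
  indeg <- tabulate(net$edges$to, nbins = max(net$nodes))
  keep <- indeg[net$edges$to] >= 2 & !net$edges$acceptor &
    !(paste(net$edges$from, net$edges$to) %in%
        paste(b$edges$from, b$edges$to))
  cbind(net$edges$from[keep], net$edges$to[keep])
}

oracle_displacement <- function(net, b, mode = "children") {
  y <- oracle_y(b, mode)
  re <- oracle_rd_edges(net, b)
  if (nrow(re) == 0) return(0)
  sum(abs(y[re[, 1]] - y[re[, 2]]))
}

# all permutations of 1..k as a matrix (k! rows)
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

# global minimum displacement over ALL joint child orders of B, by full
# enumeration (recursion over multi-child nodes)
oracle_joint_optimum <- function(net, b, mode = "children") {
  multi <- b$nodes[vapply(b$nodes, function(v)
    length(b$children[[v]]) >= 2, logical(1))]
  best <- Inf
  rec <- function(i) {
    if (i > length(multi)) {
      best <<- min(best, oracle_displacement(net, b, mode))
      return(invisible())
    }
    v <- multi[i]
    kids <- b$children[[v]]
    pm <- all_perms(length(kids))
    for (r in seq_len(nrow(pm))) {
      b$children[[v]] <<- kids[pm[r, ]]
      rec(i + 1L)
    }
    b$children[[v]] <<- kids
  }
  rec(1L)
  best
}

# brute-force MinLA optimum by enumerating all n! linear arrangements
oracle_minla_brute <- function(n, em) {
  pm <- all_perms(n)           # pm[i, v] = position of vertex v
  cost <- numeric(nrow(pm))
  for (r in seq_len(NROW(em)))
    cost <- cost + abs(pm[, em[r, 1]] - pm[, em[r, 2]])
  min(cost)
}

# exact MinLA optimum by dynamic programming over vertex subsets
# (min over orders of the sum of cut sizes over prefixes)
oracle_minla_dp <- function(n, em) {
  full <- 2^n
  f <- rep(Inf, full); f[1] <- 0
  bits <- bitwShiftL(1L, 0:(n - 1))
  for (S in 1:(full - 1)) {
    inS1 <- bitwAnd(S, bits[em[, 1]]) > 0
    inS2 <- bitwAnd(S, bits[em[, 2]]) > 0
    cS <- sum(inS1 != inS2)
    for (v in seq_len(n)) if (bitwAnd(S, bits[v]) > 0) {
      val <- f[S - bits[v] + 1] + cS
      if (val < f[S + 1]) f[S + 1] <- val
    }
  }
  f[full]
}

# random connected undirected graph on n vertices (edge prob p, plus a
# random spanning path to guarantee connectivity)
random_graph <- function(n, p = 0.4) {
  em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  em <- em[stats::runif(nrow(em)) < p, , drop = FALSE]
  sp <- sample(n)
  em <- rbind(em, cbind(pmin(sp[-n], sp[-1]), pmax(sp[-n], sp[-1])))
  unique(em)
}

# smallest fixpoint >= d of the transfer-depth constraint system, computed
# by one-at-a-time constraint repair in arbitrary order
oracle_depth_fixpoint <- function(net, d, max_iter = 10000) {
  kinds <- phynetdraw:::edge_kinds(net)
  tr <- which(kinds == "transfer")
  keep <- which(kinds %in% c("tree", "transfer_acceptor"))
  for (i in seq_len(max_iter)) {
    done <- TRUE
    for (e in sample(c(tr, keep))) {
      u <- net$edges$from[e]; w <- net$edges$to[e]
      if (e %in% tr) {
        if (d[u] < d[w]) { d[u] <- d[w]; done <- FALSE }
      } else {
        if (d[w] < d[u] + 1) { d[w] <- d[u] + 1; done <- FALSE }
      }
    }
    if (done) return(d)
  }
  stop("no fixpoint found")
}
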