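#' Simulate a random rooted phylogenetic network
#'
#' Grows a random rooted binary tree on `n` leaves by uniform edge
#' attachment, assigns node times increasing from the root, and adds `h`
#' reticulations: each reticulation samples a time point, picks two distinct
#' tree edges alive at that time (so transfers connect contemporaneous
#' lineages and the network is globally time-consistent), subdivides both,
#' and adds a reticulate edge between the new nodes. Tree edges carry
#' weights equal to their time spans, so phylograms can be drawn directly.
#'
#' @param n number of taxa (leaves), at least 2; leaves are labeled
#'   `t1..tn`
#' @param h number of reticulations (default `round(0.2 * n)`)
#' @param seed optional integer seed (deterministic output per seed)
#' @param acceptors flag the pre-existing lineage's in-edge of every
#'   reticulate node as the transfer-acceptor edge (making each
#'   reticulation a transfer node)
#' @param max_tries resampling budget for placing reticulations
#' @return a valid `phylo_network` with exactly `n` labeled leaves and `h`
#'   reticulate nodes
#' @export
random_network <- function(n, h = round(0.2 * n), seed = NULL,
                           acceptors = FALSE, max_tries = 200 * (h + 1)) {
  n <- as.integer(n); h <- as.integer(h)
  if (n < 2) stop("n must be at least 2")
  if (h < 0) stop("h must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  # binary tree by uniform edge attachment
  from <- c(1L, 1L); to <- c(2L, 3L)
  nextid <- 4L
  nleaf <- 2L
  while (nleaf < n) {
    e <- sample.int(length(from), 1L)
    m <- nextid; l <- nextid + 1L; nextid <- nextid + 2L
    v <- to[e]
    to[e] <- m
    from <- c(from, m, m); to <- c(to, v, l)
    nleaf <- nleaf + 1L
  }

  # node times strictly increasing from the root
  tm <- rep(NA_real_, nextid - 1L)
  tm[1L] <- 0
  ch <- split(to, from)
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- ch[[as.character(v)]]
    for (w in kids) {
      tm[w] <- tm[v] + stats::runif(1, 0.3, 1.2)
      queue <- c(queue, w)
    }
  }

  weight <- tm[to] - tm[from]
  acceptor <- rep(FALSE, length(from))
  is_retic_target <- rep(FALSE, nextid - 1L)

  placed <- 0L; tries <- 0L
  tmax <- max(tm)
  while (placed < h) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", h, " reticulations (", placed,
           " placed after ", max_tries, " tries)")
    tstar <- stats::runif(1, 0, tmax)
    alive <- which(tm[from] < tstar & tm[to] > tstar & !is_retic_target[to])
    if (length(alive) < 2) next
    pick <- sample(alive, 2L)
    e1 <- pick[1]; e2 <- pick[2]
    # subdivide e1 at tstar -> transfer source a
    a <- nextid; nextid <- nextid + 1L
    v1 <- to[e1]
    to[e1] <- a; weight[e1] <- tstar - tm[from[e1]]
    from <- c(from, a); to <- c(to, v1)
    weight <- c(weight, tm[v1] - tstar); acceptor <- c(acceptor, FALSE)
    # subdivide e2 at tstar -> reticulate node bnode
    bnode <- nextid; nextid <- nextid + 1L
    v2 <- to[e2]
    to[e2] <- bnode; weight[e2] <- tstar - tm[from[e2]]
    if (acceptors) acceptor[e2] <- TRUE
    from <- c(from, bnode); to <- c(to, v2)
    weight <- c(weight, tm[v2] - tstar); acceptor <- c(acceptor, FALSE)
    # the transfer itself
    from <- c(from, a); to <- c(to, bnode)
    weight <- c(weight, NA_real_); acceptor <- c(acceptor, FALSE)
    tm <- c(tm, tstar, tstar)
    is_retic_target <- c(is_retic_target, FALSE, FALSE)
    is_retic_target[bnode] <- TRUE
    placed <- placed + 1L
  }

  leaves <- setdiff(to, from)
  leaves <- sort(leaves)
  taxa <- stats::setNames(leaves, paste0("t", seq_along(leaves)))
  phylo_network(data.frame(from = from, to = to, weight = weight,
                           acceptor = acceptor),
                taxa = taxa, root = 1L)
}
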