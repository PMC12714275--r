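## Topology capture from raster figures.
##
## Pixel convention: images are logical/numeric matrices indexed [row, col];
## point coordinates are given as (x = column, y = row), so they match the
## layout convention (y downward). The pipeline assumes a phylogeny drawn in
## dark thin lines on a white background:
## binarize -> skeletonize -> detect_nodes -> trace_paths ->
## filter_label_paths -> assemble_network.

#' Binarize a raster image
#'
#' Converts a grayscale/color raster to a logical foreground mask: pixels
#' darker than the threshold (default: Otsu's automatic threshold on the
#' luminance) are foreground.
#'
#' @param image a file path (read via EBImage), an EBImage `Image`, a
#'   numeric matrix of luminances in `[0, 1]`, or an already-logical mask
#'   (returned unchanged)
#' @param threshold luminance cutoff; `NULL` for automatic selection
#' @return logical matrix (`TRUE` = foreground), `[row, col]`
#' @export
binarize <- function(image, threshold = NULL) {
  if (is.logical(image)) {
    if (!any(image)) stop("no drawable content (empty foreground)")
    return(image)
  }
  if (is.character(image)) image <- EBImage::readImage(image)
  if (inherits(image, "Image")) {
    if (EBImage::colorMode(image) > 0)
      image <- EBImage::channel(image, "luminance")
    image <- t(EBImage::imageData(image))  # EBImage stores [x, y]
  }
  m <- as.matrix(image)
  if (length(dim(m)) != 2) stop("expected a 2-d image")
  m <- pmin(pmax(m, 0), 1)
  if (is.null(threshold)) threshold <- EBImage::otsu(m, range = c(0, 1))
  fg <- m < threshold
  if (!any(fg)) stop("no drawable content (empty foreground)")
  fg
}

shift_mat <- function(m, dr, dc) {
  # value of the neighbor at (row + dr, col + dc); zero outside
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Skeletonize a binary image
#'
#' Morphological thinning (Zhang-Suen) to single-pixel-wide lines,
#' preserving the image's topology (8-connectivity for the foreground,
#' 4-connectivity for the background).
#'
#' @param grid logical foreground matrix
#' @return logical matrix of the same size, lines one pixel wide
#' @export
skeletonize <- function(grid) {
  img <- matrix(0L, nrow(grid) + 2, ncol(grid) + 2)
  img[2:(nrow(grid) + 1), 2:(ncol(grid) + 1)] <- grid * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1)
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      else
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      del <- img == 1L & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img[2:(nrow(grid) + 1), 2:(ncol(grid) + 1), drop = FALSE] == 1L
}

neighbor_count <- function(sk) {
  m <- sk * 1L
  shift_mat(m, -1, 0) + shift_mat(m, -1, 1) + shift_mat(m, 0, 1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, 0) + shift_mat(m, 1, -1) +
    shift_mat(m, 0, -1) + shift_mat(m, -1, -1)
}

#' Detect skeleton nodes
#'
#' Applies the 8-neighbor count mask to a unit-width skeleton: pixels with
#' exactly one neighbor are endpoints, pixels with three or more are
#' junction pixels; 8-adjacent junction pixels are merged into one node
#' cluster whose position is the pixel centroid. Isolated pixels count as
#' endpoints.
#'
#' @param sk logical skeleton matrix
#' @return list with `nodes` (data frame `id`, `x`, `y`, `type`) and
#'   `nodemap` (integer matrix, 0 where no node, else node id)
#' @export
detect_nodes <- function(sk) {
  nb <- neighbor_count(sk)
  endpoint <- sk & nb <= 1
  junction <- sk & nb >= 3
  nodemap <- matrix(0L, nrow(sk), ncol(sk))
  nodes <- list()
  nid <- 0L
  if (any(junction)) {
    dil <- EBImage::dilate(junction * 1, EBImage::makeBrush(3, "box"))
    lab <- EBImage::bwlabel(dil)
    labs <- sort(unique(lab[junction]))
    for (l in labs) {
      nid <- nid + 1L
      sel <- which(junction & lab == l, arr.ind = TRUE)
      nodemap[sel] <- nid
      nodes[[nid]] <- data.frame(id = nid, x = mean(sel[, 2]),
                                 y = mean(sel[, 1]), type = "junction")
    }
  }
  eps <- which(endpoint, arr.ind = TRUE)
  if (nrow(eps)) for (i in seq_len(nrow(eps))) {
    nid <- nid + 1L
    nodemap[eps[i, 1], eps[i, 2]] <- nid
    nodes[[nid]] <- data.frame(id = nid, x = eps[i, 2], y = eps[i, 1],
                               type = "endpoint")
  }
  list(nodes = if (length(nodes)) do.call(rbind, nodes)
       else data.frame(id = integer(), x = numeric(), y = numeric(),
                       type = character()),
       nodemap = nodemap)
}

offs8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Trace skeleton paths between nodes
#'
#' Flood-fill style tracing: every degree-2 skeleton pixel is assigned to
#' exactly one path; each path connects two node clusters (or one cluster to
#' itself). Closed curves with no node at all are reported as loops with
#' `NA` end nodes; stray pixels unreachable from any node are dropped.
#'
#' @param sk logical skeleton matrix
#' @param nodes result of [detect_nodes()]
#' @return list of paths; each has `from`, `to` (node ids or `NA`) and
#'   `pixels` (n x 2 matrix of (row, col), first/last pixel adjacent or
#'   equal to the end clusters)
#' @export
trace_paths <- function(sk, nodes) {
  nodemap <- nodes$nodemap
  pathpix <- sk & nodemap == 0L
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  nr <- nrow(sk); nc <- ncol(sk)
  paths <- list()

  walk <- function(startnode, r0, c0, r1, c1) {
    chain <- rbind(c(r0, c0), c(r1, c1))
    visited[r1, c1] <<- TRUE
    cur <- c(r1, c1)
    repeat {
      rs <- cur[1] + offs8[, 1]; cs <- cur[2] + offs8[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      rs <- rs[ok]; cs <- cs[ok]
      skn <- sk[cbind(rs, cs)]
      nm <- nodemap[cbind(rs, cs)]
      # terminate at a node cluster (not immediately back at the start)
      term <- which(skn & nm > 0 &
                    !(nm == startnode & nrow(chain) <= 2 &
                      abs(rs - r0) <= 1 & abs(cs - c0) <= 1))
      if (length(term)) {
        t1 <- term[1]
        chain <- rbind(chain, c(rs[t1], cs[t1]))
        return(list(to = nm[t1], pixels = chain))
      }
      nxt <- which(skn & nm == 0 & !visited[cbind(rs, cs)])
      if (length(nxt) == 0) return(list(to = NA_integer_, pixels = chain))
      j <- nxt[1]
      cur <- c(rs[j], cs[j])
      visited[cur[1], cur[2]] <<- TRUE
      chain <- rbind(chain, cur)
    }
  }

  ntab <- nodes$nodes
  npix <- which(nodemap > 0L, arr.ind = TRUE)
  if (nrow(npix)) {
    npix <- npix[order(nodemap[npix]), , drop = FALSE]
    seen_pairs <- character(0)
    for (i in seq_len(nrow(npix))) {
      r <- npix[i, 1]; cc <- npix[i, 2]
      id <- nodemap[r, cc]
      rs <- r + offs8[, 1]; cs <- cc + offs8[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      rs <- rs[ok]; cs <- cs[ok]
      for (j in seq_along(rs)) {
        if (pathpix[rs[j], cs[j]] && !visited[rs[j], cs[j]]) {
          res <- walk(id, r, cc, rs[j], cs[j])
          if (!is.na(res$to))   # dead-end walks are stray artifacts: drop
            paths[[length(paths) + 1L]] <-
              list(from = id, to = res$to, pixels = res$pixels)
        } else if (nodemap[rs[j], cs[j]] > 0L &&
                   nodemap[rs[j], cs[j]] != id) {
          # directly adjacent clusters: zero-interior path
          other <- nodemap[rs[j], cs[j]]
          key <- paste(sort(c(id, other)), collapse = "-")
          if (!(key %in% seen_pairs)) {
            seen_pairs <- c(seen_pairs, key)
            paths[[length(paths) + 1L]] <-
              list(from = id, to = other,
                   pixels = rbind(c(r, cc), c(rs[j], cs[j])))
          }
        }
      }
    }
  }
  # closed curves without any node
  left <- which(pathpix & !visited, arr.ind = TRUE)
  while (nrow(left)) {
    r0 <- left[1, 1]; c0 <- left[1, 2]
    visited[r0, c0] <- TRUE
    chain <- rbind(c(r0, c0))
    cur <- c(r0, c0)
    repeat {
      rs <- cur[1] + offs8[, 1]; cs <- cur[2] + offs8[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      rs <- rs[ok]; cs <- cs[ok]
      nxt <- which(pathpix[cbind(rs, cs)] & !visited[cbind(rs, cs)])
      if (length(nxt) == 0) break
      cur <- c(rs[nxt[1]], cs[nxt[1]])
      visited[cur[1], cur[2]] <- TRUE
      chain <- rbind(chain, cur)
    }
    paths[[length(paths) + 1L]] <-
      list(from = NA_integer_, to = NA_integer_, pixels = chain)
    left <- which(pathpix & !visited, arr.ind = TRUE)
  }
  paths
}

#' Remove paths lying inside label boxes
#'
#' Removes exactly those paths whose every pixel lies inside some single
#' label bounding box.
#'
#' @param paths list of paths from [trace_paths()]
#' @param label_boxes data frame with columns `x0`, `y0`, `x1`, `y1`
#'   (pixel coordinates, x = column, y = row); `NULL` for no boxes
#' @return filtered path list
#' @export
filter_label_paths <- function(paths, label_boxes) {
  if (is.null(label_boxes) || nrow(label_boxes) == 0) return(paths)
  inside <- vapply(paths, function(p) {
    px <- p$pixels
    for (i in seq_len(nrow(label_boxes))) {
      bx <- label_boxes[i, ]
      if (all(px[, 2] >= bx$x0 & px[, 2] <= bx$x1 &
              px[, 1] >= bx$y0 & px[, 1] <= bx$y1)) return(TRUE)
    }
    FALSE
  }, logical(1))
  paths[!inside]
}

#' Assemble a rooted network from traced paths
#'
#' Creates the root at the user-indicated location (splitting a path if the
#' nearest skeleton pixel is a path interior), infers the layout orientation
#' by comparing the root location with the detected node positions, and then
#' incorporates paths as directed edges in order of increasing distance from
#' the growing connected component: a path with exactly one connected
#' endpoint is oriented away from it; a path whose two endpoints are both
#' connected is oriented along the inferred drawing direction, and goes to
#' `unresolved_paths` when that direction is ambiguous or the resulting edge
#' would create a directed cycle. Labels are attached to the nearest
#' captured leaves.
#'
#' @param paths filtered path list
#' @param nodes result of [detect_nodes()]
#' @param root_location `c(x, y)` pixel location of the root
#' @param label_boxes optional data frame `label`, `x0`, `y0`, `x1`, `y1`
#' @param tolerance maximum distance (pixels) from `root_location` to the
#'   nearest skeleton pixel
#' @return object of class `capture_result`: `network`, `node_positions`
#'   (data frame `node`, `x`, `y`), `unresolved_paths` (each with a
#'   `reason`), `orientation`, `violations` (from [validate_network()])
#' @export
assemble_network <- function(paths, nodes, root_location,
                             label_boxes = NULL, tolerance = 5) {
  ntab <- nodes$nodes
  rx <- root_location[1]; ry <- root_location[2]

  # nearest node or path pixel
  best <- list(d = Inf)
  if (nrow(ntab)) {
    d <- sqrt((ntab$x - rx)^2 + (ntab$y - ry)^2)
    i <- which.min(d)
    best <- list(d = d[i], what = "node", id = ntab$id[i])
  }
  for (pi in seq_along(paths)) {
    px <- paths[[pi]]$pixels
    d <- sqrt((px[, 2] - rx)^2 + (px[, 1] - ry)^2)
    i <- which.min(d)
    if (d[i] < best$d)
      best <- list(d = d[i], what = "path", path = pi, at = i)
  }
  if (!is.finite(best$d) || best$d > tolerance)
    stop("root location is farther than ", tolerance,
         " pixels from any skeleton pixel")

  if (best$what == "node") {
    root_id <- best$id
  } else {
    # split the path at the chosen interior pixel
    p <- paths[[best$path]]
    root_id <- max(ntab$id, 0L) + 1L
    at <- best$at
    px <- p$pixels
    ntab <- rbind(ntab, data.frame(id = root_id, x = px[at, 2],
                                   y = px[at, 1], type = "root"))
    first <- list(from = p$from, to = root_id,
                  pixels = px[seq_len(at), , drop = FALSE])
    second <- list(from = root_id, to = p$to,
                   pixels = px[at:nrow(px), , drop = FALSE])
    if (is.na(p$from) && is.na(p$to)) {
      # loop split at the root: one path from the root back to itself
      paths[[best$path]] <-
        list(from = root_id, to = root_id,
             pixels = rbind(px[at:nrow(px), , drop = FALSE],
                            px[seq_len(at), , drop = FALSE]))
    } else {
      paths[[best$path]] <- first
      paths[[length(paths) + 1L]] <- second
    }
  }

  # orientation from root location vs node bounding box
  if (nrow(ntab) >= 2) {
    xr <- range(ntab$x); yr <- range(ntab$y)
    cx <- mean(xr); cy <- mean(yr)
    inx <- abs(rx - cx) <= 0.25 * max(diff(xr), 1) / 2 * 2
    iny <- abs(ry - cy) <= 0.25 * max(diff(yr), 1) / 2 * 2
    if (inx && iny) orientation <- "radial"
    else if (abs(rx - cx) >= abs(ry - cy))
      orientation <- if (rx <= cx) "left_right" else "right_left"
    else orientation <- if (ry <= cy) "top_bottom" else "bottom_top"
  } else orientation <- "left_right"

  proj <- function(id) {
    i <- match(id, ntab$id)
    switch(orientation,
           left_right = ntab$x[i], right_left = -ntab$x[i],
           top_bottom = ntab$y[i], bottom_top = -ntab$y[i],
           radial = sqrt((ntab$x[i] - rx)^2 + (ntab$y[i] - ry)^2))
  }

  connected <- root_id
  add_time <- stats::setNames(0L, root_id)
  efrom <- integer(); eto <- integer()
  unresolved <- list()
  remaining <- paths
  has_dirpath <- function(a, b) {  # directed path a ->* b in current edges
    if (a == b) return(TRUE)
    q <- a; seen <- a
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nxt <- eto[efrom == v]
      nxt <- setdiff(nxt, seen)
      if (b %in% nxt) return(TRUE)
      seen <- c(seen, nxt); q <- c(q, nxt)
    }
    FALSE
  }
  npos <- function(ids) ntab[match(ids, ntab$id), c("x", "y")]

  while (length(remaining)) {
    # primary key: distance from the connected component; secondary key for
    # touching (distance-0) paths: when their connected endpoint joined, so
    # the component grows breadth-first from the root
    keys <- vapply(remaining, function(p) {
      ends <- c(p$from, p$to)
      if (anyNA(ends)) return(c(Inf, Inf))
      incon <- ends %in% connected
      if (any(incon))
        return(c(0, min(add_time[as.character(ends[incon])])))
      cp <- npos(connected); ep <- npos(ends)
      dmin <- min(outer(seq_len(nrow(ep)), seq_len(nrow(cp)), function(i, j)
        sqrt((ep$x[i] - cp$x[j])^2 + (ep$y[i] - cp$y[j])^2)))
      c(dmin, Inf)
    }, numeric(2))
    k <- order(keys[1, ], keys[2, ])[1]
    p <- remaining[[k]]
    remaining <- remaining[-k]
    ends <- c(p$from, p$to)
    if (anyNA(ends)) {
      unresolved[[length(unresolved) + 1L]] <- c(p, reason = "loop")
      next
    }
    incon <- ends %in% connected
    if (!any(incon)) {
      unresolved[[length(unresolved) + 1L]] <- c(p, reason = "disconnected")
      next
    }
    if (ends[1] == ends[2]) {
      # a path from a node back to itself is a directed cycle however oriented
      unresolved[[length(unresolved) + 1L]] <-
        c(p, reason = "would-create-cycle")
      next
    }
    if (sum(incon) == 1) {
      src <- ends[incon]; tgt <- ends[!incon]
      efrom <- c(efrom, src); eto <- c(eto, tgt)
      connected <- c(connected, tgt)
      add_time[as.character(tgt)] <- length(add_time)
    } else {
      pu <- proj(ends[1]); pv <- proj(ends[2])
      if (abs(pu - pv) < 0.5) {
        unresolved[[length(unresolved) + 1L]] <-
          c(p, reason = "ambiguous-direction")
        next
      }
      src <- if (pu < pv) ends[1] else ends[2]
      tgt <- setdiff(ends, src)
      if (has_dirpath(tgt, src)) {
        unresolved[[length(unresolved) + 1L]] <-
          c(p, reason = "would-create-cycle")
        next
      }
      if (any(efrom == src & eto == tgt)) {
        unresolved[[length(unresolved) + 1L]] <-
          c(p, reason = "duplicate-edge")
        next
      }
      efrom <- c(efrom, src); eto <- c(eto, tgt)
    }
  }

  used <- sort(unique(c(root_id, efrom, eto)))
  newid <- stats::setNames(seq_along(used), used)
  ed <- data.frame(from = unname(newid[as.character(efrom)]),
                   to = unname(newid[as.character(eto)]))

  # leaves and labels
  taxa <- stats::setNames(integer(), character())
  if (!is.null(label_boxes) && nrow(label_boxes) &&
      "label" %in% names(label_boxes) && nrow(ed)) {
    leaf_old <- used[!(seq_along(used) %in% ed$from)]
    if (length(leaf_old)) {
      lp <- npos(leaf_old)
      assigned <- rep(NA_character_, length(leaf_old))
      bx <- (label_boxes$x0 + label_boxes$x1) / 2
      by <- (label_boxes$y0 + label_boxes$y1) / 2
      for (i in seq_len(nrow(label_boxes))) {
        d <- sqrt((lp$x - bx[i])^2 + (lp$y - by[i])^2)
        j <- which.min(d)
        if (is.na(assigned[j])) assigned[j] <- as.character(label_boxes$label[i])
      }
      ok <- !is.na(assigned)
      taxa <- stats::setNames(unname(newid[as.character(leaf_old[ok])]),
                              assigned[ok])
    }
  }

  net <- phylo_network(if (nrow(ed)) ed else
                         data.frame(from = integer(), to = integer()),
                       taxa = taxa, root = unname(newid[as.character(root_id)]))
  structure(list(
    network = net,
    node_positions = data.frame(node = unname(newid[as.character(used)]),
                                x = ntab$x[match(used, ntab$id)],
                                y = ntab$y[match(used, ntab$id)]),
    unresolved_paths = unresolved,
    orientation = orientation,
    violations = validate_network(net)), class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("Captured network (%s): %d nodes, %d edges, %d taxa\n",
              x$orientation, length(x$network$nodes), nrow(x$network$edges),
              length(x$network$taxa)))
  if (length(x$unresolved_paths))
    cat(length(x$unresolved_paths), "unresolved path(s):",
        paste(vapply(x$unresolved_paths, `[[`, "", "reason"),
              collapse = ", "), "\n")
  if (nrow(x$violations))
    cat(nrow(x$violations), "validation violation(s) pending user edits\n")
  invisible(x)
}

#' Capture a network topology from an image
#'
#' End-to-end wrapper around the capture pipeline:
#' [binarize()] -> [skeletonize()] -> [detect_nodes()] -> [trace_paths()] ->
#' [filter_label_paths()] -> [assemble_network()]. Label text is taken from
#' a sidecar table (e.g. produced by [render_raster_fixture()] or an
#' external OCR step); the pipeline itself performs no OCR.
#'
#' @param image see [binarize()]
#' @param root_location `c(x, y)` pixel location of the root
#' @param labels optional label table (`label`, `x0`, `y0`, `x1`, `y1`) or
#'   path to a TSV with those columns
#' @param threshold see [binarize()]
#' @param tolerance see [assemble_network()]
#' @return a `capture_result`
#' @export
capture_network <- function(image, root_location, labels = NULL,
                            threshold = NULL, tolerance = 5) {
  if (is.character(labels))
    labels <- utils::read.delim(labels, stringsAsFactors = FALSE)
  fg <- binarize(image, threshold)
  sk <- skeletonize(fg)
  nodes <- detect_nodes(sk)
  paths <- trace_paths(sk, nodes)
  paths <- filter_label_paths(paths, labels)
  assemble_network(paths, nodes, root_location, label_boxes = labels,
                   tolerance = tolerance)
}
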