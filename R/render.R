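## Rendering: SVG output and deterministic raster fixtures.

svg_num <- function(x) formatC(x, format = "f", digits = 2)

#' Render a layout as SVG
#'
#' Tree and transfer-acceptor edges are drawn as right-angled two-segment
#' polylines (vertical, then horizontal); the remaining reticulate and
#' transfer edges as dashed quadratic curves. Taxon labels sit right of the
#' leaves (linear layouts) or radially outside the circle (circular
#' layouts), where circular main edges become arc + radial segment paths.
#'
#' @param lr a `phynet_layout`
#' @param file optional output path; when given the SVG is written there
#' @param unit_x,unit_y drawing units per x/y step (linear layouts)
#' @param unit_r drawing units per radius step (circular layouts)
#' @param margin margin in drawing units
#' @return SVG document as a single character string (invisibly when `file`
#'   is given)
#' @export
render_svg <- function(lr, file = NULL, unit_x = 48, unit_y = 24,
                       unit_r = 48, margin = 20) {
  net <- lr$net
  kinds <- edge_kinds(net)
  main_edge <- kinds %in% c("tree", "transfer_acceptor")
  labels <- names(net$taxa)
  els <- character(0)

  if (is.null(lr$circular)) {
    px <- stats::setNames(lr$xy$x * unit_x + margin, lr$xy$node)
    py <- stats::setNames(lr$xy$y * unit_y + margin, lr$xy$node)
    w <- max(px) + margin + 9 * max(nchar(labels), 0)
    h <- max(py) + margin
    for (i in seq_len(nrow(net$edges))) {
      u <- as.character(net$edges$from[i]); v <- as.character(net$edges$to[i])
      if (main_edge[i]) {
        els <- c(els, sprintf(
          '<polyline points="%s,%s %s,%s %s,%s" fill="none" stroke="black" stroke-width="1.5"/>',
          svg_num(px[u]), svg_num(py[u]), svg_num(px[u]), svg_num(py[v]),
          svg_num(px[v]), svg_num(py[v])))
      } else {
        els <- c(els, sprintf(
          '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="#c0392b" stroke-width="1" stroke-dasharray="4 2"/>',
          svg_num(px[u]), svg_num(py[u]), svg_num(px[u]), svg_num(py[v]),
          svg_num(px[v]), svg_num(py[v])))
      }
    }
    for (i in seq_along(net$taxa)) {
      v <- as.character(net$taxa[i])
      els <- c(els, sprintf(
        '<text x="%s" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">%s</text>',
        svg_num(px[v] + 5), svg_num(py[v]), xml_escape(labels[i])))
    }
  } else {
    cc <- lr$circular
    rownames(cc) <- cc$node
    rad <- cc$radius * unit_r
    th <- cc$angle * pi / 180
    cxy <- function(node) {
      i <- match(node, cc$node)
      c(rad[i] * cos(th[i]), rad[i] * sin(th[i]))
    }
    lim <- max(rad) + margin + 9 * max(nchar(labels), 0)
    w <- h <- 2 * lim
    ctr <- lim
    for (i in seq_len(nrow(net$edges))) {
      u <- net$edges$from[i]; v <- net$edges$to[i]
      iu <- match(u, cc$node); iv <- match(v, cc$node)
      pu <- cxy(u) + ctr; pv <- cxy(v) + ctr
      if (main_edge[i]) {
        # arc at radius(u) from angle(u) to angle(v), then radial to v
        mid <- c(rad[iu] * cos(th[iv]), rad[iu] * sin(th[iv])) + ctr
        dth <- (cc$angle[iv] - cc$angle[iu]) %% 360
        sweep <- if (dth <= 180) 1 else 0
        large <- if (min(dth, 360 - dth) > 180) 1 else 0
        els <- c(els, sprintf(
          '<path d="M %s %s A %s %s 0 %d %d %s %s L %s %s" fill="none" stroke="black" stroke-width="1.5"/>',
          svg_num(pu[1]), svg_num(pu[2]), svg_num(rad[iu]), svg_num(rad[iu]),
          large, sweep, svg_num(mid[1]), svg_num(mid[2]),
          svg_num(pv[1]), svg_num(pv[2])))
      } else {
        els <- c(els, sprintf(
          '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="#c0392b" stroke-width="1" stroke-dasharray="4 2"/>',
          svg_num(pu[1]), svg_num(pu[2]), svg_num(ctr), svg_num(ctr),
          svg_num(pv[1]), svg_num(pv[2])))
      }
    }
    for (i in seq_along(net$taxa)) {
      v <- net$taxa[i]
      p <- cxy(v) * ((max(rad) + 8) / max(rad, 1e-9)) + ctr
      els <- c(els, sprintf(
        '<text x="%s" y="%s" font-size="12" font-family="sans-serif" dominant-baseline="middle">%s</text>',
        svg_num(p[1]), svg_num(p[2]), xml_escape(labels[i])))
    }
  }
  doc <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            svg_num(w), svg_num(h), svg_num(w), svg_num(h)),
    '<rect width="100%" height="100%" fill="white"/>\n',
    paste(els, collapse = "\n"), "\n</svg>\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a layout as a black-on-white raster fixture
#'
#' Rasterizes the linear layout geometry into a logical pixel matrix
#' (`TRUE` = ink): main edges as 1-pixel axis-aligned two-segment paths,
#' reticulate/transfer edges as straight 1-pixel lines. Labels are not
#' inked; instead a sidecar table records each taxon label's text and the
#' pixel bounding box it would occupy right of its leaf. The output is a
#' deterministic function of the layout, which makes it suitable as a
#' ground-truthed input for the capture pipeline.
#'
#' @param lr a linear `phynet_layout`
#' @param unit_x,unit_y pixels per x/y step
#' @param margin margin in pixels
#' @param file optional PNG path (written via EBImage); the sidecar is then
#'   written next to it as `<file>.labels.tsv`
#' @return list with `raster` (logical matrix, row = y pixel, col = x
#'   pixel), `labels` (data frame `label`, `x0`, `y0`, `x1`, `y1`),
#'   `root` (c(x, y) pixel location of the root) and `positions`
#'   (data frame `node`, `x`, `y`)
#' @export
render_raster_fixture <- function(lr, unit_x = 16, unit_y = 12, margin = 6,
                                  file = NULL) {
  if (!is.null(lr$circular))
    stop("raster fixtures are rendered from linear layouts")
  net <- lr$net
  kinds <- edge_kinds(net)
  main_edge <- kinds %in% c("tree", "transfer_acceptor")
  px <- stats::setNames(round(lr$xy$x * unit_x) + margin + 1, lr$xy$node)
  py <- stats::setNames(round(lr$xy$y * unit_y) + margin + 1, lr$xy$node)
  labels <- names(net$taxa)
  wlab <- 6 * max(nchar(labels), 1) + 4
  W <- max(px) + margin + wlab
  H <- max(py) + margin + 4
  img <- matrix(FALSE, nrow = H, ncol = W)

  draw_line <- function(img, x0, y0, x1, y1) {
    npt <- max(abs(x1 - x0), abs(y1 - y0)) + 1
    xs <- round(seq(x0, x1, length.out = npt))
    ys <- round(seq(y0, y1, length.out = npt))
    img[cbind(ys, xs)] <- TRUE
    img
  }
  for (i in seq_len(nrow(net$edges))) {
    u <- as.character(net$edges$from[i]); v <- as.character(net$edges$to[i])
    if (main_edge[i]) {
      img <- draw_line(img, px[u], py[u], px[u], py[v])
      img <- draw_line(img, px[u], py[v], px[v], py[v])
    } else {
      img <- draw_line(img, px[u], py[u], px[v], py[v])
    }
  }

  lab <- data.frame(
    label = labels,
    x0 = px[as.character(net$taxa)] + 3,
    y0 = py[as.character(net$taxa)] - 4,
    x1 = px[as.character(net$taxa)] + 3 + 6 * nchar(labels),
    y1 = py[as.character(net$taxa)] + 4,
    row.names = NULL)

  out <- list(raster = img,
              labels = lab,
              root = c(x = unname(px[as.character(net$root)]),
                       y = unname(py[as.character(net$root)])),
              positions = data.frame(node = lr$xy$node,
                                     x = unname(px[as.character(lr$xy$node)]),
                                     y = unname(py[as.character(lr$xy$node)])))
  if (!is.null(file)) {
    EBImage::writeImage(t(1 - img * 1), file)   # EBImage uses [x, y]
    utils::write.table(lab, paste0(file, ".labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  out
}
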