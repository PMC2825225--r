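#' Visual style map for rendering
#'
#' Resolves, for every node, a glyph shape and fill color with precedence
#' module -> class -> default. Supported shapes: `square`, `rectangle`,
#' `round-rectangle`, `ellipse`, `circle`, `diamond`.
#'
#' @param module named list: module label -> list(shape =, fill =).
#' @param class named list: class label (`"metabolite"`, `"reaction"`) ->
#'   list(shape =, fill =).
#' @param default list(shape =, fill =) fallback.
#' @param edge list(color =, width =) for edge lines.
#' @param cell size of one grid cell in SVG user units.
#' @param label_mode `"none"` (default), `"all"`, or `"listed"` (label only
#'   the nodes in `label_nodes`).
#' @param label_nodes node ids to label under `label_mode = "listed"`.
#' @return an object of class `"netgrid_vstyle"`.
#' @export
visual_style <- function(module = list(), class = list(), default = NULL,
                         edge = NULL, cell = 24,
                         label_mode = c("none", "all", "listed"),
                         label_nodes = character()) {
  default <- utils::modifyList(list(shape = "circle", fill = "#b8b8b8"),
                               as.list(default))
  edge <- utils::modifyList(list(color = "#999999", width = 1), as.list(edge))
  structure(list(module = module, class = class, default = default,
                 edge = edge, cell = cell, label_mode = match.arg(label_mode),
                 label_nodes = label_nodes),
            class = "netgrid_vstyle")
}

#' Read a visual style map from a YAML or JSON file
#'
#' The file may contain any of the [visual_style()] fields, e.g. a
#' `module:` mapping of label to `{shape: ..., fill: ...}`.
#'
#' @param source path to a `.yaml`/`.yml` or `.json` file.
#' @return a `"netgrid_vstyle"` object.
#' @export
read_style_map <- function(source) {
  raw <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
    yaml::read_yaml(source)
  } else {
    jsonlite::read_json(source, simplifyVector = FALSE)
  }
  do.call(visual_style, raw[intersect(names(raw), names(formals(visual_style)))])
}

resolve_vstyle <- function(vstyle, module, class) {
  st <- vstyle$module[[module]]
  if (is.null(st)) st <- vstyle$class[[class]]
  if (is.null(st)) st <- vstyle$default
  utils::modifyList(vstyle$default, as.list(st))
}

svg_num <- function(x) {
  # fixed formatting so identical inputs give byte-identical documents
  sub("\\.?0+$", "", sprintf("%.3f", x))
}

svg_glyph <- function(shape, cx, cy, r, fill) {
  f <- svg_num
  switch(shape,
    circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                     f(cx), f(cy), f(r), fill),
    ellipse = sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="%s"/>',
                      f(cx), f(cy), f(r * 1.25), f(r * 0.8), fill),
    square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                     f(cx - r), f(cy - r), f(2 * r), f(2 * r), fill),
    rectangle = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                        f(cx - r * 1.25), f(cy - r * 0.8), f(2.5 * r),
                        f(1.6 * r), fill),
    `round-rectangle` = sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" rx="%s" fill="%s"/>',
      f(cx - r * 1.25), f(cy - r * 0.8), f(2.5 * r), f(1.6 * r), f(r * 0.4),
      fill),
    diamond = sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s"/>',
                      f(cx), f(cy - r), f(cx + r), f(cy), f(cx), f(cy + r),
                      f(cx - r), f(cy), fill),
    stop("unknown shape: ", shape))
}

#' Render a layout to SVG
#'
#' Produces a static SVG 1.1 drawing: one straight line per edge drawn
#' beneath one glyph per node, each glyph centered on its grid cell and
#' styled by the visual style map. The grid's y axis points up, the SVG y
#' axis down; coordinates are flipped at render time only. Output is
#' deterministic: identical inputs yield byte-identical documents.
#'
#' @param net a [netgrid_network()] object.
#' @param layout a [grid_layout()] covering all nodes of `net` (row names
#'   must include every node id), or a fitted [netgrid()] object (in which
#'   case `net` may be omitted).
#' @param vstyle a [visual_style()] map.
#' @param file optional path; when given the document is written there.
#' @return the SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
render_svg <- function(net, layout = NULL, vstyle = visual_style(),
                       file = NULL) {
  if (inherits(net, "netgrid")) {
    layout <- net$layout
    net <- net$network
  }
  stopifnot(inherits(net, "netgrid_network"), inherits(layout, "grid_layout"))
  ids <- rownames(layout$coords)
  if (is.null(ids)) stop("layout carries no node ids")
  missing <- setdiff(net$nodes, ids)
  if (length(missing)) {
    stop("node(s) missing coordinates: ", paste(missing, collapse = ", "))
  }
  cellsz <- vstyle$cell
  margin <- cellsz
  px <- function(x) margin + x * cellsz
  py <- function(y) margin + (layout$height - 1 - y) * cellsz
  co <- layout$coords[net$nodes, , drop = FALSE]
  wpx <- 2 * margin + (layout$width - 1) * cellsz
  hpx <- 2 * margin + (layout$height - 1) * cellsz

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            svg_num(wpx), svg_num(hpx), svg_num(wpx), svg_num(hpx)))
  e <- net$edges
  if (nrow(e)) {
    i <- match(e[, 1L], net$nodes)
    j <- match(e[, 2L], net$nodes)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      svg_num(px(co[i, 1L])), svg_num(py(co[i, 2L])),
      svg_num(px(co[j, 1L])), svg_num(py(co[j, 2L])),
      vstyle$edge$color, svg_num(vstyle$edge$width)))
  }
  mods <- node_modules(net)
  classes <- node_classes(net)
  r <- cellsz * 0.3
  out <- c(out, vapply(seq_along(net$nodes), function(k) {
    st <- resolve_vstyle(vstyle, mods[[k]], classes[[k]])
    svg_glyph(st$shape, px(co[k, 1L]), py(co[k, 2L]), r, st$fill)
  }, character(1L)))
  lab <- switch(vstyle$label_mode,
                none = character(),
                all = net$nodes,
                listed = intersect(net$nodes, vstyle$label_nodes))
  if (length(lab)) {
    k <- match(lab, net$nodes)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="middle">%s</text>',
      svg_num(px(co[k, 1L])), svg_num(py(co[k, 2L]) - r - 2),
      svg_num(cellsz * 0.35), lab))
  }
  doc <- paste(c(out, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Write / read a layout as TSV
#'
#' The on-disk form is one `node<TAB>x<TAB>y` row per node, preceded by a
#' `# grid <width> <height>` comment so the grid dimensions round-trip.
#' `read_layout(write_layout(l, f))` reproduces coordinates and dimensions
#' exactly; duplicate cells or malformed rows are rejected with the
#' offending line number.
#'
#' @param layout a [grid_layout()] with node row names.
#' @param sink path of the TSV file to write.
#' @return `write_layout()` returns `layout` invisibly; `read_layout()`
#'   returns the [grid_layout()].
#' @export
write_layout <- function(layout, sink) {
  stopifnot(inherits(layout, "grid_layout"))
  ids <- rownames(layout$coords)
  if (is.null(ids)) stop("layout carries no node ids")
  writeLines(c(sprintf("# grid %d %d", layout$width, layout$height),
               sprintf("%s\t%d\t%d", ids, layout$coords[, 1L],
                       layout$coords[, 2L])),
             sink)
  invisible(layout)
}

#' @rdname write_layout
#' @param source path of a TSV file written by [write_layout()].
#' @export
read_layout <- function(source) {
  lines <- readLines(source, warn = FALSE)
  grid <- NULL
  m <- regmatches(lines, regexec("^#\\s*grid\\s+(\\d+)\\s+(\\d+)", lines))
  hit <- which(vapply(m, length, 1L) == 3L)
  if (length(hit)) grid <- as.integer(m[[hit[1L]]][2:3])
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no nodes in ", source)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed layout line %d: '%s'", keep[bad[1L]],
                 lines[keep[bad[1L]]]))
  }
  ids <- vapply(fields, `[`, "", 1L)
  xy <- suppressWarnings(
    cbind(as.integer(vapply(fields, `[`, "", 2L)),
          as.integer(vapply(fields, `[`, "", 3L))))
  if (anyNA(xy)) {
    stop(sprintf("malformed layout line %d: non-integer coordinate",
                 keep[which(rowSums(is.na(xy)) > 0)[1L]]))
  }
  if (anyDuplicated(ids)) stop("duplicate node id in layout file")
  if (is.null(grid)) grid <- c(max(xy[, 1L]) + 1L, max(xy[, 2L]) + 1L)
  rownames(xy) <- ids
  grid_layout(xy, grid[1L], grid[2L])
}

#' Write the fit metadata sidecar
#'
#' Serializes the parameters, seed, final cost and accepted-cost trace of a
#' fit to JSON, alongside the TSV written by [write_layout()].
#'
#' @param fit a fitted [netgrid()] object.
#' @param sink path of the JSON file to write.
#' @return `fit`, invisibly.
#' @export
write_fit_json <- function(fit, sink) {
  stopifnot(inherits(fit, "netgrid"))
  jsonlite::write_json(
    list(params = fit$params, cost = fit$cost, trace = fit$trace,
         evaluations = fit$evaluations),
    sink, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(fit)
}
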