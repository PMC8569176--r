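#' @useDynLib wusgrad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Default per-layer cell counts for the 7-layer template; they sum to 1366.
.default_layer_counts <- c(105L, 135L, 165L, 195L, 225L, 255L, 286L)

#' In-plane spacing constant of the sunflower (Vogel) layout
#'
#' One point per `(2 r)^2` of disc area, so nearest-neighbour spacing is
#' close to one cell diameter.
#' @noRd
.vogel_c <- function(cell_radius) 2 * cell_radius / sqrt(pi)

#' Default layer radii for the shipped template
#'
#' Radii are chosen so that the Vogel disc of layer l holds exactly
#' `.default_layer_counts[l]` cells; the dome widens with depth.
#'
#' @param cell_radius ball radius of a cell (length units).
#' @return numeric vector of 7 layer radii, shallowest (L1) first.
#' @export
default_layer_radii <- function(cell_radius = 0.25) {
  .vogel_c(cell_radius) * sqrt(.default_layer_counts + 0.5)
}

#' Build the layered SAM cell template
#'
#' Constructs a deterministic, seedless 3D cell-ball template of the shoot
#' apical meristem: `n_layers` horizontal layers of cells, each layer a
#' sunflower-spiral disc of radius `layer_radii[l]`, stacked one cell
#' diameter apart. The same spiral is shared by all layers, so a cell and
#' the cell directly beneath it touch exactly. Depth is measured downward
#' from the L1 surface (`z = 0` at the surface).
#'
#' Cells whose centres lie within `neighbor_factor` diameters of each other
#' are adjacent; every contact is assigned a constant contact area
#' `pi * cell_radius^2` and the centre-to-centre distance, the two
#' quantities entering the graph-diffusion conductance `A_ij / l_ij`.
#' There are no edges out of the tissue (no-flux boundary).
#'
#' @param n_layers number of layers (>= 3). Layer 1 is L1 (surface).
#' @param layer_radii disc radius per layer, shallowest first, non-decreasing
#'   with depth (dome shape). `NULL` uses the shipped 7-layer configuration,
#'   which emits exactly 1366 cells.
#' @param cell_radius ball radius of every cell.
#' @param neighbor_factor adjacency cutoff in units of cell diameters.
#' @param apex_width number of cells per layer flagged as the central apex
#'   column (3-5).
#' @return an object of class `cell_graph`: list with `cells` (data frame
#'   `id, x, y, z, radius, layer, label, apex`), `edges` (symmetric data
#'   frame `i, j, area, distance`), conductance matrix `G` (sparse,
#'   `G[i,j] = A_ij / l_ij`), cell count `n`, and `meta`.
#' @export
build_sam_template <- function(n_layers = 7L,
                               layer_radii = NULL,
                               cell_radius = 0.25,
                               neighbor_factor = 1.15,
                               apex_width = 3L) {
  if (cell_radius <= 0) stop("cell_radius must be positive")
  if (n_layers < 3) stop("n_layers must be >= 3")
  if (is.null(layer_radii)) {
    if (n_layers != 7L)
      stop("default layer_radii are defined for the 7-layer template only")
    layer_radii <- default_layer_radii(cell_radius)
  }
  if (length(layer_radii) != n_layers)
    stop("layer_radii must have one entry per layer")
  if (any(layer_radii <= 0)) stop("layer radii must be positive")
  if (any(diff(layer_radii) < 0))
    stop("layer_radii must be non-decreasing with depth (dome shape)")

  cvog <- .vogel_c(cell_radius)
  counts <- pmax(1L, as.integer(floor((layer_radii / cvog)^2)))

  golden <- pi * (3 - sqrt(5))
  cell_list <- lapply(seq_len(n_layers), function(l) {
    t <- seq_len(counts[l])
    r <- cvog * sqrt(t)
    th <- t * golden
    data.frame(x = r * cos(th), y = r * sin(th),
               z = (2 * l - 1) * cell_radius, layer = l, spiral = t)
  })
  cells <- do.call(rbind, cell_list)
  cells$id <- seq_len(nrow(cells))
  cells$radius <- cell_radius
  cells$label <- ifelse(cells$layer == 1L, "L1",
                 ifelse(cells$layer == 2L, "L2",
                 ifelse(cells$layer == 3L, "L3", "deeper")))

  # adjacency: centre distance below the cutoff (cells in the same or an
  # adjacent layer only; the layer spacing already exceeds half the cutoff)
  n <- nrow(cells)
  cutoff <- neighbor_factor * 2 * cell_radius
  xyz <- as.matrix(cells[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))
  adj <- which(d2 > 0 & d2 <= cutoff, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  if (nrow(adj) == 0L) stop("packing produced no cell-cell contacts")
  area <- pi * cell_radius^2
  l_ij <- d2[adj]
  edges <- data.frame(i = c(adj[, 1], adj[, 2]),
                      j = c(adj[, 2], adj[, 1]),
                      area = area,
                      distance = c(l_ij, l_ij))
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL

  G <- Matrix::sparseMatrix(i = edges$i, j = edges$j,
                            x = edges$area / edges$distance,
                            dims = c(n, n))

  # connectivity (breadth-first over the adjacency)
  nbr <- split(edges$j, edges$i)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(nbr[as.character(queue)], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  if (!all(seen)) stop("packing produced a disconnected cell graph")

  cells$apex <- FALSE
  g <- structure(list(cells = cells, edges = edges, G = G, n = n,
                      meta = list(cell_radius = cell_radius,
                                  n_layers = n_layers,
                                  layer_radii = layer_radii,
                                  layer_counts = counts,
                                  neighbor_factor = neighbor_factor,
                                  apex_width = as.integer(apex_width))),
                 class = "cell_graph")
  if (all(counts >= apex_width))  # degenerate mini-templates carry no flags
    g$cells$apex <- g$cells$id %in% apex_cells(g, apex_width)$id
  g
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("SAM cell graph:", x$n, "cells in", x$meta$n_layers, "layers;",
      nrow(x$edges) / 2, "contacts\n")
  cat("layer counts:", paste(x$meta$layer_counts, collapse = ", "), "\n")
  invisible(x)
}

#' WUS synthesis-domain indicator
#'
#' A cell synthesises WUS mRNA iff its centre lies in the central column
#' `x^2 + y^2 <= r_w^2` at depth `z_min < z <= L_w` (closed upper boundary).
#' With the default `z_min = 0` the predicate is purely `z <= L_w`; the
#' shipped model configuration sets `z_min` to one cell diameter so the
#' synthesis domain starts at the L2 layer and excludes the L1.
#'
#' @param cells a `cell_graph` or its `cells` data frame.
#' @param r_w lateral radius of the synthesis domain.
#' @param L_w maximum depth of the synthesis domain.
#' @param z_min depth above which cells are excluded (default 0).
#' @return integer vector of 0/1, one per cell.
#' @export
wus_synthesis_indicator <- function(cells, r_w, L_w, z_min = 0) {
  if (inherits(cells, "cell_graph")) cells <- cells$cells
  if (r_w <= 0 || L_w <= 0) stop("r_w and L_w must be positive")
  as.integer(cells$x^2 + cells$y^2 <= r_w^2 &
             cells$z <= L_w & cells$z > z_min)
}

#' Central apex cells used for gradient quantification
#'
#' Returns, for every layer, the `width` cells whose centres are nearest
#' the tissue axis, mirroring quantification restricted to the 3-5 cell
#' wide centre apex column.
#'
#' @param graph a `cell_graph`.
#' @param width cells per layer (3-5).
#' @return data frame `id, layer, axial_dist`, ordered by layer then
#'   distance from the axis.
#' @export
apex_cells <- function(graph, width = 3L) {
  stopifnot(inherits(graph, "cell_graph"))
  if (width < 3 || width > 5) stop("width must be between 3 and 5")
  cells <- graph$cells
  out <- lapply(split(cells, cells$layer), function(cl) {
    if (nrow(cl) < width)
      stop("layer ", cl$layer[1], " has fewer than ", width, " cells")
    r2 <- cl$x^2 + cl$y^2
    ord <- order(r2, cl$id)[seq_len(width)]
    data.frame(id = cl$id[ord], layer = cl$layer[1],
               axial_dist = sqrt(r2[ord]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a cell graph to plain-text files
#'
#' Writes `<prefix>_cells.csv`, `<prefix>_edges.csv` and
#' `<prefix>_meta.json`.
#' @param graph a `cell_graph`.
#' @param prefix file path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cellgraph <- function(graph, prefix) {
  stopifnot(inherits(graph, "cell_graph"))
  fc <- paste0(prefix, "_cells.csv")
  fe <- paste0(prefix, "_edges.csv")
  fm <- paste0(prefix, "_meta.json")
  utils::write.csv(graph$cells[, c("id", "x", "y", "z", "radius",
                                   "layer", "label", "apex")],
                   fc, row.names = FALSE)
  utils::write.csv(graph$edges, fe, row.names = FALSE)
  jsonlite::write_json(graph$meta, fm, auto_unbox = TRUE, digits = NA)
  invisible(c(fc, fe, fm))
}

#' Read a cell graph written by [write_cellgraph()]
#' @param prefix file path prefix used at write time.
#' @return a `cell_graph`.
#' @export
read_cellgraph <- function(prefix) {
  cells <- utils::read.csv(paste0(prefix, "_cells.csv"))
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  n <- nrow(cells)
  G <- Matrix::sparseMatrix(i = edges$i, j = edges$j,
                            x = edges$area / edges$distance,
                            dims = c(n, n))
  structure(list(cells = cells, edges = edges, G = G, n = n, meta = meta),
            class = "cell_graph")
}

#' Per-layer cell ids of a graph
#' @noRd
.layer_ids <- function(graph, layer) graph$cells$id[graph$cells$layer == layer]
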