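# Vascular graph construction: each centerline voxel becomes a pressure
# node, 26-neighbourhood voxel pairs become edges, and the largest connected
# component is kept as the working vasculature.

#' Construct a vascular graph from node and edge tables
#'
#' Low-level constructor; most users build graphs from images with
#' [build_vessel_graph()] or synthetically with [make_tree()].
#'
#' @param nodes data.frame with columns `id` (1..n), `x`, `y`, `z`
#'   (mm), `radius` (mm) and optionally `i`, `j`, `k` (0-based voxel
#'   indices), `lin` (linear voxel index) and `role`.
#' @param edges data.frame with columns `from`, `to` (node ids), and
#'   optionally `length` (mm) and `radius` (mm).
#' @return An object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges),
            all(c("id", "x", "y", "z", "radius") %in% names(nodes)))
  n <- nrow(nodes)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (any(edges$from < 1 | edges$from > n | edges$to < 1 | edges$to > n))
      stop("edge endpoints out of range")
  }
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  nodes$degree <- deg
  if (is.null(nodes$role)) nodes$role <- NA_character_
  structure(list(nodes = nodes, edges = edges), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (!all(is.na(x$nodes$role)))
    cat(sprintf("  roles: %d root, %d interior, %d terminal\n",
                sum(x$nodes$role == "root", na.rm = TRUE),
                sum(x$nodes$role == "interior", na.rm = TRUE),
                sum(x$nodes$role == "terminal", na.rm = TRUE)))
  invisible(x)
}

# 26-neighbourhood half-offsets: every unordered neighbour pair is visited
# once by scanning the 13 offsets that are lexicographically positive.
half_offsets_26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  keep <- g$dk > 0 | (g$dk == 0 & g$dj > 0) |
    (g$dk == 0 & g$dj == 0 & g$di > 0)
  as.matrix(g[keep, , drop = FALSE])
}

#' Split a centerline volume into connected candidate graphs
#'
#' Every nonzero voxel becomes a node; edges connect voxel pairs within one
#' voxel of each other in every axis (26-neighbourhood, diagonals included).
#' Edge lengths are Euclidean distances between voxel centers under the
#' affine. Components are returned sorted by node count (descending), ties
#' broken by smallest minimum linear voxel index, so builds are
#' deterministic.
#'
#' @param vol A [centerline_volume()] with at least one nonzero voxel.
#' @return List of `vessel_graph` objects (node/edge geometry attached,
#'   roles unset), largest first.
#' @export
build_components <- function(vol) {
  stopifnot(inherits(vol, "centerline_volume"))
  dims <- dim(vol$values)
  lin <- which(vol$values > 0)  # ascending linear (1-based) voxel index
  if (length(lin) == 0L) stop("centerline volume is empty (all voxels zero)")
  ijk <- arrayInd(lin, dims) - 1L  # 0-based
  n <- length(lin)
  node_of <- structure(seq_len(n), names = as.character(lin))

  offs <- half_offsets_26()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2L, offs[r, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
      nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + 1L + nb[ok, 2] * dims[1] +
      nb[ok, 3] * dims[1] * dims[2]
    hit <- node_of[as.character(nb_lin)]
    found <- !is.na(hit)
    if (any(found)) {
      from <- c(from, which(ok)[found])
      to <- c(to, unname(hit[found]))
    }
  }

  xyz <- voxel_to_mm(ijk, vol$affine)
  nodes <- data.frame(id = seq_len(n), i = ijk[, 1], j = ijk[, 2],
                      k = ijk[, 3], lin = lin,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = vol$values[lin])
  elen <- sqrt(rowSums((xyz[from, , drop = FALSE] -
                          xyz[to, , drop = FALSE])^2))
  edges <- data.frame(from = from, to = to, length = elen)

  ig <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(ig)$membership[as.character(seq_len(n))]

  comps <- lapply(unique(memb), function(m) {
    keep <- which(memb == m)
    sub_nodes <- nodes[keep, , drop = FALSE]
    remap <- integer(n); remap[keep] <- seq_along(keep)
    ekeep <- edges[memb[edges$from] == m, , drop = FALSE]
    ekeep$from <- remap[ekeep$from]; ekeep$to <- remap[ekeep$to]
    sub_nodes$id <- seq_along(keep)
    rownames(sub_nodes) <- NULL; rownames(ekeep) <- NULL
    vessel_graph(sub_nodes, ekeep)
  })
  sizes <- vapply(comps, function(g) nrow(g$nodes), integer(1))
  min_lin <- vapply(comps, function(g) min(g$nodes$lin), numeric(1))
  comps[order(-sizes, min_lin)]
}

#' Select the largest connected component
#'
#' Gaps from imaging resolution can split the centerline into multiple
#' trees; the one with the most connected voxels is retained. Ties go to
#' the component containing the smallest linear voxel index.
#'
#' @param components List of `vessel_graph` objects from
#'   [build_components()].
#' @return The selected `vessel_graph`.
#' @export
select_largest <- function(components) {
  if (length(components) == 0L) stop("no components to select from")
  sizes <- vapply(components, function(g) nrow(g$nodes), integer(1))
  min_lin <- vapply(components, function(g) {
    if (!is.null(g$nodes$lin)) min(g$nodes$lin) else Inf
  }, numeric(1))
  components[[order(-sizes, min_lin)[1]]]
}

#' Assign root / interior / terminal roles
#'
#' The root is the pressurized inlet (the catheterized vessel end) and must
#' have exactly one neighbour; remaining degree-1 nodes are terminals
#' (outflow into the unsegmented downstream bed); degree >= 2 nodes are
#' interior.
#'
#' @param g A `vessel_graph`.
#' @param root Node id of the root; must have degree 1.
#' @return `g` with the `role` column filled.
#' @export
classify_nodes <- function(g, root) {
  stopifnot(inherits(g, "vessel_graph"))
  root <- as.integer(root)
  if (root < 1 || root > nrow(g$nodes)) stop("root id out of range")
  deg <- g$nodes$degree
  if (deg[root] != 1L)
    stop("root must have degree 1 (a pressurized end of the tree), got ",
         deg[root])
  role <- ifelse(deg == 1L, "terminal", "interior")
  role[root] <- "root"
  g$nodes$role <- role
  g
}

#' Default root choice: degree-1 node with the largest radius
#'
#' The feeding (catheterized) artery is anatomically the widest vessel end;
#' ties go to the smallest node id.
#'
#' @param g A `vessel_graph`.
#' @return Node id.
#' @export
pick_root <- function(g) {
  cand <- which(g$nodes$degree == 1L)
  if (length(cand) == 0L) stop("graph has no degree-1 node to use as root")
  cand[order(-g$nodes$radius[cand], cand)][1]
}

#' Attach physical edge geometry
#'
#' Edge radius is the arithmetic mean of the endpoint node radii (symmetric
#' and order-independent); edge length is the Euclidean distance between
#' voxel centers in mm. Both must be strictly positive.
#'
#' @param g A `vessel_graph` whose nodes carry radii.
#' @return `g` with `length` and `radius` columns on the edges.
#' @export
edge_geometry <- function(g) {
  stopifnot(inherits(g, "vessel_graph"))
  r <- g$nodes$radius
  if (any(r <= 0))
    stop("all node radii on the selected component must be positive")
  e <- g$edges
  e$radius <- (r[e$from] + r[e$to]) / 2
  if (is.null(e$length)) {
    p <- as.matrix(g$nodes[, c("x", "y", "z")])
    e$length <- sqrt(rowSums((p[e$from, , drop = FALSE] -
                                p[e$to, , drop = FALSE])^2))
  }
  if (nrow(e) > 0 && any(e$length <= 0))
    stop("edge lengths must be strictly positive")
  g$edges <- e
  g
}

#' Build the working vascular graph from a centerline volume
#'
#' Convenience pipeline: connected components, largest-component selection,
#' root classification and edge geometry in one call.
#'
#' @param vol A [centerline_volume()].
#' @param root_ijk Optional 0-based voxel index (length-3) overriding the
#'   default largest-radius root choice.
#' @return A fully annotated `vessel_graph`.
#' @export
build_vessel_graph <- function(vol, root_ijk = NULL) {
  g <- select_largest(build_components(vol))
  root <- if (is.null(root_ijk)) {
    pick_root(g)
  } else {
    hit <- which(g$nodes$i == root_ijk[1] & g$nodes$j == root_ijk[2] &
                   g$nodes$k == root_ijk[3])
    if (length(hit) != 1L) stop("root voxel not found on the largest component")
    hit
  }
  edge_geometry(classify_nodes(g, root))
}

#' Serialize a vascular graph to JSON
#'
#' @param g A `vessel_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
graph_to_json <- function(g, path) {
  cols <- intersect(c("id", "i", "j", "k", "x", "y", "z", "radius", "role"),
                    names(g$nodes))
  jsonlite::write_json(list(nodes = g$nodes[, cols], edges = g$edges),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
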