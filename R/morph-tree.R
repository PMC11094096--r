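#' Neuronal / glial reconstruction as an SWC-style node table
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (coordinates and radii in um; the root has
#'   `parent == -1`).
#' @return An object of class `"morph_tree"` (validated node table).
#' @export
morph_tree <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L)
    stop(sprintf("tree must have exactly one root (found %d)", length(roots)))
  known <- c(-1, nodes$id)
  bad <- which(!(nodes$parent %in% known))
  if (length(bad))
    stop(sprintf("node %d references missing parent %d",
                 nodes$id[bad[1]], nodes$parent[bad[1]]))
  # cycle check: walk each node to the root
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- integer(0); cur <- id
    while (cur != -1) {
      if (cur %in% seen) stop(sprintf("cycle detected at node %d", cur))
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  structure(list(nodes = nodes, root = nodes$id[roots]),
            class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("<morph_tree> %d nodes, root id %d, total length %.2f um\n",
              nrow(x$nodes), x$root, total_cable_length(x)))
  invisible(x)
}

#' Read / write trees in 7-column SWC format
#'
#' Standard space-separated SWC (`id type x y z radius parent`), comment
#' lines starting with `#`. Units are assumed to be um. Malformed files
#' (multiple roots, dangling parents, cycles) raise an error naming the
#' offending node.
#'
#' @param path file path.
#' @param tree a [morph_tree()].
#' @return `read_swc` returns a [morph_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty SWC file: ", path)
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7L))
    stop("SWC lines must have 7 columns: ", path)
  m <- do.call(rbind, lapply(fields, as.numeric))
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  morph_tree(nodes)
}

#' @rdname read_swc
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  writeLines(c("# SWC (id type x y z radius parent), um",
               sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                       n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)),
             path)
  invisible(path)
}

# matrix of segments (parent -> child): columns x0 y0 z0 x1 y1 z1
.tree_segments <- function(tree) {
  n <- tree$nodes
  child <- n[n$parent != -1, , drop = FALSE]
  pidx <- match(child$parent, n$id)
  cbind(x0 = n$x[pidx], y0 = n$y[pidx], z0 = n$z[pidx],
        x1 = child$x, y1 = child$y, z1 = child$z)
}

#' Total cable length of a tree
#'
#' Sum of Euclidean parent-to-child segment lengths, in um.
#'
#' @param tree a [morph_tree()].
#' @export
total_cable_length <- function(tree) {
  s <- .tree_segments(tree)
  if (!nrow(s)) return(0)
  sum(sqrt((s[, "x1"] - s[, "x0"])^2 + (s[, "y1"] - s[, "y0"])^2 +
             (s[, "z1"] - s[, "z0"])^2))
}

# soma center: centroid of type-1 nodes if present, else the root coordinate
.soma_center <- function(tree) {
  n <- tree$nodes
  soma <- n[n$type == 1L, , drop = FALSE]
  if (!nrow(soma)) soma <- n[n$parent == -1, , drop = FALSE]
  c(mean(soma$x), mean(soma$y), mean(soma$z))
}
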