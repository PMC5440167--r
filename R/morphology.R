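#' Neuron morphology objects
#'
#' A morphology is a rooted tree of 3-D points with radii, the standard
#' skeleton representation of a reconstructed neuron (one node per marker
#' point, one edge per parent link). Coordinates and radii are in micrometres.
#' `morphology()` validates a node table and returns a `morphology` object;
#' the node table is a tibble with columns `id`, `parent_id` (`-1` for the
#' root), `x`, `y`, `z`, `radius` and the SWC structure `label`
#' (1 = soma, 3 = dendrite).
#'
#' @param nodes Data frame of nodes with the columns listed above.
#' @return A `morphology` object: the node tibble (topologically sorted so
#'   every parent precedes its children) with the root id as an attribute.
#' @examples
#' m <- morphology(tibble::tibble(
#'   id = 1:3, parent_id = c(-1L, 1L, 2L),
#'   x = c(0, 10, 20), y = 0, z = 0, radius = 0.5, label = c(1L, 3L, 3L)
#' ))
#' total_path_length(m)
#' @export
morphology <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("id", "parent_id", "x", "y", "z", "radius", "label")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("node table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(nodes) == 0) abort("morphology must contain at least one node")
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    abort(paste0("duplicate node id: ", dup))
  }
  roots <- nodes$id[nodes$parent_id == -1]
  if (length(roots) != 1) {
    abort(paste0("morphology must have exactly one root, found ",
                 length(roots)))
  }
  orphan <- setdiff(nodes$parent_id, c(-1, nodes$id))
  if (length(orphan) > 0) {
    bad <- nodes$id[nodes$parent_id == orphan[1]][1]
    abort(paste0("node ", bad, " references missing parent ", orphan[1]))
  }
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z))) {
    abort("coordinates must be finite")
  }
  if (any(nodes$radius <= 0)) {
    abort(paste0("non-positive radius at node ",
                 nodes$id[nodes$radius <= 0][1]))
  }
  nodes <- sort_topologically(nodes, roots)
  structure(nodes, class = c("morphology", class(nodes)), root_id = roots)
}

# Order nodes so every parent precedes its children; detects cycles.
sort_topologically <- function(nodes, root_id) {
  idx <- match(nodes$parent_id, nodes$id)   # NA for root
  children <- split(seq_len(nrow(nodes)), idx)
  order <- integer(nrow(nodes))
  order[1] <- which(nodes$id == root_id)
  filled <- 1L
  cursor <- 1L
  while (cursor <= filled) {
    kids <- children[[as.character(order[cursor])]]
    if (!is.null(kids)) {
      order[filled + seq_along(kids)] <- kids
      filled <- filled + length(kids)
    }
    cursor <- cursor + 1L
  }
  if (filled < nrow(nodes)) {
    left_over <- setdiff(seq_len(nrow(nodes)), order[seq_len(filled)])
    abort(paste0("cyclic parent links involving node ",
                 nodes$id[left_over[1]]))
  }
  nodes[order, , drop = FALSE]
}

#' @exportS3Method base::print
print.morphology <- function(x, ...) {
  cat("<morphology> ", nrow(x), " nodes, root id ", attr(x, "root_id"),
      ", total path length ", format(total_path_length(x), digits = 5),
      " um\n", sep = "")
  invisible(x)
}

#' @rdname morphology
#' @param morph A `morphology` object.
#' @export
morphology_root <- function(morph) attr(morph, "root_id")

# Edge table: one row per (parent -> child) link with Euclidean length.
morphology_edges <- function(morph) {
  pidx <- match(morph$parent_id, morph$id)
  has_parent <- !is.na(pidx)
  child <- which(has_parent)
  parent <- pidx[has_parent]
  tibble::tibble(
    child_id = morph$id[child],
    parent_id = morph$id[parent],
    length = sqrt((morph$x[child] - morph$x[parent])^2 +
                  (morph$y[child] - morph$y[parent])^2 +
                  (morph$z[child] - morph$z[parent])^2)
  )
}

#' Read and write SWC skeleton files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated, `#` comments allowed, coordinates and radii in micrometres,
#' 1-based ids with `-1` marking the root's parent.
#'
#' @param path File path.
#' @return `read_swc()` returns a [morphology()]; `write_swc()` returns
#'   `path` invisibly.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad) > 0) {
    abort(paste0("malformed SWC line ", which(keep)[bad[1]],
                 ": expected 7 columns"))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  morphology(tibble::tibble(
    id = as.integer(m[, 1]),
    label = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6],
    parent_id = as.integer(m[, 7])
  ))
}

#' @rdname read_swc
#' @param morph A [morphology()].
#' @export
write_swc <- function(morph, path) {
  df <- data.frame(morph$id, morph$label, morph$x, morph$y, morph$z,
                   morph$radius, morph$parent_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC exported by glomsim (units: um)", con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Total dendritic path length
#'
#' Sum of Euclidean distances between connected nodes, optionally restricted
#' to the subtree rooted at a given node (the upstream cable leading into
#' that node is excluded).
#'
#' @param morph A [morphology()].
#' @param subtree_root Node id at which to root the sum; default the tree root.
#' @return Path length in micrometres.
#' @export
total_path_length <- function(morph, subtree_root = NULL) {
  if (is.null(subtree_root)) subtree_root <- attr(morph, "root_id")
  if (!subtree_root %in% morph$id) {
    abort(paste0("subtree_root ", subtree_root, " is not a node id"))
  }
  in_sub <- descendant_ids(morph, subtree_root)
  e <- morphology_edges(morph)
  sum(e$length[e$child_id %in% in_sub & e$parent_id %in% in_sub])
}

descendant_ids <- function(morph, root) {
  # nodes are topologically sorted, so a single forward pass suffices
  keep <- morph$id == root
  for (i in seq_len(nrow(morph))) {
    if (!keep[i]) {
      p <- match(morph$parent_id[i], morph$id)
      if (!is.na(p) && keep[p]) keep[i] <- TRUE
    }
  }
  morph$id[keep]
}

# Resample a skeleton at <= `step` um spacing. Returns sample points with the
# length of the interval each point represents (midpoint rule per edge piece).
resample_skeleton <- function(morph, step = 0.1) {
  pidx <- match(morph$parent_id, morph$id)
  has_parent <- which(!is.na(pidx))
  pieces <- purrr::map(has_parent, function(i) {
    j <- pidx[i]
    d <- sqrt((morph$x[i] - morph$x[j])^2 + (morph$y[i] - morph$y[j])^2 +
              (morph$z[i] - morph$z[j])^2)
    if (d == 0) return(NULL)
    k <- ceiling(d / step)
    frac <- (seq_len(k) - 0.5) / k
    tibble::tibble(
      x = morph$x[j] + frac * (morph$x[i] - morph$x[j]),
      y = morph$y[j] + frac * (morph$y[i] - morph$y[j]),
      z = morph$z[j] + frac * (morph$z[i] - morph$z[j]),
      seg_length = d / k
    )
  })
  dplyr::bind_rows(pieces)
}

#' Potential connection length between a dendrite and an axon
#'
#' Total path length of the dendrite that lies within a criterion distance of
#' the axon, the anatomical upper bound on where synapses could form.
#' Both skeletons are resampled at a fine spacing and each dendritic interval
#' is counted when its midpoint falls within `radius` of any axon sample
#' point. Monotone non-decreasing in `radius`.
#'
#' @param dendrite,axon [morphology()] objects.
#' @param radius Criterion distance in micrometres (default 0.5, i.e. 500 nm).
#' @param step Resampling interval in micrometres.
#' @return Path length in micrometres.
#' @export
potential_connection_length <- function(dendrite, axon, radius = 0.5,
                                        step = 0.1) {
  dpts <- resample_skeleton(dendrite, step)
  apts <- resample_skeleton(axon, step)
  if (nrow(dpts) == 0 || nrow(apts) == 0) return(0)
  ax <- cbind(apts$x, apts$y, apts$z)
  r2 <- radius^2
  close <- logical(nrow(dpts))
  chunk <- max(1L, floor(2e6 / nrow(ax)))
  for (start in seq(1L, nrow(dpts), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(dpts))
    dx <- outer(dpts$x[idx], ax[, 1], "-")
    dy <- outer(dpts$y[idx], ax[, 2], "-")
    dz <- outer(dpts$z[idx], ax[, 3], "-")
    close[idx] <- apply(dx * dx + dy * dy + dz * dz <= r2, 1, any)
  }
  sum(dpts$seg_length[close])
}
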