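# Skeletonization, vessel-graph extraction, tortuosity, and layer-wise
# morphometry (vessel density, skeleton density, bifurcation index).

#' Skeletonize a binary vasculature volume
#'
#' 3D parallel thinning: border voxels are collected per face direction and
#' deleted sequentially if they are topologically simple (26-connectivity of
#' the object, 6-connectivity of the background) and not curve endpoints,
#' iterating until the volume no longer changes. The result is a one-voxel-
#' thick centerline skeleton preserving the 26-connectivity of every
#' component.
#'
#' @param binary logical 3D array.
#' @return logical 3D array (skeleton), a subset of `binary`.
#' @export
skeletonize <- function(binary) {
  .check_volume(binary, "binary")
  if (!is.logical(binary)) binary <- binary > 0
  out <- thin3d_cpp(.as_int_volume(binary), dim(binary))
  array(out > 0L, dim(binary))
}

#' Cortical layer specification
#'
#' Contiguous half-open depth strata `[k*t, (k+1)*t)` micrometers measured
#' from the aligned surface (z = 0); the defaults give L1 (0-100 um) through
#' L5 (400-500 um).
#'
#' @param layer_thickness_um stratum thickness (default 100).
#' @param n_layers number of strata (default 5).
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(layer_thickness_um = 100, n_layers = 5L) {
  stopifnot(layer_thickness_um > 0, n_layers >= 1)
  structure(list(layer_thickness_um = layer_thickness_um,
                 n_layers = as.integer(n_layers)),
            class = "layer_spec")
}

# Physical length of a digital centerline: voxel steps are summed after a
# centred moving average of the coordinates (endpoints fixed, shrinking
# window). Raw voxel chains overestimate smooth-curve length by 5-10%
# (staircase bias); smoothing removes that while shortening true curvature
# only negligibly at these radii.
.digital_path_length <- function(pts, voxel_size_um, w = 5L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (n > 3L && w > 1L) {
    h <- w %/% 2L
    sm <- apply(pts, 2, function(v) {
      cs <- c(0, cumsum(v))
      lo <- pmax(1L, seq_len(n) - h)
      hi <- pmin(n, seq_len(n) + h)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    })
    sm[1, ] <- pts[1, ]; sm[n, ] <- pts[n, ]
    pts <- sm
  }
  sum(sqrt(rowSums(diff(pts)^2))) * voxel_size_um
}

# 26-neighbourhood offsets as a 26 x 3 matrix
.offs26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
})

#' Build a vessel graph from a one-voxel-thick skeleton
#'
#' Skeleton voxels with a 26-neighbour count different from 2 become nodes
#' (adjacent node voxels are merged into a single node at their centroid);
#' maximal chains of degree-2 voxels become edges carrying the ordered
#' centerline path, the physical path length (sum of Euclidean inter-voxel
#' steps times voxel size) and the chord length (straight node-to-node
#' distance). Terminal spur edges shorter than `spur_min_voxels` are pruned
#' (thinning burrs otherwise inflate bifurcation counts) and the through
#' nodes this leaves behind are dissolved into their merged edge. Self-loop
#' edges shorter than 3 voxels are dropped with a warning.
#'
#' @param skeleton logical 3D array (one-voxel-thick).
#' @param voxel_size_um voxel size, micrometers.
#' @param spur_min_voxels prune terminal edges with fewer path voxels than
#'   this (default 3; 0 disables).
#' @return object of class `skeleton_graph` with `nodes` (node_id, z_um,
#'   y_um, x_um, degree, kind) and `edges` (edge_id, node_a, node_b, path,
#'   path_length_um, chord_length_um, n_voxels).
#' @export
build_graph <- function(skeleton, voxel_size_um = 4, spur_min_voxels = 3L) {
  .check_volume(skeleton, "skeleton")
  if (!is.logical(skeleton)) skeleton <- skeleton > 0
  d <- dim(skeleton)
  nb <- neighbor_count_cpp(.as_int_volume(skeleton), d)
  idx <- which(skeleton)
  if (!length(idx))
    return(structure(list(nodes = data.frame(node_id = integer(),
                                             z_um = numeric(), y_um = numeric(),
                                             x_um = numeric(),
                                             degree = integer(),
                                             kind = character()),
                          edges = data.frame(edge_id = integer(),
                                             node_a = integer(),
                                             node_b = integer(),
                                             path_length_um = numeric(),
                                             chord_length_um = numeric(),
                                             n_voxels = integer()),
                          voxel_size_um = voxel_size_um),
                     class = "skeleton_graph"))

  coord <- cbind(z = ((idx - 1L) %% d[1]) + 1L,
                 y = ((idx - 1L) %/% d[1]) %% d[2] + 1L,
                 x = (idx - 1L) %/% (d[1] * d[2]) + 1L)
  is_node_vox <- nb[idx] != 2L
  # handle pure cycles (components with no node voxel): promote one voxel
  if (any(!is_node_vox)) {
    lab <- .label3(skeleton)
    comp <- lab[idx]
    has_node <- tapply(is_node_vox, comp, any)
    for (cmp in as.integer(names(has_node))[!has_node])
      is_node_vox[which(comp == cmp)[1]] <- TRUE
  }
  # merge 26-adjacent node voxels into node clusters
  nodemask <- array(FALSE, d); nodemask[idx[is_node_vox]] <- TRUE
  clust <- .label3(nodemask)
  vox_cluster <- clust[idx]                  # 0 for chain voxels
  n_nodes <- max(vox_cluster)
  pos <- matrix(0, n_nodes, 3)
  for (k in seq_len(n_nodes)) {
    sel <- vox_cluster == k
    pos[k, ] <- colMeans(coord[sel, , drop = FALSE])
  }

  rowid <- array(0L, d); rowid[idx] <- seq_along(idx)
  nbrs_of <- function(r) {
    p <- coord[r, ]
    cand <- sweep(.offs26, 2, p, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    r2 <- rowid[cand[ok, , drop = FALSE]]
    r2[r2 > 0L]
  }

  visited <- logical(length(idx))
  edges <- list()
  pair_seen <- character(0)
  add_edge <- function(ca, cb, path_rows) {
    edges[[length(edges) + 1L]] <<- list(a = ca, b = cb, rows = path_rows)
    invisible(NULL)
  }
  node_rows <- which(is_node_vox)
  for (r in node_rows) {
    for (u in nbrs_of(r)) {
      if (is_node_vox[u]) {
        ca <- vox_cluster[r]; cb <- vox_cluster[u]
        if (ca == cb) next
        key <- paste(min(ca, cb), max(ca, cb), sep = "-")
        if (key %in% pair_seen) next
        pair_seen <- c(pair_seen, key)
        add_edge(ca, cb, c(r, u))
      } else if (!visited[u]) {
        path <- c(r, u)
        prev <- r; cur <- u
        repeat {
          visited[cur] <- TRUE
          nx <- setdiff(nbrs_of(cur), prev)
          if (!length(nx)) break             # dangling chain end
          nx <- nx[1]
          path <- c(path, nx)
          if (is_node_vox[nx]) break
          prev <- cur; cur <- nx
        }
        last <- path[length(path)]
        cb <- if (is_node_vox[last]) vox_cluster[last] else vox_cluster[r]
        add_edge(vox_cluster[r], cb, path)
      }
    }
  }

  mk_edge_df <- function(edges) {
    if (!length(edges))
      return(data.frame(edge_id = integer(), node_a = integer(),
                        node_b = integer(), path_length_um = numeric(),
                        chord_length_um = numeric(), n_voxels = integer()))
    df <- data.frame(
      edge_id = seq_along(edges),
      node_a = vapply(edges, `[[`, numeric(1), "a"),
      node_b = vapply(edges, `[[`, numeric(1), "b"))
    df$path <- lapply(edges, function(e) coord[e$rows, , drop = FALSE])
    df$path_length_um <- vapply(df$path, .digital_path_length,
                                numeric(1), voxel_size_um = voxel_size_um)
    df$chord_length_um <- sqrt(rowSums((pos[df$node_a, , drop = FALSE] -
                                          pos[df$node_b, , drop = FALSE])^2)) *
      voxel_size_um
    df$n_voxels <- vapply(df$path, nrow, integer(1))
    df
  }
  edf <- mk_edge_df(edges)

  # drop short self-loops
  loop <- edf$node_a == edf$node_b & edf$n_voxels < 3L
  if (any(loop)) {
    warning(sum(loop), " self-loop edge(s) shorter than 3 voxels pruned",
            call. = FALSE)
    edf <- edf[!loop, , drop = FALSE]
  }

  degree_of <- function(edf) {
    deg <- integer(n_nodes)
    t1 <- tabulate(edf$node_a, n_nodes); t2 <- tabulate(edf$node_b, n_nodes)
    deg + t1 + t2
  }

  # prune short terminal spurs, then dissolve the degree-2 nodes left behind
  if (spur_min_voxels > 0 && nrow(edf)) {
    repeat {
      deg <- degree_of(edf)
      spur <- (deg[edf$node_a] == 1L | deg[edf$node_b] == 1L) &
        edf$n_voxels < spur_min_voxels & edf$node_a != edf$node_b
      if (!any(spur)) break
      edf <- edf[!spur, , drop = FALSE]
    }
  }
  deg <- degree_of(edf)
  # dissolve through nodes: merge their two incident edges
  repeat {
    thr <- which(deg == 2L)
    merged <- FALSE
    for (nd in thr) {
      inc <- which(edf$node_a == nd | edf$node_b == nd)
      if (length(inc) != 2L) next              # double self-loop; leave it
      e1 <- inc[1]; e2 <- inc[2]
      if (edf$node_a[e1] == edf$node_b[e1] || edf$node_a[e2] == edf$node_b[e2])
        next
      p1 <- edf$path[[e1]]; p2 <- edf$path[[e2]]
      # orient p1 to end at nd and p2 to start at nd
      if (edf$node_b[e1] != nd) p1 <- p1[nrow(p1):1, , drop = FALSE]
      a <- if (edf$node_b[e1] != nd) edf$node_b[e1] else edf$node_a[e1]
      if (edf$node_a[e2] != nd) p2 <- p2[nrow(p2):1, , drop = FALSE]
      b <- if (edf$node_a[e2] != nd) edf$node_a[e2] else edf$node_b[e2]
      newpath <- rbind(p1, p2[-1, , drop = FALSE])
      edf$node_a[e1] <- a; edf$node_b[e1] <- b
      edf$path[[e1]] <- newpath
      edf$path_length_um[e1] <- .digital_path_length(newpath, voxel_size_um)
      edf$chord_length_um[e1] <- sqrt(sum((pos[a, ] - pos[b, ])^2)) *
        voxel_size_um
      edf$n_voxels[e1] <- nrow(newpath)
      edf <- edf[-e2, , drop = FALSE]
      deg <- degree_of(edf)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  edf$edge_id <- seq_len(nrow(edf))

  keep <- which(deg > 0L)
  nodes <- data.frame(node_id = keep,
                      z_um = (pos[keep, 1] - 1) * voxel_size_um,
                      y_um = (pos[keep, 2] - 1) * voxel_size_um,
                      x_um = (pos[keep, 3] - 1) * voxel_size_um,
                      degree = deg[keep],
                      kind = ifelse(deg[keep] == 1L, "endpoint",
                                    ifelse(deg[keep] >= 3L, "bifurcation",
                                           "through")),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edf, voxel_size_um = voxel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$kind == "bifurcation"), "bifurcations,",
      sum(x$nodes$kind == "endpoint"), "endpoints ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Tortuosity index of vessel branches
#'
#' The ratio of the actual centerline path length to the direct (chord)
#' length between the branch's two nodes; 1 means a straight branch, larger
#' values mean increasing tortuosity. Edges with coincident endpoints
#' (closed loops) have no defined chord and return NA with a warning.
#'
#' @param graph a `skeleton_graph`.
#' @param edge_ids edges to evaluate (default: all).
#' @return named numeric vector of tortuosity indices (>= 1).
#' @export
tortuosity_index <- function(graph, edge_ids = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  e <- graph$edges
  if (!is.null(edge_ids)) e <- e[match(edge_ids, e$edge_id), , drop = FALSE]
  ti <- e$path_length_um / e$chord_length_um
  bad <- e$chord_length_um <= 0
  if (any(bad)) {
    warning(sum(bad), " closed-loop edge(s) skipped: tortuosity undefined",
            call. = FALSE)
    ti[bad] <- NA_real_
  }
  names(ti) <- e$edge_id
  ti
}

#' Layer-wise morphometry
#'
#' Per 100-um stratum from the aligned surface: vessel density (vessel
#' voxels / layer voxels), skeleton density (skeleton voxels / layer
#' voxels), the bifurcation count (graph nodes of degree >= 3 whose depth
#' falls in the layer, counted once each), and the bifurcation index
#' (count per mm^3 of layer volume). A voxel belongs to the stratum
#' containing the depth of its upper face, so layers partition the volume.
#'
#' @param binary logical 3D vessel mask (surface-aligned).
#' @param skeleton logical 3D skeleton of `binary`.
#' @param graph `skeleton_graph` of `skeleton`.
#' @param layers a [layer_spec()].
#' @param voxel_size_um voxel size, micrometers.
#' @param surface_aligned assertion that the volume was aligned with
#'   [align_surface_plane()] (or generated flat); `FALSE` raises an error.
#' @return data.frame: `layer, vessel_density, skeleton_density,
#'   bifurcation_count, bifurcation_per_mm3`.
#' @export
layer_metrics <- function(binary, skeleton, graph, layers = layer_spec(),
                          voxel_size_um = 4, surface_aligned = TRUE) {
  if (!isTRUE(surface_aligned))
    stop("align before layer analysis", call. = FALSE)
  .check_volume(binary, "binary"); .check_volume(skeleton, "skeleton")
  d <- dim(binary)
  lay_vox <- layers$layer_thickness_um / voxel_size_um
  layer_of_z <- floor(((seq_len(d[1]) - 1)) / lay_vox) + 1L
  layer_voxels <- d[2] * d[3] * lay_vox
  layer_mm3 <- layer_voxels * (voxel_size_um * 1e-3)^3
  bif_z <- graph$nodes$z_um[graph$nodes$degree >= 3L]
  out <- lapply(seq_len(layers$n_layers), function(k) {
    zsel <- which(layer_of_z == k)
    lo <- (k - 1) * layers$layer_thickness_um
    hi <- k * layers$layer_thickness_um
    nbif <- sum(bif_z >= lo & bif_z < hi)
    data.frame(layer = k,
               vessel_density = sum(binary[zsel, , ]) / layer_voxels,
               skeleton_density = sum(skeleton[zsel, , ]) / layer_voxels,
               bifurcation_count = nbif,
               bifurcation_per_mm3 = nbif / layer_mm3)
  })
  do.call(rbind, out)
}
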