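#' Local element connectivity graph at a vertex
#'
#' Builds the graph whose nodes are the elements of the vertex star and
#' whose edges connect elements sharing a face that is not designated
#' fibrotic. The connected components of this graph determine how many
#' copies of the vertex are needed for a topologically tight splitting and
#' which elements each copy is assigned to.
#'
#' Because node duplication at one vertex never changes which elements
#' contain another vertex, the analysis at each vertex depends only on the
#' original mesh connectivity and the network, making the splitting
#' order-independent.
#'
#' @param mesh a `dfe_mesh`
#' @param vertex 1-based vertex index
#' @param network a `fibrosis_network`
#' @param adjacency optional precomputed `adjacency_index`
#' @return object of class `local_element_graph`: list with `vertex`,
#'   `nodes` (element indices), `edges` (data.frame `ea`, `eb`, `key`,
#'   `face` columns, `active` flag), `split_faces` (data.frame of in-star
#'   network faces with their adjacent elements), `removed` (keys of faces
#'   removed by fallback disconnection)
#' @export
local_element_graph <- function(mesh, vertex, network, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  star <- adjacency$star[[vertex]]
  net <- .network_env(network)
  el <- mesh$elements
  k <- ncol(el)
  ea <- eb <- integer(0)
  key <- character(0)
  fverts <- NULL
  s_ea <- s_eb <- integer(0)
  s_key <- character(0)
  s_fverts <- NULL
  if (length(star) >= 2) {
    for (i in seq_len(length(star) - 1L)) {
      for (j in (i + 1L):length(star)) {
        shared <- intersect(el[star[i], ], el[star[j], ])
        if (length(shared) == k - 1L) {
          fk <- .face_keys(matrix(sort.int(shared), nrow = 1))
          if (is.null(net[[fk]])) {
            ea <- c(ea, star[i]); eb <- c(eb, star[j]); key <- c(key, fk)
            fverts <- rbind(fverts, sort.int(shared))
          } else {
            s_ea <- c(s_ea, star[i]); s_eb <- c(s_eb, star[j])
            s_key <- c(s_key, fk)
            s_fverts <- rbind(s_fverts, sort.int(shared))
          }
        }
      }
    }
  }
  structure(list(
    vertex = vertex, nodes = star,
    edges = list(ea = ea, eb = eb, key = key, faces = fverts,
                 active = rep(TRUE, length(ea))),
    split_faces = list(ea = s_ea, eb = s_eb, key = s_key, faces = s_fverts),
    removed = character(0)),
    class = "local_element_graph")
}

.network_env <- function(network) {
  env <- new.env(parent = emptyenv(), size = max(16L, length(network$faces)))
  for (kk in network$faces) assign(kk, TRUE, envir = env)
  env
}

#' Connected components of a local element graph
#'
#' @param graph a `local_element_graph`
#' @return list of integer vectors of element indices, ordered by their
#'   minimum element index (the first component keeps the original vertex)
#' @export
graph_components <- function(graph) {
  .uf_components(graph$nodes,
                 cbind(graph$edges$ea, graph$edges$eb)[graph$edges$active, ,
                                                       drop = FALSE])
}

# union-find components over arbitrary integer node labels
.uf_components <- function(nodes, edges) {
  idx <- match(nodes, nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    a <- match(edges[, 1], nodes)
    b <- match(edges[, 2], nodes)
    for (r in seq_len(nrow(edges))) {
      ra <- find(a[r]); rb <- find(b[r])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  comps <- split(nodes, root)
  comps <- lapply(comps, sort.int)
  comps[order(vapply(comps, min, numeric(1)))]
}

.connected_in_graph <- function(graph, e1, e2) {
  comps <- graph_components(graph)
  for (cp in comps) if (e1 %in% cp) return(e2 %in% cp)
  FALSE
}

#' Fallback disconnection of a local element graph
#'
#' When a designated fibrotic face does not by itself separate its two
#' adjacent elements in the local graph (e.g. the vertex touches only one
#' split edge in 2D, or the 3D network does not close around the vertex),
#' additional faces are removed from the *local* connectivity only. In 2D
#' the single mesh edge whose angle to the split edge is closest to 180
#' degrees is removed. In 3D, candidate faces are ranked by the absolute
#' dot product of their normal with the split-face normal and removed in
#' ascending order until the two adjacent elements fall into different
#' components. The removed faces are not added to the global no-flux set.
#'
#' @param graph a `local_element_graph`
#' @param face face key (string) or vertex index vector of the split face
#' @param mesh the `dfe_mesh` providing geometry
#' @return the modified `local_element_graph`
#' @export
fallback_disconnect <- function(graph, face, mesh) {
  if (!is.character(face)) face <- .face_keys(matrix(sort.int(face), nrow = 1))
  si <- match(face, graph$split_faces$key)
  if (is.na(si)) stop("face ", face, " is not a split face of this star")
  e1 <- graph$split_faces$ea[si]
  e2 <- graph$split_faces$eb[si]
  if (!.connected_in_graph(graph, e1, e2)) return(graph)

  v <- graph$vertex
  coords <- mesh$vertices
  act <- which(graph$edges$active)
  if (mesh$dim == 2L) {
    fv <- graph$split_faces$faces[si, ]
    a <- setdiff(fv, v)
    dir_split <- coords[a, ] - coords[v, ]
    best <- NA_integer_; best_ang <- -Inf
    for (r in act) {
      bv <- setdiff(graph$edges$faces[r, ], v)
      dir <- coords[bv, ] - coords[v, ]
      ang <- acos(max(-1, min(1, sum(dir_split * dir) /
                                sqrt(sum(dir_split^2) * sum(dir^2)))))
      if (ang > best_ang + 1e-12 ||
          (abs(ang - best_ang) <= 1e-12 && !is.na(best) &&
           graph$edges$key[r] < graph$edges$key[best])) {
        best <- r; best_ang <- ang
      }
    }
    if (is.na(best))
      stop("degenerate star at vertex ", v,
           ": no candidate edge for fallback disconnection")
    graph$edges$active[best] <- FALSE
    graph$removed <- c(graph$removed, graph$edges$key[best])
  } else {
    nf <- .face_normals(mesh, graph$split_faces$faces[si, , drop = FALSE])
    cand <- act
    if (!length(cand))
      stop("degenerate star at vertex ", v,
           ": no candidate faces for fallback disconnection")
    nc <- .face_normals(mesh, graph$edges$faces[cand, , drop = FALSE])
    dp <- abs(as.vector(nc %*% t(nf)))
    ord <- cand[order(dp, graph$edges$key[cand], method = "radix")]
    for (r in ord) {
      graph$edges$active[r] <- FALSE
      graph$removed <- c(graph$removed, graph$edges$key[r])
      if (!.connected_in_graph(graph, e1, e2)) return(graph)
    }
    stop("fallback disconnection exhausted all candidate faces at vertex ",
         v, " (degenerate star)")
  }
  graph
}

# Full per-vertex analysis: apply fallback for every in-star split face
# whose adjacent elements remain connected, then return components.
# leaky = TRUE applies the degraded assignment: components are ordered by
# the angular position of their elements around the vertex and alternating
# components are merged (emulating naive per-edge node doubling, which
# leaves diagonally opposite groups connected).
.vertex_components <- function(mesh, vertex, network, adjacency,
                               leaky = FALSE) {
  g <- local_element_graph(mesh, vertex, network, adjacency = adjacency)
  ns <- length(g$split_faces$key)
  if (ns == 0) {
    comps <- graph_components(g)
    return(list(components = comps, reference = comps, graph = g))
  }
  for (si in seq_len(ns)) {
    g <- fallback_disconnect(g, g$split_faces$key[si], mesh)
  }
  comps <- graph_components(g)
  reference <- comps
  if (leaky && length(comps) > 2) {
    if (mesh$dim != 2L)
      stop("the degraded (leaky) assignment is only defined for 2D meshes")
    ctr <- element_centroids(mesh)
    vx <- mesh$vertices[vertex, ]
    angle_of <- vapply(comps, function(cp) {
      d <- colMeans(ctr[cp, , drop = FALSE]) - vx
      atan2(d[2], d[1])
    }, numeric(1))
    ord <- order(angle_of)
    odd <- ord[seq(1, length(ord), by = 2)]
    even <- ord[seq(2, length(ord), by = 2)]
    comps <- list(sort.int(unlist(comps[odd])),
                  sort.int(unlist(comps[even])))
    comps <- comps[order(vapply(comps, min, numeric(1)))]
  }
  list(components = comps, reference = reference, graph = g)
}

#' Split a mesh along a fibrosis network
#'
#' The core discrete finite element operation: for every vertex lying on at
#' least one designated fibrotic face, a local connectivity analysis
#' determines the element groups separated by the network (with fallback
#' disconnection where a face does not separate its neighbours), and each
#' group beyond the first receives a fresh copy of the vertex at the same
#' coordinates. The two elements adjacent to any network face then
#' reference disjoint vertex sets on that face, so the face becomes an
#' internal no-flux boundary of the finite element problem.
#'
#' @param mesh a `dfe_mesh`
#' @param network a `fibrosis_network` of interior faces of `mesh`;
#'   boundary faces are ignored with a warning
#' @param leaky_vertices vertices at which the degraded (leaky, naive
#'   node-doubling) assignment is applied instead of the
#'   connectivity-consistent one; used to build the leaky test topology
#' @return an object of class `split_result`: list with `mesh` (the split
#'   mesh), `duplication_map` (data.frame `new_vertex`, `original_vertex`,
#'   `component`), `records` (per-vertex component assignments),
#'   `net_pairs` (adjacent element pair per network face),
#'   `removed_elements`, `element_map`, `vertex_map` (identity until
#'   [remove_isolated_components()] is applied), and `network`
#' @export
split_mesh <- function(mesh, network, leaky_vertices = integer(0)) {
  adjacency <- build_adjacency(mesh)
  loc <- match(network$faces, adjacency$keys)
  drop <- is.na(loc) | !adjacency$interior[replace(loc, is.na(loc), 1L)]
  if (any(drop)) {
    warning(sum(drop), " network face(s) are not interior faces of the ",
            "mesh (on the boundary, or already split) and are ignored")
    network <- fibrosis_network(network$faces[!drop], network$rho_max,
                                network$seed)
    loc <- loc[!drop]
  }
  net_pairs <- data.frame(key = network$faces,
                          e1 = adjacency$e1[loc], e2 = adjacency$e2[loc],
                          stringsAsFactors = FALSE)

  fmat <- .key_to_face(network$faces)
  visit <- if (is.null(fmat)) integer(0) else sort(unique(as.vector(fmat)))

  el <- mesh$elements
  nv0 <- nrow(mesh$vertices)
  next_id <- nv0
  new_orig <- integer(0)
  new_comp <- integer(0)
  records <- vector("list", length(visit))
  for (vi in seq_along(visit)) {
    v <- visit[vi]
    res <- .vertex_components(mesh, v, network, adjacency,
                              leaky = v %in% leaky_vertices)
    comps <- res$components
    ids <- v
    if (length(comps) > 1) {
      for (ci in 2:length(comps)) {
        next_id <- next_id + 1L
        new_orig <- c(new_orig, v)
        new_comp <- c(new_comp, ci - 1L)
        ids <- c(ids, next_id)
        for (e in comps[[ci]]) el[e, el[e, ] == v] <- next_id
      }
    }
    records[[vi]] <- list(vertex = v, components = comps,
                          reference = res$reference, ids = ids,
                          fallback_removed = res$graph$removed)
  }
  coords <- rbind(mesh$vertices, mesh$vertices[new_orig, , drop = FALSE])
  out_mesh <- dfe_mesh(coords, el, region = mesh$region,
                       fibres = mesh$fibres, sheets = mesh$sheets,
                       normals = mesh$normals)
  structure(list(
    mesh = out_mesh,
    duplication_map = data.frame(new_vertex = seq_len(length(new_orig)) + nv0,
                                 original_vertex = new_orig,
                                 component = new_comp),
    records = records,
    net_pairs = net_pairs,
    removed_elements = integer(0),
    element_map = seq_len(nrow(el)),
    vertex_map = seq_len(nrow(coords)),
    network = network),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(paste0("split_result: %d network faces, %d duplicated ",
                     "vertices, %d removed elements\n"),
              nrow(x$net_pairs), nrow(x$duplication_map),
              length(x$removed_elements)))
  invisible(x)
}

#' Remove electrically isolated components
#'
#' A closed surface of split faces can fully enclose elements, leaving them
#' electrically isolated after splitting. Electrical coupling in the P1
#' discretization flows through shared nodes, so isolation is judged on the
#' node-sharing element graph of the split mesh: two elements are connected
#' when they reference at least one common vertex (a shared unsplit face,
#' or a pivot vertex). All but the largest connected component are pruned
#' (ties broken towards the component containing the lowest element index,
#' with a warning), unreferenced vertices dropped, and the removed element
#' indices recorded.
#'
#' @param split a `split_result`
#' @return the updated `split_result` with `removed_elements`,
#'   `element_map` and `vertex_map` filled in
#' @export
remove_isolated_components <- function(split) {
  m <- split$mesh
  nel <- nrow(m$elements)
  star <- split(rep.int(seq_len(nel), ncol(m$elements)),
                factor(as.vector(m$elements),
                       levels = seq_len(nrow(m$vertices))))
  edges <- do.call(rbind, lapply(star, function(es)
    if (length(es) > 1) cbind(es[1], es[-1]) else NULL))
  g <- igraph::make_empty_graph(n = nel, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  cmp <- igraph::components(g)
  sizes <- cmp$csize
  if (sum(sizes == max(sizes)) > 1) {
    warning("tie for largest connected component; keeping the one with ",
            "the lowest minimum element index")
    cand <- which(sizes == max(sizes))
    mins <- vapply(cand, function(ci) min(which(cmp$membership == ci)),
                   integer(1))
    keep_comp <- cand[which.min(mins)]
  } else {
    keep_comp <- which.max(sizes)
  }
  keep <- which(cmp$membership == keep_comp)
  removed <- setdiff(seq_len(nrow(m$elements)), keep)
  if (!length(removed)) return(split)

  el <- m$elements[keep, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  vmap <- rep(NA_integer_, nrow(m$vertices))
  vmap[used] <- seq_along(used)
  el[] <- vmap[el]
  new_mesh <- dfe_mesh(m$vertices[used, , drop = FALSE], el,
                       region = m$region[keep],
                       fibres = if (is.null(m$fibres)) NULL else
                         m$fibres[keep, , drop = FALSE],
                       sheets = if (is.null(m$sheets)) NULL else
                         m$sheets[keep, , drop = FALSE],
                       normals = if (is.null(m$normals)) NULL else
                         m$normals[keep, , drop = FALSE])
  emap <- rep(NA_integer_, nrow(m$elements))
  emap[keep] <- seq_along(keep)

  dm <- split$duplication_map
  keep_dup <- !is.na(vmap[dm$new_vertex])
  dm <- dm[keep_dup, , drop = FALSE]
  dm$new_vertex <- vmap[dm$new_vertex]
  dm$original_vertex_old_index <- dm$original_vertex
  dm$original_vertex <- vmap[dm$original_vertex]

  split$mesh <- new_mesh
  split$duplication_map <- dm
  split$removed_elements <- removed
  split$element_map <- emap
  split$vertex_map <- vmap
  split
}

#' Audit the tightness of a split mesh
#'
#' Verifies that a splitting produced a topology through which current
#' cannot leak: (1) for every network face, the two originally adjacent
#' elements share no vertex in the split mesh; (2) at every visited vertex,
#' elements belonging to different local connectivity components (as
#' recomputed by the connectivity-consistent analysis on the original
#' connectivity) hold different copies of the vertex. Failures are
#' enumerated rather than raised.
#'
#' @param split a `split_result`
#' @param network the `fibrosis_network` used for the split (defaults to
#'   the one recorded in `split`)
#' @return object of class `tightness_audit`: list with logical `pass` and
#'   a data.frame `failures` (`kind`, `where`, `detail`)
#' @export
audit_tightness <- function(split, network = split$network) {
  m <- split$mesh
  emap <- split$element_map
  fail_kind <- character(0); fail_where <- character(0)
  fail_detail <- character(0)

  np <- split$net_pairs
  for (r in seq_len(nrow(np))) {
    e1 <- emap[np$e1[r]]; e2 <- emap[np$e2[r]]
    if (is.na(e1) || is.na(e2)) next
    shared <- intersect(m$elements[e1, ], m$elements[e2, ])
    if (length(shared)) {
      fail_kind <- c(fail_kind, "face_leak")
      fail_where <- c(fail_where, np$key[r])
      fail_detail <- c(fail_detail,
                       sprintf("elements %d,%d share vertices %s",
                               np$e1[r], np$e2[r],
                               paste(shared, collapse = ",")))
    }
  }

  for (rec in split$records) {
    comps <- rec$reference
    if (length(comps) < 2) next
    # the ids actually used at this vertex slot, per reference component
    used <- lapply(comps, function(cp) {
      cp2 <- emap[cp]
      cp2 <- cp2[!is.na(cp2)]
      if (!length(cp2)) return(integer(0))
      ids <- unique(unlist(lapply(cp2, function(e)
        intersect(m$elements[e, ],
                  stats::na.omit(split$vertex_map[rec$ids])))))
      ids
    })
    for (i in seq_along(used)) {
      for (j in seq_along(used)) {
        if (j <= i) next
        if (length(intersect(used[[i]], used[[j]]))) {
          fail_kind <- c(fail_kind, "component_leak")
          fail_where <- c(fail_where, as.character(rec$vertex))
          fail_detail <- c(fail_detail,
                           sprintf("components %d and %d share a copy", i, j))
        }
      }
    }
  }
  structure(list(pass = length(fail_kind) == 0,
                 failures = data.frame(kind = fail_kind, where = fail_where,
                                       detail = fail_detail,
                                       stringsAsFactors = FALSE)),
            class = "tightness_audit")
}

#' @export
print.tightness_audit <- function(x, ...) {
  if (x$pass) cat("tightness audit: PASS\n")
  else {
    cat("tightness audit: FAIL (", nrow(x$failures), " failures)\n", sep = "")
    print(utils::head(x$failures, 10))
  }
  invisible(x)
}
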