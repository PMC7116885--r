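#' Normalized fibrosis intensity
#'
#' Maps a raw image intensity to `(I - I_ref) / (I_max - I_ref)`, clamped to
#' `[0, 1]`. `I_ref` is the reference (mean non-enhanced) intensity and
#' `I_max` the maximum enhanced intensity.
#'
#' @param I raw intensity (vectorized), image units
#' @param I_ref,I_max reference and maximum intensity, `I_max > I_ref`
#' @return normalized intensity in `[0, 1]`
#' @export
normalize_intensity <- function(I, I_ref, I_max) {
  if (I_max <= I_ref) stop("I_max must exceed I_ref")
  pmin(pmax((I - I_ref) / (I_max - I_ref), 0), 1)
}

#' Per-face fibrosis probability
#'
#' The probability that a mesh face hosts a fibrotic cleft is
#' `rho_max * |cos(theta)| * I_star`, where `theta` is the angle between the
#' face normal and the local myocardial sheet-normal direction: clefts
#' preferentially align with the sheet planes, so faces whose normal is
#' parallel to the sheet normal (theta = 0) are most likely fibrotic, and
#' faces perpendicular to the sheets (theta = pi/2) never are. The absolute
#' value resolves the sign ambiguity of the (unoriented) face normal: a
#' face and its flipped normal describe the same cleft.
#'
#' @param I_star normalized intensity in `[0, 1]` (vectorized)
#' @param theta angle between face normal and sheet normal, radians
#' @param rho_max global maximum fibrosis density in `[0, 1]`
#' @return probability in `[0, rho_max]`
#' @export
face_probability <- function(I_star, theta, rho_max) {
  if (any(I_star < -1e-12 | I_star > 1 + 1e-12)) stop("I_star must be in [0, 1]")
  if (rho_max < 0 || rho_max > 1) stop("rho_max must be in [0, 1]")
  rho_max * abs(cos(theta)) * I_star
}

#' Fibrosis probability map for a mesh
#'
#' Combines an element intensity field and the element sheet normals into a
#' per-face probability of fibrosis over the interior faces of the LGE
#' region. A face is considered inside the LGE when both adjacent elements
#' are tagged LGE; its normalized intensity is the mean of the two adjacent
#' element values; its sheet-normal direction is the (renormalized) average
#' of the adjacent elements' sheet normals, with the second flipped if it
#' opposes the first.
#'
#' @param mesh a `dfe_mesh` with orientation triads
#' @param adjacency the mesh's `adjacency_index` (built if `NULL`)
#' @param intensity an `intensity_field`
#' @param rho_max global maximum fibrosis density in `[0, 1]`
#' @return object of class `probability_map`: list with `keys` (face keys of
#'   candidate interior LGE faces), `p`, `theta`, `rho_max`
#' @export
probability_map <- function(mesh, intensity, rho_max, adjacency = NULL) {
  if (is.null(mesh$normals)) stop("mesh has no orientation triads")
  if (rho_max < 0 || rho_max > 1) stop("rho_max must be in [0, 1]")
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  lge <- mesh$region == 1L
  sel <- which(adjacency$interior & lge[adjacency$e1] &
                 lge[replace(adjacency$e2, is.na(adjacency$e2), 1L)])
  keys <- adjacency$keys[sel]
  faces <- adjacency$faces[sel, , drop = FALSE]
  e1 <- adjacency$e1[sel]
  e2 <- adjacency$e2[sel]

  istar_el <- normalize_intensity(intensity$value, intensity$I_ref,
                                  intensity$I_max)
  istar <- (istar_el[e1] + istar_el[e2]) / 2

  n1 <- mesh$normals[e1, , drop = FALSE]
  n2 <- mesh$normals[e2, , drop = FALSE]
  flip <- rowSums(n1 * n2) < 0
  n2[flip, ] <- -n2[flip, ]
  ns <- n1 + n2
  ns <- ns / sqrt(rowSums(ns^2))
  fn <- .face_normals(mesh, faces)
  ct <- pmin(1, abs(rowSums(fn * ns)))
  theta <- acos(ct)

  structure(list(keys = keys, p = rho_max * ct * istar, theta = theta,
                 rho_max = rho_max),
            class = "probability_map")
}

#' Fibrosis network constructor
#'
#' A set of interior face keys designated as no-flux clefts, together with
#' the sampling provenance.
#'
#' @param keys character vector of canonical face keys (see the adjacency
#'   index); may be empty
#' @param rho_max the density parameter used to generate the network
#'   (`NA` for hand-designated networks)
#' @param seed the sampling seed (`NA` for hand-designated networks)
#' @return an object of class `fibrosis_network`
#' @export
fibrosis_network <- function(keys, rho_max = NA_real_, seed = NA_integer_) {
  structure(list(faces = unique(as.character(keys)), rho_max = rho_max,
                 seed = seed),
            class = "fibrosis_network")
}

#' @export
print.fibrosis_network <- function(x, ...) {
  cat(sprintf("fibrosis_network: %d faces (rho_max = %s, seed = %s)\n",
              length(x$faces), format(x$rho_max), format(x$seed)))
  invisible(x)
}

#' @export
length.fibrosis_network <- function(x) length(x$faces)

#' Sample a fibrosis network realization
#'
#' Draws one independent uniform number per candidate face and includes the
#' face when the draw falls below its probability (a standard Bernoulli
#' sample, so that faces with higher probability are more likely to be
#' fibrotic). Deterministic given the seed.
#'
#' @param pmap a `probability_map`
#' @param seed integer seed
#' @return a `fibrosis_network`
#' @export
sample_network <- function(pmap, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  u <- stats::runif(length(pmap$p))
  fibrosis_network(pmap$keys[u < pmap$p], rho_max = pmap$rho_max,
                   seed = as.integer(seed))
}

#' Density sweep of fibrosis network realizations
#'
#' Generates `n_realizations` seeded network realizations for each maximum
#' density in `densities`, plus one fibrosis-free control network. The
#' standard sweep (densities 0.1 to 1.0 in steps of 0.1, 15 realizations
#' each) yields 151 model configurations. Seeds are derived as
#' `base_seed + 1000 * density_index + realization_index`, so the sweep is
#' reproducible and collision-free.
#'
#' @param mesh a `dfe_mesh` with orientation triads and LGE tags
#' @param intensity an `intensity_field`
#' @param densities vector of `rho_max` values in `(0, 1]`
#' @param n_realizations realizations per density (>= 1)
#' @param base_seed integer base seed
#' @param adjacency optional precomputed `adjacency_index`
#' @return list of `fibrosis_network` objects, the control (empty, rho 0)
#'   network last
#' @export
density_sweep <- function(mesh, intensity, densities = seq(0.1, 1, by = 0.1),
                          n_realizations = 15, base_seed = 0,
                          adjacency = NULL) {
  if (any(densities <= 0 | densities > 1))
    stop("densities must lie in (0, 1]")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  nets <- vector("list", length(densities) * n_realizations)
  idx <- 1L
  for (di in seq_along(densities)) {
    pmap <- probability_map(mesh, intensity, densities[di],
                            adjacency = adjacency)
    for (ri in seq_len(n_realizations)) {
      nets[[idx]] <- sample_network(pmap, base_seed + 1000L * di + ri)
      idx <- idx + 1L
    }
  }
  control <- fibrosis_network(character(0), rho_max = 0,
                              seed = as.integer(base_seed))
  c(nets, list(control))
}

#' Write / read a fibrosis network as plain text
#'
#' One face per line (sorted vertex indices, 0-based on disk for
#' consistency with the mesh dialect), preceded by a header comment that
#' records `rho_max` and the seed.
#'
#' @param network a `fibrosis_network`
#' @param file path
#' @return `write_network`: invisibly, `file`; `read_network`: a
#'   `fibrosis_network`
#' @export
write_network <- function(network, file) {
  faces <- .key_to_face(network$faces)
  header <- sprintf("# fibrosis_network rho_max=%s seed=%s",
                    format(network$rho_max), format(network$seed))
  body <- if (is.null(faces) || nrow(faces) == 0) character(0) else
    apply(faces - 1L, 1L, paste, collapse = " ")
  writeLines(c(header, body), file)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  rho <- NA_real_; seed <- NA_integer_
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("rho_max=([^ ]+) seed=([^ ]+)", hdr[1]))[[1]]
    if (length(m) == 3) {
      rho <- suppressWarnings(as.numeric(m[2]))
      seed <- suppressWarnings(as.integer(m[3]))
    }
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) return(fibrosis_network(character(0), rho, seed))
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                               as.integer)) + 1L
  fibrosis_network(.face_keys(mat), rho, seed)
}
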