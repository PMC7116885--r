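#' Tune a conductivity to a conduction velocity target
#'
#' Finds the scalar conductivity (mS/cm) that reproduces a target planar
#' conduction velocity on a strand mesh of the given resolution, by
#' fixed-point iteration on the square-root scaling law `CV ~ sqrt(sigma)`
#' (each iteration is a full strand simulation and CV measurement). The
#' numerical CV depends on the mesh edge length, so conductivities must be
#' tuned per resolution; results are cached per
#' (target, direction, edge, model) for the session.
#'
#' @param target_cv target conduction velocity (cm/s)
#' @param direction `"fibre"` (3D strand, propagation along fibres),
#'   `"transverse"` (3D strand, fibres across the propagation axis), or
#'   `"isotropic2d"` (triangulated 2D strip, as in the 2D test meshes)
#' @param edge_length mesh edge length (mm)
#' @param model an `ionic_model_spec`
#' @param tol relative CV tolerance (default 1%)
#' @param max_iter iteration cap
#' @return list with `sigma` (mS/cm), `cv` (measured, cm/s), `history`
#'   (data.frame of iterates)
#' @export
tune_conductivity <- function(target_cv,
                              direction = c("fibre", "transverse",
                                            "isotropic2d"),
                              edge_length = 0.4,
                              model = ionic_model("tt06"),
                              tol = 0.01, max_iter = 25) {
  direction <- match.arg(direction)
  if (target_cv <= 0) stop("target_cv must be positive")
  key <- sprintf("tune_%s_%s_%g_%g", model$name, direction, edge_length,
                 target_cv)
  if (!is.null(.fibro_cache[[key]])) return(.fibro_cache[[key]])

  geo <- .strand_geometry(direction, edge_length)
  sigma <- 3.0 * (target_cv / 84)^2
  hist_sigma <- hist_cv <- numeric(0)
  for (it in seq_len(max_iter)) {
    cv <- tryCatch(
      .strand_cv(geo, sigma, model, target_cv),
      error = function(e) NA_real_)
    if (is.na(cv)) {           # wave failed to propagate: raise conductivity
      sigma <- sigma * 4
      next
    }
    hist_sigma <- c(hist_sigma, sigma); hist_cv <- c(hist_cv, cv)
    if (abs(cv - target_cv) / target_cv <= tol) {
      out <- list(sigma = sigma, cv = cv,
                  history = data.frame(sigma = hist_sigma, cv = hist_cv))
      .fibro_cache[[key]] <- out
      return(out)
    }
    sigma <- sigma * (target_cv / cv)^2
  }
  stop("conductivity tuning did not converge in ", max_iter,
       " iterations; history: ",
       paste(sprintf("(%.4g, %.3g)", hist_sigma, hist_cv), collapse = " "))
}

.strand_geometry <- function(direction, edge) {
  if (direction == "isotropic2d") {
    ny <- max(24L, as.integer(round(8 / edge)))
    mesh <- .make_grid_rect(4L, ny, edge)
    axis <- c(0, 1, 0)
    L <- ny * edge
  } else {
    L <- 12
    w <- 2 * edge
    rule <- if (direction == "fibre") NULL else
      function(ctr) list(f = c(0, 1, 0), s = c(1, 0, 0), n = c(0, 0, 1))
    mesh <- make_slab_3d(c(L, w, w), edge, orientation_rule = rule)
    axis <- c(1, 0, 0)
  }
  s <- as.numeric(mesh$vertices %*% axis)
  list(mesh = mesh, axis = axis, L = L, s = s,
       stim_nodes = which(s <= edge * 1.1),
       window = c(0.3 * L, 0.75 * L),
       stop_nodes = which(s <= 0.78 * L),
       direction = direction, edge = edge)
}

.strand_cv <- function(geo, sigma, model, target_cv) {
  cond <- if (geo$direction == "fibre")
    conductivity_field(geo$mesh, sigma_l = sigma, sigma_t = sigma / 4)
  else
    conductivity_field(geo$mesh, sigma_l = sigma, sigma_t = sigma)
  # for the transverse strand the propagation axis samples sigma_t = sigma
  dur <- 10 + 2.5 * geo$L / (target_cv / 100)
  run <- run_monodomain(geo$mesh, cond,
                        stimulus(onsets = 0, nodes = geo$stim_nodes),
                        duration = dur, model = model,
                        stop_nodes = geo$stop_nodes)
  measure_cv(run, geo$mesh, axis = geo$axis, window = geo$window)
}

#' Conductivity field from conduction velocity targets
#'
#' Builds a per-element conductivity field by tuning conductivities to the
#' given fibre and transverse CV targets at the mesh resolution, with
#' intensity-band scaling of the targets inside the LGE region (see
#' [lge_conductivity_bands()]): band scales are applied to the CV targets
#' and each distinct scaled target is tuned separately (tuning results are
#' cached, so the handful of band targets costs a few strand simulations
#' each, once per session).
#'
#' @param mesh a `dfe_mesh` (region tags select the LGE elements)
#' @param cvf,cvt fibre and transverse CV targets in normal tissue (cm/s)
#' @param intensity optional `intensity_field`; required when the mesh has
#'   LGE-tagged elements
#' @param edge_length mesh edge length used for tuning (mm); scalar
#' @param model an `ionic_model_spec`
#' @return a `conductivity_field`
#' @export
conductivity_from_cv <- function(mesh, cvf = 84, cvt = 23, intensity = NULL,
                                 edge_length = 0.4,
                                 model = ionic_model("tt06")) {
  m <- n_elements(mesh)
  cvf_el <- rep(cvf, m)
  cvt_el <- rep(cvt, m)
  lge <- mesh$region == 1L
  if (any(lge)) {
    if (is.null(intensity))
      stop("mesh has LGE elements; an intensity field is required")
    istar <- normalize_intensity(intensity$value, intensity$I_ref,
                                 intensity$I_max)
    sc <- lge_conductivity_bands(istar)
    cvf_el[lge] <- cvf * sc[lge, "scale_fibre"]
    cvt_el[lge] <- cvt * sc[lge, "scale_transverse"]
  }
  sl <- st <- numeric(m)
  for (cv in unique(cvf_el))
    sl[cvf_el == cv] <- tune_conductivity(cv, "fibre", edge_length,
                                          model)$sigma
  for (cv in unique(cvt_el))
    st[cvt_el == cv] <- tune_conductivity(cv, "transverse", edge_length,
                                          model)$sigma
  conductivity_field(mesh, sigma_l = sl, sigma_t = st)
}
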