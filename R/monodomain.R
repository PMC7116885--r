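# Fixed monodomain constants: membrane capacitance (uF/cm^2) and
# surface-to-volume ratio (1/cm). Any mismatch with a particular tissue
# preparation is absorbed by conduction-velocity tuning, which is the
# calibration procedure used throughout.
.MONO_CM <- 1
.MONO_BETA <- 1400

#' Per-element conductivity field
#'
#' Transversely isotropic conductivity built from the element orientation
#' triads: `sigma = sigma_l f f' + sigma_t (I - f f')`, with longitudinal
#' (along-fibre) and transverse scalar conductivities in mS/cm, optionally
#' modulated by per-element scale factors in `(0, 1]` (see
#' [lge_conductivity_bands()] for the intensity-driven scaling, which is
#' applied to CV targets before tuning rather than to conductivities).
#'
#' @param mesh a `dfe_mesh`
#' @param sigma_l,sigma_t longitudinal and transverse conductivity (mS/cm),
#'   scalar or per-element
#' @return object of class `conductivity_field`
#' @export
conductivity_field <- function(mesh, sigma_l, sigma_t = sigma_l) {
  m <- n_elements(mesh)
  sigma_l <- rep_len(as.numeric(sigma_l), m)
  sigma_t <- rep_len(as.numeric(sigma_t), m)
  if (any(sigma_l <= 0) || any(sigma_t <= 0))
    stop("conductivities must be positive")
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t),
            class = "conductivity_field")
}

#' LGE intensity-band conduction velocity scaling
#'
#' Maps normalized LGE intensity to (fibre, transverse) conduction-velocity
#' scale factors: intensities 0-25% and 25-50% above the reference reduce
#' transverse CV by 25% and 50% with normal fibre CV; 50-75% and 75-100%
#' additionally reduce fibre CV by 25% and 50% (transverse stays at 50%).
#' Bands are half-open `[lo, hi)`; an intensity of exactly 0 falls in the
#' lowest band.
#'
#' @param I_star normalized intensity in `[0, 1]` (vectorized)
#' @return matrix with columns `scale_fibre`, `scale_transverse`
#' @export
lge_conductivity_bands <- function(I_star) {
  if (any(I_star < 0 | I_star > 1)) stop("I_star must be in [0, 1]")
  band <- findInterval(I_star, c(0.25, 0.5, 0.75)) + 1L   # 1..4
  sf <- c(1.00, 1.00, 0.75, 0.50)[band]
  st <- c(0.75, 0.50, 0.50, 0.50)[band]
  cbind(scale_fibre = sf, scale_transverse = st)
}

# Per-element diffusion tensors D = sigma / (beta * Cm) in cm^2/ms,
# flattened row-major to an m x d^2 matrix for the assembler.
.diffusion_tensors <- function(mesh, cond) {
  m <- n_elements(mesh)
  sl <- cond$sigma_l / (.MONO_BETA * .MONO_CM)
  st <- cond$sigma_t / (.MONO_BETA * .MONO_CM)
  if (is.null(mesh$fibres)) {
    f <- matrix(rep(c(1, 0, 0), each = m), ncol = 3)
  } else {
    f <- mesh$fibres
  }
  d <- mesh$dim
  if (d == 2L) {
    fx <- f[, 1]; fy <- f[, 2]
    nrm <- sqrt(fx^2 + fy^2)
    iso <- nrm < 1e-8   # fibre out of plane: treat as isotropic transverse
    fx <- ifelse(iso, 1, fx / pmax(nrm, 1e-12))
    fy <- ifelse(iso, 0, fy / pmax(nrm, 1e-12))
    slv <- ifelse(iso, st, sl)
    cbind(st + (slv - st) * fx * fx, (slv - st) * fx * fy,
          (slv - st) * fy * fx, st + (slv - st) * fy * fy)
  } else {
    out <- matrix(0, m, 9)
    for (r in 1:3) for (c in 1:3) {
      out[, (r - 1) * 3 + c] <- (sl - st) * f[, r] * f[, c] +
        if (r == c) st else 0
    }
    out
  }
}

#' Assemble monodomain finite element operators
#'
#' Piecewise linear (P1) mass and stiffness operators with natural (no-flux)
#' boundary conditions: the stiffness matrix has zero row sums, which is
#' exactly what makes split faces insulating — duplicated vertices carry no
#' coupling across the cleft. The mass matrix is lumped (row-sum diagonal).
#'
#' @param mesh a `dfe_mesh`
#' @param cond a `conductivity_field`
#' @return object of class `monodomain_operators`: list with `mass`
#'   (numeric vector, lumped, cm^dim), `stiffness` (sparse `dgCMatrix`,
#'   cm^dim/ms), `mesh_dim`
#' @export
assemble_operators <- function(mesh, cond) {
  dt <- .diffusion_tensors(mesh, cond)
  trip <- .fem_assemble(mesh$vertices * 0.1, mesh$elements - 1L, dt)
  K <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
                            dims = rep(nrow(mesh$vertices), 2))
  structure(list(mass = trip$mass, stiffness = K, mesh_dim = mesh$dim),
            class = "monodomain_operators")
}

#' Stimulus specification
#'
#' A transmembrane stimulus delivered to all vertices within `radius` of
#' `site` (or to an explicit vertex set), with the standard strength of
#' 500 uA/cm^2 for 2 ms.
#'
#' @param site stimulus centre (mm; length 2 or 3)
#' @param onsets onset times (ms)
#' @param strength current density (uA/cm^2, positive depolarizing)
#' @param duration stimulus duration (ms)
#' @param radius capture radius around `site` (mm)
#' @param nodes optional explicit vertex indices (overrides `site`/`radius`)
#' @return object of class `stimulus_spec`
#' @export
stimulus <- function(site = NULL, onsets, strength = 500, duration = 2,
                     radius = 1, nodes = NULL) {
  if (is.null(site) && is.null(nodes))
    stop("either site or nodes must be given")
  if (!is.null(site) && length(site) == 2) site <- c(site, 0)
  structure(list(site = site, onsets = sort(as.numeric(onsets)),
                 strength = strength, duration = duration, radius = radius,
                 nodes = nodes),
            class = "stimulus_spec")
}

.stim_nodes <- function(stim, mesh) {
  if (!is.null(stim$nodes)) return(as.integer(stim$nodes))
  d2 <- rowSums((mesh$vertices -
                   matrix(stim$site, nrow(mesh$vertices), 3,
                          byrow = TRUE))^2)
  nodes <- which(d2 <= stim$radius^2)
  if (!length(nodes)) stop("no vertices within the stimulus radius")
  nodes
}

#' Run a monodomain simulation
#'
#' Operator-splitting (Godunov) time integration of the monodomain
#' reaction-diffusion equation: at each step of `dt` (equal to the ionic
#' model's `dt_ode`) the membrane model is advanced at every vertex, then
#' an implicit Euler diffusion step is solved with the lumped mass matrix
#' via a sparse Cholesky factorization computed once. Activation times
#' (first upward crossing of 0 mV, linearly interpolated) are recorded
#' online at full solver resolution.
#'
#' @param mesh a `dfe_mesh`
#' @param cond a `conductivity_field` (ignored if `ops` given)
#' @param stimuli a `stimulus_spec` or list of them
#' @param duration simulation length (ms)
#' @param model an `ionic_model_spec`
#' @param init_state optional initial state: a single state vector
#'   (replicated) or an n x state_dim matrix (e.g. the `state` of a
#'   previous run)
#' @param ops optional precomputed `monodomain_operators`
#' @param record_vm `"none"`, `"probes"` or `"all"`: membrane potential
#'   storage (sampled every `vm_interval` ms)
#' @param probes vertex indices recorded when `record_vm = "probes"`
#' @param vm_interval sampling interval for stored vm (ms)
#' @param stop_nodes optional vertex set: the run ends early once every one
#'   of these vertices has activated
#' @param t0 time of the first step (ms); stimulus onsets are absolute
#' @return object of class `monodomain_run`: list with `activations`
#'   (data.frame `node`, `time`), `state` (final state matrix), `vm`,
#'   `vm_time`, `probes`, `t0`, `t_end`, `dt`, `model`
#' @export
run_monodomain <- function(mesh, cond = NULL, stimuli = list(), duration,
                           model = ionic_model("tt06"), init_state = NULL,
                           ops = NULL, record_vm = c("none", "probes", "all"),
                           probes = NULL, vm_interval = 1,
                           stop_nodes = NULL, t0 = 0) {
  record_vm <- match.arg(record_vm)
  if (duration <= 0) stop("duration must be positive")
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (is.null(ops)) {
    if (is.null(cond)) stop("either cond or ops must be supplied")
    ops <- assemble_operators(mesh, cond)
  }
  n <- nrow(mesh$vertices)
  dt <- model$dt_ode

  if (is.null(init_state)) init_state <- resting_state(model)
  if (is.null(dim(init_state))) {
    S <- matrix(rep(as.numeric(init_state), each = n), nrow = n)
  } else {
    if (nrow(init_state) != n) stop("init_state has wrong number of rows")
    S <- init_state + 0   # force a copy; advanced in place
  }

  A <- Matrix::Diagonal(x = ops$mass) + dt * ops$stiffness
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  mass <- ops$mass

  stim_nodes <- lapply(stimuli, .stim_nodes, mesh = mesh)
  stim_tab <- lapply(stimuli, function(s)
    cbind(start = s$onsets, end = s$onsets + s$duration))

  nsteps <- as.integer(round(duration / dt))
  every_vm <- max(1L, as.integer(round(vm_interval / dt)))
  vm_list <- list(); vm_time <- numeric(0)
  if (record_vm == "probes" && is.null(probes))
    stop("record_vm = 'probes' requires probe vertex indices")
  acc_node <- vector("list", 64L); acc_time <- vector("list", 64L)
  acc_n <- 0L
  activated <- logical(n)
  iext <- numeric(n)
  check_every <- 25L

  for (step in seq_len(nsteps)) {
    t <- t0 + (step - 1L) * dt
    iext[] <- 0
    for (si in seq_along(stimuli)) {
      tab <- stim_tab[[si]]
      on <- any(t >= tab[, "start"] - 1e-9 & t < tab[, "end"] - 1e-9)
      if (on) iext[stim_nodes[[si]]] <- iext[stim_nodes[[si]]] +
          stimuli[[si]]$strength / .MONO_CM
    }
    vprev <- S[, 1]
    .ionic_step_inplace(S, model$name, iext, dt, 1L)
    vnew <- as.numeric(Matrix::solve(ch, mass * S[, 1], system = "A"))
    S[, 1] <- vnew
    up <- which(vprev < 0 & vnew >= 0)
    if (length(up)) {
      tc <- t + dt * (0 - vprev[up]) / (vnew[up] - vprev[up])
      acc_n <- acc_n + 1L
      acc_node[[acc_n]] <- up
      acc_time[[acc_n]] <- tc
      activated[up] <- TRUE
    }
    if (record_vm != "none" && step %% every_vm == 0L) {
      vm_time <- c(vm_time, t + dt)
      vm_list[[length(vm_list) + 1L]] <-
        if (record_vm == "all") vnew else vnew[probes]
    }
    if (!is.null(stop_nodes) && step %% check_every == 0L &&
        all(activated[stop_nodes])) break
  }

  activations <- data.frame(
    node = unlist(acc_node[seq_len(acc_n)]),
    time = unlist(acc_time[seq_len(acc_n)]))
  if (!nrow(activations))
    activations <- data.frame(node = integer(0), time = numeric(0))
  vm <- if (length(vm_list)) do.call(rbind, vm_list) else NULL
  structure(list(activations = activations, state = S, vm = vm,
                 vm_time = vm_time, probes = probes, t0 = t0,
                 t_end = t0 + step * dt, dt = dt, model = model),
            class = "monodomain_run")
}

#' @export
print.monodomain_run <- function(x, ...) {
  cat(sprintf(paste0("monodomain_run (%s): t = [%g, %g] ms, ",
                     "%d activation events over %d vertices\n"),
              x$model$name, x$t0, x$t_end, nrow(x$activations),
              nrow(x$state)))
  invisible(x)
}

#' Pure diffusion relaxation
#'
#' Implicit Euler integration of `M dv/dt = -K v` without membrane
#' kinetics. Used to verify that a split mesh is non-leaking: two regions
#' separated by a complete split fence, initialized to different constants,
#' must hold their plateaus indefinitely.
#'
#' @param mesh a `dfe_mesh`
#' @param cond a `conductivity_field`
#' @param v0 initial per-vertex values
#' @param duration duration (ms)
#' @param dt time step (ms)
#' @return final per-vertex values
#' @export
run_diffusion <- function(mesh, cond, v0, duration, dt = 0.1) {
  ops <- assemble_operators(mesh, cond)
  A <- Matrix::Diagonal(x = ops$mass) + dt * ops$stiffness
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  v <- as.numeric(v0)
  for (s in seq_len(as.integer(round(duration / dt))))
    v <- as.numeric(Matrix::solve(ch, ops$mass * v, system = "A"))
  v
}

#' First upward 0 mV crossing of a sampled trace
#'
#' Linear-interpolated time of the first crossing of 0 mV with positive
#' temporal derivative, or `NA` (the never-activated sentinel).
#'
#' @param time,vm sampled trace (fixed output interval)
#' @return crossing time (ms) or `NA`
#' @export
detect_activation_times <- function(time, vm) {
  n <- length(vm)
  if (n < 2) return(NA_real_)
  up <- which(vm[-n] < 0 & vm[-1] >= 0)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  time[i] + (time[i + 1] - time[i]) * (0 - vm[i]) / (vm[i + 1] - vm[i])
}

#' Per-vertex, per-beat activation map
#'
#' Assigns each recorded activation event of a run to the beat window it
#' falls in (`[onset_i, onset_{i+1})`, the last window extending to the end
#' of the run) and keeps the first activation per vertex and beat.
#'
#' @param run a `monodomain_run`
#' @param beat_onsets beat onset times (ms), increasing
#' @return numeric matrix (vertices x beats) of first-activation times,
#'   `NA` where a vertex never activated in a window
#' @export
activation_map <- function(run, beat_onsets) {
  n <- nrow(run$state)
  nb <- length(beat_onsets)
  out <- matrix(NA_real_, n, nb)
  act <- run$activations
  if (!nrow(act)) return(out)
  beat <- findInterval(act$time, beat_onsets)
  ok <- beat >= 1L
  act <- act[ok, , drop = FALSE]; beat <- beat[ok]
  o <- order(act$time)
  for (r in o) {
    if (is.na(out[act$node[r], beat[r]]))
      out[act$node[r], beat[r]] <- act$time[r]
  }
  out
}

#' Planar conduction velocity from an activation map
#'
#' Least-squares regression of first-activation time on distance along an
#' axis, inverted to cm/s. Intended for an established planar wave within
#' the given window of projected coordinates.
#'
#' @param run a `monodomain_run` (its earliest activation per vertex is
#'   used), or a numeric vector of per-vertex activation times
#' @param mesh the mesh the run was computed on
#' @param axis propagation direction (mm units; need not be unit length)
#' @param window range `c(lo, hi)` of projected coordinate (mm) to include
#' @return velocity in cm/s
#' @export
measure_cv <- function(run, mesh, axis = c(1, 0, 0), window = NULL) {
  if (inherits(run, "monodomain_run")) {
    act <- rep(NA_real_, nrow(mesh$vertices))
    a <- run$activations
    if (nrow(a)) {
      first <- tapply(a$time, a$node, min)
      act[as.integer(names(first))] <- as.numeric(first)
    }
  } else {
    act <- as.numeric(run)
  }
  axis <- c(axis, 0, 0)[1:3]
  axis <- axis / sqrt(sum(axis^2))
  s <- as.numeric(mesh$vertices %*% axis)
  sel <- !is.na(act)
  if (!is.null(window)) sel <- sel & s >= window[1] & s <= window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 activated vertices in the measurement window")
  fit <- stats::lm.fit(cbind(1, s[sel]), act[sel])
  slope <- fit$coefficients[2]           # ms per mm
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive activation-time slope; no planar wave along axis")
  as.numeric(100 / slope)                # mm/ms -> cm/s
}
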