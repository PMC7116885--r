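#' Detect a new propagating wave after a stimulus
#'
#' A stimulus is considered captured (a new activation wave exists) when
#' any vertex within 4.2 cm of the stimulus site activates between 110 and
#' 120 ms after stimulus onset. Distances are Euclidean from the site
#' centre.
#'
#' @param run a `monodomain_run` (or a data.frame of `node`, `time`
#'   activation events)
#' @param mesh the simulation mesh
#' @param site stimulus site (mm)
#' @param stim_time stimulus onset (ms)
#' @param radius detection radius (mm; default 42 mm = 4.2 cm)
#' @param window detection window relative to `stim_time` (ms)
#' @return logical
#' @export
detect_new_wave <- function(run, mesh, site, stim_time, radius = 42,
                            window = c(110, 120)) {
  act <- if (inherits(run, "monodomain_run")) run$activations else run
  if (!nrow(act)) return(FALSE)
  if (length(site) == 2) site <- c(site, 0)
  sel <- act$time >= stim_time + window[1] & act$time <= stim_time + window[2]
  if (!any(sel)) return(FALSE)
  d2 <- rowSums((mesh$vertices[act$node[sel], , drop = FALSE] -
                   matrix(site, sum(sel), 3, byrow = TRUE))^2)
  any(d2 <= radius^2)
}

#' Detect reentry after a stimulated beat
#'
#' Reentry is flagged when any vertex within 1 cm of the stimulus site
#' activates later than 300 ms after the stimulus: by then the primary
#' wave has long left the neighbourhood, so a late local activation can
#' only be a returning (reentrant) wave.
#'
#' @inheritParams detect_new_wave
#' @param radius detection radius (mm; default 10 mm = 1 cm)
#' @param after latency threshold relative to `stim_time` (ms)
#' @return logical
#' @export
detect_reentry <- function(run, mesh, site, stim_time, radius = 10,
                           after = 300) {
  act <- if (inherits(run, "monodomain_run")) run$activations else run
  if (!nrow(act)) return(FALSE)
  if (length(site) == 2) site <- c(site, 0)
  sel <- act$time > stim_time + after
  if (!any(sel)) return(FALSE)
  d2 <- rowSums((mesh$vertices[act$node[sel], , drop = FALSE] -
                   matrix(site, sum(sel), 3, byrow = TRUE))^2)
  any(d2 <= radius^2)
}

#' Binary search for the effective refractory period
#'
#' Bisects the coupling interval between a non-capturing lower bound and a
#' capturing upper bound until two CIs one `resolution` apart are found
#' such that the longer captures and the shorter does not.
#'
#' @param runner function `f(ci)` returning `TRUE` when a stimulus at
#'   coupling interval `ci` (ms) initiates a new wave
#' @param bounds initial `(failing, capturing)` bracket (ms)
#' @param resolution final bracket width (ms)
#' @return named numeric vector `c(fail = ..., capture = ...)`
#' @export
erp_binary_search <- function(runner, bounds = c(200, 450), resolution = 10) {
  lo <- bounds[1]; hi <- bounds[2]
  if (runner(lo))
    stop("bracket error: stimulus captures at the lower bound (", lo,
         " ms); the protocol bracket must be widened")
  if (!runner(hi))
    stop("bracket error: stimulus fails to capture at the upper bound (",
         hi, " ms)")
  while (hi - lo > resolution) {
    mid <- round((lo + hi) / 2 / resolution) * resolution
    if (mid <= lo) mid <- lo + resolution
    if (mid >= hi) mid <- hi - resolution
    if (runner(mid)) hi <- mid else lo <- mid
  }
  c(fail = lo, capture = hi)
}

#' Simulated programmed electrical stimulation
#'
#' Delivers a preconditioning cycle of 3 beats at 600 ms intervals, then up
#' to 3 extra-stimuli, each timed at the capturing end of the effective
#' refractory period bracket found by binary search from the current
#' tissue state. After each extra-stimulus 800 ms are simulated and checked
#' for reentry (late re-activation near the pacing site); the protocol
#' stops at the first reentry.
#'
#' @param mesh a (split) `dfe_mesh`
#' @param cond a `conductivity_field`
#' @param pacing_site stimulus location (mm)
#' @param model an `ionic_model_spec`
#' @param precond_n,precond_ci preconditioning beat count and interval (ms)
#' @param max_dynamic maximum number of extra-stimuli
#' @param erp_bounds,resolution ERP search bracket (ms) and resolution (ms)
#' @param observe post-beat observation window for reentry detection (ms)
#' @param stim_strength,stim_duration,stim_radius stimulus parameters
#' @param new_wave_radius radius for capture detection (mm)
#' @return object of class `pes_outcome`: list with `erp_brackets` (one row
#'   per dynamic beat), `beats_delivered`, `reentry`, `reentry_beat`
#' @export
run_pes <- function(mesh, cond, pacing_site, model = ionic_model("tt06"),
                    precond_n = 3, precond_ci = 600, max_dynamic = 3,
                    erp_bounds = c(200, 450), resolution = 10,
                    observe = 800, stim_strength = 500, stim_duration = 2,
                    stim_radius = 1, new_wave_radius = 42) {
  ops <- assemble_operators(mesh, cond)
  site <- if (length(pacing_site) == 2) c(pacing_site, 0) else pacing_site
  mk_stim <- function(onset) stimulus(site = site, onsets = onset,
                                      strength = stim_strength,
                                      duration = stim_duration,
                                      radius = stim_radius)
  seg <- function(state, t0, duration, stim = NULL) {
    run_monodomain(mesh, ops = ops,
                   stimuli = if (is.null(stim)) list() else stim,
                   duration = duration, model = model, init_state = state,
                   t0 = t0)
  }

  # preconditioning: beats at 0, ci, 2 ci, ...; carry the state through and
  # leave a checkpoint erp_bounds[1] ms after the last beat
  state <- resting_state(model)
  t <- 0
  for (b in seq_len(precond_n - 1L)) {
    r <- seg(state, t, precond_ci, mk_stim(t))
    state <- r$state
    t <- t + precond_ci
  }
  r <- seg(state, t, erp_bounds[1], mk_stim(t))
  last_beat <- t
  ckpt <- r$state
  ckpt_t <- t + erp_bounds[1]

  brackets <- NULL
  reentry <- FALSE
  reentry_beat <- NA_integer_
  beats <- 0L
  for (k in seq_len(max_dynamic)) {
    probe <- function(ci) {
      tb <- last_beat + ci
      gap <- tb - ckpt_t
      st <- ckpt
      if (gap > 0) st <- seg(st, ckpt_t, gap)$state
      pr <- seg(st, tb, 130, mk_stim(tb))
      detect_new_wave(pr, mesh, site, tb, radius = new_wave_radius)
    }
    br <- erp_binary_search(probe, bounds = erp_bounds,
                            resolution = resolution)
    brackets <- rbind(brackets, br)
    tb <- last_beat + br[["capture"]]
    st <- ckpt
    if (tb - ckpt_t > 0) st <- seg(st, ckpt_t, tb - ckpt_t)$state
    beats <- beats + 1L
    # deliver in two segments so the next checkpoint (beat + erp lower
    # bound) is available without re-simulation
    r1 <- seg(st, tb, erp_bounds[1], mk_stim(tb))
    r2 <- seg(r1$state, tb + erp_bounds[1], observe - erp_bounds[1])
    acts <- rbind(r1$activations, r2$activations)
    if (detect_reentry(acts, mesh, site, tb)) {
      reentry <- TRUE
      reentry_beat <- k
      break
    }
    last_beat <- tb
    ckpt <- r1$state
    ckpt_t <- tb + erp_bounds[1]
  }
  structure(list(erp_brackets = brackets, beats_delivered = beats,
                 reentry = reentry, reentry_beat = reentry_beat),
            class = "pes_outcome")
}

#' @export
print.pes_outcome <- function(x, ...) {
  cat(sprintf("pes_outcome: %d dynamic beat(s), reentry = %s%s\n",
              x$beats_delivered, x$reentry,
              if (x$reentry) sprintf(" (beat %d)", x$reentry_beat) else ""))
  if (!is.null(x$erp_brackets)) {
    cat("  ERP brackets (fail, capture) ms:\n")
    print(unname(x$erp_brackets))
  }
  invisible(x)
}

#' Transmural activation time pacing protocol
#'
#' Runs the decremental pacing sequence (3 beats at 600 ms coupling
#' interval, then 350 ms, then 270 ms), and records the transmural
#' activation time — the latency from stimulus onset to the first
#' activation of a measurement site on the far wall — for the final three
#' beats.
#'
#' @param mesh a (split) `dfe_mesh`
#' @param cond a `conductivity_field`
#' @param pacing_site,measurement_site stimulus location and far-wall
#'   measurement location (mm); the nearest vertex to `measurement_site`
#'   is used
#' @param model an `ionic_model_spec`
#' @param cis coupling intervals of the beat train (ms)
#' @param tail_window simulation time after the last beat (ms)
#' @param stim_strength,stim_duration,stim_radius stimulus parameters
#' @return object of class `tat_record`: data.frame with `beat`, `onset`,
#'   `ci`, `tat` (ms; `NA` with a warning when the site never activates)
#' @export
run_tat_protocol <- function(mesh, cond, pacing_site, measurement_site,
                             model = ionic_model("tt06"),
                             cis = c(600, 600, 600, 350, 270),
                             tail_window = 300, stim_strength = 500,
                             stim_duration = 2, stim_radius = 1) {
  site <- if (length(pacing_site) == 2) c(pacing_site, 0) else pacing_site
  ms <- if (length(measurement_site) == 2) c(measurement_site, 0) else
    measurement_site
  d2 <- rowSums((mesh$vertices - matrix(ms, nrow(mesh$vertices), 3,
                                        byrow = TRUE))^2)
  mnode <- which.min(d2)
  onsets <- cumsum(c(0, cis[-length(cis)]))
  run <- run_monodomain(
    mesh, cond,
    stimulus(site = site, onsets = onsets, strength = stim_strength,
             duration = stim_duration, radius = stim_radius),
    duration = onsets[length(onsets)] + tail_window, model = model)
  amap <- activation_map(run, onsets)
  nb <- length(onsets)
  beats <- (nb - 2):nb
  tat <- amap[mnode, beats] - onsets[beats]
  if (anyNA(tat))
    warning("measurement site never activated for beat(s) ",
            paste(beats[is.na(tat)], collapse = ", "))
  structure(data.frame(beat = beats, onset = onsets[beats],
                       ci = cis[beats], tat = as.numeric(tat)),
            class = c("tat_record", "data.frame"),
            measurement_node = mnode)
}

#' Transient-block experiment on the 2D topology test meshes
#'
#' Stimulates the tight or leaky cross test mesh twice from the middle of
#' the bottom edge with a coupling interval of 340 ms (so the second wave
#' travels through partially recovered tissue), with conductivity tuned to
#' an effective conduction velocity of 17 cm/s, and classifies per wave
#' whether the wavefront crossed the row of fibrotic crosses.
#'
#' @param topology `"tight"` or `"leaky"`
#' @param model an `ionic_model_spec`
#' @param ci coupling interval between the two stimuli (ms)
#' @param cv_target effective conduction velocity (cm/s)
#' @param cross_margin a wave counts as having crossed when a vertex at
#'   least this many element rows above the fibrotic row activates
#' @param window classification window after each stimulus (ms)
#' @return object of class `block_experiment`: list with `topology`,
#'   `crossed` (logical per wave), `run` (the `monodomain_run`), `row_y`
#' @export
run_block_experiment <- function(topology = c("tight", "leaky"),
                                 model = ionic_model("tt06"), ci = 340,
                                 cv_target = 17, cross_margin = 2,
                                 window = 300) {
  topology <- match.arg(topology)
  tc <- make_cross_testcase(topology)
  split <- split_mesh(tc$mesh, tc$network,
                      leaky_vertices = tc$leaky_vertices)
  smesh <- split$mesh
  tun <- tune_conductivity(cv_target, "isotropic2d", 0.25, model)
  cond <- conductivity_field(smesh, sigma_l = tun$sigma,
                             sigma_t = tun$sigma)
  width <- max(smesh$vertices[, 1])
  site <- c(width / 2, 0, 0)
  run <- run_monodomain(smesh, cond,
                        stimulus(site = site, onsets = c(0, ci)),
                        duration = ci + window, model = model)
  row_y <- 19 * 0.25
  above <- smesh$vertices[, 2] >= row_y + cross_margin * 0.25 - 1e-9
  act <- run$activations
  crossed <- vapply(c(0, ci), function(on) {
    sel <- act$time >= on & act$time < on + window
    any(above[act$node[sel]])
  }, logical(1))
  if (!crossed[1])
    stop("calibration error: the first wave failed to cross the fibrotic ",
         "row (conduction velocity or refractoriness mistuned)")
  structure(list(topology = topology, crossed = crossed, run = run,
                 row_y = row_y, mesh = smesh),
            class = "block_experiment")
}

#' @export
print.block_experiment <- function(x, ...) {
  cat(sprintf("block_experiment (%s): wave 1 %s, wave 2 %s\n", x$topology,
              if (x$crossed[1]) "crossed" else "blocked",
              if (x$crossed[2]) "crossed" else "blocked"))
  invisible(x)
}
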