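# package-session cache (relaxed resting states, tuned conductivities)
.fibro_cache <- new.env(parent = emptyenv())

#' Ionic model specification
#'
#' Two membrane models are available: `"tt06"`, the ten Tusscher 2006 human
#' ventricular action potential model (epicardial parameter set, 19 state
#' variables, 20 us integration step, Rush-Larsen for the gating variables
#' and forward Euler otherwise), and `"ms"`, a two-variable
#' threshold-and-recovery (Mitchell-Schaeffer type) reduced model mapped to
#' millivolts, used for fast protocol-level property checks.
#'
#' @param name `"tt06"` or `"ms"`
#' @return object of class `ionic_model_spec`: list with `name`,
#'   `state_dim`, `dt_ode` (ms), `state_names`
#' @export
ionic_model <- function(name = c("tt06", "ms")) {
  name <- match.arg(name)
  s0 <- .ionic_published_state(name)
  structure(list(name = name, state_dim = length(s0),
                 dt_ode = if (name == "tt06") 0.02 else 0.1,
                 state_names = names(s0)),
            class = "ionic_model_spec")
}

#' @export
print.ionic_model_spec <- function(x, ...) {
  cat(sprintf("ionic_model_spec: %s (%d state variables, dt_ode = %g ms)\n",
              x$name, x$state_dim, x$dt_ode))
  invisible(x)
}

#' Resting state of an ionic model
#'
#' For `tt06`, the published initial conditions are relaxed by 10 s of
#' stimulus-free integration (once per session; the result is cached). The
#' reduced model has an exact analytic rest point and is returned directly.
#'
#' @param model an `ionic_model_spec`
#' @return named numeric state vector
#' @export
resting_state <- function(model) {
  key <- paste0("rest_", model$name)
  if (!is.null(.fibro_cache[[key]])) return(.fibro_cache[[key]])
  s0 <- .ionic_published_state(model$name)
  if (model$name == "tt06") {
    out <- .cell_run(model$name, s0, numeric(0), 0, 0, 10000, model$dt_ode,
                     1000)
    s0 <- out$state
  }
  .fibro_cache[[key]] <- s0
  s0
}

#' Advance a single-cell state by one step
#'
#' One forward step of the ionic model. `i_stim` is the external stimulus
#' current density in uA/cm^2 (positive depolarizing, membrane capacitance
#' 1 uF/cm^2).
#'
#' @param state named numeric state vector
#' @param i_stim stimulus current density (uA/cm^2)
#' @param dt step in ms, must not exceed the model's `dt_ode`
#' @param model an `ionic_model_spec`
#' @return updated state vector
#' @export
cell_step <- function(state, i_stim = 0, dt = NULL,
                      model = ionic_model("tt06")) {
  if (is.null(dt)) dt <- model$dt_ode
  if (dt > model$dt_ode + 1e-12)
    stop("dt (", dt, " ms) exceeds the model's dt_ode (", model$dt_ode,
         " ms)")
  if (length(state) != model$state_dim) stop("state has wrong dimension")
  s <- matrix(as.numeric(state), nrow = 1)
  .ionic_step_inplace(s, model$name, as.numeric(i_stim), dt, 1L)
  stats::setNames(as.numeric(s), model$state_names)
}

#' Run a single cell with a stimulus train
#'
#' Integrates one cell from its resting state (or `state0`) with identical
#' rectangular stimuli at the given onset times, entirely in compiled code.
#'
#' @param model an `ionic_model_spec`
#' @param stim_onsets stimulus onset times (ms)
#' @param duration total duration (ms)
#' @param stim_dur stimulus duration (ms)
#' @param stim_amp stimulus amplitude (uA/cm^2, positive depolarizing)
#' @param state0 optional starting state (defaults to [resting_state()])
#' @param sample_dt output sampling interval (ms)
#' @return list with `trace` (data.frame `time`, `vm`) and `state` (final
#'   state vector)
#' @export
run_cell <- function(model, stim_onsets, duration, stim_dur = 2,
                     stim_amp = 500, state0 = NULL, sample_dt = 0.5) {
  if (is.null(state0)) state0 <- resting_state(model)
  out <- .cell_run(model$name, state0, as.numeric(stim_onsets), stim_dur,
                   stim_amp, duration, model$dt_ode, sample_dt)
  list(trace = data.frame(time = out$time, vm = out$vm), state = out$state)
}

#' Action potential duration from a membrane potential trace
#'
#' APD at repolarization fraction `level` for the beat starting at `onset`:
#' the time from the upstroke (maximum dV/dt after onset) until vm first
#' returns below `rest + (1 - level) * amplitude`.
#'
#' @param time,vm sampled trace
#' @param onset beat onset (ms)
#' @param level repolarization fraction (0.9 for APD90)
#' @param window how far past `onset` to look (ms)
#' @return APD in ms, or `NA` if the beat did not repolarize in the window
#' @export
measure_apd <- function(time, vm, onset, level = 0.9, window = 600) {
  sel <- time >= onset & time <= onset + window
  t <- time[sel]; v <- vm[sel]
  if (length(t) < 3) return(NA_real_)
  dv <- diff(v) / diff(t)
  iup <- which.max(dv)
  rest <- v[1]
  peak <- max(v)
  if (peak - rest < 20) return(NA_real_)   # no action potential
  thr <- rest + (1 - level) * (peak - rest)
  after <- which(v < thr & seq_along(v) > which.max(v))
  if (!length(after)) return(NA_real_)
  t[after[1]] - t[iup]
}
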