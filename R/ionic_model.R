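# internal: map cell type name to the C++ code
cell_type_code <- function(cell_type) {
  ct <- match.arg(cell_type, c("epi", "endo", "M"))
  c(epi = 0L, endo = 1L, M = 2L)[[ct]]
}

#' Resting state of the human ventricular myocyte model
#'
#' Returns the published resting state of the 2006 human ventricular myocyte
#' formulation (epicardial parameter set by default): membrane voltage plus
#' 12 gating variables, the ryanodine-receptor adaptation variable and five
#' ion concentrations.
#'
#' @param cell_type `"epi"`, `"endo"` or `"M"`. The endo/M parameter
#'   variants share the epicardial resting values (they relax to their own
#'   steady state within a short quiescent integration).
#' @return Named numeric vector of length 19 (`Vm` in mV first).
#' @export
initial_state <- function(cell_type = "epi") {
  cell_type_code(cell_type)  # validates
  tt06_initial_state_cpp()
}

#' Membrane currents at a given state
#'
#' Evaluates the twelve membrane currents (pA/pF) and their total, the
#' reaction term of the bidomain membrane equation.
#'
#' @param state named state vector as from [initial_state()].
#' @param cell_type `"epi"`, `"endo"` or `"M"`.
#' @return Named vector of the 12 current components plus `I_ion_total`.
#' @export
compute_currents <- function(state, cell_type = "epi") {
  tt06_currents_cpp(as.numeric(state), cell_type_code(cell_type))
}

#' Advance gating variables and concentrations
#'
#' Advances the state by forward Euler (default) or the exponential
#' (Rush-Larsen) gate update. The membrane voltage is held fixed: in tissue
#' it is advanced by the bidomain solver, and in a single cell by
#' [simulate_cell()].
#'
#' @param state state vector.
#' @param dt time step in ms.
#' @param n_steps number of steps to take.
#' @param cell_type `"epi"`, `"endo"` or `"M"`.
#' @param exp_gates use the exponential gate update (unconditionally stable
#'   for the gates) instead of forward Euler.
#' @return Updated state vector.
#' @export
advance_state <- function(state, dt, n_steps = 1L, cell_type = "epi",
                          exp_gates = FALSE) {
  stopifnot(dt > 0)
  tt06_advance_cpp(as.numeric(state), dt, as.integer(n_steps),
                   cell_type_code(cell_type), exp_gates,
                   update_V = FALSE, stim_papF = 0)
}

#' Single-cell action potential simulation
#'
#' Integrates the full myocyte model (voltage included) with an optional
#' square stimulus current, recording the voltage trace and the maximal
#' upstroke velocity.
#'
#' @param duration_ms total simulated time (ms).
#' @param dt time step (ms).
#' @param state initial state; defaults to [initial_state()].
#' @param stim_start_ms,stim_dur_ms,stim_papF square stimulus window and
#'   amplitude (pA/pF; positive value depolarizes).
#' @param record_every record the voltage every this many steps.
#' @param cell_type,exp_gates see [advance_state()].
#' @return List with `times_ms`, `Vm_mV`, `max_upstroke_V_per_s`,
#'   `t_max_upstroke_ms` and the final `state`.
#' @export
simulate_cell <- function(duration_ms, dt = 0.001, state = initial_state(),
                          stim_start_ms = -1, stim_dur_ms = 1,
                          stim_papF = 52, record_every = 10L,
                          cell_type = "epi", exp_gates = FALSE) {
  stopifnot(dt > 0, duration_ms > 0)
  tt06_cell_trace_cpp(as.numeric(state), duration_ms, dt,
                      as.integer(record_every), cell_type_code(cell_type),
                      exp_gates, stim_start_ms, stim_dur_ms, -abs(stim_papF))
}
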