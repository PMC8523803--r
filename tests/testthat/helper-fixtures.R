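# Shared fixtures. Tests run the generator and solver at reduced scale
# (coarser pixels, coarser time step with the exponential gate update) so the
# whole suite stays fast; the acceptance tests run the full protocol.

# small synthetic image: 500 um edge at 2 um pixels -> 250 px, 10x10 tiles
small_spec <- function(group = "donor", seed = 1L, ...) {
  tissue_spec(group = group, image_edge_um = 500, pixel_size_nm = 2000,
              rng_seed = seed, ...)
}

# coarse-step simulation config for solver tests (documented fast option:
# exponential gate update keeps the stiff gates stable at dt = 2e-6 s)
coarse_config <- function(...) {
  args <- list(dt = 2e-6, exp_gates = TRUE, record_every_ms = 0.002)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulation_config, args)
}

donor_mean_mesh <- function(preset = "sim", ny = 20, nx = 20) {
  homogeneous_mesh(V_e = 0.201, V_f = 0.01, V_mf = 0.01, ny = ny, nx = nx,
                   params = conductivity_params(preset))
}

# memoized coarse donor recordings shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_recording <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}
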