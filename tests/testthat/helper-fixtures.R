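# Shared fixtures: a small-grid phantom keeps the bilateral section layout
# but shrinks the disks so left/right ROIs stay disjoint on a 24-voxel-wide
# grid; tiny cohorts are generated in code at test time.

small_phantom <- function(grid_dims = c(24L, 24L, 9L)) {
  default_phantom_spec(grid_dims = grid_dims,
                       section_radii = c(2, 2, 0.45))
}

small_cohort_spec <- function(noise_sigma = 0, n_dark = 2L, n_light = 2L,
                              master_seed = 11L, ...) {
  cohort_spec(n_dark = n_dark, n_light = n_light,
              acquisition = acquisition_spec(noise_sigma = noise_sigma),
              phantom = small_phantom(), master_seed = master_seed, ...)
}

# long-format cohort table with given per-cell generator, for stats tests
toy_table <- function(n_dark, n_light, value_fn) {
  regions <- c("wulst", "thalamus_gld", "optic_tectum")
  conds <- c(rep("dark", n_dark), rep("light", n_light))
  ids <- sprintf("s%02d", seq_along(conds))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(subject_id = ids[i], condition = conds[i], region = regions,
               lateralization_index = vapply(regions, value_fn,
                                             numeric(1), conds[i]),
               stringsAsFactors = FALSE)
  }))
}

sr2_signal <- function(t1_ms, s0 = 100, tr = vtr_tr_schedule()) {
  s0 * (1 - exp(-tr / t1_ms))
}
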