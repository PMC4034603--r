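# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the study-condition phantom subject (noiseless, motion-free)
default_subject <- function() {
  fixture("default_subject", function() simulate_subject(phantom_spec()))
}

default_fractions <- function() {
  fixture("default_fractions", function() tissue_fractions(phantom_spec()))
}

# spatially uniform truth maps on a tiny grid (algebraic fixtures)
uniform_truth <- function(A = 1000, T1 = 1800, delta = 0.0140, R2star = 22.6,
                          d = c(6, 6, 4)) {
  aff <- centred_affine(d, c(1, 1, 3))
  list(A = vol3d(array(A, d), aff), T1 = vol3d(array(T1, d), aff),
       delta = vol3d(array(delta, d), aff),
       R2star = vol3d(array(R2star, d), aff))
}

uniform_dataset <- function(truth = uniform_truth(), mode = "approx",
                            b1 = NULL) {
  acq <- default_acquisition()
  list(pd = simulate_echoes(truth, acq$pd, b1, mode),
       t1 = simulate_echoes(truth, acq$t1, b1, mode),
       mt = simulate_echoes(truth, acq$mt, b1, mode))
}

const_vol <- function(value, d = c(4, 4, 2)) {
  vol3d(array(value, d), centred_affine(d, c(1, 1, 1)))
}

# whole-cord (WM + GM) weighted mean of one parameter from a summary table
cord_mean <- function(summary_tab, parameter) {
  g <- summary_tab[summary_tab$parameter == parameter &
                   summary_tab$region %in% c("GM", "dorsal_WM",
                                             "left_lateral_WM",
                                             "right_lateral_WM"), ]
  sum(g$mean * g$n_voxels) / sum(g$n_voxels)
}
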