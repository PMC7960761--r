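# Shared fixtures: noiseless extraction config and a curve builder for
# hand-drawn shapes used by the extraction tests.

# noiseless synthetic traces are extracted without smoothing
cfg_nosmooth <- extract_config(smooth_window = 1)

# build a preprocessed curve from explicit (osmolality, EI) points,
# without smoothing, for direct calls to the locator functions
prep_curve <- function(o, e) preprocess(osmoscan_curve(o, e), smooth_window = 1)

expect_indices_close <- function(ix, truth, tol_o = 1, tol_ei = 0.002,
                                 tol_area = 0.01) {
  expect_lt(abs(ix$o_min - truth$o_min), tol_o)
  expect_lt(abs(ix$o_eimax - truth$o_eimax), tol_o)
  expect_lt(abs(ix$o_hyper - truth$o_hyper), tol_o)
  expect_lt(abs(ix$ei_min - truth$ei_min), tol_ei)
  expect_lt(abs(ix$ei_max - truth$ei_max), tol_ei)
  expect_lt(abs(ix$area / truth$area - 1), tol_area)
}
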