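# Small shared fixtures, built once per test run.

# short myelinated fiber used by solver/analysis tests
fix_myel <- function(d = 10, n_nodes = 11L) myelinated_fiber(d, n_nodes = n_nodes)

# short unmyelinated fiber
fix_unmyel <- function(d = 1, len = 2000) unmyelinated_fiber(d, len)

# suprathreshold proximal test clamp
fix_test_clamp <- function(t0 = 0.1, amp = 0.005, dur = 0.1)
  clamp_current(1L, make_pulse(t0, amp, dur))

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
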