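# Shared fixtures, built in code.

# Single-shell step kernel: DER = value for r <= radius_nm, 1 beyond.
step_kernel <- function(value = 2, radius_nm = 1000) {
  der_profile(radii = radius_nm / 2, der = value, support_max = radius_nm,
              edges = c(0, radius_nm))
}

# Kernel that is exactly 1 everywhere (no enhancement).
unit_kernel <- function(grid = shell_grid(10, 10, 0, 50)) {
  der_profile(radii = shell_midpoints_test(grid), der = rep(1, length(grid$outer)),
              support_max = max(grid$outer), edges = c(grid$inner[1], grid$outer))
}

shell_midpoints_test <- function(grid) (grid$inner + grid$outer) / 2

# Prefix-subset of a placement (positions are i.i.d., so the first k rows
# are themselves a valid placement with the same distribution).
placement_prefix <- function(placement, k) {
  out <- placement
  out$positions <- placement$positions[seq_len(k), , drop = FALSE]
  out
}

# SER of a model curve against the analytic radiation-only response.
pipeline_ser <- function(curve, lq) {
  mid(lq) / mid(fit_lq(curve))
}

# Analytic LQ survival curve as a survival_curve object.
analytic_curve <- function(lq, doses = c(2, 4, 6, 8)) {
  survival_curve(doses, exp(local_log_survival(doses, lq)), source = "model")
}
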