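# Shared fixtures: reduced-concentration aerosols keep Poisson draws cheap
# while still giving >= 1e5 expected counts per measurement where needed.

# ~1.4e6 expected counts per minute on the canonical grid
fast_aerosol <- function(number_conc_per_cm3 = 3.3e4, ...) {
  aerosol_params(number_conc_per_cm3 = number_conc_per_cm3, ...)
}

# a deterministic (sigma 0, no defects) flat-penetration mask
flat_mask <- function(q) {
  mask_model(p_mpps = q, curvature_k = 0, mask_sigma = 0,
             defect_fraction = 0, defect_p = max(q, 1))
}

# coarse grid for brute-force oracles
coarse_grid <- function() size_grid(90, 7500, 12)

# expected per-class counts per minute for an aerosol on a grid (closed form)
expected_rates <- function(aerosol, grid, sample_flow_lpm = 0.1, dilution = 1) {
  class_probabilities(aerosol, grid) * aerosol$number_conc_per_cm3 *
    sample_flow_lpm * 1000 / dilution
}

# mass-weighted planted passage implied by a penetration vector (lower-edge
# volume convention, matching the detected-mass definition)
planted_total_passage <- function(pen, rates, grid) {
  w <- rates * grid$d_min_nm^3
  sum(w * pen) / sum(w)
}
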