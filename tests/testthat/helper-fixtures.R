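# Shared fixtures: a standard synthetic eye and brute-force oracles.

make_test_eye <- function(seed = 11L, n_large_vessels = 3L,
                          deficit = 0.166, axial = 23.3) {
  generate_eye(
    vf_scp = vessel_field_params(0.431, n_large_vessels = n_large_vessels,
                                 seed = seed, target_density_wo_lv = 0.298),
    vf_dcp = vessel_field_params(0.392, seed = seed + 1L),
    faz_s = faz_params(0.25, seed = seed + 2L, target_circularity = 1.16),
    faz_d = faz_params(1.23, seed = seed + 3L, target_circularity = 1.27),
    cc = cc_params(deficit_fraction = deficit, seed = seed + 4L),
    biometry = eye_biometry(axial)
  )
}

# brute-force nested-loop density oracle (percent)
brute_density <- function(num, region) {
  hit <- 0L; tot <- 0L
  for (i in seq_len(nrow(region))) {
    for (j in seq_len(ncol(region))) {
      if (region[i, j]) {
        tot <- tot + 1L
        if (num[i, j]) hit <- hit + 1L
      }
    }
  }
  100 * hit / tot
}

# brute-force shoelace oracle over explicit vertex loop
brute_shoelace <- function(poly) {
  n <- nrow(poly); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
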