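# shared fixtures built in code

# reared-cod group summaries with derived per-group endmember objects
cod_groups <- reared_cod_groups()

group_endmembers <- function(i, groups = cod_groups) {
  endmembers(d13C_DIC = c(groups$d13C_DIC_1[i], groups$d13C_DIC_2[i]),
             d13C_diet = groups$d13C_diet[i],
             d13C_DIC_sd = 0.03, d13C_diet_sd = 0.86)
}

# noise-free saturating-curve points for calibration tests
sat_points <- function(C = 0.243, k = 0.0088, n = 12) {
  o2 <- seq(20, 250, length.out = n)
  list(o2 = o2, moto = C * (1 - exp(-k * o2)))
}
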