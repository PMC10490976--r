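# shared fixtures, all built in code at test time

# a synthetic_config with every stochastic nuisance switched off: no device
# bias or noise, no surgical change, no teacher -- decomposition must then
# invert the generator exactly
zero_noise_config <- function(n_eyes = 10, seed = 99) {
  z3 <- c(0, 0, 0)
  synthetic_config(
    n_eyes = n_eyes, seed = seed, teacher = NULL,
    sia_bias = list(front = z3, back = z3),
    sia_sd = list(front = z3, back = z3),
    bias = list(IOLM = list(front = z3, back = z3),
                CASIA = list(front = z3, back = z3)),
    noise = list(IOLM = list(front = z3, back = z3),
                 CASIA = list(front = z3, back = z3)),
    total_offset = list(IOLM = z3, CASIA = z3))
}

make_panel <- function(n_eyes = 40, seed = 7, ...) {
  co <- generate_cohort(synthetic_config(n_eyes = n_eyes, seed = seed, ...))
  decompose_cohort(co$records)
}

write_cohort_fixture <- function(records) {
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(records, path)
  path
}
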