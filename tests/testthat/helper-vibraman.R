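# shared builders for toy inputs

toy_modes <- function(wn = c(500, 1000, 1500), act = c(1, 2, 3),
                      frag = "ligand") {
  mode_table(seq_along(wn), wn, act, frag)
}

write_spectrum_file <- function(wn, it, path = tempfile(fileext = ".txt"),
                                sep = "\t") {
  writeLines(paste(wn, it, sep = sep), path)
  path
}

# independent scalar oracle for the activity-to-intensity conversion:
# plain elementwise arithmetic, no shared code with the implementation
oracle_intensity <- function(nu0, nu, A, temp, f, c2) {
  n <- length(nu)
  nu0 <- rep_len(nu0, n); A <- rep_len(A, n); temp <- rep_len(temp, n)
  f <- rep_len(f, n); c2 <- rep_len(c2, n)
  vapply(seq_len(n), function(i) {
    numerator <- f[i] * (nu0[i] - nu[i])^4 * A[i]
    boltzmann <- 1 - exp(-(c2[i] * nu[i]) / temp[i])
    numerator / (nu[i] * boltzmann)
  }, numeric(1))
}

# one shift-recovery experiment: well-separated synthetic peaks, full
# generate -> bin -> normalize -> detect -> match chain, median shift over
# the recovered matches
recover_shift <- function(delta, seed, noise_sd = 0.02) {
  sp <- synthetic_spec(n_modes = 12L, wavenumber_range = c(450, 1750),
                       activity_law = c(0.5, 1.5), joint_fraction = 0,
                       noise_sd = noise_sd, injected_shift = delta,
                       seed = seed)
  tab <- generate_mode_table(sp)
  raw <- generate_sers_spectrum(tab, sp)
  binned <- normalize_to_100(bin_spectrum(raw))
  bands <- detect_bands(binned, prominence_fraction = 0.05)
  m <- match_modes_to_bands(tab, bands, tolerance = 10)
  stats::median(m$shift)
}
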