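# Shared fixtures, all generated in code.

# compact balanced spectrum set for fast model tests
small_spectrum_set <- function(seed = 1, n = c(tuberous = 24, taproot = 12,
                                               old = 12)) {
  simulate_spectrum_set(sim_config(samples_per_class = n, seed = seed))
}

# noise-free, scatter-free configuration (deterministic reflectance model)
clean_config <- function(seed = 1, ...) {
  sim_config(scatter_sdlog = 0, scatter_add_sd = 0, noise_sd = 0,
             seed = seed, ...)
}

# class profiles with all analyte concentrations forced to zero
zero_conc_profiles <- function(wavelength = default_wavelength()) {
  cp <- class_profiles(wavelength)
  for (nm in names(cp)) {
    cp[[nm]]$conc_meanlog <- rep(-Inf, 3)
    cp[[nm]]$conc_sdlog <- rep(0, 3)
  }
  cp
}

# class profiles with fixed (degenerate) concentrations
fixed_conc_profiles <- function(conc, wavelength = default_wavelength()) {
  cp <- class_profiles(wavelength)
  for (nm in names(cp)) {
    cp[[nm]]$conc_meanlog <- log(conc)
    cp[[nm]]$conc_sdlog <- rep(0, 3)
  }
  cp
}
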