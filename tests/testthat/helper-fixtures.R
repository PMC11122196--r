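# Shared fixtures: a canonical synthetic patient at therapy scale, random
# patient draws for property tests, and small utilities.

ref_coeffs <- function() dose_coefficients(108, 0.0188)

std_blood <- function() biexp_clearance(c(1.5e-5, 0.7e-5), c(0.10, 0.012))
std_wholebody <- function() biexp_clearance(c(0.75, 0.25), c(0.07, 0.006))

std_patient <- function(A0 = 3.5, wt = 75) {
  patient_dosimetry(A0, wt, std_blood(), std_wholebody(), ref_coeffs())
}

# random dosimetry within the generator's plausibility ranges (caller seeds)
random_patient <- function() {
  bl <- biexp_clearance(c(runif(1, 1e-5, 2e-5), runif(1, 4e-6, 1e-5)),
                        c(runif(1, 0.06, 0.14), runif(1, 0.008, 0.016)))
  u <- runif(1, 0.65, 0.85)
  wb <- biexp_clearance(c(u, 1 - u),
                        c(runif(1, 0.05, 0.09), runif(1, 0.004, 0.009)))
  patient_dosimetry(runif(1, 3.43, 3.91), runif(1, 46, 115), bl, wb,
                    ref_coeffs())
}

nominal_times <- c(1, 2, 3, 4, 24, 48, 96, 168)

# noise-free RIF series from a kinetic truth (constant nominal sigma)
exact_rif <- function(truth, pd, times = nominal_times, sigma = 0.08,
                      sigma0 = 0.04) {
  out <- data.frame(t = times, N = model_rif(times, truth, pd), sigma = sigma)
  attr(out, "sigma0") <- sigma0
  out
}

# Poisson-count RIF series from a kinetic truth (caller seeds)
noisy_rif <- function(truth, pd, base_rate = 0.15, cells = 100,
                      times = nominal_times) {
  mu <- pmax(base_rate + model_rif(times, truth, pd), 0)
  foci <- rpois(length(times), cells * mu)
  b <- rpois(1, cells * base_rate)
  rif_from_counts(times, foci, rep(cells, length(times)), b, cells)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}
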