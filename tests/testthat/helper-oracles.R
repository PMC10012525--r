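# Shared fixtures and independent oracles, kept deliberately naive so they
# validate the package implementations from first principles.

# Long-layout tibble from a families x replicates value matrix (one trait,
# one condition).
long_from_matrix <- function(m, trait = "t1", condition = "normal",
                             families = paste0("f", seq_len(nrow(m))),
                             replicates = paste0("r", seq_len(ncol(m)))) {
  grid <- expand.grid(replicate = replicates, family = families,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    family = grid$family, replicate = grid$replicate,
    condition = condition, trait = trait,
    value = as.vector(t(m))
  )
}

# Spec-style tiny RCBD fixture: families A (4,6), B (8,10), C (6,8) over
# replicates r1, r2.
tiny_rcbd <- function() {
  long_from_matrix(matrix(c(4, 6, 8, 10, 6, 8), 3, 2, byrow = TRUE),
                   families = c("A", "B", "C"), replicates = c("r1", "r2"))
}

# Brute-force RCBD sums of squares by explicit summation.
rcbd_ss_oracle <- function(m) {
  g <- nrow(m); r <- ncol(m)
  grand <- mean(m)
  ss_rep <- g * sum((colMeans(m) - grand)^2)
  ss_fam <- r * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  list(ss_rep = ss_rep, ss_fam = ss_fam, ss_err = ss_tot - ss_rep - ss_fam,
       df = c(r - 1, g - 1, (g - 1) * (r - 1)))
}

# Genetic covariance oracle via the sums-of-squares combination identity:
# CP(x, y) = (SS(x + y) - SS(x) - SS(y)) / 2 for each stratum.
cov_g_oracle <- function(mx, my) {
  r <- ncol(mx)
  sx <- rcbd_ss_oracle(mx); sy <- rcbd_ss_oracle(my)
  sxy <- rcbd_ss_oracle(mx + my)
  cp_fam <- (sxy$ss_fam - sx$ss_fam - sy$ss_fam) / 2
  cp_err <- (sxy$ss_err - sx$ss_err - sy$ss_err) / 2
  g <- nrow(mx)
  (cp_fam / (g - 1) - cp_err / ((g - 1) * (r - 1))) / r
}

# Random balanced two-condition dataset for property tests.
random_trial <- function(seed, g = 5, r = 3, traits = c("x", "y")) {
  spec <- sim_spec(
    traits = data.frame(trait = traits, mean = seq_along(traits) * 10,
                        sigma2_g = 2, sigma2_e = 1),
    n_families = g, n_reps = r,
    stress = data.frame(trait = traits, slope = 0.8, noise_var = 0.3)
  )
  simulate_trial(spec, seed = seed)
}
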