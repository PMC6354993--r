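# Shared fixtures: all test data is generated in code at run time.

# Small synthetic dataset for structural tests; 20x20 pixels keeps the
# full 405-image factorial cheap (< 1 s).
make_dataset <- function(seed = 42, h = 20, w = 20, ...) {
  generate_dataset(generator_config(image_height = h, image_width = w,
                                    seed = seed, ...))
}

# Noiseless, clutter-free configuration used for exact-recovery checks.
noiseless_config <- function(seed = 5, h = 32, w = 32, control = TRUE) {
  args <- list(image_height = h, image_width = w, seed = seed,
               noise_sd = 0, group_sd = 0)
  if (!control) args$planted_control <- matrix(0, 8, 3)
  do.call(generator_config, args)
}

# Trajectories of a planted linear map observed through a random lifting,
# for small-scale DMD oracles.
lifted_trajectories <- function(a_op, q_lift, z0_list, n_steps = 4) {
  xp <- NULL
  xpp <- NULL
  for (z0 in z0_list) {
    z <- z0
    for (k in seq_len(n_steps)) {
      z_next <- a_op %*% z
      xp <- cbind(xp, q_lift %*% z)
      xpp <- cbind(xpp, q_lift %*% z_next)
      z <- z_next
    }
  }
  list(x_prime = xp, x_dprime = xpp)
}

# Seeded label shuffle for permutation-null checks.
with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# Minimal hand-built mode_basis for spectrum tests.
fake_dmd_basis <- function(lambda, amplitudes) {
  structure(list(method = "DMD",
                 modes = matrix(0, 4, length(lambda)),
                 singular_values = rep(1, length(lambda)),
                 eigenvalues = lambda,
                 omega = suppressWarnings(continuous_frequencies(lambda)),
                 amplitudes = amplitudes,
                 mean = NULL, state_basis = NULL,
                 rank_used = length(lambda)),
            class = "mode_basis")
}
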