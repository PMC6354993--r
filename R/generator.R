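# Synthetic exhaled-aerosol image generator with planted linear latent
# dynamics. The generator emulates the structure of the breath-test image
# database: 5 disease classes x 3 inhalation flow rates x 9 particle sizes
# x 3 stochastic replicates = 405 images, a shared background deposition
# pattern, and factor effects whose periodicities (3, 5 and 9 in the
# standard column ordering) are recoverable as amplitude-spectrum peaks.

FLOW_RATES <- c(27, 30, 33)
PARTICLE_SIZES <- c(0.2, 0.4, 0.6, 0.8, 1, 2, 3, 5, 10)
REPLICATES <- 1:3
CLASS_LABELS <- c("A0", "A1", "A2", "A3", "A4")
N_STAGES <- 5L

#' Configuration for the synthetic aerosol-image generator
#'
#' The generator plants a discrete-time linear system in a low-dimensional
#' latent space: within each (flow, size, replicate) group the latent state
#' follows `z[k+1] = A z[k] + C y[k]`, where `A` (`planted_dynamics`) is a
#' stable transition operator and `C` (`planted_control`) maps the
#' standardized control vector (particle size, flow rate, severity of the
#' target stage) into latent state changes. Each image is
#' `mean_pattern + spatial_modes %*% z + group fingerprint + noise`,
#' clipped at zero.
#'
#' The default transition operator has three rotation blocks at angles
#' `2*pi/3`, `2*pi/5` and `2*pi/9` (driven by the flow-rate, severity and
#' particle-size inputs respectively), so the flow, disease-stage and size
#' effects recur with periods 3, 5 and 9 along the standard column
#' ordering, plus two real decaying modes; its spectral radius is below 1,
#' matching the expectation that the exhalation dynamics are stable.
#'
#' All planted perturbations (baseline latent excitation, initial-state
#' jitter, group fingerprints, control couplings) scale with
#' `effect_sizes`, so setting all three effects to zero with `noise_sd = 0`
#' yields a dataset in which every image equals the mean pattern.
#'
#' @param image_height,image_width image size in pixels (>= 8). Default
#'   128 x 128; every invariant of the downstream analysis is
#'   resolution-independent because it depends only on the column space.
#' @param latent_rank number of planted latent modes (>= 8; dimensions
#'   beyond 8 receive additional real decaying eigenvalues).
#' @param planted_dynamics optional `latent_rank x latent_rank` transition
#'   operator; spectral radius must not exceed 1.
#' @param planted_control optional `latent_rank x 3` control operator;
#'   columns act on the standardized (particle size, flow rate, severity)
#'   inputs. The default is built from `effect_sizes`.
#' @param effect_sizes named numeric of per-factor perturbation magnitudes
#'   `c(severity=, flow=, size=)`, in latent units (the spatial modes have
#'   unit norm, so these are also image-space L2 amplitudes).
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param group_sd amplitude of the static per-group "fingerprint" field
#'   (condition-specific deposition structure shared by the five stages of
#'   a group), in units of the largest factor effect size.
#' @param init_sd standard deviation of the per-group initial latent state
#'   jitter (relative units, scaled per dimension by the factor effect
#'   sizes); emulates stochastic inlet profiles.
#' @param seed RNG seed; required, so every dataset is reproducible.
#' @return A validated list of class `generator_config`.
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(image_height = 128, image_width = 128,
                             latent_rank = 8,
                             planted_dynamics = NULL,
                             planted_control = NULL,
                             effect_sizes = c(severity = 0.13, flow = 0.30,
                                              size = 0.30),
                             noise_sd = 0.015,
                             group_sd = 2.7,
                             init_sd = 0.5,
                             seed) {
  abort_if(missing(seed) || is.null(seed), "seed must be supplied")
  abort_if(!is_number(seed), "seed must be a single finite number")
  abort_if(!is_number(image_height) || !is_number(image_width) ||
             image_height < 8 || image_width < 8,
           "image dimensions must be >= 8 pixels")
  abort_if(!is_number(latent_rank) || latent_rank < 8,
           "latent_rank must be >= 8")
  latent_rank <- as.integer(latent_rank)
  abort_if(!is.numeric(effect_sizes) || length(effect_sizes) != 3L ||
             any(!is.finite(effect_sizes)) || any(effect_sizes < 0),
           "effect_sizes must be three finite nonnegative numbers")
  if (is.null(names(effect_sizes))) {
    names(effect_sizes) <- c("severity", "flow", "size")
  }
  abort_if(!setequal(names(effect_sizes), c("severity", "flow", "size")),
           "effect_sizes must be named severity, flow, size")
  effect_sizes <- effect_sizes[c("severity", "flow", "size")]
  abort_if(!is_number(noise_sd) || noise_sd < 0, "noise_sd must be >= 0")
  abort_if(!is_number(group_sd) || group_sd < 0, "group_sd must be >= 0")
  abort_if(!is_number(init_sd) || init_sd < 0, "init_sd must be >= 0")

  if (is.null(planted_dynamics)) {
    planted_dynamics <- default_planted_dynamics(latent_rank)
  }
  abort_if(!is.matrix(planted_dynamics) ||
             nrow(planted_dynamics) != latent_rank ||
             ncol(planted_dynamics) != latent_rank,
           "planted_dynamics must be a %d x %d matrix", latent_rank,
           latent_rank)
  rho <- max(Mod(eigen(planted_dynamics, only.values = TRUE)$values))
  abort_if(rho > 1 + 1e-8,
           "planted_dynamics spectral radius %.4f exceeds 1 (unstable)", rho)

  if (is.null(planted_control)) {
    planted_control <- default_planted_control(latent_rank, effect_sizes)
  }
  abort_if(!is.matrix(planted_control) ||
             nrow(planted_control) != latent_rank ||
             ncol(planted_control) != 3L,
           "planted_control must be a %d x 3 matrix", latent_rank)
  abort_if(any(!is.finite(planted_control)),
           "planted_control entries must be finite")

  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         latent_rank = latent_rank,
         planted_dynamics = planted_dynamics,
         planted_control = planted_control,
         effect_sizes = effect_sizes,
         noise_sd = noise_sd,
         group_sd = group_sd,
         init_sd = init_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @noRd
rotation_block <- function(rho, theta) {
  rho * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Default planted latent transition operator
#'
#' Block-diagonal: lightly damped rotation blocks (moduli 0.94-0.96) of
#' period 3 (flow factor, dims 1:2), period 5 (disease stage, dims 3:4)
#' and period 9 (particle size, dims 5:6) — eigenvalues close to the
#' unit circle, as expected for modes arising from the recursive use of
#' a fixed set of flow rates and particle sizes, and giving every
#' consecutive disease-stage pair nearly the same phase separation —
#' plus a fast-forgetting real mode (dim 7) that tracks the current
#' severity input quasi-statically and a mixing real mode (dim 8).
#' Dimensions beyond 8 decay with eigenvalues spaced in (0.2, 0.7).
#'
#' @param rank latent dimension (>= 8).
#' @return a `rank x rank` matrix with spectral radius below 1.
#' @export
default_planted_dynamics <- function(rank = 8) {
  rank <- as.integer(rank)
  abort_if(rank < 8, "default dynamics require rank >= 8")
  a <- matrix(0, rank, rank)
  a[1:2, 1:2] <- rotation_block(0.96, 2 * pi / 3)
  a[3:4, 3:4] <- rotation_block(0.94, 2 * pi / 5)
  a[5:6, 5:6] <- rotation_block(0.95, 2 * pi / 9)
  a[7, 7] <- 0.02
  a[8, 8] <- 0.55
  if (rank > 8) {
    extra <- seq(0.2, 0.7, length.out = rank - 8L)
    for (i in seq_along(extra)) a[8L + i, 8L + i] <- extra[i]
  }
  a
}

#' Default planted control operator
#'
#' Routes the standardized particle-size input into the period-9 block,
#' the flow-rate input into the period-3 block, and the severity input
#' into both the period-5 block and the quasi-static severity mode
#' (dimension 7), with mild mixing into dimension 8. Column magnitudes
#' are set by `effect_sizes`. The severity column carries the main
#' persistent forcing (it is the disease signal the decompositions must
#' attribute); the flow/size columns are kept weak because those factors
#' act chiefly through the initial state of each group's trajectory —
#' persistent forcing that rivals the free response would bend the
#' eigenvalues a control-blind fit recovers.
#'
#' @param rank latent dimension (>= 8).
#' @param effect_sizes named `c(severity=, flow=, size=)` magnitudes.
#' @return a `rank x 3` matrix; columns are (particle_size, flow_rate,
#'   severity).
#' @export
default_planted_control <- function(rank = 8,
                                    effect_sizes = c(severity = 0.13,
                                                     flow = 0.30,
                                                     size = 0.30)) {
  rank <- as.integer(rank)
  abort_if(rank < 8, "default control requires rank >= 8")
  e <- effect_sizes[c("severity", "flow", "size")]
  ctrl <- matrix(0, rank, 3,
                 dimnames = list(NULL,
                                 c("particle_size", "flow_rate", "severity")))
  ctrl[5, 1] <- 0.10 * e[["size"]]
  ctrl[6, 1] <- 0.05 * e[["size"]]
  ctrl[1, 2] <- 0.25 * e[["flow"]]
  ctrl[2, 2] <- 0.10 * e[["flow"]]
  ctrl[3, 3] <- 0.20 * e[["severity"]]
  ctrl[4, 3] <- 0.05 * e[["severity"]]
  # the dominant severity channel: a quasi-static mode tracking the
  # constriction level, so between-class contrasts inherit the severity
  # gaps (A2-A3 smallest); the stage-block phase adds an equal
  # separation to every consecutive pair and preserves that ordering
  ctrl[7, 3] <- 2.0 * e[["severity"]]
  ctrl[8, 1] <- 0.10 * e[["size"]]
  ctrl[8, 2] <- 0.10 * e[["flow"]]
  ctrl
}

#' Initial-state loading of the test-condition inputs: particle size
#' excites the period-9 block and flow rate the period-3 block at the
#' start of each trajectory (free response), which is where most of the
#' between-condition variance of the images comes from.
#' @noRd
initial_loading <- function(rank, effect_sizes) {
  e <- effect_sizes[c("severity", "flow", "size")]
  b0 <- matrix(0, rank, 3)
  b0[5, 1] <- 1.2 * e[["size"]]
  b0[6, 1] <- 0.4 * e[["size"]]
  b0[1, 2] <- 1.2 * e[["flow"]]
  b0[2, 2] <- 0.4 * e[["flow"]]
  b0[8, 1] <- 0.3 * e[["size"]]
  b0[8, 2] <- 0.3 * e[["flow"]]
  b0
}

#' Per-dimension excitation scale derived from the factor effect sizes
#' @noRd
dimension_effect_scale <- function(cfg) {
  e <- cfg$effect_sizes
  base <- c(e[["flow"]], e[["flow"]],
            e[["severity"]], e[["severity"]],
            e[["size"]], e[["size"]],
            e[["severity"]],
            (e[["flow"]] + e[["size"]]) / 2)
  if (cfg$latent_rank > 8L) {
    base <- c(base, rep(mean(e), cfg$latent_rank - 8L))
  }
  base
}

#' Baseline latent excitation (unit scale, multiplied by the per-dimension
#' effect scale); sets the zero-input oscillation amplitudes that make the
#' planted periodicities visible in the amplitude spectrum.
#' @noRd
base_excitation <- function(rank) {
  z <- c(1.6, 0, 2.8, 0, 1.6, 0, 1.0, 0.7)
  if (rank > 8L) z <- c(z, rep(0.3, rank - 8L))
  z
}

#' The full factorial design of test conditions
#'
#' One row per (flow rate, particle size, replicate) group, ordered by
#' flow rate, then particle size, then replicate ascending — the standard
#' group ordering used for snapshot assembly.
#'
#' @return data frame with columns `group`, `flow_rate`, `particle_size`,
#'   `replicate` (81 rows).
#' @export
test_conditions <- function() {
  grid <- expand.grid(replicate = REPLICATES,
                      particle_size = PARTICLE_SIZES,
                      flow_rate = FLOW_RATES,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$flow_rate, grid$particle_size, grid$replicate), ,
               drop = FALSE]
  rownames(grid) <- NULL
  cbind(group = seq_len(nrow(grid)),
        grid[, c("flow_rate", "particle_size", "replicate")])
}

#' Standardize matrix rows to mean 0, sd 1 (constant rows left at zero)
#' @noRd
standardize_rows <- function(m) {
  ctr <- rowMeans(m)
  centered <- m - ctr
  scl <- apply(m, 1, stats::sd)
  const <- !is.finite(scl) | scl < 1e-12
  if (any(const)) {
    message("constant control row(s) left at zero after centering: ",
            paste(rownames(m)[const], collapse = ", "))
    scl[const] <- 1
  }
  list(values = centered / scl, center = ctr, scale = scl,
       constant = const)
}

#' Raw (unstandardized) control design for the 324 transitions, in the
#' standard group ordering: for the transition into stage k of group g the
#' column is (particle_size(g), flow_rate(g), severity(stage k)).
#' @noRd
control_design_raw <- function(conditions = test_conditions()) {
  sev <- airway_disease_specs()$severity
  n_groups <- nrow(conditions)
  cols <- matrix(0, 3, 4L * n_groups,
                 dimnames = list(c("particle_size", "flow_rate", "severity"),
                                 NULL))
  for (g in seq_len(n_groups)) {
    idx <- (g - 1L) * 4L + 1:4
    cols[1, idx] <- conditions$particle_size[g]
    cols[2, idx] <- conditions$flow_rate[g]
    cols[3, idx] <- sev[2:5]
  }
  cols
}

#' Gaussian blur of a matrix (separable, circular boundary)
#' @noRd
blur_gaussian <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm <- apply(m, 2, function(col) {
    as.numeric(stats::filter(col, k, circular = TRUE))
  })
  t(apply(sm, 1, function(row) {
    as.numeric(stats::filter(row, k, circular = TRUE))
  }))
}

#' Smooth random field, flattened row-major, as a unit-norm vector
#' @noRd
smooth_field <- function(h, w, sigma) {
  f <- blur_gaussian(matrix(stats::rnorm(h * w), h, w), sigma)
  v <- as.vector(t(f))
  v / sqrt(sum(v^2))
}

#' Shared background deposition pattern
#'
#' A deterministic mean image emulating the coherent structures of an
#' averaged exhaled-aerosol fingerprint: a uniform deposition floor, five
#' localized Gaussian blobs (vortex-like spots) and two curved streaks
#' (sprout- and hairpin-like filaments). Positions and widths are fixed
#' fractions of the image size, so the same structures appear at any
#' resolution.
#'
#' @param h,w image height and width in pixels.
#' @return numeric vector of length `h * w` (row-major flattening).
#' @export
mean_pattern <- function(h, w) {
  # pixel-center coordinates in [0, 1] x [0, 1]; row-major flattening
  ys <- (rep(seq_len(h), each = w) - 0.5) / h
  xs <- (rep(seq_len(w), times = h) - 0.5) / w
  img <- rep(0.22, h * w)
  blobs <- list(list(cx = 0.30, cy = 0.30, s = 0.08, a = 0.35),
                list(cx = 0.72, cy = 0.25, s = 0.06, a = 0.30),
                list(cx = 0.25, cy = 0.70, s = 0.07, a = 0.28),
                list(cx = 0.55, cy = 0.55, s = 0.05, a = 0.32),
                list(cx = 0.80, cy = 0.75, s = 0.09, a = 0.25))
  for (b in blobs) {
    img <- img + b$a * exp(-((xs - b$cx)^2 + (ys - b$cy)^2) / (2 * b$s^2))
  }
  # two curved streaks: Gaussian ridges along quadratic arcs
  streaks <- list(
    list(x0 = 0.10, x1 = 0.90, base = 0.15, bow = 0.25, wd = 0.02,
         a = 0.20),
    list(x0 = 0.20, x1 = 0.85, base = 0.85, bow = -0.20, wd = 0.025,
         a = 0.18)
  )
  for (s in streaks) {
    ts <- seq(0, 1, length.out = 160)
    px <- s$x0 + (s$x1 - s$x0) * ts
    py <- s$base + s$bow * 4 * ts * (1 - ts)
    d2 <- rep(Inf, h * w)
    for (i in seq_along(ts)) {
      d2 <- pmin(d2, (xs - px[i])^2 + (ys - py[i])^2)
    }
    img <- img + s$a * exp(-d2 / (2 * s$wd^2))
  }
  img
}

#' Generate a synthetic exhaled-aerosol image dataset
#'
#' Emits one image per (class, flow rate, particle size, replicate)
#' combination — `5 * 3 * 9 * 3 = 405` images — together with a manifest
#' and the full ground truth of the planted latent system. Within each
#' (flow, size, replicate) group the five stage images A0-A4 are generated
#' from a latent trajectory that satisfies the planted linear recursion
#' exactly; pixel images add the shared mean pattern, a static per-group
#' fingerprint field and i.i.d. Gaussian noise, clipped at zero.
#'
#' @param config a [generator_config()].
#' @return An object of class `aerosol_dataset`: a list with `images`
#'   (`height x width x 405` array, stage-within-group order), `manifest`
#'   (data frame: filename, class_label, flow_rate_L_min, particle_size_um,
#'   replicate, seed) and `ground_truth` (class `aerosol_ground_truth`:
#'   planted eigenvalues and operators, per-group latent trajectories, the
#'   noiseless mean pattern, spatial modes, group fingerprint fields and
#'   the standardized control design).
#' @examples
#' d <- generate_dataset(generator_config(image_height = 16,
#'                                        image_width = 16, seed = 1))
#' nrow(d$manifest) # 405
#' @export
generate_dataset <- function(config) {
  abort_if(!inherits(config, "generator_config"),
           "config must be a generator_config")
  h <- config$image_height
  w <- config$image_width
  npix <- h * w
  rank <- config$latent_rank
  a_op <- config$planted_dynamics
  c_op <- config$planted_control
  conditions <- test_conditions()
  n_groups <- nrow(conditions)
  n_img <- n_groups * N_STAGES

  ctrl_raw <- control_design_raw(conditions)
  std <- standardize_rows(ctrl_raw)
  y_std <- std$values # 3 x 324, group-major, 4 transitions per group

  # standardized per-group condition values (same standardization)
  size_z <- (conditions$particle_size - std$center[1]) / std$scale[1]
  flow_z <- (conditions$flow_rate - std$center[2]) / std$scale[2]

  d_scale <- dimension_effect_scale(config)
  z_base <- base_excitation(rank)
  clutter_amp <- config$group_sd * max(config$effect_sizes)
  blur_sigma <- max(1, min(h, w) / 16)

  mean_img <- mean_pattern(h, w)

  out <- with_seed(config$seed, {
    spatial <- matrix(0, npix, rank)
    for (j in seq_len(rank)) spatial[, j] <- smooth_field(h, w, blur_sigma)
    spatial <- qr.Q(qr(spatial)) # orthonormal columns
    group_fields <- matrix(0, npix, n_groups)
    for (g in seq_len(n_groups)) {
      group_fields[, g] <- smooth_field(h, w, blur_sigma)
    }
    jitter <- matrix(stats::rnorm(rank * n_groups, sd = config$init_sd),
                     rank, n_groups)

    traj <- array(0, dim = c(rank, N_STAGES, n_groups))
    values <- matrix(0, npix, n_img)
    b0 <- initial_loading(rank, config$effect_sizes)
    for (g in seq_len(n_groups)) {
      u0 <- c(size_z[g], flow_z[g], 0)
      z <- d_scale * (z_base + jitter[, g]) + b0 %*% u0
      traj[, 1, g] <- z
      for (k in 1:4) {
        y_k <- y_std[, (g - 1L) * 4L + k]
        z <- a_op %*% z + c_op %*% y_k
        traj[, k + 1L, g] <- z
      }
      for (s in seq_len(N_STAGES)) {
        col <- (g - 1L) * N_STAGES + s
        img <- mean_img + spatial %*% traj[, s, g] +
          clutter_amp * group_fields[, g]
        if (config$noise_sd > 0) {
          img <- img + stats::rnorm(npix, sd = config$noise_sd)
        }
        values[, col] <- pmax(img, 0)
      }
    }
    list(spatial = spatial, group_fields = group_fields, traj = traj,
         values = values)
  })

  manifest <- data.frame(
    filename = character(n_img), class_label = character(n_img),
    flow_rate_L_min = numeric(n_img), particle_size_um = numeric(n_img),
    replicate = integer(n_img), seed = rep(config$seed, n_img),
    stringsAsFactors = FALSE
  )
  images <- array(0, dim = c(h, w, n_img))
  for (g in seq_len(n_groups)) {
    for (s in seq_len(N_STAGES)) {
      col <- (g - 1L) * N_STAGES + s
      images[, , col] <- matrix(out$values[, col], h, w, byrow = TRUE)
      manifest$class_label[col] <- CLASS_LABELS[s]
      manifest$flow_rate_L_min[col] <- conditions$flow_rate[g]
      manifest$particle_size_um[col] <- conditions$particle_size[g]
      manifest$replicate[col] <- conditions$replicate[g]
      manifest$filename[col] <- sprintf(
        "aerosol_%s_f%02d_d%04.1fum_r%d.png", CLASS_LABELS[s],
        conditions$flow_rate[g], conditions$particle_size[g],
        conditions$replicate[g])
    }
  }

  ground_truth <- structure(
    list(eigenvalues = eigen(a_op, only.values = TRUE)$values,
         planted_dynamics = a_op,
         planted_control = c_op,
         trajectories = out$traj,
         mean_pattern = mean_img,
         spatial_modes = out$spatial,
         group_fields = out$group_fields,
         group_amplitude = clutter_amp,
         control_matrix = y_std,
         control_center = std$center,
         control_scale = std$scale,
         conditions = conditions,
         config = config),
    class = "aerosol_ground_truth"
  )

  structure(
    list(images = images, manifest = manifest,
         ground_truth = ground_truth,
         height = h, width = w),
    class = "aerosol_dataset"
  )
}

#' @export
print.aerosol_dataset <- function(x, ...) {
  cat(sprintf("aerosol_dataset: %d images (%d x %d), %d classes\n",
              dim(x$images)[3], x$height, x$width,
              length(unique(x$manifest$class_label))))
  cat(sprintf("  flow rates: %s L/min; particle sizes: %s um\n",
              paste(unique(x$manifest$flow_rate_L_min), collapse = "/"),
              paste(unique(x$manifest$particle_size_um), collapse = ", ")))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d planted latent modes\n",
                length(x$ground_truth$eigenvalues)))
  }
  invisible(x)
}
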