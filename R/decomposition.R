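# SVD-based eigenmode extractors: proper orthogonal decomposition (POD),
# principal component analysis (PCA), exact dynamic mode decomposition
# (DMD) and DMD with control (DMDC), plus the eigenvalue transform,
# amplitude spectra, cumulative energy and mode projections.

INV_TOL <- 1e-10 # relative singular-value cutoff for every inversion

#' @noRd
new_mode_basis <- function(method, modes, singular_values, rank_used,
                           eigenvalues = NULL, omega = NULL,
                           amplitudes = NULL, mean = NULL,
                           state_basis = NULL) {
  structure(list(method = method, modes = modes,
                 singular_values = singular_values,
                 eigenvalues = eigenvalues, omega = omega,
                 amplitudes = amplitudes, mean = mean,
                 state_basis = state_basis,
                 rank_used = as.integer(rank_used)),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode_basis: %s, %d modes over %d pixels\n", x$method,
              x$rank_used, nrow(x$modes)))
  if (!is.null(x$eigenvalues)) {
    cat(sprintf("  |lambda| range: %.3f - %.3f\n",
                min(Mod(x$eigenvalues)), max(Mod(x$eigenvalues))))
  }
  invisible(x)
}

#' @noRd
clip_rank <- function(r, d, what) {
  num_rank <- sum(d > INV_TOL * d[1])
  abort_if(num_rank == 0, "%s matrix is numerically zero", what)
  if (r > num_rank) {
    warning(sprintf("requested rank %d exceeds numerical rank %d of %s; truncated",
                    r, num_rank, what), call. = FALSE)
    r <- num_rank
  }
  as.integer(r)
}

#' Proper orthogonal decomposition of a snapshot matrix
#'
#' The left singular vectors of the raw snapshot matrix, ranked by
#' singular value: orthonormal spatial patterns ordered by captured
#' energy. POD operates on the original images (no mean removal).
#'
#' @param x a `snapshot_matrix` or numeric matrix (images as columns).
#' @param r number of modes to retain (`<= min(n_pixels, n_snapshots)`);
#'   requests beyond the numerical rank are truncated with a warning.
#' @return a `mode_basis` with orthonormal `modes` (`n_pixels x r`) and
#'   the full singular-value spectrum.
#' @export
pod <- function(x, r) {
  v <- snapshot_values(x)
  abort_if(!is_number(r) || r < 1, "r must be a positive integer")
  abort_if(r > min(dim(v)), "r exceeds min(n_pixels, n_snapshots)")
  s <- svd(v)
  r <- clip_rank(r, s$d, "snapshot")
  new_mode_basis("POD", s$u[, seq_len(r), drop = FALSE], s$d, r)
}

#' Principal component analysis of a snapshot matrix
#'
#' POD applied to the mean-centered snapshot matrix; the subtracted mean
#' image is stored in the basis and removed again before projection.
#'
#' @inheritParams pod
#' @return a `mode_basis` with `method = "PCA"` and the stored `mean`.
#' @export
pca <- function(x, r) {
  v <- snapshot_values(x)
  abort_if(ncol(v) == 0, "snapshot matrix has no columns")
  m <- rowMeans(v)
  basis <- pod(v - m, r)
  basis$method <- "PCA"
  basis$mean <- m
  basis
}

#' @noRd
group_initial_columns <- function(x) {
  if (inherits(x, "snapshot_matrix") && !is.null(x$columns$stage)) {
    idx <- which(x$columns$stage == min(x$columns$stage))
    x$values[, idx, drop = FALSE]
  } else {
    snapshot_values(x)[, 1, drop = FALSE]
  }
}

#' Mode amplitudes: coefficients of the averaged group-initial snapshot,
#' taken as its deviation from the average over all input snapshots.
#' Subtracting the ensemble mean keeps the static background (which has
#' its own near-unity eigenmode) from leaking across the non-orthogonal
#' modes and drowning the oscillatory part of the spectrum.
#' @noRd
dmd_amplitudes <- function(modes, x0_cols, reference) {
  x0 <- rowMeans(x0_cols) - reference
  as.vector(pinv(modes, INV_TOL) %*% x0)
}

#' Scale mode columns to unit norm, absorbing the norms into the
#' amplitudes so mode magnitudes are comparable across the spectrum.
#' @noRd
normalize_modes <- function(modes, amplitudes) {
  nrm <- sqrt(colSums(Mod(modes)^2))
  nrm[nrm < .Machine$double.eps] <- 1
  list(modes = sweep(modes, 2, nrm, "/"), amplitudes = amplitudes * nrm)
}

#' @noRd
order_by_amplitude <- function(basis) {
  ord <- order(-Mod(basis$amplitudes), -Mod(basis$eigenvalues))
  basis$modes <- basis$modes[, ord, drop = FALSE]
  basis$eigenvalues <- basis$eigenvalues[ord]
  basis$omega <- basis$omega[ord]
  basis$amplitudes <- basis$amplitudes[ord]
  basis
}

#' Exact dynamic mode decomposition
#'
#' Estimates the linear operator `A` best mapping the before-transition
#' snapshots onto the after-transition snapshots (`X'' ~ A X'`) and
#' returns its leading eigenmodes. Recipe: economy SVD `X' = U S V*`
#' truncated at `r`; reduced operator `At = U* X'' V S^-1`;
#' eigendecomposition `At = W L W^-1`; exact modes
#' `Phi = X'' V S^-1 W`; discrete eigenvalues `lambda = diag(L)`;
#' continuous eigenvalues `omega = log(lambda) / (2 pi)`; amplitudes
#' `b = Phi^+ x0` with `x0` the average of the group-initial (stage A0)
#' columns, taken relative to the ensemble-mean snapshot (the static
#' background belongs to the near-unity eigenmode; removing it before
#' the solve keeps it from leaking across the non-orthogonal modes and
#' masking the oscillatory spectrum). Mode columns are scaled to unit
#' norm (the scale
#' lives in the amplitudes, keeping spectrum magnitudes comparable), and
#' modes are ordered by amplitude magnitude (ties by `|lambda|`), the
#' order used when retaining "the first r modes" as classification
#' features.
#'
#' @param x_prime,x_dprime before/after transition matrices from
#'   [split_transitions()] (or plain matrices with matching column
#'   counts).
#' @param r modes to retain (`<=` numerical rank of `x_prime`).
#' @return a `mode_basis` with complex `modes`, `eigenvalues`, `omega`
#'   and `amplitudes`; `singular_values` are those of `x_prime`.
#' @export
dmd <- function(x_prime, x_dprime, r) {
  xp <- snapshot_values(x_prime)
  xpp <- snapshot_values(x_dprime)
  abort_if(ncol(xp) != ncol(xpp),
           "x_prime and x_dprime must have matching column counts")
  abort_if(all(xp == 0), "x_prime is identically zero")
  abort_if(!is_number(r) || r < 1, "r must be a positive integer")
  s <- svd(xp)
  r <- clip_rank(r, s$d, "x_prime")
  u_r <- s$u[, seq_len(r), drop = FALSE]
  v_r <- s$v[, seq_len(r), drop = FALSE]
  dinv <- 1 / s$d[seq_len(r)]
  m <- xpp %*% (v_r * rep(dinv, each = nrow(v_r))) # X'' V S^-1
  a_tilde <- crossprod(u_r, m)
  eg <- eigen(a_tilde)
  modes <- normalize_modes(m %*% eg$vectors, 1)$modes
  basis <- new_mode_basis("DMD", modes, s$d, r,
                          eigenvalues = eg$values,
                          omega = continuous_frequencies(eg$values),
                          amplitudes = dmd_amplitudes(
                            modes, group_initial_columns(x_prime),
                            rowMeans(xp)))
  order_by_amplitude(basis)
}

#' Dynamic mode decomposition with control
#'
#' Fits `X'' ~ A X' + C Y`, separating the intrinsic dynamics `A` from
#' the effect `C` of exogenous controls `Y` (particle size, flow rate,
#' severity of the target stage). Two-SVD formulation: the augmented
#' data `Omega = [X'; Y]` is truncated at rank `p` with split
#' `Ut = [Ut1; Ut2]` (pixel rows / control rows), the output `X''` at
#' rank `r` giving `Uh`; then `At = Uh* X'' Vt St^-1 Ut1* Uh` and
#' `Ct = Uh* X'' Vt St^-1 Ut2*`. Eigenmodes, eigenvalue transforms,
#' amplitudes and ordering are as in [dmd()].
#'
#' @inheritParams dmd
#' @param y a `control_matrix` (or `q x n_transitions` matrix) whose
#'   columns align with the columns of `x_prime`.
#' @param p truncation rank for the augmented input SVD; defaults to
#'   `r + q`, reflecting that the input space is larger than the output
#'   space by the number of controls.
#' @param r truncation rank for the output SVD (the retained modes).
#' @return list with `basis` (a `mode_basis`, `method = "DMDC"`, also
#'   carrying the reduced-state basis) and `control` (class
#'   `control_operator`: the reduced control map `values` (`r x q`) and
#'   the `state_basis` needed to lift it to pixel space).
#' @export
dmdc <- function(x_prime, x_dprime, y, p = NULL, r) {
  xp <- snapshot_values(x_prime)
  xpp <- snapshot_values(x_dprime)
  yv <- control_values(y)
  abort_if(ncol(xp) != ncol(xpp),
           "x_prime and x_dprime must have matching column counts")
  abort_if(ncol(yv) != ncol(xp),
           "control matrix has %d columns but x_prime has %d",
           ncol(yv), ncol(xp))
  abort_if(all(xp == 0), "x_prime is identically zero")
  abort_if(!is_number(r) || r < 1, "r must be a positive integer")
  q <- nrow(yv)
  if (is.null(p)) p <- r + q
  abort_if(!is_number(p) || p < 1, "p must be a positive integer")

  n <- nrow(xp)
  omega_mat <- rbind(xp, yv)
  s_in <- svd(omega_mat)
  p <- clip_rank(p, s_in$d, "augmented input")
  ut1 <- s_in$u[seq_len(n), seq_len(p), drop = FALSE]
  ut2 <- s_in$u[n + seq_len(q), seq_len(p), drop = FALSE]
  vt <- s_in$v[, seq_len(p), drop = FALSE]
  dinv <- 1 / s_in$d[seq_len(p)]

  s_out <- svd(xpp)
  r <- clip_rank(r, s_out$d, "x_dprime")
  uh <- s_out$u[, seq_len(r), drop = FALSE]

  m <- xpp %*% (vt * rep(dinv, each = nrow(vt))) # X'' Vt St^-1
  a_tilde <- crossprod(uh, m) %*% crossprod(ut1, uh)
  c_tilde <- crossprod(uh, m) %*% t(ut2)
  eg <- eigen(a_tilde)
  modes <- normalize_modes(m %*% crossprod(ut1, uh) %*% eg$vectors,
                           1)$modes
  basis <- new_mode_basis("DMDC", modes, s_out$d, r,
                          eigenvalues = eg$values,
                          omega = continuous_frequencies(eg$values),
                          amplitudes = dmd_amplitudes(
                            modes, group_initial_columns(x_prime),
                            rowMeans(xp)),
                          state_basis = uh)
  basis <- order_by_amplitude(basis)
  control <- structure(list(values = c_tilde, state_basis = uh),
                       class = "control_operator")
  list(basis = basis, control = control)
}

#' Continuous eigenvalues from discrete DMD eigenvalues
#'
#' `omega = log(lambda) / (2 pi)` on the principal branch, so
#' `Im(omega)` lies in `(-1/2, 1/2]` and is the oscillation frequency in
#' progression-index units, while the sign of `Re(omega)` matches the
#' position of `lambda` relative to the unit circle (negative real part
#' for decaying modes). `lambda = 0` maps to the sentinel `-Inf + 0i`
#' with a warning.
#'
#' @param lambda complex (or numeric) eigenvalues.
#' @return complex vector of the same length.
#' @examples
#' continuous_frequencies(1)        # 0
#' continuous_frequencies(exp(-pi)) # -0.5 + 0i
#' @export
continuous_frequencies <- function(lambda) {
  lambda <- as.complex(lambda)
  out <- complex(length(lambda))
  zero <- Mod(lambda) == 0
  if (any(zero)) {
    warning("zero eigenvalue(s) mapped to -Inf continuous frequency",
            call. = FALSE)
    out[zero] <- complex(real = -Inf, imaginary = 0)
  }
  out[!zero] <- log(lambda[!zero]) / (2 * pi)
  out
}

#' Dominant frequency peaks of a DMD/DMDC amplitude spectrum
#'
#' Finds strict local maxima of the amplitude magnitude `|b|` over the
#' oscillation frequency `Im(omega)`, restricted to positive frequencies
#' (quasi-static modes near zero frequency, including the background
#' mean, are not oscillation peaks), and returns the strongest
#' `n_peaks`. On the default synthetic dataset the three planted factor
#' periodicities appear as peaks at frequencies 1/3, 1/5 and 1/9.
#'
#' @param basis a DMD or DMDC `mode_basis` (must carry amplitudes).
#' @param n_peaks maximum number of peaks to return (default 3).
#' @param min_frequency lower frequency cutoff excluding quasi-static
#'   modes (default 0.02 progression-index cycles).
#' @return data frame with columns `frequency`, `period`, `amplitude`,
#'   sorted by amplitude descending; fewer rows than `n_peaks` if fewer
#'   local maxima exist.
#' @export
spectrum_peaks <- function(basis, n_peaks = 3, min_frequency = 0.02) {
  abort_if(!inherits(basis, "mode_basis") || is.null(basis$amplitudes),
           "basis must be a DMD/DMDC mode_basis with amplitudes")
  freq <- Im(basis$omega)
  amp <- Mod(basis$amplitudes)
  keep <- is.finite(freq) & freq > min_frequency
  freq <- freq[keep]
  amp <- amp[keep]
  empty <- data.frame(frequency = numeric(0), period = numeric(0),
                      amplitude = numeric(0))
  if (length(freq) == 0) return(empty)
  ord <- order(freq)
  freq <- freq[ord]
  amp <- amp[ord]
  n <- length(amp)
  if (n == 1L) {
    is_peak <- TRUE
  } else {
    left <- c(-Inf, amp[-n])
    right <- c(amp[-1], -Inf)
    is_peak <- amp > left & amp > right
  }
  if (!any(is_peak)) return(empty)
  peaks <- data.frame(frequency = freq[is_peak],
                      period = 1 / freq[is_peak],
                      amplitude = amp[is_peak])
  peaks <- peaks[order(-peaks$amplitude), , drop = FALSE]
  rownames(peaks) <- NULL
  utils::head(peaks, n_peaks)
}

#' Cumulative energy captured by the leading singular values
#'
#' `sum(sigma[1:k]^2) / sum(sigma^2)`: the fraction of total
#' (Frobenius) energy captured by the first `k` modes. Nondecreasing in
#' `k` and equal to 1 at `k = length(sigma)`.
#'
#' @param sigma nonnegative singular values, descending.
#' @param k number of leading modes (vectorized; `1 <= k <=
#'   length(sigma)`).
#' @return fraction(s) in (0, 1\].
#' @export
cumulative_energy <- function(sigma, k) {
  abort_if(!is.numeric(sigma) || length(sigma) == 0 || any(sigma < 0),
           "sigma must be nonnegative singular values")
  total <- sum(sigma^2)
  abort_if(total == 0, "all singular values are zero")
  abort_if(any(k < 1) || any(k > length(sigma)),
           "k must lie in 1..length(sigma)")
  cumsum(sigma^2)[k] / total
}

#' Project images onto the leading modes of a basis
#'
#' Least-squares coefficients of each image on the first `r` modes
#' (sigma-ranked for POD/PCA, amplitude-ranked for DMD/DMDC); the real
#' part is returned, since conjugate-pair modes make the imaginary
#' parts redundant for real images. For PCA the stored mean image is
#' subtracted first. For orthonormal POD/PCA bases the least-squares
#' solution reduces to the transpose product.
#'
#' @param basis a `mode_basis`.
#' @param x image vector of length `n_pixels`, or a matrix with one
#'   image per column (a `snapshot_matrix` is also accepted).
#' @param r modes to use (`<= basis$rank_used`; default all).
#' @return `r x n_images` real matrix (a vector for a single image).
#' @export
project_modes <- function(basis, x, r = basis$rank_used) {
  abort_if(!inherits(basis, "mode_basis"), "basis must be a mode_basis")
  abort_if(!is_number(r) || r < 1 || r > basis$rank_used,
           "r must lie in 1..rank_used (%d)", basis$rank_used)
  v <- if (inherits(x, "snapshot_matrix")) x$values
       else if (is.matrix(x)) x
       else matrix(x, ncol = 1)
  out <- Re(mode_coefficients(basis, v, r))
  if (ncol(out) == 1L && !is.matrix(x) &&
      !inherits(x, "snapshot_matrix")) {
    out <- drop(out)
  }
  out
}

#' Least-squares coefficients of images on the first r modes (complex
#' for DMD/DMDC, real for orthonormal POD/PCA where the solve reduces to
#' the transpose product)
#' @noRd
mode_coefficients <- function(basis, v, r) {
  abort_if(nrow(v) != nrow(basis$modes),
           "image length %d does not match basis pixel count %d",
           nrow(v), nrow(basis$modes))
  if (!is.null(basis$mean)) v <- v - basis$mean
  phi <- basis$modes[, seq_len(r), drop = FALSE]
  if (basis$method %in% c("POD", "PCA")) {
    crossprod(phi, v)
  } else {
    pinv(phi, INV_TOL) %*% v
  }
}

#' Pairwise realification of complex mode coefficients: modes with
#' eigenvalues in the closed upper half-plane contribute real parts,
#' their lower-half-plane conjugate partners imaginary parts.
#' @noRd
realify_coefficients <- function(basis, coef, r) {
  if (is.null(basis$eigenvalues) || !is.complex(coef)) {
    return(Re(coef))
  }
  out <- Re(coef)
  lower <- Im(basis$eigenvalues[seq_len(r)]) < 0
  out[lower, ] <- Im(coef[lower, , drop = FALSE])
  out
}

#' Build a per-image feature table from a mode basis
#'
#' Projects every image of the dataset onto the first `r` modes of the
#' basis, yielding one real feature vector per image in manifest
#' (canonical snapshot) order, together with class labels and test
#' conditions — the input to the classifiers.
#'
#' For the complex-valued DMD/DMDC bases the `r` least-squares
#' coefficients are realified pairwise: a mode whose eigenvalue has
#' nonnegative imaginary part contributes the real part of its
#' coefficient, its conjugate partner the imaginary part. Conjugate
#' pairs of a real image carry conjugate coefficients, so taking real
#' parts of both members would duplicate columns and silently halve the
#' information in the feature set; the pairwise encoding keeps `r`
#' non-redundant real features. POD/PCA coefficients are real and are
#' used as-is.
#'
#' @param basis a `mode_basis`.
#' @param data an `aerosol_dataset` or an assembled `snapshot_matrix`.
#' @param r retained modes (`<= basis$rank_used`).
#' @return An object of class `feature_table`: list with `features`
#'   (`n_images x r` matrix, columns `mode_1..mode_r`), `labels`
#'   (factor with levels A0-A4), `conditions` (data frame), `method`,
#'   `r`.
#' @export
build_feature_table <- function(basis, data, r = basis$rank_used) {
  snap <- if (inherits(data, "aerosol_dataset")) assemble_snapshots(data)
          else data
  abort_if(!inherits(snap, "snapshot_matrix"),
           "data must be an aerosol_dataset or snapshot_matrix")
  coef <- mode_coefficients(basis, snap$values, r)
  features <- t(realify_coefficients(basis, coef, r))
  colnames(features) <- paste0("mode_", seq_len(ncol(features)))
  structure(list(features = features,
                 labels = factor(snap$columns$class_label,
                                 levels = CLASS_LABELS),
                 conditions = snap$columns[, c("flow_rate",
                                               "particle_size",
                                               "replicate")],
                 method = basis$method, r = as.integer(r)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d images x %d %s features\n",
              nrow(x$features), ncol(x$features), x$method))
  invisible(x)
}
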