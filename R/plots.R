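# Diagnostic figures for mode bases (base graphics).

#' Singular-value spectrum of a mode basis
#'
#' @param basis a `mode_basis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_singular_values <- function(basis, ...) {
  abort_if(!inherits(basis, "mode_basis"), "basis must be a mode_basis")
  graphics::plot(basis$singular_values, log = "y", type = "b", pch = 20,
                 xlab = "mode index", ylab = "singular value",
                 main = sprintf("%s singular values", basis$method), ...)
}

#' Discrete eigenvalues against the unit circle
#'
#' Modes inside the circle decay with disease progression; modes on it
#' persist.
#'
#' @param basis a DMD/DMDC `mode_basis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_eigenvalues <- function(basis, ...) {
  abort_if(!inherits(basis, "mode_basis") || is.null(basis$eigenvalues),
           "basis must carry eigenvalues")
  lam <- basis$eigenvalues
  lim <- max(1.05, max(Mod(lam)) * 1.05)
  graphics::plot(Re(lam), Im(lam), pch = 20, asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "Re(lambda)", ylab = "Im(lambda)",
                 main = sprintf("%s eigenvalues", basis$method), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), lty = 2, col = "blue")
}

#' Continuous-eigenvalue (frequency) plane
#'
#' `omega = log(lambda)/(2 pi)`: decay rate against oscillation
#' frequency in progression-index units.
#'
#' @param basis a DMD/DMDC `mode_basis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_frequency_plane <- function(basis, ...) {
  abort_if(!inherits(basis, "mode_basis") || is.null(basis$omega),
           "basis must carry continuous eigenvalues")
  om <- basis$omega[is.finite(Re(basis$omega))]
  graphics::plot(Re(om), Im(om), pch = 20,
                 xlab = "Re(omega) (decay)", ylab = "Im(omega) (frequency)",
                 main = sprintf("%s frequency plane", basis$method), ...)
  graphics::abline(v = 0, lty = 2, col = "blue")
}

#' Amplitude spectrum of a dynamic mode basis
#'
#' Mode amplitude magnitude `|b|` against oscillation frequency; the
#' factor periodicities of the dataset appear as isolated peaks.
#'
#' @param basis a DMD/DMDC `mode_basis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_spectrum <- function(basis, ...) {
  abort_if(!inherits(basis, "mode_basis") || is.null(basis$amplitudes),
           "basis must carry amplitudes")
  ok <- is.finite(Re(basis$omega))
  f <- Im(basis$omega[ok])
  a <- Mod(basis$amplitudes[ok])
  graphics::plot(f, a, type = "h", lwd = 2,
                 xlab = "Im(omega) (frequency)", ylab = "|amplitude|",
                 main = sprintf("%s spectrum", basis$method), ...)
  graphics::points(f, a, pch = 20)
}
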