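#' Acquisition parameters for a multi-gradient-echo sequence
#'
#' Bundles the echo-train timing and geometry of a 3D multi-gradient-echo
#' acquisition. Defaults correspond to a high-resolution protocol with ten
#' echoes starting at TE1 = 4 ms with 4 ms spacing, TR = 50 ms, a 30 degree
#' flip angle and 1 x 1 x 2 mm voxels.
#'
#' @param te_first First echo time in seconds.
#' @param te_spacing Echo spacing in seconds.
#' @param n_echoes Number of echoes; must be at least 4 so that the echo
#'   train over-determines the decay model.
#' @param tr Repetition time in seconds.
#' @param flip_angle Excitation flip angle in degrees.
#' @param voxel_size Numeric length-3 vector of voxel dimensions in mm
#'   (x, y, z); the third dimension is the slab (through-slice) direction
#'   used by the field-gradient attenuation term.
#' @return An object of class \code{acq_params}.
#' @export
#' @examples
#' acq <- acq_params()
#' echo_times(acq)
acq_params <- function(te_first = 0.004, te_spacing = 0.004, n_echoes = 10L,
                       tr = 0.050, flip_angle = 30, voxel_size = c(1, 1, 2)) {
  stopifnot(te_first > 0, te_spacing > 0, length(voxel_size) == 3,
            all(voxel_size > 0), tr > 0)
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 4L)
    stop("n_echoes must be >= 4 (echo train must exceed the number of free fit parameters)")
  structure(list(te_first = te_first, te_spacing = te_spacing,
                 n_echoes = n_echoes, tr = tr, flip_angle = flip_angle,
                 voxel_size = as.numeric(voxel_size)),
            class = "acq_params")
}

#' Echo times of an acquisition
#'
#' @param acq An \code{acq_params} object.
#' @return Numeric vector of echo times in seconds,
#'   \code{te_first + (0:(n_echoes-1)) * te_spacing}.
#' @export
echo_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  acq$te_first + (seq_len(acq$n_echoes) - 1) * acq$te_spacing
}

# 1 - J0(z) with series protection against cancellation at small z.
one_minus_j0 <- function(z) {
  out <- numeric(length(z))
  small <- z < 1e-3
  if (any(small)) {
    zs <- z[small]
    z2 <- zs * zs
    # 1 - J0(z) = z^2/4 - z^4/64 + z^6/2304 - ...
    out[small] <- z2 / 4 * (1 - z2 / 16 * (1 - z2 / 36))
  }
  if (any(!small)) out[!small] <- 1 - besselJ(z[!small], 0)
  out
}

# Static-dephasing integrand after the substitution u = 1 - t^2, which
# removes the sqrt(1-u) derivative singularity at u = 1:
#   f_s(x) = (1/3) Int_0^1 2 t^2 (3 - t^2) (1 - J0(1.5 x (1 - t^2))) / (1 - t^2)^2 dt
# The (1 - J0)/u^2 factor has a finite limit (1.5 x)^2 / 4 as u -> 0 (t -> 1).
fs_integrand_t <- function(t, x) {
  u <- 1 - t * t
  core <- ifelse(u < 1e-9,
                 (1.5 * x)^2 / 4,
                 one_minus_j0(1.5 * x * u) / (u * u))
  2 * t * t * (3 - t * t) * core
}

# Environment caching the dense lookup table used by the fast path.
.fs_cache <- new.env(parent = emptyenv())

fs_build_table <- function(x_max = 100, dx = 0.01, n_nodes = 256) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  xg <- seq(0, x_max, by = dx)
  u <- 1 - gl$x^2
  core_coef <- 2 * gl$x^2 * (3 - gl$x^2) * gl$w      # weight * smooth prefactor
  # f_s(xg) for all grid points at once: outer over (x, node)
  z <- outer(xg, 1.5 * u)                            # length(xg) x n_nodes
  num <- matrix(one_minus_j0(as.vector(z)), nrow = length(xg))
  vals <- (num %*% (core_coef / (u * u))) / 3
  vals[1] <- 0
  fun <- stats::splinefun(xg, vals, method = "monoH.FC")
  slope_end <- (vals[length(xg)] - vals[length(xg) - 1]) / dx
  list(fun = fun, x_max = x_max, f_max = vals[length(xg)], slope_end = slope_end)
}

fs_table <- function() {
  if (is.null(.fs_cache$table)) .fs_cache$table <- fs_build_table()
  .fs_cache$table
}

#' Static-dephasing attenuation exponent
#'
#' Evaluates the dimensionless attenuation exponent of the static dephasing
#' regime around a randomly oriented vessel network,
#' \deqn{f_s(x) = \frac{1}{3}\int_0^1 (2+u)\sqrt{1-u}\,
#'   \frac{1 - J_0(1.5\,x\,u)}{u^2}\,du,}
#' with \eqn{J_0} the zeroth-order Bessel function. \eqn{f_s} is monotone
#' non-decreasing, behaves as \eqn{0.3\,x^2} for small \eqn{x} and grows with
#' unit slope for large \eqn{x}.
#'
#' @param x Non-negative numeric vector (the product of characteristic
#'   frequency shift and echo time, dimensionless).
#' @param method \code{"table"} (default) uses a precomputed dense lookup
#'   table with monotone spline interpolation (grid spacing 0.01 on
#'   \eqn{[0, 100]}, linear continuation beyond); \code{"quadrature"}
#'   evaluates the integral by adaptive quadrature to relative tolerance
#'   1e-10 per element.
#' @return \code{f_s(x)}, same length as \code{x}.
#' @export
#' @examples
#' fs_static_dephasing(c(0, 0.5, 3.2))
#' fs_static_dephasing(0.01, method = "quadrature") / 0.01^2  # ~ 0.3
fs_static_dephasing <- function(x, method = c("table", "quadrature")) {
  method <- match.arg(method)
  if (any(!is.finite(x)) || any(x < 0))
    stop("fs_static_dephasing: x must be finite and >= 0")
  if (method == "quadrature") {
    vapply(x, function(xi) {
      if (xi == 0) return(0)
      stats::integrate(fs_integrand_t, 0, 1, x = xi,
                       rel.tol = 1e-10, abs.tol = 0,
                       subdivisions = 400L)$value / 3
    }, numeric(1))
  } else {
    tab <- fs_table()
    out <- numeric(length(x))
    inside <- x <= tab$x_max
    if (any(inside)) out[inside] <- pmax(0, tab$fun(x[inside]))
    if (any(!inside))
      out[!inside] <- tab$f_max + tab$slope_end * (x[!inside] - tab$x_max)
    out
  }
}

#' BOLD attenuation factor
#'
#' Multiplicative signal attenuation from dephasing around deoxygenated
#' blood in the static dephasing regime:
#' \eqn{F_{BOLD}(TE) = \exp(-\zeta f_s(\delta\omega \cdot TE))}, where
#' \eqn{\zeta} is the deoxygenated-blood volume fraction and
#' \eqn{\delta\omega} the characteristic frequency shift (s^-1).
#'
#' @param te Echo time(s) in seconds, non-negative.
#' @param zeta Deoxygenated-blood volume fraction, in \eqn{[0, 1)}.
#' @param delta_omega Characteristic frequency shift in s^-1, non-negative.
#' @param fs_method Evaluation method for \code{\link{fs_static_dephasing}}.
#' @return Attenuation factor(s) in (0, 1]; exactly 1 when \code{zeta = 0}
#'   or \code{te = 0}.
#' @export
f_bold <- function(te, zeta, delta_omega, fs_method = "table") {
  stopifnot(all(te >= 0), zeta >= 0, zeta < 1, delta_omega >= 0)
  exp(-zeta * fs_static_dephasing(delta_omega * te, method = fs_method))
}

#' Macroscopic-field attenuation factor
#'
#' First-order model of signal loss from a macroscopic field gradient across
#' the voxel: a linear through-voxel gradient dephases the voxel's spins
#' uniformly, giving a sinc attenuation
#' \eqn{F(TE) = |\mathrm{sinc}(g \cdot \Delta z \cdot TE)|} with
#' \eqn{\mathrm{sinc}(y) = \sin(\pi y)/(\pi y)}; the argument is the number
#' of dephasing cycles across the voxel.
#'
#' @param te Echo time(s) in seconds, non-negative.
#' @param g_through Through-voxel field gradient in Hz/mm.
#' @param slab_thickness Voxel extent along the dephasing dimension in mm.
#' @return Attenuation factor(s) in \eqn{[0, 1]}; 1 at \code{te = 0} or
#'   \code{g_through = 0}.
#' @export
f_macro <- function(te, g_through, slab_thickness) {
  stopifnot(all(te >= 0), slab_thickness > 0)
  y <- g_through * slab_thickness * te
  out <- rep(1, length(y))
  nz <- y != 0
  out[nz] <- abs(sin(pi * y[nz]) / (pi * y[nz]))
  out
}

#' Forward multi-gradient-echo signal model
#'
#' Magnitude signal of the decomposed gradient-echo decay model
#' \deqn{S(TE) = S_0 \exp(-R2t^* \cdot TE)\, F_{BOLD}(TE)\, F(TE),}
#' the product of mono-exponential tissue-specific decay, BOLD
#' static-dephasing attenuation (\code{\link{f_bold}}) and the through-voxel
#' field-gradient attenuation (\code{\link{f_macro}}).
#'
#' @param s0 Signal magnitude at TE = 0 (arbitrary units), >= 0.
#' @param r2t_star Tissue-specific transverse relaxation rate in s^-1, >= 0.
#' @param zeta,delta_omega BOLD parameters, see \code{\link{f_bold}}.
#' @param g_through,slab_thickness Macroscopic-field parameters, see
#'   \code{\link{f_macro}}.
#' @param acq An \code{\link{acq_params}} object defining the echo grid, or
#'   \code{NULL} if \code{te} is given explicitly.
#' @param te Optional explicit echo-time vector in seconds (overrides
#'   \code{acq}); allows non-uniform echo grids.
#' @param fs_method Evaluation method for \code{\link{fs_static_dephasing}}.
#' @return Numeric vector of signal magnitudes, one per echo. With
#'   \code{zeta = 0} and \code{g_through = 0} the log-signal is exactly
#'   linear in TE with slope \code{-r2t_star}.
#' @export
#' @examples
#' forward_signal(100, 15, zeta = 0, delta_omega = 70, g_through = 0)
forward_signal <- function(s0, r2t_star, zeta = 0, delta_omega = 70,
                           g_through = 0, slab_thickness = 2,
                           acq = NULL, te = NULL, fs_method = "table") {
  stopifnot(s0 >= 0, r2t_star >= 0)
  if (is.null(te)) {
    if (is.null(acq)) acq <- acq_params()
    te <- echo_times(acq)
  }
  s0 * exp(-r2t_star * te) *
    f_bold(te, zeta, delta_omega, fs_method = fs_method) *
    f_macro(te, g_through, slab_thickness)
}
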