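#' Fit options for voxelwise model estimation
#'
#' @param mode \code{"fit_zeta_only"} (default; the BOLD frequency shift
#'   \eqn{\delta\omega} is held at \code{delta_omega_fixed}) or
#'   \code{"fit_zeta_and_delta_omega"} (joint fit). Ten magnitude echoes
#'   constrain a four-parameter model poorly, hence the fixed default.
#' @param delta_omega_fixed Fixed characteristic frequency shift, s^-1.
#' @param macro_mode How the macroscopic-field term enters:
#'   \code{"model"} multiplies the forward model by \code{\link{f_macro}};
#'   \code{"precorrect"} divides the data by it before fitting;
#'   \code{"none"} ignores it.
#' @param bounds Named list of length-2 numeric vectors (lower, upper) for
#'   \code{s0}, \code{r2t_star}, \code{zeta}, \code{delta_omega}. Defaults
#'   bracket physiologic tissue values, except that the fitting range of
#'   \code{zeta} is symmetric about zero: the deoxygenated-blood fraction
#'   is physically non-negative, but constraining the fit at 0 censors the
#'   noise distribution of the estimate and biases R2t* downward at
#'   moderate SNR, so the optimizer may explore small negative values and
#'   users clip the reported map if a strictly physical \code{zeta} is
#'   needed.
#' @param max_iterations Maximum Levenberg-Marquardt iterations.
#' @param tolerance Convergence tolerance on the cost decrease.
#' @param zeta_init Initial deoxygenated-blood volume fraction.
#' @param f_macro_floor Quality threshold: voxels whose macroscopic-field
#'   attenuation at the last echo falls below this are excluded from the
#'   quality mask.
#' @param noise_sigma Optional known noise standard deviation (same units as
#'   the signal); used for the quality mask's SNR floor (last-echo expected
#'   SNR >= \code{snr_floor}) and residual screening.
#' @param snr_floor Minimum last-echo model SNR for the quality mask.
#' @param residual_mult Voxels with residual RMS above
#'   \code{residual_mult * noise_sigma} are excluded from the quality mask.
#' @return An object of class \code{fit_options}.
#' @export
fit_options <- function(mode = c("fit_zeta_only", "fit_zeta_and_delta_omega"),
                        delta_omega_fixed = 70,
                        macro_mode = c("model", "precorrect", "none"),
                        bounds = list(s0 = c(0, Inf),
                                      r2t_star = c(0, 100),
                                      zeta = c(-0.2, 0.2),
                                      delta_omega = c(10, 300)),
                        max_iterations = 200L,
                        tolerance = 1e-10,
                        zeta_init = 0.01,
                        f_macro_floor = 0.3,
                        noise_sigma = NULL,
                        snr_floor = 3,
                        residual_mult = 3) {
  mode <- match.arg(mode)
  macro_mode <- match.arg(macro_mode)
  stopifnot(tolerance > 0, max_iterations >= 1)
  for (nm in names(bounds))
    if (bounds[[nm]][1] > bounds[[nm]][2])
      stop("bounds for ", nm, ": lower > upper")
  structure(list(mode = mode, delta_omega_fixed = delta_omega_fixed,
                 macro_mode = macro_mode, bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, zeta_init = zeta_init,
                 f_macro_floor = f_macro_floor, noise_sigma = noise_sigma,
                 snr_floor = snr_floor, residual_mult = residual_mult),
            class = "fit_options")
}

# Apply per-excitation phases to the k-space lines of a 4D complex array
# along the phase-encode (second) axis; sign = +1 injects, -1 corrects.
apply_excitation_phase <- function(cplx, nav, sign = -1) {
  dm <- dim(cplx)
  perm <- aperm(cplx, c(2, 1, 3, 4))                 # y first
  m <- matrix(perm, nrow = dm[2])
  k <- stats::mvfft(m)                               # one FFT per (x,z,echo)
  k <- k * exp(sign * 1i * nav)                      # recycles down k-lines
  m2 <- stats::mvfft(k, inverse = TRUE) / dm[2]
  aperm(array(m2, dim(perm)), c(2, 1, 3, 4))
}

#' Navigator-based phase-fluctuation correction
#'
#' Removes per-excitation global phase fluctuations recorded by navigator
#' echoes. The model is zeroth order: each excitation acquires one k-space
#' line along the phase-encode (second image) axis and contributes a single
#' global phase to that line; uncorrected, such phases ghost the magnitude
#' image along the phase-encode direction. The correction transforms the
#' complex data to k-space along that axis, multiplies line \eqn{j} by
#' \eqn{\exp(-i\,\varphi_{nav,j})} and transforms back. It is exact (up to
#' floating point) when the fluctuation truly is one global phase per
#' excitation; spatially varying components remain. A zero navigator trace
#' returns the input unchanged.
#'
#' @param image A \code{\link{multi_echo_image}} with phase data.
#' @param nav Numeric vector of navigator phases in radians, one per
#'   excitation (length equal to the second spatial dimension).
#' @return The corrected \code{multi_echo_image}.
#' @export
navigator_correct <- function(image, nav) {
  stopifnot(inherits(image, "multi_echo_image"))
  if (is.null(image$phase))
    stop("navigator correction requires phase data; image is magnitude-only")
  nav <- as.numeric(nav)
  if (any(!is.finite(nav))) stop("navigator phases must be finite")
  dm <- dim(image$phase)
  if (length(nav) != dm[2])
    stop("navigator length (", length(nav), ") must equal the number of excitations (",
         dm[2], " phase-encode lines)")
  if (all(nav == 0)) return(image)
  cplx <- complex_data(image)
  corrected <- apply_excitation_phase(cplx, nav, sign = -1)
  image$magnitude <- array(Mod(corrected), dm)
  image$phase <- array(Arg(corrected), dm)
  image
}

#' Estimate the B0 field map and through-slab gradient
#'
#' Per-voxel field offset from the slope of the temporally-unwrapped phase
#' across echoes (ordinary least squares of phase on TE, divided by
#' \eqn{2\pi}, in Hz), then the through-slab gradient from finite
#' differences of the field map along the slab (third) axis divided by the
#' slab voxel size: central differences in the mask interior, one-sided at
#' mask edges. Temporal unwrapping handles inter-echo phase wraps for
#' \eqn{|B0| < 1/(2 \Delta TE)}.
#'
#' @param image A \code{\link{multi_echo_image}} with phase data and at
#'   least two echoes.
#' @return A list of class \code{field_gradient_map} with 3D arrays
#'   \code{b0_map} (Hz) and \code{g_through} (Hz/mm).
#' @export
estimate_field <- function(image) {
  stopifnot(inherits(image, "multi_echo_image"))
  if (is.null(image$phase)) stop("field estimation requires phase data")
  dm <- dim(image$phase)
  n_echo <- dm[4]
  if (n_echo < 2) stop("field estimation requires >= 2 echoes")
  te <- echo_times(image$acq)
  nv <- prod(dm[1:3])
  ph <- matrix(image$phase, nrow = nv, ncol = n_echo)
  # temporal unwrapping: wrap successive differences into (-pi, pi]
  dph <- ph[, -1, drop = FALSE] - ph[, -n_echo, drop = FALSE]
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  unwrapped <- cbind(ph[, 1], ph[, 1] + t(apply(dph, 1, cumsum)))
  # closed-form OLS slope of phase on TE
  tc <- te - mean(te)
  slope <- (unwrapped %*% tc) / sum(tc * tc)
  b0 <- array(slope / (2 * pi), dim = dm[1:3])
  mask <- image$brain_mask
  b0[!mask] <- NA_real_
  dz <- image$acq$voxel_size[3]
  nz <- dm[3]
  g <- array(NA_real_, dm[1:3])
  if (nz >= 2) {
    for (k in seq_len(nz)) {
      up <- if (k < nz) b0[, , k + 1] else NULL
      dn <- if (k > 1) b0[, , k - 1] else NULL
      cur <- b0[, , k]
      have_up <- if (is.null(up)) matrix(FALSE, dm[1], dm[2]) else !is.na(up)
      have_dn <- if (is.null(dn)) matrix(FALSE, dm[1], dm[2]) else !is.na(dn)
      gk <- matrix(NA_real_, dm[1], dm[2])
      both <- have_up & have_dn
      gk[both] <- (up[both] - dn[both]) / (2 * dz)
      only_up <- have_up & !have_dn
      gk[only_up] <- (up[only_up] - cur[only_up]) / dz
      only_dn <- have_dn & !have_up
      gk[only_dn] <- (cur[only_dn] - dn[only_dn]) / dz
      isolated <- !have_up & !have_dn & !is.na(cur)
      gk[isolated] <- 0
      g[, , k] <- gk
    }
  } else {
    g[mask] <- 0
  }
  g[!mask] <- NA_real_
  structure(list(b0_map = b0, g_through = g), class = "field_gradient_map")
}

#' Log-linear initialization of the mono-exponential decay
#'
#' Ordinary least squares of \code{log(signal)} on TE. The intercept gives
#' \code{s0}, the negated slope (floored at 0) gives \code{r2t_star}. With a
#' BOLD term present in the data the slope over-estimates the decay rate, so
#' this serves as initialization, not as the final estimate.
#'
#' @param signal Positive magnitude series, one value per echo.
#' @param te Echo times in seconds, same length.
#' @return List with \code{s0} and \code{r2t_star}.
#' @export
init_loglinear <- function(signal, te) {
  if (length(signal) != length(te)) stop("signal and te lengths differ")
  if (any(signal <= 0)) stop("init_loglinear requires strictly positive signal")
  y <- log(signal)
  tc <- te - mean(te)
  slope <- sum(tc * (y - mean(y))) / sum(tc * tc)
  intercept <- mean(y) - slope * mean(te)
  list(s0 = exp(intercept), r2t_star = max(0, -slope))
}

fit_model_signal <- function(p, te, opts, g_through, slab_thickness) {
  zeta <- p[["zeta"]]
  domega <- if (opts$mode == "fit_zeta_and_delta_omega") p[["delta_omega"]] else opts$delta_omega_fixed
  s <- p[["s0"]] * exp(-p[["r2t_star"]] * te) *
    exp(-zeta * fs_static_dephasing(domega * te, method = "table"))
  if (opts$macro_mode == "model")
    s <- s * f_macro(te, g_through, slab_thickness)
  s
}

# Hot path for the default fixed-delta-omega mode: f_s(domega * te) and the
# sinc attenuation are parameter-independent, so they are precomputed per
# voxel and the model has the closed-form Jacobian
#   dS/ds0 = S/s0, dS/dr2t = -te * S, dS/dzeta = -fs * S.
fit_voxel_fixed_domega <- function(data, te, fs_vec, fm_vec, start, lower,
                                   upper, opts) {
  resid_fun <- function(p) {
    p[1] * exp(-p[2] * te - p[3] * fs_vec) * fm_vec - data
  }
  jac_fun <- function(p) {
    m <- exp(-p[2] * te - p[3] * fs_vec) * fm_vec
    cbind(m, -te * p[1] * m, -fs_vec * p[1] * m)
  }
  tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fun, jac = jac_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = opts$max_iterations,
                         ftol = opts$tolerance, ptol = opts$tolerance)),
    error = function(e) NULL)
}

#' Fit the decomposed decay model to one voxel's echo series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nls.lm}) of the magnitude forward model
#' \eqn{S_0 e^{-R2t^* TE} F_{BOLD}(TE) F(TE)} to a measured magnitude
#' series. The macroscopic-field term is either part of the model
#' (\code{macro_mode = "model"}), divided out of the data beforehand
#' (\code{"precorrect"}), or ignored (\code{"none"}). Initialization is the
#' log-linear estimate for \code{(s0, r2t_star)} plus configured starting
#' values for the BOLD parameters. Non-convergence returns the
#' initialization with \code{converged = FALSE} rather than an error.
#'
#' @param signal Magnitude series, one value per echo.
#' @param te Echo times in seconds.
#' @param g_through Through-voxel field gradient in Hz/mm at this voxel.
#' @param slab_thickness Voxel extent along the slab axis in mm.
#' @param opts A \code{\link{fit_options}} object.
#' @return List with elements \code{s0}, \code{r2t_star}, \code{zeta},
#'   \code{delta_omega}, \code{residual_rms}, \code{iterations},
#'   \code{converged}.
#' @export
fit_voxel <- function(signal, te, g_through = 0, slab_thickness = 2,
                      opts = fit_options()) {
  n_free <- if (opts$mode == "fit_zeta_and_delta_omega") 4L else 3L
  if (length(signal) != length(te))
    stop("signal and te lengths differ")
  if (length(signal) < n_free + 1L)
    stop("need at least ", n_free + 1L, " echoes for ", n_free, " free parameters")
  if (any(!is.finite(signal)))
    stop("non-finite signal values; mask or skip this voxel")

  data <- signal
  if (opts$macro_mode == "precorrect") {
    fm <- f_macro(te, g_through, slab_thickness)
    fm <- pmax(fm, 1e-3)  # guard sinc zeros; such voxels fail the quality floor anyway
    data <- data / fm
  }

  init_fail <- any(data <= 0)
  init <- if (init_fail) list(s0 = max(data, 1e-6), r2t_star = 20)
          else init_loglinear(data, te)
  b <- opts$bounds
  start <- c(s0 = min(max(init$s0, b$s0[1]), b$s0[2]),
             r2t_star = min(max(init$r2t_star, b$r2t_star[1]), b$r2t_star[2]),
             zeta = min(max(opts$zeta_init, b$zeta[1]), b$zeta[2]))
  lower <- c(b$s0[1], b$r2t_star[1], b$zeta[1])
  upper <- c(b$s0[2], b$r2t_star[2], b$zeta[2])
  if (opts$mode == "fit_zeta_and_delta_omega") {
    start <- c(start, delta_omega = min(max(opts$delta_omega_fixed,
                                            b$delta_omega[1]), b$delta_omega[2]))
    lower <- c(lower, b$delta_omega[1])
    upper <- c(upper, b$delta_omega[2])
  }

  if (opts$mode == "fit_zeta_only") {
    fs_vec <- fs_static_dephasing(opts$delta_omega_fixed * te, method = "table")
    fm_vec <- if (opts$macro_mode == "model")
      f_macro(te, g_through, slab_thickness) else rep(1, length(te))
    resid_fun <- function(p) p[1] * exp(-p[2] * te - p[3] * fs_vec) * fm_vec - data
    fit <- fit_voxel_fixed_domega(data, te, fs_vec, fm_vec, start, lower,
                                  upper, opts)
  } else {
    resid_fun <- function(p) {
      fit_model_signal(as.list(p), te, opts, g_through, slab_thickness) - data
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = opts$max_iterations,
                           ftol = opts$tolerance, ptol = opts$tolerance)),
      error = function(e) NULL)
  }

  if (is.null(fit) || !fit$info %in% 1:4) {
    return(list(s0 = unname(start["s0"]), r2t_star = unname(start["r2t_star"]),
                zeta = unname(start["zeta"]),
                delta_omega = opts$delta_omega_fixed,
                residual_rms = sqrt(mean(resid_fun(start)^2)),
                iterations = if (is.null(fit)) 0L else fit$niter,
                converged = FALSE))
  }
  p <- fit$par
  list(s0 = unname(p["s0"]), r2t_star = unname(p["r2t_star"]),
       zeta = unname(p["zeta"]),
       delta_omega = if (opts$mode == "fit_zeta_and_delta_omega")
         unname(p["delta_omega"]) else opts$delta_omega_fixed,
       residual_rms = sqrt(mean(fit$fvec^2)),
       iterations = fit$niter,
       converged = TRUE)
}

#' Fit the decay model over a whole volume
#'
#' Applies \code{\link{fit_voxel}} independently to every voxel inside the
#' brain mask (the result is independent of traversal order). Voxels with
#' non-finite signal are skipped and flagged. The quality mask excludes,
#' inside the brain mask, voxels that did not converge, voxels whose
#' macroscopic-field attenuation at the last echo falls below
#' \code{opts$f_macro_floor}, and -- when \code{opts$noise_sigma} is given
#' -- voxels whose expected last-echo SNR is below \code{opts$snr_floor} or
#' whose residual RMS exceeds \code{opts$residual_mult * noise_sigma}.
#'
#' @param image A \code{\link{multi_echo_image}}.
#' @param field Optional \code{field_gradient_map} from
#'   \code{\link{estimate_field}}; when \code{NULL} the gradient is taken
#'   as zero everywhere.
#' @param opts A \code{\link{fit_options}} object.
#' @return An object of class \code{qmaps}: 3D arrays \code{s0_map},
#'   \code{r2t_star_map}, \code{zeta_map}, \code{delta_omega_map},
#'   \code{residual_rms_map}, logical \code{converged_mask} and
#'   \code{quality_mask}, plus the acquisition parameters.
#' @export
fit_volume <- function(image, field = NULL, opts = fit_options()) {
  stopifnot(inherits(image, "multi_echo_image"))
  dm <- dim(image$magnitude)
  sp <- dm[1:3]
  if (!is.null(field)) {
    if (!identical(dim(field$g_through), sp))
      stop("field map dimensions do not match the image")
    gmap <- field$g_through
  } else {
    gmap <- array(0, sp)
  }
  te <- echo_times(image$acq)
  dz <- image$acq$voxel_size[3]
  mask_idx <- which(image$brain_mask)
  nv <- prod(sp)
  mag <- matrix(image$magnitude, nrow = nv)

  empty <- array(NA_real_, sp)
  out <- list(s0_map = empty, r2t_star_map = empty, zeta_map = empty,
              delta_omega_map = empty, residual_rms_map = empty,
              converged_mask = array(FALSE, sp),
              quality_mask = array(FALSE, sp),
              acq = image$acq)
  for (i in mask_idx) {
    sig <- mag[i, ]
    if (any(!is.finite(sig))) next  # skipped voxel: stays out of quality mask
    g <- gmap[i]
    if (is.na(g)) g <- 0
    fit <- fit_voxel(sig, te, g_through = g, slab_thickness = dz, opts = opts)
    out$s0_map[i] <- fit$s0
    out$r2t_star_map[i] <- fit$r2t_star
    out$zeta_map[i] <- fit$zeta
    out$delta_omega_map[i] <- fit$delta_omega
    out$residual_rms_map[i] <- fit$residual_rms
    out$converged_mask[i] <- fit$converged
    ok <- fit$converged
    if (ok) {
      fm_last <- f_macro(te[length(te)], g, dz)
      ok <- fm_last >= opts$f_macro_floor
      if (ok && !is.null(opts$noise_sigma)) {
        s_last <- fit$s0 * exp(-fit$r2t_star * te[length(te)])
        ok <- (s_last / opts$noise_sigma >= opts$snr_floor) &&
          (fit$residual_rms <= opts$residual_mult * opts$noise_sigma)
      }
    }
    out$quality_mask[i] <- ok
  }
  class(out) <- "qmaps"
  out
}

#' @export
print.qmaps <- function(x, ...) {
  n_fit <- sum(!is.na(x$r2t_star_map))
  cat("qmaps:", paste(dim(x$r2t_star_map), collapse = " x "),
      "|", n_fit, "fitted voxels,", sum(x$quality_mask), "pass quality\n")
  if (n_fit > 0)
    cat("  R2t* median:",
        signif(stats::median(x$r2t_star_map[x$quality_mask]), 4), "s^-1\n")
  invisible(x)
}

#' Write quantitative maps as NIfTI volumes
#'
#' One NIfTI file per map (\code{<prefix>_<map>.nii}) plus a small JSON
#' provenance sidecar.
#'
#' @param qmaps A \code{qmaps} object from \code{\link{fit_volume}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_qmaps <- function(qmaps, prefix) {
  vs <- qmaps$acq$voxel_size
  maps <- c("s0_map", "r2t_star_map", "zeta_map", "delta_omega_map",
            "residual_rms_map", "converged_mask", "quality_mask")
  files <- vapply(maps, function(nm) {
    arr <- qmaps[[nm]]
    if (is.logical(arr)) arr <- arr + 0L
    path <- paste0(prefix, "_", sub("_map$", "", nm), ".nii")
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(vs, 1)), path)
    path
  }, character(1))
  meta <- list(maps = unname(files), n_quality = sum(qmaps$quality_mask))
  jsonlite::write_json(meta, paste0(prefix, "_qmaps.json"), auto_unbox = TRUE)
  invisible(unname(files))
}
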