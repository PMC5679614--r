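acq <- acq_params()
te <- echo_times(acq)

test_that("navigator correction round-trips injected drift and flags bad input", {
  clean <- make_phantom(phantom_spec(seed = 5, snr = Inf, nav_amplitude = 0))
  drift <- make_phantom(phantom_spec(seed = 5, snr = Inf, nav_amplitude = 0.4))

  # the drift really ghosts the magnitude image
  expect_gt(max(abs(drift$image$magnitude - clean$image$magnitude)), 1)

  corr <- navigator_correct(drift$image, drift$nav)
  expect_lt(max(abs(corr$magnitude - clean$image$magnitude)), 1e-10)
  bright <- clean$image$magnitude > 1
  ph_res <- Arg(exp(1i * (corr$phase - clean$image$phase)))
  expect_lt(max(abs(ph_res[bright])), 1e-10)

  # zero navigator phases: exact identity
  same <- navigator_correct(clean$image, rep(0, dim(clean$image$phase)[2]))
  expect_identical(same$magnitude, clean$image$magnitude)

  # a spatially varying phase violates the zeroth-order model and survives
  psi <- 0.2  # constant extra phase on one x-half: not a per-excitation global
  half <- clean$image
  sel <- array(FALSE, dim(half$phase))
  sel[1:8, , , ] <- TRUE
  half$phase[sel] <- half$phase[sel] + psi
  cor2 <- navigator_correct(half, rep(0.0, dim(half$phase)[2]))
  res <- Arg(exp(1i * (cor2$phase - clean$image$phase)))
  expect_equal(max(abs(res[sel & bright])), psi, tolerance = 1e-10)

  mag_only <- multi_echo_image(clean$image$magnitude, acq = clean$image$acq)
  expect_error(navigator_correct(mag_only, drift$nav), "magnitude-only")
  expect_error(navigator_correct(clean$image, rep(0, 3)), "excitations")
})

test_that("field estimation recovers constant offsets, ramps and wrapped phases", {
  g <- c(12L, 12L, 8L)
  mk_phase_image <- function(b0_fun) {
    vs <- c(1, 1, 2)
    zs <- (seq_len(g[3]) - (g[3] + 1) / 2) * vs[3]
    b0 <- array(0, g)
    for (k in seq_len(g[3])) b0[, , k] <- b0_fun(zs[k])
    mag <- array(100, c(g, 10))
    ph <- array(0, c(g, 10))
    for (e in 1:10) ph[, , , e] <- Arg(exp(1i * 2 * pi * b0 * te[e]))
    list(img = multi_echo_image(mag, ph, acq = acq), b0 = b0)
  }

  # constant 10 Hz offset
  const <- mk_phase_image(function(z) 10)
  f <- estimate_field(const$img)
  expect_equal(max(abs(f$b0_map - 10)), 0, tolerance = 1e-8)
  expect_equal(max(abs(f$g_through)), 0, tolerance = 1e-8)

  # 4 Hz/mm ramp along z: exact in interior and at one-sided edges
  ramp <- mk_phase_image(function(z) 4 * z)
  f2 <- estimate_field(ramp$img)
  expect_equal(max(abs(f2$b0_map - ramp$b0)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f2$g_through - 4)), 0, tolerance = 1e-8)

  # 100 Hz offset wraps between 4 ms echoes (|dphi| > pi); temporal
  # unwrapping recovers it (unambiguous below 1/(2*dTE) = 125 Hz)
  wrap <- mk_phase_image(function(z) 100)
  f3 <- estimate_field(wrap$img)
  expect_equal(max(abs(f3$b0_map - 100)), 0, tolerance = 1e-6)

  few <- multi_echo_image(array(1, c(g, 4)), array(0, c(g, 4)),
                          acq = acq_params(n_echoes = 4))
  expect_no_error(estimate_field(few))
  mag_only <- multi_echo_image(array(1, c(g, 10)), acq = acq)
  expect_error(estimate_field(mag_only), "phase")
})

test_that("log-linear initialization is exact without BOLD and biased high with it", {
  sig <- forward_signal(100, 15, zeta = 0, g_through = 0, te = te)
  init <- init_loglinear(sig, te)
  expect_equal(init$s0, 100, tolerance = 1e-10)
  expect_equal(init$r2t_star, 15, tolerance = 1e-10)

  flat <- init_loglinear(rep(42, 10), te)
  expect_equal(flat$r2t_star, 0)

  # with a BOLD term the slope excess equals the OLS projection of
  # zeta * f_s(domega * te) onto te
  sig_b <- forward_signal(100, 15, zeta = 0.02, delta_omega = 80,
                          g_through = 0, te = te)
  init_b <- init_loglinear(sig_b, te)
  tc <- te - mean(te)
  fsv <- 0.02 * fs_static_dephasing(80 * te, method = "quadrature")
  excess <- sum(tc * (fsv - mean(fsv))) / sum(tc * tc)
  expect_gt(init_b$r2t_star, 15)
  expect_equal(init_b$r2t_star, 15 + excess, tolerance = 1e-10)

  expect_error(init_loglinear(c(1, -1, rep(1, 8)), te), "positive")
  expect_error(init_loglinear(1:5, te), "lengths")
})

test_that("voxel fit recovers noiseless truths over a parameter grid", {
  opts <- fit_options()
  for (r2t in c(10, 15, 20)) {
    for (zeta in c(0, 0.01, 0.03)) {
      sig <- forward_signal(100, r2t, zeta = zeta, delta_omega = 70,
                            g_through = 0, te = te)
      fit <- fit_voxel(sig, te, opts = opts)
      expect_true(fit$converged)
      expect_equal(fit$r2t_star, r2t, tolerance = 1e-5)
      expect_equal(fit$s0, 100, tolerance = 1e-5)
      expect_equal(fit$zeta, zeta, tolerance = 1e-5)
    }
  }
})

test_that("voxel fit degenerates gracefully and validates inputs", {
  # zeta = 0 truth: zeta estimate vanishes and r2t matches the log-linear
  # solution (which is exact here)
  sig <- forward_signal(100, 15, zeta = 0, g_through = 0, te = te)
  fit <- fit_voxel(sig, te, opts = fit_options())
  expect_equal(fit$zeta, 0, tolerance = 1e-8)
  expect_equal(fit$r2t_star, init_loglinear(sig, te)$r2t_star,
               tolerance = 1e-8)

  expect_error(fit_voxel(sig[1:5], te, opts = fit_options()), "lengths")
  expect_error(fit_voxel(c(sig[1:9], NaN), te, opts = fit_options()),
               "non-finite")
  expect_error(fit_voxel(sig[1:3], te[1:3], opts = fit_options()), "echoes")

  # joint zeta + delta_omega mode also recovers a noiseless voxel
  sig_j <- forward_signal(100, 18, zeta = 0.03, delta_omega = 90,
                          g_through = 0, te = te)
  fit_j <- fit_voxel(sig_j, te,
                     opts = fit_options(mode = "fit_zeta_and_delta_omega"))
  expect_equal(fit_j$r2t_star, 18, tolerance = 1e-4)
  expect_equal(fit_j$delta_omega, 90, tolerance = 1e-2)
})

test_that("macroscopic-field term can enter as model factor or pre-correction", {
  sig <- forward_signal(100, 18, zeta = 0.015, delta_omega = 70,
                        g_through = 4, slab_thickness = 2, te = te)
  fit_model <- fit_voxel(sig, te, g_through = 4, slab_thickness = 2,
                         opts = fit_options(macro_mode = "model"))
  fit_pre <- fit_voxel(sig, te, g_through = 4, slab_thickness = 2,
                       opts = fit_options(macro_mode = "precorrect"))
  fit_none <- fit_voxel(sig, te, g_through = 4, slab_thickness = 2,
                        opts = fit_options(macro_mode = "none"))
  expect_equal(fit_model$r2t_star, 18, tolerance = 1e-6)
  expect_equal(fit_pre$r2t_star, 18, tolerance = 1e-6)
  # ignoring the attenuation leaves a substantial bias (part of the sinc
  # decay aliases into the BOLD term, so the net shift can go either way)
  expect_gt(abs(fit_none$r2t_star - 18), 0.5)
})

test_that("volume fit reproduces per-voxel fits, honors masks and flags quality", {
  ph <- noiseless_phantom()
  img <- ph$image
  qm <- fit_volume(img, NULL, fit_options())
  mask <- img$brain_mask
  expect_true(all(qm$converged_mask[mask]))
  expect_equal(max(abs(qm$r2t_star_map[mask] - ph$truth$r2t_star_map[mask])),
               0, tolerance = 1e-5)
  expect_true(all(qm$r2t_star_map[qm$quality_mask] >= 0))
  expect_true(all(is.na(qm$r2t_star_map[!mask])))

  # result equals independent per-voxel fits (traversal-order independence)
  idx <- which(mask)[c(1, 50, 400)]
  mag <- matrix(img$magnitude, nrow = prod(dim(mask)))
  for (i in idx) {
    fv <- fit_voxel(mag[i, ], te, opts = fit_options())
    expect_identical(qm$r2t_star_map[i], fv$r2t_star)
  }

  # two runs are bit-identical
  qm2 <- fit_volume(img, NULL, fit_options())
  expect_identical(qm$r2t_star_map, qm2$r2t_star_map)

  # empty mask: nothing fitted
  img0 <- img
  img0$brain_mask[] <- FALSE
  qm0 <- fit_volume(img0, NULL, fit_options())
  expect_true(all(is.na(qm0$r2t_star_map)))
  expect_false(any(qm0$quality_mask))

  # voxels under a strong through-slab gradient drop out of quality
  field <- list(b0_map = array(0, dim(mask)),
                g_through = array(0, dim(mask)))
  field$g_through[8, 8, 4] <- 40  # sinc(40*2*0.04) ~ 0.09 < 0.3 floor
  class(field) <- "field_gradient_map"
  qm3 <- fit_volume(img, field, fit_options(macro_mode = "model"))
  expect_false(qm3$quality_mask[8, 8, 4])
})
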