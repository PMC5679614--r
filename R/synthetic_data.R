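with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Describes a piecewise-constant digital phantom: a bordered grid split
#' into left/right hemispheres along x, a CSF slab, and one box-shaped
#' region per (region, hemisphere) pair tiled along y. Per-region tissue
#' truths, a smooth polynomial B0 field with a through-slice component,
#' a sinusoidal per-excitation navigator phase drift, and complex Gaussian
#' noise parameterized as 1/SNR of the mean tissue signal magnitude.
#'
#' @param grid Integer length-3 grid shape; default \code{c(16, 16, 8)}
#'   keeps round-trip tests fast, full-size geometry is available by
#'   passing a larger grid.
#' @param regions data.frame with columns \code{region_name},
#'   \code{hemisphere}, \code{r2t_star} (s^-1) and optionally \code{zeta},
#'   \code{s0}; defaults to the limbic region set at tissue-like values
#'   (15-20 s^-1).
#' @param csf_r2t_star CSF relaxation rate, s^-1 (about 1 in pure fluid).
#' @param csf_s0 CSF signal magnitude.
#' @param zeta,delta_omega Default BOLD parameters for tissue regions.
#' @param s0 Default tissue signal magnitude.
#' @param b0_coef Named numeric vector of B0 polynomial coefficients
#'   (\code{const} Hz, \code{x}, \code{y}, \code{z} Hz/mm, \code{z2}
#'   Hz/mm^2), evaluated on voxel-center coordinates in mm.
#' @param nav_amplitude,nav_frequency Navigator drift amplitude (rad) and
#'   frequency (Hz); the drift is \code{A * sin(2 pi f * t_exc)} with one
#'   excitation per phase-encode row spaced by TR.
#' @param snr Signal-to-noise ratio; complex Gaussian noise with
#'   \code{sigma = mean(tissue s0)/snr} per real/imaginary channel.
#'   \code{Inf} for noiseless.
#' @param acq An \code{\link{acq_params}} object.
#' @param seed Mandatory integer seed.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid = c(16L, 16L, 8L), regions = NULL,
                         csf_r2t_star = 1, csf_s0 = 120,
                         zeta = 0.015, delta_omega = 70, s0 = 100,
                         b0_coef = c(const = 2, x = 0.1, y = 0.1,
                                     z = 0.5, z2 = 0),
                         nav_amplitude = 0.3, nav_frequency = 0.3,
                         snr = 50, acq = acq_params(), seed) {
  if (missing(seed)) stop("phantom_spec: seed is mandatory")
  stopifnot(length(grid) == 3, all(grid >= 6), snr > 0)
  if (is.null(regions)) {
    rn <- limbic_regions()
    base <- seq(15, 20, length.out = length(rn))
    regions <- data.frame(
      region_name = rep(rn, each = 2),
      hemisphere = rep(c("left", "right"), length(rn)),
      r2t_star = rep(base, each = 2),
      stringsAsFactors = FALSE)
  }
  if (is.null(regions$zeta)) regions$zeta <- zeta
  if (is.null(regions$s0)) regions$s0 <- s0
  structure(list(grid = as.integer(grid), regions = regions,
                 csf_r2t_star = csf_r2t_star, csf_s0 = csf_s0,
                 zeta = zeta, delta_omega = delta_omega, s0 = s0,
                 b0_coef = b0_coef, nav_amplitude = nav_amplitude,
                 nav_frequency = nav_frequency, snr = snr, acq = acq,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_label_map <- function(spec) {
  g <- spec$grid
  labels <- array(0L, g)
  regions <- unique(spec$regions[, c("region_name", "hemisphere")])
  tab <- data.frame(label_id = integer(0), region_name = character(0),
                    hemisphere = character(0), stringsAsFactors = FALSE)
  # interior excludes a 1-voxel border; x splits hemispheres, z = 2 is CSF
  x_left <- 2:(floor(g[1] / 2))
  x_right <- (floor(g[1] / 2) + 1):(g[1] - 1)
  y_int <- 2:(g[2] - 1)
  z_csf <- 2L
  z_tis <- 3:(g[3] - 1)
  csf_id <- 1000L
  labels[c(x_left, x_right), y_int, z_csf] <- csf_id
  tab <- rbind(tab, data.frame(label_id = csf_id, region_name = "csf",
                               hemisphere = "none", stringsAsFactors = FALSE))
  rn <- unique(regions$region_name)
  n_reg <- length(rn)
  # partition the interior y range into one strip per region
  bounds <- round(seq(y_int[1] - 1, y_int[length(y_int)],
                      length.out = n_reg + 1))
  next_id <- 1L
  for (i in seq_len(n_reg)) {
    ys <- (bounds[i] + 1):bounds[i + 1]
    for (hemi in c("left", "right")) {
      if (!any(regions$region_name == rn[i] & regions$hemisphere == hemi))
        next
      xs <- if (hemi == "left") x_left else x_right
      labels[xs, ys, z_tis] <- next_id
      tab <- rbind(tab, data.frame(label_id = next_id, region_name = rn[i],
                                   hemisphere = hemi,
                                   stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
  }
  roi_label_map(labels, tab)
}

#' Generate a multi-echo phantom with known ground truth
#'
#' Synthesizes the complex multi-echo signal voxel by voxel from the
#' forward decay model: \code{forward_signal} magnitude (including the BOLD
#' term and the through-slice sinc attenuation implied by the B0 field's
#' z-gradient) times \code{exp(i 2 pi B0 TE)}, with the per-excitation
#' navigator phase drift applied to the k-space line each excitation
#' acquires (ghosting the magnitude image until corrected), plus complex
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List with \code{image} (a \code{\link{multi_echo_image}}),
#'   \code{nav} (the injected navigator phase trace, radians, one per
#'   phase-encode row), \code{truth} (qmaps-style ground-truth arrays:
#'   \code{s0_map}, \code{r2t_star_map}, \code{zeta_map},
#'   \code{delta_omega_map}, \code{b0_map}, \code{g_through}) and
#'   \code{label_map} (an \code{\link{roi_label_map}}).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    g <- spec$grid
    acq <- spec$acq
    te <- echo_times(acq)
    vs <- acq$voxel_size
    label_map <- phantom_label_map(spec)
    labels <- label_map$labels
    tab <- label_map$label_table

    s0_map <- array(0, g)
    r2t_map <- array(0, g)
    zeta_map <- array(0, g)
    for (i in seq_len(nrow(tab))) {
      sel <- labels == tab$label_id[i]
      if (tab$region_name[i] == "csf") {
        s0_map[sel] <- spec$csf_s0
        r2t_map[sel] <- spec$csf_r2t_star
        zeta_map[sel] <- 0
      } else {
        row <- spec$regions[spec$regions$region_name == tab$region_name[i] &
                            spec$regions$hemisphere == tab$hemisphere[i], ]
        s0_map[sel] <- row$s0[1]
        r2t_map[sel] <- row$r2t_star[1]
        zeta_map[sel] <- row$zeta[1]
      }
    }
    mask <- labels > 0

    # voxel-center world coordinates in mm, centered on the grid
    xs <- (seq_len(g[1]) - (g[1] + 1) / 2) * vs[1]
    ys <- (seq_len(g[2]) - (g[2] + 1) / 2) * vs[2]
    zs <- (seq_len(g[3]) - (g[3] + 1) / 2) * vs[3]
    co <- expand.grid(x = xs, y = ys, z = zs)
    bc <- spec$b0_coef
    getc <- function(nm) if (nm %in% names(bc)) bc[[nm]] else 0
    b0 <- getc("const") + getc("x") * co$x + getc("y") * co$y +
      getc("z") * co$z + getc("z2") * co$z^2
    b0_map <- array(b0, g)
    g_map <- array(getc("z") + 2 * getc("z2") * co$z, g)  # analytic dB0/dz

    nvox <- prod(g)
    fs_vec <- fs_static_dephasing(spec$delta_omega * te, method = "table")
    mag <- matrix(0, nvox, length(te))
    ph <- matrix(0, nvox, length(te))
    for (e in seq_along(te)) {
      fm <- f_macro(te[e], as.vector(g_map), vs[3])
      mag[, e] <- as.vector(s0_map) * exp(-as.vector(r2t_map) * te[e] -
                                          as.vector(zeta_map) * fs_vec[e]) * fm
      ph[, e] <- 2 * pi * b0 * te[e]
    }
    cplx <- mag * exp(1i * ph)
    # per-excitation navigator phase drift, applied to the k-space line
    # each excitation acquires (one line per TR along the phase-encode axis)
    t_exc <- (seq_len(g[2]) - 1) * acq$tr
    nav <- spec$nav_amplitude * sin(2 * pi * spec$nav_frequency * t_exc)
    if (any(nav != 0)) {
      cplx4 <- array(cplx, c(g, length(te)))
      cplx <- matrix(apply_excitation_phase(cplx4, nav, sign = +1),
                     nvox, length(te))
    }
    if (is.finite(spec$snr)) {
      sigma <- mean(s0_map[mask & r2t_map > 5]) / spec$snr
      if (!is.finite(sigma)) sigma <- mean(s0_map[mask]) / spec$snr
      noise <- matrix(stats::rnorm(nvox * length(te), 0, sigma), nvox) +
        1i * matrix(stats::rnorm(nvox * length(te), 0, sigma), nvox)
      cplx <- cplx + noise
    } else sigma <- 0

    image <- multi_echo_image(
      magnitude = array(Mod(cplx), c(g, length(te))),
      phase = array(Arg(cplx), c(g, length(te))),
      acq = acq, brain_mask = mask)

    truth <- list(s0_map = s0_map, r2t_star_map = r2t_map,
                  zeta_map = zeta_map,
                  delta_omega_map = array(spec$delta_omega, g),
                  b0_map = b0_map, g_through = g_map,
                  noise_sigma = sigma)
    list(image = image, nav = nav, truth = truth, label_map = label_map)
  })
}

default_region_truths <- function() {
  rn <- limbic_regions()
  # HC mean R2t* (s^-1) and normalized volume (mm^3) per region; volumes
  # are plausible bilateral-structure scales, values vary by region
  r2t <- c(16.8, 17.5, 16.0, 17.0, 15.5, 16.3, 16.1, 17.2, 16.6, 16.9, 17.4)
  nv <- c(3800, 1600, 2100, 6500, 1800, 7500, 5200, 2000, 2400, 2600, 3100)
  data.frame(region_name = rep(rn, each = 2),
             hemisphere = rep(c("left", "right"), length(rn)),
             hc_r2t_star = rep(r2t, each = 2),
             hc_nv = rep(nv, each = 2),
             stringsAsFactors = FALSE)
}

#' Cohort specification
#'
#' Defines a synthetic study cohort emulating a healthy-control versus
#' multiple-sclerosis design: group sizes (defaults 31 HC, 32 RRMS, 32
#' SPMS, 16 PPMS), age and gender composition per group, per-region healthy
#' means, designed group deficits on R2t* (s^-1) and on normalized volume
#' (fractional), and designed covariate-adjusted correlations between
#' chosen (region, hemisphere, measure) cells and clinical scores.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param region_truths data.frame with \code{region_name},
#'   \code{hemisphere}, \code{hc_r2t_star}, \code{hc_nv}.
#' @param group_effect_r2t Named numeric: additive R2t* shift per MS group
#'   (s^-1, negative = deficit).
#' @param group_effect_nv Named numeric: fractional normalized-volume shift
#'   per MS group.
#' @param age_slope_r2t R2t* change per year of age, s^-1/yr.
#' @param subject_sd_r2t Between-subject SD of regional R2t*, s^-1.
#' @param subject_sd_nv Fractional between-subject SD of normalized volume.
#' @param score_targets data.frame of designed couplings with columns
#'   \code{score}, \code{region_name}, \code{hemisphere}, \code{measure}
#'   ("R2t*" or "NV") and \code{rho} (target covariate-adjusted
#'   correlation); scores not listed are generated with zero designed
#'   coupling. Defaults couple SDMT and PASAT2 to limbic R2t* and EDSS
#'   (negatively) to right-amygdala R2t*, mirroring the direction of the
#'   clinical effects the generator emulates.
#' @param n_right_handed Number of right-handed MS subjects (rest are
#'   left-handed); default 73 of 80.
#' @param prop_treated Probability an MS subject is on treatment.
#' @param seed Mandatory integer seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_per_group = c(HC = 31L, RRMS = 32L, SPMS = 32L,
                                        PPMS = 16L),
                        region_truths = default_region_truths(),
                        group_effect_r2t = c(RRMS = -0.3, SPMS = -0.9,
                                             PPMS = -0.5),
                        group_effect_nv = c(RRMS = -0.03, SPMS = -0.09,
                                            PPMS = -0.05),
                        age_slope_r2t = -0.01,
                        subject_sd_r2t = 0.6,
                        subject_sd_nv = 0.07,
                        score_targets = data.frame(
                          score = c("SDMT", "PASAT2", "EDSS"),
                          region_name = c("hippocampus", "amygdala", "amygdala"),
                          hemisphere = c("left", "left", "right"),
                          measure = c("R2t*", "R2t*", "R2t*"),
                          rho = c(0.4, 0.36, -0.29),
                          stringsAsFactors = FALSE),
                        n_right_handed = 73L,
                        prop_treated = 0.75,
                        seed) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory")
  if (!is.null(score_targets) && nrow(score_targets) > 0 &&
      any(abs(score_targets$rho) >= 1))
    stop("target correlations must lie in (-1, 1)")
  structure(list(n_per_group = n_per_group, region_truths = region_truths,
                 group_effect_r2t = group_effect_r2t,
                 group_effect_nv = group_effect_nv,
                 age_slope_r2t = age_slope_r2t,
                 subject_sd_r2t = subject_sd_r2t,
                 subject_sd_nv = subject_sd_nv,
                 score_targets = score_targets,
                 n_right_handed = as.integer(n_right_handed),
                 prop_treated = prop_treated,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Group x gender composition and age moments emulating the study
# demographics (age in years; mean/sd per group x gender).
cohort_demographics <- function() {
  list(
    gender_f = c(HC = 21, RRMS = 27, SPMS = 20, PPMS = 10),
    age_mean = list(HC = c(F = 53.0, M = 42.2), RRMS = c(F = 54.7, M = 51.8),
                    SPMS = c(F = 57.5, M = 56.7), PPMS = c(F = 56.4, M = 53.5)),
    age_sd = list(HC = c(F = 14.5, M = 17.2), RRMS = c(F = 8.0, M = 16.3),
                  SPMS = c(F = 8.7, M = 10.8), PPMS = c(F = 8.6, M = 10.4)))
}

score_models <- function() {
  # base mean/SD of the raw scores in MS plus an age effect; latent scores
  # for the skewed tests are transformed monotonically afterwards
  data.frame(
    score = c("PASAT3", "PASAT2", "SDMT", "EDSS", "T25FW",
              "NHPT_dom", "NHPT_nondom"),
    mean = c(46, 34, 49, 0, 0, 0, 0),
    sd = c(11, 10, 12, 1, 1, 1, 1),
    age_coef = c(-0.15, -0.15, -0.30, 0.02, 0.02, 0.02, 0.02),
    latent = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# monotone transforms from a latent standard-normal scale to plausible
# skewed clinical supports
latent_transform <- function(score, z) {
  switch(score,
         EDSS = pmin(10, pmax(0, round((4 + 1.6 * z) * 2) / 2)),
         T25FW = 6 * exp(0.5 * z),
         NHPT_dom = 25 * exp(0.35 * z),
         NHPT_nondom = 26 * exp(0.35 * z),
         stop("unknown latent score ", score))
}

#' Generate a synthetic cohort with designed effects
#'
#' Draws demographics (group, age, gender, lesion load, treatment,
#' handedness), per-subject regional truths (healthy mean + group effect +
#' age slope + subject noise for R2t*; fractional effects for normalized
#' volume), and clinical scores built to carry designed covariate-adjusted
#' correlations: for a designed cell the score loads on the empirical
#' covariate-residual of that cell's values with weight \eqn{\rho} and on
#' independent noise with weight \eqn{\sqrt{1-\rho^2}}, so the partial
#' correlation is centered on the target. Skewed scores (EDSS, timed walk,
#' peg test) are produced by monotone transforms of a latent Gaussian so
#' rank-based analyses are exercised. Scores are missing for HC.
#' Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List with \code{cohort} (one row per subject) and
#'   \code{summaries} (region-summary truth rows: \code{subject_id},
#'   \code{region_name}, \code{hemisphere}, \code{median_r2t_star},
#'   \code{n_voxels}, \code{volume_mm3}, \code{normalized_volume},
#'   \code{scaling_factor}).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    demo <- cohort_demographics()
    groups <- names(spec$n_per_group)
    subj <- list()
    for (g in groups) {
      n <- spec$n_per_group[[g]]
      # female share follows the emulated study composition, scaled to n
      design_n <- c(HC = 31, RRMS = 32, SPMS = 32, PPMS = 16)
      frac_f <- if (g %in% names(design_n))
        demo$gender_f[[g]] / design_n[[g]] else 0.6
      n_f <- max(min(n - 1L, round(frac_f * n)), 1L)
      if (n < 2L) n_f <- n
      gender <- c(rep("F", n_f), rep("M", n - n_f))
      age <- numeric(n)
      for (i in seq_len(n)) {
        m <- demo$age_mean[[g]][[gender[i]]]
        s <- demo$age_sd[[g]][[gender[i]]]
        age[i] <- min(90, max(20, stats::rnorm(1, m, s)))
      }
      subj[[g]] <- data.frame(group = g, gender = gender, age = age,
                              stringsAsFactors = FALSE)
    }
    cohort <- do.call(rbind, subj)
    n_total <- nrow(cohort)
    cohort$subject_id <- sprintf("sub-%03d", seq_len(n_total))
    is_ms <- cohort$group != "HC"
    n_ms <- sum(is_ms)
    cohort$lesion_load <- NA_real_
    cohort$lesion_load[is_ms] <- stats::rlnorm(n_ms, log(8), 0.8)
    cohort$treatment <- 0L
    cohort$treatment[is_ms] <- stats::rbinom(n_ms, 1, spec$prop_treated)
    hand <- rep("right", n_total)
    n_left <- max(0, n_ms - spec$n_right_handed)
    if (n_left > 0)
      hand[sample(which(is_ms), n_left)] <- "left"
    cohort$handedness <- hand

    # regional truths
    rt <- spec$region_truths
    n_reg <- nrow(rt)
    age_c <- cohort$age - 50
    summaries <- list()
    scaling <- stats::rnorm(n_total, 1, 0.04)
    scaling[scaling < 0.8] <- 0.8
    for (i in seq_len(n_reg)) {
      ge_r2t <- ifelse(is_ms, spec$group_effect_r2t[cohort$group], 0)
      ge_nv <- ifelse(is_ms, spec$group_effect_nv[cohort$group], 0)
      r2t <- rt$hc_r2t_star[i] + ge_r2t + spec$age_slope_r2t * age_c +
        stats::rnorm(n_total, 0, spec$subject_sd_r2t)
      nv <- rt$hc_nv[i] * (1 + ge_nv - 0.002 * age_c +
                             stats::rnorm(n_total, 0, spec$subject_sd_nv))
      summaries[[i]] <- data.frame(
        subject_id = cohort$subject_id,
        region_name = rt$region_name[i], hemisphere = rt$hemisphere[i],
        median_r2t_star = r2t, n_voxels = NA_integer_,
        volume_mm3 = nv / scaling, normalized_volume = nv,
        scaling_factor = scaling, stringsAsFactors = FALSE)
    }
    summaries <- do.call(rbind, summaries)

    # clinical scores for MS subjects with designed partial correlations
    ms <- cohort[is_ms, ]
    C <- cbind(age = ms$age,
               gender = as.numeric(ms$gender == "M"),
               lesion_load = ms$lesion_load,
               treatment = ms$treatment)
    # degenerate small cohorts can make a dummy constant; drop it from the
    # coupling model (the battery itself still errors informatively)
    C <- C[, apply(C, 2, function(col) stats::sd(col) > 0), drop = FALSE]
    mcol <- c(`R2t*` = "median_r2t_star", NV = "normalized_volume")
    sm <- score_models()
    targets <- spec$score_targets
    for (si in seq_len(nrow(sm))) {
      sc <- sm$score[si]
      tgt_name <- if (sc %in% c("NHPT_dom", "NHPT_nondom")) "NHPT" else sc
      tgt <- NULL
      if (!is.null(targets) && any(targets$score == tgt_name)) {
        tgt <- targets[which(targets$score == tgt_name)[1], , drop = FALSE]
        # peg-test lateralization: dominant hand pairs with the left
        # hemisphere, non-dominant with the right
        if (tgt_name == "NHPT")
          tgt$hemisphere <- if (sc == "NHPT_dom") "left" else "right"
      }
      eta <- stats::rnorm(n_ms)
      if (!is.null(tgt) && nrow(tgt) == 1) {
        cell <- summaries[summaries$region_name == tgt$region_name &
                          summaries$hemisphere == tgt$hemisphere, ]
        x <- cell[[mcol[[tgt$measure]]]][match(ms$subject_id, cell$subject_id)]
        rx <- residualize(x, C)
        core <- tgt$rho * rx / stats::sd(rx) +
          sqrt(1 - tgt$rho^2) * eta
      } else core <- eta
      raw <- sm$mean[si] + sm$age_coef[si] * (ms$age - 50) + sm$sd[si] * core
      if (sm$latent[si]) raw <- latent_transform(sc, raw)
      cohort[[sc]] <- NA_real_
      cohort[[sc]][is_ms] <- raw
    }
    # z-scores from fixed normative anchors (published-control convention)
    for (sc in c("PASAT3", "PASAT2", "SDMT")) {
      si <- match(sc, sm$score)
      cohort[[paste0(sc, "_z")]] <- (cohort[[sc]] - sm$mean[si]) / sm$sd[si]
    }
    rownames(cohort) <- NULL
    list(cohort = cohort, summaries = summaries)
  })
}

#' Write a complete miniature study to disk
#'
#' Builds a cohort with \code{\link{make_cohort}}, then one phantom per
#' subject whose per-region R2t* truths are that subject's cohort truth
#' rows, and writes everything the pipeline consumes: per-subject
#' multi-echo NIfTI volumes with JSON echo-time sidecars, navigator traces,
#' a shared ROI label volume + TSV table, per-subject skull scaling
#' factors, the cohort TSV and a truth-summary TSV.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the whole fixture.
#' @param cohort_args Optional list of overrides passed to
#'   \code{\link{cohort_spec}}.
#' @param grid Phantom grid shape.
#' @param snr Phantom signal-to-noise ratio. The default (300) is chosen so
#'   that the regional median's sampling error at the reduced grid's region
#'   sizes (about 35-70 voxels) matches the error that an SNR-50
#'   acquisition yields at anatomical region sizes (thousands of voxels):
#'   the median's standard error scales as the voxelwise error over the
#'   square root of the region voxel count, and the reduced grid shrinks
#'   regions roughly 50-fold.
#' @param region_set Regions included in the phantoms; defaults to the full
#'   limbic set.
#' @return Invisibly, a list with the fixture paths and the generating
#'   truth objects.
#' @export
make_end_to_end_fixture <- function(dir, seed, cohort_args = list(),
                                    grid = c(16L, 16L, 8L), snr = 300,
                                    region_set = limbic_regions()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cspec <- do.call(cohort_spec, c(list(seed = seed), cohort_args))
  cs <- make_cohort(cspec)
  cohort <- cs$cohort
  truth_sum <- cs$summaries
  truth_sum <- truth_sum[truth_sum$region_name %in% region_set, ]

  # shared geometry: one label map for all subjects
  proto <- phantom_spec(grid = grid, seed = seed,
                        regions = data.frame(
                          region_name = rep(region_set, each = 2),
                          hemisphere = rep(c("left", "right"),
                                           length(region_set)),
                          r2t_star = 17, stringsAsFactors = FALSE))
  label_map <- phantom_label_map(proto)
  write_label_map(label_map, file.path(dir, "labels.nii"),
                  file.path(dir, "labels.tsv"),
                  voxel_size = proto$acq$voxel_size)

  scaling <- unique(truth_sum[, c("subject_id", "scaling_factor")])
  utils::write.table(scaling, file.path(dir, "scaling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv(cohort, file.path(dir, "cohort.tsv"))
  write_tsv(truth_sum, file.path(dir, "truth_summaries.tsv"))

  subj_dir <- file.path(dir, "subjects")
  dir.create(subj_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    rows <- truth_sum[truth_sum$subject_id == sid, ]
    regions <- data.frame(region_name = rows$region_name,
                          hemisphere = rows$hemisphere,
                          r2t_star = pmax(5, rows$median_r2t_star),
                          stringsAsFactors = FALSE)
    pspec <- phantom_spec(grid = grid, regions = regions, snr = snr,
                          seed = seed + i)
    ph <- make_phantom(pspec)
    prefix <- file.path(subj_dir, sid)
    write_multi_echo(ph$image, prefix)
    utils::write.table(
      data.frame(excitation = seq_along(ph$nav), phase = ph$nav),
      paste0(prefix, "_nav.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(list(dir = dir, cohort = cohort, truth_summaries = truth_sum,
                 label_map = label_map, spec = cspec))
}
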