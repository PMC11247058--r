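# run expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generative ground truth for the synthetic cohort
#'
#' Defines the data-generating models the synthetic cohort is drawn from,
#' so that downstream estimates can be scored against known coefficients.
#' The observable models are linear in realized RBC and platelet content
#' (and clot diameter for the contrast-density increase), matching the
#' regression family the analysis fits. Coefficient defaults mirror the
#' multiple-regression estimates of the laboratory study this generator
#' emulates; the contraction model is the package's own parameterisation
#' of platelet-driven serum expulsion.
#'
#' Noise defaults represent instrument-level repeatability (CT: 3 HU at
#' the clot level; mechanics: additive per-feature scatter), not the much
#' larger biological clot-to-clot dispersion of real cohorts; see the
#' methods vignette.
#'
#' @param ncct Named list `beta0`, `beta_rbc`, `beta_plt`, `sd` for NCCT
#'   density (HU; slopes per % content).
#' @param cect Named list `gamma0`, `gamma_plt`, `gamma_diameter`, `sd`
#'   for CECT density increase (HU; diameter slope per mm).
#' @param mech Named list of four models (`low_strain_stiffness`,
#'   `high_strain_stiffness` in kPa; `hysteresis_loss`, `plastic_strain`
#'   in %), each `beta0`, `beta_rbc`, `beta_plt`, `sd`.
#' @param mech_noise_type `"additive"` (Gaussian, default) or
#'   `"multiplicative"` (lognormal factor with sdlog `mech_sdlog`).
#' @param mech_sdlog Lognormal sigma when `mech_noise_type` is
#'   multiplicative.
#' @param contraction Named list: `lambda` (serum-expulsion decay constant
#'   of platelet concentration, 10^3/ul), `s_min` (minimum retained serum
#'   fraction), `platelet_volume` (effective platelet-mesh volume fraction
#'   per 10^3 platelets/ul), `jitter_sd` (lognormal sd of clot-to-clot
#'   contraction variability).
#' @param softening Per-cycle stress softening factor of the cyclic
#'   compression response, in (0, 1].
#' @param syringe_diameters Initial clot diameters (mm) for the 3 ml and
#'   1 ml syringes; the 40% RBC-volume recipes use the smaller syringe.
#'
#' @return An object of class `generative_truth`.
#' @export
generative_truth <- function(
    ncct = list(beta0 = 17.32, beta_rbc = 0.35, beta_plt = 0.22, sd = 3),
    cect = list(gamma0 = 90, gamma_plt = 0.49, gamma_diameter = -10.23,
                sd = 3),
    mech = list(
      low_strain_stiffness = list(beta0 = -0.26, beta_rbc = -0.001,
                                  beta_plt = 0.09, sd = 0.05),
      high_strain_stiffness = list(beta0 = -1.973, beta_rbc = 0.54,
                                   beta_plt = 10.22, sd = 25),
      hysteresis_loss = list(beta0 = 80.97, beta_rbc = -0.21,
                             beta_plt = -0.35, sd = 3),
      plastic_strain = list(beta0 = 78.25, beta_rbc = -0.26,
                            beta_plt = -0.67, sd = 3)),
    mech_noise_type = c("additive", "multiplicative"),
    mech_sdlog = 0.15,
    contraction = list(lambda = 40, s_min = 0.002,
                       platelet_volume = 4.7e-5, jitter_sd = 0.2),
    softening = 0.95,
    syringe_diameters = c(large = 8.6, small = 4.7)) {
  structure(list(ncct = ncct, cect = cect, mech = mech,
                 mech_noise_type = match.arg(mech_noise_type),
                 mech_sdlog = mech_sdlog,
                 contraction = contraction, softening = softening,
                 syringe_diameters = syringe_diameters),
            class = "generative_truth")
}

#' Default factorial recipe design
#'
#' The 3 x 5 factorial: platelet concentrations 30, 90 and 270 x 10^3
#' platelets/ul crossed with volumetric RBC percentages 0, 0.5, 2, 5 and
#' 40%.
#'
#' @param platelet_concs Target platelet concentrations, 10^3/ul.
#' @param rbc_fractions Volumetric RBC fractions.
#' @param total_volume Reconstitution volume, ul.
#' @return Data frame with one row per design cell.
#' @export
default_design <- function(platelet_concs = c(30, 90, 270),
                           rbc_fractions = c(0, 0.005, 0.02, 0.05, 0.40),
                           total_volume = 1000) {
  d <- expand.grid(target_platelet_conc = platelet_concs,
                   rbc_volume_fraction = rbc_fractions,
                   KEEP.OUT.ATTRS = FALSE)
  d$total_volume <- total_volume
  d
}

#' Platelet-driven contraction model
#'
#' Maps a recipe (platelet concentration and RBC volume fraction) to the
#' retained-volume fraction and realized cellular content of the fully
#' contracted clot. Platelets pull on the fibrin network and expel serum:
#' the retained serum fraction decays exponentially with platelet
#' concentration down to a residual minimum, while the packed RBC volume
#' and an effective platelet-mesh volume are conserved. Content
#' percentages are the conserved component volumes over the retained
#' volume, so RBCs are concentrated by contraction.
#'
#' @param platelet_conc Platelet concentration(s), 10^3/ul.
#' @param rbc_fraction Volumetric RBC fraction(s).
#' @param contraction Contraction parameter list (see
#'   [generative_truth()]).
#' @param jitter_plt,jitter_serum Optional multiplicative (lognormal)
#'   variability factors for the platelet-mesh and serum volumes; default
#'   1 (deterministic).
#'
#' @return Data frame with `rbc_content`, `platelet_content` (% of
#'   retained volume, capped at 99.9 / 99.5) and `retained_fraction`.
#' @export
simulate_contraction <- function(platelet_conc, rbc_fraction,
                                 contraction = generative_truth()$contraction,
                                 jitter_plt = 1, jitter_serum = 1) {
  s <- contraction$s_min +
    (1 - contraction$s_min) * exp(-platelet_conc / contraction$lambda)
  v_rbc <- rbc_fraction
  v_plt <- contraction$platelet_volume * platelet_conc * jitter_plt
  v_ser <- pmax(1 - rbc_fraction - contraction$platelet_volume *
                  platelet_conc, 0) * s * jitter_serum
  phi <- v_rbc + v_plt + v_ser
  data.frame(rbc_content = pmin(100 * v_rbc / phi, 99.9),
             platelet_content = pmin(100 * v_plt / phi, 99.5),
             retained_fraction = phi)
}

#' Generate a synthetic clot cohort
#'
#' Crosses the recipe design with the donor panel, drops recipes that are
#' infeasible for a donor's PRP concentration (with the default donors and
#' design this yields the 87-clot cohort), realizes cellular content and
#' clot diameter through the contraction model, and draws the CT and
#' mechanical observables from the linear truth models plus noise.
#' Deterministic under a fixed seed.
#'
#' @param truth A [generative_truth()].
#' @param donors List of [donor_blood()] objects.
#' @param design Recipe design data frame (see [default_design()]).
#' @param seed Integer seed (optional).
#' @param flag_prob Probability that a clot is flagged as compromised
#'   (for example pre-deformed during handling before testing); default 0.
#'
#' @return A data frame of class `clot_cohort`, one row per clot, with the
#'   recipe, blending volumes, realized contents, diameter and the six
#'   observables; the truth object is attached as attribute `"truth"`.
#' @export
generate_cohort <- function(truth = generative_truth(),
                            donors = default_donors(),
                            design = default_design(),
                            seed = NULL, flag_prob = 0) {
  with_seed(seed, {
    rows <- list()
    for (d in donors) {
      g <- design
      g$donor_id <- d$donor_id
      g$prp_platelet_conc <- d$prp_platelet_conc
      rows[[length(rows) + 1]] <- g
    }
    cohort <- do.call(rbind, rows)
    cohort <- suppressMessages(blend_cohort(cohort, on_infeasible = "drop"))
    n <- nrow(cohort)
    cohort$clot_id <- sprintf("%s_P%03d_R%04.1f", cohort$donor_id,
                              cohort$target_platelet_conc,
                              100 * cohort$rbc_volume_fraction)
    ct <- truth$contraction
    jp <- exp(stats::rnorm(n, 0, ct$jitter_sd))
    js <- exp(stats::rnorm(n, 0, ct$jitter_sd))
    cc <- simulate_contraction(cohort$target_platelet_conc,
                               cohort$rbc_volume_fraction, ct, jp, js)
    cohort$rbc_content <- cc$rbc_content
    cohort$platelet_content <- cc$platelet_content
    cohort$retained_fraction <- cc$retained_fraction
    d0 <- ifelse(cohort$rbc_volume_fraction >= 0.2,
                 truth$syringe_diameters[["small"]],
                 truth$syringe_diameters[["large"]])
    cohort$diameter_mm <- d0 * cc$retained_fraction^(1 / 3)

    cohort$ncct_density <- truth$ncct$beta0 +
      truth$ncct$beta_rbc * cohort$rbc_content +
      truth$ncct$beta_plt * cohort$platelet_content +
      stats::rnorm(n, 0, truth$ncct$sd)
    cohort$cect_increase <- truth$cect$gamma0 +
      truth$cect$gamma_plt * cohort$platelet_content +
      truth$cect$gamma_diameter * cohort$diameter_mm +
      stats::rnorm(n, 0, truth$cect$sd)
    for (f in names(truth$mech)) {
      m <- truth$mech[[f]]
      mu <- m$beta0 + m$beta_rbc * cohort$rbc_content +
        m$beta_plt * cohort$platelet_content
      cohort[[f]] <- if (truth$mech_noise_type == "additive") {
        mu + stats::rnorm(n, 0, m$sd)
      } else {
        mu * exp(stats::rnorm(n, 0, truth$mech_sdlog))
      }
    }
    cohort$flagged <- if (flag_prob > 0) {
      stats::runif(n) < flag_prob
    } else {
      rep(FALSE, n)
    }
    rownames(cohort) <- NULL
    structure(cohort, truth = truth,
              class = c("clot_cohort", "data.frame"))
  })
}

# Regression coefficient of stress on strain for sigma = eps^5 over a
# continuous uniform strain window [a, b] (per unit of the quintic
# coefficient): Cov(eps, eps^5) / Var(eps) with analytic moments.
quintic_window_slope <- function(a, b) {
  m1 <- (a + b) / 2
  v <- (b - a)^2 / 12
  e5 <- (b^6 - a^6) / (6 * (b - a))
  e6 <- (b^7 - a^7) / (7 * (b - a))
  (e6 - m1 * e5) / v
}

#' Solve the loading curve for target secant stiffnesses
#'
#' The synthetic loading branch is \eqn{\sigma(\epsilon) = A\epsilon +
#' B\epsilon^5} (strain as a fraction). Its secant modulus over a strain
#' window, defined as the OLS slope of stress on strain over that window,
#' is \eqn{A + B c_w} with \eqn{c_w} a closed-form window constant, so the
#' (A, B) that realise given low- and high-strain stiffness targets solve
#' a 2 x 2 linear system.
#'
#' @param low,high Target secant moduli, kPa, over `low_window` and
#'   `high_window`.
#' @param low_window,high_window Strain windows, % strain.
#' @return List with `A`, `B` (kPa).
#' @export
solve_loading_curve <- function(low, high, low_window = c(0, 10),
                                high_window = c(75, 80)) {
  cl <- quintic_window_slope(low_window[1] / 100, low_window[2] / 100)
  ch <- quintic_window_slope(high_window[1] / 100, high_window[2] / 100)
  B <- (high - low) / (ch - cl)
  A <- low - B * cl
  if (B < 0 || A <= 0) {
    stop("infeasible feature set: stiffness targets need A > 0, B >= 0",
         call. = FALSE)
  }
  list(A = A, B = B)
}

#' Generate a cyclic compression trace with closed-form features
#'
#' Builds a 10-cycle triangular-strain compression record whose four
#' mechanical characteristics are known exactly. The loading branch is
#' \eqn{\sigma = A\epsilon + B\epsilon^5} with (A, B) solved from the
#' stiffness targets ([solve_loading_curve()]); the unloading branch is
#' the power law \eqn{\sigma = \sigma_{max} ((\epsilon - \epsilon_p) /
#' (\epsilon_{max} - \epsilon_p))^q}, which vanishes at the target plastic
#' strain \eqn{\epsilon_p} and whose exponent q is chosen so the
#' hysteresis ratio is exact. Later cycles are scaled by the softening
#' factor. Strain runs at 10%/s to 80% peak strain.
#'
#' @param features Named list or vector with `low_strain_stiffness`,
#'   `high_strain_stiffness` (kPa), `hysteresis_loss`, `plastic_strain`
#'   (%).
#' @param geometry A [section_geometry()] used to convert stress back to
#'   force for the recorded trace.
#' @param delta_eps_pct Strain sampling step, % strain (default 0.1).
#' @param n_cycles Number of cycles.
#' @param peak_strain_pct Peak strain, %.
#' @param softening Per-cycle stress scaling factor.
#' @param strain_rate_pct_s Strain rate, %/s.
#' @param low_window,high_window Secant windows, % strain.
#' @param strain_noise_pct,stress_noise_kpa Optional additive zero-mean
#'   Gaussian noise on the recorded channels.
#' @param seed Optional seed for the noise.
#'
#' @return A list with `trace` ([mech_trace()]), `geometry`, and
#'   `analytic`: the curve parameters (`A`, `B`, `sigma_max`, `q`,
#'   `eps_p`, `eps_max`) and the exact feature values.
#' @export
generate_mech_trace <- function(features, geometry = section_geometry(25),
                                delta_eps_pct = 0.1, n_cycles = 10,
                                peak_strain_pct = 80, softening = 0.95,
                                strain_rate_pct_s = 10,
                                low_window = c(0, 10),
                                high_window = c(75, 80),
                                strain_noise_pct = 0, stress_noise_kpa = 0,
                                seed = NULL) {
  low <- features[["low_strain_stiffness"]]
  high <- features[["high_strain_stiffness"]]
  hyst <- features[["hysteresis_loss"]]
  plas <- features[["plastic_strain"]]
  em <- peak_strain_pct / 100
  ep <- plas / 100
  if (hyst < 0 || hyst >= 100 || ep < 0 || ep >= em) {
    stop("infeasible feature set: need 0 <= hysteresis < 100 and ",
         "0 <= plastic strain < peak strain", call. = FALSE)
  }
  ab <- solve_loading_curve(low, high, low_window, high_window)
  A <- ab$A; B <- ab$B
  sigma_max <- A * em + B * em^5
  a_load <- A * em^2 / 2 + B * em^6 / 6
  a_unload <- a_load * (1 - hyst / 100)
  if (a_unload <= 0) stop("infeasible feature set: no recoverable energy",
                          call. = FALSE)
  q <- sigma_max * (em - ep) / a_unload - 1
  if (q < 1) {
    stop(sprintf(paste0(
      "infeasible feature set: hysteresis %.1f%% with plastic strain ",
      "%.1f%% requires unloading exponent q = %.2f < 1"),
      hyst, plas, q), call. = FALSE)
  }
  de <- delta_eps_pct / 100
  up <- seq(0, em, by = de)
  if (abs(up[length(up)] - em) > 1e-12) up <- c(up, em)
  down <- rev(up)
  load_stress <- A * up + B * up^5
  unload_stress <- sigma_max * (pmax(down - ep, 0) / (em - ep))^q
  strain <- c(up, down[-1])
  stress1 <- c(load_stress, unload_stress[-1])
  strain_all <- strain
  stress_all <- stress1
  if (n_cycles > 1) {
    for (k in 2:n_cycles) {
      strain_all <- c(strain_all, strain[-1])
      stress_all <- c(stress_all, (stress1 * softening^(k - 1))[-1])
    }
  }
  dt <- delta_eps_pct / strain_rate_pct_s
  time <- (seq_along(strain_all) - 1) * dt
  strain_pct <- strain_all * 100
  with_seed(seed, {
    if (strain_noise_pct > 0) {
      strain_pct <- strain_pct +
        stats::rnorm(length(strain_pct), 0, strain_noise_pct)
      strain_pct <- pmin(pmax(strain_pct, 0), 99.999)
    }
    if (stress_noise_kpa > 0) {
      stress_all <- stress_all +
        stats::rnorm(length(stress_all), 0, stress_noise_kpa)
    }
    force <- stress_all * geometry$cross_sectional_area / 1000
    list(trace = mech_trace(time, strain_pct, force),
         geometry = geometry,
         analytic = list(A = A, B = B, sigma_max = sigma_max, q = q,
                         eps_p = ep, eps_max = em,
                         low_strain_stiffness = low,
                         high_strain_stiffness = high,
                         hysteresis_loss = hyst, plastic_strain = plas,
                         softening = softening,
                         peak_times = (which(strain_all == em)[
                           seq_len(n_cycles)] - 1) * dt))
  })
}

#' Closed-form baseline-return strain of a synthetic unloading branch
#'
#' The strain (in %) at which the synthetic power-law unloading stress
#' falls to `baseline_tol`: the analytic counterpart of what
#' [plastic_strain()] measures with a finite baseline tolerance. With
#' `baseline_tol = 0` this is the true permanent set `eps_p`.
#'
#' @param analytic The `analytic` element returned by
#'   [generate_mech_trace()].
#' @param baseline_tol Baseline tolerance, kPa.
#' @return Strain, percent.
#' @export
analytic_return_strain <- function(analytic, baseline_tol = 0.01) {
  if (baseline_tol <= 0) return(100 * analytic$eps_p)
  t <- (baseline_tol / analytic$sigma_max)^(1 / analytic$q)
  100 * (analytic$eps_p + (analytic$eps_max - analytic$eps_p) * min(t, 1))
}

#' Generate an aligned NCCT/CECT phantom pair for one clot
#'
#' A cylindrical clot of uniform HU inside a tube of contrast-free media;
#' the contrast-enhanced grid raises the media by the contrast
#' concentration and the clot voxels by the contrast-penetration increment
#' (floored at zero). Optional voxel-level Gaussian HU noise. Grids are
#' aligned by construction.
#'
#' @param ncct_hu True clot NCCT density, HU.
#' @param increase_hu Contrast penetration increment of the clot, HU.
#' @param diameter Clot diameter, mm.
#' @param voxel_size Voxel size, mm.
#' @param length_mm Axial extent of the grid, mm.
#' @param margin_mm In-plane media margin around the clot, mm.
#' @param media_hu,contrast_hu Media HU and contrast-induced media HU
#'   increase.
#' @param noise_sd Voxel HU noise sd.
#' @param seed Optional seed for the noise.
#'
#' @return List with `ncct` and `cect` [ct_image()] objects.
#' @export
generate_ct_phantom <- function(ncct_hu, increase_hu, diameter,
                                voxel_size = 0.25, length_mm = 6,
                                margin_mm = 2, media_hu = 10,
                                contrast_hu = 250, noise_sd = 0,
                                seed = NULL) {
  tube_d <- diameter + 2 * margin_mm
  if (diameter <= 0 || diameter >= tube_d) {
    stop("infeasible geometry: clot must fit inside the tube", call. = FALSE)
  }
  nx <- ceiling(tube_d / voxel_size)
  nz <- max(ceiling(length_mm / voxel_size), 3)
  xs <- axis_coords(nx, voxel_size)
  ctr <- nx * voxel_size / 2
  in_clot2d <- outer(xs, xs, function(x, y)
    (x - ctr)^2 + (y - ctr)^2 <= (diameter / 2)^2)
  mask <- array(rep(in_clot2d, nz), c(nx, nx, nz))
  ncct <- array(media_hu, c(nx, nx, nz))
  ncct[mask] <- ncct_hu
  cect <- array(media_hu + contrast_hu, c(nx, nx, nz))
  cect[mask] <- ncct_hu + max(increase_hu, 0)
  with_seed(seed, {
    if (noise_sd > 0) {
      ncct <- ncct + array(stats::rnorm(length(ncct), 0, noise_sd), dim(ncct))
      cect <- cect + array(stats::rnorm(length(cect), 0, noise_sd), dim(cect))
    }
    list(ncct = ct_image(ncct, voxel_size, mask),
         cect = ct_image(cect, voxel_size, mask))
  })
}

# 2-D box blur with replicated edges, applied `passes` times
box_blur <- function(m, k = 7, passes = 3) {
  half <- k %/% 2
  blur1 <- function(mat) {
    n <- nrow(mat)
    padded <- rbind(mat[rep(1, half), , drop = FALSE], mat,
                    mat[rep(n, half), , drop = FALSE])
    out <- apply(padded, 2, function(col) {
      cs <- cumsum(col)
      (cs[(k):length(cs)] - c(0, cs[seq_len(length(cs) - k)])) / k
    })
    out
  }
  for (i in seq_len(passes)) {
    m <- blur1(m)
    m <- t(blur1(t(m)))
  }
  m
}

#' Generate an MSB-like / CD42b-like label mask pair for one clot
#'
#' Produces two labelled masks of the same clot cross-section: an MSB-like
#' mask carrying the RBC class and a CD42b-like mask carrying the platelet
#' class (remaining clot pixels are fibrin/other). `style = "exact"`
#' allocates pixel counts so the measured content matches the request to
#' the nearest pixel (with the default 10000-pixel clot region, contents
#' specified to 0.01% are reproduced exactly); `style = "blob"` thresholds
#' a smoothed random field, giving spatially coherent regions whose
#' content matches within about 1%.
#'
#' @param rbc_content,platelet_content Target contents, % of clot area.
#' @param n_pixels Number of clot-region pixels (default 10000).
#' @param shape Mask dimensions in pixels.
#' @param style `"exact"` or `"blob"`.
#' @param pixel_size Pixel size, micrometres.
#' @param seed Optional seed.
#'
#' @return List with `msb` and `cd42b` [label_mask()] objects.
#' @export
generate_label_mask <- function(rbc_content, platelet_content,
                                n_pixels = 10000, shape = c(128, 128),
                                style = c("exact", "blob"),
                                pixel_size = 0.23, seed = NULL) {
  style <- match.arg(style)
  if (rbc_content < 0 || rbc_content > 100 ||
      platelet_content < 0 || platelet_content > 100) {
    stop("contents must lie in [0, 100]", call. = FALSE)
  }
  ctr <- (shape + 1) / 2
  r2 <- outer(seq_len(shape[1]), seq_len(shape[2]),
              function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2)
  ord <- order(r2)
  if (n_pixels > length(ord)) {
    stop("`n_pixels` exceeds the mask size", call. = FALSE)
  }
  clot_idx <- ord[seq_len(n_pixels)]
  with_seed(seed, {
    fill_mask <- function(content, class_code) {
      labels <- matrix(clot_classes[["background"]], shape[1], shape[2])
      labels[clot_idx] <- clot_classes[["fibrin_other"]]
      n_comp <- round(content / 100 * n_pixels)
      if (n_comp > 0) {
        if (style == "exact") {
          sel <- sample(clot_idx, n_comp)
        } else {
          field <- box_blur(matrix(stats::rnorm(prod(shape)),
                                   shape[1], shape[2]))
          vals <- field[clot_idx]
          sel <- clot_idx[rank(-vals, ties.method = "first") <= n_comp]
        }
        labels[sel] <- class_code
      }
      label_mask(labels, pixel_size)
    }
    list(msb = fill_mask(rbc_content, clot_classes[["RBC"]]),
         cd42b = fill_mask(platelet_content, clot_classes[["platelet"]]))
  })
}

#' Parameter recovery over replicate synthetic cohorts
#'
#' Draws `n_replicates` cohorts from the truth, refits the generative
#' multiple regressions on each (NCCT density and the four mechanical
#' features on RBC + platelet content; CECT density increase on platelet
#' content + diameter), and scores every slope coefficient for bias and
#' 95% confidence-interval coverage of the generative value.
#'
#' @param truth A [generative_truth()].
#' @param donors,design Passed to [generate_cohort()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Integer seed; replicate r uses `seed + r`.
#'
#' @return Data frame with one row per (outcome, coefficient): `true_beta`,
#'   `mean_estimate`, `bias`, `rel_bias_pct` (bias as % of |true beta|) and
#'   `coverage_pct`.
#' @export
recover_truth <- function(truth = generative_truth(),
                          donors = default_donors(),
                          design = default_design(),
                          n_replicates = 200, seed = 1) {
  models <- list(
    ncct_density = list(preds = c("rbc_content", "platelet_content"),
                        beta = c(truth$ncct$beta_rbc, truth$ncct$beta_plt)),
    cect_increase = list(preds = c("platelet_content", "diameter_mm"),
                         beta = c(truth$cect$gamma_plt,
                                  truth$cect$gamma_diameter)))
  for (f in names(truth$mech)) {
    models[[f]] <- list(preds = c("rbc_content", "platelet_content"),
                        beta = c(truth$mech[[f]]$beta_rbc,
                                 truth$mech[[f]]$beta_plt))
  }
  est <- cov_hits <- lapply(models, function(m) {
    matrix(NA_real_, n_replicates, length(m$beta))
  })
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(truth, donors, design, seed = seed + r)
    for (nm in names(models)) {
      m <- models[[nm]]
      fit <- multiple_ols(cohort[[nm]], cohort[m$preds])
      est[[nm]][r, ] <- fit$beta
      cov_hits[[nm]][r, ] <- fit$ci95[, 1] <= m$beta & m$beta <= fit$ci95[, 2]
    }
  }
  do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    mean_est <- colMeans(est[[nm]])
    bias <- mean_est - m$beta
    data.frame(outcome = nm, coefficient = m$preds, true_beta = m$beta,
               mean_estimate = mean_est, bias = bias,
               rel_bias_pct = 100 * abs(bias) / abs(m$beta),
               coverage_pct = 100 * colMeans(cov_hits[[nm]]),
               row.names = NULL)
  }))
}
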