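#' Section geometry for nominal stress conversion
#'
#' @param cross_sectional_area Initial cross-sectional area of the 2 mm
#'   clot section, mm^2.
#' @param feret_diameter Feret's (maximum caliper) diameter of the section,
#'   mm; also used as the sample diameter for the CT region-of-interest
#'   protocol.
#' @param thickness Section thickness, mm (nominal 2 mm).
#'
#' @return An object of class `section_geometry`.
#' @export
section_geometry <- function(cross_sectional_area, feret_diameter = NA_real_,
                             thickness = 2) {
  if (!is.finite(cross_sectional_area) || cross_sectional_area <= 0) {
    stop("`cross_sectional_area` must be positive", call. = FALSE)
  }
  if (!is.na(feret_diameter) && feret_diameter <= 0) {
    stop("`feret_diameter` must be positive", call. = FALSE)
  }
  structure(list(cross_sectional_area = cross_sectional_area,
                 feret_diameter = feret_diameter, thickness = thickness),
            class = "section_geometry")
}

#' Cyclic compression trace
#'
#' A sampled force--displacement record from cyclic unconfined compression,
#' stored as time (s), nominal strain (% of initial thickness, compressive
#' positive) and force (N).
#'
#' @param time Sample times, s, monotone increasing.
#' @param strain_pct Nominal compressive strain, percent, in `[0, 100)`.
#' @param force_N Measured force, N.
#'
#' @return An object of class `mech_trace` (a data frame).
#' @export
mech_trace <- function(time, strain_pct, force_N) {
  n <- length(time)
  if (length(strain_pct) != n || length(force_N) != n) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(strain_pct < -1e-9) || any(strain_pct >= 100)) {
    stop("`strain_pct` must lie in [0, 100)", call. = FALSE)
  }
  structure(data.frame(time = time, strain_pct = strain_pct,
                       force_N = force_N),
            class = c("mech_trace", "data.frame"))
}

#' Read a cyclic compression trace from CSV
#'
#' Expects columns `time_s`, `strain_pct`, `force_N`.
#'
#' @param path Path to the CSV file.
#' @return A [mech_trace()].
#' @export
read_mech_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "strain_pct", "force_N")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  mech_trace(d$time_s, d$strain_pct, d$force_N)
}

#' Convert force to nominal stress
#'
#' Nominal (engineering) stress: measured force divided by the initial
#' cross-sectional area of the section, for every sample. Returned in kPa
#' (1 N/mm^2 = 1000 kPa).
#'
#' @param trace A [mech_trace()].
#' @param geometry A [section_geometry()].
#' @return Numeric vector of nominal stress, kPa, one value per sample.
#' @export
to_nominal_stress <- function(trace, geometry) {
  stopifnot(inherits(geometry, "section_geometry"))
  trace$force_N / geometry$cross_sectional_area * 1000
}

# Strain excursion peaks by turning-point detection with a hysteresis band:
# a peak is registered only once the signal has dropped `prominence` below
# the running maximum, which makes the detector immune to noise smaller
# than the band. O(n).
find_strain_peaks <- function(x, prominence) {
  n <- length(x)
  if (n < 2) return(integer(0))
  peaks <- integer(0)
  rising <- TRUE
  cur_max <- x[1]; cur_max_i <- 1L
  cur_min <- x[1]
  for (i in 2:n) {
    if (rising) {
      if (x[i] >= cur_max) { cur_max <- x[i]; cur_max_i <- i }
      else if (cur_max - x[i] >= prominence) {
        peaks <- c(peaks, cur_max_i)
        rising <- FALSE
        cur_min <- x[i]
      }
    } else {
      if (x[i] <= cur_min) cur_min <- x[i]
      else if (x[i] - cur_min >= prominence) {
        rising <- TRUE
        cur_max <- x[i]; cur_max_i <- i
      }
    }
  }
  peaks
}

#' Segment a cyclic trace into loading/unloading branches
#'
#' Detects the strain peaks of the cyclic protocol (local maxima above a
#' prominence threshold, default 5% strain), places cycle boundaries at the
#' strain minima between consecutive peaks, and splits each cycle into a
#' loading branch (valley to peak) and an unloading branch (peak to the
#' next valley). The peak sample is shared by both branches of its cycle.
#'
#' @param trace A [mech_trace()].
#' @param stress_kpa Nominal stress channel, kPa (from
#'   [to_nominal_stress()]).
#' @param expected_cycles Number of cycles the protocol applied (10 in the
#'   standard protocol). Fewer detected excursions is an error; extra
#'   excursions beyond `expected_cycles` are ignored with a warning.
#' @param prominence Minimum peak prominence, % strain.
#'
#' @return A list of `cycle_branch` objects; each has `cycle_index`,
#'   `loading` and `unloading` data frames with `strain_pct` and
#'   `stress_kpa` columns.
#' @export
segment_cycles <- function(trace, stress_kpa, expected_cycles = 10,
                           prominence = 5) {
  x <- trace$strain_pct
  peaks <- find_strain_peaks(x, prominence)
  if (length(peaks) < expected_cycles) {
    stop(sprintf("%d cycle(s) detected, expected %d",
                 length(peaks), expected_cycles), call. = FALSE)
  }
  if (length(peaks) > expected_cycles) {
    warning(sprintf("%d excursions detected; using the first %d",
                    length(peaks), expected_cycles))
    peaks <- peaks[seq_len(expected_cycles)]
  }
  n <- length(x)
  starts <- integer(expected_cycles)
  ends <- integer(expected_cycles)
  starts[1] <- which.min(x[1:peaks[1]])
  for (k in seq_len(expected_cycles)) {
    to <- if (k < expected_cycles) peaks[k + 1] else n
    ends[k] <- peaks[k] - 1 + which.min(x[peaks[k]:to])
    if (k < expected_cycles) starts[k + 1] <- ends[k]
  }
  lapply(seq_len(expected_cycles), function(k) {
    li <- starts[k]:peaks[k]
    ui <- peaks[k]:ends[k]
    structure(list(
      cycle_index = k,
      loading = data.frame(strain_pct = x[li], stress_kpa = stress_kpa[li]),
      unloading = data.frame(strain_pct = x[ui], stress_kpa = stress_kpa[ui])),
      class = "cycle_branch")
  })
}

#' Secant modulus over a strain window
#'
#' Slope of an ordinary least-squares (free-intercept) linear fit of stress
#' on strain over a closed strain window of the loading branch. Strain
#' enters the fit as a fraction, so the slope is in kPa. The standard
#' windows are 0--10% (low-strain) and 75--80% (high-strain).
#'
#' @param branch A `cycle_branch` (normally the first cycle).
#' @param window Closed strain window, % strain, length 2.
#' @return Secant modulus, kPa.
#' @export
secant_modulus <- function(branch, window = c(0, 10)) {
  stopifnot(inherits(branch, "cycle_branch"), length(window) == 2)
  d <- branch$loading
  sel <- d$strain_pct >= window[1] - 1e-9 & d$strain_pct <= window[2] + 1e-9
  if (sum(sel) < 2) {
    stop(sprintf("fewer than 2 samples in the [%g, %g]%% strain window",
                 window[1], window[2]), call. = FALSE)
  }
  eps <- d$strain_pct[sel] / 100
  unname(stats::coef(stats::lm(d$stress_kpa[sel] ~ eps))[2])
}

# trapezoidal integral of y over x (signed)
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Hysteresis loss of the first compression cycle
#'
#' Energy dissipated over the loading--unloading cycle expressed as a
#' percentage of the energy supplied during loading: the area between the
#' branches over the area under the loading branch, both by trapezoidal
#' integration of stress over strain.
#'
#' @param cycle1 The first `cycle_branch`.
#' @return Hysteresis loss, percent.
#' @export
hysteresis_loss <- function(cycle1) {
  stopifnot(inherits(cycle1, "cycle_branch"))
  a_load <- trapz_int(cycle1$loading$strain_pct / 100,
                      cycle1$loading$stress_kpa)
  if (a_load <= 0) stop("non-positive loading energy", call. = FALSE)
  # unloading strain runs high to low; integrate on increasing strain
  a_unload <- -trapz_int(cycle1$unloading$strain_pct / 100,
                         cycle1$unloading$stress_kpa)
  100 * (a_load - a_unload) / a_load
}

#' Plastic compressive strain from the first unloading branch
#'
#' The permanent set: the largest strain on the unloading branch at which
#' the stress first returns to baseline. Walking the unloading branch down
#' from peak strain, the crossing of `baseline + baseline_tol` is located
#' by linear interpolation between the bracketing samples. If the stress
#' never returns to baseline before the minimum applied strain, the minimum
#' strain is returned with attribute `no_return = TRUE`.
#'
#' @param cycle1 The first `cycle_branch`.
#' @param baseline Baseline stress, kPa; default 0 (use the median pre-load
#'   stress when the rig has an offset).
#' @param baseline_tol Tolerance above baseline treated as "returned", kPa.
#' @return Plastic strain, percent, with attribute `no_return`.
#' @export
plastic_strain <- function(cycle1, baseline = 0, baseline_tol = 0.01) {
  stopifnot(inherits(cycle1, "cycle_branch"))
  u <- cycle1$unloading
  thr <- baseline + baseline_tol
  below <- which(u$stress_kpa <= thr)
  if (!length(below)) {
    res <- min(u$strain_pct)
    attr(res, "no_return") <- TRUE
    return(res)
  }
  i <- below[1]
  if (i == 1) {
    res <- u$strain_pct[1]
  } else {
    s0 <- u$stress_kpa[i - 1]; s1 <- u$stress_kpa[i]
    e0 <- u$strain_pct[i - 1]; e1 <- u$strain_pct[i]
    res <- if (s0 == s1) e1 else e0 + (thr - s0) * (e1 - e0) / (s1 - s0)
  }
  res <- unname(res)
  attr(res, "no_return") <- FALSE
  res
}

#' Extract the four compressive mechanical characteristics
#'
#' Converts force to nominal stress, segments the cyclic trace, and
#' computes the low- and high-strain secant stiffness from the first
#' loading branch, and the hysteresis loss and plastic strain from the
#' first loading--unloading cycle. Peak stresses of all cycles are retained
#' for diagnostics.
#'
#' @param trace A [mech_trace()].
#' @param geometry A [section_geometry()].
#' @param expected_cycles Number of cycles in the protocol.
#' @param low_window,high_window Secant windows, % strain.
#' @param baseline,baseline_tol Passed to [plastic_strain()].
#' @param prominence Passed to [segment_cycles()].
#'
#' @return An object of class `mech_features`: a list with
#'   `low_strain_stiffness`, `high_strain_stiffness` (kPa),
#'   `hysteresis_loss`, `plastic_strain` (%), `no_return` flag and
#'   `peak_stress_per_cycle` (kPa).
#' @export
extract_mech_features <- function(trace, geometry, expected_cycles = 10,
                                  low_window = c(0, 10),
                                  high_window = c(75, 80),
                                  baseline = 0, baseline_tol = 0.01,
                                  prominence = 5) {
  stress <- to_nominal_stress(trace, geometry)
  cycles <- segment_cycles(trace, stress, expected_cycles, prominence)
  c1 <- cycles[[1]]
  ps <- plastic_strain(c1, baseline, baseline_tol)
  structure(list(
    low_strain_stiffness = secant_modulus(c1, low_window),
    high_strain_stiffness = secant_modulus(c1, high_window),
    hysteresis_loss = hysteresis_loss(c1),
    plastic_strain = as.numeric(ps),
    no_return = isTRUE(attr(ps, "no_return")),
    peak_stress_per_cycle = vapply(cycles, function(cy)
      max(cy$loading$stress_kpa), numeric(1))),
    class = "mech_features")
}

#' @export
print.mech_features <- function(x, ...) {
  cat(sprintf(paste0(
    "Compressive mechanical characteristics\n",
    "  low-strain stiffness:  %8.3f kPa\n",
    "  high-strain stiffness: %8.3f kPa\n",
    "  hysteresis loss:       %8.2f %%\n",
    "  plastic strain:        %8.2f %%%s\n"),
    x$low_strain_stiffness, x$high_strain_stiffness,
    x$hysteresis_loss, x$plastic_strain,
    if (x$no_return) " (no baseline return)" else ""))
  invisible(x)
}
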