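#' Donor blood characteristics
#'
#' Bundles the per-donor quantities needed to plan a clot reconstitution:
#' the measured platelet concentration of the donor's platelet-rich plasma
#' (PRP), and optionally the whole-blood platelet count, haematocrit and
#' fibrinogen level.
#'
#' @param donor_id Character identifier for the donor.
#' @param prp_platelet_conc Measured PRP platelet concentration,
#'   in 10^3 platelets per microlitre. Must be positive.
#' @param wb_platelet_conc Whole-blood platelet count, 10^3 per microlitre.
#' @param haematocrit Whole-blood haematocrit as a fraction in (0, 1).
#' @param fibrinogen Plasma fibrinogen, g/l.
#'
#' @return An object of class `donor_blood`.
#' @seealso [compute_blending_volumes()], [default_donors()]
#' @export
donor_blood <- function(donor_id, prp_platelet_conc, wb_platelet_conc = NA_real_,
                        haematocrit = NA_real_, fibrinogen = NA_real_) {
  if (!is.numeric(prp_platelet_conc) || length(prp_platelet_conc) != 1 ||
      !is.finite(prp_platelet_conc) || prp_platelet_conc <= 0) {
    stop("`prp_platelet_conc` must be a single positive number", call. = FALSE)
  }
  if (!is.na(haematocrit) && (haematocrit <= 0 || haematocrit >= 1)) {
    stop("`haematocrit` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(donor_id = as.character(donor_id),
         prp_platelet_conc = prp_platelet_conc,
         wb_platelet_conc = wb_platelet_conc,
         haematocrit = haematocrit,
         fibrinogen = fibrinogen),
    class = "donor_blood"
  )
}

#' Clot reconstitution recipe
#'
#' A target composition for one reconstituted clot: the platelet
#' concentration of the final blend and the volumetric fraction of packed
#' red blood cells, in a fixed total volume.
#'
#' @param target_platelet_conc Target platelet concentration of the blend,
#'   10^3 platelets per microlitre (the factorial design uses 30, 90, 270).
#' @param rbc_volume_fraction Volumetric RBC fraction in `[0, 1)` (the
#'   design uses 0, 0.005, 0.02, 0.05 and 0.40).
#' @param total_volume Total reconstitution volume, microlitres.
#'
#' @return An object of class `clot_recipe`.
#' @export
clot_recipe <- function(target_platelet_conc, rbc_volume_fraction, total_volume) {
  if (target_platelet_conc < 0) {
    stop("`target_platelet_conc` must be non-negative", call. = FALSE)
  }
  if (rbc_volume_fraction < 0 || rbc_volume_fraction >= 1) {
    stop("`rbc_volume_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (total_volume <= 0) stop("`total_volume` must be positive", call. = FALSE)
  structure(
    list(target_platelet_conc = target_platelet_conc,
         rbc_volume_fraction = rbc_volume_fraction,
         total_volume = total_volume),
    class = "clot_recipe"
  )
}

#' Compute PRP/RBC/PDP blending volumes for a clot recipe
#'
#' Solves the two conservation equations that define the blend: platelet
#' number is conserved (all platelets come from the PRP), and the three
#' component volumes sum to the total reconstitution volume. Packed RBC
#' volume is set directly by the target volumetric fraction, and
#' platelet-depleted plasma (PDP) makes up the remainder.
#'
#' \deqn{v_{PRP} = C_{target} V / C_{PRP}, \quad v_{RBC} = f_{RBC} V, \quad
#'       v_{PDP} = V - v_{PRP} - v_{RBC}}
#'
#' A recipe is infeasible when the PRP is too dilute (the PRP volume needed
#' to supply the platelets exceeds the non-RBC volume); infeasibility is an
#' error, never a clamp, because a clamped blend would silently change the
#' clot composition.
#'
#' @param donor A [donor_blood()] object.
#' @param recipe A [clot_recipe()] object.
#'
#' @return An object of class `blending_volumes`: a list with `v_prp`,
#'   `v_rbc`, `v_pdp` (microlitres).
#' @examples
#' d <- donor_blood("d1", prp_platelet_conc = 300)
#' r <- clot_recipe(30, 0.40, 1000)
#' compute_blending_volumes(d, r)  # 100, 400, 500 ul
#' @export
compute_blending_volumes <- function(donor, recipe) {
  stopifnot(inherits(donor, "donor_blood"), inherits(recipe, "clot_recipe"))
  v <- recipe$total_volume
  v_prp <- recipe$target_platelet_conc * v / donor$prp_platelet_conc
  v_rbc <- recipe$rbc_volume_fraction * v
  v_pdp <- v - v_prp - v_rbc
  if (v_pdp < -1e-9 * v) {
    stop(sprintf(paste0(
      "infeasible recipe: PRP too dilute (needs %.1f ul PRP + %.1f ul RBC ",
      "in a %.1f ul blend); limiting component: PRP"),
      v_prp, v_rbc, v), call. = FALSE)
  }
  structure(
    list(v_prp = v_prp, v_rbc = v_rbc, v_pdp = max(v_pdp, 0)),
    class = "blending_volumes"
  )
}

#' @export
print.blending_volumes <- function(x, ...) {
  cat(sprintf("Blending volumes (ul): PRP %.1f | RBC %.1f | PDP %.1f\n",
              x$v_prp, x$v_rbc, x$v_pdp))
  invisible(x)
}

#' Check whether a recipe is feasible for a donor
#'
#' @inheritParams compute_blending_volumes
#' @return `TRUE` if the blend can be made, else `FALSE`.
#' @export
recipe_feasible <- function(donor, recipe) {
  frac <- recipe$target_platelet_conc / donor$prp_platelet_conc +
    recipe$rbc_volume_fraction
  frac <= 1 + 1e-9
}

#' Compute blending volumes for a cohort table
#'
#' Vectorised, table-level interface: takes a data frame with one row per
#' planned clot and appends the three blending volumes.
#'
#' @param cohort A data frame with columns `donor_id`, `prp_platelet_conc`,
#'   `target_platelet_conc`, `rbc_volume_fraction`, `total_volume`.
#' @param on_infeasible `"error"` (default) or `"drop"`: whether an
#'   infeasible row aborts the call or is removed (with a message).
#'
#' @return The input data frame with `v_prp`, `v_rbc`, `v_pdp` columns
#'   appended (microlitres).
#' @export
blend_cohort <- function(cohort, on_infeasible = c("error", "drop")) {
  on_infeasible <- match.arg(on_infeasible)
  need <- c("donor_id", "prp_platelet_conc", "target_platelet_conc",
            "rbc_volume_fraction", "total_volume")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  v_prp <- cohort$target_platelet_conc * cohort$total_volume /
    cohort$prp_platelet_conc
  v_rbc <- cohort$rbc_volume_fraction * cohort$total_volume
  v_pdp <- cohort$total_volume - v_prp - v_rbc
  bad <- v_pdp < -1e-9 * cohort$total_volume
  if (any(bad)) {
    if (on_infeasible == "error") {
      stop(sprintf("infeasible recipe in row(s) %s: PRP too dilute",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    message(sum(bad), " infeasible recipe(s) dropped (PRP too dilute)")
    cohort <- cohort[!bad, , drop = FALSE]
    v_prp <- v_prp[!bad]; v_rbc <- v_rbc[!bad]; v_pdp <- v_pdp[!bad]
  }
  cohort$v_prp <- v_prp
  cohort$v_rbc <- v_rbc
  cohort$v_pdp <- pmax(v_pdp, 0)
  cohort
}

#' Default synthetic donor panel
#'
#' Six healthy adult donors. Whole-blood platelet counts, haematocrit and
#' fibrinogen follow the published cohort characteristics; the PRP platelet
#' concentrations are synthetic values in the realistic 2.3--2.7x
#' whole-blood yield range of soft-spin PRP preparation. Three of the six
#' donors have PRP below the 450 x 10^3/ul needed to reach the densest
#' recipe (270 x 10^3 platelets/ul at 40% RBC volume), so those three
#' recipes drop out of the full factorial and the default cohort contains
#' 87 clots.
#'
#' @return A list of [donor_blood()] objects.
#' @export
default_donors <- function() {
  wb  <- c(170, 172, 242, 185, 146, 164)
  hct <- c(0.45, 0.40, 0.40, 0.43, 0.42, 0.39)
  fib <- c(3.2, 4.0, 3.0, 2.2, 2.8, 2.4)
  prp <- c(430, 520, 640, 495, 410, 445)  # synthetic PRP concentrations
  lapply(seq_along(wb), function(i) {
    donor_blood(paste0("D", i), prp_platelet_conc = prp[i],
                wb_platelet_conc = wb[i], haematocrit = hct[i],
                fibrinogen = fib[i])
  })
}
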