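#' CT image container
#'
#' A 3-D grid of Hounsfield Units with isotropic-or-not voxel spacing and a
#' boolean clot mask on the same grid. Axes are (x, y, z) with z the axial
#' (slice) direction.
#'
#' @param hu 3-D numeric array of Hounsfield Units.
#' @param voxel_size Voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param clot_mask Logical array of the same shape marking clot voxels.
#'
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(hu, voxel_size, clot_mask) {
  if (length(dim(hu)) != 3) stop("`hu` must be a 3-D array", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive", call. = FALSE)
  if (!identical(dim(hu), dim(clot_mask))) {
    stop("`clot_mask` shape must match `hu`", call. = FALSE)
  }
  structure(list(hu = hu, voxel_size = voxel_size,
                 clot_mask = array(as.logical(clot_mask), dim(hu))),
            class = "ct_image")
}

# voxel-centre coordinates (mm) along one axis
axis_coords <- function(n, vox) (seq_len(n) - 0.5) * vox

# logical in-plane disc membership (centre-of-voxel rule)
disc_membership <- function(image, center, diameter) {
  dm <- dim(image$hu)
  xs <- axis_coords(dm[1], image$voxel_size[1])
  ys <- axis_coords(dm[2], image$voxel_size[2])
  r2 <- (diameter / 2)^2
  outer(xs, ys, function(x, y) (x - center[1])^2 + (y - center[2])^2 <= r2)
}

#' Place circular ROIs on a clot CT image
#'
#' Implements the densitometry protocol: `n` circular non-overlapping
#' regions of interest, each with a diameter half that of the sample
#' diameter. Because three such discs cannot be disjoint within one
#' circular cross-section, the ROIs are placed on `n` distinct axial
#' slices (evenly spread over the eligible slices), each centred on the
#' clot centroid of its slice; non-overlap is then guaranteed by slice
#' separation.
#'
#' @param image A [ct_image()].
#' @param sample_diameter Sample (clot section) diameter in mm, normally
#'   the Feret diameter measured for the mechanical characterisation. Each
#'   ROI gets diameter `sample_diameter / 2`.
#' @param n Number of ROIs (default 3).
#'
#' @return A list of `roi_spec` objects with `slice_index`, `center` (mm)
#'   and `diameter` (mm).
#' @export
place_rois <- function(image, sample_diameter, n = 3) {
  stopifnot(inherits(image, "ct_image"))
  roi_d <- sample_diameter / 2
  dm <- dim(image$hu)
  xs <- axis_coords(dm[1], image$voxel_size[1])
  ys <- axis_coords(dm[2], image$voxel_size[2])
  eligible <- integer(0)
  centers <- list()
  for (z in seq_len(dm[3])) {
    m <- image$clot_mask[, , z]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    ctr <- c(mean(xs[idx[, 1]]), mean(ys[idx[, 2]]))
    # disc must lie entirely inside the clot on this slice
    disc <- disc_membership(image, ctr, roi_d)
    if (any(disc)) {
      z_ok <- all(m[disc])
      if (z_ok) {
        eligible <- c(eligible, z)
        centers[[length(eligible)]] <- ctr
      }
    }
  }
  if (length(eligible) < n) {
    stop(sprintf(
      "clot too small: only %d slice(s) can inscribe a %.2f mm ROI (need %d)",
      length(eligible), roi_d, n), call. = FALSE)
  }
  pick <- unique(round(seq(1, length(eligible), length.out = n)))
  if (length(pick) < n) pick <- seq_len(n)
  lapply(seq_len(n), function(k) {
    structure(list(slice_index = eligible[pick[k]],
                   center = centers[[pick[k]]],
                   diameter = roi_d),
              class = "roi_spec")
  })
}

#' Mean HU over circular ROIs
#'
#' Per-ROI mean Hounsfield Unit over the voxels whose centres fall inside
#' the disc, then the unweighted mean of the per-ROI means.
#'
#' @param image A [ct_image()].
#' @param rois List of `roi_spec` objects from [place_rois()].
#'
#' @return A list with `roi_means` (HU per ROI) and `mean` (overall HU).
#' @export
roi_mean_density <- function(image, rois) {
  stopifnot(inherits(image, "ct_image"))
  roi_means <- vapply(rois, function(r) {
    disc <- disc_membership(image, r$center, r$diameter)
    if (!any(disc)) stop("empty ROI (no voxel centres inside the disc)",
                         call. = FALSE)
    mean(image$hu[, , r$slice_index][disc])
  }, numeric(1))
  list(roi_means = roi_means, mean = mean(roi_means))
}

#' NCCT/CECT density result for one clot
#'
#' Applies the ROI protocol to an aligned non-contrast / contrast-enhanced
#' scan pair: ROIs are placed once on the NCCT clot mask and reused on the
#' CECT grid, and the contrast-driven density increase is the CECT mean
#' minus the NCCT mean.
#'
#' @param ncct,cect [ct_image()] objects on aligned grids.
#' @param sample_diameter Sample diameter, mm (see [place_rois()]).
#' @param n Number of ROIs.
#'
#' @return An object of class `density_result`: `ncct_density`,
#'   `cect_density`, `cect_increase` (HU), per-scan `roi_means`, and the
#'   `rois` used.
#' @export
density_result <- function(ncct, cect, sample_diameter, n = 3) {
  if (!identical(dim(ncct$hu), dim(cect$hu)) ||
      !isTRUE(all.equal(ncct$voxel_size, cect$voxel_size))) {
    stop("NCCT and CECT grids are not aligned", call. = FALSE)
  }
  rois <- place_rois(ncct, sample_diameter, n)
  rn <- roi_mean_density(ncct, rois)
  rc <- roi_mean_density(cect, rois)
  structure(list(ncct_density = rn$mean, cect_density = rc$mean,
                 cect_increase = rc$mean - rn$mean,
                 roi_means = list(ncct = rn$roi_means, cect = rc$roi_means),
                 rois = rois),
            class = "density_result")
}

#' Contrast-enhanced density increase
#'
#' CECT mean density minus NCCT mean density, the in-vitro proxy for
#' clinical thrombus perviousness. Both summaries must have been computed
#' with the same ROI geometry; the difference may be negative (no
#' clamping).
#'
#' @param ncct_mean,cect_mean Outputs of [roi_mean_density()] for the two
#'   scans.
#' @param ncct_rois,cect_rois The ROI lists used for each scan.
#' @return Density increase, HU.
#' @export
cect_increase <- function(ncct_mean, cect_mean, ncct_rois, cect_rois) {
  same <- length(ncct_rois) == length(cect_rois) &&
    all(vapply(seq_along(ncct_rois), function(i) {
      a <- ncct_rois[[i]]; b <- cect_rois[[i]]
      a$slice_index == b$slice_index &&
        isTRUE(all.equal(a$center, b$center)) &&
        isTRUE(all.equal(a$diameter, b$diameter))
    }, logical(1)))
  if (!same) stop("mismatched ROI geometry between scans", call. = FALSE)
  cect_mean$mean - ncct_mean$mean
}

#' Read / write a CT HU grid as NIfTI
#'
#' The clot mask is stored as a companion NIfTI file (suffix `_mask`).
#'
#' @param image A [ct_image()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `read_ct_nifti()` returns a [ct_image()]; `write_ct_nifti()`
#'   returns `path` invisibly.
#' @export
write_ct_nifti <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  img <- RNifti::asNifti(image$hu)
  RNifti::pixdim(img) <- image$voxel_size
  RNifti::writeNifti(img, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- RNifti::asNifti(array(as.integer(image$clot_mask),
                                dim(image$hu)))
  RNifti::pixdim(mask) <- image$voxel_size
  RNifti::writeNifti(mask, mask_path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- RNifti::readNifti(mask_path)
  ct_image(array(as.numeric(img), dim(img)),
           voxel_size = RNifti::pixdim(img)[1:3],
           clot_mask = array(as.numeric(mask) > 0.5, dim(img)))
}
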