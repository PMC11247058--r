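#' Histology label classes
#'
#' Integer codes used in label masks: background 0, RBC 1, platelet 2,
#' fibrin/other 3, white blood cell 4. The clot region is every
#' non-background pixel.
#'
#' @format Named integer vector.
#' @export
clot_classes <- c(background = 0L, RBC = 1L, platelet = 2L,
                  fibrin_other = 3L, WBC = 4L)

#' Labelled histology mask
#'
#' A 2-D integer grid of tissue classes (see [clot_classes]) from a
#' classified stained section: an MSB-like mask carries the RBC class, a
#' CD42b-like mask the platelet class.
#'
#' @param labels Integer matrix with values in `clot_classes`.
#' @param pixel_size Pixel edge length, micrometres.
#'
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size = 0.23) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% clot_classes)) {
    stop("`labels` contains codes outside the documented class set",
         call. = FALSE)
  }
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_mask")
}

#' Component content as percent of clot cross-sectional area
#'
#' @param mask A [label_mask()].
#' @param component Class name: one of `"RBC"`, `"platelet"`,
#'   `"fibrin_other"`, `"WBC"`.
#' @return Content, percent of the clot (non-background) area.
#' @export
content_percent <- function(mask, component = c("RBC", "platelet",
                                                "fibrin_other", "WBC")) {
  stopifnot(inherits(mask, "label_mask"))
  component <- match.arg(component)
  clot <- sum(mask$labels != clot_classes[["background"]])
  if (clot == 0) stop("empty clot region", call. = FALSE)
  100 * sum(mask$labels == clot_classes[[component]]) / clot
}

#' Normalized clot composition across the two stains
#'
#' RBC and platelet areas expressed as a percentage of the combined MSB
#' clot area and CD42b platelet area; the remainder is "other" (fibrin and
#' white blood cells). This combines areas measured on two different
#' stains of the same clot, exactly as the denominator is defined for
#' comparison with published AIS thrombus compositions.
#'
#' @param msb_clot_area Total clot area on the MSB section (pixels or any
#'   consistent unit).
#' @param rbc_area RBC area on the MSB section.
#' @param platelet_area Platelet area on the CD42b section.
#' @return Named numeric vector `normalized_rbc`, `normalized_platelet`,
#'   `normalized_other` (percent, summing to 100).
#' @export
normalized_composition <- function(msb_clot_area, rbc_area, platelet_area) {
  denom <- msb_clot_area + platelet_area
  if (denom <= 0) stop("zero denominator (no measured clot area)",
                       call. = FALSE)
  nr <- 100 * rbc_area / denom
  np <- 100 * platelet_area / denom
  c(normalized_rbc = nr, normalized_platelet = np,
    normalized_other = 100 - nr - np)
}

#' Composition result for one section slice
#'
#' @param rbc_content,platelet_content Percent of the clot cross-section.
#' @param normalized Output of [normalized_composition()] (optional).
#' @return An object of class `composition_result`.
#' @export
composition_result <- function(rbc_content, platelet_content,
                               normalized = NULL) {
  structure(list(rbc_content = rbc_content,
                 platelet_content = platelet_content,
                 normalized = normalized),
            class = "composition_result")
}

#' Average composition over one or two slices
#'
#' Field-wise arithmetic mean of the per-slice composition results; a
#' single slice passes through unchanged. Where possible two slices per
#' clot are measured and their average reported.
#'
#' @param results A list of one or two [composition_result()] objects.
#' @return A [composition_result()].
#' @export
average_slices <- function(results) {
  if (inherits(results, "composition_result")) results <- list(results)
  stopifnot(length(results) %in% 1:2,
            all(vapply(results, inherits, logical(1), "composition_result")))
  if (length(results) == 1) return(results[[1]])
  avg <- function(f) mean(vapply(results, function(r) r[[f]], numeric(1)))
  norm <- NULL
  if (!is.null(results[[1]]$normalized) && !is.null(results[[2]]$normalized)) {
    norm <- (results[[1]]$normalized + results[[2]]$normalized) / 2
  }
  composition_result(avg("rbc_content"), avg("platelet_content"), norm)
}

#' Read / write a label mask as 8-bit TIFF
#'
#' Class codes are stored in the 8-bit channel directly (0--4).
#'
#' @param mask A [label_mask()].
#' @param path TIFF file path.
#' @param pixel_size Pixel size in micrometres (not stored in the TIFF;
#'   supply on read).
#' @return `read_label_mask()` returns a [label_mask()];
#'   `write_label_mask()` returns `path` invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, pixel_size = 0.23) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_mask(round(m * 255), pixel_size = pixel_size)
}
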