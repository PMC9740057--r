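# Quantifiers for categorical histology fields.  Instance counting uses
# 4-connected components (EBImage::bwlabel), which keeps diagonally
# touching nuclei separate and is deterministic.

.field_classes <- function(field) {
  if (inherits(field, "histology_field")) field$classes else field
}

#' Necrosis area fraction
#'
#' Percentage of tissue area occupied by necrosis:
#' `100 * necrosis / (necrosis + viable tissue)`, where viable tissue is
#' the nucleus classes; background and vessel lumina are excluded from the
#' denominator.
#'
#' @param field A [histology_field()] (or class matrix).
#' @return Percent in \[0, 100\].
#' @export
necrosis_fraction <- function(field) {
  cls <- .field_classes(field)
  necro <- sum(cls == HISTO_CLASSES[["necrosis"]])
  viable <- sum(cls == HISTO_CLASSES[["viable_nucleus"]] |
                  cls == HISTO_CLASSES[["positive_nucleus"]])
  if (necro + viable == 0) stop("field contains no tissue pixels")
  100 * necro / (necro + viable)
}

# Label nuclei instances; returns per-instance positivity (logical vector).
.nucleus_instances <- function(cls) {
  nuc <- cls == HISTO_CLASSES[["viable_nucleus"]] |
    cls == HISTO_CLASSES[["positive_nucleus"]]
  lab <- EBImage::bwlabel(nuc * 1)
  n <- max(lab)
  if (n == 0) return(logical(0))
  # an instance is positive when the majority of its pixels are stained
  pos_px <- tabulate(lab[cls == HISTO_CLASSES[["positive_nucleus"]]], n)
  all_px <- tabulate(lab[lab > 0], n)
  pos_px > all_px / 2
}

#' Pooled positive-cell rate
#'
#' Percentage of positively stained nuclei over all nuclei, pooled across
#' the supplied fields (instance counts from 4-connected component
#' labelling, not pixel areas).  Conventionally three x200 fields are
#' scored per marker.  Per-field rates are attached as attribute
#' `per_field`.
#'
#' @param fields List of [histology_field()]s (a single field is accepted).
#' @param marker Optional marker tag (e.g. `"Ki67"`, `"CD31"`), recorded as
#'   an attribute.
#' @return Percent in \[0, 100\] with attributes `per_field`, `n_cells`,
#'   `n_positive`, `marker`.
#' @export
positive_rate <- function(fields, marker = NULL) {
  if (inherits(fields, "histology_field")) fields <- list(fields)
  per <- lapply(fields, function(f) .nucleus_instances(.field_classes(f)))
  n_all <- vapply(per, length, integer(1))
  n_pos <- vapply(per, sum, integer(1))
  if (sum(n_all) == 0) stop("no nuclei found in any field")
  rate <- 100 * sum(n_pos) / sum(n_all)
  attr(rate, "per_field") <- ifelse(n_all > 0, 100 * n_pos / n_all, NA_real_)
  attr(rate, "n_cells") <- sum(n_all)
  attr(rate, "n_positive") <- sum(n_pos)
  attr(rate, "marker") <- marker
  rate
}

#' Mean vessel cross-sectional area
#'
#' Connected components (4-connectivity) of the vessel-lumen class; each
#' component's area is its pixel count times the squared pixel size.  With
#' no vessels the mean is reported as missing, not zero.
#'
#' @param field A [histology_field()].
#' @return List with `mean_area_um2`, `n_vessels`, `areas_um2`.
#' @export
vessel_mean_area <- function(field) {
  stopifnot(inherits(field, "histology_field"))
  lum <- field$classes == HISTO_CLASSES[["vessel"]]
  lab <- EBImage::bwlabel(lum * 1)
  n <- max(lab)
  if (n == 0)
    return(list(mean_area_um2 = NA_real_, n_vessels = 0L,
                areas_um2 = numeric(0)))
  areas <- tabulate(lab[lab > 0], n) * field$pixel_size_um^2
  list(mean_area_um2 = mean(areas), n_vessels = as.integer(n),
       areas_um2 = areas)
}

#' Summarize a set of histology fields
#'
#' Convenience wrapper pooling [positive_rate()] across fields and
#' averaging [necrosis_fraction()] and [vessel_mean_area()] per field.
#'
#' @param fields List of [histology_field()]s.
#' @param marker Optional marker tag for the positive rate.
#' @return List with `positive_rate_pct`, `per_field_rates`,
#'   `necrosis_fraction_pct`, `mean_vessel_area_um2`, `n_vessels`,
#'   `n_fields`, `n_cells_total`.
#' @export
quantify_histology <- function(fields, marker = NULL) {
  if (inherits(fields, "histology_field")) fields <- list(fields)
  pr <- positive_rate(fields, marker)
  va <- lapply(fields, vessel_mean_area)
  areas <- unlist(lapply(va, `[[`, "areas_um2"))
  list(positive_rate_pct = as.numeric(pr),
       per_field_rates = attr(pr, "per_field"),
       necrosis_fraction_pct = mean(vapply(fields, necrosis_fraction,
                                           numeric(1))),
       mean_vessel_area_um2 = if (length(areas)) mean(areas) else NA_real_,
       n_vessels = length(areas),
       n_fields = length(fields),
       n_cells_total = attr(pr, "n_cells"))
}
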