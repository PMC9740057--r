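#' Histology field class codes
#'
#' Categorical pixel classes of a synthetic (or pre-segmented) histology
#' field: background, viable (unstained) nucleus, positively stained
#' nucleus, necrosis, vessel lumen.
#' @export
HISTO_CLASSES <- c(background = 0L, viable_nucleus = 1L,
                   positive_nucleus = 2L, necrosis = 3L, vessel = 4L)

#' Histology field
#'
#' @param classes 2D integer matrix with values from [HISTO_CLASSES].
#' @param pixel_size_um Physical pixel edge length (um, > 0).
#' @param magnification Magnification tag (default `"x200"`).
#' @return A `histology_field` object.
#' @export
histology_field <- function(classes, pixel_size_um, magnification = "x200") {
  stopifnot(is.matrix(classes))
  if (!all(classes %in% HISTO_CLASSES))
    stop("classes contains values outside the class dictionary")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(classes = classes, pixel_size_um = pixel_size_um,
                 magnification = magnification),
            class = "histology_field")
}

#' @export
print.histology_field <- function(x, ...) {
  cat(sprintf("Histology field %d x %d px (%.2f um/px, %s)\n",
              nrow(x$classes), ncol(x$classes), x$pixel_size_um,
              x$magnification))
  print(table(factor(x$classes, levels = HISTO_CLASSES,
                     labels = names(HISTO_CLASSES))))
  invisible(x)
}

# round-half-up (R's round() is round-half-even)
.round_half_up <- function(x) floor(x + 0.5)

# Digital disc offsets (dx, dy) with dx^2 + dy^2 <= r^2.
.disc_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

#' Simulate a x200 histology field
#'
#' Paints a categorical field with vessel lumina, a contiguous necrotic
#' region, and `n_cells` non-touching nucleus discs of which exactly
#' `round(n_cells * positive_fraction)` (half rounded up) are positively
#' stained — positives are placed by exact count, not Bernoulli draws, so
#' the positive rate is exact by construction.  The necrotic pixel count is
#' `round(necrosis_fraction / (1 - necrosis_fraction) * viable_pixels)`,
#' making the necrosis area fraction over tissue (necrosis + nuclei)
#' exact up to one pixel of rounding.
#'
#' @param n_cells Number of nuclei to place (>= 0).
#' @param positive_fraction Fraction of positive nuclei in \[0, 1\].
#' @param necrosis_fraction Necrotic fraction of tissue area in \[0, 1\];
#'   1 requires `n_cells = 0`.
#' @param vessel_spec Vessel lumen areas in um^2 (numeric vector); `NULL`
#'   for the default five lumina.
#' @param pixel_size_um Physical pixel size (um).
#' @param seed Optional seed; the same seed reproduces the field exactly.
#' @param field_px Field edge lengths in pixels.
#' @param nucleus_radius_px Nucleus disc radius (px).
#' @param n_positive Override the positive count (used when pooling several
#'   fields to an exact overall rate).
#' @return A [histology_field()].
#' @examples
#' f <- simulate_histology_field(200, 0.25, 0.2, seed = 1)
#' positive_rate(list(f))  # 25
#' @export
simulate_histology_field <- function(n_cells, positive_fraction,
                                     necrosis_fraction = 0.2,
                                     vessel_spec = NULL,
                                     pixel_size_um = 0.5, seed = NULL,
                                     field_px = c(512, 512),
                                     nucleus_radius_px = 2,
                                     n_positive = NULL) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  if (necrosis_fraction < 0 || necrosis_fraction > 1)
    stop("necrosis_fraction must lie in [0, 1]")
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (necrosis_fraction == 1 && n_cells > 0)
    stop("necrosis_fraction = 1 is incompatible with viable cells")
  if (is.null(vessel_spec)) vessel_spec <- c(150, 200, 250, 300, 400)
  if (is.null(n_positive))
    n_positive <- .round_half_up(n_cells * positive_fraction)
  if (n_positive > n_cells) stop("more positive nuclei than nuclei")

  build <- function() {
    nr <- field_px[1]; nc <- field_px[2]
    cls <- matrix(HISTO_CLASSES[["background"]], nr, nc)
    # vessels: non-overlapping discs with the requested lumen areas
    for (a_um2 in vessel_spec) {
      r <- max(1, round(sqrt(a_um2 / pi) / pixel_size_um))
      off <- .disc_offsets(r)
      for (try in 1:500) {
        cx <- sample((r + 2):(nr - r - 1), 1)
        cy <- sample((r + 2):(nc - r - 1), 1)
        ii <- cbind(cx + off$dx, cy + off$dy)
        if (all(cls[ii] == 0)) { cls[ii] <- HISTO_CLASSES[["vessel"]]; break }
        if (try == 500) stop("field too small to place vessels")
      }
    }
    disc <- .disc_offsets(nucleus_radius_px)
    disc_px <- nrow(disc)
    viable_px <- n_cells * disc_px
    n_necro <- if (necrosis_fraction == 1) {
      .round_half_up(0.4 * nr * nc)
    } else {
      .round_half_up(necrosis_fraction / (1 - necrosis_fraction) * viable_px)
    }
    # contiguous necrotic blob: nearest non-vessel pixels to a random center
    if (n_necro > 0) {
      free <- which(cls == 0)
      if (n_necro > length(free)) stop("field too small for necrosis area")
      cx <- sample.int(nr, 1); cy <- sample.int(nc, 1)
      fx <- (free - 1) %% nr + 1; fy <- (free - 1) %/% nr + 1
      d2 <- (fx - cx)^2 + (fy - cy)^2
      cls[free[order(d2)[seq_len(n_necro)]]] <- HISTO_CLASSES[["necrosis"]]
    }
    # nuclei: rejection-sample disc centers; forbid overlap and 4-adjacency
    if (n_cells > 0) {
      m <- nucleus_radius_px + 1
      allowed <- cls == 0
      forbidden <- matrix(FALSE, nr, nc)
      dil <- .disc_offsets(nucleus_radius_px + 1)  # disc + 1-px guard ring
      classes_seq <- c(rep(HISTO_CLASSES[["positive_nucleus"]], n_positive),
                       rep(HISTO_CLASSES[["viable_nucleus"]],
                           n_cells - n_positive))
      classes_seq <- sample(classes_seq)
      placed <- 0; attempts <- 0
      max_attempts <- 400 * n_cells + 1000
      while (placed < n_cells) {
        attempts <- attempts + 1
        if (attempts > max_attempts)
          stop("field too small to place ", n_cells, " nuclei")
        cx <- sample((m + 1):(nr - m), 1)
        cy <- sample((m + 1):(nc - m), 1)
        ii <- cbind(cx + disc$dx, cy + disc$dy)
        if (any(!allowed[ii]) || any(forbidden[ii])) next
        placed <- placed + 1
        cls[ii] <- classes_seq[placed]
        forbidden[cbind(cx + dil$dx, cy + dil$dy)] <- TRUE
      }
    }
    cls
  }
  cls <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  histology_field(cls, pixel_size_um)
}

# Largest-remainder allocation of `total` into `k` near-proportional parts.
.allocate_counts <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a set of histology fields with an exact pooled positive rate
#'
#' Splits `n_cells_total` nuclei near-evenly across `n_fields` fields and
#' allocates `round(n_cells_total * positive_fraction)` positive nuclei
#' (half rounded up) among them by largest remainder, so the pooled
#' positive rate over the set is exact.  Mirrors the three randomly
#' selected x200 fields used for IHC scoring.
#'
#' @param n_cells_total Total nuclei across all fields.
#' @param positive_fraction Target pooled positive fraction in \[0, 1\].
#' @param n_fields Number of fields (default 3).
#' @param seed Optional seed; per-field seeds are derived from it.
#' @param ... Passed to [simulate_histology_field()].
#' @return List of [histology_field()]s.
#' @export
simulate_histology_fields <- function(n_cells_total = 1000,
                                      positive_fraction = 0.5,
                                      n_fields = 3, seed = NULL, ...) {
  n_cells <- .allocate_counts(n_cells_total, rep(1, n_fields))
  n_pos_total <- .round_half_up(n_cells_total * positive_fraction)
  n_pos <- .allocate_counts(n_pos_total, pmax(n_cells, 1e-9))
  lapply(seq_len(n_fields), function(i) {
    simulate_histology_field(n_cells[i], positive_fraction,
                             seed = if (is.null(seed)) NULL else seed + i,
                             n_positive = n_pos[i], ...)
  })
}
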