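#' @keywords internal
"_PACKAGE"

#' Measurement kinds recognised in a cell record
#'
#' Three width measurements are taken per cell: the flagellum width (minimum
#' width per half-gyre), the combined flagellum plus helix width (maximum width
#' per half-gyre, from which the helix minor axis is obtained by subtraction),
#' and the major axis of the helix cross-section (at most once per gyre, where
#' the helix lies over the flagellum).
#' @export
measurement_kinds <- function() {
  c("flagellum_width", "flagellum_plus_minor", "major_axis")
}

round_half_up <- function(x) floor(x + 0.5)

#' Construct a single sperm cell record
#'
#' Bundles the per-measurement table for one cell with its segment lengths and
#' metadata. Lengths are micrometres throughout; longitudinal positions are
#' measured from the neck end of the flagellum (0 at the head-flagellum
#' junction), increasing tailward.
#'
#' @param cell_id Identifier, unique within a dataset.
#' @param species Species name; must match a tree tip for comparative stages.
#' @param family Taxonomic family label (used for family-level exclusions).
#' @param measurements Data frame with columns `gyre_index` (positive integer),
#'   `half` (1 or 2), `kind` (see [measurement_kinds()]), `value_um` (width in
#'   um, `NA` when obscured), `center_position_um` (longitudinal midpoint of
#'   the measurement, um), `obscured` (logical).
#' @param midpiece_um,tail_um Segmented-line lengths of the midpiece and the
#'   exposed flagellum (tail), um. Flagellum length is their sum.
#' @param nucleus_diameter_um Nucleus diameter, um (`NA` if not measured).
#' @param obscured_sections_um Numeric vector of lengths of fully unmeasurable
#'   midpiece stretches, um (empty if none).
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_id, species, family = NA_character_,
                        measurements,
                        midpiece_um, tail_um,
                        nucleus_diameter_um = NA_real_,
                        obscured_sections_um = numeric(0)) {
  rec <- structure(list(
    cell_id = as.character(cell_id),
    species = as.character(species),
    family = as.character(family),
    measurements = as.data.frame(measurements),
    midpiece_um = as.numeric(midpiece_um),
    tail_um = as.numeric(tail_um),
    nucleus_diameter_um = as.numeric(nucleus_diameter_um),
    obscured_sections_um = as.numeric(obscured_sections_um)
  ), class = "cell_record")
  validate_cell_record(rec)
  rec
}

#' Validate a cell record's invariants
#'
#' Checks the measurement-schema invariants: positive widths, combined width
#' at least the flagellum width within a half-gyre, at most one major-axis
#' measurement per gyre, at most two half-gyres per gyre, and longitudinal
#' positions non-decreasing with gyre index.
#'
#' @param rec A [cell_record()].
#' @return `rec`, invisibly; errors describe the first violation found.
#' @export
validate_cell_record <- function(rec) {
  m <- rec$measurements
  needed <- c("gyre_index", "half", "kind", "value_um",
              "center_position_um", "obscured")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols) > 0) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(m$kind %in% measurement_kinds())) {
    stop("unknown measurement kind(s): ",
         paste(setdiff(unique(m$kind), measurement_kinds()), collapse = ", "))
  }
  if (!all(m$half %in% c(1L, 2L))) stop("'half' must be 1 or 2")
  if (any(m$gyre_index < 1)) stop("'gyre_index' must be a positive integer")
  ok <- is.na(m$value_um) | m$value_um > 0
  if (!all(ok)) stop("non-positive width at row(s): ",
                     paste(which(!ok), collapse = ", "))
  if (any(!is.na(m$value_um) & m$obscured)) {
    stop("a measurement cannot both carry a value and be flagged obscured")
  }
  flag <- m[m$kind == "flagellum_width" & !is.na(m$value_um), ]
  fpm <- m[m$kind == "flagellum_plus_minor" & !is.na(m$value_um), ]
  if (nrow(flag) > 0 && nrow(fpm) > 0) {
    key <- function(d) paste(d$gyre_index, d$half, sep = ":")
    both <- intersect(key(flag), key(fpm))
    if (length(both) > 0) {
      f <- flag$value_um[match(both, key(flag))]
      p <- fpm$value_um[match(both, key(fpm))]
      bad <- which(p < f)
      if (length(bad) > 0) {
        stop("combined width smaller than flagellum width at gyre:half ",
             paste(both[bad], collapse = ", "))
      }
    }
  }
  maj <- m[m$kind == "major_axis", ]
  if (nrow(maj) > 0 && any(table(maj$gyre_index) > 1)) {
    stop("more than one major-axis measurement in a gyre")
  }
  for (k in measurement_kinds()) {
    for (h in 1:2) {
      sub <- m[m$kind == k & m$half == h & !is.na(m$center_position_um), ]
      sub <- sub[order(sub$gyre_index), ]
      if (nrow(sub) > 1 && any(diff(sub$center_position_um) < 0)) {
        stop("center positions decrease with gyre index for kind ", k)
      }
    }
  }
  if (!is.finite(rec$midpiece_um) || !is.finite(rec$tail_um) ||
      rec$midpiece_um + rec$tail_um <= 0) {
    stop("flagellum length (midpiece + tail) must be positive")
  }
  if (any(rec$obscured_sections_um < 0)) {
    stop("obscured section lengths must be non-negative")
  }
  if (!nzchar(rec$species)) stop("species must be non-empty")
  invisible(rec)
}

#' @export
print.cell_record <- function(x, ...) {
  cat("<cell_record> ", x$cell_id, " (", x$species, ")\n", sep = "")
  cat(sprintf("  midpiece %.2f um + tail %.2f um = flagellum %.2f um\n",
              x$midpiece_um, x$tail_um, x$midpiece_um + x$tail_um))
  cat("  measurements:", nrow(x$measurements), "rows,",
      length(unique(x$measurements$gyre_index)), "gyres\n")
  if (length(x$obscured_sections_um) > 0) {
    cat("  obscured sections (um):",
        paste(format(x$obscured_sections_um), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Helix minor-axis diameter by subtraction
#'
#' The minor axis of the helix cross-section cannot be measured directly on a
#' projection; it is obtained as the combined flagellum-plus-helix width minus
#' the flagellum width of the same half-gyre.
#'
#' @param flag_plus_minor_um Combined width, um (> 0).
#' @param flagellum_um Flagellum width, um (> 0).
#' @return Minor-axis diameter, um. A negative difference signals an
#'   inconsistent measurement pair and is an error, never clamped to zero.
#' @export
minor_axis_diameter <- function(flag_plus_minor_um, flagellum_um) {
  if (any(flag_plus_minor_um <= 0) || any(flagellum_um <= 0)) {
    stop("widths must be positive")
  }
  d <- flag_plus_minor_um - flagellum_um
  if (any(d < 0)) {
    stop("inconsistent measurement pair: combined width < flagellum width")
  }
  d
}

#' Elliptical cross-section area of the mitochondrial helix
#'
#' The helix cross-section is approximated as an ellipse, so the area is the
#' product of the two semi-axes and pi.
#'
#' @param major_axis_um,minor_axis_um Full axis diameters, um (>= 0).
#' @return Area in um^2.
#' @export
ellipse_cross_section_area <- function(major_axis_um, minor_axis_um) {
  if (any(major_axis_um < 0) || any(minor_axis_um < 0)) {
    stop("axis lengths must be non-negative")
  }
  pi * (major_axis_um / 2) * (minor_axis_um / 2)
}

#' Flagellum circumference from its diameter
#'
#' @param mean_diameter_um Mean flagellum diameter in the gyre, um (>= 0).
#' @return Circumference pi * diameter, um.
#' @export
flagellum_circumference <- function(mean_diameter_um) {
  if (any(mean_diameter_um < 0)) stop("diameter must be non-negative")
  pi * mean_diameter_um
}

#' Length of the mitochondrial helix within one gyre
#'
#' One wrap of the helix is unrolled to the hypotenuse of the axial advance
#' (the gyre interval) and the circumferential travel (the flagellum
#' circumference): sqrt(g^2 + c^2).
#'
#' @param gyre_interval_um Axial distance between consecutive gyres, um (>= 0).
#' @param circumference_um Flagellum circumference, um (>= 0).
#' @return Helical segment length, um; always >= max of the two inputs.
#' @export
helical_segment_length <- function(gyre_interval_um, circumference_um) {
  if (any(gyre_interval_um < 0) || any(circumference_um < 0)) {
    stop("inputs must be non-negative")
  }
  sqrt(gyre_interval_um^2 + circumference_um^2)
}

#' Gyre intervals of a cell
#'
#' The length of each gyre is estimated as the distance between the centre
#' points of corresponding measurements (same kind, same half-gyre) from
#' consecutive gyres; when several correspondences exist their mean is taken.
#' If the two gyres bracketing an interval are not adjacent in index (fully
#' obscured gyres in between), the position difference is divided by the index
#' gap to give a per-gyre interval.
#'
#' @param cell A [cell_record()].
#' @return Data frame with columns `gyre_index` (the proximal gyre of each
#'   pair) and `interval_um`.
#' @export
gyre_intervals <- function(cell) {
  m <- cell$measurements
  m <- m[!is.na(m$center_position_um), , drop = FALSE]
  gy <- sort(unique(m$gyre_index))
  if (length(gy) < 2) stop("insufficient gyres: need >= 2 positioned gyres")
  out <- data.frame(gyre_index = gy[-length(gy)], interval_um = NA_real_)
  for (i in seq_len(length(gy) - 1)) {
    a <- m[m$gyre_index == gy[i], c("half", "kind", "center_position_um")]
    b <- m[m$gyre_index == gy[i + 1], c("half", "kind", "center_position_um")]
    mg <- merge(a, b, by = c("half", "kind"), suffixes = c("_a", "_b"))
    d <- if (nrow(mg) > 0) {
      mean(mg$center_position_um_b - mg$center_position_um_a)
    } else {
      # no corresponding (kind, half) pair: fall back to mean positions
      mean(b$center_position_um) - mean(a$center_position_um)
    }
    out$interval_um[i] <- d / (gy[i + 1] - gy[i])
  }
  if (any(!is.finite(out$interval_um) | out$interval_um <= 0)) {
    stop("non-positive gyre interval; check measurement positions")
  }
  out
}

#' Assemble per-gyre geometry with cell-mean imputation
#'
#' For every gyre the mean flagellum diameter (of up to two half-gyre widths),
#' the mean subtraction-derived minor axis, the major axis, and the gyre
#' interval are collected. A component missing in a gyre (debris, obscured) is
#' replaced by the cell-wide mean of that component, computed from directly
#' measured values only; `imputed_fields` records every substitution. The
#' terminal gyre, which has no following gyre to define its interval, is
#' assigned the preceding gyre's interval.
#'
#' @param cell A [cell_record()].
#' @return Data frame with one row per gyre: `gyre_index`, `gyre_interval_um`,
#'   `mean_flagellum_diameter_um`, `mean_minor_axis_um`, `major_axis_um`, and
#'   a list column `imputed_fields`.
#' @export
assemble_gyre_geometries <- function(cell) {
  m <- cell$measurements
  gy <- sort(unique(m$gyre_index))
  if (length(gy) < 1) stop("cell has no measured gyres")

  per_gyre <- lapply(gy, function(g) {
    sub <- m[m$gyre_index == g, ]
    flag <- sub$value_um[sub$kind == "flagellum_width" & !is.na(sub$value_um)]
    minors <- numeric(0)
    for (h in 1:2) {
      f <- sub$value_um[sub$kind == "flagellum_width" & sub$half == h]
      p <- sub$value_um[sub$kind == "flagellum_plus_minor" & sub$half == h]
      if (length(f) == 1 && length(p) == 1 && !is.na(f) && !is.na(p)) {
        minors <- c(minors, minor_axis_diameter(p, f))
      }
    }
    maj <- sub$value_um[sub$kind == "major_axis" & !is.na(sub$value_um)]
    list(
      mf = if (length(flag) > 0) mean(flag) else NA_real_,
      mm = if (length(minors) > 0) mean(minors) else NA_real_,
      ma = if (length(maj) > 0) maj[1] else NA_real_
    )
  })
  mf <- vapply(per_gyre, `[[`, numeric(1), "mf")
  mm <- vapply(per_gyre, `[[`, numeric(1), "mm")
  ma <- vapply(per_gyre, `[[`, numeric(1), "ma")

  cell_means <- c(
    mean_flagellum_diameter_um = mean(mf[!is.na(mf)]),
    mean_minor_axis_um = mean(mm[!is.na(mm)]),
    major_axis_um = mean(ma[!is.na(ma)])
  )
  all_missing <- names(cell_means)[!is.finite(cell_means)]
  if (length(all_missing) > 0) {
    stop("cannot impute: no measured values for ",
         paste(all_missing, collapse = ", "))
  }

  imputed <- lapply(seq_along(gy), function(i) {
    fields <- character(0)
    if (is.na(mf[i])) fields <- c(fields, "mean_flagellum_diameter_um")
    if (is.na(mm[i])) fields <- c(fields, "mean_minor_axis_um")
    if (is.na(ma[i])) fields <- c(fields, "major_axis_um")
    fields
  })
  mf[is.na(mf)] <- cell_means["mean_flagellum_diameter_um"]
  mm[is.na(mm)] <- cell_means["mean_minor_axis_um"]
  ma[is.na(ma)] <- cell_means["major_axis_um"]

  iv <- gyre_intervals(cell)
  iv_full <- iv$interval_um[match(gy, iv$gyre_index)]
  iv_full[length(iv_full)] <- iv$interval_um[nrow(iv)]
  if (any(is.na(iv_full))) iv_full[is.na(iv_full)] <- mean(iv$interval_um)

  out <- data.frame(
    gyre_index = gy,
    gyre_interval_um = iv_full,
    mean_flagellum_diameter_um = mf,
    mean_minor_axis_um = mm,
    major_axis_um = ma
  )
  out$imputed_fields <- I(imputed)
  out
}

#' Volume of the mitochondrial helix within one gyre
#'
#' Cross-sectional ellipse area times the helical length of the wrap.
#'
#' @param g A one-row data frame or list with `gyre_interval_um`,
#'   `mean_flagellum_diameter_um`, `mean_minor_axis_um`, `major_axis_um`.
#' @return Volume in um^3 (vectorised over rows of a data frame).
#' @export
gyre_volume <- function(g) {
  area <- ellipse_cross_section_area(g$major_axis_um, g$mean_minor_axis_um)
  len <- helical_segment_length(
    g$gyre_interval_um,
    flagellum_circumference(g$mean_flagellum_diameter_um)
  )
  area * len
}

#' Number of gyres hidden in an obscured section
#'
#' Rounds the obscured length divided by the cell's mean gyre interval to the
#' nearest integer (half-up), floored at zero.
#'
#' @param obscured_length_um Length of the unmeasurable section, um (>= 0).
#' @param mean_gyre_interval_um Mean measured gyre interval, um (> 0).
#' @return Integer count of missing gyres.
#' @export
estimate_missing_gyre_count <- function(obscured_length_um,
                                        mean_gyre_interval_um) {
  if (any(obscured_length_um < 0)) stop("obscured length must be >= 0")
  if (any(!is.finite(mean_gyre_interval_um)) ||
      any(mean_gyre_interval_um <= 0)) {
    stop("mean gyre interval must be positive")
  }
  pmax(0L, as.integer(round_half_up(obscured_length_um /
                                      mean_gyre_interval_um)))
}

#' Whole-cell mitochondrial helix volume
#'
#' Estimates the helix volume gyre by gyre and sums over the cell. Gyres lost
#' to fully obscured sections are counted from the section lengths and
#' assigned the mean per-gyre volume of the measured gyres.
#'
#' @param cell A [cell_record()].
#' @return An object of class `cell_volume_estimate` with fields `cell_id`,
#'   `per_gyre_volumes_um3`, `n_measured_gyres`, `n_estimated_missing_gyres`,
#'   `total_volume_um3`.
#' @export
cell_volume <- function(cell) {
  gg <- assemble_gyre_geometries(cell)
  vols <- gyre_volume(gg)
  n_missing <- 0L
  if (length(cell$obscured_sections_um) > 0 &&
      sum(cell$obscured_sections_um) > 0) {
    mean_iv <- mean(gyre_intervals(cell)$interval_um)
    n_missing <- sum(estimate_missing_gyre_count(cell$obscured_sections_um,
                                                 mean_iv))
  }
  total <- sum(vols) + n_missing * mean(vols)
  structure(list(
    cell_id = cell$cell_id,
    species = cell$species,
    per_gyre_volumes_um3 = vols,
    n_measured_gyres = length(vols),
    n_estimated_missing_gyres = as.integer(n_missing),
    total_volume_um3 = total
  ), class = "cell_volume_estimate")
}

#' @export
print.cell_volume_estimate <- function(x, ...) {
  cat("<cell_volume_estimate> ", x$cell_id, "\n", sep = "")
  cat(sprintf("  %d measured gyres + %d estimated missing\n",
              x$n_measured_gyres, x$n_estimated_missing_gyres))
  cat(sprintf("  total volume: %.4f um^3\n", x$total_volume_um3))
  invisible(x)
}
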