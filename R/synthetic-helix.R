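# Synthetic 3D sperm-cell geometry: a flagellum that tapers linearly along
# its arc, wrapped over the midpiece by an elliptical mitochondrial tube whose
# axes and pitch also taper linearly. The generator is the ground truth for
# validating the per-gyre volume estimator.

#' Specify a synthetic helical cell
#'
#' All tapering quantities vary linearly: the flagellum diameter over the full
#' flagellum length, the tube axes and the pitch over the (nominal) midpiece.
#' The helix is truncated at the last complete gyre so that the generated cell
#' ends on a whole wrap.
#'
#' Defaults reflect typical passerine values: flagellum ~0.33 um wide at the
#' neck tapering to ~0.22 um, helix minor axis 0.15 to 0.09 um, major axis
#' 0.24 to 0.18 um, pitch around 4 um, and a midpiece covering ~74% of the
#' flagellum.
#'
#' @param flagellum_length_um Total flagellum length, um.
#' @param base_flagellum_diameter_um,tip_flagellum_diameter_um Flagellum
#'   diameter at the neck and at the flagellum tip, um.
#' @param midpiece_fraction Fraction of the flagellum wrapped by the helix,
#'   in (0, 1].
#' @param base_minor_axis_um,tip_minor_axis_um Helix minor-axis endpoints, um.
#' @param base_major_axis_um,tip_major_axis_um Helix major-axis endpoints, um.
#' @param pitch_base_um,pitch_tip_um Gyre interval (helix pitch) at the two
#'   ends of the midpiece, um; equal values give a constant pitch.
#' @param seed Optional integer seed recorded with the spec (the geometry
#'   itself is deterministic; the seed feeds measurement noise downstream).
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(flagellum_length_um = 120,
                       base_flagellum_diameter_um = 0.33,
                       tip_flagellum_diameter_um = 0.22,
                       midpiece_fraction = 0.74,
                       base_minor_axis_um = 0.15,
                       tip_minor_axis_um = 0.09,
                       base_major_axis_um = 0.24,
                       tip_major_axis_um = 0.18,
                       pitch_base_um = 4.2,
                       pitch_tip_um = 3.9,
                       seed = NULL) {
  spec <- structure(as.list(environment()), class = "helix_spec")
  with(spec, {
    stopifnot(
      flagellum_length_um > 0,
      base_flagellum_diameter_um > 0, tip_flagellum_diameter_um >= 0,
      tip_flagellum_diameter_um <= base_flagellum_diameter_um,
      base_minor_axis_um > 0, tip_minor_axis_um >= 0,
      tip_minor_axis_um <= base_minor_axis_um,
      base_major_axis_um > 0, tip_major_axis_um >= 0,
      tip_major_axis_um <= base_major_axis_um,
      pitch_base_um > 0, pitch_tip_um > 0,
      midpiece_fraction > 0, midpiece_fraction <= 1
    )
  })
  spec
}

# Piecewise-linear profiles as functions of axial position s (um from neck).
helix_profiles <- function(spec) {
  L <- spec$flagellum_length_um
  M <- spec$midpiece_fraction * L
  p0 <- spec$pitch_base_um
  k <- (spec$pitch_tip_um - p0) / M
  lin <- function(a, b, over) function(s) a + (b - a) * s / over
  turns <- function(s) {
    if (abs(k) < 1e-12) s / p0 else log1p(k * s / p0) / k
  }
  inv_turns <- function(t) {
    if (abs(k) < 1e-12) t * p0 else p0 * expm1(k * t) / k
  }
  list(
    L = L, M = M,
    d = lin(spec$base_flagellum_diameter_um,
            spec$tip_flagellum_diameter_um, L),
    b = lin(spec$base_minor_axis_um, spec$tip_minor_axis_um, M),
    a = lin(spec$base_major_axis_um, spec$tip_major_axis_um, M),
    p = function(s) p0 + k * s,
    turns = turns, inv_turns = inv_turns,
    n_gyres = floor(turns(M) + 1e-9)
  )
}

#' Numerically integrated true helix volume
#'
#' Independent oracle for the per-gyre volume estimator: the elliptical
#' cross-section area is integrated along the arc length of the 3D helical
#' centreline. The centreline winds at radius flagellum radius + minor
#' semi-axis, so the arc element per unit axial advance is
#' sqrt(1 + (2 pi r(s) / p(s))^2). Simpson's rule is used and convergence is
#' verified by doubling the step count.
#'
#' @param spec A [helix_spec()].
#' @param n_steps Number of integration intervals (>= 1000).
#' @return Volume in um^3.
#' @export
true_helix_volume <- function(spec, n_steps = 2000) {
  if (n_steps < 1000) stop("n_steps must be >= 1000")
  pr <- helix_profiles(spec)
  if (pr$n_gyres < 1) stop("midpiece too short for a complete gyre")
  M_used <- pr$inv_turns(pr$n_gyres)
  integrand <- function(s) {
    r <- pr$d(s) / 2 + pr$b(s) / 2
    pi * (pr$a(s) / 2) * (pr$b(s) / 2) * sqrt(1 + (2 * pi * r / pr$p(s))^2)
  }
  simpson <- function(n) {
    n <- if (n %% 2 == 1) n + 1 else n
    s <- seq(0, M_used, length.out = n + 1)
    f <- integrand(s)
    h <- M_used / n
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f) * h / 3
  }
  v1 <- simpson(n_steps)
  v2 <- simpson(2 * n_steps)
  if (abs(v2 - v1) > 1e-6 * abs(v2)) {
    stop("helix volume integration did not converge; increase n_steps")
  }
  v2
}

#' Specify the measurement-noise model
#'
#' Widths are positive, so measurement error is modelled as multiplicative
#' lognormal noise with unit mean; its coefficient of variation is calibrated
#' so that repeated measurements of one point spread by a few percent, as seen
#' in repeat-measurement checks of SEM data. Missingness operates at two
#' levels: individual measurements obscured by debris, and whole sections of
#' the midpiece that cannot be measured at all.
#'
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param p_missing_value Probability that any single measurement is obscured.
#' @param p_obscured_section Probability that the cell carries one fully
#'   obscured section.
#' @param obscured_section_length_um Length of such a section, um.
#' @param position_sd_um SD of Gaussian jitter on longitudinal centre
#'   positions, um (0 = exact placement).
#' @param seed Optional integer seed for the noise draws.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.02,
                       p_missing_value = 0,
                       p_obscured_section = 0,
                       obscured_section_length_um = 8,
                       position_sd_um = 0,
                       seed = NULL) {
  stopifnot(cv >= 0, p_missing_value >= 0, p_missing_value <= 1,
            p_obscured_section >= 0, p_obscured_section <= 1,
            obscured_section_length_um >= 0, position_sd_um >= 0)
  structure(as.list(environment()), class = "noise_spec")
}

# Unit-mean lognormal factors with coefficient of variation cv.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Project a synthetic helix into SEM-style measurements
#'
#' Emulates the measurement protocol: two flagellum widths and two combined
#' flagellum-plus-helix widths per gyre at half-gyre spacing, and one major
#' axis per gyre at the gyre centre (where the helix lies over the flagellum).
#' The projected maximum width is the local flagellum diameter plus the local
#' minor-axis diameter, so subtraction recovers the minor axis exactly in the
#' noise-free case. Measurement noise, per-value missingness and whole-section
#' obscuring are then applied.
#'
#' @param spec A [helix_spec()].
#' @param noise A [noise_spec()].
#' @param cell_id,species,family Metadata for the emitted record.
#' @return A [cell_record()].
#' @export
project_measurements <- function(spec, noise = noise_spec(),
                                 cell_id = "synth1", species = "synthetic_sp",
                                 family = "synthetic_fam") {
  seed <- if (!is.null(noise$seed)) noise$seed else spec$seed
  if (!is.null(seed)) set.seed(seed)
  pr <- helix_profiles(spec)
  n_g <- pr$n_gyres
  if (n_g < 2) stop("spec yields fewer than 2 complete gyres")
  M_used <- pr$inv_turns(n_g)

  rows <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    s_half <- c(pr$inv_turns(g - 0.75), pr$inv_turns(g - 0.25))
    s_mid <- pr$inv_turns(g - 0.5)
    d <- pr$d(s_half)
    b <- pr$b(s_half)
    flag <- d * lognormal_factor(2, noise$cv)
    fpm <- (d + b) * lognormal_factor(2, noise$cv)
    # measured independently, but a valid image always shows fpm >= flag
    for (tries in 1:100) {
      bad <- fpm < flag
      if (!any(bad)) break
      fpm[bad] <- (d + b)[bad] * lognormal_factor(sum(bad), noise$cv)
    }
    maj <- pr$a(s_mid) * lognormal_factor(1, noise$cv)
    rows[[g]] <- data.frame(
      gyre_index = g,
      half = c(1L, 2L, 1L, 2L, 1L),
      kind = c("flagellum_width", "flagellum_width",
               "flagellum_plus_minor", "flagellum_plus_minor", "major_axis"),
      value_um = c(flag, fpm, maj),
      center_position_um = c(s_half, s_half, s_mid)
    )
  }
  m <- do.call(rbind, rows)

  obscured_sections <- numeric(0)
  if (noise$p_obscured_section > 0 &&
      stats::runif(1) < noise$p_obscured_section) {
    len <- noise$obscured_section_length_um
    start <- stats::runif(1, 0, max(M_used - len, 0))
    centre_of_gyre <- vapply(seq_len(n_g),
                             function(g) pr$inv_turns(g - 0.5), numeric(1))
    drop_g <- which(centre_of_gyre >= start & centre_of_gyre <= start + len)
    if (length(drop_g) > 0 && n_g - length(drop_g) >= 2) {
      m <- m[!(m$gyre_index %in% drop_g), ]
      obscured_sections <- len
    }
  }
  if (noise$p_missing_value > 0) {
    hide <- stats::runif(nrow(m)) < noise$p_missing_value
    m$value_um[hide] <- NA_real_
    m$obscured <- hide
  } else {
    m$obscured <- FALSE
  }
  if (noise$position_sd_um > 0) {
    m$center_position_um <- m$center_position_um +
      stats::rnorm(nrow(m), 0, noise$position_sd_um)
    # jitter must not reorder a measurement series along the cell
    for (k in unique(m$kind)) {
      for (h in 1:2) {
        idx <- which(m$kind == k & m$half == h)
        idx <- idx[order(m$gyre_index[idx])]
        m$center_position_um[idx] <- sort(m$center_position_um[idx])
      }
    }
  }

  nucleus <- max((pr$d(0) - 0.13) / 0.27, 0.3)
  cell_record(
    cell_id = cell_id, species = species, family = family,
    measurements = m,
    midpiece_um = M_used,
    tail_um = pr$L - M_used,
    nucleus_diameter_um = nucleus,
    obscured_sections_um = obscured_sections
  )
}
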