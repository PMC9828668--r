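# Simulated comparative study: a Yule tree, species traits evolving by
# Brownian motion with tunable phylogenetic signal, and per-cell measurement
# tables whose width and gyre-interval responses follow the same linear
# models the pipeline fits, so that every stage can be checked against known
# generating values.

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_species` tips, rescaled to unit root-to-tip height.
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Optional integer seed.
#' @return A rooted ultrametric `phylo` tree with tips `sp_01`, `sp_02`, ...
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 3) stop("need at least 3 species")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp_%02d", seq_len(n_species))
  tr
}

#' Specify a simulated comparative study
#'
#' Default coefficient values mirror the empirical patterns of passerine
#' sperm: positive midpiece-flagellum allometry on the natural-log scale
#' (slope 1.38), a flagellum diameter around 0.33 um at the neck tapering by
#' 0.11 um along the cell and wider for longer flagella, log minor and major
#' helix axes declining with position, and a log gyre interval around
#' exp(1.43) = 4.2 um increasing with flagellum length. Flagellum length
#' enters every width model centred and divided by 100 (so a unit is 100 um),
#' longitudinal position as a 0-1 proportion. Species-level effect and
#' residual SDs are set so the phylogenetic variance proportions land near
#' the observed ones (roughly 0.85, 0.66, 0.57, 0.86).
#'
#' Coefficient vectors are ordered (intercept, position, length, interaction).
#'
#' @param n_species Number of species (>= 3).
#' @param lambda_true Phylogenetic-vs-independent mixing of the species trait
#'   draws, in `[0, 1]` (1 = pure Brownian).
#' @param root_log_flagellum Root value for log flagellum length (log um).
#' @param bm_sd SD of log flagellum length across species.
#' @param allometry_intercept,allometry_slope,allometry_resid_sd Log-log link
#'   from flagellum to midpiece length.
#' @param flag_diameter,flag_sd_species,flag_sd_resid Flagellum-diameter
#'   model (um, raw scale) and its SDs.
#' @param minor_log,minor_sd_species,minor_sd_resid Log minor-axis model.
#' @param major_log,major_sd_species,major_sd_resid Log major-axis model.
#' @param gyre_log,gyre_sd_species,gyre_sd_resid Log gyre-interval model.
#' @param cell_length_cv CV of a cell's SEM lengths around its species mean.
#' @param head_mean,head_sd Species head length distribution (um).
#' @param seed Optional integer seed.
#' @return An object of class `comparative_spec`.
#' @export
comparative_spec <- function(n_species = 55,
                             lambda_true = 0.9,
                             root_log_flagellum = log(110),
                             bm_sd = 0.30,
                             allometry_intercept = -1.99,
                             allometry_slope = 1.38,
                             allometry_resid_sd = 0.12,
                             flag_diameter = c(intercept = 0.33,
                                               position = -0.11,
                                               length = 0.04,
                                               interaction = -0.03),
                             flag_sd_species = 0.03,
                             flag_sd_resid = 0.012,
                             minor_log = c(intercept = -1.87,
                                           position = -0.51,
                                           length = -0.04,
                                           interaction = 0),
                             minor_sd_species = 0.18,
                             minor_sd_resid = 0.13,
                             major_log = c(intercept = -1.44,
                                           position = -0.25,
                                           length = -0.07,
                                           interaction = 0),
                             major_sd_species = 0.12,
                             major_sd_resid = 0.10,
                             gyre_log = c(intercept = 1.43,
                                          position = -0.08,
                                          length = 0.23,
                                          interaction = 0.05),
                             gyre_sd_species = 0.15,
                             gyre_sd_resid = 0.06,
                             cell_length_cv = 0.02,
                             head_mean = 13,
                             head_sd = 1,
                             seed = NULL) {
  spec <- structure(as.list(environment()), class = "comparative_spec")
  stopifnot(spec$n_species >= 3,
            spec$lambda_true >= 0, spec$lambda_true <= 1,
            spec$bm_sd > 0, spec$allometry_resid_sd > 0)
  for (nm in c("flag_diameter", "minor_log", "major_log", "gyre_log")) {
    if (!all(c("intercept", "position", "length", "interaction") %in%
             names(spec[[nm]]))) {
      stop(nm, " must name intercept, position, length, interaction")
    }
  }
  spec
}

# lambda-mixed species covariance on unit scale: lam*C/height + (1-lam)*I
mixed_cov <- function(C, lam) {
  Cs <- C / max(diag(C))
  lam * Cs + (1 - lam) * diag(nrow(Cs))
}

#' Simulate species trait means
#'
#' Log flagellum length is drawn with covariance
#' `bm_sd^2 (lambda_true C + (1 - lambda_true) I)`; log midpiece length
#' follows the allometric link with residuals sharing the same phylogenetic
#' mixing. Also draws a head length and derives a tail length (floored at a
#' small positive value where the allometric draw leaves almost no tail).
#'
#' @param tree A rooted `phylo` tree.
#' @param spec A [comparative_spec()].
#' @return Data frame (species, head_um, midpiece_um, tail_um, flagellum_um)
#'   with the generating parameters in `attr(, "truth")`.
#' @export
simulate_species_traits <- function(tree, spec = comparative_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  C <- phylo_covariance(tree)$C
  n <- nrow(C)
  V <- mixed_cov(C, spec$lambda_true)
  log_flag <- spec$root_log_flagellum +
    drop(MASS::mvrnorm(1, rep(0, n), spec$bm_sd^2 * V))
  log_mid <- spec$allometry_intercept + spec$allometry_slope * log_flag +
    drop(MASS::mvrnorm(1, rep(0, n), spec$allometry_resid_sd^2 * V))
  flag <- exp(log_flag)
  mid <- exp(log_mid)
  out <- data.frame(
    species = rownames(C),
    head_um = stats::rnorm(n, spec$head_mean, spec$head_sd),
    midpiece_um = mid,
    tail_um = pmax(flag - mid, 2),
    flagellum_um = flag
  )
  attr(out, "truth") <- list(
    lambda_true = spec$lambda_true,
    allometry_intercept = spec$allometry_intercept,
    allometry_slope = spec$allometry_slope,
    bm_sd = spec$bm_sd,
    allometry_resid_sd = spec$allometry_resid_sd
  )
  out
}

linpred <- function(coefs, x, ls) {
  coefs[["intercept"]] + coefs[["position"]] * x + coefs[["length"]] * ls +
    coefs[["interaction"]] * ls * x
}

#' Simulate a full comparative study in memory
#'
#' Draws a tree, species traits, species-level random effects (pure
#' phylogenetic, `N(0, sd_species^2 C)`), and one cell per species whose
#' measurement series follow the generating linear models exactly in the
#' analysis' coordinates: longitudinal position as the rank proportion of the
#' measurement series, flagellum length centred at the realized cell mean and
#' divided by 100. Gyre centre positions are accumulated from the generated
#' intervals, so the emitted table is geometrically consistent.
#'
#' @param spec A [comparative_spec()].
#' @param noise A [noise_spec()] controlling per-value missingness applied to
#'   the measurement rows (the model residual SDs live in `spec`).
#' @return List with `tree`, `species_table`, `cells` (list of
#'   [cell_record()]), and `truth` (generating parameters, per-cell covariate
#'   values and noise-free per-cell volumes).
#' @export
simulate_study <- function(spec = comparative_spec(), noise = noise_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tree <- simulate_tree(spec$n_species)
  spec_noseed <- spec
  spec_noseed$seed <- NULL
  traits <- simulate_species_traits(tree, spec_noseed)
  n <- spec$n_species
  C <- phylo_covariance(tree)$C
  Cs <- C / max(diag(C))

  u <- list(
    flag = drop(MASS::mvrnorm(1, rep(0, n), spec$flag_sd_species^2 * Cs)),
    minor = drop(MASS::mvrnorm(1, rep(0, n), spec$minor_sd_species^2 * Cs)),
    major = drop(MASS::mvrnorm(1, rep(0, n), spec$major_sd_species^2 * Cs)),
    gyre = drop(MASS::mvrnorm(1, rep(0, n), spec$gyre_sd_species^2 * Cs))
  )

  flag_cell <- traits$flagellum_um *
    exp(stats::rnorm(n, 0, spec$cell_length_cv))
  mid_cell <- pmin(traits$midpiece_um *
                     exp(stats::rnorm(n, 0, spec$cell_length_cv)),
                   0.95 * flag_cell)
  ls <- (flag_cell - mean(flag_cell)) / 100

  fam_size <- 5
  fam_id <- ceiling(seq_len(n) / fam_size)
  fams <- sprintf("fam_%02d", fam_id)
  fams[fam_id == max(fam_id) %/% 2] <- "Turdidae"

  cells <- vector("list", n)
  true_volumes <- numeric(n)
  for (i in seq_len(n)) {
    p_base <- exp(spec$gyre_log[["intercept"]] +
                    spec$gyre_log[["length"]] * ls[i] + u$gyre[i])
    n_g <- max(4, round_half_up(mid_cell[i] / p_base))
    n_int <- n_g - 1
    t_int <- (seq_len(n_int) - 1) / (n_int - 1)
    iv <- exp(linpred(spec$gyre_log, t_int, ls[i]) + u$gyre[i] +
                stats::rnorm(n_int, 0, spec$gyre_sd_resid))
    centers <- iv[1] / 2 + c(0, cumsum(iv))

    nw <- 2 * n_g
    x_w <- (seq_len(nw) - 1) / (nw - 1)
    f <- linpred(spec$flag_diameter, x_w, ls[i]) + u$flag[i] +
      stats::rnorm(nw, 0, spec$flag_sd_resid)
    f <- pmax(f, 0.05)
    mnr <- exp(linpred(spec$minor_log, x_w, ls[i]) + u$minor[i] +
                 stats::rnorm(nw, 0, spec$minor_sd_resid))
    gyre_of <- ceiling(seq_len(nw) / 2)
    half_of <- rep(c(1L, 2L), n_g)
    iv_local <- iv[pmin(gyre_of, n_int)]
    pos_w <- centers[gyre_of] + ifelse(half_of == 1L, -1, 1) * iv_local / 4

    x_a <- (seq_len(n_g) - 1) / (n_g - 1)
    a <- exp(linpred(spec$major_log, x_a, ls[i]) + u$major[i] +
               stats::rnorm(n_g, 0, spec$major_sd_resid))

    m <- data.frame(
      gyre_index = c(gyre_of, gyre_of, seq_len(n_g)),
      half = c(half_of, half_of, rep(1L, n_g)),
      kind = c(rep("flagellum_width", nw), rep("flagellum_plus_minor", nw),
               rep("major_axis", n_g)),
      value_um = c(f, f + mnr, a),
      center_position_um = c(pos_w, pos_w, centers)
    )
    m$obscured <- FALSE
    if (noise$p_missing_value > 0) {
      hide <- stats::runif(nrow(m)) < noise$p_missing_value
      # keep at least one value of every kind so imputation stays possible
      for (k in unique(m$kind)) {
        rows <- which(m$kind == k)
        if (all(hide[rows])) hide[rows[1]] <- FALSE
      }
      m$value_um[hide] <- NA_real_
      m$obscured <- hide
    }

    midpiece_i <- centers[n_g] + iv[n_int] / 2
    nucleus_i <- max((spec$flag_diameter[["intercept"]] +
                        spec$flag_diameter[["length"]] * ls[i] + u$flag[i] -
                        0.13) / 0.27 + stats::rnorm(1, 0, 0.02), 0.2)
    cells[[i]] <- cell_record(
      cell_id = sprintf("cell_%02d", i),
      species = tree$tip.label[i],
      family = fams[i],
      measurements = m,
      midpiece_um = midpiece_i,
      tail_um = max(flag_cell[i] - midpiece_i, 1),
      nucleus_diameter_um = nucleus_i
    )

    # noise-free widths on the realized gyre layout define the cell's target
    # volume for the volume-recovery checks
    f0 <- linpred(spec$flag_diameter, x_w, ls[i]) + u$flag[i]
    m0 <- exp(linpred(spec$minor_log, x_w, ls[i]) + u$minor[i])
    a0 <- exp(linpred(spec$major_log, x_a, ls[i]) + u$major[i])
    fbar <- (f0[c(TRUE, FALSE)] + f0[c(FALSE, TRUE)]) / 2
    mbar <- (m0[c(TRUE, FALSE)] + m0[c(FALSE, TRUE)]) / 2
    iv_g <- c(iv, iv[n_int])
    true_volumes[i] <- sum(pi * (a0 / 2) * (mbar / 2) *
                             sqrt(iv_g^2 + (pi * fbar)^2))
  }

  species_table <- traits[, c("species", "head_um", "midpiece_um", "tail_um")]
  truth <- list(
    spec = spec,
    lambda = c(
      flag = spec$flag_sd_species^2 /
        (spec$flag_sd_species^2 + spec$flag_sd_resid^2),
      minor = spec$minor_sd_species^2 /
        (spec$minor_sd_species^2 + spec$minor_sd_resid^2),
      major = spec$major_sd_species^2 /
        (spec$major_sd_species^2 + spec$major_sd_resid^2),
      gyre = spec$gyre_sd_species^2 /
        (spec$gyre_sd_species^2 + spec$gyre_sd_resid^2)
    ),
    flagellum_cell_um = flag_cell,
    length_scaled = ls,
    species_effects = u,
    true_volumes_um3 = stats::setNames(true_volumes, tree$tip.label)
  )
  list(tree = tree, species_table = species_table, cells = cells,
       truth = truth)
}

#' Simulate repeated measurements of fixed points
#'
#' Emulates a repeatability protocol: a set of measurement points (optionally
#' of several measurement kinds) each measured `n_repeats` times with
#' multiplicative lognormal error. If `true_values` is omitted, a default
#' protocol of 4 cells x 3 gyres x 3 kinds is generated with typical passerine
#' widths whose spread gives a generating ICC near 0.998.
#'
#' @param true_values Numeric vector of true point values (um); optional.
#' @param cv Coefficient of variation of the measurement error.
#' @param n_repeats Repeats per point (>= 2).
#' @param kind Optional kind label per point (fixed effect downstream).
#' @param seed Optional integer seed.
#' @return List with `data` (point_id, kind, rep, value) and `truth`
#'   (sigma2_point, sigma2_within, icc).
#' @export
simulate_repeat_measures <- function(true_values = NULL, cv = 0.02,
                                     n_repeats = 4, kind = NULL,
                                     seed = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (n_repeats < 2) stop("need >= 2 repeats")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_values)) {
    kinds <- c(major_axis = 0.20, flagellum_width = 0.30,
               flagellum_plus_minor = 0.45)
    n_points <- 12                       # 4 cells x 3 gyres
    kind <- rep(names(kinds), each = n_points)
    true_values <- rep(kinds, each = n_points) *
      exp(stats::rnorm(3 * n_points, 0, 0.4))
  }
  n_pt <- length(true_values)
  if (is.null(kind)) kind <- rep("value", n_pt)
  if (length(kind) != n_pt) stop("kind must match true_values in length")
  dat <- data.frame(
    point_id = rep(sprintf("pt_%02d", seq_len(n_pt)), each = n_repeats),
    kind = rep(kind, each = n_repeats),
    rep = rep(seq_len(n_repeats), n_pt),
    value = rep(true_values, each = n_repeats) *
      lognormal_factor(n_pt * n_repeats, cv)
  )
  centred <- true_values - stats::ave(true_values, kind)
  s2p <- stats::var(centred)
  s2w <- mean((true_values * cv)^2)
  list(data = dat,
       truth = list(sigma2_point = s2p, sigma2_within = s2w,
                    icc = if (s2p + s2w == 0) 1 else s2p / (s2p + s2w)))
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs [simulate_study()] and writes the four pipeline inputs (measurement
#' CSV, cell CSV, species CSV, newick tree) plus a JSON truth record holding
#' every generating parameter and the per-cell noise-free volumes.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [comparative_spec()].
#' @param noise A [noise_spec()].
#' @return Invisibly, a list with the file paths and the truth record.
#' @export
generate_dataset <- function(dir, spec = comparative_spec(),
                             noise = noise_spec()) {
  study <- simulate_study(spec, noise)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    measurements = file.path(dir, "measurements.csv"),
    cells = file.path(dir, "cells.csv"),
    species = file.path(dir, "species.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_measurements(study$cells, paths$measurements)
  write_cells(study$cells, paths$cells)
  utils::write.csv(study$species_table, paths$species, row.names = FALSE)
  ape::write.tree(study$tree, paths$tree)
  truth_out <- study$truth
  truth_out$spec <- truth_out$spec[!vapply(truth_out$spec, is.null,
                                           logical(1))]
  jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(study = study)))
}
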