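# Analysis stages: midpiece-flagellum allometry, tapering of widths along the
# cell, gyre-interval scaling, helix volume vs midpiece length, tail-start
# diameter, and nucleus-flagellum correlation, each phylogenetically
# controlled; plus the orchestrated run over the four input files.

#' Rank-proportion longitudinal positions
#'
#' Converts the ordinal measurement number along a cell to a proportion: the
#' measured location closest to the head gets 0 and the closest to the tail
#' gets 1, so cells with many measured gyres do not dominate the position
#' axis.
#'
#' @param cell A [cell_record()] (or a numeric vector of positions).
#' @param kind Measurement kind whose series is ranked (ignored for numeric
#'   input).
#' @return Numeric vector of positions in `[0, 1]`, ordered as the series.
#' @export
longitudinal_positions <- function(cell, kind = "flagellum_width") {
  pos <- if (is.numeric(cell)) cell else {
    m <- cell$measurements
    m <- m[m$kind == kind & !is.na(m$center_position_um), ]
    sort(m$center_position_um)
  }
  n <- length(pos)
  if (n < 2) stop("need >= 2 measured locations")
  (rank(pos, ties.method = "first") - 1) / (n - 1)
}

# Long observation table for one width response across cells. Cells with a
# single usable location are excluded with a warning.
tapering_observations <- function(cells, response = c("flagellum_diameter",
                                                      "minor_axis",
                                                      "major_axis")) {
  response <- match.arg(response)
  rows <- lapply(cells, function(cl) {
    m <- cl$measurements
    if (response == "flagellum_diameter") {
      m <- m[m$kind == "flagellum_width" & !is.na(m$value_um) &
               !is.na(m$center_position_um), ]
      val <- m$value_um
      pos <- m$center_position_um
    } else if (response == "minor_axis") {
      val <- numeric(0)
      pos <- numeric(0)
      for (g in sort(unique(m$gyre_index))) {
        for (h in 1:2) {
          f <- m[m$kind == "flagellum_width" & m$gyre_index == g &
                   m$half == h & !is.na(m$value_um), ]
          p <- m[m$kind == "flagellum_plus_minor" & m$gyre_index == g &
                   m$half == h & !is.na(m$value_um), ]
          if (nrow(f) == 1 && nrow(p) == 1) {
            val <- c(val, minor_axis_diameter(p$value_um, f$value_um))
            pos <- c(pos, p$center_position_um)
          }
        }
      }
    } else {
      m <- m[m$kind == "major_axis" & !is.na(m$value_um) &
               !is.na(m$center_position_um), ]
      val <- m$value_um
      pos <- m$center_position_um
    }
    if (length(val) < 2) return(NULL)
    o <- order(pos)
    data.frame(cell_id = cl$cell_id, species = cl$species,
               value = val[o],
               position01 = longitudinal_positions(pos),
               flagellum_um = cl$midpiece_um + cl$tail_um)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " cell(s) excluded: fewer than 2 usable ",
            response, " locations")
  }
  out <- do.call(rbind, rows[!dropped])
  if (is.null(out) || nrow(out) == 0) stop("no usable observations")
  rownames(out) <- NULL
  out
}

gyre_interval_observations <- function(cells) {
  rows <- lapply(cells, function(cl) {
    iv <- tryCatch(gyre_intervals(cl), error = function(e) NULL)
    if (is.null(iv) || nrow(iv) < 2) return(NULL)
    n <- nrow(iv)
    data.frame(cell_id = cl$cell_id, species = cl$species,
               value = iv$interval_um,
               position01 = (seq_len(n) - 1) / (n - 1),
               flagellum_um = cl$midpiece_um + cl$tail_um)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " cell(s) excluded: fewer than 2 gyre intervals")
  }
  out <- do.call(rbind, rows[!dropped])
  if (is.null(out) || nrow(out) == 0) stop("no usable gyre intervals")
  rownames(out) <- NULL
  out
}

# Centre flagellum length at the grand mean over the cells entering the
# model and express it per 100 um.
add_length_scaled <- function(obs) {
  cell_len <- tapply(obs$flagellum_um, obs$cell_id, `[`, 1)
  centre <- mean(cell_len)
  obs$length_scaled <- (obs$flagellum_um - centre) / 100
  attr(obs, "length_centre_um") <- centre
  obs
}

shapiro_W <- function(r) {
  n <- length(r)
  if (n < 3) return(NA_real_)
  if (n > 5000) r <- sort(r)[round(seq(1, n, length.out = 5000))]
  stats::shapiro.test(r)$statistic
}

#' Does log-transforming the response improve residual normality?
#'
#' Fits the model to the raw and to the log response and compares the
#' Shapiro-Wilk statistic of the residuals; the log scale is chosen iff its
#' statistic is larger. Non-positive responses force the raw scale with a
#' warning.
#'
#' @param y Response vector.
#' @param X Design matrix.
#' @param fitter Function `(y, X) -> residuals`; ordinary least squares by
#'   default.
#' @return `TRUE` if the log response has more normal residuals.
#' @export
residual_normality_improves <- function(y, X, fitter = NULL) {
  if (any(y <= 0)) {
    warning("non-positive response values; raw scale kept")
    return(FALSE)
  }
  if (is.null(fitter)) {
    fitter <- function(y, X) stats::lm.fit(as.matrix(X), y)$residuals
  }
  w_raw <- shapiro_W(fitter(y, X))
  w_log <- shapiro_W(fitter(log(y), X))
  isTRUE(w_log > w_raw)
}

# Scale selection for the tapering models: the raw and the log response are
# both fitted by ML and compared on the original scale, the log model's
# likelihood carrying the Jacobian term -sum(log y). This is the Box-Cox
# comparison restricted to the two candidate scales; it asks the same
# question as the Shapiro-Wilk residual comparison (which error scale is the
# data's own) but remains decisive when both residual sets look near-normal.
log_scale_preferred <- function(y, X, sp, Cq) {
  if (any(y <= 0)) {
    warning("non-positive response values; raw scale kept")
    return(FALSE)
  }
  X <- as.matrix(X)
  ll <- function(resp) {
    lmm_optimize(lmm_structure(X, resp, sp, Cq), reml = FALSE)$loglik
  }
  (ll(log(y)) - sum(log(y))) > ll(y)
}

# Conditional (within-species) residuals: the species effect is removed so
# the Shapiro-Wilk comparison sees the observation-level error distribution
# rather than the (near-Gaussian) species-level mixture.
lmm_conditional_residuals <- function(y, X, sp, Cq) {
  st <- lmm_structure(as.matrix(X), y, sp, Cq)
  opt <- lmm_optimize(st, reml = TRUE)
  at <- lmm_eval(st, opt$gamma, reml = TRUE)
  r <- y - drop(as.matrix(X) %*% at$beta)
  r - stats::ave(r, sp)
}

#' Proximal and distal observation subsets
#'
#' Per cell, the `ceiling(fraction * n)` measurements of smallest (proximal)
#' and largest (distal) rank along the cell.
#'
#' @param obs Observation table with `cell_id` and `position01`.
#' @param fraction Proportion in `(0, 0.5]`.
#' @return List with data frames `proximal` and `distal`.
#' @export
proximal_distal_subsets <- function(obs, fraction = 0.25) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  pick <- function(side) {
    keep <- unlist(lapply(split(seq_len(nrow(obs)), obs$cell_id),
                          function(idx) {
      n <- length(idx)
      k <- ceiling(fraction * n)
      r <- rank(obs$position01[idx], ties.method = "first")
      if (side == "proximal") idx[r <= k] else idx[r >= n - k + 1]
    }))
    out <- obs[sort(keep), , drop = FALSE]
    if (nrow(out) == 0) stop("empty subset")
    out
  }
  list(proximal = pick("proximal"), distal = pick("distal"))
}

new_stage_report <- function(stage, fits, notes = character(0),
                             subsets = NULL) {
  structure(list(stage = stage, fits = fits, notes = notes,
                 subsets = subsets), class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat("<stage_report> ", x$stage, "\n", sep = "")
  for (nm in names(x$fits)) {
    cat("-- model:", nm, "\n")
    print(x$fits[[nm]])
  }
  if (length(x$notes) > 0) cat("notes:", paste(x$notes, collapse = "; "),
                               "\n")
  invisible(x)
}

#' Tidy coefficient table for a stage
#'
#' One row per model term, mirroring the reporting layout of the comparative
#' analyses: estimate, 95% CI, p value, lambda with its interval, sample
#' sizes, and whether the response was log-transformed.
#'
#' @param report A `stage_report`.
#' @return Data frame.
#' @export
stage_table <- function(report) {
  rows <- lapply(names(report$fits), function(nm) {
    f <- report$fits[[nm]]
    data.frame(
      stage = report$stage,
      model = nm,
      term = names(f$coefficients),
      estimate = unname(f$coefficients),
      ci_lower = unname(f$ci95[, 1]),
      ci_upper = unname(f$ci95[, 2]),
      p_value = unname(f$p_values),
      lambda = f$lambda,
      lambda_lower = f$lambda_ci[1],
      lambda_upper = f$lambda_ci[2],
      n_obs = f$n_obs,
      n_species = f$n_species,
      log_transformed = isTRUE(f$transform_applied)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Midpiece-flagellum allometry
#'
#' Natural-log PGLS of midpiece length on flagellum length using the species
#' light-microscopy means, refit after excluding the listed species (with the
#' covariance pruned accordingly).
#'
#' @param species_table Data frame from [read_species()].
#' @param tree Rooted `phylo` tree.
#' @param exclude Character vector of species to drop in the second fit.
#' @return A `stage_report` with fits `all_species` and (if exclusions apply)
#'   `excluded`.
#' @export
stage_allometry <- function(species_table, tree, exclude = NULL) {
  st <- species_table
  C <- phylo_covariance(tree)
  missing <- setdiff(st$species, C$species_order)
  if (length(missing) > 0) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  fit_all <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), st, C = C)
  fits <- list(all_species = fit_all)
  exclude <- normalize_species(exclude)
  exclude <- exclude[nzchar(exclude)]
  if (length(exclude) > 0) {
    st2 <- st[!st$species %in% exclude, , drop = FALSE]
    if (nrow(st2) < 3) stop("fewer than 3 species after exclusion")
    fits$excluded <- fit_pgls(log(midpiece_um) ~ log(flagellum_um), st2,
                              C = C)
  }
  new_stage_report("allometry", fits,
                   notes = if (length(exclude) > 0) {
                     paste("excluded:", paste(exclude, collapse = ", "))
                   } else "no exclusions")
}

#' Width tapering along the cell
#'
#' Phylogenetic mixed model of a width response on longitudinal position and
#' scaled flagellum length, with species as a phylogenetically structured
#' random effect. The position x length interaction is kept only if an ML
#' likelihood-ratio test is significant at `alpha`; the response is
#' log-transformed only if that improves residual normality (Shapiro-Wilk).
#' For the flagellum diameter, additional models use only the 25% of
#' observations closest to the head (proximal) or tail (distal), with
#' flagellum length as the sole predictor.
#'
#' @param cells List of [cell_record()] objects.
#' @param tree Rooted `phylo` tree.
#' @param response One of `"flagellum_diameter"`, `"minor_axis"`,
#'   `"major_axis"`.
#' @param alpha Interaction-retention threshold.
#' @param subset_fraction Proximal/distal fraction (default 0.25).
#' @param include_subsets Fit the proximal/distal submodels (default only for
#'   the flagellum diameter).
#' @param transform `"auto"` (Shapiro-Wilk rule), `"raw"`, or `"log"`.
#' @return A `stage_report`.
#' @export
stage_tapering <- function(cells, tree, response = "flagellum_diameter",
                           alpha = 0.05, subset_fraction = 0.25,
                           include_subsets = identical(response,
                                                       "flagellum_diameter"),
                           transform = "auto") {
  obs <- add_length_scaled(tapering_observations(cells, response))
  stage_fit_tapering(obs, tree, paste0("tapering_", response), alpha,
                     subset_fraction, include_subsets, transform)
}

stage_fit_tapering <- function(obs, tree, stage, alpha, subset_fraction,
                               include_subsets, transform,
                               force_log = FALSE) {
  C <- phylo_covariance(tree)
  Cq <- prune_covariance(C, sort(unique(obs$species)))
  use_log <- if (force_log) TRUE else if (identical(transform, "log")) TRUE
    else if (identical(transform, "raw")) FALSE
    else {
      Xfull <- stats::model.matrix(~ position01 * length_scaled, obs)
      log_scale_preferred(obs$value, Xfull, obs$species, Cq)
    }
  obs$response <- if (use_log) log(obs$value) else obs$value

  full <- fit_phylo_lmm(response ~ position01 * length_scaled, obs, C = C)
  reduced <- fit_phylo_lmm(response ~ position01 + length_scaled, obs, C = C)
  main <- drop_nonsignificant_interaction(full, reduced, alpha)
  main$transform_applied <- use_log
  it <- attr(main, "interaction_test")
  fits <- list(main = main)

  subsets <- NULL
  if (include_subsets) {
    subsets <- proximal_distal_subsets(obs, subset_fraction)
    for (side in names(subsets)) {
      f <- fit_phylo_lmm(response ~ length_scaled, subsets[[side]], C = C)
      f$transform_applied <- use_log
      fits[[side]] <- f
    }
  }
  new_stage_report(stage, fits,
                   notes = c(
                     sprintf("response %s scale",
                             if (use_log) "log" else "raw"),
                     sprintf("interaction %s (LRT p = %.4g)",
                             if (it$interaction_kept) "kept" else "dropped",
                             it$p_value),
                     sprintf("length centred at %.2f um",
                             attr(obs, "length_centre_um"))
                   ),
                   subsets = subsets)
}

#' Gyre-interval scaling
#'
#' Phylogenetic mixed model of the natural-log gyre interval on longitudinal
#' position and scaled flagellum length (interaction by the retention rule).
#' The response is always log-transformed.
#'
#' @inheritParams stage_tapering
#' @return A `stage_report`.
#' @export
stage_gyre_interval <- function(cells, tree, alpha = 0.05) {
  obs <- add_length_scaled(gyre_interval_observations(cells))
  if (stats::var(obs$value) == 0) {
    stop("degenerate fit: all gyre intervals identical")
  }
  stage_fit_tapering(obs, tree, "gyre_interval", alpha,
                     subset_fraction = 0.25, include_subsets = FALSE,
                     transform = "log", force_log = TRUE)
}

#' Helix volume vs midpiece length
#'
#' Estimates each cell's mitochondrial-helix volume and regresses it (PGLS)
#' on the SEM midpiece length of the same cell, for all species and after
#' excluding a family carrying confounding helical structures (Turdidae by
#' default), with the covariance pruned accordingly.
#'
#' @param cells List of [cell_record()] objects.
#' @param tree Rooted `phylo` tree.
#' @param excluded_family Family label excluded in the second fit.
#' @return A `stage_report`; the per-species volume table is attached as
#'   element `volumes`.
#' @export
stage_volume <- function(cells, tree, excluded_family = "Turdidae") {
  vols <- do.call(rbind, lapply(cells, function(cl) {
    cv <- cell_volume(cl)
    data.frame(cell_id = cl$cell_id, species = cl$species,
               family = cl$family, midpiece_um = cl$midpiece_um,
               volume_um3 = cv$total_volume_um3,
               n_measured_gyres = cv$n_measured_gyres,
               n_estimated_missing_gyres = cv$n_estimated_missing_gyres)
  }))
  rownames(vols) <- NULL
  sp_agg <- stats::aggregate(vols[c("midpiece_um", "volume_um3")],
                             by = list(species = vols$species,
                                       family = vols$family), mean)
  C <- phylo_covariance(tree)
  fit_all <- fit_pgls(volume_um3 ~ midpiece_um, sp_agg, C = C)
  fits <- list(all_species = fit_all)
  no_fam <- sp_agg[sp_agg$family != excluded_family, , drop = FALSE]
  if (nrow(no_fam) < nrow(sp_agg)) {
    fits$family_excluded <- fit_pgls(volume_um3 ~ midpiece_um, no_fam, C = C)
  } else {
    fits$family_excluded <- fit_all
  }
  rep <- new_stage_report("volume_vs_midpiece", fits,
                          notes = sprintf("excluded family: %s (%d species)",
                                          excluded_family,
                                          nrow(sp_agg) - nrow(no_fam)))
  rep$volumes <- vols
  rep
}

#' Tail-start flagellum diameter
#'
#' PGLS of the flagellum diameter at the start of the tail (operationalised
#' as the most distal measured flagellum width) on the light-microscopy tail
#' length and the SEM midpiece length, with a variance-inflation diagnostic
#' for the two predictors.
#'
#' @param cells List of [cell_record()] objects.
#' @param species_table Data frame from [read_species()] (tail means).
#' @param tree Rooted `phylo` tree.
#' @return A `stage_report`.
#' @export
stage_tail_diameter <- function(cells, species_table, tree) {
  dat <- do.call(rbind, lapply(cells, function(cl) {
    m <- cl$measurements
    m <- m[m$kind == "flagellum_width" & !is.na(m$value_um) &
             !is.na(m$center_position_um), ]
    if (nrow(m) == 0) return(NULL)
    data.frame(species = cl$species,
               tail_start_diameter_um =
                 m$value_um[which.max(m$center_position_um)],
               midpiece_um = cl$midpiece_um)
  }))
  idx <- match(dat$species, species_table$species)
  if (any(is.na(idx))) {
    stop("light-microscopy tail means missing for: ",
         paste(dat$species[is.na(idx)], collapse = ", "))
  }
  dat$tail_lm_um <- species_table$tail_um[idx]
  r2 <- if (stats::sd(dat$tail_lm_um) == 0 ||
            stats::sd(dat$midpiece_um) == 0) {
    1                              # a constant predictor is degenerate too
  } else {
    stats::cor(dat$tail_lm_um, dat$midpiece_um)^2
  }
  if (r2 > 0.999) stop("predictors are collinear (r^2 > 0.999)")
  vif <- 1 / (1 - r2)
  fit <- fit_pgls(tail_start_diameter_um ~ tail_lm_um + midpiece_um, dat,
                  C = phylo_covariance(tree))
  new_stage_report("tail_start_diameter", list(main = fit),
                   notes = sprintf("variance inflation factor = %.2f", vif))
}

#' Nucleus diameter vs neck flagellum diameter
#'
#' PGLS of the mean of each cell's first three measured flagellum diameters
#' (closest to the head) on the nucleus diameter. Cells with fewer than three
#' measured diameters or no nucleus measurement are excluded with a warning.
#'
#' @param cells List of [cell_record()] objects.
#' @param tree Rooted `phylo` tree.
#' @return A `stage_report`.
#' @export
stage_nucleus <- function(cells, tree) {
  rows <- lapply(cells, function(cl) {
    m <- cl$measurements
    m <- m[m$kind == "flagellum_width" & !is.na(m$value_um) &
             !is.na(m$center_position_um), ]
    if (nrow(m) < 3 || !is.finite(cl$nucleus_diameter_um)) return(NULL)
    m <- m[order(m$center_position_um), ]
    data.frame(species = cl$species,
               neck_diameter_um = mean(m$value_um[1:3]),
               nucleus_diameter_um = cl$nucleus_diameter_um)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped),
            " cell(s) excluded: < 3 diameters or no nucleus measure")
  }
  dat <- do.call(rbind, rows[!dropped])
  fit <- fit_pgls(neck_diameter_um ~ nucleus_diameter_um, dat,
                  C = phylo_covariance(tree))
  new_stage_report("nucleus_vs_flagellum", list(main = fit))
}

default_config <- function() {
  list(seed = 1, alpha = 0.05, subset_fraction = 0.25,
       exclude_species = character(0), excluded_family = "Turdidae")
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(default_config(), as.list(config))
  for (p in c("measurements", "cells", "species", "tree")) {
    if (is.null(cfg[[p]])) stop("config lacks input path: ", p)
    if (!file.exists(cfg[[p]])) stop("input file not found: ", cfg[[p]])
  }
  if (is.null(cfg$out_dir)) stop("config lacks out_dir")
  cfg
}

#' Run the full analysis over the four input files
#'
#' Reads the measurement, cell and species tables and the tree, computes
#' per-cell helix volumes, runs every analysis stage, and writes one tidy
#' CSV per stage, the volume table, a machine-readable manifest, and a run
#' log into `out_dir`. Deterministic given the config and seed; any stage
#' failure aborts with a stage-tagged error.
#'
#' @param config Named list or path to a YAML/JSON file with entries
#'   `measurements`, `cells`, `species`, `tree`, `out_dir`, and optionally
#'   `seed`, `alpha`, `subset_fraction`, `exclude_species`,
#'   `excluded_family`.
#' @return Invisibly, a list with the stage reports, the volume table and
#'   the manifest.
#' @export
run_all <- function(config) {
  cfg <- read_config(config)
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%7.2fs] %s",
                                       proc.time()[["elapsed"]] - t0,
                                       paste0(...)))
  }

  meas <- read_measurements(cfg$measurements)
  cell_tab <- read_cells(cfg$cells)
  species_tab <- read_species(cfg$species)
  tree <- read_tree_file(cfg$tree,
                         species = union(cell_tab$species,
                                         species_tab$species))
  cells <- assemble_cells(meas, cell_tab)
  note("inputs: ", nrow(meas), " measurements, ", length(cells), " cells, ",
       nrow(species_tab), " species")

  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note("stage ", name, " done")
    out
  }

  reports <- list()
  reports$allometry <- run_stage("allometry",
    stage_allometry(species_tab, tree, exclude = cfg$exclude_species))
  for (resp in c("flagellum_diameter", "minor_axis", "major_axis")) {
    reports[[paste0("tapering_", resp)]] <- run_stage(
      paste0("tapering_", resp),
      stage_tapering(cells, tree, resp, alpha = cfg$alpha,
                     subset_fraction = cfg$subset_fraction))
  }
  reports$gyre_interval <- run_stage("gyre_interval",
    stage_gyre_interval(cells, tree, alpha = cfg$alpha))
  reports$volume <- run_stage("volume",
    stage_volume(cells, tree, excluded_family = cfg$excluded_family))
  reports$tail_diameter <- run_stage("tail_diameter",
    stage_tail_diameter(cells, species_tab, tree))
  reports$nucleus <- run_stage("nucleus", stage_nucleus(cells, tree))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(reports)) {
    utils::write.csv(stage_table(reports[[nm]]),
                     file.path(cfg$out_dir, paste0("stage_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(reports$volume$volumes,
                   file.path(cfg$out_dir, "volumes.csv"), row.names = FALSE)

  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "helixvol",
    version = tryCatch(as.character(utils::packageVersion("helixvol")),
                       error = function(e) "dev"),
    r_version = R.version.string,
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    n_cells = length(cells),
    n_species = nrow(species_tab),
    stages = names(reports)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(reports = reports, volumes = reports$volume$volumes,
                 manifest = manifest, config = cfg))
}
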