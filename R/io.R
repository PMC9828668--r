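# Readers and writers for the measurement/cell/species CSV dialects and the
# newick tree. All lengths are micrometres; volumes cubic micrometres. CSV is
# RFC-4180 with a mandatory header row, UTF-8.

#' Normalise a species name
#'
#' Tree tip labels and table entries may differ in underscore/space
#' convention; both are mapped to underscores before matching.
#' @param x Character vector of names.
#' @return Normalised names.
#' @export
normalize_species <- function(x) gsub(" ", "_", trimws(as.character(x)))

io_stop <- function(path, ...) stop("[", path, "] ", ..., call. = FALSE)

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    io_stop(path, "missing column(s): ", paste(missing, collapse = ", "))
  }
}

#' Read the per-measurement CSV
#'
#' One row per width measurement with columns `cell_id, species, family,
#' gyre_index, half, kind, value_um, center_position_um, obscured`.
#' Schema violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return Data frame of typed measurement rows.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) io_stop(path, "file not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) io_stop(path, "no records")
  require_columns(df, c("cell_id", "species", "family", "gyre_index", "half",
                        "kind", "value_um", "center_position_um", "obscured"),
                  path)
  df$gyre_index <- as.integer(df$gyre_index)
  df$half <- as.integer(df$half)
  df$value_um <- suppressWarnings(as.numeric(df$value_um))
  df$center_position_um <- suppressWarnings(as.numeric(df$center_position_um))
  df$obscured <- as.logical(df$obscured)
  df$species <- normalize_species(df$species)

  bad <- which(!df$kind %in% measurement_kinds())
  if (length(bad) > 0) io_stop(path, "unknown kind at row(s): ",
                               paste(bad, collapse = ", "))
  bad <- which(!df$obscured & (is.na(df$value_um) | df$value_um <= 0))
  if (length(bad) > 0) io_stop(path, "non-positive or missing width at ",
                               "non-obscured row(s): ",
                               paste(bad, collapse = ", "))
  key <- paste(df$cell_id, df$gyre_index, df$half, df$kind)
  if (anyDuplicated(key)) {
    io_stop(path, "duplicate (cell, gyre, half, kind) at row(s): ",
            paste(which(duplicated(key)), collapse = ", "))
  }
  # pairwise width consistency, addressed by row
  fl <- df$kind == "flagellum_width" & !is.na(df$value_um)
  fp <- df$kind == "flagellum_plus_minor" & !is.na(df$value_um)
  k2 <- paste(df$cell_id, df$gyre_index, df$half)
  idx <- match(k2[fp], k2[fl])
  bad <- which(fp)[!is.na(idx) &
                     df$value_um[fp] < df$value_um[which(fl)[idx]]]
  if (length(bad) > 0) {
    io_stop(path, "combined width smaller than flagellum width at row(s): ",
            paste(bad, collapse = ", "))
  }
  df
}

#' Read the per-cell CSV
#'
#' Columns `cell_id, species, family, midpiece_um, tail_um,
#' nucleus_diameter_um, obscured_sections_um` (the last a semicolon-separated
#' list of lengths, possibly empty).
#'
#' @param path CSV file path.
#' @return Data frame, one row per cell; `obscured_sections_um` is a list
#'   column of numeric vectors.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) io_stop(path, "file not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(obscured_sections_um = "character"))
  if (nrow(df) == 0) io_stop(path, "no records")
  require_columns(df, c("cell_id", "species", "family", "midpiece_um",
                        "tail_um", "nucleus_diameter_um",
                        "obscured_sections_um"), path)
  df$species <- normalize_species(df$species)
  bad <- which(!is.finite(df$midpiece_um) | !is.finite(df$tail_um) |
                 df$midpiece_um + df$tail_um <= 0)
  if (length(bad) > 0) io_stop(path, "invalid segment lengths at row(s): ",
                               paste(bad, collapse = ", "))
  df$obscured_sections_um <- lapply(df$obscured_sections_um, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  df
}

#' Read the species light-microscopy table
#'
#' Columns `species, head_um, midpiece_um, tail_um` (species means).
#'
#' @param path CSV file path.
#' @return Data frame with a derived `flagellum_um = midpiece_um + tail_um`.
#' @export
read_species <- function(path) {
  if (!file.exists(path)) io_stop(path, "file not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) io_stop(path, "no records")
  require_columns(df, c("species", "head_um", "midpiece_um", "tail_um"), path)
  df$species <- normalize_species(df$species)
  df$flagellum_um <- df$midpiece_um + df$tail_um
  df
}

#' Read a rooted newick tree with branch lengths
#'
#' @param path Newick file path.
#' @param species Optional character vector of species names that must all
#'   appear among the (normalised) tip labels; mismatches are listed.
#' @return A `phylo` tree with normalised tip labels.
#' @export
read_tree_file <- function(path, species = NULL) {
  if (!file.exists(path)) io_stop(path, "file not found")
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) io_stop(path, "not a parseable newick tree")
  if (is.null(tr$edge.length)) io_stop(path, "tree has no branch lengths")
  if (any(!nzchar(tr$tip.label))) io_stop(path, "tree has unlabelled tips")
  tr$tip.label <- normalize_species(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) io_stop(path, "duplicate tip labels")
  # trees with a basal polytomy are read as rooted polytomies
  if (!is.null(species)) {
    missing <- setdiff(normalize_species(species), tr$tip.label)
    if (length(missing) > 0) {
      io_stop(path, "species absent from tree: ",
              paste(missing, collapse = ", "))
    }
  }
  tr
}

#' Assemble cell records from the two input tables
#'
#' @param measurements Data frame from [read_measurements()].
#' @param cells Data frame from [read_cells()].
#' @return Named list of [cell_record()] objects.
#' @export
assemble_cells <- function(measurements, cells) {
  extra <- setdiff(unique(measurements$cell_id), cells$cell_id)
  if (length(extra) > 0) {
    stop("measurement rows for unknown cell(s): ",
         paste(extra, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    m <- measurements[measurements$cell_id == row$cell_id,
                      c("gyre_index", "half", "kind", "value_um",
                        "center_position_um", "obscured")]
    if (nrow(m) == 0) stop("cell ", row$cell_id, " has no measurements")
    cell_record(
      cell_id = row$cell_id, species = row$species, family = row$family,
      measurements = m,
      midpiece_um = row$midpiece_um, tail_um = row$tail_um,
      nucleus_diameter_um = row$nucleus_diameter_um,
      obscured_sections_um = row$obscured_sections_um[[1]]
    )
  })
  stats::setNames(out, cells$cell_id)
}

#' Write cell measurement rows to the measurement CSV
#' @param cells List of [cell_record()] objects.
#' @param path Output CSV path.
#' @export
write_measurements <- function(cells, path) {
  rows <- lapply(cells, function(cl) {
    m <- cl$measurements
    data.frame(cell_id = cl$cell_id, species = cl$species,
               family = cl$family, m[c("gyre_index", "half", "kind",
                                       "value_um", "center_position_um",
                                       "obscured")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
}

#' Write the per-cell CSV
#' @param cells List of [cell_record()] objects.
#' @param path Output CSV path.
#' @export
write_cells <- function(cells, path) {
  df <- do.call(rbind, lapply(cells, function(cl) {
    data.frame(
      cell_id = cl$cell_id, species = cl$species, family = cl$family,
      midpiece_um = cl$midpiece_um, tail_um = cl$tail_um,
      nucleus_diameter_um = cl$nucleus_diameter_um,
      obscured_sections_um = paste(cl$obscured_sections_um, collapse = ";")
    )
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
}
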