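# Fixtures built in code: no data files.

# A cell with constant widths and pitch; volume has the closed form
# n * pi * (maj/2) * (minr/2) * sqrt(p^2 + (pi * d)^2).
make_constant_cell <- function(n_gyres = 5, d = 0.30, minr = 0.10,
                               maj = 0.20, pitch = 2.5,
                               cell_id = "const", species = "sp_a",
                               family = "fam", obscured_sections = numeric(0),
                               tail_um = 30) {
  rows <- lapply(seq_len(n_gyres), function(g) {
    c0 <- (g - 0.5) * pitch
    data.frame(
      gyre_index = g,
      half = c(1L, 2L, 1L, 2L, 1L),
      kind = c("flagellum_width", "flagellum_width",
               "flagellum_plus_minor", "flagellum_plus_minor", "major_axis"),
      value_um = c(d, d, d + minr, d + minr, maj),
      center_position_um = c(c0 - pitch / 4, c0 + pitch / 4,
                             c0 - pitch / 4, c0 + pitch / 4, c0),
      obscured = FALSE
    )
  })
  cell_record(cell_id = cell_id, species = species, family = family,
              measurements = do.call(rbind, rows),
              midpiece_um = n_gyres * pitch, tail_um = tail_um,
              nucleus_diameter_um = 0.6,
              obscured_sections_um = obscured_sections)
}

constant_cell_volume_closed_form <- function(n_gyres, d, minr, maj, pitch) {
  n_gyres * pi * (maj / 2) * (minr / 2) * sqrt(pitch^2 + (pi * d)^2)
}

# Independent GLS oracle: explicit matrix inversion, no shared code paths
# with gls_fit.
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}

# Small fixed trees.
star_tree_3 <- function() {
  ape::read.tree(text = "(a:1,b:1,c:1);")
}
sisters_tree <- function() {
  # a and b diverge at depth 0.6 of a unit-height tree
  ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
}
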