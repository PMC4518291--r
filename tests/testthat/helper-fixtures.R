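# shared fixtures, loaded once per test run
TMPL <- default_template()
PANEL <- default_reference_panel()
AQP4_REC <- aqp_record(TMPL$template_id, TMPL$template_peptide)

# independent brute-force NPA scan: walks every position by hand
oracle_npa_scan <- function(peptide, alike = c("A","S","T","V","L","I","M")) {
  n <- nchar(peptide)
  out <- integer(0)
  for (i in seq_len(max(0, n - 2))) {
    if (substr(peptide, i, i) == "N" &&
        substr(peptide, i + 1, i + 1) == "P" &&
        substr(peptide, i + 2, i + 2) %in% alike)
      out <- c(out, i)
  }
  out
}

# exhaustive fine-grid pore oracle: no refinement, just a dense grid
oracle_pore_radius <- function(atoms, z, disc = 5, grid_step = 0.02) {
  g <- seq(-disc, disc, by = grid_step)
  best <- 0
  for (px in g) for (py in g) {
    if (px^2 + py^2 > disc^2) next
    d <- sqrt((atoms$x - px)^2 + (atoms$y - py)^2 + (atoms$z - z)^2) -
      atoms$radius
    best <- max(best, min(d))
  }
  best
}

# exact cylinder model built in memory (no PDB coordinate rounding)
cylinder_model <- function(ring_radii, atoms_per_ring = 12, atom_radius = 1.7,
                           spacing = 2) {
  rows <- list()
  for (i in seq_along(ring_radii)) {
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
    rows[[i]] <- data.frame(element = "C",
                            x = ring_radii[i] * cos(ang),
                            y = ring_radii[i] * sin(ang),
                            z = (i - 1) * spacing,
                            radius = atom_radius)
  }
  structure_model(do.call(rbind, rows), source_id = "cylinder")
}

z_axis <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
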