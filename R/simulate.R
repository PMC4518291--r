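# run expr under a temporary, seeded RNG state; generators stay pure
# functions of (config, seed) and never disturb the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for every generator")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

NPA_ALIKE <- c("A", "S", "T", "V", "L", "I", "M")

# replace any non-planted N-P-[A-like] triplet so canonical scans stay clean
scrub_npa <- function(x, keep_starts, frozen) {
  repeat {
    hits <- gregexpr(paste0("NP[", paste(NPA_ALIKE, collapse = ""), "]"),
                     x, perl = TRUE)[[1]]
    hits <- hits[hits > 0 & !(hits %in% keep_starts)]
    if (length(hits) == 0L) return(x)
    for (h in hits) {
      tgt <- h + 1L
      if (tgt %in% frozen) tgt <- h + 2L
      if (tgt %in% frozen) tgt <- h
      if (tgt %in% frozen) stop("motif overlaps frozen sites; cannot scrub")
      substr(x, tgt, tgt) <- "G"
    }
  }
}

#' Recipe for a synthetic aquaporin cohort
#'
#' Defines how many sequences to derive per subfamily from the packaged
#' reference scaffolds, the per-site background substitution probability,
#' and the TMD5 residue distribution planted in Eglp sequences. Defaults
#' emulate the observed entomoglyceroporin residue spectrum: TMD5 drawn
#' from {Ala, Ser, Val} with weights 0.40/0.33/0.27, i.e. an expected 73%
#' Ala-or-Ser, while Prip and Drip sequences keep the conserved His.
#'
#' @param n Named integer vector: sequences per subfamily (names from
#'   `Glp`, `Prip`, `Drip`, `Eglp`, `Bib`, `Aqp12like`).
#' @param divergence Per-site background substitution probability at
#'   non-anchor sites (default 0.1; values above 0.5 warn, classification
#'   recovery is then not guaranteed).
#' @param eglp_tmd5_weights Named weights over the planted Eglp TMD5
#'   residues.
#' @param seed Mandatory RNG seed.
#' @return Object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n = c(Eglp = 10), divergence = 0.1,
                          eglp_tmd5_weights = c(A = 0.40, S = 0.33, V = 0.27),
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  bad <- setdiff(names(n), names(SUBFAMILY_BRANCH))
  if (length(bad)) stop("unknown subfamily in recipe: ", paste(bad, collapse = ", "))
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  if (divergence > 0.5)
    warning("divergence > 0.5: classification recovery is not guaranteed")
  w <- eglp_tmd5_weights / sum(eglp_tmd5_weights)
  structure(list(n = n, divergence = divergence,
                 eglp_tmd5_weights = w, seed = seed),
            class = "cohort_recipe")
}

#' Generate a synthetic aquaporin cohort with known truth
#'
#' Each sequence is derived from its subfamily's packaged reference scaffold
#' by seeded random substitutions at non-anchor sites; NPA boxes and the
#' ar/R quartet are planted exactly (Eglp TMD5 drawn from the recipe's
#' residue distribution). Substitution-created spurious NPA triplets are
#' scrubbed so every synthetic channel scans to exactly two boxes. The truth
#' table records subfamily, planted TMD5 residue and the permeability call
#' the TMD5 rule should make.
#'
#' @param recipe A [cohort_recipe].
#' @param panel A [reference_panel] providing the scaffolds (default
#'   packaged panel).
#' @param fasta Optional path: write the cohort as FASTA.
#' @return List with `records` (list of [aqp_record]) and `truth`
#'   (data.frame `id`, `subfamily`, `tmd5_aa`, `expected_prediction`).
#' @export
generate_aquaporin_cohort <- function(recipe, panel = default_reference_panel(),
                                      fasta = NULL) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  meta <- reference_panel_annotation()
  by_subfam <- setNames(names(panel$records), panel$subfamilies)
  with_seed(recipe$seed, {
    records <- list()
    truth <- list()
    k <- 0L
    for (sf in names(recipe$n)) {
      nn <- recipe$n[[sf]]
      if (nn == 0L) next
      ref_id <- by_subfam[[sf]]
      if (is.null(ref_id)) stop("panel has no reference for subfamily ", sf)
      scaffold <- panel$records[[ref_id]]$peptide
      mi <- meta[[ref_id]]
      anchor_pos <- c(mi$npa1_pos + 0:2, mi$npa2_pos + 0:2,
                      unlist(mi$arR_positions))
      frozen <- sort(unique(unlist(lapply(anchor_pos,
                                          function(p) (p - 2):(p + 2)))))
      frozen <- frozen[frozen >= 1 & frozen <= nchar(scaffold)]
      free <- setdiff(seq_len(nchar(scaffold)), frozen)
      tmd5_pos <- mi$arR_positions$TMD5
      for (i in seq_len(nn)) {
        k <- k + 1L
        x <- scaffold
        hit <- free[runif(length(free)) < recipe$divergence]
        for (s in hit) {
          cur <- substr(x, s, s)
          substr(x, s, s) <- sample(setdiff(AA_ALPHABET, cur), 1)
        }
        tmd5 <- mi$tmd5_aa
        if (sf == "Eglp") {
          tmd5 <- sample(names(recipe$eglp_tmd5_weights), 1,
                         prob = recipe$eglp_tmd5_weights)
          substr(x, tmd5_pos, tmd5_pos) <- tmd5
        }
        x <- scrub_npa(x, keep_starts = c(mi$npa1_pos, mi$npa2_pos),
                       frozen = frozen)
        id <- sprintf("syn_%s_%03d", sf, i)
        records[[id]] <- aqp_record(id, x, lineage_tags = sf)
        truth[[id]] <- data.frame(
          id = id, subfamily = sf, tmd5_aa = tmd5,
          expected_prediction = predict_permeability(
            tmd5, SUBFAMILY_BRANCH[[sf]])$prediction)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(0), subfamily = character(0),
                 tmd5_aa = character(0), expected_prediction = character(0))
    rownames(truth) <- NULL
    if (!is.null(fasta)) write_fasta(records, fasta)
    list(records = records, truth = truth)
  })
}

#' Configuration for the osmotic swelling simulator
#'
#' @param pf True osmotic water permeability, cm s^-1.
#' @param geometry An [oocyte_geometry]; default a 0.06 cm-radius sphere
#'   (V0 = 9.05e-4 cm^3, apparent area 4.52e-2 cm^2, 9x folding).
#' @param osm_in,osm_out Osmolalities, mOsm (defaults 200 and 20: isotonic
#'   medium and its 10-fold dilution).
#' @param sigma Gaussian noise s.d. on sampled relative volume
#'   (default 0.002, resembling video-tracking jitter).
#' @param times Sampling times, s (default 0 to 20 s every 2 s).
#' @param n_oocytes Number of replicate courses.
#' @param seed Mandatory RNG seed.
#' @return Object of class `swelling_sim_config`.
#' @export
swelling_sim_config <- function(pf, geometry = NULL, osm_in = 200,
                                osm_out = 20, sigma = 0.002,
                                times = seq(0, 20, by = 2),
                                n_oocytes = 10, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (pf < 0) stop("true Pf cannot be negative")
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (is.null(geometry)) {
    r <- 0.06
    geometry <- oocyte_geometry(V0 = 4 / 3 * pi * r^3,
                                apparent_area = 4 * pi * r^2)
  }
  structure(list(pf = pf, geometry = geometry, osm_in = osm_in,
                 osm_out = osm_out, sigma = sigma, times = times,
                 n_oocytes = n_oocytes, seed = seed),
            class = "swelling_sim_config")
}

#' Simulate oocyte swelling time-courses
#'
#' Integrates the two-compartment osmotic flux law
#' `dV/dt = Pf * S * Vw * (C_in(t) - C_out)` with the internal osmolyte
#' amount conserved, `C_in(t) = C_in(0) * V0 / V(t)`, by fixed-step RK4 at
#' 0.1 s, then samples `V/V0` at the configured times with i.i.d. Gaussian
#' noise. The analytic initial slope `Pf * S * Vw * (C_in - C_out) / V0` is
#' recorded as the ground truth for estimator checks.
#'
#' @param cfg A [swelling_sim_config].
#' @return List with `timecourses` (list of [swelling_timecourse]) and
#'   `truth` (list: `pf`, `initial_slope`).
#' @export
simulate_swelling <- function(cfg) {
  stopifnot(inherits(cfg, "swelling_sim_config"))
  g <- cfg$geometry
  Vw <- 18
  cin0 <- cfg$osm_in * 1e-6; cout <- cfg$osm_out * 1e-6  # mol cm^-3
  dVdt <- function(V) cfg$pf * g$S * Vw * (cin0 * g$V0 / V - cout)
  dt <- 0.1
  t_end <- max(cfg$times)
  steps <- round(t_end / dt)
  V <- numeric(steps + 1L); V[1] <- g$V0
  for (i in seq_len(steps)) {
    k1 <- dVdt(V[i])
    k2 <- dVdt(V[i] + dt / 2 * k1)
    k3 <- dVdt(V[i] + dt / 2 * k2)
    k4 <- dVdt(V[i] + dt * k3)
    V[i + 1L] <- V[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  tgrid <- seq(0, t_end, by = dt)
  rel_clean <- V[vapply(cfg$times, function(tt)
    which.min(abs(tgrid - tt)), 1L)] / g$V0
  truth_slope <- cfg$pf * g$S * Vw * (cin0 - cout) / g$V0
  with_seed(cfg$seed, {
    tcs <- lapply(seq_len(cfg$n_oocytes), function(i) {
      rel <- rel_clean + rnorm(length(cfg$times), 0, cfg$sigma)
      swelling_timecourse(cfg$times, rel, cfg$osm_in, cfg$osm_out, g,
                          group = sprintf("sim_oocyte_%02d", i))
    })
    list(timecourses = tcs,
         truth = list(pf = cfg$pf, initial_slope = truth_slope,
                      rel_volume_clean = rel_clean))
  })
}

#' Simulate radiotracer uptake counts with Poisson counting noise
#'
#' Expected counts are `background + truth_pmol * conversion`; observed
#' counts are Poisson draws, as are the zero-time background counts.
#'
#' @param truth_pmol True solute uptake, pmol per oocyte (non-negative).
#' @param conversion Counts per pmol of total solute. A value of 0 destroys
#'   all information and triggers a warning.
#' @param background Expected zero-time (externally bound) counts.
#' @param n Oocytes in the exposed group.
#' @param n_zero Oocytes in the zero-time group (default `n`).
#' @param seed Mandatory RNG seed.
#' @return An [uptake_measurement] with attribute `truth_pmol`.
#' @export
simulate_uptake_counts <- function(truth_pmol, conversion, background,
                                   n, n_zero = n, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (truth_pmol < 0) stop("true uptake cannot be negative")
  if (conversion == 0)
    warning("conversion is 0: counts carry no information about uptake")
  with_seed(seed, {
    m <- uptake_measurement(
      counts = rpois(n, background + truth_pmol * conversion),
      zero_time_counts = rpois(n_zero, background))
    attr(m, "truth_pmol") <- truth_pmol
    attr(m, "conversion") <- conversion
    m
  })
}

#' Write a toy channel structure as PDB text
#'
#' Stacks rings of pseudo-atoms around the z axis: ring `i` has the given
#' radius, `atoms_per_ring` atoms and sits at `z = (i - 1) * spacing`. The
#' known minimal pore radius is `min(ring_radii) - atom_radius` (clamped at
#' 0; a ring radius at or below the atom radius occludes the pore, which is
#' allowed but flagged with a warning).
#'
#' @param ring_radii Ring radii, Angstrom.
#' @param atoms_per_ring Atoms per ring (default 12).
#' @param atom_radius Nominal atom radius used for the known-truth
#'   calculation (default 1.7, the carbon van der Waals radius, matching the
#'   `C` element written to the file).
#' @param spacing Axial spacing between rings, Angstrom (default 2).
#' @param path Optional output path.
#' @return Character vector of PDB lines, with attributes `known_min_radius`
#'   and `ring_z`. Written to `path` when given.
#' @export
make_toy_channel_structure <- function(ring_radii, atoms_per_ring = 12,
                                       atom_radius = 1.7, spacing = 2,
                                       path = NULL) {
  if (any(ring_radii <= 0) || atoms_per_ring < 3 || spacing <= 0)
    stop("ring radii, spacing must be positive and atoms_per_ring >= 3")
  if (any(ring_radii <= atom_radius))
    warning("ring radius <= atom radius: pore fully occluded at that ring")
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(ring_radii)) {
    z <- (i - 1) * spacing
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
    for (j in seq_len(atoms_per_ring)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  C   RNG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, i, ring_radii[i] * cos(ang[j]),
        ring_radii[i] * sin(ang[j]), z))
    }
  }
  lines <- c(lines, "END")
  attr(lines, "known_min_radius") <- max(0, min(ring_radii) - atom_radius)
  attr(lines, "ring_z") <- (seq_along(ring_radii) - 1) * spacing
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
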