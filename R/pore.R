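# Bondi (1964) van der Waals radii, Angstrom; the packaged radii table
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90)
VDW_TABLE_VERSION <- "bondi-1964"

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `element`, `residue_name`,
#'   `residue_index`, `chain`, `x`, `y`, `z` and optionally `radius`
#'   (Angstrom); missing radii are filled from the packaged van der Waals
#'   table.
#' @param source_id Label (e.g. a PDB code) recorded in outputs.
#' @param default_radius Radius assigned to elements absent from the table;
#'   `NULL` (default) makes an unknown element an error.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, source_id = "model", default_radius = NULL) {
  needed <- c("element", "x", "y", "z")
  if (!all(needed %in% names(atoms)))
    stop("atoms table must have columns: ", paste(needed, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  el <- toupper(atoms$element)
  fill <- is.na(atoms$radius)
  atoms$radius[fill] <- VDW_RADII[el[fill]]
  if (anyNA(atoms$radius)) {
    unknown <- unique(el[is.na(atoms$radius)])
    if (is.null(default_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "),
           " (supply default_radius to override)")
    atoms$radius[is.na(atoms$radius)] <- default_radius
  }
  if (any(atoms$radius <= 0)) stop("van der Waals radii must be positive")
  structure(list(atoms = atoms, source_id = source_id,
                 radii_version = VDW_TABLE_VERSION),
            class = "structure_model")
}

#' Read channel coordinates from a PDB file
#'
#' Reads heavy atoms of the selected chain; waters, heteroatoms and
#' hydrogens are excluded by default. Radii are assigned per element from
#' the packaged Bondi table.
#'
#' @param path PDB file.
#' @param chain Chain identifier; `NULL` keeps all chains.
#' @param include_hetero Keep HETATM records (default `FALSE`).
#' @param default_radius Radius for elements missing from the table.
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain = NULL, include_hetero = FALSE,
                           default_radius = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetero) at <- at[at$type == "ATOM" & at$resid != "HOH", ]
  if (!is.null(chain)) {
    if (!(chain %in% at$chain))
      stop("chain '", chain, "' not present; available chains: ",
           paste(sort(unique(at$chain)), collapse = ", "))
    at <- at[at$chain == chain, ]
  }
  el <- toupper(trimws(at$elesy))
  noel <- is.na(el) | el == ""
  el[noel] <- substr(gsub("[^A-Za-z]", "", at$elety[noel]), 1, 1)
  keep <- el != "H"
  at <- at[keep, ]; el <- el[keep]
  structure_model(
    data.frame(element = el, residue_name = at$resid,
               residue_index = at$resno, chain = at$chain,
               x = at$x, y = at$y, z = at$z),
    source_id = sub("\\.pdb$", "", basename(path)),
    default_radius = default_radius)
}

# orthonormal basis (u, v) perpendicular to unit vector d
.axis_basis <- function(d) {
  e <- diag(3)[, which.min(abs(d))]
  u <- c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3],
         d[1] * e[2] - d[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Pore-radius profile along a channel axis
#'
#' At each axial sample the profile reports the radius of the largest sphere
#' that can be centred in the perpendicular plane (within a search disc
#' around the axis) without overlapping any atom: for every atom, distance
#' from sphere centre to atom centre must be at least the atom's van der
#' Waals radius plus the sphere radius. The optimum is located by a coarse
#' 2-D grid search over the disc followed by pattern-search refinement. A
#' fully occluded plane reports radius 0, not an error.
#'
#' @param model A [structure_model] (at least 4 atoms).
#' @param axis List with `origin` (length-3) and `direction` (length-3 unit
#'   vector). Default: centroid and first principal axis of the atoms.
#' @param span Axial range `c(lo, hi)` in Angstrom relative to the origin;
#'   default covers the atoms' axial extent.
#' @param step Axial sampling interval (Angstrom, default 1).
#' @param disc_radius Search-disc radius around the axis (default 5).
#' @param coarse Coarse grid spacing (default 0.2).
#' @param refine_tol Pattern-search step at which refinement stops
#'   (default 1e-7; tight enough that the profile is rigid-motion invariant
#'   to ~1e-6 Angstrom).
#' @return Object of class `pore_profile`: list with `samples` (data.frame
#'   `position`, `radius`, `offset`), `min_radius`, `min_position`, `axis`,
#'   `radii_version`.
#' @export
pore_radius_profile <- function(model, axis = NULL, span = NULL, step = 1,
                                disc_radius = 5, coarse = 0.2,
                                refine_tol = 1e-7) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (nrow(at) < 4L) stop("need at least 4 atoms to profile a pore")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (is.null(axis)) {
    ctr <- colMeans(xyz)
    pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
    axis <- list(origin = ctr, direction = pc$rotation[, 1])
  }
  d <- axis$direction / sqrt(sum(axis$direction^2))
  basis <- .axis_basis(d)
  rel <- sweep(xyz, 2, axis$origin)
  ax <- drop(rel %*% d)
  au <- drop(rel %*% basis$u)
  av <- drop(rel %*% basis$v)
  r <- at$radius
  if (is.null(span)) span <- range(ax)
  if (span[2] < span[1]) stop("empty axial span")
  positions <- seq(span[1], span[2], by = step)

  # coarse grid over the search disc, fixed in the (u, v) frame
  g <- seq(-disc_radius, disc_radius, by = coarse)
  grid <- expand.grid(px = g, py = g)
  grid <- grid[grid$px^2 + grid$py^2 <= disc_radius^2, ]

  one_sample <- function(a0) {
    # vectorised clearance over the coarse grid
    da2 <- (ax - a0)^2
    best_val <- -Inf; best <- c(0, 0)
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      min(sqrt(da2 + (au - grid$px[i])^2 + (av - grid$py[i])^2) - r)
    }, numeric(1))
    i0 <- which.max(vals)
    best <- c(grid$px[i0], grid$py[i0]); best_val <- vals[i0]
    # pattern-search refinement
    s <- coarse
    clear <- function(p) min(sqrt(da2 + (au - p[1])^2 + (av - p[2])^2) - r)
    while (s > refine_tol) {
      moved <- FALSE
      for (dxy in list(c(s, 0), c(-s, 0), c(0, s), c(0, -s),
                       c(s, s), c(s, -s), c(-s, s), c(-s, -s))) {
        cand <- best + dxy
        if (sum(cand^2) > disc_radius^2) next
        v <- clear(cand)
        if (v > best_val + 1e-12) { best <- cand; best_val <- v; moved <- TRUE }
      }
      if (!moved) s <- s / 2
    }
    c(radius = max(0, best_val), offset = sqrt(sum(best^2)))
  }

  res <- t(vapply(positions, one_sample, c(radius = 0, offset = 0)))
  samples <- data.frame(position = positions, radius = res[, "radius"],
                        offset = res[, "offset"])
  imin <- which.min(samples$radius)
  structure(list(samples = samples,
                 min_radius = samples$radius[imin],
                 min_position = samples$position[imin],
                 axis = list(origin = axis$origin, direction = d),
                 radii_version = model$radii_version),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("<pore_profile> ", nrow(x$samples), " samples, min radius ",
      sprintf("%.2f", x$min_radius), " A at ",
      sprintf("%.1f", x$min_position), " A\n", sep = "")
  invisible(x)
}

#' Constriction minimum within an axial window
#'
#' Reports the minimum pore radius (and its axial position) within a stated
#' window — typically placed around the ar/R filter — for comparing
#' wild-type against in-silico mutant geometries. Note the quantity is a
#' radius (largest inscribed sphere), stated explicitly to avoid the
#' radius/diameter ambiguity common in pore-size reporting.
#'
#' @param profile A [pore_radius_profile()] result.
#' @param window Axial window `c(lo, hi)` in the profile's coordinates.
#' @return List with `min_radius`, `position`, `window`.
#' @export
constriction_report <- function(profile, window) {
  stopifnot(inherits(profile, "pore_profile"))
  s <- profile$samples
  if (window[1] > max(s$position) || window[2] < min(s$position))
    stop("window [", window[1], ", ", window[2],
         "] lies outside the profiled span [",
         min(s$position), ", ", max(s$position), "]")
  inw <- s[s$position >= window[1] & s$position <= window[2], ]
  if (nrow(inw) == 0L) stop("no profile samples inside the window")
  i <- which.min(inw$radius)
  list(min_radius = inw$radius[i], position = inw$position[i],
       window = window)
}
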