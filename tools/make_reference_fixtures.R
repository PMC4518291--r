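# Builds the packaged synthetic reference fixtures under inst/extdata/.
#
# The shipped template and reference panel are SYNTHETIC surrogate sequences,
# not database records: each is a randomly composed membrane-protein-like
# scaffold that carries the literature anchor residues at their literature
# coordinates (human AQP4: ar/R TMD5 His201, trim core Thr31-Phe258; the Prip
# reference carries His197; the Eglp reference carries Ala174 after its
# N-terminal truncation). Subfamily references diverge from the scaffold at
# disjoint random site sets so nearest-reference classification is well posed.
#
# Run from the package root:  Rscript tools/make_reference_fixtures.R

set.seed(1031)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# membrane-protein-ish composition: hydrophobics enriched
W <- c(A = 9, C = 1.5, D = 3, E = 3, F = 6, G = 8, H = 2, I = 7, K = 3,
       L = 11, M = 2.5, N = 3.5, P = 4, Q = 3, R = 3, S = 7, T = 6,
       V = 8, W = 2, Y = 3.5)[AA]

L <- 300
anchors <- c(`31` = "T", `77` = "F", `97` = "N", `98` = "P", `99` = "A",
             `201` = "H", `210` = "A", `213` = "N", `214` = "P", `215` = "A",
             `216` = "R", `258` = "F")
anchor_pos <- as.integer(names(anchors))
# sites frozen in every derived sequence (anchor +/- 2 context)
protected <- sort(unique(unlist(lapply(anchor_pos, function(p) (p - 2):(p + 2)))))
protected <- protected[protected >= 1 & protected <= L]

alike <- c("A", "S", "T", "V", "L", "I", "M")

scrub_spurious_npa <- function(x, keep_starts, frozen) {
  # replace the Pro of any N-P-[A-like] triplet that was not planted
  repeat {
    hits <- gregexpr(paste0("NP[", paste(alike, collapse = ""), "]"), x, perl = TRUE)[[1]]
    hits <- hits[hits > 0 & !(hits %in% keep_starts)]
    if (length(hits) == 0) return(x)
    fixed <- FALSE
    for (h in hits) {
      tgt <- h + 1L          # the P
      if (tgt %in% frozen) tgt <- h + 2L  # else mutate the A-like slot
      if (tgt %in% frozen) tgt <- h       # last resort: the N
      if (tgt %in% frozen) next
      substr(x, tgt, tgt) <- "G"
      fixed <- TRUE
    }
    if (!fixed) stop("cannot scrub motif overlapping protected sites")
  }
}

scaffold <- paste(sample(AA, L, replace = TRUE, prob = W), collapse = "")
for (i in seq_along(anchors)) substr(scaffold, anchor_pos[i], anchor_pos[i]) <- anchors[i]
scaffold <- scrub_spurious_npa(scaffold, keep_starts = c(97L, 213L), frozen = protected)

diverge <- function(seq, rate, frozen, tmd5 = NULL, tmd5_pos = 201L, n_del = 0L) {
  x <- seq
  free <- setdiff(seq_len(nchar(x)), frozen)
  nsub <- round(rate * length(free))
  sites <- sample(free, nsub)
  for (s in sites) {
    cur <- substr(x, s, s)
    substr(x, s, s) <- sample(setdiff(AA, cur), 1)
  }
  if (!is.null(tmd5)) substr(x, tmd5_pos, tmd5_pos) <- tmd5
  if (n_del > 0L) x <- substr(x, n_del + 1L, nchar(x))
  keep <- c(97L, 213L) - n_del
  frozen_s <- setdiff(protected, seq_len(n_del)) - n_del
  scrub_spurious_npa(x, keep_starts = keep, frozen = frozen_s)
}

# subfamily references: water-branch refs closer to the AQP4-like scaffold,
# Glp / Bib / unorthodox refs more remote, as in the superfamily itself
refs <- list(
  PhGlp_syn     = list(subfamily = "Glp",      rate = 0.40, tmd5 = "G", del = 0L),
  BgAqp_syn     = list(subfamily = "Prip",     rate = 0.25, tmd5 = "H", del = 4L),
  DmDrip_syn    = list(subfamily = "Drip",     rate = 0.25, tmd5 = "H", del = 0L),
  PvAqp2_syn    = list(subfamily = "Eglp",     rate = 0.25, tmd5 = "A", del = 27L),
  DmBib_syn     = list(subfamily = "Bib",      rate = 0.35, tmd5 = "E", del = 0L),
  HsAqp12L_syn  = list(subfamily = "Aqp12like", rate = 0.40, tmd5 = "C", del = 0L)
)

panel <- lapply(refs, function(r)
  diverge(scaffold, r$rate, protected, tmd5 = r$tmd5, n_del = r$del))

fa <- character(0)
meta <- list()
for (nm in names(panel)) {
  r <- refs[[nm]]
  off <- r$del
  fa <- c(fa, sprintf(">%s subfamily=%s synthetic=true", nm, r$subfamily),
          panel[[nm]])
  meta[[nm]] <- list(
    subfamily = r$subfamily,
    npa1_pos = 97L - off, npa2_pos = 213L - off,
    arR_positions = list(TMD2_aromatic = 77L - off, TMD5 = 201L - off,
                         LE1 = 210L - off, LE2 = 216L - off),
    tmd5_aa = r$tmd5
  )
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(fa, "inst/extdata/reference_panel_synthetic.fasta")

template <- list(
  template_id = "HsAQP4_syn",
  note = paste("Synthetic human-AQP4 surrogate: random scaffold carrying the",
               "published annotation anchors at their published coordinates."),
  version = "1.0",
  template_peptide = scaffold,
  npa1_pos = 97L, npa2_pos = 213L,
  arR_positions = list(TMD2_aromatic = 77L, TMD5 = 201L, LE1 = 210L, LE2 = 216L),
  trim_range = c(31L, 258L)
)
jsonlite::write_json(template, "inst/extdata/aqp4_template_synthetic.json",
                     auto_unbox = TRUE, pretty = TRUE)
jsonlite::write_json(meta, "inst/extdata/reference_panel_synthetic.json",
                     auto_unbox = TRUE, pretty = TRUE)

# quick self-checks
stopifnot(substr(scaffold, 31, 31) == "T", substr(scaffold, 258, 258) == "F",
          substr(scaffold, 201, 201) == "H",
          substr(panel$PvAqp2_syn, 174, 174) == "A",
          substr(panel$BgAqp_syn, 197, 197) == "H")
n_npa <- function(x) length(gregexpr("NP[ASTVLIM]", x)[[1]])
stopifnot(all(vapply(c(scaffold, unlist(panel)), n_npa, 1L) == 2L))
cat("fixtures written\n")
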