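SUBFAMILY_BRANCH <- c(Glp = "glp_branch", Prip = "water_branch",
                      Drip = "water_branch", Eglp = "water_branch",
                      Bib = "water_branch", Aqp12like = "unorthodox")

#' Build a reference panel for subfamily classification
#'
#' @param records Named list of [aqp_record] objects (reference sequences).
#' @param subfamilies Character vector, one label per record, each one of
#'   `Glp`, `Prip`, `Drip`, `Eglp`, `Bib`, `Aqp12like`.
#' @return Object of class `reference_panel`.
#' @export
reference_panel <- function(records, subfamilies) {
  if (length(records) == 0L) stop("reference panel is empty")
  if (length(subfamilies) != length(records))
    stop("one subfamily label per reference record is required")
  bad <- setdiff(subfamilies, names(SUBFAMILY_BRANCH))
  if (length(bad)) stop("unknown subfamily label(s): ", paste(bad, collapse = ", "))
  structure(list(records = records,
                 subfamilies = as.character(subfamilies)),
            class = "reference_panel")
}

#' Load the packaged synthetic reference panel
#'
#' One representative per arthropod aquaporin subfamily. The references are
#' synthetic surrogates (see [default_template()]) whose names echo the
#' channels they stand in for: `PhGlp_syn` (Glp), `BgAqp_syn` (Prip, ar/R
#' TMD5 His197), `DmDrip_syn` (Drip), `PvAqp2_syn` (Eglp, TMD5 Ala174),
#' `DmBib_syn` (Bib) and `HsAqp12L_syn` (Aqp12like). Water-branch references
#' sit closer to the AQP4-like scaffold than the Glp/Bib/unorthodox ones, as
#' in the superfamily itself.
#'
#' @return A [reference_panel].
#' @export
default_reference_panel <- function() {
  fa <- system.file("extdata", "reference_panel_synthetic.fasta",
                    package = "eglporin", mustWork = TRUE)
  meta <- jsonlite::read_json(
    system.file("extdata", "reference_panel_synthetic.json",
                package = "eglporin", mustWork = TRUE),
    simplifyVector = TRUE)
  recs <- read_fasta(fa)
  reference_panel(recs, vapply(names(recs), function(n) meta[[n]]$subfamily, ""))
}

# packaged per-reference annotation (NPA / ar/R coordinates in each
# reference's own numbering); used by the synthetic cohort generator
reference_panel_annotation <- function() {
  jsonlite::read_json(
    system.file("extdata", "reference_panel_synthetic.json",
                package = "eglporin", mustWork = TRUE),
    simplifyVector = TRUE)
}

#' Classify a record into an aquaporin subfamily by nearest reference
#'
#' A desk-scale surrogate for tree-based subfamily assignment: the query is
#' globally aligned to every panel reference and assigned the subfamily of
#' the best length-normalised alignment score (score divided by alignment
#' length). The margin between best and second-best normalised scores acts
#' as a confidence surrogate; below `margin_threshold` the subfamily is
#' reported `"unclassified"`, though the branch is still reported when every
#' reference within the margin lies on the same branch. Ties are broken by
#' panel order.
#'
#' Branches: Glp maps to `glp_branch`; Prip, Drip, Eglp and Bib to
#' `water_branch`; Aqp12like to `unorthodox`.
#'
#' @param record Query [aqp_record].
#' @param filter Its [extract_selectivity_filter()] result (used for the
#'   permeability call carried in the result).
#' @param panel A [reference_panel].
#' @param margin_threshold Minimum normalised-score margin for a confident
#'   subfamily call (default 0.05).
#' @param uncharged Uncharged-residue set passed to [predict_permeability()].
#' @return Object of class `classification_result`.
#' @export
classify_subfamily <- function(record, filter, panel,
                               margin_threshold = 0.05,
                               uncharged = setdiff(AA_ALPHABET, CHARGED_SET)) {
  stopifnot(inherits(panel, "reference_panel"))
  mat <- get_blosum62()
  scores <- vapply(panel$records, function(ref) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref$peptide), Biostrings::AAString(record$peptide),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "global")
    Biostrings::score(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- ord[1]
  margin <- if (length(scores) > 1) scores[best] - scores[ord[2]] else Inf
  top <- which(scores >= scores[best] - margin_threshold)
  top_branches <- unique(unname(SUBFAMILY_BRANCH[panel$subfamilies[top]]))
  if (margin >= margin_threshold) {
    subfamily <- panel$subfamilies[best]
    branch <- unname(SUBFAMILY_BRANCH[subfamily])
  } else {
    subfamily <- "unclassified"
    branch <- if (length(top_branches) == 1L) top_branches else "unclassified"
  }
  pred <- predict_permeability(filter, branch, uncharged = uncharged)
  structure(list(id = record$id,
                 branch = branch,
                 subfamily = subfamily,
                 nearest_reference_id = panel$records[[best]]$id,
                 score_margin = unname(margin),
                 scores = scores,
                 tmd5_index = filter$tmd5_index,
                 tmd5_aa = filter$tmd5_aa,
                 glycerol_prediction = pred$prediction,
                 rationale = pred$rationale,
                 rule_extrapolated = pred$rule_extrapolated),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification> ", x$id, ": ", x$subfamily, " (", x$branch,
      "), TMD5 ", x$tmd5_aa, x$tmd5_index, " -> ", x$glycerol_prediction,
      " [", x$rationale, "]\n", sep = "")
  invisible(x)
}

#' Predict glycerol permeability from the TMD5 ar/R residue
#'
#' The single-residue rule: channels on the aquaglyceroporin branch
#' transport glycerol constitutively; on the water-selective branch the TMD5
#' ar/R residue decides — an uncharged residue opens the constriction to
#' glycerol (the entomoglyceroporin configuration, with Ala/Ser/Val the
#' functionally verified members), whereas the conserved His (or another
#' charged residue) keeps the channel water-selective. An ambiguous (`X`) or
#' unmappable TMD5 residue yields `indeterminate`: the rule refuses to call
#' what it cannot see.
#'
#' @param filter A [extract_selectivity_filter()] result, or a single TMD5
#'   amino-acid letter.
#' @param branch `"glp_branch"`, `"water_branch"`, `"unorthodox"` or
#'   `"unclassified"`.
#' @param uncharged The residue set treated as uncharged (default: all
#'   canonical residues except H, K, R, D, E).
#' @return List with `prediction` (`transporter` / `water_selective` /
#'   `indeterminate`), `rationale` (machine-readable code) and
#'   `rule_extrapolated` (`TRUE` for uncharged residues outside the
#'   functionally verified A/S/V subset).
#' @export
predict_permeability <- function(filter, branch,
                                 uncharged = setdiff(AA_ALPHABET, CHARGED_SET)) {
  aa <- if (inherits(filter, "selectivity_filter")) filter$tmd5_aa else filter
  if (identical(branch, "glp_branch"))
    return(list(prediction = "transporter", rationale = "GLP_BRANCH",
                rule_extrapolated = FALSE))
  if (is.na(aa) || identical(aa, "X"))
    return(list(prediction = "indeterminate", rationale = "TMD5_INDETERMINATE",
                rule_extrapolated = FALSE))
  if (aa %in% CHARGED_SET)
    return(list(prediction = "water_selective",
                rationale = if (aa == "H") "TMD5_HIS" else "TMD5_CHARGED",
                rule_extrapolated = FALSE))
  if (aa %in% uncharged)
    return(list(prediction = "transporter", rationale = "TMD5_UNCHARGED",
                rule_extrapolated = !(aa %in% c("A", "S", "V"))))
  list(prediction = "indeterminate", rationale = "TMD5_INDETERMINATE",
       rule_extrapolated = FALSE)
}

#' Summarise the TMD5 residue spectrum of a cohort
#'
#' Tabulates the TMD5 ar/R residues of a set of classification results
#' (typically restricted to one subfamily) and reports the percentage
#' carrying Ala or Ser and the percentage carrying any uncharged residue —
#' the two headline statistics of the entomoglyceroporin residue spectrum.
#'
#' @param results List of `classification_result` objects, or a character
#'   vector of TMD5 residues.
#' @return Object of class `cohort_summary`: list with `n_sequences`,
#'   `tmd5_frequency` (named counts), `pct_ala_or_ser`, `pct_uncharged`.
#' @export
summarize_cohort <- function(results) {
  aas <- if (is.character(results)) results
         else vapply(results, function(r) r$tmd5_aa, "")
  if (length(aas) == 0L) stop("cannot summarise an empty cohort")
  freq <- table(aas)
  n <- length(aas)
  structure(list(
    n_sequences = n,
    tmd5_frequency = setNames(as.integer(freq), names(freq)),
    pct_ala_or_ser = 100 * sum(aas %in% c("A", "S")) / n,
    pct_uncharged = 100 * sum(!(aas %in% CHARGED_SET)) / n),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n_sequences,
      sprintf("| Ala/Ser %.1f%% | uncharged %.1f%%\n",
              x$pct_ala_or_ser, x$pct_uncharged))
  invisible(x)
}
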