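#' Scan a peptide for NPA boxes
#'
#' Finds all Asn-Pro-X triplets where X belongs to the "A-like" set. The two
#' canonical NPA boxes meet at the channel centre, one contributed by each
#' pseudo-symmetric half of the protein, so each hit is labelled `N` or `C`
#' by its position relative to the sequence midpoint. Zero hits is a valid
#' result (not every input is a channel).
#'
#' @param record An [aqp_record].
#' @param alike Allowed third residues. The default admits the small/neutral
#'   substitutions seen across the superfamily; `alike = "A"` is strict mode.
#' @return Object of class `motif_hits`: data.frame with columns `start`
#'   (1-based), `triplet`, `half`.
#' @examples
#' scan_npa(aqp_record("q", "GGNPAGGGGGGGNPSGG"))
#' @export
scan_npa <- function(record, alike = c("A", "S", "T", "V", "L", "I", "M")) {
  stopifnot(inherits(record, "aqp_record"))
  pat <- paste0("NP[", paste(alike, collapse = ""), "]")
  m <- gregexpr(pat, record$peptide, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    hits <- data.frame(start = integer(0), triplet = character(0),
                       half = character(0))
  } else {
    start <- as.integer(m)
    hits <- data.frame(
      start = start,
      triplet = substring(record$peptide, start, start + 2L),
      half = ifelse(start <= nchar(record$peptide) / 2, "N", "C"))
  }
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Align a query peptide onto an annotated template
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring and affine gaps
#' (open 11, extend 1), the standard parameterisation for protein-level
#' comparisons. The returned residue mapping lists all columns where both
#' sequences place a residue, as strictly increasing 1-based index pairs.
#' Coverage is the fraction of template positions inside the conserved core
#' (`trim_range`) that align to a query residue; mappings covering less than
#' `min_coverage` of the core abort with a low-confidence error, since
#' selectivity-filter extraction would not be trustworthy.
#'
#' @param record Query [aqp_record].
#' @param template A [template_annotation].
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param min_coverage Minimum core coverage fraction (default 0.5).
#' @return Object of class `residue_mapping`: list with `pairs` (data.frame
#'   `template_index`, `query_index`), `alignment_score`,
#'   `fraction_template_covered`.
#' @export
align_to_template <- function(record, template,
                              gap_opening = 11, gap_extension = 1,
                              min_coverage = 0.5) {
  stopifnot(inherits(record, "aqp_record"),
            inherits(template, "template_annotation"))
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(template$template_peptide),
    Biostrings::AAString(record$peptide),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  tchars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qchars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ti <- cumsum(tchars != "-")
  qi <- cumsum(qchars != "-")
  both <- tchars != "-" & qchars != "-"
  pairs <- data.frame(template_index = ti[both], query_index = qi[both])
  core <- seq(template$trim_range[1], template$trim_range[2])
  cov <- sum(pairs$template_index %in% core) / length(core)
  if (cov < min_coverage) {
    cond <- structure(
      class = c("eglporin_low_coverage", "error", "condition"),
      list(message = sprintf(
        "alignment of '%s' covers only %.1f%% of the template core (minimum %.0f%%)",
        record$id, 100 * cov, 100 * min_coverage),
        call = sys.call(-1), coverage = cov))
    stop(cond)
  }
  structure(list(pairs = pairs,
                 alignment_score = Biostrings::score(pa),
                 fraction_template_covered = cov),
            class = "residue_mapping")
}

# BLOSUM62 with rows/cols restricted to residues we emit; cached per session
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Extract the ar/R selectivity filter of an aligned query
#'
#' Reads off, for each annotated ar/R template position, the query residue it
#' aligns to. A template position that aligns into a gap yields an absent
#' entry; an absent or gapped TMD5 position is an error, because the
#' glycerol-permeability rule cannot be applied without it. The derived flag
#' `tmd5_charged` is `TRUE` when the TMD5 residue is one of His/Lys/Arg/Asp/
#' Glu — the charged residues that close the constriction to glycerol.
#'
#' @param record Query [aqp_record].
#' @param mapping A [residue_mapping] from [align_to_template()].
#' @param template The [template_annotation] used for the mapping.
#' @return Object of class `selectivity_filter`: list with `residues`
#'   (data.frame `label`, `template_index`, `query_index`, `amino_acid`) and
#'   `tmd5_charged`.
#' @export
extract_selectivity_filter <- function(record, mapping, template) {
  stopifnot(inherits(mapping, "residue_mapping"),
            inherits(template, "template_annotation"))
  labels <- arR_LABELS[arR_LABELS %in% names(template$arR_positions)]
  rows <- lapply(labels, function(lab) {
    tpos <- template$arR_positions[[lab]]
    hit <- mapping$pairs$query_index[mapping$pairs$template_index == tpos]
    if (length(hit) == 0L)
      data.frame(label = lab, template_index = tpos,
                 query_index = NA_integer_, amino_acid = NA_character_)
    else
      data.frame(label = lab, template_index = tpos, query_index = hit[1],
                 amino_acid = substr(record$peptide, hit[1], hit[1]))
  })
  residues <- do.call(rbind, rows)
  tmd5 <- residues[residues$label == "TMD5", ]
  if (is.na(tmd5$query_index))
    stop("record '", record$id,
         "': TMD5 ar/R position aligns to a gap; filter cannot be extracted")
  structure(list(id = record$id, residues = residues,
                 tmd5_index = tmd5$query_index,
                 tmd5_aa = tmd5$amino_acid,
                 tmd5_charged = isTRUE(tmd5$amino_acid %in% CHARGED_SET)),
            class = "selectivity_filter")
}

#' @export
print.selectivity_filter <- function(x, ...) {
  cat("<selectivity_filter> ", x$id, ": TMD5 ", x$tmd5_aa, x$tmd5_index,
      if (x$tmd5_charged) " (charged)" else " (uncharged)", "\n", sep = "")
  invisible(x)
}

#' Annotate one record end to end
#'
#' Convenience wrapper: NPA scan, template alignment and selectivity-filter
#' extraction in one call.
#'
#' @inheritParams align_to_template
#' @param ... Passed to [align_to_template()].
#' @return List with elements `record`, `npa` ([scan_npa()] hits), `mapping`,
#'   `filter`.
#' @export
annotate_record <- function(record, template = default_template(), ...) {
  mapping <- align_to_template(record, template, ...)
  list(record = record,
       npa = scan_npa(record),
       mapping = mapping,
       filter = extract_selectivity_filter(record, mapping, template))
}

#' Annotate a cohort and tabulate the results
#'
#' Applies [annotate_record()] to every record, collecting per-record errors
#' instead of aborting the cohort (fragmentary sequences are expected in
#' genome-mined data). The table follows the package's annotation format:
#' one row per record with NPA starts, the ar/R quartet and core coverage.
#'
#' @param records List of [aqp_record] objects.
#' @param template A [template_annotation].
#' @param ... Passed to [align_to_template()].
#' @return List with `table` (data.frame: id, npa1, npa2, tmd2_aromatic,
#'   tmd5_index, tmd5_aa, le1, le2, coverage), `annotations` (per-record
#'   results) and `errors` (data.frame id, message).
#' @export
annotate_cohort <- function(records, template = default_template(), ...) {
  anns <- list(); errs <- list()
  for (r in records) {
    res <- tryCatch(annotate_record(r, template, ...),
                    error = function(e) e)
    if (inherits(res, "error"))
      errs[[r$id]] <- conditionMessage(res)
    else anns[[r$id]] <- res
  }
  row1 <- function(a) {
    res <- a$filter$residues
    g <- function(lab, col) {
      v <- res[res$label == lab, col]
      if (length(v) == 0) NA else v
    }
    npa_n <- a$npa$start[a$npa$half == "N"]
    npa_c <- a$npa$start[a$npa$half == "C"]
    data.frame(id = a$record$id,
               npa1 = if (length(npa_n)) npa_n[1] else NA_integer_,
               npa2 = if (length(npa_c)) npa_c[1] else NA_integer_,
               tmd2_aromatic = g("TMD2_aromatic", "amino_acid"),
               tmd5_index = a$filter$tmd5_index,
               tmd5_aa = a$filter$tmd5_aa,
               le1 = g("LE1", "amino_acid"),
               le2 = g("LE2", "amino_acid"),
               coverage = a$mapping$fraction_template_covered)
  }
  tab <- if (length(anns)) do.call(rbind, lapply(anns, row1)) else
    data.frame(id = character(0))
  rownames(tab) <- NULL
  err_tab <- data.frame(id = names(errs),
                        message = unlist(errs, use.names = FALSE))
  list(table = tab, annotations = anns, errors = err_tab)
}
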