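#' Parse or construct a single-substitution mutation spec
#'
#' Mutations use the compact protein grammar `"<wt><position><mut>"`, e.g.
#' `"H201A"` (His at position 201 replaced by Ala). Multi-mutants are
#' expressed as sequential applications of single specs.
#'
#' @param x A spec string, or a wild-type letter when `position`/`mutant`
#'   are given separately.
#' @param position,mutant Optional explicit components.
#' @return Object of class `mutation_spec` with fields `wild_type_aa`,
#'   `position`, `mutant_aa`.
#' @examples
#' mutation_spec("H201A")
#' @export
mutation_spec <- function(x, position = NULL, mutant = NULL) {
  if (is.null(position)) {
    m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(x)))[[1]]
    if (length(m) != 4L)
      stop("cannot parse mutation spec '", x,
           "'; expected e.g. \"H201A\"")
    wt <- m[2]; position <- as.integer(m[3]); mutant <- m[4]
  } else {
    wt <- toupper(x); mutant <- toupper(mutant); position <- as.integer(position)
  }
  if (!(wt %in% c(AA_ALPHABET, "X")) || !(mutant %in% c(AA_ALPHABET, "X")))
    stop("mutation spec residues must be canonical amino acids")
  if (position < 1L) stop("mutation position must be >= 1")
  structure(list(wild_type_aa = wt, position = position, mutant_aa = mutant),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...)
  paste0(x$wild_type_aa, x$position, x$mutant_aa)

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec>", format(x), "\n")
  invisible(x)
}

#' Apply a point mutation to a peptide record
#'
#' In-silico analogue of site-directed mutagenesis. The spec's wild-type
#' residue must match the peptide at the stated position — a mismatch aborts
#' with an error naming expected versus found residue, which guards against
#' numbering drift between constructs. The input record is left untouched;
#' the returned record's id is suffixed with the spec (e.g. `AQP4-H201A`).
#'
#' @param record An [aqp_record].
#' @param spec A [mutation_spec] or spec string.
#' @return A new [aqp_record] differing at exactly one position.
#' @export
apply_mutation <- function(record, spec) {
  stopifnot(inherits(record, "aqp_record"))
  if (is.character(spec)) spec <- mutation_spec(spec)
  if (spec$position > nchar(record$peptide))
    stop("position ", spec$position, " outside peptide of '", record$id,
         "' (length ", nchar(record$peptide), ")")
  found <- substr(record$peptide, spec$position, spec$position)
  if (found != spec$wild_type_aa)
    stop("wild-type mismatch in '", record$id, "' at position ",
         spec$position, ": expected ", spec$wild_type_aa,
         ", found ", found)
  pep <- record$peptide
  substr(pep, spec$position, spec$position) <- spec$mutant_aa
  aqp_record(paste0(record$id, "-", format(spec)), pep,
             species = record$species, lineage_tags = record$lineage_tags,
             description = record$description)
}

#' Packaged default mutant panel
#'
#' The seven-channel panel used to probe the TMD5 rule experimentally:
#' wild-type and mutant forms of the Eglp reference (`PvAqp2`, TMD5 Ala174,
#' mutated A174H to restore the ancestral Prip constraint), the Prip
#' reference (`BgAqp`, TMD5 His197, mutated H197S) and the AQP4 template
#' (TMD5 His201, mutated H201A and H201S). Sequences are the packaged
#' synthetic surrogates.
#'
#' @param template A [template_annotation] supplying the AQP4 record.
#' @param panel A [reference_panel] supplying PvAqp2 and BgAqp.
#' @return List of `list(record =, mutation =)` entries suitable for
#'   [recapitulate_mutant_panel()].
#' @export
default_mutant_panel <- function(template = default_template(),
                                 panel = default_reference_panel()) {
  aqp4 <- aqp_record(template$template_id, template$template_peptide)
  pv <- panel$records[["PvAqp2_syn"]]
  bg <- panel$records[["BgAqp_syn"]]
  if (is.null(pv) || is.null(bg))
    stop("panel does not contain the PvAqp2_syn / BgAqp_syn references")
  list(list(record = pv,   mutation = NULL),
       list(record = pv,   mutation = "A174H"),
       list(record = bg,   mutation = NULL),
       list(record = bg,   mutation = "H197S"),
       list(record = aqp4, mutation = NULL),
       list(record = aqp4, mutation = "H201A"),
       list(record = aqp4, mutation = "H201S"))
}

#' Run annotation, mutation and permeability prediction over a mutant panel
#'
#' For each entry the record is (optionally) mutated, annotated against the
#' template, classified against the panel, and its glycerol permeability
#' predicted from the TMD5 rule. This is the in-silico recapitulation of the
#' wet-lab mutant series: a single TMD5 substitution flips the prediction
#' between `water_selective` and `transporter`.
#'
#' @param entries List of `list(record =, mutation = NULL | spec)`; default
#'   [default_mutant_panel()].
#' @param template A [template_annotation].
#' @param panel A [reference_panel].
#' @return data.frame with columns `id`, `tmd5_index`, `tmd5_aa`,
#'   `subfamily`, `branch`, `prediction`, `rationale`.
#' @export
recapitulate_mutant_panel <- function(entries = default_mutant_panel(),
                                      template = default_template(),
                                      panel = default_reference_panel()) {
  if (length(entries) == 0L)
    return(data.frame(id = character(0), tmd5_index = integer(0),
                      tmd5_aa = character(0), subfamily = character(0),
                      branch = character(0), prediction = character(0),
                      rationale = character(0)))
  rows <- lapply(entries, function(e) {
    rec <- e$record
    if (!is.null(e$mutation)) rec <- apply_mutation(rec, e$mutation)
    ann <- annotate_record(rec, template)
    cls <- classify_subfamily(rec, ann$filter, panel)
    data.frame(id = rec$id,
               tmd5_index = ann$filter$tmd5_index,
               tmd5_aa = ann$filter$tmd5_aa,
               subfamily = cls$subfamily,
               branch = cls$branch,
               prediction = cls$glycerol_prediction,
               rationale = cls$rationale)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
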