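#' Template annotation for selectivity-filter mapping
#'
#' A template annotation carries a reference peptide together with the
#' 1-based coordinates of its two NPA boxes, the four ar/R selectivity-filter
#' residues (labelled `TMD2_aromatic`, `TMD5`, `LE1`, `LE2`), and the
#' inclusive range of the conserved transmembrane core used to anchor
#' alignments and judge coverage.
#'
#' @param template_id Identifier string.
#' @param template_peptide Template amino-acid sequence.
#' @param npa1_pos,npa2_pos 1-based index of the first residue of each NPA box.
#' @param arR_positions Named list/vector with entries `TMD2_aromatic`,
#'   `TMD5`, `LE1`, `LE2` (1-based indices; `TMD5` mandatory).
#' @param trim_range Inclusive 1-based `c(start, end)` of the conserved core.
#' @param version Version tag recorded in outputs.
#' @return An object of class `template_annotation`.
#' @export
template_annotation <- function(template_id, template_peptide,
                                npa1_pos, npa2_pos, arR_positions,
                                trim_range, version = "unversioned") {
  len <- nchar(template_peptide)
  arR <- lapply(arR_positions, as.integer)
  if (is.null(arR$TMD5)) stop("arR_positions must include a TMD5 index")
  idx <- c(npa1_pos, npa2_pos, unlist(arR), trim_range)
  if (any(idx < 1L | idx > len))
    stop("annotated index outside template peptide (length ", len, ")")
  if (any(unlist(arR) < trim_range[1] | unlist(arR) > trim_range[2]))
    stop("trim_range must contain all ar/R positions")
  structure(list(template_id = template_id,
                 template_peptide = toupper(template_peptide),
                 npa1_pos = as.integer(npa1_pos),
                 npa2_pos = as.integer(npa2_pos),
                 arR_positions = arR,
                 trim_range = as.integer(trim_range),
                 version = version),
            class = "template_annotation")
}

#' Load the packaged default template
#'
#' The default template is a synthetic human-AQP4 surrogate: a randomly
#' composed membrane-protein-like scaffold that carries the literature
#' annotation anchors at their literature coordinates — ar/R TMD5 His at
#' index 201, NPA boxes, and the conserved core Thr31--Phe258. It is
#' synthetic (no database sequence is shipped) but positionally faithful, so
#' residue indices reported against it match the human-AQP4 numbering used
#' in the field.
#'
#' @param path Optional path to an alternative template JSON file.
#' @return A [template_annotation] object.
#' @export
default_template <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aqp4_template_synthetic.json",
                        package = "eglporin", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  template_annotation(j$template_id, j$template_peptide,
                      j$npa1_pos, j$npa2_pos,
                      as.list(j$arR_positions), j$trim_range,
                      version = if (is.null(j$version)) "unversioned" else j$version)
}

#' @export
print.template_annotation <- function(x, ...) {
  cat("<template_annotation> ", x$template_id,
      " (", nchar(x$template_peptide), " aa, v", x$version, ")\n",
      "  NPA boxes at ", x$npa1_pos, ", ", x$npa2_pos,
      "; TMD5 at ", x$arR_positions$TMD5,
      "; core ", x$trim_range[1], "-", x$trim_range[2], "\n", sep = "")
  invisible(x)
}
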