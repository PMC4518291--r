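#' Construct an aquaporin peptide record
#'
#' A record holds one peptide with its identifier and optional taxon
#' metadata. Peptides are restricted to the 20 canonical residues plus `X`
#' (ambiguous); residue numbering is 1-based throughout the package, the
#' protein convention in which the AQP4 TMD5 histidine is "His201".
#'
#' @param id Accession or label (non-empty string, unique within a cohort).
#' @param peptide Amino-acid string; lowercase accepted, a single terminal
#'   `*` stop is stripped.
#' @param species Optional free-text species name.
#' @param lineage_tags Optional character vector of ordered lineage labels.
#' @param description Optional free-text description (FASTA header remainder).
#' @return An object of class `aqp_record`.
#' @examples
#' r <- aqp_record("q1", "MNPAV")
#' nchar(r$peptide)
#' @export
aqp_record <- function(id, peptide, species = NA_character_,
                       lineage_tags = character(0),
                       description = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  peptide <- toupper(as.character(peptide))
  peptide <- sub("\\*$", "", peptide)
  if (!nzchar(peptide)) stop("peptide is empty for record '", id, "'")
  bad <- regexpr(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]"), peptide)
  if (bad > 0L)
    stop("record '", id, "': invalid residue '",
         substr(peptide, bad, bad), "' at position ", bad)
  structure(list(id = id, species = species, peptide = peptide,
                 lineage_tags = lineage_tags, description = description),
            class = "aqp_record")
}

#' @export
print.aqp_record <- function(x, ...) {
  cat("<aqp_record> ", x$id, " (", nchar(x$peptide), " aa)\n", sep = "")
  invisible(x)
}

#' Read aquaporin peptides from a FASTA file
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder is kept as the description. Sequences are uppercased and a
#' terminal stop (`*`) is stripped. Wrapped and unwrapped sequences are both
#' accepted.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named list of [aqp_record] objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  recs <- lapply(seq_along(set), function(i)
    aqp_record(ids[i], as.character(set[[i]]), description = desc[i]))
  names(recs) <- ids
  recs
}

#' Write aquaporin records to a FASTA file
#'
#' @param records List of [aqp_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    hdr <- if (is.na(r$description)) r$id else paste(r$id, r$description)
    c(paste0(">", hdr), r$peptide)
  }))
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}
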