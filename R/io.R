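#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a [ProteinSet-class] with empty location sets
#' (query proteins). Sequences are uppercased and non-standard residues
#' resolved per `sanitize`.
#'
#' @param path path to a FASTA file.
#' @param sanitize policy for non-standard residues, see
#'   [sanitizeSequences()].
#' @return a [ProteinSet-class].
#' @export
readProteinFasta <- function(path, sanitize = c("drop", "map", "reject")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[1], ">"))
    stop("malformed FASTA: line 1 does not start with '>'")
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e)))
  if (!length(seqs)) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header as id
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  ProteinSet(seqs, sanitize = match.arg(sanitize))
}

#' Write a ProteinSet to FASTA
#'
#' @param x a [ProteinSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  stopifnot(is(x, "ProteinSet"))
  Biostrings::writeXStringSet(proteinSequences(x), path)
  invisible(path)
}

#' Read per-protein location annotations
#'
#' Tab-separated file, one line per protein: `id TAB label1,label2,...`.
#' Labels are matched case-insensitively against the six compartments and
#' their synonyms ([normalizeLocation()]).
#'
#' @param path path to the TSV file.
#' @return named list of canonical location label sets.
#' @export
readLocationAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(trimws(parts[2])))
      stop("line ", ln, ": labeled records need at least one location")
    id <- trimws(parts[1])
    if (id %in% names(out)) stop("line ", ln, ": duplicate id '", id, "'")
    labs <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    labs <- labs[nzchar(labs)]
    if (!length(labs))
      stop("line ", ln, ": labeled records need at least one location")
    out[[id]] <- tryCatch(unique(normalizeLocation(labs)),
                          error = function(e)
                            stop("line ", ln, ": ", conditionMessage(e),
                                 call. = FALSE))
  }
  out
}

#' Attach annotations to a ProteinSet
#'
#' @param x a [ProteinSet-class].
#' @param locations named list of location label sets (ids matching `x`).
#' @param goTerms named list of GO id vectors.
#' @param saProfiles named list of SA profile data frames.
#' @return the updated [ProteinSet-class].
#' @export
setAnnotations <- function(x, locations = NULL, goTerms = NULL,
                           saProfiles = NULL) {
  ids <- names(x)
  if (!is.null(locations)) {
    unknown <- setdiff(names(locations), ids)
    if (length(unknown))
      stop("annotation ids not in the set: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    sets <- lapply(ids, function(id)
      if (id %in% names(locations)) locations[[id]] else character(0))
    x@locations <- .locationMatrixFromSets(sets, ids)
  }
  if (!is.null(goTerms)) {
    x@goTerms <- lapply(ids, function(id)
      if (id %in% names(goTerms)) unique(goTerms[[id]]) else character(0))
  }
  if (!is.null(saProfiles)) {
    x@saProfiles <- lapply(ids, function(id)
      if (id %in% names(saProfiles)) saProfiles[[id]] else NULL)
  }
  validObject(x)
  x
}

#' Read GO annotations
#'
#' Two-column TSV: `protein_id TAB GO:NNNNNNN` (one term per line, GAF-like)
#' or `protein_id TAB GO:...,GO:...`.
#'
#' @param path path to the TSV file.
#' @return named list of GO id character vectors.
#' @export
readGOAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("GO annotation file needs two columns")
  out <- list()
  for (i in seq_len(nrow(tab))) {
    terms <- trimws(strsplit(tab[i, 2], ",", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    bad <- terms[!grepl("^GO:\\d{7}$", terms)]
    if (length(bad))
      stop("line ", i, ": malformed GO id '", bad[1], "'")
    id <- trimws(tab[i, 1])
    out[[id]] <- unique(c(out[[id]], terms))
  }
  out
}

#' Read surface-accessibility profiles
#'
#' TSV with a NetSurfP-compatible column subset:
#' `protein_id, residue_index, aa, class, RSA, ASA`. `class` is
#' `E` (exposed) or `B` (buried); RSA is a fraction, ASA in square Angstrom.
#'
#' @param path path to the TSV file.
#' @return named list of per-protein data frames ordered by residue index.
#' @export
readSAProfiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "aa", "class", "RSA", "ASA")
  if (!all(need %in% names(tab)))
    stop("SA profile file needs columns: ", paste(need, collapse = ", "))
  split_tab <- split(tab[need[-1]], tab$protein_id)
  lapply(split_tab, function(d) d[order(d$residue_index), , drop = FALSE])
}

#' Drop proteins shorter than a minimum length
#'
#' Mirrors the training-data construction rule of removing sequences shorter
#' than 80 residues; order of the retained records is preserved.
#'
#' @param x a [ProteinSet-class].
#' @param minLength minimum sequence length retained (default 80).
#' @return the filtered [ProteinSet-class].
#' @export
filterMinLength <- function(x, minLength = 80L) {
  stopifnot(is(x, "ProteinSet"))
  keep <- Biostrings::width(proteinSequences(x)) >= minLength
  x[which(keep)]
}

#' Keep only proteins in a pre-clustered id list
#'
#' Hook for redundancy reduction performed externally (e.g. CD-HIT at 0.7
#' identity): supply the representative ids and the set is subset to them.
#'
#' @param x a [ProteinSet-class].
#' @param ids character vector of ids to retain.
#' @return the subset [ProteinSet-class].
#' @export
applyClusterRepresentatives <- function(x, ids) {
  missing <- setdiff(ids, names(x))
  if (length(missing))
    stop("ids not present: ", paste(utils::head(missing, 5), collapse = ", "))
  x[ids]
}
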