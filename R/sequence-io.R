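## Sequence and dataset I/O: FASTA proteins, labelled hexapeptide TSVs and
## region annotations.  Coordinates are 1-based inclusive throughout.

## Conventional nearest standard residue for ambiguity/rare codes.  X has no
## nearest standard residue and is only tolerated under "skip-window".
NONSTANDARD_MAP <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")

#' Validate a raw amino-acid string into a protein sequence
#'
#' Uppercases the input and checks it against the 20-letter amino-acid
#' alphabet.  Nonstandard letters (B, J, O, U, X, Z) are handled according to
#' `policy`:
#' \describe{
#'   \item{`"reject"`}{(default) any nonstandard letter is an error;}
#'   \item{`"map-to-nearest"`}{B\eqn{\to}D, Z\eqn{\to}E, J\eqn{\to}L,
#'     U\eqn{\to}C, O\eqn{\to}K; X cannot be mapped and is an error;}
#'   \item{`"skip-window"`}{the sequence is accepted and the positions of
#'     nonstandard letters are recorded so that any 6-residue window covering
#'     one is flagged unscoreable (`NA` in profiles).}
#' }
#'
#' @param raw character scalar, the amino-acid sequence.
#' @param id sequence identifier.
#' @param policy one of `"reject"`, `"map-to-nearest"`, `"skip-window"`.
#' @return An object of class `"protein_sequence"`: a list with `id`,
#'   `residues` (uppercase string) and `unscoreable` (integer positions of
#'   residues that cannot be scored, empty unless `policy = "skip-window"`).
#' @examples
#' validate_sequence("mkvlaa", id = "p1")
#' validate_sequence("MKXLAA", policy = "skip-window")
#' @export
validate_sequence <- function(raw, id = "seq",
                              policy = c("reject", "map-to-nearest",
                                         "skip-window")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string")
  }
  res <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(res)) stop("empty sequence for id '", id, "'")
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  unscoreable <- integer(0)
  if (length(bad)) {
    if (policy == "reject") {
      stop("sequence '", id, "': illegal residue '", chars[bad[1]],
           "' at position ", bad[1])
    }
    if (policy == "map-to-nearest") {
      mappable <- chars[bad] %in% names(NONSTANDARD_MAP)
      if (!all(mappable)) {
        p <- bad[!mappable][1]
        stop("sequence '", id, "': residue '", chars[p], "' at position ", p,
             " has no nearest standard residue; use policy = \"skip-window\"")
      }
      chars[bad] <- NONSTANDARD_MAP[chars[bad]]
      res <- paste(chars, collapse = "")
    } else { # skip-window
      unscoreable <- bad
    }
  }
  structure(list(id = as.character(id), residues = res,
                 unscoreable = unscoreable),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat("Protein sequence '", x$id, "' (", n, " aa)\n", sep = "")
  show <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(" ", show, "\n", sep = "")
  if (length(x$unscoreable)) {
    cat("  unscoreable positions:",
        paste(x$unscoreable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.character.protein_sequence <- function(x, ...) x$residues

## coerce user input (string or protein_sequence) to protein_sequence
as_protein_sequence <- function(x, id = "seq",
                                policy = "reject") {
  if (inherits(x, "protein_sequence")) return(x)
  validate_sequence(x, id = id, policy = policy)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file (via Biostrings) and validates every record against
#' the amino-acid alphabet.  The header token before the first whitespace
#' becomes the sequence id; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @inheritParams validate_sequence
#' @return A list of [validate_sequence()] objects.
#' @export
read_fasta <- function(path, policy = c("reject", "map-to-nearest",
                                        "skip-window")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in '", path, "': line ", nonblank[1],
         " does not start a record ('>' expected)")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- validate_sequence(as.character(set[[i]]), id = ids[i],
                                  policy = policy)
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a `protein_sequence` or list of them.
#' @param path output path.
#' @param width line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    res <- s$residues
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))),
               con)
  }
  invisible(path)
}

#' Read a labelled hexapeptide dataset
#'
#' Reads a tab-separated file with header columns `peptide` (6-mer over the
#' amino-acid alphabet) and `label` (0 = non-amyloid, 1 = amyloid).
#'
#' @param path path to the TSV file.
#' @param provenance free-text provenance tag stored with the dataset.
#' @return An object of class `"hex_dataset"`: a data frame with columns
#'   `peptide` and `label` (integer), plus a `provenance` attribute.
#' @export
read_hex_dataset <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "label") %in% names(d))) {
    stop("hexapeptide TSV must have columns 'peptide' and 'label'")
  }
  hex_dataset(d$peptide, d$label, provenance = provenance)
}

#' Construct a labelled hexapeptide dataset
#'
#' @param peptide character vector of 6-mers.
#' @param label binary labels (0/1).
#' @param provenance free-text provenance tag.
#' @return A `"hex_dataset"` data frame; see [read_hex_dataset()].
#' @export
hex_dataset <- function(peptide, label, provenance = "constructed") {
  peptide <- toupper(as.character(peptide))
  if (length(peptide) != length(label)) {
    stop("peptide and label lengths differ")
  }
  badlen <- which(nchar(peptide) != 6L)
  if (length(badlen)) {
    stop("row ", badlen[1], ": peptide '", peptide[badlen[1]],
         "' does not have length 6")
  }
  badaa <- which(!vapply(strsplit(peptide, "", fixed = TRUE),
                         function(ch) all(ch %in% AA_ALPHABET), TRUE))
  if (length(badaa)) {
    stop("row ", badaa[1], ": peptide '", peptide[badaa[1]],
         "' contains a non-amino-acid letter")
  }
  if (is.logical(label)) label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) {
    bad <- which(!label %in% c(0L, 1L))[1]
    stop("row ", bad, ": label must be 0 or 1, got '", label[bad], "'")
  }
  if (anyDuplicated(paste(peptide, label))) {
    stop("duplicate (peptide, label) pair: '",
         peptide[duplicated(paste(peptide, label))][1], "'")
  }
  structure(data.frame(peptide = peptide, label = as.integer(label),
                       stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("hex_dataset", "data.frame"))
}

#' @export
print.hex_dataset <- function(x, ...) {
  cat("Labelled hexapeptide dataset (", nrow(x), " peptides: ",
      sum(x$label == 1L), " amyloid, ", sum(x$label == 0L),
      " non-amyloid)\n", sep = "")
  cat("provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a labelled hexapeptide dataset to TSV
#'
#' @param dataset a `"hex_dataset"` (or data frame with `peptide`, `label`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hex_dataset <- function(dataset, path) {
  utils::write.table(dataset[c("peptide", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read region annotations
#'
#' Reads a tab-separated file of experimentally validated (or predicted)
#' amyloid regions with header columns `sequence_id`, `start`, `end`
#' (1-based, inclusive).
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `sequence_id`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "start", "end")
  if (!all(need %in% names(d))) {
    stop("region TSV must have columns sequence_id, start, end")
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  bad <- which(is.na(d$start) | is.na(d$end) | d$start < 1L |
                 d$end < d$start)
  if (length(bad)) {
    stop("row ", bad[1], ": invalid region [", d$start[bad[1]], ", ",
         d$end[bad[1]], "]")
  }
  d[need]
}
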