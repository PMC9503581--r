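# Protein sequence input: plain ASCII, one- or three-letter codes.

#' Construct a protein sequence object
#'
#' @param residues character vector of one-letter codes.
#' @param origin index of the first residue (default 1).
#' @return a `protein_sequence`.
#' @export
protein_sequence <- function(residues, origin = 1L) {
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AA_ONE)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  structure(list(residues = residues, origin = as.integer(origin)),
            class = "protein_sequence")
}

sequence_residues <- function(sequence) {
  if (inherits(sequence, "protein_sequence")) sequence$residues
  else toupper(as.character(sequence))
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("protein sequence: ", length(x$residues), " residues (",
      x$origin, "-", x$origin + length(x$residues) - 1L, ")\n", sep = "")
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Read a protein sequence from an ASCII text file
#'
#' Whitespace and line breaks are ignored. Input may be a run of one-letter
#' codes or whitespace-separated three-letter tokens (case-insensitive); the
#' two styles may not be mixed within one token.
#'
#' @param path file path.
#' @return a `protein_sequence` numbered from 1.
#' @export
read_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  # drop FASTA-style header lines
  lines <- lines[!grepl("^\\s*>", lines)]
  residues <- character(0)
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      up <- toupper(tok)
      if (!is.na(AA_THREE[up])) {
        residues <- c(residues, unname(AA_THREE[up]))
      } else {
        codes <- strsplit(up, "")[[1]]
        bad <- setdiff(codes, AA_ONE)
        if (length(bad))
          stop("unknown residue token '", tok, "' on line ", ln,
               " of ", path)
        residues <- c(residues, codes)
      }
    }
  }
  if (!length(residues)) stop("no residues found in ", path)
  protein_sequence(residues)
}
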