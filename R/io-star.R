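# NMR-STAR 2.1 / 3.1 chemical-shift tables, Sparky resonance lists, and the
# plain 4-column tabular shift format.
#
# No STAR library exists for R, so a minimal loop parser is implemented
# here. It handles the subset needed for shift tables: `loop_`, `_Tag`
# headers, whitespace-separated values, `stop_`, and comments. That covers
# files this package writes plus typical deposited shift loops.

# ---- shift table container -------------------------------------------------

#' Construct a shift table
#'
#' @param seq_id integer residue numbers.
#' @param res_type one-letter residue codes.
#' @param atom atom names ("N", "C", "CA", "CB", side-chain carbons; "CO" is
#'   accepted as an alias of "C").
#' @param value chemical shifts in ppm.
#' @param prob optional per-atom probabilities.
#' @return data.frame of class `shift_table`.
#' @export
shift_table <- function(seq_id, res_type, atom, value, prob = NULL) {
  res_type <- toupper(res_type)
  res_type <- ifelse(res_type %in% names(AA_THREE),
                     unname(AA_THREE[res_type]), res_type)
  bad <- setdiff(unique(res_type), AA_ONE)
  if (length(bad)) stop("unknown residue type(s): ", paste(bad, collapse = ", "))
  df <- data.frame(seq_id = as.integer(seq_id), res_type = res_type,
                   atom = normalize_atom(atom), value = as.numeric(value))
  df$prob <- if (is.null(prob)) rep(NA_real_, nrow(df)) else as.numeric(prob)
  class(df) <- c("shift_table", "data.frame")
  df
}

.star_tokens <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- unlist(strsplit(paste(lines, collapse = "\n"), "[ \t\r\n]+"))
  toks[nzchar(toks)]
}

# Parse every loop in a STAR file into (tags, value matrix).
.star_loops <- function(tokens) {
  loops <- list(); i <- 1L; n <- length(tokens)
  while (i <= n) {
    if (identical(tokens[i], "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(tokens[i], "_")) {
        tags <- c(tags, tokens[i]); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n && !identical(tokens[i], "stop_") &&
             !identical(tokens[i], "loop_") && !startsWith(tokens[i], "_") &&
             !grepl("^(save_|data_)", tokens[i])) {
        vals <- c(vals, tokens[i]); i <- i + 1L
      }
      if (i <= n && identical(tokens[i], "stop_")) i <- i + 1L
      if (length(tags) && length(vals) %% length(tags) == 0L && length(vals)) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tags
        loops[[length(loops) + 1L]] <- m
      }
    } else i <- i + 1L
  }
  loops
}

.pick <- function(m, candidates) {
  hit <- candidates[candidates %in% colnames(m)]
  if (!length(hit)) return(NULL)
  m[, hit[1]]
}

#' Load a chemical-shift table
#'
#' Accepts NMR-STAR 2.1 (`_Residue_seq_code` style tags), NMR-STAR 3.1
#' (`_Atom_chem_shift.*` tags), or plain 4/5-column tabular text
#' (`seq_id res_type atom ppm [prob]`). Only carbon and nitrogen shifts are
#' returned; protons are dropped.
#'
#' @param path file path.
#' @return a `shift_table`.
#' @export
load_shift_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("loop_", lines))) {
    loops <- .star_loops(.star_tokens(lines))
    for (m in loops) {
      seq_id <- .pick(m, c("_Atom_chem_shift.Seq_ID",
                           "_Atom_chem_shift.Comp_index_ID",
                           "_Residue_seq_code"))
      res <- .pick(m, c("_Atom_chem_shift.Comp_ID", "_Residue_label"))
      atom <- .pick(m, c("_Atom_chem_shift.Atom_ID", "_Atom_name"))
      val <- .pick(m, c("_Atom_chem_shift.Val", "_Chem_shift_value"))
      if (is.null(seq_id) || is.null(res) || is.null(atom) || is.null(val))
        next
      atom <- normalize_atom(atom)
      keep <- substr(atom, 1, 1) %in% c("C", "N")
      tab <- shift_table(as.integer(seq_id[keep]), res[keep], atom[keep],
                         as.numeric(val[keep]))
      return(tab)
    }
    stop("no parsable chemical-shift loop in ", path)
  }
  # tabular fallback
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no parsable chemical-shift loop in ", path)
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) < 4L)) stop("malformed tabular shift row in ", path)
  atom <- normalize_atom(vapply(toks, `[[`, "", 3))
  keep <- substr(atom, 1, 1) %in% c("C", "N")
  shift_table(as.integer(vapply(toks, `[[`, "", 1))[keep],
              vapply(toks, `[[`, "", 2)[keep], atom[keep],
              as.numeric(vapply(toks, `[[`, "", 4))[keep],
              prob = if (all(lengths(toks) >= 5L))
                as.numeric(vapply(toks, `[[`, "", 5))[keep] else NULL)
}

#' Write a chemical-shift table in NMR-STAR format
#'
#' @param result an `assignment_result` or a `shift_table`.
#' @param dialect "3.1" (default) or "2.1".
#' @param path output path.
#' @export
write_shift_table <- function(result, path, dialect = c("3.1", "2.1")) {
  dialect <- match.arg(dialect)
  tab <- as_shift_table(result)
  if (!nrow(tab)) stop("refusing to write an empty shift table")
  tab <- tab[order(tab$seq_id, tab$atom), ]
  res3 <- AA_ONE_TO_THREE[tab$res_type]
  elem <- substr(tab$atom, 1, 1)
  prob <- ifelse(is.na(tab$prob), 1, tab$prob)
  if (dialect == "3.1") {
    rows <- sprintf("  %6d %6d %-4s %-5s %-2s %10.3f %6.3f",
                    seq_len(nrow(tab)), tab$seq_id, res3, tab$atom, elem,
                    tab$value, prob)
    out <- c("data_assigned_chemical_shifts", "",
             "save_assigned_chem_shift_list_1",
             "  _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
             "", "  loop_",
             "    _Atom_chem_shift.ID",
             "    _Atom_chem_shift.Seq_ID",
             "    _Atom_chem_shift.Comp_ID",
             "    _Atom_chem_shift.Atom_ID",
             "    _Atom_chem_shift.Atom_type",
             "    _Atom_chem_shift.Val",
             "    _Atom_chem_shift.Assign_fig_of_merit",
             "", rows, "  stop_", "save_")
  } else {
    rows <- sprintf("  %6d %6d %-4s %-5s %-2s %10.3f %d",
                    seq_len(nrow(tab)), tab$seq_id, res3, tab$atom, elem,
                    tab$value, 1L)
    out <- c("data_assigned_chemical_shifts", "",
             sprintf("# probabilities: %s",
                     paste(sprintf("%d:%s:%.3f", tab$seq_id, tab$atom, prob),
                           collapse = " ")),
             "  loop_",
             "    _Atom_shift_assign_ID",
             "    _Residue_seq_code",
             "    _Residue_label",
             "    _Atom_name",
             "    _Atom_type",
             "    _Chem_shift_value",
             "    _Chem_shift_ambiguity_code",
             "", rows, "  stop_")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a Sparky resonance list
#'
#' One line per assigned atom: group (one-letter code + residue number),
#' atom name, shift in ppm. Atoms without a shift are omitted.
#'
#' @param result an `assignment_result` or `shift_table`.
#' @param path output path.
#' @export
write_sparky_resonances <- function(result, path) {
  tab <- as_shift_table(result)
  tab <- tab[is.finite(tab$value), ]
  tab <- tab[order(tab$seq_id, tab$atom), ]
  writeLines(sprintf("%s%d %s %.3f", tab$res_type, tab$seq_id, tab$atom,
                     tab$value), path)
  invisible(path)
}

#' Read a Sparky resonance list written by [write_sparky_resonances()]
#'
#' @param path file path.
#' @return a `shift_table`.
#' @export
read_sparky_resonances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  grp <- vapply(toks, `[[`, "", 1)
  shift_table(as.integer(sub("^[A-Za-z]", "", grp)),
              substr(grp, 1, 1),
              vapply(toks, `[[`, "", 2),
              as.numeric(vapply(toks, `[[`, "", 3)))
}

#' Load a locally saved NMR-STAR entry: shift table plus sequence
#'
#' No network access is performed; the file must already be on disk.
#' The sequence is reconstructed from the shift loop's residue numbering.
#' Residues inside the numbering range that carry no carbon or nitrogen
#' shift are reported in `missing_residues`.
#'
#' @param path file path of a saved NMR-STAR 2.1/3.1 file.
#' @return list with `shifts` (a `shift_table`), `sequence`
#'   (a `protein_sequence`), and `missing_residues` (integer vector).
#' @export
load_bmrb_star <- function(path) {
  tab <- load_shift_table(path)
  ids <- sort(unique(tab$seq_id))
  rng <- seq(min(ids), max(ids))
  types <- rep(NA_character_, length(rng))
  for (k in seq_along(rng)) {
    hit <- tab$res_type[tab$seq_id == rng[k]]
    if (length(hit)) types[k] <- hit[1]
  }
  missing <- rng[is.na(types)]
  types[is.na(types)] <- "A"   # placeholder for gap residues
  list(shifts = tab,
       sequence = protein_sequence(types, origin = min(ids)),
       missing_residues = missing)
}
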