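# Peak-list readers and writers.
#
# Supported dialects:
#   Sparky `.list`  — whitespace-separated; optional header line
#                     ("Assignment w1 w2 ... Data Height"); optional leading
#                     assignment-label column ("?-?-?" accepted); optional
#                     trailing height column.
#   XEASY  `.peaks` — standard columns: index, w1..wn, color code, spectrum
#                     type, intensity, intensity error, ...; only the ppm
#                     coordinates and the intensity are retained.
#   tab    `.txt`   — tab-separated: one peak per line, position columns in
#                     the profile's axis order, then an optional height
#                     column. Lines starting with '#' are comments.

#' Construct a peak list
#'
#' @param experiment experiment token (resolved against the profile registry).
#' @param peaks data.frame with columns `w1..wd` (ppm) and optionally
#'   `height`, `label`.
#' @param axis_offsets per-axis referencing correction in ppm (default 0).
#' @return a `peak_list`.
#' @export
peak_list <- function(experiment, peaks, axis_offsets = NULL) {
  prof <- get_profile(experiment)
  d <- prof$dimensionality
  wcols <- paste0("w", seq_len(d))
  if (!all(wcols %in% names(peaks)))
    stop("peaks must have columns ", paste(wcols, collapse = ", "))
  if (nrow(peaks)) {
    vals <- as.matrix(peaks[, wcols, drop = FALSE])
    if (!all(is.finite(vals))) stop("non-finite ppm value in peak list")
  }
  if (is.null(peaks$height)) peaks$height <- rep(NA_real_, nrow(peaks))
  if (is.null(peaks$label)) peaks$label <- rep(NA_character_, nrow(peaks))
  if (is.null(axis_offsets)) axis_offsets <- rep(0, d)
  nuclei <- vapply(prof$axes, function(ax)
    if (identical(ax$roles, "N")) "N" else "C", "")
  structure(list(experiment = prof$name, dimensionality = d,
                 axis_nuclei = nuclei,
                 peaks = peaks[, c(wcols, "height", "label"), drop = FALSE],
                 axis_offsets = axis_offsets,
                 n_skipped = 0L),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("peak list ", x$experiment, " (", x$dimensionality, "D): ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

.is_number <- function(x) grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", x)

.parse_sparky <- function(lines, d) {
  peaks <- list(); skipped <- 0L
  for (raw in lines) {
    ln <- trimws(raw)
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (grepl("^Assignment$", toks[1], ignore.case = TRUE)) next
    label <- NA_character_
    if (!.is_number(toks[1])) { label <- toks[1]; toks <- toks[-1] }
    if (length(toks) < d || !all(.is_number(toks[seq_len(d)]))) {
      skipped <- skipped + 1L; next
    }
    pos <- as.numeric(toks[seq_len(d)])
    height <- if (length(toks) > d && .is_number(toks[d + 1L]))
      as.numeric(toks[d + 1L]) else NA_real_
    peaks[[length(peaks) + 1L]] <- c(list(label = label, height = height),
                                     as.list(pos))
  }
  list(peaks = peaks, skipped = skipped)
}

.parse_xeasy <- function(lines, d) {
  peaks <- list(); skipped <- 0L
  for (raw in lines) {
    ln <- trimws(raw)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < d + 1L || !.is_number(toks[1]) ||
        !all(.is_number(toks[1L + seq_len(d)]))) {
      skipped <- skipped + 1L; next
    }
    pos <- as.numeric(toks[1L + seq_len(d)])
    # columns after the coordinates: color, spectrum type, intensity, ...
    height <- NA_real_
    if (length(toks) >= d + 4L && .is_number(toks[d + 4L]))
      height <- as.numeric(toks[d + 4L])
    peaks[[length(peaks) + 1L]] <- c(list(label = NA_character_,
                                          height = height), as.list(pos))
  }
  list(peaks = peaks, skipped = skipped)
}

.parse_tab <- function(lines, d) {
  peaks <- list(); skipped <- 0L
  for (raw in lines) {
    ln <- trimws(raw)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[\t ]+")[[1]]
    if (length(toks) < d || !all(.is_number(toks[seq_len(d)]))) {
      skipped <- skipped + 1L; next
    }
    pos <- as.numeric(toks[seq_len(d)])
    height <- if (length(toks) > d && .is_number(toks[d + 1L]))
      as.numeric(toks[d + 1L]) else NA_real_
    peaks[[length(peaks) + 1L]] <- c(list(label = NA_character_,
                                          height = height), as.list(pos))
  }
  list(peaks = peaks, skipped = skipped)
}

#' Read a peak list file
#'
#' The dialect is inferred from the extension (`.list` Sparky, `.peaks`
#' XEASY, `.txt` tab-separated) unless `format_hint` is one of "sparky",
#' "xeasy", "tab". Unparseable peak lines are skipped and counted in the
#' returned object's `n_skipped`.
#'
#' @param path file path.
#' @param experiment_name experiment token naming the profile.
#' @param format_hint optional dialect override.
#' @param axis_permutation optional integer permutation mapping file columns
#'   to the profile's axis order (e.g. `c(2, 1)` when the file's first
#'   column is the profile's second axis).
#' @return a `peak_list`.
#' @export
read_peak_list <- function(path, experiment_name, format_hint = NULL,
                           axis_permutation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  prof <- get_profile(experiment_name)
  d <- prof$dimensionality
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- switch(tolower(tools::file_ext(path)),
                  list = "sparky", peaks = "xeasy", txt = "tab",
                  stop("cannot infer peak-list format from extension of ",
                       path, "; pass format_hint"))
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(match.arg(fmt, c("sparky", "xeasy", "tab")),
                   sparky = .parse_sparky(lines, d),
                   xeasy  = .parse_xeasy(lines, d),
                   tab    = .parse_tab(lines, d))
  n <- length(parsed$peaks)
  wcols <- paste0("w", seq_len(d))
  df <- as.data.frame(stats::setNames(
    lapply(seq_len(d), function(k)
      vapply(parsed$peaks, function(p) p[[2L + k]], 0)), wcols))
  if (n == 0L)
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), d), wcols))
  df$height <- if (n) vapply(parsed$peaks, function(p) p$height, 0) else numeric(0)
  df$label <- if (n) vapply(parsed$peaks, function(p) p$label, "") else character(0)
  if (!is.null(axis_permutation)) {
    if (!setequal(axis_permutation, seq_len(d)))
      stop("axis_permutation must be a permutation of 1..", d)
    df[, wcols] <- df[, paste0("w", axis_permutation), drop = FALSE]
  }
  pl <- peak_list(experiment_name, df)
  pl$n_skipped <- parsed$skipped
  if (parsed$skipped > 0L)
    message(parsed$skipped, " unparseable line(s) skipped in ", path)
  pl
}

#' Write a peak list in Sparky format
#'
#' Deterministic formatting: same peaks produce byte-identical files.
#'
#' @param pl a `peak_list`.
#' @param path output path.
#' @export
write_sparky_list <- function(pl, path) {
  d <- pl$dimensionality
  header <- paste(c("Assignment", paste0("w", seq_len(d)), "Data", "Height"),
                  collapse = "    ")
  rows <- character(nrow(pl$peaks))
  if (nrow(pl$peaks)) {
    lab <- ifelse(is.na(pl$peaks$label),
                  paste(rep("?", d), collapse = "-"), pl$peaks$label)
    ht <- ifelse(is.na(pl$peaks$height), 1,  pl$peaks$height)
    pos <- vapply(seq_len(d), function(k)
      sprintf("%10.3f", pl$peaks[[paste0("w", k)]]), character(nrow(pl$peaks)))
    pos <- if (is.matrix(pos)) apply(pos, 1L, paste, collapse = " ")
           else paste(pos, collapse = " ")
    rows <- sprintf("%12s %s %14.6g", lab, pos, ht)
  }
  writeLines(c(header, "", rows), path)
  invisible(path)
}

#' Write a peak list in XEASY format
#'
#' @param pl a `peak_list`.
#' @param path output path.
#' @export
write_xeasy_peaks <- function(pl, path) {
  d <- pl$dimensionality
  hdr <- c(sprintf("# Number of dimensions %d", d),
           vapply(seq_len(d), function(k)
             sprintf("#INAME %d %s", k, pl$axis_nuclei[k]), ""))
  rows <- character(nrow(pl$peaks))
  if (nrow(pl$peaks)) {
    ht <- ifelse(is.na(pl$peaks$height), 1, pl$peaks$height)
    pos <- vapply(seq_len(d), function(k)
      sprintf("%9.3f", pl$peaks[[paste0("w", k)]]), character(nrow(pl$peaks)))
    pos <- if (is.matrix(pos)) apply(pos, 1L, paste, collapse = " ")
           else paste(pos, collapse = " ")
    rows <- sprintf("%5d %s 1 U %13.6e %9.2e e 0 0 0 0",
                    seq_len(nrow(pl$peaks)), pos, ht, 0)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
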