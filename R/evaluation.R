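# Completeness / correctness evaluation against a reference shift table,
# probability bin categories, and candidate-count curves.

.match_tol_for <- function(atom, match_tol) {
  ifelse(atom == "N", match_tol[["N"]], match_tol[["C"]])
}

#' Assignment completeness
#'
#' Number of reference shifts carrying a valid assignment (probability at
#' or above the cutoff) divided by the number of reference shifts. Only the
#' highest-probability candidate per atom is considered.
#'
#' @param result `assignment_result` or `shift_table` with probabilities.
#' @param reference a `shift_table` (ground truth).
#' @param cutoff probability cutoff (default 0.6).
#' @return list with `percent` (to 0.01 resolution), `numerator`,
#'   `denominator`.
#' @export
completeness <- function(result, reference, cutoff = 0.6) {
  reference <- as_shift_table(reference)
  if (!nrow(reference)) stop("empty reference")
  tab <- as_shift_table(result)
  tab <- tab[!is.na(tab$prob) & tab$prob >= cutoff, , drop = FALSE]
  ref_key <- paste0(reference$seq_id, ".", reference$atom)
  got_key <- paste0(tab$seq_id, ".", tab$atom)
  num <- sum(ref_key %in% got_key)
  den <- nrow(reference)
  list(percent = round(100 * num / den, 2), numerator = num,
       denominator = den)
}

#' Assignment correctness
#'
#' Denominator: "given" assignments, i.e. those with probability at or
#' above the cutoff. Numerator: given assignments whose shift matches the
#' reference value for the same residue/atom within the match tolerance.
#' With zero given assignments the result is not-applicable (`NA`).
#'
#' @inheritParams completeness
#' @param match_tol named ppm tolerances, default `c(C = 0.3, N = 0.5)`.
#' @return list with `percent` (NA when no assignment is given),
#'   `correct`, `given`.
#' @export
correctness <- function(result, reference, cutoff = 0.6,
                        match_tol = c(C = 0.3, N = 0.5)) {
  reference <- as_shift_table(reference)
  if (!nrow(reference)) stop("empty reference")
  tab <- as_shift_table(result)
  tab <- tab[!is.na(tab$prob) & tab$prob >= cutoff, , drop = FALSE]
  if (!nrow(tab))
    return(list(percent = NA_real_, correct = 0L, given = 0L))
  ref_key <- paste0(reference$seq_id, ".", reference$atom)
  ok <- vapply(seq_len(nrow(tab)), function(i) {
    j <- match(paste0(tab$seq_id[i], ".", tab$atom[i]), ref_key)
    if (is.na(j)) return(FALSE)
    abs(tab$value[i] - reference$value[j]) <=
      .match_tol_for(tab$atom[i], as.list(match_tol))
  }, TRUE)
  list(percent = round(100 * sum(ok) / nrow(tab), 2),
       correct = sum(ok), given = nrow(tab))
}

#' Probability bin categories
#'
#' green: p in (0.99, 1]; cyan: p in [0.85, 0.99]; yellow: p in
#' [0.5, 0.85); red: p in [0, 0.5); gray: no assignment (`NA`).
#'
#' @param p numeric vector of probabilities (NA = unassigned).
#' @return character vector of bin names.
#' @export
probability_bins <- function(p) {
  out <- rep("gray", length(p))
  out[!is.na(p) & p < 0.5] <- "red"
  out[!is.na(p) & p >= 0.5 & p < 0.85] <- "yellow"
  out[!is.na(p) & p >= 0.85 & p <= 0.99] <- "cyan"
  out[!is.na(p) & p > 0.99] <- "green"
  out
}

#' Candidate-count curves over a probability grid
#'
#' At each threshold from 1.0 down to 0.0 in steps of 0.05: `all` counts
#' every candidate, `given` those with probability at or above the
#' threshold, and `correct`/`incorrect` partition the given ones by
#' reference agreement. Multiple (result, reference) pairs are pooled.
#'
#' @param results list of `assignment_result`s (or a single one).
#' @param references list of reference `shift_table`s (matched by index).
#' @param match_tol ppm tolerances for agreement.
#' @return data.frame with columns `probability`, `all`, `given`,
#'   `correct`, `incorrect`, `completeness`, `correctness`.
#' @export
candidate_curves <- function(results, references,
                             match_tol = c(C = 0.3, N = 0.5)) {
  if (inherits(results, "assignment_result") || is.data.frame(results))
    results <- list(results)
  if (inherits(references, "shift_table") || is.data.frame(references))
    references <- list(references)
  stopifnot(length(results) == length(references))
  probs <- numeric(0); correct <- logical(0); n_ref <- 0L
  for (k in seq_along(results)) {
    tab <- as_shift_table(results[[k]])
    ref <- as_shift_table(references[[k]])
    n_ref <- n_ref + nrow(ref)
    ref_key <- paste0(ref$seq_id, ".", ref$atom)
    for (i in seq_len(nrow(tab))) {
      p <- tab$prob[i]
      if (is.na(p)) next
      j <- match(paste0(tab$seq_id[i], ".", tab$atom[i]), ref_key)
      ok <- !is.na(j) && abs(tab$value[i] - ref$value[j]) <=
        .match_tol_for(tab$atom[i], as.list(match_tol))
      probs <- c(probs, p); correct <- c(correct, ok)
    }
  }
  grid <- seq(1, 0, by = -0.05)
  do.call(rbind, lapply(grid, function(th) {
    given <- probs >= th
    data.frame(probability = th,
               all = length(probs),
               given = sum(given),
               correct = sum(correct & given),
               incorrect = sum(!correct & given),
               completeness = round(100 * sum(given) / max(n_ref, 1L), 2),
               correctness = if (any(given))
                 round(100 * sum(correct & given) / sum(given), 2)
               else NA_real_)
  }))
}

#' Tab-separated per-residue probability report (bar-graph data)
#'
#' @param result an `assignment_result`.
#' @param path optional output path.
#' @return the data.frame, invisibly when written.
#' @export
probability_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "assignment_result"), !isTRUE(result$terminated))
  df <- result$residues
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
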