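# Chemical-shift reference statistics and amino-acid typing.
#
# The typing model is a product of independent Gaussians, one per observed
# atom. Missing atoms are marginalized (omitted from the product); observing
# an atom a residue type does not possess (CB for glycine) makes that type's
# likelihood exactly zero. Unclassified carbon observations ("CX" values
# whose atom identity is unknown) are scored against the type's remaining
# carbon inventory by greedy one-to-one best-density matching, floored so a
# single stray value cannot annihilate a type.

#' Load chemical-shift reference statistics
#'
#' With no path, returns the snapshot bundled with the package. A user table
#' must be whitespace-separated with five columns: one-letter residue type,
#' atom name, mean (ppm), sd (ppm), observation count. Standard deviations
#' below the configured floor (0.3 ppm carbon / 0.5 ppm nitrogen) are
#' clamped with a warning.
#'
#' @param path optional file path overriding the bundled snapshot.
#' @param config configuration list from [ssa_config()].
#' @return a `shift_statistics` object.
#' @export
load_statistics <- function(path = NULL, config = ssa_config()) {
  if (is.null(path))
    path <- system.file("extdata", "shift_statistics.tsv",
                        package = "ssassign", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  src <- if (any(grepl("SYNTHETIC SNAPSHOT", lines))) "bundled snapshot"
         else path
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != 5L ||
        !all(.is_number(toks[[i]][3:5])))
      stop("malformed statistics row on line ", i, " (after comments): '",
           body[i], "'")
  }
  type <- toupper(vapply(toks, `[[`, "", 1))
  atom <- normalize_atom(vapply(toks, `[[`, "", 2))
  mean <- as.numeric(vapply(toks, `[[`, "", 3))
  sd <- as.numeric(vapply(toks, `[[`, "", 4))
  count <- as.numeric(vapply(toks, `[[`, "", 5))
  floor_ <- ifelse(atom == "N", config$sd_floor_n, config$sd_floor_c)
  clamped <- sd < floor_
  if (any(clamped)) {
    warning(sum(clamped), " statistics entr",
            if (sum(clamped) == 1) "y" else "ies",
            " had sd below the floor and were clamped")
    sd[clamped] <- floor_[clamped]
  }
  tab <- data.frame(type = type, atom = atom, mean = mean, sd = sd,
                    count = count)
  key <- paste(tab$type, tab$atom)
  lookup_mean <- stats::setNames(tab$mean, key)
  lookup_sd <- stats::setNames(tab$sd, key)
  structure(list(table = tab, mean = lookup_mean, sd = lookup_sd,
                 source = src),
            class = "shift_statistics")
}

#' @export
print.shift_statistics <- function(x, ...) {
  cat("shift statistics: ", nrow(x$table), " (type, atom) entries, source: ",
      x$source, "\n", sep = "")
  invisible(x)
}

stats_mean <- function(stats, type, atom) {
  unname(stats$mean[paste(type, atom)])
}

stats_density <- function(stats, type, atom, ppm) {
  key <- paste(type, atom)   # recycles over vector type/atom/ppm inputs
  n <- max(length(ppm), length(key))
  m <- rep_len(unname(stats$mean[key]), n)
  s <- rep_len(unname(stats$sd[key]), n)
  bad <- is.na(m)
  m[bad] <- 0; s[bad] <- 1
  out <- stats::dnorm(ppm, m, s)
  out[bad] <- 0
  out
}

#' Typing likelihood of observed shifts under one residue type
#'
#' Product over named observed atoms of the Gaussian density at the table's
#' (mean, sd). If the type lacks an observed named atom the score is 0.
#' Values in `cx` (carbons of unknown atom identity) are matched greedily,
#' one-to-one and best-density-first, against the type's carbon atoms not
#' already used; an unmatchable value contributes the configured floor.
#'
#' @param observed named numeric vector, atom name -> ppm.
#' @param residue_type one-letter code.
#' @param stats a `shift_statistics`.
#' @param cx optional numeric vector of unclassified carbon shifts.
#' @param config configuration list.
#' @return non-negative likelihood score.
#' @export
type_likelihood <- function(observed, residue_type, stats, cx = numeric(0),
                            config = ssa_config(), spec = NULL) {
  if (!length(observed) && !length(cx)) stop("observed shifts are empty")
  have <- residue_atoms(residue_type)
  score <- 1
  used <- character(0)
  if (length(observed)) {
    atoms <- normalize_atom(names(observed))
    for (k in seq_along(observed)) {
      a <- atoms[k]
      if (!(a %in% have)) {
        # atoms attached through a single-anchor strip may be strip-
        # collision artifacts: penalize instead of vetoing the type
        sp <- if (is.null(spec)) 2 else spec[[names(observed)[k]]] %||% 2
        if (sp <= 1) { score <- score * config$cx_floor; next }
        return(0)
      }
      score <- score * stats_density(stats, residue_type, a, observed[[k]])
      used <- c(used, a)
    }
  }
  if (length(cx)) {
    avail <- setdiff(setdiff(have, "N"), used)
    for (v in sort(cx)) {
      if (!length(avail)) { score <- score * config$cx_floor; next }
      dens <- vapply(avail, function(a)
        stats_density(stats, residue_type, a, v), 0)
      j <- which.max(dens)
      if (dens[j] <= config$cx_floor) {
        score <- score * config$cx_floor
      } else {
        score <- score * dens[j]
        avail <- avail[-j]
      }
    }
  }
  unname(score)
}

#' Posterior over the 20 residue types given observed shifts
#'
#' Posterior is proportional to prior times [type_likelihood()], normalized
#' over the 20 standard types. With no observations the prior is returned.
#' If every type has zero likelihood a uniform posterior is returned with a
#' warning.
#'
#' @param observed named numeric vector, atom name -> ppm (may be empty).
#' @param stats a `shift_statistics`.
#' @param prior optional named numeric vector over types; default uniform.
#' @param cx optional unclassified carbon shifts.
#' @param config configuration list.
#' @return named numeric vector over the 20 types, summing to 1.
#' @export
type_posterior <- function(observed, stats, prior = NULL, cx = numeric(0),
                           config = ssa_config()) {
  if (is.null(prior)) prior <- stats::setNames(rep(1 / 20, 20), AA_ONE)
  prior <- prior[AA_ONE] / sum(prior[AA_ONE])
  if (!length(observed) && !length(cx)) return(prior)
  lik <- vapply(AA_ONE, function(t)
    type_likelihood(observed, t, stats, cx = cx, config = config), 0)
  post <- prior * lik
  s <- sum(post)
  if (s <= 0) {
    warning("all residue types have zero likelihood; returning uniform")
    return(stats::setNames(rep(1 / 20, 20), AA_ONE))
  }
  post / s
}
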