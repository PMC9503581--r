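# Synthetic peak-list generation from an assigned shift table.
#
# The generator instantiates exactly the sequential cross-peak templates of
# each experiment profile at the table's shift values and degrades them
# under controlled options: per-nucleus Gaussian jitter, independent peak
# dropout, uniform false positives, and per-experiment referencing offsets.
# Everything is reproducible from the seed.

#' Options for the synthetic peak-list generator
#'
#' @param jitter_c,jitter_n Gaussian jitter sd in ppm (default 0).
#' @param missing_rate probability a true peak is dropped (default 0).
#' @param false_positive_rate expected spurious peaks per true peak
#'   (default 0).
#' @param offsets named list: experiment -> c(C =, N =) referencing error
#'   added to the emitted coordinates (default none).
#' @param seed integer RNG seed.
#' @return list of options.
#' @export
synthetic_options <- function(jitter_c = 0, jitter_n = 0, missing_rate = 0,
                              false_positive_rate = 0, offsets = list(),
                              seed = 1L) {
  stopifnot(jitter_c >= 0, jitter_n >= 0,
            missing_rate >= 0, missing_rate <= 1,
            false_positive_rate >= 0)
  list(jitter_c = jitter_c, jitter_n = jitter_n,
       missing_rate = missing_rate,
       false_positive_rate = false_positive_rate,
       offsets = offsets, seed = as.integer(seed))
}

#' Generate synthetic peak lists from a shift table
#'
#' Only sequential (i, i-1) cross-peaks are generated. Templates touching a
#' shift absent from the table are skipped and counted in the
#' `skipped_templates` attribute of each list.
#'
#' @param shifts a `shift_table` covering the sequence (gaps allowed).
#' @param sequence a `protein_sequence` or character vector.
#' @param experiments character vector of experiment tokens.
#' @param options from [synthetic_options()].
#' @return named list of `peak_list` objects, one per experiment.
#' @export
generate_peaklists <- function(shifts, sequence, experiments,
                               options = synthetic_options()) {
  shifts <- as_shift_table(shifts)
  if (!nrow(shifts)) stop("empty shift table")
  res <- sequence_residues(sequence)
  lookup <- stats::setNames(shifts$value,
                            paste0(shifts$seq_id, ".", shifts$atom))
  out <- list()
  for (ename in experiments) {
    prof <- get_profile(ename)
    d <- prof$dimensionality
    set.seed(derive_seed(options$seed, prof$name))
    tmpl <- expected_peaks(prof, res)
    skipped <- 0L
    pos <- matrix(NA_real_, nrow = nrow(tmpl), ncol = d)
    keep <- rep(TRUE, nrow(tmpl))
    for (k in seq_len(d)) {
      key <- paste0(tmpl[[paste0("res", k)]], ".", tmpl[[paste0("atom", k)]])
      pos[, k] <- lookup[key]
    }
    if (nrow(tmpl)) {
      miss <- !stats::complete.cases(pos)
      skipped <- sum(miss)
      keep <- !miss
    }
    pos <- pos[keep, , drop = FALSE]
    nuclei <- vapply(prof$axes, function(ax)
      if (identical(ax$roles, "N")) "N" else "C", "")
    # jitter
    if (nrow(pos)) {
      for (k in seq_len(d)) {
        sdv <- if (nuclei[k] == "N") options$jitter_n else options$jitter_c
        if (sdv > 0) pos[, k] <- pos[, k] + stats::rnorm(nrow(pos), 0, sdv)
      }
      # dropout
      if (options$missing_rate > 0) {
        drop <- stats::runif(nrow(pos)) < options$missing_rate
        pos <- pos[!drop, , drop = FALSE]
      }
    }
    # false positives, uniform within each axis's observed range
    if (options$false_positive_rate > 0 && nrow(pos) > 1L) {
      n_fp <- stats::rpois(1, options$false_positive_rate * nrow(pos))
      if (n_fp > 0) {
        fp <- vapply(seq_len(d), function(k)
          stats::runif(n_fp, min(pos[, k]), max(pos[, k])),
          numeric(n_fp))
        if (n_fp == 1L) fp <- matrix(fp, nrow = 1L)
        pos <- rbind(pos, fp)
      }
    }
    # per-experiment referencing error, added last
    eoff <- options$offsets[[prof$name]]
    if (!is.null(eoff)) {
      for (k in seq_len(d)) pos[, k] <- pos[, k] + eoff[[nuclei[k]]]
    }
    df <- as.data.frame(stats::setNames(
      lapply(seq_len(d), function(k) pos[, k]), paste0("w", seq_len(d))))
    if (!nrow(pos))
      df <- as.data.frame(stats::setNames(rep(list(numeric(0)), d),
                                          paste0("w", seq_len(d))))
    df$height <- rep(1, nrow(df))
    pl <- peak_list(ename, df)
    attr(pl, "skipped_templates") <- skipped
    out[[prof$name]] <- pl
  }
  out
}

#' Draw a synthetic shift table from the reference statistics
#'
#' Per-residue shifts are sampled from the bundled per-(type, atom)
#' Gaussians, i.e. the table stays statistically plausible. With
#' `min_separation > 0`, a residue's draw is rejected (and redrawn) when it
#' would create one of the collisions that actually confuse strip matching
#' and linking:
#' * an (N, CA) anchor pair within `min_separation` of another residue's
#'   on both axes, or
#' * a (CA, CB, C) linking triplet agreeing with another residue's on
#'   every shared atom within `min_separation`.
#' Global per-atom-class separation is deliberately not enforced — for a
#' protein-sized sequence it is infeasible inside realistic shift ranges.
#'
#' @param sequence a `protein_sequence` or character vector.
#' @param stats a `shift_statistics`.
#' @param seed RNG seed.
#' @param min_separation ppm; joint-collision threshold (0 disables).
#' @param backbone_only only N, CA, CB, C shifts when TRUE.
#' @return a `shift_table`.
#' @export
simulate_shift_table <- function(sequence, stats = load_statistics(),
                                 seed = 1L, min_separation = 0,
                                 backbone_only = FALSE) {
  res <- sequence_residues(sequence)
  set.seed(derive_seed(seed, "shift-table"))
  draw_residue <- function(type, atoms) {
    stats::setNames(vapply(atoms, function(a)
      stats::rnorm(1, stats_mean(stats, type, a),
                   stats$sd[paste(type, a)]), 0), atoms)
  }
  collides <- function(v, prev_list, sep) {
    for (w in prev_list) {
      if (abs(v[["N"]] - w[["N"]]) < sep &&
          abs(v[["CA"]] - w[["CA"]]) < sep) return(TRUE)
      shared <- intersect(intersect(names(v), names(w)), c("CA", "CB", "C"))
      if (length(shared) &&
          all(abs(v[shared] - w[shared]) < sep)) return(TRUE)
    }
    FALSE
  }
  drawn <- list()
  rows <- list()
  for (i in seq_along(res)) {
    atoms <- residue_atoms(res[i])
    if (backbone_only) atoms <- intersect(atoms, c("N", "C", "CA", "CB"))
    v <- draw_residue(res[i], atoms)
    if (min_separation > 0) {
      tries <- 0L
      while (collides(v, drawn, min_separation) && tries < 200L) {
        v <- draw_residue(res[i], atoms)
        tries <- tries + 1L
      }
    }
    drawn[[i]] <- v
    rows[[i]] <- data.frame(seq_id = i, res_type = res[i],
                            atom = names(v), value = unname(v))
  }
  df <- do.call(rbind, rows)
  shift_table(df$seq_id, df$res_type, df$atom, df$value)
}

#' Write generated peak lists plus a provenance manifest
#'
#' @param peaklists named list from [generate_peaklists()].
#' @param dir output directory (created if needed).
#' @param options the generator options used.
#' @param format "sparky" (default) or "xeasy".
#' @return character vector of written file paths.
#' @export
write_peaklists <- function(peaklists, dir, options = synthetic_options(),
                            format = c("sparky", "xeasy")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(peaklists)) {
    ext <- if (format == "sparky") ".list" else ".peaks"
    path <- file.path(dir, paste0(nm, ext))
    if (format == "sparky") write_sparky_list(peaklists[[nm]], path)
    else write_xeasy_peaks(peaklists[[nm]], path)
    paths <- c(paths, path)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = options$seed, jitter_c = options$jitter_c,
         jitter_n = options$jitter_n, missing_rate = options$missing_rate,
         false_positive_rate = options$false_positive_rate,
         offsets = options$offsets, format = format,
         experiments = names(peaklists)),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(paths, manifest)
}
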