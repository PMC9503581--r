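# Assignment engine: iteration of assembly, belief propagation, and
# referencing-offset re-estimation to convergence.

# Support records of every assigned, confident system resolved to
# (experiment, residue, atom, observed value).
.confident_contributions <- function(matrix, assign, prob, config) {
  out <- list()
  for (i in seq_along(matrix$systems)) {
    if (assign[i] == 0L || prob[i] < config$offset_conf) next
    sup <- matrix$systems[[i]]$support
    if (!nrow(sup)) next
    keep <- sup$slot %in% c("own.N", "own.CA", "own.CB", "own.C",
                            "prev.CA", "prev.CB", "prev.C")
    if (!any(keep)) next
    sup <- sup[keep, , drop = FALSE]
    side <- sub("\\..*$", "", sup$slot)
    atom <- sub("^.*\\.", "", sup$slot)
    seq_id <- ifelse(side == "own", assign[i], assign[i] - 1L)
    out[[length(out) + 1L]] <- data.frame(
      experiment = sup$experiment,
      nucleus = ifelse(atom == "N", "N", "C"),
      key = paste0(seq_id, ".", atom),
      value = sup$value)
  }
  if (!length(out))
    return(data.frame(experiment = character(0), nucleus = character(0),
                      key = character(0), value = numeric(0)))
  do.call(rbind, out)
}


# Sequential corroboration: a placement is trustworthy when the system is
# linked to a system placed at an adjacent position. Placements without
# such support keep their shifts but their probability is capped below the
# reporting cutoff — on complete data every correct placement is
# corroborated, while misplaced systems rarely are.
.corroborate <- function(mapres, links, config) {
  pos <- mapres$position; prob <- mapres$prob
  if (!length(pos)) return(prob)
  pos_of <- function(i) pos[i]
  at <- function(p) which(pos == p)
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p == 0L) next
    ok <- FALSE
    pred <- at(p - 1L); succ <- at(p + 1L)
    if (length(pred) &&
        any(links$from_id %in% pred & links$to_id == i)) ok <- TRUE
    if (!ok && length(succ) &&
        any(links$from_id == i & links$to_id %in% succ)) ok <- TRUE
    if (!ok) prob[i] <- min(prob[i], config$corroboration_cap)
  }
  prob
}

#' Detect per-experiment referencing offsets
#'
#' A simplified surrogate for full linear chemical-shift analysis: for each
#' experiment and nucleus, the offset is the median leave-one-out residual
#' of that experiment's contributions against the mean of the other
#' experiments' contributions to the same atom, over confidently assigned
#' atoms. Offsets smaller than 0.1 ppm in magnitude are reported as zero,
#' as are experiments with fewer than the configured number of confident,
#' corroborated atoms.
#'
#' @param matrix assembled `spin_system_matrix` with support records.
#' @param assign integer vector of assigned positions per system (0 =
#'   unassigned).
#' @param prob assigned-position probabilities per system.
#' @param config configuration list.
#' @return data.frame with `experiment`, `nucleus`, `offset`,
#'   `n_support`.
#' @export
detect_reference_offset <- function(matrix, assign, prob,
                                    config = ssa_config()) {
  contrib <- .confident_contributions(matrix, assign, prob, config)
  exps <- unique(unlist(lapply(matrix$systems, function(s)
    s$support$experiment)))
  out <- list()
  for (e in exps) {
    for (nuc in c("C", "N")) {
      rows <- contrib[contrib$experiment == e & contrib$nucleus == nuc, ,
                      drop = FALSE]
      res <- numeric(0)
      for (r in seq_len(nrow(rows))) {
        others <- contrib$value[contrib$key == rows$key[r] &
                                contrib$experiment != e &
                                contrib$nucleus == nuc]
        if (length(others))
          res <- c(res, rows$value[r] - mean(others))
      }
      off <- 0
      if (length(res) >= config$offset_min_support) {
        off <- stats::median(res)
        # significance gate: the median must stand out from the scatter of
        # the residuals, otherwise peak-position noise masquerades as a
        # referencing error and the "correction" degrades the next round
        se <- 1.4826 * stats::mad(res, constant = 1) / sqrt(length(res))
        if (abs(off) < config$offset_min_report ||
            abs(off) < 3 * se) off <- 0
      } else if (nrow(rows)) {
        warning("experiment ", e, " (", nuc, "): too few corroborated ",
                "confident assignments for offset detection; reporting 0",
                call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(experiment = e, nucleus = nuc,
                                            offset = off,
                                            n_support = length(res))
    }
  }
  if (!length(out))
    return(data.frame(experiment = character(0), nucleus = character(0),
                      offset = numeric(0), n_support = integer(0)))
  do.call(rbind, out)
}


# Referencing-error scan for experiments that fail to attach: when most of
# an experiment's peaks match no root, a uniform axis offset is the usual
# culprit. Scan a coarse offset grid per nucleus for the shift that
# maximizes anchor matches; accept it only when it at least doubles the
# match count and explains at least half the peaks.
.scan_attachment_offset <- function(pl, matrix, tol, config) {
  prof <- get_profile(pl$experiment)
  if (prof$name == "CC") return(NULL)
  kinds <- .axis_kinds(prof)
  anchor_idx <- which(kinds != "free")
  if (!length(anchor_idx)) return(NULL)
  coords <- .corrected_coords(pl)
  if (nrow(coords) < 5L) return(NULL)
  systems <- matrix$systems
  targets <- lapply(anchor_idx, function(ai) vapply(systems, function(sys)
    switch(kinds[ai], anchor_N = sys$root[["N"]],
           anchor_CA = sys$root[["CA"]], anchor_CO = sys$root[["CO_prev"]]),
    0))
  nuclei <- vapply(prof$axes, function(ax)
    if (identical(ax$roles, "N")) "N" else "C", "")
  count_matches <- function(d_c, d_n) {
    # joint matching: one system must satisfy every anchor simultaneously
    ok <- matrix(TRUE, nrow = nrow(coords), ncol = length(systems))
    for (k in seq_along(anchor_idx)) {
      ai <- anchor_idx[k]
      atol <- if (nuclei[ai] == "N") tol[["N"]] else tol[["C"]]
      delta <- if (nuclei[ai] == "N") d_n else d_c
      tg <- targets[[k]]
      dd <- abs(outer(coords[, ai] - delta, tg, `-`))
      ok <- ok & !is.na(dd) & dd <= atol
    }
    sum(rowSums(ok) > 0L)
  }
  base <- count_matches(0, 0)
  if (base >= 0.5 * nrow(coords)) return(NULL)
  grid <- seq(-1, 1, by = 0.05)
  best <- c(C = 0, N = 0); best_n <- base
  for (d in grid) {
    m <- count_matches(d, 0)
    if (m > best_n || (m == best_n && abs(d) < abs(best[["C"]]))) {
      best_n <- m; best <- c(C = d, N = 0)
    }
  }
  if (any(nuclei == "N")) {
    bc <- best[["C"]]
    for (d in grid) {
      m <- count_matches(bc, d)
      if (m > best_n || (m == best_n && abs(d) < abs(best[["N"]]))) {
        best_n <- m; best <- c(C = bc, N = d)
      }
    }
  }
  if (best_n >= max(2L * max(base, 1L), 0.5 * nrow(coords)) &&
      any(abs(best) >= config$offset_min_report)) {
    best[abs(best) < config$offset_min_report] <- 0
    return(best)
  }
  NULL
}

# Merge named backbone shifts from winning systems into per-atom rows.
.collect_backbone <- function(matrix, assign, prob, sequence) {
  res <- sequence_residues(sequence)
  acc <- new.env(parent = emptyenv())
  add <- function(seq_id, atom, value, weight, p, sys_id) {
    if (seq_id < 1L || seq_id > length(res)) return()
    type <- res[seq_id]
    if (!(atom %in% residue_atoms(type))) return()
    key <- paste0(seq_id, ".", atom)
    cur <- acc[[key]]
    if (is.null(cur)) {
      acc[[key]] <- list(seq_id = seq_id, atom = atom, num = value * weight,
                         den = weight, prob = p, systems = sys_id)
    } else {
      cur$num <- cur$num + value * weight
      cur$den <- cur$den + weight
      cur$prob <- max(cur$prob, p)
      cur$systems <- union(cur$systems, sys_id)
      acc[[key]] <- cur
    }
  }
  for (i in seq_along(matrix$systems)) {
    if (assign[i] == 0L) next
    sys <- matrix$systems[[i]]
    p <- assign[i]
    for (a in names(sys$own))
      add(p, a, sys$own[[a]], sys$weights$own[[a]], prob[i], sys$id)
    for (a in names(sys$prev))
      add(p - 1L, a, sys$prev[[a]], sys$weights$prev[[a]], prob[i], sys$id)
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(seq_id = integer(0), atom = character(0),
                      value = numeric(0), prob = numeric(0)))
  df <- do.call(rbind, lapply(keys, function(k) {
    x <- acc[[k]]
    data.frame(seq_id = x$seq_id, atom = x$atom, value = x$num / x$den,
               prob = x$prob)
  }))
  df[order(df$seq_id, df$atom), , drop = FALSE]
}

#' Construct an assignment result object
#' @keywords internal
make_assignment_result <- function(matrix, assign, prob, beliefs, doms,
                                   sequence, offsets, convergence,
                                   terminated = FALSE, message = NULL) {
  res <- sequence_residues(sequence)
  if (terminated) {
    return(structure(list(terminated = TRUE, message = message,
                          sequence = res),
                     class = "assignment_result"))
  }
  bb <- .collect_backbone(matrix, assign, prob, sequence)
  shifts <- shift_table(bb$seq_id, res[bb$seq_id], bb$atom, bb$value,
                        prob = bb$prob)
  per_res <- data.frame(seq_id = seq_along(res), res_type = res,
                        best_prob = NA_real_)
  for (i in seq_along(matrix$systems)) {
    if (assign[i] == 0L) next
    j <- assign[i]
    if (is.na(per_res$best_prob[j]) || prob[i] > per_res$best_prob[j])
      per_res$best_prob[j] <- prob[i]
  }
  per_res$bin <- probability_bins(per_res$best_prob)
  cand <- list()
  for (i in seq_along(beliefs)) {
    b <- beliefs[[i]]; dom <- doms[[i]]
    pos <- dom > 0L
    if (any(pos))
      cand[[length(cand) + 1L]] <- data.frame(
        system_id = matrix$systems[[i]]$id, seq_id = dom[pos],
        prob = unname(b[pos]))
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(system_id = integer(0), seq_id = integer(0),
               prob = numeric(0))
  structure(list(terminated = FALSE, shifts = shifts, residues = per_res,
                 candidates = cand, offsets = offsets,
                 convergence = convergence, assign = assign,
                 system_prob = prob, matrix = matrix, sequence = res),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  if (isTRUE(x$terminated)) {
    cat("assignment terminated:", x$message, "\n")
    return(invisible(x))
  }
  cat("assignment result: ", nrow(x$shifts), " shifts over ",
      sum(!is.na(x$residues$best_prob)), "/", nrow(x$residues),
      " residues; ", sum(x$residues$bin == "green", na.rm = TRUE),
      " green, ", sum(x$residues$bin == "red", na.rm = TRUE), " red\n",
      sep = "")
  invisible(x)
}

#' Coerce to a shift table
#' @param x an `assignment_result` or `shift_table`.
#' @return a `shift_table`.
#' @export
as_shift_table <- function(x) {
  if (inherits(x, "shift_table")) return(x)
  if (inherits(x, "assignment_result")) {
    if (isTRUE(x$terminated)) stop("terminated result carries no shifts")
    return(x$shifts)
  }
  if (is.data.frame(x) &&
      all(c("seq_id", "res_type", "atom", "value") %in% names(x)))
    return(shift_table(x$seq_id, x$res_type, x$atom, x$value, x$prob))
  stop("cannot coerce to shift_table")
}

#' Full backbone assignment with offset iteration
#'
#' Runs tolerance optimization, gates on data quality, then iterates
#' {belief propagation -> offset detection -> referencing correction ->
#' re-assembly} until the assignment map is stable or the round limit is
#' reached. Returns a terminated result (see `$terminated`) when the
#' quality gate fails.
#'
#' @param peaklists list of `peak_list` objects.
#' @param sequence a `protein_sequence` or character vector.
#' @param stats a `shift_statistics`.
#' @param config configuration from [ssa_config()].
#' @param verbose emit progress messages.
#' @return an `assignment_result`.
#' @export
iterate_assignment <- function(peaklists, sequence,
                               stats = load_statistics(),
                               config = ssa_config(), verbose = FALSE) {
  opt <- optimize_tolerances(peaklists, sequence, stats, config)
  if (is.null(opt$matrix) || !length(opt$matrix$systems)) {
    return(make_assignment_result(NULL, NULL, NULL, NULL, NULL, sequence,
                                  NULL, list(quality_trace = opt$trace),
                                  terminated = TRUE,
                                  message = gate_quality(0, config$quality_threshold)$message))
  }
  gate <- gate_quality(opt$matrix$quality, config$quality_threshold)
  if (!gate$proceed) {
    return(make_assignment_result(NULL, NULL, NULL, NULL, NULL, sequence,
                                  NULL, list(quality_trace = opt$trace),
                                  terminated = TRUE, message = gate$message))
  }
  ssa_message("tolerances C=", opt$tol[["C"]], " N=", opt$tol[["N"]],
              " quality=", sprintf("%.3f", opt$matrix$quality),
              verbose = verbose)
  matrix <- opt$matrix
  applied <- list()   # experiment -> c(C=, N=) cumulative corrections
  prev_map <- NULL
  round <- 0L; bp <- NULL; mapres <- NULL; offsets <- NULL
  repeat {
    round <- round + 1L
    links <- link_spin_systems(matrix, matrix$tolerances, config)
    pp <- generate_pentapeptides(links, matrix, sequence, stats, config)
    bp <- run_belief_propagation(matrix, links, sequence, stats, config,
                                 domains = pp$domains, unary = pp$unary)
    mapres <- map_assignment(bp$beliefs, bp$domains)
    mapres$prob <- .corroborate(mapres, links, config)
    offsets <- detect_reference_offset(matrix, mapres$position, mapres$prob,
                                       config)
    # experiments whose strips largely failed to attach: scan for a
    # uniform referencing shift
    for (pl in peaklists) {
      sc <- .scan_attachment_offset(pl, matrix, matrix$tolerances, config)
      if (is.null(sc)) next
      for (nuc in c("C", "N")) {
        if (sc[[nuc]] == 0) next
        hit <- offsets$experiment == pl$experiment & offsets$nucleus == nuc
        if (any(hit)) offsets$offset[hit] <- sc[[nuc]]
        else offsets <- rbind(offsets, data.frame(
          experiment = pl$experiment, nucleus = nuc, offset = sc[[nuc]],
          n_support = NA_integer_))
      }
    }
    cur_map <- paste(mapres$position, collapse = ",")
    new_off <- offsets[offsets$offset != 0, , drop = FALSE]
    ssa_message("round ", round, ": ", sum(mapres$position > 0),
                " systems placed, ", nrow(new_off), " nonzero offsets",
                verbose = verbose)
    if (!nrow(new_off) || identical(cur_map, prev_map) ||
        round >= config$max_rounds) break
    prev_map <- cur_map
    # apply corrections and re-assemble
    for (r in seq_len(nrow(new_off))) {
      e <- new_off$experiment[r]; nuc <- new_off$nucleus[r]
      cur <- applied[[e]]
      if (is.null(cur)) cur <- c(C = 0, N = 0)
      cur[nuc] <- cur[nuc] + new_off$offset[r]
      applied[[e]] <- cur
    }
    for (j in seq_along(peaklists)) {
      pl <- peaklists[[j]]
      cur <- applied[[pl$experiment]]
      if (is.null(cur)) next
      pl$axis_offsets <- unname(cur[pl$axis_nuclei])
      peaklists[[j]] <- pl
    }
    matrix <- assemble_matrix(peaklists, matrix$tolerances, stats)
    q <- assess_quality(matrix, sequence, stats = stats, config = config)
    matrix$quality <- q
    gate <- gate_quality(q, config$quality_threshold)
    if (!gate$proceed)
      return(make_assignment_result(NULL, NULL, NULL, NULL, NULL, sequence,
                                    NULL, list(quality_trace = opt$trace),
                                    terminated = TRUE,
                                    message = gate$message))
  }
  # fold cumulative applied corrections into the reported offsets
  rep_off <- offsets
  for (e in names(applied)) {
    for (nuc in c("C", "N")) {
      if (applied[[e]][nuc] == 0) next
      hit <- rep_off$experiment == e & rep_off$nucleus == nuc
      if (any(hit)) rep_off$offset[hit] <- rep_off$offset[hit] +
          applied[[e]][nuc]
      else rep_off <- rbind(rep_off, data.frame(
        experiment = e, nucleus = nuc, offset = applied[[e]][nuc],
        n_support = NA_integer_))
    }
  }
  convergence <- list(rounds = round, bp_converged = bp$converged,
                      bp_iterations = bp$iterations,
                      bp_final_delta = bp$final_delta,
                      quality = matrix$quality,
                      quality_trace = opt$trace,
                      tolerances = matrix$tolerances)
  make_assignment_result(matrix, mapres$position, mapres$prob, bp$beliefs,
                         bp$domains, sequence, rep_off, convergence)
}
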