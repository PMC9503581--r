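# Side-chain carbon assignment given a backbone assignment.
#
# For each confidently assigned residue, candidate carbon values are pooled
# from the unclassified-carbon slots of its own spin system, the
# preceding-residue slots of its successor's system, and 2D carbon-carbon
# peaks anchored at an already-assigned carbon of the residue. Candidates
# are matched one-to-one to the residue type's unassigned side-chain atoms
# by maximizing the summed log Gaussian density; ties between swapped
# degenerate pairs are broken by pairing ascending ppm with ascending atom
# name.

# Exhaustive best one-to-one matching of values to atoms (small sizes);
# returns list(atom = , value = , logd = ) rows.
.best_matching <- function(values, atoms, type, stats, min_density) {
  nv <- length(values); na <- length(atoms)
  if (!nv || !na) return(NULL)
  dens <- outer(seq_len(nv), seq_len(na), function(iv, ia)
    stats_density(stats, type, atoms[ia], values[iv]))
  dens[dens < min_density] <- NA_real_
  # each value is either matched (log density) or left to the noise
  # background (log min_density); matching is then worthwhile exactly when
  # the density beats the background
  bg <- log(min_density)
  best <- NULL; best_ll <- -Inf
  # branch over value-to-atom injections, values in ascending ppm order so
  # the declared tie-break (ascending ppm -> ascending atom name) falls out
  # of the first-found maximum
  ord_v <- order(values)
  ord_a <- order(atoms)
  max_gain <- log(2)   # generous per-value bound above the background
  rec <- function(vi, used, pairs, ll) {
    if (ll + (nv - vi + 1) * (max_gain - bg + 1) < best_ll - abs(bg) * nv)
      return()
    if (vi > nv) {
      if (length(pairs) && ll > best_ll + 1e-12) {
        best <<- pairs; best_ll <<- ll
      }
      return()
    }
    v <- ord_v[vi]
    # option: leave this value to the background
    rec(vi + 1L, used, pairs, ll + bg)
    for (a in ord_a) {
      if (used[a]) next
      d <- dens[v, a]
      if (is.na(d)) next
      used[a] <- TRUE
      rec(vi + 1L, used, c(pairs, list(c(v, a))), ll + log(d))
      used[a] <- FALSE
    }
  }
  if (nv <= 9L) {
    rec(1L, rep(FALSE, na), list(), 0)
  } else {
    # greedy fallback for unusually large pools
    used_a <- rep(FALSE, na); pairs <- list()
    for (v in ord_v) {
      cand <- which(!used_a & !is.na(dens[v, ]))
      if (!length(cand)) next
      a <- cand[which.max(dens[v, cand])]
      used_a[a] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(v, a)
    }
    best <- pairs
  }
  if (is.null(best) || !length(best)) return(NULL)
  do.call(rbind, lapply(best, function(pr) data.frame(
    atom = atoms[pr[2]], value = values[pr[1]],
    dens = stats_density(stats, type, atoms[pr[2]], values[pr[1]]))))
}

#' Assign side-chain carbons onto a backbone assignment result
#'
#' Residues whose backbone probability is below the cutoff are left
#' backbone-only. Each matched atom's probability is the backbone
#' probability times its normalized match posterior (the matched density
#' divided by the summed density of all candidate values for that atom).
#'
#' @param result an `assignment_result` from [iterate_assignment()].
#' @param peaklists the peak lists (used for anchored 2D-CC candidates).
#' @param stats a `shift_statistics`.
#' @param config configuration list (`sidechain_cutoff`, tolerance is the
#'   matrix's carbon tolerance).
#' @return the augmented `assignment_result`.
#' @export
assign_sidechains <- function(result, peaklists = list(),
                              stats = load_statistics(),
                              config = ssa_config()) {
  stopifnot(inherits(result, "assignment_result"))
  if (isTRUE(result$terminated)) return(result)
  matrix <- result$matrix
  tol_c <- matrix$tolerances[["C"]]
  res <- result$sequence
  assign <- result$assign; prob <- result$system_prob
  pos2sys <- stats::setNames(seq_along(assign), assign)
  cc <- NULL
  for (pl in peaklists) {
    if (get_profile(pl$experiment)$name == "CC") {
      m <- .corrected_coords(pl)
      if (nrow(m)) cc <- rbind(cc, m)
    }
  }
  sh <- result$shifts
  extra <- list()
  for (i in seq_along(assign)) {
    p <- assign[i]
    if (p == 0L || prob[i] < config$sidechain_cutoff) next
    type <- res[p]
    sys <- matrix$systems[[i]]
    assigned_atoms <- sh$atom[sh$seq_id == p]
    assigned_vals <- sh$value[sh$seq_id == p]
    # candidate pool: own unclassified carbons, successor's
    # preceding-residue pool, anchored CC partners
    cand <- sys$own_cx
    succ <- pos2sys[as.character(p + 1L)]
    if (!is.na(succ)) cand <- c(cand, matrix$systems[[succ]]$prev_cx)
    if (!is.null(cc) && length(assigned_vals)) {
      for (r in seq_len(nrow(cc))) {
        a1 <- min(abs(cc[r, 1] - assigned_vals))
        a2 <- min(abs(cc[r, 2] - assigned_vals))
        if (a1 <= tol_c) cand <- c(cand, cc[r, 2])
        if (a2 <= tol_c) cand <- c(cand, cc[r, 1])
      }
    }
    if (!length(cand)) next
    # de-duplicate within tolerance and drop values explained by atoms
    # already assigned
    cand <- sort(cand)
    merged <- cand[1]
    for (v in cand[-1]) {
      if (v - merged[length(merged)] > tol_c) merged <- c(merged, v)
      else merged[length(merged)] <- (merged[length(merged)] + v) / 2
    }
    if (length(assigned_vals))
      merged <- merged[vapply(merged, function(v)
        min(abs(v - assigned_vals)) > tol_c, TRUE)]
    if (!length(merged)) next
    open_atoms <- setdiff(SIDECHAIN_CARBONS[[type]], assigned_atoms)
    mm <- .best_matching(merged, open_atoms, type, stats,
                         min_density = config$cx_floor)
    if (is.null(mm)) next
    for (r in seq_len(nrow(mm))) {
      denom <- sum(stats_density(stats, type, mm$atom[r], merged))
      posterior <- if (denom > 0) mm$dens[r] / denom else 0
      extra[[length(extra) + 1L]] <- data.frame(
        seq_id = p, res_type = type, atom = mm$atom[r],
        value = mm$value[r], prob = prob[i] * posterior)
    }
  }
  if (length(extra)) {
    add <- do.call(rbind, extra)
    keep <- !(paste0(add$seq_id, ".", add$atom) %in%
                paste0(sh$seq_id, ".", sh$atom))
    add <- add[keep, , drop = FALSE]
    if (nrow(add)) {
      combined <- rbind(as.data.frame(sh), add)
      result$shifts <- shift_table(combined$seq_id, combined$res_type,
                                   combined$atom, combined$value,
                                   combined$prob)
    }
  }
  result
}
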