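# Spin-system matrix assembly.
#
# A spin system is anchored by a root triple (CO of the preceding residue,
# amide N, CA). Roots are read directly from experiments that carry all
# three roles and are additionally joined from (N, CA) and (N, CO-1) pairs
# across experiments. Every other peak list then contributes its remaining
# axes into the system's own-residue / preceding-residue shift slots by
# matching the root coordinates within the active tolerance.

CO_RANGE <- c(165, 190)   # ppm window considered carbonyl-like

.in_co_range <- function(v) v > CO_RANGE[1] & v <= CO_RANGE[2]

# Maximum Gaussian density over all residue types possessing `atom`;
# used to arbitrate CA-vs-CB identity on union axes.
.atom_plausibility <- function(stats, atom, v) {
  keys <- stats$table$atom == atom
  if (!any(keys)) return(0)
  max(stats::dnorm(v, stats$table$mean[keys], stats$table$sd[keys]))
}

# Effective (referencing-corrected) coordinates of one peak list.
.corrected_coords <- function(pl) {
  d <- pl$dimensionality
  m <- as.matrix(pl$peaks[, paste0("w", seq_len(d)), drop = FALSE])
  if (nrow(m)) sweep(m, 2L, pl$axis_offsets, `-`) else m
}

# Axis classification for one profile relative to the root anchors.
.axis_kinds <- function(prof) {
  vapply(prof$axes, function(ax) {
    if (length(ax$roles) == 1L) {
      r <- ax$roles
      if (r == "N" && ax$offset == 0L) return("anchor_N")
      if (r == "CA" && ax$offset == 0L) return("anchor_CA")
      if (r == "CO" && ax$offset == -1L) return("anchor_CO")
    }
    "free"
  }, "")
}

# Greedy single-linkage clustering of root triples; clusters whose members
# all sit within tolerance collapse to their support-weighted centroid.
.merge_roots <- function(df, tol_c, tol_n) {
  if (!nrow(df)) return(df)
  df <- df[order(df$n), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # rows are n-sorted: only a sliding window of neighbours can merge
  for (i in seq_len(max(n - 1L, 0L))) {
    j <- i + 1L
    while (j <= n && df$n[j] - df$n[i] <= tol_n) {
      same_partial <- is.na(df$co_prev[i]) == is.na(df$co_prev[j])
      co_ok <- (is.na(df$co_prev[i]) && is.na(df$co_prev[j])) ||
        (!is.na(df$co_prev[i]) && !is.na(df$co_prev[j]) &&
           abs(df$co_prev[i] - df$co_prev[j]) <= tol_c)
      if (same_partial && co_ok &&
          abs(df$ca[i] - df$ca[j]) <= tol_c) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(idx) {
    w <- df$weight[idx]
    data.frame(
      co_prev = if (all(is.na(df$co_prev[idx]))) NA_real_
                else stats::weighted.mean(df$co_prev[idx], w, na.rm = TRUE),
      n = stats::weighted.mean(df$n[idx], w),
      ca = stats::weighted.mean(df$ca[idx], w),
      weight = sum(w),
      direct = if ("direct" %in% names(df)) any(df$direct[idx]) else TRUE)
  }))
  rownames(out) <- NULL
  out[order(out$n, out$ca), , drop = FALSE]
}


# Cluster two-column evidence (n, second coordinate) within tolerance and
# return the cluster centroids; near-duplicate observations of the same
# correlation collapse to one row.
.cluster_pairs <- function(df, tol1, tol2) {
  names(df)[1] <- "n"
  df <- df[order(df$n, df[[2L]]), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  if (n < 2L) return(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && df$n[j] - df$n[i] <= tol1) {
      if (abs(df[[2L]][j] - df[[2L]][i]) <= tol2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(idx)
    data.frame(n = mean(df$n[idx]), v = mean(df[[2L]][idx]))))
  names(out)[2] <- names(df)[2]
  rownames(out) <- NULL
  out
}

#' Find root triples (CO of preceding residue, N, CA)
#'
#' Roots come (a) directly from experiments whose axes carry CA(i), N(i),
#' and CO(i-1) — for union axes the carbonyl coordinate must fall in the
#' 165–190 ppm window — and (b) from joining (N, CO-1) evidence to (N, CA)
#' evidence on the shared nitrogen within tolerance. Joins are suppressed
#' when the (N, CA) pair already sits under a direct root, which prevents
#' chimeric triples when nitrogens collide. Near-duplicate triples merge to
#' their support-weighted centroid.
#'
#' @param peaklists list of `peak_list` objects.
#' @param tol named numeric `c(C = ..., N = ...)` tolerances in ppm.
#' @return data.frame with columns `co_prev`, `n`, `ca`, `weight`.
#' @export
find_roots <- function(peaklists, tol) {
  tol_c <- tol[["C"]]; tol_n <- tol[["N"]]
  direct <- list(); nca_ev <- list(); nco_ev <- list()
  for (pl in peaklists) {
    prof <- get_profile(pl$experiment)
    if (prof$name == "CC") next
    kinds <- .axis_kinds(prof)
    coords <- .corrected_coords(pl)
    if (!nrow(coords)) next
    iN <- which(kinds == "anchor_N"); iCA <- which(kinds == "anchor_CA")
    iCO <- which(kinds == "anchor_CO")
    # union axis that may carry the preceding carbonyl
    iUco <- which(vapply(prof$axes, function(ax)
      ax$offset == -1L && "CO" %in% ax$roles && length(ax$roles) > 1L, TRUE))
    if (length(iN) && length(iCA) && length(iCO)) {
      direct[[length(direct) + 1L]] <- data.frame(
        co_prev = coords[, iCO], n = coords[, iN], ca = coords[, iCA],
        weight = 1, direct = TRUE)
    } else if (length(iN) && length(iCA) && length(iUco)) {
      sel <- .in_co_range(coords[, iUco[1]])
      if (any(sel))
        direct[[length(direct) + 1L]] <- data.frame(
          co_prev = coords[sel, iUco[1]], n = coords[sel, iN],
          ca = coords[sel, iCA], weight = 1, direct = TRUE)
    }
    if (length(iN) && length(iCA) && !length(iCO) && !length(iUco)) {
      nca_ev[[length(nca_ev) + 1L]] <- data.frame(n = coords[, iN],
                                                  ca = coords[, iCA])
    }
    if (length(iN) && length(iCO)) {
      nco_ev[[length(nco_ev) + 1L]] <- data.frame(n = coords[, iN],
                                                  co = coords[, iCO])
    }
  }
  direct <- if (length(direct)) do.call(rbind, direct) else
    data.frame(co_prev = numeric(0), n = numeric(0), ca = numeric(0),
               weight = numeric(0), direct = logical(0))
  joins <- list()
  if (length(nca_ev) && length(nco_ev)) {
    nca <- .cluster_pairs(do.call(rbind, nca_ev), tol_n, tol_c)
    nco <- .cluster_pairs(do.call(rbind, nco_ev), tol_n, tol_c)
    # joins only fill gaps: (N, CA) anchors already under a direct root
    # are skipped (tight window — ghost joins would otherwise bridge and
    # contaminate distinct residues' root clusters)
    if (nrow(direct)) {
      covered <- vapply(seq_len(nrow(nca)), function(a)
        any(abs(direct$n - nca$n[a]) <= min(tol_n, 0.3) &
            abs(direct$ca - nca[[2L]][a]) <= min(tol_c, 0.2)), TRUE)
      nca <- nca[!covered, , drop = FALSE]
    }
    ord <- order(nco$n)
    nco <- nco[ord, , drop = FALSE]
    for (a in seq_len(nrow(nca))) {
      lo <- findInterval(nca$n[a] - tol_n, nco$n) + 1L
      hi <- findInterval(nca$n[a] + tol_n, nco$n)
      if (hi < lo) next
      for (b in lo:hi) {
        joins[[length(joins) + 1L]] <- data.frame(
          co_prev = nco[[2L]][b], n = (nca$n[a] + nco$n[b]) / 2,
          ca = nca[[2L]][a], weight = 1, direct = FALSE)
      }
    }
  }
  all <- rbind(direct, if (length(joins)) do.call(rbind, joins))
  if (is.null(all) || !nrow(all)) {
    message("no root triples found in the supplied peak lists")
    return(data.frame(co_prev = numeric(0), n = numeric(0), ca = numeric(0),
                      weight = numeric(0), direct = logical(0)))
  }
  merged <- .merge_roots(all, tol_c, tol_n)
  .resolve_root_ambiguity(merged, tol_c, tol_n)
}

# Roots sharing an (N, CA) anchor but disagreeing on the preceding
# carbonyl are ambiguous: side-chain carbonyls on CX/CO union axes and
# nitrogen-collision joins both produce such ghosts. Keep, per (N, CA)
# cluster, only the co_prev alternative with the largest support weight;
# ties go to the value closest to the canonical backbone-carbonyl region.
.resolve_root_ambiguity <- function(df, tol_c, tol_n) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$n), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # ghost alternatives re-use the same (N, CA) evidence, so they sit at
  # (nearly) identical coordinates; the grouping window therefore stays
  # tight even when the matching tolerance is opened up, lest genuinely
  # distinct residues with nearby anchors annihilate each other
  win_n <- min(tol_n, 0.3); win_c <- min(tol_c, 0.2)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && df$n[j] - df$n[i] <= win_n) {
      if (abs(df$ca[i] - df$ca[j]) <= win_c) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  keep <- unlist(lapply(split(seq_len(n), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    if ("direct" %in% names(df) && any(df$direct[idx]))
      idx <- idx[df$direct[idx]]
    w <- df$weight[idx]
    top <- idx[w == max(w)]
    if (length(top) > 1L)
      top <- top[which.min(abs(df$co_prev[top] - 176.4))]
    top[1]
  }))
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# (N, CA) evidence with no root within tolerance becomes a partial,
# own-only spin system so that the first residue (which has no preceding
# carbonyl and can never seed a root) remains assignable.
.partial_roots <- function(peaklists, roots, tol) {
  tol_c <- tol[["C"]]; tol_n <- tol[["N"]]
  ev <- list()
  for (pl in peaklists) {
    prof <- get_profile(pl$experiment)
    kinds <- .axis_kinds(prof)
    iN <- which(kinds == "anchor_N"); iCA <- which(kinds == "anchor_CA")
    if (!length(iN) || !length(iCA)) next
    coords <- .corrected_coords(pl)
    if (!nrow(coords)) next
    ev[[length(ev) + 1L]] <- data.frame(n = coords[, iN], ca = coords[, iCA])
  }
  if (!length(ev)) return(NULL)
  ev <- .cluster_pairs(do.call(rbind, ev), tol_n, tol_c)
  names(ev)[2] <- "ca"
  blocking <- roots[if ("direct" %in% names(roots)) roots$direct else
                      rep(TRUE, nrow(roots)), , drop = FALSE]
  free <- vapply(seq_len(nrow(ev)), function(k) {
    !nrow(blocking) || !any(abs(blocking$n - ev$n[k]) <= tol_n &
                            abs(blocking$ca - ev$ca[k]) <= tol_c)
  }, TRUE)
  if (!any(free)) return(NULL)
  df <- data.frame(co_prev = NA_real_, n = ev$n[free], ca = ev$ca[free],
                   weight = 1, direct = FALSE)
  .merge_roots(df, tol_c, tol_n)
}

.new_system <- function(id, co_prev, n, ca) {
  prev <- if (is.na(co_prev)) stats::setNames(numeric(0), character(0))
          else c(C = co_prev)
  list(id = id, root = c(CO_prev = co_prev, N = n, CA = ca),
       own = c(N = n, CA = ca), own_cx = numeric(0),
       prev = prev, prev_cx = numeric(0),
       weights = list(own = c(N = 1, CA = 1),
                      prev = if (is.na(co_prev)) numeric(0) else c(C = 1)),
       spec = list(own = c(N = 3, CA = 3),
                   prev = if (is.na(co_prev)) numeric(0) else c(C = 3)),
       contested = list(own = character(0), prev = character(0)),
       support = list(), n_conflicts = 0L)
}

# Merge a value into a named slot of a system map ("own"/"prev"), tracking
# the anchor specificity (number of root coordinates the contributing
# strip was matched on). Values agreeing within tolerance are averaged; on
# conflict a better-anchored value wins, a worse-anchored one is ignored,
# and equal specificity is arbitrated by reference-statistics
# plausibility. Root-backed slots (own N, own CA, preceding CO — anchor
# specificity 3) are never overwritten.
.merge_named <- function(sys, side, atom, v, tol_c, stats, spec = 1) {
  if (atom %in% sys$contested[[side]]) {
    fld <- paste0(side, "_cx")
    sys[[fld]] <- c(sys[[fld]], v)
    return(sys)
  }
  cur <- sys[[side]][atom]
  if (is.na(cur)) {
    sys[[side]][atom] <- v
    sys$weights[[side]][atom] <- 1
    sys$spec[[side]][atom] <- spec
  } else if (abs(cur - v) <= tol_c) {
    w <- sys$weights[[side]][atom]
    sys[[side]][atom] <- (cur * w + v) / (w + 1)
    sys$weights[[side]][atom] <- w + 1
    sys$spec[[side]][atom] <- max(sys$spec[[side]][atom], spec)
  } else {
    sys$n_conflicts <- sys$n_conflicts + 1L
    cur_spec <- sys$spec[[side]][atom]
    if (spec > cur_spec) {
      sys[[side]][atom] <- v
      sys$weights[[side]][atom] <- 1
      sys$spec[[side]][atom] <- spec
    } else if (spec == cur_spec) {
      root_backed <- (side == "own" && atom %in% c("N", "CA")) ||
                     (side == "prev" && atom == "C")
      if (!root_backed) {
        # equal evidence for two inconsistent values: the atom identity is
        # genuinely ambiguous, so demote both to the unclassified pool and
        # close the slot against further naming
        fld <- paste0(side, "_cx")
        sys[[fld]] <- c(sys[[fld]], unname(cur), v)
        sys[[side]] <- sys[[side]][names(sys[[side]]) != atom]
        sys$contested[[side]] <- union(sys$contested[[side]], atom)
      }
    }
  }
  sys
}

# Route one free-axis value into a system given the axis role set/offset.
.classify_value <- function(sys, v, roles, offset, tol_c, stats, spec = 1) {
  side <- if (offset == 0L) "own" else "prev"
  named <- sys[[side]]
  if ("CO" %in% roles) {
    cur <- named["C"]
    if (!is.na(cur) && abs(v - cur) <= tol_c)
      return(.merge_named(sys, side, "C", v, tol_c, stats, spec))
    if (length(roles) == 1L)
      return(.merge_named(sys, side, "C", v, tol_c, stats, spec))
    # union axis: carbonyl-range values not matching the known CO are
    # side-chain carbonyls -> unclassified carbon pool
    if (.in_co_range(v) && "CX" %in% roles) {
      sys[[paste0(side, "_cx")]] <- c(sys[[paste0(side, "_cx")]], v)
      return(sys)
    }
    if (.in_co_range(v) && !("CX" %in% roles))
      return(.merge_named(sys, side, "C", v, tol_c, stats, spec))
    roles <- setdiff(roles, "CO")
  }
  if ("CX" %in% roles) {
    # absorb into a named slot when the value duplicates one
    for (a in intersect(names(named), c("CA", "CB"))) {
      if (!is.na(named[a]) && abs(v - named[a]) <= tol_c)
        return(.merge_named(sys, side, a, v, tol_c, stats, spec))
    }
    sys[[paste0(side, "_cx")]] <- c(sys[[paste0(side, "_cx")]], v)
    return(sys)
  }
  if (all(roles %in% c("CA", "CB"))) {
    for (a in intersect(roles, names(named))) {
      if (!is.na(named[a]) && abs(v - named[a]) <= tol_c)
        return(.merge_named(sys, side, a, v, tol_c, stats, spec))
    }
    if (length(roles) == 1L)
      return(.merge_named(sys, side, roles, v, tol_c, stats, spec))
    # when one of CA/CB is already filled (and mismatched), the value
    # belongs to the open slot; only with both open (or both filled) does
    # reference-statistics plausibility arbitrate
    open <- roles[vapply(roles, function(a) is.na(named[a]), TRUE)]
    if (length(open) == 1L)
      return(.merge_named(sys, side, open, v, tol_c, stats, spec))
    a <- if (.atom_plausibility(stats, "CA", v) >=
             .atom_plausibility(stats, "CB", v)) "CA" else "CB"
    return(.merge_named(sys, side, a, v, tol_c, stats, spec))
  }
  sys
}

#' Attach strip correlations from all peak lists to root triples
#'
#' For each root, peaks whose anchor coordinates (N, CA, preceding CO —
#' whichever the experiment's profile carries) all match within tolerance
#' contribute their remaining-axis shifts into the system's own/preceding
#' residue maps. Conflicting values within tolerance are averaged; outside
#' tolerance the value closer to the reference statistics wins and the
#' conflict is counted.
#'
#' @param roots data.frame from [find_roots()] (a `co_prev` of `NA` marks a
#'   partial, own-only system).
#' @param peaklists list of `peak_list` objects.
#' @param tol named tolerances `c(C = , N = )`.
#' @param stats a `shift_statistics`.
#' @return a `spin_system_matrix`.
#' @export
attach_correlations <- function(roots, peaklists, tol,
                                stats = load_statistics()) {
  tol_c <- tol[["C"]]; tol_n <- tol[["N"]]
  systems <- lapply(seq_len(nrow(roots)), function(i)
    .new_system(i, roots$co_prev[i], roots$n[i], roots$ca[i]))
  # better-anchored experiments first: their strip matches are more
  # specific, so they fill named slots before single-anchor 2D strips can
  n_anchor <- vapply(peaklists, function(pl)
    sum(.axis_kinds(get_profile(pl$experiment)) != "free"), 0L)
  peaklists <- peaklists[order(n_anchor, decreasing = TRUE)]
  for (pl in peaklists) {
    prof <- get_profile(pl$experiment)
    if (prof$name == "CC") next     # CX/CX ambiguity: side-chain stage only
    kinds <- .axis_kinds(prof)
    coords <- .corrected_coords(pl)
    if (!nrow(coords)) next
    anchor_idx <- which(kinds != "free")
    free_idx <- which(kinds == "free")
    if (!length(anchor_idx)) next
    if (prof$dimensionality == 3L && length(anchor_idx) < 2L) next
    # anchor targets per system; a peak attaches only to the single
    # best-matching root (competitive strip extraction) so anchor-space
    # collisions do not contaminate every nearby system
    ns <- length(systems)
    dist2 <- matrix(0, nrow = nrow(coords), ncol = ns)
    okm <- matrix(TRUE, nrow = nrow(coords), ncol = ns)
    for (ai in anchor_idx) {
      atol <- if (kinds[ai] == "anchor_N") tol_n else tol_c
      targets <- vapply(systems, function(sys)
        switch(kinds[ai],
               anchor_N = sys$root[["N"]],
               anchor_CA = sys$root[["CA"]],
               anchor_CO = sys$root[["CO_prev"]]), 0)
      dd <- abs(outer(coords[, ai], targets, `-`)) / atol
      okm <- okm & !is.na(dd) & dd <= 1
      dd[is.na(dd)] <- Inf
      dist2 <- dist2 + dd^2
    }
    dist2[!okm] <- Inf
    ambiguous_1a <- length(anchor_idx) == 1L & rowSums(okm) > 1L
    for (h in seq_len(nrow(coords))) {
      if (!any(okm[h, ])) next
      # single-anchor strips carry no second coordinate to disambiguate:
      # attach them only when exactly one system matches
      if (ambiguous_1a[h]) next
      si <- which.min(dist2[h, ])
      sys <- systems[[si]]
      for (fi in free_idx) {
        ax <- prof$axes[[fi]]
        sys <- .classify_value(sys, coords[h, fi], ax$roles, ax$offset,
                               tol_c, stats, spec = length(anchor_idx))
      }
      # anchors themselves are support for the root slots
      slots <- vapply(seq_len(prof$dimensionality), function(k)
        switch(kinds[k], anchor_N = "own.N", anchor_CA = "own.CA",
               anchor_CO = "prev.C", "free"), "")
      sys$support[[length(sys$support) + 1L]] <-
        list(experiment = prof$name, peak = h, slots = slots,
             values = coords[h, ])
      systems[[si]] <- sys
    }
  }
  # consolidate unclassified-carbon pools: cluster within tolerance, then
  # drop values explained by a named slot (duplicate observations of the
  # same atom arrive from several experiments, in arbitrary order)
  for (si in seq_along(systems)) {
    sys <- systems[[si]]
    for (side in c("own", "prev")) {
      fld <- paste0(side, "_cx")
      vals <- sort(sys[[fld]])
      if (!length(vals)) next
      merged <- vals[1]; cnt <- 1
      for (v in vals[-1]) {
        k <- length(merged)
        if (v - merged[k] <= tol_c) {
          merged[k] <- (merged[k] * cnt[k] + v) / (cnt[k] + 1)
          cnt[k] <- cnt[k] + 1
        } else { merged <- c(merged, v); cnt <- c(cnt, 1) }
      }
      named <- sys[[side]]
      named <- named[!is.na(named)]
      if (length(named))
        merged <- merged[vapply(merged, function(v)
          min(abs(v - named)) > tol_c, TRUE)]
      sys[[fld]] <- merged
    }
    systems[[si]] <- sys
  }
  # resolve free-axis support slots now that classification is done
  for (si in seq_along(systems)) {
    sys <- systems[[si]]
    if (length(sys$support)) {
      d_each <- vapply(sys$support, function(s) length(s$slots), 0L)
      sup <- data.frame(
        experiment = rep(vapply(sys$support, `[[`, "", "experiment"), d_each),
        peak = rep(vapply(sys$support, `[[`, 0L, "peak"), d_each),
        axis = unlist(lapply(d_each, seq_len)),
        slot = unlist(lapply(sys$support, `[[`, "slots")),
        value = unlist(lapply(sys$support, `[[`, "values")))
      free_rows <- sup$slot == "free"
      if (any(free_rows)) {
        sup$slot[free_rows] <- vapply(which(free_rows), function(r) {
          v <- sup$value[r]
          for (side in c("own", "prev")) {
            nm <- sys[[side]]
            j <- which(!is.na(nm) & abs(nm - v) <= tol_c)
            if (length(j)) return(paste0(side, ".", names(nm)[j[1]]))
          }
          if (length(sys$own_cx) && any(abs(sys$own_cx - v) <= tol_c))
            return("own.cx")
          if (length(sys$prev_cx) && any(abs(sys$prev_cx - v) <= tol_c))
            return("prev.cx")
          "unmatched"
        }, "")
      }
      sys$support <- sup
    } else {
      sys$support <- data.frame(experiment = character(0), peak = integer(0),
                                axis = integer(0), slot = character(0),
                                value = numeric(0))
    }
    systems[[si]] <- sys
  }
  structure(list(systems = systems, tolerances = c(C = tol_c, N = tol_n),
                 quality = NA_real_, n_pruned = 0L),
            class = "spin_system_matrix")
}

#' @export
print.spin_system_matrix <- function(x, ...) {
  full <- sum(vapply(x$systems, function(s) !is.na(s$root[["CO_prev"]]), TRUE))
  cat("spin system matrix: ", length(x$systems), " systems (", full,
      " with a root triple), tolerances C=", x$tolerances[["C"]], " N=",
      x$tolerances[["N"]], " ppm\n", sep = "")
  invisible(x)
}

#' Dump a spin-system matrix as a tab-separated table
#'
#' One row per spin system; columns follow the matrix layout: preceding
#' residue CA/CB/CO, root N, own CA/CB/CO, then unclassified carbons.
#'
#' @param matrix a `spin_system_matrix`.
#' @param path optional output path; with `NULL` the data.frame is returned.
#' @export
dump_matrix <- function(matrix, path = NULL) {
  g <- function(s, side, a) {
    v <- s[[side]][a]
    if (is.na(v)) NA_real_ else unname(v)
  }
  df <- do.call(rbind, lapply(matrix$systems, function(s) data.frame(
    id = s$id,
    CA_prev = g(s, "prev", "CA"), CB_prev = g(s, "prev", "CB"),
    CO_prev = g(s, "prev", "C"), N = unname(s$own["N"]),
    CA = unname(s$own["CA"]), CB = g(s, "own", "CB"), CO = g(s, "own", "C"),
    CX_own = paste(sprintf("%.3f", sort(s$own_cx)), collapse = ","),
    CX_prev = paste(sprintf("%.3f", sort(s$prev_cx)), collapse = ","))))
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the spin-system matrix at one tolerance setting
#'
#' Convenience wrapper: [find_roots()], partial own-only systems for
#' unrooted (N, CA) evidence, then [attach_correlations()].
#'
#' @inheritParams attach_correlations
#' @export
assemble_matrix <- function(peaklists, tol, stats = load_statistics()) {
  roots <- find_roots(peaklists, tol)
  part <- .partial_roots(peaklists, roots, tol)
  all_roots <- if (is.null(part)) roots else {
    rbind(roots, part)
  }
  all_roots <- all_roots[order(all_roots$n, all_roots$ca), , drop = FALSE]
  m <- attach_correlations(all_roots, peaklists, tol, stats)
  # drop systems whose strips come from fewer than two distinct
  # experiments: false-positive roots match (essentially) only the peak
  # that created them, while genuine residues collect strips from most of
  # the experiment set
  n_exp <- vapply(m$systems, function(s)
    length(unique(s$support$experiment)), 0L)
  keep <- n_exp >= 2L
  m$systems <- m$systems[keep]
  for (si in seq_along(m$systems)) m$systems[[si]]$id <- si
  m$n_pruned <- sum(!keep)
  m
}

#' Data-quality score of an assembled matrix
#'
#' `q = sqrt(q_sys * q_link)` where `q_sys` is the fraction of expected
#' spin systems found (expected = residues with a preceding residue) and
#' `q_link` the fraction of expected sequential links found, both capped
#' at 1.
#'
#' @param matrix a `spin_system_matrix`.
#' @param sequence a `protein_sequence` or character vector.
#' @param links optional precomputed result of [link_spin_systems()].
#' @param stats,config passed through when `links` must be computed.
#' @return quality in `[0, 1]`.
#' @export
assess_quality <- function(matrix, sequence, links = NULL,
                           stats = load_statistics(), config = ssa_config()) {
  res <- sequence_residues(sequence)
  if (!length(res)) stop("empty sequence")
  expected <- max(length(res) - 1L, 1L)
  full <- sum(vapply(matrix$systems, function(s)
    !is.na(s$root[["CO_prev"]]), TRUE))
  if (full == 0L) return(0)
  # symmetric ratio: both missing systems and ghost inflation (duplicate or
  # false roots) reduce the score
  q_sys <- min(full, expected) / max(full, expected)
  if (is.null(links)) links <- link_spin_systems(matrix, matrix$tolerances,
                                                 config = config)
  n_link <- if (is.null(links) || !nrow(links)) 0L
            else length(unique(links$from_id))
  q_link <- min(1, n_link / max(full, expected))
  sqrt(q_sys * q_link)
}

#' Tolerance-grid search for the best spin-system matrix
#'
#' Assembles and scores the matrix over the Cartesian product of the carbon
#' and nitrogen tolerance grids; returns the highest-quality matrix, ties
#' broken toward the smallest tolerances.
#'
#' @param peaklists list of `peak_list` objects.
#' @param sequence protein sequence.
#' @param stats a `shift_statistics`.
#' @param config configuration from [ssa_config()].
#' @return list with `matrix`, `tol`, and `trace` (data.frame of
#'   tolerance pairs and qualities).
#' @export
optimize_tolerances <- function(peaklists, sequence,
                                stats = load_statistics(),
                                config = ssa_config()) {
  grid <- expand.grid(C = sort(config$tol_c_grid),
                      N = sort(config$tol_n_grid))
  grid <- grid[order(grid$C + grid$N, grid$C), ]
  best <- NULL; best_q <- -1; best_tol <- NULL
  trace <- data.frame(tol_c = numeric(0), tol_n = numeric(0),
                      quality = numeric(0))
  for (g in seq_len(nrow(grid))) {
    tol <- c(C = grid$C[g], N = grid$N[g])
    m <- assemble_matrix(peaklists, tol, stats)
    q <- if (length(m$systems)) assess_quality(m, sequence, stats = stats,
                                               config = config) else 0
    m$quality <- q
    trace <- rbind(trace, data.frame(tol_c = tol[["C"]], tol_n = tol[["N"]],
                                     quality = q))
    if (q > best_q + 1e-12) { best <- m; best_q <- q; best_tol <- tol }
  }
  list(matrix = best, tol = best_tol, trace = trace)
}

#' Quality gate
#'
#' @param quality score in `[0, 1]`.
#' @param threshold closed lower bound (default from configuration, 0.3).
#' @return list with `proceed` (logical) and `message`.
#' @export
gate_quality <- function(quality, threshold = ssa_config()$quality_threshold) {
  if (quality >= threshold)
    list(proceed = TRUE, message = "quality sufficient")
  else
    list(proceed = FALSE,
         message = paste0("data quality ", sprintf("%.3f", quality),
                          " below threshold ", threshold,
                          ": more information is required"))
}
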