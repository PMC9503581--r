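# Di-peptide linking of spin systems and pentapeptide fragment scoring.

# Carbon inventory of one side of a system: named values (CA/CB/C) plus the
# unclassified pool.
.side_carbons <- function(sys, side) {
  named <- sys[[side]]
  named <- named[names(named) %in% c("CA", "CB", "C")]
  list(named = named, cx = sys[[paste0(side, "_cx")]])
}

# Compare A's own carbons with B's preceding-residue carbons. Atoms named
# on both sides must each agree within tolerance or there is no link;
# remaining values are matched greedily one-to-one (nearest pair first)
# within tolerance. Returns NULL or a list(deltas, n_shared).
.match_sides <- function(a_side, b_side, tol_c) {
  deltas <- numeric(0)
  a_named <- a_side$named; b_named <- b_side$named
  shared <- intersect(names(a_named), names(b_named))
  for (at in shared) {
    d <- abs(a_named[[at]] - b_named[[at]])
    if (d > tol_c) return(NULL)
    deltas <- c(deltas, d)
  }
  a_rest <- c(unname(a_named[setdiff(names(a_named), shared)]), a_side$cx)
  b_rest <- c(unname(b_named[setdiff(names(b_named), shared)]), b_side$cx)
  while (length(a_rest) && length(b_rest)) {
    dm <- abs(outer(a_rest, b_rest, `-`))
    k <- arrayInd(which.min(dm), dim(dm))
    if (dm[k] > tol_c) break
    deltas <- c(deltas, dm[k])
    a_rest <- a_rest[-k[1]]; b_rest <- b_rest[-k[2]]
  }
  if (!length(deltas)) return(NULL)
  list(deltas = deltas, n_shared = length(deltas))
}

#' Link spin systems into di-peptide candidates
#'
#' For every ordered pair (A, B) the carbons of A's own residue are compared
#' with the carbons B carries for its preceding residue. A link is emitted
#' when at least one atom is shared and every atom named on both sides
#' agrees within tolerance; the score is
#' `exp(-sum(delta^2) / (2 * sigma^2))` with `sigma = tol/2`.
#'
#' @param matrix a `spin_system_matrix`.
#' @param tol named tolerances `c(C =, N =)`; defaults to the matrix's own.
#' @param config configuration list.
#' @return data.frame with `from_id`, `to_id`, `score`, `n_shared`.
#' @export
link_spin_systems <- function(matrix, tol = matrix$tolerances,
                              config = ssa_config()) {
  systems <- matrix$systems
  tol_c <- tol[["C"]]
  sigma <- tol_c / 2
  out <- list()
  sides_own <- lapply(systems, .side_carbons, side = "own")
  sides_prev <- lapply(systems, .side_carbons, side = "prev")
  has_prev <- vapply(systems, function(s)
    length(s$prev) + length(s$prev_cx) > 0, TRUE)
  for (a in seq_along(systems)) {
    for (b in seq_along(systems)) {
      if (a == b || !has_prev[b]) next
      m <- .match_sides(sides_own[[a]], sides_prev[[b]], tol_c)
      if (is.null(m)) next
      out[[length(out) + 1L]] <- data.frame(
        from_id = systems[[a]]$id, to_id = systems[[b]]$id,
        score = exp(-sum(m$deltas^2) / (2 * sigma^2)),
        n_shared = m$n_shared)
    }
  }
  if (!length(out))
    return(data.frame(from_id = integer(0), to_id = integer(0),
                      score = numeric(0), n_shared = integer(0)))
  do.call(rbind, out)
}

# Normalized unary placement scores: U[s, p] proportional to the typing
# likelihood of system s's own shifts at sequence position p times its
# preceding-residue shifts at p - 1, rescaled so each system's best
# position scores 1. Position 1 is closed to systems carrying
# preceding-residue evidence.
unary_scores <- function(matrix, sequence, stats, config = ssa_config()) {
  res <- sequence_residues(sequence)
  L <- length(res)
  systems <- matrix$systems
  n <- length(systems)
  U <- matrix(0, nrow = n, ncol = L)
  own_lik <- function(sys, type)
    type_likelihood(as.list(sys$own), type, stats, cx = sys$own_cx,
                    config = config, spec = as.list(sys$spec$own))
  prev_lik <- function(sys, type) {
    if (!length(sys$prev) && !length(sys$prev_cx)) return(1)
    type_likelihood(as.list(sys$prev), type, stats, cx = sys$prev_cx,
                    config = config, spec = as.list(sys$spec$prev))
  }
  # a system carrying preceding-residue evidence may still sit at position
  # 1 (chimeric roots from nitrogen collisions produce spurious preceding
  # carbonyls) but pays the unexplained-value penalty for every piece of
  # preceding-residue evidence, keeping the cost commensurate with a
  # partially contaminated prev pool at a genuine position
  raw_max <- numeric(n)
  n_c <- integer(n); n_n <- integer(n)
  for (i in seq_len(n)) {
    sys <- systems[[i]]
    o <- vapply(AA_ONE, function(t) own_lik(sys, t), 0)
    p <- vapply(AA_ONE, function(t) prev_lik(sys, t), 0)
    k_prev <- length(sys$prev) + length(sys$prev_cx)
    orphan_penalty <- config$cx_floor ^ k_prev
    for (pos in seq_len(L)) {
      U[i, pos] <- if (pos == 1L) {
        o[[res[pos]]] * orphan_penalty
      } else o[[res[pos]]] * p[[res[pos - 1L]]]
    }
    mx <- max(U[i, ])
    raw_max[i] <- mx
    n_n[i] <- sum(names(sys$own) == "N")
    n_c[i] <- length(sys$own) - n_n[i] + length(sys$own_cx) +
      length(sys$prev) + length(sys$prev_cx)
    if (mx > 0) U[i, ] <- U[i, ] / mx
  }
  attr(U, "raw_max") <- raw_max
  attr(U, "n_carbon") <- n_c
  attr(U, "n_nitrogen") <- n_n
  U
}

#' Pentapeptide fragment generation and candidate-domain pruning
#'
#' Chains of up to five linked spin systems are scored against every
#' equal-length sequence window by the product of their link scores and the
#' per-position unary typing scores. A system's candidate domain is every
#' position at which some surviving fragment places it (fragments below the
#' configured floor are pruned); systems not covered by any fragment fall
#' back to their singleton unary candidates.
#'
#' @param links data.frame from [link_spin_systems()].
#' @param matrix a `spin_system_matrix`.
#' @param sequence protein sequence.
#' @param stats a `shift_statistics`.
#' @param config configuration list.
#' @param unary optional precomputed matrix from `unary_scores`.
#' @return list with `domains` (list of integer position vectors per
#'   system), `unary` (the score matrix), `fragments` (data.frame of
#'   scored placements).
#' @export
generate_pentapeptides <- function(links, matrix, sequence,
                                   stats = load_statistics(),
                                   config = ssa_config(), unary = NULL) {
  systems <- matrix$systems
  n <- length(systems)
  res <- sequence_residues(sequence)
  L <- length(res)
  if (is.null(unary)) unary <- unary_scores(matrix, sequence, stats, config)
  floor_ <- config$fragment_floor
  id2idx <- stats::setNames(seq_len(n), vapply(systems, function(s) as.integer(s$id), 0L))
  succ <- split(seq_len(nrow(links)), links$from_id)
  # enumerate chains of length 2..5 by depth-first extension
  chains <- list()
  max_chains <- 50000L   # guard against combinatorial blow-up in dense data
  extend <- function(chain, link_score) {
    if (length(chains) >= max_chains) return()
    len <- length(chain)
    if (len >= 2L)
      chains[[length(chains) + 1L]] <<- list(ids = chain, w = link_score)
    if (len == 5L) return()
    nxt <- succ[[as.character(chain[len])]]
    for (r in nxt) {
      to <- links$to_id[r]
      if (to %in% chain) next
      extend(c(chain, to), link_score * links$score[r])
    }
  }
  for (s in systems) extend(s$id, 1)
  domains <- vector("list", n)
  frags <- list()
  for (ch in chains) {
    idx <- id2idx[as.character(ch$ids)]
    k <- length(idx)
    if (k > L) next
    np <- L - k + 1L
    # vectorized placement scores over all start positions
    sc <- rep(ch$w, np)
    for (m in seq_len(k))
      sc <- sc * unary[idx[m], m:(m + np - 1L)]
    hits <- which(sc >= floor_)
    if (!length(hits)) next
    for (p0 in hits) {
      for (m in seq_len(k))
        domains[[idx[m]]] <- c(domains[[idx[m]]], p0 + m - 1L)
    }
    frags[[length(frags) + 1L]] <- data.frame(
      start = hits, length = k, score = sc[hits],
      ids = paste(ch$ids, collapse = "-"))
  }
  # singleton fallback and unary-supported positions; domains are capped
  # at the best-scoring candidates to bound the factor graph
  cap <- 15L
  for (i in seq_len(n)) {
    dom <- sort(unique(domains[[i]]))
    extra <- which(unary[i, ] >= max(floor_, 1e-6))
    dom <- sort(unique(c(dom, extra)))
    if (length(dom) > cap) {
      dom <- dom[order(unary[i, dom], decreasing = TRUE)[seq_len(cap)]]
      dom <- sort(dom)
    }
    domains[[i]] <- dom
  }
  list(domains = domains, unary = unary,
       fragments = if (length(frags)) do.call(rbind, frags) else
         data.frame(start = integer(0), length = integer(0),
                    score = numeric(0), ids = character(0)))
}
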