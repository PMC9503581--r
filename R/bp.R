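# Loopy sum-product belief propagation for spin-system placement.
#
# Factor graph: one variable per spin system with domain
# {candidate positions} + {0 = unassigned}. Unary potentials are the
# normalized typing scores, with a pseudo-likelihood for the unassigned
# slot. Pairwise factors:
#   link factors    phi(p, q) = 1 + link_weight * score  when q = p + 1
#                   (both assigned), 1 otherwise — sequential placement of
#                   linked systems is favoured;
#   exclusion       phi(p, p) = exclusion_penalty for every assigned
#                   position two systems could both claim — a soft
#                   one-to-one constraint.
# Both factor types admit O(domain) message updates, which keeps loopy BP
# linear in the number of factors per sweep. On an acyclic factor graph
# the converged beliefs equal the exact marginals.

# Build the pairwise factor list: one factor per di-peptide link plus one
# exclusion factor per pair of systems with overlapping position domains.
# With `prefer` (a list of each variable's preferred positions), exclusion
# factors are instantiated only where contention is plausible: a shared
# position that is preferred by at least one of the pair. Greedy MAP
# extraction enforces hard uniqueness afterwards either way.
bp_build_factors <- function(domains, links, id2idx, prefer = NULL) {
  factors <- list()
  n <- length(domains)
  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      a <- id2idx[[as.character(links$from_id[r])]]
      b <- id2idx[[as.character(links$to_id[r])]]
      factors[[length(factors) + 1L]] <-
        list(type = "link", a = a, b = b, w = links$score[r])
    }
  }
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      da <- setdiff(domains[[a]], 0L); db <- setdiff(domains[[b]], 0L)
      shared <- intersect(da, db)
      if (!length(shared)) next
      if (!is.null(prefer) &&
          !length(intersect(shared, c(prefer[[a]], prefer[[b]])))) next
      factors[[length(factors) + 1L]] <-
        list(type = "excl", a = a, b = b, w = NA_real_)
    }
  }
  factors
}

# Pairwise potential value on explicit state pairs (shared by the solver's
# message shortcuts conceptually; used directly by tests and by exact
# enumeration).
bp_pair_potential <- function(f, xa, xb, config) {
  if (f$type == "link") {
    ifelse(xa > 0L & xb == xa + 1L, 1 + config$link_weight * f$w, 1)
  } else {
    ifelse(xa > 0L & xa == xb, config$exclusion_penalty, 1)
  }
}

#' Sum-product message passing on a placement factor graph
#'
#' Core solver shared by [run_belief_propagation()] and directly usable on
#' hand-built problems. Messages are updated flooding-style in a fixed
#' factor order with damping, until the largest message change falls below
#' `config$bp_tol_msg` or `config$bp_max_iters` sweeps have run.
#'
#' @param psis list of non-negative unary vectors, one per variable,
#'   aligned with `doms`.
#' @param doms list of integer domains per variable (0 = unassigned slot).
#' @param factors list of pairwise factors from `bp_build_factors`.
#' @param config configuration list.
#' @return list with `beliefs` (named numeric vectors), `converged`,
#'   `iterations`, `final_delta`.
#' @export
bp_sum_product <- function(psis, doms, factors, config = ssa_config()) {
  n <- length(psis)
  psis <- lapply(psis, function(p) {
    s <- sum(p)
    if (s > 0) p / s else rep(1 / length(p), length(p))
  })
  nf <- length(factors)
  msg_to_a <- vector("list", nf); msg_to_b <- vector("list", nf)
  fa <- integer(nf); fb <- integer(nf); ftype <- character(nf); fw <- numeric(nf)
  for (k in seq_len(nf)) {
    fa[k] <- factors[[k]]$a; fb[k] <- factors[[k]]$b
    ftype[k] <- factors[[k]]$type; fw[k] <- factors[[k]]$w
    msg_to_a[[k]] <- rep(1 / length(doms[[fa[k]]]), length(doms[[fa[k]]]))
    msg_to_b[[k]] <- rep(1 / length(doms[[fb[k]]]), length(doms[[fb[k]]]))
  }
  inc <- vector("list", n)
  for (k in seq_len(nf)) {
    inc[[fa[k]]] <- c(inc[[fa[k]]], k)
    inc[[fb[k]]] <- c(inc[[fb[k]]], k)
  }
  # full belief product per variable; per-factor cavity beliefs are then a
  # single division (messages are strictly positive) so each sweep costs
  # O(sum(domain sizes) + factors)
  full_beliefs <- function() {
    lapply(seq_len(n), function(i) {
      b <- psis[[i]]
      for (k in inc[[i]]) {
        m <- if (fa[k] == i) msg_to_a[[k]] else msg_to_b[[k]]
        b <- b * m
      }
      s <- sum(b)
      if (s > 0) b / s else rep(1 / length(b), length(b))
    })
  }
  excl_msg <- function(mu_from, dom_from, dom_to) {
    S <- sum(mu_from)
    out <- rep(S, length(dom_to))
    idx <- match(dom_to, dom_from)
    hit <- which(!is.na(idx) & dom_to > 0L)
    out[hit] <- out[hit] - (1 - config$exclusion_penalty) * mu_from[idx[hit]]
    out
  }
  link_msg <- function(w, mu_from, dom_from, dom_to, towards_b) {
    S <- sum(mu_from)
    out <- rep(S, length(dom_to))
    if (towards_b) {
      idx <- match(dom_to - 1L, dom_from)
      hit <- which(!is.na(idx) & dom_to > 0L & (dom_to - 1L) > 0L)
    } else {
      idx <- match(dom_to + 1L, dom_from)
      hit <- which(!is.na(idx) & dom_to > 0L)
    }
    out[hit] <- out[hit] + config$link_weight * w * mu_from[idx[hit]]
    out
  }
  damping <- config$bp_damping
  converged <- nf == 0L; iter <- 0L; delta <- 0
  while (!converged && iter < config$bp_max_iters) {
    iter <- iter + 1L
    delta <- 0
    bel <- full_beliefs()
    for (k in seq_len(nf)) {
      mu_a <- bel[[fa[k]]] / msg_to_a[[k]]
      mu_a <- mu_a / sum(mu_a)
      mu_b <- bel[[fb[k]]] / msg_to_b[[k]]
      mu_b <- mu_b / sum(mu_b)
      if (ftype[k] == "link") {
        new_b <- link_msg(fw[k], mu_a, doms[[fa[k]]], doms[[fb[k]]], TRUE)
        new_a <- link_msg(fw[k], mu_b, doms[[fb[k]]], doms[[fa[k]]], FALSE)
      } else {
        new_b <- excl_msg(mu_a, doms[[fa[k]]], doms[[fb[k]]])
        new_a <- excl_msg(mu_b, doms[[fb[k]]], doms[[fa[k]]])
      }
      new_b <- new_b / sum(new_b); new_a <- new_a / sum(new_a)
      upd_b <- damping * msg_to_b[[k]] + (1 - damping) * new_b
      upd_a <- damping * msg_to_a[[k]] + (1 - damping) * new_a
      delta <- max(delta, max(abs(upd_b - msg_to_b[[k]])),
                   max(abs(upd_a - msg_to_a[[k]])))
      msg_to_b[[k]] <- upd_b; msg_to_a[[k]] <- upd_a
    }
    if (delta < config$bp_tol_msg) converged <- TRUE
  }
  beliefs <- full_beliefs()
  for (i in seq_len(n)) names(beliefs[[i]]) <- as.character(doms[[i]])
  list(beliefs = beliefs, converged = converged, iterations = iter,
       final_delta = delta)
}

#' Loopy belief propagation over spin-system placements
#'
#' Builds the placement factor graph — unary typing potentials with an
#' unassigned pseudo-likelihood, link factors, soft exclusion factors —
#' and runs [bp_sum_product()].
#'
#' @param matrix a `spin_system_matrix`.
#' @param links data.frame from [link_spin_systems()].
#' @param sequence protein sequence.
#' @param stats a `shift_statistics`.
#' @param config configuration list (`bp_max_iters`, `bp_damping`,
#'   `bp_tol_msg`, `link_weight`, `exclusion_penalty`, `unassigned_rel`).
#' @param domains optional candidate domains (list of integer vectors per
#'   system, positions only; 0 is added internally). Defaults to the
#'   pentapeptide-pruned domains.
#' @param unary optional unary score matrix from `unary_scores`.
#' @return list with `beliefs` (named numeric vectors over each system's
#'   domain, "0" = unassigned), `converged`, `iterations`, `final_delta`,
#'   `domains`.
#' @export
run_belief_propagation <- function(matrix, links, sequence,
                                   stats = load_statistics(),
                                   config = ssa_config(),
                                   domains = NULL, unary = NULL) {
  systems <- matrix$systems
  n <- length(systems)
  if (!n)
    return(list(beliefs = list(), converged = TRUE, iterations = 0L,
                final_delta = 0, domains = list()))
  if (is.null(unary)) unary <- unary_scores(matrix, sequence, stats, config)
  if (is.null(domains)) {
    pp <- generate_pentapeptides(links, matrix, sequence, stats, config,
                                 unary = unary)
    domains <- pp$domains
  }
  id2idx <- stats::setNames(as.list(seq_len(n)),
                            vapply(systems, function(s) as.integer(s$id), 0L))
  psis <- vector("list", n)
  doms <- vector("list", n)
  raw_max <- attr(unary, "raw_max")
  n_c <- attr(unary, "n_carbon"); n_n <- attr(unary, "n_nitrogen")
  for (i in seq_len(n)) {
    dom <- setdiff(domains[[i]], 0L)
    u_pos <- if (length(dom)) unary[i, dom] else numeric(0)
    # unassigned pseudo-likelihood: the evidence explained as pure noise
    # (background density per observed value), on the same raw scale as
    # the typing likelihoods; junk systems then prefer to drop out while
    # any decently matching placement beats the background by orders of
    # magnitude
    u0 <- if (!is.null(raw_max) && raw_max[i] > 0) {
      bg <- config$cx_floor ^ n_c[i] * config$bg_n ^ n_n[i]
      max(min(bg / raw_max[i], 1e6), config$unassigned_rel)
    } else {
      max(stats::quantile(unary[i, ], 0.05, names = FALSE),
          config$unassigned_rel * max(unary[i, ], 0), 1e-12)
    }
    doms[[i]] <- c(0L, dom)
    psis[[i]] <- c(u0, u_pos)
  }
  # contention shortlist: each system's best few candidate positions
  prefer <- lapply(seq_len(n), function(i) {
    dom <- setdiff(doms[[i]], 0L)
    if (!length(dom)) return(integer(0))
    dom[order(unary[i, dom], decreasing = TRUE)[seq_len(min(5L, length(dom)))]]
  })
  factors <- bp_build_factors(doms, links, id2idx, prefer = prefer)
  sol <- bp_sum_product(psis, doms, factors, config)
  c(sol, list(domains = doms))
}

# Greedy hard one-to-one extraction from marginals: systems in descending
# order of their best placement probability take their best still-free
# position (or stay unassigned).
map_assignment <- function(beliefs, doms) {
  n <- length(beliefs)
  best_p <- numeric(n)
  for (i in seq_len(n)) {
    pos <- doms[[i]] > 0L
    best_p[i] <- if (any(pos)) max(beliefs[[i]][pos]) else 0
  }
  assign <- rep(0L, n); prob <- rep(0, n); taken <- integer(0)
  for (i in order(best_p, decreasing = TRUE)) {
    b <- beliefs[[i]]; dom <- doms[[i]]
    for (j in order(b, decreasing = TRUE)) {
      p <- dom[j]
      if (p == 0L) break                       # unassigned preferred
      if (!(p %in% taken)) {
        assign[i] <- p; prob[i] <- b[j]; taken <- c(taken, p)
        break
      }
    }
  }
  list(position = assign, prob = prob)
}
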