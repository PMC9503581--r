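# Shared fixtures and independent oracles for the test suite.

# 56-residue immunoglobulin-binding-domain sequence used as the standard
# recovery fixture (no prolines, mixed composition).
GB1_SEQ <- strsplit("MQYKLILNGKTLKGETTTEAVDAATAEKVFKQYANDNGVDGEWTYDDATKTFTVTE",
                    "")[[1]]

# The twelve experiments the synthetic benchmark protocol simulates.
BENCH_EXPERIMENTS <- c("CC", "NCA", "NCACB-2D", "NCO", "NCACB-3D", "NCACX",
                       "NCACO", "CANCO", "CANCOCX", "NCOCA", "NCOCACB",
                       "NCOCX")

STATS <- load_statistics()

backbone_reference <- function(tab) {
  tab[tab$atom %in% c("N", "CA", "CB", "C"), , drop = FALSE]
}

# A small clean end-to-end fixture: table + peak lists + reference.
make_clean_fixture <- function(sequence, seed, experiments = BENCH_EXPERIMENTS) {
  tab <- simulate_shift_table(sequence, STATS, seed = seed,
                              min_separation = 0.8)
  pls <- generate_peaklists(tab, sequence, experiments,
                            synthetic_options(seed = seed + 1000L))
  list(tab = tab, pls = pls, ref = backbone_reference(tab))
}

# ---- independent exact-marginal oracle -------------------------------------
# Enumerates the full joint over all domain combinations; potentials are
# written out directly from their definitions (not via the solver's message
# shortcuts).
enumerate_marginals <- function(psis, doms, factors, config) {
  n <- length(psis)
  psis <- lapply(psis, function(p) p / sum(p))
  grid <- expand.grid(lapply(doms, seq_along), KEEP.OUT.ATTRS = FALSE)
  marg <- lapply(seq_len(n), function(i) numeric(length(doms[[i]])))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    w <- 1
    for (i in seq_len(n)) w <- w * psis[[i]][idx[i]]
    for (f in factors) {
      xa <- doms[[f$a]][idx[f$a]]
      xb <- doms[[f$b]][idx[f$b]]
      if (f$type == "link") {
        if (xa > 0 && xb == xa + 1) w <- w * (1 + config$link_weight * f$w)
      } else {
        if (xa > 0 && xa == xb) w <- w * config$exclusion_penalty
      }
    }
    total <- total + w
    for (i in seq_len(n)) marg[[i]][idx[i]] <- marg[[i]][idx[i]] + w
  }
  lapply(marg, function(m) m / total)
}

# Random acyclic placement problem: a chain (or star) of linked variables
# with pairwise-disjoint position domains (so no exclusion factor arises
# and the factor graph is a tree).
random_acyclic_problem <- function(n_sys, n_pos) {
  # partition a shuffled position pool into disjoint, non-empty chunks so
  # no exclusion factor can arise and the factor graph is a tree
  pool <- sample(seq_len(n_pos))
  cuts <- if (n_sys > 1L) sort(sample(seq_len(n_pos - 1L), n_sys - 1L))
          else integer(0)
  bounds <- c(0L, cuts, n_pos)
  doms <- lapply(seq_len(n_sys), function(i)
    c(0L, sort(pool[(bounds[i] + 1L):bounds[i + 1L]])))
  psis <- lapply(doms, function(d) stats::runif(length(d), 0.05, 1))
  links <- if (n_sys > 1L)
    data.frame(from_id = seq_len(n_sys - 1L), to_id = seq(2L, n_sys),
               score = stats::runif(n_sys - 1L))
  else data.frame(from_id = integer(0), to_id = integer(0),
                  score = numeric(0))
  list(psis = psis, doms = doms, links = links)
}

# Build a reference with n atoms and a "result" where the first k carry a
# valid probability and the first c of those match the reference value.
ratio_fixture <- function(n_ref, n_given, n_correct) {
  seq_id <- rep(seq_len(ceiling(n_ref / 4)), each = 4)[seq_len(n_ref)]
  atom <- rep(c("N", "CA", "CB", "C"), length.out = n_ref)
  type <- rep("A", n_ref)
  value <- seq(10, 180, length.out = n_ref)
  ref <- shift_table(seq_id, type, atom, value)
  got_value <- value
  if (n_given > n_correct)
    got_value[(n_correct + 1):n_given] <- value[(n_correct + 1):n_given] + 5
  prob <- c(rep(0.9, n_given), rep(0.1, n_ref - n_given))
  got <- shift_table(seq_id, type, atom, got_value, prob = prob)
  list(ref = ref, got = got)
}

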