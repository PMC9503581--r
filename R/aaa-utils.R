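# Amino-acid dictionaries and small shared helpers.

AA_ONE <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE), unname(AA_THREE))

# Side-chain carbons per residue type, standard heavy-atom nomenclature.
# Only A/B/D/E/G/H carbon positions are listed (zeta carbons and the backbone
# carbonyl are excluded from the CX role by definition); CB appears here so
# that CX expansion is a single lookup plus CA.
SIDECHAIN_CARBONS <- list(
  A = c("CB"),
  R = c("CB","CG","CD"),
  N = c("CB","CG"),
  D = c("CB","CG"),
  C = c("CB"),
  Q = c("CB","CG","CD"),
  E = c("CB","CG","CD"),
  G = character(0),
  H = c("CB","CG","CD2","CE1"),
  I = c("CB","CG1","CG2","CD1"),
  L = c("CB","CG","CD1","CD2"),
  K = c("CB","CG","CD","CE"),
  M = c("CB","CG","CE"),
  F = c("CB","CG","CD1","CD2","CE1","CE2"),
  P = c("CB","CG","CD"),
  S = c("CB"),
  T = c("CB","CG2"),
  W = c("CB","CG","CD1","CD2","CE2","CE3","CH2"),
  Y = c("CB","CG","CD1","CD2","CE1","CE2"),
  V = c("CB","CG1","CG2")
)

#' Carbon atoms covered by the CX role for a residue type
#'
#' CX denotes any alpha, beta, delta, epsilon, gamma, or eta carbon of a
#' residue; it therefore includes CA and excludes the backbone carbonyl.
#'
#' @param type one-letter residue code
#' @return character vector of atom names
#' @keywords internal
cx_atoms <- function(type) {
  c("CA", SIDECHAIN_CARBONS[[type]])
}

# All nitrogen/carbon atoms a residue type possesses (backbone amide N,
# carbonyl C, CA, and the side-chain carbons).
residue_atoms <- function(type) {
  c("N", "C", "CA", SIDECHAIN_CARBONS[[type]])
}

atom_nucleus <- function(atom) {
  ifelse(atom == "N", "N", "C")
}

# Canonical atom naming: carbonyl is "C"; accept "CO" as an alias on input.
normalize_atom <- function(atom) {
  atom <- toupper(trimws(atom))
  atom[atom == "CO"] <- "C"
  atom
}

#' Default configuration for the assignment pipeline
#'
#' All tunable parameters in one place. Values can be overridden by passing
#' a named list to the pipeline entry points; unknown names are rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of configuration values.
#' @export
ssa_config <- function(...) {
  cfg <- list(
    tol_c_grid = c(0.2, 0.35, 0.5),   # carbon tolerance grid, ppm
    tol_n_grid = c(0.3, 0.55, 0.8),   # nitrogen tolerance grid, ppm
    quality_threshold = 0.3,          # gate: terminate below this
    bp_max_iters = 200L,
    bp_damping = 0.5,
    bp_tol_msg = 1e-6,
    exclusion_penalty = 1e-3,         # soft one-to-one collision factor
    link_weight = 10,                 # pairwise boost for consecutive placement
    unassigned_rel = 1e-3,            # floor for the unassigned pseudo-likelihood
    fragment_floor = 1e-8,            # pentapeptide pruning floor
    cx_floor = 1e-3,                  # penalty density for an observed carbon
                                      # the type cannot explain (noise model)
    bg_n = 1e-3,                      # same for nitrogen values
    corroboration_cap = 0.49,         # probability cap for placements without
                                      # a link to a placed sequence neighbour
    max_rounds = 5L,                  # assignment/offset iteration rounds
    offset_min_report = 0.1,          # ppm; smaller detected offsets report as 0
    offset_min_support = 5L,          # confident atoms required per experiment
    offset_conf = 0.85,               # probability cutoff for offset evidence
    sidechain_cutoff = 0.6,           # backbone probability needed for side chains
    sd_floor_c = 0.3,                 # ppm, statistics sd clamps
    sd_floor_n = 0.5
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown configuration option(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

# Stable small-integer substream derivation, kept below 2^31.
derive_seed <- function(seed, key) {
  v <- utf8ToInt(as.character(key))
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

ssa_message <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
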