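# Registry of supported carbon/nitrogen-detected ssNMR experiments.
#
# Each profile records, per axis, the set of atom roles the axis can carry
# and the residue offset (0 = residue i, -1 = preceding residue). Slash
# notation in the printed profile string ("CX/C") means the union of roles
# on that one axis.

.make_profile <- function(name, dim, axes, minimum_set, profile_string) {
  stopifnot(length(axes) == dim)
  structure(list(name = name, dimensionality = dim, axes = axes,
                 minimum_set = minimum_set, profile_string = profile_string),
            class = "ssa_profile")
}

.ax <- function(roles, offset) list(roles = roles, offset = offset)

PROFILE_REGISTRY <- local({
  p <- list(
    .make_profile("CC", 2L,
      list(.ax(c("CX","CO"), 0L), .ax(c("CX","CO"), 0L)),
      TRUE,  "CX/O(i)-CX/O(i)"),
    .make_profile("NCA", 2L,
      list(.ax("N", 0L), .ax("CA", 0L)),
      TRUE,  "N(i)-CA(i)"),
    .make_profile("NCACB-2D", 2L,
      list(.ax("N", 0L), .ax(c("CA","CB"), 0L)),
      FALSE, "N(i)-CA/B(i)"),
    .make_profile("NCO", 2L,
      list(.ax("N", 0L), .ax("CO", -1L)),
      TRUE,  "N(i)-CO(i - 1)"),
    .make_profile("NCACO", 3L,
      list(.ax("N", 0L), .ax("CA", 0L), .ax("CO", 0L)),
      FALSE, "N(i)-CA(i)-CO(i)"),
    .make_profile("NCACB-3D", 3L,
      list(.ax("N", 0L), .ax("CA", 0L), .ax(c("CA","CB"), 0L)),
      FALSE, "N(i)-CA(i)-CA/B(i)"),
    .make_profile("NCACX", 3L,
      list(.ax("N", 0L), .ax("CA", 0L), .ax("CX", 0L)),
      TRUE,  "N(i)-CA(i)-CX(i)"),
    .make_profile("NCOCX", 3L,
      list(.ax("N", 0L), .ax("CO", -1L), .ax(c("CX","CO"), -1L)),
      TRUE,  "N(i)-CO(i - 1)-CX/C(i - 1)"),
    .make_profile("NCOCA", 3L,
      list(.ax("N", 0L), .ax("CO", -1L), .ax("CA", -1L)),
      FALSE, "N(i)-CO(i - 1)-CA(i - 1)"),
    .make_profile("NCOCACB", 3L,
      list(.ax("N", 0L), .ax("CO", -1L), .ax(c("CA","CB"), -1L)),
      FALSE, "N(i)-CO(i - 1)-CA/B(i - 1)"),
    .make_profile("CANCO", 3L,
      list(.ax("CA", 0L), .ax("N", 0L), .ax("CO", -1L)),
      FALSE, "CA(i)-N(i)-CO(i - 1)"),
    .make_profile("CANCOCX", 3L,
      list(.ax("CA", 0L), .ax("N", 0L), .ax(c("CX","CO"), -1L)),
      TRUE,  "CA(i)-N(i)-CX/O(i - 1)"),
    .make_profile("CANCOCA", 3L,
      list(.ax("CA", 0L), .ax("N", 0L), .ax(c("CA","CO"), -1L)),
      FALSE, "CA(i)-N(i)-CA/O(i - 1)"),
    .make_profile("CANCOCACB", 3L,
      list(.ax("CA", 0L), .ax("N", 0L), .ax(c("CO","CA","CB"), -1L)),
      FALSE, "CA(i)-N(i)-CO/A/B(i - 1)")
  )
  stats::setNames(p, vapply(p, `[[`, "", "name"))
})

# Normalize a user token to a registry key. Dimensional prefixes ("2D-",
# "3D-") select between the two NCACB entries; a bare "NCACB" defaults to
# the 3D experiment. "CAN(CO)CX" style parentheses are stripped.
normalize_experiment_name <- function(name) {
  tok <- toupper(gsub("[()\\s]", "", gsub("\\s", "", name)))
  dim_hint <- NA_integer_
  if (grepl("^2D-?", tok)) { dim_hint <- 2L; tok <- sub("^2D-?", "", tok) }
  if (grepl("^3D-?", tok)) { dim_hint <- 3L; tok <- sub("^3D-?", "", tok) }
  if (tok == "NCACB") {
    tok <- if (identical(dim_hint, 2L)) "NCACB-2D" else "NCACB-3D"
  }
  tok
}

#' Look up an experiment profile
#'
#' Names are matched case-insensitively and a "2D-"/"3D-" prefix is honoured
#' ("2D-NCA" and "NCA" resolve identically). The ambiguous token "NCACB"
#' resolves to the 3D experiment; use "NCACB-2D" / "2D-NCACB" for the 2D one.
#'
#' @param name experiment token.
#' @return an `ssa_profile` with fields `name`, `dimensionality`, `axes`
#'   (list of `roles`/`offset`), `minimum_set`, `profile_string`.
#' @export
#' @examples
#' get_profile("NCOCX")$dimensionality
get_profile <- function(name) {
  key <- normalize_experiment_name(name)
  prof <- PROFILE_REGISTRY[[key]]
  if (is.null(prof))
    stop("unknown experiment '", name, "'; supported: ",
         paste(names(PROFILE_REGISTRY), collapse = ", "))
  prof
}

#' The experiment registry as a data frame
#'
#' @return data.frame with columns `name`, `dimension`, `profile`,
#'   `minimum_set`, one row per supported experiment.
#' @export
profile_table <- function() {
  data.frame(
    name = vapply(PROFILE_REGISTRY, `[[`, "", "name"),
    dimension = vapply(PROFILE_REGISTRY, `[[`, 0L, "dimensionality"),
    profile = vapply(PROFILE_REGISTRY, `[[`, "", "profile_string"),
    minimum_set = vapply(PROFILE_REGISTRY, `[[`, TRUE, "minimum_set"),
    row.names = NULL
  )
}

# TRUE if profile `sup` contains every axis of `sub`: for each axis of sub
# there is a distinct axis of sup at the same residue offset whose role set
# is a superset. A 3D experiment then satisfies its 2D projections.
profile_covers <- function(sup, sub) {
  used <- rep(FALSE, sup$dimensionality)
  for (ax in sub$axes) {
    found <- FALSE
    for (j in seq_along(sup$axes)) {
      if (used[j]) next
      sax <- sup$axes[[j]]
      if (sax$offset == ax$offset && all(ax$roles %in% sax$roles)) {
        used[j] <- TRUE; found <- TRUE; break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Validate a set of experiments against the minimum requirement
#'
#' The minimum set (CC, NCA, NCO, NCACX, NCOCX, CANCOCX) must be present
#' either directly or through a superset experiment whose axes cover the
#' missing member (e.g. 3D-NCACX covers 2D-NCA). Unknown names are reported
#' but are not fatal.
#'
#' @param names character vector of experiment tokens.
#' @return list with `ok`, `missing` (canonical names of unmet minimum-set
#'   members), `unknown` (tokens that did not resolve), `covered_by`
#'   (named list: minimum-set member -> experiment that covers it).
#' @export
validate_experiment_set <- function(names) {
  keys <- character(0); unknown <- character(0)
  for (nm in names) {
    key <- normalize_experiment_name(nm)
    if (is.null(PROFILE_REGISTRY[[key]])) unknown <- c(unknown, nm)
    else keys <- c(keys, key)
  }
  keys <- unique(keys)
  minimum <- names(PROFILE_REGISTRY)[vapply(PROFILE_REGISTRY, `[[`, TRUE,
                                            "minimum_set")]
  missing <- character(0); covered_by <- list()
  for (m in minimum) {
    if (m %in% keys) { covered_by[[m]] <- m; next }
    hit <- NA_character_
    for (k in keys) {
      if (profile_covers(PROFILE_REGISTRY[[k]], PROFILE_REGISTRY[[m]])) {
        hit <- k; break
      }
    }
    if (is.na(hit)) missing <- c(missing, m) else covered_by[[m]] <- hit
  }
  list(ok = length(missing) == 0L, missing = missing, unknown = unknown,
       covered_by = covered_by)
}

# Expand one axis role set into concrete atom names for a residue type.
expand_roles <- function(roles, type) {
  atoms <- character(0)
  for (r in roles) {
    atoms <- c(atoms, switch(r,
      N = "N", CA = "CA", CO = "C",
      CB = intersect("CB", SIDECHAIN_CARBONS[[type]]),
      CX = cx_atoms(type),
      stop("unknown role ", r)))
  }
  unique(atoms)
}

#' Enumerate the sequential cross-peaks an experiment predicts
#'
#' For every residue i (starting at 2 when any axis addresses the preceding
#' residue) one template is produced per combination of concrete atoms in
#' each axis's role set, given that residue's atom inventory (glycine has no
#' CB, etc.). For the 2D carbon-carbon experiment, whose two axes address
#' the same residue, only unordered pairs of distinct atoms are produced.
#'
#' @param profile an `ssa_profile` (or experiment token).
#' @param sequence a `protein_sequence` or plain one-letter character vector.
#' @return data.frame with columns `res<k>` and `atom<k>` per axis k.
#' @export
expected_peaks <- function(profile, sequence) {
  if (is.character(profile)) profile <- get_profile(profile)
  res <- sequence_residues(sequence)
  L <- length(res)
  d <- profile$dimensionality
  offs <- vapply(profile$axes, `[[`, 0L, "offset")
  start <- if (any(offs < 0L)) 2L else 1L
  out <- vector("list", max(L, 1L))
  empty <- {
    cols <- c(t(vapply(seq_len(d),
      function(k) c(paste0("res", k), paste0("atom", k)), character(2))))
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), 2 * d), cols))
    for (k in seq_len(d)) { df[[paste0("res", k)]] <- integer(0)
                            df[[paste0("atom", k)]] <- character(0) }
    df
  }
  if (L < start) return(empty)
  same_residue_pair <- d == 2L && offs[1] == offs[2] &&
    length(profile$axes[[1]]$roles) > 1L &&
    identical(sort(profile$axes[[1]]$roles), sort(profile$axes[[2]]$roles))
  n_out <- 0L
  for (i in start:L) {
    choices <- lapply(seq_len(d), function(k) {
      j <- i + offs[k]
      expand_roles(profile$axes[[k]]$roles, res[j])
    })
    if (any(lengths(choices) == 0L)) next
    grid <- expand.grid(choices, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- paste0("atom", seq_len(d))
    if (same_residue_pair) {
      grid <- grid[grid$atom1 < grid$atom2, , drop = FALSE]
    }
    if (!nrow(grid)) next
    for (k in seq_len(d)) grid[[paste0("res", k)]] <- i + offs[k]
    n_out <- n_out + 1L
    out[[n_out]] <- grid
  }
  if (n_out == 0L) return(empty)
  df <- do.call(rbind, out[seq_len(n_out)])
  rownames(df) <- NULL
  df[, c(rbind(paste0("res", seq_len(d)), paste0("atom", seq_len(d))))]
}
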