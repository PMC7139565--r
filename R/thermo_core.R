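# Core domain types: species states, reference enthalpies, enthalpy ledgers.
# Canonical internal unit is kJ/mol throughout; Hartree only at I/O.

KJ_PER_HARTREE <- 2625.4996
GAS_CONSTANT_KJ <- 8.31446e-3  # kJ/(mol K)

.SITE_STATES <- c("OH", "O-", "O*")  # protonated, deprotonated, radical

#' Convert Hartree to kJ/mol
#'
#' Unit conversion at the input boundary; all internal arithmetic is in
#' kJ/mol. Uses 1 Hartree = 2625.4996 kJ/mol.
#'
#' @param x numeric vector of enthalpies in Hartree.
#' @return numeric vector in kJ/mol.
#' @seealso [kjmol_to_hartree()]
#' @export
#' @examples
#' hartree_to_kjmol(-0.5)
hartree_to_kjmol <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("enthalpy values must be finite numbers", call. = FALSE)
  }
  x * KJ_PER_HARTREE
}

#' Convert kJ/mol to Hartree
#'
#' @param x numeric vector of enthalpies in kJ/mol.
#' @return numeric vector in Hartree.
#' @export
kjmol_to_hartree <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("enthalpy values must be finite numbers", call. = FALSE)
  }
  x / KJ_PER_HARTREE
}

#' Gas-phase proton enthalpy
#'
#' The translational + PV enthalpy of an ideal-gas proton, (5/2) R T.
#' A bare proton has no electronic or vibrational degrees of freedom, so
#' this is its full gas-phase enthalpy; add it to a solvation constant when
#' placing absolute quantum-chemistry ledgers and the bundled reference
#' enthalpies on a common scale.
#'
#' @param temperature temperature in kelvin (default 298.15).
#' @return enthalpy in kJ/mol.
#' @export
#' @examples
#' gas_phase_proton_enthalpy()        # 6.197 kJ/mol at 298.15 K
gas_phase_proton_enthalpy <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number (kelvin)", call. = FALSE)
  }
  2.5 * GAS_CONSTANT_KJ * temperature
}

#' Reference enthalpies of the small species
#'
#' Bundles the enthalpies assigned to the solvated hydrogen atom, proton and
#' electron, plus the reduction enthalpy of the partner radical that accepts
#' the transferred electron (DPPH in the methanol/DPPH assay). The defaults
#' are the methanol constants used throughout: H atom +5 kJ/mol (its
#' solvation enthalpy in common organic solvents), proton -1071 kJ/mol and
#' electron -77 kJ/mol (computed solvation enthalpies in methanol), and
#' -303 kJ/mol for the reduction of DPPH by an electron.
#'
#' These constants enter the descriptor definitions directly as H(H.),
#' H(H+) and H(e-); they are stored values, never recomputed.
#'
#' @param h_atom enthalpy of the solvated hydrogen atom, kJ/mol.
#' @param h_proton enthalpy of the solvated proton, kJ/mol.
#' @param h_electron enthalpy of the solvated electron, kJ/mol.
#' @param radical_reduction reduction enthalpy of the partner radical
#'   (DPPH), kJ/mol; added to electron-transfer steps when coupling.
#' @param temperature temperature in kelvin.
#' @param solvent solvent label (bookkeeping only).
#' @return an object of class `reference_enthalpies`.
#' @export
#' @examples
#' refs <- reference_enthalpies()
#' refs$h_proton
reference_enthalpies <- function(h_atom = 5, h_proton = -1071,
                                 h_electron = -77, radical_reduction = -303,
                                 temperature = 298.15, solvent = "methanol") {
  vals <- c(h_atom = h_atom, h_proton = h_proton, h_electron = h_electron,
            radical_reduction = radical_reduction)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("reference enthalpies must be finite numbers (kJ/mol)", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  structure(
    list(h_atom = as.numeric(h_atom), h_proton = as.numeric(h_proton),
         h_electron = as.numeric(h_electron),
         radical_reduction = as.numeric(radical_reduction),
         temperature = as.numeric(temperature), solvent = solvent),
    class = "reference_enthalpies"
  )
}

#' @export
print.reference_enthalpies <- function(x, ...) {
  cat("Reference enthalpies (", x$solvent, ", ", x$temperature, " K), kJ/mol:\n",
      sep = "")
  cat(sprintf("  H atom      %8.1f\n", x$h_atom))
  cat(sprintf("  proton      %8.1f\n", x$h_proton))
  cat(sprintf("  electron    %8.1f\n", x$h_electron))
  cat(sprintf("  radical red %8.1f\n", x$radical_reduction))
  invisible(x)
}

#' Species state of a multi-phenol compound
#'
#' A species state records, for every phenolic O-H site of a compound,
#' whether it is protonated (`"OH"`), deprotonated to the phenoxide
#' (`"O-"`) or oxidized to the phenoxy radical (`"O*"`), plus a
#' molecule-level flag for the radical cation formed by electron loss from
#' the neutral parent. The radical-cation flag is only meaningful on the
#' all-protonated parent (the SET-PT path ionizes the neutral phenol).
#'
#' @param states named character vector, one of `"OH"`, `"O-"`, `"O*"` per
#'   site; names are the site labels (e.g. `X`, `X'`, `Y`).
#' @param radical_cation logical; `TRUE` for the radical cation of the
#'   parent.
#' @return an object of class `species_state` (canonicalized: sites sorted
#'   by label).
#' @export
#' @examples
#' species_state(c(X = "O-", Y = "OH", `X'` = "OH"))
species_state <- function(states, radical_cation = FALSE) {
  if (length(states) < 1L) {
    stop("a compound has at least one phenolic site", call. = FALSE)
  }
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("site states must be named by site label", call. = FALSE)
  }
  if (anyDuplicated(names(states))) {
    stop("site labels must be unique within a compound", call. = FALSE)
  }
  states <- vapply(states, as.character, character(1))
  bad <- !(states %in% .SITE_STATES)
  if (any(bad)) {
    stop("invalid site state(s): ", paste(states[bad], collapse = ", "),
         " (must be one of OH, O-, O*)", call. = FALSE)
  }
  if (isTRUE(radical_cation) && any(states == "O-")) {
    stop("radical_cation requires no deprotonated site ",
         "(electron loss operates on the neutral parent)", call. = FALSE)
  }
  states <- states[order(names(states), method = "radix")]
  structure(list(states = states, radical_cation = isTRUE(radical_cation)),
            class = "species_state")
}

#' Formal charge of a species state
#'
#' Derived, never stored: minus the number of deprotonated sites, plus one
#' for the radical cation.
#'
#' @param state a `species_state`.
#' @return integer formal charge.
#' @export
formal_charge <- function(state) {
  stopifnot(inherits(state, "species_state"))
  -sum(state$states == "O-") + as.integer(state$radical_cation)
}

#' Canonical state code of a species state
#'
#' Serializes a species state as semicolon-separated `site:state` pairs in
#' sorted site order, with a `+cation` suffix for the radical cation, e.g.
#' `"X:O-;X':OH;Y:OH"`. This string is the ledger key.
#'
#' @param state a `species_state`.
#' @return a single string.
#' @seealso [parse_state_code()]
#' @export
state_code <- function(state) {
  stopifnot(inherits(state, "species_state"))
  code <- paste(names(state$states), state$states, sep = ":", collapse = ";")
  if (state$radical_cation) code <- paste0(code, "+cation")
  code
}

#' Parse a state code into a species state
#'
#' @param code state-code string (see [state_code()] for the grammar).
#' @param sites optional character vector of the compound's site labels; if
#'   given, the code must cover exactly these sites.
#' @return a `species_state`.
#' @export
parse_state_code <- function(code, sites = NULL) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    stop("state code must be a single non-empty string", call. = FALSE)
  }
  cation <- grepl("\\+cation$", code)
  body <- sub("\\+cation$", "", code)
  parts <- strsplit(body, ";", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^\\s*([^:]+?)\\s*:\\s*(O\\*|O-|OH)\\s*$", parts))
  ok <- lengths(kv) == 3L
  if (!all(ok)) {
    stop("malformed state code near: ",
         paste(parts[!ok], collapse = ", "), call. = FALSE)
  }
  states <- vapply(kv, `[`, character(1), 3L)
  names(states) <- vapply(kv, `[`, character(1), 2L)
  if (!is.null(sites)) {
    if (!setequal(names(states), sites) || length(states) != length(sites)) {
      stop("state code sites {", paste(sort(names(states)), collapse = ", "),
           "} do not match compound sites {",
           paste(sort(sites), collapse = ", "), "}", call. = FALSE)
    }
  }
  species_state(states, radical_cation = cation)
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state> ", state_code(x),
      "  (charge ", formal_charge(x), ")\n", sep = "")
  invisible(x)
}

#' All-protonated parent state
#'
#' @param sites character vector of site labels.
#' @return the parent `species_state` (all sites `"OH"`).
#' @export
parent_state <- function(sites) {
  species_state(stats::setNames(rep("OH", length(sites)), sites))
}

# Return a copy of `state` with one site moved to `new` ("OH"/"O-"/"O*").
set_site_state <- function(state, site, new) {
  states <- state$states
  if (!site %in% names(states)) {
    stop("unknown site label: ", site, call. = FALSE)
  }
  states[[site]] <- new
  species_state(states, radical_cation = state$radical_cation)
}

#' Species-enthalpy ledger for one compound
#'
#' Maps species states of a single compound in a single solvent to their
#' enthalpies (kJ/mol). The ledger must contain the all-protonated parent;
#' looking up a state that was never computed is an error, never an
#' imputation.
#'
#' @param compound_id compound identifier.
#' @param sites character vector of phenolic site labels.
#' @param entries named numeric vector of enthalpies in kJ/mol, keyed by
#'   state code (keys are canonicalized on construction).
#' @param solvent solvent label.
#' @param equivalent_sites optional list of character vectors naming groups
#'   of chemically equivalent sites (e.g. `list(c("X", "X'"))`), used for
#'   report-time averaging.
#' @return an object of class `enthalpy_ledger`.
#' @export
#' @examples
#' led <- enthalpy_ledger("demo", sites = c("X", "Y"),
#'   entries = c("X:OH;Y:OH" = -1000, "X:O-;Y:OH" = 71, "X:O*;Y:OH" = -850))
#' ledger_lookup(led, parent_state(c("X", "Y")))
enthalpy_ledger <- function(compound_id, sites, entries,
                            solvent = "methanol", equivalent_sites = NULL) {
  if (!is.character(compound_id) || length(compound_id) != 1L) {
    stop("compound_id must be a single string", call. = FALSE)
  }
  if (length(sites) < 1L || anyDuplicated(sites)) {
    stop("sites must be one or more unique labels", call. = FALSE)
  }
  if (!is.numeric(entries) || is.null(names(entries))) {
    stop("entries must be a named numeric vector keyed by state code",
         call. = FALSE)
  }
  if (any(!is.finite(entries))) {
    stop("ledger enthalpies must be finite (kJ/mol)", call. = FALSE)
  }
  sites <- as.character(sites)
  keys <- vapply(names(entries),
                 function(k) state_code(parse_state_code(k, sites = sites)),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate species state(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  entries <- stats::setNames(as.numeric(entries), keys)
  parent_key <- state_code(parent_state(sites))
  if (!parent_key %in% keys) {
    stop("ledger for '", compound_id,
         "' lacks the all-protonated parent state ", parent_key, call. = FALSE)
  }
  if (!is.null(equivalent_sites)) {
    for (grp in equivalent_sites) {
      if (length(grp) < 2L || !all(grp %in% sites)) {
        stop("equivalent_sites must be groups of >= 2 known site labels",
             call. = FALSE)
      }
    }
  }
  structure(
    list(compound_id = compound_id, solvent = solvent,
         sites = sort(sites, method = "radix"), entries = entries,
         equivalent_sites = equivalent_sites),
    class = "enthalpy_ledger"
  )
}

#' Look up a species enthalpy
#'
#' @param ledger an `enthalpy_ledger`.
#' @param state a `species_state` or state-code string.
#' @return the stored enthalpy in kJ/mol.
#' @export
ledger_lookup <- function(ledger, state) {
  stopifnot(inherits(ledger, "enthalpy_ledger"))
  if (is.character(state)) state <- parse_state_code(state, ledger$sites)
  stopifnot(inherits(state, "species_state"))
  if (!setequal(names(state$states), ledger$sites)) {
    stop("state sites do not match ledger sites for '",
         ledger$compound_id, "'", call. = FALSE)
  }
  key <- state_code(state)
  idx <- match(key, names(ledger$entries))
  if (is.na(idx)) {
    stop("species not computed for '", ledger$compound_id, "': ", key,
         call. = FALSE)
  }
  unname(ledger$entries[[idx]])
}

has_state <- function(ledger, state) {
  state_code(state) %in% names(ledger$entries)
}

#' States recorded in a ledger
#'
#' @param ledger an `enthalpy_ledger`.
#' @return character vector of canonical state codes.
#' @export
ledger_states <- function(ledger) {
  stopifnot(inherits(ledger, "enthalpy_ledger"))
  names(ledger$entries)
}

#' @export
print.enthalpy_ledger <- function(x, ...) {
  cat("<enthalpy_ledger> compound '", x$compound_id, "' in ", x$solvent,
      "\n  sites: ", paste(x$sites, collapse = ", "),
      "\n  species: ", length(x$entries), " state(s)\n", sep = "")
  invisible(x)
}
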