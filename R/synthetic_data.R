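# Seeded synthetic ledgers for multi-site dendritic phenols, plus bundled
# literature benchmark step values.
#
# Generator model, per species state s over sites i:
#   H(s) = base + sum_i cost_i(s_i)
#            + sum_{i<j} eps_ij * [both i and j non-protonated]
#            + Gaussian noise (per species)
# with cost_i(OH) = 0, cost_i(O-) chosen so the parent-state PA of site i
# equals pa_base + delta_pa_i under the given reference enthalpies, and
# cost_i(O*) chosen likewise for the parent-state ETE. The radical cation
# gets the enthalpy that reproduces the requested IP. An
# electron-donating substituent maps to delta_ete < 0 (and mildly
# delta_pa > 0); electron-withdrawing is the mirror image.

#' Specification of a synthetic dendritic-phenol ledger
#'
#' Defaults emulate a tri-phenolic dendritic antioxidant in methanol with
#' first-step enthalpies in the published range for such compounds
#' (parent-state PA 150, raw ETE 355, IP 470 kJ/mol), no ring-ring
#' interaction and no noise.
#'
#' @param n_sites number of phenolic sites (>= 1).
#' @param site_labels optional site labels (default `S1..Sn`).
#' @param base_parent_enthalpy enthalpy of the all-protonated parent,
#'   kJ/mol (an arbitrary offset; only differences matter).
#' @param pa_base,ete_base parent-state PA and raw ETE of an unsubstituted
#'   site, kJ/mol.
#' @param delta_pa,delta_ete per-site substituent offsets added to
#'   `pa_base` / `ete_base`, recycled to `n_sites`.
#' @param ip_value ionization potential assigned to the compound, kJ/mol.
#' @param interaction pairwise ring-ring penalty: a symmetric zero-diagonal
#'   matrix (kJ/mol), or a scalar applied to every pair.
#' @param noise_sd standard deviation of Gaussian noise added to every
#'   species enthalpy, kJ/mol.
#' @param seed integer seed; generation is fully deterministic for a fixed
#'   seed (there is no unseeded path).
#' @param equivalent_sites optional equivalence groups passed to the
#'   ledger.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 3, site_labels = NULL,
                           base_parent_enthalpy = -1000,
                           pa_base = 150, ete_base = 355,
                           delta_pa = 0, delta_ete = 0, ip_value = 470,
                           interaction = 0, noise_sd = 0, seed = 1,
                           equivalent_sites = NULL) {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(site_labels)) site_labels <- sprintf("S%d", seq_len(n_sites))
  if (length(site_labels) != n_sites || anyDuplicated(site_labels)) {
    stop("site_labels must be ", n_sites, " unique labels", call. = FALSE)
  }
  if (length(interaction) == 1L) {
    eps <- matrix(interaction, n_sites, n_sites)
    diag(eps) <- 0
  } else {
    eps <- as.matrix(interaction)
  }
  if (!isTRUE(all.equal(eps, t(eps))) || any(diag(eps) != 0)) {
    stop("interaction must be symmetric with zero diagonal", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites), site_labels = site_labels,
         base_parent_enthalpy = base_parent_enthalpy,
         pa_base = pa_base, ete_base = ete_base,
         delta_pa = rep_len(delta_pa, n_sites),
         delta_ete = rep_len(delta_ete, n_sites),
         ip_value = ip_value, interaction = eps,
         noise_sd = noise_sd, seed = as.integer(seed),
         equivalent_sites = equivalent_sites),
    class = "synthetic_spec"
  )
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic species-enthalpy ledger
#'
#' Produces an enthalpy for every reachable species state (all 3^n
#' protonation/oxidation combinations plus the radical cation of the
#' parent), so every cascade path is executable. With zero interaction and
#' zero noise the ledger is exactly additive: the cumulative cascade total
#' equals the naive per-site sum [dh_tot()].
#'
#' @param spec a [synthetic_spec()].
#' @param refs [reference_enthalpies()] used to invert the requested
#'   parent-state PA/ETE into species enthalpies.
#' @return an [enthalpy_ledger()].
#' @export
generate_ledger <- function(spec, refs = reference_enthalpies()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_sites
  sites <- sort(spec$site_labels, method = "radix")
  ord <- match(sites, spec$site_labels)  # costs follow the user's label order
  anion_cost <- (spec$pa_base + spec$delta_pa[ord]) - refs$h_proton
  radical_cost <- anion_cost +
    (spec$ete_base + spec$delta_ete[ord]) - refs$h_electron
  eps <- spec$interaction[ord, ord, drop = FALSE]

  combos <- expand.grid(rep(list(c("OH", "O-", "O*")), n),
                        stringsAsFactors = FALSE)
  names(combos) <- sites
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, stats::rnorm(nrow(combos) + 1L, 0, spec$noise_sd))
  } else {
    numeric(nrow(combos) + 1L)
  }
  entries <- numeric(nrow(combos))
  codes <- character(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    st <- unlist(combos[k, , drop = TRUE])
    open <- st != "OH"
    h <- spec$base_parent_enthalpy +
      sum(anion_cost[st == "O-"]) + sum(radical_cost[st == "O*"])
    if (any(open) && sum(open) > 1L) {
      h <- h + sum(eps[open, open][upper.tri(eps[open, open])])
    }
    entries[k] <- h + noise[k]
    codes[k] <- state_code(species_state(stats::setNames(st, sites)))
  }
  cation_h <- spec$base_parent_enthalpy +
    (spec$ip_value - refs$h_electron) + noise[nrow(combos) + 1L]
  entries <- c(entries, cation_h)
  codes <- c(codes, state_code(species_state(
    stats::setNames(rep("OH", n), sites), radical_cation = TRUE)))
  enthalpy_ledger(
    compound_id = sprintf("synthetic-seed%d", spec$seed),
    sites = sites, entries = stats::setNames(entries, codes),
    solvent = refs$solvent, equivalent_sites = spec$equivalent_sites
  )
}

#' Recover substituent offsets from a generated ledger
#'
#' Inverts the generator: estimates each site's `delta_pa` and `delta_ete`
#' from the parent-state descriptors. Exact for a noiseless ledger; under
#' Gaussian species noise the recovery error is the difference of two
#' species noises, so its standard deviation is `sqrt(2) * noise_sd`.
#'
#' @param ledger an [enthalpy_ledger()] (typically from
#'   [generate_ledger()]).
#' @param refs [reference_enthalpies()].
#' @param pa_base,ete_base the generator baselines to subtract.
#' @return list with named numeric vectors `delta_pa` and `delta_ete`.
#' @export
recover_offsets <- function(ledger, refs = reference_enthalpies(),
                            pa_base = 150, ete_base = 355) {
  ds <- descriptor_set(ledger, refs)
  list(
    delta_pa = stats::setNames(ds$sites$pa - pa_base, ds$sites$site),
    delta_ete = stats::setNames(ds$sites$ete - ete_base, ds$sites$site)
  )
}

#' Reconstruct a ledger from per-step cascade values
#'
#' Builds a species-enthalpy ledger whose greedy cascade reproduces a given
#' sequence of per-step PA and ETE values — the inverse of [run_cascade()]
#' for a known path. Sites are visited in label order (`S1`, `S2`, ...).
#' Off-path phenoxide states (needed so the greedy rule can rank the
#' remaining sites) are placed `margin` kJ/mol per rank above the chosen
#' step's PA, which fixes the intended order without affecting any step or
#' total along the path.
#'
#' @param pa_steps per-step proton affinities, kJ/mol, in cascade order.
#' @param ete_steps per-step electron transfer enthalpies, kJ/mol;
#'   radical-coupled (net) values by default.
#' @param refs [reference_enthalpies()].
#' @param ete_type `"net"` (coupled; the radical-reduction enthalpy is
#'   removed to store raw species energetics) or `"raw"`.
#' @param compound_id compound id for the ledger.
#' @param base_enthalpy parent enthalpy, kJ/mol.
#' @param margin spacing of off-path phenoxide states, kJ/mol (> 0).
#' @return an [enthalpy_ledger()].
#' @export
#' @examples
#' refs <- reference_enthalpies()
#' led <- ledger_from_step_values(c(150, 147, 128), c(52, 56, 61), refs)
#' run_cascade(led, refs)$dh_cum_net   # 594
ledger_from_step_values <- function(pa_steps, ete_steps,
                                    refs = reference_enthalpies(),
                                    ete_type = c("net", "raw"),
                                    compound_id = "compound",
                                    base_enthalpy = -1000, margin = 1) {
  ete_type <- match.arg(ete_type)
  n <- length(pa_steps)
  stopifnot(n >= 1L, length(ete_steps) == n, margin > 0)
  ete_raw <- if (ete_type == "net") ete_steps - refs$radical_reduction
             else ete_steps
  sites <- sprintf("S%d", seq_len(n))
  entries <- numeric(0)
  state <- parent_state(sites)
  h_here <- base_enthalpy
  entries[state_code(state)] <- h_here
  for (k in seq_len(n)) {
    # phenoxide states of every still-protonated site, ranked so that the
    # site due at step k carries the lowest PA from the current state
    for (m in k:n) {
      pa_m <- pa_steps[[k]] + margin * (m - k)
      anion <- set_site_state(state, sites[[m]], "O-")
      entries[state_code(anion)] <- h_here + pa_m - refs$h_proton
    }
    h_anion <- entries[[state_code(set_site_state(state, sites[[k]], "O-"))]]
    state <- set_site_state(state, sites[[k]], "O*")
    h_here <- h_anion + ete_raw[[k]] - refs$h_electron
    entries[state_code(state)] <- h_here
  }
  enthalpy_ledger(compound_id = compound_id, sites = sites,
                  entries = entries, solvent = refs$solvent)
}

#' Literature benchmark step values for six dendritic antioxidants
#'
#' Published per-step cascade values (PA and radical-coupled net ETE,
#' kJ/mol, in greedy order) for a family of tri-phenolic dendritic
#' antioxidants in methanol: an unsubstituted reference and five variants
#' carrying ortho electron-donating (`cpd1` one OCH3 per outer ring, `cpd2`
#' two OCH3) or electron-withdrawing (`cpd3` NO2, `cpd4` Br, `cpd5` Cl)
#' substituents. Also carries the methanol reference enthalpies and the
#' printed starting-material aggregate for `cpd2` (2 syringaldehyde + 1
#' vanillin equivalents: PA 356, ETE 1128 kJ/mol) and the tripled-vanillin
#' total for `cpd1` (1518 kJ/mol).
#'
#' @return list with elements `steps` (data frame: compound, step, pa,
#'   ete_net), `refs` ([reference_enthalpies()]), and
#'   `starting_materials` (data frame: compound, pa, ete, dh; `NA` where
#'   only the total was published).
#' @export
dendritic_benchmark <- function() {
  steps <- data.frame(
    compound = rep(c("ref", "cpd1", "cpd2", "cpd3", "cpd4", "cpd5"),
                   each = 3L),
    step = rep(1:3, 6L),
    pa = c(150, 147, 128,
           154, 150, 147,
           151, 149, 148,
           116, 116, 69,
           132, 130, 114,
           136, 133, 118),
    ete_net = c(52, 56, 61,
                30, 37, 41,
                16, 19, 40,
                119, 116, 119,
                66, 70, 73,
                61, 66, 70),
    stringsAsFactors = FALSE
  )
  starting_materials <- data.frame(
    compound = c("cpd1", "cpd2"),
    pa = c(NA_real_, 356), ete = c(NA_real_, 1128),
    dh = c(1518, 1484),
    stringsAsFactors = FALSE
  )
  list(steps = steps, refs = reference_enthalpies(),
       starting_materials = starting_materials)
}

#' Ledgers reconstructed from the bundled benchmark
#'
#' Convenience wrapper: one [ledger_from_step_values()] ledger per
#' benchmark compound, ready for [run_cascade()].
#'
#' @param refs [reference_enthalpies()].
#' @return named list of [enthalpy_ledger()] objects.
#' @export
benchmark_ledgers <- function(refs = reference_enthalpies()) {
  bm <- dendritic_benchmark()
  ids <- unique(bm$steps$compound)
  out <- lapply(ids, function(id) {
    rows <- bm$steps[bm$steps$compound == id, ]
    rows <- rows[order(rows$step), ]
    ledger_from_step_values(rows$pa, rows$ete_net, refs,
                            ete_type = "net", compound_id = id)
  })
  stats::setNames(out, ids)
}
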