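# Mechanism descriptors from a species-enthalpy ledger.
#
# HAT:     PhOH -> PhO* + H*             BDE = H(PhO*) + H(H*)  - H(PhOH)
# SET-PT:  PhOH -> PhOH*+ + e-           IP  = H(PhOH*+) + H(e-) - H(PhOH)
#          PhOH*+ -> PhO* + H+           PDE = H(PhO*) + H(H+)  - H(PhOH*+)
# SPLET:   PhOH -> PhO- + H+             PA  = H(PhO-) + H(H+)  - H(PhOH)
#          PhO-  -> PhO* + e-            ETE = H(PhO*) + H(e-)  - H(PhO-)
#
# All per-site quantities use the single-site change from the all-protonated
# parent; IP is a molecule-level (global) property.

single_site_state <- function(ledger, site, new) {
  if (!site %in% ledger$sites) {
    stop("unknown site '", site, "' for compound '", ledger$compound_id, "'",
         call. = FALSE)
  }
  set_site_state(parent_state(ledger$sites), site, new)
}

cation_state <- function(ledger) {
  species_state(parent_state(ledger$sites)$states, radical_cation = TRUE)
}

#' Bond dissociation enthalpy (HAT descriptor)
#'
#' Enthalpy of homolytic O-H cleavage at one phenolic site:
#' `H(PhO*) + H(H*) - H(PhOH)`.
#'
#' @param ledger an [enthalpy_ledger()].
#' @param site site label.
#' @param refs [reference_enthalpies()].
#' @return enthalpy in kJ/mol.
#' @export
#' @examples
#' led <- enthalpy_ledger("demo", sites = "X",
#'   entries = c("X:OH" = -1000, "X:O*" = -850))
#' bde(led, "X", reference_enthalpies())   # 155
bde <- function(ledger, site, refs = reference_enthalpies()) {
  ledger_lookup(ledger, single_site_state(ledger, site, "O*")) +
    refs$h_atom - ledger_lookup(ledger, parent_state(ledger$sites))
}

#' Ionization potential (SET-PT first step)
#'
#' Enthalpy of electron loss from the neutral parent:
#' `H(PhOH*+) + H(e-) - H(PhOH)`. Electron loss is a global property of the
#' molecule, so there is exactly one IP per compound.
#'
#' @inheritParams bde
#' @return enthalpy in kJ/mol.
#' @export
ip <- function(ledger, refs = reference_enthalpies()) {
  ledger_lookup(ledger, cation_state(ledger)) + refs$h_electron -
    ledger_lookup(ledger, parent_state(ledger$sites))
}

#' Proton dissociation enthalpy (SET-PT second step)
#'
#' Enthalpy of deprotonating the radical cation at one site:
#' `H(PhO*) + H(H+) - H(PhOH*+)`.
#'
#' @inheritParams bde
#' @return enthalpy in kJ/mol.
#' @export
pde <- function(ledger, site, refs = reference_enthalpies()) {
  ledger_lookup(ledger, single_site_state(ledger, site, "O*")) +
    refs$h_proton - ledger_lookup(ledger, cation_state(ledger))
}

#' Proton affinity (SPLET first step)
#'
#' Enthalpy of deprotonating the parent at one site to the phenoxide:
#' `H(PhO-) + H(H+) - H(PhOH)`.
#'
#' @inheritParams bde
#' @return enthalpy in kJ/mol.
#' @export
pa <- function(ledger, site, refs = reference_enthalpies()) {
  ledger_lookup(ledger, single_site_state(ledger, site, "O-")) +
    refs$h_proton - ledger_lookup(ledger, parent_state(ledger$sites))
}

#' Electron transfer enthalpy (SPLET second step)
#'
#' Enthalpy of electron loss from the phenoxide at one site:
#' `H(PhO*) + H(e-) - H(PhO-)`.
#'
#' @inheritParams bde
#' @return enthalpy in kJ/mol.
#' @export
ete <- function(ledger, site, refs = reference_enthalpies()) {
  ledger_lookup(ledger, single_site_state(ledger, site, "O*")) +
    refs$h_electron -
    ledger_lookup(ledger, single_site_state(ledger, site, "O-"))
}

#' All mechanism descriptors of one compound
#'
#' Computes per-site BDE, PA and ETE and the global IP and PDE of a
#' compound. The global PDE is the minimum per-site PDE (the most favorable
#' deprotonation of the radical cation); per-site values remain available
#' through [pde()].
#'
#' The descriptors obey the thermodynamic cycle identity
#' `IP + PDE = PA + ETE = BDE + (h_proton + h_electron - h_atom)`
#' for every site (same end species, different routes), which serves as an
#' internal consistency check of any ledger.
#'
#' @inheritParams bde
#' @return an object of class `descriptor_set` with elements `compound_id`,
#'   `solvent`, `sites` (data frame: site, bde, pa, ete, pde), `ip`, `pde`
#'   (global) and `equivalent_sites`.
#' @export
descriptor_set <- function(ledger, refs = reference_enthalpies()) {
  stopifnot(inherits(ledger, "enthalpy_ledger"))
  sites <- ledger$sites
  per_site <- data.frame(
    site = sites,
    bde = vapply(sites, function(s) bde(ledger, s, refs), numeric(1)),
    pa = vapply(sites, function(s) pa(ledger, s, refs), numeric(1)),
    ete = vapply(sites, function(s) ete(ledger, s, refs), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  has_cation <- has_state(ledger, cation_state(ledger))
  ip_val <- if (has_cation) ip(ledger, refs) else NA_real_
  if (has_cation) {
    per_site$pde <- vapply(sites, function(s) pde(ledger, s, refs), numeric(1))
    pde_global <- min(per_site$pde)
  } else {
    per_site$pde <- NA_real_
    pde_global <- NA_real_
  }
  structure(
    list(compound_id = ledger$compound_id, solvent = ledger$solvent,
         sites = per_site, ip = ip_val, pde = pde_global,
         equivalent_sites = ledger$equivalent_sites),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> '", x$compound_id, "' (", x$solvent, "), kJ/mol\n",
      sep = "")
  tab <- x$sites
  tab[-1] <- lapply(tab[-1], round_half_up)
  print(tab, row.names = FALSE)
  cat(sprintf("  global IP %s, PDE %s\n",
              format(round_half_up(x$ip)), format(round_half_up(x$pde))))
  invisible(x)
}

#' Descriptor table with equivalent-site averaging
#'
#' Assembles per-site descriptors for a collection of compounds into one
#' data frame and, for sites declared chemically equivalent (e.g. the two
#' outer rings X and X' of a symmetric dendritic antioxidant), adds the
#' group-averaged columns. Equivalence is declared in the ledger metadata
#' (or via `equivalent`), never inferred from enthalpy closeness.
#'
#' For a single-site compound the average equals the site value; sites of a
#' multi-site compound that belong to no declared group get `NA` averages.
#'
#' @param x list of [enthalpy_ledger()] objects or of [descriptor_set()]
#'   objects.
#' @param refs [reference_enthalpies()] (used when `x` holds ledgers).
#' @param equivalent optional named list (by compound id) of equivalence
#'   groups, overriding ledger metadata; every label must be a site of the
#'   compound.
#' @return data frame with columns compound_id, solvent, site, equiv_group,
#'   bde, pa, ete, ip, pde, bde_avg, pa_avg, ete_avg.
#' @export
descriptor_table <- function(x, refs = reference_enthalpies(),
                             equivalent = NULL) {
  if (inherits(x, "enthalpy_ledger") || inherits(x, "descriptor_set")) {
    x <- list(x)
  }
  if (!length(x)) {
    return(data.frame(compound_id = character(0), solvent = character(0),
                      site = character(0), equiv_group = character(0),
                      bde = numeric(0), pa = numeric(0), ete = numeric(0),
                      ip = numeric(0), pde = numeric(0),
                      bde_avg = numeric(0), pa_avg = numeric(0),
                      ete_avg = numeric(0), stringsAsFactors = FALSE))
  }
  sets <- lapply(x, function(el) {
    if (inherits(el, "enthalpy_ledger")) descriptor_set(el, refs) else el
  })
  rows <- lapply(sets, function(ds) {
    tab <- ds$sites
    groups <- ds$equivalent_sites
    if (!is.null(equivalent) && ds$compound_id %in% names(equivalent)) {
      groups <- equivalent[[ds$compound_id]]
      if (!is.list(groups)) groups <- list(groups)
    }
    tab$equiv_group <- NA_character_
    for (col in c("bde", "pa", "ete")) tab[[paste0(col, "_avg")]] <- NA_real_
    if (!is.null(groups)) {
      for (grp in groups) {
        if (!all(grp %in% tab$site)) {
          stop("averaging requested for unknown site(s) of '",
               ds$compound_id, "': ",
               paste(setdiff(grp, tab$site), collapse = ", "), call. = FALSE)
        }
        idx <- tab$site %in% grp
        tab$equiv_group[idx] <- paste(sort(grp), collapse = "|")
        for (col in c("bde", "pa", "ete")) {
          tab[[paste0(col, "_avg")]][idx] <- mean(tab[[col]][idx])
        }
      }
    }
    if (nrow(tab) == 1L) {
      for (col in c("bde", "pa", "ete")) {
        tab[[paste0(col, "_avg")]] <- tab[[col]]
      }
    }
    data.frame(compound_id = ds$compound_id, solvent = ds$solvent,
               site = tab$site, equiv_group = tab$equiv_group,
               bde = tab$bde, pa = tab$pa, ete = tab$ete,
               ip = ds$ip, pde = ds$pde,
               bde_avg = tab$bde_avg, pa_avg = tab$pa_avg,
               ete_avg = tab$ete_avg,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
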