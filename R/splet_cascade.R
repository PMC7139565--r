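# Cumulative multi-site SPLET cascade.
#
# Each step takes one phenolic site from OH to O- (deprotonation, PA) and
# immediately on to O* (electron loss, ETE) before the next site is chosen;
# the cascade ends when every site is a phenoxy radical. Site order is
# greedy by the lowest PA evaluated from the CURRENT, partially oxidized
# species, because earlier deprotonations/oxidations shift the remaining
# sites' enthalpies. The net ETE of a step couples the electron transfer to
# the reduction of the partner radical (DPPH), i.e. raw ETE plus the
# radical-reduction enthalpy.

#' Net (radical-coupled) electron transfer enthalpy
#'
#' The SPLET second step does not happen in isolation: the electron leaving
#' the phenoxide reduces the partner radical (DPPH) in the same event, so
#' the net step enthalpy is the raw ETE plus the radical's reduction
#' enthalpy (-303 kJ/mol for DPPH in methanol).
#'
#' @param ete_raw raw electron transfer enthalpy, kJ/mol.
#' @param refs [reference_enthalpies()].
#' @return net ETE in kJ/mol.
#' @export
#' @examples
#' net_ete(355)   # 52
net_ete <- function(ete_raw, refs = reference_enthalpies()) {
  ete_raw + refs$radical_reduction
}

#' Run the cumulative SPLET cascade
#'
#' Sequentially deprotonates and oxidizes every phenolic site of a compound
#' and accumulates the step enthalpies. With `ordering = "greedy_pa"` the
#' next site is always the remaining protonated site with the lowest PA
#' computed from the current species state (ties broken by site label);
#' a character vector of site labels fixes the order instead.
#'
#' By Hess's law the raw cumulative total depends only on the parent and
#' the all-radical end species, not on the visiting order; the per-step
#' decomposition does depend on it.
#'
#' @param ledger an [enthalpy_ledger()] holding every species the path
#'   visits (a missing intermediate is an error naming the state).
#' @param refs [reference_enthalpies()].
#' @param ordering `"greedy_pa"` or a character vector giving the complete
#'   site order.
#' @return an object of class `cascade_trace`: the per-step table (site,
#'   `pa`, `ete_raw`, `ete_net`, states before/after) and the running
#'   totals `pa_cum`, `ete_cum_raw`, `ete_cum_net`, `dh_cum_raw`,
#'   `dh_cum_net`.
#' @export
run_cascade <- function(ledger, refs = reference_enthalpies(),
                        ordering = "greedy_pa") {
  stopifnot(inherits(ledger, "enthalpy_ledger"))
  sites <- ledger$sites
  greedy <- identical(ordering, "greedy_pa")
  if (!greedy) {
    if (!is.character(ordering) || !setequal(ordering, sites) ||
        length(ordering) != length(sites)) {
      stop("ordering must be \"greedy_pa\" or a permutation of the sites: ",
           paste(sites, collapse = ", "), call. = FALSE)
    }
  }
  state <- parent_state(sites)
  h_here <- ledger_lookup(ledger, state)
  steps <- vector("list", length(sites))
  for (k in seq_along(sites)) {
    remaining <- names(state$states)[state$states == "OH"]
    if (greedy) {
      pa_now <- vapply(remaining, function(s) {
        ledger_lookup(ledger, set_site_state(state, s, "O-")) +
          refs$h_proton - h_here
      }, numeric(1))
      # ties break by site-label order; `remaining` is already label-sorted
      site <- remaining[[which.min(pa_now)]]
      pa_k <- pa_now[[site]]
    } else {
      site <- ordering[[k]]
      if (!site %in% remaining) {
        stop("ordering revisits site '", site, "'", call. = FALSE)
      }
      pa_k <- ledger_lookup(ledger, set_site_state(state, site, "O-")) +
        refs$h_proton - h_here
    }
    anion <- set_site_state(state, site, "O-")
    after <- set_site_state(state, site, "O*")
    h_after <- ledger_lookup(ledger, after)
    ete_raw_k <- h_after + refs$h_electron - ledger_lookup(ledger, anion)
    steps[[k]] <- data.frame(
      step = k, site = site, pa = pa_k, ete_raw = ete_raw_k,
      ete_net = net_ete(ete_raw_k, refs),
      state_before = state_code(state), state_after = state_code(after),
      stringsAsFactors = FALSE
    )
    state <- after
    h_here <- h_after
  }
  steps <- do.call(rbind, steps)
  trace <- list(
    compound_id = ledger$compound_id, solvent = ledger$solvent,
    ordering = if (greedy) "greedy_pa" else "fixed",
    steps = steps,
    pa_cum = sum(steps$pa),
    ete_cum_raw = sum(steps$ete_raw),
    ete_cum_net = sum(steps$ete_net),
    radical_reduction = refs$radical_reduction
  )
  trace$dh_cum_raw <- trace$pa_cum + trace$ete_cum_raw
  trace$dh_cum_net <- trace$pa_cum + trace$ete_cum_net
  structure(trace, class = "cascade_trace")
}

#' @export
print.cascade_trace <- function(x, ...) {
  cat("<cascade_trace> '", x$compound_id, "' (", x$solvent, "), ",
      nrow(x$steps), " steps, ", x$ordering, " ordering\n", sep = "")
  tab <- x$steps[c("step", "site", "pa", "ete_raw", "ete_net")]
  tab[-(1:2)] <- lapply(tab[-(1:2)], round_half_up)
  print(tab, row.names = FALSE)
  cat(sprintf("  PA_cum %.0f  ETE_cum(raw) %.0f  ETE_cum(net) %.0f\n",
              round_half_up(x$pa_cum), round_half_up(x$ete_cum_raw),
              round_half_up(x$ete_cum_net)))
  cat(sprintf("  dH_cum: %.0f kJ/mol coupled, %.0f kJ/mol raw\n",
              round_half_up(x$dh_cum_net), round_half_up(x$dh_cum_raw)))
  invisible(x)
}

#' Naive summed total enthalpy of all sites
#'
#' The sum over sites of parent-state PA + ETE, i.e. every site scored as
#' if it reacted first. The cumulative cascade total equals this exactly
#' when the sites are energetically independent; mutual dependence (ring to
#' ring interaction) makes the cascade total exceed it.
#'
#' @param x a [descriptor_set()] or an [enthalpy_ledger()].
#' @param refs [reference_enthalpies()] (used when `x` is a ledger).
#' @return total enthalpy in kJ/mol.
#' @export
dh_tot <- function(x, refs = reference_enthalpies()) {
  if (inherits(x, "enthalpy_ledger")) x <- descriptor_set(x, refs)
  stopifnot(inherits(x, "descriptor_set"))
  sum(x$sites$pa + x$sites$ete)
}

#' Compare a dendritic compound with its fragments or starting materials
#'
#' Scores a hypothetical mixture of independent mono-phenolic fragments
#' (each taken `multiplicity` times) against the compound's cumulative
#' cascade: fragment PA and ETE are weighted-summed and their total
#' enthalpy is set against the compound's `pa_cum` / `ete_cum_raw` /
#' `dh_cum_raw`.
#'
#' @param cascade a [run_cascade()] trace for the compound.
#' @param fragments data frame with columns `pa`, `ete`, `multiplicity`
#'   (positive integers) and optionally `fragment_id`; or a list of such
#'   records.
#' @return a list with the fragment totals, the compound totals and the
#'   compound-minus-fragments differences.
#' @export
fragment_comparison <- function(cascade, fragments) {
  stopifnot(inherits(cascade, "cascade_trace"))
  if (is.list(fragments) && !is.data.frame(fragments)) {
    fragments <- do.call(rbind, lapply(fragments, as.data.frame))
  }
  if (!is.data.frame(fragments) || !nrow(fragments)) {
    stop("fragments must be a non-empty collection", call. = FALSE)
  }
  if (!all(c("pa", "ete", "multiplicity") %in% names(fragments))) {
    stop("fragments need columns pa, ete, multiplicity", call. = FALSE)
  }
  m <- fragments$multiplicity
  if (any(m != as.integer(m)) || any(m < 1)) {
    stop("multiplicities must be positive integers", call. = FALSE)
  }
  frag_pa <- sum(m * fragments$pa)
  frag_ete <- sum(m * fragments$ete)
  list(
    compound_id = cascade$compound_id,
    fragment_pa = frag_pa, fragment_ete = frag_ete,
    fragment_dh = frag_pa + frag_ete,
    compound_pa = cascade$pa_cum, compound_ete = cascade$ete_cum_raw,
    compound_dh = cascade$dh_cum_raw,
    delta_pa = cascade$pa_cum - frag_pa,
    delta_ete = cascade$ete_cum_raw - frag_ete,
    delta_dh = cascade$dh_cum_raw - (frag_pa + frag_ete)
  )
}

#' Rank compounds by coupled cumulative enthalpy
#'
#' Orders cascade traces ascending by `dh_cum_net` (lower cumulative
#' enthalpy = more favorable overall radical scavenging), ties broken by
#' compound id.
#'
#' @param traces list of [run_cascade()] traces.
#' @return data frame with compound_id, n_steps, pa_cum, ete_cum_net,
#'   ete_cum_raw, dh_cum_net, dh_cum_raw, in rank order.
#' @export
rank_compounds <- function(traces) {
  if (inherits(traces, "cascade_trace")) traces <- list(traces)
  if (!length(traces)) stop("at least one trace is required", call. = FALSE)
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(compound_id = tr$compound_id, n_steps = nrow(tr$steps),
               pa_cum = tr$pa_cum, ete_cum_net = tr$ete_cum_net,
               ete_cum_raw = tr$ete_cum_raw, dh_cum_net = tr$dh_cum_net,
               dh_cum_raw = tr$dh_cum_raw, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$dh_cum_net, tab$compound_id, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}
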