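test_that("net ETE couples the raw step to the partner-radical reduction", {
  expect_equal(net_ete(355, methanol_refs), 52)
  expect_equal(net_ete(303, methanol_refs), 0)
  expect_equal(net_ete(0, methanol_refs), -303)
})

test_that("reconstructed ledgers replay their step values under greedy ordering", {
  refs <- methanol_refs
  set.seed(42)
  for (i in 1:8) {
    n <- sample(2:4, 1)
    pa_in <- stats::runif(n, 60, 160)
    ete_in <- stats::runif(n, 100, 400)
    led <- ledger_from_step_values(pa_in, ete_in, refs, ete_type = "raw")
    tr <- run_cascade(led, refs)
    expect_equal(tr$steps$pa, pa_in, tolerance = 1e-9)
    expect_equal(tr$steps$ete_raw, ete_in, tolerance = 1e-9)
    expect_equal(tr$dh_cum_raw, sum(pa_in) + sum(ete_in), tolerance = 1e-9)
    expect_equal(tr$dh_cum_net, tr$dh_cum_raw + n * refs$radical_reduction)
  }
})

test_that("cumulative totals are path-invariant (Hess's law) but steps are not", {
  refs <- methanol_refs
  for (n in 2:3) {
    led <- generate_ledger(random_spec(101 + n, n_sites = n, noise_sd = 5),
                           refs)
    perms <- all_permutations(led$sites)
    traces <- lapply(perms, function(p) run_cascade(led, refs, ordering = p))
    raws <- vapply(traces, function(tr) tr$dh_cum_raw, numeric(1))
    expect_lt(max(raws) - min(raws), 1e-9)
    greedy <- run_cascade(led, refs)
    expect_equal(greedy$dh_cum_raw, raws[[1]], tolerance = 1e-9)
    # greedy's first deprotonation is the cheapest possible first step
    first_pas <- vapply(traces, function(tr) tr$steps$pa[[1]], numeric(1))
    expect_equal(greedy$steps$pa[[1]], min(first_pas), tolerance = 1e-9)
  }
})

test_that("coupled and raw totals differ by n_steps times the reduction enthalpy", {
  refs <- methanol_refs
  for (seed in 1:5) {
    led <- generate_ledger(random_spec(seed, n_sites = 3, noise_sd = 2), refs)
    tr <- run_cascade(led, refs)
    expect_equal(tr$dh_cum_net - tr$dh_cum_raw,
                 nrow(tr$steps) * refs$radical_reduction)
    expect_equal(tr$dh_cum_net, tr$pa_cum + tr$ete_cum_net)
    expect_equal(tr$dh_cum_raw, tr$pa_cum + tr$ete_cum_raw)
  }
})

test_that("raw cascade total telescopes to the end-species difference", {
  refs <- methanol_refs
  led <- generate_ledger(random_spec(77, n_sites = 3, noise_sd = 4), refs)
  tr <- run_cascade(led, refs)
  n <- length(led$sites)
  all_rad <- species_state(stats::setNames(rep("O*", n), led$sites))
  expect_equal(
    tr$dh_cum_raw,
    ledger_lookup(led, all_rad) - ledger_lookup(led, parent_state(led$sites)) +
      n * (refs$h_proton + refs$h_electron),
    tolerance = 1e-9)
})

test_that("greedy ties break deterministically by site label", {
  refs <- methanol_refs
  spec <- synthetic_spec(n_sites = 2, site_labels = c("B", "A"))
  led <- generate_ledger(spec, refs)  # identical sites -> PA tie at step 1
  tr <- run_cascade(led, refs)
  expect_equal(tr$steps$site, c("A", "B"))
})

test_that("a missing intermediate species fails naming the exact state", {
  refs <- methanol_refs
  led <- ledger_from_step_values(c(150, 147), c(52, 56), refs)
  pruned <- led
  drop <- "S1:O*;S2:O-"
  pruned$entries <- pruned$entries[names(pruned$entries) != drop]
  expect_error(run_cascade(pruned, refs, ordering = c("S1", "S2")),
               "species not computed.*S1:O\\*;S2:O-")
})

test_that("dh_tot sums parent-state PA and ETE over sites", {
  refs <- methanol_refs
  spec <- synthetic_spec(n_sites = 3, pa_base = 100, ete_base = 200)
  led <- generate_ledger(spec, refs)
  expect_equal(dh_tot(led, refs), 900)
  expect_equal(dh_tot(descriptor_set(led, refs)), 900)
})

test_that("non-interacting ledgers make the cascade total equal dh_tot exactly", {
  refs <- methanol_refs
  spec <- synthetic_spec(n_sites = 3, delta_pa = c(-5, 0, 5),
                         delta_ete = c(10, -10, 0), interaction = 0)
  led <- generate_ledger(spec, refs)
  tr <- run_cascade(led, refs)
  expect_equal(tr$dh_cum_raw, dh_tot(led, refs), tolerance = 1e-9)
})

test_that("positive ring-ring interaction raises the cascade total monotonically", {
  refs <- methanol_refs
  gaps <- vapply(c(0, 2, 5, 10), function(eps) {
    spec <- synthetic_spec(n_sites = 3, interaction = eps)
    led <- generate_ledger(spec, refs)
    run_cascade(led, refs)$dh_cum_raw - dh_tot(led, refs)
  }, numeric(1))
  expect_equal(gaps[[1]], 0, tolerance = 1e-9)
  expect_true(all(diff(gaps) > 0))
  # closed form: the gap is the sum of pairwise penalties, 3 pairs here
  expect_equal(gaps, c(0, 2, 5, 10) * 3, tolerance = 1e-9)
})

test_that("fragment comparison scales by multiplicity and reports differences", {
  refs <- methanol_refs
  tr <- run_cascade(ledger_from_step_values(c(150, 147), c(52, 56), refs),
                    refs)
  one <- fragment_comparison(tr, data.frame(pa = 10, ete = 20,
                                            multiplicity = 1))
  expect_equal(one$fragment_dh, 30)
  expect_equal(one$delta_dh, tr$dh_cum_raw - 30)
  tripled <- fragment_comparison(tr, data.frame(pa = 10, ete = 20,
                                                multiplicity = 3))
  expect_equal(tripled$fragment_pa, 30)
  expect_equal(tripled$fragment_ete, 60)
  expect_error(fragment_comparison(tr, data.frame()), "non-empty")
  expect_error(
    fragment_comparison(tr, data.frame(pa = 1, ete = 2, multiplicity = 0.5)),
    "positive integers")
})

test_that("compounds rank ascending by coupled cumulative enthalpy", {
  refs <- methanol_refs
  traces <- lapply(names(benchmark_ledgers(refs)), function(id) {
    run_cascade(benchmark_ledgers(refs)[[id]], refs)
  })
  ranked <- rank_compounds(traces)
  expect_equal(ranked$compound_id,
               c("cpd2", "cpd1", "cpd5", "cpd4", "ref", "cpd3"))
  expect_equal(ranked$dh_cum_net, c(523, 559, 584, 585, 594, 655))
  # ties resolve by compound id; a singleton passes through
  t1 <- traces[[1]]; t2 <- traces[[1]]
  t2$compound_id <- "aaa"
  expect_equal(rank_compounds(list(t1, t2))$compound_id[[1]], "aaa")
  expect_equal(nrow(rank_compounds(list(t1))), 1)
})
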