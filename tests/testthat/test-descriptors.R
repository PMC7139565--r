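test_that("descriptor arithmetic matches hand-computed species sums", {
  led <- enthalpy_ledger(
    "hand", sites = "X",
    entries = c("X:OH" = -1000, "X:O*" = -850, "X:O-" = -900,
                "X:OH+cation" = -600)
  )
  refs <- methanol_refs
  expect_equal(bde(led, "X", refs), -850 + 5 - (-1000))      # 155
  expect_equal(ip(led, refs), -600 - 77 - (-1000))           # 323
  expect_equal(pde(led, "X", refs), -850 - 1071 - (-600))    # -1321
  expect_equal(pa(led, "X", refs), -900 - 1071 - (-1000))    # -971
  expect_equal(ete(led, "X", refs), -850 - 77 - (-900))      # -27
})

test_that("missing species produce missing-species errors, not values", {
  led <- enthalpy_ledger("sparse", sites = "X", entries = c("X:OH" = -1000))
  expect_error(bde(led, "X", methanol_refs), "species not computed")
  expect_error(ip(led, methanol_refs), "species not computed")
  expect_error(pa(led, "X", methanol_refs), "species not computed")
  expect_error(bde(led, "Q", methanol_refs), "unknown site")
})

test_that("two sites with identical species enthalpies give identical descriptors", {
  led <- make_two_site_ledger()
  led$entries[["A:OH;B:O*"]] <- led$entries[["A:O*;B:OH"]]
  led$entries[["A:OH;B:O-"]] <- led$entries[["A:O-;B:OH"]]
  expect_equal(bde(led, "A", methanol_refs), bde(led, "B", methanol_refs))
  expect_equal(pde(led, "A", methanol_refs), pde(led, "B", methanol_refs))
  expect_equal(pa(led, "A", methanol_refs), pa(led, "B", methanol_refs))
})

test_that("thermodynamic cycle closes on arbitrary ledgers", {
  # IP + PDE = PA + ETE = BDE + (h_proton + h_electron - h_atom): same end
  # species by different routes, so closure is exact algebra per site.
  refs <- methanol_refs
  const <- refs$h_proton + refs$h_electron - refs$h_atom
  for (seed in 1:10) {
    led <- generate_ledger(random_spec(seed, n_sites = 3, noise_sd = 3), refs)
    ds <- descriptor_set(led, refs)
    for (i in seq_len(nrow(ds$sites))) {
      s <- ds$sites[i, ]
      expect_equal(ds$ip + s$pde, s$pa + s$ete, tolerance = 1e-9)
      expect_lt(abs((s$pa + s$ete) - (s$bde + const)), 1e-6)
    }
  }
})

test_that("descriptors are invariant under a uniform enthalpy shift", {
  led <- make_two_site_ledger()
  shifted <- led
  shifted$entries <- led$entries + 1234.5678
  for (fn in list(bde, pa, ete, pde)) {
    expect_equal(fn(shifted, "A", methanol_refs), fn(led, "A", methanol_refs))
  }
  expect_equal(ip(shifted, methanol_refs), ip(led, methanol_refs))
})

test_that("relabeling sites permutes but never changes descriptor values", {
  led <- make_two_site_ledger()
  relabeled <- enthalpy_ledger(
    "demo2r", sites = c("P", "Q"),
    entries = stats::setNames(
      unname(led$entries),
      gsub("B", "Q", gsub("A", "P", names(led$entries), fixed = TRUE),
           fixed = TRUE))
  )
  expect_equal(pa(relabeled, "P", methanol_refs), pa(led, "A", methanol_refs))
  expect_equal(ete(relabeled, "Q", methanol_refs), ete(led, "B", methanol_refs))
  ds1 <- descriptor_set(led, methanol_refs)
  ds2 <- descriptor_set(relabeled, methanol_refs)
  expect_equal(sort(ds1$sites$bde), sort(ds2$sites$bde))
  expect_equal(ds1$ip, ds2$ip)
})

test_that("stabilizing the phenoxide by delta lowers PA by exactly delta", {
  led <- make_two_site_ledger()
  delta <- 17.25
  perturbed <- led
  perturbed$entries[["A:O-;B:OH"]] <-
    perturbed$entries[["A:O-;B:OH"]] - delta
  expect_equal(pa(perturbed, "A", methanol_refs),
               pa(led, "A", methanol_refs) - delta)
  # the second SPLET step absorbs the opposite shift
  expect_equal(ete(perturbed, "A", methanol_refs),
               ete(led, "A", methanol_refs) + delta)
})

test_that("descriptor tables average only declared equivalent pairs", {
  spec <- synthetic_spec(n_sites = 3, site_labels = c("X", "X2", "Y"),
                         delta_pa = c(2, 4, -10), delta_ete = c(1, 3, 12),
                         equivalent_sites = list(c("X", "X2")))
  led <- generate_ledger(spec, methanol_refs)
  tab <- descriptor_table(led, methanol_refs)
  expect_equal(tab$pa_avg[tab$site == "X"],
               mean(tab$pa[tab$site %in% c("X", "X2")]))
  expect_true(is.na(tab$pa_avg[tab$site == "Y"]))
  expect_equal(unique(tab$equiv_group[tab$site %in% c("X", "X2")]), "X|X2")
  # identical equivalent sites average to themselves
  spec_eq <- synthetic_spec(n_sites = 2, site_labels = c("X", "X2"),
                            equivalent_sites = list(c("X", "X2")))
  tab_eq <- descriptor_table(generate_ledger(spec_eq, methanol_refs),
                             methanol_refs)
  expect_equal(tab_eq$pa_avg, tab_eq$pa)
  expect_error(
    descriptor_table(led, methanol_refs,
                     equivalent = list("synthetic-seed1" = c("X", "ZZ"))),
    "unknown site")
})
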