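# Shared fixtures: small hand-built ledgers and randomized synthetic specs.

methanol_refs <- reference_enthalpies()

# Two-site compound with hand-picked enthalpies; every species present.
make_two_site_ledger <- function(compound_id = "demo2") {
  enthalpy_ledger(
    compound_id, sites = c("A", "B"),
    entries = c(
      "A:OH;B:OH" = -1000,
      "A:O-;B:OH" = 221, "A:OH;B:O-" = 231,
      "A:O*;B:OH" = 650, "A:OH;B:O*" = 660,
      "A:O-;B:O-" = 1455, "A:O-;B:O*" = 1884,
      "A:O*;B:O-" = 1890, "A:O*;B:O*" = 2320,
      "A:OH;B:OH+cation" = -453
    )
  )
}

# Randomized synthetic spec for property-style loops.
random_spec <- function(seed, n_sites = 3, noise_sd = 0) {
  set.seed(seed)
  synthetic_spec(
    n_sites = n_sites,
    delta_pa = stats::runif(n_sites, -30, 30),
    delta_ete = stats::runif(n_sites, -40, 40),
    ip_value = 470 + stats::runif(1, -20, 20),
    interaction = abs(stats::runif(1, 0, 10)),
    noise_sd = noise_sd, seed = seed
  )
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[[i]], rest)
  }
  out
}
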