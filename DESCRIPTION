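Package: spletcascade
Title: Multi-Site SPLET Thermochemistry for Dendritic Phenolic Antioxidants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the thermochemical descriptors of the three proposed
    radical-scavenging mechanisms of phenolic antioxidants (bond dissociation
    enthalpy for HAT, ionization potential and proton dissociation enthalpy
    for SET-PT, proton affinity and electron transfer enthalpy for SPLET)
    from tables of species enthalpies, runs the cumulative multi-site SPLET
    cascade for dendritic (multi-phenol) antioxidants with greedy lowest-PA
    site ordering and partner-radical (DPPH) coupling, compares mechanism
    preference by rate-limiting step enthalpy, and correlates cumulative
    enthalpies with experimental IC50 values via Pearson correlation and
    Fisher-Z confidence intervals. Includes readers and writers for
    species-state enthalpy ledgers, a scraper for quantum-chemistry log
    thermochemistry, and a seeded synthetic-ledger generator with
    substituent offsets and ring-ring interaction terms for testing every
    pipeline stage without quantum-chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
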