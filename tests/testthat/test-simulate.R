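# The codon-evolution simulator: contracts, determinism, and recovery of
# planted rates by the estimator it is meant to exercise.

test_that("ancestral CDS generation honours its contract", {
  cds <- generate_ancestral_cds(1, 100, seed = 7)
  expect_equal(nchar(cds[[1]]), 300)
  expect_equal(substr(cds[[1]], 1, 3), "ATG")
  codons <- split_codons(cds[[1]])
  aas <- Biostrings::GENETIC_CODE[codons]
  expect_equal(unname(aas[length(aas)]), "*")
  expect_false(any(aas[-length(aas)] == "*"))
  expect_error(generate_ancestral_cds(0, 100), "n_genes")
})

test_that("generation is deterministic in the seed", {
  expect_identical(generate_ancestral_cds(5, 100, seed = 7),
                   generate_ancestral_cds(5, 100, seed = 7))
  expect_false(identical(generate_ancestral_cds(1, 100, seed = 7),
                         generate_ancestral_cds(1, 100, seed = 8)))
})

test_that("zero-distance evolution is the identity", {
  cds <- generate_ancestral_cds(1, 80, seed = 2)[[1]]
  pair <- evolve_pair(cds, 0, 1, seed = 4)
  expect_identical(pair$cds_a, cds)
  expect_identical(pair$cds_b, cds)
  expect_error(evolve_pair(cds, -0.1, 1), "target_ks")
  expect_error(evolve_pair(cds, 0.1, 0), "omega")
})

test_that("evolved sequences stay valid coding sequences", {
  cds <- generate_ancestral_cds(20, 100, seed = 5)
  set.seed(6)
  for (x in cds) {
    pair <- evolve_pair(x, 0.3, 0.5)
    for (y in c(pair$cds_a, pair$cds_b)) {
      expect_equal(nchar(y), nchar(x))
      aas <- Biostrings::GENETIC_CODE[split_codons(y)]
      expect_false(any(aas[-length(aas)] == "*"))
    }
  }
})

test_that("planted Ks and omega are recovered by the NG estimator", {
  set.seed(31)
  anc <- generate_ancestral_cds(150, 150, seed = 31)
  est <- t(vapply(anc, function(cds) {
    p <- evolve_pair(cds, 0.1, 0.3)
    r <- ng_rates(split_codons(p$cds_a)[-150], split_codons(p$cds_b)[-150])
    c(ks = r$Ks, ka = r$Ka)
  }, numeric(2)))
  mean_ks <- mean(est[, "ks"], na.rm = TRUE)
  mean_omega <- mean(est[, "ka"], na.rm = TRUE) / mean_ks
  expect_lt(abs(mean_ks - 0.1) / 0.1, 0.2)
  expect_lt(abs(mean_omega - 0.3) / 0.3, 0.3)
})

test_that("planted-vs-estimated Ks is consistent across the Ks range", {
  # regression of estimated on planted Ks over [0.02, 1]; the estimator
  # should be close to unbiased where JC correction holds
  set.seed(33)
  planted <- rep(c(0.02, 0.1, 0.3, 0.6, 1.0), each = 24)
  anc <- generate_ancestral_cds(length(planted), 120, seed = 33)
  est <- vapply(seq_along(planted), function(i) {
    p <- evolve_pair(anc[[i]], planted[i], 0.3)
    ng_rates(split_codons(p$cds_a)[-120], split_codons(p$cds_b)[-120])$Ks
  }, numeric(1))
  ok <- !is.na(est)
  slope <- stats::coef(stats::lm(est[ok] ~ planted[ok]))[[2]]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("scenario bookkeeping: speciation only", {
  sc <- two_species_scenario(ks = 0.05, n_families = 50, seed = 17)
  sim <- simulate_scenario(sc)
  expect_equal(sum(sim$truth$relation == "ortholog"), 50)
  expect_equal(sum(sim$truth$relation == "paralog"), 0)
  expect_equal(as.integer(table(sim$genes$species)[c("s1", "s2")]),
               c(50L, 50L))
})

test_that("scenario bookkeeping: WGD before speciation, full retention", {
  sc <- two_species_scenario(ks = 0.05, n_families = 40, wgd_ks = 0.1,
                             retention_prob = 1, seed = 18)
  sim <- simulate_scenario(sc)
  expect_equal(as.integer(table(sim$genes$species)[c("s1", "s2")]),
               c(80L, 80L))
  paralogs <- sim$truth[sim$truth$relation == "paralog", ]
  expect_equal(nrow(paralogs), 80)  # one pair per species per family
  expect_true(all(paralogs$planted_ks == 0.1))
})

test_that("scenarios are reproducible and reject unknown lineages", {
  sc <- two_species_scenario(n_families = 5, seed = 19)
  expect_identical(simulate_scenario(sc)$genes,
                   simulate_scenario(sc)$genes)
  expect_error(
    evol_scenario(species = c("s1", "s2"),
                  events = list(list(kind = "wgd", lineage = "nope",
                                     ks = 0.1),
                                list(kind = "speciation", lineage = "root",
                                     into = c("s1", "s2"), ks = 0.05))),
    "unknown lineage")
})
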