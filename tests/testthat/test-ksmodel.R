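# Exclusion ledger, mixture fitting, peak extraction, clock dating, and
# the selection screen.

fake_rates <- function(flags, ks) {
  data.frame(gene_a = paste0("a", seq_along(flags)),
             gene_b = paste0("b", seq_along(flags)),
             Sd = ifelse(flags %in% c("identical", "only_nonsyn"), 0, 2),
             Nd = ifelse(flags %in% c("identical", "only_syn"), 0, 2),
             Ka = 0.01, Ks = ks, omega = 0.5, p_value = 0.5,
             flag = flags, stringsAsFactors = FALSE)
}

test_that("the ledger partitions crafted pairs one per category", {
  rates <- fake_rates(
    c("identical", "ks_undefined", "only_nonsyn", "only_syn", "ok", "ok"),
    c(0, NA, 0, 0.05, 0.5, 0.05))
  res <- apply_exclusion_ledger(rates, ks_cutoff = 0.1)
  led <- res$ledger
  expect_equal(led$n_input, 6)
  expect_equal(led$n_identical, 1)
  expect_equal(led$n_ks_undefined, 1)
  expect_equal(led$n_only_nonsyn, 1)
  expect_equal(led$n_only_syn, 1)
  expect_equal(led$n_ks_above_cutoff, 1)
  expect_equal(led$n_retained, 1)
  expect_equal(res$retained$gene_a, "a6")
  # partition invariant
  expect_equal(led$n_input,
               led$n_identical + led$n_ks_undefined + led$n_only_nonsyn +
                 led$n_only_syn + led$n_ks_above_cutoff + led$n_retained)
})

test_that("an infinite cutoff disables the Ks filter", {
  rates <- fake_rates(c("ok", "ok"), c(0.5, 3))
  res <- apply_exclusion_ledger(rates, ks_cutoff = Inf)
  expect_equal(res$ledger$n_ks_above_cutoff, 0)
  expect_equal(res$ledger$n_retained, 2)
})

test_that("ledger arithmetic reproduces published-style bookkeeping", {
  led <- exclusion_ledger(4512, n_identical = 137, n_ks_undefined = 53,
                          n_only_nonsyn = 118, n_only_syn = 630,
                          n_ks_above_cutoff = 990)
  expect_equal(led$n_retained, 2584)
  expect_error(exclusion_ledger(10, n_identical = 20), "exceed")
})

test_that("a single log-normal component is recovered", {
  set.seed(61)
  ks <- stats::rlnorm(1000, log(0.1), 0.3)
  fit <- fit_log_gaussian_mixture(ks, k_candidates = 1:3)
  expect_equal(fit$k, 1)
  expect_gt(fit$components$ks_peak, 0.09)
  expect_lt(fit$components$ks_peak, 0.11)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
  # chosen model has the lowest BIC among candidates
  expect_equal(fit$bic, min(fit$candidates$bic))
})

test_that("a two-component mixture separates well-spaced modes", {
  set.seed(62)
  ks <- c(stats::rlnorm(1000, log(0.05), 0.25),
          stats::rlnorm(1000, log(0.5), 0.25))
  fit <- fit_log_gaussian_mixture(ks, k_candidates = 1:3)
  expect_equal(fit$k, 2)
  peaks <- sort(fit$components$ks_peak)
  expect_lt(abs(peaks[1] - 0.05) / 0.05, 0.2)
  expect_lt(abs(peaks[2] - 0.5) / 0.5, 0.2)
})

test_that("mixture fitting agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(63)
  ks <- stats::rlnorm(600, log(0.2), 0.4)
  fit <- fit_log_gaussian_mixture(ks, k_candidates = 1)
  mc <- Mclust(log(ks[ks >= 0.005 & ks <= 2]), G = 1,
               modelNames = "V", verbose = FALSE)
  expect_equal(fit$components$mu, unname(mc$parameters$mean),
               tolerance = 1e-3)
})

test_that("too little data is refused", {
  expect_error(fit_log_gaussian_mixture(stats::rlnorm(10, log(0.1), 0.2)),
               "need >= 20")
})

test_that("fitting is deterministic", {
  set.seed(64)
  ks <- stats::rlnorm(400, log(0.1), 0.5)
  f1 <- fit_log_gaussian_mixture(ks, k_candidates = 1:3)
  f2 <- fit_log_gaussian_mixture(ks, k_candidates = 1:3)
  expect_identical(f1$components, f2$components)
})

test_that("peaks respect the weight threshold and flag the dominant one", {
  fit <- structure(list(components = data.frame(
    weight = c(0.05, 0.95), mu = log(c(0.75, 0.1)),
    sigma = c(0.3, 0.2), ks_peak = c(0.75, 0.1))),
    class = "ks_mixture_fit")
  pk <- find_peaks(fit, min_weight = 0.10)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$ks_peak, 0.1)
  expect_true(pk$dominant)
  pk2 <- find_peaks(fit, min_weight = 0.01)
  expect_equal(pk2$ks_peak, c(0.1, 0.75))
  expect_equal(pk2$dominant, c(TRUE, FALSE))
})

test_that("clock dating reproduces the standard dicot-rate ages", {
  expect_equal(round(date_event(0.5)$T_my, 1), 16.7)
  expect_equal(round(date_event(0.1)$T_my, 1), 3.3)
  expect_equal(round(date_event(0.05)$T_my, 1), 1.7)
  expect_equal(date_event(0)$T_my, 0)
  expect_error(date_event(0.5, rate = 0), "rate")
})

test_that("dating is linear in the peak position", {
  for (ks in c(0.01, 0.2, 0.9)) {
    expect_equal(date_event(2 * ks)$T_my, 2 * date_event(ks)$T_my)
  }
})

test_that("selection classes split at omega = 1", {
  retained <- data.frame(
    gene_a = c("a", "b", "c"), gene_b = c("x", "y", "z"),
    Ka = c(0.01, 0.05, 0.02), Ks = c(0.03, 0.03, 0.02),
    omega = c(0.3, 1.5, 1.0), p_value = c(0.01, 0.2, 0.5),
    stringsAsFactors = FALSE)
  res <- classify_selection(retained)
  expect_equal(res$calls$class, c("purifying", "positive", "purifying"))
  gated <- classify_selection(retained, require_significance = TRUE)
  expect_equal(gated$calls$class, rep("purifying", 3))
  retained$omega[2] <- NA
  expect_error(classify_selection(retained), "without defined")
})

test_that("summary percentages are reported to two decimals", {
  pct <- selection_percentages(2477, 107)
  expect_equal(pct$pct_purifying, 95.86)
  expect_equal(pct$pct_positive, 4.14)
})

test_that("simulated purifying pairs are classified as purifying", {
  set.seed(66)
  anc <- generate_ancestral_cds(60, 120, seed = 66)
  rates <- do.call(rbind, lapply(seq_along(anc), function(i) {
    p <- evolve_pair(anc[[i]], 0.08, 0.3)
    r <- ng_rates(split_codons(p$cds_a), split_codons(p$cds_b))
    data.frame(gene_a = paste0("a", i), gene_b = paste0("b", i),
               Ka = r$Ka, Ks = r$Ks, omega = r$omega,
               p_value = r$p_value, Sd = r$Sd, Nd = r$Nd, flag = r$flag,
               stringsAsFactors = FALSE)
  }))
  scr <- apply_exclusion_ledger(rates, ks_cutoff = Inf)
  res <- classify_selection(scr$retained)
  expect_gte(res$summary$pct_purifying, 80)
})
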