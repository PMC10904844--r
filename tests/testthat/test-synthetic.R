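# Synthetic-data generators: reproducibility, planted-signal recovery,
# null calibration, and trace round-trips.

make_specs <- function(n_cohorts = 4, n_genes = 300, n = 10, noise_sd = 0.5) {
  lapply(seq_len(n_cohorts), function(i)
    cohort_spec(sprintf("c%02d", i), n_genes, n, n,
                noise_sd = noise_sd, seed = 100 + i))
}

test_that("fixed seeds give bit-identical cohorts and traces", {
  truth <- planted_truth(up_genes = gene_universe(300)[1:5],
                         effect_size = 2, penetrance = 0.5)
  a <- simulate_cohorts(make_specs(), truth, carrier_seed = 7)
  b <- simulate_cohorts(make_specs(), truth, carrier_seed = 7)
  expect_identical(a, b)
  expect_identical(simulate_plate_traces(seed = 3),
                   simulate_plate_traces(seed = 3))
  expect_identical(simulate_survival(50, 0.4, 0.2, seed = 5),
                   simulate_survival(50, 0.4, 0.2, seed = 5))
})

test_that("planted effects are recovered within 3 standard errors", {
  genes <- gene_universe(300)
  truth <- planted_truth(up_genes = genes[1:10], down_genes = genes[11:20],
                         effect_size = 2.5, penetrance = 1)
  sim <- simulate_cohorts(make_specs(noise_sd = 0.4), truth)
  se <- 0.4 * sqrt(1 / 10 + 1 / 10)
  for (co in sim$cohorts) {
    de <- differential_expression(co)
    expect_true(all(abs(de$log2fc[1:10] - 2.5) < 3 * se))
    expect_true(all(abs(de$log2fc[11:20] + 2.5) < 3 * se))
  }
})

test_that("penetrance controls the fraction of carrier cohorts", {
  genes <- gene_universe(500)
  truth <- planted_truth(up_genes = genes[1:200], effect_size = 3,
                         penetrance = 0.8)
  sim <- simulate_cohorts(make_specs(n_cohorts = 10, n_genes = 500), truth,
                          carrier_seed = 11)
  carriers <- as.matrix(sim$truth[1:200, -(1:3)])
  expect_equal(mean(carriers), 0.8, tolerance = 0.05)
  # null genes never carry an effect
  expect_true(all(!as.matrix(sim$truth[201:500, -(1:3)])))
})

test_that("null-gene p-values are approximately uniform (KS at alpha = 0.01)", {
  spec <- cohort_spec("null", 1500, 10, 10, noise_sd = 0.5, seed = 42)
  sim <- simulate_cohorts(list(spec), planted_truth())
  de <- differential_expression(sim$cohorts[[1]])
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generator validates its inputs", {
  expect_error(simulate_cohorts(list()), "empty")
  truth <- planted_truth(up_genes = "not_a_gene", effect_size = 2)
  expect_error(simulate_cohorts(make_specs(), truth), "absent from the universe")
  expect_error(cohort_spec("x", 10, 1, 5), "n_tumor")
  expect_error(cohort_spec("x", 10, 5, 5, noise_sd = 0), "noise_sd")
  expect_error(planted_truth(up_genes = "g", effect_size = -1), "effect_size")
  expect_error(simulate_survival(50, Inf), "finite")
  expect_error(simulate_survival(5, 0), "n >= 10")
})

test_that("survival generator: exponential mean, hazard link, truncation", {
  # beta = 0, no censoring: empirical mean ~ 1/lambda (law of large numbers)
  s <- simulate_survival(4000, 0, 0, seed = 9, baseline_rate = 0.1,
                         horizon = Inf)
  expect_equal(mean(s$time), 10, tolerance = 0.5)
  expect_true(all(s$time > 0) && all(s$event == 1L))
  # beta > 0, no censoring: high-expression stratum dies sooner
  s2 <- simulate_survival(600, 0.8, 0, seed = 10)
  strat <- stratify_by_expression(s2, "median")
  expect_lt(median(strat$time[strat$stratum == "high"]),
            median(strat$time[strat$stratum == "low"]))
  # administrative censoring at the horizon
  expect_true(all(s2$time <= 60))
  expect_true(all(s2$event[s2$time == 60] == 0L))
})

test_that("plate traces: noiseless round-trip is exact, noisy within CLT bound", {
  prof <- bioenergetic_profile(noise_sd = 0)
  tr <- simulate_plate_traces(seed = 1, profile = prof)
  mito <- summarize_trace(tr$mito, "mito")
  expect_equal(unname(mito$ocr),
               unname(prof$mito$ocr[c("baseline", "post_oligomycin",
                                      "post_uncoupler", "post_rotAA")]))
  m <- mito_metrics(mito)
  expect_equal(unname(m), c(80, 60, 20, 160, 80))
  g <- glyco_metrics(summarize_trace(tr$glyco, "glyco"))
  expect_equal(unname(g), c(50, 80, 30))

  prof2 <- bioenergetic_profile(noise_sd = 2)
  tr2 <- simulate_plate_traces(seed = 2, profile = prof2, n_wells = 5,
                               points_per_phase = 3)
  mito2 <- summarize_trace(tr2$mito, "mito")
  n_pts <- 5 * 3
  expect_true(all(abs(mito2$ocr - prof2$mito$ocr) <= 3 * 2 / sqrt(n_pts)))
})

test_that("all plateaus equal gives zero ATP-linked and zero spare capacity", {
  prof <- bioenergetic_profile(noise_sd = 0)
  prof$mito$ocr[] <- 50
  tr <- simulate_plate_traces(seed = 1, profile = prof)
  m <- mito_metrics(summarize_trace(tr$mito, "mito"))
  expect_equal(unname(m), c(0, 0, 0, 0, 0))
})

test_that("trace summary rejects a missing phase", {
  tr <- simulate_plate_traces(seed = 1)
  broken <- tr$mito[tr$mito$phase != "post_uncoupler", ]
  expect_error(summarize_trace(broken, "mito"), "missing phase")
})
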