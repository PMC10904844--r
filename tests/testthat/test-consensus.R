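# Cross-cohort metabolic consensus: restriction, adaptive cutoff,
# direction classification, and the exclusive vote.

fake_table <- function(genes, log2fc, p_value = rep(1e-6, length(genes)),
                       cohort_id = "c1", gate = TRUE) {
  df <- data.frame(gene = genes, log2fc = log2fc, p_value = p_value,
                   passes_gate = NA, stringsAsFactors = FALSE)
  attr(df, "cohort_id") <- cohort_id
  class(df) <- c("diffexp_table", "data.frame")
  if (gate) apply_de_gate(df) else df
}

test_that("metabolic restriction keeps exactly the gated genes in the set", {
  tab <- fake_table(paste0("g", 1:5), c(2, -2, 3, 2.5, -1.8))
  out <- restrict_to_metabolic(tab, c("g1", "g3", "g5"))
  expect_equal(out$gene, c("g1", "g3", "g5"))
  # empty intersection is valid and yields an empty table
  expect_message(out0 <- restrict_to_metabolic(tab, "absent_gene"),
                 "no gated genes")
  expect_equal(nrow(out0), 0)
  # gate interacts: a non-passing gene is dropped even if in the set
  tab2 <- fake_table(c("g1", "g2"), c(2, 0.5))
  expect_equal(restrict_to_metabolic(tab2, c("g1", "g2"))$gene, "g1")
  # independent oracle: plain set filter on a larger random instance
  set.seed(8)
  genes <- paste0("g", 1:200)
  tab3 <- fake_table(genes, runif(200, 1.6, 4) * sign(rnorm(200)))
  setg <- sample(genes, 60)
  expect_equal(restrict_to_metabolic(tab3, setg)$gene,
               genes[genes %in% setg])
})

test_that("adaptive cutoff is the mean absolute log2FC of gate passers", {
  tab <- fake_table(paste0("g", 1:4), c(1.6, 2.0, -1.8, -2.6))
  expect_equal(adaptive_cutoff(tab), 2.0)
  expect_equal(adaptive_cutoff(fake_table("g1", -3)), 3)
  # genes failing the gate do not enter the average
  tab2 <- fake_table(paste0("g", 1:3), c(1.6, 2.4, 0.5))
  expect_equal(adaptive_cutoff(tab2), 2.0)
  expect_error(adaptive_cutoff(fake_table("g1", 0.2)), "no DEGs")
})

test_that("cutoff on a planted cohort sits within 3 SE of the planted effect", {
  spec <- cohort_spec("c1", 600, 15, 15, noise_sd = 0.4, seed = 21)
  genes <- gene_universe(600)
  truth <- planted_truth(up_genes = genes[1:30], down_genes = genes[31:60],
                         effect_size = 2.8, penetrance = 1)
  sim <- simulate_cohorts(list(spec), truth)
  gated <- apply_de_gate(differential_expression(sim$cohorts[[1]]))
  se <- 0.4 * sqrt(2 / 15) / sqrt(60)
  expect_lt(abs(adaptive_cutoff(gated) - 2.8), 3 * se + 0.02)
})

test_that("direction boundaries are inclusive: at-or-above / at-or-below", {
  tab <- fake_table(paste0("g", 1:5), c(2.0, -2.0, 0, 1.99, -1.99))
  dir <- classify_direction(tab, 2.0)
  expect_equal(unname(dir), c("up", "down", "ns", "ns", "ns"))
  expect_error(classify_direction(tab, 0), "positive")
})

test_that("the vote requires >= min_datasets in one exclusive direction", {
  dirs <- function(...) {
    v <- c(...)
    lapply(seq_along(v), function(i) setNames(v[i], "g1"))
  }
  up10 <- consensus_vote(dirs(rep("up", 10)))
  expect_equal(up10$status, "consistent_up")
  up8ns2 <- consensus_vote(dirs(rep("up", 8), rep("ns", 2)))
  expect_equal(up8ns2$status, "consistent_up")
  # one opposite call voids the consensus even with 8 agreeing
  mixed <- consensus_vote(dirs(rep("up", 8), "down", "ns"))
  expect_equal(mixed$status, "not_consistent")
  up7 <- consensus_vote(dirs(rep("up", 7), rep("ns", 3)))
  expect_equal(up7$status, "not_consistent")
  # a gene absent from some cohorts counts ns there
  calls <- c(lapply(1:8, function(i) c(g1 = "up", g2 = "up")),
             lapply(1:2, function(i) c(g2 = "down")))
  both <- consensus_vote(calls)
  expect_equal(both$status[both$gene == "g1"], "consistent_up")
  expect_equal(both$status[both$gene == "g2"], "not_consistent")
  expect_error(consensus_vote(dirs("up"), n_datasets = 10, min_datasets = 11),
               "min_datasets")
})

test_that("negating all log2fc swaps up and down consensus calls", {
  set.seed(14)
  genes <- paste0("g", 1:80)
  tabs <- lapply(1:10, function(i)
    fake_table(genes, rnorm(80, 0, 3), cohort_id = paste0("c", i),
               gate = FALSE))
  run <- function(tabs) {
    calls <- lapply(tabs, function(tb) {
      g <- apply_de_gate(tb)
      classify_direction(g, adaptive_cutoff(g))
    })
    names(calls) <- paste0("c", 1:10)
    consensus_vote(calls, 10, 6)
  }
  fwd <- run(tabs)
  rev <- run(lapply(tabs, function(tb) { tb$log2fc <- -tb$log2fc; tb }))
  expect_equal(rev$status[rev$status != "not_consistent"] ==
                 "consistent_up",
               fwd$status[fwd$status != "not_consistent"] ==
                 "consistent_down")
  expect_equal(fwd$gene[fwd$status == "consistent_up"],
               rev$gene[rev$status == "consistent_down"])
  expect_equal(fwd$gene[fwd$status == "not_consistent"],
               rev$gene[rev$status == "not_consistent"])
})

test_that("raising min_datasets never adds consistent genes", {
  set.seed(15)
  calls <- lapply(1:10, function(i) {
    v <- sample(c("up", "down", "ns"), 50, replace = TRUE,
                prob = c(0.45, 0.15, 0.4))
    setNames(v, paste0("g", 1:50))
  })
  prev <- NULL
  for (k in 5:10) {
    cons <- consensus_vote(calls, 10, k)
    got <- cons$gene[cons$status != "not_consistent"]
    if (!is.null(prev)) expect_true(all(got %in% prev))
    prev <- got
  }
})

test_that("the full wrapper recovers penetrant planted genes per the binomial tail", {
  # strong planted signal, penetrance 0.8: a planted gene carries its
  # effect in ~Bin(10, 0.8) cohorts; classification against the adaptive
  # cutoff then decides the per-cohort call. The carrier count sets a hard
  # upper envelope: no gene can be consistent in more cohorts than it
  # carries the effect in.
  genes <- gene_universe(800)
  specs <- lapply(1:10, function(i)
    cohort_spec(paste0("c", i), 800, 20, 20, noise_sd = 0.5, seed = 300 + i))
  truth <- planted_truth(up_genes = genes[1:60], down_genes = genes[61:120],
                         effect_size = 3, penetrance = 0.8)
  sim <- simulate_cohorts(specs, truth, carrier_seed = 19)
  tables <- lapply(sim$cohorts, differential_expression)
  cons <- metabolic_consensus(tables, genes[1:400], min_datasets = 8)
  planted <- cons[cons$gene %in% genes[1:120], ]
  carriers <- rowSums(as.matrix(sim$truth[1:120, -(1:3)]))
  consistent <- planted$status != "not_consistent"
  # envelope: consistency implies >= 8 carrier cohorts
  expect_true(all(carriers[match(planted$gene[consistent],
                                 sim$truth$gene[1:120])] >= 8))
  # direction is never flipped
  expect_true(all(planted$status[planted$gene %in% genes[1:60]] %in%
                    c("consistent_up", "not_consistent")))
  expect_true(all(planted$status[planted$gene %in% genes[61:120]] %in%
                    c("consistent_down", "not_consistent")))
  # null metabolic genes are never consistent here (gate at 9.5 sigma)
  nulls <- cons[!(cons$gene %in% genes[1:120]), ]
  expect_true(all(nulls$status == "not_consistent"))
})
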