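# hccflux

Computational pipeline for studies of tumor metabolic reprogramming in
hepatocellular carcinoma (HCC). Many such studies combine four analyses
that are rarely available as tested, reusable code:

1. **Cross-cohort consensus calling of tumor-altered metabolic genes** —
   per-cohort two-group differential expression (Welch *t* on log2
   intensities) gated at raw *P* < 0.001 and |log2FC| > 1.5, restricted to
   a metabolism-annotated gene list, classified up/down against a
   per-cohort *adaptive cutoff* (the mean |log2FC| of that cohort's
   gate-passing genes), and voted across cohorts: a gene is *consistently
   altered* if it falls exclusively in one direction in ≥ 8 of 10 cohorts.
2. **¹³C isotopologue route prediction** — an exact, atom-mapped label
   propagation engine for central carbon metabolism (glycolysis, PDH/PC
   entry into the TCA cycle, oxidative/reductive glutamine metabolism,
   oxidative and non-oxidative pentose phosphate pathway) that computes
   mass isotopologue distributions (MIDs) f(m+0)…f(m+C) along declared
   routes, with explicit unlabeled-pool assumptions.
3. **Expression-stratified survival analysis** — Kaplan–Meier
   product-limit estimation and the log-rank (Mantel–Cox) test,
   implemented from the formulas, with median (bottom 50% vs top 50%) or
   tertile stratification and a 60-month follow-up horizon.
4. **ATP-rate partitioning** — Seahorse-style mito/glycolysis stress-test
   metrics and conversion of OCR/ECAR into oxidative vs glycolytic ATP
   production rates (J_ox = 2·P/O·ATP-linked OCR;
   J_glyc from the CO2-corrected proton efflux).

A synthetic-data module generates every input the pipeline consumes
(multi-cohort expression with planted effects, survival tables with an
expression-linked hazard, plate traces with injection phases), so the
whole pipeline is testable end-to-end without downloads, and `run_all()`
produces a byte-reproducible demonstration run with a digest manifest.

Everything is base R plus `jsonlite`; the `survival` package is used only
as an independent oracle in the test suite.

## Worked example

Cross-cohort consensus on synthetic cohorts (10 cohorts, 20 tumor vs 20
normal, noise sd 0.5) with 30 strongly altered metabolic genes
(|log2FC| 2.8–4) over a background of 120 moderate DEGs (1.7–2.3),
penetrance 0.9:

```r
library(hccflux)
set.seed(1)
genes <- gene_universe(1200)
truth <- planted_truth(
  up_genes   = c(genes[1:15],  genes[301:360]),
  down_genes = c(genes[16:30], genes[361:420]),
  effect_size = c(runif(15, 2.8, 4), runif(60, 1.7, 2.3),
                  runif(15, 2.8, 4), runif(60, 1.7, 2.3)),
  penetrance = 0.9)
specs <- lapply(1:10, function(i)
  cohort_spec(sprintf("c%02d", i), 1200, 20, 20, noise_sd = 0.5, seed = i))
sim    <- simulate_cohorts(specs, truth, metabolic_ids = genes[1:300])
tables <- lapply(sim$cohorts, differential_expression)
cons   <- metabolic_consensus(tables, genes[1:300], min_datasets = 8)
cons
#> Consensus calls over 30 genes (>= 8 of 10 cohorts, exclusive direction)
#>   consistent_up: 15, consistent_down: 14, not_consistent: 1
round(attr(cons, "cutoffs"), 2)
#>  c01  c02  c03  c04  c05  c06  c07  c08  c09  c10
#> 2.27 2.30 2.33 2.30 2.29 2.29 2.28 2.27 2.30 2.28
```

The moderate background drags each cohort's adaptive cutoff to ≈ 2.3, so
the strongly altered metabolic genes are classified decisively and
29 of 30 survive the exclusive ≥ 8/10 vote (the background genes are
non-metabolic and are filtered out before voting).

Tracer predictions for U-¹³C₅-glutamine:

```r
net <- build_default_network(); rts <- default_routes()
predict_named_routes("U-13C5-glutamine", net, rts)[, c("route", "metabolite", "mass_shift")]
#>               route metabolite mass_shift
#> 1     gls_glutamate  glutamate          5
#> 2           gln_akg        akg          5
#> 3  gln_ox_succinate  succinate          4
#> 4   gln_ox_fumarate   fumarate          4
#> 5     gln_ox_malate     malate          4
#> 6  gln_ox_aspartate  aspartate          4
#> 7    gln_ox_citrate    citrate          4
#> 8   gln_red_citrate    citrate          5
#> 9 gln_red_aspartate  aspartate          3
```

Oxidative glutaminolysis yields the m+4 series (one CO2 lost from m+5
α-ketoglutarate); reductive carboxylation yields m+5 citrate and, after
ATP-citrate lyase cleavage and transamination, m+3 aspartate — the
signatures used to apportion the two routes from measured citrate MIDs
(`mid_fit_weights()` recovers mixture weights to 1e-9).

Survival and bioenergetics on synthetic inputs:

```r
co <- simulate_survival(200, beta = 0.5, censor_rate = 0.2, seed = 7)
survival_comparison(co, "median")$test
#> Log-rank (Mantel-Cox) test: chi-square = 8.0397 (1 df), p = 0.004576
#>   observed events A/B: 62/72, expected: 78.10/55.90

tr <- simulate_plate_traces(seed = 1)
mm <- mito_metrics(summarize_trace(tr$mito, "mito"))
round(mm, 1)
#>       basal  atp_linked proton_leak     maximal       spare
#>        80.1        60.0        20.1       161.5        81.4
atp_partition(mm[["atp_linked"]],
              summarize_trace(tr$glyco, "glyco")$ecar[["post_glucose"]])
#> ATP production: glycolytic 769.9 + oxidative 298.2 = 1068.1 pmol ATP/min
#>   glycolytic fraction: 72.1%
```

Here the high-expression stratum has significantly worse survival (the
generator's hazard increases with expression), and the simulated
glycolytic cell profile derives ~72% of its ATP from glycolysis.

An end-to-end run writing every stage's files plus a digest manifest:

```r
run_all(run_config(seed = 1, out_dir = "demo_run"))
```

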