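# Synthetic-data generators: multi-cohort expression matrices with planted
# tumor-altered genes, survival cohorts with an expression-linked hazard,
# and stress-test plate traces. These provide every input the pipeline
# consumes, with the statistical structure the analysis assumes.

#' Specification of one synthetic expression cohort
#'
#' @param cohort_id Cohort identifier.
#' @param n_genes Number of genes in the shared gene universe.
#' @param n_tumor,n_normal Group sizes (each >= 2).
#' @param baseline_mean Baseline log2 intensity (default 8, a typical
#'   normalized microarray level).
#' @param noise_sd I.i.d. Gaussian noise standard deviation on the log2
#'   scale (> 0).
#' @param seed Integer seed for this cohort's noise.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(cohort_id, n_genes, n_tumor, n_normal,
                        baseline_mean = 8, noise_sd = 0.5, seed = 1L) {
  if (n_tumor < 2 || n_normal < 2) stop("need n_tumor >= 2 and n_normal >= 2")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(cohort_id = as.character(cohort_id),
                 n_genes = as.integer(n_genes),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Planted ground truth for the multi-cohort generator
#'
#' @param up_genes,down_genes Gene ids carrying a planted tumor-vs-normal
#'   effect (`+effect_size` resp. `-effect_size` log2 units).
#' @param effect_size Positive log2 fold change of planted genes: a single
#'   value shared by all planted genes, or one value per planted gene
#'   (ordered as `c(up_genes, down_genes)`) for heterogeneous effects.
#' @param penetrance Fraction of cohorts in which a planted gene actually
#'   carries its effect (in [0, 1]); each gene's carrier cohorts are drawn
#'   independently as Bernoulli(penetrance). This abstracts between-cohort
#'   heterogeneity of true effects.
#' @return A `"planted_truth"` list.
#' @export
planted_truth <- function(up_genes = character(0), down_genes = character(0),
                          effect_size = 3, penetrance = 1) {
  if (length(intersect(up_genes, down_genes))) {
    stop("a gene cannot be planted both up and down")
  }
  n_planted <- length(up_genes) + length(down_genes)
  if (n_planted && any(effect_size <= 0)) {
    stop("effect_size must be > 0 for non-null genes")
  }
  if (!length(effect_size) %in% c(1L, max(n_planted, 1L))) {
    stop("effect_size must have length 1 or one value per planted gene")
  }
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  structure(list(up_genes = as.character(up_genes),
                 down_genes = as.character(down_genes),
                 effect_size = effect_size, penetrance = penetrance),
            class = "planted_truth")
}

#' Default gene-id universe
#' @param n_genes Number of genes.
#' @return Character vector `gene_00001`, ...
#' @export
gene_universe <- function(n_genes) sprintf("gene_%05d", seq_len(n_genes))

#' Generate multiple expression cohorts with planted alterations
#'
#' Simulates per-cohort tumor/normal log2 expression matrices over a shared
#' gene universe: i.i.d. Gaussian noise around each cohort's baseline
#' (microarray-like, RMA-normalized scale), with the planted genes' tumor
#' means shifted by the signed effect size in a Bernoulli(penetrance)
#' subset of cohorts (drawn per gene).
#'
#' @param specs List of [cohort_spec()]s; all must share `n_genes`.
#' @param truth A [planted_truth()].
#' @param metabolic_ids Optional metabolic gene-id set (checked to lie in
#'   the universe; carried through in the result for convenience).
#' @param carrier_seed Seed for the per-gene carrier-cohort draw.
#' @return List with `cohorts` (named list of `"expression_cohort"`),
#'   `truth` (data frame: gene, direction, effect_size plus one logical
#'   carrier column per cohort) and `metabolic_ids`.
#' @export
simulate_cohorts <- function(specs, truth = planted_truth(),
                             metabolic_ids = NULL, carrier_seed = 1L) {
  if (length(specs) == 0) stop("empty cohort spec list")
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  n_genes <- unique(vapply(specs, `[[`, integer(1), "n_genes"))
  if (length(n_genes) != 1) stop("all cohorts must share the same gene universe")
  genes <- gene_universe(n_genes)
  planted <- c(truth$up_genes, truth$down_genes)
  if (!all(planted %in% genes)) {
    stop("planted effect on gene(s) absent from the universe: ",
         paste(setdiff(planted, genes), collapse = ", "))
  }
  if (!is.null(metabolic_ids) && !all(metabolic_ids %in% genes)) {
    stop("metabolic_ids must be a subset of the gene universe")
  }
  direction <- stats::setNames(rep("null", n_genes), genes)
  direction[truth$up_genes] <- "up"
  direction[truth$down_genes] <- "down"
  es <- rep(truth$effect_size, length.out = max(length(planted), 1L))
  eff <- stats::setNames(numeric(n_genes), genes)
  eff[truth$up_genes] <- es[seq_along(truth$up_genes)]
  eff[truth$down_genes] <- -es[length(truth$up_genes) +
                                 seq_along(truth$down_genes)]
  set.seed(carrier_seed)
  carriers <- matrix(FALSE, n_genes, length(specs),
                     dimnames = list(genes, vapply(specs, `[[`,
                                                   character(1), "cohort_id")))
  carriers[planted, ] <- matrix(
    stats::runif(length(planted) * length(specs)) < truth$penetrance,
    length(planted), length(specs))
  cohorts <- list()
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    set.seed(sp$seed)
    n_s <- sp$n_tumor + sp$n_normal
    vals <- matrix(stats::rnorm(n_genes * n_s, sp$baseline_mean, sp$noise_sd),
                   n_genes, n_s)
    vals[, seq_len(sp$n_tumor)] <- vals[, seq_len(sp$n_tumor)] +
      eff * carriers[, j]
    group <- rep(c("tumor", "normal"), c(sp$n_tumor, sp$n_normal))
    sample_ids <- paste0(sp$cohort_id, "_",
                         c(paste0("T", seq_len(sp$n_tumor)),
                           paste0("N", seq_len(sp$n_normal))))
    cohorts[[sp$cohort_id]] <- expression_cohort(
      sp$cohort_id, vals, group, gene_ids = genes, sample_ids = sample_ids)
  }
  truth_df <- data.frame(gene = genes, direction = unname(direction),
                         effect_size = unname(eff), carriers,
                         row.names = NULL, check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(cohorts = cohorts, truth = truth_df, metabolic_ids = metabolic_ids)
}

#' Generate a survival cohort with an expression-linked hazard
#'
#' Exponential proportional-hazards generator: expression is standard
#' normal, event times are exponential with rate
#' `baseline_rate * exp(beta * expression)`. Censoring is two-part: an
#' independent Bernoulli(`censor_rate`) coin censors a subject at a uniform
#' fraction of its event time, and follow-up is administratively truncated
#' at `horizon` months (5-year follow-up by default).
#'
#' @param n Number of subjects (>= 10).
#' @param beta Log-hazard per expression unit (finite).
#' @param censor_rate Pre-horizon random censoring fraction in [0, 1).
#' @param seed Integer seed.
#' @param baseline_rate Baseline exponential event rate per month
#'   (default 0.03, i.e. median survival around 23 months at beta = 0,
#'   typical of advanced HCC cohorts).
#' @param horizon Administrative censoring horizon in months (default 60).
#' @return A `"survival_cohort"` (see [survival_cohort()]).
#' @export
simulate_survival <- function(n, beta, censor_rate = 0, seed = 1L,
                              baseline_rate = 0.03, horizon = 60) {
  if (n < 10) stop("need n >= 10")
  if (!is.finite(beta)) stop("beta must be finite")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  set.seed(seed)
  expression <- stats::rnorm(n)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(beta * expression))
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  event <- as.integer(!censored)
  over <- time > horizon
  time[over] <- horizon
  event[over] <- 0L
  survival_cohort(id = sprintf("pt_%04d", seq_len(n)), time = time,
                  event = event, expression = expression)
}

#' Default bioenergetic profile for the plate-trace generator
#'
#' Plateau rates of a healthy respiring, moderately glycolytic cell line:
#' mito-assay OCR 100/40/180/20 pmol O2/min across
#' baseline/oligomycin/uncoupler/rotenone+antimycin (so basal 80,
#' ATP-linked 60, leak 20, maximal 160, spare 80), and glyco-assay ECAR
#' 10/60/90/12 mpH/min across baseline/glucose/oligomycin/2-DG
#' (glycolysis 50, capacity 80, reserve 30).
#'
#' @param noise_sd Gaussian measurement noise sd added to every point
#'   (default 2; 0 gives exact plateaus).
#' @return A `"bioenergetic_profile"` list.
#' @export
bioenergetic_profile <- function(noise_sd = 2) {
  structure(list(
    mito = list(
      ocr = c(baseline = 100, post_oligomycin = 40,
              post_uncoupler = 180, post_rotAA = 20),
      ecar = c(baseline = 15, post_oligomycin = 30,
               post_uncoupler = 28, post_rotAA = 25)),
    glyco = list(
      ocr = c(baseline = 90, post_glucose = 85,
              post_oligomycin = 35, post_2DG = 30),
      ecar = c(baseline = 10, post_glucose = 60,
               post_oligomycin = 90, post_2DG = 12)),
    noise_sd = noise_sd), class = "bioenergetic_profile")
}

#' Generate mito- and glycolysis-stress plate traces
#'
#' Simulates long-format well traces for both stress tests, with the fixed
#' injection sequences (mito: baseline, oligomycin, CCCP/FCCP,
#' rotenone + antimycin A; glyco: baseline, glucose, oligomycin, 2-DG),
#' `points_per_phase` measurement points per phase (3, the plate-reader
#' convention) and i.i.d. Gaussian noise around the profile plateaus.
#' With `noise_sd = 0` the traces reproduce the plateaus exactly.
#'
#' @param seed Integer seed.
#' @param profile A [bioenergetic_profile()].
#' @param n_wells Number of replicate wells per assay.
#' @param points_per_phase Measurement points per phase.
#' @return List of two data frames (`mito`, `glyco`) with columns `well`,
#'   `phase`, `timepoint`, `OCR`, `ECAR`.
#' @export
simulate_plate_traces <- function(seed = 1L, profile = bioenergetic_profile(),
                                  n_wells = 5, points_per_phase = 3) {
  stopifnot(inherits(profile, "bioenergetic_profile"))
  if (any(unlist(profile$mito) < 0) || any(unlist(profile$glyco) < 0)) {
    stop("profile rates must be non-negative")
  }
  set.seed(seed)
  one <- function(assay) {
    p <- profile[[assay]]
    phases <- names(p$ocr)
    grid <- expand.grid(timepoint = seq_len(points_per_phase),
                        phase = phases, well = paste0("W", seq_len(n_wells)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    noise <- function(mu) pmax(0, mu + stats::rnorm(nrow(grid),
                                                    sd = profile$noise_sd))
    data.frame(assay = assay, well = grid$well, phase = grid$phase,
               timepoint = (match(grid$phase, phases) - 1L) *
                 points_per_phase + grid$timepoint,
               OCR = noise(p$ocr[grid$phase]),
               ECAR = noise(p$ecar[grid$phase]),
               stringsAsFactors = FALSE)
  }
  list(mito = one("mito"), glyco = one("glyco"))
}
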