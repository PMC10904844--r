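# Extracellular-flux (Seahorse-style) stress-test metrics and ATP-rate
# partitioning into glycolytic and oxidative production.

.mito_phases <- c("baseline", "post_oligomycin", "post_uncoupler", "post_rotAA")
.glyco_phases <- c("baseline", "post_glucose", "post_oligomycin", "post_2DG")

#' Summarize a plate trace into per-phase plateau rates
#'
#' Collapses a long-format trace table (one row per well/phase/timepoint)
#' into the per-phase mean OCR and ECAR over all wells and measurement
#' points, the conventional plateau summary with three points per phase.
#'
#' @param trace Data frame with columns `phase`, `OCR`, `ECAR` (and
#'   typically `well`, `timepoint`) as produced by [simulate_plate_traces()].
#' @param assay `"mito"` or `"glyco"`; phases are validated against the
#'   assay's injection sequence.
#' @return A `"stress_trace"`: list with `assay`, `ocr` and `ecar` named
#'   per-phase vectors.
#' @export
summarize_trace <- function(trace, assay = c("mito", "glyco")) {
  assay <- match.arg(assay)
  phases <- if (assay == "mito") .mito_phases else .glyco_phases
  miss <- setdiff(phases, unique(as.character(trace$phase)))
  if (length(miss)) {
    stop(sprintf("missing phase(s) for %s assay: %s", assay,
                 paste(miss, collapse = ", ")))
  }
  ocr <- tapply(trace$OCR, factor(trace$phase, levels = phases), mean)
  ecar <- tapply(trace$ECAR, factor(trace$phase, levels = phases), mean)
  if (any(ocr < 0) || any(ecar < 0)) stop("negative plateau rates")
  structure(list(assay = assay, ocr = c(ocr), ecar = c(ecar)),
            class = "stress_trace")
}

#' @export
print.stress_trace <- function(x, ...) {
  cat(sprintf("%s stress-test trace (per-phase plateau means)\n",
              ifelse(x$assay == "mito", "Mitochondrial", "Glycolysis")))
  print(round(rbind(OCR = x$ocr, ECAR = x$ecar), 3))
  invisible(x)
}

.clip0 <- function(x, what) {
  neg <- x < 0
  if (any(neg)) {
    warning(sprintf("negative %s clipped to 0: %s", what,
                    paste(names(x)[neg], collapse = ", ")))
    x[neg] <- 0
  }
  x
}

#' Mitochondrial stress-test metrics
#'
#' Classical respirometry decomposition of the OCR plateaus of the
#' mitochondrial stress test (injections: oligomycin, then an uncoupler
#' such as CCCP/FCCP, then rotenone + antimycin A). Non-mitochondrial
#' respiration is the post-rotenone/antimycin plateau; then
#' `basal = baseline - post_rotAA`, `atp_linked = baseline -
#' post_oligomycin`, `proton_leak = post_oligomycin - post_rotAA`,
#' `maximal = post_uncoupler - post_rotAA`, `spare = maximal - basal`.
#' Negative values (measurement noise) are clipped to 0 with a warning.
#'
#' @param trace A `"stress_trace"` with `assay = "mito"`.
#' @return Named numeric vector `basal`, `atp_linked`, `proton_leak`,
#'   `maximal`, `spare` (pmol O2/min).
#' @export
mito_metrics <- function(trace) {
  stopifnot(inherits(trace, "stress_trace"))
  if (trace$assay != "mito") stop("mito_metrics() needs a mito-assay trace")
  o <- trace$ocr
  m <- c(basal = o[["baseline"]] - o[["post_rotAA"]],
         atp_linked = o[["baseline"]] - o[["post_oligomycin"]],
         proton_leak = o[["post_oligomycin"]] - o[["post_rotAA"]],
         maximal = o[["post_uncoupler"]] - o[["post_rotAA"]])
  m <- .clip0(m, "mito metrics")
  c(m, spare = max(m[["maximal"]] - m[["basal"]], 0))
}

#' Glycolysis stress-test metrics
#'
#' ECAR decomposition of the glycolysis stress test (injections: glucose,
#' oligomycin, 2-deoxyglucose): `glycolysis = post_glucose - baseline`,
#' `glycolytic_capacity = post_oligomycin - baseline`,
#' `glycolytic_reserve = capacity - glycolysis`. Negative values are
#' clipped to 0 with a warning.
#'
#' @param trace A `"stress_trace"` with `assay = "glyco"`.
#' @return Named numeric vector `glycolysis`, `glycolytic_capacity`,
#'   `glycolytic_reserve` (mpH/min).
#' @export
glyco_metrics <- function(trace) {
  stopifnot(inherits(trace, "stress_trace"))
  if (trace$assay != "glyco") stop("glyco_metrics() needs a glyco-assay trace")
  e <- trace$ecar
  m <- c(glycolysis = e[["post_glucose"]] - e[["baseline"]],
         glycolytic_capacity = e[["post_oligomycin"]] - e[["baseline"]])
  m <- .clip0(m, "glyco metrics")
  c(m, glycolytic_reserve = max(m[["glycolytic_capacity"]] -
                                  m[["glycolysis"]], 0))
}

#' Default ATP-partition stoichiometric constants
#'
#' Constants for converting OCR/ECAR into ATP production rates, following
#' the extracellular-flux bioenergetics methodology of Mookerjee and
#' Brand: `atp_per_lactate` ATP per lactate exported (1, substrate-level
#' glycolytic yield per lactate + H+); `p_o_ratio`, ATP per O atom for
#' coupled respiration (2.486, the maximal oxidative phosphorylation P/O);
#' `buffering_factor`, pmol H+/min per mpH/min (instrument/medium
#' dependent; 1 by default so ECAR is read as a proton flux);
#' `co2_acidification_correction`, H+ per O2 of respiratory CO2-derived
#' acidification subtracted from the measured proton flux (1 for complete
#' oxidation at physiological pH).
#'
#' `buffering_factor` is the one instrument-dependent constant: it is the
#' reciprocal buffering power of the assay medium scaled by the
#' measurement-chamber volume, about 14 pmol H+/min per mpH/min for
#' standard bicarbonate-free XF medium, and should be recalibrated per
#' instrument and medium.
#'
#' @return Named list of the four constants.
#' @export
atp_constants <- function() {
  list(atp_per_lactate = 1.0,
       p_o_ratio = 2.486,
       buffering_factor = 14.0,
       co2_acidification_correction = 1.0)
}

#' Partition ATP production into glycolytic and oxidative rates
#'
#' Converts paired extracellular-flux measurements into ATP production
#' rates: the measured acidification is first converted to a proton flux
#' (`ecar * buffering_factor`), the respiratory CO2 contribution
#' (`co2_acidification_correction * atp_linked_ocr`) is subtracted, and the
#' lactate-attributable remainder yields
#' `J_glyc = corrected_H_flux * atp_per_lactate` (floored at 0 with a
#' warning if the correction exceeds the measurement). Oxidative ATP is
#' `J_ox = 2 * p_o_ratio * atp_linked_ocr` (two O atoms per O2).
#'
#' @param atp_linked_ocr ATP-linked (oligomycin-sensitive) OCR from
#'   [mito_metrics()], pmol O2/min.
#' @param ecar Glycolytic-phase ECAR, mpH/min (e.g. the post-glucose
#'   plateau of the glycolysis stress test).
#' @param constants Stoichiometric constants, see [atp_constants()].
#' @return An `"atp_partition"` list: `J_glyc`, `J_ox`, `J_total`,
#'   `fraction_glyc`.
#' @export
atp_partition <- function(atp_linked_ocr, ecar,
                          constants = atp_constants()) {
  k <- utils::modifyList(atp_constants(), as.list(constants))
  if (any(unlist(k) <= 0)) stop("constants must be positive")
  if (atp_linked_ocr < 0 || ecar < 0) stop("rates must be non-negative")
  h_flux <- ecar * k$buffering_factor -
    k$co2_acidification_correction * atp_linked_ocr
  if (h_flux < 0) {
    warning("CO2 correction exceeds measured proton flux; J_glyc set to 0")
    h_flux <- 0
  }
  j_glyc <- h_flux * k$atp_per_lactate
  j_ox <- 2 * k$p_o_ratio * atp_linked_ocr
  total <- j_glyc + j_ox
  structure(list(J_glyc = j_glyc, J_ox = j_ox, J_total = total,
                 fraction_glyc = if (total > 0) j_glyc / total else NA_real_,
                 constants = k),
            class = "atp_partition")
}

#' @export
print.atp_partition <- function(x, ...) {
  cat(sprintf("ATP production: glycolytic %.1f + oxidative %.1f = %.1f pmol ATP/min\n",
              x$J_glyc, x$J_ox, x$J_total))
  if (is.finite(x$fraction_glyc)) {
    cat(sprintf("  glycolytic fraction: %.1f%%\n", 100 * x$fraction_glyc))
  }
  invisible(x)
}
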