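# Atom-mapped label propagation: network validation, stated predictions,
# convolution algebra, scrambling invariance, and the brute-force oracle.

net <- build_default_network()
rts <- default_routes()

test_that("every shipped reaction conserves carbon and maps bijectively", {
  for (r in net$reactions) {
    ns <- sum(vapply(r$substrates, `[[`, integer(1), "n"))
    np <- sum(vapply(r$products, `[[`, integer(1), "n"))
    expect_identical(ns, np)
    expect_setequal(r$map, seq_len(ns))
  }
  # a conservation-violating reaction is rejected at load
  bad <- tempfile(fileext = ".json")
  raw <- jsonlite::fromJSON(net$source, simplifyVector = FALSE)
  raw$reactions[[1]]$products[[1]]$met <- "g3p"
  raw$reactions[[1]]$products[[1]]$carbons <- 3
  jsonlite::write_json(raw, bad, auto_unbox = TRUE)
  expect_error(build_default_network(bad), "carbon")
})

test_that("PDH and PC entries give the canonical citrate isotopologues", {
  # PDH on m+3 pyruvate: m+2 acetyl-CoA; condensed with unlabeled OAA: m+2 citrate
  accoa <- propagate(net, "pdh_accoa", rts)
  expect_equal(mass_shift(accoa), 2)
  expect_equal(as.numeric(accoa), c(0, 0, 1))
  cit_pdh <- propagate(net, "pdh_citrate", rts)
  expect_equal(mass_shift(cit_pdh), 2)
  # PC on m+3 pyruvate with unlabeled CO2: m+3 OAA
  oaa <- propagate(net, "pc_oaa", rts)
  expect_equal(mass_shift(oaa), 3)
  # both entries from labeled pyruvate: m+5 citrate
  cit_both <- propagate(net, "pdh_pc_citrate", rts)
  expect_equal(mass_shift(cit_both), 5)
  expect_equal(sum(as.numeric(cit_both)), 1, tolerance = 1e-12)
})

test_that("glucose routes: lactate/alanine m+3, PPP m+6/m+5/m+3, TCA m+2", {
  ks <- sapply(c(glycolysis_lactate = "glycolysis_lactate",
                 glycolysis_alanine = "glycolysis_alanine",
                 oxppp_6pg = "oxppp_6pg", oxppp_r5p = "oxppp_r5p",
                 nonoxppp_r5p = "nonoxppp_r5p",
                 glucose_ox_tca_succinate = "glucose_ox_tca_succinate",
                 glucose_ox_tca_malate = "glucose_ox_tca_malate"),
               function(r) mass_shift(propagate(net, r, rts)))
  expect_equal(unname(ks), c(3, 3, 6, 5, 3, 2, 2))
})

test_that("glutamine routes: oxidative m+4 series, reductive m+5/m+3", {
  ks <- sapply(c("gls_glutamate", "gln_akg", "gln_ox_succinate",
                 "gln_ox_fumarate", "gln_ox_malate", "gln_ox_aspartate",
                 "gln_ox_citrate", "gln_red_citrate", "gln_red_aspartate"),
               function(r) mass_shift(propagate(net, r, rts)))
  expect_equal(unname(ks), c(5, 5, 4, 4, 4, 4, 4, 5, 3))
})

test_that("an unlabeled tracer yields m+0 everywhere", {
  rts0 <- rts
  rts0$tracers[["12C-glucose"]] <- list(met = "glucose", labeled = integer(0))
  # (routes whose pools are themselves tracer-derived, e.g. the PC+PDH
  # citrate condensation, stay labeled and are exercised elsewhere)
  for (nm in c("glycolysis_lactate", "pdh_citrate", "oxppp_r5p")) {
    route <- rts0$routes[[nm]]
    route$tracer <- "12C-glucose"
    d <- propagate(net, route, rts0)
    expect_equal(mass_shift(d), 0)
    expect_equal(as.numeric(d)[1], 1)
  }
})

test_that("propagate validates routes and normalizes its output", {
  broken <- list(name = "broken", tracer = "U-13C6-glucose",
                 steps = list(list(reaction = "gls")))
  expect_error(propagate(net, broken, rts), "not a substrate")
  expect_error(propagate(net, list(name = "x", tracer = "nope",
                                   steps = list()), rts), "unknown tracer")
  for (nm in names(rts$routes)) {
    d <- propagate(net, nm, rts)
    expect_lt(abs(sum(as.numeric(d)) - 1), 1e-9)
    expect_true(all(as.numeric(d) >= 0))
  }
})

test_that("convolution: identity element, worked citrate examples", {
  accoa2 <- mid(c("m+2" = 1), "accoa")
  oaa0 <- mid(c("m+0" = 1), "oaa")
  oaa3 <- mid(c("m+3" = 1), "oaa")
  expect_equal(mass_shift(mid_convolve(accoa2, oaa0)), 2)
  expect_equal(mass_shift(mid_convolve(accoa2, oaa3)), 5)
  # m+0 is the identity element of the convolution
  set.seed(2)
  f <- runif(5); f <- f / sum(f)
  d <- mid(f)
  expect_equal(as.numeric(mid_convolve(d, mid(1)))[1:5], as.numeric(d))
  # convolution agrees with direct enumeration on dense inputs
  d2 <- mid(c(0.2, 0.3, 0.5))
  conv <- as.numeric(mid_convolve(d, d2))
  brute <- numeric(7)
  for (j in 0:4) for (k in 0:2) {
    brute[j + k + 1] <- brute[j + k + 1] + f[j + 1] * c(0.2, 0.3, 0.5)[k + 1]
  }
  expect_equal(conv, brute, tolerance = 1e-12)
})

test_that("mixtures: weighted sum and exact weight recovery", {
  ox <- propagate(net, "gln_ox_citrate", rts)
  red <- propagate(net, "gln_red_citrate", rts)
  m <- mid_mix(list(ox, red), c(0.5, 0.5), "citrate")
  expect_equal(as.numeric(m)[5:6], c(0.5, 0.5))
  expect_equal(as.numeric(mid_mix(list(ox, red), c(1, 0))),
               as.numeric(ox))
  # least-squares inversion recovers the mixing weight to 1e-9
  for (w in c(0.1, 0.37, 0.8)) {
    mixed <- mid_mix(list(ox, red), c(w, 1 - w), "citrate")
    fit <- mid_fit_weights(mixed, list(ox = ox, red = red))
    expect_lt(abs(fit[["ox"]] - w), 1e-9)
    expect_lt(abs(sum(fit) - 1), 1e-9)
  }
  expect_error(mid_mix(list(ox), c(0.5, 0.5)), "same length")
  expect_error(mid_mix(list(ox, red), c(0.6, 0.6)), "sum to 1")
})

test_that("succinate/fumarate scrambling never changes the mass distribution", {
  for (nm in c("gln_ox_succinate", "gln_ox_fumarate", "gln_ox_malate",
               "gln_ox_aspartate", "gln_ox_citrate",
               "glucose_ox_tca_succinate", "glucose_ox_tca_malate")) {
    on <- propagate(net, nm, rts, scramble = TRUE)
    off <- propagate(net, nm, rts, scramble = FALSE)
    expect_equal(as.numeric(on), as.numeric(off), tolerance = 1e-12)
  }
})

test_that("engine matches the single-molecule brute-force oracle on all routes", {
  for (nm in names(rts$routes)) {
    d <- propagate(net, nm, rts)
    oracle <- mc_route_mid(nm, n_mol = 300, seed = 4)
    expect_identical(oracle$met, attr(d, "metabolite"))
    # shipped routes are deterministic point masses; the empirical MID of
    # the oracle must coincide exactly
    expect_equal(oracle$mid, as.numeric(d), tolerance = 1e-12)
  }
})

test_that("predict_named_routes enumerates the stated predictions", {
  glc <- predict_named_routes("U-13C6-glucose", net, rts)
  expect_true(all(glc$fraction == 1))
  expect_equal(glc$mass_shift[glc$route == "glycolysis_lactate"], 3)
  expect_equal(glc$mass_shift[glc$route == "nonoxppp_r5p"], 3)
  gln <- predict_named_routes("U-13C5-glutamine", net, rts)
  expect_equal(sort(unique(gln$mass_shift)), c(3, 4, 5))
  expect_error(predict_named_routes("U-2H-water"), "unknown tracer")
})
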