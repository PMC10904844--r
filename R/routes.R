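# Route definitions and single-pass label propagation.

#' Load the canonical tracer routes
#'
#' Routes are ordered reaction lists from a tracer entry metabolite to a
#' target metabolite, together with explicit co-substrate pool declarations:
#' a pool is either `"unlabeled"` (all-12C, the default for any co-substrate
#' not mentioned) or a reference to another route whose terminal label
#' distribution supplies the co-substrate (used when both condensation
#' partners descend from the tracer, as for the m+5 citrate formed from
#' PC-derived OAA and PDH-derived acetyl-CoA).
#'
#' @param path Path to a routes JSON file; `NULL` uses the shipped set.
#' @return An object of class `"route_set"` with elements `tracers` and
#'   `routes`.
#' @export
default_routes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "routes.json", package = "hccflux",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tracers <- lapply(raw$tracers, function(t)
    list(met = t$met, labeled = as.integer(unlist(t$labeled))))
  routes <- list()
  for (r in raw$routes) routes[[r$name]] <- r
  structure(list(tracers = tracers, routes = routes, source = path),
            class = "route_set")
}

#' @export
print.route_set <- function(x, ...) {
  cat("Tracer route set:", length(x$routes), "routes,",
      length(x$tracers), "tracers\n")
  for (r in x$routes) {
    cat(sprintf("  %-24s [%s] %s\n", r$name, r$tracer, r$label %||% ""))
  }
  invisible(x)
}

.tracer_state <- function(network, routes, tracer) {
  tr <- routes$tracers[[tracer]]
  if (is.null(tr)) {
    stop(sprintf("unknown tracer '%s' (known: %s)", tracer,
                 paste(names(routes$tracers), collapse = ", ")))
  }
  .lp_pure(network, tr$met, tr$labeled)
}

# Internal propagation returning the full label-pattern state.
.propagate_state <- function(network, route, routes, scramble = TRUE,
                             .depth = 0L) {
  if (.depth > 20L) stop("route pool references nest too deeply (cycle?)")
  if (is.character(route)) {
    route <- routes$routes[[route]] %||%
      stop(sprintf("unknown route '%s'", route))
  }
  state <- .tracer_state(network, routes, route$tracer)
  for (step in route$steps) {
    rxn <- network$reactions[[step$reaction]]
    if (is.null(rxn)) {
      stop(sprintf("route '%s': unknown reaction '%s'",
                   route$name %||% "?", step$reaction))
    }
    sub_mets <- vapply(rxn$substrates, `[[`, character(1), "met")
    if (!(state$met %in% sub_mets)) {
      stop(sprintf("route '%s' step '%s': carried metabolite '%s' is not a substrate",
                   route$name %||% "?", step$reaction, state$met))
    }
    states <- list()
    states[[state$met]] <- state
    for (other in setdiff(sub_mets, state$met)) {
      pool <- step$pools[[other]]
      if (is.null(pool) || identical(pool, "unlabeled")) {
        states[[other]] <- .lp_pure(network, other)
      } else if (is.list(pool) && !is.null(pool$route)) {
        ref <- .propagate_state(network, pool$route, routes,
                                scramble = scramble, .depth = .depth + 1L)
        if (ref$met != other) {
          stop(sprintf("pool route '%s' ends at '%s', expected '%s'",
                       pool$route, ref$met, other))
        }
        states[[other]] <- ref
      } else {
        stop(sprintf("route '%s' step '%s': bad pool declaration for '%s'",
                     route$name %||% "?", step$reaction, other))
      }
    }
    state <- .apply_reaction(network, step$reaction, states,
                             follow = step$follow, scramble = scramble)
  }
  state
}

#' Propagate a tracer along a route
#'
#' Runs the single-pass ("first turn") label propagation of a tracer through
#' an ordered reaction route and returns the mass isotopologue distribution
#' of the terminal metabolite. Condensation co-substrates come from the
#' route's declared pools (unlabeled by default). Carbon conservation is
#' asserted at every reaction application, and the returned distribution is
#' normalized to 1 within 1e-9.
#'
#' @param network A `"flux_network"` from [build_default_network()].
#' @param route A route name in `routes`, or a route definition list with
#'   elements `tracer` and `steps`.
#' @param routes A `"route_set"` from [default_routes()].
#' @param scramble Apply the 50/50 orientation mixing at the symmetric
#'   succinate/fumarate carriers. This changes positional patterns only;
#'   the mass-shift distribution is invariant.
#' @return The terminal metabolite's `"mid"`.
#' @examples
#' net <- build_default_network()
#' rts <- default_routes()
#' propagate(net, "glycolysis_lactate", rts)   # lactate m+3
#' propagate(net, "gln_red_citrate", rts)      # citrate m+5
#' @export
propagate <- function(network, route, routes = default_routes(),
                      scramble = TRUE) {
  stopifnot(inherits(network, "flux_network"))
  .lp_mid(.propagate_state(network, route, routes, scramble = scramble))
}

#' Enumerate the labeling predictions of a tracer
#'
#' Runs every canonical route of the given tracer and tabulates the
#' predicted mass shift of each terminal metabolite: the glycolytic m+3
#' species, PDH (m+2 citrate) vs PC (m+3 OAA) pyruvate entry and their m+5
#' citrate combination, first-turn oxidative TCA, the oxidative (m+5) and
#' non-oxidative (m+3) PPP routes to ribose 5-phosphate, and the oxidative
#' (m+4) vs reductive (m+5 citrate / m+3 aspartate) fates of glutamine.
#'
#' @param tracer `"U-13C6-glucose"` or `"U-13C5-glutamine"` (the shipped
#'   non-oxidative PPP route uses the derived `"13C3-G3P"` tracer and is
#'   listed under glucose).
#' @param network,routes Network and route set to use.
#' @return A data frame with columns `route`, `tracer`, `metabolite`,
#'   `mass_shift`, `fraction` (abundance of that isotopologue) and `label`.
#' @export
predict_named_routes <- function(tracer,
                                 network = build_default_network(),
                                 routes = default_routes()) {
  known <- c("U-13C6-glucose", "U-13C5-glutamine")
  if (!tracer %in% known) {
    stop(sprintf("unknown tracer '%s' (use one of: %s)", tracer,
                 paste(known, collapse = ", ")))
  }
  # m+3 G3P is glucose-derived; its routes belong to the glucose tracer.
  want <- if (tracer == "U-13C6-glucose") c(tracer, "13C3-G3P") else tracer
  sel <- Filter(function(r) r$tracer %in% want, routes$routes)
  rows <- lapply(sel, function(r) {
    d <- propagate(network, r, routes)
    k <- mass_shift(d)
    data.frame(route = r$name, tracer = r$tracer,
               metabolite = attr(d, "metabolite"),
               mass_shift = k, fraction = as.numeric(d)[k + 1L],
               label = r$label %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
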