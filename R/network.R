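# Atom-mapped reaction network: load, validate, and apply reactions to
# label-pattern distributions.
#
# A label state is an exact distribution over binary 13C patterns of one
# metabolite: list(met, n, patterns = 0/1 matrix (rows = patterns), prob).
# Propagation is exact enumeration, feasible because every metabolite here
# has <= 7 carbons.

#' Load and validate the atom-mapped reaction library
#'
#' Reads the carbon-mapped reaction network shipped with the package (or a
#' user-supplied JSON file in the same format) and validates every reaction:
#' total substrate carbons must equal total product carbons (CO2 included),
#' the atom map must be a bijection between substrate and product carbon
#' slots, and declared carbon counts must match the metabolite table.
#' A reaction violating carbon conservation is rejected at load.
#'
#' The default library covers lumped glycolysis (with the aldolase/TPI
#' split), LDH, ALT, PDH (substrate C1 released as CO2), pyruvate
#' carboxylase, citrate synthase, oxidative aconitase/IDH, the
#' alpha-KG-to-succinate step, the symmetric succinate/fumarate pair,
#' fumarase, MDH, GOT2, reverse IDH (reductive carboxylation), ATP-citrate
#' lyase, glutaminase, glutamate deamination/transamination, the oxidative
#' PPP (G6PDH, 6PGD releasing glucose C1) and the non-oxidative PPP
#' (transketolase, transaldolase, epimerase, isomerase).
#'
#' @param path Path to a reaction JSON file; `NULL` uses the shipped library.
#' @return An object of class `"flux_network"`.
#' @export
build_default_network <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reactions.json", package = "hccflux",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- list()
  for (m in raw$metabolites) {
    if (!is.character(m$name) || m$carbons < 1) {
      stop("metabolite entries need a name and carbons >= 1")
    }
    mets[[m$name]] <- list(name = m$name, n = as.integer(m$carbons),
                           symmetric = isTRUE(m$symmetric))
  }
  rxns <- list()
  for (r in raw$reactions) {
    sub <- lapply(r$substrates, function(s)
      list(met = s$met, n = as.integer(s$carbons)))
    prod <- lapply(r$products, function(s)
      list(met = s$met, n = as.integer(s$carbons)))
    for (side in c(sub, prod)) {
      if (is.null(mets[[side$met]])) {
        stop(sprintf("reaction '%s': unknown metabolite '%s'", r$id, side$met))
      }
      if (mets[[side$met]]$n != side$n) {
        stop(sprintf("reaction '%s': carbon count of '%s' disagrees with the metabolite table",
                     r$id, side$met))
      }
    }
    ns <- sum(vapply(sub, `[[`, integer(1), "n"))
    np <- sum(vapply(prod, `[[`, integer(1), "n"))
    if (ns != np) {
      stop(sprintf("reaction '%s' violates carbon conservation (%d substrate vs %d product carbons)",
                   r$id, ns, np))
    }
    map <- as.integer(unlist(r$map))
    if (length(map) != ns || !setequal(map, seq_len(ns))) {
      stop(sprintf("reaction '%s': atom map is not a bijection over %d carbon slots",
                   r$id, ns))
    }
    rxns[[r$id]] <- list(id = r$id, name = r$name %||% r$id,
                         substrates = sub, products = prod, map = map)
  }
  structure(list(metabolites = mets, reactions = rxns, source = path),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("Atom-mapped reaction network:",
      length(x$reactions), "reactions over",
      length(x$metabolites), "metabolites\n")
  cat("  reactions:", paste(names(x$reactions), collapse = ", "), "\n")
  invisible(x)
}

# --- label-pattern states -------------------------------------------------

.lp_new <- function(met, patterns, prob) {
  keep <- prob > 0
  patterns <- patterns[keep, , drop = FALSE]
  prob <- prob[keep]
  key <- apply(patterns, 1L, paste, collapse = "")
  agg <- rowsum(prob, key)
  upat <- do.call(rbind, lapply(strsplit(rownames(agg), ""), as.integer))
  list(met = met, n = ncol(patterns), patterns = upat,
       prob = as.numeric(agg))
}

.lp_pure <- function(net, met, labeled = integer(0)) {
  n <- net$metabolites[[met]]$n
  if (is.null(n)) stop(sprintf("unknown metabolite '%s'", met))
  if (length(labeled) && (min(labeled) < 1 || max(labeled) > n)) {
    stop(sprintf("labeled positions out of range for '%s'", met))
  }
  pat <- matrix(0L, 1L, n)
  pat[1L, labeled] <- 1L
  list(met = met, n = n, patterns = pat, prob = 1)
}

.lp_mid <- function(state) {
  k <- as.integer(state$patterns %*% rep(1L, state$n))
  f <- numeric(state$n + 1L)
  for (i in seq_along(k)) f[k[i] + 1L] <- f[k[i] + 1L] + state$prob[i]
  mid(f, metabolite = state$met)
}

.lp_scramble <- function(state) {
  flipped <- state$patterns[, rev(seq_len(state$n)), drop = FALSE]
  .lp_new(state$met,
          rbind(state$patterns, flipped),
          c(state$prob, state$prob) / 2)
}

# Apply one reaction to label states supplied per substrate metabolite.
# 'states' is a named list keyed by substrate metabolite; every substrate of
# the reaction must be present. Returns the label state of the product named
# in 'follow' (defaults to the sole product). Conservation of the number of
# labeled carbons is asserted on every pattern combination.
.apply_reaction <- function(net, rxn_id, states, follow = NULL,
                            scramble = TRUE) {
  rxn <- net$reactions[[rxn_id]]
  if (is.null(rxn)) stop(sprintf("unknown reaction '%s'", rxn_id))
  sub_mets <- vapply(rxn$substrates, `[[`, character(1), "met")
  if (!all(sub_mets %in% names(states))) {
    stop(sprintf("reaction '%s': missing substrate state for %s", rxn_id,
                 paste(setdiff(sub_mets, names(states)), collapse = ", ")))
  }
  sts <- states[sub_mets]
  idx <- expand.grid(lapply(sts, function(s) seq_along(s$prob)),
                     KEEP.OUT.ATTRS = FALSE)
  nsub <- length(sts)
  prob <- rep(1, nrow(idx))
  bits <- NULL
  for (j in seq_len(nsub)) {
    prob <- prob * sts[[j]]$prob[idx[[j]]]
    bits <- cbind(bits, sts[[j]]$patterns[idx[[j]], , drop = FALSE])
  }
  out <- matrix(0L, nrow(bits), ncol(bits))
  out[, rxn$map] <- bits
  stopifnot(all(rowSums(out) == rowSums(bits)))  # carbon/label conservation
  prod_mets <- vapply(rxn$products, `[[`, character(1), "met")
  if (is.null(follow)) {
    if (length(prod_mets) > 1L) {
      stop(sprintf("reaction '%s' has several products; say which to follow",
                   rxn_id))
    }
    follow <- prod_mets[1L]
  }
  p <- match(follow, prod_mets)
  if (is.na(p)) {
    stop(sprintf("reaction '%s' has no product '%s'", rxn_id, follow))
  }
  offs <- cumsum(c(0L, vapply(rxn$products, `[[`, integer(1), "n")))
  cols <- (offs[p] + 1L):offs[p + 1L]
  st <- .lp_new(follow, out[, cols, drop = FALSE], prob)
  if (scramble && isTRUE(net$metabolites[[follow]]$symmetric)) {
    st <- .lp_scramble(st)
  }
  st
}
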