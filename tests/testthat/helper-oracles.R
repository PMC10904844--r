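# Independent oracles used across the suite. These deliberately share no
# code with the package implementation they check.

# Exact two-sided permutation test for a difference in means between two
# small samples: enumerates every reassignment of the pooled values.
perm_test_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(n, length(x))
  stats <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}

# Textbook Welch t: statistic, Welch-Satterthwaite df, two-sided p.
welch_hand <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = tstat, df = df, p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# Hand risk-table Kaplan-Meier: step through distinct times computing the
# product limit from scratch (no vectorized shortcuts shared with the
# implementation).
km_hand <- function(time, event) {
  tt <- sort(unique(time))
  surv <- 1
  out <- data.frame(time = tt, n_risk = NA_real_, n_event = NA_real_,
                    surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- 0
    d <- 0
    for (j in seq_along(time)) {
      if (time[j] >= tt[i]) at_risk <- at_risk + 1
      if (time[j] == tt[i] && event[j] == 1) d <- d + 1
    }
    surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$surv[i] <- surv
  }
  out
}

# Monte-Carlo single-molecule label simulator: an independent brute-force
# oracle for the propagation engine. Re-reads the shipped JSON definitions
# and pushes individual molecules through a route, tallying mass shifts.
mc_route_mid <- function(route_name, n_mol = 4000, seed = 1,
                         net_path = system.file("extdata", "reactions.json",
                                                package = "hccflux"),
                         routes_path = system.file("extdata", "routes.json",
                                                   package = "hccflux")) {
  net <- jsonlite::fromJSON(net_path, simplifyVector = FALSE)
  rts <- jsonlite::fromJSON(routes_path, simplifyVector = FALSE)
  mets <- list()
  for (m in net$metabolites) mets[[m$name]] <- m
  rxns <- list()
  for (r in net$reactions) rxns[[r$id]] <- r
  routes <- list()
  for (r in rts$routes) routes[[r$name]] <- r

  sim_one <- function(name) {
    route <- routes[[name]]
    tr <- rts$tracers[[route$tracer]]
    bits <- rep(0L, mets[[tr$met]]$carbons)
    bits[unlist(tr$labeled)] <- 1L
    met <- tr$met
    for (step in route$steps) {
      r <- rxns[[step$reaction]]
      allbits <- integer(0)
      for (s in r$substrates) {
        if (s$met == met) {
          allbits <- c(allbits, bits)
        } else {
          pool <- step$pools[[s$met]]
          if (is.null(pool) || identical(pool, "unlabeled")) {
            allbits <- c(allbits, rep(0L, s$carbons))
          } else {
            ref <- sim_one(pool$route)
            stopifnot(ref$met == s$met)
            allbits <- c(allbits, ref$bits)
          }
        }
      }
      out <- integer(length(allbits))
      out[unlist(r$map)] <- allbits
      follow <- step$follow
      prod_mets <- vapply(r$products, function(p) p$met, character(1))
      if (is.null(follow)) follow <- prod_mets[1]
      p <- match(follow, prod_mets)
      offs <- cumsum(c(0L, vapply(r$products, function(q) q$carbons, 1)))
      bits <- out[(offs[p] + 1):offs[p + 1]]
      met <- follow
      if (isTRUE(mets[[met]]$symmetric) && runif(1) < 0.5) bits <- rev(bits)
    }
    list(met = met, bits = bits)
  }

  set.seed(seed)
  first <- sim_one(route_name)
  counts <- numeric(length(first$bits) + 1L)
  for (i in seq_len(n_mol)) {
    k <- sum(sim_one(route_name)$bits)
    counts[k + 1L] <- counts[k + 1L] + 1
  }
  list(met = first$met, mid = counts / n_mol)
}

# Binomial tail P(X >= k), X ~ Bin(n, p).
binom_tail <- function(k, n, p) pbinom(k - 1, n, p, lower.tail = FALSE)
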