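#' Mass isotopologue distribution (MID)
#'
#' An MID stores the fractional abundance of each isotopologue m+0 ... m+C of
#' a metabolite with C carbons, i.e. the probability that a molecule carries
#' exactly k heavy (13C) atoms. Fractions must be non-negative and sum to 1.
#'
#' @param fractions Numeric vector of length C+1 giving f(m+0) ... f(m+C).
#'   Alternatively a named vector with names `"m+0"`, `"m+1"`, ... in any
#'   order; missing isotopologues are taken as 0 up to the largest named k.
#' @param metabolite Optional metabolite name carried along for printing.
#' @param tol Tolerance on the normalization check.
#' @return An object of class `"mid"`: a numeric vector named
#'   `m+0 ... m+C` with attribute `metabolite`.
#' @examples
#' mid(c(0, 0, 1), metabolite = "accoa")      # pure m+2 acetyl-CoA
#' mid(c("m+4" = 0.5, "m+5" = 0.5), metabolite = "citrate")
#' @export
mid <- function(fractions, metabolite = NULL, tol = 1e-9) {
  if (!is.numeric(fractions) || length(fractions) < 1L) {
    stop("'fractions' must be a non-empty numeric vector")
  }
  if (!is.null(names(fractions))) {
    k <- suppressWarnings(as.integer(sub("^m\\+", "", names(fractions))))
    if (anyNA(k) || any(k < 0)) stop("names must be of the form 'm+k', k >= 0")
    f <- numeric(max(k) + 1L)
    f[k + 1L] <- fractions
    fractions <- f
  }
  if (any(!is.finite(fractions)) || any(fractions < -tol)) {
    stop("MID fractions must be finite and non-negative")
  }
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    stop(sprintf("MID fractions must sum to 1 (got %.12f)", s))
  }
  fractions <- fractions / s
  names(fractions) <- paste0("m+", seq_along(fractions) - 1L)
  structure(fractions, metabolite = metabolite, class = "mid")
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  met <- attr(x, "metabolite")
  cat("Mass isotopologue distribution",
      if (!is.null(met)) paste0(" of ", met), "\n", sep = "")
  nz <- which(unclass(x) > 0)
  v <- round(unclass(x)[nz], digits)
  cat(paste(sprintf("  %s: %g", names(x)[nz], v), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.mid <- function(x, ...) {
  data.frame(metabolite = attr(x, "metabolite") %||% NA_character_,
             isotopologue = names(x),
             k = seq_along(x) - 1L,
             fraction = as.numeric(x),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dominant mass shift of an MID
#'
#' Returns the number of labeled carbons of the most abundant isotopologue.
#' For the single-pass routes shipped with the package the terminal MID is a
#' point mass, so this is the route's predicted m+k.
#'
#' @param x An object of class `"mid"`.
#' @return Integer mass shift k.
#' @export
mass_shift <- function(x) {
  stopifnot(inherits(x, "mid"))
  as.integer(which.max(unclass(x)) - 1L)
}

#' Convolve two isotopologue distributions
#'
#' Condensation reactions (citrate synthase, pyruvate carboxylase) join two
#' carbon skeletons; under the assumption that the two substrate pools label
#' independently, the product MID is the discrete convolution
#' f_out(m+k) = sum_j f1(m+j) f2(m+(k-j)).
#'
#' @param d1,d2 Objects of class `"mid"`.
#' @param metabolite Optional name for the product.
#' @return The product `"mid"`, with support up to the summed carbon counts.
#' @examples
#' accoa <- mid(c("m+2" = 1), metabolite = "accoa")
#' oaa   <- mid(c("m+0" = 1), metabolite = "oaa")
#' mid_convolve(accoa, oaa, metabolite = "citrate")  # m+2 citrate
#' @export
mid_convolve <- function(d1, d2, metabolite = NULL) {
  stopifnot(inherits(d1, "mid"), inherits(d2, "mid"))
  f1 <- as.numeric(d1); f2 <- as.numeric(d2)
  out <- numeric(length(f1) + length(f2) - 1L)
  for (j in seq_along(f1)) {
    out[j + seq_along(f2) - 1L] <- out[j + seq_along(f2) - 1L] + f1[j] * f2
  }
  mid(out, metabolite = metabolite)
}

#' Mix isotopologue distributions
#'
#' A measured MID is a weighted mixture when several routes feed the same
#' metabolite pool (e.g. oxidative m+4 citrate vs reductive m+5 citrate from
#' 13C5-glutamine). Weights must sum to 1.
#'
#' @param distributions List of `"mid"` objects over the same metabolite.
#' @param weights Numeric vector of route weights, same length, summing to 1.
#' @param metabolite Optional name for the mixture.
#' @return The mixture `"mid"`.
#' @export
mid_mix <- function(distributions, weights, metabolite = NULL) {
  if (length(distributions) != length(weights)) {
    stop("'distributions' and 'weights' must have the same length")
  }
  stopifnot(all(vapply(distributions, inherits, logical(1), "mid")))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  nmax <- max(vapply(distributions, length, integer(1)))
  out <- numeric(nmax)
  for (i in seq_along(distributions)) {
    f <- as.numeric(distributions[[i]])
    out[seq_along(f)] <- out[seq_along(f)] + weights[i] * f
  }
  mid(out, metabolite = metabolite)
}

#' Recover route weights from a mixed MID
#'
#' Solves the least-squares problem `measured ~ basis %*% w` over the route
#' basis MIDs, the standard way a measured isotopologue distribution is
#' decomposed into contributions of candidate routes (e.g. the oxidative vs
#' reductive share of glutamine-derived citrate).
#'
#' @param measured The observed `"mid"`.
#' @param basis List of route basis `"mid"` objects.
#' @return Numeric vector of fitted weights (one per basis route).
#' @export
mid_fit_weights <- function(measured, basis) {
  stopifnot(inherits(measured, "mid"),
            all(vapply(basis, inherits, logical(1), "mid")))
  nmax <- max(length(measured), max(vapply(basis, length, integer(1))))
  pad <- function(f) c(as.numeric(f), numeric(nmax - length(f)))
  X <- vapply(basis, pad, numeric(nmax))
  y <- pad(measured)
  w <- qr.solve(X, y)
  names(w) <- names(basis)
  w
}
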