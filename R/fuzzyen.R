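#' Fuzzy-entropy parameter set
#'
#' Bundles the tunable parameters of the fuzzy-entropy measure: the embedding
#' dimension `m`, the similarity gradient `n`, the tolerance expressed as a
#' fraction `r_factor` of the series' standard deviation, and the functional
#' form of the exponential similarity.
#'
#' The defaults (`m = 2`, `n = 4`, `r_factor = 0.2`) are the standard operating
#' point for short EEG epochs. The effective tolerance `r = r_factor * SD(x)`
#' is recomputed for every input series, using the population standard
#' deviation (divide by N).
#'
#' Two similarity forms are supported. `"as_printed"` uses
#' `exp(-d^n / r)`; `"normalized"` uses the variant common in the
#' fuzzy-entropy literature, `exp(-(d / r)^n)`. They agree for `n = 1` and
#' differ otherwise; only the normalized form is invariant under rescaling of
#' the input (see the methods vignette).
#'
#' @param m Embedding dimension, a positive integer (default 2).
#' @param n Similarity gradient, a positive real (default 4).
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @param form `"as_printed"` or `"normalized"` similarity form.
#'
#' @return An object of class `fuzzyen_params` (a named list).
#' @examples
#' fuzzyen_params()
#' fuzzyen_params(m = 3, form = "normalized")
#' @export
fuzzyen_params <- function(m = 2, n = 4, r_factor = 0.2,
                           form = c("as_printed", "normalized")) {
  form <- match.arg(form)
  if (length(m) != 1 || m < 1 || m != as.integer(m)) {
    abort("`m` must be a single positive integer")
  }
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    abort("`n` must be a single positive number")
  }
  if (length(r_factor) != 1 || !is.finite(r_factor) || r_factor <= 0) {
    abort("`r_factor` must be a single positive number")
  }
  structure(
    list(m = as.integer(m), n = as.numeric(n),
         r_factor = as.numeric(r_factor), form = form),
    class = "fuzzyen_params"
  )
}

#' @export
print.fuzzyen_params <- function(x, ...) {
  cat(sprintf("<fuzzyen_params> m = %d, n = %g, r = %g x SD, form = %s\n",
              x$m, x$n, x$r_factor, x$form))
  invisible(x)
}

check_series <- function(x, m, min_windows = 2) {
  if (!is.numeric(x)) abort("series must be numeric")
  if (any(!is.finite(x))) abort("series contains non-finite samples")
  N <- length(x)
  if (N - m < min_windows) {
    abort(sprintf(
      "series too short for embedding: N = %d, m = %d (need N >= m + %d)",
      N, m, min_windows))
  }
  invisible(N)
}

#' Phase-space embedding with local mean removal
#'
#' Slides a window of length `m` along the series and subtracts each window's
#' own mean, producing the centered vectors on which fuzzy similarity is
#' computed. Exactly `N - m` windows are returned, the number entering the
#' downstream similarity averages at both dimension `m` and `m + 1`, so the
#' two averages are taken over the same index range.
#'
#' @param x Numeric series (all finite), length `N >= m + 2`.
#' @param m Embedding dimension.
#' @return A numeric matrix with `N - m` rows and `m` columns; each row sums
#'   to zero (up to floating error).
#' @examples
#' embed_windows(c(0, 1, 0, 2), m = 2)
#' @export
embed_windows <- function(x, m) {
  check_series(x, m)
  M <- length(x) - m
  idx <- outer(seq_len(M), 0:(m - 1), `+`)
  w <- matrix(x[idx], nrow = M, ncol = m)
  w - rowMeans(w)
}

#' Chebyshev distance between two vectors
#'
#' The maximum absolute componentwise difference, the metric used to compare
#' embedded windows.
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return A nonnegative scalar; zero iff the vectors are identical.
#' @examples
#' chebyshev_distance(c(-0.5, 0.5), c(0.5, -0.5))
#' @export
chebyshev_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    abort("vectors must have the same dimension")
  }
  max(abs(v1 - v2))
}

#' Exponential fuzzy similarity
#'
#' Maps a Chebyshev distance to a similarity degree in (0, 1] via a decaying
#' exponential membership function, with gradient `n` and tolerance `r`.
#'
#' @param d Nonnegative distance(s).
#' @param n Gradient of the exponential.
#' @param r Tolerance (width), must be positive.
#' @param form `"as_printed"` for `exp(-d^n / r)`, `"normalized"` for
#'   `exp(-(d / r)^n)`.
#' @return Similarity value(s) in (0, 1]; 1 at `d = 0`, strictly decreasing
#'   in `d`.
#' @examples
#' fuzzy_similarity(1, n = 4, r = 0.2)           # exp(-5)
#' fuzzy_similarity(1, n = 4, r = 0.2, form = "normalized")
#' @export
fuzzy_similarity <- function(d, n, r, form = c("as_printed", "normalized")) {
  form <- match.arg(form)
  if (length(r) != 1 || !is.finite(r) || r <= 0) abort("`r` must be > 0")
  if (any(d < 0)) abort("distances must be nonnegative")
  if (form == "as_printed") exp(-d^n / r) else exp(-(d / r)^n)
}

#' Average fuzzy similarity at one embedding dimension
#'
#' Computes `phi^m(n, r)`: the mean over the `N - m` embedded windows `i` of
#' the mean similarity between window `i` and every other window `j != i`.
#'
#' @inheritParams embed_windows
#' @param n,r,form As in [fuzzy_similarity()]; `r` here is the absolute
#'   tolerance, already scaled by the series SD if desired.
#' @return A scalar in (0, 1].
#' @export
phi_fuzzy <- function(x, m, n, r, form = c("as_printed", "normalized")) {
  form <- match.arg(form)
  check_series(x, m)
  if (length(r) != 1 || !is.finite(r) || r <= 0) abort("`r` must be > 0")
  fuzzyen_phi_cpp(as.numeric(x), as.integer(m), as.numeric(n),
                  as.numeric(r), form == "normalized")
}

#' Fuzzy entropy of a scalar time series
#'
#' The negative log-ratio of average fuzzy similarity between embedding
#' dimensions `m` and `m + 1`:
#' `FuzzyEn(m, n, r, N) = ln phi^m(n, r) - ln phi^(m+1)(n, r)`,
#' with tolerance `r = r_factor * SD(x)` recomputed on the input series
#' (population SD). Higher values indicate a less regular, more complex
#' signal; in the driver-fatigue setting, fatigue-state EEG epochs score
#' higher than alert-state epochs.
#'
#' A constant series carries no complexity: its SD is zero, and the function
#' returns 0 with a warning rather than dividing by zero.
#'
#' @param x Numeric series (all finite), length `N >= m + 2`.
#' @param params A [fuzzyen_params()] object.
#' @return A single numeric entropy value (0 for constant or affine-ramp
#'   input).
#' @examples
#' set.seed(1)
#' fuzzy_entropy(rnorm(500))              # white noise: high complexity
#' fuzzy_entropy(sin(2 * pi * 10 * (1:500) / 1000))  # regular: low
#' fuzzy_entropy(rep(3, 100))             # constant: 0, with a warning
#' @seealso [fuzzy_entropy_oracle()] for the reference implementation.
#' @export
fuzzy_entropy <- function(x, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  # phi at dimension m + 1 needs >= 2 windows, i.e. N - m >= 3
  check_series(x, params$m, min_windows = 3)
  N <- length(x)
  sdx <- sqrt(sum((x - mean(x))^2) / N)  # population SD
  if (sdx == 0) {
    warn("constant series: SD = 0, returning fuzzy entropy 0")
    return(0)
  }
  r <- params$r_factor * sdx
  norm <- params$form == "normalized"
  phi_m <- fuzzyen_phi_cpp(x, params$m, params$n, r, norm)
  phi_m1 <- fuzzyen_phi_cpp(x, params$m + 1L, params$n, r, norm)
  if (phi_m <= 0 || phi_m1 <= 0) {
    warn("similarity average underflowed to 0; entropy is not finite")
  }
  log(phi_m) - log(phi_m1)
}

#' Reference fuzzy-entropy implementation (naive loops)
#'
#' A literal, loop-by-loop transcription of the fuzzy-entropy definition:
#' explicit window construction, pairwise Chebyshev distances, similarity
#' averaging, all in plain R. Intentionally unoptimized; it exists so the
#' fast path can be verified against an independent route in the test suite.
#' Intended for short series (N up to a few hundred).
#'
#' @inheritParams fuzzy_entropy
#' @return A single numeric entropy value, equal to [fuzzy_entropy()] within
#'   1e-10.
#' @export
fuzzy_entropy_oracle <- function(x, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  check_series(x, params$m, min_windows = 3)
  N <- length(x)
  sdx <- sqrt(sum((x - mean(x))^2) / N)
  if (sdx == 0) {
    warn("constant series: SD = 0, returning fuzzy entropy 0")
    return(0)
  }
  r <- params$r_factor * sdx

  phi_dim <- function(m) {
    M <- N - m
    # windows, each centered by its own mean
    Y <- vector("list", M)
    for (i in seq_len(M)) {
      win <- x[i:(i + m - 1)]
      Y[[i]] <- win - mean(win)
    }
    outer_sum <- 0
    for (i in seq_len(M)) {
      inner_sum <- 0
      for (j in seq_len(M)) {
        if (j == i) next
        d <- chebyshev_distance(Y[[i]], Y[[j]])
        inner_sum <- inner_sum +
          fuzzy_similarity(d, params$n, r, params$form)
      }
      outer_sum <- outer_sum + inner_sum / (M - 1)
    }
    outer_sum / M
  }

  log(phi_dim(params$m)) - log(phi_dim(params$m + 1L))
}
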