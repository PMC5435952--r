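test_that("parameter set validates its fields and carries the defaults", {
  p <- fuzzyen_params()
  expect_equal(p$m, 2L)
  expect_equal(p$n, 4)
  expect_equal(p$r_factor, 0.2)
  expect_equal(p$form, "as_printed")
  expect_error(fuzzyen_params(m = 0), "positive integer")
  expect_error(fuzzyen_params(m = 2.5), "positive integer")
  expect_error(fuzzyen_params(n = -1), "positive")
  expect_error(fuzzyen_params(r_factor = 0), "positive")
})

test_that("embedding centers each window by its own mean and exposes N - m windows", {
  # linear ramp: every centered window identical
  w <- embed_windows(c(1, 2, 3, 4, 5), m = 2)
  expect_equal(nrow(w), 3)
  expect_true(all(apply(w, 1, function(v) isTRUE(all.equal(v, c(-0.5, 0.5))))))

  # hand-evaluated windows of x = (0, 1, 0, 2)
  w2 <- embed_windows(c(0, 1, 0, 2), m = 2)
  expect_equal(nrow(w2), 2)
  expect_equal(w2[1, ], c(-0.5, 0.5))
  expect_equal(w2[2, ], c(0.5, -0.5))

  # constant series: zero vectors
  wc <- embed_windows(rep(4, 10), m = 3)
  expect_true(all(wc == 0))

  # every row sums to zero by construction
  set.seed(5)
  wr <- embed_windows(rnorm(50), m = 4)
  expect_lt(max(abs(rowSums(wr))), 1e-12)

  expect_error(embed_windows(c(1, 2), m = 2), "too short")
  expect_error(embed_windows(c(1, NA, 3, 4, 5), m = 2), "non-finite")
})

test_that("Chebyshev distance is the max componentwise gap, symmetric, zero at identity", {
  expect_equal(chebyshev_distance(c(-0.5, 0.5), c(0.5, -0.5)), 1)
  v <- c(0.3, -0.7, 2)
  expect_equal(chebyshev_distance(v, v), 0)
  a <- 1.7
  expect_equal(chebyshev_distance(c(0, 0), c(a, -a)), abs(a))
  expect_equal(chebyshev_distance(c(a, -a), c(0, 0)), abs(a))
  expect_error(chebyshev_distance(1:2, 1:3), "dimension")
})

test_that("fuzzy similarity is 1 at zero distance, bounded, strictly decreasing", {
  expect_equal(fuzzy_similarity(0, n = 4, r = 0.2), 1)
  expect_equal(fuzzy_similarity(0, n = 2, r = 1, form = "normalized"), 1)
  expect_equal(fuzzy_similarity(1, n = 4, r = 0.2), exp(-5))
  # keep the exponent within the representable range: exp underflows to an
  # exact 0 once d^n/r exceeds ~745
  d <- seq(0, 1.2, by = 0.1)
  for (form in c("as_printed", "normalized")) {
    s <- fuzzy_similarity(d, n = 4, r = 0.25, form = form)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) < 0))
  }
  expect_error(fuzzy_similarity(1, n = 4, r = 0), "> 0")
})

test_that("phi is 1 for perfectly regular series and matches a direct evaluation", {
  for (m in 1:3) {
    expect_equal(phi_fuzzy(rep(2.5, 30), m, n = 4, r = 1), 1)
    expect_equal(phi_fuzzy(seq(1, 10, length.out = 30), m, n = 4, r = 0.1), 1)
  }

  # independent route: embed + pairwise distances + similarity, in R
  set.seed(7)
  x <- rnorm(50)
  for (form in c("as_printed", "normalized")) {
    w <- embed_windows(x, 2)
    M <- nrow(w)
    D <- outer(seq_len(M), seq_len(M), Vectorize(function(i, j) {
      fuzzy_similarity(chebyshev_distance(w[i, ], w[j, ]), 4, 0.3, form)
    }))
    diag(D) <- NA
    expected <- mean(rowMeans(D, na.rm = TRUE))
    expect_equal(phi_fuzzy(x, 2, n = 4, r = 0.3, form = form), expected,
                 tolerance = 1e-12)
  }
})

test_that("fuzzy entropy of constant and affine-ramp series is exactly zero", {
  expect_warning(z <- fuzzy_entropy(rep(3, 100)), "SD = 0")
  expect_identical(z, 0)
  expect_identical(fuzzy_entropy(as.numeric(1:10)), 0)
  expect_identical(fuzzy_entropy(seq(-5, 5, by = 0.25)), 0)
  expect_identical(fuzzy_entropy_oracle(as.numeric(1:10)), 0)
  expect_warning(zo <- fuzzy_entropy_oracle(rep(1, 20)), "SD = 0")
  expect_identical(zo, 0)
})

test_that("length and finiteness preconditions produce informative errors", {
  expect_error(fuzzy_entropy(c(1, 2, 3)), "N = 3, m = 2")
  expect_error(fuzzy_entropy(c(1, 2, Inf, 4, 5, 6)), "non-finite")
  expect_error(fuzzy_entropy_oracle(c(1, 2, 3)), "N = 3")
})

test_that("fast path and naive oracle agree across random series", {
  p <- fuzzyen_params()
  pn <- fuzzyen_params(form = "normalized")
  for (N in c(20, 50, 200)) {
    for (s in 1:4) {
      set.seed(N + s)
      x <- rnorm(N)
      expect_equal(fuzzy_entropy(x, p), fuzzy_entropy_oracle(x, p),
                   tolerance = 1e-12)
    }
  }
  set.seed(99)
  x <- rnorm(60)
  expect_equal(fuzzy_entropy(x, pn), fuzzy_entropy_oracle(x, pn),
               tolerance = 1e-12)
  p3 <- fuzzyen_params(m = 3, n = 2.5)  # non-integer gradient path
  expect_equal(fuzzy_entropy(x, p3), fuzzy_entropy_oracle(x, p3),
               tolerance = 1e-12)
})

test_that("entropy is invariant to constant shifts", {
  set.seed(21)
  x <- rnorm(300)
  for (c0 in c(-1000, 3.7, 250)) {
    expect_equal(fuzzy_entropy(x + c0), fuzzy_entropy(x), tolerance = 1e-12)
  }
})

test_that("scale invariance holds for the normalized form only", {
  set.seed(31)
  x <- rnorm(250)
  pn <- fuzzyen_params(form = "normalized")
  pa <- fuzzyen_params()
  base_n <- fuzzy_entropy(x, pn)
  base_a <- fuzzy_entropy(x, pa)
  for (a in c(0.1, 10, 1000)) {
    expect_equal(fuzzy_entropy(a * x, pn), base_n, tolerance = 1e-10)
  }
  # the as-printed form rescales the exponent by a^(n-1): not invariant
  expect_gt(abs(fuzzy_entropy(10 * x, pa) - base_a), 1e-3)
})

test_that("white-noise entropy stays nonnegative within tolerance", {
  p <- fuzzyen_params()
  vals <- vapply(1:60, function(s) {
    set.seed(s)
    fuzzy_entropy(rnorm(500), p)
  }, 0)
  expect_true(all(vals >= -1e-9))
})
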