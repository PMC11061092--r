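test_that("band-pass keeps in-band tones and suppresses out-of-band energy", {
  fs <- 500
  t <- seq_len(5000) / fs
  mid <- 1000:4000
  rms <- function(x) sqrt(mean(x^2))

  tone10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass(tone10, fs, c(6, 13))
  expect_equal(rms(out10[mid]) / rms(tone10[mid]), 1, tolerance = 0.05)

  tone2 <- sin(2 * pi * 2 * t)
  out2 <- bandpass(tone2, fs, c(6, 13))
  expect_lt(rms(out2[mid]) / rms(tone2[mid]), 0.1)

  flat <- bandpass(rep(1, 5000), fs, c(6, 13))
  expect_lt(max(abs(flat[mid])), 1e-4)

  expect_error(bandpass(tone2, fs, c(6, 300)), class = "eidyn_error_band")

  # matrix input filters row-wise
  m <- rbind(tone10, tone2)
  fm <- bandpass(m, fs, c(6, 13))
  expect_equal(fm[1, ], out10)
  expect_equal(dim(fm), dim(m))
})

test_that("symbolization encodes windows as claimed", {
  expect_equal(as.integer(suppressWarnings(symbolize(c(0, 1, 2, 3)))), 0L)

  s <- suppressWarnings(symbolize(rnorm(10), n = 4, tau = 2))
  expect_length(unclass(s), 10 - 3 * 2)

  expect_error(suppressWarnings(symbolize(rnorm(5), n = 4, tau = 2)),
               class = "eidyn_error_short_series")

  # matches a naive per-window oracle on noisy data, including ties
  x <- round(rnorm(500), 1)                 # rounding forces ties
  for (tau in c(1, 3)) {
    s <- suppressWarnings(symbolize(x, n = 4, tau = tau))
    expect_equal(as.integer(s), as.integer(oracle_symbolize(x, 4, tau)))
  }
})

test_that("the 24 orderings of 4 distinct values give 24 distinct symbols", {
  pats <- ordinal_patterns(4)
  expect_equal(dim(pats), c(24L, 4L))
  vals <- c(3, 11, 27, 40)
  syms <- apply(pats, 1, function(perm) {
    window <- numeric(4)
    window[perm + 1] <- sort(vals)           # realize the ordering
    as.integer(suppressWarnings(symbolize(window, n = 4)))
  })
  expect_setequal(syms, 0:23)
})

test_that("permutation entropy hits its bounds and matches the oracle", {
  expect_equal(permutation_entropy(seq_len(2000)), 0)

  x <- rnorm(2000)
  counts <- tabulate(oracle_symbolize(x) + 1, nbins = 24)
  expect_equal(permutation_entropy(x), oracle_entropy(counts) / log(24))

  big <- with_seed(1, rnorm(1e5))
  expect_gt(permutation_entropy(big), 0.99)

  # invariance under strictly monotone transforms
  y <- with_seed(2, rnorm(3000))
  expect_identical(permutation_entropy(y), permutation_entropy(exp(2 * y)))
  expect_identical(permutation_entropy(y), permutation_entropy(y^3 + 5 * y))
})

test_that("joint symbol distribution is a probability table with the right mass", {
  x <- with_seed(3, rnorm(5000))
  sx <- symbolize(x)
  expect_equal(sum(joint_symbol_distribution(sx, sx)), 1)
  expect_equal(sum(diag(joint_symbol_distribution(sx, sx))), 1)

  y <- with_seed(4, rnorm(5000))
  sy <- symbolize(y)
  P <- joint_symbol_distribution(sx, sy)
  expect_equal(dim(P), c(24, 24))
  expect_true(all(P >= 0))
  expect_equal(sum(P), 1)

  # long independent uniform streams approach the 1/576 product law
  xl <- with_seed(5, rnorm(1e5))
  yl <- with_seed(6, rnorm(1e5))
  Pl <- joint_symbol_distribution(symbolize(xl), symbolize(yl))
  expect_lt(max(abs(Pl - 1 / 576)), 1e-3)

  sz <- suppressWarnings(symbolize(rnorm(100), tau = 2))
  expect_error(joint_symbol_distribution(sx, sz),
               class = "eidyn_error_param_mismatch")
})

test_that("volume-conduction correction zeroes self- and inverted-signal wsMI", {
  x <- with_seed(7, as.vector(bandpass(rnorm(6000), 500, c(1, 40))))
  sx <- symbolize(x)
  expect_equal(wsmi(sx, sx), 0)

  # the sign-flipped signal produces exactly the opposite patterns
  s_neg <- symbolize(-x)
  omap <- opposite_patterns(4)
  expect_equal(as.integer(s_neg), omap[as.integer(sx) + 1])
  expect_equal(wsmi(sx, s_neg), 0)

  # without the correction self-information equals the signal's own
  # pattern entropy (MI(X, X) = H(X) on the log(n!) scale)
  expect_equal(wsmi(sx, sx, vc_correction = FALSE), permutation_entropy(x))
})

test_that("wsMI is symmetric and vanishes for independent streams", {
  x <- with_seed(8, rnorm(2e4))
  y <- with_seed(9, rnorm(2e4))
  sx <- symbolize(x); sy <- symbolize(y)
  expect_equal(wsmi(sx, sy), wsmi(sy, sx))
  expect_lt(abs(wsmi(sx, sy)), 0.01)
})

test_that("inverted joint permutation entropy behaves as a coupling measure", {
  # independent streams: joint entropy maximal, measure near 0
  x <- with_seed(10, rnorm(1e5))
  y <- with_seed(11, rnorm(1e5))
  v_indep <- jpe_inv(symbolize(x), symbolize(y))
  expect_lt(abs(v_indep), 0.02)

  # bounds hold for arbitrary inputs
  for (seed in 1:4) {
    a <- with_seed(seed, rnorm(400))
    b <- with_seed(seed + 50, rnorm(400))
    v <- jpe_inv(suppressWarnings(symbolize(a)),
                 suppressWarnings(symbolize(b)))
    expect_gte(v, 0); expect_lte(v, 1)
  }

  # a delayed copy with pattern-preserving jitter couples the streams
  xs <- with_seed(12, as.vector(bandpass(rnorm(1e4), 500, c(1, 40))))
  lagged <- c(xs[1], xs[-length(xs)]) + with_seed(13, rnorm(1e4, 0, 1e-4))
  v_coupled <- jpe_inv(symbolize(xs), symbolize(lagged))
  expect_gt(v_coupled, v_indep)

  expect_equal(jpe_inv(symbolize(xs), symbolize(lagged)),
               jpe_inv(symbolize(lagged), symbolize(xs)))

  # identical streams have no admissible joint states after masking
  expect_error(jpe_inv(symbolize(xs), symbolize(xs)),
               class = "eidyn_error_empty_joint")
})

test_that("connectivity_matrix is symmetric, equivariant and near-zero under the null", {
  X <- with_seed(14, matrix(rnorm(5 * 16000), 5))
  rownames(X) <- letters[1:5]
  cm <- connectivity_matrix(X, "wsmi")
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  expect_lt(abs(mean(cm[upper.tri(cm)])), 0.01)   # independent-noise null

  # permuting regions permutes rows and columns identically
  perm <- c(3, 1, 5, 2, 4)
  cmp <- connectivity_matrix(X[perm, ], "wsmi")
  expect_equal(unclass(cmp), unclass(cm)[perm, perm], ignore_attr = TRUE)

  # two regions: equal off-diagonal entries
  cm2 <- connectivity_matrix(X[1:2, ], "jpe_inv")
  expect_equal(cm2[1, 2], cm2[2, 1])

  # run averaging equals the mean of per-run matrices
  Y <- with_seed(15, matrix(rnorm(5 * 16000), 5))
  cm_avg <- connectivity_matrix(list(X, Y), "wsmi")
  cm_y <- connectivity_matrix(Y, "wsmi")
  expect_equal(unclass(cm_avg), (unclass(cm) + unclass(cm_y)) / 2,
               ignore_attr = TRUE)

  expect_error(connectivity_matrix(list(X, Y[1:3, ]), "wsmi"),
               class = "eidyn_error_ragged")
})

test_that("pairwise measures agree with the two-sequence functions", {
  X <- with_seed(16, matrix(rnorm(4 * 3000), 4))
  cm_w <- connectivity_matrix(X, "wsmi")
  cm_j <- connectivity_matrix(X, "jpe_inv")
  s1 <- symbolize(X[2, ]); s2 <- symbolize(X[4, ])
  expect_equal(cm_w[2, 4], wsmi(s1, s2))
  expect_equal(cm_j[2, 4], jpe_inv(s1, s2))

  pe_tab <- regional_entropy(X)
  expect_equal(pe_tab$pe[3], permutation_entropy(X[3, ]))
})

test_that("symbolization parameters validate and drive symbolize()", {
  sp <- sym_params(n = 4, tau = 3, band = c(6, 13))
  expect_equal(sp$n, 4L)
  expect_equal(sp$tau, 3L)
  expect_error(sym_params(n = 1), "at least 2")
  expect_error(sym_params(tau = 0), "at least 1")
  expect_error(sym_params(band = c(13, 6)), "low < high")

  x <- with_seed(40, rnorm(400))
  expect_identical(as.integer(symbolize(x, sp)),
                   as.integer(symbolize(x, n = 4, tau = 3)))
})
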