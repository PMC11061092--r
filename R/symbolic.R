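# Ordinal symbolization and symbolic-dynamics measures:
# permutation entropy (PE), weighted symbolic mutual information (wsMI),
# inverted joint permutation entropy (JPE_inv).
#
# Conventions (fixed and documented):
#  * ties in a window are broken by temporal order (earlier sample ranks
#    lower), the classic ordinal-pattern convention;
#  * a symbol is the lexicographic rank (0-based) of the argsort permutation
#    of the window;
#  * natural logarithms with explicit normalization constants throughout;
#  * 0 * log(0) := 0.

#' Symbolization parameters
#'
#' @param n Embedding dimension (window length); `n >= 2`. With the study
#'   default `n = 4` there are `factorial(4) = 24` ordinal patterns.
#' @param tau Time delay in samples between the points of a window;
#'   `tau >= 1`. The study uses 1 (fast dynamics) and 50 (slow dynamics).
#' @param band Optional length-2 pass-band in Hz applied (zero-phase) before
#'   symbolization; the study uses 0.5-70 Hz and 6-13 Hz.
#' @return A `sym_params` object.
#' @export
sym_params <- function(n = 4, tau = 1, band = NULL) {
  n <- as.integer(n); tau <- as.integer(tau)
  if (n < 2) abort("embedding dimension `n` must be at least 2")
  if (tau < 1) abort("time delay `tau` must be at least 1")
  if (!is.null(band)) {
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
      abort("`band` must be (low, high) with 0 < low < high")
    }
  }
  structure(list(n = n, tau = tau, band = band), class = "sym_params")
}

#' All ordinal patterns of dimension n
#'
#' @param n Embedding dimension.
#' @return A `factorial(n) x n` integer matrix; row `k + 1` is the argsort
#'   permutation (0-based) whose lexicographic rank is `k`, i.e. the window
#'   ordering encoded by symbol `k`.
#' @export
ordinal_patterns <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    out <- lapply(seq_along(v), function(i) cbind(v[i], perms(v[-i])))
    do.call(rbind, out)
  }
  p <- perms(0:(n - 1L))
  storage.mode(p) <- "integer"
  p
}

# lexicographic rank (0-based) of one permutation via its Lehmer code
lehmer_rank <- function(sigma) {
  n <- length(sigma)
  f <- rev(cumprod(c(1, seq_len(n - 1))))
  code <- 0
  for (i in seq_len(n - 1)) {
    code <- code + sum(sigma[(i + 1):n] < sigma[i]) * f[i]
  }
  as.integer(code)
}

#' Sign-opposite ordinal pattern map
#'
#' Maps each symbol to the symbol of the amplitude-inverted window (the
#' rank-reversed pattern): the ordinal pattern that `-x` produces where `x`
#' produces the original. Used by the volume-conduction correction, which
#' zero-weights identical and sign-opposite pattern pairs.
#'
#' @param n Embedding dimension.
#' @return Integer vector `v` of length `factorial(n)`; symbol `k` maps to
#'   `v[k + 1]` (0-based symbols).
#' @export
opposite_patterns <- function(n) {
  pats <- ordinal_patterns(n)
  vapply(seq_len(nrow(pats)), function(i) lehmer_rank(rev(pats[i, ])),
         integer(1))
}

# Symbolize every row of a regions x time matrix; returns regions x L
# integer matrix of 0-based symbols. Vectorized over time.
symbolize_matrix <- function(X, n = 4, tau = 1) {
  n <- as.integer(n); tau <- as.integer(tau)
  len <- ncol(X)
  L <- len - (n - 1L) * tau
  if (L < 1L) {
    abort(sprintf(
      "series of length %d too short for n=%d, tau=%d (need >= %d samples)",
      len, n, tau, (n - 1L) * tau + 1L
    ), class = "eidyn_error_short_series")
  }
  nr <- nrow(X)
  f <- rev(cumprod(c(1, seq_len(n - 1))))
  S <- matrix(0L, nr, L)
  for (r in seq_len(nr)) {
    x <- X[r, ]
    V <- matrix(vapply(0:(n - 1L), function(k) x[(1L + k * tau):(L + k * tau)],
                       numeric(L)), L, n)         # L x n windows
    Rk <- matrix(0L, L, n)                        # ranks, earlier-lower ties
    for (k in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j == k) next
        Rk[, k] <- Rk[, k] +
          if (j < k) (V[, j] <= V[, k]) else (V[, j] < V[, k])
      }
    }
    Sg <- matrix(0L, L, n)                        # argsort = inverse of ranks
    for (k in seq_len(n)) Sg[cbind(seq_len(L), Rk[, k] + 1L)] <- k - 1L
    code <- integer(L)                            # Lehmer -> lexicographic
    for (i in seq_len(n - 1L)) {
      li <- integer(L)
      for (j in (i + 1L):n) li <- li + (Sg[, j] < Sg[, i])
      code <- code + li * f[i]
    }
    S[r, ] <- code
  }
  S
}

new_ordinal_seq <- function(symbols, n, tau, source_length) {
  structure(as.integer(symbols), class = "ordinal_seq",
            n = as.integer(n), tau = as.integer(tau),
            source_length = as.integer(source_length))
}

#' Symbolize a time series into ordinal patterns
#'
#' Slides a window of `n` samples spaced `tau` apart along the series and
#' encodes the amplitude ordering of each window as an integer symbol in
#' `[0, n! - 1]` (lexicographic rank of the argsort permutation; ties broken
#' by temporal order). The result has `length(series) - (n - 1) * tau`
#' symbols.
#'
#' @param series Numeric time series.
#' @param n Embedding dimension, or a [sym_params()] object supplying both
#'   `n` and `tau`.
#' @param tau Time delay in samples.
#' @return An `ordinal_seq`: integer vector with attributes `n`, `tau` and
#'   `source_length`.
#' @examples
#' symbolize(c(0, 1, 2, 3), n = 4)     # single ascending pattern: symbol 0
#' @export
symbolize <- function(series, n = 4, tau = 1) {
  if (inherits(n, "sym_params")) {
    tau <- n$tau
    n <- n$n
  }
  if (length(series) < 10 * factorial(n)) {
    warn(sprintf(
      "series length %d < 10 * n! = %d; pattern probabilities will be noisy",
      length(series), 10 * factorial(n)
    ), class = "eidyn_warn_short_series")
  }
  S <- symbolize_matrix(matrix(series, nrow = 1L), n = n, tau = tau)
  new_ordinal_seq(S[1L, ], n, tau, length(series))
}

#' @export
print.ordinal_seq <- function(x, ...) {
  cat(sprintf("<ordinal_seq> %d symbols, n=%d (of %d patterns), tau=%d\n",
              length(unclass(x)), attr(x, "n"),
              factorial(attr(x, "n")), attr(x, "tau")))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase), giving effectively 8th-order magnitude response and no
#' phase distortion, which matters because ordinal patterns are sensitive to
#' local temporal structure.
#'
#' @param x Numeric vector, or a regions-by-time matrix filtered row-wise.
#' @param fs Sampling frequency in Hz.
#' @param band Length-2 pass-band (low, high) in Hz; must lie inside
#'   (0, fs/2).
#' @return Filtered series of the same shape as `x`.
#' @export
bandpass <- function(x, fs, band) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    abort(sprintf(
      "pass-band (%.3g, %.3g) must satisfy 0 < low < high < fs/2 = %.3g",
      band[1], band[2], fs / 2
    ), class = "eidyn_error_band")
  }
  bf <- butter(4, band / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, function(row) filtfilt(bf, row)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    filtfilt(bf, x)
  }
}

check_seq_pair <- function(sx, sy) {
  stopifnot(inherits(sx, "ordinal_seq"), inherits(sy, "ordinal_seq"))
  if (attr(sx, "n") != attr(sy, "n") || attr(sx, "tau") != attr(sy, "tau")) {
    abort("ordinal sequences have mismatched (n, tau) parameters",
          class = "eidyn_error_param_mismatch")
  }
  if (length(unclass(sx)) != length(unclass(sy))) {
    abort("ordinal sequences have different lengths",
          class = "eidyn_error_param_mismatch")
  }
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy of a symbol sequence
#'
#' Shannon entropy of the ordinal-pattern distribution normalized by
#' `log(n!)`, so that 0 means a fully regular signal (one pattern) and 1 a
#' maximally variable one (uniform pattern use).
#'
#' @param x An `ordinal_seq` from [symbolize()], or a numeric series (then
#'   symbolized with `n`, `tau` first).
#' @param n,tau Embedding parameters used when `x` is a raw series.
#' @return Scalar in \[0, 1\].
#' @export
permutation_entropy <- function(x, n = 4, tau = 1) {
  if (!inherits(x, "ordinal_seq")) x <- symbolize(x, n = n, tau = tau)
  nfac <- factorial(attr(x, "n"))
  counts <- tabulate(unclass(x) + 1L, nbins = nfac)
  entropy_nat(counts / sum(counts)) / log(nfac)
}

#' Joint distribution of co-occurring ordinal patterns
#'
#' @param sx,sy `ordinal_seq` objects of equal length and equal `(n, tau)`.
#' @return An `n! x n!` matrix of joint probabilities (rows: `sx` symbols,
#'   columns: `sy` symbols) summing to 1, before any weighting.
#' @export
joint_symbol_distribution <- function(sx, sy) {
  check_seq_pair(sx, sy)
  nfac <- factorial(attr(sx, "n"))
  counts <- tabulate(unclass(sx) + nfac * unclass(sy) + 1L,
                     nbins = nfac * nfac)
  matrix(counts / sum(counts), nfac, nfac)
}

# weight matrix of the volume-conduction correction: zero on identical and
# sign-opposite pattern pairs, one elsewhere
vc_weight_matrix <- function(n) {
  nfac <- factorial(n)
  W <- matrix(1, nfac, nfac)
  diag(W) <- 0
  W[cbind(seq_len(nfac), opposite_patterns(n) + 1L)] <- 0
  W
}

#' Weighted symbolic mutual information
#'
#' Mutual information over the joint ordinal-pattern distribution of two
#' signals, normalized by `log(n!)`. With the volume-conduction correction
#' (default) identical and sign-opposite pattern pairs carry zero weight, so
#' instantaneous mixing of one source into both signals contributes nothing:
#' a signal has zero wsMI with itself and with its sign-inverse.
#'
#' @param sx,sy `ordinal_seq` objects with matching parameters.
#' @param vc_correction Apply the volume-conduction weight mask
#'   (default `TRUE`).
#' @return Scalar; near 0 for independent signals, positive for coupled
#'   signals sharing non-trivial pattern co-occurrences.
#' @export
wsmi <- function(sx, sy, vc_correction = TRUE) {
  check_seq_pair(sx, sy)
  n <- attr(sx, "n")
  nfac <- factorial(n)
  P <- joint_symbol_distribution(sx, sy)
  px <- rowSums(P); py <- colSums(P)
  W <- if (vc_correction) vc_weight_matrix(n) else matrix(1, nfac, nfac)
  nz <- which(P > 0 & W > 0, arr.ind = TRUE)
  p <- P[nz]
  sum(p * log(p / (px[nz[, 1L]] * py[nz[, 2L]]))) / log(nfac)
}

#' Inverted joint permutation entropy
#'
#' One minus the normalized joint Shannon entropy of the co-occurring
#' ordinal patterns of two signals. With the volume-conduction correction
#' (default) identical and sign-opposite pattern cells are masked out and
#' the distribution renormalized; the entropy is normalized by the log of
#' the number of admissible joint states (`n!^2 - 2 n!` masked, `n!^2`
#' unmasked) so the result lies in \[0, 1\]. Higher values mean stronger
#' coupling: independent signals spread mass over all admissible cells
#' (value near 0), coupled signals concentrate it (value near 1).
#'
#' @inheritParams wsmi
#' @return Scalar in \[0, 1\].
#' @export
jpe_inv <- function(sx, sy, vc_correction = TRUE) {
  check_seq_pair(sx, sy)
  n <- attr(sx, "n")
  nfac <- factorial(n)
  P <- joint_symbol_distribution(sx, sy)
  if (vc_correction) {
    P[vc_weight_matrix(n) == 0] <- 0
    m_states <- nfac * nfac - 2L * nfac
  } else {
    m_states <- nfac * nfac
  }
  tot <- sum(P)
  if (tot == 0) {
    abort("joint distribution is empty after volume-conduction masking",
          class = "eidyn_error_empty_joint")
  }
  1 - entropy_nat(P / tot) / log(m_states)
}

# One pass over all region pairs computing wsMI and JPE_inv together from a
# regions x L symbol matrix (integer, 0-based). Returns both matrices.
pairwise_symbolic <- function(S, n, vc_correction = TRUE) {
  nfac <- factorial(n)
  nr <- nrow(S)
  L <- ncol(S)
  marg <- apply(S + 1L, 1L, tabulate, nbins = nfac) / L   # nfac x regions
  W <- vc_weight_matrix(n)
  mask0 <- which(W == 0)
  m_states <- if (vc_correction) nfac * nfac - 2L * nfac else nfac * nfac
  log_nfac <- log(nfac); log_m <- log(m_states)
  wsmi_m <- jpe_m <- matrix(0, nr, nr)
  for (i in seq_len(nr - 1L)) {
    si <- S[i, ]
    for (j in (i + 1L):nr) {
      counts <- tabulate(si + nfac * S[j, ] + 1L, nbins = nfac * nfac)
      p <- counts / L
      nz <- which(p > 0)
      if (vc_correction) {
        keep <- !(nz %in% mask0)
        pnz <- p[nz[keep]]
        ix <- ((nz[keep] - 1L) %% nfac) + 1L
        iy <- ((nz[keep] - 1L) %/% nfac) + 1L
        ws <- sum(pnz * log(pnz / (marg[ix, i] * marg[iy, j]))) / log_nfac
        pj <- pnz / sum(pnz)
      } else {
        pnz <- p[nz]
        ix <- ((nz - 1L) %% nfac) + 1L
        iy <- ((nz - 1L) %/% nfac) + 1L
        ws <- sum(pnz * log(pnz / (marg[ix, i] * marg[iy, j]))) / log_nfac
        pj <- pnz
      }
      wsmi_m[i, j] <- wsmi_m[j, i] <- ws
      jpe_m[i, j] <- jpe_m[j, i] <- 1 + sum(pj * log(pj)) / log_m
    }
  }
  list(wsmi = wsmi_m, jpe_inv = jpe_m,
       pe = apply(marg, 2L, entropy_nat) / log_nfac)
}

#' Pairwise symbolic connectivity matrix
#'
#' Computes the region-by-region connectivity matrix for one measure from
#' multichannel data. Input may be a regions-by-time numeric matrix (one
#' run) or a list of such matrices (independent runs, averaged).
#'
#' @param x Regions-by-time numeric matrix, or list of such matrices.
#' @param measure `"wsmi"` or `"jpe_inv"`.
#' @param n,tau Embedding parameters.
#' @param vc_correction Apply the volume-conduction mask (default `TRUE`).
#' @return A `connectivity_matrix`: symmetric numeric matrix (zero diagonal,
#'   excluded from all summaries) with attributes `measure`, `n`, `tau`.
#' @export
connectivity_matrix <- function(x, measure = c("wsmi", "jpe_inv"),
                                n = 4, tau = 1, vc_correction = TRUE) {
  measure <- match.arg(measure)
  runs <- if (is.list(x)) x else list(x)
  nr <- nrow(runs[[1L]])
  if (nr < 2) abort("at least 2 regions are required")
  if (!all(vapply(runs, function(m) nrow(m) == nr && is.matrix(m),
                  logical(1)))) {
    abort("all runs must be matrices with the same number of regions",
          class = "eidyn_error_ragged")
  }
  acc <- matrix(0, nr, nr)
  for (run in runs) {
    S <- symbolize_matrix(run, n = n, tau = tau)
    acc <- acc + pairwise_symbolic(S, n, vc_correction)[[measure]]
  }
  out <- acc / length(runs)
  dimnames(out) <- dimnames(runs[[1L]])[c(1L, 1L)]
  structure(out, class = c("connectivity_matrix", "matrix", "array"),
            measure = measure, n = as.integer(n), tau = as.integer(tau))
}

#' Per-region permutation entropy of multichannel data
#'
#' @param x Regions-by-time numeric matrix, or list of such matrices
#'   (independent runs, averaged).
#' @param n,tau Embedding parameters.
#' @return Tibble with columns `region`, `pe`.
#' @export
regional_entropy <- function(x, n = 4, tau = 1) {
  runs <- if (is.list(x)) x else list(x)
  nr <- nrow(runs[[1L]])
  vals <- rowMeans(vapply(runs, function(run) {
    S <- symbolize_matrix(run, n = n, tau = tau)
    nfac <- factorial(n)
    counts <- apply(S + 1L, 1L, tabulate, nbins = nfac)
    apply(counts / ncol(S), 2L, entropy_nat) / log(nfac)
  }, numeric(nr)))
  labels <- rownames(runs[[1L]])
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(nr))
  tibble(region = labels, pe = vals)
}
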