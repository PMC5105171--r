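#' Singular spectrum analysis of a series
#'
#' Embeds the series in a trajectory matrix of window length `L` (Hankel
#' matrix of lagged segments), takes its singular value decomposition, and
#' reconstructs one elementary series per eigentriple by diagonal
#' (anti-diagonal) averaging. The elementary components sum exactly to the
#' original series; the squared singular values ("eigenvalues") are
#' non-negative and returned in descending order, and their sum equals the
#' squared Frobenius norm of the trajectory matrix.
#'
#' Each component is assigned a characteristic frequency: the argmax of its
#' zero-padded periodogram (in cycles per time step; a dominant frequency of
#' 0 corresponds to trend, period infinity).
#'
#' @param x Numeric series, no missing values.
#' @param L Window length, `2 <= L <= length(x)/2`; default
#'   `floor(length(x)/2)`.
#' @param nfft Zero-padded FFT length for the component periodograms.
#' @return An object of class `"ssa_decomp"`: list with `series`, `L`,
#'   `eigenvalues`, `components` (n x r matrix), `frequency`, `period`.
#' @export
ssa_decompose <- function(x, L = floor(length(x) / 2), nfft = 512) {
  if (any(!is.finite(x))) abort("`x` must be finite with no missing values.")
  n <- length(x)
  if (L < 2 || L > n / 2) abort("`L` must satisfy 2 <= L <= length(x)/2.")
  K <- n - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1)]
  sv <- svd(X)
  r <- sum(sv$d > 0)
  r <- max(r, 1)
  diag_idx <- factor(as.vector(row(X) + col(X)) - 1L, levels = seq_len(n))
  comps <- matrix(0, n, r)
  for (k in seq_len(r)) {
    Xk <- sv$d[k] * tcrossprod(sv$u[, k], sv$v[, k])
    comps[, k] <- as.vector(tapply(as.vector(Xk), diag_idx, mean))
  }
  freq <- apply(comps, 2, dominant_frequency, nfft = nfft)
  structure(list(
    series = x, L = L, eigenvalues = sv$d[seq_len(r)]^2,
    components = comps, frequency = freq, period = 1 / freq
  ), class = "ssa_decomp")
}

## argmax of the zero-padded periodogram, in cycles per step (0 = trend)
dominant_frequency <- function(comp, nfft = 512) {
  n <- length(comp)
  nfft <- max(nfft, n)
  p <- Mod(fft(c(comp, rep(0, nfft - n))))^2
  half <- seq_len(nfft %/% 2 + 1)
  (which.max(p[half]) - 1) / nfft
}

#' @export
print.ssa_decomp <- function(x, ...) {
  cat(sprintf("SSA decomposition: n = %d, L = %d, %d components\n",
              length(x$series), x$L, ncol(x$components)))
  share <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("  leading eigenvalue shares: %s\n",
              paste(sprintf("%.3f", head(share, 5)), collapse = " ")))
  invisible(x)
}

#' @export
tidy.ssa_decomp <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    share = x$eigenvalues / sum(x$eigenvalues),
    frequency = x$frequency,
    period = x$period
  )
}

#' @export
glance.ssa_decomp <- function(x, ...) {
  tibble(
    n = length(x$series), L = x$L, n_components = ncol(x$components),
    leading_share = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

#' Extract the low-frequency subsignal from an SSA decomposition
#'
#' Sums the elementary components whose dominant period is at least
#' `min_period` time steps (default 5, the "5-year dynamic" when applied to
#' annual series: trend plus oscillations slower than 5 years). The
#' alternative mode `"nearest"` selects only the component(s) whose dominant
#' period is closest to `min_period`.
#'
#' @param decomp An `"ssa_decomp"` object.
#' @param min_period Minimum period (time steps) of retained components.
#' @param mode `"low"` (band of periods >= `min_period`) or `"nearest"`.
#' @return A tibble `index, x5, residual` with `x5 + residual` equal to the
#'   original series.
#' @export
extract_band <- function(decomp, min_period = 5, mode = c("low", "nearest")) {
  mode <- match.arg(mode)
  sel <- switch(mode,
    low = decomp$period >= min_period,
    nearest = {
      d <- abs(decomp$period - min_period)
      d == min(d)
    }
  )
  if (!any(sel)) {
    warn("No component in the requested band; subsignal is identically zero.")
    x5 <- rep(0, length(decomp$series))
  } else {
    x5 <- rowSums(decomp$components[, sel, drop = FALSE])
  }
  tibble(index = seq_along(decomp$series), x5 = x5,
         residual = decomp$series - x5)
}

#' IAAFT surrogate of a series
#'
#' Iterative Amplitude Adjusted Fourier Transform: generates a surrogate
#' whose sorted values equal the original's sorted values exactly (amplitude
#' distribution preserved) and whose power spectrum matches the original's
#' to within the iteration tolerance. Starting from a random permutation of
#' the data, each iteration (i) imposes the original Fourier amplitudes
#' while keeping the current phases, then (ii) rank-maps the result back
#' onto the original values. Deterministic for a given seed.
#'
#' Because the iteration's fixed point depends on the random initial
#' permutation, several restarts are performed and the surrogate with the
#' smallest spectral mismatch is returned (every candidate has exactly the
#' original amplitudes, so the restart selection only improves the spectrum).
#'
#' @param x Numeric series, length >= 8, finite.
#' @param n_iter Maximum number of iterations per restart.
#' @param tol Convergence tolerance on the change of the relative spectrum
#'   mismatch between iterations.
#' @param n_restart Number of random initialisations.
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG state.
#' @return A numeric surrogate series of the same length.
#' @export
iaaft_surrogate <- function(x, n_iter = 1000, tol = 1e-8, n_restart = 10,
                            seed = NULL) {
  if (any(!is.finite(x))) abort("`x` must be finite.")
  n <- length(x)
  if (n < 8) abort("`x` must have at least 8 observations.")
  if (!is.null(seed)) withr::local_seed(seed)
  sorted_x <- sort(x)
  target_amp <- Mod(fft(x))
  amp_norm <- sum(target_amp^2)
  best <- NULL
  best_err <- Inf
  for (re in seq_len(n_restart)) {
    s <- sample(x)
    last_err <- Inf
    for (iter in seq_len(n_iter)) {
      phase <- Arg(fft(s))
      s_spec <- Re(fft(target_amp * exp(1i * phase), inverse = TRUE)) / n
      s <- sorted_x[rank(s_spec, ties.method = "first")]
      err <- sqrt(sum((Mod(fft(s)) - target_amp)^2) / amp_norm)
      if (is.finite(last_err) && abs(last_err - err) < tol) break
      last_err <- err
    }
    if (err < best_err) {
      best <- s
      best_err <- err
    }
  }
  best
}

#' Extraction uncertainty of the low-frequency subsignal
#'
#' Quantifies the inseparability of closely spaced SSA modes with a
#' surrogate ensemble: the residual (series minus subsignal) is replaced by
#' IAAFT surrogates, the subsignal is added back, and the decomposition and
#' band extraction are repeated; the pointwise standard deviation of the
#' re-extracted subsignals measures the extraction uncertainty.
#'
#' @param x Numeric series.
#' @param L SSA window length (default `floor(length(x)/2)`).
#' @param min_period Band definition passed to [extract_band()].
#' @param n_surrogates Ensemble size (default 100).
#' @param seed Integer seed for the surrogate ensemble.
#' @return A tibble `index, x5, sd` with the subsignal of the original
#'   series and its pointwise extraction uncertainty.
#' @export
subsignal_uncertainty <- function(x, L = floor(length(x) / 2), min_period = 5,
                                  n_surrogates = 100, seed = 1) {
  base <- extract_band(ssa_decompose(x, L), min_period)
  if (all(abs(base$residual) < .Machine$double.eps^0.5)) {
    return(tibble(index = base$index, x5 = base$x5, sd = 0))
  }
  withr::local_seed(seed)
  reps <- vapply(seq_len(n_surrogates), function(i) {
    y <- base$x5 + iaaft_surrogate(base$residual)
    extract_band(ssa_decompose(y, L), min_period)$x5
  }, numeric(length(x)))
  tibble(index = base$index, x5 = base$x5, sd = apply(reps, 1, sd))
}

#' @export
autoplot.ssa_decomp <- function(object, min_period = 5, ...) {
  band <- extract_band(object, min_period)
  df <- tibble(index = band$index, series = object$series, x5 = band$x5)
  ggplot2::ggplot(df, ggplot2::aes(.data$index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$series), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$x5), linewidth = 0.9) +
    ggplot2::labs(
      x = "Time step", y = "Value",
      title = sprintf("SSA low-frequency subsignal (periods >= %g steps)",
                      min_period)
    ) +
    ggplot2::theme_minimal()
}
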