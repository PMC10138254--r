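# Seeded generators for single BOLD-like signals with prescribed
# scale-wise variance structure.
#
# A signal is a sum of band-limited components (white noise passed
# through the level's MODWT-rescaled equivalent wavelet filter,
# circularly) plus an optional AR(1)-spectrum background synthesized as
# a circularly stationary Gaussian process. Because every ingredient is
# circularly stationary, the expected wavelet variance at each level is
# available in closed form from the filters' squared gains, and the
# component amplitudes are solved (linear system in the squared gains)
# so that the expected wavelet variance of the sum matches the requested
# per-level targets exactly, with the background contribution added on
# top.

.gen_cache <- new.env(parent = emptyenv())

# rescaled equivalent wavelet filter of level j (memoized: the cascade
# convolution is identical across the many signals of a cohort)
.equiv_wavelet <- function(filter, j) {
  key <- paste0("h_", filter, "_", j)
  if (is.null(.gen_cache[[key]])) {
    base <- wavelet_filter(filter)$wavelet
    .gen_cache[[key]] <- level_filter(base, j, rescale = TRUE)$equivalent_values
  }
  .gen_cache[[key]]
}

.equiv_wavelet_fft <- function(filter, j, N) {
  key <- paste0("F_", filter, "_", j, "_", N)
  if (is.null(.gen_cache[[key]])) {
    h <- .equiv_wavelet(filter, j)
    .gen_cache[[key]] <- stats::fft(c(h, rep(0, N - length(h))))
  }
  .gen_cache[[key]]
}

# squared gain of each level's rescaled equivalent wavelet filter at the
# N Fourier frequencies; N x J0 matrix (memoized per (filter, J0, N))
.level_gain_matrix <- function(filter, J0, N) {
  key <- paste0("G_", filter, "_", J0, "_", N)
  if (!is.null(.gen_cache[[key]])) return(.gen_cache[[key]])
  G <- matrix(0, N, J0)
  for (j in seq_len(J0)) {
    h <- .equiv_wavelet(filter, j)
    if (length(h) > N) {
      stop(sprintf("level %d infeasible: equivalent filter length %d exceeds N = %d",
                   j, length(h), N), call. = FALSE)
    }
    G[, j] <- Mod(stats::fft(c(h, rep(0, N - length(h)))))^2
  }
  .gen_cache[[key]] <- G
  G
}

# AR(1) power spectrum at the N Fourier frequencies
.ar1_spectrum <- function(N, ar1, noise_sd) {
  f <- (seq_len(N) - 1) / N
  noise_sd^2 / Mod(1 - ar1 * exp(-2i * pi * f))^2
}

# Solve B a^2 = targets for the squared component amplitudes, where
# B[j,k] = (1/N) sum_f |H_j|^2 |H_k|^2 couples the levels through the
# overlap of their pass-bands. When the exact solution needs a negative
# component (a target sitting below the leakage from its neighbours)
# the non-negative least-squares projection is used instead, and
# expected_wvar() reports the realized expectation B a^2.
.solve_component_sd <- function(G, level_variances) {
  B <- crossprod(G) / nrow(G)
  a2 <- solve(B, level_variances)
  if (any(a2 < -1e-10)) {
    a2 <- pracma::lsqnonneg(B, level_variances)$x
  }
  sqrt(pmax(a2, 0))
}

#' Specification for a synthetic BOLD-like signal
#'
#' @param n Number of samples.
#' @param dt Sampling interval in seconds (default 0.8).
#' @param level_variances Target expected wavelet variance per level
#'   `1..J0` (signal units squared); `J0` is its length.
#' @param ar1 Lag-1 autoregressive coefficient of the background, in
#'   (-1, 1).
#' @param noise_sd Innovation standard deviation of the background.
#' @param filter Filter identifier (default `"la8"`).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n, level_variances, dt = 0.8, ar1 = 0,
                            noise_sd = 0, filter = "la8", seed = NULL) {
  stopifnot(n >= 2, all(level_variances >= 0), abs(ar1) < 1, noise_sd >= 0,
            dt > 0)
  structure(
    list(n = as.integer(n), dt = dt,
         level_variances = as.numeric(level_variances),
         ar1 = ar1, noise_sd = noise_sd, filter = filter, seed = seed),
    class = "simulation_spec"
  )
}

#' Expected wavelet variance of a simulated signal
#'
#' Closed-form expectation of the (unbiased) wavelet-variance estimate
#' at each level for a signal drawn from `spec`: the band-component
#' contribution (equal to `level_variances` whenever a non-negative
#' component mix can reproduce them, otherwise its non-negative
#' least-squares projection) plus the background's band contribution
#' `(1/N) sum_f |H_j(f)|^2 S_ar1(f)`.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with columns `level`, `target` and `expected`.
#' @export
expected_wvar <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  J0 <- length(spec$level_variances)
  G <- .level_gain_matrix(spec$filter, J0, spec$n)
  B <- crossprod(G) / spec$n
  amp <- .solve_component_sd(G, spec$level_variances)
  comp <- as.numeric(B %*% amp^2)
  bg <- if (spec$noise_sd > 0) {
    as.numeric(crossprod(G, .ar1_spectrum(spec$n, spec$ar1, spec$noise_sd))) / spec$n
  } else {
    numeric(J0)
  }
  tibble::tibble(level = seq_len(J0),
                 target = spec$level_variances,
                 expected = comp + bg)
}

#' Simulate a BOLD-like signal with prescribed scale structure
#'
#' Draws one realization from the generative model described in
#' [simulation_spec()]: independent Gaussian noise filtered circularly
#' through each level's equivalent wavelet filter, with amplitudes
#' solved so the expected wavelet variance per level equals
#' `level_variances`, plus an AR(1)-spectrum background. Rest-like BOLD
#' series are obtained with variances increasing towards high levels
#' (low frequencies), task-like series with the bulk at low levels.
#'
#' @param spec A [simulation_spec()].
#' @return Numeric vector of length `spec$n` with attribute `dt`.
#' @examples
#' spec <- simulation_spec(450, level_variances = c(1, 2, 4, 8, 16) / 100,
#'                         seed = 42)
#' x <- simulate_signal(spec)
#' wvar_profile(x)
#' @export
simulate_signal <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  J0 <- length(spec$level_variances)
  N <- spec$n
  G <- .level_gain_matrix(spec$filter, J0, N)
  amp <- .solve_component_sd(G, spec$level_variances)
  x <- numeric(N)
  for (j in seq_len(J0)) {
    if (amp[j] == 0) next
    hf <- .equiv_wavelet_fft(spec$filter, j, N)
    eps <- stats::rnorm(N)
    comp <- Re(stats::fft(stats::fft(eps) * hf, inverse = TRUE)) / N
    x <- x + amp[j] * comp
  }
  if (spec$noise_sd > 0) {
    if (spec$ar1 == 0) {
      x <- x + stats::rnorm(N, sd = spec$noise_sd)
    } else {
      lambda <- .ar1_spectrum(N, spec$ar1, spec$noise_sd)
      eta <- complex(real = stats::rnorm(N, sd = sqrt(0.5)),
                     imaginary = stats::rnorm(N, sd = sqrt(0.5)))
      z <- stats::fft(sqrt(lambda) * eta, inverse = TRUE) / sqrt(N)
      x <- x + sqrt(2) * Re(z)
    }
  }
  attr(x, "dt") <- spec$dt
  x
}
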