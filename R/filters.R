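# Base wavelet/scaling filter construction and validation.
#
# Filter taps are stored in the DWT normalization (scaling taps sum to
# sqrt(2), unit energy); the MODWT-rescaled form (division by 2^(j/2)) is
# produced by level_filter(). Tap tables are the published double-precision
# values of the Daubechies families; orientation follows the decomposition
# (analysis) convention in which the wavelet filter is obtained from the
# scaling filter by h_l = (-1)^(l+1) g_(L-1-l).

# scaling (low-pass) taps, DWT normalization
.filter_tables <- list(
  haar = c(0.7071067811865475, 0.7071067811865475),
  # extremal-phase (minimum delay) D(4)
  d4 = c(0.48296291314453416, 0.8365163037378079,
         0.2241438680420134, -0.12940952255126037),
  # least-asymmetric LA(8)
  la8 = c(-0.07576571478927333, -0.02963552764599851,
          0.49761866763201545, 0.80373875180591614,
          0.29785779560527736, -0.09921954357684722,
          -0.01260396726203783, 0.03222310060404270)
)

.filter_id <- function(L, family) {
  family <- match.arg(family, c("least-asymmetric", "extremal-phase", "haar"))
  id <- switch(family,
    "haar" = if (L == 2L) "haar",
    "extremal-phase" = if (L == 4L) "d4",
    "least-asymmetric" = if (L == 8L) "la8"
  )
  if (is.null(id)) {
    stop(sprintf("unsupported filter: family '%s' with length L = %d", family, L),
         call. = FALSE)
  }
  id
}

.id_family <- c(haar = "haar", d4 = "extremal-phase", la8 = "least-asymmetric")

new_wavelet_filter <- function(values, family, kind,
                               normalization = "dwt", id = NA_character_) {
  structure(
    list(values = as.numeric(values), L = length(values), family = family,
         kind = kind, normalization = normalization, id = id),
    class = "wavelet_filter"
  )
}

#' Construct a base scaling/wavelet filter pair
#'
#' Builds the length-`L` decomposition scaling (low-pass) filter of the
#' requested Daubechies family in the DWT normalization and derives its
#' wavelet (high-pass) partner through the quadrature-mirror relation.
#' Both filters satisfy the admissibility conditions: the wavelet taps sum
#' to zero, the scaling taps sum to `sqrt(2)`, both have unit energy, and
#' even shifts are orthogonal.
#'
#' @param L Even filter length. Supported: 2 (`"haar"`), 4
#'   (`"extremal-phase"`), 8 (`"least-asymmetric"`).
#' @param family One of `"least-asymmetric"`, `"extremal-phase"`, `"haar"`.
#' @return A list with elements `scaling` and `wavelet`, each a
#'   `wavelet_filter` object with fields `values`, `L`, `family`, `kind`,
#'   `normalization` and `id`.
#' @examples
#' f <- make_base_filters(8, "least-asymmetric")
#' round(f$wavelet$values, 4)
#' @export
make_base_filters <- function(L = 8, family = "least-asymmetric") {
  if (length(L) != 1L || L < 2 || L %% 2 != 0) {
    stop("filter length L must be a single even integer >= 2", call. = FALSE)
  }
  id <- .filter_id(as.integer(L), family)
  g <- new_wavelet_filter(.filter_tables[[id]], .id_family[[id]],
                          kind = "scaling", id = id)
  list(scaling = g, wavelet = qmf(g))
}

#' Look up a base filter pair by identifier
#'
#' Convenience wrapper around [make_base_filters()] accepting the short
#' identifiers used in run configurations.
#'
#' @param id `"la8"`, `"d4"` or `"haar"`.
#' @return As [make_base_filters()].
#' @export
wavelet_filter <- function(id = "la8") {
  id <- match.arg(id, names(.filter_tables))
  L <- length(.filter_tables[[id]])
  make_base_filters(L, .id_family[[id]])
}

#' Quadrature mirror filter
#'
#' Converts a scaling filter into its wavelet partner and vice versa.
#' For a scaling filter `g` the wavelet taps are
#' `h_l = (-1)^(l+1) g_(L-1-l)` (decomposition orientation); the inverse
#' map `g_l = (-1)^l h_(L-1-l)` is applied when a wavelet filter is given,
#' so `qmf(qmf(f))` recovers `f` exactly.
#'
#' @param f A `wavelet_filter` in DWT normalization.
#' @return The mirror `wavelet_filter`; the `kind` field flips.
#' @export
qmf <- function(f) {
  stopifnot(inherits(f, "wavelet_filter"))
  if (!identical(f$normalization, "dwt")) {
    stop("qmf() expects a DWT-normalized filter", call. = FALSE)
  }
  L <- f$L
  l <- seq_len(L) - 1L
  if (f$kind == "scaling") {
    vals <- (-1)^(l + 1) * rev(f$values)
    kind <- "wavelet"
  } else {
    vals <- (-1)^l * rev(f$values)
    kind <- "scaling"
  }
  new_wavelet_filter(vals, f$family, kind, f$normalization, f$id)
}

#' Check filter admissibility
#'
#' Reports the three admissibility diagnostics for a DWT-normalized
#' filter: the tap sum (0 for a wavelet filter, `sqrt(2)` for a scaling
#' filter), the tap energy (1 for both), and the largest absolute inner
#' product between the filter and its nonzero even shifts (0).
#'
#' @param f A `wavelet_filter`.
#' @param tol Absolute tolerance for the pass verdict (default `1e-10`).
#' @return A one-row tibble with columns `kind`, `tap_sum`, `energy`,
#'   `max_even_shift_dot`, and logical `pass`.
#' @export
check_admissibility <- function(f, tol = 1e-10) {
  stopifnot(inherits(f, "wavelet_filter"))
  v <- f$values
  L <- f$L
  target_sum <- if (f$kind == "wavelet") 0 else sqrt(2)
  shifts <- if (L >= 4L) seq(2L, L - 2L, by = 2L) else integer(0)
  dots <- vapply(shifts, function(s) {
    sum(v[seq_len(L - s)] * v[seq_len(L - s) + s])
  }, numeric(1))
  max_dot <- if (length(dots)) max(abs(dots)) else 0
  tibble::tibble(
    kind = f$kind,
    tap_sum = sum(v),
    energy = sum(v^2),
    max_even_shift_dot = max_dot,
    pass = abs(sum(v) - target_sum) < tol &&
      abs(sum(v^2) - 1) < tol && max_dot < tol
  )
}

# insert 2^(j-1)-1 zeros between consecutive taps
.upsample <- function(v, j) {
  if (j == 1L) return(v)
  step <- 2L^(j - 1L)
  out <- numeric(step * (length(v) - 1L) + 1L)
  out[seq_along(v) * step - step + 1L] <- v
  out
}

#' Level-j MODWT filter
#'
#' Builds the stage filter (base taps with `2^(j-1) - 1` zeros inserted
#' between consecutive taps) and the equivalent filter of level `j`
#' (cascade of stage filters of levels `1..j` by linear convolution),
#' whose length is `L_j = (2^j - 1)(L - 1) + 1`. With `rescale = TRUE`
#' the equivalent taps are divided by `2^(j/2)`, giving the MODWT filter
#' whose squared norm is `2^(-j)` for a wavelet filter.
#'
#' @param base A `wavelet_filter` in DWT normalization.
#' @param j Decomposition level, `j >= 1`.
#' @param rescale Apply the MODWT rescaling `2^(-j/2)` (default `TRUE`).
#' @return A `level_filter` object: list with `base`, `level`,
#'   `stage_values`, `equivalent_values`, `rescaled`, and `phase_shift`
#'   (integer circular advance aligning the filter output with the input;
#'   the energy centroid of the equivalent filter, populated for the
#'   least-asymmetric and haar families).
#' @export
level_filter <- function(base, j, rescale = TRUE) {
  stopifnot(inherits(base, "wavelet_filter"), j >= 1)
  j <- as.integer(j)
  pair <- if (base$kind == "scaling") {
    list(scaling = base, wavelet = qmf(base))
  } else {
    list(scaling = qmf(base), wavelet = base)
  }
  stage <- .upsample(base$values, j)
  # cascade: scaling stages 1..j-1, then the target filter at stage j
  equiv <- pair[[base$kind]]$values
  if (j > 1L) {
    equiv <- pair$scaling$values
    for (k in seq_len(j - 1L)[-1L]) {
      equiv <- stats::convolve(.upsample(pair$scaling$values, k),
                               rev(equiv), type = "open")
    }
    equiv <- stats::convolve(.upsample(base$values, j),
                             rev(equiv), type = "open")
  }
  if (rescale) equiv <- equiv / 2^(j / 2)
  centroid <- sum((seq_along(equiv) - 1L) * equiv^2) / sum(equiv^2)
  structure(
    list(base = base, level = j,
         stage_values = stage, equivalent_values = equiv,
         rescaled = rescale,
         phase_shift = -as.integer(round(centroid))),
    class = "level_filter"
  )
}

#' Squared gain of a level filter
#'
#' Squared magnitude of the equivalent filter's transfer function
#' `U(f) = sum_l u_l exp(-i 2 pi f l)` at the requested frequencies.
#' Level-`j` wavelet filters approximate band-pass filters over
#' `[1/2^(j+1), 1/2^j]` cycles/sample; the scaling filter concentrates on
#' `[0, 1/2^(j+1)]`.
#'
#' @param lf A `level_filter`.
#' @param frequencies Frequencies in cycles/sample, in `[0, 0.5]`.
#' @return Numeric vector of squared gains.
#' @export
squared_gain <- function(lf, frequencies) {
  stopifnot(inherits(lf, "level_filter"), all(frequencies >= 0),
            all(frequencies <= 0.5))
  u <- lf$equivalent_values
  l <- seq_along(u) - 1L
  vapply(frequencies, function(f) {
    Mod(sum(u * exp(-2i * pi * f * l)))^2
  }, numeric(1))
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat(sprintf("<wavelet_filter> %s %s (L = %d, %s)\n",
              x$family, x$kind, x$L, x$normalization))
  print(round(x$values, 6))
  invisible(x)
}
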