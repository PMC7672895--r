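## Physicochemical feature blocks: classic type-1 pseudo amino-acid
## composition (40) and Haar-wavelet statistics of three property profiles
## (42).

#' Standardize a property scale over the 20 residues
#'
#' Zero mean and unit variance (population variance, denominator 20) across
#' the alphabet, the normalization under which the PseAAC correlation factors
#' are computed.
#'
#' @param scale A [property_scale()].
#' @return Named numeric vector over [AA_ALPHABET].
#' @export
standardize_scale <- function(scale) {
  v <- as.numeric(scale)
  names(v) <- AA_ALPHABET
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  (v - mu) / sd_pop
}

## Standardized 3 x 20 property matrix (hydrophobicity, hydrophilicity,
## side-chain mass) used by the PseAAC correlation factors; cached.
.pseaac_props <- function() {
  if (is.null(.pkg_cache$pseaac_props)) {
    scales <- property_scales()
    .pkg_cache$pseaac_props <- rbind(standardize_scale(scales$hydrophobicity),
                                     standardize_scale(scales$hydrophilicity),
                                     standardize_scale(scales$sidechain_mass))
  }
  .pkg_cache$pseaac_props
}

#' Classic type-1 pseudo amino-acid composition (dimension 40)
#'
#' Entries 1-20 are damped residue frequencies, entries 21-40 the weighted
#' sequence-order correlation factors theta_k, k = 1..min(lam, L-1),
#' zero-padded to a fixed 40-wide layout (20 composition + 20 theta slots).
#' theta_k averages, over positions i, the mean squared difference of three
#' standardized property values (hydrophobicity, hydrophilicity, side-chain
#' mass) between residues i and i+k. All non-padding entries share the
#' denominator sum(f) + w * sum(theta) and therefore sum to one.
#'
#' @param seq An [aa_sequence()] or residue string, length >= 2.
#' @param lam Maximum correlation rank; values above 19 are clipped with a
#'   warning (a 20-residue fragment supports at most k = 19).
#' @param w Weight of the sequence-order terms (conventional default 0.05).
#' @return A `FeatureBlock` of dimension 40.
#' @export
pseaac <- function(seq, lam = 19L, w = 0.05) {
  res <- .residues_of(seq)
  L <- length(res)
  if (L < 2L) stop("pseaac requires length >= 2")
  if (w <= 0) stop("w must be positive")
  if (lam < 1L) stop("lam must be >= 1")
  if (lam > 19L) {
    warning("pseaac: lam clipped to 19 (fragments are at most 20 residues)")
    lam <- 19L
  }
  props <- .pseaac_props()[, res, drop = FALSE]
  k_max <- min(lam, L - 1L)
  theta <- vapply(seq_len(k_max), function(k) {
    d <- props[, 1:(L - k), drop = FALSE] - props[, (1 + k):L, drop = FALSE]
    mean(colMeans(d^2))
  }, numeric(1))
  f <- vapply(AA_ALPHABET, function(a) sum(res == a), numeric(1)) / L
  denom <- sum(f) + w * sum(theta)
  .feature_block("pseaac", c(f / denom, w * theta / denom, numeric(20L - k_max)))
}

#' Per-position property profile
#'
#' @param seq An [aa_sequence()] or residue string.
#' @param scale A [property_scale()].
#' @return Numeric vector of length L.
#' @export
property_profile <- function(seq, scale) {
  v <- as.numeric(scale)
  names(v) <- AA_ALPHABET
  unname(v[.residues_of(seq)])
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Multi-level analysis of a signal whose length is divisible by
#' 2^levels. Approximation/detail pairs use the orthonormal filters
#' (1/sqrt(2), 1/sqrt(2)) and (1/sqrt(2), -1/sqrt(2)), so the transform
#' preserves energy (Parseval).
#'
#' @param x Numeric signal.
#' @param levels Number of decomposition levels.
#' @return List with `approx` (final approximation band) and `details`
#'   (list of detail bands, coarsest first).
#' @export
haar_dwt <- function(x, levels = 3L) {
  if (length(x) %% 2^levels != 0L)
    stop("signal length must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    odd <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details[[levels - l + 1L]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details)
}

.resample_linear <- function(x, n) {
  if (length(x) == 1L) return(rep(x, n))
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n))$y
}

.dwt_stats_one <- function(profile) {
  x <- .resample_linear(profile, 32L)
  dec <- haar_dwt(x, 3L)
  bands <- c(list(dec$approx), dec$details)  # A3, D3, D2, D1
  stats <- unlist(lapply(bands, function(b) c(mean(b), stats::sd(b), max(b))))
  coefs <- unlist(bands)
  energy <- sum(coefs^2)
  entropy <- if (energy > 0) .shannon_bits(coefs^2) else 0
  c(stats, energy, entropy)
}

#' Wavelet statistics of physicochemical profiles (dimension 42)
#'
#' Each of three property profiles (hydrophobicity, flexibility, mean
#' accessible surface area) is linearly resampled to 32 points and analysed
#' with a 3-level orthonormal Haar transform. Per profile, 14 statistics are
#' emitted: mean, standard deviation and maximum of each sub-band (A3, D3,
#' D2, D1), total coefficient energy, and the Shannon entropy (bits) of the
#' normalized squared-coefficient distribution.
#'
#' @param seq An [aa_sequence()] or residue string, length >= 4.
#' @param scales List of three [property_scale()]s; defaults to the bundled
#'   hydrophobicity, flexibility and accessible-surface-area scales.
#' @return A `FeatureBlock` of dimension 42.
#' @export
dwt_features <- function(seq, scales = NULL) {
  res <- .residues_of(seq)
  if (length(res) < 4L) stop("dwt_features requires length >= 4")
  if (is.null(scales)) {
    all <- property_scales()
    scales <- list(all$hydrophobicity, all$flexibility, all$asa)
  }
  vals <- unlist(lapply(scales, function(sc) .dwt_stats_one(property_profile(res, sc))))
  .feature_block("dwt", vals)
}

#' Concatenated physicochemical feature group (dimension 82)
#'
#' @inheritParams dwt_features
#' @return List of two `FeatureBlock`s (PseAAC 40, wavelet 42).
#' @export
physchem_group_features <- function(seq) {
  list(pseaac(seq), dwt_features(seq))
}
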