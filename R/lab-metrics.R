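# Bench-side calculators: gel-band splice-variant quantification,
# restriction-digest ratios, tumour volume, % specific lysis. All pure and
# deterministic.

#' Molar proportions of gel bands
#'
#' Band intensity is proportional to the mass of DNA, so dividing by the
#' product length converts to molar units:
#' `fraction_i = (I_i / L_i) / sum_j (I_j / L_j)`.
#'
#' @param bands Tibble with columns `label`, `intensity` (>= 0) and
#'   `length_bp` (> 0).
#' @return `bands` with a `fraction` column summing to 1.
#' @export
molar_proportions <- function(bands) {
  if (nrow(bands) == 0) abort("molar_proportions: no bands")
  if (any(bands$intensity < 0)) abort("molar_proportions: negative intensity")
  if (any(bands$length_bp <= 0)) abort("molar_proportions: non-positive length")
  molar <- bands$intensity / bands$length_bp
  total <- sum(molar)
  if (total <= 0) abort("molar_proportions: all intensities are zero")
  mutate(as_tibble(bands), fraction = molar / total)
}

#' Splice-variant proportions from a two-band restriction digest
#'
#' Length-normalized proportions of the uncut 309 bp band (the E26+ E27-
#' splice variant) and the 150 bp cut fragment (the E26- E27+ variant).
#'
#' @param intensity_uncut,intensity_cut Band intensities (>= 0, not both 0).
#' @param len_uncut,len_cut Product sizes in bp (defaults 309 and 150).
#' @return A one-row tibble with `prop_uncut` and `prop_cut` summing to 1.
#' @export
digest_variant_ratio <- function(intensity_uncut, intensity_cut,
                                 len_uncut = 309, len_cut = 150) {
  bands <- tibble(label = c("uncut", "cut"),
                  intensity = c(intensity_uncut, intensity_cut),
                  length_bp = c(len_uncut, len_cut))
  fr <- molar_proportions(bands)
  tibble(prop_uncut = fr$fraction[1], prop_cut = fr$fraction[2])
}

#' Ellipsoid tumour volume from caliper measurements
#'
#' `V = (pi / 6) * length * width^2`, in cubic millimetres.
#'
#' @param length,width Caliper measurements in mm (> 0); vectorized.
#' @return Volume(s) in mm^3.
#' @export
tumour_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    abort("tumour_volume: length and width must be positive")
  }
  pi / 6 * length * width^2
}

#' Percent specific lysis from an LDH-release assay
#'
#' `(sample - spontaneous) / (maximal - spontaneous) * 100`. Values outside
#' `[0, 100]` are reported as-is and flagged, never clipped, so assay
#' problems stay visible.
#'
#' @param sample,spontaneous,maximal LDH activities; `maximal` must exceed
#'   `spontaneous`. Vectorized.
#' @return A tibble with `percent_lysis` and `out_of_range`.
#' @export
specific_lysis <- function(sample, spontaneous, maximal) {
  if (any(maximal <= spontaneous)) {
    abort("specific_lysis: maximal LDH must exceed spontaneous LDH")
  }
  pct <- (sample - spontaneous) / (maximal - spontaneous) * 100
  tibble(percent_lysis = pct, out_of_range = pct < 0 | pct > 100)
}
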