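# Formula-defined quantifications used around the screen: comet-assay
# tail moment, RNA-ISH scoring, DAB positivity, densitometry ratios,
# caliper tumor volume, and cohort mutation frequency.

#' Olive tail moment of a comet-assay cell
#'
#' Implements the intensity-difference form
#' `OTM = (mean tail intensity - mean head intensity) * tail%DNA / 100`;
#' negative values (head brighter than tail) are retained. The classical
#' Olive definition uses the head-tail centroid distance instead of the
#' intensity difference; [olive_tail_moment_canonical()] computes that
#' variant for comparison.
#'
#' @param head_intensity,tail_intensity Mean head / tail intensities
#'   (arbitrary units, >= 0).
#' @param tail_pct_dna Percent of DNA in the tail, in \[0, 100\].
#' @return OTM in intensity units.
#' @examples
#' olive_tail_moment(100, 160, 50)  # 30
#' @export
olive_tail_moment <- function(head_intensity, tail_intensity, tail_pct_dna) {
  if (any(tail_pct_dna < 0 | tail_pct_dna > 100)) {
    stop("tail_pct_dna must lie in [0, 100]", call. = FALSE)
  }
  if (any(head_intensity < 0) || any(tail_intensity < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  (tail_intensity - head_intensity) * tail_pct_dna / 100
}

#' @rdname olive_tail_moment
#' @param head_centroid,tail_centroid Centroid positions (pixels) of the
#'   head and tail along the comet axis.
#' @export
olive_tail_moment_canonical <- function(head_centroid, tail_centroid,
                                        tail_pct_dna) {
  if (any(tail_pct_dna < 0 | tail_pct_dna > 100)) {
    stop("tail_pct_dna must lie in [0, 100]", call. = FALSE)
  }
  abs(tail_centroid - head_centroid) * tail_pct_dna / 100
}

#' Semi-quantitative RNA in situ hybridization score
#'
#' Bins the mean number of signal dots per cell into the 0-4 rubric:
#' 0 for no staining or fewer than 1 dot per 10 cells, 1 for 1-3
#' dots/cell, 2 for 4-9, 3 for 10-15, 4 for more than 15. Non-integer
#' means fall into the half-open bins \[0,1), \[1,4), \[4,10), \[10,16),
#' \[16, Inf).
#'
#' @param mean_dots_per_cell Mean dots per cell (>= 0).
#' @return Integer score 0-4 (vectorized).
#' @export
ish_score <- function(mean_dots_per_cell) {
  if (any(mean_dots_per_cell < 0)) {
    stop("mean dots per cell must be >= 0", call. = FALSE)
  }
  findInterval(mean_dots_per_cell, c(1, 4, 10, 16))
}

#' Percent DAB-positive cells
#'
#' @param n_positive,n_total Cell counts, `0 <= n_positive <= n_total`,
#'   `n_total > 0`.
#' @return Percentage.
#' @export
dab_percent <- function(n_positive, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0", call. = FALSE)
  if (any(n_positive < 0 | n_positive > n_total)) {
    stop("need 0 <= n_positive <= n_total", call. = FALSE)
  }
  100 * n_positive / n_total
}

#' Loading-control-normalized densitometry fold-ratio
#'
#' `(target_combo / control_combo) / (target_comparator /
#' control_comparator)`: the band intensity of the combination-treated
#' lane over the comparator lane, each first normalized to its
#' loading-control band.
#'
#' @param target_combo,control_combo Target and loading-control band
#'   intensities in the combination lane.
#' @param target_comparator,control_comparator Same for the comparator
#'   lane.
#' @return Fold ratio.
#' @export
densitometry_fold <- function(target_combo, control_combo,
                              target_comparator, control_comparator) {
  if (any(control_combo <= 0) || any(control_comparator <= 0)) {
    stop("loading-control intensities must be > 0", call. = FALSE)
  }
  if (any(target_comparator == 0)) {
    stop("comparator target band is zero; fold undefined", call. = FALSE)
  }
  (target_combo / control_combo) / (target_comparator / control_comparator)
}

#' Caliper tumor volume
#'
#' `volume = length * width^2 * 3.14159 / 6` (modified-ellipsoid
#' caliper formula). By convention length is the longer axis; a width
#' exceeding the length is computed anyway with a warning.
#'
#' @param length_mm,width_mm Caliper measurements in mm (width > 0).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 130.8996
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0)) {
    stop("dimensions must be > 0", call. = FALSE)
  }
  if (any(width_mm > length_mm)) {
    warning("width exceeds length; check caliper axis convention",
            call. = FALSE)
  }
  length_mm * width_mm^2 * 3.14159 / 6
}

#' Cohort mutation frequency, percent to one decimal
#'
#' `100 * n_mutant / n_cohort`, rounded half-away-from-zero to one
#' decimal place (so 4.45 reports as 4.5).
#'
#' @param n_mutant,n_cohort Counts, `0 <= n_mutant <= n_cohort`,
#'   `n_cohort > 0`.
#' @return Percentage with one decimal.
#' @examples
#' cohort_frequency(8, 178)  # 4.5
#' cohort_frequency(8, 564)  # 1.4
#' @export
cohort_frequency <- function(n_mutant, n_cohort) {
  if (any(n_cohort <= 0)) stop("empty cohort", call. = FALSE)
  if (any(n_mutant < 0 | n_mutant > n_cohort)) {
    stop("need 0 <= n_mutant <= n_cohort", call. = FALSE)
  }
  pct <- 100 * n_mutant / n_cohort
  sign(pct) * floor(abs(pct) * 10 + 0.5) / 10
}
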