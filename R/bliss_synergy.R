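# Bliss independence scoring of drug-combination dose matrices.
#
# "Response" throughout is fractional growth inhibition f in [0, 1]; the
# Bliss expectation fA + fB - fA*fB is then the probabilistic union of
# two independent kills, and the combination index CI = expected -
# observed carries the printed sign convention (CI < 0 = synergy,
# CI > 0 = antagonism).

#' Fractional inhibition from percent viability
#'
#' `f = clip(1 - viability/100, 0, 1)`; growth stimulation (viability
#' above 100%) clips to 0 inhibition.
#'
#' @param viability_pct Percent viability (finite).
#' @return Fractional inhibition in \[0, 1\].
#' @export
fractional_inhibition <- function(viability_pct) {
  if (any(!is.finite(viability_pct))) {
    stop("non-finite viability", call. = FALSE)
  }
  pmin(pmax(1 - viability_pct / 100, 0), 1)
}

#' Bliss-expected combination inhibition
#'
#' Under independence the expected fractional inhibition of the
#' combination is `fA + fB - fA * fB`.
#'
#' @param f_a,f_b Single-agent fractional inhibitions in \[0, 1\].
#' @return Expected combination inhibition.
#' @export
bliss_expected <- function(f_a, f_b) {
  if (any(f_a < 0 | f_a > 1 | f_b < 0 | f_b > 1, na.rm = FALSE) ||
      any(!is.finite(f_a)) || any(!is.finite(f_b))) {
    stop("fractional inhibitions must lie in [0, 1]", call. = FALSE)
  }
  f_a + f_b - f_a * f_b
}

#' Bliss combination index of one dose pair
#'
#' `CI = expected - observed`: observed inhibition above the Bliss
#' expectation gives CI < 0 (synergy), below gives CI > 0 (antagonism).
#'
#' @param observed_f,expected_f Fractional inhibitions in \[0, 1\].
#' @return The combination index.
#' @export
bliss_score <- function(observed_f, expected_f) {
  bad <- function(x) any(!is.finite(x)) || any(x < 0 | x > 1)
  if (bad(observed_f) || bad(expected_f)) {
    stop("inhibitions must lie in [0, 1]", call. = FALSE)
  }
  expected_f - observed_f
}

#' Replicate-averaged dose matrix from a long combination table
#'
#' Collapses the long table emitted by [generate_dose_matrix()] (or any
#' table with the same columns) to one cell line's dose-a x dose-b matrix
#' of mean observed fractional inhibition. Viability is converted to
#' clipped fractional inhibition per replicate before averaging; raw mean
#' viability is retained for audit.
#'
#' @param long data.frame with `cell_line`, `dose_a_um`, `dose_b_um`,
#'   `replicate`, `viability_pct`.
#' @param cell_line Which line to extract (default: the only one present).
#' @return A `dose_matrix`: list with `doses_a`, `doses_b` (both
#'   including 0), `observed` inhibition matrix, `viability` matrix and
#'   `n_replicates`.
#' @export
as_dose_matrix <- function(long, cell_line = NULL) {
  need <- c("cell_line", "dose_a_um", "dose_b_um", "replicate",
            "viability_pct")
  stopifnot(all(need %in% names(long)))
  if (is.null(cell_line)) {
    lines <- unique(long$cell_line)
    if (length(lines) != 1) {
      stop("multiple cell lines present; pick one via cell_line=",
           call. = FALSE)
    }
    cell_line <- lines
  }
  sub <- long[long$cell_line == cell_line, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for cell line ", cell_line, call. = FALSE)
  doses_a <- sort(unique(sub$dose_a_um))
  doses_b <- sort(unique(sub$dose_b_um))
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    stop("single-agent margins (dose 0) missing from the matrix",
         call. = FALSE)
  }
  sub$f <- fractional_inhibition(sub$viability_pct)
  obs <- tapply(sub$f, list(factor(sub$dose_a_um, doses_a),
                            factor(sub$dose_b_um, doses_b)), mean)
  viab <- tapply(sub$viability_pct,
                 list(factor(sub$dose_a_um, doses_a),
                      factor(sub$dose_b_um, doses_b)), mean)
  if (anyNA(obs)) stop("incomplete dose grid", call. = FALSE)
  n_rep <- max(sub$replicate)
  structure(list(cell_line = cell_line, doses_a = doses_a,
                 doses_b = doses_b, observed = unclass(obs),
                 viability = unclass(viab), n_replicates = n_rep),
            class = "dose_matrix")
}

#' Bliss synergy surface over a dose matrix
#'
#' Expected inhibition for every cell is computed from the single-agent
#' margins (dose-0 row and column) of the same replicate-averaged
#' matrix; the combination index CI = expected - observed is reported
#' per cell. Interior cells where either single agent already inhibits
#' at least `saturation` are flagged saturated and excluded from the summary
#' statistics, since the Bliss score is numerically meaningless at full
#' kill.
#'
#' @param dm A `dose_matrix` from [as_dose_matrix()].
#' @param saturation Single-agent inhibition above which a cell is
#'   excluded from summaries (default 0.99).
#' @return A `bliss_surface`: `expected` and `score` matrices aligned
#'   with `dm$observed`, a logical `saturated` matrix, and `summary`
#'   (mean and min CI over unsaturated interior cells).
#' @export
bliss_surface <- function(dm, saturation = 0.99) {
  stopifnot(inherits(dm, "dose_matrix"))
  f_a <- dm$observed[, 1]  # drug A alone (dose_b = 0)
  f_b <- dm$observed[1, ]  # drug B alone (dose_a = 0)
  expected <- outer(f_a, f_b, bliss_expected)
  score <- expected - dm$observed
  interior <- outer(dm$doses_a > 0, dm$doses_b > 0, `&`)
  saturated <- outer(f_a >= saturation, f_b >= saturation, `|`)
  use <- interior & !saturated
  summary <- list(
    mean_ci = if (any(use)) mean(score[use]) else NA_real_,
    min_ci = if (any(use)) min(score[use]) else NA_real_,
    n_interior = sum(interior), n_saturated = sum(interior & saturated))
  structure(list(cell_line = dm$cell_line, doses_a = dm$doses_a,
                 doses_b = dm$doses_b, observed = dm$observed,
                 expected = expected, score = score,
                 interior = interior, saturated = saturated,
                 summary = summary),
            class = "bliss_surface")
}

#' @export
print.bliss_surface <- function(x, ...) {
  cat(sprintf(
    "bliss_surface [%s]: %d x %d doses, mean interior CI %.3f, min %.3f (%d saturated cell(s) excluded)\n",
    x$cell_line, length(x$doses_a), length(x$doses_b),
    x$summary$mean_ci, x$summary$min_ci, x$summary$n_saturated))
  invisible(x)
}
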