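#' Inhibition score (I-score) of a treated well
#'
#' `i_score = (1 - signal / median(DMSO signals)) * 100`, i.e. percent
#' growth inhibition relative to the median vehicle-control signal. The
#' value is deliberately not clipped: 0 means the signal equals the DMSO
#' median, 100 means zero signal, and negative values record growth
#' stimulation.
#'
#' @param signal Numeric vector of treated-well signals (RLU).
#' @param dmso_signals Vehicle-control signals from the same plate (or
#'   pooled run); the median must be positive.
#' @return Percent inhibition, same length as `signal`.
#' @examples
#' i_score(400, c(900, 1000, 1100))  # 60
#' i_score(1200, c(1000))            # -20: stimulation, retained
#' @export
i_score <- function(signal, dmso_signals) {
  if (!length(dmso_signals)) stop("empty DMSO signal set", call. = FALSE)
  med <- stats::median(dmso_signals)
  if (!is.finite(med) || med <= 0) {
    stop("DMSO median must be positive, got ", med, call. = FALSE)
  }
  (1 - signal / med) * 100
}

#' Score every treated well of a screen against its plate's DMSO median
#'
#' The DMSO median is computed per plate by default, so plate-level
#' multiplicative effects cancel exactly; pooling all control wells of
#' the run is available for designs without per-plate controls.
#'
#' @param dataset A [screen_dataset()].
#' @param pooling `"plate"` (default) or `"run"`.
#' @return data.frame of treated wells with an added `i_score` column.
#' @export
score_screen <- function(dataset, pooling = c("plate", "run")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  pooling <- match.arg(pooling)
  sentinel <- attr(dataset, "control_sentinel")
  df <- as.data.frame(dataset)
  is_ctrl <- df$compound == sentinel
  treated <- df[!is_ctrl, , drop = FALSE]
  if (pooling == "run") {
    treated$i_score <- i_score(treated$luminescence,
                               df$luminescence[is_ctrl])
  } else {
    meds <- tapply(df$luminescence[is_ctrl], df$plate_id[is_ctrl],
                   stats::median)
    if (any(!is.finite(meds) | meds <= 0)) {
      stop("non-positive DMSO median on plate(s): ",
           paste(names(meds)[!is.finite(meds) | meds <= 0], collapse = ", "),
           call. = FALSE)
    }
    treated$i_score <- (1 - treated$luminescence /
                          as.numeric(meds[treated$plate_id])) * 100
  }
  rownames(treated) <- NULL
  treated
}

#' Aggregate per-well I-scores over replicates
#'
#' One row per (compound, cell line, dose): replicate mean, sample
#' standard deviation (0 for a single replicate) and replicate count.
#'
#' @param scored Output of [score_screen()].
#' @return data.frame with columns `compound`, `cell_line`, `dose_um`,
#'   `i_score`, `sd`, `n_replicates`.
#' @export
aggregate_scores <- function(scored) {
  stopifnot(all(c("compound", "cell_line", "dose_um", "i_score") %in%
                  names(scored)))
  if (!nrow(scored)) stop("no treated wells to aggregate", call. = FALSE)
  key <- interaction(scored$compound, scored$cell_line, scored$dose_um,
                     drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(scored, key), function(g) {
    data.frame(compound = g$compound[1], cell_line = g$cell_line[1],
               dose_um = g$dose_um[1],
               i_score = mean(g$i_score),
               sd = if (nrow(g) > 1) stats::sd(g$i_score) else 0,
               n_replicates = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$compound, agg$cell_line, agg$dose_um), , drop = FALSE]
}

#' Compound x cell-line inhibition profile matrix
#'
#' Collapses aggregated I-scores to one value per (compound, line). The
#' default aggregation takes the maximum over the screened doses — a
#' compound active at either screening dose counts as active — and the
#' rule used is recorded in the `aggregation` attribute.
#'
#' @param agg Output of [aggregate_scores()].
#' @param aggregation `"max"` over doses (default) or a single dose value
#'   to select.
#' @return Numeric matrix, compounds in rows, cell lines in columns.
#' @export
inhibition_profile <- function(agg, aggregation = "max") {
  if (identical(aggregation, "max")) {
    sel <- agg
  } else {
    sel <- agg[agg$dose_um == as.numeric(aggregation), , drop = FALSE]
    if (!nrow(sel)) stop("no records at dose ", aggregation, call. = FALSE)
  }
  prof <- tapply(sel$i_score, list(sel$compound, sel$cell_line), max)
  if (anyNA(prof)) {
    stop("incomplete profile: some compound is missing a cell line",
         call. = FALSE)
  }
  prof <- prof[order(rownames(prof)), order(colnames(prof)), drop = FALSE]
  attr(prof, "aggregation") <- if (identical(aggregation, "max")) {
    "max over screened doses"
  } else sprintf("dose %s uM", aggregation)
  prof
}

#' Efficacy filter: active in at least one line
#'
#' A compound is efficacious when its inhibition exceeds `threshold`
#' percent in at least one panel line. The inequality is strict, so a
#' score of exactly 50 does not pass.
#'
#' @param profile Matrix from [inhibition_profile()].
#' @param threshold Percent inhibition cut-off (default 50).
#' @return Named logical vector over compounds.
#' @export
efficacy_filter <- function(profile, threshold = 50) {
  apply(profile, 1, function(row) max(row) > threshold)
}

# "p53_R158G" -> "R158G_selective", "p53_wt" -> "WT_selective", etc.
.line_class <- function(line) {
  short <- sub("^p53[_-]?", "", line)
  short <- switch(tolower(short), wt = "WT", null = "NULL", short)
  paste0(short, "_selective")
}

#' Selectivity class of one compound's profile row
#'
#' Line-selective means strictly above `threshold` in exactly one line
#' and strictly below it in every other line; above in all lines is
#' pan-active; any other efficacious pattern (including scores exactly at
#' the threshold) is `other_selective_pattern`; a row that clears the
#' threshold nowhere is `inactive`.
#'
#' @param row Named numeric vector of I-scores, one per panel line.
#' @param threshold Percent inhibition cut-off (default 50).
#' @return Character class label.
#' @examples
#' selectivity_class(c(p53_R158G = 60, p53_wt = 20, p53_null = 30))
#' # "R158G_selective"
#' @export
selectivity_class <- function(row, threshold = 50) {
  stopifnot(!is.null(names(row)), all(nzchar(names(row))))
  above <- row > threshold
  below <- row < threshold
  if (!any(above)) return("inactive")
  if (all(above)) return("pan_active")
  if (sum(above) == 1 && all(below[!above])) {
    return(.line_class(names(row)[above]))
  }
  "other_selective_pattern"
}

#' Call hits over a whole inhibition profile
#'
#' @param profile Matrix from [inhibition_profile()].
#' @param threshold Percent inhibition cut-off (default 50).
#' @return data.frame with `compound`, `efficacious`,
#'   `selectivity_class` (classes are mutually exclusive; selectivity is
#'   only assigned to efficacious compounds).
#' @export
hit_calls <- function(profile, threshold = 50) {
  eff <- efficacy_filter(profile, threshold)
  cls <- vapply(rownames(profile), function(cmp) {
    if (!eff[[cmp]]) "inactive" else
      selectivity_class(profile[cmp, ], threshold)
  }, character(1))
  data.frame(compound = rownames(profile), efficacious = unname(eff),
             selectivity_class = unname(cls), stringsAsFactors = FALSE)
}

#' Hierarchically cluster compound inhibition profiles
#'
#' Agglomerative complete-linkage clustering on Euclidean distances
#' between compound rows, the standard choice for inhibition heatmaps.
#'
#' @param profile Matrix from [inhibition_profile()] (>= 2 rows, no
#'   missing values).
#' @return An [stats::hclust] tree; `$order` gives the heatmap leaf
#'   order, `$height` the merge heights.
#' @export
cluster_profiles <- function(profile) {
  if (nrow(profile) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (anyNA(profile) || any(!is.finite(profile))) {
    stop("profile contains missing or non-finite values", call. = FALSE)
  }
  stats::hclust(stats::dist(profile, method = "euclidean"),
                method = "complete")
}
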