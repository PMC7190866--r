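#' Simulation configuration
#'
#' Bundles every knob of the synthetic screen generator. The defaults
#' mirror the screened design: 384-well plates, triplicate wells, and a
#' multiplicative log-normal well noise whose log has mean zero. With the
#' same config (including `seed`) every generator is byte-identical across
#' calls.
#'
#' @param seed Integer RNG seed.
#' @param plate_format 96 or 384.
#' @param n_replicates Replicate wells per (line, compound, dose).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal well noise (0 disables noise).
#' @param control_wells_per_plate Vehicle (DMSO) wells placed on each plate.
#' @param baseline_luminescence Expected signal of an untreated well (RLU).
#' @param plate_shift_sd Standard deviation of an optional log-normal
#'   plate-level multiplicative shift; defaults to 0 (no plate effects).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, plate_format = 384, n_replicates = 3L,
                       noise_cv = 0.05, control_wells_per_plate = 16L,
                       baseline_luminescence = 10000,
                       plate_shift_sd = 0) {
  stopifnot(noise_cv >= 0, plate_shift_sd >= 0,
            n_replicates >= 1, control_wells_per_plate >= 1,
            baseline_luminescence > 0)
  .plate_dims(plate_format)  # validates the format
  structure(list(seed = as.integer(seed),
                 plate_format = as.integer(plate_format),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv,
                 control_wells_per_plate = as.integer(control_wells_per_plate),
                 baseline_luminescence = baseline_luminescence,
                 plate_shift_sd = plate_shift_sd),
            class = "sim_config")
}

#' Ground-truth potency of one compound across the panel
#'
#' Each cell line gets a Hill dose-inhibition curve
#' `inhibition(d) = emax * d^hill / (ed50^hill + d^hill)`, the monotone
#' special case of the 4PL curves fitted downstream, so the generator's
#' truth is exactly recoverable by the dose-response module.
#'
#' @param compound_id Compound identifier.
#' @param potencies Named list, one entry per cell line, each a list with
#'   `ed50` (µM, > 0), `hill` (slope >= 0) and `emax` (maximal fractional
#'   inhibition in \[0, 1\]).
#' @return A `compound_truth` object.
#' @examples
#' compound_truth("cmpd1", list(
#'   p53_R158G = list(ed50 = 0.05, hill = 1, emax = 0.95),
#'   p53_wt    = list(ed50 = 50,   hill = 1, emax = 0.95)))
#' @export
compound_truth <- function(compound_id, potencies) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.list(potencies), length(potencies) >= 1L,
            !is.null(names(potencies)), all(nzchar(names(potencies))))
  for (line in names(potencies)) {
    p <- potencies[[line]]
    if (!all(c("ed50", "hill", "emax") %in% names(p))) {
      stop("potency entry for ", line, " needs ed50, hill, emax",
           call. = FALSE)
    }
    if (p$ed50 <= 0) stop("ed50 must be > 0 (", line, ")", call. = FALSE)
    if (p$hill < 0) stop("hill must be >= 0 (", line, ")", call. = FALSE)
    if (p$emax < 0 || p$emax > 1) {
      stop("emax must lie in [0, 1] (", line, ")", call. = FALSE)
    }
  }
  structure(list(compound_id = compound_id, potencies = potencies),
            class = "compound_truth")
}

# True fractional inhibition of one line at the given doses.
hill_inhibition <- function(dose, ed50, hill, emax) {
  ifelse(dose <= 0, 0, emax * dose^hill / (ed50^hill + dose^hill))
}

.truth_inhibition <- function(truth, cell_line, dose) {
  p <- truth$potencies[[cell_line]]
  if (is.null(p)) {
    stop("cell line ", cell_line, " missing from truth for ",
         truth$compound_id, call. = FALSE)
  }
  hill_inhibition(dose, p$ed50, p$hill, p$emax)
}

# Multiplicative log-normal noise factors: log mean 0, CV = noise_cv.
.noise_factor <- function(n, noise_cv) {
  if (noise_cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + noise_cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

#' Simulate a single-dose (or few-dose) viability screen
#'
#' Lays treated wells plate by plate for every (cell line, replicate)
#' series, reserving the right-most plate columns for DMSO vehicle wells.
#' Well luminescence is `baseline * (1 - true_inhibition) * noise` and
#' control luminescence `baseline * noise`.
#'
#' @param config A [sim_config()].
#' @param truths List of [compound_truth()] objects; every cell line in
#'   the panel must appear in each truth.
#' @param doses Numeric vector of doses (µM, all > 0) screened per
#'   compound.
#' @return A [screen_dataset()] whose `provenance` attribute records the
#'   config and planted truths.
#' @export
generate_single_dose_screen <- function(config, truths, doses) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(truths)) stop("empty truth list", call. = FALSE)
  if (!length(doses) || any(doses <= 0)) {
    stop("doses must be non-empty and > 0", call. = FALSE)
  }
  truths <- lapply(truths, function(t) {
    stopifnot(inherits(t, "compound_truth")); t
  })
  panel <- sort(Reduce(union, lapply(truths, function(t) names(t$potencies))))
  for (t in truths) {
    miss <- setdiff(panel, names(t$potencies))
    if (length(miss)) {
      stop("truth for ", t$compound_id, " missing line(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  dims <- .plate_dims(config$plate_format)
  n_rows <- dims[["rows"]]; n_cols <- dims[["cols"]]
  n_ctrl_cols <- ceiling(config$control_wells_per_plate / n_rows)
  n_treat_cols <- n_cols - n_ctrl_cols
  if (n_treat_cols < 1) stop("too many control wells for plate", call. = FALSE)
  capacity <- n_rows * n_treat_cols

  compound_ids <- vapply(truths, `[[`, character(1), "compound_id")
  combos <- expand.grid(dose = doses, compound = compound_ids,
                        stringsAsFactors = FALSE)[, c("compound", "dose")]

  with_seed(config$seed, {
    parts <- list()
    for (line in panel) {
      truth_by_id <- stats::setNames(truths, compound_ids)
      for (rep_i in seq_len(config$n_replicates)) {
        n_plates <- ceiling(nrow(combos) / capacity)
        for (pl in seq_len(n_plates)) {
          idx <- ((pl - 1L) * capacity + 1L):min(pl * capacity, nrow(combos))
          chunk <- combos[idx, , drop = FALSE]
          plate_id <- sprintf("%s_rep%d_p%02d", line, rep_i, pl)
          shift <- if (config$plate_shift_sd > 0) {
            exp(stats::rnorm(1, 0, config$plate_shift_sd))
          } else 1
          # treated wells fill the treatment block in row-major order
          k <- seq_len(nrow(chunk)) - 1L
          t_row <- k %/% n_treat_cols
          t_col <- k %% n_treat_cols
          inh <- mapply(function(cmp, d) {
            .truth_inhibition(truth_by_id[[cmp]], line, d)
          }, chunk$compound, chunk$dose)
          treat <- data.frame(
            plate_id = plate_id,
            well = well_label(t_row, t_col),
            cell_line = line,
            compound = chunk$compound,
            dose_um = chunk$dose,
            replicate = rep_i,
            luminescence = config$baseline_luminescence * (1 - inh) *
              shift * .noise_factor(nrow(chunk), config$noise_cv),
            stringsAsFactors = FALSE)
          # controls fill the reserved right-most columns, column-major
          j <- seq_len(config$control_wells_per_plate) - 1L
          c_row <- j %% n_rows
          c_col <- n_treat_cols + j %/% n_rows
          ctrl <- data.frame(
            plate_id = plate_id,
            well = well_label(c_row, c_col),
            cell_line = line,
            compound = DMSO_SENTINEL,
            dose_um = 0,
            replicate = rep_i,
            luminescence = config$baseline_luminescence * shift *
              .noise_factor(config$control_wells_per_plate, config$noise_cv),
            stringsAsFactors = FALSE)
          parts[[length(parts) + 1L]] <- rbind(treat, ctrl)
        }
      }
    }
    screen_dataset(do.call(rbind, parts),
                   plate_format = config$plate_format,
                   provenance = list(config = config, truths = truths,
                                     doses = doses))
  })
}

#' Ground-truth Bliss deviation for a drug pair
#'
#' `delta` is added to the Bliss-expected fractional inhibition in
#' combination wells only (never to single-agent margins). Positive
#' `delta` means more inhibition than independence predicts — synergy —
#' and surfaces downstream as a negative combination index.
#'
#' @param delta Named numeric vector, one Bliss-deviation term per cell
#'   line (in fractional-inhibition units).
#' @return An `interaction_truth` object.
#' @export
interaction_truth <- function(delta) {
  stopifnot(is.numeric(delta), !is.null(names(delta)),
            all(nzchar(names(delta))), all(is.finite(delta)))
  structure(list(delta = delta), class = "interaction_truth")
}

#' Simulate a two-drug dose-matrix viability experiment
#'
#' Generates replicate viability readings over the full dose grid of two
#' compounds, including the single-agent margins (partner dose 0). The
#' true combination inhibition is
#' `clip(fA + fB - fA*fB + delta, 0, 1)` with `delta` applied only when
#' both doses are positive.
#'
#' @param config A [sim_config()].
#' @param truth_a,truth_b [compound_truth()] objects for the two drugs.
#' @param interaction An [interaction_truth()] covering every shared line.
#' @param doses_a,doses_b Positive dose grids (µM); dose 0 margins are
#'   added automatically.
#' @return Long data.frame with columns `cell_line`, `dose_a_um`,
#'   `dose_b_um`, `replicate`, `viability_pct`; drug ids and truth kept
#'   as attributes.
#' @export
generate_dose_matrix <- function(config, truth_a, truth_b, interaction,
                                 doses_a, doses_b) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth_a, "compound_truth"),
            inherits(truth_b, "compound_truth"),
            inherits(interaction, "interaction_truth"))
  if (!length(doses_a) || !length(doses_b) ||
      any(doses_a <= 0) || any(doses_b <= 0)) {
    stop("dose grids must be non-empty and strictly positive", call. = FALSE)
  }
  panel <- intersect(names(truth_a$potencies), names(truth_b$potencies))
  if (!length(panel)) stop("truths share no cell line", call. = FALSE)
  miss <- setdiff(panel, names(interaction$delta))
  if (length(miss)) {
    stop("interaction delta missing for line(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  grid_a <- c(0, sort(unique(doses_a)))
  grid_b <- c(0, sort(unique(doses_b)))

  with_seed(config$seed, {
    cells <- expand.grid(dose_a_um = grid_a, dose_b_um = grid_b,
                         cell_line = panel, stringsAsFactors = FALSE)
    parts <- lapply(seq_len(config$n_replicates), function(rep_i) {
      f_a <- mapply(function(l, d) .truth_inhibition(truth_a, l, d),
                    cells$cell_line, cells$dose_a_um)
      f_b <- mapply(function(l, d) .truth_inhibition(truth_b, l, d),
                    cells$cell_line, cells$dose_b_um)
      delta <- interaction$delta[cells$cell_line] *
        (cells$dose_a_um > 0 & cells$dose_b_um > 0)
      f_true <- pmin(pmax(f_a + f_b - f_a * f_b + delta, 0), 1)
      data.frame(cell_line = cells$cell_line,
                 dose_a_um = cells$dose_a_um,
                 dose_b_um = cells$dose_b_um,
                 replicate = rep_i,
                 viability_pct = 100 * (1 - f_true) *
                   .noise_factor(nrow(cells), config$noise_cv),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    structure(out,
              drug_a = truth_a$compound_id, drug_b = truth_b$compound_id,
              interaction = interaction, config = config)
  })
}

#' Simulate a peak / TSS / expression fixture with planted direct targets
#'
#' Genes are spaced 100 kb apart on one synthetic chromosome so peak-gene
#' assignments are unambiguous. Planted targets receive a
#' shortlist-passing peak within 10 kb of their TSS and a strong
#' expression change; every decoy gene violates exactly one of the three
#' calling conditions (peak too far, peak failing the enrichment
#' shortlist, or expression change below threshold).
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param n_genes Total genes in the fixture.
#' @param n_planted_targets Genes planted as true direct targets.
#' @return List with `peaks`, `tss`, `deg` data.frames (BED-style 0-based
#'   half-open peak coordinates) and `truth`, the planted gene ids.
#' @export
generate_genomic_fixture <- function(config, n_genes = 50,
                                     n_planted_targets = 5) {
  stopifnot(inherits(config, "sim_config"),
            n_genes >= 0, n_planted_targets >= 0,
            n_planted_targets <= n_genes)
  with_seed(config$seed + 104729L, {
    gene_id <- sprintf("GENE%03d", seq_len(n_genes))
    tss_pos <- 50000 + (seq_len(n_genes) - 1L) * 100000
    strand <- rep_len(c("+", "-"), n_genes)
    tss <- data.frame(gene_id = gene_id, chrom = "chr1", tss = tss_pos,
                      strand = strand, stringsAsFactors = FALSE)

    planted <- if (n_planted_targets > 0) {
      sort(sample(n_genes, n_planted_targets))
    } else integer(0)
    decoys <- setdiff(seq_len(n_genes), planted)
    # decoy failure modes cycle: 1 = far peak, 2 = weak peak, 3 = small LFC
    decoy_mode <- stats::setNames(rep_len(1:3, length(decoys)), decoys)

    lfc <- numeric(n_genes)
    peak_rows <- list()
    add_peak <- function(center, fold, pileup, q) {
      half <- round(stats::runif(1, 100, 300))
      peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
        chrom = "chr1", start = max(0, center - half), end = center + half,
        fold_enrichment = fold, pileup = pileup, q_value = q,
        stringsAsFactors = FALSE)
    }
    strong_lfc <- function(n) {
      sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 2, 3.5)
    }
    for (i in seq_len(n_genes)) {
      offset <- round(stats::runif(1, 500, 8000)) * sample(c(-1, 1), 1)
      if (i %in% planted) {
        lfc[i] <- strong_lfc(1)
        add_peak(tss_pos[i] + offset, stats::runif(1, 6, 20),
                 round(stats::runif(1, 30, 120)), stats::runif(1, 1e-6, 5e-3))
      } else {
        mode <- decoy_mode[[as.character(i)]]
        if (mode == 1) {         # shortlist-passing peak, but too far
          far <- round(stats::runif(1, 15000, 45000)) * sample(c(-1, 1), 1)
          lfc[i] <- strong_lfc(1)
          add_peak(tss_pos[i] + far, stats::runif(1, 6, 20),
                   round(stats::runif(1, 30, 120)),
                   stats::runif(1, 1e-6, 5e-3))
        } else if (mode == 2) {  # near peak failing the enrichment shortlist
          lfc[i] <- strong_lfc(1)
          add_peak(tss_pos[i] + offset, stats::runif(1, 1, 4.5),
                   round(stats::runif(1, 5, 20)), stats::runif(1, 0.02, 0.5))
        } else {                 # good near peak, weak expression change
          lfc[i] <- stats::runif(1, -1.2, 1.2)
          add_peak(tss_pos[i] + offset, stats::runif(1, 6, 20),
                   round(stats::runif(1, 30, 120)),
                   stats::runif(1, 1e-6, 5e-3))
        }
      }
    }
    peaks <- if (length(peak_rows)) {
      do.call(rbind, peak_rows)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 fold_enrichment = numeric(), pileup = numeric(),
                 q_value = numeric(), stringsAsFactors = FALSE)
    }
    rownames(peaks) <- NULL
    list(peaks = peaks, tss = tss,
         deg = data.frame(gene_id = gene_id, log2_fold_change = lfc,
                          stringsAsFactors = FALSE),
         truth = gene_id[planted])
  })
}

#' Default planted compound panel for the demonstration screen
#'
#' Builds ground truths for a three-line isogenic panel (p53-null,
#' p53 wild-type, p53 R158G mutant): a set of mutant-selective compounds
#' (potent only in the R158G line), a few compounds selective for each of
#' the other lines, some pan-active and dual-active compounds, and an
#' inactive remainder. Selective compounds use ed50 0.05 µM in their
#' target line and 50 µM elsewhere, a thousand-fold potency window.
#'
#' @param n_compounds Total compounds (default 200).
#' @param n_r158g,n_wt,n_null Line-selective counts per target line
#'   (defaults 17, 5, 5).
#' @param n_pan,n_dual Pan-active and two-line-active counts.
#' @param panel Cell-line ids; the third entry is the mutant line.
#' @return List of [compound_truth()] with a `classes` attribute naming
#'   each compound's planted category.
#' @export
demo_screen_truths <- function(n_compounds = 200, n_r158g = 17,
                               n_wt = 5, n_null = 5, n_pan = 20, n_dual = 5,
                               panel = c("p53_null", "p53_wt", "p53_R158G")) {
  stopifnot(length(panel) == 3,
            n_r158g + n_wt + n_null + n_pan + n_dual <= n_compounds)
  pot <- function(ed50) list(ed50 = ed50, hill = 1, emax = 0.95)
  selective_for <- function(line) {
    p <- stats::setNames(rep(list(pot(50)), 3), panel)
    p[[line]] <- pot(0.05)
    p
  }
  classes <- c(rep("R158G_selective", n_r158g),
               rep("WT_selective", n_wt),
               rep("NULL_selective", n_null),
               rep("pan_active", n_pan),
               rep("dual_active", n_dual),
               rep("inactive", n_compounds - n_r158g - n_wt - n_null -
                     n_pan - n_dual))
  truths <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    id <- sprintf("CMPD%03d", i)
    p <- switch(classes[i],
      R158G_selective = selective_for(panel[3]),
      WT_selective    = selective_for(panel[2]),
      NULL_selective  = selective_for(panel[1]),
      pan_active      = stats::setNames(rep(list(pot(0.05)), 3), panel),
      dual_active     = {
        q <- selective_for(panel[3]); q[[panel[2]]] <- pot(0.05); q
      },
      inactive        = stats::setNames(rep(list(pot(500)), 3), panel))
    truths[[i]] <- compound_truth(id, p)
  }
  structure(truths,
            classes = stats::setNames(
              classes, vapply(truths, `[[`, character(1), "compound_id")))
}
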