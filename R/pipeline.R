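# End-to-end orchestration of the synthetic demonstration pipeline:
# simulate -> validate -> score -> hits -> fit -> synergy -> targets.
# All stage seeds derive from the single run seed by fixed offsets, so a
# run is reproducible from (config) alone.

.seed_offsets <- c(screen = 0L, dose_response = 1000L, synergy = 2000L,
                   genomic = 3000L)

#' Resolved configuration for a pipeline run
#'
#' Collects the run seed, plate design, synthetic-screen size and every
#' analysis threshold actually applied. The resolved config is written
#' next to the outputs of each run as an audit trail.
#'
#' @param seed Run seed; all stage RNG streams derive from it.
#' @param out_dir Output directory (created if absent).
#' @param n_compounds Compounds in the simulated screen.
#' @param doses Screening doses in µM.
#' @param noise_cv Well-noise coefficient of variation.
#' @param n_replicates Replicates per well condition.
#' @param plate_format 96 or 384.
#' @param efficacy_threshold,selectivity_threshold Percent-inhibition
#'   cut-offs for hit calling.
#' @param fold_change_threshold ED50 fold-change flag threshold.
#' @param bliss_saturation Single-agent inhibition above which matrix
#'   cells are excluded from Bliss summaries.
#' @param peak_min_fold,peak_min_pileup,peak_max_q Peak shortlist
#'   thresholds.
#' @param target_max_dist,target_min_abs_lfc Direct-target thresholds.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("isoscreen_run_"),
                       n_compounds = 200L, doses = c(0.1, 1),
                       noise_cv = 0.05, n_replicates = 3L,
                       plate_format = 384L,
                       efficacy_threshold = 50, selectivity_threshold = 50,
                       fold_change_threshold = 10,
                       bliss_saturation = 0.99,
                       peak_min_fold = 5, peak_min_pileup = 25,
                       peak_max_q = 0.01,
                       target_max_dist = 10000, target_min_abs_lfc = 1.5) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_compounds = as.integer(n_compounds), doses = doses,
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 plate_format = as.integer(plate_format),
                 efficacy_threshold = efficacy_threshold,
                 selectivity_threshold = selectivity_threshold,
                 fold_change_threshold = fold_change_threshold,
                 bliss_saturation = bliss_saturation,
                 peak_min_fold = peak_min_fold,
                 peak_min_pileup = peak_min_pileup,
                 peak_max_q = peak_max_q,
                 target_max_dist = target_max_dist,
                 target_min_abs_lfc = target_min_abs_lfc),
            class = "run_config")
}

# Drug pair emulating an HDAC-inhibitor modulator combined with a
# DNA-damaging agent across the isogenic panel, with planted Bliss
# deviations: synergy in the mutant line, mild antagonism in wild-type,
# independence in the null line.
.demo_combination <- function(panel = c("p53_null", "p53_wt", "p53_R158G")) {
  pot <- function(ed50) list(ed50 = ed50, hill = 1, emax = 0.95)
  modulator <- compound_truth(
    "MODULATOR", stats::setNames(rep(list(pot(5)), 3), panel))
  cytotoxic <- compound_truth(
    "CYTOTOXIC", stats::setNames(rep(list(pot(3)), 3), panel))
  interaction <- interaction_truth(stats::setNames(
    c(0, -0.1, 0.2), panel))
  list(modulator = modulator, cytotoxic = cytotoxic,
       interaction = interaction)
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates the three-line screen with planted ground truth, validates
#' a CSV round-trip, scores and calls hits, fits dose-response curves
#' for one planted selective compound, computes Bliss surfaces for a
#' planted drug combination, runs IC50-shift analysis under the
#' modulator, calls direct targets on a planted genomic fixture, and
#' writes every table plus a resolved config and an md5 manifest to
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output `manifest` (file, md5) and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  panel <- c("p53_null", "p53_wt", "p53_R158G")

  # --- simulate + validate screen -----------------------------------
  # planted class counts scale with the screen size (17/5/5/20/5 of 200
  # at full size), keeping at least one compound per class
  f <- config$n_compounds / 200
  truths <- demo_screen_truths(
    n_compounds = config$n_compounds,
    n_r158g = max(1, round(17 * f)), n_wt = max(1, round(5 * f)),
    n_null = max(1, round(5 * f)), n_pan = max(1, round(20 * f)),
    n_dual = max(1, round(5 * f)), panel = panel)
  sc <- sim_config(seed = config$seed + .seed_offsets[["screen"]],
                   plate_format = config$plate_format,
                   n_replicates = config$n_replicates,
                   noise_cv = config$noise_cv)
  screen <- generate_single_dose_screen(sc, truths, config$doses)
  write_screen(screen, out("screen.csv"))
  screen <- read_screen(out("screen.csv"),
                        plate_format = config$plate_format)

  # --- score + hits -------------------------------------------------
  scored <- score_screen(screen)
  agg <- aggregate_scores(scored)
  utils::write.csv(agg, out("iscores.csv"), row.names = FALSE)
  profile <- inhibition_profile(agg)
  hits <- hit_calls(profile, threshold = config$selectivity_threshold)
  utils::write.csv(hits, out("hits.csv"), row.names = FALSE)
  tree <- cluster_profiles(profile)
  prof_out <- data.frame(compound = rownames(profile)[tree$order],
                         profile[tree$order, , drop = FALSE],
                         row.names = NULL, check.names = FALSE)
  utils::write.csv(prof_out, out("profile.csv"), row.names = FALSE)

  # --- dose-response on the first planted selective compound --------
  classes <- attr(truths, "classes")
  sel_id <- names(classes)[classes == "R158G_selective"][1]
  sel_truth <- truths[[match(sel_id, names(classes))]]
  dr_doses <- 10^seq(-3, 2, length.out = 8)
  dr_config <- sim_config(seed = config$seed +
                            .seed_offsets[["dose_response"]],
                          plate_format = config$plate_format,
                          n_replicates = config$n_replicates,
                          noise_cv = config$noise_cv)
  dr_screen <- generate_single_dose_screen(dr_config, list(sel_truth),
                                           dr_doses)
  dr_agg <- aggregate_scores(score_screen(dr_screen))
  fits <- lapply(stats::setNames(panel, panel), function(line) {
    sub <- dr_agg[dr_agg$cell_line == line, ]
    fit_4pl(sub$dose_um, 100 - sub$i_score)
  })
  fit_rows <- do.call(rbind, lapply(panel, function(line) {
    f <- fits[[line]]
    data.frame(cell_line = line, bottom = f$bottom, top = f$top,
               hill = f$hill, ec50_um = f$ec50,
               ic50_um = if (f$converged) {
                 suppressWarnings(ic50_absolute(f))
               } else NA_real_,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  utils::write.csv(fit_rows, out("fits.csv"), row.names = FALSE)
  fold <- potency_fold_change(fits[["p53_R158G"]], fits[["p53_wt"]],
                              threshold = config$fold_change_threshold)

  # --- Bliss synergy surfaces ---------------------------------------
  combo <- .demo_combination(panel)
  syn_config <- sim_config(seed = config$seed + .seed_offsets[["synergy"]],
                           plate_format = config$plate_format,
                           n_replicates = config$n_replicates,
                           noise_cv = config$noise_cv)
  matrix_long <- generate_dose_matrix(
    syn_config, combo$modulator, combo$cytotoxic, combo$interaction,
    doses_a = c(0.1, 0.3, 1), doses_b = c(0.1, 0.3, 1, 3, 10))
  surfaces <- lapply(stats::setNames(panel, panel), function(line) {
    bliss_surface(as_dose_matrix(matrix_long, line),
                  saturation = config$bliss_saturation)
  })
  for (line in panel) {
    utils::write.csv(
      data.frame(dose_a_um = rep(surfaces[[line]]$doses_a,
                                 times = length(surfaces[[line]]$doses_b)),
                 dose_b_um = rep(surfaces[[line]]$doses_b,
                                 each = length(surfaces[[line]]$doses_a)),
                 observed = as.vector(surfaces[[line]]$observed),
                 expected = as.vector(surfaces[[line]]$expected),
                 ci = as.vector(surfaces[[line]]$score)),
      out(sprintf("bliss_%s.csv", line)), row.names = FALSE)
  }

  # --- IC50 shift under the fixed modulator -------------------------
  shifts <- vapply(stats::setNames(panel, panel), function(line) {
    sub <- matrix_long[matrix_long$cell_line == line, ]
    mean_v <- function(da) {
      s <- sub[sub$dose_a_um == da & sub$dose_b_um > 0, ]
      v <- tapply(s$viability_pct, s$dose_b_um, mean)
      list(d = as.numeric(names(v)), v = as.numeric(v))
    }
    alone <- mean_v(0)
    with_mod <- mean_v(0.1)
    ic50_shift(fit_4pl(alone$d, alone$v), fit_4pl(with_mod$d, with_mod$v))
  }, numeric(1))

  # --- direct targets on the planted genomic fixture ----------------
  gen_config <- sim_config(seed = config$seed + .seed_offsets[["genomic"]])
  fixture <- generate_genomic_fixture(gen_config, n_genes = 50,
                                      n_planted_targets = 5)
  write_peaks(fixture$peaks, out("peaks.tsv"))
  write_tss(fixture$tss, out("tss.tsv"))
  write_deg(fixture$deg, out("deg.tsv"))
  shortlisted <- shortlist_peaks(fixture$peaks,
                                 min_fold = config$peak_min_fold,
                                 min_pileup = config$peak_min_pileup,
                                 max_q = config$peak_max_q)
  targets <- call_direct_targets(shortlisted, fixture$tss, fixture$deg,
                                 max_dist = config$target_max_dist,
                                 min_abs_lfc = config$target_min_abs_lfc)
  utils::write.table(targets, out("targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- resolved config + manifest -----------------------------------
  # out_dir is a run location, not an analysis parameter: keeping it out
  # of the resolved config makes same-seed manifests identical.
  cfg_lines <- vapply(setdiff(names(config), "out_dir"), function(k) {
    sprintf("%s=%s", k, paste(format(config[[k]], trim = TRUE),
                              collapse = ","))
  }, character(1))
  writeLines(cfg_lines, out("run_config.txt"))
  files <- sort(list.files(config$out_dir))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(
                           file.path(config$out_dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, out("manifest.csv"), row.names = FALSE)

  invisible(list(manifest = manifest, screen = screen, profile = profile,
                 hits = hits, tree = tree, fits = fits, fold = fold,
                 surfaces = surfaces, ic50_shifts = shifts,
                 targets = targets, fixture = fixture,
                 planted_classes = attr(truths, "classes")))
}
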