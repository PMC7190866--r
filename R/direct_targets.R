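# Direct-target calling: intersect enrichment-shortlisted ChIP peaks
# proximal to gene TSSs with strong expression changes. Peak coordinates
# are BED-convention 0-based half-open [start, end).

.validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "fold_enrichment", "pileup", "q_value")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(peaks)) {
    if (any(peaks$start >= peaks$end)) {
      stop("peak with start >= end", call. = FALSE)
    }
    if (any(peaks$q_value < 0 | peaks$q_value > 1)) {
      stop("q_value outside [0, 1]", call. = FALSE)
    }
    if (any(peaks$fold_enrichment < 0)) {
      stop("negative fold_enrichment", call. = FALSE)
    }
  }
  peaks
}

#' Shortlist highly enriched, highly significant peaks
#'
#' Keeps peaks with `fold_enrichment >= min_fold`, `pileup >= min_pileup`
#' and `q_value < max_q`. The enrichment and pileup cut-offs are
#' inclusive; the q-value cut-off is strict.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`,
#'   `fold_enrichment`, `pileup`, `q_value`.
#' @param min_fold Minimum fold enrichment over background (default 5).
#' @param min_pileup Minimum read pileup (default 25).
#' @param max_q Strict q-value bound (default 0.01).
#' @return The retained rows of `peaks`.
#' @export
shortlist_peaks <- function(peaks, min_fold = 5, min_pileup = 25,
                            max_q = 0.01) {
  peaks <- .validate_peaks(peaks)
  keep <- peaks$fold_enrichment >= min_fold & peaks$pileup >= min_pileup &
    peaks$q_value < max_q
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance from a peak to a TSS position
#'
#' Zero when the TSS lies inside the half-open peak interval
#' `[start, end)`; otherwise the distance to the nearest covered base,
#' `min(|tss - start|, |tss - (end - 1)|)`. Strand only determines which
#' coordinate the caller uses as the TSS; it does not change the
#' distance.
#'
#' @param start,end Peak interval, 0-based half-open.
#' @param tss TSS position (bp).
#' @param chrom_peak,chrom_tss Optional chromosome names; if both are
#'   given and differ the distance is undefined and an error is raised.
#' @return Distance in bp (vectorized).
#' @export
peak_tss_distance <- function(start, end, tss,
                              chrom_peak = NULL, chrom_tss = NULL) {
  stopifnot(all(start < end))
  if (!is.null(chrom_peak) && !is.null(chrom_tss) &&
      any(chrom_peak != chrom_tss)) {
    stop("peak and TSS lie on different chromosomes; distance undefined",
         call. = FALSE)
  }
  ifelse(tss >= start & tss < end, 0L,
         pmin(abs(tss - start), abs(tss - (end - 1L))))
}

#' Call direct targets from shortlisted peaks and expression changes
#'
#' A gene is called a direct target when (a) some shortlisted peak on
#' the gene's chromosome lies strictly closer than `max_dist` to its
#' TSS, and (b) its absolute log2 fold-change strictly exceeds
#' `min_abs_lfc`. Both thresholds are strict, so distance exactly 10 kb
#' or |log2FC| exactly 1.5 do not qualify under the defaults. The
#' nearest peak is reported per called gene; output is sorted by
#' |log2FC| descending (ties by gene id).
#'
#' @param peaks Shortlisted peak table (see [shortlist_peaks()]).
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param degs data.frame with `gene_id`, `log2_fold_change`.
#' @param max_dist Strict distance bound in bp (default 10000).
#' @param min_abs_lfc Strict |log2FC| bound (default 1.5).
#' @return data.frame with `gene_id`, `chrom`, `peak_start`, `peak_end`,
#'   `distance_bp`, `log2_fold_change`. Genes in the DEG table missing
#'   from the TSS table are skipped with a warning.
#' @export
call_direct_targets <- function(peaks, tss_table, degs,
                                max_dist = 10000, min_abs_lfc = 1.5) {
  peaks <- .validate_peaks(peaks)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss_table)),
            all(c("gene_id", "log2_fold_change") %in% names(degs)))
  if (any(!is.finite(degs$log2_fold_change))) {
    stop("non-finite log2 fold-change", call. = FALSE)
  }
  if (nrow(tss_table) &&
      (any(tss_table$tss < 0) || !all(tss_table$strand %in% c("+", "-")))) {
    stop("invalid TSS table", call. = FALSE)
  }

  cand <- degs[abs(degs$log2_fold_change) > min_abs_lfc, , drop = FALSE]
  missing <- setdiff(cand$gene_id, tss_table$gene_id)
  if (length(missing)) {
    warning("DEG gene(s) missing from TSS table, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    cand <- cand[!cand$gene_id %in% missing, , drop = FALSE]
  }

  calls <- list()
  peaks_by_chrom <- split(peaks, peaks$chrom)
  for (i in seq_len(nrow(cand))) {
    g <- cand$gene_id[i]
    trow <- tss_table[match(g, tss_table$gene_id), ]
    pk <- peaks_by_chrom[[trow$chrom]]
    if (is.null(pk) || !nrow(pk)) next
    d <- peak_tss_distance(pk$start, pk$end, trow$tss)
    j <- which.min(d)
    if (d[j] < max_dist) {
      calls[[length(calls) + 1L]] <- data.frame(
        gene_id = g, chrom = trow$chrom,
        peak_start = pk$start[j], peak_end = pk$end[j],
        distance_bp = as.integer(d[j]),
        log2_fold_change = cand$log2_fold_change[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      peak_start = integer(), peak_end = integer(),
                      distance_bp = integer(),
                      log2_fold_change = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out <- out[order(-abs(out$log2_fold_change), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write helpers for the genomic tables
#'
#' Plain TSVs: peaks with the six shortlist columns, TSS as BED-like
#' four columns, DEGs as two columns. All coordinates 0-based half-open.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_*` return data.frames; `write_*` return `path`
#'   invisibly.
#' @name genomic_io
NULL

#' @rdname genomic_io
#' @export
write_peaks <- function(x, path) {
  utils::write.table(.validate_peaks(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname genomic_io
#' @export
read_peaks <- function(path) {
  .validate_peaks(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname genomic_io
#' @export
write_tss <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genomic_io
#' @export
read_tss <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname genomic_io
#' @export
write_deg <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genomic_io
#' @export
read_deg <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
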