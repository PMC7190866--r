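# Plate geometry per supported format: rows x cols.
.plate_dims <- function(plate_format) {
  plate_format <- as.integer(plate_format)
  switch(as.character(plate_format),
    "96"  = c(rows = 8L,  cols = 12L),
    "384" = c(rows = 16L, cols = 24L),
    stop("unsupported plate format: ", plate_format, " (use 96 or 384)",
         call. = FALSE)
  )
}

#' Parse a well label into 0-based plate coordinates
#'
#' Well labels use the familiar letter-row, 1-based-column convention
#' ("A1" is the top-left well). Internally rows and columns are 0-based
#' indices; `well_label()` is the exact inverse.
#'
#' @param label Character vector of labels such as `"A1"`, `"P24"`.
#' @param plate_format Plate size, `96` (8 x 12) or `384` (16 x 24).
#' @return A data.frame with columns `row`, `col` (0-based integers) and
#'   `label` (the canonical re-rendered label).
#' @examples
#' well_from_label("A1", 384)   # row 0, col 0
#' well_from_label("P24", 384)  # row 15, col 23
#' @export
well_from_label <- function(label, plate_format = 384) {
  dims <- .plate_dims(plate_format)
  label <- toupper(trimws(as.character(label)))
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)$", label))
  bad <- vapply(m, function(x) length(x) != 3L, logical(1))
  if (any(bad)) {
    stop("malformed well label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- match(vapply(m, `[[`, character(1), 2L), LETTERS) - 1L
  col <- as.integer(vapply(m, `[[`, character(1), 3L)) - 1L
  oob <- row >= dims[["rows"]] | col >= dims[["cols"]] | col < 0L
  if (any(oob)) {
    stop("well label(s) out of range for ", plate_format, "-well plate: ",
         paste(label[oob], collapse = ", "), call. = FALSE)
  }
  data.frame(row = row, col = col, label = well_label(row, col),
             stringsAsFactors = FALSE)
}

#' Render 0-based plate coordinates as a well label
#'
#' @param row,col 0-based integer vectors.
#' @return Character labels like `"A1"`.
#' @export
well_label <- function(row, col) {
  paste0(LETTERS[row + 1L], col + 1L)
}

#' The compound identifier used for vehicle-control wells
#'
#' Control wells are marked by this sentinel in the `compound` column,
#' not by a zero dose alone, so that genuinely untreated (dose 0)
#' compound wells can never be mistaken for controls.
#' @export
DMSO_SENTINEL <- "DMSO"

.screen_columns <- c("plate_id", "well", "cell_line", "compound",
                     "dose_um", "replicate", "luminescence")

#' Construct a validated screen dataset
#'
#' A `screen_dataset` is a long-format table of plate-well records, one
#' well per row, with the cell-line panel and provenance kept as
#' attributes. Validation is total: any malformed record raises an error
#' rather than returning a partial dataset.
#'
#' @param records data.frame with columns `plate_id`, `well`, `cell_line`,
#'   `compound`, `dose_um`, `replicate`, `luminescence`.
#' @param plate_format 96 or 384.
#' @param control_sentinel Compound id marking vehicle wells.
#' @param provenance Optional list of generator config / seed metadata.
#' @return A `screen_dataset` (data.frame subclass).
#' @export
screen_dataset <- function(records, plate_format = 384,
                           control_sentinel = DMSO_SENTINEL,
                           provenance = list()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.screen_columns, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[.screen_columns]
  records$plate_id <- as.character(records$plate_id)
  records$well <- toupper(as.character(records$well))
  records$cell_line <- as.character(records$cell_line)
  records$compound <- as.character(records$compound)
  records$dose_um <- as.numeric(records$dose_um)
  records$replicate <- as.integer(records$replicate)
  records$luminescence <- as.numeric(records$luminescence)

  if (nrow(records)) {
    wells <- well_from_label(records$well, plate_format)
    records$well <- wells$label

    bad_lum <- which(!is.finite(records$luminescence) |
                       records$luminescence < 0)
    if (length(bad_lum)) {
      stop("negative or non-finite luminescence at row(s): ",
           paste(utils::head(bad_lum, 5L), collapse = ", "), call. = FALSE)
    }
    bad_dose <- which(!is.finite(records$dose_um) | records$dose_um < 0)
    if (length(bad_dose)) {
      stop("negative or non-finite dose at row(s): ",
           paste(utils::head(bad_dose, 5L), collapse = ", "), call. = FALSE)
    }
    is_ctrl <- records$compound == control_sentinel
    if (any(records$dose_um[is_ctrl] != 0)) {
      stop("control wells must have dose 0", call. = FALSE)
    }
    key <- paste(records$plate_id, records$well)
    if (anyDuplicated(key)) {
      stop("duplicate (plate, well) record(s): ",
           paste(utils::head(unique(key[duplicated(key)]), 5L),
                 collapse = "; "), call. = FALSE)
    }
    ctrl_plates <- unique(records$plate_id[is_ctrl])
    no_ctrl <- setdiff(unique(records$plate_id), ctrl_plates)
    if (length(no_ctrl)) {
      stop("no controls on plate: ", paste(no_ctrl, collapse = ", "),
           call. = FALSE)
    }
    # deterministic row order: plate, then physical well position
    ord <- order(records$plate_id, wells$row, wells$col)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }

  structure(records,
            class = c("screen_dataset", "data.frame"),
            plate_format = as.integer(plate_format),
            control_sentinel = control_sentinel,
            panel = sort(unique(records$cell_line)),
            provenance = provenance)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("screen_dataset: %d wells, %d plate(s), %d-well format\n",
              nrow(x), length(unique(x$plate_id)), attr(x, "plate_format")))
  cat("panel:", paste(attr(x, "panel"), collapse = ", "), "\n")
  NextMethod()
}

#' Read a long-format screen CSV
#'
#' Expects the canonical columns `plate_id, well, cell_line, compound,
#' dose_um, replicate, luminescence`. All records are validated;
#' duplicate wells, negative signals and plates without vehicle controls
#' are rejected.
#'
#' @inheritParams screen_dataset
#' @param path CSV file path.
#' @return A [screen_dataset()].
#' @export
read_screen <- function(path, plate_format = 384,
                        control_sentinel = DMSO_SENTINEL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  screen_dataset(records, plate_format = plate_format,
                 control_sentinel = control_sentinel)
}

#' Write a screen dataset to CSV
#'
#' Output is deterministic: fixed column order, rows sorted by plate and
#' physical well position, `.` decimal separator, full numeric precision.
#' Two writes of the same dataset produce identical bytes.
#'
#' @param dataset A [screen_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_screen <- function(dataset, path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  out <- as.data.frame(dataset)[.screen_columns]
  out$dose_um <- format(out$dose_um, digits = 17, trim = TRUE,
                        scientific = FALSE)
  out$luminescence <- format(out$luminescence, digits = 17, trim = TRUE,
                             scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
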