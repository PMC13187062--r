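#' Read traced contours from JSON
#'
#' Input schema: an object with `specimen_id`, `calibration_um_per_px` and
#' `osteons`, an array of `{id, outline: [[x, y], ...], canal: [[x, y], ...]}`
#' with vertices in pixel units (0-based pixel centres, fractional allowed).
#'
#' @param path JSON file.
#' @return A `contour_set`: list with `specimen_id`,
#'   `calibration_um_per_px` and `osteons` (each a list with `id`,
#'   `outline`, `canal` vertex matrices).
#' @seealso [measure_contours()], [write_contours_json()]
#' @export
read_contours_json <- function(path) {
  if (!file.exists(path)) {
    abort_stage("read_contours_json", paste0("file not found: ", path))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  needed <- c("specimen_id", "calibration_um_per_px", "osteons")
  missing_f <- setdiff(needed, names(raw))
  if (length(missing_f) > 0) {
    abort_stage("read_contours_json",
                paste0("missing field(s): ", paste(missing_f, collapse = ", ")))
  }
  osteons <- lapply(raw$osteons, function(o) {
    list(id = as.character(o$id),
         outline = do.call(rbind, lapply(o$outline, unlist)),
         canal = do.call(rbind, lapply(o$canal, unlist)))
  })
  structure(
    list(specimen_id = raw$specimen_id,
         calibration_um_per_px = as.numeric(raw$calibration_um_per_px),
         osteons = osteons),
    class = "contour_set"
  )
}

#' Write a contour set to JSON
#'
#' Deterministic serialization (fixed field order, fixed precision) so a
#' generator run with a fixed seed produces byte-identical files.
#'
#' @param contours A `contour_set` (see [read_contours_json()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  obj <- list(
    specimen_id = jsonlite::unbox(contours$specimen_id),
    calibration_um_per_px = jsonlite::unbox(contours$calibration_um_per_px),
    osteons = lapply(contours$osteons, function(o) {
      list(id = jsonlite::unbox(as.character(o$id)),
           outline = unname(lapply(seq_len(nrow(o$outline)),
                                   function(i) unname(o$outline[i, ]))),
           canal = unname(lapply(seq_len(nrow(o$canal)),
                                 function(i) unname(o$canal[i, ]))))
    })
  )
  json <- jsonlite::toJSON(obj, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read traced contours from long-format CSV
#'
#' Equivalent to the JSON schema: columns `specimen_id`, `osteon_id`,
#' `role` (`outline`/`canal`), `vertex_index`, `x`, `y`,
#' `calibration_um_per_px`.
#'
#' @param path CSV file.
#' @return A `contour_set`.
#' @export
read_contours_csv <- function(path) {
  if (!file.exists(path)) {
    abort_stage("read_contours_csv", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "osteon_id", "role", "vertex_index", "x", "y",
              "calibration_um_per_px")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_stage("read_contours_csv",
                paste0("schema mismatch, missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  sid <- unique(df$specimen_id)
  if (length(sid) != 1) {
    abort_stage("read_contours_csv", "file must contain a single specimen")
  }
  cal <- unique(df$calibration_um_per_px)
  if (length(cal) != 1) {
    abort_stage("read_contours_csv", "calibration must be constant per file")
  }
  osteons <- lapply(split(df, df$osteon_id), function(d) {
    pull <- function(role) {
      dd <- d[d$role == role, ]
      dd <- dd[order(dd$vertex_index), ]
      cbind(dd$x, dd$y)
    }
    list(id = as.character(d$osteon_id[1]),
         outline = pull("outline"), canal = pull("canal"))
  })
  structure(
    list(specimen_id = sid, calibration_um_per_px = cal,
         osteons = unname(osteons)),
    class = "contour_set"
  )
}

#' Measure every osteon in a contour set
#'
#' Applies [measure_osteon()] to each outline/canal pair using the set's
#' calibration.
#'
#' @param contours A `contour_set`.
#' @return Data frame with one row per osteon: `specimen_id`, `osteon_id`,
#'   `onar_um2`, `har_um2`.
#' @export
measure_contours <- function(contours) {
  if (length(contours$osteons) == 0) {
    return(data.frame(specimen_id = character(0), osteon_id = character(0),
                      onar_um2 = numeric(0), har_um2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(contours$osteons, function(o) {
    measure_osteon(o$outline, o$canal, contours$calibration_um_per_px,
                   specimen_id = contours$specimen_id, osteon_id = o$id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-osteon measurements to CSV
#'
#' @param measurements Data frame from [measure_contours()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
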