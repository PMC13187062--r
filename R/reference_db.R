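#' Comparative reference database
#'
#' The package ships a transcription of a published comparative mammalian
#' histomorphometry table: one row per reference specimen with osteon area
#' (On.Ar) and Haversian-canal area (H.Ar) summary statistics. Dispersions
#' are stored with an explicit kind tag (`SE` or `SD`) because the source
#' table mixes both; conversion to SD happens downstream where N is known
#' (see [dispersion_to_sd()]). Rows whose only tissue is plexiform bone
#' (`PF`) carry no osteon metrics.
#'
#' @name reference_db
NULL

REFERENCE_COLUMNS <- c(
  "taxon", "specimen_id", "element", "tissue",
  "n_onar", "mean_onar", "disp_onar", "disp_kind_onar",
  "n_har", "mean_har", "disp_har", "disp_kind_har",
  "n_bones", "source"
)

VALID_SOURCES <- c("this-study", "sawada", "external-literature")

#' Load the comparative reference database
#'
#' Reads and validates a reference CSV (see `REFERENCE_COLUMNS` for the
#' frozen schema). Each row describes one reference specimen: taxon,
#' specimen ID, skeletal element code, tissue types observed (`SO` =
#' secondary osteons, `PF` = plexiform bone, `SO;PF` = both), per-metric
#' osteon counts, means and dispersions (with kind `SE` or `SD`), number of
#' bones sampled, and data source (`this-study`, `sawada`,
#' `external-literature`).
#'
#' @param path CSV file; defaults to the packaged fixture.
#' @return A `data.frame` of class `reference_db`, one row per specimen.
#' @examples
#' ref <- load_reference()
#' nrow(ref)
#' subset(ref, specimen_id == "PLN01Tp")$mean_onar
#' @export
load_reference <- function(path = osteohist_fixture("reference")) {
  if (!file.exists(path)) {
    abort_stage("load_reference", paste0("file not found: ", path))
  }
  ref <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      abort_stage("load_reference", paste0("cannot parse CSV: ", conditionMessage(e)))
    }
  )
  missing_cols <- setdiff(REFERENCE_COLUMNS, names(ref))
  if (length(missing_cols) > 0) {
    abort_stage("load_reference",
                paste0("schema mismatch, missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(ref) == 0) {
    abort_stage("load_reference", "no records in file")
  }
  ref <- ref[, REFERENCE_COLUMNS]
  num_cols <- c("n_onar", "mean_onar", "disp_onar", "n_har", "mean_har",
                "disp_har", "n_bones")
  for (col in num_cols) ref[[col]] <- as.numeric(ref[[col]])

  validate_reference(ref)
  class(ref) <- c("reference_db", "data.frame")
  ref
}

validate_reference <- function(ref) {
  bad_source <- setdiff(unique(ref$source), VALID_SOURCES)
  if (length(bad_source) > 0) {
    abort_stage("load_reference",
                paste0("unknown data source code(s): ",
                       paste(bad_source, collapse = ", ")))
  }
  for (metric in c("onar", "har")) {
    m <- ref[[paste0("mean_", metric)]]
    d <- ref[[paste0("disp_", metric)]]
    k <- ref[[paste0("disp_kind_", metric)]]
    bad <- !is.na(m) & m <= 0
    if (any(bad)) {
      abort_stage("load_reference",
                  paste0("non-positive mean_", metric, " for: ",
                         paste(ref$specimen_id[bad], collapse = ", ")))
    }
    bad <- !is.na(d) & d <= 0
    if (any(bad)) {
      abort_stage("load_reference",
                  paste0("non-positive disp_", metric, " for: ",
                         paste(ref$specimen_id[bad], collapse = ", ")))
    }
    bad <- !is.na(d) & (is.na(k) | !k %in% c("SE", "SD"))
    if (any(bad)) {
      abort_stage("load_reference",
                  paste0("dispersion without valid kind (SE/SD) for: ",
                         paste(ref$specimen_id[bad], collapse = ", ")))
    }
  }
  # PF-only rows must not carry osteon metrics
  pf_only <- ref$tissue == "PF"
  has_metric <- !is.na(ref$mean_onar) | !is.na(ref$mean_har)
  if (any(pf_only & has_metric)) {
    abort_stage("load_reference",
                paste0("plexiform-only row carries osteon metrics: ",
                       paste(ref$specimen_id[pf_only & has_metric], collapse = ", ")))
  }
  bad_n <- !is.na(ref$n_bones) & ref$n_bones < 1
  if (any(bad_n)) {
    abort_stage("load_reference",
                paste0("n_bones < 1 for: ",
                       paste(ref$specimen_id[bad_n], collapse = ", ")))
  }
  invisible(ref)
}

#' Restrict the reference database to the statistical comparison set
#'
#' The pairwise statistical comparisons use only specimens measured in the
#' source study or by the same laboratory's earlier work
#' (`source` in `this-study`, `sawada`); values transcribed from external
#' literature are excluded, as are plexiform-only rows lacking osteon
#' metrics. Idempotent.
#'
#' @param records A `reference_db` data frame from [load_reference()].
#' @return Filtered `reference_db`.
#' @examples
#' nrow(filter_statistical_set(load_reference())) # 45
#' @export
filter_statistical_set <- function(records) {
  keep <- records$source %in% c("this-study", "sawada") &
    !is.na(records$mean_onar) & !is.na(records$mean_har)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_db", "data.frame")
  out
}

#' Load the taxon-to-group table
#'
#' Maps each reference taxon to one of eight labels combining order-level
#' taxonomy with body size: `proboscideans`, `human`, `medium_primates`,
#' `lagomorphs`, `medium_artiodactyls`, `large_artiodactyls`,
#' `medium_carnivores`, `large_carnivores`.
#'
#' @param path CSV with columns `taxon,group_label`; defaults to the
#'   packaged fixture.
#' @return Data frame with columns `taxon` and `group_label`.
#' @export
load_taxon_groups <- function(path = osteohist_fixture("taxon_groups")) {
  tg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group_label") %in% names(tg))) {
    abort_stage("load_taxon_groups", "schema mismatch: need taxon,group_label")
  }
  if (anyDuplicated(tg$taxon)) {
    abort_stage("load_taxon_groups", "duplicated taxon in group table")
  }
  tg
}

#' Partition reference records into taxon groups
#'
#' Splits the reference records into the order-level/body-size groups
#' defined by the taxon-to-group table. The result is a partition: every
#' record appears in exactly one group.
#'
#' @param records A `reference_db` data frame.
#' @param taxon_groups Data frame from [load_taxon_groups()].
#' @return Named list of `reference_db` data frames, one per group label
#'   present in the input.
#' @examples
#' groups <- group_records(load_reference())
#' nrow(groups$proboscideans) # 3
#' @export
group_records <- function(records, taxon_groups = load_taxon_groups()) {
  if (nrow(records) == 0) {
    return(stats::setNames(list(), character(0)))
  }
  unknown <- setdiff(unique(records$taxon), taxon_groups$taxon)
  if (length(unknown) > 0) {
    abort_stage("group_records",
                paste0("taxon not in group table: ",
                       paste(unknown, collapse = ", ")))
  }
  label <- taxon_groups$group_label[match(records$taxon, taxon_groups$taxon)]
  out <- split(records, label)
  lapply(out, function(df) {
    rownames(df) <- NULL
    class(df) <- c("reference_db", "data.frame")
    df
  })
}

#' Load the burned-fragment registry
#'
#' One row per excavated burned bone fragment: maximum length (mm), bone
#' type, histomorphological condition (`good`, `not_good`), and structure
#' observed in the CT slices (`osteon`, `osteon_uncertain`, `plexiform`).
#' Fragments whose osteon outlines were too indistinct to trace are coded
#' `osteon_uncertain` with condition `not_good` and take no part in the
#' quantitative stages.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame of fragment records.
#' @export
load_fragments <- function(path = osteohist_fixture("fragments")) {
  fr <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "length_mm", "bone_type", "condition", "structure")
  missing_cols <- setdiff(needed, names(fr))
  if (length(missing_cols) > 0) {
    abort_stage("load_fragments",
                paste0("schema mismatch, missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  bad <- !fr$condition %in% c("good", "not_good")
  if (any(bad)) {
    abort_stage("load_fragments",
                paste0("invalid condition for: ",
                       paste(fr$specimen_id[bad], collapse = ", ")))
  }
  bad <- !fr$structure %in% c("osteon", "osteon_uncertain", "plexiform")
  if (any(bad)) {
    abort_stage("load_fragments",
                paste0("invalid structure for: ",
                       paste(fr$specimen_id[bad], collapse = ", ")))
  }
  fr
}

#' Count fragments by observed structure and condition
#'
#' @param fragments Data frame from [load_fragments()].
#' @param structure One of `"osteon"`, `"osteon_uncertain"`, `"plexiform"`.
#' @param condition `"good"`, `"not_good"` or `"any"` (default `"any"`).
#' @return Integer count.
#' @examples
#' fr <- load_fragments()
#' count_fragments_by_structure(fr, "osteon", "good")    # 3
#' count_fragments_by_structure(fr, "plexiform", "good") # 1
#' @export
count_fragments_by_structure <- function(fragments, structure,
                                         condition = "any") {
  if (is.null(fragments) || nrow(fragments) == 0) return(0L)
  keep <- fragments$structure == structure
  if (condition != "any") keep <- keep & fragments$condition == condition
  sum(keep)
}

#' Load the fragment summary statistics
#'
#' Per-fragment osteon counts, means and SDs of On.Ar and H.Ar as measured
#' on the CT slices (lower-bound scale, i.e. assuming no burning
#' shrinkage). These are the inputs to [apply_shrinkage_bounds()].
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return List of `specimen_summary` objects (see [summarize_specimen()]),
#'   one per fragment.
#' @export
load_fragment_summaries <- function(path = osteohist_fixture("fukui_summaries")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "n_on", "mean_onar", "sd_onar", "mean_har", "sd_har")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_stage("load_fragment_summaries",
                paste0("schema mismatch, missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    specimen_summary(
      specimen_id = row$specimen_id, n_on = row$n_on,
      mean_onar = row$mean_onar, sd_onar = row$sd_onar,
      mean_har = row$mean_har, sd_har = row$sd_har
    )
  })
}
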