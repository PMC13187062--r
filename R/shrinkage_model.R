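#' Burning-shrinkage model
#'
#' Interval model for the effect of burning temperature on osteon and
#' Haversian-canal cross-sectional areas in gray (calcined) bone, which is
#' produced at burning temperatures of roughly 500-700 degrees C:
#' \itemize{
#'   \item at 500-600 degrees C areas do not shrink, so measured values
#'     equal original values (`lower_factor = 1`);
#'   \item at ~700 degrees C areas shrink to 75\% of their original size,
#'     so original values are recovered as measured / 0.75
#'     (`upper_factor = 0.75`).
#' }
#' The operational factor 0.75 is a rounding of experimentally observed
#' post/pre area ratios (osteons 76.6\%, canals 76.4\%), which are stored
#' as provenance metadata in `$reference_ratios`. Temperatures above
#' 700 degrees C are outside the model's quantitative range: histological
#' structure becomes indistinct in bone fired hotter.
#'
#' @param lower_factor Area scale factor at the low end of the temperature
#'   range (default 1: no shrinkage).
#' @param upper_factor Area scale factor at the high end (default 0.75).
#' @param temp_range_c Temperature range in degrees C (default c(500, 700)).
#' @return Object of class `shrinkage_model`.
#' @examples
#' m <- shrinkage_model()
#' m$upper_factor
#' @export
shrinkage_model <- function(lower_factor = 1, upper_factor = 0.75,
                            temp_range_c = c(500, 700)) {
  if (!is_scalar_number(upper_factor) || upper_factor <= 0) {
    abort_stage("shrinkage_model", "upper_factor must be > 0")
  }
  if (!is_scalar_number(lower_factor) ||
      upper_factor > lower_factor || lower_factor > 1) {
    abort_stage("shrinkage_model",
                "factors must satisfy 0 < upper_factor <= lower_factor <= 1")
  }
  if (max(temp_range_c) > 700) {
    abort_stage("shrinkage_model",
                "temperatures above 700 C are outside the quantitative range of the model")
  }
  structure(
    list(lower_factor = lower_factor,
         upper_factor = upper_factor,
         temp_range_c = temp_range_c,
         reference_ratios = list(
           osteon = list(ratio = 0.766, pre_um2 = 28089.85, post_um2 = 21504.71),
           canal = list(ratio = 0.764, pre_um2 = 2172.26, post_um2 = 1659.02)
         )),
    class = "shrinkage_model"
  )
}

#' Read or write a shrinkage model as a JSON config
#'
#' @param path JSON file with fields `lower_factor`, `upper_factor`,
#'   `temp_range_c`.
#' @return For `read_shrinkage_model()`, a `shrinkage_model`.
#' @rdname shrinkage_model_io
#' @export
read_shrinkage_model <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  shrinkage_model(lower_factor = cfg$lower_factor,
                  upper_factor = cfg$upper_factor,
                  temp_range_c = cfg$temp_range_c)
}

#' @param model A `shrinkage_model`.
#' @rdname shrinkage_model_io
#' @export
write_shrinkage_model <- function(model, path) {
  jsonlite::write_json(
    list(lower_factor = model$lower_factor,
         upper_factor = model$upper_factor,
         temp_range_c = model$temp_range_c),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Map burned-bone colour to a burning-temperature range
#'
#' Bone colour changes with burning temperature: brown at low temperatures,
#' then black, then bluish/gray, finally white (calcined). Gray bone maps
#' to the quantitative range 500-700 degrees C used by the shrinkage model;
#' the other colours return coarse qualitative ranges flagged as such.
#'
#' @param color One of `"brown"`, `"black"`, `"gray"`, `"white"`.
#' @return List with `range_c` (length-2 numeric, degrees C), `coarse`
#'   (logical: TRUE when the range is qualitative only) and `calcined`
#'   (logical: TRUE for colours implying exposure above ~550 degrees C).
#' @examples
#' color_to_temperature("gray")$range_c # c(500, 700)
#' @export
color_to_temperature <- function(color) {
  table <- list(
    # qualitative low-temperature ranges; exact bounds vary with oxygen
    # availability, duration and cortical thickness
    brown = list(range_c = c(100, 400), coarse = TRUE, calcined = FALSE),
    black = list(range_c = c(300, 600), coarse = TRUE, calcined = FALSE),
    gray  = list(range_c = c(500, 700), coarse = FALSE, calcined = TRUE),
    white = list(range_c = c(550, 900), coarse = TRUE, calcined = TRUE)
  )
  if (length(color) != 1 || !color %in% names(table)) {
    abort_stage("color_to_temperature",
                paste0("unknown bone colour: '", paste(color, collapse = ","),
                       "' (expected brown, black, gray or white)"))
  }
  table[[color]]
}

#' Propagate burning shrinkage as interval bounds on a specimen summary
#'
#' The lower bound is the summary unchanged (no shrinkage at 500-600
#' degrees C); the upper bound divides every mean and SD by the model's
#' `upper_factor` (areas scale linearly under the shrinkage model, so the
#' SD scales by the same factor). The operation is homogeneous of order 1:
#' scaling the input means by c scales both bounds by c.
#'
#' @param summary A `specimen_summary`.
#' @param model A `shrinkage_model` (default [shrinkage_model()]).
#' @return Object of class `interval_summary`: list with `specimen_id`,
#'   `lower` and `upper` (`specimen_summary` objects).
#' @examples
#' s <- specimen_summary("FK-B-003", 21, 18174.1, 5226.5, 478.7, 186.2)
#' iv <- apply_shrinkage_bounds(s)
#' round_report(iv$upper$mean_onar) # 24232.1
#' @export
apply_shrinkage_bounds <- function(summary, model = shrinkage_model()) {
  if (!inherits(summary, "specimen_summary")) {
    abort_stage("apply_shrinkage_bounds", "summary must be a specimen_summary")
  }
  if (!inherits(model, "shrinkage_model")) {
    abort_stage("apply_shrinkage_bounds", "model must be a shrinkage_model")
  }
  if (summary$mean_onar <= 0 || summary$mean_har <= 0) {
    abort_stage("apply_shrinkage_bounds", "summary means must be positive")
  }
  scale_summary <- function(s, f) {
    specimen_summary(
      specimen_id = s$specimen_id, n_on = s$n_on,
      mean_onar = s$mean_onar / f, sd_onar = s$sd_onar / f,
      mean_har = s$mean_har / f, sd_har = s$sd_har / f
    )
  }
  structure(
    list(specimen_id = summary$specimen_id,
         lower = scale_summary(summary, model$lower_factor),
         upper = scale_summary(summary, model$upper_factor)),
    class = "interval_summary"
  )
}

#' @export
print.interval_summary <- function(x, ...) {
  fmt <- function(s) {
    sprintf("On.Ar %s (+/- %s), H.Ar %s (+/- %s)",
            format(round_report(s$mean_onar)), format(round_report(s$sd_onar)),
            format(round_report(s$mean_har)), format(round_report(s$sd_har)))
  }
  cat(sprintf("Fragment %s shrinkage-bounded summary (um^2)\n", x$specimen_id))
  cat("  lower (500-600 C): ", fmt(x$lower), "\n", sep = "")
  cat("  upper (~700 C)   : ", fmt(x$upper), "\n", sep = "")
  invisible(x)
}

#' Post/pre burning area ratio, as a percentage
#'
#' @param pre_mean Mean area before burning (um^2).
#' @param post_mean Mean area after burning (um^2).
#' @return Percentage post/pre * 100 (unrounded; round at report time).
#' @examples
#' round_report(shrinkage_ratio(28089.85, 21504.71)) # 76.6
#' @export
shrinkage_ratio <- function(pre_mean, post_mean) {
  if (!is_scalar_number(pre_mean) || pre_mean <= 0 ||
      !is_scalar_number(post_mean) || post_mean <= 0) {
    abort_stage("shrinkage_ratio", "means must be positive numbers")
  }
  post_mean / pre_mean * 100
}
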