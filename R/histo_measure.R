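#' Polygon area from traced contour vertices
#'
#' Computes the enclosed area of a simple polygon by the shoelace formula
#' and converts from pixel units to square micrometres with the image
#' calibration. This mirrors polygon-ROI measurement semantics in standard
#' image-analysis software: the contour is a vertex list in pixel
#' coordinates (0-based pixel centres, fractional values allowed) and the
#' area is |shoelace sum| / 2 scaled by the squared pixel pitch.
#'
#' @param vertices Two-column numeric matrix (or data frame) of (x, y)
#'   vertex coordinates in pixel units, in drawing order; at least 3
#'   vertices; must be simple (non-self-intersecting).
#' @param pixel_pitch Isotropic calibration in micrometres per pixel
#'   (default 1, i.e. pixel^2 units).
#' @return Area in square micrometres (positive scalar), independent of
#'   vertex orientation and of which vertex starts the contour.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(sq)              # 1
#' polygon_area(sq, 2.74)        # 7.5076
#' @export
polygon_area <- function(vertices, pixel_pitch = 1) {
  v <- as_vertex_matrix(vertices)
  if (!is_scalar_number(pixel_pitch) || pixel_pitch <= 0) {
    abort_stage("polygon_area", "pixel_pitch must be a positive number")
  }
  validate_simple_polygon(v)
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  a <- abs(sum(x * ys - xs * y)) / 2
  if (a == 0) {
    abort_stage("polygon_area", "degenerate polygon with zero area")
  }
  a * pixel_pitch^2
}

as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2) {
    abort_stage("polygon_area", "vertices must be a two-column numeric matrix")
  }
  if (anyNA(v) || any(!is.finite(v))) {
    abort_stage("polygon_area", "vertices contain missing or non-finite values")
  }
  # drop an explicitly closed repeat of the first vertex
  n <- nrow(v)
  if (n >= 2 && all(v[n, ] == v[1, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3) {
    abort_stage("polygon_area", "a contour needs at least 3 distinct vertices")
  }
  v
}

# Simplicity check: any proper crossing between non-adjacent edges is an
# error naming the first offending edge pair. O(n^2) over edges, vectorized
# per edge; fine for traced contours (tens to hundreds of vertices).
validate_simple_polygon <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    j <- setdiff(seq.int(i + 2, n), if (i == 1) n else integer(0))
    if (length(j) == 0) next
    # orientation of edge-j endpoints about edge i and vice versa
    d1 <- cross2(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                 p1[j, 1] - p1[i, 1], p1[j, 2] - p1[i, 2])
    d2 <- cross2(p2[i, 1] - p1[i, 1], p2[i, 2] - p1[i, 2],
                 p2[j, 1] - p1[i, 1], p2[j, 2] - p1[i, 2])
    d3 <- cross2(p2[j, 1] - p1[j, 1], p2[j, 2] - p1[j, 2],
                 p1[i, 1] - p1[j, 1], p1[i, 2] - p1[j, 2])
    d4 <- cross2(p2[j, 1] - p1[j, 1], p2[j, 2] - p1[j, 2],
                 p2[i, 1] - p1[j, 1], p2[i, 2] - p1[j, 2])
    crossing <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(crossing)) {
      jj <- j[which(crossing)[1]]
      abort_stage("polygon_area",
                  sprintf("self-intersecting contour: edge %d crosses edge %d",
                          i, jj))
    }
  }
  invisible(TRUE)
}

# Even-odd ray-casting point-in-polygon test (points on the boundary count
# as inside, which is the permissive choice for canal-inside-osteon checks).
points_in_polygon <- function(pts, poly) {
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xk <- xj[k]; yk <- yj[k]
    crosses <- ((yi > py) != (yk > py)) &
      (px < (xk - xi) * (py - yi) / (yk - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Measure one osteon from its traced outline and canal contours
#'
#' @param outline Vertex matrix of the osteon outline (pixel units).
#' @param canal Vertex matrix of the Haversian canal outline, geometrically
#'   inside the osteon outline.
#' @param pixel_pitch Micrometres per pixel (isotropic).
#' @param specimen_id,osteon_id Identifiers carried into the result.
#' @return A one-row data frame with columns `specimen_id`, `osteon_id`,
#'   `onar_um2`, `har_um2`. The invariant 0 < H.Ar < On.Ar is enforced;
#'   violations flag a mis-traced contour pair.
#' @examples
#' outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' inner <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
#' measure_osteon(outer, inner, 1, "S1", "os1")
#' @export
measure_osteon <- function(outline, canal, pixel_pitch = 1,
                           specimen_id = NA_character_,
                           osteon_id = NA_character_) {
  onar <- polygon_area(outline, pixel_pitch)
  har <- polygon_area(canal, pixel_pitch)
  if (har >= onar) {
    abort_stage("measure_osteon",
                sprintf("canal area (%.6g) >= osteon area (%.6g) for osteon '%s': mis-traced contour pair",
                        har, onar, osteon_id))
  }
  cv <- as_vertex_matrix(canal)
  ov <- as_vertex_matrix(outline)
  if (!all(points_in_polygon(cv, ov))) {
    abort_stage("measure_osteon",
                sprintf("canal contour not inside osteon outline for osteon '%s'",
                        osteon_id))
  }
  data.frame(specimen_id = specimen_id, osteon_id = osteon_id,
             onar_um2 = onar, har_um2 = har, stringsAsFactors = FALSE)
}

#' Specimen summary constructor
#'
#' @param specimen_id Identifier.
#' @param n_on Number of osteons measured.
#' @param mean_onar,sd_onar,mean_har,sd_har Summary statistics in
#'   square micrometres; SDs may be `NA` when `n_on == 1`.
#' @return Object of class `specimen_summary` with derived standard errors
#'   `se_onar`, `se_har` (SD / sqrt(n)).
#' @export
specimen_summary <- function(specimen_id, n_on, mean_onar, sd_onar,
                             mean_har, sd_har) {
  if (!is_count(n_on) || n_on < 1) {
    abort_stage("specimen_summary", "n_on must be a count >= 1")
  }
  if (n_on == 1 && (!is.na(sd_onar) || !is.na(sd_har))) {
    abort_stage("specimen_summary", "SD requires at least 2 measurements")
  }
  structure(
    list(specimen_id = specimen_id, n_on = as.integer(n_on),
         mean_onar = mean_onar, sd_onar = sd_onar,
         se_onar = if (is.na(sd_onar)) NA_real_ else sd_onar / sqrt(n_on),
         mean_har = mean_har, sd_har = sd_har,
         se_har = if (is.na(sd_har)) NA_real_ else sd_har / sqrt(n_on)),
    class = "specimen_summary"
  )
}

#' @export
print.specimen_summary <- function(x, ...) {
  cat(sprintf("Specimen %s (N.On = %d)\n", x$specimen_id, x$n_on))
  cat(sprintf("  On.Ar: %s +/- %s um^2\n",
              format(round_report(x$mean_onar)),
              if (is.na(x$sd_onar)) "NA" else format(round_report(x$sd_onar))))
  cat(sprintf("  H.Ar : %s +/- %s um^2\n",
              format(round_report(x$mean_har)),
              if (is.na(x$sd_har)) "NA" else format(round_report(x$sd_har))))
  invisible(x)
}

#' Reduce per-osteon measurements to a specimen summary
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of On.Ar and H.Ar over
#' all complete osteons measured for one specimen; SE = SD / sqrt(n). No
#' rounding is applied internally; use [round_report()] at report time.
#'
#' @param measurements Data frame with columns `specimen_id`, `onar_um2`,
#'   `har_um2` (one row per osteon), as produced by [measure_osteon()] /
#'   [measure_contours()]. All rows must belong to one specimen.
#' @return A `specimen_summary`.
#' @examples
#' m <- data.frame(specimen_id = "S", osteon_id = 1:3,
#'                 onar_um2 = c(13000, 13500, 14731.7),
#'                 har_um2 = c(400, 450, 500))
#' summarize_specimen(m)$mean_onar # 13743.9
#' @export
summarize_specimen <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    abort_stage("summarize_specimen", "no measurements supplied")
  }
  ids <- unique(measurements$specimen_id)
  if (length(ids) != 1) {
    abort_stage("summarize_specimen",
                paste0("measurements span multiple specimens: ",
                       paste(ids, collapse = ", ")))
  }
  n <- nrow(measurements)
  specimen_summary(
    specimen_id = ids,
    n_on = n,
    mean_onar = mean(measurements$onar_um2),
    sd_onar = if (n >= 2) stats::sd(measurements$onar_um2) else NA_real_,
    mean_har = mean(measurements$har_um2),
    sd_har = if (n >= 2) stats::sd(measurements$har_um2) else NA_real_
  )
}

#' Convert a reported dispersion to a standard deviation
#'
#' The reference table reports SE for most specimens and SD for a few
#' literature rows; the Games-Howell computation needs SDs. `kind = "SD"`
#' is the identity; `kind = "SE"` multiplies by sqrt(n).
#'
#' @param mean Reported mean (unused in the conversion; kept so calls read
#'   like the table rows they convert).
#' @param dispersion Reported dispersion value.
#' @param kind `"SE"` or `"SD"`.
#' @param n Number of measurements behind the dispersion; must be >= 2.
#' @return SD in the units of `dispersion`.
#' @examples
#' dispersion_to_sd(224893.3, 27974.9, "SE", 18) # 27974.9 * sqrt(18)
#' @export
dispersion_to_sd <- function(mean, dispersion, kind, n) {
  if (!kind %in% c("SE", "SD")) {
    abort_stage("dispersion_to_sd", paste0("unknown dispersion kind: ", kind))
  }
  if (is.na(n) || !is_count(n) || n < 2) {
    abort_stage("dispersion_to_sd", "n must be a count >= 2")
  }
  if (kind == "SD") dispersion else dispersion * sqrt(n)
}
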