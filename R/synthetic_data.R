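#' Configuration for a synthetic per-osteon area population
#'
#' Describes a population of paired (On.Ar, H.Ar) measurements with target
#' mean/SD per metric. The default distribution is a normal truncated at
#' zero — areas are positive, and for canal-area populations whose SD is a
#' large fraction of the mean the truncation visibly reshapes the
#' distribution, so the parent parameters are moment-matched numerically
#' to hit the targets on the truncated scale. A lognormal alternative is
#' offered (moment-matched in closed form). Pairs are coupled through a
#' Gaussian copula with correlation `correlation`, and every canal draw is
#' constrained below its paired osteon draw.
#'
#' @param specimen_id Identifier carried into the measurements.
#' @param n_on Number of osteons to draw.
#' @param target_mean_onar,target_sd_onar Targets for On.Ar (um^2).
#' @param target_mean_har,target_sd_har Targets for H.Ar (um^2).
#' @param correlation On.Ar-H.Ar copula correlation in [0, 1); default 0.3,
#'   a plausible positive coupling (not an empirical estimate).
#' @param distribution `"truncated_normal"` (default) or `"lognormal"`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `population_config`.
#' @export
population_config <- function(specimen_id, n_on,
                              target_mean_onar, target_sd_onar,
                              target_mean_har, target_sd_har,
                              correlation = 0.3,
                              distribution = c("truncated_normal", "lognormal"),
                              seed = 1L) {
  distribution <- match.arg(distribution)
  if (!is_count(n_on) || n_on < 1) {
    abort_stage("population_config", "n_on must be a count >= 1")
  }
  targets <- c(target_mean_onar, target_sd_onar, target_mean_har, target_sd_har)
  if (anyNA(targets) || any(targets <= 0)) {
    abort_stage("population_config", "targets must be positive")
  }
  if (target_mean_har >= target_mean_onar) {
    abort_stage("population_config",
                "infeasible targets: mean H.Ar must be below mean On.Ar")
  }
  if (correlation < 0 || correlation >= 1) {
    abort_stage("population_config", "correlation must be in [0, 1)")
  }
  structure(
    list(specimen_id = specimen_id, n_on = as.integer(n_on),
         target_mean_onar = target_mean_onar, target_sd_onar = target_sd_onar,
         target_mean_har = target_mean_har, target_sd_har = target_sd_har,
         correlation = correlation, distribution = distribution,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

# Mean and SD of a normal(mu, sigma) truncated to (0, Inf).
truncnorm_moments <- function(mu, sigma) {
  alpha <- -mu / sigma
  z <- stats::pnorm(alpha, lower.tail = FALSE)
  lambda <- stats::dnorm(alpha) / z
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Numerically find parent (mu, sigma) whose zero-truncated moments match
# the requested (mean, sd). Relative-error objective; the parent values
# are an excellent start because truncation is mild unless sd ~ mean.
match_truncnorm_moments <- function(mean, sd) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]))
    (mo["mean"] / mean - 1)^2 + (mo["sd"] / sd - 1)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8) {
    abort_stage("generate_population",
                sprintf("truncated-normal moment matching failed (mean %.4g, sd %.4g)",
                        mean, sd))
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse CDF of the zero-truncated normal, for copula coupling.
qtruncnorm0 <- function(u, mu, sigma) {
  p0 <- stats::pnorm(0, mu, sigma)
  stats::qnorm(p0 + u * (1 - p0), mu, sigma)
}

#' Generate a synthetic per-osteon area population
#'
#' Draws `n_on` paired (On.Ar, H.Ar) measurements whose empirical mean and
#' SD converge to the configured targets as n grows. Deterministic given
#' the config seed; every H.Ar draw is below its paired On.Ar draw
#' (violating pairs are redrawn).
#'
#' @param cfg A `population_config`.
#' @return Data frame with columns `specimen_id`, `osteon_id`, `onar_um2`,
#'   `har_um2`, suitable for [summarize_specimen()]. The config seed is
#'   recorded in the `seed` attribute.
#' @examples
#' cfg <- population_config("SYN", 500, 18174.1, 5226.5, 478.7, 186.2,
#'                          seed = 7)
#' m <- generate_population(cfg)
#' summarize_specimen(m)
#' @export
generate_population <- function(cfg) {
  if (!inherits(cfg, "population_config")) {
    abort_stage("generate_population", "cfg must be a population_config")
  }
  qfun <- function(metric) {
    m <- cfg[[paste0("target_mean_", metric)]]
    s <- cfg[[paste0("target_sd_", metric)]]
    if (cfg$distribution == "truncated_normal") {
      par <- match_truncnorm_moments(m, s)
      function(u) qtruncnorm0(u, par["mu"], par["sigma"])
    } else {
      sigma2 <- log(1 + (s / m)^2)
      mu <- log(m) - sigma2 / 2
      function(u) stats::qlnorm(u, mu, sqrt(sigma2))
    }
  }
  q_on <- qfun("onar")
  q_ha <- qfun("har")
  rho <- cfg$correlation

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  draw <- function(n) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(onar_um2 = q_on(stats::pnorm(z1)),
               har_um2 = q_ha(stats::pnorm(z2)))
  }
  out <- draw(cfg$n_on)
  for (it in seq_len(1000)) {
    bad <- which(out$har_um2 >= out$onar_um2)
    if (length(bad) == 0) break
    out[bad, ] <- draw(length(bad))
  }
  if (any(out$har_um2 >= out$onar_um2)) {
    abort_stage("generate_population",
                "could not satisfy H.Ar < On.Ar after bounded redraws; targets too close")
  }
  out <- data.frame(specimen_id = cfg$specimen_id,
                    osteon_id = sprintf("os%04d", seq_len(cfg$n_on)),
                    onar_um2 = out$onar_um2, har_um2 = out$har_um2,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- cfg$seed
  out
}

#' Configuration for a synthetic annular-osteon slice image
#'
#' Describes a CT-like grayscale slice: circular osteons (brighter annuli)
#' with darker central lumens (Haversian canals) on a mid-gray matrix,
#' with optional additive Gaussian noise. Osteon and canal radii derive
#' from the target areas (r = sqrt(A / pi), in micrometres, converted to
#' pixels by the pitch). Circles keep the ground truth analytic; real
#' osteons are irregular, but circularity is irrelevant to an area-based
#' pipeline.
#'
#' @param image_size Image side length in pixels (square image).
#' @param pixel_pitch Micrometres per pixel (default 2.74).
#' @param osteon_count Number of osteons to place (non-overlapping disks,
#'   rejection-sampled; total osteon area must stay below 40\% of the
#'   frame).
#' @param target_onar,target_har Per-osteon target areas in um^2.
#' @param noise_sd Additive Gaussian noise SD in gray levels on the [0, 1]
#'   scale (default 0.02).
#' @param contour_vertices Vertices per ground-truth circle polygon
#'   (default 256; at >= 128 the polygon area is within 0.05\% of pi r^2).
#' @param seed Integer seed.
#' @return Object of class `slice_config`.
#' @export
slice_config <- function(image_size = 512, pixel_pitch = 2.74,
                         osteon_count = 10,
                         target_onar = 18000, target_har = 500,
                         noise_sd = 0.02, contour_vertices = 256,
                         seed = 1L) {
  if (!is_count(osteon_count)) {
    abort_stage("slice_config", "osteon_count must be a count >= 0")
  }
  if (target_har >= target_onar) {
    abort_stage("slice_config", "target H.Ar must be below target On.Ar")
  }
  r_ost_px <- sqrt(target_onar / pi) / pixel_pitch
  packing <- osteon_count * pi * r_ost_px^2 / image_size^2
  if (packing > 0.4) {
    abort_stage("slice_config",
                sprintf("infeasible packing: osteons would cover %.0f%% of the frame (limit 40%%); reduce osteon_count or target_onar",
                        100 * packing))
  }
  if (contour_vertices < 128) {
    abort_stage("slice_config", "contour_vertices must be >= 128")
  }
  structure(
    list(image_size = as.integer(image_size), pixel_pitch = pixel_pitch,
         osteon_count = as.integer(osteon_count),
         target_onar = target_onar, target_har = target_har,
         noise_sd = noise_sd, contour_vertices = as.integer(contour_vertices),
         seed = as.integer(seed)),
    class = "slice_config"
  )
}

circle_polygon <- function(cx, cy, r, n_vertices) {
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate a synthetic slice image with ground-truth contours
#'
#' Renders non-overlapping annular osteons (bright annulus, dark lumen) on
#' a mid-gray matrix and returns both the image and ground-truth contour
#' polygons in the same schema consumed by [measure_contours()]. The
#' ground-truth polygon areas match the analytic circle areas to within
#' the polygonization error (< 0.05\% at 256 vertices).
#'
#' @param cfg A `slice_config`.
#' @return Object of class `synthetic_slice`: list with `image` (numeric
#'   matrix in [0, 1], rows = y), `contours` (a `contour_set`), and
#'   `ground_truth` (data frame of analytic `onar_um2`, `har_um2` and
#'   centre coordinates per osteon). Deterministic given the config seed.
#' @seealso [write_slice_tiff()], [write_contours_json()]
#' @export
generate_slice <- function(cfg) {
  if (!inherits(cfg, "slice_config")) {
    abort_stage("generate_slice", "cfg must be a slice_config")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  r_ost <- sqrt(cfg$target_onar / pi) / cfg$pixel_pitch # px
  r_can <- sqrt(cfg$target_har / pi) / cfg$pixel_pitch  # px
  margin <- r_ost + 2
  if (cfg$osteon_count > 0 && 2 * margin >= cfg$image_size) {
    abort_stage("generate_slice", "osteon radius too large for the frame")
  }

  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < cfg$osteon_count) {
    tries <- tries + 1
    if (tries > 5000) {
      abort_stage("generate_slice",
                  "packing failed after 5000 attempts; reduce osteon_count")
    }
    cand <- stats::runif(2, margin, cfg$image_size - margin)
    ok <- nrow(centers) == 0 ||
      all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
            2 * r_ost + 2)
    if (ok) centers <- rbind(centers, cand)
  }

  # pixel (i = row = y + 1, j = col = x + 1), centres at 0-based coords
  img <- matrix(0.5, cfg$image_size, cfg$image_size)
  xs <- matrix(rep(0:(cfg$image_size - 1), each = cfg$image_size),
               cfg$image_size)
  ys <- matrix(rep(0:(cfg$image_size - 1), times = cfg$image_size),
               cfg$image_size)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    img[d2 <= r_ost^2] <- 0.8
    img[d2 <= r_can^2] <- 0.2
  }
  if (cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                        nrow(img))
    img <- pmin(pmax(img, 0), 1)
  }

  osteons <- lapply(seq_len(nrow(centers)), function(i) {
    list(id = sprintf("os%03d", i),
         outline = circle_polygon(centers[i, 1], centers[i, 2], r_ost,
                                  cfg$contour_vertices),
         canal = circle_polygon(centers[i, 1], centers[i, 2], r_can,
                                cfg$contour_vertices))
  })
  contours <- structure(
    list(specimen_id = sprintf("synthetic-seed%d", cfg$seed),
         calibration_um_per_px = cfg$pixel_pitch,
         osteons = osteons),
    class = "contour_set"
  )
  ground_truth <- data.frame(
    osteon_id = vapply(osteons, `[[`, character(1), "id"),
    center_x_px = if (nrow(centers)) centers[, 1] else numeric(0),
    center_y_px = if (nrow(centers)) centers[, 2] else numeric(0),
    onar_um2 = rep(pi * (r_ost * cfg$pixel_pitch)^2, nrow(centers)),
    har_um2 = rep(pi * (r_can * cfg$pixel_pitch)^2, nrow(centers)),
    stringsAsFactors = FALSE
  )
  structure(
    list(image = img, contours = contours, ground_truth = ground_truth,
         config = cfg),
    class = "synthetic_slice"
  )
}

#' Write a synthetic slice image as grayscale TIFF
#'
#' @param slice A `synthetic_slice` from [generate_slice()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slice_tiff <- function(slice, path) {
  tiff::writeTIFF(slice$image, path, bits.per.sample = 16)
  invisible(path)
}

#' Generate group summaries under a shared null distribution
#'
#' Draws `k` groups of `n` values from one normal distribution and reduces
#' each to a [group_summary()]. Used to calibrate the type-I error of the
#' Games-Howell test: under this null, rejections at level alpha should
#' occur at rate alpha.
#'
#' @param k Number of groups (>= 2).
#' @param mean,sd Shared normal parameters.
#' @param n Per-group sample size (>= 2).
#' @param seed Optional integer seed (set it for reproducibility across
#'   calls; leave `NULL` inside a loop that manages its own seed).
#' @return List of `k` `group_summary` objects.
#' @export
generate_null_groups <- function(k, mean, sd, n, seed = NULL) {
  if (!is_count(k) || k < 2) {
    abort_stage("generate_null_groups", "k must be a count >= 2")
  }
  if (!is_count(n) || n < 2) {
    abort_stage("generate_null_groups", "n must be a count >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(k), function(i) {
    x <- stats::rnorm(n, mean, sd)
    group_summary(paste0("g", i), base::mean(x), stats::sd(x), n)
  })
}
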