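#' Default aging law for synthetic worms
#'
#' Parameters tying a synthetic worm's appearance to its age. Width grows
#' linearly with age (aging worms thicken), curvature amplitude shrinks
#' (aging worms straighten and move less), and bright speckle density
#' inside the body rises (a stand-in for age-correlated gut
#' autofluorescence, with no biochemical claim attached). The worm is
#' darker than the background, as required by the inverted-threshold
#' segmentation rule.
#'
#' @param w0 Body width (px) at age 0.
#' @param k Width growth per day (px/day, > 0).
#' @param width_sd Gaussian jitter of the width (px).
#' @param length0,length_sd Body length mean and jitter (px).
#' @param curvature0 Curvature amplitude (px) at age 0.
#' @param curvature_decay Amplitude loss per day (px/day).
#' @param curvature_min Floor for the amplitude (px).
#' @param speckle0,speckle_k Speckle density intercept and slope per day.
#' @param noise_sigma Gaussian background noise sd (grey levels).
#' @param body_intensity,background_intensity 8-bit body and background
#'   grey levels; body must be darker.
#' @param accel Aging acceleration factor: phenotypes are evaluated at
#'   `accel * age_days`. Use > 1 to emulate stressed, prematurely aging
#'   cohorts (e.g. glycation stress).
#' @return An `aging_law` parameter list.
#' @export
aging_law <- function(w0 = 6, k = 0.5, width_sd = 0.3,
                      length0 = 120, length_sd = 8,
                      curvature0 = 14, curvature_decay = 0.5,
                      curvature_min = 2,
                      speckle0 = 0.02, speckle_k = 0.012,
                      noise_sigma = 8,
                      body_intensity = 60L, background_intensity = 200L,
                      accel = 1) {
  if (k <= 0) stop("width growth rate k must be > 0")
  if (body_intensity >= background_intensity)
    stop("worm must be darker than the background")
  structure(list(w0 = w0, k = k, width_sd = width_sd, length0 = length0,
                 length_sd = length_sd, curvature0 = curvature0,
                 curvature_decay = curvature_decay,
                 curvature_min = curvature_min, speckle0 = speckle0,
                 speckle_k = speckle_k, noise_sigma = noise_sigma,
                 body_intensity = as.integer(body_intensity),
                 background_intensity = as.integer(background_intensity),
                 accel = accel),
            class = "aging_law")
}

#' Sample a synthetic worm phenotype
#'
#' Draws a worm appearance at a given chronological age under an aging
#' law. Deterministic given `(age_days, params, seed)`.
#'
#' @param age_days Chronological age (days, >= 0).
#' @param params An [aging_law()].
#' @param seed Integer seed.
#' @return A `worm_phenotype` list.
#' @export
sample_phenotype <- function(age_days, params = aging_law(), seed = 1L) {
  if (age_days < 0) stop("age_days must be >= 0")
  a <- params$accel * age_days
  with_seed(seed, {
    width <- params$w0 + params$k * a +
      if (params$width_sd > 0) rnorm(1, 0, params$width_sd) else 0
    len <- params$length0 +
      if (params$length_sd > 0) rnorm(1, 0, params$length_sd) else 0
    structure(list(
      age_days = age_days,
      body_length_px = max(20L, as.integer(round(len))),
      body_width_px = max(2, width),
      curvature_amplitude = max(params$curvature_min,
                                params$curvature0 - params$curvature_decay * a),
      speckle_density = min(1, max(0, params$speckle0 + params$speckle_k * a)),
      noise_sigma = params$noise_sigma,
      body_intensity = params$body_intensity,
      background_intensity = params$background_intensity
    ), class = "worm_phenotype")
  })
}

#' Render a synthetic well image from a phenotype
#'
#' Draws a single worm as a dark tube along a smooth parametric curve (a
#' straight axis plus two low-frequency sinusoidal offsets scaled by the
#' curvature amplitude) on a brighter noisy background, with bright
#' speckles inside the body. Also returns the exact tube-support mask and
#' the ordered ground-truth centerline.
#'
#' @param phenotype A [sample_phenotype()] result.
#' @param canvas_shape `(rows, cols)` of the well image, default 256x256.
#' @param seed Integer seed (noise, speckles, sinusoid phases).
#' @param orientation Body-axis angle in radians; 0 (default) renders an
#'   axis-aligned worm.
#' @return A `synthetic_sample`: list with `image` (8-bit matrix), `mask`
#'   (0/255), `centerline` (ordered x,y matrix) and `phenotype`.
#' @export
render_worm <- function(phenotype, canvas_shape = c(256L, 256L), seed = 1L,
                        orientation = 0) {
  H <- canvas_shape[1]; W <- canvas_shape[2]
  L <- phenotype$body_length_px
  radius <- phenotype$body_width_px / 2
  with_seed(seed, {
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    tt <- seq(0, 1, length.out = max(2L, 2L * L))
    s <- (tt - 0.5) * L
    amp <- phenotype$curvature_amplitude
    d <- amp * sin(2 * pi * tt + ph1) + 0.4 * amp * sin(4 * pi * tt + ph2)
    ux <- cos(orientation); uy <- sin(orientation)
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    xs <- cx + s * ux - d * uy
    ys <- cy + s * uy + d * ux
    margin <- radius + 2
    if (any(xs < margin | xs > W - 1 - margin |
            ys < margin | ys > H - 1 - margin))
      stop(sprintf(paste("worm (length %d px, width %.1f px) exceeds the",
                         "%dx%d canvas; enlarge the canvas or shorten the",
                         "worm"), L, 2 * radius, H, W))
    mask <- cpp_stamp_tube(H, W, xs, ys, radius)
    img <- matrix(ifelse(mask == 1L, phenotype$body_intensity,
                         phenotype$background_intensity), H, W)
    if (phenotype$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, phenotype$noise_sigma), H, W)
    body_idx <- which(mask == 1L)
    if (phenotype$speckle_density > 0 && length(body_idx) > 0) {
      nspk <- round(phenotype$speckle_density * length(body_idx))
      if (nspk > 0) {
        spk <- sample(body_idx, nspk)
        img[spk] <- pmin(255, phenotype$body_intensity + 120)
      }
    }
    cl <- cbind(x = round(xs), y = round(ys))
    cl <- cl[c(TRUE, rowSums(abs(diff(cl))) > 0), , drop = FALSE]
    structure(list(image = as_u8(img), mask = mask255(mask),
                   centerline = cl, phenotype = phenotype),
              class = "synthetic_sample")
  })
}

#' Gompertz-like lifespan sampler
#'
#' Draws integer death days from a discretized Gompertz distribution,
#' the standard shape for C. elegans lifespan data. Defaults give a
#' median lifespan near 10 days with a tail to roughly 20 days.
#'
#' @param n Number of worms.
#' @param shape Gompertz shape (per day).
#' @param rate Gompertz baseline hazard (per day).
#' @return Integer vector of death days (>= 1).
#' @export
rlifespan_gompertz <- function(n, shape = 0.3, rate = 0.012) {
  u <- runif(n)
  t <- (1 / shape) * log(1 - (shape / rate) * log(u))
  pmax(1L, as.integer(ceiling(t)))
}

#' Generate a synthetic imaging cohort
#'
#' Simulates a plate of single-worm wells followed daily until death:
#' each worm receives a lifespan from `lifespan_sampler`, is imaged on
#' every day of `imaging_days` on which it is still alive (its death day
#' included, later days excluded), and contributes one manifest row per
#' image. Images are rendered lazily via [cohort_sample()] unless
#' `render = TRUE`.
#'
#' @param n_worms Number of worms (>= 1).
#' @param lifespan_sampler Function `n -> integer death days`; default
#'   [rlifespan_gompertz()].
#' @param imaging_days Days on which imaging happens; default every day.
#' @param seed Integer master seed; all randomness derives from it.
#' @param canvas_shape Well-image shape, default 256x256.
#' @param aging An [aging_law()]; use `accel > 1` for stressed cohorts.
#' @param group Cohort label carried into the manifest (e.g. "control",
#'   "GS").
#' @param render If `TRUE`, renders and stores every sample up front.
#' @return A `worm_cohort`: list with `manifest` (data.frame: worm_id,
#'   well_id, day, age_days, death_day, group, sample_seed), `survival`
#'   (worm_id, death_day, censored), `aging`, `canvas_shape`, `seed`, and
#'   optionally `samples`.
#' @export
generate_cohort <- function(n_worms, lifespan_sampler = rlifespan_gompertz,
                            imaging_days = NULL, seed = 1L,
                            canvas_shape = c(256L, 256L),
                            aging = aging_law(), group = "control",
                            render = FALSE) {
  if (n_worms < 1L) stop("n_worms must be >= 1")
  if (!is.null(imaging_days) && length(imaging_days) == 0L)
    stop("imaging_days must be non-empty (or NULL for daily imaging)")
  deaths <- with_seed(seed, as.integer(lifespan_sampler(n_worms)))
  if (any(deaths < 1L)) stop("lifespans must be >= 1 day")
  wells <- paste0(rep(LETTERS[1:16], length.out = n_worms),
                  sprintf("%02d", ((seq_len(n_worms) - 1L) %/% 16L) + 1L))
  rows <- lapply(seq_len(n_worms), function(i) {
    days <- seq_len(deaths[i])
    if (!is.null(imaging_days)) days <- intersect(days, imaging_days)
    if (length(days) == 0L) return(NULL)
    data.frame(worm_id = sprintf("w%04d", i), well_id = wells[i],
               day = as.integer(days), age_days = as.numeric(days),
               death_day = deaths[i], group = group,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest$sample_seed <-
    as.integer((seed + 7919 * seq_len(nrow(manifest))) %% .Machine$integer.max)
  survival <- data.frame(worm_id = sprintf("w%04d", seq_len(n_worms)),
                         death_day = deaths, censored = FALSE,
                         stringsAsFactors = FALSE)
  cohort <- structure(list(manifest = manifest, survival = survival,
                           aging = aging, canvas_shape = canvas_shape,
                           seed = as.integer(seed), samples = NULL),
                      class = "worm_cohort")
  if (render)
    cohort$samples <- lapply(seq_len(nrow(manifest)),
                             function(i) cohort_sample(cohort, i))
  cohort
}

#' Render one cohort sample
#'
#' Materializes the synthetic image, mask and centerline for row `i` of a
#' cohort manifest. Deterministic: repeated calls return identical
#' samples.
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Manifest row index.
#' @return A `synthetic_sample`.
#' @export
cohort_sample <- function(cohort, i) {
  if (!is.null(cohort$samples)) return(cohort$samples[[i]])
  row <- cohort$manifest[i, ]
  phen <- sample_phenotype(row$age_days, cohort$aging, seed = row$sample_seed)
  ang <- with_seed(row$sample_seed + 1L, runif(1, 0, pi))
  render_worm(phen, cohort$canvas_shape, seed = row$sample_seed + 2L,
              orientation = ang)
}

#' @export
print.worm_cohort <- function(x, ...) {
  cat(sprintf("synthetic worm cohort: %d worms, %d images, group(s): %s\n",
              nrow(x$survival), nrow(x$manifest),
              paste(unique(x$manifest$group), collapse = ", ")))
  cat(sprintf("  canvas %dx%d, median lifespan %.0f d, seed %d\n",
              x$canvas_shape[1], x$canvas_shape[2],
              median(x$survival$death_day), x$seed))
  invisible(x)
}
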