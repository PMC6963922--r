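#' Candidate absorption-feature wavelengths
#'
#' The 22 NIR wavelengths (nm) at which the three origin classes carry
#' their distinguishing absorption structure; used as the default feature
#' centers of the synthetic origin signatures and as the reference list for
#' fixed-wavelength subsetting.
#'
#' @return numeric vector of 22 wavelengths in nm.
#' @export
candidate_feature_wavelengths <- function() {
  c(995, 1022, 1032, 1042, 1056, 1072, 1089, 1136, 1190, 1244, 1274,
    1284, 1315, 1352, 1365, 1375, 1402, 1433, 1456, 1487, 1500, 1632)
}

origin_names <- function() c("Gansu", "Ningxia", "Xinjiang")

# Pick k class-distinguishing centers: only centers isolated from every
# other absorption feature (>= isolation nm) are candidates, and kept
# centers are mutually spaced (>= min_spacing nm), so the planted class
# contrasts stay localizable after derivative smoothing.
pick_spaced <- function(centers, k, min_spacing, isolation = 30,
                        range_nm = c(1000, 1620)) {
  nn <- vapply(seq_along(centers), function(i)
    min(abs(centers[-i] - centers[i])), numeric(1))
  pool <- centers[nn >= isolation &
                    centers >= range_nm[1] & centers <= range_nm[2]]
  perm <- sample(pool)
  kept <- numeric(0)
  for (c0 in perm) {
    if (!length(kept) || all(abs(kept - c0) >= min_spacing)) kept <- c(kept, c0)
    if (length(kept) == k) break
  }
  sort(kept)
}

#' Synthetic origin reflectance signature
#'
#' Builds the mean reflectance curve of one geographical origin over the
#' 256-band axis: a smooth shared baseline (seeded, common to all origins
#' for the same `seed`) minus Gaussian absorption dips at the candidate
#' feature wavelengths. A seeded subset of well-separated centers carries
#' origin-specific depth modulation, so the three classes are distinct but
#' share most of their structure (distinct yet overlapping class means).
#'
#' @param origin_id 0 (Gansu), 1 (Ningxia) or 2 (Xinjiang).
#' @param seed integer; same seed implies the same shared baseline, base
#'   depths and variable-center subset across origins.
#' @param wavelength wavelength axis in nm.
#' @param feature_centers,feature_depths,feature_widths optional explicit
#'   absorption features (nm / reflectance units / nm sigma); defaults are
#'   seeded draws around the candidate wavelength list.
#' @param n_variable how many centers carry origin-specific depth
#'   modulation (default 8, capped by the number of identifiable centers).
#' @param variable_modulation relative depth-modulation amplitude at the
#'   variable centers (default 0.35): each such center modulates the three
#'   origins by a seeded permutation of `(-a, 0, +a)`, so every planted
#'   contrast is material and the three curves are pairwise distinct.
#' @return an `origin_signature`: list with `origin_id`, `wavelength`,
#'   `reflectance`, `baseline`, `feature_centers`, `feature_depths`,
#'   `feature_widths`, `variable_centers`.
#' @export
make_signature <- function(origin_id, seed,
                           wavelength = default_wavelengths(),
                           feature_centers = NULL,
                           feature_depths = NULL,
                           feature_widths = NULL,
                           n_variable = 8L,
                           variable_modulation = 0.35) {
  if (!is.numeric(origin_id) || length(origin_id) != 1 ||
      !origin_id %in% 0:2)
    hsi_abort(sprintf("unknown origin_id: %s (must be 0, 1 or 2)",
                      paste(origin_id, collapse = ",")),
              "hsi_invalid_argument")
  origin_id <- as.integer(origin_id)

  shared <- with_seed(derive_seed(seed, 11L), {
    centers <- feature_centers %||% candidate_feature_wavelengths()
    k <- length(centers)
    base_depths <- feature_depths %||% runif(k, 0.03, 0.08)
    widths <- feature_widths %||% runif(k, 9, 14)
    # baseline: typical dried-fruit NIR reflectance shape plus three broad
    # seeded undulations; stays well inside (0.01, 0.99)
    bc <- runif(3, 950, 1650)
    bw <- runif(3, 120, 260)
    ba <- runif(3, -0.03, 0.03)
    baseline <- 0.42 +
      0.16 * exp(-((wavelength - 1120) / 280)^2) +
      0.08 * exp(-((wavelength - 1600) / 320)^2) -
      0.10 * exp(-((wavelength - 1450) / 70)^2)
    for (i in 1:3) baseline <- baseline + ba[i] * exp(-((wavelength - bc[i]) / bw[i])^2)
    var_centers <- pick_spaced(centers, min(n_variable, k), 30)
    # one permutation of (-a, 0, +a) per variable center, shared across
    # origins, so each planted contrast separates the classes; cycling
    # through distinct permutations keeps the three class-mean curves
    # non-collinear (three separable clusters, not classes on a line)
    all_perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
    pool <- sample(all_perms)
    perms <- vapply(seq_along(var_centers), function(i)
      pool[[(i - 1L) %% 6L + 1L]], integer(3))
    list(centers = centers, base_depths = base_depths, widths = widths,
         baseline = baseline, var_centers = var_centers, perms = perms)
  })

  depths <- shared$base_depths
  is_var <- which(shared$centers %in% shared$var_centers)
  lev <- c(-1, 0, 1) * variable_modulation
  for (j in seq_along(is_var)) {
    depths[is_var[j]] <- depths[is_var[j]] *
      (1 + lev[shared$perms[origin_id + 1L, j]])
  }

  refl <- shared$baseline
  for (i in seq_along(shared$centers)) {
    refl <- refl - depths[i] *
      exp(-0.5 * ((wavelength - shared$centers[i]) / shared$widths[i])^2)
  }
  if (any(refl <= 0.01) || any(refl >= 0.99))
    hsi_abort("signature leaves the (0.01, 0.99) reflectance range",
              "hsi_invalid_argument")
  structure(list(origin_id = origin_id, wavelength = wavelength,
                 reflectance = refl, baseline = shared$baseline,
                 feature_centers = shared$centers, feature_depths = depths,
                 feature_widths = shared$widths,
                 variable_centers = shared$var_centers),
            class = "origin_signature")
}

#' Synthetic scene configuration
#'
#' Parameters of the emulated acquisition. Defaults state the synthetic
#' world once: per-pixel additive reflectance noise sd 0.02 (a typical
#' InGaAs line-scan SNR), per-scan-line multiplicative illumination gain
#' sd 0.02, per-fruit relative depth variability 0.10 (biological
#' fruit-to-fruit variation), dark level 120 and white level 3900 digital
#' numbers (stored as float), 320-pixel-wide scenes on a black plate with
#' background reflectance 0.02.
#'
#' @param n_fruits_per_class fruits per origin class in one scene.
#' @param fruit_axis_range ellipse semi-axis range in px.
#' @param scene_width,scene_length_L scene size in px.
#' @param noise_sd_additive per pixel-band additive noise, reflectance units.
#' @param illumination_gain_sd sd of per-scan-line multiplicative gain.
#' @param fruit_effect_sd sd of per-fruit relative absorption-depth jitter.
#' @param dark_level,white_level reference digital numbers.
#' @param background_reflectance reflectance of the black plate.
#' @param min_gap_px minimum gap between fruit bounding radii.
#' @param max_place_tries consecutive rejection-sampling failures allowed
#'   before a capacity error.
#' @param n_fruits_per_scene dataset-level cap on fruits per rendered scene.
#' @param seed integer.
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_fruits_per_class = 20L,
                         fruit_axis_range = c(8, 14),
                         scene_width = 320L,
                         scene_length_L = 320L,
                         noise_sd_additive = 0.02,
                         illumination_gain_sd = 0.02,
                         fruit_effect_sd = 0.10,
                         dark_level = 120,
                         white_level = 3900,
                         background_reflectance = 0.02,
                         min_gap_px = 3,
                         max_place_tries = 400L,
                         n_fruits_per_scene = 60L,
                         seed = 1L) {
  cfg <- list(n_fruits_per_class = as.integer(n_fruits_per_class),
              fruit_axis_range = fruit_axis_range,
              scene_width = as.integer(scene_width),
              scene_length_L = as.integer(scene_length_L),
              noise_sd_additive = noise_sd_additive,
              illumination_gain_sd = illumination_gain_sd,
              fruit_effect_sd = fruit_effect_sd,
              dark_level = dark_level, white_level = white_level,
              background_reflectance = background_reflectance,
              min_gap_px = min_gap_px,
              max_place_tries = as.integer(max_place_tries),
              n_fruits_per_scene = as.integer(n_fruits_per_scene),
              seed = as.integer(seed))
  if (any(cfg$n_fruits_per_class < 0) || cfg$scene_width <= 0 ||
      cfg$scene_length_L <= 0)
    hsi_abort("counts and scene dimensions must be positive",
              "hsi_invalid_argument")
  if (cfg$dark_level >= cfg$white_level)
    hsi_abort("dark_level must be below white_level", "hsi_invalid_argument")
  class(cfg) <- "scene_config"
  cfg
}

# Rejection-sampled non-overlapping ellipse placement. Fruits never touch:
# centers are kept further apart than the sum of the larger semi-axes plus
# the configured gap.
place_fruits <- function(n, cfg) {
  amin <- cfg$fruit_axis_range[1]; amax <- cfg$fruit_axis_range[2]
  cx <- cy <- a <- b <- numeric(0)
  fails <- 0L
  while (length(cx) < n) {
    ai <- runif(1, amin, amax); bi <- runif(1, amin, amax)
    r <- max(ai, bi)
    x <- runif(1, r + 1, cfg$scene_width - r - 1)
    y <- runif(1, r + 1, cfg$scene_length_L - r - 1)
    ok <- !length(cx) ||
      all(sqrt((cx - x)^2 + (cy - y)^2) >
            pmax(a, b) + r + cfg$min_gap_px)
    if (ok) {
      cx <- c(cx, x); cy <- c(cy, y); a <- c(a, ai); b <- c(b, bi)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg$max_place_tries)
        hsi_abort(sprintf(
          "scene capacity exceeded: placed %d of %d fruits in %d x %d px (limit: %d consecutive rejections)",
          length(cx), n, cfg$scene_width, cfg$scene_length_L,
          cfg$max_place_tries), "hsi_capacity_error")
    }
  }
  data.frame(cx = cx, cy = cy, a = a, b = b)
}

#' Render one synthetic scene
#'
#' Draws non-overlapping elliptical fruits on a dark plate, assigns each
#' fruit a per-fruit jittered copy of its origin signature, and inverts
#' the reflectance-correction equation to produce raw digital numbers:
#' `raw = dark + (gain_line * reflectance + noise) * (white - dark)`.
#' With all stochastic terms zero, correcting the raw cube recovers each
#' origin signature exactly at every fruit pixel.
#'
#' @param signatures list of three `origin_signature`s (origins 0,1,2).
#' @param cfg a [scene_config()].
#' @param origins integer vector of per-fruit origins; default
#'   `rep(0:2, each = cfg$n_fruits_per_class)`.
#' @return list with `raw` (hypercube), `dark`, `white` (width x bands
#'   per-line frames), `wavelength`, and `truth` (`label_image`,
#'   `fruit_origins`).
#' @export
render_scene <- function(signatures, cfg, origins = NULL) {
  stopifnot(length(signatures) == 3)
  origins <- origins %||% rep(0:2, each = cfg$n_fruits_per_class)
  origins <- as.integer(origins)
  n <- length(origins)
  wl <- signatures[[1]]$wavelength
  nb <- length(wl)
  W <- cfg$scene_width; L <- cfg$scene_length_L

  with_seed(derive_seed(cfg$seed, 7L), {
    pl <- place_fruits(n, cfg)

    # label image: ids 1..n in placement order
    label <- matrix(0L, W, L)
    xs <- matrix(seq_len(W), W, L)
    ys <- matrix(rep(seq_len(L), each = W), W, L)
    for (i in seq_len(n)) {
      inside <- ((xs - pl$cx[i]) / pl$a[i])^2 + ((ys - pl$cy[i]) / pl$b[i])^2 <= 1
      label[inside] <- i
    }

    # per-fruit signatures: relative depth jitter around the origin curve
    S <- matrix(0, n + 1L, nb)
    S[1L, ] <- cfg$background_reflectance
    for (i in seq_len(n)) {
      sig <- signatures[[origins[i] + 1L]]
      jit <- if (cfg$fruit_effect_sd > 0)
        rnorm(length(sig$feature_depths), 0, cfg$fruit_effect_sd) else 0
      depths <- sig$feature_depths * (1 + jit)
      r <- sig$baseline
      for (k in seq_along(sig$feature_centers))
        r <- r - depths[k] *
          exp(-0.5 * ((wl - sig$feature_centers[k]) / sig$feature_widths[k])^2)
      S[i + 1L, ] <- r
    }

    gain <- if (cfg$illumination_gain_sd > 0)
      rnorm(L, 1, cfg$illumination_gain_sd) else rep(1, L)
    G <- matrix(rep(gain, each = W), W, L)

    dark <- matrix(cfg$dark_level, W, nb)
    white <- matrix(cfg$white_level, W, nb)
    span <- cfg$white_level - cfg$dark_level

    idx <- label + 1L
    raw <- array(0, c(W, L, nb))
    for (b in seq_len(nb)) {
      refl <- matrix(S[idx, b], W, L)
      eps <- if (cfg$noise_sd_additive > 0)
        matrix(rnorm(W * L, 0, cfg$noise_sd_additive), W, L) else 0
      raw[, , b] <- cfg$dark_level + (G * refl + eps) * span
    }

    list(raw = hypercube(raw, wl, kind = "raw"),
         dark = dark, white = white, wavelength = wl,
         truth = list(label_image = label, fruit_origins = origins),
         placements = pl)
  })
}

#' Plan scenes for a dataset
#'
#' Splits requested per-class fruit counts into single-origin scenes of at
#' most `cfg$n_fruits_per_scene` fruits (the acquisition images each hold
#' fruits of one origin). Owns the count bookkeeping that
#' [generate_dataset()] renders.
#'
#' @param n_per_class integer vector of length 3.
#' @param cfg a [scene_config()].
#' @return data.frame with columns `scene`, `origin`, `n_fruits`.
#' @export
plan_scenes <- function(n_per_class, cfg) {
  stopifnot(length(n_per_class) == 3)
  rows <- list()
  s <- 0L
  for (o in 0:2) {
    left <- as.integer(n_per_class[o + 1])
    while (left > 0L) {
      s <- s + 1L
      take <- min(left, cfg$n_fruits_per_scene)
      rows[[s]] <- data.frame(scene = s, origin = o, n_fruits = take)
      left <- left - take
    }
  }
  do.call(rbind, rows)
}

#' Generate a multi-scene synthetic dataset
#'
#' Renders the scenes planned by [plan_scenes()] with per-scene seeds
#' derived from `seed`; a fixed seed gives bit-identical output.
#'
#' @param cfg a [scene_config()]; `cfg$n_fruits_per_class` gives the
#'   per-class totals (scalar or length-3).
#' @param seed integer master seed (defaults to `cfg$seed`).
#' @return list with `scenes` (list of [render_scene()] outputs),
#'   `signatures`, `plan`, `config`.
#' @export
generate_dataset <- function(cfg, seed = cfg$seed) {
  n_per_class <- rep(cfg$n_fruits_per_class, length.out = 3)
  signatures <- lapply(0:2, make_signature, seed = seed)
  plan <- plan_scenes(n_per_class, cfg)
  scenes <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    scfg <- cfg
    scfg$seed <- derive_seed(seed, 1000L + i)
    scenes[[i]] <- render_scene(signatures, scfg,
                                origins = rep(plan$origin[i], plan$n_fruits[i]))
  }
  list(scenes = scenes, signatures = signatures, plan = plan, config = cfg)
}
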