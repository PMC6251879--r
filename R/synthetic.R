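#' Specification for a synthetic microscope field
#'
#' Describes the statistical structure of a simulated field: nuclei placed
#' without overlap on a background gradient, damage-marker foci planted as
#' sharp Gaussian blobs co-localized across the two marker channels, and
#' dimmer, broader background speckles planted independently per channel.
#' Each nucleus is assigned a focal plane; the other four z-planes render its
#' blobs defocused (wider, flatter, integral-preserving).
#'
#' Defaults emulate the acquisition this pipeline targets: 8-bit fields of
#' 1024 x 1360 px holding ~50 fibroblast nuclei, 120 px single-cell crops,
#' background speckles outnumbering true foci roughly 10- to 20-fold, and a
#' mostly non-dividing (G1) population with small S/G2 and dying fractions.
#'
#' @param field_size_px Integer `(rows, cols)` of the field.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius_px Mean and sd of the nucleus radius (px).
#' @param foci_per_cell Expected planted foci per nucleus (Poisson mean).
#' @param focus_amplitude Peak grey-value amplitude of a focus above the
#'   nuclear marker baseline.
#' @param focus_sigma_px Gaussian scale of a focus in the focal plane.
#' @param focus_amplitude_sdlog Log-normal spread of per-focus amplitudes.
#' @param focus_sigma_sdlog Log-normal spread of per-focus widths; widths
#'   vary at roughly constant integrated flux, so broader planted foci are
#'   proportionally dimmer. Zero (the default) renders homogeneous foci;
#'   positive values emulate the size/sharpness heterogeneity of real foci
#'   and are used for rating-benchmark experiments.
#' @param speckle_rate Expected background speckles per nucleus and
#'   channel; both channels together default to 12 planted background
#'   signals per nucleus, 10-20 times the default focus count.
#' @param speckle_amplitude_range,speckle_sigma_range Speckle amplitude and
#'   scale as fractions of the focus values; dimmer and slightly broader
#'   blobs are less compact under the inverse-moment definition and create
#'   the overlapping score tails around the histogram valley.
#' @param smear_rate Expected bright diffuse background smears (antibody
#'   aggregates, debris) per nucleus and channel.
#' @param smear_amplitude_range,smear_sigma_range Smear amplitude and scale
#'   as fractions of the focus values: bright but much broader than foci,
#'   so brightness alone cannot classify them.
#' @param colocalization Fraction of foci rendered in both channels; the rest
#'   appear in one channel only (half red-only, half green-only).
#' @param channel_noise_sd Additive Gaussian read-noise sd per channel (grey
#'   values).
#' @param background_gradient Amplitude of a linear left-to-right background
#'   ramp (grey values).
#' @param zstack_defocus_sigmas Extra blur scales by distance from the focal
#'   plane (index 1 = in focus).
#' @param marker_baseline Mean in-nucleus marker intensity (grey values);
#'   defines the intensity floor objects must exceed.
#' @param texture_sd Amplitude (grey values) of the shared intranuclear
#'   texture (chromatin structure, nucleoli) rendered identically in both
#'   marker channels; this shared structure is what correlates the two
#'   channels of real images even in cells without foci.
#' @param texture_sigma_range Spatial scale range of the texture bumps (px).
#' @param dapi_level Mean DAPI grey level of a G1 nucleus.
#' @param cycle_fractions Named fractions `g1`, `sg2`, `dying`; S/G2 nuclei
#'   double the DAPI level (2x DNA content), dying nuclei are undersized and
#'   over-bright with pan-nuclear green signal.
#' @param rng_seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `synth_spec` (a validated list).
#' @export
synth_spec <- function(field_size_px = c(1024L, 1360L),
                       n_nuclei = 50L,
                       nucleus_radius_px = c(mean = 30, sd = 3),
                       foci_per_cell = 1,
                       focus_amplitude = 150,
                       focus_sigma_px = 1.5,
                       focus_amplitude_sdlog = 0.15,
                       focus_sigma_sdlog = 0,
                       speckle_rate = 6,
                       speckle_amplitude_range = c(0.3, 0.6),
                       speckle_sigma_range = c(0.9, 1.3),
                       smear_rate = 0,
                       smear_amplitude_range = c(0.6, 1.0),
                       smear_sigma_range = c(3, 5),
                       colocalization = 1,
                       channel_noise_sd = 1,
                       background_gradient = 10,
                       zstack_defocus_sigmas = c(0, 1.4, 2.8, 4.2, 5.6),
                       marker_baseline = 20,
                       texture_sd = 5,
                       texture_sigma_range = c(5, 10),
                       dapi_level = 110,
                       cycle_fractions = c(g1 = 0.90, sg2 = 0.08, dying = 0.02),
                       rng_seed = 1L) {
  spec <- list(
    field_size_px = as.integer(field_size_px), n_nuclei = as.integer(n_nuclei),
    nucleus_radius_px = c(mean = unname(nucleus_radius_px[1]),
                          sd = unname(nucleus_radius_px[2])),
    foci_per_cell = foci_per_cell, focus_amplitude = focus_amplitude,
    focus_amplitude_sdlog = focus_amplitude_sdlog,
    focus_sigma_sdlog = focus_sigma_sdlog,
    focus_sigma_px = focus_sigma_px, speckle_rate = speckle_rate,
    speckle_amplitude_range = speckle_amplitude_range,
    speckle_sigma_range = speckle_sigma_range,
    smear_rate = smear_rate,
    smear_amplitude_range = smear_amplitude_range,
    smear_sigma_range = smear_sigma_range,
    colocalization = colocalization, channel_noise_sd = channel_noise_sd,
    background_gradient = background_gradient,
    zstack_defocus_sigmas = zstack_defocus_sigmas,
    marker_baseline = marker_baseline, texture_sd = texture_sd,
    texture_sigma_range = texture_sigma_range, dapi_level = dapi_level,
    cycle_fractions = cycle_fractions, rng_seed = as.integer(rng_seed)
  )
  validate_synth_spec(structure(spec, class = "synth_spec"))
}

validate_synth_spec <- function(spec) {
  stopifnot(length(spec$field_size_px) == 2)
  if (spec$n_nuclei < 0 || spec$foci_per_cell < 0 || spec$speckle_rate < 0)
    abort("Counts and rates must be non-negative.")
  if (spec$focus_amplitude <= 0 || spec$focus_sigma_px <= 0)
    abort("Focus amplitude and sigma must be positive.")
  if (spec$channel_noise_sd < 0) abort("`channel_noise_sd` must be >= 0.")
  if (spec$colocalization < 0 || spec$colocalization > 1)
    abort("`colocalization` must lie in [0, 1].")
  if (length(spec$zstack_defocus_sigmas) != 5)
    abort("`zstack_defocus_sigmas` must hold 5 blur scales.")
  if (abs(sum(spec$cycle_fractions) - 1) > 1e-8)
    abort("`cycle_fractions` must sum to 1.")
  # crude capacity check: packed discs at twice the area each
  r <- spec$nucleus_radius_px[["mean"]] + 2 * spec$nucleus_radius_px[["sd"]]
  need <- spec$n_nuclei * (2 * r)^2 * 2
  if (need > prod(spec$field_size_px))
    abort("Field too small to place the requested nuclei without overlap.")
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> field", paste(x$field_size_px, collapse = " x "),
      "px,", x$n_nuclei, "nuclei,", x$foci_per_cell, "foci/cell,",
      x$speckle_rate, "speckles/cell/channel, seed", x$rng_seed, "\n")
  invisible(x)
}

#' Multi-channel field container
#'
#' Bundles one DAPI plane with the two damage-marker z-stacks (5 planes each)
#' acquired for a microscope field. All planes share dimensions; grey values
#' are 8-bit (0-255) when produced by the simulator or read from disk.
#'
#' @param dapi Numeric matrix.
#' @param red_stack,green_stack Numeric arrays `(rows, cols, 5)`; red carries
#'   the 53BP1 signal, green the gamma-H2AX signal.
#' @return An object of class `field_image`.
#' @export
field_image <- function(dapi, red_stack, green_stack) {
  dapi <- as_image_matrix(dapi, "dapi")
  for (nm in c("red_stack", "green_stack")) {
    s <- get(nm)
    if (!is.array(s) || length(dim(s)) != 3 || dim(s)[3] != 5)
      abort(sprintf("`%s` must be a (rows, cols, 5) array.", nm))
    if (!all(dim(s)[1:2] == dim(dapi)))
      abort("All planes of a field must share dimensions.")
  }
  structure(list(dapi = dapi, red_stack = red_stack, green_stack = green_stack),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat("<field_image>", nrow(x$dapi), "x", ncol(x$dapi),
      "px; DAPI + 2 marker stacks of 5 planes\n")
  invisible(x)
}

# Render a list of additive items into one plane. Blobs are defocus-widened
# Gaussians with preserved 2-D integral (amplitude scales by
# sigma^2 / sigma_eff^2); discs have a sigmoidal rim of ~1.5 px. Rendering a
# whole plane inside one frame keeps the subassignments copy-free.
render_plane <- function(nr, nc, items) {
  m <- matrix(0, nr, nc)
  for (it in items) {
    if (it$kind == "blob") {
      sig <- sqrt(it$sigma^2 + it$defocus^2)
      amp <- it$amplitude * it$sigma^2 / sig^2
      ext <- ceiling(4 * sig)
    } else {
      ext <- ceiling(it$radius + 6)
    }
    r0 <- max(1L, floor(it$row - ext)); r1 <- min(nr, ceiling(it$row + ext))
    c0 <- max(1L, floor(it$col - ext)); c1 <- min(nc, ceiling(it$col + ext))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - it$row)^2, (cc - it$col)^2, "+")
    patch <- if (it$kind == "blob") {
      amp * exp(-d2 / (2 * sig^2))
    } else {
      it$level * plogis((it$radius - sqrt(d2)) / 1.5)
    }
    m[rr, cc] <- m[rr, cc] + patch
  }
  m
}

blob_item <- function(row, col, amplitude, sigma, defocus = 0) {
  list(kind = "blob", row = row, col = col, amplitude = amplitude,
       sigma = sigma, defocus = defocus)
}

disc_item <- function(row, col, radius, level) {
  list(kind = "disc", row = row, col = col, radius = radius, level = level)
}

place_nuclei <- function(spec, n_tries = 2000L) {
  fs <- spec$field_size_px
  rows <- numeric(0); cols <- numeric(0); radii <- numeric(0)
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (t in seq_len(n_tries)) {
      r <- max(5, rnorm(1, spec$nucleus_radius_px[["mean"]],
                        spec$nucleus_radius_px[["sd"]]))
      margin <- r + 2
      row <- runif(1, 1 + margin, fs[1] - margin)
      col <- runif(1, 1 + margin, fs[2] - margin)
      if (length(rows) == 0 ||
          all(sqrt((rows - row)^2 + (cols - col)^2) >= radii + r + 4)) {
        rows <- c(rows, row); cols <- c(cols, col); radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("Could not place all nuclei without overlap; enlarge the field.",
            class = "focimetry_placement_error")
    }
  }
  tibble(nucleus = seq_len(spec$n_nuclei), row = rows, col = cols, radius = radii)
}

random_in_disc <- function(n, row, col, radius) {
  u <- runif(n); theta <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(u)
  tibble(row = row + r * sin(theta), col = col + r * cos(theta))
}

#' Generate a synthetic field with known ground truth
#'
#' Renders a field per a [synth_spec()]: DAPI nuclei as smooth discs whose
#' brightness and size encode the cell-cycle class, and two 5-plane marker
#' stacks in which each nucleus has one focal plane rendering its blobs sharp
#' while the other planes render them defocused. Foci are bright compact blobs
#' co-localized across channels; speckles are dimmer, channel-independent
#' blobs. Blobs are rendered before noise; noise is additive Gaussian, then
#' clipped to [0, 255] and quantized to whole 8-bit grey values.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; defaults to `spec$rng_seed`.
#' @return A list with elements `field` ([field_image()]) and `truth`, where
#'   `truth` is a list of tibbles: `nuclei` (centre, radius, cycle class,
#'   focal plane, DAPI level), `foci` (planted focus centres, amplitudes and
#'   channel presence) and `speckles` (per-channel speckle centres).
#' @export
#' @examples
#' sim <- synth_field(synth_spec(field_size_px = c(256, 256), n_nuclei = 4,
#'                               rng_seed = 7))
#' nrow(sim$truth$nuclei)
synth_field <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fs <- spec$field_size_px
  # render items collected per target plane, rendered in one pass at the end
  dapi_items <- list()
  red_items <- rep(list(list()), 5)
  green_items <- rep(list(list()), 5)
  push <- function(store, plane, item) {
    store[[plane]][[length(store[[plane]]) + 1]] <- item
    store
  }

  empty_truth <- list(
    nuclei = tibble(nucleus = integer(), row = numeric(), col = numeric(),
                    radius = numeric(), cycle_class = character(),
                    focal_plane = integer(), dapi_level = numeric()),
    foci = tibble(nucleus = integer(), row = numeric(), col = numeric(),
                  amplitude = numeric(), sigma = numeric(),
                  in_red = logical(), in_green = logical()),
    speckles = tibble(nucleus = integer(), channel = character(),
                      kind = character(), row = numeric(), col = numeric(),
                      amplitude = numeric(), sigma = numeric())
  )

  nuc <- if (spec$n_nuclei > 0) place_nuclei(spec) else empty_truth$nuclei[, 1:4]
  n <- nrow(nuc)
  cycle <- if (n > 0) sample(names(spec$cycle_fractions), n, replace = TRUE,
                             prob = spec$cycle_fractions) else character()
  focal <- if (n > 0) sample(2:4, n, replace = TRUE) else integer()
  dapi_lv <- numeric(n)
  foci_list <- list(); spk_list <- list()

  for (i in seq_len(n)) {
    r <- nuc$radius[i]; row <- nuc$row[i]; col <- nuc$col[i]
    lv <- rnorm(1, spec$dapi_level, spec$dapi_level * 0.05)
    if (cycle[i] == "sg2") lv <- 2 * lv
    if (cycle[i] == "dying") { lv <- 2.2 * lv; r <- 0.55 * r; nuc$radius[i] <- r }
    dapi_lv[i] <- lv
    dapi_items[[length(dapi_items) + 1]] <- disc_item(row, col, r, lv)

    # in-nucleus marker baseline; dying cells show pan-nuclear green signal
    green_base <- spec$marker_baseline * (if (cycle[i] == "dying") 4 else 1)
    for (p in 1:5) {
      red_items <- push(red_items, p, disc_item(row, col, r, spec$marker_baseline))
      green_items <- push(green_items, p, disc_item(row, col, r, green_base))
    }

    # shared intranuclear texture, identical in both marker channels
    if (spec$texture_sd > 0) {
      n_tex <- max(1L, round(12 * (r / 30)^2))
      tex <- random_in_disc(n_tex, row, col, 0.9 * r)
      tex_amp <- rnorm(n_tex, 0, spec$texture_sd)
      tex_sig <- runif(n_tex, spec$texture_sigma_range[1],
                       spec$texture_sigma_range[2])
      for (j in seq_len(n_tex)) {
        it <- blob_item(tex$row[j], tex$col[j], tex_amp[j], tex_sig[j], 0)
        for (p in 1:5) {
          red_items <- push(red_items, p, it)
          green_items <- push(green_items, p, it)
        }
      }
    }

    # planted foci: co-localized compact blobs
    nf <- rpois(1, spec$foci_per_cell)
    if (nf > 0) {
      pos <- random_in_disc(nf, row, col, 0.8 * r)
      both <- runif(nf) < spec$colocalization
      red_only <- !both & (runif(nf) < 0.5)
      sig <- spec$focus_sigma_px * exp(rnorm(nf, 0, spec$focus_sigma_sdlog))
      # width varies at constant flux: broader foci are proportionally dimmer
      amp <- spec$focus_amplitude * (spec$focus_sigma_px / sig)^2 *
        exp(rnorm(nf, 0, spec$focus_amplitude_sdlog))
      for (j in seq_len(nf)) {
        for (p in 1:5) {
          dz <- spec$zstack_defocus_sigmas[abs(p - focal[i]) + 1]
          it <- blob_item(pos$row[j], pos$col[j], amp[j], sig[j], dz)
          if (both[j] || red_only[j]) red_items <- push(red_items, p, it)
          if (both[j] || !red_only[j]) green_items <- push(green_items, p, it)
        }
      }
      foci_list[[length(foci_list) + 1]] <- tibble(
        nucleus = nuc$nucleus[i], row = pos$row, col = pos$col, amplitude = amp,
        sigma = sig, in_red = both | red_only, in_green = both | !red_only)
    }

    # channel-independent background: dim narrow speckles plus occasional
    # bright diffuse smears
    for (ch in c("red", "green")) {
      for (kind in c("speckle", "smear")) {
        rate <- if (kind == "speckle") spec$speckle_rate else spec$smear_rate
        arange <- if (kind == "speckle") spec$speckle_amplitude_range else
          spec$smear_amplitude_range
        srange <- if (kind == "speckle") spec$speckle_sigma_range else
          spec$smear_sigma_range
        ns <- rpois(1, rate)
        if (ns == 0) next
        pos <- random_in_disc(ns, row, col,
                              (if (kind == "speckle") 0.85 else 0.7) * r)
        amp <- spec$focus_amplitude * runif(ns, arange[1], arange[2])
        sig <- spec$focus_sigma_px * runif(ns, srange[1], srange[2])
        for (j in seq_len(ns)) {
          for (p in 1:5) {
            dz <- spec$zstack_defocus_sigmas[abs(p - focal[i]) + 1]
            it <- blob_item(pos$row[j], pos$col[j], amp[j], sig[j], dz)
            if (ch == "red") red_items <- push(red_items, p, it)
            else green_items <- push(green_items, p, it)
          }
        }
        spk_list[[length(spk_list) + 1]] <- tibble(
          nucleus = nuc$nucleus[i], channel = ch, kind = kind, row = pos$row,
          col = pos$col, amplitude = amp, sigma = sig)
      }
    }
  }

  # render, then background gradient + noise, clip, 8-bit quantization
  ramp <- outer(rep(1, fs[1]), seq(0, 1, length.out = fs[2])) *
    spec$background_gradient
  finish <- function(m) {
    m <- m + 8 + ramp + rnorm(length(m), 0, spec$channel_noise_sd)
    matrix(pmin(pmax(round(m), 0), 255), fs[1], fs[2])
  }
  dapi <- finish(render_plane(fs[1], fs[2], dapi_items))
  red <- array(0, c(fs, 5L)); green <- array(0, c(fs, 5L))
  for (p in 1:5) {
    red[, , p] <- finish(render_plane(fs[1], fs[2], red_items[[p]]))
    green[, , p] <- finish(render_plane(fs[1], fs[2], green_items[[p]]))
  }

  truth <- empty_truth
  if (n > 0) {
    truth$nuclei <- tibble(nucleus = nuc$nucleus, row = nuc$row, col = nuc$col,
                           radius = nuc$radius, cycle_class = cycle,
                           focal_plane = as.integer(focal), dapi_level = dapi_lv)
  }
  if (length(foci_list)) truth$foci <- dplyr::bind_rows(foci_list)
  if (length(spk_list)) truth$speckles <- dplyr::bind_rows(spk_list)

  list(field = field_image(dapi, red, green), truth = truth)
}

#' Labelled two-component score mixture
#'
#' Draws log-normal object scores for a background and a focus population.
#' Used to exercise histogram construction and threshold estimation without
#' rendering images: the log of the sample is a two-component Gaussian
#' mixture, mirroring the bimodal log-score histograms of real samples.
#'
#' @param n_bg,n_foci Component sizes.
#' @param bg_logmean,bg_logsd,foci_logmean,foci_logsd Component parameters on
#'   the natural-log scale.
#' @param seed Integer seed.
#' @return A tibble with columns `oep` (positive score) and `label`
#'   (`"background"` or `"focus"`).
#' @export
synth_oep_mixture <- function(n_bg, n_foci, bg_logmean = log(0.5), bg_logsd = 0.5,
                              foci_logmean = log(50), foci_logsd = 0.5,
                              seed = 1L) {
  stopifnot(n_bg >= 0, n_foci >= 0, bg_logsd > 0, foci_logsd > 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  comp <- list(
    list(n = n_bg, m = bg_logmean, s = bg_logsd, label = "background"),
    list(n = n_foci, m = foci_logmean, s = foci_logsd, label = "focus")
  )
  # draw in canonical parameter order so that swapping the two components'
  # parameters swaps labels but reproduces the same value multiset
  ord <- order(vapply(comp, `[[`, 0, "m"), vapply(comp, `[[`, 0, "s"),
               vapply(comp, `[[`, 0, "n"))
  drawn <- lapply(comp[ord], function(cm) {
    tibble(oep = exp(rnorm(cm$n, cm$m, cm$s)), label = rep(cm$label, cm$n))
  })
  out <- dplyr::bind_rows(drawn)
  dplyr::arrange(out, factor(.data$label, levels = c("background", "focus")))
}
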