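# Synthetic multi-cat world: procedural identities, rendered body-crop
# frames grouped into sessions, color-temperature filtering, gradual
# appearance drift (kitten -> adult morphology) and population churn.

ADULT_BODY_SCALE <- 0.9
SUPPORTED_KELVINS <- c(2700, 4100, 6500, 10000)

#' Create an appearance genotype for one synthetic cat
#'
#' A genotype is the stable, identity-defining parameter set from which every
#' frame of a cat is rendered: coat base color, a sinusoidal stripe pattern
#' (frequency and phase), initial body scale and a growth rate that drives the
#' kitten-to-adult morph.
#'
#' @param identity_id Character token naming the identity.
#' @param base_color Numeric length-3 RGB coat color, components in `[0, 1]`.
#' @param pattern_frequency Positive stripe frequency (stripes per image width).
#' @param pattern_phase Stripe phase in `[0, 2*pi)`.
#' @param body_scale Initial body size as a fraction of frame height, in `(0, 1]`.
#' @param growth_rate Nonnegative logistic growth rate per unit age.
#' @return An object of class `cat_genotype`.
#' @export
cat_genotype <- function(identity_id, base_color, pattern_frequency,
                         pattern_phase, body_scale, growth_rate) {
  if (!is.character(identity_id) || length(identity_id) != 1L || !nzchar(identity_id))
    stop_arg("identity_id must be a non-empty string")
  if (length(base_color) != 3L || any(base_color < 0) || any(base_color > 1))
    stop_arg("base_color must be 3 values in [0, 1]")
  if (pattern_frequency <= 0) stop_arg("pattern_frequency must be positive")
  if (body_scale <= 0 || body_scale > 1) stop_arg("body_scale must be in (0, 1]")
  if (growth_rate < 0) stop_arg("growth_rate must be nonnegative")
  structure(
    list(identity_id = identity_id,
         base_color = as.numeric(base_color),
         pattern_frequency = as.numeric(pattern_frequency),
         pattern_phase = as.numeric(pattern_phase) %% (2 * pi),
         body_scale = as.numeric(body_scale),
         growth_rate = as.numeric(growth_rate)),
    class = "cat_genotype")
}

#' Draw a single random genotype for a named identity
#'
#' @param identity_id Identity token.
#' @param seed Integer seed; the genotype is a pure function of it.
#' @return A `cat_genotype`.
#' @export
spawn_genotype <- function(identity_id, seed) {
  withr::with_seed(derive_seed(seed, "genotype", identity_id), {
    cat_genotype(
      identity_id = identity_id,
      base_color = runif(3, 0.15, 0.95),
      pattern_frequency = runif(1, 2, 8),
      pattern_phase = runif(1, 0, 2 * pi),
      body_scale = runif(1, 0.35, 0.6),
      growth_rate = runif(1, 0.05, 0.15))
  })
}

#' Generate a population of distinct synthetic cats
#'
#' @param n_identities Positive integer number of cats.
#' @param seed Integer seed; the population is deterministic in it.
#' @return A list of `cat_genotype` objects with distinct identity ids
#'   (`"cat01"`, `"cat02"`, ...).
#' @export
generate_population <- function(n_identities, seed = 1L) {
  if (length(n_identities) != 1L || is.na(n_identities) || n_identities < 1)
    stop_arg("n_identities must be a positive integer")
  n_identities <- as.integer(n_identities)
  ids <- sprintf("cat%02d", seq_len(n_identities))
  lapply(ids, function(id) spawn_genotype(id, derive_seed(seed, "pop", id)))
}

# Logistic body-size growth saturating at the adult scale.
body_scale_at_age <- function(genotype, age) {
  s0 <- genotype$body_scale
  K <- max(ADULT_BODY_SCALE, s0)
  e <- exp(genotype$growth_rate * age)
  K * s0 * e / (K + s0 * (e - 1))
}

# Coat maturation: kittens render brighter, adults darker; deterministic in age.
maturation_factor <- function(age) 0.55 + 0.45 * exp(-0.15 * age)

#' Render one body-crop frame of a synthetic cat
#'
#' The appearance is a deterministic function of the genotype and the cat's
#' age (body scale grows logistically toward a fixed adult value, coat color
#' darkens as the cat matures), plus seeded per-pixel Gaussian noise.
#'
#' @param genotype A `cat_genotype`.
#' @param age Nonnegative age in simulator time units; drives the morph.
#' @param noise_seed Integer seed for the pixel noise.
#' @param size Integer `(H, W)`, both at least 16.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @return An `H x W x 3` array with values in `[0, 1]`.
#' @export
render_frame <- function(genotype, age = 0, noise_seed = 0L, size = c(32L, 32L),
                         noise_sd = 0.02) {
  if (!inherits(genotype, "cat_genotype")) stop_arg("genotype must be a cat_genotype")
  if (age < 0) stop_arg("age must be nonnegative")
  h <- as.integer(size[1]); w <- as.integer(size[if (length(size) > 1) 2 else 1])
  if (is.na(h) || is.na(w) || h < 16L || w < 16L)
    stop_arg("frame size must be at least 16 x 16")

  s <- body_scale_at_age(genotype, age)
  col <- genotype$base_color * maturation_factor(age)

  x <- matrix((seq_len(w) - 0.5) / w, nrow = h, ncol = w, byrow = TRUE)
  y <- matrix((seq_len(h) - 0.5) / h, nrow = h, ncol = w)
  ax <- 0.45 * s
  ay <- 0.30 * s
  body <- ((x - 0.5) / ax)^2 + ((y - 0.5) / ay)^2 <= 1
  stripes <- 0.75 + 0.25 * sin(2 * pi * genotype$pattern_frequency * x +
                                 genotype$pattern_phase)
  img <- array(0.45, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[body] <- (col[ch] * stripes)[body]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(noise_seed),
                              array(rnorm(h * w * 3, 0, noise_sd), dim = c(h, w, 3)))
    img <- img + noise
  }
  clip01(img)
}

# Blackbody RGB approximation (piecewise log/power fit), on a 0-255 scale.
blackbody_rgb <- function(kelvin) {
  t <- kelvin / 100
  r <- if (t >= 66) 329.698727446 * (t - 60)^-0.1332047592 else 255
  g <- if (t <= 66) 99.4708025861 * log(t) - 161.1195681661 else
    288.1221695283 * (t - 60)^-0.0755148492
  b <- if (t >= 66) 255 else if (t <= 19) 0 else
    138.5177312231 * log(t - 10) - 305.0447927307
  pmin(pmax(c(r, g, b), 0), 255)
}

#' Apply a color-temperature filter to an image
#'
#' Per-channel gains come from a blackbody RGB approximation at the requested
#' color temperature, normalized so that 6500 K (the assumed capture
#' temperature, "cool white") yields exactly unit gains and leaves the image
#' unchanged. Supported temperatures are the four lighting conditions used for
#' dataset diversification: 2700 K (warm white), 4100 K (natural white),
#' 6500 K (cool white) and 10,000 K (LED).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param kelvin One of 2700, 4100, 6500, 10000.
#' @return The filtered image, clipped to `[0, 1]`.
#' @export
apply_color_filter <- function(image, kelvin) {
  check_image(image)
  if (length(kelvin) != 1L || !(kelvin %in% SUPPORTED_KELVINS))
    stop_arg("kelvin must be one of ", paste(SUPPORTED_KELVINS, collapse = ", "))
  gains <- blackbody_rgb(kelvin) / blackbody_rgb(6500)
  for (ch in 1:3) image[, , ch] <- image[, , ch] * gains[ch]
  clip01(image)
}

#' Define a concept-drift scenario
#'
#' @param duration Positive integer number of ticks.
#' @param morph_rate Nonnegative real; a cat's age at tick `t` is
#'   `t * morph_rate`, so 0 freezes appearance.
#' @param env_events List of `list(tick =, kelvin =)` lighting switches; a
#'   frame uses the most recent event's color temperature (6500 K before any).
#' @param population_events List of `list(tick =, action = "add"|"remove",
#'   identity_id =)` describing population churn.
#' @return An object of class `drift_scenario`.
#' @export
drift_scenario <- function(duration, morph_rate = 0, env_events = list(),
                           population_events = list()) {
  if (length(duration) != 1L || duration < 1) stop_arg("duration must be >= 1")
  if (morph_rate < 0) stop_arg("morph_rate must be nonnegative")
  duration <- as.integer(duration)
  for (ev in env_events) {
    if (is.null(ev$tick) || is.null(ev$kelvin)) stop_arg("env_events need tick and kelvin")
    if (ev$tick < 0 || ev$tick > duration) stop_arg("env_event tick outside [0, duration]")
    if (!(ev$kelvin %in% SUPPORTED_KELVINS))
      stop_arg("env_event kelvin must be one of ", paste(SUPPORTED_KELVINS, collapse = ", "))
  }
  for (ev in population_events) {
    if (is.null(ev$tick) || is.null(ev$action) || is.null(ev$identity_id))
      stop_arg("population_events need tick, action and identity_id")
    if (ev$tick < 0 || ev$tick > duration) stop_arg("population_event tick outside [0, duration]")
    if (!(ev$action %in% c("add", "remove"))) stop_arg("population_event action must be add or remove")
  }
  structure(list(duration = duration, morph_rate = as.numeric(morph_rate),
                 env_events = env_events, population_events = population_events),
            class = "drift_scenario")
}

new_session_record <- function(session_id, identity_id, frames, tick, kelvin) {
  structure(list(session_id = session_id, identity_id = identity_id,
                 frames = frames, tick = as.integer(tick), kelvin = kelvin),
            class = "session_record")
}

#' Generate a stream of labeled sessions under a drift scenario
#'
#' Each tick emits `sessions_per_tick` sessions (one litter-box visit each,
#' one identity per session), drawn only from identities alive at that tick.
#' Frames are rendered at age `tick * morph_rate` and filtered with the
#' currently active color temperature. Identities introduced by `add` events
#' get a fresh genotype derived from `genotype_seed`, so two streams sharing
#' that seed agree on who the new cats are.
#'
#' @param population List of `cat_genotype` present at tick 0.
#' @param scenario A `drift_scenario`.
#' @param frames_per_session Frames rendered per session.
#' @param sessions_per_tick Sessions emitted per tick.
#' @param seed Integer seed; the stream is deterministic in it.
#' @param size Frame size `(H, W)`.
#' @param noise_sd Pixel noise level.
#' @param genotype_seed Seed for genotypes of cats added mid-stream
#'   (defaults to `seed`).
#' @return A list of `session_record`, ordered by tick, with the full genotype
#'   table attached as attribute `"genotypes"`.
#' @export
generate_stream <- function(population, scenario, frames_per_session = 5L,
                            sessions_per_tick = 2L, seed = 1L,
                            size = c(32L, 32L), noise_sd = 0.02,
                            genotype_seed = seed) {
  if (!inherits(scenario, "drift_scenario")) stop_arg("scenario must be a drift_scenario")
  if (length(population) < 1L) stop_arg("population must be non-empty at tick 0")
  genotypes <- stats::setNames(population, vapply(population, `[[`, "", "identity_id"))
  alive <- names(genotypes)

  sessions <- list()
  kelvin <- 6500
  counter <- 0L
  withr::with_seed(derive_seed(seed, "stream"), {
    for (t in 0:(scenario$duration - 1L)) {
      for (ev in scenario$env_events) if (ev$tick == t) kelvin <- ev$kelvin
      for (ev in scenario$population_events) {
        if (ev$tick != t) next
        if (ev$action == "add") {
          if (ev$identity_id %in% names(genotypes) && ev$identity_id %in% alive)
            stop_arg("scenario error: add for already-alive identity ", ev$identity_id)
          if (!(ev$identity_id %in% names(genotypes)))
            genotypes[[ev$identity_id]] <- spawn_genotype(ev$identity_id, genotype_seed)
          alive <- union(alive, ev$identity_id)
        } else {
          if (!(ev$identity_id %in% alive))
            stop_arg("scenario error: remove for unknown identity ", ev$identity_id)
          alive <- setdiff(alive, ev$identity_id)
        }
      }
      if (length(alive) == 0L) next
      age <- t * scenario$morph_rate
      for (s in seq_len(sessions_per_tick)) {
        id <- if (length(alive) == 1L) alive else sample(alive, 1L)
        counter <- counter + 1L
        frames <- lapply(seq_len(frames_per_session), function(k) {
          ns <- sample.int(2147483646L, 1L)
          apply_color_filter(
            render_frame(genotypes[[id]], age = age, noise_seed = ns,
                         size = size, noise_sd = noise_sd),
            kelvin)
        })
        sessions[[counter]] <- new_session_record(
          session_id = sprintf("s%05d_t%03d", counter, t),
          identity_id = id, frames = frames, tick = t, kelvin = kelvin)
      }
    }
  })
  attr(sessions, "genotypes") <- genotypes
  sessions
}

#' Write a session stream to disk as PNG frames plus a manifest
#'
#' Frames go to `sessions/<session_id>/frame_<k>.png` under `dir`; the
#' manifest CSV has columns session_id, tick, identity_id, kelvin, frame_count.
#'
#' @param sessions List of `session_record`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_sessions <- function(sessions, dir) {
  dir.create(file.path(dir, "sessions"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sessions, function(s) {
    sdir <- file.path(dir, "sessions", s$session_id)
    dir.create(sdir, showWarnings = FALSE)
    for (k in seq_along(s$frames))
      png::writePNG(s$frames[[k]], file.path(sdir, sprintf("frame_%03d.png", k)))
    data.frame(session_id = s$session_id, tick = s$tick,
               identity_id = s$identity_id, kelvin = s$kelvin,
               frame_count = length(s$frames))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a session stream previously written with [write_sessions()]
#'
#' @param dir Directory containing `manifest.csv` and `sessions/`.
#' @return A list of `session_record`.
#' @export
read_sessions <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_arg("no manifest.csv under ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    sdir <- file.path(dir, "sessions", row$session_id)
    frames <- lapply(seq_len(row$frame_count), function(k) {
      img <- png::readPNG(file.path(sdir, sprintf("frame_%03d.png", k)))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
      img[, , 1:3, drop = FALSE]
    })
    new_session_record(row$session_id, row$identity_id, frames, row$tick, row$kelvin)
  })
}
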