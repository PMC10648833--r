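test_that("population generation is counted, distinct and seed-deterministic", {
  pop <- generate_population(36, seed = 1)
  expect_length(pop, 36)
  expect_length(unique(vapply(pop, `[[`, "", "identity_id")), 36)

  g1 <- generate_population(1, seed = 7)[[1]]
  g2 <- generate_population(1, seed = 7)[[1]]
  expect_identical(g1, g2)

  a <- generate_population(5, seed = 1)
  b <- generate_population(5, seed = 2)
  fields <- function(p) unlist(lapply(p, function(g) g[c("base_color",
    "pattern_frequency", "pattern_phase", "body_scale", "growth_rate")]))
  expect_false(isTRUE(all.equal(fields(a), fields(b))))

  expect_error(generate_population(0), "positive")
})

test_that("rendered frames are deterministic, bounded and morph with age", {
  g <- spawn_genotype("x", 3)
  f1 <- render_frame(g, age = 2, noise_seed = 5)
  f2 <- render_frame(g, age = 2, noise_seed = 5)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  expect_equal(dim(f1), c(32, 32, 3))

  young <- render_frame(g, age = 0, noise_seed = 5)
  old <- render_frame(g, age = 10, noise_seed = 5)
  expect_gt(mean(abs(young - old)), 0)

  h <- spawn_genotype("y", 4)
  expect_gt(mean(abs(render_frame(h, 2, 5) - f1)), 0)

  expect_error(render_frame(g, size = c(8, 8)), "at least 16")
  expect_error(render_frame(g, age = -1), "nonnegative")
})

test_that("color filter: 6500 K is the identity, 2700 K is warm, output clipped", {
  set.seed(42)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(apply_color_filter(img, 6500), img)

  gray <- array(0.5, c(32, 32, 3))
  warm <- apply_color_filter(gray, 2700)
  expect_gt(mean(warm[, , 1]), mean(warm[, , 3]))

  ones <- array(1, c(20, 20, 3))
  for (k in c(2700, 4100, 6500, 10000))
    expect_true(all(apply_color_filter(ones, k) <= 1))

  expect_error(apply_color_filter(img, 5000), "kelvin")
})

test_that("session streams honor counts, liveness and the no-drift case", {
  pop <- generate_population(3, seed = 9)
  sc <- drift_scenario(duration = 10)
  st <- generate_stream(pop, sc, frames_per_session = 2, sessions_per_tick = 2,
                        seed = 5, size = c(16, 16))
  expect_length(st, 20)
  expect_true(all(vapply(st, function(s) length(s$frames) == 2, TRUE)))

  sc_rm <- drift_scenario(duration = 10, population_events = list(
    list(tick = 5, action = "remove", identity_id = "cat01")))
  st_rm <- generate_stream(pop, sc_rm, 1, 3, seed = 5, size = c(16, 16))
  late <- Filter(function(s) s$tick >= 5, st_rm)
  expect_false("cat01" %in% vapply(late, `[[`, "", "identity_id"))

  bad <- drift_scenario(duration = 4, population_events = list(
    list(tick = 1, action = "remove", identity_id = "nosuchcat")))
  expect_error(generate_stream(pop, bad, 1, 1, seed = 5, size = c(16, 16)),
               "scenario error")

  # morph_rate 0: a frame is a pure function of (genotype, noise seed, kelvin)
  g <- pop[[1]]
  expect_identical(render_frame(g, age = 0 * 0, noise_seed = 77),
                   render_frame(g, age = 9 * 0, noise_seed = 77))

  # streams are deterministic per seed
  st2 <- generate_stream(pop, sc, 2, 2, seed = 5, size = c(16, 16))
  expect_identical(st[[7]]$frames, st2[[7]]$frames)
})

test_that("identities are separable in pixel space at low noise", {
  pop <- generate_population(5, seed = 21)
  frames <- list(); labels <- character(0)
  for (g in pop) for (k in 1:20) {
    frames[[length(frames) + 1L]] <- render_frame(g, age = 0, noise_seed = k,
                                                  size = c(24, 24), noise_sd = 0.02)
    labels <- c(labels, g$identity_id)
  }
  M <- do.call(rbind, lapply(frames, as.vector))
  D <- as.matrix(dist(M))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  expect_gt(mean(D[!same], na.rm = TRUE), mean(D[same & !is.na(same)], na.rm = TRUE))
})

test_that("session streams round-trip through PNG frames and manifest", {
  pop <- generate_population(2, seed = 3)
  st <- generate_stream(pop, drift_scenario(duration = 2), 2, 2, seed = 3,
                        size = c(16, 16))
  dir <- withr::local_tempdir()
  manifest <- write_sessions(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 4)
  expect_named(manifest, c("session_id", "tick", "identity_id", "kelvin",
                           "frame_count"))
  back <- read_sessions(dir)
  expect_length(back, 4)
  expect_equal(back[[1]]$identity_id, st[[1]]$identity_id)
  # PNG is 8-bit, so round-tripped pixels agree to 1/255
  expect_lt(max(abs(back[[1]]$frames[[1]] - st[[1]]$frames[[1]])), 1 / 254)
})
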