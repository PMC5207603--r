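# World model: geometry, perception, predator tactics, synchronous update.

test_that("relative bearing follows the left-negative convention", {
  expect_equal(relative_bearing(c(0, 0), 0, c(10, 0)), 0)
  expect_equal(relative_bearing(c(0, 0), 0, c(0, 10)), -90)   # left
  expect_equal(relative_bearing(c(0, 0), 0, c(0, -10)), 90)   # right
  expect_equal(abs(relative_bearing(c(0, 0), 0, c(-10, 0))), 180)
  expect_error(relative_bearing(c(1, 1), 0, c(1, 1)), "coincides")
  # mirror antisymmetry on random scenes (reflection across the x axis)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(2, -100, 100)
    h <- runif(1, -180, 180)
    t <- runif(2, -100, 100)
    b <- relative_bearing(p, h, t)
    bm <- relative_bearing(p * c(1, -1), -h, t * c(1, -1))
    expect_equal(sin(bm * pi / 180), -sin(b * pi / 180), tolerance = 1e-9)
    expect_equal(cos(bm * pi / 180), cos(b * pi / 180), tolerance = 1e-9)
  }
})

test_that("relative heading is the wrapped signed difference", {
  expect_equal(relative_heading(45, 45), 0)
  expect_equal(relative_heading(0, 180), 180)
  expect_equal(relative_heading(90, 0), -90)
  expect_equal(relative_heading(-170, 170), -20)
})

test_that("closest border point handles inside, outside and the centre tie", {
  b <- closest_border_point(c(100, 0), 375)
  expect_equal(b$point, c(187.5, 0))
  expect_equal(b$distance, 87.5)
  # centre tie broken towards +x
  b0 <- closest_border_point(c(0, 0), 375)
  expect_equal(b0$point, c(187.5, 0))
  expect_equal(b0$distance, 187.5)
  # outside: clamps to the nearest corner
  b1 <- closest_border_point(c(300, 300), 375)
  expect_equal(b1$point, c(187.5, 187.5))
  expect_equal(b1$distance, sqrt(2 * 112.5^2))
  # dense-perimeter oracle on random positions
  set.seed(3)
  for (i in 1:20) {
    pos <- runif(2, -400, 400)
    got <- closest_border_point(pos, 375)
    ref <- oracle_border(pos, 375)
    expect_equal(got$distance, ref$distance, tolerance = 1e-2)
  }
})

test_that("interaction partner sampling is inverse-distance weighted", {
  # no neighbour in range
  pos <- rbind(c(0, 0), c(500, 0))
  expect_true(is.na(sample_interaction_partner(1, pos)))
  # single neighbour: certainty
  pos2 <- rbind(c(0, 0), c(50, 0))
  expect_identical(sample_interaction_partner(1, pos2), 2L)
  # weights 1/25 : 1/75 = 3 : 1
  set.seed(19)
  pos3 <- rbind(c(0, 0), c(25, 0), c(-75, 0))
  draws <- sample_interaction_partner(1, pos3, draws = 1e5)
  expect_equal(mean(draws == 2L), 0.75, tolerance = 0.01)
  expect_equal(mean(draws == 3L), 0.25, tolerance = 0.01)
})

test_that("perception nulls out-of-range aspects and reports the worked scene", {
  cfg <- world_config(n_prey = 2)
  scene <- make_pursuit_scene()
  st <- scene_to_state(scene, world_config(n_prey = 1))
  set.seed(1)
  inp <- build_perception(1, st$state, st$cfg)
  expect_equal(unname(inp["predator.relative_bearing"]), -126)
  expect_equal(unname(inp["predator.distance"]), 50)
  # no conspecific: interaction variables null
  expect_true(all(is.na(inp[1:3])))
  # at the living-area centre the border is beyond perception
  expect_true(all(is.na(inp[7:8])))
  # predator beyond perception distance: predator inputs null
  far <- make_pursuit_scene(distance = 150)
  st2 <- scene_to_state(far, world_config(n_prey = 1))
  inp2 <- build_perception(1, st2$state, st2$cfg)
  expect_true(all(is.na(inp2[4:6])))
  # near the border the living-area inputs appear
  st3 <- st$state
  st3$px <- 150
  inp3 <- build_perception(1, st3, st$cfg)
  expect_equal(unname(inp3["living_area.distance"]), 37.5)
  expect_equal(unname(inp3["living_area.relative_bearing"]), 0)
})

test_that("predator target selection implements the four tactics", {
  prey <- rbind(c(50, 0), c(80, 0), c(120, 0))
  expect_identical(select_target("nearest", c(0, 0), prey)$target, 1L)
  # most isolated: three clustered, one distant
  prey2 <- rbind(c(0, 0), c(5, 0), c(0, 5), c(200, 200))
  expect_identical(select_target("most_isolated", c(0, 0), prey2)$target, 4L)
  # most central: symmetric ring plus centre agent
  phi <- seq(0, 2 * pi, length.out = 9)[-9]
  prey3 <- rbind(cbind(60 * cos(phi), 60 * sin(phi)), c(0, 0))
  expect_identical(select_target("most_central", c(10, 0), prey3)$target, 9L)
  # hda: returns the densest prey's position
  prey4 <- rbind(c(0, 0), c(4, 0), c(0, 4), c(300, 0))
  out <- select_target("hda", c(10, 10), prey4, catch = 12)
  expect_identical(out$target, NA_integer_)
  expect_equal(out$point, c(0, 0))
  # nothing perceivable
  expect_true(is.na(select_target("nearest", c(0, 0), rbind(c(900, 0)))$target))
})

test_that("the preset pursuit controller holds ahead and mirrors left/right", {
  expect_equal(predator_heading_change(0), 0, tolerance = 1e-9)
  expect_equal(length(predator_rule_base()), 4L)
  # mirror antisymmetry where the rear rule is silent
  for (b in c(10, 45, 80)) {
    expect_equal(predator_heading_change(-b), -predator_heading_change(b),
                 tolerance = 1e-9)
  }
  # pursuing: left target yields a left (negative) turn
  expect_true(predator_heading_change(-60) < 0)
  expect_true(predator_heading_change(60) > 0)
})

test_that("prey with only a no-turn rule move straight at constant speed", {
  cfg <- world_config(n_prey = 10, n_predators = 0)
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  set.seed(2)
  state <- init_world(cfg, pool = rep(list(rb), 10))
  before <- cbind(state$px, state$py)
  h <- state$heading
  state2 <- step_world(state, cfg, steps = 5, mode = "frozen",
                       pool = list(rb))
  expect_equal(state2$heading, h)
  moved <- cbind(state2$px, state2$py) - before
  expect_equal(sqrt(rowSums(moved^2)), rep(10, 10))  # 5 steps at speed 2
})

test_that("energy accounting: foraging, collision death and replacement", {
  cfg <- world_config(n_prey = 3, n_predators = 0, spawn_radius = 10)
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  # two overlapping prey plus one distant: colliders lose 1 - 10 per step
  state <- init_world(cfg, pool = rep(list(rb), 3),
                      positions = rbind(c(0, 0), c(0.5, 0), c(120, 0)),
                      headings = c(90, 90, 0))
  set.seed(4)
  sim <- simulate_world(cfg, steps = 1, mode = "frozen", pool = list(rb),
                        state = state, record_events = TRUE)
  expect_equal(sort(sim$events$event[sim$events$id %in% c(1, 2)]),
               c("collision", "collision"))
  expect_equal(sim$state$energy[3], 1001)
  # a prey at energy 5 colliding once: 5 + 1 - 10 <= 0, replaced this step
  state$energy <- c(5, 1000, 1000)
  set.seed(4)
  sim2 <- simulate_world(cfg, steps = 1, mode = "frozen", pool = list(rb),
                         state = state, record_events = TRUE)
  expect_true(any(sim2$events$event == "death" & sim2$events$id == 1))
  expect_true(any(sim2$events$event == "birth"))
  expect_equal(length(sim2$state$px), 3L)
  expect_equal(sim2$state$energy[1], 1000)  # newborn at initial energy
})

test_that("population size is conserved and the energy ledger balances", {
  set.seed(99)
  cfg <- world_config(n_prey = 40, initial_energy = 60)
  sim <- simulate_world(cfg, steps = 1000, mode = "evolve",
                        record_events = TRUE, record_every = 250)
  # conservation at every snapshot
  for (p in sim$snapshots$prey) expect_equal(nrow(p), 40L)
  expect_true(sim$counts["births"] > 0)  # replacement actually exercised
  # ledger: final energy = initial + gains - penalties, per surviving prey
  ev <- sim$events
  st <- sim$state
  for (i in seq_len(40)) {
    mine <- ev[ev$id == st$id[i], ]
    expect_equal(
      st$energy[i],
      cfg$initial_energy + (st$step - st$birth[i]) * cfg$foraging_gain +
        cfg$collision_penalty * sum(mine$event == "collision") +
        cfg$wandering_penalty * sum(mine$event == "wander"))
  }
})

test_that("at most n_predators predators exist and they obey the schedule", {
  set.seed(123)
  cfg <- world_config(n_prey = 20, n_predators = 3, reenter_min = 50,
                      reenter_max = 100, hunt_duration = 40)
  sim <- simulate_world(cfg, steps = 400, mode = "evolve", record_every = 1)
  active <- vapply(sim$snapshots$predators, function(m) sum(m[, 1]), numeric(1))
  expect_true(all(active <= 3))
  expect_true(any(active > 0))
  # predators enter at the ambush distance heading for the centre
  first_on <- which(active > 0)[1]
  m <- sim$snapshots$predators[[first_on]]
  on <- which(m[, 1] > 0)
  d <- sqrt(m[on, 2]^2 + m[on, 3]^2)
  expect_true(all(d < cfg$ambush_distance + cfg$st_speed * cfg$hunt_duration))
})

test_that("a lone predator converges on scripted prey and captures", {
  cfg <- world_config(n_prey = 4, n_predators = 1, spawn_radius = 30)
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  scene <- make_pursuit_scene(bearing = 170, distance = 90)
  st <- scene_to_state(scene, cfg, rule_base = rb)
  st$state$predators$tactic[1] <- 0L
  set.seed(8)
  sim <- simulate_world(st$cfg, steps = 300, mode = "frozen", pool = list(rb),
                        state = st$state, record_events = TRUE,
                        fixed_tactic = 0L)
  expect_true(sim$counts["captures"] >= 1)
})

test_that("mirrored worlds evolve mirrored trajectories under one seed", {
  cfg <- world_config(n_prey = 12, n_predators = 0,
                      initial_energy = 1e6)  # no deaths: pure kinematics
  set.seed(77)
  pool <- replicate(12, random_rule_base(), simplify = FALSE)
  positions <- cbind(runif(12, -150, 150), runif(12, -150, 150))
  headings <- runif(12, -180, 180)
  state <- init_world(cfg, pool = pool, positions = positions,
                      headings = headings)
  state_m <- init_world(cfg, pool = lapply(pool, mirror_rule_base),
                        positions = positions %*% diag(c(1, -1)),
                        headings = -headings)
  set.seed(42)
  a <- simulate_world(cfg, steps = 40, mode = "frozen", pool = pool,
                      state = state)$state
  set.seed(42)
  b <- simulate_world(cfg, steps = 40, mode = "frozen", pool = pool,
                      state = state_m)$state
  expect_equal(b$px, a$px, tolerance = 1e-6)
  expect_equal(b$py, -a$py, tolerance = 1e-6)
  expect_equal(sin(b$heading * pi / 180), -sin(a$heading * pi / 180),
               tolerance = 1e-6)
})

test_that("trajectories round-trip through the CSV dialect", {
  set.seed(55)
  cfg <- world_config(n_prey = 8, n_predators = 1, reenter_min = 1,
                      reenter_max = 2)
  sim <- simulate_world(cfg, steps = 10, mode = "evolve", record_every = 2)
  traj <- as_trajectory(sim)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$x, traj$x, tolerance = 1e-12)
  expect_equal(back$heading, traj$heading, tolerance = 1e-12)
  expect_identical(back$kind, traj$kind)
})
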