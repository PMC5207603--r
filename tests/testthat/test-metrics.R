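# Order parameters, grouping, state classification, time allocation,
# density, bootstrap CIs and the validation protocol.

test_that("polarization measures heading alignment", {
  expect_equal(polarization(rep(37, 10)), 1)
  expect_equal(polarization(c(0, 180)), 0)
  expect_equal(polarization(c(0, 90)), sqrt(2) / 2)
})

test_that("rotation measures milling about the centroid", {
  mill <- make_mill(12, radius = 40)
  expect_equal(rotation(mill$positions, mill$headings), 1)
  # radial outward motion: no rotation
  phi <- seq(0, 2 * pi, length.out = 9)[-9]
  pos <- cbind(40 * cos(phi), 40 * sin(phi))
  out_h <- vapply(seq_along(phi), function(i)
    relative_heading(0, 0) + atan2(-sin(phi[i]), cos(phi[i])) * 180 / pi,
    numeric(1))
  expect_equal(rotation(pos, out_h), 0, tolerance = 1e-9)
  # two agents orbiting in opposite senses cancel
  cw <- make_mill(8, radius = 30, sense = 1)
  ccw <- make_mill(8, radius = 30, sense = -1)
  pos2 <- rbind(cw$positions, ccw$positions)
  h2 <- c(cw$headings, ccw$headings)
  expect_equal(rotation(pos2, h2), 0, tolerance = 1e-9)
})

test_that("polarization and rotation are invariant under scene isometries", {
  set.seed(201)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    pos <- matrix(runif(2 * n, -100, 100), n, 2)
    h <- runif(n, -180, 180)
    p0 <- polarization(h)
    m0 <- rotation(pos, h)
    expect_true(p0 >= 0 && p0 <= 1)
    expect_true(m0 >= 0 && m0 <= 1)
    # translation
    shift <- runif(2, -500, 500)
    expect_equal(rotation(sweep(pos, 2, shift, "+"), h), m0)
    # rotation of the whole scene by a random angle (clockwise convention)
    ang <- runif(1, -180, 180)
    a <- -ang * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    pos_r <- pos %*% t(R)
    h_r <- h + ang
    expect_equal(polarization(h_r), p0, tolerance = 1e-9)
    expect_equal(rotation(pos_r, h_r), m0, tolerance = 1e-9)
  }
})

test_that("group finding equals brute-force transitive closure", {
  # chain at 0, 80, 160 with perception 100: one group of three
  chain <- rbind(c(0, 0), c(80, 0), c(160, 0))
  gp <- find_groups(chain, 100)
  expect_equal(length(gp$groups), 1L)
  expect_equal(sort(gp$groups[[1]]), 1:3)
  # distant agent is a straggler
  four <- rbind(chain, c(700, 0))
  gp2 <- find_groups(four, 100)
  expect_equal(gp2$stragglers, 4L)
  # oracle equivalence on random instances
  set.seed(202)
  for (i in 1:60) {
    n <- sample(2:60, 1)
    pos <- matrix(runif(2 * n, 0, 500), n, 2)
    d <- runif(1, 20, 200)
    lab <- find_groups(pos, d)$membership
    ref <- oracle_groups(pos, d)
    # same partition up to label names
    expect_equal(outer(lab, lab, "=="), outer(ref, ref, "=="))
  }
})

test_that("state classification follows the printed thresholds", {
  expect_identical(classify_state(0.9, 0.1), "P")
  expect_identical(classify_state(0.1, 0.9), "M")
  expect_identical(classify_state(0.1, 0.1), "S")
  expect_identical(classify_state(0.5, 0.5), "T")
  # boundary values are transition (strict inequalities)
  expect_identical(classify_state(0.65, 0.1), "T")
  expect_identical(classify_state(0.35, 0.35), "T")
  # total on a grid of the unit square
  g <- expand.grid(p = seq(0, 1, 0.05), m = seq(0, 1, 0.05))
  expect_true(all(classify_state(g$p, g$m) %in% c("P", "M", "S", "T")))
})

test_that("local density counts neighbours within the radius", {
  spread <- rbind(c(0, 0), c(500, 0), c(0, 500))
  expect_equal(local_density(spread, 100)$mean, 0)
  stacked <- matrix(0, 5, 2)
  expect_equal(local_density(stacked, 10)$counts, rep(4L, 5))
  set.seed(203)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    pos <- matrix(runif(2 * n, 0, 400), n, 2)
    r <- runif(1, 10, 150)
    expect_equal(local_density(pos, r)$counts,
                 unname(oracle_density(pos, r)))
  }
  # pluggable measure
  inv <- local_density(spread, 100, measure = function(p, r) rep(1, nrow(p)))
  expect_equal(inv$mean, 1)
})

test_that("state time is split equally across concurrent groups", {
  expect_equal(state_time_proportions(list("P", c("P", "M"))),
               c(P = 0.75, M = 0.25, S = 0, T = 0))
  expect_equal(state_time_proportions(list(c("P", "M", "S")))[c("P", "M", "S")],
               c(P = 1, M = 1, S = 1) / 3)
  expect_equal(unname(state_time_proportions(list("P", "P", "P"))["P"]), 1)
  # zero-group steps reduce the denominator
  expect_equal(state_time_proportions(list("M", character(0), "M")),
               c(P = 0, M = 1, S = 0, T = 0))
  # fractions always sum to one
  set.seed(204)
  for (i in 1:20) {
    steps <- replicate(30, sample(c("P", "M", "S", "T"), sample(0:4, 1),
                                  replace = TRUE), simplify = FALSE)
    if (all(lengths(steps) == 0)) next
    expect_equal(sum(state_time_proportions(steps)), 1)
  }
})

test_that("bootstrap CI is reproducible, degenerate on constants, covers the mean", {
  expect_equal(bootstrap_ci(rep(3.5, 10), 200), c(3.5, 3.5))
  set.seed(205)
  a <- bootstrap_ci(rnorm(50), 500)
  set.seed(205)
  b <- bootstrap_ci(rnorm(50), 500)
  expect_identical(a, b)
  set.seed(206)
  hits <- 0
  for (i in 1:50) {
    x <- rnorm(40)
    ci <- bootstrap_ci(x, 400)
    expect_lt(ci[1], ci[2])
    if (mean(x) >= ci[1] && mean(x) <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 49)
})

test_that("scripted scenes are classified P / M / S", {
  lane <- make_parallel(36, spacing = 12)
  expect_identical(classify_state(polarization(lane$headings),
                                  rotation(lane$positions, lane$headings)),
                   "P")
  ring <- make_mill(36, radius = 60)
  expect_identical(classify_state(polarization(ring$headings),
                                  rotation(ring$positions, ring$headings)),
                   "M")
  set.seed(207)
  blob <- make_swarm(200, radius = 120)
  expect_identical(classify_state(polarization(blob$headings),
                                  rotation(blob$positions, blob$headings)),
                   "S")
})

test_that("trajectory metrics carry group and global rows per recorded step", {
  set.seed(208)
  cfg <- world_config(n_prey = 25, n_predators = 0)
  sim <- simulate_world(cfg, steps = 30, mode = "evolve", record_every = 10)
  mm <- trajectory_metrics(sim)
  expect_true(all(c("GLOBAL") %in% mm$group_id))
  glob <- mm[mm$group_id == "GLOBAL", ]
  expect_equal(glob$step, sim$snapshots$step)
  expect_true(all(mm$polarization >= 0 & mm$polarization <= 1))
  expect_true(all(mm$rotation >= 0 & mm$rotation <= 1))
  expect_true(all(mm$state %in% c("P", "M", "S", "T")))
  # group rows match an independent find_groups pass on the same snapshot
  last <- sim$snapshots$prey[[length(sim$snapshots$prey)]]
  gp <- find_groups(last[, 2:3])
  expect_equal(sum(mm$step == max(mm$step)) - 1, length(gp$groups))
})

test_that("the validation protocol gates the predator at its introduction step", {
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  pool <- rep(list(rb), 20)
  cfg <- world_config(n_prey = 20, initial_energy = 5000, spawn_radius = 50)
  vc <- validation_config(replicates = 2, stabilisation = 40,
                          predator_introduction = 120, total = 200)
  set.seed(209)
  val <- run_validation(pool, cfg, vc)
  expect_s3_class(val, "flock_validation")
  expect_equal(sort(unique(val$metrics$replicate)), 1:2)
  expect_true(all(val$metrics$phase[val$metrics$step < 120] == "no_predator"))
  expect_true(all(val$metrics$phase[val$metrics$step >= 120] == "predator"))
  # state-time proportions sum to one in each phase
  for (ph in c("no_predator", "predator")) {
    st <- val$summary[[ph]]$state_time
    if (!anyNA(st)) expect_equal(sum(st), 1)
  }
  expect_true(val$summary$behaviour_class %in% c("P", "M", "S", "D"))
})

test_that("an all-parallel no-turn pool stays fully polarized while undisturbed", {
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  pool <- rep(list(rb), 16)
  lane <- make_parallel(16, spacing = 15, heading = 90)
  cfg <- world_config(n_prey = 16, initial_energy = 10000)
  vc <- validation_config(replicates = 1, stabilisation = 20,
                          predator_introduction = 60, total = 80)
  set.seed(210)
  val <- run_validation(pool, cfg, vc, init = list(
    positions = lane$positions, headings = lane$headings))
  pre <- val$metrics[val$metrics$phase == "no_predator" &
                     val$metrics$group_id == "GLOBAL", ]
  expect_true(all(pre$polarization == 1))
})

test_that("the group-size experiment emits bounded order parameters per size", {
  rb <- rule_base(fuzzy_rule(c(interaction.distance = "far"), "none"))
  pool <- rep(list(rb), 10)
  set.seed(211)
  gs <- group_size_experiment(pool, sizes = c(5, 10), replicates = 2,
                              cfg = world_config(n_prey = 5),
                              steps = 60, record_start = 30)
  expect_equal(nrow(gs), 2 * 2 * 31)
  expect_true(all(gs$polarization >= 0 & gs$polarization <= 1))
  expect_true(all(gs$rotation >= 0 & gs$rotation <= 1))
  expect_equal(sort(unique(gs$size)), c(5, 10))
})
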