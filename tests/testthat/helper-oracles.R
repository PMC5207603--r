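# Independent reference implementations used as oracles.  These are written
# in plain R directly from the defining formulas, independent of the C++
# inference path.

# triangular membership, straight from the defining max(min(...), 0) form
oracle_tri <- function(x, l, m, r) {
  left <- if (m > l) (x - l) / (m - l) else ifelse(x >= m, Inf, -Inf)
  right <- if (r > m) (r - x) / (r - m) else ifelse(x <= m, Inf, -Inf)
  pmin(pmax(pmin(left, right), 0), 1)
}

# periodic triangular membership by explicit shifting of x over one period
oracle_ptri <- function(x, l, m, r, c = 360) {
  mm <- l + ((m - l) %% c)
  rr <- mm + ((r - m) %% c)
  xx <- l + ((x - l) %% c)
  oracle_tri(xx, l, mm, rr)
}

# value parameters from the data base
db_params <- function(variable, value) {
  db <- fuzzy_database()
  db[db$variable == variable & db$value == value, ]
}

# fine-grid trapezoid centre of gravity for an aggregate of (activation,
# consequent value) pairs, computed at `factor` times the engine resolution
oracle_centroid <- function(activations, consequents, resolution = 0.25,
                            factor = 10) {
  xs <- seq(-180, 180, by = resolution / factor)
  mu <- rep(0, length(xs))
  for (k in seq_along(activations)) {
    p <- db_params("action.heading_change", consequents[k])
    scaled <- activations[k] * oracle_tri(xs, p$l, p$m, p$r)
    mu <- mu + scaled - mu * scaled  # probabilistic sum
  }
  den <- sum(diff(xs) * (mu[-1] + mu[-length(mu)])) / 2
  if (den < 1e-12) return(0)
  xm <- xs * mu
  num <- sum(diff(xs) * (xm[-1] + xm[-length(xm)])) / 2
  num / den
}

# transitive closure grouping by repeated boolean matrix products
oracle_groups <- function(positions, perception) {
  n <- nrow(positions)
  adj <- as.matrix(stats::dist(positions)) < perception
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% adj) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  nxt_lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nxt_lab <- nxt_lab + 1L
      labels[reach[i, ]] <- nxt_lab
    }
  }
  labels
}

# brute-force neighbour counts
oracle_density <- function(positions, radius) {
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  rowSums(d < radius)
}

# nearest point on the square perimeter by dense sampling
oracle_border <- function(pos, side, k = 200000) {
  half <- side / 2
  t <- seq(0, 4, length.out = k + 1)[-(k + 1)]
  seg <- floor(t)
  f <- t - seg
  px <- ifelse(seg == 0, -half + f * side,
        ifelse(seg == 1, half,
        ifelse(seg == 2, half - f * side, -half)))
  py <- ifelse(seg == 0, -half,
        ifelse(seg == 1, -half + f * side,
        ifelse(seg == 2, half, half - f * side)))
  d <- sqrt((px - pos[1])^2 + (py - pos[2])^2)
  i <- which.min(d)
  list(point = c(px[i], py[i]), distance = d[i])
}

# random perception inputs honouring the joint-nullability invariant
random_inputs <- function() {
  perception_input(
    interaction = if (runif(1) < 0.7) c(runif(1, 0, 100), runif(1, -180, 180),
                                        runif(1, -180, 180)),
    predator = if (runif(1) < 0.5) c(runif(1, 0, 100), runif(1, -180, 180),
                                     runif(1, -180, 180)),
    living_area = if (runif(1) < 0.5) c(runif(1, 0, 100), runif(1, -180, 180))
  )
}

# mirror a rule base across the agent's axis: swap left/right antecedent
# values and mirror the consequents
mirror_rule_base <- function(rb) {
  flip_val <- function(v) switch(v, left = "right", right = "left", v)
  flip_out <- function(v) switch(v,
    "hard left" = "hard right", "left" = "right",
    "right" = "left", "hard right" = "hard left", v)
  rule_base(lapply(unclass(rb), function(r) {
    ants <- vapply(r$antecedents, function(v) flip_val(v), character(1))
    names(ants) <- names(r$antecedents)
    fuzzy_rule(ants, flip_out(r$consequent))
  }))
}

# mirror a perception input vector (negate all angular slots)
mirror_inputs <- function(inputs) {
  ang <- c(2, 3, 5, 6, 8)
  w <- function(a) { r <- a %% 360; r[!is.na(r) & r > 180] <- r[!is.na(r) & r > 180] - 360; r }
  inputs[ang] <- w(-inputs[ang])
  inputs
}
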