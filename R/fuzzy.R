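# Linguistic fuzzy rule-based system: fixed data base, rule representation,
# Mamdani inference (product t-norm, probabilistic-sum aggregation,
# centre-of-gravity defuzzification).

.db_cache <- new.env(parent = emptyenv())

#' The prey agent fuzzy data base
#'
#' The fixed decomposition of the eight input variables (interacting
#' conspecific, nearest predator and living-area border, each described by
#' distance and angles) and of the single output variable
#' (`action.heading_change`) into linguistic values.  Each value is a
#' triangular fuzzy number `<l, m, r>`; the `behind`/`opposite` angular
#' values are periodic with period 360.  Distance universes run from 0 to
#' 100 (inputs are clamped), angular universes over (-180, 180].
#'
#' @return A data frame with columns `variable`, `value`, `l`, `m`, `r`,
#'   `periodic`.
#' @export
#' @examples
#' db <- fuzzy_database()
#' subset(db, variable == "action.heading_change")
fuzzy_database <- function() {
  if (is.null(.db_cache$db)) .db_cache$db <- cpp_database()
  .db_cache$db
}

# named list: variable -> character vector of its value names
.db_values <- function() {
  if (is.null(.db_cache$values)) {
    db <- fuzzy_database()
    .db_cache$values <- split(db$value, factor(db$variable, levels = unique(db$variable)))
  }
  .db_cache$values
}

#' Triangular membership function
#'
#' Membership degree of `x` in the triangular fuzzy number `<l, m, r>`,
#' piecewise linear with peak 1 at `m` and support `[l, r]`.  A zero-width
#' side (`l == m` or `m == r`) is treated as a crisp shoulder: membership is
#' 1 at the boundary on the degenerate side.
#'
#' @param x numeric vector of crisp inputs.
#' @param l,m,r triangle parameters, `l <= m <= r`.
#' @return Membership degrees in `[0, 1]`.
#' @export
#' @examples
#' tri_membership(-126, -180, -90, 0) # 0.6
tri_membership <- function(x, l, m, r) {
  stopifnot(l <= m, m <= r)
  cpp_tri_mf(as.numeric(x), l, m, r)
}

#' Periodic triangular membership function
#'
#' Membership in a triangular fuzzy number wrapped on a circular universe of
#' period `c`, so that membership is invariant under `x -> x + c`.  Used for
#' the `behind`/`opposite` angular values `<90, 180, -90>` with period 360.
#'
#' @param x numeric vector of crisp inputs (degrees).
#' @param l,m,r triangle parameters on the circle.
#' @param c period, default 360.
#' @return Membership degrees in `[0, 1]`.
#' @export
#' @examples
#' periodic_membership(-126, 90, 180, -90) # 0.4
periodic_membership <- function(x, l, m, r, c = 360) {
  stopifnot(c > 0)
  cpp_ptri_mf(as.numeric(x), l, m, r, c)
}

#' Construct a fuzzy if-then rule
#'
#' @param antecedents named character vector: names are input variables of
#'   the data base, values their linguistic values; 1 to 4 antecedents over
#'   distinct variables.
#' @param consequent one heading-change value (`"hard left"`, `"left"`,
#'   `"none"`, `"right"`, `"hard right"`).
#' @return A `fuzzy_rule` object.
#' @export
#' @examples
#' fuzzy_rule(c(predator.relative_bearing = "left"), "right")
fuzzy_rule <- function(antecedents, consequent) {
  vars <- names(antecedents)
  vals <- .db_values()
  if (is.null(vars) || any(!nzchar(vars)))
    stop("antecedents must be a named character vector", call. = FALSE)
  if (length(antecedents) < 1 || length(antecedents) > 4)
    stop("a rule takes 1 to 4 antecedents", call. = FALSE)
  if (anyDuplicated(vars))
    stop("antecedent variables must be distinct within a rule", call. = FALSE)
  for (k in seq_along(antecedents)) {
    if (!vars[k] %in% .input_vars)
      stop("unknown input variable: ", vars[k], call. = FALSE)
    if (!antecedents[[k]] %in% vals[[vars[k]]])
      stop("unknown value '", antecedents[[k]], "' for variable ", vars[k],
           call. = FALSE)
  }
  if (!consequent %in% .heading_change_values)
    stop("unknown heading-change value: ", consequent, call. = FALSE)
  structure(list(antecedents = antecedents, consequent = consequent),
            class = "fuzzy_rule")
}

#' Construct a fuzzy rule base
#'
#' A prey agent's evolvable chromosome: an ordered list of if-then rules
#' over the fixed data base.  Duplicate rules are permitted (multiset
#' semantics, required by joint-set crossover).
#'
#' @param rules list of [fuzzy_rule()] objects (or a single rule).
#' @param cap upper bound on the number of rules (default 50).
#' @return A `fuzzy_rulebase` object.
#' @export
rule_base <- function(rules, cap = 50) {
  if (inherits(rules, "fuzzy_rule")) rules <- list(rules)
  if (length(rules) < 1) stop("a rule base holds at least one rule", call. = FALSE)
  if (length(rules) > cap)
    stop("a rule base holds at most ", cap, " rules", call. = FALSE)
  for (r in rules) if (!inherits(r, "fuzzy_rule"))
    stop("all elements must be fuzzy_rule objects", call. = FALSE)
  structure(rules, class = "fuzzy_rulebase")
}

# ---- integer encoding shared with the C++ engine --------------------------

.rule_encode <- function(rule) {
  vals <- .db_values()
  row <- rep(-1L, 9L)
  vars <- names(rule$antecedents)
  for (k in seq_along(vars)) {
    vi <- match(vars[k], .input_vars) - 1L
    li <- match(rule$antecedents[[k]], vals[[vars[k]]]) - 1L
    row[2 * k - 1] <- vi
    row[2 * k] <- li
  }
  row[9] <- match(rule$consequent, .heading_change_values) - 1L
  row
}

.rb_encode <- function(rb) {
  m <- t(vapply(unclass(rb), .rule_encode, integer(9)))
  dim(m) <- c(length(rb), 9L)
  storage.mode(m) <- "integer"
  m
}

.rule_decode <- function(row) {
  vals <- .db_values()
  ants <- character(0)
  for (k in 1:4) {
    vi <- row[2 * k - 1]
    if (vi < 0) next
    var <- .input_vars[vi + 1]
    ants[var] <- vals[[var]][row[2 * k] + 1]
  }
  fuzzy_rule(ants, .heading_change_values[row[9] + 1])
}

.rb_decode <- function(m) {
  rule_base(lapply(seq_len(nrow(m)), function(i) .rule_decode(m[i, ])))
}

# ---- inference ------------------------------------------------------------

#' Assemble the crisp perception input vector
#'
#' The eight nullable singleton inputs a prey agent perceives on one update
#' step.  The three interaction inputs are jointly null or jointly present;
#' likewise the three predator inputs and the two living-area inputs.
#'
#' @param interaction numeric `c(distance, bearing, heading)` or `NULL`.
#' @param predator numeric `c(distance, bearing, heading)` or `NULL`.
#' @param living_area numeric `c(distance, bearing)` or `NULL`.
#' @return A named numeric vector of length 8 with `NA` for null variables.
#' @export
#' @examples
#' perception_input(predator = c(50, -126, 0))
perception_input <- function(interaction = NULL, predator = NULL,
                             living_area = NULL) {
  out <- rep(NA_real_, 8)
  names(out) <- .input_vars
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 3)
    out[1:3] <- interaction
  }
  if (!is.null(predator)) {
    stopifnot(length(predator) == 3)
    out[4:6] <- predator
  }
  if (!is.null(living_area)) {
    stopifnot(length(living_area) == 2)
    out[7:8] <- living_area
  }
  dists <- out[c(1, 4, 7)]
  if (any(!is.na(dists) & dists < 0)) stop("distances must be >= 0", call. = FALSE)
  out
}

.as_inputs <- function(inputs) {
  if (!is.null(names(inputs)) && all(.input_vars %in% names(inputs)))
    inputs <- inputs[.input_vars]
  stopifnot(length(inputs) == 8)
  as.numeric(inputs)
}

#' Rule activation degree
#'
#' Product t-norm over the rule's antecedent membership degrees; exactly 0
#' when any antecedent variable is null in the inputs, so that rules
#' mentioning an unperceived aspect of the world do not fire.
#'
#' @param rule a [fuzzy_rule()].
#' @param inputs a [perception_input()] vector.
#' @return Activation degree in `[0, 1]`.
#' @export
rule_activation <- function(rule, inputs) {
  m <- .rb_encode(rule_base(rule))
  as.numeric(cpp_activations(m, .as_inputs(inputs)))
}

#' Aggregate activated consequents into an output fuzzy set
#'
#' Product implication scales each consequent's triangular value by its
#' rule's activation; the scaled sets are combined pointwise with the
#' probabilistic sum s-norm (`x + y - xy`) on a uniform grid over
#' `[-180, 180]`.
#'
#' @param activations numeric vector of activation degrees in `[0, 1]`.
#' @param consequents character vector of heading-change value names, same
#'   length as `activations`.
#' @param resolution grid spacing in degrees (default 0.25).
#' @return A `fuzzy_curve`: list with `x` (grid) and `mu` (membership).
#' @export
aggregate_consequents <- function(activations, consequents,
                                  resolution = 0.25) {
  stopifnot(length(activations) == length(consequents),
            all(activations >= 0), all(activations <= 1))
  ci <- match(consequents, .heading_change_values) - 1L
  if (anyNA(ci)) stop("unknown heading-change value", call. = FALSE)
  out <- cpp_aggregate(as.numeric(activations), as.integer(ci), resolution)
  structure(out, class = "fuzzy_curve")
}

#' Centre-of-gravity defuzzification
#'
#' Crisp output of a sampled membership curve by trapezoidal quadrature of
#' `integral(x * mu) / integral(mu)`.  An identically-zero curve (no rule
#' fired) defuzzifies to 0, the neutral "no turn" action.
#'
#' @param curve a `fuzzy_curve` from [aggregate_consequents()], or a list
#'   with components `x` and `mu`.
#' @return Crisp value in degrees.
#' @export
centroid_defuzzify <- function(curve) {
  x <- curve$x
  mu <- curve$mu
  stopifnot(length(x) == length(mu), all(mu >= 0))
  dx <- diff(x)
  den <- sum(dx * (mu[-1] + mu[-length(mu)])) / 2
  if (den < 1e-12) return(0)
  xm <- x * mu
  num <- sum(dx * (xm[-1] + xm[-length(xm)])) / 2
  num / den
}

#' Fuzzy inference of the desired heading change
#'
#' Full Mamdani pipeline: rule activation (product t-norm, null gating),
#' product implication, probabilistic-sum aggregation and centre-of-gravity
#' defuzzification.  Returns 0 when no rule fires.
#'
#' @param rb a [rule_base()].
#' @param inputs a [perception_input()] vector.
#' @param resolution defuzzification grid spacing in degrees (default 0.25).
#' @return Desired heading change in degrees, in `[-180, 180]`; positive
#'   values turn right.
#' @export
#' @examples
#' rb <- rule_base(list(
#'   fuzzy_rule(c(predator.relative_bearing = "left"), "right"),
#'   fuzzy_rule(c(predator.relative_bearing = "behind"), "none")
#' ))
#' infer_heading_change(rb, perception_input(predator = c(50, -126, 0)))
infer_heading_change <- function(rb, inputs, resolution = 0.25) {
  cpp_infer(.rb_encode(rb), .as_inputs(inputs), resolution)
}

# ---- printing -------------------------------------------------------------

.pretty_var <- function(v) gsub("[._]", " ", v)

#' @export
format.fuzzy_rule <- function(x, ...) {
  ants <- paste(sprintf("%s IS %s", .pretty_var(names(x$antecedents)),
                        unlist(x$antecedents)),
                collapse = " AND ")
  sprintf("IF %s THEN heading change IS %s", ants, x$consequent)
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.fuzzy_rulebase <- function(x, ...) {
  vapply(unclass(x), format, character(1))
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat(sprintf("<fuzzy rule base: %d rules>\n", length(x)))
  cat(paste0("  ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

# ---- JSON serialization ---------------------------------------------------

.rb_to_list <- function(rb) {
  list(rules = lapply(unclass(rb), function(r) {
    list(
      "if" = lapply(seq_along(r$antecedents), function(k)
        c(names(r$antecedents)[k], r$antecedents[[k]])),
      "then" = r$consequent
    )
  }))
}

.rb_from_list <- function(obj) {
  rules <- lapply(obj$rules, function(r) {
    pairs <- r[["if"]]
    ants <- vapply(pairs, function(p) p[[2]], character(1))
    names(ants) <- vapply(pairs, function(p) p[[1]], character(1))
    fuzzy_rule(ants, r[["then"]])
  })
  rule_base(rules)
}

#' Write / read a single rule base as JSON
#'
#' Format: `{"rules": [{"if": [["variable", "value"], ...],
#' "then": "<heading change value>"}, ...]}`.  The reader validates every
#' name against the fuzzy data base.
#'
#' @param rb a [rule_base()].
#' @param path file path.
#' @return `write_rule_base` returns `path` invisibly; `read_rule_base`
#'   returns a `fuzzy_rulebase`.
#' @export
write_rule_base <- function(rb, path) {
  jsonlite::write_json(.rb_to_list(rb), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rule_base
#' @export
read_rule_base <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  .rb_from_list(obj)
}

#' Write / read a pool of rule bases as JSON
#'
#' A pool is the set of rule bases of the currently-live prey; the
#' end-of-run pool is the evolved behaviour.  The file carries the rule
#' bases plus a metadata block (seed, steps, config hash) for traceability.
#'
#' @param pool list of `fuzzy_rulebase` objects.
#' @param path file path.
#' @param meta named list of run metadata stored alongside the pool.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   list with `pool` and `meta`.
#' @export
write_pool <- function(pool, path, meta = list()) {
  meta$package <- as.character(packageVersion("fuzzyflock"))
  obj <- list(meta = meta, rule_bases = lapply(pool, .rb_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(pool = lapply(obj$rule_bases, .rb_from_list), meta = obj$meta)
}
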