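# Summary statistics of evolved rule bases: attention proportions,
# specificity, turning bias and size.

.aspect_of <- function(vars) {
  out <- rep("prey", length(vars))
  out[startsWith(vars, "predator")] <- "predator"
  out[startsWith(vars, "living_area")] <- "living_area"
  out
}

#' Attention proportions of a rule base
#'
#' Average proportion of rule antecedents devoted to each aspect of the
#' world: the living-area border, the nearest predator, and the
#' interacting conspecific.  For each rule the per-aspect antecedent count
#' is divided by the rule's antecedent count, then averaged over rules; the
#' three proportions sum to 1.  Equal attention to every input variable
#' gives 2/8 for the living area (two variables) and 3/8 for predator and
#' prey (three variables each).
#'
#' @param rb a `fuzzy_rulebase`.
#' @return Named numeric `c(living_area, predator, prey)`.
#' @export
attention_proportions <- function(rb) {
  stopifnot(length(rb) >= 1)
  acc <- c(living_area = 0, predator = 0, prey = 0)
  for (r in unclass(rb)) {
    asp <- .aspect_of(names(r$antecedents))
    for (a in names(acc)) acc[a] <- acc[a] + sum(asp == a) / length(asp)
  }
  acc / length(rb)
}

#' Rule-base specificity
#'
#' Mean of `(a_i - 1) / (m - 1)` over rules, where `a_i` is the antecedent
#' count of rule `i` and `m` the maximum antecedent count: 0 when every
#' rule uses a single antecedent (very general rules), 1 when every rule
#' uses the maximum (highly specific rules).
#'
#' @param rb a `fuzzy_rulebase`.
#' @param max_antecedents the bound `m` (default 4).
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(rb, max_antecedents = 4) {
  stopifnot(length(rb) >= 1, max_antecedents > 1)
  a <- vapply(unclass(rb), function(r) length(r$antecedents), numeric(1))
  mean((a - 1) / (max_antecedents - 1))
}

# centroid of a heading-change value's triangle, (l + m + r) / 3
.consequent_centroid <- function(value) {
  db <- fuzzy_database()
  row <- db[db$variable == "action.heading_change" & db$value == value, ]
  (row$l + row$m + row$r) / 3
}

#' Turning-side bias of a rule base
#'
#' Rough approximation of the prey's turning preference:
#' `beta = 1/(2n) * sum(1 + o_i / 180)` where `o_i` is the centroid of the
#' consequent value of rule `i`.  Values below 0.5 indicate a left-turn
#' bias, above 0.5 a right-turn bias.
#'
#' @param rb a `fuzzy_rulebase`.
#' @return Bias in `[0, 1]`.
#' @export
turning_bias <- function(rb) {
  stopifnot(length(rb) >= 1)
  o <- vapply(unclass(rb), function(r) .consequent_centroid(r$consequent),
              numeric(1))
  mean(1 + o / 180) / 2
}

#' Rule-base size fraction
#'
#' Number of rules divided by the maximum number of rules possible.
#'
#' @param rb a `fuzzy_rulebase`.
#' @param upper the rule-base upper bound (default 50).
#' @return Size in `(0, 1]`.
#' @export
size_fraction <- function(rb, upper = 50) {
  stopifnot(length(rb) >= 1)
  length(rb) / upper
}

#' Summarize a pool of rule bases
#'
#' One row per rule base with the six summary parameters (three attention
#' proportions, specificity, bias, size), plus the pool medians of each
#' parameter.  The table is analysis-ready for external statistical
#' comparison across behaviour classes.
#'
#' @param pool list of `fuzzy_rulebase`.
#' @param max_antecedents specificity bound `m`.
#' @param upper rule-base size bound.
#' @param class optional behaviour class label attached to every row.
#' @return A `pool_summary`: list with `parameters` (data frame) and
#'   `medians` (named numeric).
#' @export
summarize_pool <- function(pool, max_antecedents = 4, upper = 50,
                           class = NA_character_) {
  rows <- lapply(seq_along(pool), function(i) {
    rb <- pool[[i]]
    att <- attention_proportions(rb)
    data.frame(pool_id = i, class = class, n_rules = length(rb),
               rho_living_area = att[["living_area"]],
               rho_predator = att[["predator"]],
               rho_prey = att[["prey"]],
               specificity = specificity(rb, max_antecedents),
               bias = turning_bias(rb),
               size = size_fraction(rb, upper))
  })
  parameters <- do.call(rbind, rows)
  num <- c("rho_living_area", "rho_predator", "rho_prey", "specificity",
           "bias", "size")
  medians <- vapply(parameters[num], median, numeric(1))
  structure(list(parameters = parameters, medians = medians),
            class = "pool_summary")
}

#' @export
print.pool_summary <- function(x, ...) {
  cat(sprintf("<pool_summary: %d rule bases>\nmedians:\n",
              nrow(x$parameters)))
  print(round(x$medians, 4))
  invisible(x)
}
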