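# Scenario modelling. Fortification modifies the daily recall records
# *before* model fitting (add-then-shrink, because fortification changes
# what a 24-h recall would capture). Supplement programs and fixed additions
# (breast milk, reported supplements) modify the simulated usual intakes
# *after* fitting (shrink-then-add, because their temporal scope is already
# "usual"). The pipeline enforces this ordering structurally regardless of
# the order scenarios are listed.

#' Intervention scenario specifications
#'
#' * `fortification(vehicle, level)`: adds `level` nutrient units per gram of
#'   the named fortifiable-vehicle column to every recall's intake.
#' * `supplement_program(dose, coverage, eligible, label)`: each eligible
#'   pseudo-person independently receives `dose` units/day with probability
#'   `coverage` (seeded Bernoulli; assignment is independent of food intake,
#'   as for a program reaching a random sample of the target population).
#' * `fixed_addition(amounts, key, eligible, label)`: adds a deterministic
#'   amount looked up by `key` (a stratum or person-id column) to eligible
#'   pseudo-persons; used for breast-milk contributions or reported
#'   supplement use with group- or individual-level amounts.
#'
#' `eligible` is `NULL` (everyone) or a `function(df) -> logical` over the
#' pseudo-population's columns.
#'
#' @param vehicle name of the vehicle column (without any `vehicle_` prefix
#'   handling; pass the column name as stored).
#' @param level nutrient units per gram of vehicle, >= 0.
#' @param dose daily dose, nutrient units/day, >= 0.
#' @param coverage program coverage probability in \[0, 1\].
#' @param eligible eligibility predicate or `NULL`.
#' @param label scenario label; seeds the program's random stream, so two
#'   programs with different labels draw independently.
#' @param amounts named numeric vector (names = key values) or data.frame
#'   with columns `key`, `amount`.
#' @param key column of the pseudo-population to look amounts up by
#'   (e.g. `"stratum"` or `"source_person_id"`).
#' @return an `intervention_spec`.
#' @export
fortification <- function(vehicle, level, label = paste0("fort_", vehicle)) {
  stopifnot(is.character(vehicle), length(vehicle) == 1L,
            is.numeric(level), length(level) == 1L)
  if (level < 0) stop("fortification level must be >= 0", call. = FALSE)
  structure(list(kind = "fortification", vehicle = vehicle, level = level,
                 label = label), class = "intervention_spec")
}

#' @rdname fortification
#' @export
supplement_program <- function(dose, coverage, eligible = NULL,
                               label = "supplement_program") {
  stopifnot(is.numeric(dose), length(dose) == 1L,
            is.numeric(coverage), length(coverage) == 1L)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]", call. = FALSE)
  stopifnot(is.null(eligible) || is.function(eligible))
  structure(list(kind = "supplement_program", dose = dose,
                 coverage = coverage, eligible = eligible, label = label),
            class = "intervention_spec")
}

#' @rdname fortification
#' @export
fixed_addition <- function(amounts, key, eligible = NULL,
                           label = "fixed_addition") {
  if (is.data.frame(amounts)) {
    stopifnot(all(c("key", "amount") %in% names(amounts)))
    amounts <- stats::setNames(amounts$amount, amounts$key)
  }
  stopifnot(is.numeric(amounts), !is.null(names(amounts)))
  if (any(amounts < 0)) stop("amounts must be >= 0", call. = FALSE)
  stopifnot(is.null(eligible) || is.function(eligible))
  structure(list(kind = "fixed_addition", amounts = amounts, key = key,
                 eligible = eligible, label = label),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("<intervention_spec> ", x$kind, " [", x$label, "]\n", sep = "")
  invisible(x)
}

#' Apply a fortification scenario to recall records
#'
#' Returns a new dataset with `intake' = intake + vehicle_grams x level` for
#' every recall; the input is untouched. Must be applied before model
#' fitting (add-then-shrink) — the orchestrated pipeline does this
#' automatically.
#'
#' @param data a [recall_data()].
#' @param spec a [fortification()] spec.
#' @return a new `recall_data`.
#' @export
apply_fortification <- function(data, spec) {
  stopifnot(inherits(data, "recall_data"),
            inherits(spec, "intervention_spec"))
  if (spec$kind != "fortification")
    stop("apply_fortification() needs a fortification spec", call. = FALSE)
  if (!spec$vehicle %in% names(data$recalls))
    stop("vehicle column not found in recall table: ", spec$vehicle,
         call. = FALSE)
  v <- data$vars
  data$recalls[[v$intake]] <- data$recalls[[v$intake]] +
    data$recalls[[spec$vehicle]] * spec$level
  data
}

eligibility_mask <- function(pseudo, eligible) {
  if (is.null(eligible)) rep(TRUE, nrow(pseudo))
  else {
    mask <- eligible(pseudo)
    stopifnot(is.logical(mask), length(mask) == nrow(pseudo))
    mask & !is.na(mask)
  }
}

add_contribution <- function(pseudo, amount, mask) {
  pseudo$supplement_contribution[mask] <-
    pseudo$supplement_contribution[mask] + amount
  pseudo$total_intake <- pseudo$usual_food_intake +
    pseudo$supplement_contribution
  pseudo
}

#' Apply a supplement program to the pseudo-population
#'
#' Eligible pseudo-persons independently receive the program dose with the
#' coverage probability. Draws come from a stream derived from the root
#' `seed` and the spec's `label`, so adding a second scenario never perturbs
#' the first, and reruns are reproducible.
#'
#' @param pseudo a `pseudo_pop`.
#' @param spec a [supplement_program()] spec.
#' @param seed root seed.
#' @return the updated `pseudo_pop` (conservation holds exactly:
#'   `total_intake = usual_food_intake + supplement_contribution`).
#' @export
add_supplement_program <- function(pseudo, spec, seed = 1) {
  stopifnot(inherits(pseudo, "pseudo_pop"),
            inherits(spec, "intervention_spec"))
  if (spec$kind != "supplement_program")
    stop("add_supplement_program() needs a supplement_program spec",
         call. = FALSE)
  mask <- eligibility_mask(pseudo, spec$eligible)
  if (spec$coverage > 0 && any(mask)) {
    takes <- with_seed(derive_seed(seed, paste0("program:", spec$label)),
                       stats::runif(sum(mask)) < spec$coverage)
    idx <- which(mask)[takes]
    pseudo <- add_contribution(pseudo, spec$dose, idx)
  } else {
    pseudo$total_intake <- pseudo$usual_food_intake +
      pseudo$supplement_contribution
  }
  pseudo
}

#' Add fixed amounts (breast milk, reported supplements) to usual intakes
#'
#' Deterministically adds the mapped amount to each eligible pseudo-person,
#' looked up by the spec's key column (stratum for group-level estimates,
#' person id for individual-level data).
#'
#' @inheritParams add_supplement_program
#' @param spec a [fixed_addition()] spec.
#' @export
add_fixed_amounts <- function(pseudo, spec) {
  stopifnot(inherits(pseudo, "pseudo_pop"),
            inherits(spec, "intervention_spec"))
  if (spec$kind != "fixed_addition")
    stop("add_fixed_amounts() needs a fixed_addition spec", call. = FALSE)
  if (!spec$key %in% names(pseudo))
    stop("key column not on the pseudo-population: ", spec$key,
         call. = FALSE)
  mask <- eligibility_mask(pseudo, spec$eligible)
  keys <- as.character(pseudo[[spec$key]][mask])
  unmapped <- setdiff(unique(keys), names(spec$amounts))
  if (length(unmapped))
    stop("eligible persons with unmapped key value(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  amt <- unname(spec$amounts[keys])
  add_contribution(pseudo, amt, which(mask))
}

#' Apply the shrink-then-add scenarios of an ordered list
#' @noRd
apply_additive_specs <- function(pseudo, specs, seed) {
  for (sp in specs) {
    pseudo <- switch(sp$kind,
      supplement_program = add_supplement_program(pseudo, sp, seed = seed),
      fixed_addition = add_fixed_amounts(pseudo, sp),
      stop("not an additive scenario: ", sp$kind, call. = FALSE))
  }
  pseudo
}
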