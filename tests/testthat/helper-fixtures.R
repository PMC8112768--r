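# Shared fixtures, built in code.

# tiny hand-made recall table: 3 persons, 2 recalls each
tiny_recalls <- function() {
  data.frame(
    person_id = rep(c("a", "b", "c"), each = 2),
    recall_index = rep(1:2, 3),
    intake = c(10, 12, 8, 9, 15, 14),
    vehicle_oil = rep(c(10, 0, 5), each = 2),
    sex = rep(c("F", "M", "F"), each = 2),
    age = rep(c(30, 45, 60), each = 2),
    stratum = rep(c("S1", "S1", "S2"), each = 2),
    psu = rep(c("S1-P1", "S1-P2", "S2-P1"), each = 2),
    weight = rep(c(1, 2, 1), each = 2),
    stringsAsFactors = FALSE
  )
}

tiny_data <- function() {
  recall_data(tiny_recalls(), weight = "weight", covariates = c("sex", "age"),
              stratum = "stratum", psu = "psu", vehicles = "vehicle_oil")
}

# directly build a pseudo-population without running the pipeline
make_pseudo <- function(total, weight = rep(1, length(total)),
                        supplement = rep(0, length(total)), ...) {
  extra <- list(...)
  out <- data.frame(source_person_id = sprintf("p%03d", seq_along(total)),
                    weight_share = weight, stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out$usual_food_intake <- total - supplement
  out$supplement_contribution <- supplement
  out$total_intake <- total
  class(out) <- c("pseudo_pop", "data.frame")
  out
}

# calcium-style reference table (EAR/UL switch at age 50)
calcium_refs <- function() {
  reference_table(data.frame(
    sex = c("F", "F"),
    age_min = c(18, 50),
    age_max = c(50, 150),
    status = "none",
    ear = c(800, 1000),
    ul = c(2500, 2000)
  ))
}
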