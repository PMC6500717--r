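# Classed conditions so callers (and the CLI) can distinguish validation
# failures from numerical failures.

plan_error <- function(class, message, ...) {
  stop(errorCondition(message,
                      ...,
                      class = c(class, "reintroplan_error")))
}

is_validation_error <- function(cond) {
  inherits(cond, c("non_square_error", "stage_count_error",
                   "negative_entry_error", "transition_bound_error",
                   "survival_budget_error", "imprimitive_error",
                   "dimension_mismatch_error", "no_breeding_stage_error",
                   "non_positive_total_error", "all_zero_release_error",
                   "no_breeding_stage_error", "goal_error", "input_error"))
}
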