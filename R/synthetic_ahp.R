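#' Simulate ages at death from an adapted Heligman-Pollard schedule
#'
#' Draws integer ages at death by seeded multinomial sampling from the
#' age-at-death distribution implied by an aHP `q(x)` schedule (the class
#' death proportions of its life table, with cohort closure at `max_age`).
#' Because the hump term already contains the anthropogenic component, the
#' sample emulates a stranding record whose total mortality is exactly an
#' aHP curve — the well-specified case for recovery and coverage checks.
#'
#' @param n number of deaths.
#' @param params generating [ahp_params].
#' @param max_age oldest age class.
#' @param hump_offset hump-term age offset (class midpoint 0.5 by default,
#'   matching the fitting convention).
#' @param seed seed.
#' @return an [age_sample].
#' @export
simulate_ahp <- function(n, params, max_age, hump_offset = 0.5, seed = NULL) {
  if (n == 0) return(age_sample(numeric(0)))
  q <- ahp_qx(params, 0:max_age, hump_offset = hump_offset)$total
  q[length(q)] <- 1
  lt <- life_table_from_qx(q)
  ages <- with_substream(seed, "simulate-ahp",
                         sample(lt$x, n, replace = TRUE, prob = lt$d))
  age_sample(ages)
}

#' True mortality schedule of an aHP generator
#'
#' Exact death probabilities and age-at-death pmf for [simulate_ahp].
#'
#' @inheritParams simulate_ahp
#' @return data frame with columns `age`, `f`, `q`.
#' @export
ahp_truth <- function(params, max_age, hump_offset = 0.5) {
  q <- ahp_qx(params, 0:max_age, hump_offset = hump_offset)$total
  q[length(q)] <- 1
  lt <- life_table_from_qx(q)
  data.frame(age = lt$x, f = lt$d, q = q)
}
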