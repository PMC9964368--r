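#' Construct growth records for rearing groups
#'
#' Group-level bookkeeping from a feeding trial: each record is one beaker /
#' group of larvae with start and end total weights, counts and the dry feed
#' consumed over the experiment.
#'
#' @param group character group labels.
#' @param n_start larvae count at start (> 0).
#' @param n_dead number of dead larvae (<= n_start).
#' @param start_weight,end_weight total larval weight, mg, >= 0.
#' @param feed_consumed dry feed consumed, mg (offered minus residual minus
#'   frass; the weekly fresh-carrot water source is not counted as feed).
#' @param days experiment duration in days (> 0).
#' @return data.frame of class `growth_records`.
#' @export
growth_records <- function(group, n_start, n_dead, start_weight, end_weight,
                           feed_consumed, days) {
  df <- data.frame(group = as.character(group),
                   n_start = as.integer(n_start),
                   n_dead = as.integer(n_dead),
                   start_weight = as.numeric(start_weight),
                   end_weight = as.numeric(end_weight),
                   feed_consumed = as.numeric(feed_consumed),
                   days = as.numeric(days),
                   stringsAsFactors = FALSE)
  if (any(df$n_start <= 0)) stop("n_start must be > 0", call. = FALSE)
  if (any(df$n_dead < 0) || any(df$n_dead > df$n_start)) {
    stop("n_dead must be between 0 and n_start", call. = FALSE)
  }
  if (any(df$start_weight < 0) || any(df$end_weight < 0)) {
    stop("weights must be >= 0", call. = FALSE)
  }
  if (any(df$days <= 0)) stop("days must be > 0", call. = FALSE)
  class(df) <- c("growth_records", "data.frame")
  df
}

#' Larval weight gain per larva
#'
#' (total end weight - total start weight) / number of surviving larvae,
#' in mg per larva.
#'
#' @param record a `growth_records` data.frame (vectorised over rows).
#' @return numeric vector, mg per larva.
#' @export
lwgpl <- function(record) {
  surv <- record$n_start - record$n_dead
  if (any(surv <= 0)) stop("no surviving larvae: weight gain per larva ",
                           "undefined", call. = FALSE)
  (record$end_weight - record$start_weight) / surv
}

#' Feed conversion ratio
#'
#' Feed consumed divided by weight gained (dimensionless; lower is more
#' efficient).
#'
#' @inheritParams lwgpl
#' @return numeric vector.
#' @export
fcr <- function(record) {
  gain <- record$end_weight - record$start_weight
  if (any(gain <= 0)) stop("weight gained must be > 0 for FCR",
                           call. = FALSE)
  record$feed_consumed / gain
}

#' Efficiency of conversion of ingested food
#'
#' Weight gained as a percentage of feed consumed; identically 100 / FCR.
#'
#' @inheritParams lwgpl
#' @return numeric vector, %.
#' @export
eci <- function(record) {
  if (any(record$feed_consumed <= 0)) {
    stop("feed consumed must be > 0 for ECI", call. = FALSE)
  }
  100 * (record$end_weight - record$start_weight) / record$feed_consumed
}

#' Specific growth rate
#'
#' (ln(final mean body weight) - ln(initial mean body weight)) / days x 100,
#' in % per day. Body weight is the mean per-larva weight; with equal
#' survivor counts at both ends the ratio of totals gives the same value, so
#' records store totals and counts.
#'
#' @inheritParams lwgpl
#' @return numeric vector, % per day.
#' @export
sgr <- function(record) {
  surv <- record$n_start - record$n_dead
  if (any(surv <= 0)) stop("no surviving larvae", call. = FALSE)
  w0 <- record$start_weight / record$n_start
  w1 <- record$end_weight / surv
  if (any(w0 <= 0) || any(w1 <= 0)) {
    stop("body weights must be > 0 for SGR", call. = FALSE)
  }
  100 * (log(w1) - log(w0)) / record$days
}

#' Survival rate
#'
#' @inheritParams lwgpl
#' @return numeric vector, % of starting larvae alive at the end.
#' @export
survival_rate <- function(record) {
  100 * (record$n_start - record$n_dead) / record$n_start
}

#' All growth metrics for a set of records
#'
#' @inheritParams lwgpl
#' @return data.frame with columns `group`, `lwgpl` (mg/larva), `fcr`,
#'   `eci` (%), `sgr` (%/day), `survival` (%).
#' @export
growth_metrics <- function(record) {
  data.frame(group = record$group,
             lwgpl = lwgpl(record),
             fcr = fcr(record),
             eci = eci(record),
             sgr = sgr(record),
             survival = survival_rate(record),
             stringsAsFactors = FALSE)
}

# ---- diet formulation -----------------------------------------------------

#' Mix component nutrient vectors into a diet
#'
#' Computes the mass-fraction-weighted mean of each nutrient over the diet
#' components — the linear mixing model behind formulating substrates of a
#' target fat content from an oil-rich flour and wheat bran.
#'
#' @param formulation data.frame with columns `name`, `fraction` (mass
#'   fractions summing to 1) and one column per nutrient (% fresh weight).
#' @return named numeric vector of mixed nutrient percentages.
#' @export
mix_nutrients <- function(formulation) {
  fr <- formulation$fraction
  if (is.null(fr) || any(fr < 0)) {
    stop("formulation needs nonnegative 'fraction' column", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("component fractions must sum to 1 (got ", format(sum(fr)), ")",
         call. = FALSE)
  }
  nutr <- setdiff(names(formulation), c("name", "fraction"))
  if (length(nutr) == 0) stop("no nutrient columns", call. = FALSE)
  vapply(nutr, function(cl) sum(fr * formulation[[cl]]), numeric(1))
}

#' Solve the inclusion fraction for a nutrient target
#'
#' For a two-component mix (substrate + base), finds the substrate mass
#' fraction p with p * substrate + (1 - p) * base = target.
#'
#' @param target target nutrient value (e.g. 20.0 for a 20% fat diet).
#' @param substrate_value nutrient value of the pure substrate.
#' @param base_value nutrient value of the base (e.g. wheat bran).
#' @return fraction in `[0, 1]`.
#' @export
solve_inclusion <- function(target, substrate_value, base_value) {
  if (abs(substrate_value - base_value) < 1e-12) {
    stop("substrate and base have the same value: inclusion undetermined",
         call. = FALSE)
  }
  lo <- min(substrate_value, base_value)
  hi <- max(substrate_value, base_value)
  if (target < lo - 1e-9 || target > hi + 1e-9) {
    stop("target ", target, " outside the attainable range [", lo, ", ", hi,
         "]", call. = FALSE)
  }
  (target - base_value) / (substrate_value - base_value)
}

#' Recover component nutrient values from two mixtures
#'
#' Inverse of [mix_nutrients()] for two mixtures of the same substrate/base
#' pair: given (fraction, mixed value) for two diets, solves the 2x2 linear
#' system for the pure substrate and base values.
#'
#' @param mix1,mix2 numeric length-2 vectors `c(fraction, value)`.
#' @return named numeric vector `c(substrate = ..., base = ...)`.
#' @export
solve_component_values <- function(mix1, mix2) {
  f1 <- mix1[[1]]; t1 <- mix1[[2]]
  f2 <- mix2[[1]]; t2 <- mix2[[2]]
  A <- rbind(c(f1, 1 - f1), c(f2, 1 - f2))
  if (abs(det(A)) < 1e-12) {
    stop("mixture fractions coincide: system is singular", call. = FALSE)
  }
  sol <- solve(A, c(t1, t2))
  c(substrate = sol[1], base = sol[2])
}

#' Bundled diet formulation and nutrient tables
#'
#' `diet_formulations()`: substrate inclusion percentages for the fifteen
#' feeding groups (substrate name, substrate %, wheat bran %).
#' `diet_nutrients()`: proximate composition (% fresh weight) of each mixed
#' diet: moisture, protein, fat, carbohydrate, fiber, ash.
#'
#' @return data.frame.
#' @export
diet_formulations <- function() {
  path <- system.file("extdata", "diet_formulations.csv",
                      package = "mealwormNIRS", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname diet_formulations
#' @export
diet_nutrients <- function() {
  path <- system.file("extdata", "diet_nutrients.csv",
                      package = "mealwormNIRS", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
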