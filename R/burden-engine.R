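# Counterfactual cohort construction and the annual fiscal-flow engine.
#
# The control cohort is the observed population split over four BMI
# categories; the intervention cohort reassigns all OAO mass to normal
# weight. The fiscal burden of OAO is the incremental net fiscal effect
# (taxes minus transfers and healthcare) between the two cohorts.

#' Construct a cohort from a stratum table
#'
#' @param strata Stratum data frame.
#' @param role `"control"` or `"intervention"`.
#' @return An object of class `fbod_cohort`.
#' @export
build_cohort <- function(strata, role = c("control", "intervention")) {
  role <- match.arg(role)
  # remember the reference (pre-reassignment) proportions: per-capita
  # healthcare by category is anchored to the control prevalence, so a
  # counterfactual cohort keeps the control cohort's category price tags
  if (!"ref_p_under" %in% names(strata)) {
    strata$ref_p_under <- strata$p_under
    strata$ref_p_normal <- strata$p_normal
    strata$ref_p_over <- strata$p_over
    strata$ref_p_obese <- strata$p_obese
  }
  structure(list(role = role, strata = strata), class = "fbod_cohort")
}

#' Build the counterfactual (intervention) cohort
#'
#' Every stratum's proportions in the OAO categories are set to zero and
#' added to the normal-weight category; population counts are unchanged
#' (mass conservation) and the proportions remain a simplex.
#'
#' @param control An `fbod_cohort` (or stratum data frame).
#' @param oao_set Categories reassigned to normal weight.
#' @return An `fbod_cohort` with `role = "intervention"`.
#' @export
build_intervention_cohort <- function(control,
                                      oao_set = c("overweight", "obese")) {
  .check_oao_set(oao_set)
  if (!inherits(control, "fbod_cohort")) control <- build_cohort(control)
  strata <- control$strata
  for (k in oao_set) {
    col <- .bmi_cols[[k]]
    strata$p_normal <- strata$p_normal + strata[[col]]
    strata[[col]] <- 0
  }
  build_cohort(strata, "intervention")
}

# reassign a fraction f of each OAO category's mass to normal weight
.partial_reassign <- function(strata, oao_set, fraction) {
  for (k in oao_set) {
    col <- .bmi_cols[[k]]
    moved <- fraction * strata[[col]]
    strata$p_normal <- strata$p_normal + moved
    strata[[col]] <- strata[[col]] - moved
  }
  strata
}

.flows <- function(direct = 0, indirect = 0, transfers = 0, healthcare = 0) {
  structure(list(direct_tax = direct, indirect_tax = indirect,
                 transfers = transfers, healthcare = healthcare,
                 net = direct + indirect - transfers - healthcare),
            class = "fbod_flows")
}

# per-stratum, per-BMI-category fiscal flows; the heart of the model
.stratum_flows <- function(s, modifiers, fiscal, oao_set, sickleave_scope,
                           use_elderly_rr, mortality_adjust) {
  sex <- s$sex
  rr <- modifiers$rr_mortality
  if (use_elderly_rr && !is.null(modifiers$rr_mortality_elderly) &&
      s$age_lo >= 65)
    rr <- modifiers$rr_mortality_elderly
  props <- stats::setNames(
    c(s$p_under, s$p_normal, s$p_over, s$p_obese), .bmi_labels)
  ref_props <- if ("ref_p_under" %in% names(s)) {
    stats::setNames(c(s$ref_p_under, s$ref_p_normal, s$ref_p_over,
                      s$ref_p_obese), .bmi_labels)
  } else props

  # per-capita healthcare by category, anchored to the reference
  # prevalence (conserves the control stratum's mean expenditure)
  af <- modifiers$af_healthcare
  mepc_k <- if (af > 0 && sum(ref_props[oao_set]) > 0) {
    adjust_mepc(s$mepc, ref_props, af, oao_set)
  } else {
    # af = 0 or a population with no OAO exposure: nothing to attribute
    stats::setNames(rep(s$mepc, 4), .bmi_labels)
  }

  # OAO-attributable deaths; mid-year convention halves the
  # person-years lost by each death within the year
  paf <- .stratum_oao_paf(props, rr, oao_set)
  deaths_oao <- paf * s$count * s$mortality
  w <- props[oao_set] * rr[oao_set]
  deaths_k <- stats::setNames(rep(0, 4), .bmi_labels)
  if (sum(w) > 0) deaths_k[oao_set] <- deaths_oao * w / sum(w)

  direct <- indirect <- transfers <- healthcare <- 0
  for (k in .bmi_labels) {
    n_k <- s$count * props[[k]]
    if (n_k <= 0) next
    is_oao <- k %in% oao_set
    grp <- if (is_oao) "OAO" else "reference"
    b_e <- if (is_oao) .mod_value(modifiers$beta_employment, sex) else 0
    b_y <- if (is_oao) .mod_value(modifiers$beta_income, sex) else 0
    hr_sl <- if (is_oao) .mod_value(modifiers$hr_sickleave, sex) else 1
    hr_rt <- if (is_oao) .mod_value(modifiers$hr_retirement, sex) else 1

    # adjusted rates and income; the retired are removed from
    # the employment-eligible pool
    p_ret <- adjust_welfare_rate(s$retirement, hr_rt)
    p_ft <- adjust_employment(s$emp_ft, b_e, grp) * (1 - p_ret)
    p_pt <- adjust_employment(s$emp_pt, b_e, grp) * (1 - p_ret)
    p_sl <- adjust_welfare_rate(s$sickleave, hr_sl)
    y_ft <- adjust_income(s$income_ft, b_y, grp)
    y_pt <- adjust_income(s$income_pt, b_y, grp)

    # income aggregation
    lab <- total_income(n_k, p_ft, p_pt, p_sl, p_ret, y_ft, y_pt, fiscal,
                        sickleave_scope)
    surv <- 1
    if (mortality_adjust && is_oao && n_k > 0)
      surv <- max(0, 1 - 0.5 * deaths_k[[k]] / n_k)
    income <- lab$income_total * surv
    transfer <- lab$transfer_income * surv

    # direct tax via the wedge, VAT on disposable + transfer income
    d_tax <- direct_tax(income, fiscal)
    i_tax <- indirect_tax(income - d_tax, transfer, fiscal)

    direct <- direct + d_tax
    indirect <- indirect + i_tax
    transfers <- transfers + transfer
    healthcare <- healthcare + n_k * mepc_k[[k]]
  }
  .flows(direct, indirect, transfers, healthcare)
}

#' Annual fiscal flows of a cohort
#'
#' Aggregates, over all strata and BMI categories, direct tax (tax wedge
#' on labor income), indirect tax (VAT on disposable plus transfer
#' income), pension transfers and healthcare costs. The `net` field is
#' `direct + indirect - transfers - healthcare`.
#'
#' @param cohort An `fbod_cohort` (or stratum data frame, treated as a
#'   control cohort).
#' @param modifiers An `fbod_modifiers` object.
#' @param fiscal An `fbod_fiscal` object.
#' @param oao_set Categories treated as OAO.
#' @param sickleave_scope `"ft_only"` (base case) or `"ft_and_pt"`.
#' @param use_elderly_rr Use `rr_mortality_elderly` for bands at >= 65.
#' @param mortality_adjust If `TRUE` (default), OAO-attributable deaths
#'   remove half a person-year each from the OAO group's labor income and
#'   transfer receipts (mid-year convention).
#' @return An `fbod_flows` object with attribute `by_stratum` (a data
#'   frame of per-stratum flows).
#' @export
annual_fiscal_effect <- function(cohort, modifiers, fiscal,
                                 oao_set = c("overweight", "obese"),
                                 sickleave_scope = c("ft_only", "ft_and_pt"),
                                 use_elderly_rr = FALSE,
                                 mortality_adjust = TRUE) {
  sickleave_scope <- match.arg(sickleave_scope)
  .check_oao_set(oao_set)
  strata <- if (inherits(cohort, "fbod_cohort")) cohort$strata else cohort
  per <- lapply(seq_len(nrow(strata)), function(i) {
    fl <- .stratum_flows(strata[i, ], modifiers, fiscal, oao_set,
                         sickleave_scope, use_elderly_rr, mortality_adjust)
    data.frame(age_lo = strata$age_lo[i], age_hi = strata$age_hi[i],
               sex = strata$sex[i], direct_tax = fl$direct_tax,
               indirect_tax = fl$indirect_tax, transfers = fl$transfers,
               healthcare = fl$healthcare, net = fl$net)
  })
  by_stratum <- do.call(rbind, per)
  out <- .flows(sum(by_stratum$direct_tax), sum(by_stratum$indirect_tax),
                sum(by_stratum$transfers), sum(by_stratum$healthcare))
  attr(out, "by_stratum") <- by_stratum
  out
}

#' Fiscal burden as the difference between control and intervention flows
#'
#' Burden components follow the positive-burden sign convention: tax
#' components are intervention minus control (revenue forgone because of
#' OAO), spending components are control minus intervention (excess
#' spending caused by OAO). The total equals the sum of the four
#' components and also the difference in net fiscal effect.
#'
#' @param control_flows,intervention_flows `fbod_flows` objects computed
#'   on the same population and fiscal parameters.
#' @return An object of class `fbod_burden` with elements
#'   `direct_tax_loss`, `indirect_tax_loss`, `transfer_excess`,
#'   `healthcare_excess` and `total` (all JPY/year).
#' @export
fiscal_burden <- function(control_flows, intervention_flows) {
  comp <- c(direct_tax_loss =
              intervention_flows$direct_tax - control_flows$direct_tax,
            indirect_tax_loss =
              intervention_flows$indirect_tax - control_flows$indirect_tax,
            transfer_excess =
              control_flows$transfers - intervention_flows$transfers,
            healthcare_excess =
              control_flows$healthcare - intervention_flows$healthcare)
  structure(list(components = comp, total = sum(comp),
                 control = control_flows, intervention = intervention_flows),
            class = "fbod_burden")
}

#' Fit the fiscal burden-of-disease model
#'
#' The top-level estimator: builds the control cohort from the stratum
#' table (optionally restricted to an age range), constructs the
#' counterfactual cohort with OAO reassigned to normal weight, computes
#' annual fiscal flows for both, and returns their difference decomposed
#' into direct tax losses, indirect tax losses, excess retirement
#' (pension) payments and excess healthcare costs.
#'
#' @param strata Stratum data frame (see [read_stratum_table()]).
#' @param modifiers An `fbod_modifiers` object.
#' @param fiscal An `fbod_fiscal` object.
#' @param oao_set Categories treated as OAO; default the Japanese
#'   definition (BMI >= 25).
#' @param age_range Closed age range `c(lo, hi)`; strata whose band lies
#'   outside are dropped. `NULL` keeps all strata.
#' @param sex `"both"`, `"male"` or `"female"`; the excluded sex's counts
#'   are zeroed (output shapes stay constant).
#' @param sickleave_scope,use_elderly_rr,mortality_adjust Passed to
#'   [annual_fiscal_effect()].
#' @return An object of class `fbod` containing the burden decomposition
#'   (`$burden`), both cohorts and flow sets, and the options used.
#'   Methods: [print.fbod()], [summary.fbod()], [coef.fbod()],
#'   [plot.fbod()].
#' @examples
#' inp <- japan_like_fixture()
#' fit <- fiscal_bod(inp$strata, inp$modifiers, inp$fiscal)
#' coef(fit) / 1e9  # burden components, billion JPY
#' @export
fiscal_bod <- function(strata, modifiers, fiscal,
                       oao_set = c("overweight", "obese"),
                       age_range = c(18, 70), sex = c("both", "male", "female"),
                       sickleave_scope = c("ft_only", "ft_and_pt"),
                       use_elderly_rr = FALSE, mortality_adjust = TRUE) {
  sex <- match.arg(sex)
  sickleave_scope <- match.arg(sickleave_scope)
  .assert_valid(validate_inputs(strata, modifiers, fiscal))
  strata_full <- strata
  strata <- .apply_population_filters(strata, age_range, sex)
  control <- build_cohort(strata, "control")
  intervention <- build_intervention_cohort(control, oao_set)
  cf <- annual_fiscal_effect(control, modifiers, fiscal, oao_set,
                             sickleave_scope, use_elderly_rr, mortality_adjust)
  if_ <- annual_fiscal_effect(intervention, modifiers, fiscal, oao_set,
                              sickleave_scope, use_elderly_rr,
                              mortality_adjust)
  structure(list(burden = fiscal_burden(cf, if_),
                 control_flows = cf, intervention_flows = if_,
                 control = control, intervention = intervention,
                 strata_full = strata_full,
                 modifiers = modifiers, fiscal = fiscal,
                 options = list(oao_set = oao_set, age_range = age_range,
                                sex = sex, sickleave_scope = sickleave_scope,
                                use_elderly_rr = use_elderly_rr,
                                mortality_adjust = mortality_adjust),
                 call = match.call()),
            class = "fbod")
}

.apply_population_filters <- function(strata, age_range, sex) {
  if (!is.null(age_range))
    strata <- strata[strata$age_lo >= age_range[1] &
                       strata$age_hi <= age_range[2], , drop = FALSE]
  if (nrow(strata) == 0) stop("no strata left after the age-range filter")
  if (sex != "both") strata$count[strata$sex != sex] <- 0
  strata
}

#' Net fiscal gain from partial reductions in OAO prevalence
#'
#' For each fraction `f`, a cohort with `f` of every OAO category's mass
#' reassigned to normal weight is evaluated; the gain is its net fiscal
#' effect minus the control's. `f = 0` gives 0 and `f = 1` the full
#' burden total.
#'
#' @param fit An `fbod` object, or a stratum data frame (then `modifiers`
#'   and `fiscal` must be supplied and the `fiscal_bod` defaults apply).
#' @param fractions Increasing vector of reduction fractions in `[0, 1]`.
#' @param modifiers,fiscal Used only when `fit` is a stratum table.
#' @param ... Options passed to [fiscal_bod()] in that case.
#' @return A data frame of class `fbod_curve` with columns `fraction` and
#'   `gain` (JPY/year).
#' @export
reduction_curve <- function(fit, fractions = seq(0, 1, by = 0.01),
                            modifiers = NULL, fiscal = NULL, ...) {
  if (!inherits(fit, "fbod"))
    fit <- fiscal_bod(fit, modifiers, fiscal, ...)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0,1]")
  if (is.unsorted(fractions)) stop("fractions must be sorted increasing")
  o <- fit$options
  strata <- fit$control$strata
  base_net <- fit$control_flows$net
  gain <- vapply(fractions, function(f) {
    s_f <- .partial_reassign(strata, o$oao_set, f)
    fl <- annual_fiscal_effect(build_cohort(s_f), fit$modifiers, fit$fiscal,
                               o$oao_set, o$sickleave_scope, o$use_elderly_rr,
                               o$mortality_adjust)
    fl$net - base_net
  }, numeric(1))
  structure(data.frame(fraction = fractions, gain = gain),
            class = c("fbod_curve", "data.frame"))
}
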