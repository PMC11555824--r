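# One-way sensitivity analysis (tornado) and the scenario battery.

# resolve / set a dotted parameter path inside (fiscal | modifiers)
.get_param <- function(fiscal, modifiers, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  obj <- switch(parts[1], fiscal = fiscal, modifiers = modifiers,
                stop("unresolvable parameter path: ", path))
  cur <- obj
  for (p in parts[-1]) {
    if (is.null(cur[[p]]))
      stop("unresolvable parameter path: ", path)
    cur <- cur[[p]]
  }
  if (!is.numeric(cur) || length(cur) != 1)
    stop("parameter path must resolve to a scalar: ", path)
  cur
}

.set_param <- function(fiscal, modifiers, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "fiscal") {
    if (length(parts) == 2) fiscal[[parts[2]]] <- value
    else fiscal[[parts[2]]][[parts[3]]] <- value
  } else if (parts[1] == "modifiers") {
    if (length(parts) == 2) modifiers[[parts[2]]] <- value
    else modifiers[[parts[2]]][[parts[3]]] <- value
  } else stop("unresolvable parameter path: ", path)
  list(fiscal = fiscal, modifiers = modifiers)
}

#' Default one-way sensitivity specification
#'
#' Every scalar modifier and the main fiscal levers, varied by a
#' symmetric relative range around the base value (default +/- 20%, used
#' when no confidence interval is available for a parameter).
#'
#' @param fiscal,modifiers Base parameter objects.
#' @param rel Relative half-width of the range.
#' @return Data frame with columns `parameter`, `low`, `high`.
#' @export
default_owsa_spec <- function(fiscal, modifiers, rel = 0.20) {
  paths <- c("modifiers.beta_employment", "modifiers.beta_income",
             "modifiers.hr_sickleave", "modifiers.hr_retirement",
             "modifiers.af_healthcare",
             "modifiers.rr_mortality.overweight",
             "modifiers.rr_mortality.obese",
             "fiscal.tax_wedge", "fiscal.vat_rate",
             "fiscal.pension_benefit", "fiscal.sickpay_fraction")
  keep <- vapply(paths, function(p) {
    ok <- TRUE
    tryCatch(.get_param(fiscal, modifiers, p), error = function(e) ok <<- FALSE)
    ok
  }, logical(1))
  paths <- paths[keep]
  base <- vapply(paths, .get_param, numeric(1),
                 fiscal = fiscal, modifiers = modifiers)
  lo <- pmin(base * (1 - rel), base * (1 + rel))
  hi <- pmax(base * (1 - rel), base * (1 + rel))
  data.frame(parameter = paths, low = lo, high = hi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way sensitivity analysis of the fiscal burden
#'
#' Re-estimates the burden total with each parameter set to its low and
#' high value in turn, holding everything else at base. Rows are sorted
#' by bar width `|high - low burden|` descending, the tornado-diagram
#' convention.
#'
#' @param fit An `fbod` object (the base-case fit).
#' @param specs Data frame `parameter, low, high` (dotted paths into
#'   `fiscal.*` / `modifiers.*`); default [default_owsa_spec()].
#' @return A data frame of class `fbod_owsa` with the base value, the
#'   burden at the low and high settings, and the bar width; attribute
#'   `base_burden` carries the base-case total.
#' @export
run_owsa <- function(fit, specs = NULL) {
  stopifnot(inherits(fit, "fbod"))
  if (is.null(specs)) specs <- default_owsa_spec(fit$fiscal, fit$modifiers)
  if (any(specs$low > specs$high)) stop("low must be <= high")
  o <- fit$options
  strata <- fit$control$strata
  rerun <- function(fiscal, modifiers) {
    fiscal_bod(strata, modifiers, fiscal, oao_set = o$oao_set,
               age_range = NULL, sex = "both",
               sickleave_scope = o$sickleave_scope,
               use_elderly_rr = o$use_elderly_rr,
               mortality_adjust = o$mortality_adjust)$burden$total
  }
  base_total <- fit$burden$total
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    p <- specs$parameter[i]
    base_val <- .get_param(fit$fiscal, fit$modifiers, p)
    at <- function(v) {
      s <- .set_param(fit$fiscal, fit$modifiers, p, v)
      rerun(s$fiscal, s$modifiers)
    }
    b_lo <- at(specs$low[i])
    b_hi <- at(specs$high[i])
    data.frame(parameter = p, base = base_val,
               low = specs$low[i], high = specs$high[i],
               burden_low = b_lo, burden_high = b_hi,
               width = abs(b_hi - b_lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_burden") <- base_total
  class(out) <- c("fbod_owsa", "data.frame")
  out
}

#' Scenario battery mirroring the standard sensitivity scenarios
#'
#' The shipped set covers: the base case (ages 18-70); the age-range
#' variants 18-65, 18-75 and 18-104; the WHO obesity definition
#' (BMI >= 30 only); alternate mortality relative risks at ages >= 65;
#' sick leave applied to part-time as well as full-time employees; and
#' single-sex populations.
#'
#' @return A list of scenario specifications (name + overrides).
#' @export
table_scenarios <- function() {
  list(
    list(name = "Base case (18-70 y)"),
    list(name = "18-65 y", age_range = c(18, 65)),
    list(name = "18-75 y", age_range = c(18, 75)),
    list(name = "18-104 y", age_range = c(18, 104)),
    list(name = "Obesity defined as BMI >= 30", oao_set = "obese"),
    list(name = "Alternate mortality data (>= 65 y)", use_elderly_rr = TRUE),
    list(name = "Sick leave applied to FT and PT",
         sickleave_scope = "ft_and_pt"),
    list(name = "Male only", sex = "male"),
    list(name = "Female only", sex = "female")
  )
}

#' Run the scenario battery
#'
#' Each scenario reruns the full model end-to-end with its overrides
#' (age range, OAO definition, elderly mortality source, sick-leave
#' scope, sex filter) applied on top of the base-case options. The
#' output mirrors the standard scenario-table layout: tax revenue loss
#' (direct + indirect), transfer spending (pensions + healthcare) and
#' their sum, the net fiscal effect, in JPY/year. For every row
#' `net = tax_loss + transfer_spending` by construction.
#'
#' @param fit An `fbod` object providing the base inputs and options.
#' @param scenarios List of scenario specs (default [table_scenarios()]).
#' @return A data frame of class `fbod_scenarios` with columns `name`,
#'   `tax_loss`, `transfer_spending`, `net`.
#' @export
run_scenarios <- function(fit, scenarios = table_scenarios()) {
  stopifnot(inherits(fit, "fbod"))
  o <- fit$options
  strata <- fit$strata_full  # scenarios may widen the age range
  rows <- lapply(scenarios, function(sc) {
    known <- c("name", "age_range", "oao_set", "use_elderly_rr",
               "sickleave_scope", "sex")
    bad <- setdiff(names(sc), known)
    if (length(bad))
      stop("unknown scenario override(s): ", paste(bad, collapse = ", "))
    b <- fiscal_bod(
      strata, fit$modifiers, fit$fiscal,
      oao_set = if (!is.null(sc$oao_set)) sc$oao_set else o$oao_set,
      age_range = if (!is.null(sc$age_range)) sc$age_range else o$age_range,
      sex = if (!is.null(sc$sex)) sc$sex else o$sex,
      sickleave_scope = if (!is.null(sc$sickleave_scope)) sc$sickleave_scope
                        else o$sickleave_scope,
      use_elderly_rr = if (!is.null(sc$use_elderly_rr)) sc$use_elderly_rr
                       else o$use_elderly_rr,
      mortality_adjust = o$mortality_adjust)
    comp <- coef(b)
    data.frame(name = sc$name,
               tax_loss = comp[["direct_tax_loss"]] +
                 comp[["indirect_tax_loss"]],
               transfer_spending = comp[["transfer_excess"]] +
                 comp[["healthcare_excess"]],
               net = b$burden$total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fbod_scenarios", "data.frame")
  out
}
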