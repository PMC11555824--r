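# Input containers, readers/writers and validation.
#
# A stratum table is a plain data frame with one row per (age band, sex)
# cell; modifier sets and fiscal parameter sets are validated lists. All
# currency is stored in JPY; USD appears only at reporting time.

.stratum_cols <- c("age_lo", "age_hi", "sex", "count",
                   "p_under", "p_normal", "p_over", "p_obese",
                   "emp_ft", "emp_pt", "income_ft", "income_pt",
                   "sickleave", "retirement", "mepc", "mortality")

#' Construct the modifier set linking OAO status to fiscal outcomes
#'
#' Effect sizes applied to the OAO group relative to the general
#' population: an additive marginal effect on the probability of
#' employment, a relative marginal effect on income, hazard ratios on
#' sick-leave and early-retirement rates, all-cause mortality relative
#' risks per BMI category (reference = normal weight), and the fraction
#' of total medical expenditure attributable to OAO.
#'
#' `beta_employment`, `beta_income`, `hr_sickleave` and `hr_retirement`
#' may be length 1 (pooled) or a named vector `c(male = , female = )`;
#' a pooled value is used for both sexes.
#'
#' @param beta_employment Additive shift in employment probability for
#'   the OAO group (e.g. `-0.03` means 3 percentage points lower).
#' @param beta_income Relative shift in labor income (e.g. `-0.05`).
#' @param hr_sickleave,hr_retirement Hazard ratios (>= 0) multiplying the
#'   population sick-leave and retirement rates.
#' @param rr_mortality Named vector of mortality relative risks over the
#'   four BMI categories; `rr_mortality["normal"]` must equal 1.
#' @param rr_mortality_elderly Optional alternate relative-risk vector
#'   applied to age bands starting at 65 or above when an analysis is run
#'   with `use_elderly_rr = TRUE`.
#' @param af_healthcare Attributable fraction of total medical spending,
#'   in `[0, 1)`.
#' @return An object of class `fbod_modifiers`.
#' @export
modifier_set <- function(beta_employment = 0, beta_income = 0,
                         hr_sickleave = 1, hr_retirement = 1,
                         rr_mortality = c(underweight = 1, normal = 1,
                                          overweight = 1, obese = 1),
                         rr_mortality_elderly = NULL,
                         af_healthcare = 0) {
  m <- structure(list(beta_employment = beta_employment,
                      beta_income = beta_income,
                      hr_sickleave = hr_sickleave,
                      hr_retirement = hr_retirement,
                      rr_mortality = rr_mortality,
                      rr_mortality_elderly = rr_mortality_elderly,
                      af_healthcare = af_healthcare),
                 class = "fbod_modifiers")
  .assert_valid(validate_modifiers(m))
  m
}

#' Null modifier set (OAO indistinguishable from the reference group)
#' @return An `fbod_modifiers` object with beta = 0, HR = 1, RR = 1, AF = 0.
#' @export
null_modifiers <- function() modifier_set()

# sex-aware lookup: pooled scalar or c(male=, female=)
.mod_value <- function(x, sex) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && sex %in% names(x)) return(unname(x[[sex]]))
  unname(x[[1L]])
}

#' Construct the fiscal parameter set
#'
#' @param tax_wedge Fraction of labor cost collected as direct tax
#'   (OECD-style tax wedge), in `[0, 1)`.
#' @param vat_rate Consumption-tax rate applied to disposable income and
#'   transfer income, in `[0, 1)`.
#' @param pension_benefit Annual pension payment per retired person, JPY.
#' @param sickpay_fraction Fraction of salary received while on sick
#'   leave, in `[0, 1]`. Default 2/3, the Japanese sickness-allowance
#'   replacement rate.
#' @param discount_rate Annual discount rate.
#' @param wage_growth Annual wage growth rate.
#' @param prevalence_growth Named vector `c(male = , female = )`: annual
#'   relative growth of the combined OAO prevalence.
#' @param horizon_years Projection horizon (years beyond the base year).
#' @param yen_per_usd Exchange rate used only when reporting in USD.
#' @return An object of class `fbod_fiscal`.
#' @export
fiscal_params <- function(tax_wedge = 0.327, vat_rate = 0.10,
                          pension_benefit = 1.8e6,
                          sickpay_fraction = 2 / 3,
                          discount_rate = 0.02, wage_growth = 0.02,
                          prevalence_growth = c(male = 0.0147,
                                                female = 0.0047),
                          horizon_years = 10, yen_per_usd = 143.58) {
  f <- structure(list(tax_wedge = tax_wedge, vat_rate = vat_rate,
                      pension_benefit = pension_benefit,
                      sickpay_fraction = sickpay_fraction,
                      discount_rate = discount_rate,
                      wage_growth = wage_growth,
                      prevalence_growth = prevalence_growth,
                      horizon_years = horizon_years,
                      yen_per_usd = yen_per_usd),
                 class = "fbod_fiscal")
  .assert_valid(validate_fiscal(f))
  f
}

.assert_valid <- function(report) {
  if (nrow(report)) {
    stop("invalid inputs:\n  ",
         paste(sprintf("%s / %s: %s", report$where, report$field,
                       report$message), collapse = "\n  "))
  }
  invisible(TRUE)
}

.report <- function(where = character(), field = character(),
                    message = character()) {
  data.frame(where = where, field = field, message = message,
             stringsAsFactors = FALSE)
}

.breach <- function(where, field, message) .report(where, field, message)

#' Validate a stratum table, modifier set and fiscal parameters
#'
#' Checks every structural invariant the model relies on (simplex BMI
#' proportions, probabilities in range, `emp_ft + emp_pt <= 1`,
#' non-negative counts and incomes, reference relative risk equal to 1,
#' fiscal fractions in range) and returns a report rather than stopping:
#' one row per breach, with coordinates. The report is empty if and only
#' if all invariants hold. The function is side-effect free.
#'
#' @param strata A stratum data frame (see [read_stratum_table()]).
#' @param modifiers An `fbod_modifiers` object, or `NULL` to skip.
#' @param fiscal An `fbod_fiscal` object, or `NULL` to skip.
#' @param life_table A life-table data frame (`sex`, `age`, `qx`), or
#'   `NULL` to skip.
#' @return A data frame with columns `where`, `field`, `message`.
#' @export
validate_inputs <- function(strata = NULL, modifiers = NULL, fiscal = NULL,
                            life_table = NULL) {
  rep <- .report()
  if (!is.null(strata)) rep <- rbind(rep, validate_strata(strata))
  if (!is.null(modifiers)) rep <- rbind(rep, validate_modifiers(modifiers))
  if (!is.null(fiscal)) rep <- rbind(rep, validate_fiscal(fiscal))
  if (!is.null(life_table)) rep <- rbind(rep, validate_life_table(life_table))
  rep
}

#' @rdname validate_inputs
#' @export
validate_strata <- function(strata) {
  rep <- .report()
  missing <- setdiff(.stratum_cols, names(strata))
  if (length(missing)) {
    return(.breach("strata", paste(missing, collapse = ","),
                   "missing required column(s)"))
  }
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    where <- sprintf("stratum[%s %d-%d]", s$sex, s$age_lo, s$age_hi)
    props <- c(s$p_under, s$p_normal, s$p_over, s$p_obese)
    if (abs(sum(props) - 1) > 1e-9)
      rep <- rbind(rep, .breach(where, "bmi_proportions",
                                sprintf("sum %.6f != 1", sum(props))))
    if (any(props < 0 | props > 1))
      rep <- rbind(rep, .breach(where, "bmi_proportions", "outside [0,1]"))
    for (f in c("emp_ft", "emp_pt", "sickleave", "retirement", "mortality")) {
      v <- s[[f]]
      if (is.na(v) || v < 0 || v > 1)
        rep <- rbind(rep, .breach(where, f, "probability outside [0,1]"))
    }
    if (!is.na(s$emp_ft) && !is.na(s$emp_pt) && s$emp_ft + s$emp_pt > 1 + 1e-9)
      rep <- rbind(rep, .breach(where, "emp_ft+emp_pt", "exceeds 1"))
    if (s$count < 0)
      rep <- rbind(rep, .breach(where, "count", "negative"))
    for (f in c("income_ft", "income_pt", "mepc"))
      if (s[[f]] < 0) rep <- rbind(rep, .breach(where, f, "negative"))
    if (s$age_hi < s$age_lo)
      rep <- rbind(rep, .breach(where, "age_band", "age_hi < age_lo"))
  }
  # contiguous, non-overlapping bands per sex
  for (sx in unique(strata$sex)) {
    b <- strata[strata$sex == sx, ]
    b <- b[order(b$age_lo), ]
    if (nrow(b) > 1 && any(b$age_lo[-1] != b$age_hi[-nrow(b)] + 1))
      rep <- rbind(rep, .breach(sprintf("strata[%s]", sx), "age_bands",
                                "bands not contiguous/non-overlapping"))
  }
  rep
}

#' @rdname validate_inputs
#' @export
validate_modifiers <- function(m) {
  rep <- .report()
  rr <- m$rr_mortality
  if (!all(.bmi_labels %in% names(rr))) {
    rep <- rbind(rep, .breach("modifiers", "rr_mortality",
                              "must be named over all four BMI categories"))
  } else {
    if (abs(rr[["normal"]] - 1) > 1e-12)
      rep <- rbind(rep, .breach("modifiers", "rr_mortality[normal]",
                                "reference category must have RR = 1"))
    if (any(rr < 0))
      rep <- rbind(rep, .breach("modifiers", "rr_mortality", "negative RR"))
  }
  if (!is.null(m$rr_mortality_elderly)) {
    rre <- m$rr_mortality_elderly
    if (!all(.bmi_labels %in% names(rre)) || any(rre < 0) ||
        abs(rre[["normal"]] - 1) > 1e-12)
      rep <- rbind(rep, .breach("modifiers", "rr_mortality_elderly",
                                "must cover all categories, RR >= 0, normal = 1"))
  }
  for (f in c("hr_sickleave", "hr_retirement"))
    if (any(m[[f]] < 0))
      rep <- rbind(rep, .breach("modifiers", f, "hazard ratio negative"))
  if (m$af_healthcare < 0 || m$af_healthcare >= 1)
    rep <- rbind(rep, .breach("modifiers", "af_healthcare",
                              "outside [0,1)"))
  rep
}

#' @rdname validate_inputs
#' @export
validate_fiscal <- function(f) {
  rep <- .report()
  in01 <- function(x) x >= 0 && x < 1
  if (!in01(f$tax_wedge))
    rep <- rbind(rep, .breach("fiscal", "tax_wedge", "outside [0,1)"))
  if (!in01(f$vat_rate))
    rep <- rbind(rep, .breach("fiscal", "vat_rate", "outside [0,1)"))
  if (f$sickpay_fraction < 0 || f$sickpay_fraction > 1)
    rep <- rbind(rep, .breach("fiscal", "sickpay_fraction", "outside [0,1]"))
  if (f$pension_benefit < 0)
    rep <- rbind(rep, .breach("fiscal", "pension_benefit", "negative"))
  if (f$horizon_years < 1)
    rep <- rbind(rep, .breach("fiscal", "horizon_years", "must be >= 1"))
  if (f$yen_per_usd <= 0)
    rep <- rbind(rep, .breach("fiscal", "yen_per_usd", "must be positive"))
  rep
}

#' @rdname validate_inputs
#' @export
validate_life_table <- function(lt) {
  rep <- .report()
  need <- c("sex", "age", "qx")
  missing <- setdiff(need, names(lt))
  if (length(missing))
    return(.breach("life_table", paste(missing, collapse = ","),
                   "missing required column(s)"))
  if (any(lt$qx < 0 | lt$qx > 1))
    rep <- rbind(rep, .breach("life_table", "qx", "outside [0,1]"))
  for (sx in unique(lt$sex)) {
    q <- lt[lt$sex == sx, ]
    q <- q[order(q$age), ]
    if (any(diff(q$age) != 1))
      rep <- rbind(rep, .breach(sprintf("life_table[%s]", sx), "age",
                                "ages not consecutive"))
    if (q$qx[nrow(q)] != 1)
      rep <- rbind(rep, .breach(sprintf("life_table[%s]", sx), "qx",
                                "terminal age must have qx = 1"))
  }
  rep
}

# ---- readers / writers ----------------------------------------------------

#' Read or write a stratum table
#'
#' CSV with mandatory header and one row per (age band, sex):
#' `age_lo, age_hi, sex, count, p_under, p_normal, p_over, p_obese,
#' emp_ft, emp_pt, income_ft, income_pt, sickleave, retirement, mepc,
#' mortality`. Comment lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_stratum_table` returns the validated data frame;
#'   `write_stratum_table` returns `path` invisibly.
#' @export
read_stratum_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.stratum_cols, names(d))
  if (length(missing))
    stop("stratum table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  d <- d[, .stratum_cols]
  .assert_valid(validate_strata(d))
  d
}

#' @rdname read_stratum_table
#' @param strata Stratum data frame to write.
#' @export
write_stratum_table <- function(strata, path) {
  utils::write.csv(strata[, .stratum_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read or write a life table
#'
#' CSV columns `sex, age, qx` with single-year ages; the terminal age of
#' each sex must have `qx = 1`.
#' @param path File path.
#' @return `read_life_table` returns the validated data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .assert_valid(validate_life_table(d))
  d
}

#' @rdname read_life_table
#' @param lt Life-table data frame to write.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(lt[, c("sex", "age", "qx")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- config file ----------------------------------------------------------

# flat key = value document with [fiscal], [modifiers], [run] sections

.config_defaults <- function() {
  list(
    fiscal = list(tax_wedge = 0.327, vat_rate = 0.10,
                  pension_benefit = 1.8e6, sickpay_fraction = 2 / 3,
                  discount_rate = 0.02, wage_growth = 0.02,
                  prevalence_growth_male = 0.0147,
                  prevalence_growth_female = 0.0047,
                  horizon_years = 10, yen_per_usd = 143.58),
    modifiers = list(beta_employment = 0, beta_income = 0,
                     hr_sickleave = 1, hr_retirement = 1,
                     rr_underweight = 1, rr_normal = 1,
                     rr_overweight = 1, rr_obese = 1,
                     af_healthcare = 0),
    run = list(oao_set = "overweight,obese", sickleave_scope = "ft_only",
               age_lo = 18, age_hi = 70, use_elderly_rr = FALSE,
               mortality_adjust = TRUE)
  )
}

#' Load model configuration from a key-value file
#'
#' The configuration file is a flat `key = value` document with three
#' sections, `[fiscal]`, `[modifiers]` and `[run]`. Keys omitted from the
#' file take documented defaults (e.g. `sickpay_fraction` defaults to
#' 2/3); unknown keys produce a warning but are not fatal. Out-of-range
#' values (e.g. `vat_rate` of 1.5) are a validation error.
#'
#' Sex-specific modifier keys are written `beta_employment_male` /
#' `beta_employment_female`; elderly relative risks as
#' `rr_elderly_overweight` etc.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `fiscal` (`fbod_fiscal`), `modifiers`
#'   (`fbod_modifiers`) and `run` (list of run options).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  raw <- list(fiscal = list(), modifiers = list(), run = list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(raw)) {
        warning("unknown config section [", section, "] ignored")
        section <- NA_character_
      }
      next
    }
    if (is.na(section) || !grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    raw[[section]][[key]] <- val
  }
  .config_build(raw)
}

.parse_scalar <- function(x) {
  if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  x
}

.config_build <- function(raw) {
  def <- .config_defaults()
  out <- def
  sexed <- c("beta_employment", "beta_income", "hr_sickleave", "hr_retirement")
  for (sec in names(raw)) {
    for (key in names(raw[[sec]])) {
      known <- key %in% names(def[[sec]]) ||
        (sec == "modifiers" &&
           (key %in% c(outer(sexed, c("_male", "_female"), paste0)) ||
              grepl("^rr_elderly_", key)))
      if (!known) {
        warning("unknown config key '", key, "' in [", sec, "] ignored")
        next
      }
      out[[sec]][[key]] <- .parse_scalar(raw[[sec]][[key]])
    }
  }
  fis <- out$fiscal
  fiscal <- fiscal_params(
    tax_wedge = fis$tax_wedge, vat_rate = fis$vat_rate,
    pension_benefit = fis$pension_benefit,
    sickpay_fraction = fis$sickpay_fraction,
    discount_rate = fis$discount_rate, wage_growth = fis$wage_growth,
    prevalence_growth = c(male = fis$prevalence_growth_male,
                          female = fis$prevalence_growth_female),
    horizon_years = fis$horizon_years, yen_per_usd = fis$yen_per_usd)
  mo <- out$modifiers
  pick <- function(base) {
    m <- raw$modifiers[[paste0(base, "_male")]]
    f <- raw$modifiers[[paste0(base, "_female")]]
    if (!is.null(m) || !is.null(f)) {
      pooled <- mo[[base]]
      c(male = if (is.null(m)) pooled else .parse_scalar(m),
        female = if (is.null(f)) pooled else .parse_scalar(f))
    } else mo[[base]]
  }
  rre_keys <- grep("^rr_elderly_", names(raw$modifiers), value = TRUE)
  rre <- NULL
  if (length(rre_keys)) {
    rre <- c(underweight = 1, normal = 1, overweight = 1, obese = 1)
    for (k in rre_keys)
      rre[[sub("^rr_elderly_", "", k)]] <- .parse_scalar(raw$modifiers[[k]])
  }
  modifiers <- modifier_set(
    beta_employment = pick("beta_employment"),
    beta_income = pick("beta_income"),
    hr_sickleave = pick("hr_sickleave"),
    hr_retirement = pick("hr_retirement"),
    rr_mortality = c(underweight = mo$rr_underweight, normal = mo$rr_normal,
                     overweight = mo$rr_overweight, obese = mo$rr_obese),
    rr_mortality_elderly = rre,
    af_healthcare = mo$af_healthcare)
  run <- out$run
  run$oao_set <- .check_oao_set(strsplit(run$oao_set, ",")[[1]])
  list(fiscal = fiscal, modifiers = modifiers, run = run)
}

#' Write a configuration file
#'
#' Inverse of [load_config()]: serialises fiscal parameters, modifiers
#' and run options into the `[fiscal]` / `[modifiers]` / `[run]`
#' key-value format.
#'
#' @param fiscal An `fbod_fiscal` object.
#' @param modifiers An `fbod_modifiers` object.
#' @param run Optional list of run options.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(fiscal, modifiers, path, run = list()) {
  fmt <- function(x) {
    if (is.logical(x)) return(ifelse(x, "true", "false"))
    if (is.numeric(x)) return(format(x, digits = 15, scientific = FALSE))
    as.character(x)
  }
  out <- c("# fiscalbod model configuration", "[fiscal]")
  fis <- fiscal
  kv <- c(tax_wedge = fis$tax_wedge, vat_rate = fis$vat_rate,
          pension_benefit = fis$pension_benefit,
          sickpay_fraction = fis$sickpay_fraction,
          discount_rate = fis$discount_rate, wage_growth = fis$wage_growth,
          prevalence_growth_male = unname(fis$prevalence_growth[["male"]]),
          prevalence_growth_female = unname(fis$prevalence_growth[["female"]]),
          horizon_years = fis$horizon_years, yen_per_usd = fis$yen_per_usd)
  out <- c(out, sprintf("%s = %s", names(kv), vapply(kv, fmt, "")))
  out <- c(out, "", "[modifiers]")
  m <- modifiers
  emit_sexed <- function(base) {
    v <- m[[base]]
    if (length(v) > 1 && !is.null(names(v)))
      sprintf("%s_%s = %s", base, names(v), vapply(v, fmt, ""))
    else sprintf("%s = %s", base, fmt(unname(v)))
  }
  out <- c(out, unlist(lapply(c("beta_employment", "beta_income",
                                "hr_sickleave", "hr_retirement"),
                              emit_sexed)))
  out <- c(out,
           sprintf("rr_underweight = %s", fmt(m$rr_mortality[["underweight"]])),
           sprintf("rr_normal = %s", fmt(m$rr_mortality[["normal"]])),
           sprintf("rr_overweight = %s", fmt(m$rr_mortality[["overweight"]])),
           sprintf("rr_obese = %s", fmt(m$rr_mortality[["obese"]])),
           sprintf("af_healthcare = %s", fmt(m$af_healthcare)))
  if (!is.null(m$rr_mortality_elderly))
    out <- c(out, sprintf("rr_elderly_%s = %s",
                          names(m$rr_mortality_elderly),
                          vapply(m$rr_mortality_elderly, fmt, "")))
  out <- c(out, "", "[run]")
  run_def <- .config_defaults()$run
  for (k in names(run_def)) {
    v <- if (!is.null(run[[k]])) run[[k]] else run_def[[k]]
    if (k == "oao_set") v <- paste(v, collapse = ",")
    out <- c(out, sprintf("%s = %s", k, fmt(v)))
  }
  writeLines(out, path)
  invisible(path)
}
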