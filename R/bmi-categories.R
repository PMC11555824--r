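#' BMI category definitions
#'
#' The model stratifies the population into four BMI categories:
#' underweight (BMI < 18.5), normal weight (18.5 to < 25), overweight
#' (25 to < 30) and obese (>= 30). The categories partition `[0, Inf)`
#' without gaps or overlaps. "OAO" (overweight and obesity) is the union
#' of the overweight and obese categories under the Japanese
#' categorisation (BMI >= 25); scenario analyses may restrict it to the
#' obese category alone (the WHO cut-off, BMI >= 30).
#'
#' @return A data frame with columns `label`, `lower` (inclusive) and
#'   `upper` (exclusive; `Inf` for obese).
#' @examples
#' bmi_categories()
#' @export
bmi_categories <- function() {
  data.frame(
    label = c("underweight", "normal", "overweight", "obese"),
    lower = c(0, 18.5, 25, 30),
    upper = c(18.5, 25, 30, Inf),
    stringsAsFactors = FALSE
  )
}

# proportion-column lookup used throughout the engine
.bmi_labels <- c("underweight", "normal", "overweight", "obese")
.bmi_cols <- c(underweight = "p_under", normal = "p_normal",
               overweight = "p_over", obese = "p_obese")

#' Default OAO category set
#'
#' @param definition `"japanese"` (BMI >= 25: overweight + obese, the base
#'   case) or `"who"` (BMI >= 30: obese only).
#' @return Character vector of category labels.
#' @export
oao_categories <- function(definition = c("japanese", "who")) {
  definition <- match.arg(definition)
  if (definition == "japanese") c("overweight", "obese") else "obese"
}

.check_oao_set <- function(oao_set) {
  bad <- setdiff(oao_set, .bmi_labels)
  if (length(bad))
    stop("unknown BMI categories in oao_set: ", paste(bad, collapse = ", "))
  if (!length(oao_set)) stop("oao_set must name at least one category")
  oao_set
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)
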