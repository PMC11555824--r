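# Report rendering and S3 methods.

#' Render the burden decomposition as a five-row table
#'
#' Mirrors the standard burden-table layout: direct tax losses, indirect
#' tax losses, retirement (pension) payments, healthcare costs, and the
#' total, in billions of JPY to two decimals. The total row is the sum
#' of the rounded component rows, so the printed table is internally
#' consistent. When `fiscal` is supplied a USD column (billions, at
#' `yen_per_usd`) is added.
#'
#' @param result An `fbod_burden` / `fbod` object (components in JPY), or
#'   a numeric vector of the four components already expressed in
#'   billions of JPY, in the order direct tax, indirect tax, retirement
#'   payments, healthcare costs.
#' @param fiscal Optional `fbod_fiscal` (for the USD column).
#' @return Data frame with columns `component`, `billion_jpy` (and
#'   `billion_usd`).
#' @export
render_burden_table <- function(result, fiscal = NULL) {
  if (inherits(result, "fbod")) result <- result$burden
  comp_bn <- if (inherits(result, "fbod_burden")) {
    unname(result$components) / 1e9
  } else if (is.numeric(result) && length(result) == 4) {
    unname(result)
  } else stop("result must be an fbod/fbod_burden object or 4 components")
  comp_bn <- round(comp_bn, 2)
  out <- data.frame(
    component = c("Direct tax losses from employment",
                  "Indirect tax losses (employment income and transfers)",
                  "Retirement payments", "Healthcare costs",
                  "Total fiscal burden of OAO"),
    billion_jpy = c(comp_bn, round(sum(comp_bn), 2)),
    stringsAsFactors = FALSE)
  if (!is.null(fiscal))
    out$billion_usd <- round(out$billion_jpy / fiscal$yen_per_usd, 2)
  out
}

#' @export
print.fbod <- function(x, ...) {
  cat("Fiscal burden-of-disease model (OAO)\n")
  cat(sprintf("  OAO definition: %s\n",
              paste(x$options$oao_set, collapse = " + ")))
  if (!is.null(x$options$age_range))
    cat(sprintf("  Age range: %d-%d, sex: %s\n", x$options$age_range[1],
                x$options$age_range[2], x$options$sex))
  cat(sprintf("  Population: %.1f million\n",
              sum(x$control$strata$count) / 1e6))
  print(render_burden_table(x$burden, x$fiscal), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fbod <- function(object, ...) object$burden$components

#' @export
summary.fbod <- function(object, ...) {
  structure(list(fit = object,
                 table = render_burden_table(object$burden, object$fiscal),
                 oao_prevalence = .overall_oao(object$control$strata,
                                               object$options$oao_set),
                 net_control = object$control_flows$net,
                 net_intervention = object$intervention_flows$net),
            class = "summary.fbod")
}

.overall_oao <- function(strata, oao_set) {
  p <- rowSums(vapply(oao_set, function(k) strata[[.bmi_cols[[k]]]],
                      numeric(nrow(strata))))
  sum(strata$count * p) / sum(strata$count)
}

#' @export
print.summary.fbod <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\n  Overall OAO prevalence: %.1f%%\n",
              100 * x$oao_prevalence))
  cat(sprintf("  Net fiscal effect, control:      %10.2f bn JPY\n",
              x$net_control / 1e9))
  cat(sprintf("  Net fiscal effect, intervention: %10.2f bn JPY\n",
              x$net_intervention / 1e9))
  invisible(x)
}

#' @export
plot.fbod <- function(x, ...) {
  comp <- coef(x) / 1e9
  graphics::barplot(comp, names.arg = c("direct\ntax", "indirect\ntax",
                                        "pension", "healthcare"),
                    ylab = "billion JPY / year",
                    main = "Fiscal burden of OAO by component", ...)
  invisible(x)
}

#' @export
print.fbod_burden <- function(x, ...) {
  print(render_burden_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
print.fbod_projection <- function(x, ...) {
  cat(sprintf("Projection, %d-%d (discount %.1f%%, wage growth %.1f%%)\n",
              x$base_year, x$base_year + x$horizon,
              100 * x$fiscal$discount_rate, 100 * x$fiscal$wage_growth))
  py <- x$per_year
  print(data.frame(year = py$year,
                   total_bn = round(py$total / 1e9, 2),
                   discounted_bn = round(py$discounted_total / 1e9, 2)),
        row.names = FALSE)
  cat(sprintf("NPV over horizon: %.2f bn JPY; growth over horizon: %.1f%%\n",
              x$npv_total / 1e9, decade_growth(x)))
  invisible(x)
}

#' @export
plot.fbod_projection <- function(x, ...) {
  py <- x$per_year
  graphics::plot(py$year, py$discounted_total / 1e9, type = "b",
                 xlab = "year", ylab = "discounted burden (bn JPY)",
                 main = "Projected fiscal burden of OAO", ...)
  invisible(x)
}

#' @export
print.fbod_lifetime <- function(x, ...) {
  cat(sprintf("Per-person lifetime fiscal burden of OAO (start age %d)\n",
              x$start_age))
  cat(sprintf("  Tax revenue loss:  %12.0f JPY\n", x$tax_loss))
  cat(sprintf("  Transfer spending: %12.0f JPY\n", x$transfer_excess))
  cat(sprintf("  Total:             %12.0f JPY\n", x$total))
  invisible(x)
}

#' @export
print.fbod_owsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (base burden %.2f bn JPY)\n",
              attr(x, "base_burden") / 1e9))
  d <- as.data.frame(x)
  d$burden_low <- round(d$burden_low / 1e9, 2)
  d$burden_high <- round(d$burden_high / 1e9, 2)
  d$width <- round(d$width / 1e9, 2)
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fbod_owsa <- function(x, ...) {
  base <- attr(x, "base_burden") / 1e9
  d <- x[nrow(x):1, ]
  lo <- pmin(d$burden_low, d$burden_high) / 1e9
  hi <- pmax(d$burden_low, d$burden_high) / 1e9
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "burden total (bn JPY)", ylab = "",
                 main = "Tornado diagram", ...)
  graphics::segments(lo, seq_len(nrow(d)), hi, seq_len(nrow(d)), lwd = 8,
                     col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)),
                 labels = sub("^(fiscal|modifiers)\\.", "", d$parameter),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}

#' @export
print.fbod_scenarios <- function(x, ...) {
  d <- as.data.frame(x)
  d$tax_loss <- round(d$tax_loss / 1e9, 2)
  d$transfer_spending <- round(d$transfer_spending / 1e9, 2)
  d$net <- round(d$net / 1e9, 2)
  names(d) <- c("scenario", "tax_loss_bn", "transfer_bn", "net_bn")
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fbod_curve <- function(x, ...) {
  graphics::plot(100 * x$fraction, x$gain / 1e9, type = "l",
                 xlab = "reduction in OAO prevalence (%)",
                 ylab = "net fiscal gain (bn JPY / year)",
                 main = "Prevalence reduction vs fiscal gain", ...)
  invisible(x)
}
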