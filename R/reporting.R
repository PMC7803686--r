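# Fit metrics and cross-treatment comparison arithmetic, plus the published
# quality/energy/power tables used as inputs to the comparison reports.

#' Goodness-of-fit statistics
#'
#' Coefficient of determination, root mean square error, and absolute
#' average deviation
#' \deqn{AAD = \frac{100}{n}\sum_i \frac{|D_{i,p} - D_{i,e}|}{D_{i,e}}.}
#'
#' @param predicted Model predictions.
#' @param observed Observations, same length (>= 2), nonzero for the AAD.
#' @return A list with elements `r_squared`, `rmse`, `aad_percent`.
#' @export
fit_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  if (length(observed) < 2L)
    stop("at least 2 observations are required", call. = FALSE)
  if (stats::var(observed) == 0)
    stop("constant observed series: R^2 is undefined", call. = FALSE)
  if (any(observed == 0))
    stop("observed values must be nonzero for the AAD", call. = FALSE)
  res <- predicted - observed
  list(r_squared = 1 - sum(res^2) / sum((observed - mean(observed))^2),
       rmse = sqrt(mean(res^2)),
       aad_percent = mean(abs(res) / abs(observed)) * 100)
}

#' Percent difference relative to a baseline
#'
#' `(a - b) / b * 100`: positive when `a` exceeds the baseline `b`
#' ("x percent higher"), negative when below ("x percent lower").
#'
#' @param a Value to compare.
#' @param b Baseline value, nonzero.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("baseline `b` must be nonzero", call. = FALSE)
  (a - b) / b * 100
}

#' A single labelled comparison record
#'
#' @param label Description of the compared quantity.
#' @param value_a Value of the treatment of interest.
#' @param value_b Baseline value.
#' @param unit Unit string for the absolute difference.
#' @return A one-row data.frame with the percent difference (relative to
#'   the baseline) and the absolute difference.
#' @export
comparison_record <- function(label, value_a, value_b, unit = "") {
  data.frame(label = label, value_a = value_a, value_b = value_b,
             percent_difference = percent_difference(value_a, value_b),
             absolute_difference = value_a - value_b,
             unit = unit, stringsAsFactors = FALSE)
}

#' Published quality indices of dried blackberry
#'
#' Mean quality indices (total phenolics, total anthocyanins, individual
#' anthocyanins, organic acids, ABTS and FRAP antioxidant capacities) of
#' blackberries dehydrated by freeze drying, hot air alone, and hot air
#' with airborne or contact sonication.  These printed values are inputs to
#' the comparison arithmetic, not results computed by this package.
#'
#' @return A data.frame with columns `index`, `unit`, `freeze`, `air`,
#'   `airborne`, `contact`.
#' @export
blackberry_quality_table <- function() {
  data.frame(
    index = c("total_phenolic_content", "total_anthocyanin_content",
              "cyanidin_3_O_glucoside", "peonidin_3_O_glucoside",
              "malvidin_3_O_glucoside", "oxalic_acid", "malic_acid",
              "tartaric_acid", "citric_acid", "abts_scavenging",
              "frap_power"),
    unit = c("mg gallic acid/g DM", "mg cyanidin-3-O-glucoside/g DM",
             rep("ug/g DM", 7), "umol Trolox/g DM", "umol Fe2+/g DM"),
    freeze   = c(60.49, 6.57, 5993.1, 1201.9, 148.6, 1681.9, 59201.6,
                 8896.4, 10562.7, 2114.8, 0.935),
    air      = c(58.08, 5.47, 4622.5, 726.6, 84.7, 671.7, 36001.2,
                 4755.1, 4403.7, 2328.7, 0.962),
    airborne = c(62.14, 5.62, 5242.3, 901.0, 115.0, 1002.5, 33530.7,
                 5853.2, 4058.8, 2521.6, 1.031),
    contact  = c(69.71, 6.66, 5935.8, 1139.8, 146.5, 1427.1, 35972.2,
                 5114.9, 5639.8, 2610.4, 1.055),
    stringsAsFactors = FALSE)
}

#' Published drying-run summary values
#'
#' Measured calorimetric ultrasound powers (W), total electrical energies
#' to reach 1.0 kg/kg DM (kWh), and drying times to the same target (min)
#' for the three treatments.  Inputs to comparison arithmetic.
#'
#' @return A data.frame with columns `mode`, `power_W`, `energy_kWh`,
#'   `drying_time_min`.
#' @export
blackberry_run_table <- function() {
  data.frame(mode = c("none", "airborne", "contact"),
             power_W = c(0, 0.245, 0.299),
             energy_kWh = c(2.67, 1.89, 1.38),
             drying_time_min = c(390, 205, 150),
             stringsAsFactors = FALSE)
}

#' Cross-treatment quality comparison
#'
#' Per quality index, percent and absolute differences of a treatment
#' against a baseline treatment.
#'
#' @param table A quality table as returned by
#'   [blackberry_quality_table()]: one row per index, one column per
#'   treatment, plus `index` and optional `unit` columns.
#' @param treatment Column name of the treatment of interest.
#' @param baseline Column name of the baseline treatment.
#' @return A data.frame of [comparison_record()] rows, one per index.
#' @export
quality_comparison <- function(table, treatment = "contact",
                               baseline = "air") {
  for (col in c(treatment, baseline, "index"))
    if (!col %in% names(table))
      stop("column `", col, "` not found in the quality table", call. = FALSE)
  unit <- if ("unit" %in% names(table)) table$unit else ""
  out <- do.call(rbind, lapply(seq_len(nrow(table)), function(i)
    comparison_record(table$index[i], table[[treatment]][i],
                      table[[baseline]][i],
                      unit = if (length(unit) > 1L) unit[i] else unit)))
  out
}

#' Headline cross-treatment comparison report
#'
#' Derived comparison statistics of a drying study: ultrasound power and
#' energy consumption of contact versus airborne sonication, and every
#' quality index of contact and airborne sonication versus hot air alone.
#'
#' @param run_table A run summary as [blackberry_run_table()].
#' @param quality A quality table as [blackberry_quality_table()].
#' @return A data.frame of comparison records.
#' @export
treatment_comparison_report <- function(run_table = blackberry_run_table(),
                                        quality = blackberry_quality_table()) {
  rt <- function(mode, col) run_table[[col]][run_table$mode == mode]
  rbind(
    comparison_record("ultrasound_power_contact_vs_airborne",
                      rt("contact", "power_W"), rt("airborne", "power_W"), "W"),
    comparison_record("energy_contact_vs_airborne",
                      rt("contact", "energy_kWh"), rt("airborne", "energy_kWh"),
                      "kWh"),
    cbind(quality_comparison(quality, "contact", "air")[, -1, drop = FALSE],
          label = paste0(quality$index, "_contact_vs_air"))[,
            c("label", "value_a", "value_b", "percent_difference",
              "absolute_difference", "unit")],
    cbind(quality_comparison(quality, "airborne", "air")[, -1, drop = FALSE],
          label = paste0(quality$index, "_airborne_vs_air"))[,
            c("label", "value_a", "value_b", "percent_difference",
              "absolute_difference", "unit")])
}
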