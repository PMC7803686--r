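# CSV input/output for the four experimental series and the simulation
# results.  Schemas (header row mandatory, UTF-8, decimal point):
#   kinetics:    time_s, moisture_db
#   cooling:     time_s, temp_K
#   calorimetry: time_s, temp_K
#   sorption:    aw, weq_db
#   profiles:    time_s, xi, temp_K, moisture_db
#   summary:     time_s, radius_m, w_avg_db, t_surface_K, t_center_K

.read_schema <- function(path, cols) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read / write a drying-kinetics CSV (`time_s, moisture_db`)
#' @param path File path.
#' @return A [kinetics_series()].
#' @export
read_kinetics_csv <- function(path) {
  df <- .read_schema(path, c("time_s", "moisture_db"))
  kinetics_series(time = df$time_s, moisture = df$moisture_db)
}

#' @rdname read_kinetics_csv
#' @param series The series to write.
#' @export
write_kinetics_csv <- function(series, path) {
  stopifnot(inherits(series, "kinetics_series"))
  utils::write.csv(data.frame(time_s = series$time,
                              moisture_db = series$moisture),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sphere-cooling CSV (`time_s, temp_K`)
#' @param path File path.
#' @param sphere A [copper_sphere()] attached to the series.
#' @return A [cooling_series()].
#' @export
read_cooling_csv <- function(path, sphere = copper_sphere()) {
  df <- .read_schema(path, c("time_s", "temp_K"))
  cooling_series(time = df$time_s, T_surface = df$temp_K, sphere = sphere)
}

#' @rdname read_cooling_csv
#' @param series The series to write.
#' @export
write_cooling_csv <- function(series, path) {
  stopifnot(inherits(series, "cooling_series"))
  utils::write.csv(data.frame(time_s = series$time, temp_K = series$T_surface),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a calorimetry CSV (`time_s, temp_K`)
#' @param path File path.
#' @return A [calorimetry_series()].
#' @export
read_calorimetry_csv <- function(path) {
  df <- .read_schema(path, c("time_s", "temp_K"))
  calorimetry_series(time = df$time_s, temperature = df$temp_K)
}

#' @rdname read_calorimetry_csv
#' @param series The series to write.
#' @export
write_calorimetry_csv <- function(series, path) {
  stopifnot(inherits(series, "calorimetry_series"))
  utils::write.csv(data.frame(time_s = series$time,
                              temp_K = series$temperature),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sorption-equilibrium CSV (`aw, weq_db`)
#' @param path File path.
#' @return A [sorption_table()].
#' @export
read_sorption_csv <- function(path) {
  df <- .read_schema(path, c("aw", "weq_db"))
  sorption_table(a_w = df$aw, W_eq = df$weq_db)
}

#' @rdname read_sorption_csv
#' @param table The table to write.
#' @export
write_sorption_csv <- function(table, path) {
  stopifnot(inherits(table, "sorption_table"))
  utils::write.csv(data.frame(aw = table$aw, weq_db = table$weq_db),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write simulation results to tidy CSV files
#'
#' `write_profiles_csv()` writes the full radial profiles in long form
#' (`time_s, xi, temp_K, moisture_db`); `write_summary_csv()` writes the
#' per-time summary (`time_s, radius_m, w_avg_db, t_surface_K,
#' t_center_K`).
#'
#' @param result A [simulate_drying()] result.
#' @param path Output file path.
#' @export
write_profiles_csv <- function(result, path) {
  stopifnot(inherits(result, "drying_simulation"))
  nt <- length(result$times); nx <- length(result$xi)
  utils::write.csv(data.frame(time_s = rep(result$times, each = nx),
                              xi = rep(result$xi, times = nt),
                              temp_K = as.vector(t(result$T)),
                              moisture_db = as.vector(t(result$W))),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_summary_csv <- function(result, path) {
  stopifnot(inherits(result, "drying_simulation"))
  utils::write.csv(data.frame(time_s = result$times,
                              radius_m = result$radius,
                              w_avg_db = result$W_avg,
                              t_surface_K = result$T_surface,
                              t_center_K = result$T_center),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
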