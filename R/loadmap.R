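#' The seven anatomical hand areas
#'
#' Manugraphy load-distribution analysis divides the contact area between the
#' hand and the sensor-covered cylinder into seven representative regions:
#' the thumb (I), the four fingers (II-V), and the thenar (TH) and
#' hypothenar (HY) eminences. All percent-contribution vectors in this
#' package are named by these codes, in this order.
#'
#' @return Character vector of the seven area codes:
#'   `c("I","II","III","IV","V","TH","HY")`.
#' @export
#' @examples
#' hand_areas()
hand_areas <- function() c("I", "II", "III", "IV", "V", "TH", "HY")

#' Area-load record: total grip force plus percent contributions
#'
#' An `area_loads` object holds the total grip force (newtons) of one hand in
#' one trial together with the percent contribution of each of the seven
#' anatomical areas to that total. Percents are stored in percentage points
#' (0-100, never fractions) and must sum to 100.
#'
#' @param total_force Total grip force in newtons (non-negative scalar).
#' @param percent Numeric vector of length 7 giving the percent contribution
#'   of each area. May be named by [hand_areas()] codes (any order) or
#'   unnamed, in which case [hand_areas()] order is assumed.
#' @return An object of class `area_loads`: a list with elements
#'   `total_force` and `percent` (named numeric, [hand_areas()] order).
#' @export
#' @examples
#' area_loads(350, c(I = 20, II = 12, III = 16, IV = 13, V = 8, TH = 16, HY = 15))
area_loads <- function(total_force, percent) {
  stopifnot(is.numeric(total_force), length(total_force) == 1L,
            is.finite(total_force), total_force >= 0,
            is.numeric(percent), length(percent) == 7L, all(is.finite(percent)))
  areas <- hand_areas()
  if (!is.null(names(percent))) {
    if (!setequal(names(percent), areas))
      stop("percent names must be exactly the seven area codes: ",
           paste(areas, collapse = ", "))
    percent <- percent[areas]
  } else {
    names(percent) <- areas
  }
  if (any(percent < 0))
    stop("percent contributions must be non-negative")
  if (total_force > 0 && abs(sum(percent) - 100) > 1e-6)
    stop("percent contributions must sum to 100 (got ",
         format(sum(percent)), ")")
  structure(list(total_force = total_force, percent = percent),
            class = "area_loads")
}

#' @export
print.area_loads <- function(x, ...) {
  cat("Area loads: total force", format(x$total_force, digits = 6), "N\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Pressure-sensor grid of one grip
#'
#' A rectangular matrix of perpendicular force values (newtons) on the
#' unrolled cylinder surface, stored row-major. The sensor matrix of the
#' measurement cylinder has a spatial resolution of two sensors per square
#' centimetre with individual sensors of 7 mm2.
#'
#' @param values Numeric matrix of non-negative forces, one cell per sensor.
#' @param sensor_area Area of one sensor in mm2 (default 7).
#' @param density Sensors per cm2 (default 2).
#' @param cylinder_label Nominal cylinder size in mm (default 200).
#' @return An object of class `sensor_grid`.
#' @export
sensor_grid <- function(values, sensor_area = 7, density = 2,
                        cylinder_label = 200) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("sensor values must be finite and non-negative")
  stopifnot(sensor_area > 0, density > 0)
  structure(list(values = values, sensor_area = sensor_area,
                 density = density, cylinder_label = cylinder_label),
            class = "sensor_grid")
}

#' @export
print.sensor_grid <- function(x, ...) {
  cat(sprintf("Sensor grid %d x %d (%.0f mm cylinder, %g sensors/cm2), %d active sensors\n",
              nrow(x$values), ncol(x$values), x$cylinder_label, x$density,
              sum(x$values > 0)))
  invisible(x)
}

#' Area mask for a sensor grid
#'
#' Assigns each sensor cell either one of the seven anatomical area codes or
#' background (`NA`). Mask construction from anatomical landmarks is accepted
#' as input, not inferred from the force image.
#'
#' @param assignment Character matrix: each cell one of [hand_areas()] or
#'   `NA` for background.
#' @return An object of class `area_mask`.
#' @export
area_mask <- function(assignment) {
  stopifnot(is.matrix(assignment))
  assignment[assignment %in% c("", "bg", ".")] <- NA_character_
  mode(assignment) <- "character"
  bad <- !is.na(assignment) & !(assignment %in% hand_areas())
  if (any(bad))
    stop("unknown area codes in mask: ",
         paste(unique(assignment[bad]), collapse = ", "))
  structure(list(assignment = assignment), class = "area_mask")
}

#' Aggregate a sensor grid into per-area loads
#'
#' Sums the perpendicular force of every masked sensor per anatomical area
#' and converts the area totals into percent contributions of the total grip
#' force. Background (unmasked) sensors contribute nothing; only contact
#' points carry load.
#'
#' @param grid A [sensor_grid()] (or bare numeric matrix).
#' @param mask An [area_mask()] (or bare character matrix) of the same shape.
#' @return An [area_loads()] object.
#' @export
#' @examples
#' g <- matrix(0, 4, 4); g[1, 1] <- 5; g[2, 2] <- 15
#' m <- matrix(NA_character_, 4, 4); m[1, 1] <- "TH"; m[2, 2] <- "II"
#' aggregate_map(g, m)
aggregate_map <- function(grid, mask) {
  v <- if (inherits(grid, "sensor_grid")) grid$values else grid
  a <- if (inherits(mask, "area_mask")) mask$assignment else mask
  stopifnot(is.matrix(v), is.matrix(a))
  if (!all(dim(v) == dim(a)))
    stop("grid and mask shapes differ: ", paste(dim(v), collapse = "x"),
         " vs ", paste(dim(a), collapse = "x"))
  if (any(v < 0, na.rm = TRUE)) stop("negative sensor forces")
  areas <- hand_areas()
  keep <- !is.na(a)
  force_by_area <- vapply(areas, function(code) sum(v[keep & a == code]),
                          numeric(1))
  total <- sum(force_by_area)
  if (total <= 0)
    stop("empty or failed grip: total masked force is zero")
  area_loads(total, 100 * force_by_area / total)
}

.trial_columns <- c("subject_id", "session", "trial", "hand", "effort",
                    "age", "sex", "handedness", "total_force",
                    paste0("pct_", hand_areas()))

#' Read trial records from CSV
#'
#' Reads a trials table with one row per hand per trial. Required columns:
#' `subject_id, session, trial, hand, effort, age, sex, handedness,
#' total_force, pct_I, pct_II, pct_III, pct_IV, pct_V, pct_TH, pct_HY`
#' (UTF-8, dot decimal separator). Percent columns are renormalised to sum
#' exactly to 100 when their sum lies within 0.5 of 100; rows outside that
#' tolerance are rejected with an error naming the row.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of validated trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
}

#' Validate (and renormalise) a trials data frame
#'
#' @param df Data frame with the columns documented in [read_trials()].
#' @return The validated data frame, percent columns renormalised to 100.
#' @export
validate_trials <- function(df) {
  missing_cols <- setdiff(.trial_columns, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  pct_cols <- paste0("pct_", hand_areas())
  if (any(df$total_force < 0)) {
    stop("negative total_force in row(s) ",
         paste(which(df$total_force < 0), collapse = ", "))
  }
  pm <- as.matrix(df[pct_cols])
  if (any(!is.finite(pm)) || any(pm < 0))
    stop("percent contributions must be finite and non-negative")
  sums <- rowSums(pm)
  off <- which(abs(sums - 100) > 0.5)
  if (length(off))
    stop("percent contributions sum to ", format(sums[off[1]]),
         " (outside 100 +/- 0.5) in row ", off[1])
  df[pct_cols] <- pm * (100 / sums)
  if (!all(df$hand %in% c("left", "right")))
    stop("hand must be 'left' or 'right'")
  if (!all(df$effort %in% c("maximal", "submaximal", "unknown")))
    stop("effort must be 'maximal', 'submaximal' or 'unknown'")
  df
}

#' Write trial records to CSV
#'
#' Writes the documented column order with stable formatting (numbers via
#' base R's default 15-significant-digit representation), so identical
#' inputs produce byte-identical files.
#'
#' @param records Trials data frame (see [read_trials()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  records <- validate_trials(records)
  utils::write.csv(records[.trial_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the [area_loads()] of one trial row
#'
#' @param row One-row slice of a trials data frame.
#' @return An [area_loads()] object.
#' @export
trial_loads <- function(row) {
  stopifnot(nrow(row) == 1L)
  p <- as.numeric(row[paste0("pct_", hand_areas())])
  names(p) <- hand_areas()
  area_loads(row$total_force, p * (100 / sum(p)))
}

#' Read / write plain-text sensor grid and mask files
#'
#' Grid files are whitespace-delimited numeric matrices, one file per trial;
#' mask files are whitespace-delimited area codes with `.` for background.
#'
#' @param path File path.
#' @return `read_grid` returns a [sensor_grid()]; `read_mask` an
#'   [area_mask()].
#' @export
read_grid <- function(path) {
  sensor_grid(as.matrix(utils::read.table(path, header = FALSE)))
}

#' @rdname read_grid
#' @param grid A [sensor_grid()] to write.
#' @export
write_grid <- function(grid, path) {
  v <- if (inherits(grid, "sensor_grid")) grid$values else grid
  utils::write.table(v, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_grid
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "character"))
  area_mask(m)
}

#' @rdname read_grid
#' @param mask An [area_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  a <- if (inherits(mask, "area_mask")) mask$assignment else mask
  a[is.na(a)] <- "."
  utils::write.table(a, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
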