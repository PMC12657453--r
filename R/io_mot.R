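#' Joint-angle time series
#'
#' A `joint_angle_series` holds time-stamped joint angles in degrees for named
#' degrees of freedom (OpenSim coordinate names: `pelvis_tilt`, `pelvis_list`,
#' `pelvis_rotation` and left/right `hip_flexion`, `hip_adduction`,
#' `hip_rotation`, `knee_angle`, `ankle_angle`, `subtalar_angle`), the payload
#' of an OpenSim MOT file.
#'
#' @param data Tibble with a `time` column (seconds, strictly increasing)
#'   followed by one numeric column per degree of freedom, in degrees.
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(data) {
  data <- as_tibble(data)
  assert_that(names(data)[1] == "time", "first column must be 'time'")
  assert_that(ncol(data) >= 2, "at least one degree-of-freedom column required")
  check_time(data$time)
  dofs <- names(data)[-1]
  assert_that(!anyDuplicated(dofs), "dof names must be unique")
  frame_rate <- if (nrow(data) > 1) 1 / median(diff(data$time)) else NA_real_
  structure(
    list(data = data, dof_names = dofs, frame_rate = frame_rate),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames at %.4g Hz, %d dofs:\n",
              nrow(x$data), x$frame_rate, length(x$dof_names)))
  cat(" ", paste(x$dof_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.joint_angle_series <- function(x, ...) x$data

#' Read an OpenSim MOT joint-angle file
#'
#' Parses the MOT dialect: a free-form header block terminated by the literal
#' line `endheader`, then a column-name line whose first column is `time`,
#' then whitespace/tab-delimited numeric rows. Column order is preserved.
#'
#' @param path Path to a `.mot` file.
#' @return A [joint_angle_series()].
#' @export
read_mot <- function(path) {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) {
    stop_format("MOT file '%s' has no 'endheader' line", path)
  }
  rest <- lines[-seq_len(end[1])]
  rest <- rest[trimws(rest) != ""]
  assert_that(length(rest) >= 1, "MOT file has no column-name line")
  cols <- strsplit(trimws(rest[1]), "[\t ]+")[[1]]
  assert_that(tolower(cols[1]) == "time", "first MOT column must be 'time'")
  data_lines <- rest[-1]
  if (length(data_lines) == 0) {
    stop_format("MOT file '%s' has an empty data block", path)
  }
  cells <- strsplit(trimws(data_lines), "[\t ]+")
  mat <- matrix(NA_real_, nrow = length(cells), ncol = length(cols))
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) != length(cols)) {
      stop_format("MOT row %d has %d columns, expected %d", i, length(row),
                  length(cols))
    }
    num <- suppressWarnings(as.numeric(row))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop_format("MOT row %d, column %d ('%s'): non-numeric cell '%s'",
                  i, bad, cols[bad], row[bad])
    }
    mat[i, ] <- num
  }
  colnames(mat) <- cols
  joint_angle_series(as_tibble(mat))
}

#' Write an OpenSim MOT joint-angle file
#'
#' Inverse of [read_mot()]: writes a standard MOT header (`inDegrees=yes`),
#' the `endheader` terminator, the column-name line, and tab-delimited rows
#' at 6 decimal places so that a round trip reproduces the series to 1e-6.
#'
#' @param x A [joint_angle_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(x, path) {
  assert_that(inherits(x, "joint_angle_series"), "'x' must be a joint_angle_series")
  d <- x$data
  header <- c(
    basename(path),
    "version=1",
    sprintf("nRows=%d", nrow(d)),
    sprintf("nColumns=%d", ncol(d)),
    "inDegrees=yes",
    "endheader",
    paste(names(d), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(fmt_num(as.numeric(d[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
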