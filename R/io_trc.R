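#' Marker trajectory sets
#'
#' A `marker_set` holds time-stamped 3-D positions for a collection of named
#' markers sampled at a fixed frame rate, as produced by OpenSim-style motion
#' capture exports (TRC files). Positions are stored in the declared unit
#' (`"mm"` or `"m"`); downstream computations convert to metres through
#' [marker_xyz()], the single conversion point. Missing samples are `NA`.
#'
#' @param data Tibble with columns `frame`, `time` and, for every marker `M`,
#'   `M_X`, `M_Y`, `M_Z`.
#' @param frame_rate Sampling rate in Hz.
#' @param units `"mm"` or `"m"`.
#' @param vertical_axis Which coordinate axis is vertical; `"Y"` is the
#'   OpenSim default, the walking plane being X-Z.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(data, frame_rate, units = c("mm", "m"),
                       vertical_axis = "Y") {
  units <- match.arg(units)
  data <- as_tibble(data)
  assert_that(all(c("frame", "time") %in% names(data)),
              "marker data needs 'frame' and 'time' columns")
  coord_cols <- setdiff(names(data), c("frame", "time"))
  assert_that(length(coord_cols) > 0 && length(coord_cols) %% 3 == 0,
              "marker data needs X/Y/Z column triples")
  markers <- unique(sub("_[XYZ]$", "", coord_cols))
  expected <- as.vector(t(outer(markers, c("X", "Y", "Z"),
                                function(m, a) paste(m, a, sep = "_"))))
  assert_that(identical(coord_cols, expected),
              "marker columns must be contiguous <name>_X/_Y/_Z triples")
  check_time(data$time)
  nt <- nrow(data)
  span <- max(data$time) - min(data$time)
  if (nt > 1) {
    assert_that(abs(span * frame_rate - (nt - 1)) <= 0.5,
                "time span inconsistent with frame rate (%.3f s at %g Hz over %d frames)",
                span, frame_rate, nt)
  }
  structure(
    list(data = data, marker_names = markers, frame_rate = frame_rate,
         units = units, vertical_axis = toupper(vertical_axis)),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d frames at %g Hz, units %s, %d markers:\n",
              nrow(x$data), x$frame_rate, x$units, length(x$marker_names)))
  cat(" ", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.marker_set <- function(x, ...) x$data

#' Extract one marker trajectory in metres
#'
#' Returns the trajectory of a single marker as a tidy tibble in metres and
#' seconds regardless of the file's declared unit, with the vertical
#' coordinate and the two horizontal coordinates identified.
#'
#' @param x A [marker_set()].
#' @param marker Marker name.
#' @return Tibble with columns `time`, `x`, `y`, `z` (file axes, metres) and
#'   `vertical`, `h1`, `h2` (vertical and horizontal-plane coordinates).
#' @export
marker_xyz <- function(x, marker) {
  assert_that(inherits(x, "marker_set"), "'x' must be a marker_set")
  assert_that(marker %in% x$marker_names, "marker '%s' not present", marker)
  scale <- if (x$units == "mm") 1e-3 else 1
  cols <- paste(marker, c("X", "Y", "Z"), sep = "_")
  xs <- x$data[[cols[1]]] * scale
  ys <- x$data[[cols[2]]] * scale
  zs <- x$data[[cols[3]]] * scale
  out <- tibble(time = x$data$time, x = xs, y = ys, z = zs)
  axes <- c("X", "Y", "Z")
  v <- match(x$vertical_axis, axes)
  h <- setdiff(seq_len(3), v)
  out$vertical <- out[[c("x", "y", "z")[v]]]
  out$h1 <- out[[c("x", "y", "z")[h[1]]]]
  out$h2 <- out[[c("x", "y", "z")[h[2]]]]
  out
}

#' Read a TRC marker trajectory file
#'
#' Parses the tab-delimited TRC dialect written by OpenSim/OpenCap: a path
#' line, a field-name line, a field-value line (must declare `DataRate` and
#' `Units`), a marker-name line, an `X1/Y1/Z1` sub-header, then `Frame#` and
#' `Time` followed by three coordinate columns per marker. Blank cells are
#' read as missing samples. Coordinates are kept in the declared unit; no
#' rescaling happens here.
#'
#' @param path Path to a `.trc` file.
#' @param vertical_axis Vertical axis tag stored on the result (default
#'   `"Y"`, the OpenSim convention).
#' @return A [marker_set()].
#' @export
read_trc <- function(path, vertical_axis = "Y") {
  assert_that(file.exists(path), "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) >= 6, "TRC file '%s' is truncated", path)

  fields <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  values <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(fields) == 0 || !all(c("DataRate", "Units") %in% fields)) {
    stop_format("malformed TRC header line 2 ('%s'): DataRate and Units required",
                lines[2])
  }
  hdr <- setNames(as.list(values[seq_along(fields)]), fields)
  frame_rate <- suppressWarnings(as.numeric(hdr$DataRate))
  if (!is_number(frame_rate) || frame_rate <= 0) {
    stop_format("malformed TRC header line 3 ('%s'): DataRate not a positive number",
                lines[3])
  }
  units <- hdr$Units
  if (!units %in% c("mm", "m")) {
    stop_format("malformed TRC header line 3 ('%s'): Units must be 'mm' or 'm'",
                lines[3])
  }

  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  if (length(name_row) < 3 || toupper(sub("#", "", name_row[1])) != "FRAME") {
    stop_format("malformed TRC marker-name line ('%s')", lines[4])
  }
  markers <- name_row[-(1:2)]
  markers <- markers[markers != ""]
  assert_that(length(markers) >= 1, "TRC file declares no markers")
  ncol_expected <- 2L + 3L * length(markers)

  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  assert_that(length(data_lines) >= 1, "TRC file has no data rows")

  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol_expected)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) > ncol_expected) {
      stop_format("TRC row %d has %d columns, expected %d for %d markers",
                  i, length(row), ncol_expected, length(markers))
    }
    length(row) <- ncol_expected   # pad trailing blanks
    filled <- !is.na(row) & row != ""
    if (!all(filled[1:2])) {
      stop_format("TRC row %d is missing Frame#/Time", i)
    }
    num <- suppressWarnings(as.numeric(row[filled]))
    if (anyNA(num)) {
      bad <- which(filled)[which(is.na(num))[1]]
      stop_format("TRC row %d, column %d: non-numeric cell '%s'", i, bad, row[bad])
    }
    mat[i, filled] <- num
  }
  colnames(mat) <- c("frame", "time",
                     as.vector(t(outer(markers, c("X", "Y", "Z"),
                                       function(m, a) paste(m, a, sep = "_")))))
  marker_set(as_tibble(mat), frame_rate = frame_rate, units = units,
             vertical_axis = vertical_axis)
}

#' Write a TRC marker trajectory file
#'
#' Inverse of [read_trc()]: writes the standard 5-line TRC header followed by
#' tab-delimited rows; missing samples become blank cells and survive a
#' read/write round trip. Values are printed with 6 decimal places.
#'
#' @param x A [marker_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(x, path) {
  assert_that(inherits(x, "marker_set"), "'x' must be a marker_set")
  d <- x$data
  nm <- x$marker_names
  n <- nrow(d)
  header <- c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
            x$frame_rate, x$frame_rate, n, length(nm), x$units, x$frame_rate, n),
    paste(c("Frame#", "Time",
            as.vector(rbind(nm, "", ""))), collapse = "\t"),
    paste(c("", "",
            as.vector(rbind(paste0("X", seq_along(nm)),
                            paste0("Y", seq_along(nm)),
                            paste0("Z", seq_along(nm))))), collapse = "\t")
  )
  coord_cols <- setdiff(names(d), c("frame", "time"))
  body <- vapply(seq_len(n), function(i) {
    paste(c(format(as.integer(d$frame[i])), fmt_num(d$time[i]),
            fmt_num(as.numeric(d[i, coord_cols]))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
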