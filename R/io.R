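# CSV dialects: comma-separated, "." decimal, "#"-prefixed metadata lines,
# numbers written with %.17g so read(write(x)) round-trips bit-exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NaN"
  out
}

meta_lines <- function(meta) {
  sprintf("# %s: %s", names(meta), vapply(meta, function(v) paste(format(v), collapse = ","), ""))
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  if (!length(lines)) return(list())
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(as.list(vals), trimws(keys))
}

#' Read and write marker trajectory CSVs
#'
#' The on-disk dialect mirrors 3D-point exports from marker tracking software:
#' a 1-based integer `frame` column plus one `<body>_<marker>_X/Y/Z` column
#' triple per marker (mm), missing observations written as `NaN`, and a
#' `# frame_rate: <Hz>` metadata line. In memory the table is long:
#' `frame`, `body`, `marker`, `x`, `y`, `z`, with attribute `frame_rate`.
#'
#' @param path File path.
#' @return `read_marker_csv()`: long trajectory tibble with attribute
#'   `frame_rate`.
#' @export
read_marker_csv <- function(path) {
  meta <- read_meta(path)
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         na = c("NaN", "NA", ""))
  if (!identical(names(tab)[1], "frame")) {
    abort("marker CSV: first column must be 'frame'", class = "chewkin_error_parse")
  }
  cols <- names(tab)[-1]
  m <- regmatches(cols, regexec("^(.*)_([^_]+)_([XYZ])$", cols))
  bad <- cols[vapply(m, length, 0L) != 4L]
  if (length(bad)) {
    abort(paste("marker CSV: malformed column name(s):", paste(bad, collapse = ", ")),
          class = "chewkin_error_parse")
  }
  info <- tibble::tibble(col = cols,
                         body = vapply(m, `[`, "", 2),
                         marker = vapply(m, `[`, "", 3),
                         axis = tolower(vapply(m, `[`, "", 4)))
  incomplete <- info |>
    dplyr::count(.data$body, .data$marker) |>
    dplyr::filter(.data$n != 3L)
  if (nrow(incomplete)) {
    abort(sprintf("marker CSV: body '%s' marker '%s' is missing a coordinate column",
                  incomplete$body[1], incomplete$marker[1]),
          class = "chewkin_error_parse")
  }
  frames <- tab$frame
  if (any(frames != seq_along(frames))) {
    abort("marker CSV: frame column must be contiguous and 1-based",
          class = "chewkin_error_parse")
  }
  out <- tab |>
    tidyr::pivot_longer(-"frame", names_to = "col", values_to = "value") |>
    dplyr::left_join(info, by = "col") |>
    dplyr::select("frame", "body", "marker", "axis", "value") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "value") |>
    dplyr::arrange(.data$frame, .data$body, .data$marker)
  attr(out, "frame_rate") <- as.numeric(meta$frame_rate %||% NA)
  out
}

#' @rdname read_marker_csv
#' @param trajectories Long trajectory tibble (`frame`, `body`, `marker`,
#'   `x`, `y`, `z`).
#' @param frame_rate Recording rate in Hz, written to the metadata block.
#' @export
write_marker_csv <- function(trajectories, path, frame_rate) {
  traj <- tibble::as_tibble(trajectories)
  wide <- traj |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis", values_to = "value") |>
    dplyr::mutate(col = paste0(.data$body, "_", .data$marker, "_", toupper(.data$axis))) |>
    dplyr::select("frame", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value") |>
    dplyr::arrange(.data$frame)
  body <- apply(as.matrix(wide[, -1]), 1, function(r) paste(fmt_num(r), collapse = ","))
  lines <- c(meta_lines(list(frame_rate = frame_rate)),
             paste(c("frame", names(wide)[-1]), collapse = ","),
             paste(wide$frame, body, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write rigid-transform CSVs
#'
#' Per body, 16 columns `<body>_R11 .. <body>_R44` holding the row-major 4x4
#' homogeneous transform per frame, `NaN`-filled for missing poses.
#'
#' @param poses Pose tibble (`frame`, `body`, `transform`, `ok`).
#' @param path File path.
#' @export
write_transform_csv <- function(poses, path) {
  bodies <- unique(poses$body)
  frames <- sort(unique(poses$frame))
  cols <- list(frame = frames)
  for (b in bodies) {
    pb <- poses[poses$body == b, ]
    m <- matrix(NA_real_, length(frames), 16)
    for (i in seq_along(frames)) {
      tr <- pb$transform[[match(frames[i], pb$frame)]]
      if (!is.null(tr)) {
        hom <- rbind(cbind(tr$R, tr$t), c(0, 0, 0, 1))
        m[i, ] <- as.numeric(t(hom))
      }
    }
    nm <- paste0(b, "_R", rep(1:4, each = 4), rep(1:4, 4))
    for (j in 1:16) cols[[nm[j]]] <- m[, j]
  }
  tab <- tibble::as_tibble(cols)
  body <- apply(as.matrix(tab[, -1]), 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(c(paste(names(tab), collapse = ","), paste(tab$frame, body, sep = ",")), path)
  invisible(path)
}

#' @rdname write_transform_csv
#' @export
read_transform_csv <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         na = c("NaN", "NA", ""))
  cols <- names(tab)[-1]
  bodies <- unique(sub("_R[1-4][1-4]$", "", cols))
  purrr::map_dfr(bodies, function(b) {
    m <- as.matrix(tab[, paste0(b, "_R", rep(1:4, each = 4), rep(1:4, 4))])
    tibble::tibble(frame = tab$frame, body = b,
                   transform = purrr::map(seq_len(nrow(m)), function(i) {
                     if (any(is.na(m[i, ]))) return(NULL)
                     hom <- matrix(m[i, ], 4, 4, byrow = TRUE)
                     rigid_transform(hom[1:3, 1:3], hom[1:3, 4])
                   }),
                   ok = !is.na(m[, 1]))
  })
}

#' Read and write landmark files
#'
#' Landmarks are anatomical points in each bone's model frame:
#' `body,landmark,X,Y,Z` in mm. Required names for a full jaw analysis:
#' `cusp_1..cusp_n` (>= 3), `condyle_centroid_left/right`,
#' `symphysis_centroid`, `molar2_locator`, `maxillary_occlusal_center`,
#' `cranial_axis_anterior`, `cranial_axis_posterior`.
#'
#' @param path File path.
#' @param landmarks Tibble `body`, `landmark`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("body", "landmark", "x", "y", "z") %in% names(tab))) {
    abort("landmark file needs columns body,landmark,X,Y,Z",
          class = "chewkin_error_parse")
  }
  tibble::as_tibble(tab[, c("body", "landmark", "x", "y", "z")])
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  lines <- c("body,landmark,X,Y,Z",
             paste(landmarks$body, landmarks$landmark,
                   fmt_num(landmarks$x), fmt_num(landmarks$y), fmt_num(landmarks$z),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a 6-DOF joint trace CSV
#'
#' `frame,Rx_deg,Ry_deg,Rz_deg,Tx_mm,Ty_mm,Tz_mm` with `#` metadata lines
#' (joint name, fixed/mobile bodies, zero frame, filter settings).
#'
#' @param trace A `jcs_trace` tibble.
#' @param path File path.
#' @param filter_meta Optional named list echoed into the metadata block.
#' @export
write_trace_csv <- function(trace, path, filter_meta = list()) {
  meta <- c(list(joint = attr(trace, "joint") %||% "joint",
                 fixed_body = attr(trace, "fixed_body") %||% "",
                 mobile_body = attr(trace, "mobile_body") %||% "",
                 zero_frame = attr(trace, "zero_frame") %||% ""),
            filter_meta)
  if ("rx" %in% names(trace)) {
    vals <- as.matrix(trace[, c("rx", "ry", "rz", "tx", "ty", "tz")])
    header <- "frame,Rx_deg,Ry_deg,Rz_deg,Tx_mm,Ty_mm,Tz_mm"
  } else {
    # translation-only locator trace
    vals <- as.matrix(trace[, c("tx", "ty", "tz")])
    header <- "frame,Tx_mm,Ty_mm,Tz_mm"
  }
  lines <- c(meta_lines(meta), header,
             paste(trace$frame, apply(vals, 1, function(r) paste(fmt_num(r), collapse = ",")),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a self-contained synthetic fixture directory
#'
#' Writes everything needed to re-run an analysis of a simulated trial:
#' `markers.csv`, `constellations.csv`, `landmarks.csv`,
#' `truth_transforms.csv`, `truth_jcs.csv` and `config.txt` (all parameters,
#' including the seed).
#'
#' @param sim A `chew_sim` from [simulate_chew_trial()] or
#'   [simulate_cadaver_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chew_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_marker_csv(sim$markers, file.path(dir, "markers.csv"), sim$frame_rate)
  cons <- purrr::map_dfr(sim$constellations,
                         ~ dplyr::mutate(.x$markers, body = .x$body, .before = 1))
  readr::write_csv(cons, file.path(dir, "constellations.csv"))
  write_landmarks(sim$landmarks, file.path(dir, "landmarks.csv"))
  write_transform_csv(sim$kinematics$poses, file.path(dir, "truth_transforms.csv"))
  if (!is.null(sim$kinematics$truth)) {
    readr::write_csv(sim$kinematics$truth, file.path(dir, "truth_jcs.csv"))
  }
  write_run_config(unclass(sim$params), file.path(dir, "config.txt"))
  invisible(dir)
}

#' Flat key-value run configuration files
#'
#' `key = value` lines with `#` comments; numeric values are parsed back to
#' numbers, everything else stays character. Unknown structure (nested lists)
#' is rejected.
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  bad <- names(config)[!vapply(config, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
  if (length(bad)) {
    abort(paste("config values must be scalar:", paste(bad, collapse = ", ")),
          class = "chewkin_error_config")
  }
  vals <- vapply(config, function(v) if (is.numeric(v)) fmt_num(v) else as.character(v), "")
  writeLines(c("# chewkin run configuration", sprintf("%s = %s", names(config), vals)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  out <- purrr::map2(vals, num, function(v, n) if (is.na(n) && v != "NaN") v else n)
  setNames(out, keys)
}
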