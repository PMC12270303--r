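# Delimited-text readers/writers for the pipeline's three artifact kinds:
# coordinate files (x,y per cell), barcode files (dim, birth, death with an
# "inf" sentinel), and landscape matrices (header row of grid values, one
# row per landscape function). All round-trip losslessly at full double
# precision.

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

#' Read a coordinate file into a point cloud
#'
#' Accepts comma- or tab-delimited files of two numeric columns (x, y),
#' with or without a header row. Malformed rows are reported with their
#' line numbers.
#'
#' @param path File path.
#' @return A `point_cloud` tibble with columns `x`, `y`.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("coordinate file not found: %s", path),
          class = "colonytda_missing_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("coordinate file is empty: %s", path),
          class = "colonytda_parse_error")
  }
  delim <- detect_delim(lines[[1]])
  fields <- strsplit(lines, delim, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1]]))
  start <- if (any(is.na(first))) 2L else 1L
  if (start > length(lines)) {
    abort(sprintf("no data rows in %s", path), class = "colonytda_parse_error")
  }
  rows <- lapply(seq.int(start, length(lines)), function(i) {
    f <- fields[[i]]
    vals <- suppressWarnings(as.numeric(trimws(f)))
    if (length(vals) < 2 || any(is.na(vals[1:2]))) {
      abort(sprintf("malformed row at line %d of %s: '%s'", i, path,
                    lines[[i]]),
            class = "colonytda_parse_error")
    }
    vals[1:2]
  })
  m <- do.call(rbind, rows)
  out <- tibble::tibble(x = m[, 1], y = m[, 2])
  class(out) <- c("point_cloud", class(out))
  out
}

#' @rdname read_coordinates
#' @param cloud A point cloud (data frame with `x`, `y`).
#' @param header Write a header row (default TRUE).
#' @export
write_coordinates <- function(cloud, path, header = TRUE) {
  lines <- sprintf("%.17g,%.17g", cloud$x, cloud$y)
  if (header) lines <- c("x,y", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write barcode files
#'
#' Barcodes are tab-delimited with columns `dim`, `birth`, `death`; the
#' death of an essential class is the sentinel `inf`. Round-trips are
#' bit-exact.
#'
#' @param diagram A `persistence_diagram`.
#' @param path File path.
#' @param threshold Threshold recorded on reading (attribute only).
#' @return `read_barcode` returns a `persistence_diagram`.
#' @export
write_barcode <- function(diagram, path) {
  death <- ifelse(is.finite(diagram$death),
                  sprintf("%.17g", diagram$death), "inf")
  lines <- c("dim\tbirth\tdeath",
             sprintf("%d\t%.17g\t%s", diagram$dimension, diagram$birth, death))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path, threshold = NA_real_) {
  if (!file.exists(path)) {
    abort(sprintf("barcode file not found: %s", path),
          class = "colonytda_missing_input")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) {
    abort(sprintf("barcode file is empty: %s", path),
          class = "colonytda_parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(new_diagram(integer(0), numeric(0), numeric(0), threshold))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed row at line %d of %s", bad[1] + 1L, path),
          class = "colonytda_parse_error")
  }
  m <- do.call(rbind, parts)
  death <- ifelse(m[, 3] == "inf", Inf, suppressWarnings(as.numeric(m[, 3])))
  dim <- suppressWarnings(as.integer(m[, 1]))
  birth <- suppressWarnings(as.numeric(m[, 2]))
  if (any(is.na(dim)) || any(is.na(birth)) || any(is.na(death))) {
    abort(sprintf("non-numeric fields in %s", path),
          class = "colonytda_parse_error")
  }
  new_diagram(dim, birth, death, threshold)
}

#' Read and write landscape matrix files
#'
#' Tab-delimited: a header row of grid sample points, then one row per
#' landscape function, each row led by the function name. Round-trips are
#' exact.
#'
#' @param lm A `landscape_matrix`.
#' @param path File path.
#' @return `read_landscape` returns a `landscape_matrix`.
#' @export
write_landscape <- function(lm, path) {
  t <- attr(lm, "sample_points")
  header <- paste(c("function", sprintf("%.17g", t)), collapse = "\t")
  body <- vapply(seq_len(nrow(lm)), function(i) {
    paste(c(rownames(lm)[i], sprintf("%.17g", lm[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("landscape file not found: %s", path),
          class = "colonytda_missing_input")
  }
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  t <- as.numeric(header[-1])
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(vals) <- vapply(parts, `[[`, character(1), 1)
  colnames(vals) <- sprintf("t%g", t)
  dims <- unique(as.integer(sub("dim(\\d+)_.*", "\\1", rownames(vals))))
  n_fun <- sum(grepl(sprintf("^dim%d_", dims[1]), rownames(vals)))
  attr(vals, "sample_points") <- t
  attr(vals, "dims_used") <- dims
  attr(vals, "n_functions") <- n_fun
  class(vals) <- c("landscape_matrix", class(vals))
  vals
}

#' Write a dataset as per-frame coordinate files plus a label table
#'
#' One file `<colony>_<timepoint>.csv` per colony frame (pattern
#' configurable) and a `labels.csv` mapping colony to class.
#'
#' @param dataset Dataset tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param pattern `sprintf` pattern with two placeholders: colony id and
#'   timepoint.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, pattern = "%s_t%03d.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    dataset[c("colony_id", "timepoint", "points")],
    function(colony_id, timepoint, points) {
      p <- file.path(dir, sprintf(pattern, colony_id, timepoint))
      write_coordinates(points, p)
      p
    })
  lab <- dataset_labels(dataset)
  lab_path <- file.path(dir, "labels.csv")
  writeLines(c("colony_id,class",
               sprintf("%s,%s", lab$colony_id, lab$class)), lab_path)
  invisible(c(paths, lab_path))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing coordinate files and `labels.csv`.
#' @param pattern Filename pattern used when writing.
#' @return A dataset tibble (`colony_id`, `class`, `timepoint`, `points`).
#' @export
read_dataset <- function(dir, pattern = "%s_t%03d.csv") {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    abort(sprintf("label table not found: %s", lab_path),
          class = "colonytda_missing_input")
  }
  lab <- utils::read.csv(lab_path, colClasses = "character")
  rx <- paste0("^", gsub("%s", "(.+)", gsub("%03d", "(\\\\d+)",
               gsub("\\.", "\\\\.", pattern))), "$")
  files <- setdiff(list.files(dir), "labels.csv")
  hits <- regmatches(files, regexec(rx, files))
  rows <- purrr::compact(purrr::map2(files, hits, function(f, h) {
    if (length(h) != 3) return(NULL)
    cls <- lab$class[match(h[2], lab$colony_id)]
    if (is.na(cls)) return(NULL)
    tibble::tibble(colony_id = h[2], class = cls,
                   timepoint = as.integer(h[3]),
                   points = list(read_coordinates(file.path(dir, f))))
  }))
  dplyr::arrange(dplyr::bind_rows(rows), .data$colony_id, .data$timepoint)
}
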