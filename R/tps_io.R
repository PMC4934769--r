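#' Landmark configuration for one specimen
#'
#' Bundles one specimen's ordered 2-D landmark coordinates with the roles of
#' the points (fixed anatomical landmarks vs outline semi-landmarks) and
#' specimen metadata. Points are stored fixed-landmarks-first; semi-landmark
#' indices therefore form a consecutive block after the fixed ones. The
#' outline ordering used for tangent estimation during sliding is carried
#' separately (see [sliding_spec()]).
#'
#' @param specimen_id character scalar identifying the specimen.
#' @param points numeric n x 2 matrix of (x, y) coordinates, n >= 3.
#' @param fixed integer indices of anatomical landmarks.
#' @param semi integer indices of outline semi-landmarks (a consecutive run).
#' @param scale optional image scale factor already applied to `points`.
#' @param meta named list of metadata (site, phase, taxon, status, ...).
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, points, fixed = NULL, semi = NULL,
                            scale = NULL, meta = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (ncol(points) != 2L)
    stop("points must be an n x 2 matrix of 2-D coordinates", call. = FALSE)
  if (n < 3L) stop("a configuration needs at least 3 points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("non-finite coordinates in configuration '", specimen_id, "'",
         call. = FALSE)
  if (is.null(fixed) && is.null(semi)) {
    fixed <- seq_len(n)
    semi <- integer(0)
  }
  fixed <- as.integer(fixed %||% setdiff(seq_len(n), semi))
  semi <- as.integer(semi %||% integer(0))
  idx <- sort(c(fixed, semi))
  if (!identical(idx, seq_len(n)))
    stop("fixed and semi indices must partition 1..", n, call. = FALSE)
  if (length(semi) > 1L && !all(diff(sort(semi)) == 1L))
    stop("semi-landmark indices must be consecutive along the outline",
         call. = FALSE)
  structure(
    list(specimen_id = as.character(specimen_id), points = points,
         fixed = fixed, semi = semi, scale = scale, meta = meta),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("landmark_config '", x$specimen_id, "': ", nrow(x$points), " points (",
      length(x$fixed), " fixed, ", length(x$semi), " semi)\n", sep = "")
  invisible(x)
}

# split a TPS "KEY=value" line
.tps_key <- function(line) {
  m <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
  if (length(m) == 0L) NULL else list(key = toupper(m[2]), value = trimws(m[3]))
}

#' Read landmark data in TPS format
#'
#' Parses the TPS dialect written by the tpsDig digitizing tools: records are
#' introduced by an `LM=` count line, followed by that many coordinate rows,
#' optional `CURVES=`/`POINTS=` outline blocks (whose points are appended
#' after the fixed landmarks and flagged as semi-landmarks), and trailing
#' `ID=`, `IMAGE=` and `SCALE=` lines. When a `SCALE=` factor is present the
#' coordinates are multiplied by it. 3-D records (`LM3=`) are rejected.
#'
#' @param path path to a TPS file.
#' @return A list of [landmark_config] objects, one per record, in file order.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  n_lines <- length(lines)

  read_coords <- function(start, count) {
    if (start + count - 1L > n_lines)
      stop("TPS parse error at line ", start,
           ": fewer coordinate rows than declared", call. = FALSE)
    block <- lines[seq(start, length.out = count)]
    vals <- lapply(seq_along(block), function(k) {
      fields <- strsplit(trimws(block[k]), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(fields))
      if (length(num) == 3L && all(is.finite(num)))
        stop("TPS dimensionality error at line ", start + k - 1L,
             ": 3-D coordinates are not supported", call. = FALSE)
      if (length(num) != 2L || anyNA(num))
        stop("TPS parse error at line ", start + k - 1L,
             ": expected two numeric coordinates", call. = FALSE)
      num
    })
    do.call(rbind, vals)
  }

  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    kv <- .tps_key(lines[i])
    if (is.null(kv) || !(kv$key %in% c("LM", "LM3")))
      stop("TPS parse error at line ", i, ": expected an LM= record header",
           call. = FALSE)
    if (kv$key == "LM3")
      stop("TPS dimensionality error at line ", i,
           ": 3-D (LM3=) records are not supported", call. = FALSE)
    n_lm <- suppressWarnings(as.integer(kv$value))
    if (is.na(n_lm) || n_lm < 0L)
      stop("TPS parse error at line ", i, ": malformed landmark count",
           call. = FALSE)
    i <- i + 1L
    pts <- if (n_lm > 0L) read_coords(i, n_lm) else matrix(0, 0L, 2L)
    i <- i + n_lm
    semi_pts <- matrix(0, 0L, 2L)
    id <- NULL; scale <- NULL
    while (i <= n_lines) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      kv <- .tps_key(lines[i])
      if (is.null(kv))
        stop("TPS parse error at line ", i, ": unexpected content", call. = FALSE)
      if (kv$key %in% c("LM", "LM3")) break
      if (kv$key == "CURVES") {
        n_curves <- suppressWarnings(as.integer(kv$value))
        if (is.na(n_curves))
          stop("TPS parse error at line ", i, ": malformed CURVES count",
               call. = FALSE)
        i <- i + 1L
        for (cu in seq_len(n_curves)) {
          kvp <- .tps_key(lines[i])
          if (is.null(kvp) || kvp$key != "POINTS")
            stop("TPS parse error at line ", i, ": expected POINTS= line",
                 call. = FALSE)
          n_pts <- suppressWarnings(as.integer(kvp$value))
          if (is.na(n_pts) || n_pts < 0L)
            stop("TPS parse error at line ", i, ": malformed POINTS count",
                 call. = FALSE)
          i <- i + 1L
          semi_pts <- rbind(semi_pts, read_coords(i, n_pts))
          i <- i + n_pts
        }
      } else if (kv$key == "ID") {
        id <- kv$value; i <- i + 1L
      } else if (kv$key == "SCALE") {
        scale <- suppressWarnings(as.numeric(kv$value))
        if (is.na(scale))
          stop("TPS parse error at line ", i, ": malformed SCALE value",
               call. = FALSE)
        i <- i + 1L
      } else {
        i <- i + 1L  # IMAGE=, COMMENT=, etc.: ignored
      }
    }
    all_pts <- rbind(pts, semi_pts)
    if (!is.null(scale)) all_pts <- all_pts * scale
    configs[[length(configs) + 1L]] <- landmark_config(
      specimen_id = id %||% as.character(length(configs) + 1L),
      points = all_pts,
      fixed = seq_len(nrow(pts)),
      semi = if (nrow(semi_pts) > 0L) nrow(pts) + seq_len(nrow(semi_pts))
             else integer(0),
      scale = scale)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' The inverse of [read_tps()]: fixed landmarks go under `LM=`, semi-landmarks
#' under one `CURVES=1`/`POINTS=` block, followed by `ID=` and, when a scale
#' factor is recorded, a `SCALE=` line (coordinates are divided by the scale
#' on output so the read/write round trip is the identity).
#'
#' @param configs non-empty list of [landmark_config] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stop("configs must be non-empty", call. = FALSE)
  fmt <- function(p) paste(sprintf("%.12g", p[, 1]), sprintf("%.12g", p[, 2]))
  out <- unlist(lapply(configs, function(cf) {
    pts <- cf$points
    if (!is.null(cf$scale)) pts <- pts / cf$scale
    rec <- c(sprintf("LM=%d", length(cf$fixed)),
             if (length(cf$fixed)) fmt(pts[cf$fixed, , drop = FALSE]))
    if (length(cf$semi)) {
      rec <- c(rec, "CURVES=1", sprintf("POINTS=%d", length(cf$semi)),
               fmt(pts[cf$semi, , drop = FALSE]))
    }
    rec <- c(rec, sprintf("ID=%s", cf$specimen_id))
    if (!is.null(cf$scale)) rec <- c(rec, sprintf("SCALE=%.12g", cf$scale))
    rec
  }))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a specimen isotope table
#'
#' Reads a CSV of bone-collagen stable isotope measurements with one row per
#' specimen. Required columns: `specimen_id`, `taxon`, `phase`, `d13C`
#' (per mil VPDB), `d15N` (per mil AIR). Optional: `dental_stage`,
#' `M3_length` (mm), `site`, `status`. Rows with non-numeric mandatory delta
#' values are rejected with the offending specimen ids.
#'
#' @param path path to a CSV file (UTF-8, decimal point).
#' @return A data frame of class `isotope_data`, empty if the file has only a
#'   header.
#' @export
read_isotope_csv <- function(path) {
  if (!file.exists(path)) stop("isotope CSV not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("specimen_id", "taxon", "phase", "d13C", "d15N")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("isotope CSV missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0L) {
    for (col in c("d13C", "d15N")) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
      if (length(bad))
        stop("non-numeric ", col, " for specimen(s): ",
             paste(df$specimen_id[bad], collapse = ", "), call. = FALSE)
      if (anyNA(vals))
        stop("missing ", col, " for specimen(s): ",
             paste(df$specimen_id[is.na(vals)], collapse = ", "), call. = FALSE)
      df[[col]] <- vals
    }
    for (col in c("dental_stage", "M3_length"))
      if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  class(df) <- c("isotope_data", "data.frame")
  df
}
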