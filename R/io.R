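# Serialization of pipeline artifacts.
#
# Delimited dialect everywhere: comma-separated, UTF-8, '.' decimal, first
# column the sample id. Numeric values are written with "%.17g" so that a
# text round trip reproduces the doubles bit-exactly. Map grids carry their
# metadata in leading '#' comment lines. The binary-array alternative
# (format = "rds") uses R's serialization with a fixed version.

fmt_num <- function(x) sprintf("%.17g", x)

detect_format <- function(path) if (grepl("\\.rds$", path)) "rds" else "csv"

#' Write / read a feature matrix
#'
#' Delimited format: header `id,f1,...,fF`, one row per sample, first column
#' the unique sample id. `format = "rds"` writes the same object as a binary
#' array container.
#'
#' @param x numeric matrix with unique row-name ids (ids `s1`, `s2`, ... are
#'   generated when absent).
#' @param path file path; a `.rds` extension selects the binary format when
#'   `format` is not given.
#' @param format `"csv"` or `"rds"`.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the matrix with id row names.
#' @export
write_feature_matrix <- function(x, path, format = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stopf("duplicate sample ids")
  if (is.null(format)) format <- detect_format(path)
  if (format == "rds") {
    saveRDS(x, path, version = 2)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("id", sprintf("f%d", seq_len(ncol(x)))), collapse = ","), con)
    body <- vapply(seq_len(nrow(x)), function(i)
      paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = ","), character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("feature file not found: %s", path)
  if (is.null(format)) format <- detect_format(path)
  if (format == "rds") {
    x <- readRDS(path)
    if (!is.matrix(x) || !is.numeric(x)) stopf("not a numeric feature matrix: %s", path)
    return(x)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stopf("feature file has no data rows: %s", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- length(parts[[1]])
  if (nfield < 2L) stopf("feature file needs an id column plus features: %s", path)
  bad <- which(lengths(parts) != nfield)
  if (length(bad) > 0) stopf("ragged row %d: expected %d fields, found %d",
                             bad[1], nfield, length(parts[[bad[1]]]))
  ids <- vapply(parts[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate sample id '%s' at row %d",
                                ids[anyDuplicated(ids)],
                                anyDuplicated(ids) + 1L)
  vals <- suppressWarnings(
    vapply(parts[-1L], function(p) as.numeric(p[-1L]), numeric(nfield - 1L)))
  vals <- if (nfield == 2L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1L, anyNA))[1]
    stopf("non-numeric cell at row %d", bad_row + 1L)
  }
  rownames(vals) <- ids
  colnames(vals) <- sprintf("f%d", seq_len(ncol(vals)))
  vals
}

#' Write / read a label table
#'
#' CSV with required columns `image_id`, `category`, `animacy`, `size` (plus
#' an optional `split` tag). Attribute values are validated: `animacy` must
#' be `animate`/`inanimate`, `size` must be `big`/`small`.
#'
#' @param labels data frame of labels.
#' @param path file path.
#' @return `read_label_table` returns the validated data frame.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  labels <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "category", "animacy", "size")
  miss <- setdiff(required, names(labels))
  if (length(miss) > 0) stopf("label table missing column(s): %s",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(labels$image_id))
    stopf("duplicate image_id '%s'", labels$image_id[anyDuplicated(labels$image_id)])
  bad_a <- setdiff(unique(labels$animacy), c("animate", "inanimate"))
  if (length(bad_a) > 0) stopf("unknown animacy value(s): %s", paste(bad_a, collapse = ", "))
  bad_s <- setdiff(unique(labels$size), c("big", "small"))
  if (length(bad_s) > 0) stopf("unknown size value(s): %s", paste(bad_s, collapse = ", "))
  labels
}

#' Save / load a fitted map archive
#'
#' Writes the codebook as a full-precision delimited matrix (or `.rds`
#' binary array with `format = "rds"`) plus a JSON sidecar carrying the grid
#' shape, feature dimension, config echo (including the seed), the
#' quantization-error and schedule traces, and a format version. Two runs
#' with the same seed produce byte-identical archives; run timestamps belong
#' in the separate run manifest ([write_manifest()]).
#'
#' @param object a fitted [som()] object.
#' @param stem path stem; files `<stem>_codebook.csv` (or `.rds`) and
#'   `<stem>_codebook.json` are written.
#' @param format `"csv"` (default) or `"rds"`.
#' @return `write_som` returns the sidecar path invisibly; `read_som`
#'   returns a `"som"` object (without training data).
#' @export
write_som <- function(object, stem, format = c("csv", "rds")) {
  stopifnot(inherits(object, "som"))
  format <- match.arg(format)
  cb_path <- paste0(stem, "_codebook.", format)
  write_feature_matrix(`rownames<-`(object$codebook,
                                    sprintf("u%04d", seq_len(nrow(object$codebook)) - 1L)),
                       cb_path, format = format)
  sidecar <- list(
    format_version = "somtopo-codebook-1",
    grid = list(W = unname(object$grid[1]), H = unname(object$grid[2])),
    feature_dim = ncol(object$codebook),
    n_samples = object$n_samples,
    config = object$config,
    trace = object$trace,
    codebook_file = basename(cb_path),
    codebook_format = format)
  json_path <- paste0(stem, "_codebook.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}

#' @rdname write_som
#' @export
read_som <- function(stem) {
  json_path <- paste0(stem, "_codebook.json")
  if (!file.exists(json_path)) stopf("codebook sidecar not found: %s", json_path)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(side$format_version, "somtopo-codebook-1"))
    stopf("unsupported codebook archive version: %s", side$format_version)
  cb <- read_feature_matrix(file.path(dirname(json_path), side$codebook_file),
                            format = side$codebook_format)
  dimnames(cb) <- NULL
  W <- side$grid$W; H <- side$grid$H
  structure(list(
    codebook = cb, grid = c(W = W, H = H), coords = grid_coords(W, H),
    trace = list(qe = side$trace$qe, qe_initial = side$trace$qe_initial,
                 learning_rate = side$trace$learning_rate,
                 radius = side$trace$radius),
    plane = NULL, config = side$config, n_samples = side$n_samples,
    data = NULL, call = NULL), class = "som")
}

#' Write / read a numeric map grid
#'
#' W x H CSV grid, row-major (one line per grid row `w`), preceded by `#`
#' metadata lines (`# key: value`) that always include the grid shape.
#'
#' @param grid W x H numeric matrix (e.g. from [activation_map()], or the
#'   `score` matrix of a selectivity map).
#' @param path file path.
#' @param meta named list of scalar metadata to record.
#' @return `read_map_grid` returns the matrix with the metadata in attribute
#'   `"meta"`.
#' @export
write_map_grid <- function(grid, path, meta = list()) {
  grid <- as.matrix(grid)
  meta <- c(list(grid = paste(dim(grid), collapse = " ")), meta)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), vapply(meta, as.character, character(1))), con)
  writeLines(vapply(seq_len(nrow(grid)), function(i)
    paste(fmt_num(grid[i, ]), collapse = ","), character(1)), con)
  invisible(path)
}

#' @rdname write_map_grid
#' @export
read_map_grid <- function(path) {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  meta <- as.list(sub("^[^:]+:\\s*", "", meta_raw))
  names(meta) <- sub(":.*$", "", meta_raw)
  rows <- strsplit(lines[!is_meta], ",", fixed = TRUE)
  grid <- do.call(rbind, lapply(rows, as.numeric))
  if (!is.null(meta$grid)) {
    shape <- as.integer(strsplit(meta$grid, " ")[[1]])
    if (!identical(dim(grid), shape) && !identical(as.integer(dim(grid)), shape))
      stopf("map grid shape %dx%d does not match header %s",
            nrow(grid), ncol(grid), meta$grid)
  }
  attr(grid, "meta") <- meta
  grid
}

#' Write / read a preference map
#'
#' Long-format CSV (`w,h,preferred,strength,tie`, 0-based row-major
#' coordinates) with `#` metadata lines carrying the grid shape, condition
#' list, mode, and grouping attribute.
#'
#' @param pref a [preference_map()] object.
#' @param path file path.
#' @return `read_preference_map` returns a `"preference_map"` object.
#' @export
write_preference_map <- function(pref, path) {
  stopifnot(inherits(pref, "preference_map"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# grid: %d %d", pref$grid[1], pref$grid[2]),
               sprintf("# conditions: %s", paste(pref$conditions, collapse = ",")),
               sprintf("# mode: %s", pref$mode),
               sprintf("# grouping: %s", pref$grouping),
               "w,h,preferred,strength,tie"), con)
  co <- grid_coords(pref$grid[1], pref$grid[2])
  writeLines(sprintf("%d,%d,%s,%s,%d", co[, 1], co[, 2],
                     grid_to_unit(pref$preferred),
                     fmt_num(grid_to_unit(pref$strength)),
                     as.integer(grid_to_unit(pref$tie))), con)
  invisible(path)
}

#' @rdname write_preference_map
#' @export
read_preference_map <- function(path) {
  if (!file.exists(path)) stopf("preference map not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  meta <- as.list(sub("^[^:]+:\\s*", "", meta_raw))
  names(meta) <- sub(":.*$", "", meta_raw)
  grid <- as.integer(strsplit(meta$grid, " ")[[1]])
  df <- utils::read.csv(text = lines[!is_meta], stringsAsFactors = FALSE)
  ord <- order(df$w, df$h)  # row-major
  df <- df[ord, ]
  structure(list(
    preferred = unit_to_grid(df$preferred, grid),
    strength = unit_to_grid(as.numeric(df$strength), grid),
    tie = unit_to_grid(df$tie == 1L, grid),
    conditions = strsplit(meta$conditions, ",")[[1]],
    mode = meta$mode, grouping = meta$grouping,
    grid = c(W = grid[1], H = grid[2])), class = "preference_map")
}

#' Render a map grid as a PNG heatmap
#'
#' Writes a heatmap with symmetric color limits and saturation clipping:
#' values beyond `clim` render at the end colors, and the same limits can be
#' reused across maps so their colors are comparable.
#'
#' @param grid W x H numeric matrix.
#' @param path output PNG path.
#' @param clim color limits `c(lo, hi)`; default symmetric about 0 at the
#'   largest absolute finite value.
#' @param palette color vector (default a diverging blue-red ramp).
#' @param width,height device size in pixels.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(grid, path, clim = NULL, palette = NULL,
                          width = 480, height = 480, main = "") {
  if (is.null(clim)) {
    m <- max(abs(grid[is.finite(grid)]))
    if (m == 0) m <- 1
    clim <- c(-m, m)
  }
  if (is.null(palette)) palette <- grDevices::hcl.colors(64, "Blue-Red 3")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  image_grid(as.matrix(grid), main = main, zlim = clim, col = palette)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline stage bit-identically:
#' config echoes, input-file MD5 digests, seeds, package version, timestamp,
#' and the ordered stage log.
#'
#' @param path output JSON path.
#' @param stage name of the pipeline stage.
#' @param config named list of configuration (must include any seeds).
#' @param inputs character vector of input file paths (digested if present).
#' @param log character vector of stage log lines.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, config = list(), inputs = character(),
                           log = character()) {
  digests <- if (length(inputs) > 0) {
    md5 <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(md5)
  } else list()
  manifest <- list(stage = stage,
                   software = paste0("somtopo ", as.character(utils::packageVersion("somtopo"))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config,
                   input_digests = digests,
                   log = as.list(log))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
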