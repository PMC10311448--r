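#' Load an image or video from standard formats
#'
#' Images: PNG or TIFF (8/16-bit greyscale; colour is converted by channel
#' averaging). Videos: multi-page TIFF, or a directory of numbered
#' PNG/TIFF frames. Values are returned as real numbers in `[0, 1]`
#' (readers scale by the file bit depth); metadata records the source.
#'
#' The returned array follows the package convention: first index `x1`,
#' second `x2` (and third `t` for videos).
#'
#' @param path File (image, multi-page TIFF) or directory (frame sequence).
#' @param kind `"image"` or `"video"`.
#' @return Array with attribute `media_meta` (list with `path`, `format`,
#'   `n_frames` for videos).
#' @export
load_media <- function(path, kind = c("image", "video")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (kind == "image") {
    img <- read_frame(path)
    attr(img, "media_meta") <- list(path = path,
                                    format = tools::file_ext(path))
    img
  } else {
    frames <- if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0L) stop("no frames found in directory: ", path)
      lapply(files, read_frame)
    } else {
      pages <- tiff::readTIFF(path, all = TRUE)
      lapply(pages, frame_to_x1x2)
    }
    d1 <- vapply(frames, nrow, integer(1))
    d2 <- vapply(frames, ncol, integer(1))
    if (length(unique(d1)) != 1L || length(unique(d2)) != 1L)
      stop("inconsistent frame sizes in video source")
    out <- array(unlist(frames), c(d1[1L], d2[1L], length(frames)))
    attr(out, "media_meta") <- list(path = path,
                                    format = if (dir.exists(path))
                                      "frame_directory" else "tiff",
                                    n_frames = length(frames))
    out
  }
}

# read one image file as an [x1, x2] matrix in [0, 1]
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  frame_to_x1x2(raw)
}

# image readers return [row = y, col = x] matrices (possibly with channel
# planes); average channels and transpose into the [x1, x2] convention
frame_to_x1x2 <- function(raw) {
  if (length(dim(raw)) == 3L) raw <- apply(raw, c(1, 2), mean)
  t(raw)
}

#' Write an image or video to PNG/TIFF
#'
#' Images are written as 8-bit greyscale PNG or 16-bit TIFF (by
#' extension); videos as 16-bit multi-page TIFF. Values are clipped to
#' `[0, 1]`.
#'
#' @param x Array in the `[x1, x2(, t)]` convention.
#' @param path Output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_media <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  clip <- function(v) pmin(pmax(v, 0), 1)
  if (length(dim(x)) == 2L) {
    m <- t(clip(x))
    switch(ext,
           png = png::writePNG(m, path),
           tif = ,
           tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
           stop("unsupported image format: ", ext))
  } else {
    pages <- lapply(seq_len(dim(x)[3L]), function(k) t(clip(x[, , k])))
    if (!ext %in% c("tif", "tiff"))
      stop("videos are written as multi-page TIFF")
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Export a kernel as CSV
#'
#' Row-major CSV of kernel weights preceded by comment lines carrying the
#' generating parameters, so a kernel file is self-describing.
#'
#' @param kernel 2-D kernel matrix (with optional `spec` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_kernel_csv <- function(kernel, path) {
  spec <- attr(kernel, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec)) {
    fields <- vapply(names(unclass(spec)), function(nm) {
      v <- unclass(spec)[[nm]]
      if (inherits(v, "spatial_covariance"))
        sprintf("%s=lam1:%g,lam2:%g,phi:%g", nm, v$lam1, v$lam2, v$phi)
      else sprintf("%s=%s", nm, paste(format(unlist(v)), collapse = ","))
    }, character(1))
    writeLines(paste("#", fields), con)
  }
  utils::write.table(kernel, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Render a kernel to PNG with a signed colour scale
#'
#' Maps kernel weights symmetrically around zero onto a blue-white-red
#' ramp, so excitatory and inhibitory lobes are distinguishable, and writes
#' a PNG.
#'
#' @param kernel 2-D kernel matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_kernel_png <- function(kernel, path) {
  a <- max(abs(kernel))
  if (a == 0) a <- 1
  z <- kernel / a  # [-1, 1]
  r <- ifelse(z >= 0, 1, 1 + z)
  g <- 1 - abs(z)
  b <- ifelse(z <= 0, 1, 1 - z)
  img <- array(c(t(r), t(g), t(b)), c(ncol(kernel), nrow(kernel), 3L))
  png::writePNG(img, path)
  invisible(path)
}

#' Load a suite configuration from YAML or JSON
#'
#' Unknown top-level keys are rejected; omitted keys are filled from
#' [default_suite_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON"))
  def <- default_suite_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(def, cfg)
}

#' Write a covariance or hypothesis report to disk
#'
#' Serialises the report as schema-stable JSON plus a CSV summary table.
#' The JSON embeds the full resolved configuration and seed (for
#' covariance reports), giving complete provenance.
#'
#' @param report A `covariance_report` or `hypothesis_report`.
#' @param path Output path without extension (or with `.json`, stripped).
#' @return Invisibly, a list with `json` and `csv` paths and `ok` (TRUE
#'   when every contained assertion passed).
#' @export
write_report <- function(report, path) {
  stem <- sub("\\.json$", "", path)
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  if (inherits(report, "covariance_report")) {
    payload <- list(schema = "gaussrf-covariance-report/1",
                    config = report$config,
                    entries = report$entries,
                    n_pass = report$n_pass, n_fail = report$n_fail)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    utils::write.csv(report$entries, csv_path, row.names = FALSE)
    ok <- report$n_fail == 0L
  } else if (inherits(report, "hypothesis_report")) {
    payload <- list(schema = "gaussrf-hypothesis-report/1",
                    eccentricity = report$eccentricity,
                    v_speed = report$v_speed,
                    sigma_space = report$sigma_space,
                    sigma_time = report$sigma_time,
                    H1 = report$H1, H2 = report$H2, H3 = report$H3,
                    degenerate = report$degenerate,
                    thresholds = report$thresholds)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    df <- data.frame(eccentricity = report$eccentricity,
                     v_speed = if (is.null(report$v_speed)) NA
                               else report$v_speed,
                     sigma_space = report$sigma_space,
                     sigma_time = report$sigma_time)
    utils::write.csv(df, csv_path, row.names = FALSE)
    ok <- TRUE
  } else stop("unsupported report type")
  invisible(list(json = json_path, csv = csv_path, ok = ok))
}
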