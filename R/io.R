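# File interchange: multi-page TIFF movies and stacks with YAML
# metadata sidecars, localization CSV (with ThunderSTORM-dialect header
# aliases), rendered-image TIFF, and foci CSV.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write / read a simulated movie as 16-bit multi-page TIFF + YAML
#'
#' The TIFF stores integer counts; acquisition metadata (pixel size,
#' gain, offset and the full parameter set) goes to a `<path>.yaml`
#' sidecar so a movie round-trips losslessly.
#'
#' @param stack a `movie_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(f) stack$data[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- stack$params
  class(meta) <- NULL
  yaml::write_yaml(list(type = "fbalm_movie", params = meta),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_movie
#' @param params optional [acquisition_params()] overriding the sidecar.
#' @export
read_movie <- function(path, params = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  arr <- array(0L, dim = d)
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  if (is.null(params)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop_param("no metadata sidecar found at %s; pass `params`", sc)
    meta <- yaml::read_yaml(sc)$params
    meta$fov_px <- d[1:2]
    params <- do.call(acquisition_params, meta[names(meta) != "n_frames"])
    params$n_frames <- d[3]
  }
  structure(list(data = arr, params = params), class = "movie_stack")
}

loc_columns <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons",
                 "background", "precision_nm", "n_merged")

# ThunderSTORM-dialect column aliases accepted on read.
loc_aliases <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm",
                 "sigma [nm]" = "sigma_nm",
                 "intensity [photon]" = "photons",
                 "bkgstd [photon]" = "background",
                 "uncertainty [nm]" = "precision_nm",
                 "uncertainty_xy [nm]" = "precision_nm",
                 "detections" = "n_merged", "id" = "id")

#' Write / read a localization table as CSV
#'
#' The canonical header is
#' `frame,x_nm,y_nm,sigma_nm,photons,background,precision_nm,n_merged`.
#' On read, ThunderSTORM-dialect names (`x [nm]`, `y [nm]`,
#' `sigma [nm]`, `intensity [photon]`, `bkgstd [photon]`,
#' `uncertainty [nm]`) are accepted as aliases; unknown extra columns
#' are preserved. Missing `sigma_nm`/`photons`/`background`/
#' `precision_nm`/`n_merged` are tolerated and filled with defaults
#' (`NA` or 1), but `frame`, `x_nm` and `y_nm` are mandatory.
#'
#' @param table a `loc_table`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `loc_table` (read).
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @param pixel_size_nm pixel size recorded on the returned table.
#' @export
read_localizations <- function(path, pixel_size_nm = NA_real_) {
  df <- read.csv(path, check.names = FALSE)
  hit <- names(df) %in% names(loc_aliases)
  names(df)[hit] <- loc_aliases[names(df)[hit]]
  miss <- setdiff(c("frame", "x_nm", "y_nm"), names(df))
  if (length(miss) > 0L)
    stop_param("localization CSV is missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  if (is.null(df$sigma_nm)) df$sigma_nm <- NA_real_
  if (is.null(df$photons)) df$photons <- NA_real_
  if (is.null(df$background)) df$background <- NA_real_
  if (is.null(df$precision_nm)) df$precision_nm <- NA_real_
  if (is.null(df$n_merged)) df$n_merged <- 1L
  loc_table(df, pixel_size_nm, source = path)
}

#' Write / read a rendered image as 32-bit float TIFF + YAML
#'
#' @param image a `rendered_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rendered <- function(image, path) {
  stopifnot(inherits(image, "rendered_image"))
  v <- image$values
  hi <- max(v, 1)
  tiff::writeTIFF(v / hi, path, bits.per.sample = 32L,
                  compression = "none")
  yaml::write_yaml(list(type = "fbalm_rendered", mode = image$mode,
                        pixel_size_nm = image$pixel_size_nm,
                        origin_nm = as.numeric(image$origin_nm),
                        scale = hi, sum = sum(v)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_rendered
#' @export
read_rendered <- function(path) {
  v <- tiff::readTIFF(path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop_param("no metadata sidecar found at %s", sc)
  meta <- yaml::read_yaml(sc)
  new_rendered_image(v * meta$scale, meta$pixel_size_nm,
                     as.numeric(meta$origin_nm), meta$mode)
}

#' Write / read a 3D foci table as CSV (`x_nm,y_nm,z_nm,intensity`)
#'
#' @param foci a `foci3d` object.
#' @param path CSV path.
#' @return `path` invisibly (write); a `foci3d` (read).
#' @export
write_foci <- function(foci, path) {
  stopifnot(inherits(foci, "foci3d"))
  df <- data.frame(x_nm = foci$positions[, 1],
                   y_nm = foci$positions[, 2],
                   z_nm = foci$positions[, 3],
                   intensity = foci$intensities)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_foci
#' @export
read_foci <- function(path) {
  df <- read.csv(path)
  miss <- setdiff(c("x_nm", "y_nm", "z_nm"), names(df))
  if (length(miss) > 0L)
    stop_param("foci CSV is missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  structure(list(positions = as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
                 intensities = if (is.null(df$intensity)) rep(1, nrow(df))
                               else df$intensity,
                 nucleus = NULL),
            class = "foci3d")
}

#' Write an FRC curve as CSV (`q_per_nm,frc,n_pixels`)
#'
#' @param curve an `frc_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frc_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
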