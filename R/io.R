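## Readers and writers: PDB coordinates (via bio3d), MRC2014 density maps
## (no R package provides MRC, so the format is implemented here with
## readBin/writeBin), point-cloud CSV, and TIFF/PNG images when the optional
## packages are present.

#' Read coordinates from a PDB file
#'
#' @param path PDB file.
#' @param selection \code{"all"} (every atom record) or \code{"ca"}
#'   (C-alpha atoms of amino-acid residues).
#' @param stride Keep every \code{stride}-th atom of the selected list (in
#'   file order, starting with the first), i.e. \code{ceiling(n / stride)}
#'   coordinates.
#' @return \code{n x 3} coordinate matrix (Angstrom).
#' @export
read_pdb_coordinates <- function(path, selection = c("all", "ca"), stride = 1) {
  selection <- match.arg(selection)
  pdb <- bio3d::read.pdb(path)
  xyz <- if (selection == "ca") {
    sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
    pdb$atom[sel$atom, c("x", "y", "z")]
  } else pdb$atom[, c("x", "y", "z")]
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("no atoms after selection")
  if (stride > 1) xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  unname(xyz)
}

#' Write a cubic density map as MRC2014
#'
#' Mode-2 (float32) little-endian MRC2014 with the voxel size recorded in
#' the cell dimensions.
#'
#' @param map List with \code{density} (cubic 3D array) and
#'   \code{voxel_size}, as from \code{\link{render_volume}}, or a 3D array
#'   plus \code{voxel_size} argument.
#' @param path Output file.
#' @param voxel_size Voxel edge (Angstrom), if \code{map} is a bare array.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(map, path, voxel_size = NULL) {
  if (is.list(map)) { den <- map$density; voxel_size <- map$voxel_size }
  else den <- map
  if (length(dim(den)) != 3 || dim(den)[1] != dim(den)[2])
    stop("map must be a 3D array with square x/y sections")
  n <- dim(den)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  dims <- dim(den)
  wi(dims)                  # nx ny nz
  wi(2)                     # mode 2 = float32
  wi(c(0, 0, 0))            # nxstart
  wi(dims)                  # mx my mz
  wf(dims * voxel_size)     # cella
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc mapr maps
  wf(c(min(den), max(den), mean(den)))
  wi(c(1, 0))               # ispg, nsymbt
  wi(rep(0, 2))             # extra words 26-27
  wi(20140)                 # nversion
  wi(rep(0, 22))            # remaining extra
  wf(c(0, 0, 0))            # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(den))        # rms
  wi(0)                     # nlabl
  writeBin(raw(800), con)   # labels
  writeBin(as.numeric(den), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32); the axis order is
#' normalized to x-fastest on read.
#'
#' @param path MRC file.
#' @return List with \code{density} (3D array) and \code{voxel_size}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3)                       # nxstart
  m <- ri(3)                  # mx my mz
  cella <- rf(3)
  rf(3)                       # cellb
  axes <- ri(3)               # mapc mapr maps
  if (any(dims <= 0) || !all(sort(axes) == 1:3))
    stop("malformed MRC header")
  seek(con, 1024)
  nvox <- prod(dims)
  den <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode))
  den <- array(den, dims)
  if (!all(axes == 1:3)) den <- aperm(den, order(axes))
  list(density = den, voxel_size = cella[1] / m[1])
}

#' Write / read 2D point clouds as CSV
#'
#' Comma-separated with header \code{x,y} (optionally \code{,weight}) for 2D
#' clouds or \code{x,y,z} for 3D coordinate sets.
#'
#' @param points A \code{point_cloud_view}, or an \code{n x 2} / \code{n x 3}
#'   matrix.
#' @param path CSV file.
#' @return \code{write_point_cloud_csv} returns \code{path} invisibly;
#'   \code{read_point_cloud_csv} returns a \code{point_cloud_view} (2
#'   columns) or coordinate matrix (3 columns).
#' @export
write_point_cloud_csv <- function(points, path) {
  w <- NULL
  if (inherits(points, "point_cloud_view")) {
    w <- points$weights; points <- points$points
  }
  df <- as.data.frame(points)
  names(df) <- c("x", "y", "z")[seq_len(ncol(df))]
  if (!is.null(w)) df$weight <- w
  ## %.17g renders doubles losslessly, so read(write(x)) is bit-exact
  for (cn in names(df)) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud_csv
#' @export
read_point_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("z" %in% names(df)) return(unname(as.matrix(df[, c("x", "y", "z")])))
  point_cloud_view(as.matrix(df[, c("x", "y")]),
                   weights = df$weight %||% NULL)
}

#' Read a grayscale image as an image_view
#'
#' TIFF and PNG via the optional \pkg{tiff} / \pkg{png} packages; MRC via
#' \code{\link{read_mrc}} (first section of a stack).
#'
#' @param path Image file (extension decides the reader).
#' @param pixel_size Angstrom per pixel to attach.
#' @return An \code{image_view}.
#' @export
read_image <- function(path, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  g <- switch(ext,
    "tif" = , "tiff" = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff not installed")
      tiff::readTIFF(path)
    },
    "png" = {
      if (!requireNamespace("png", quietly = TRUE)) stop("png not installed")
      png::readPNG(path)
    },
    "mrc" = , "map" = {
      d <- read_mrc(path)
      if (is.null(pixel_size)) pixel_size <- d$voxel_size
      if (length(dim(d$density)) == 3) d$density[, , 1] else d$density
    },
    stop("unsupported image format: ", ext))
  if (length(dim(g)) == 3) g <- g[, , 1]   # first channel
  image_view(as.matrix(g), pixel_size)
}
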