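#' @include AllClasses.R
NULL

#' Write a point cloud or tomogram as ASCII PLY
#'
#' Surface point clouds carry per-vertex \code{x y z nx ny nz residual};
#' tomograms carry \code{x y z thickness variance}. \code{readPLY} reads
#' the same ASCII layout back into a data.frame of vertex properties.
#'
#' @param object a \linkS4class{SurfacePointCloud} or
#'   \linkS4class{Tomogram4D}.
#' @param path file path.
#' @return \code{readPLY} returns a data.frame with one column per vertex
#'   property.
#' @export
writePLY <- function(object, path) {
  if (is(object, "SurfacePointCloud")) {
    df <- data.frame(x = object@points[, 1], y = object@points[, 2],
                     z = object@points[, 3], nx = object@normals[, 1],
                     ny = object@normals[, 2], nz = object@normals[, 3],
                     residual = object@residuals)
  } else if (is(object, "Tomogram4D")) {
    df <- data.frame(x = object@points[, 1], y = object@points[, 2],
                     z = object@points[, 3], thickness = object@thickness,
                     variance = object@thicknessVariance)
  } else {
    stop("unsupported object for PLY export")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(df)),
               sprintf("property float %s", names(df)),
               "end_header"), con)
  utils::write.table(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writePLY
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  endH <- which(lines == "end_header")[1]
  props <- sub("^property float ", "",
               grep("^property float ", lines[seq_len(endH)], value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", lines[seq_len(endH)],
                            value = TRUE)[1]))
  body <- lines[endH + seq_len(nv)]
  df <- read.table(text = body, col.names = props)
  df
}

#' Export a cloud as CSV (mirrors the PLY columns)
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param path file path.
#' @export
writeCloudCSV <- function(cloud, path) {
  df <- data.frame(x = cloud@points[, 1], y = cloud@points[, 2],
                   z = cloud@points[, 3], nx = cloud@normals[, 1],
                   ny = cloud@normals[, 2], nz = cloud@normals[, 3],
                   residual = cloud@residuals)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Archive a simulated dataset as a hierarchical directory
#'
#' Writes a scan, its phantom summary and the MRI map into a directory
#' with groups \code{phantom/}, \code{scan/} and \code{mri/} (YAML
#' metadata plus CSV tables), with every seed recorded.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param scan a \linkS4class{NIRScan}.
#' @param mri an \linkS4class{MRIThicknessMap}.
#' @param dir target directory (created).
#' @return the directory path, invisibly.
#' @export
saveScanArchive <- function(phantom, scan, mri, dir) {
  for (g in c("phantom", "scan", "mri")) {
    dir.create(file.path(dir, g), recursive = TRUE, showWarnings = FALSE)
  }
  yaml::write_yaml(list(
    patch_mm = phantom@patchSize,
    thickness_range_mm = phantom@thicknessRange,
    tissue = list(mua = phantom@tissueProps@mua,
                  mus = phantom@tissueProps@mus,
                  g = phantom@tissueProps@g, n = phantom@tissueProps@n),
    bone = list(mua = phantom@boneProps@mua, mus = phantom@boneProps@mus,
                g = phantom@boneProps@g, n = phantom@boneProps@n),
    seed = phantom@seed), file.path(dir, "phantom", "phantom.yaml"))
  write.csv(phantom@markers, file.path(dir, "phantom", "markers.csv"),
            row.names = FALSE)
  writeTransformJSON(phantom@mriTransform,
                     file.path(dir, "phantom", "mri_transform.json"))
  cfg <- scan@config
  yaml::write_yaml(list(
    grid = list(rows = cfg@gridRows, cols = cfg@gridCols,
                col_spacing_mm = cfg@colSpacing,
                row_spacing_mm = cfg@rowSpacing,
                spot_diameter_mm = cfg@spotDiameter,
                wavelength_nm = cfg@wavelength),
    profile_model = cfg@profileModel, seed = scan@seed),
    file.path(dir, "scan", "config.yaml"))
  write.csv(scan@meta, file.path(dir, "scan", "spots.csv"),
            row.names = FALSE)
  write.csv(data.frame(x = mri@points[, 1], y = mri@points[, 2],
                       z = mri@points[, 3], thickness = mri@thickness),
            file.path(dir, "mri", "points.csv"), row.names = FALSE)
  write.csv(mri@markers, file.path(dir, "mri", "markers.csv"),
            row.names = FALSE)
  invisible(dir)
}
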