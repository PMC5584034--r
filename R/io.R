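# Readers/writers: volumes as NIfTI (via RNifti) or MetaImage (MHA, local
# raw payload), projections as raw float64 + JSON sidecar. All round trips
# are lossless (64-bit payloads).

#' Write / read an attenuation volume
#'
#' Format chosen by extension: `.nii` / `.nii.gz` (NIfTI, voxel size in the
#' header) or `.mha` (MetaImage with local raw payload). Values are stored
#' as 64-bit floats so a write/read round trip is bitwise exact.
#'
#' @param volume a `volume_image`.
#' @param path output file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   `volume_image`.
#' @export
write_volume <- function(volume, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(structure(volume$values,
                                     pixdim = volume$voxel_size),
                           datatype = "double")
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext == "mha") {
    d <- dim(volume$values)
    hdr <- paste0(
      "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
      "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
      "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
      sprintf("Offset = %.10g %.10g %.10g\n",
              volume$origin[1], volume$origin[2], volume$origin[3]),
      "CenterOfRotation = 0 0 0\nAnatomicalOrientation = RAI\n",
      sprintf("ElementSpacing = %.10g %.10g %.10g\n",
              volume$voxel_size[1], volume$voxel_size[2], volume$voxel_size[3]),
      sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
      "ElementType = MET_DOUBLE\nElementDataFile = LOCAL\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(hdr, con, eos = NULL)
    writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  } else stop("unsupported volume format: ", ext)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    volume_image(array(as.numeric(img), dim(img)),
                 voxel_size = RNifti::pixdim(img)[1:3])
  } else if (ext == "mha") {
    raw_all <- readBin(path, "raw", file.size(path))
    # header ends at the newline after "ElementDataFile = LOCAL"
    txt_end <- grepRaw("ElementDataFile = LOCAL\n", raw_all, fixed = TRUE)
    if (!length(txt_end)) stop("parse error: malformed MHA header")
    data_at <- txt_end + nchar("ElementDataFile = LOCAL\n")
    hdr_txt <- rawToChar(raw_all[seq_len(data_at - 1)])
    get_field <- function(name) {
      m <- regmatches(hdr_txt, regexpr(paste0(name, " = [^\n]+"), hdr_txt))
      if (!length(m)) stop("parse error: missing MHA field ", name)
      strsplit(sub(paste0(name, " = "), "", m), " ")[[1]]
    }
    d <- as.integer(get_field("DimSize"))
    sp <- as.numeric(get_field("ElementSpacing"))
    off <- as.numeric(get_field("Offset"))
    if (!identical(get_field("ElementType"), "MET_DOUBLE"))
      stop("parse error: unsupported MHA element type")
    vals <- readBin(raw_all[data_at:length(raw_all)], "numeric",
                    n = prod(d), size = 8, endian = "little")
    volume_image(array(vals, d), voxel_size = sp, origin = off)
  } else stop("unsupported volume format: ", ext)
}

#' Write / read a projection stack
#'
#' Stored as a raw little-endian float64 file (`<base>.raw`, frames in
#' angle-major order) plus a JSON sidecar (`<base>.json`) holding the frame
#' shape, angles, timestamps and source intensity.
#'
#' @param projections a [projection_set()].
#' @param base path base (without extension).
#' @return `write_projections` returns `base` invisibly; `read_projections`
#'   a `projection_set`.
#' @export
write_projections <- function(projections, base) {
  d <- dim(projections$frames)
  meta <- list(det_rows = d[1], det_cols = d[2], n_views = d[3],
               angles_deg = projections$angles_deg,
               times_s = projections$times_s, n0 = projections$n0,
               dtype = "float64le")
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(projections$frames), con, size = 8, endian = "little")
  invisible(base)
}

#' @rdname write_projections
#' @export
read_projections <- function(base) {
  jpath <- paste0(base, ".json")
  if (!file.exists(jpath)) stop("parse error: missing sidecar ", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  need <- c("det_rows", "det_cols", "n_views", "angles_deg", "times_s", "n0")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("parse error: sidecar missing field(s): ", paste(miss, collapse = ", "))
  n <- meta$det_rows * meta$det_cols * meta$n_views
  vals <- readBin(paste0(base, ".raw"), "numeric", n = n, size = 8,
                  endian = "little")
  if (length(vals) != n) stop("parse error: raw payload size mismatch")
  projection_set(array(vals, c(meta$det_rows, meta$det_cols, meta$n_views)),
                 meta$angles_deg, meta$times_s, meta$n0)
}
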