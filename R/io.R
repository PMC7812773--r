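#' Write a surface mesh as an ASCII GIFTI file
#'
#' Emits a minimal GIFTI surface file (`.surf.gii` dialect): one POINTSET
#' array with the vertex coordinates, one TRIANGLE array with 0-based face
#' indices, ASCII encoding, plus the hemisphere tag
#' (`AnatomicalStructurePrimary`) and any per-vertex region labels in the
#' file metadata. Round trips losslessly through [read_surface()].
#'
#' @param mesh a [cf_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  md <- xml2::xml_add_child(doc, "MetaData")
  add_md <- function(name, value) {
    e <- xml2::xml_add_child(md, "MD")
    xml2::xml_add_child(e, "Name", name)
    xml2::xml_add_child(e, "Value", value)
  }
  add_md("AnatomicalStructurePrimary",
         if (mesh$hemisphere == "L") "CortexLeft" else "CortexRight")
  if (!is.null(mesh$region)) {
    add_md("RegionLabels", paste(mesh$region, collapse = ","))
  }
  add_array <- function(intent, dtype, m, fmt) {
    da <- xml2::xml_add_child(doc, "DataArray", Intent = intent,
                              DataType = dtype,
                              ArrayIndexingOrder = "RowMajorOrder",
                              Dimensionality = "2",
                              Dim0 = as.character(nrow(m)),
                              Dim1 = as.character(ncol(m)),
                              Encoding = "ASCII", Endian = "LittleEndian")
    txt <- paste(apply(m, 1, function(r) paste(sprintf(fmt, r),
                                               collapse = " ")),
                 collapse = "\n")
    xml2::xml_add_child(da, "Data", txt)
  }
  add_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64",
            mesh$vertices, "%.17g")
  add_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
            mesh$faces - 1L, "%d")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an ASCII GIFTI surface file
#'
#' Counterpart of [write_surface()]: accepts ASCII-encoded GIFTI surface
#' files with a POINTSET and a TRIANGLE array. Face indices are validated
#' against the vertex count and converted to 1-based.
#'
#' @param path file path.
#' @return A [cf_mesh()].
#' @export
read_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  get_array <- function(intent) {
    hit <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (length(hit) != 1L) {
      stop("GIFTI file must contain exactly one ", intent, " array")
    }
    da <- hit[[1]]
    if (xml2::xml_attr(da, "Encoding") != "ASCII") {
      stop("unsupported GIFTI Encoding '", xml2::xml_attr(da, "Encoding"),
           "' (only ASCII is handled)")
    }
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, "./Data")),
                 quiet = TRUE)
    d0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    d1 <- as.integer(xml2::xml_attr(da, "Dim1"))
    if (length(vals) != d0 * d1) {
      stop("GIFTI ", intent, " Data length does not match Dim0 x Dim1")
    }
    matrix(vals, nrow = d0, ncol = d1, byrow = TRUE)
  }
  verts <- get_array("NIFTI_INTENT_POINTSET")
  faces <- get_array("NIFTI_INTENT_TRIANGLE") + 1L
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(verts))) {
    stop("GIFTI TRIANGLE array has out-of-range face indices")
  }
  mds <- xml2::xml_find_all(doc, ".//MetaData/MD")
  meta <- stats::setNames(
    xml2::xml_text(xml2::xml_find_first(mds, "./Value")),
    xml2::xml_text(xml2::xml_find_first(mds, "./Name"))
  )
  anat <- meta[["AnatomicalStructurePrimary"]]
  if (is.null(anat) || is.na(anat)) {
    stop("GIFTI file lacks an AnatomicalStructurePrimary metadata entry")
  }
  hemi <- switch(anat, CortexLeft = "L", CortexRight = "R",
                 stop("unrecognized AnatomicalStructurePrimary '", anat, "'"))
  region <- if ("RegionLabels" %in% names(meta)) {
    strsplit(meta[["RegionLabels"]], ",", fixed = TRUE)[[1]]
  } else NULL
  cf_mesh(verts, faces, hemi, region = region)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write time courses as TSV with a JSON sidecar
#'
#' The package's plain-text interchange container: a headerless TSV of the
#' vertices x timepoints matrix next to a JSON sidecar carrying the
#' sampling rate, run identifier and condition label. Values round trip at
#' full double precision.
#'
#' @param x matrix, vertices x timepoints.
#' @param path output `.tsv` path (sidecar goes to the same path with a
#'   `.json` extension).
#' @param sampling_rate Hz.
#' @param run run identifier.
#' @param condition condition label (`"retinotopy"`, `"movie"`, `"rest"`,
#'   ...).
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(x, path, sampling_rate, run = 1L,
                              condition = "rest") {
  x <- as_tc_matrix(x)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate = sampling_rate, run = run, condition = condition,
         n_vertices = nrow(x), n_timepoints = ncol(x)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-course TSV written by [write_timecourses()]
#'
#' @param path the `.tsv` path.
#' @param allow_nan if `FALSE` (default), any non-finite value in the matrix
#'   is an error.
#' @param n_vertices optional expected vertex count; mismatch is an error.
#' @return Matrix with attributes `sampling_rate`, `run`, `condition`.
#' @export
read_timecourses <- function(path, allow_nan = FALSE, n_vertices = NULL) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (nrow(x) != meta$n_vertices || ncol(x) != meta$n_timepoints) {
    stop("time-course matrix shape does not match its sidecar")
  }
  if (!is.null(n_vertices) && nrow(x) != n_vertices) {
    stop("time courses have ", nrow(x), " vertices but the mesh has ",
         n_vertices)
  }
  if (!allow_nan && any(!is.finite(x))) {
    stop("time courses contain non-finite values; pass allow_nan = TRUE ",
         "to accept them")
  }
  attr(x, "sampling_rate") <- meta$sampling_rate
  attr(x, "run") <- meta$run
  attr(x, "condition") <- meta$condition
  x
}

#' Write a geodesic distance matrix with a JSON sidecar
#'
#' @param dists a [geodesic_distances()] result.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dists, path) {
  utils::write.table(format(dists$d, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(vertices = dists$vertices, hemisphere = dists$hemisphere),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_distances()]
#'
#' @param path the `.tsv` path.
#' @return A `cf_distmat`.
#' @export
read_distances <- function(path) {
  d <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(d) <- NULL
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(d = d, vertices = as.integer(meta$vertices),
                 hemisphere = meta$hemisphere),
            class = "cf_distmat")
}
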