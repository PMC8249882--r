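# Surface and metric I/O: minimal GIFTI (XML via xml2) plus plain-text
# fallback formats. GIFTI writing uses ASCII encoding; reading also
# understands Base64Binary and GZipBase64Binary little-endian arrays, which
# covers files produced by the common surface tools.

gifti_datatype <- function(dt) {
  switch(dt,
         NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
         NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
         NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
         stop("unsupported GIFTI datatype: ", dt))
}

read_gifti_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dt <- gifti_datatype(xml2::xml_attr(node, "DataType"))
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  n <- prod(dims)
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  vals <- switch(enc,
    ASCII = scan(text = txt, quiet = TRUE),
    Base64Binary = readBin(base64_decode(txt), dt$what, n = n,
                           size = dt$size, endian = "little"),
    GZipBase64Binary = readBin(memDecompress(base64_decode(txt), "gzip"),
                               dt$what, n = n, size = dt$size,
                               endian = "little"),
    stop("unsupported GIFTI encoding: ", enc))
  if (length(dims) == 2L) {
    ord <- xml2::xml_attr(node, "ArrayIndexingOrder")
    if (identical(ord, "ColumnMajorOrder"))
      matrix(vals, dims[1], dims[2])
    else
      matrix(vals, dims[1], dims[2], byrow = TRUE)
  } else {
    vals
  }
}

base64_decode <- function(txt) {
  txt <- gsub("[\r\n\t ]", "", txt)
  chars <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrstuvwxyz0123456789+/",
                    "")[[1]]
  lut <- integer(256)
  lut[utf8ToInt(paste(chars, collapse = "")) + 1L] <- seq_along(chars) - 1L
  raw_in <- utf8ToInt(txt)
  pad <- sum(raw_in == utf8ToInt("="))
  raw_in <- raw_in[raw_in != utf8ToInt("=")]
  v <- lut[raw_in + 1L]
  n4 <- length(v) %/% 4L
  rem <- length(v) %% 4L
  out <- raw()
  if (n4 > 0) {
    m <- matrix(v[seq_len(4L * n4)], nrow = 4L)
    b1 <- bitwOr(bitwShiftL(m[1, ], 2L), bitwShiftR(m[2, ], 4L))
    b2 <- bitwAnd(bitwOr(bitwShiftL(m[2, ], 4L), bitwShiftR(m[3, ], 2L)), 255L)
    b3 <- bitwAnd(bitwOr(bitwShiftL(m[3, ], 6L), m[4, ]), 255L)
    out <- as.raw(rbind(b1, b2, b3))
  }
  if (rem > 0) {
    tail <- v[(4L * n4 + 1L):length(v)]
    tail <- c(tail, rep(0L, 4L - rem))
    b1 <- bitwOr(bitwShiftL(tail[1], 2L), bitwShiftR(tail[2], 4L))
    b2 <- bitwAnd(bitwOr(bitwShiftL(tail[2], 4L), bitwShiftR(tail[3], 2L)), 255L)
    b3 <- bitwAnd(bitwOr(bitwShiftL(tail[3], 6L), tail[4]), 255L)
    extra <- as.raw(c(b1, b2, b3))
    out <- c(out, extra)
  }
  nbytes <- (length(v) * 3L) %/% 4L
  out[seq_len(nbytes)]
}

gifti_skeleton <- function() {
  xml2::read_xml(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="0"></GIFTI>'))
}

add_gifti_array <- function(doc, values, intent, datatype, dims) {
  root <- xml2::xml_root(doc)
  da <- xml2::xml_add_child(root, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  if (length(dims) == 2L) {
    txt <- paste(apply(values, 1, paste, collapse = " "), collapse = "\n")
  } else {
    txt <- paste(values, collapse = "\n")
  }
  xml2::xml_add_child(da, "Data", txt)
  n <- as.integer(xml2::xml_attr(root, "NumberOfDataArrays")) + 1L
  xml2::xml_set_attr(root, "NumberOfDataArrays", as.character(n))
  invisible(doc)
}

#' Read and write GIFTI surfaces and metric maps
#'
#' Minimal GIFTI support: `write_gifti_surface` stores the coordinate
#' (POINTSET) and topology (TRIANGLE, 0-based) arrays with ASCII encoding;
#' `read_gifti_surface` accepts ASCII, Base64Binary and GZipBase64Binary
#' encodings. Metric files hold one scalar per vertex. The spherical
#' parameterization of a surface travels as its own `.surf.gii`; use
#' `sphere` to attach one on read.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path (.surf.gii / .func.gii / .shape.gii).
#' @param name mesh label on read.
#' @param sphere optional path of the companion sphere surface.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- gifti_skeleton()
  add_gifti_array(doc, format(mesh$vertices, digits = 10, trim = TRUE,
                              scientific = FALSE),
                  "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                  dim(mesh$vertices))
  add_gifti_array(doc, mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32", dim(mesh$faces))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gifti_surface
#' @export
read_gifti_surface <- function(path, name = basename(path), sphere = NULL) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  vp <- which(intents == "NIFTI_INTENT_POINTSET")[1]
  fp <- which(intents == "NIFTI_INTENT_TRIANGLE")[1]
  if (is.na(vp) || is.na(fp)) stop("not a GIFTI surface: ", path)
  v <- read_gifti_array(arrays[[vp]])
  f <- matrix(as.integer(read_gifti_array(arrays[[fp]])), ncol = 3) + 1L
  sph <- if (!is.null(sphere)) read_gifti_surface(sphere)$vertices else NULL
  surface_mesh(v, f, name = name, sphere = sph)
}

#' @rdname write_gifti_surface
#' @param values per-vertex metric values.
#' @export
write_gifti_metric <- function(values, path) {
  doc <- gifti_skeleton()
  add_gifti_array(doc, format(as.numeric(values), digits = 10, trim = TRUE),
                  "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                  length(values))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gifti_surface
#' @export
read_gifti_metric <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  as.numeric(read_gifti_array(arrays[[1]]))
}

#' Plain-text surface and metric formats
#'
#' Fallback formats: a surface file has a header line "V F" followed by V
#' lines "x y z" and F lines "i j k" with 0-based vertex indices; a metric
#' file is a CSV with columns `vertex` (0-based) and `value`.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_surface_text <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(mesh$faces - 1L, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_text
#' @param name mesh label on read.
#' @export
read_surface_text <- function(path, name = basename(path)) {
  hdr <- scan(path, nlines = 1, quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  dat <- scan(path, skip = 1, quiet = TRUE)
  v <- matrix(dat[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(dat[3 * nv + seq_len(3 * nf)]), ncol = 3,
              byrow = TRUE) + 1L
  surface_mesh(v, f, name = name)
}

#' @rdname write_surface_text
#' @param values per-vertex values.
#' @export
write_metric_csv <- function(values, path) {
  utils::write.csv(data.frame(vertex = seq_along(values) - 1L,
                              value = as.numeric(values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_text
#' @export
read_metric_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- numeric(nrow(d))
  out[d$vertex + 1L] <- d$value
  out
}

#' Write a synthetic cohort to a directory
#'
#' Writes per-subject baseline/follow-up surfaces, spheres and thickness
#' maps (GIFTI), truth maps for synthetic subjects, and a `cohort.csv`
#' manifest (subject_id, group, baseline_surf, followup_surf,
#' baseline_thick, followup_thick).
#'
#' @param cohort list of `subject_record`.
#' @param dir output directory (created if needed).
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(sub) {
    pre <- file.path(dir, sub$id)
    sphere_mesh <- function(m)
      surface_mesh(m$sphere, m$faces, validate = FALSE)
    write_gifti_surface(sub$baseline$mesh, paste0(pre, ".base.surf.gii"))
    write_gifti_surface(sphere_mesh(sub$baseline$mesh),
                        paste0(pre, ".base.sphere.surf.gii"))
    write_gifti_surface(sub$followup$mesh, paste0(pre, ".fu.surf.gii"))
    write_gifti_surface(sphere_mesh(sub$followup$mesh),
                        paste0(pre, ".fu.sphere.surf.gii"))
    write_gifti_metric(sub$baseline$thickness,
                       paste0(pre, ".base.thickness.func.gii"))
    write_gifti_metric(sub$followup$thickness,
                       paste0(pre, ".fu.thickness.func.gii"))
    if (!is.null(sub$truth)) {
      write_gifti_metric(sub$truth$area, paste0(pre, ".truth.area.func.gii"))
      write_gifti_metric(sub$truth$thickness,
                         paste0(pre, ".truth.thickness.func.gii"))
    }
    data.frame(subject_id = sub$id, group = sub$group,
               baseline_surf = paste0(sub$id, ".base.surf.gii"),
               followup_surf = paste0(sub$id, ".fu.surf.gii"),
               baseline_thick = paste0(sub$id, ".base.thickness.func.gii"),
               followup_thick = paste0(sub$id, ".fu.thickness.func.gii"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
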