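# Minimal DICOM support: explicit VR little endian, uncompressed 16-bit
# grayscale, multi-frame files or single-frame series. This is a format
# subset sized to the tags this pipeline reads, not a general DICOM
# implementation; no DICOM package is available in the target environment.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_pad <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_str_raw <- function(s, ui = FALSE) {
  dcm_pad(charToRaw(as.character(s)), if (ui) as.raw(0L) else charToRaw(" "))
}

dcm_u16_raw <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, x %/% 256L))
}

dcm_u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# One data element in explicit VR little endian.
dcm_element <- function(group, elem, vr, value_raw) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  header <- c(dcm_u16_raw(group), dcm_u16_raw(elem), charToRaw(vr))
  if (long_form) {
    c(header, as.raw(c(0L, 0L)), dcm_u32_raw(length(value_raw)), value_raw)
  } else {
    c(header, dcm_u16_raw(length(value_raw)), value_raw)
  }
}

dcm_view_split <- function(view) {
  list(laterality = substr(view, 1, 1),
       position = substr(view, 2, nchar(view)))
}

# Write slices as one multi-frame DICOM file (frames = 3rd array index).
# With write_window = FALSE the window tags are omitted (readers then fall
# back to the pixel-data range).
write_dicom_volume <- function(path, pixels, view = "LCC",
                               patient_id = "P0000", study_uid = "S0000",
                               series_uid = paste0(study_uid, ".", view),
                               instance_number = 1L,
                               window_center = NULL, window_width = NULL,
                               write_window = TRUE) {
  d <- dim(pixels)
  if (length(d) == 2L) d <- c(d, 1L)
  if (any(pixels < 0) || any(pixels > 65535))
    stop_dbt("format", "pixel values must fit in uint16")
  vs <- dcm_view_split(view)
  body <- c(
    dcm_element(0x0008, 0x0018, "UI",
                dcm_str_raw(paste0("1.2.826.0.1.", series_uid, ".",
                                   instance_number), ui = TRUE)),
    dcm_element(0x0008, 0x0060, "CS", dcm_str_raw("MG")),
    dcm_element(0x0010, 0x0020, "LO", dcm_str_raw(patient_id)),
    dcm_element(0x0018, 0x5101, "CS", dcm_str_raw(vs$position)),
    dcm_element(0x0020, 0x000D, "UI", dcm_str_raw(study_uid, ui = TRUE)),
    dcm_element(0x0020, 0x000E, "UI", dcm_str_raw(series_uid, ui = TRUE)),
    dcm_element(0x0020, 0x0013, "IS", dcm_str_raw(instance_number)),
    dcm_element(0x0020, 0x0062, "CS", dcm_str_raw(vs$laterality)),
    dcm_element(0x0028, 0x0002, "US", dcm_u16_raw(1L)),
    dcm_element(0x0028, 0x0008, "IS", dcm_str_raw(d[3])),
    dcm_element(0x0028, 0x0010, "US", dcm_u16_raw(d[1])),
    dcm_element(0x0028, 0x0011, "US", dcm_u16_raw(d[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_u16_raw(16L)),
    dcm_element(0x0028, 0x0101, "US", dcm_u16_raw(16L)),
    dcm_element(0x0028, 0x0102, "US", dcm_u16_raw(15L)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16_raw(0L))
  )
  if (write_window && !is.null(window_center) && !is.null(window_width)) {
    body <- c(body,
              dcm_element(0x0028, 0x1050, "DS", dcm_str_raw(window_center)),
              dcm_element(0x0028, 0x1051, "DS", dcm_str_raw(window_width)))
  }
  # frames stored row-major within each frame (standard raster order)
  px <- aperm(array(pixels, dim = d), c(2, 1, 3))
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", dcm_u16_raw(as.vector(px))))
  meta <- dcm_element(0x0002, 0x0010, "UI",
                      dcm_str_raw(DCM_TS_EXPLICIT_LE, ui = TRUE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32_raw(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Write one file per slice into a directory (a single-frame series).
write_dicom_series <- function(dir, pixels, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(pixels)
  for (k in seq_len(d[3])) {
    write_dicom_volume(file.path(dir, sprintf("slice_%04d.dcm", k)),
                       pixels[, , k, drop = FALSE], instance_number = k, ...)
  }
  invisible(dir)
}

dcm_read_u16 <- function(r) {
  as.integer(r[c(TRUE, FALSE)]) + 256L * as.integer(r[c(FALSE, TRUE)])
}

dcm_read_u32 <- function(r) {
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))
}

# Parse one explicit-VR little-endian DICOM file into a tag table.
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(r) >= 132L && rawToChar(r[129:132]) == "DICM") pos <- 133L
  tags <- list()
  while (pos + 7L <= length(r)) {
    group <- dcm_read_u16(r[pos:(pos + 1L)])
    elem <- dcm_read_u16(r[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_dbt("format", "not an explicit-VR DICOM stream: ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcm_read_u32(r[(pos + 8L):(pos + 11L)])
      vpos <- pos + 12L
    } else {
      len <- dcm_read_u16(r[(pos + 6L):(pos + 7L)])
      vpos <- pos + 8L
    }
    if (vpos + len - 1L > length(r))
      stop_dbt("format", "truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    val <- if (len > 0) r[vpos:(vpos + len - 1L)] else raw(0L)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- vpos + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  tags
}

dcm_tag_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$value[t$value != as.raw(0L)]))
}

dcm_tag_num <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  if (t$vr == "US") return(dcm_read_u16(t$value)[1])
  as.numeric(strsplit(dcm_tag_str(tags, key), "\\\\")[[1]][1])
}

dcm_file_record <- function(path) {
  tags <- read_dicom_file(path)
  rows <- dcm_tag_num(tags, "0028,0010")
  cols <- dcm_tag_num(tags, "0028,0011")
  nframes <- dcm_tag_num(tags, "0028,0008") %||% 1
  if (is.null(rows) || is.null(cols) || is.null(tags[["7FE0,0010"]]))
    stop_dbt("format", "missing image tags in ", path)
  px <- dcm_read_u16(tags[["7FE0,0010"]]$value)
  if (length(px) != rows * cols * nframes)
    stop_dbt("format", "pixel data size mismatch in ", path)
  frames <- aperm(array(px, dim = c(cols, rows, nframes)), c(2, 1, 3))
  lat <- dcm_tag_str(tags, "0020,0062") %||% "L"
  posn <- dcm_tag_str(tags, "0018,5101") %||% "CC"
  list(
    frames = frames,
    view = paste0(lat, posn),
    patient_id = dcm_tag_str(tags, "0010,0020") %||% "NA",
    study_uid = dcm_tag_str(tags, "0020,000D") %||% "NA",
    series_uid = dcm_tag_str(tags, "0020,000E") %||% "NA",
    instance = dcm_tag_num(tags, "0020,0013") %||% 1,
    window_center = dcm_tag_num(tags, "0028,1050"),
    window_width = dcm_tag_num(tags, "0028,1051")
  )
}

#' Read a DBT volume from DICOM
#'
#' Reads either a multi-frame DICOM file or a directory holding one
#' single-frame DICOM file per slice (one series). Slices are ordered by
#' instance/frame number regardless of file listing order. Window-level
#' parameters are taken from the header; when absent they fall back to
#' `(min + max) / 2` and `max - min` of the pixel data.
#'
#' @param path a DICOM file or a directory of same-series DICOM files.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop_dbt("format", "empty directory: ", path)
    recs <- lapply(files, dcm_file_record)
    series <- vapply(recs, `[[`, "", "series_uid")
    if (length(unique(series)) > 1L)
      stop_dbt("ambiguity", "directory mixes ", length(unique(series)),
               " DICOM series: ", path)
    recs <- recs[order(vapply(recs, `[[`, 0, "instance"))]
    frames <- do.call(abind3, lapply(recs, `[[`, "frames"))
    rec <- recs[[1]]
    rec$frames <- frames
  } else if (file.exists(path)) {
    rec <- dcm_file_record(path)
  } else {
    stop_dbt("format", "no such file: ", path)
  }
  new_volume(rec$frames, view = rec$view, patient_id = rec$patient_id,
             study_id = rec$study_uid, window_center = rec$window_center,
             window_width = rec$window_width)
}

# bind 3-D arrays along the slice axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  ns <- sum(vapply(parts, function(p) dim(p)[3], 0))
  array(unlist(parts, use.names = FALSE), dim = c(d[1], d[2], ns))
}
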