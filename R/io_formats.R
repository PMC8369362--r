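# Stable CSV schemas for annotations, predictions, and the volume index.
# Columns are fixed and validated; unknown class strings are errors rather
# than silently dropped rows.

ANNOTATION_COLS <- c("PatientID", "StudyUID", "View", "X", "Y", "Width",
                     "Height", "Slice", "Class", "LesionType")
PREDICTION_COLS <- c("PatientID", "StudyUID", "View", "X", "Y", "Width",
                     "Height", "Z", "Score")
INDEX_COLS <- c("PatientID", "StudyUID", "View", "Path", "NumSlices", "Group")
VIEWS <- c("LCC", "RCC", "LMLO", "RMLO")
GROUPS <- c("normal", "actionable", "benign", "cancer")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop_dbt("schema", what, " is missing column(s): ",
             paste(missing, collapse = ", "))
  df[cols]
}

norm_enum <- function(x, levels, what, rows) {
  m <- match(tolower(trimws(x)), tolower(levels))
  if (anyNA(m)) {
    bad <- rows[which(is.na(m))[1]]
    stop_dbt("validation", "unknown ", what, " value '",
             x[which(is.na(m))[1]], "' in row ", bad)
  }
  levels[m]
}

#' Read a lesion annotation table
#'
#' Annotations give the radiologist's 2-D rectangle on the lesion's center
#' slice, in full-resolution 0-based pixel coordinates (`X` along columns,
#' `Y` along rows), plus class (`cancer`/`benign`) and lesion type
#' (`mass`/`architectural_distortion`). Class strings are matched
#' case-insensitively; unknown strings and nonpositive box dimensions are
#' errors naming the offending row.
#'
#' @param path CSV file with columns
#'   `PatientID,StudyUID,View,X,Y,Width,Height,Slice,Class,LesionType`.
#' @return A data.frame with those columns, enums normalized to lowercase
#'   canonical values.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, ANNOTATION_COLS, "annotations CSV")
  rows <- seq_len(nrow(df))
  if (nrow(df) == 0L) return(df)
  bad <- which(df$Width <= 0 | df$Height <= 0)
  if (length(bad) > 0L)
    stop_dbt("validation", "nonpositive box dimensions in row ", bad[1])
  df$View <- norm_enum(df$View, VIEWS, "View", rows)
  df$Class <- norm_enum(df$Class, c("cancer", "benign"), "Class", rows)
  df$LesionType <- norm_enum(df$LesionType,
                             c("mass", "architectural_distortion"),
                             "LesionType", rows)
  df
}

#' Write a lesion annotation table
#' @param annotations data.frame in the [read_annotations()] schema.
#' @param path output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- check_schema(annotations, ANNOTATION_COLS, "annotations")
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction table
#'
#' Predicted boxes are in preprocessed-image (2x-downscaled) coordinates,
#' with `Z` the 0-based slice index and `Score` the confidence in (0, 1].
#'
#' @param path CSV with columns
#'   `PatientID,StudyUID,View,X,Y,Width,Height,Z,Score`.
#' @return data.frame in that schema.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, PREDICTION_COLS, "predictions CSV")
  if (nrow(df) == 0L) return(df)
  if (any(df$Width <= 0 | df$Height <= 0))
    stop_dbt("validation", "nonpositive box dimensions in predictions")
  if (any(df$Score <= 0 | df$Score > 1))
    stop_dbt("validation", "scores must be in (0, 1]")
  df$View <- norm_enum(df$View, VIEWS, "View", seq_len(nrow(df)))
  df
}

#' Write a prediction table
#'
#' Scores are serialized with at least 8 significant digits so that
#' `read_predictions(write_predictions(x))` round-trips within
#' serialization precision.
#'
#' @param boxes data.frame in the [read_predictions()] schema.
#' @param path output CSV path.
#' @export
write_predictions <- function(boxes, path) {
  boxes <- check_schema(boxes, PREDICTION_COLS, "predictions")
  num <- c("X", "Y", "Width", "Height", "Score")
  out <- boxes
  for (cn in num) out[[cn]] <- sprintf("%.10g", boxes[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a volume index table
#'
#' The index lists every reconstruction volume with its location on disk,
#' slice count, and cohort group (`normal`, `actionable`, `benign`,
#' `cancer`).
#'
#' @param path CSV with columns `PatientID,StudyUID,View,Path,NumSlices,Group`.
#' @return data.frame in that schema.
#' @export
read_volume_index <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, INDEX_COLS, "volume index CSV")
  if (nrow(df) == 0L) return(df)
  df$View <- norm_enum(df$View, VIEWS, "View", seq_len(nrow(df)))
  df$Group <- norm_enum(df$Group, GROUPS, "Group", seq_len(nrow(df)))
  if (anyDuplicated(vkey(df$PatientID, df$StudyUID, df$View)))
    stop_dbt("validation", "duplicate volume keys in index")
  df
}

#' Write a volume index table
#' @param index data.frame in the [read_volume_index()] schema.
#' @param path output CSV path.
#' @export
write_volume_index <- function(index, path) {
  index <- check_schema(index, INDEX_COLS, "volume index")
  utils::write.csv(index, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map annotation coordinates onto preprocessed images
#'
#' Annotations are stored at full resolution; the detector works on 2x
#' locally-mean-downscaled images. `X`, `Y`, `Width` and `Height` are
#' divided by 2 (floor); the slice index is unchanged (downscaling is
#' in-plane only).
#'
#' @param annotations data.frame in the [read_annotations()] schema.
#' @return Same schema with halved in-plane coordinates.
#' @export
annotations_to_preprocessed <- function(annotations) {
  out <- annotations
  for (cn in c("X", "Y", "Width", "Height"))
    out[[cn]] <- floor(annotations[[cn]] / 2)
  out$Width <- pmax(out$Width, 1)
  out$Height <- pmax(out$Height, 1)
  out
}
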