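# Readers and writers for masks, label maps, demographics and area tables.
# NIfTI-1 is the working format for images; PNG is accepted for fixtures;
# CSV (header row) for tabular data.

#' Read a midsagittal CC mask
#'
#' Reads a 2-D binary mask from NIfTI (2-D, or 3-D with a singleton
#' dimension, which is squeezed) or PNG. Intensities are normalised to
#' `[0, 1]` by their maximum and values strictly greater than
#' `binarizeThreshold` become foreground. NIfTI images with orientation
#' information are reoriented to a canonical axis order before the slice is
#' extracted, so on-disk orientation codes do not change the result. Any
#' 3-D image without a singleton dimension is rejected: picking the
#' midsagittal slice from a volume is a manual step outside this package.
#'
#' @param path file path (`.nii`, `.nii.gz` or `.png`).
#' @param binarizeThreshold threshold on normalised intensity (default 0.5).
#' @param spacing optional `c(row_mm, col_mm)` override; required for PNG.
#' @param subjectID identifier; defaults to the file name without extension.
#' @return A [MidsagittalMask-class].
#' @export
readMask <- function(path, binarizeThreshold = 0.5, spacing = NULL,
                     subjectID = NULL) {
  if (!file.exists(path))
    ccStop("ccmorphMissingFile", "mask file not found: %s", path)
  if (is.null(subjectID))
    subjectID <- sub("\\.(nii(\\.gz)?|png)$", "", basename(path))
  ispng <- grepl("\\.png$", path, ignore.case = TRUE)
  if (ispng) {
    if (is.null(spacing))
      ccStop("ccmorphMissingSpacing",
             "PNG carries no pixel spacing; supply `spacing` for %s", path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    dat <- arr
    sp <- as.numeric(spacing)
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) == 3) {
      # reorient so that squeezing is independent of on-disk orientation
      # codes; images without any xform cannot (and need not) be reoriented
      suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
    }
    d <- dim(img)
    pd <- RNifti::pixdim(img)
    keep <- which(d > 1)
    if (length(keep) > 2)
      ccStop("ccmorphBadDims",
             "expected a 2-D mask (or singleton 3rd dimension), got dims %s",
             paste(d, collapse = "x"))
    if (length(keep) < 1)
      ccStop("ccmorphEmptyMask", "empty mask: %s", path)
    dat <- drop(array(as.numeric(img), dim = d))
    if (is.null(dim(dat))) dat <- matrix(dat, ncol = 1)
    sp <- if (is.null(spacing)) as.numeric(pd[keep]) else as.numeric(spacing)
    if (length(sp) == 1) sp <- c(sp, sp)
  }
  mx <- max(dat)
  if (mx > 0) dat <- dat / mx
  px <- dat > binarizeThreshold
  if (!any(px))
    ccStop("ccmorphEmptyMask", "empty mask: %s", path)
  midsagittalMask(px * 1L, spacing = sp, subjectID = subjectID)
}

#' Write a mask as NIfTI
#'
#' @param mask a [MidsagittalMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(maskPixels(mask))
  RNifti::pixdim(img) <- pixelSpacing(mask)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a sub-region label map as NIfTI
#'
#' Integer labels 0-5 on the source grid, with the source pixel spacing.
#'
#' @param labelmap a [SubregionLabelMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labelmap, path) {
  img <- RNifti::asNifti(labelMatrix(labelmap))
  RNifti::pixdim(img) <- pixelSpacing(labelmap)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a demographics table
#'
#' CSV with required columns `subject_id`, `group` (CB/NC), `sex` (M/F) and
#' `age` (years, > 0); optional `site` (default `"site1"`) and
#' `linear_scale` (unitless native-to-stereotaxic scaling, default 1).
#'
#' @param path CSV file path.
#' @return data.frame with one validated row per subject.
#' @export
readDemographics <- function(path) {
  if (!file.exists(path))
    ccStop("ccmorphMissingFile", "demographics file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject_id", "group", "sex", "age")
  missing <- setdiff(required, names(df))
  if (length(missing))
    ccStop("ccmorphMissingColumn", "demographics lacks column(s): %s",
           paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("demographics file has a header but no rows: ", path)
    return(data.frame(subject_id = character(), group = character(),
                      sex = character(), age = numeric(),
                      site = character(), linear_scale = numeric()))
  }
  if (anyDuplicated(df$subject_id))
    ccStop("ccmorphDuplicateID", "duplicate subject_id: %s",
           paste(unique(df$subject_id[duplicated(df$subject_id)]),
                 collapse = ", "))
  if (!all(df$group %in% c("CB", "NC")))
    ccStop("ccmorphBadEnum", "group must be CB or NC; offending: %s",
           paste(unique(setdiff(df$group, c("CB", "NC"))), collapse = ", "))
  if (!all(df$sex %in% c("M", "F")))
    ccStop("ccmorphBadEnum", "sex must be M or F; offending: %s",
           paste(unique(setdiff(df$sex, c("M", "F"))), collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age))
  if (any(is.na(age)) || any(age <= 0))
    ccStop("ccmorphBadAge", "unparsable or non-positive age for subject(s): %s",
           paste(df$subject_id[is.na(age) | age <= 0], collapse = ", "))
  site <- if ("site" %in% names(df)) df$site else rep("site1", nrow(df))
  ls <- if ("linear_scale" %in% names(df))
    suppressWarnings(as.numeric(df$linear_scale)) else rep(1, nrow(df))
  if (any(is.na(ls)) || any(ls <= 0))
    ccStop("ccmorphBadScale", "linear_scale must be positive")
  data.frame(subject_id = df$subject_id, group = df$group, sex = df$sex,
             age = age, site = site, linear_scale = ls,
             stringsAsFactors = FALSE)
}

# Numeric columns are serialised at full double precision (%.17g) so that
# write/read round-trips are lossless.
.areaNumericCols <- c("age", "linear_scale", "stereotaxic_area_mm2",
                      "native_area_mm2", "bending_deg", "base_mm", "height_mm")

#' Write an area table
#'
#' One row per subject x region; numeric columns are written at full double
#' precision so that [readAreaTable()] round-trips exactly.
#'
#' @param table an area table data.frame (see [simulateAreaTable()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAreaTable <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    ccStop("ccmorphEmptyTable", "area table is empty")
  if (!all(table$region %in% ccRegionNames()))
    ccStop("ccmorphBadRegion", "region labels must be among: %s",
           paste(ccRegionNames(), collapse = ", "))
  out <- table
  for (cl in intersect(.areaNumericCols, names(out)))
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ccStop("ccmorphUnwritable", "cannot write area table to %s", path)
  invisible(path)
}

#' Read an area table written by [writeAreaTable()]
#'
#' @param path CSV file path.
#' @return data.frame with numeric columns restored at full precision.
#' @export
readAreaTable <- function(path) {
  if (!file.exists(path))
    ccStop("ccmorphMissingFile", "area table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cl in intersect(.areaNumericCols, names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}
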