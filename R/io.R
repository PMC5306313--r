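## io_cli (formats): NIfTI / PNG / minimal DICOM readers, NIfTI writers, and
## the CSV table schemas shared by the pipeline stages.

#' Write a lesion image (or mask) as NIfTI
#'
#' Pixel values are stored as float64 so that a write/read round trip is
#' bit-identical; the in-plane spacing goes into the header pixdim.
#'
#' @param pixels Numeric or logical matrix.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param spacing_mm In-plane pixel size in mm.
#' @return `path`, invisibly.
#' @export
write_nifti_slice <- function(pixels, path, spacing_mm) {
  ni <- RNifti::asNifti(structure(pixels * 1,
                                  pixdim = c(spacing_mm, spacing_mm)),
                        datatype = "double")
  RNifti::writeNifti(ni, path)
  invisible(path)
}

read_nifti_slice <- function(path) {
  ni <- RNifti::readNifti(path)
  px <- as.array(ni)
  if (length(dim(px)) > 2L) {
    extra <- dim(px)[-(1:2)]
    if (any(extra != 1L))
      ctta_stop(sprintf("%s is not a single 2-D slice", path), "io_error")
  }
  px <- matrix(as.numeric(px), dim(px)[1], dim(px)[2])  # strip NIfTI attrs
  ## pixdim is float32 on disk; renormalize so 0.98 mm reads back as 0.98 mm
  list(pixels = px, spacing_mm = signif(RNifti::pixdim(ni)[1], 6))
}

#' Read a lesion image and its ROI mask
#'
#' Images: NIfTI (spacing from the header) or single-slice DICOM (explicit
#' VR little endian; HU = RescaleSlope * stored + RescaleIntercept, spacing
#' from PixelSpacing). Masks: NIfTI or PNG, binarized at 0.5 and required to
#' be congruent with the image grid.
#'
#' @param image_path Path to the image (`.nii`, `.nii.gz`, `.dcm`).
#' @param mask_path Path to the mask (`.nii`, `.nii.gz`, `.png`).
#' @param spacing_mm Optional override when the header carries no usable
#'   spacing.
#' @return List with `image` ([lesion_image()]) and `mask` ([roi_mask()]).
#' @export
read_lesion <- function(image_path, mask_path, spacing_mm = NULL) {
  if (!file.exists(image_path))
    ctta_stop(paste("image not found:", image_path), "io_error")
  if (!file.exists(mask_path))
    ctta_stop(paste("mask not found:", mask_path), "io_error")
  im <- if (grepl("\\.dcm$", image_path, ignore.case = TRUE))
    read_dicom_slice(image_path) else read_nifti_slice(image_path)
  sp <- if (!is.null(spacing_mm)) spacing_mm else im$spacing_mm
  if (is.null(sp) || !is.finite(sp) || sp <= 0)
    ctta_stop(paste("no usable pixel spacing in", image_path,
                    "(use the spacing override)"), "io_error")
  img <- lesion_image(im$pixels, sp)
  mk <- if (grepl("\\.png$", mask_path, ignore.case = TRUE)) {
    arr <- png::readPNG(mask_path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    arr
  } else read_nifti_slice(mask_path)$pixels
  mask <- roi_mask(mk > 0.5)
  check_congruent(img, mask)
  list(image = img, mask = mask)
}

## --- Minimal single-slice DICOM reader (explicit VR little endian) -------
## Supports the tags a CT slice export needs: Rows, Columns, PixelSpacing,
## BitsAllocated, PixelRepresentation, RescaleIntercept/Slope, PixelData.

#' Read a single-slice DICOM CT image
#'
#' Minimal parser for uncompressed single-frame DICOM in explicit-VR
#' little-endian transfer syntax. Stored pixel values are mapped to HU via
#' `RescaleSlope * stored + RescaleIntercept` (defaults 1 and 0).
#'
#' @param path DICOM file path.
#' @return List with `pixels` (HU matrix, row-major as displayed) and
#'   `spacing_mm` (row spacing; NULL when PixelSpacing is absent).
#' @export
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 8L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      ctta_stop("unsupported DICOM encoding (implicit VR?)", "io_error")
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); ds <- pos + 12L
    } else {
      len <- u16(pos + 6L); ds <- pos + 8L
    }
    key <- sprintf("%04X,%04X", grp, ele)
    tags[[key]] <- list(vr = vr,
                        val = if (len > 0L) raw[ds:(ds + len - 1L)] else raw(0))
    pos <- ds + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts)) {
    v <- ts$val
    uid <- sub("\\s+$", "", rawToChar(v[v != as.raw(0)]))
    if (uid != "1.2.840.10008.1.2.1")
      ctta_stop(paste("unsupported DICOM transfer syntax", uid), "io_error")
  }
  need <- function(key, what) {
    if (is.null(tags[[key]]))
      ctta_stop(paste("DICOM file lacks", what), "io_error")
    tags[[key]]
  }
  us_val <- function(tag) u16_raw(tag$val)
  rows <- us_val(need("0028,0010", "Rows"))
  cols <- us_val(need("0028,0011", "Columns"))
  bits <- us_val(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) ctta_stop("only 16-bit DICOM pixel data supported", "io_error")
  signed <- !is.null(tags[["0028,0103"]]) && us_val(tags[["0028,0103"]]) == 1L
  ds_num <- function(tag, default) {
    if (is.null(tag)) return(default)
    as.numeric(strsplit(rawToChar(tag$val), "\\\\")[[1]])
  }
  slope <- ds_num(tags[["0028,1053"]], 1)[1]
  intercept <- ds_num(tags[["0028,1052"]], 0)[1]
  spacing <- ds_num(tags[["0028,0030"]], NULL)
  pd <- need("7FE0,0010", "PixelData")
  stored <- readBin(pd$val, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  hu <- matrix(slope * stored + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)
  list(pixels = hu, spacing_mm = if (is.null(spacing)) NULL else spacing[1])
}

u16_raw <- function(v) as.integer(v[1]) + 256L * as.integer(v[2])

## --- Tables ----------------------------------------------------------------

LESION_TABLE_COLS <- c("patient_id", "lesion_id", "suv_max", "area_px")
CLINICAL_TABLE_COLS <- c("patient_id", "subtype", "stage", "treatment",
                         "ipet", "bulk_px", "pfs_months", "event")

check_table <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ctta_stop(sprintf("%s table lacks column(s): %s", what,
                      paste(miss, collapse = ", ")), "bad_table")
  invisible(df)
}

#' Read the lesion and clinical CSV tables
#'
#' Lesion table: one row per lesion with `patient_id, lesion_id, suv_max,
#' area_px` plus either kurtosis columns (`k0`, `k2`, ..., `k6`) or
#' `image_path, mask_path` for on-the-fly texture computation. Clinical
#' table: one row per patient with `patient_id, subtype, stage, treatment,
#' ipet, bulk_px, pfs_months, event`.
#'
#' @param lesion_csv,clinical_csv CSV paths.
#' @return List with `lesions` and `clinical` data frames.
#' @export
read_cohort_tables <- function(lesion_csv, clinical_csv) {
  for (f in c(lesion_csv, clinical_csv))
    if (!file.exists(f)) ctta_stop(paste("table not found:", f), "io_error")
  lesions <- check_table(read.csv(lesion_csv, stringsAsFactors = FALSE),
                         LESION_TABLE_COLS, "lesion")
  clinical <- check_table(read.csv(clinical_csv, stringsAsFactors = FALSE),
                          CLINICAL_TABLE_COLS, "clinical")
  clinical$ipet[clinical$ipet %in% c("", "NA")] <- NA
  list(lesions = lesions, clinical = clinical)
}

## Write a simulated cohort to disk in the pipeline's input schemas.
write_cohort <- function(cohort, dir, phantoms = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lesions <- cohort$lesions
  if (length(phantoms)) {
    imgdir <- file.path(dir, "images")
    dir.create(imgdir, showWarnings = FALSE)
    lesions$image_path <- NA_character_
    lesions$mask_path <- NA_character_
    for (i in seq_len(nrow(lesions))) {
      lid <- lesions$lesion_id[i]
      ph <- phantoms[[lid]]
      if (is.null(ph)) next
      ip <- file.path(imgdir, paste0(lid, ".nii.gz"))
      mp <- file.path(imgdir, paste0(lid, "_mask.nii.gz"))
      write_nifti_slice(ph$image$pixels, ip, ph$image$spacing_mm)
      write_nifti_slice(ph$mask$mask, mp, ph$image$spacing_mm)
      lesions$image_path[i] <- ip
      lesions$mask_path[i] <- mp
    }
  }
  write.csv(lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' Compute the per-lesion texture table from image files
#'
#' Runs [read_lesion()] + [compute_texture_profile()] for every row of a
#' lesion table carrying `image_path` / `mask_path`, returning the table with
#' kurtosis columns filled in and `area_px` replaced by the refined (gas-
#' excluded) ROI pixel count.
#'
#' @param lesions Lesion table with `image_path` and `mask_path`.
#' @param scales Spatial scales (default `c(0, 2, 3, 4, 5, 6)`).
#' @param hu_threshold Gas-exclusion threshold (default -50).
#' @param spacing_mm Optional spacing override for all images.
#' @return The lesion table with `k*` columns and updated `area_px`.
#' @export
lesion_texture_table <- function(lesions, scales = SSF_SCALES,
                                 hu_threshold = -50, spacing_mm = NULL) {
  check_table(lesions, c(LESION_TABLE_COLS, "image_path", "mask_path"),
              "lesion")
  kc <- scale_col(scales)
  for (cn in kc) lesions[[cn]] <- NA_real_
  for (i in seq_len(nrow(lesions))) {
    l <- read_lesion(lesions$image_path[i], lesions$mask_path[i], spacing_mm)
    prof <- compute_texture_profile(l$image, l$mask, scales = scales,
                                    hu_threshold = hu_threshold)
    lesions[i, kc] <- unname(prof$values[kc])
    lesions$area_px[i] <- prof$n_pixels
  }
  lesions
}
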