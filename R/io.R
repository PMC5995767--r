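#' Participant metadata
#'
#' Covariates used for SUV computation and population-based input-function
#' normalisation, plus the clinical subgroup label.
#'
#' @param id participant identifier.
#' @param weight body weight, kg (> 0).
#' @param injected_dose injected activity, MBq (> 0).
#' @param age years (>= 0).
#' @param subgroup one of `"control"`, `"epilepsy"`,
#'   `"epilepsy_antidepressant"`.
#' @return object of class `participant_meta`.
#' @export
participant_meta <- function(id, weight, injected_dose, age,
                             subgroup = c("control", "epilepsy",
                                          "epilepsy_antidepressant")) {
  subgroup <- match.arg(subgroup)
  if (weight <= 0) stop("weight must be > 0 kg", call. = FALSE)
  if (injected_dose <= 0) stop("injected_dose must be > 0 MBq", call. = FALSE)
  if (age < 0) stop("age must be >= 0", call. = FALSE)
  structure(list(id = as.character(id), weight = weight,
                 injected_dose = injected_dose, age = age,
                 subgroup = subgroup),
            class = "participant_meta")
}

#' 3-D labelled region-of-interest map
#'
#' @param labels 3-D integer array; 0 = background.
#' @param label_table data frame with columns `label` (integer id) and
#'   `region` (name); every non-zero id in `labels` must appear.
#' @param voxel_size voxel edge lengths in mm (length 3 or scalar).
#' @return object of class `roi_map`.
#' @export
roi_map <- function(labels, label_table, voxel_size = c(2, 2, 2)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array", call. = FALSE)
  if (!all(c("label", "region") %in% names(label_table))) {
    stop("label_table needs columns `label` and `region`", call. = FALSE)
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, label_table$label)
  if (length(missing)) {
    stop("labels present in volume but absent from label_table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(label_table$label)) {
    stop("duplicate label ids in label_table", call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  structure(list(labels = labels,
                 label_table = as.data.frame(label_table),
                 voxel_size = voxel_size),
            class = "roi_map")
}

#' 4-D dynamic PET image
#'
#' Activity is stored decay-corrected to injection time, in Bq/mL.
#'
#' @param data 4-D numeric array (x, y, z, frame).
#' @param schedule a `frame_schedule` whose frame count matches dim 4.
#' @return object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule) {
  d <- dim(data)
  if (length(d) != 4L) stop("data must be a 4-D array", call. = FALSE)
  if (d[4] != n_frames(schedule)) {
    stop(sprintf("frame-count mismatch: image has %d frames, schedule %d",
                 d[4], n_frames(schedule)), call. = FALSE)
  }
  structure(list(data = data, schedule = schedule), class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames, %g s scan\n",
              d[1], d[2], d[3], d[4], scan_end(x$schedule)))
  invisible(x)
}

# ---- NIfTI + JSON sidecar I/O -----------------------------------------

#' Read / write a dynamic PET series (NIfTI + JSON frame-timing sidecar)
#'
#' The sidecar is a JSON object with arrays `FrameStart` and
#' `FrameDuration` (seconds from acquisition start, one entry per frame)
#' and a scalar `InjectionOffset` (seconds). A frame-count mismatch
#' between image and sidecar is a format error.
#'
#' @param image_path path to a 4-D NIfTI file.
#' @param timing_path path to the JSON sidecar.
#' @return [read_dynamic_pet()]: a `dynamic_image`.
#' @export
read_dynamic_pet <- function(image_path, timing_path) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  side <- jsonlite::read_json(timing_path, simplifyVector = TRUE)
  req <- c("FrameStart", "FrameDuration")
  if (!all(req %in% names(side))) {
    stop("timing sidecar must contain FrameStart and FrameDuration", call. = FALSE)
  }
  sched <- frame_schedule(side$FrameStart, side$FrameDuration,
                          injection_offset = side$InjectionOffset %||% 30)
  if (dim(arr)[4] != n_frames(sched)) {
    stop(sprintf("frame-count mismatch: image has %d frames, sidecar lists %d",
                 dim(arr)[4], n_frames(sched)), call. = FALSE)
  }
  dynamic_image(arr, sched)
}

#' @rdname read_dynamic_pet
#' @param dyn a `dynamic_image`.
#' @param voxel_size voxel edge lengths (mm) written to the NIfTI header.
#' @export
write_dynamic_pet <- function(dyn, image_path, timing_path,
                              voxel_size = c(2, 2, 2)) {
  arr <- dyn$data
  attr(arr, "pixdim") <- c(voxel_size, 1)
  RNifti::writeNifti(arr, image_path, datatype = "double")
  jsonlite::write_json(
    list(FrameStart = dyn$schedule$frame_start,
         FrameDuration = dyn$schedule$frame_duration,
         InjectionOffset = dyn$schedule$injection_offset),
    timing_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image_path, timing_path))
}

#' Read / write an ROI label map (NIfTI + CSV label table)
#'
#' @param labels_path 3-D integer NIfTI.
#' @param table_path CSV with columns `label`, `region`.
#' @return [read_roi_map()]: an `roi_map`.
#' @export
read_roi_map <- function(labels_path, table_path) {
  img <- RNifti::readNifti(labels_path)
  arr <- as.array(img)
  storage.mode(arr) <- "integer"
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  roi_map(arr, tab, voxel_size = vs)
}

#' @rdname read_roi_map
#' @param map an `roi_map`.
#' @export
write_roi_map <- function(map, labels_path, table_path) {
  arr <- map$labels
  attr(arr, "pixdim") <- map$voxel_size
  RNifti::writeNifti(arr, labels_path, datatype = "int32")
  utils::write.csv(map$label_table, table_path, row.names = FALSE)
  invisible(c(labels_path, table_path))
}

#' Write a 3-D parametric image (VT or SUV) as NIfTI
#'
#' Voxels outside the analysis mask are NA in R and written as NaN.
#'
#' @param vol 3-D numeric array.
#' @param path output NIfTI path.
#' @param voxel_size voxel edge lengths, mm.
#' @export
write_parametric_image <- function(vol, path, voxel_size = c(2, 2, 2)) {
  attr(vol, "pixdim") <- voxel_size
  RNifti::writeNifti(vol, path, datatype = "double")
  invisible(path)
}

# ---- blood tables ------------------------------------------------------

#' Read combined arterial blood data
#'
#' The continuous table (online detector, typically 0-15 min at ~1 s
#' resolution) has columns `time_s`, `wholeblood_Bq_per_mL`. The discrete
#' table (manual samples to ~90.5 min) has columns `time_s`,
#' `wholeblood_Bq_per_mL`, `plasma_Bq_per_mL`, `parent_fraction`; a
#' missing measurement is an empty cell / NA. Rows are sorted by time on
#' load. Validation errors: non-monotone duplicated times, negative
#' times, parent fractions outside [0, 1], empty tables.
#'
#' @param continuous_csv,discrete_csv file paths.
#' @return list with `continuous` (a `sampled_curve`, negative detector
#'   values retained for later clamping) and `discrete` (a
#'   `discrete_samples` data frame).
#' @export
read_blood_tables <- function(continuous_csv, discrete_csv) {
  cont <- utils::read.csv(continuous_csv)
  disc <- utils::read.csv(discrete_csv)
  if (nrow(cont) == 0L) stop("continuous blood table is empty", call. = FALSE)
  if (nrow(disc) == 0L) stop("discrete blood table is empty", call. = FALSE)
  need_c <- c("time_s", "wholeblood_Bq_per_mL")
  need_d <- c("time_s", "wholeblood_Bq_per_mL", "plasma_Bq_per_mL",
              "parent_fraction")
  if (!all(need_c %in% names(cont))) {
    stop("continuous table needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_d %in% names(disc))) {
    stop("discrete table needs columns: ", paste(need_d, collapse = ", "),
         call. = FALSE)
  }
  list(continuous = sampled_curve(cont$time_s, cont$wholeblood_Bq_per_mL,
                                  allow_negative = TRUE),
       discrete = discrete_samples(disc$time_s, disc$wholeblood_Bq_per_mL,
                                   disc$plasma_Bq_per_mL, disc$parent_fraction))
}

#' Discrete arterial sample table
#'
#' @param time seconds post-injection, strictly increasing after sorting.
#' @param wholeblood,plasma activities Bq/mL (NA = not measured).
#' @param parent_fraction fraction of plasma activity attributable to
#'   unmetabolised parent tracer, in [0, 1] (NA = not measured).
#' @return data frame of class `discrete_samples`.
#' @export
discrete_samples <- function(time, wholeblood = NA_real_, plasma = NA_real_,
                             parent_fraction = NA_real_) {
  n <- length(time)
  df <- data.frame(time = time,
                   wholeblood = rep_len(wholeblood, n),
                   plasma = rep_len(plasma, n),
                   parent_fraction = rep_len(parent_fraction, n))
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$time < 0)) stop("negative sample times", call. = FALSE)
  if (any(diff(df$time) <= 0)) stop("duplicated sample times", call. = FALSE)
  act <- c(df$wholeblood, df$plasma)
  if (any(act < 0, na.rm = TRUE)) stop("negative activities", call. = FALSE)
  pf <- df$parent_fraction
  if (any(pf < 0 | pf > 1, na.rm = TRUE)) {
    stop("parent_fraction outside [0, 1]", call. = FALSE)
  }
  structure(df, class = c("discrete_samples", "data.frame"))
}

#' @rdname read_blood_tables
#' @param continuous a `sampled_curve`; `discrete` a `discrete_samples`.
#' @param discrete see above.
#' @export
write_blood_tables <- function(continuous, discrete,
                               continuous_csv, discrete_csv) {
  utils::write.csv(data.frame(time_s = continuous$time,
                              wholeblood_Bq_per_mL = continuous$activity),
                   continuous_csv, row.names = FALSE)
  utils::write.csv(data.frame(time_s = discrete$time,
                              wholeblood_Bq_per_mL = discrete$wholeblood,
                              plasma_Bq_per_mL = discrete$plasma,
                              parent_fraction = discrete$parent_fraction),
                   discrete_csv, row.names = FALSE)
  invisible(c(continuous_csv, discrete_csv))
}

#' Read / write participant metadata CSV
#'
#' Columns: `id`, `weight_kg`, `dose_MBq`, `age_years`, `subgroup`.
#'
#' @param path CSV path.
#' @return list of `participant_meta`.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    participant_meta(df$id[i], df$weight_kg[i], df$dose_MBq[i],
                     df$age_years[i], df$subgroup[i])
  })
}

#' @rdname read_participants
#' @param metas list of `participant_meta`.
#' @export
write_participants <- function(metas, path) {
  df <- do.call(rbind, lapply(metas, function(m) {
    data.frame(id = m$id, weight_kg = m$weight, dose_MBq = m$injected_dose,
               age_years = m$age, subgroup = m$subgroup)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an input function as CSV (`time_s`, `Bq_per_mL`)
#'
#' @param x an `input_function`.
#' @param path CSV path.
#' @export
write_input_function <- function(x, path) {
  utils::write.csv(data.frame(time_s = x$time, Bq_per_mL = x$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_input_function
#' @param id,provenance metadata for the reconstructed object.
#' @export
read_input_function <- function(path, id = NA_character_, provenance = "ppif") {
  df <- utils::read.csv(path)
  input_function(df$time_s, df$Bq_per_mL, id = id, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
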