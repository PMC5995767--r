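#' Synthetic cohort specification
#'
#' Study conditions for the seeded synthetic cohort: 90-min dynamic
#' scans, injection 30 s after acquisition start, doses drawn from
#' Normal(187, 4) MBq, ages spanning 20-62 years, and regional
#' two-tissue-compartment kinetics whose closed-form VT targets lie in
#' the 8-13 range typical of high-affinity reversible tracers in grey
#' matter. Between-subject spread is a participant-level lognormal
#' factor on K1 (sdlog 0.23, giving ~23% between-subject CV in VT).
#'
#' @param n_participants cohort size (>= 2; the population-based
#'   input-function method needs a population).
#' @param seed integer seed; every generator draw derives from it.
#' @param roi_vt_means named numeric vector of target VT per region;
#'   default [default_roi_kinetics()] targets.
#' @param noise_blood proportional (multiplicative Gaussian) noise SD on
#'   discrete blood samples; 0 = noise-free.
#' @param noise_dynamic image noise scale: frame SD =
#'   `noise_dynamic * sqrt(activity / frame_duration)` (Bq/mL); 0 =
#'   noise-free.
#' @param between_subject_sdlog lognormal SD of the per-participant
#'   global K1 factor.
#' @param age_range,dose_mean_sd,weight_range cohort covariate
#'   distributions (years; MBq mean and SD; kg uniform range).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20, seed = 1,
                        roi_vt_means = NULL,
                        noise_blood = 0.03,
                        noise_dynamic = 30,
                        between_subject_sdlog = 0.23,
                        age_range = c(20, 62),
                        dose_mean_sd = c(187, 4),
                        weight_range = c(55, 95)) {
  if (n_participants < 2) {
    stop("n_participants must be >= 2 (the PBIF stage needs a population)",
         call. = FALSE)
  }
  if (is.null(roi_vt_means)) {
    rk <- default_roi_kinetics()
    roi_vt_means <- stats::setNames(rk$vt_target, rk$region)
  }
  if (any(roi_vt_means <= 0)) stop("all target VT must be > 0", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 roi_vt_means = roi_vt_means,
                 noise_blood = noise_blood,
                 noise_dynamic = noise_dynamic,
                 between_subject_sdlog = between_subject_sdlog,
                 age_range = age_range,
                 dose_mean_sd = dose_mean_sd,
                 weight_range = weight_range),
            class = "cohort_spec")
}

#' Default regional two-tissue kinetics
#'
#' Seven bilateral grey-matter analysis regions with target VT and rate
#' constants (min^-1). K1 is derived from the target VT through the
#' closed form VT = (K1/k2)(1 + k3/k4). The slow eigen-rate of the
#' medial temporal regions (hippocampus, parahippocampal gyrus; also
#' thalamus) sits just above the 90-min spectral slow boundary but below
#' the 60/70-min boundaries, which is what makes shortened-scan VT
#' regionally biased downward.
#'
#' @return data frame: region, vt_target, K1, k2, k3, k4, vb.
#' @export
default_roi_kinetics <- function() {
  df <- data.frame(
    region = c("cerebellum", "hippocampus", "occipital_lobe",
               "parahippocampal_gyrus", "putamen",
               "superior_frontal_gyrus", "thalamus"),
    vt_target = c(10.0, 11.2, 10.7, 9.9, 12.7, 10.3, 12.7),
    k2 = c(0.055, 0.045, 0.060, 0.045, 0.060, 0.055, 0.050),
    k3 = c(0.025, 0.030, 0.022, 0.032, 0.025, 0.024, 0.028),
    k4 = c(0.035, 0.025, 0.030, 0.025, 0.035, 0.030, 0.024)
  )
  df$K1 <- df$vt_target * df$k2 / (1 + df$k3 / df$k4)
  df$vb <- 0.05
  df[, c("region", "vt_target", "K1", "k2", "k3", "k4", "vb")]
}

#' Kinetic parameter list for a cohort's regions
#'
#' @param kin data frame as from [default_roi_kinetics()].
#' @param k1_factor multiplicative participant-level factor on K1.
#' @return named list of `kinetic_params`.
#' @export
roi_params_list <- function(kin = default_roi_kinetics(), k1_factor = 1) {
  stats::setNames(lapply(seq_len(nrow(kin)), function(i) {
    kinetic_params(kin$K1[i] * k1_factor, kin$k2[i], kin$k3[i], kin$k4[i],
                   kin$vb[i])
  }), kin$region)
}

#' Generate participant metadata for a synthetic cohort
#'
#' Doses ~ Normal(187, 4) MBq truncated positive; weights uniform over
#' the weight range; ages equally spaced over the age range (guaranteeing
#' span) with a small seeded jitter; subgroups assigned in the 9/7/4
#' control / epilepsy / epilepsy-on-antidepressant proportion.
#'
#' @param spec a `cohort_spec`.
#' @return list of `participant_meta`, length `n_participants`.
#' @export
make_cohort <- function(spec) {
  n <- spec$n_participants
  rs <- local_rng(spec$seed, "cohort")
  dose <- stats::rnorm(n, spec$dose_mean_sd[1], spec$dose_mean_sd[2])
  while (any(dose <= 0)) {
    dose[dose <= 0] <- stats::rnorm(sum(dose <= 0), spec$dose_mean_sd[1],
                                    spec$dose_mean_sd[2])
  }
  weight <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  age <- seq(spec$age_range[1], spec$age_range[2], length.out = n)
  if (n > 2) {
    step <- diff(spec$age_range) / (n - 1)
    age[2:(n - 1)] <- age[2:(n - 1)] + stats::runif(n - 2, -step / 3, step / 3)
  }
  age <- sample(age)   # decouple age order from id order
  grp <- rep(c("control", "epilepsy", "epilepsy_antidepressant"),
             times = pmax(round(n * c(9, 7, 4) / 20), 1))
  grp <- grp[seq_len(n)]
  restore_rng(rs)
  lapply(seq_len(n), function(i) {
    participant_meta(sprintf("P%02d", i), weight[i], dose[i], age[i], grp[i])
  })
}

# seeded sub-stream helpers: every generator derives its stream from the
# cohort seed plus a stage label, so stages are independently reproducible
local_rng <- function(seed, label, index = 0L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  offset <- sum(utf8ToInt(label)) * 131 + as.numeric(index) * 7919
  set.seed(as.integer((as.numeric(seed) * 2654435 + offset) %% 2147483647))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Simulate arterial blood data for one participant
#'
#' The whole-blood curve is a gamma-variate first-pass peak (peak time
#' drawn in 55-75 s post-injection) plus two slower washout exponentials;
#' the plasma-over-blood ratio rises slowly and linearly from ~1.04; the
#' parent fraction is the decreasing sigmoid 1 - A t^h/(t^h + T50^h)
#' with A = 0.85, h = 1.3, and T50 shortened by 8 s per year of age above
#' the cohort mean plus participant scatter -- the scatter SD (110 s) is
#' set so the expected cohort correlation between age and parent-fraction
#' AUC is about -0.66. Returns the continuous detector record (0-15 min,
#' 1-s resolution, in uncalibrated detector units: the true curve divided
#' by a participant-specific gain in 0.75-1.25), nine discrete samples
#' (5, 10, 15, 20, 30, 45, 60, 75 and 90.5 min) with proportional
#' measurement noise, and the noise-free ground-truth parent-plasma
#' input function.
#'
#' @param meta a `participant_meta`.
#' @param spec a `cohort_spec` (noise and age-effect settings).
#' @param index participant index, used to decorrelate seeds.
#' @return list: `continuous` (`sampled_curve`, detector units),
#'   `discrete` (`discrete_samples`), `true_if` (`input_function`,
#'   provenance "true"), `wholeblood` (noise-free `sampled_curve`),
#'   `pf_true` (`parent_fraction_fit`), `gain` (detector gain used).
#' @export
simulate_blood <- function(meta, spec, index = 1L) {
  rs <- local_rng(spec$seed, "blood", index)
  on.exit(restore_rng(rs))

  t_grid <- 0:5430
  tp <- stats::runif(1, 55, 75)
  # peak amplitude ~ dose diluted in ~70 mL/kg blood volume
  Ap <- meta$injected_dose * 1e6 / (70 * meta$weight)
  ramp <- 1 - exp(-(t_grid / tp)^2)
  g <- (t_grid / tp)^3 * exp(3 * (1 - t_grid / tp))
  g[t_grid <= 0] <- 0
  # between-subject washout-shape heterogeneity (~20% lognormal on the
  # tail fractions and time constants)
  f1 <- 0.12 * stats::rlnorm(1, 0, 0.2)
  f2 <- 0.05 * stats::rlnorm(1, 0, 0.2)
  tau1 <- 1200 * stats::rlnorm(1, 0, 0.2)
  tau2 <- 6000 * stats::rlnorm(1, 0, 0.2)
  cb <- Ap * (g + ramp * (f1 * exp(-t_grid / tau1) +
                          f2 * exp(-t_grid / tau2)))
  pob <- 1.04 + stats::rnorm(1, 0, 0.02) +
    8e-6 * stats::rlnorm(1, 0, 0.3) * t_grid

  age_mid <- mean(spec$age_range)
  T50 <- 1500 - 8 * (meta$age - age_mid) + stats::rnorm(1, 0, 110)
  T50 <- min(max(T50, 400), 3600)
  pf_true <- parent_fraction_fit(A = 0.85, T50 = T50, h = 1.3)
  pf <- parent_fraction_at(pf_true, t_grid)

  true_if <- input_function(t_grid, cb * pob * pf, id = meta$id,
                            provenance = "true")

  gain <- stats::runif(1, 0.75, 1.25)
  cont_idx <- t_grid <= 900
  cont <- sampled_curve(t_grid[cont_idx], cb[cont_idx] / gain,
                        allow_negative = TRUE)

  t_disc <- c(5, 10, 15, 20, 30, 45, 60, 75, 90.5) * 60
  noise <- function(n) 1 + stats::rnorm(n, 0, spec$noise_blood)
  wb_d <- curve_at(sampled_curve(t_grid, cb), t_disc) * noise(9)
  pl_d <- curve_at(sampled_curve(t_grid, cb * pob), t_disc) * noise(9)
  pf_d <- pmin(pmax(parent_fraction_at(pf_true, t_disc) * noise(9), 0), 1)
  disc <- discrete_samples(t_disc, pmax(wb_d, 0), pmax(pl_d, 0), pf_d)

  list(continuous = cont, discrete = disc, true_if = true_if,
       wholeblood = sampled_curve(t_grid, cb), pf_true = pf_true,
       gain = gain)
}

#' Simulate a dynamic image from known regional kinetics
#'
#' Every voxel of region r follows
#' (1 - vb) C_tissue(t; params_r) + vb C_wholeblood(t), frame-averaged
#' over the schedule; mean-zero Gaussian noise with SD
#' `noise_scale * sqrt(activity / frame_duration)` is added per voxel and
#' frame (a count-statistics proxy: variance inversely proportional to
#' frame duration, proportional to activity). Background voxels are 0.
#'
#' @param meta a `participant_meta` (id used for seeding).
#' @param roi an `roi_map`.
#' @param params_per_roi named list of `kinetic_params`, one per region
#'   in the map.
#' @param true_if ground-truth `input_function` (parent plasma).
#' @param schedule a `frame_schedule` covered by `true_if`.
#' @param wholeblood noise-free whole-blood `sampled_curve` for the
#'   vascular term.
#' @param noise_scale see above; 0 = noise-free.
#' @param spec optional `cohort_spec` (for the seed); `index` the
#'   participant index.
#' @param index see above.
#' @return a `dynamic_image`.
#' @export
simulate_dynamic <- function(meta, roi, params_per_roi, true_if, schedule,
                             wholeblood, noise_scale = 0,
                             spec = NULL, index = 1L) {
  regions <- roi$label_table$region
  missing <- setdiff(regions, names(params_per_roi))
  if (length(missing)) {
    stop("no kinetic parameters for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (scan_end(schedule) > max(true_if$time) + 1e-6) {
    stop("input function does not cover the schedule", call. = FALSE)
  }
  wb_grid <- curve_at(wholeblood, true_if$time)
  wb_frames <- frame_average(true_if$time, wb_grid, schedule)

  d <- c(dim(roi$labels), n_frames(schedule))
  arr <- array(0, d)
  flat <- matrix(arr, prod(d[1:3]), d[4])
  for (i in seq_along(regions)) {
    p <- params_per_roi[[regions[i]]]
    ct <- model_tissue_curve(true_if, p)
    tac <- (1 - p$vb) * frame_average(true_if$time, ct, schedule) +
      p$vb * wb_frames
    vox <- which(roi$labels == roi$label_table$label[i])
    flat[vox, ] <- matrix(tac, length(vox), d[4], byrow = TRUE)
  }
  if (noise_scale > 0) {
    seed <- if (is.null(spec)) 1L else spec$seed
    rs <- local_rng(seed, "dynamic", index)
    on.exit(restore_rng(rs))
    vox <- which(roi$labels != 0L)
    dur <- schedule$frame_duration
    for (j in seq_len(d[4])) {
      sd_j <- noise_scale * sqrt(pmax(flat[vox, j], 0) / dur[j])
      flat[vox, j] <- flat[vox, j] + stats::rnorm(length(vox), 0, sd_j)
    }
  }
  dynamic_image(array(flat, d), schedule)
}

#' Block-phantom ROI map
#'
#' A stand-in for an anatomical multi-atlas segmentation: the interior of
#' the volume (one-voxel background border) is divided into contiguous
#' equal slabs, one per region. Default regions are the seven bilateral
#' grey-matter analysis regions of [default_roi_kinetics()].
#'
#' @param shape integer length-3 volume dimensions.
#' @param regions character vector of region names (>= 1).
#' @param voxel_size mm.
#' @return an `roi_map`.
#' @export
make_roi_phantom <- function(shape = c(12, 12, 12),
                             regions = default_roi_kinetics()$region,
                             voxel_size = c(2, 2, 2)) {
  if (length(regions) < 1L) stop("need at least one region", call. = FALSE)
  if (any(shape < 1)) stop("invalid shape", call. = FALSE)
  labels <- array(0L, shape)
  interior <- array(FALSE, shape)
  if (all(shape >= 3)) {
    interior[2:(shape[1] - 1), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- TRUE
  } else {
    interior[] <- TRUE
  }
  vox <- which(interior)
  if (length(vox) < length(regions)) {
    stop("more regions than interior voxels", call. = FALSE)
  }
  nr <- length(regions)
  grp <- 1L + ((seq_along(vox) - 1L) * nr) %/% length(vox)
  labels[vox] <- grp
  roi_map(labels,
          data.frame(label = seq_along(regions), region = regions),
          voxel_size = voxel_size)
}

#' Generate a complete synthetic participant dataset
#'
#' Convenience wrapper: blood data, participant-level kinetics (global
#' lognormal K1 factor) and the dynamic image for one cohort member.
#'
#' @param meta a `participant_meta`; `spec` a `cohort_spec`; `roi` an
#'   `roi_map`; `schedule` a `frame_schedule`; `index` participant index.
#' @param spec,roi,schedule,index see above.
#' @return list: `blood` (from [simulate_blood()]), `dyn`
#'   (`dynamic_image`), `params` (per-region `kinetic_params`),
#'   `true_vt` (named vector of ground-truth VT).
#' @export
simulate_participant <- function(meta, spec, roi, schedule, index = 1L) {
  blood <- simulate_blood(meta, spec, index)
  rs <- local_rng(spec$seed, "kinetics", index)
  k1f <- stats::rlnorm(1, 0, spec$between_subject_sdlog)
  restore_rng(rs)
  kin <- default_roi_kinetics()
  kin <- kin[match(roi$label_table$region, kin$region), ]
  if (anyNA(kin$region)) {
    stop("phantom contains regions without default kinetics; supply your own",
         call. = FALSE)
  }
  kin$K1 <- spec$roi_vt_means[kin$region] * kin$k2 / (1 + kin$k3 / kin$k4)
  params <- roi_params_list(kin, k1_factor = k1f)
  dyn <- simulate_dynamic(meta, roi, params, blood$true_if, schedule,
                          blood$wholeblood, noise_scale = spec$noise_dynamic,
                          spec = spec, index = index)
  list(blood = blood, dyn = dyn, params = params,
       true_vt = vapply(params, vt_closed_form, numeric(1)))
}
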