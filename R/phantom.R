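#' @keywords internal
REGIONS <- c("wulst", "thalamus_gld", "optic_tectum")

#' @keywords internal
HEMISPHERES <- c("left", "right")

#' Repetition-time schedule of the RARE-VTR acquisition (ms)
#'
#' The 13-point variable-TR schedule used for saturation-recovery T1 mapping
#' at 7 T, in milliseconds.
#'
#' @return Numeric vector of 13 strictly increasing repetition times (ms).
#' @export
vtr_tr_schedule <- function() {
  c(169.3, 240.6, 340.6, 440.6, 540.6, 640.6, 740.6, 840.6,
    990.6, 1490.6, 1990.6, 2990.6, 4990.6)
}

#' Ellipsoidal ROI geometry
#'
#' One segmented section of a visual region in one hemisphere, modelled as an
#' axis-aligned ellipsoid on the voxel grid.
#'
#' @param label_id Positive integer label carried by the voxels of this ROI.
#' @param region One of `"wulst"`, `"thalamus_gld"`, `"optic_tectum"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param section Integer slice index of the section.
#' @param center Numeric length-3 voxel coordinates of the ellipsoid centre.
#' @param radii Numeric length-3 ellipsoid semi-axes in voxels (all >= ~0.4
#'   so that at least the centre voxel is included; in-plane radii >= 1).
#' @return An object of class `roi_geometry`.
#' @export
roi_geometry <- function(label_id, region, hemisphere, section, center, radii) {
  stopifnot(length(label_id) == 1, label_id == as.integer(label_id), label_id > 0)
  region <- match.arg(region, REGIONS)
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  stopifnot(length(section) == 1, section == as.integer(section),
            length(center) == 3, length(radii) == 3, all(radii > 0))
  structure(list(label_id = as.integer(label_id), region = region,
                 hemisphere = hemisphere, section = as.integer(section),
                 center = as.numeric(center), radii = as.numeric(radii)),
            class = "roi_geometry")
}

#' Digital egg-brain phantom specification
#'
#' @param grid_dims Integer length-3 voxel counts per axis (each >= 8).
#' @param voxel_size Numeric length-3 voxel spacing in mm (all > 0).
#' @param regions List of [roi_geometry()] objects.
#' @param background_r1 Baseline tissue relaxation rate outside the ROIs,
#'   s^-1 (must be > 0 so every voxel has a finite T1).
#' @param seed Integer seed attached to the phantom (geometry itself is
#'   deterministic; the seed travels with the spec for provenance).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims, voxel_size, regions, background_r1, seed = 1L) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 8),
            all(grid_dims == as.integer(grid_dims)),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(background_r1) == 1, background_r1 > 0)
  ids <- vapply(regions, function(r) r$label_id, integer(1))
  if (anyDuplicated(ids))
    stop("ROI label ids must be unique; duplicated: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  key <- vapply(regions, function(r)
    paste(r$region, r$hemisphere, r$section, sep = "/"), character(1))
  if (anyDuplicated(key))
    stop("(region, hemisphere, section) triples must be unique; duplicated: ",
         paste(key[duplicated(key)], collapse = ", "))
  for (r in regions) {
    lo <- r$center - r$radii
    hi <- r$center + r$radii
    if (any(lo < 1) || any(hi > grid_dims))
      stop("ROI label ", r$label_id, " (", r$region, " ", r$hemisphere,
           ") exceeds the grid bounds")
    if (r$section < 1 || r$section > grid_dims[3])
      stop("ROI label ", r$label_id, " section ", r$section,
           " outside slice range 1..", grid_dims[3])
  }
  structure(list(grid_dims = as.integer(grid_dims),
                 voxel_size = as.numeric(voxel_size),
                 regions = regions,
                 background_r1 = background_r1,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default 9-slice egg-brain phantom
#'
#' A 64 x 64 x 9 grid at 0.25 x 0.25 x 1 mm spacing holding the bilateral
#' section layout of the study: 2 Wulst sections, 3 dorsolateral-thalamus
#' (Gld) sections and 4 optic-tectum sections per hemisphere, as ellipsoidal
#' ROIs confined each to one slice.
#'
#' @param grid_dims Voxel counts per axis; default `c(64, 64, 9)`.
#' @param background_r1 Background relaxation rate, s^-1; default 1/1.4
#'   (baseline tissue T1 of 1400 ms).
#' @param section_radii Ellipsoid semi-axes of every section, voxels; the
#'   default one-slice disks hold ~37 voxels each. Shrink in-plane radii
#'   when shrinking `grid_dims` so bilateral ROIs stay disjoint.
#' @param seed Provenance seed.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(grid_dims = c(64L, 64L, 9L),
                                 background_r1 = 1 / 1.4,
                                 section_radii = c(3.5, 3.5, 0.45),
                                 seed = 1L) {
  cx <- grid_dims[1] / 2
  cy <- grid_dims[2] / 2
  # lateral offsets keep left/right ellipsoids clear of the midline
  off <- round(grid_dims[1] / 8)
  rad <- section_radii
  sections <- list(
    wulst        = list(slices = c(2L, 3L), y = cy + round(grid_dims[2] / 5)),
    thalamus_gld = list(slices = c(4L, 5L, 6L), y = cy),
    optic_tectum = list(slices = c(5L, 6L, 7L, 8L),
                        y = cy - round(grid_dims[2] / 5))
  )
  regions <- list()
  id <- 0L
  for (reg in names(sections)) {
    for (hemi in HEMISPHERES) {
      x <- if (hemi == "left") cx - off else cx + off
      for (s in sections[[reg]]$slices) {
        id <- id + 1L
        regions[[id]] <- roi_geometry(id, reg, hemi, s,
                                      center = c(x, sections[[reg]]$y, s),
                                      radii = rad)
      }
    }
  }
  phantom_spec(grid_dims, c(0.25, 0.25, 1), regions, background_r1, seed)
}

#' ROI legend of a phantom
#'
#' @param spec A [phantom_spec()].
#' @return Data frame with columns `label_id`, `region`, `hemisphere`,
#'   `section` (the ITK-SNAP-style label legend).
#' @export
phantom_legend <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  data.frame(
    label_id = vapply(spec$regions, `[[`, integer(1), "label_id"),
    region = vapply(spec$regions, `[[`, character(1), "region"),
    hemisphere = vapply(spec$regions, `[[`, character(1), "hemisphere"),
    section = vapply(spec$regions, `[[`, integer(1), "section"),
    stringsAsFactors = FALSE
  )
}

#' Rasterise a phantom into an integer label volume
#'
#' Voxels whose centres fall inside an ROI ellipsoid carry that ROI's
#' `label_id`; all other voxels are 0. Overlapping ellipsoids are an error
#' (the segmentation protocol assigns each voxel to at most one section).
#'
#' @param spec A [phantom_spec()].
#' @return 3D integer array of dimension `spec$grid_dims`.
#' @export
build_label_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol <- array(0L, dim = spec$grid_dims)
  for (r in spec$regions) {
    lo <- pmax(1L, floor(r$center - r$radii))
    hi <- pmin(spec$grid_dims, ceiling(r$center + r$radii))
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    d2 <- ((g$x - r$center[1]) / r$radii[1])^2 +
          ((g$y - r$center[2]) / r$radii[2])^2 +
          ((g$z - r$center[3]) / r$radii[3])^2
    inside <- g[d2 <= 1, , drop = FALSE]
    if (nrow(inside) == 0) next
    idx <- cbind(inside$x, inside$y, inside$z)
    prev <- vol[idx]
    if (any(prev != 0L))
      stop("ROI ellipsoids overlap: labels ", prev[prev != 0L][1], " and ",
           r$label_id, " share at least one voxel")
    vol[idx] <- r$label_id
  }
  vol
}

#' Tissue contrast model: Mn concentration to relaxation rate
#'
#' Linear fast-exchange relaxation enhancement: accumulated paramagnetic
#' Mn2+ raises the longitudinal relaxation rate proportionally to its local
#' concentration, R1 = baseline_r1 + relaxivity_r1 * concentration, i.e.
#' shortens T1 concentration-dependently.
#'
#' @param relaxivity_r1 Longitudinal relaxivity, s^-1 mM^-1 (> 0).
#' @param baseline_r1 Baseline tissue rate without Mn, s^-1 (> 0).
#' @param concentration_by_roi Optional named numeric vector of mM
#'   concentrations keyed `"region/hemisphere"` (all >= 0).
#' @return An object of class `tissue_contrast_model`.
#' @export
tissue_contrast_model <- function(relaxivity_r1 = 6, baseline_r1 = 1 / 1.4,
                                  concentration_by_roi = NULL) {
  stopifnot(relaxivity_r1 > 0, baseline_r1 > 0)
  if (!is.null(concentration_by_roi) && any(concentration_by_roi < 0))
    stop("Mn concentrations must be non-negative")
  structure(list(relaxivity_r1 = relaxivity_r1, baseline_r1 = baseline_r1,
                 concentration_by_roi = concentration_by_roi),
            class = "tissue_contrast_model")
}

#' Convert Mn concentration to longitudinal relaxation rate
#'
#' @param concentration Mn2+ concentration in mM (>= 0, vectorised).
#' @param model A [tissue_contrast_model()].
#' @return Relaxation rate(s) in s^-1, >= `baseline_r1` and strictly
#'   increasing in concentration.
#' @export
concentration_to_r1 <- function(concentration, model = tissue_contrast_model()) {
  stopifnot(inherits(model, "tissue_contrast_model"))
  if (any(concentration < 0))
    stop("Mn concentration must be non-negative")
  model$baseline_r1 + model$relaxivity_r1 * concentration
}

#' Invert the lateralization index to hemispheric rates
#'
#' Given a target index `li = (L - R) / (L + R)` and the cross-hemisphere
#' mean rate `(L + R) / 2`, returns the unique pair of hemispheric rates
#' reproducing the index exactly: `L = mean * (1 + li)`,
#' `R = mean * (1 - li)`.
#'
#' @param target_li Dimensionless index, |target_li| < 1.
#' @param mean_rate Cross-hemisphere mean relaxation rate, s^-1 (> 0).
#' @return Named numeric vector `c(left = , right = )` in s^-1.
#' @export
li_to_hemispheric_rates <- function(target_li, mean_rate) {
  stopifnot(length(target_li) == 1, length(mean_rate) == 1, mean_rate > 0)
  if (abs(target_li) >= 1)
    stop("|target_li| must be < 1 (got ", target_li, ")")
  c(left = mean_rate * (1 + target_li), right = mean_rate * (1 - target_li))
}

#' Acquisition specification for the variable-TR series
#'
#' @param tr_list_ms Strictly increasing positive repetition times (ms);
#'   default is the 13-point study schedule ([vtr_tr_schedule()]). At least
#'   3 points are required (4 for the 3-parameter model).
#' @param te_ms Echo time (ms); carried as metadata, constant across TRs.
#' @param s0 Equilibrium signal amplitude, arbitrary units (> 0).
#' @param noise_sigma Noise standard deviation in signal units (>= 0).
#' @param noise_model `"gaussian"` (magnitude clipped at 0) or `"rician"`.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_list_ms = vtr_tr_schedule(), te_ms = 6.25,
                             s0 = 100, noise_sigma = 0,
                             noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(tr_list_ms) >= 3, all(tr_list_ms > 0),
            all(diff(tr_list_ms) > 0), s0 > 0, noise_sigma >= 0)
  structure(list(tr_list_ms = as.numeric(tr_list_ms), te_ms = te_ms,
                 s0 = s0, noise_sigma = noise_sigma,
                 noise_model = noise_model),
            class = "acquisition_spec")
}

#' Multi-TR magnitude series container
#'
#' @param intensities 4D numeric array (x, y, slice, TR-index), >= 0.
#' @param tr_list_ms Repetition times (ms), one per 4th-dimension index.
#' @param te_ms Echo time (ms).
#' @param voxel_size Numeric length-3 voxel spacing (mm).
#' @return An object of class `vtr_series`.
#' @export
vtr_series <- function(intensities, tr_list_ms, te_ms = 6.25,
                       voxel_size = c(0.25, 0.25, 1)) {
  stopifnot(length(dim(intensities)) == 4,
            dim(intensities)[4] == length(tr_list_ms),
            all(tr_list_ms > 0), all(diff(tr_list_ms) > 0),
            length(voxel_size) == 3)
  if (any(intensities < 0))
    stop("magnitude intensities must be non-negative")
  structure(list(intensities = intensities,
                 tr_list_ms = as.numeric(tr_list_ms),
                 te_ms = te_ms, voxel_size = as.numeric(voxel_size)),
            class = "vtr_series")
}

#' Render per-ROI rates into an R1 volume
#'
#' @param labels 3D integer label volume.
#' @param legend Legend data frame (`label_id`, `region`, `hemisphere`, ...).
#' @param rates_by_roi Named numeric vector of rates (s^-1) keyed
#'   `"region/hemisphere"`.
#' @param background_r1 Rate assigned to unlabelled voxels, s^-1.
#' @return 3D numeric array of relaxation rates.
#' @export
render_r1_volume <- function(labels, legend, rates_by_roi, background_r1) {
  stopifnot(background_r1 > 0, all(rates_by_roi > 0))
  vol <- array(background_r1, dim = dim(labels))
  for (i in seq_len(nrow(legend))) {
    key <- paste(legend$region[i], legend$hemisphere[i], sep = "/")
    if (!key %in% names(rates_by_roi))
      stop("no rate supplied for ROI ", key)
    vol[labels == legend$label_id[i]] <- rates_by_roi[[key]]
  }
  vol
}

#' Simulate a noisy multi-TR saturation-recovery acquisition
#'
#' Forward model per voxel and repetition time:
#' `S(TR) = s0 * (1 - exp(-TR * R1 / 1000))` (TR in ms, R1 in s^-1), plus
#' additive gaussian noise (magnitude clipped at 0) or Rician noise
#' (`sqrt((S + n1)^2 + n2^2)`).
#'
#' @param r1_volume 3D array of strictly positive relaxation rates, s^-1.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed; identical seeds give identical output. The
#'   caller's RNG state is left untouched.
#' @return A [vtr_series()] with one volume per TR.
#' @export
simulate_vtr <- function(r1_volume, acq = acquisition_spec(), seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"), length(dim(r1_volume)) == 3)
  if (any(r1_volume <= 0))
    stop("relaxation rates must be strictly positive")
  dims <- dim(r1_volume)
  n_tr <- length(acq$tr_list_ms)
  clean <- vapply(acq$tr_list_ms, function(tr)
    acq$s0 * (1 - exp(-tr * r1_volume / 1000)),
    FUN.VALUE = array(0, dim = dims))
  dim(clean) <- c(dims, n_tr)
  if (acq$noise_sigma > 0) {
    clean <- withr::with_seed(seed, {
      n_total <- length(clean)
      if (acq$noise_model == "rician") {
        n1 <- array(stats::rnorm(n_total, sd = acq$noise_sigma), dim = dim(clean))
        n2 <- array(stats::rnorm(n_total, sd = acq$noise_sigma), dim = dim(clean))
        sqrt((clean + n1)^2 + n2^2)
      } else {
        pmax(clean + array(stats::rnorm(n_total, sd = acq$noise_sigma),
                           dim = dim(clean)), 0)
      }
    })
  }
  vtr_series(clean, acq$tr_list_ms, acq$te_ms)
}

#' Cohort simulation specification
#'
#' Defaults reproduce the study conditions: 8 dark-incubated and 10
#' light-exposed subjects, with per-(region, condition) lateralization-index
#' distributions calibrated to the reported group means and SEMs (the
#' between-subject SD is SEM * sqrt(n)).
#'
#' @param n_dark,n_light Subjects per condition (>= 2).
#' @param li_mean_by_region_condition,li_sd_by_region_condition Named numeric
#'   vectors keyed `"region/condition"` giving the target index mean and
#'   between-subject SD per cell.
#' @param mean_rate_by_region Named numeric vector of cross-hemisphere mean
#'   relaxation rates per region, s^-1 (all > `phantom$background_r1`).
#' @param acquisition An [acquisition_spec()].
#' @param phantom A [phantom_spec()].
#' @param master_seed Integer master seed; per-subject seeds are derived
#'   from it (see [subject_seed()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dark = 8L, n_light = 10L,
                        li_mean_by_region_condition = default_li_means(),
                        li_sd_by_region_condition = default_li_sds(),
                        mean_rate_by_region = c(wulst = 1.4,
                                                thalamus_gld = 1.5,
                                                optic_tectum = 1.6),
                        acquisition = acquisition_spec(noise_sigma = 2.5),
                        phantom = default_phantom_spec(),
                        master_seed = 1L) {
  stopifnot(n_dark >= 2, n_light >= 2,
            inherits(acquisition, "acquisition_spec"),
            inherits(phantom, "phantom_spec"))
  cells <- as.vector(outer(REGIONS, c("dark", "light"), paste, sep = "/"))
  miss <- setdiff(cells, names(li_mean_by_region_condition))
  if (length(miss)) stop("missing index mean for cell(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(cells, names(li_sd_by_region_condition))
  if (length(miss)) stop("missing index SD for cell(s): ",
                         paste(miss, collapse = ", "))
  bad <- abs(li_mean_by_region_condition[cells]) +
    3 * li_sd_by_region_condition[cells] >= 1
  if (any(bad))
    stop("|mean| + 3*sd must stay below 1 for cell(s): ",
         paste(cells[bad], collapse = ", "))
  miss <- setdiff(REGIONS, names(mean_rate_by_region))
  if (length(miss)) stop("missing mean rate for region(s): ",
                         paste(miss, collapse = ", "))
  if (any(mean_rate_by_region[REGIONS] <= phantom$background_r1))
    stop("region mean rates must exceed the background rate (Mn enhances R1)")
  structure(list(n_dark = as.integer(n_dark), n_light = as.integer(n_light),
                 li_mean_by_region_condition = li_mean_by_region_condition,
                 li_sd_by_region_condition = li_sd_by_region_condition,
                 mean_rate_by_region = mean_rate_by_region,
                 acquisition = acquisition, phantom = phantom,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Reported group means of the lateralization index
#'
#' @return Named vector keyed `"region/condition"` of the study's group-mean
#'   lateralization indices.
#' @export
default_li_means <- function() {
  c("wulst/dark" = -0.007, "wulst/light" = -0.020,
    "thalamus_gld/dark" = -0.038, "thalamus_gld/light" = -0.015,
    "optic_tectum/dark" = -0.010, "optic_tectum/light" = -0.009)
}

#' Between-subject SDs of the lateralization index
#'
#' Reported SEMs scaled by sqrt(n) (n = 8 dark, 10 light).
#'
#' @return Named vector keyed `"region/condition"`.
#' @export
default_li_sds <- function() {
  sem <- c("wulst/dark" = 0.005, "wulst/light" = 0.009,
           "thalamus_gld/dark" = 0.006, "thalamus_gld/light" = 0.006,
           "optic_tectum/dark" = 0.009, "optic_tectum/light" = 0.006)
  n <- ifelse(grepl("/dark$", names(sem)), 8, 10)
  sem * sqrt(n)
}

#' Derive a per-subject seed from the master seed
#'
#' Fixed mixing rule `(master * 1009 + ordinal * 7919) mod (2^31 - 1)` (two
#' primes), giving reproducible cohorts with independent per-subject noise.
#'
#' @param master_seed Integer master seed.
#' @param ordinal 1-based subject ordinal within the cohort.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(master_seed, ordinal) {
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(ordinal) * 7919) %%
               (2^31 - 1))
}

#' Simulate a full cohort
#'
#' For each subject, a lateralization index is drawn per region from the
#' configured normal distribution (redrawn, up to `max_redraws`, if outside
#' the open interval (-1, 1)), inverted to hemispheric rates via
#' [li_to_hemispheric_rates()], rendered into an R1 volume on the shared
#' phantom geometry and acquired with [simulate_vtr()].
#'
#' @param spec A [cohort_spec()].
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only (fast path for generator-level Monte-Carlo studies).
#' @param max_redraws Cap on per-draw retries before erroring.
#' @return List with `label_volume`, `legend`, `subjects` (each a list of
#'   `subject_id`, `condition`, `seed`, `series` (or `NULL`), `truth`), and
#'   `truth` — a long data frame (`subject_id`, `condition`, `region`,
#'   `li_true`, `left_rate`, `right_rate`).
#' @export
sample_cohort <- function(spec = cohort_spec(), render = TRUE,
                          max_redraws = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  legend <- phantom_legend(spec$phantom)
  labels <- if (render) build_label_volume(spec$phantom) else NULL
  conditions <- c(rep("dark", spec$n_dark), rep("light", spec$n_light))
  ids <- sprintf("%s_%02d", conditions,
                 c(seq_len(spec$n_dark), seq_len(spec$n_light)))
  subjects <- vector("list", length(ids))
  truth_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    seed_i <- subject_seed(spec$master_seed, i)
    draw <- withr::with_seed(seed_i, {
      vapply(REGIONS, function(reg) {
        cell <- paste(reg, conditions[i], sep = "/")
        mu <- spec$li_mean_by_region_condition[[cell]]
        sd <- spec$li_sd_by_region_condition[[cell]]
        li <- stats::rnorm(1, mu, sd)
        tries <- 0L
        while (abs(li) >= 1) {
          tries <- tries + 1L
          if (tries > max_redraws)
            stop("drawn index outside (-1, 1) after ", max_redraws,
                 " redraws for ", cell)
          li <- stats::rnorm(1, mu, sd)
        }
        li
      }, numeric(1))
    })
    rates <- lapply(REGIONS, function(reg)
      li_to_hemispheric_rates(draw[[reg]], spec$mean_rate_by_region[[reg]]))
    names(rates) <- REGIONS
    truth <- data.frame(
      subject_id = ids[i], condition = conditions[i], region = REGIONS,
      li_true = unname(draw),
      left_rate = vapply(rates, `[[`, numeric(1), "left"),
      right_rate = vapply(rates, `[[`, numeric(1), "right"),
      row.names = NULL, stringsAsFactors = FALSE
    )
    series <- NULL
    if (render) {
      flat <- unlist(lapply(REGIONS, function(reg)
        stats::setNames(as.numeric(rates[[reg]]),
                        paste(reg, HEMISPHERES, sep = "/"))))
      r1 <- render_r1_volume(labels, legend, flat,
                             spec$phantom$background_r1)
      series <- simulate_vtr(r1, spec$acquisition, seed = seed_i + 1L)
    }
    subjects[[i]] <- list(subject_id = ids[i], condition = conditions[i],
                          seed = seed_i, series = series, truth = truth)
    truth_rows[[i]] <- truth
  }
  list(label_volume = labels, legend = legend, subjects = subjects,
       truth = do.call(rbind, truth_rows))
}
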