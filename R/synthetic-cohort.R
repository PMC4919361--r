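#' Define a localized group effect for the synthetic cohort
#'
#' An effect region is a rectangular box of voxels in which the patient group
#' (label +1) differs from the control group (label -1) in exactly one
#' data-generating mechanism:
#'
#' * `"volume"` — the structural (gray-matter-volume-like) values inside the
#'   box are shifted upward by `effect_size` noise standard deviations.
#' * `"amplitude"` — a sinusoid at `frequency` Hz is added to every voxel
#'   series in the box for both groups; patients receive a fractional
#'   amplitude increase of `effect_size` over the control amplitude (which
#'   equals the noise SD), so their low-frequency fluctuation amplitude is
#'   larger.
#' * `"synchrony"` — one shared latent time series is mixed into all voxel
#'   series in the box with variance-preserving mixing coefficient
#'   `effect_size` in `[0, 1]` for patients (controls are left unmixed), so
#'   local inter-voxel rank concordance rises.
#'
#' @param box integer 3x2 matrix (or length-6 vector `xmin,xmax,ymin,ymax,
#'   zmin,zmax`) of 1-based inclusive voxel bounds per axis.
#' @param target one of `"volume"`, `"amplitude"`, `"synchrony"`.
#' @param effect_size non-negative effect size; for `"synchrony"` it is a
#'   mixing coefficient and must not exceed 1.
#' @param frequency sinusoid frequency in Hz, used by `"amplitude"` effects
#'   only; must lie strictly below the Nyquist frequency of the series.
#' @return An object of class `effect_region`.
#' @export
effect_region <- function(box, target = c("volume", "amplitude", "synchrony"),
                          effect_size, frequency = 0.05) {
  target <- match.arg(target)
  if (is.vector(box)) box <- matrix(as.integer(box), nrow = 3, byrow = TRUE)
  box <- matrix(as.integer(box), nrow = 3)
  if (ncol(box) != 2L || any(box[, 1] > box[, 2]) || any(box < 1L)) {
    stop_neuromkl("`box` must be a 3x2 matrix of 1-based inclusive bounds with lo <= hi")
  }
  check_scalar(effect_size, "effect_size", lower = 0)
  if (target == "synchrony" && effect_size > 1) {
    stop_neuromkl("synchrony mixing coefficient must be <= 1")
  }
  check_scalar(frequency, "frequency", lower = 0)
  structure(list(box = box, target = target, effect_size = effect_size,
                 frequency = frequency),
            class = "effect_region")
}

#' Configuration of a synthetic two-group MRI cohort
#'
#' Collects every parameter of the synthetic-cohort generator: group sizes,
#' grid geometry, functional-run length and sampling interval, the list of
#' [effect_region()]s, the noise level, and the seed. All randomness in
#' [generate_cohort()] flows from `seed`.
#'
#' @param n_pos,n_neg numbers of patients (label +1) and controls (label -1).
#' @param grid_dims integer length-3 voxel grid dimensions.
#' @param voxel_size voxel edge length in mm (scalar or length 3).
#' @param tr repetition time (sampling interval of the functional series), s.
#' @param n_volumes functional volumes acquired per subject.
#' @param n_discard leading volumes dropped before analysis (magnetisation
#'   equilibration); must be smaller than `n_volumes`.
#' @param effects list of [effect_region()] objects (possibly empty).
#' @param noise_sd standard deviation of the Gaussian noise, arbitrary units.
#' @param baseline_structural mean of the structural values outside any
#'   volume effect, arbitrary units.
#' @param ar_coef lag-1 autocorrelation of the functional noise; 0 (the
#'   default) gives temporally white noise.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pos, n_neg, grid_dims = c(12L, 12L, 12L),
                          voxel_size = 3, tr = 2, n_volumes = 200L,
                          n_discard = 10L, effects = list(), noise_sd = 1,
                          baseline_structural = 5, ar_coef = 0, seed = 1L) {
  check_scalar(n_pos, "n_pos", lower = 1)
  check_scalar(n_neg, "n_neg", lower = 1)
  check_scalar(tr, "tr", lower = 1e-9)
  check_scalar(n_volumes, "n_volumes", lower = 1)
  check_scalar(n_discard, "n_discard", lower = 0)
  if (n_volumes <= n_discard) stop_neuromkl("`n_volumes` must exceed `n_discard`")
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L)) {
    stop_neuromkl("`grid_dims` must be three positive integers")
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(ar_coef, "ar_coef", lower = 0, upper = 0.99)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  for (ef in effects) {
    if (!inherits(ef, "effect_region")) stop_neuromkl("`effects` must contain effect_region objects")
    if (any(ef$box[, 2] > grid_dims)) {
      stop_neuromkl("effect region box exceeds the voxel grid on at least one axis")
    }
    nyq <- 1 / (2 * tr)
    if (ef$target == "amplitude" && ef$frequency >= nyq) {
      stop_neuromkl(sprintf("amplitude effect frequency %.3f Hz is at or above Nyquist (%.3f Hz)",
                            ef$frequency, nyq))
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 grid_dims = grid_dims, voxel_size = as.numeric(voxel_size),
                 tr = tr, n_volumes = as.integer(n_volumes),
                 n_discard = as.integer(n_discard), effects = effects,
                 noise_sd = noise_sd, baseline_structural = baseline_structural,
                 ar_coef = ar_coef, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort configuration mirroring the study design
#'
#' Returns the generator configuration used throughout the package's own
#' experiments: 17 patients and 20 controls, a 12x12x12 grid of 3 mm
#' isotropic voxels, 200 functional volumes at TR = 2 s with the first 10
#' discarded downstream, and one effect region per mechanism (a structural
#' volume shift, a 0.05 Hz amplitude increase, and a synchrony increase) in
#' three disjoint boxes. Effect sizes are free parameters of the generator,
#' not estimates of any real-cohort effect.
#'
#' @param seed integer seed stored in the configuration.
#' @param effect_sizes named numeric vector with entries `volume`,
#'   `amplitude`, `synchrony`; set an entry to 0 to silence that mechanism.
#' @return A [cohort_config()] object.
#' @export
default_cohort_config <- function(seed = 1L,
                                  effect_sizes = c(volume = 1, amplitude = 0.5,
                                                   synchrony = 0.8)) {
  effs <- list(
    effect_region(rbind(c(3, 5), c(3, 5), c(3, 5)), "volume",
                  effect_sizes[["volume"]]),
    effect_region(rbind(c(8, 10), c(8, 10), c(8, 10)), "amplitude",
                  effect_sizes[["amplitude"]], frequency = 0.05),
    effect_region(rbind(c(3, 5), c(8, 10), c(6, 8)), "synchrony",
                  effect_sizes[["synchrony"]])
  )
  cohort_config(n_pos = 17, n_neg = 20, grid_dims = c(12L, 12L, 12L),
                voxel_size = 3, tr = 2, n_volumes = 200L, n_discard = 10L,
                effects = effs, noise_sd = 1, seed = seed)
}

box_index <- function(box) {
  list(x = box[1, 1]:box[1, 2], y = box[2, 1]:box[2, 2], z = box[3, 1]:box[3, 2])
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_pos + n_neg` subjects. Each subject has a structural volume
#' (baseline plus Gaussian noise, clipped at 0 since tissue volume cannot be
#' negative) and a functional 4D series (Gaussian noise, optionally AR(1)),
#' with the configured group effects injected. Identical configurations give
#' bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list of `subject_scan` objects (class `mkl_cohort`), patients
#'   first. Each scan holds `subject_id`, `label` (+1 patient, -1 control),
#'   `structural` (3D array), `functional` (4D array, time last), `tr` and
#'   `voxel_size`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dims <- config$grid_dims
  n_t <- config$n_volumes
  labels <- c(rep(1L, config$n_pos), rep(-1L, config$n_neg))
  ids <- sprintf("sub-%03d", seq_along(labels))
  tt <- (seq_len(n_t) - 1) * config$tr

  scans <- vector("list", length(labels))
  for (s in seq_along(labels)) {
    lab <- labels[s]
    structural <- array(config$baseline_structural +
                          rnorm(prod(dims), sd = config$noise_sd), dim = dims)
    functional <- array(rnorm(prod(dims) * n_t, sd = config$noise_sd),
                        dim = c(dims, n_t))
    if (config$ar_coef > 0) {
      m <- matrix(functional, nrow = prod(dims))
      for (t in 2:n_t) m[, t] <- config$ar_coef * m[, t - 1] +
          sqrt(1 - config$ar_coef^2) * m[, t]
      functional <- array(m, dim = c(dims, n_t))
    }
    for (ef in config$effects) {
      ix <- box_index(ef$box)
      if (ef$target == "volume") {
        if (lab > 0) {
          structural[ix$x, ix$y, ix$z] <- structural[ix$x, ix$y, ix$z] +
            ef$effect_size * config$noise_sd
        }
      } else if (ef$target == "amplitude") {
        amp <- config$noise_sd * (1 + if (lab > 0) ef$effect_size else 0)
        nb <- prod(lengths(ix))
        phase <- runif(nb, 0, 2 * pi)
        wave <- amp * sin(outer(phase, 2 * pi * ef$frequency * tt, `+`))
        block <- functional[ix$x, ix$y, ix$z, , drop = FALSE]
        functional[ix$x, ix$y, ix$z, ] <- block +
          array(wave, dim = c(lengths(ix), n_t))
      } else { # synchrony
        z <- rnorm(n_t)  # drawn for every subject to keep the stream aligned
        m <- if (lab > 0) ef$effect_size else 0
        if (m > 0) {
          block <- matrix(functional[ix$x, ix$y, ix$z, ], ncol = n_t)
          block <- sqrt(1 - m^2) * block +
            m * config$noise_sd * matrix(z, nrow(block), n_t, byrow = TRUE)
          functional[ix$x, ix$y, ix$z, ] <- array(block, dim = c(lengths(ix), n_t))
        }
      }
    }
    structural[structural < 0] <- 0
    scans[[s]] <- structure(list(subject_id = ids[s], label = lab,
                                 structural = structural,
                                 functional = functional, tr = config$tr,
                                 voxel_size = config$voxel_size),
                            class = "subject_scan")
  }
  structure(scans, class = "mkl_cohort", config = config)
}

#' Whole-grid brain mask for a cohort configuration
#'
#' The synthetic grid has no skull or background compartment, so the default
#' analysis mask keeps every voxel.
#'
#' @param config a [cohort_config()] (or an integer length-3 `grid_dims`).
#' @return A [brain_mask()].
#' @export
cohort_mask <- function(config) {
  dims <- if (inherits(config, "cohort_config")) config$grid_dims else as.integer(config)
  brain_mask(array(TRUE, dim = dims))
}

#' Participants table of a cohort
#'
#' @param cohort an `mkl_cohort`.
#' @return A tibble with columns `subject_id` and `label`.
#' @export
participants <- function(cohort) {
  tibble::tibble(subject_id = purrr::map_chr(cohort, "subject_id"),
                 label = purrr::map_int(cohort, ~ as.integer(.x$label)))
}

#' @export
print.mkl_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<mkl_cohort> %d subjects (%d patients, %d controls), grid %s, %d volumes @ TR=%gs\n",
              length(x), cfg$n_pos, cfg$n_neg,
              paste(cfg$grid_dims, collapse = "x"), cfg$n_volumes, cfg$tr))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a participants table
#'
#' Writes `<id>_structural.nii.gz` (3D) and `<id>_functional.nii.gz` (4D) per
#' subject and a tab-separated `participants.tsv` with subject IDs and
#' labels.
#'
#' @param cohort an `mkl_cohort`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (scan in cohort) {
    write_nifti(scan$structural, scan$voxel_size,
                file.path(dir, paste0(scan$subject_id, "_structural.nii.gz")))
    write_nifti(scan$functional, scan$voxel_size,
                file.path(dir, paste0(scan$subject_id, "_functional.nii.gz")),
                tr = scan$tr)
  }
  utils::write.table(participants(cohort), file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing the NIfTI pairs and `participants.tsv`.
#' @return An `mkl_cohort` (without a generator configuration attribute).
#' @export
read_cohort <- function(dir) {
  ptab <- utils::read.table(file.path(dir, "participants.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  scans <- purrr::pmap(ptab, function(subject_id, label) {
    st <- read_nifti(file.path(dir, paste0(subject_id, "_structural.nii.gz")))
    fn <- read_nifti(file.path(dir, paste0(subject_id, "_functional.nii.gz")))
    structure(list(subject_id = subject_id, label = as.integer(label),
                   structural = st$data, functional = fn$data,
                   tr = fn$tr %||% NA_real_, voxel_size = st$voxel_size),
              class = "subject_scan")
  })
  structure(scans, class = "mkl_cohort")
}
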