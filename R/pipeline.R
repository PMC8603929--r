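#' Default longitudinal day schedule
#'
#' Three imaging sessions (days 8, 11 and 14 after tumour implantation).
#' Tumour conductivity rises over time while tumour mean diffusivity stays
#' flat, and the necrotic core is absent on day 8 (it has not yet formed);
#' the day-14 values are the literature tissue means.
#'
#' @export
default_pipeline_days <- function() {
  list(
    list(day = 8, drop = "tumor_core",
         sigma = list(tumor_rim = 0.80, viable_tumor = 0.78)),
    list(day = 11,
         sigma = list(tumor_rim = 0.88, viable_tumor = 0.85, tumor_core = 0.76)),
    list(day = 14, sigma = list())
  )
}

#' Pipeline configuration
#'
#' @param recon a [recon_config()]; the pipeline default uses the
#'   Savitzky-Golay derivative kernel (radius 2) for noise control.
#' @param noise_sd complex-channel noise for the MSME simulation (M0 = 1;
#'   the default 0.005, magnitude SNR ~ 200 for the strongest channel, is
#'   calibrated so that per-VOI conductivity spreads match the 0.05-0.25 S/m
#'   spreads reported for this tissue set).
#' @param dwi_noise_sd complex-channel noise for the DWI simulation
#'   (S0 = 1; 0.02 = SNR 50).
#' @param seed root seed; all stage seeds are split from it.
#' @param days day schedule as in [default_pipeline_days()]; each entry may
#'   carry `sigma`/`md` overrides and `drop`ped regions for
#'   [default_phantom_spec()].
#' @param phase_smooth_radius_vox Gaussian presmoothing radius applied to
#'   the combined phase before reconstruction (standard practice for
#'   Laplacian-based reconstruction at high spatial resolution; 0 disables).
#' @param coil_count receive channels.
#' @param pearson_unit `"region_day_mean"` correlates per-region per-day
#'   means (one pair per region and day); `"voxel"` pools voxels.
#' @export
pipeline_config <- function(recon = recon_config(laplacian_kernel = "savgol",
                                                 savgol_radius_vox = 2L),
                            noise_sd = 0.005, dwi_noise_sd = 0.02,
                            seed, days = default_pipeline_days(),
                            phase_smooth_radius_vox = 3L,
                            coil_count = 4L,
                            pearson_unit = c("region_day_mean", "voxel")) {
  if (missing(seed)) stop("seed is required")
  pearson_unit <- match.arg(pearson_unit)
  day_tags <- vapply(days, function(d) as.numeric(d$day), numeric(1))
  if (anyDuplicated(day_tags)) stop("day tags must be unique")
  structure(list(recon = recon, noise_sd = noise_sd,
                 dwi_noise_sd = dwi_noise_sd, seed = as.integer(seed),
                 days = days,
                 phase_smooth_radius_vox = as.integer(phase_smooth_radius_vox),
                 coil_count = as.integer(coil_count),
                 pearson_unit = pearson_unit),
            class = "pipeline_config")
}

#' Gaussian presmoothing of an unwrapped phase map
#'
#' Slice-wise separable Gaussian low-pass (sd = radius/2 voxels). Applied
#' before reconstruction so that tissue-interface kinks in the transceive
#' phase are resolved over several voxels; differentiating an unresolved
#' kink produces locally inconsistent convection/reaction coefficients whose
#' errors advect downstream through the solve. Interior Laplacians of
#' smooth fields are unaffected (Gaussian smoothing adds only a constant to
#' a quadratic away from the edges).
#'
#' @param pm unwrapped [phase_map()].
#' @param radius kernel radius in voxels; 0 returns the input unchanged.
#' @export
smooth_phase <- function(pm, radius) {
  if (radius < 1) return(pm)
  v <- pm$values
  for (z in seq_len(dim(v)[1]))
    v[z, , ] <- smooth_gaussian2d(matrix(v[z, , ], dim(v)[2], dim(v)[3]), radius)
  phase_map(v, pm$spacing_mm, wrapped = FALSE, mask = pm$mask)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys: `seed` (required), `noise_sd`, `dwi_noise_sd`,
#' `phase_smooth_radius_vox`, `coil_count`, `pearson_unit`, and `days` — a
#' list of entries with `day` and optional `sigma`/`md` override maps and
#' `drop`ped region labels, as in [default_pipeline_days()].
#'
#' @param path path to a YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("pipeline config must set a seed")
  args <- list(seed = y$seed)
  for (key in c("noise_sd", "dwi_noise_sd", "phase_smooth_radius_vox",
                "coil_count", "pearson_unit"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$days)) args$days <- y$days
  do.call(pipeline_config, args)
}

## One imaging day: simulate, combine, unwrap, reconstruct, fit; returns
## maps, VOIs and per-region values.
run_pipeline_day <- function(cfg, day_entry, day_index) {
  ov <- day_entry
  spec <- default_phantom_spec(sigma = ov$sigma, md = ov$md, drop = ov$drop,
                               coil_count = cfg$coil_count)
  ph <- build_phantom(spec)
  phi <- forward_phase(ph$sigma, larmor_hz = cfg$recon$larmor_hz)
  seed_acq <- split_seed(cfg$seed + 131 * day_index, "acquisition")
  seed_dwi <- split_seed(cfg$seed + 131 * day_index, "dwi")
  raw <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec,
                              noise_sd = cfg$noise_sd, seed = seed_acq)
  comb <- grpc_combine(raw)
  ec <- combine_echoes(comb)
  phase_in <- smooth_phase(ec$phase, cfg$phase_smooth_radius_vox)
  rec <- cr_mrept_solve(phase_in, cfg$recon)
  rec <- erode_and_mask(rec, ph$vois)
  dwi <- simulate_dwi(ph$md, noise_sd = cfg$dwi_noise_sd, seed = seed_dwi)
  tens <- fit_tensor(dwi)
  mdm <- mean_diffusivity(tens)
  vois <- ph$vois
  vois$day <- ov$day
  list(day = ov$day, phantom = ph, phase = ec$phase, recon = rec, md = mdm,
       vois = vois,
       sigma_values = region_values(rec$sigma, vois),
       md_values = region_values(mdm, vois),
       masked_voxels = sum(!rec$sigma$mask))
}

#' Run the full simulation-to-statistics pipeline
#'
#' For every scheduled day: build the phantom, solve the forward phase
#' model, simulate the multi-coil multi-echo acquisition, combine channels
#' and echoes, reconstruct conductivity (convection-reaction solve with
#' boundary-interface erosion), simulate and fit the DWI for mean
#' diffusivity, and summarise both maps per region. Cross-region and
#' longitudinal Welch t-tests and the MD-conductivity Pearson correlation
#' are computed at the end. Deterministic given (config, seed).
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if needed). NULL skips writing.
#' @return list with `stats` (region summary table), `region_tests`,
#'   `longitudinal_tests`, `pearson`, `days` (per-day artifacts) and
#'   `manifest` (file names and md5 hashes, when `outdir` is given).
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  partial_marker <- if (!is.null(outdir)) file.path(outdir, ".partial") else NULL
  if (!is.null(partial_marker)) file.create(partial_marker)
  day_results <- list()
  for (i in seq_along(cfg$days)) {
    tag <- cfg$days[[i]]$day
    day_results[[as.character(tag)]] <- tryCatch(
      run_pipeline_day(cfg, cfg$days[[i]], i),
      error = function(e) stop(sprintf("pipeline stage failed on day %s: %s",
                                       tag, conditionMessage(e)), call. = FALSE))
    message(sprintf("day %s: c = %s, residual %.3e, %d voxels masked",
                    tag, paste(signif(day_results[[as.character(tag)]]$recon$c_used, 3),
                               collapse = ","),
                    day_results[[as.character(tag)]]$recon$residual_norm,
                    day_results[[as.character(tag)]]$masked_voxels))
  }
  stats <- do.call(rbind, unlist(lapply(day_results, function(d) list(
    region_summary(d$recon$sigma, d$vois, "conductivity"),
    region_summary(d$md, d$vois, "md"))), recursive = FALSE))
  rownames(stats) <- NULL
  region_tests <- do.call(rbind, unlist(lapply(day_results, function(d) list(
    pairwise_region_tests(d$sigma_values, d$day, "conductivity"),
    pairwise_region_tests(d$md_values, d$day, "md"))), recursive = FALSE))
  rownames(region_tests) <- NULL
  sig_by_day <- lapply(day_results, `[[`, "sigma_values")
  md_by_day <- lapply(day_results, `[[`, "md_values")
  longitudinal_tests <- rbind(
    longitudinal_compare(sig_by_day, "conductivity"),
    longitudinal_compare(md_by_day, "md"))
  rownames(longitudinal_tests) <- NULL
  pearson <- pipeline_pearson(day_results, cfg$pearson_unit)
  out <- list(stats = stats, region_tests = region_tests,
              longitudinal_tests = longitudinal_tests, pearson = pearson,
              days = day_results, manifest = NULL)
  if (!is.null(outdir)) {
    files <- character(0)
    for (d in day_results) {
      pre <- file.path(outdir, sprintf("day%02d", as.integer(d$day)))
      sig <- d$recon$sigma$values; sig[!d$recon$sigma$mask] <- NA_real_
      files <- c(files,
                 write_nifti(sig, d$recon$sigma$spacing_mm,
                             paste0(pre, "_sigma.nii")),
                 write_nifti(d$md$values, d$md$spacing_mm,
                             paste0(pre, "_md.nii")),
                 write_nifti(d$phase$values, d$phase$spacing_mm,
                             paste0(pre, "_phase.nii")),
                 write_nifti(d$vois$labels, d$phantom$sigma$spacing_mm,
                             paste0(pre, "_labels.nii")))
    }
    files <- c(files,
               write_stats_csv(stats, file.path(outdir, "region_stats.csv")),
               write_stats_csv(region_tests, file.path(outdir, "region_tests.csv")),
               write_stats_csv(longitudinal_tests,
                               file.path(outdir, "longitudinal_tests.csv")))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    report <- list(
      seed = cfg$seed,
      c_used = lapply(day_results, function(d) d$recon$c_used),
      residual_norm = lapply(day_results, function(d) d$recon$residual_norm),
      masked_voxels = lapply(day_results, function(d) d$masked_voxels),
      pearson = pearson)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
    file.remove(partial_marker)
  }
  out
}

## Pearson correlation between MD and conductivity across regions/days.
pipeline_pearson <- function(day_results, unit) {
  xs <- numeric(0); ys <- numeric(0)
  for (d in day_results) {
    regs <- intersect(names(d$sigma_values), names(d$md_values))
    for (reg in regs) {
      sv <- d$sigma_values[[reg]]; mv <- d$md_values[[reg]]
      if (unit == "region_day_mean") {
        if (length(sv) && length(mv)) {
          xs <- c(xs, mean(mv)); ys <- c(ys, mean(sv))
        }
      } else {
        # voxelwise pairing on the shared grid
        sel <- d$vois$labels == which(names(d$sigma_values) == reg) &
          d$recon$sigma$mask & d$md$mask
        xs <- c(xs, d$md$values[sel]); ys <- c(ys, d$recon$sigma$values[sel])
      }
    }
  }
  if (length(xs) < 3) return(list(r = NA_real_, p = NA_real_, n = length(xs)))
  pearson_corr(xs, ys)
}
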