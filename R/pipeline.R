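# Top-level pipeline: simulate -> fit/subtract -> pick -> screen ->
# extract -> priors -> reconstruct (C1/C2/C4) -> FSC -> symmetry report.

#' Pipeline configuration
#'
#' All stage parameters with their defaults. Every source of randomness in
#' a run derives from the single root `seed`.
#'
#' @param n_micrographs number of simulated micrographs.
#' @param grid_shape micrograph size c(nx, ny) in pixels.
#' @param pixel_size micrograph pixel size (A).
#' @param mean_diameter_nm,diameter_range_nm liposome size distribution.
#' @param dose exposure (e/A^2); NULL = noise-free.
#' @param defocus_um defocus (underfocus positive).
#' @param screen_cutoff_A particle-to-membrane screen distance.
#' @param box_nm,mask_nm extraction box edge and mask diameter.
#' @param bin reconstruction binning factor applied to the stack.
#' @param azimuth_step azimuth search step (degrees).
#' @param tilt_width,psi_width orientation prior widths (degrees).
#' @param select_quantile particles whose assignment score falls below
#'   this quantile are excluded from reconstruction (the classification /
#'   selection step of the standard workflow, reduced to a score screen).
#' @param symmetries symmetry labels to reconstruct.
#' @param strata_nm diameter class bounds (nm) for stratified
#'   reconstruction; NULL disables stratification.
#' @param seed root seed.
#' @return object of class `rsc_config` (a validated list).
#' @export
rsc_config <- function(n_micrographs = 24, grid_shape = c(768, 768),
                       pixel_size = 2.1, mean_diameter_nm = 20,
                       diameter_range_nm = c(15, 70), dose = 60,
                       defocus_um = 3.8, screen_cutoff_A = 80,
                       box_nm = 27, mask_nm = 17, bin = 2,
                       azimuth_step = 5, tilt_width = 10, psi_width = 10,
                       select_quantile = 0.25,
                       symmetries = c("C1", "C2", "C4"),
                       strata_nm = NULL, seed = 1) {
  cfg <- list(n_micrographs = n_micrographs, grid_shape = grid_shape,
              pixel_size = pixel_size, mean_diameter_nm = mean_diameter_nm,
              diameter_range_nm = diameter_range_nm, dose = dose,
              defocus_um = defocus_um, screen_cutoff_A = screen_cutoff_A,
              box_nm = box_nm, mask_nm = mask_nm, bin = bin,
              azimuth_step = azimuth_step, tilt_width = tilt_width,
              psi_width = psi_width, select_quantile = select_quantile,
              symmetries = symmetries,
              strata_nm = strata_nm, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "rsc_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_micrographs >= 1, all(cfg$grid_shape %% 2 == 0),
            cfg$pixel_size > 0, cfg$screen_cutoff_A >= 0,
            cfg$select_quantile >= 0, cfg$select_quantile < 1,
            cfg$mask_nm < cfg$box_nm, cfg$bin >= 1,
            cfg$mean_diameter_nm > cfg$diameter_range_nm[1],
            cfg$mean_diameter_nm < cfg$diameter_range_nm[2],
            all(cfg$symmetries %in% c("C1", "C2", "C4")))
  invisible(cfg)
}

#' Serialize / restore a pipeline configuration
#'
#' Plain-text `key = value` round trip (lossless for all defaults).
#'
#' @param cfg an [rsc_config()].
#' @param path file path.
#' @return `read_config` returns an [rsc_config()].
#' @export
write_config <- function(cfg, path) {
  ser <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) "NULL" else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(cfg), " = ", ser), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  cfg <- stats::setNames(lapply(kv, function(p) {
    v <- p[2]
    if (identical(v, "NULL")) return(NULL)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }), vapply(kv, `[[`, character(1), 1))
  do.call(rsc_config, cfg)
}

# Picking templates: reference projections at a few tilts (top, oblique,
# side view), rendered at the micrograph pixel size and CTF-convolved.
make_pick_templates <- function(particle_map, ctf, tilts = c(0, 50, 90),
                                crop_frac = 0.7) {
  ft <- map_cfft(particle_map)
  n <- ft$n
  m <- 4 * round(crop_frac * n / 4)   # multiple of 4 so templates bin evenly
  lo <- ctr(n) - m / 2; hi <- ctr(n) + m / 2 - 1
  lapply(tilts, function(t) {
    p <- project_map(ft, 0, t, 0)
    apply_ctf(p, ctf)[lo:hi, lo:hi]
  })
}

#' Run the full RSC pipeline on a simulated dataset
#'
#' Executes simulate -> liposome fit -> subtract -> pick -> screen ->
#' extract -> orientation priors -> constrained assignment ->
#' reconstruction under each requested symmetry -> gold-standard FSC ->
#' symmetry report. When `out_dir` is given, maps (MRC), tables (STAR),
#' FSC curves (TSV) and the config are written there; rerunning with the
#' same config reproduces them bit-for-bit.
#'
#' @param cfg an [rsc_config()].
#' @param out_dir output directory, or NULL to skip writing files.
#' @param reference reference [density_map()] for orientation assignment;
#'   defaults to the same tetramer phantom used in simulation (the
#'   pipeline performs template-based refinement, not ab initio
#'   reconstruction).
#' @param verbose print stage progress.
#' @return list with elements micrographs, fits, picks, stack, angles,
#'   recon (per symmetry: map, half1, half2, fsc), symmetry (orders 2 and
#'   4 on the C1 map), reference, config, and (if stratified) strata.
#' @export
run_pipeline <- function(cfg = rsc_config(), out_dir = NULL,
                         reference = NULL, verbose = TRUE) {
  validate_config(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(cfg$seed, 4)
  px <- cfg$pixel_size
  ctf <- ctf_params(defocus_um = cfg$defocus_um, pixel_size = px)
  phantom_n <- 2 * round(cfg$box_nm * 10 / px / 2)
  particle_map <- make_channel_phantom(phantom_n, px, c2_shift = 5)
  say("simulate: %d micrographs, %dx%d px", cfg$n_micrographs,
      cfg$grid_shape[1], cfg$grid_shape[2])
  mgs <- sample_dataset(cfg$n_micrographs, cfg$grid_shape, px,
                        cfg$mean_diameter_nm, cfg$diameter_range_nm,
                        particle_map = particle_map, ctf = ctf,
                        dose = cfg$dose, seed = seeds[1])
  say("fit + subtract liposomes")
  templates <- make_pick_templates(particle_map, ctf)
  all_fits <- list(); stacks <- list(); metas <- list()
  for (k in seq_along(mgs)) {
    mg <- mgs[[k]]
    fits <- fit_liposomes(mg, ctf)
    all_fits[[k]] <- fits
    if (nrow(fits) == 0) next
    sub <- subtract_liposomes(mg, fits, ctf)
    picks <- pick_particles(sub, templates)
    if (nrow(picks) == 0) next
    kept <- screen_particles(picks, fits, cfg$screen_cutoff_A, px)
    if (nrow(kept) == 0) next
    kept <- orientation_prior(kept, fits, px, cfg$tilt_width,
                              cfg$psi_width)
    st <- extract_boxes(sub, kept, cfg$box_nm, cfg$mask_nm)
    if (dim(st$images)[3] == 0) next
    st$meta$micrograph <- k
    st$meta$lipo_radius_A <- fits$radius_A[
      match(st$meta$nearest_liposome_id, fits$id)]
    stacks[[length(stacks) + 1]] <- st
  }
  if (length(stacks) == 0) stop("pipeline: no particles survived screening")
  images <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), c(dim(arrs[[1]])[1:2],
                          sum(vapply(arrs, function(a) dim(a)[3], 1))))
  }, lapply(stacks, function(s) s$images))
  meta <- do.call(rbind, lapply(stacks, function(s) s$meta))
  stack <- particle_stack(images, px, meta, cfg$box_nm * 10,
                          cfg$mask_nm * 10)
  say("extracted %d particles", dim(images)[3])
  stack_b <- bin_stack(stack, cfg$bin)
  reference <- reference %||% fourier_bin(particle_map, cfg$bin)
  say("assign orientations (azimuth step %g deg)", cfg$azimuth_step)
  angles <- assign_orientations(stack_b, reference, ctf,
                                azimuth_step = cfg$azimuth_step)
  if (cfg$select_quantile > 0) {
    keep <- angles$score >= stats::quantile(angles$score,
                                            cfg$select_quantile)
    stack_b <- particle_stack(stack_b$images[, , keep, drop = FALSE],
                              stack_b$pixel_size,
                              stack_b$meta[keep, , drop = FALSE],
                              stack_b$box_A, stack_b$mask_A)
    angles <- angles[keep, , drop = FALSE]
    say("selected %d particles above the %.0f%% score quantile",
        sum(keep), 100 * cfg$select_quantile)
  }
  say("reconstruct: %s", paste(cfg$symmetries, collapse = " "))
  recon <- lapply(cfg$symmetries, function(sym) {
    n_fold <- as.integer(sub("C", "", sym))
    rh <- reconstruct_halves(stack_b, angles, ctf, n_fold,
                             seed = seeds[2], weights = angles$score)
    rh$map_filtered <- lowpass_map(rh$map, attr(rh$fsc, "resolution_A"))
    rh
  })
  names(recon) <- cfg$symmetries
  c1map <- if ("C1" %in% names(recon)) recon$C1$map_filtered else
    backproject(stack_b, angles, ctf, 1)
  # symmetry scored on the FSC-filtered map within the particle envelope
  sym_mask <- min(70, 0.4 * dim(c1map$data)[1] * c1map$pixel_size)
  symrep <- list(
    c2 = symmetry_correlation(c1map, 2, mask_radius_A = sym_mask),
    c4 = symmetry_correlation(c1map, 4, mask_radius_A = sym_mask))
  strata <- NULL
  if (!is.null(cfg$strata_nm)) {
    d_nm <- stack_b$meta$lipo_radius_A * 2 / 10
    bounds <- cfg$strata_nm
    strata <- list()
    for (s in seq_len(length(bounds) - 1)) {
      idx <- which(d_nm >= bounds[s] & d_nm < bounds[s + 1])
      if (length(idx) < 4) next
      sst <- particle_stack(stack_b$images[, , idx, drop = FALSE],
                            stack_b$pixel_size,
                            stack_b$meta[idx, , drop = FALSE],
                            stack_b$box_A, stack_b$mask_A)
      strata[[paste0(bounds[s], "-", bounds[s + 1], "nm")]] <-
        backproject(sst, angles[idx, , drop = FALSE], ctf, 2,
                    min_particles = 1)
    }
  }
  res <- list(micrographs = mgs, fits = all_fits, stack = stack_b,
              angles = angles, recon = recon, symmetry = symrep,
              reference = reference, config = cfg, strata = strata)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.txt")
  write_config(res$config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  fits <- do.call(rbind, lapply(seq_along(res$fits), function(k) {
    f <- as.data.frame(res$fits[[k]])
    if (nrow(f)) f$micrograph <- k
    f
  }))
  if (!is.null(fits) && nrow(fits))
    write_star(fits, file.path(out_dir, "liposome_fits.star"))
  write_star(as.data.frame(res$stack$meta),
             file.path(out_dir, "particles.star"))
  for (sym in names(res$recon)) {
    write_mrc(res$recon[[sym]]$map,
              file.path(out_dir, paste0("map_", sym, ".mrc")))
    fsc <- res$recon[[sym]]$fsc
    utils::write.table(
      data.frame(frequency_1_per_A = fsc$freq_invA, fsc = fsc$fsc),
      file.path(out_dir, paste0("fsc_", sym, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    cat(sprintf("# resolution_A %.3f threshold %.3f config_md5 %s\n",
                attr(fsc, "resolution_A"), attr(fsc, "threshold"), hash),
        file = file.path(out_dir, paste0("fsc_", sym, ".tsv")),
        append = TRUE)
  }
  sym_tab <- data.frame(
    order = c(2, 4),
    correlation = c(res$symmetry$c2$correlation,
                    res$symmetry$c4$correlation),
    config_md5 = hash)
  utils::write.table(sym_tab, file.path(out_dir, "symmetry.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
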