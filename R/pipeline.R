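# End-to-end synthetic experiment: simulate -> render -> detect -> link ->
# assign -> diffusion + spatial statistics.

#' Simulate one imaging condition of a tracking experiment
#'
#' Generates a cell population on a non-overlapping grid, plants the
#' cell-cycle pattern of septal recruitment, simulates a Brownian mixture of
#' molecules inside the cells, and renders the molecules into an SMLM image
#' stack. Septum flags encode recruitment timing: with
#' `recruitment = "late"` only cells of at least median length carry a septum
#' (enrichment confined to late cell-cycle stages); with `"early"` every cell
#' does (the septal enrichment also appears in short, early-cycle cells).
#'
#' @param n_cells number of cells.
#' @param n_tracks number of molecules.
#' @param f mixture fractions (confined, slow, fast).
#' @param recruitment `"late"` or `"early"` septal recruitment.
#' @param septal_bias probability that a confined molecule sits at the septum
#'   of a septum-bearing cell.
#' @param D diffusion coefficients (um^2/s).
#' @param dt frame interval (s).
#' @param seed integer RNG seed.
#' @param peak_photons,background,psf_sigma,pixel_size rendering parameters
#'   (see [simulate_image_stack()]).
#' @return list with `cells`, `truth`, `stack`, `tracks_true` (the simulated
#'   ground-truth tracks) and the simulation configs.
#' @export
simulate_spt_experiment <- function(n_cells = 100L, n_tracks = 3000L,
                                    f = c(0.325, 0.335, 0.34),
                                    recruitment = c("late", "early"),
                                    septal_bias = 0.9,
                                    D = c(0.017, 0.0509, 0.394), dt = 0.013,
                                    seed = 1L, peak_photons = 400,
                                    background = 2, psf_sigma = 0.13,
                                    pixel_size = 0.0968) {
  recruitment <- match.arg(recruitment)
  cells <- simulate_cell_population(
    sim_cell_config(n_cells = n_cells, length_mean = 2.5, length_sd = 0.4,
                    width = 1, septum_prob = 1, seed = seed),
    layout = "grid")
  lens <- vapply(cells, `[[`, numeric(1), "length")
  med <- stats::median(lens)
  for (i in seq_along(cells)) {
    has <- recruitment == "early" || lens[i] >= med
    cells[[i]]$septum <- has
    cells[[i]]$septum_x <- if (has) 0 else NA_real_
  }
  mix <- sim_mixture_config(k = 3L, D = D, f = f, dt = dt, loc_sd = 0,
                            p_survive = 0.85, n_tracks = n_tracks,
                            septal_bias = septal_bias, seed = seed + 1L)
  sim <- simulate_tracks(cells, mix, stagger_start = TRUE,
                         tracks_per_frame = 8L)
  xr <- range(sim$tracks$x_um); yr <- range(sim$tracks$y_um)
  margin <- 0.8
  stack <- simulate_image_stack(
    sim$tracks, psf_sigma = psf_sigma, background = background,
    peak_photons = peak_photons, pixel_size = pixel_size, seed = seed + 2L,
    origin = c(xr[1] - margin, yr[1] - margin),
    dim_px = c(ceiling((diff(xr) + 2 * margin) / pixel_size),
               ceiling((diff(yr) + 2 * margin) / pixel_size)))
  list(cells = cells, truth = sim$truth, tracks_true = sim$tracks,
       stack = stack, mix = mix)
}

#' Run the tracking and analysis pipeline on an image stack
#'
#' Detect spots, link them into tracks, assign tracks to cells, pool jump
#' distances and fit the k-component squared-displacement mixture, project
#' localizations into the standardized cell, and compute per-cell
#' midcell/polar statistics.
#'
#' @param stack an `image_stack`.
#' @param cells list of cell outlines (non-overlapping).
#' @param dt frame interval (s).
#' @param k mixture order for the diffusion fit.
#' @param diameter,snr_min detection parameters.
#' @param max_link,min_len linking parameters.
#' @param method diffusion-fit method (see [fit_sqd_mixture()]); the default
#'   `"track_mle"` exploits the track grouping available in pipeline output.
#' @return list with `locs`, `tracks`, `fit` (`sqd_fit`), `points`
#'   (standardized points per cell), `stats` (per-cell localization stats
#'   data.frame).
#' @export
run_spt_pipeline <- function(stack, cells, dt = 0.013, k = 3L,
                             diameter = 0.5, snr_min = 5, max_link = 0.3,
                             min_len = 5L, method = "track_mle") {
  locs <- detect_spots(stack, diameter = diameter, snr_min = snr_min)
  tracks <- link_tracks(locs, max_link = max_link, min_len = min_len)
  tracks <- assign_tracks_to_cells(tracks, cells)
  jumps <- compute_jump_distances(tracks, dt = dt)
  # apparent-D fit (sigma = 0): localization error inflates every component
  # equally as an additive 4 sigma^2 scale, so population fractions remain
  # comparable across conditions without an error estimate. The MSD curve is
  # returned so callers can inspect the intercept (~ 4 sigma^2).
  msd <- compute_msd(tracks, dt = dt, max_lag = 4)
  fit <- fit_sqd_mixture(jumps, k = k, method = method,
                         outlier_frac = 0.05)
  ids <- vapply(cells, `[[`, numeric(1), "cell_id")
  per_cell <- lapply(seq_along(cells), function(i) {
    sel <- !is.na(tracks$cell_id) & tracks$cell_id == ids[i]
    if (!any(sel)) return(NULL)
    pts <- normalize_to_standard_cell(tracks[sel, ], cells[[i]])
    st <- compute_localization_stats(pts, cells[[i]])
    list(points = pts, stats = st)
  })
  keep <- !vapply(per_cell, is.null, logical(1))
  stats_df <- do.call(rbind, lapply(per_cell[keep], `[[`, "stats"))
  list(locs = locs, tracks = tracks, fit = fit, msd = msd,
       points = lapply(per_cell[keep], `[[`, "points"),
       stats = stats_df)
}

#' Compare two simulated conditions end to end
#'
#' Simulates a reference condition (late septal recruitment, wild-type-like
#' confined fraction) and a perturbed condition (early recruitment, elevated
#' confined fraction), runs the full pipeline on each, and compares: the
#' fitted confined (lowest-D) fraction, and the per-cell midcell proportion
#' of early-cycle (below-median-length) cells via the Wilcoxon rank-sum test.
#'
#' @param seed integer RNG seed.
#' @param n_cells,n_tracks per-condition sizes.
#' @param f_a,f_b mixture fractions for the two conditions; defaults are the
#'   FtsK immobile fractions of wild type (32.5%) and the SMC deletion
#'   (39.9%).
#' @param ... passed to [simulate_spt_experiment()].
#' @return list with `fit_a`, `fit_b`, `stats_a`, `stats_b`,
#'   `confined_diff` (f_conf_B - f_conf_A), `wilcoxon` (test on early-cycle
#'   midcell proportions), `midcell_short_a`, `midcell_short_b`.
#' @export
compare_conditions <- function(seed = 1L, n_cells = 100L, n_tracks = 3000L,
                               f_a = c(0.325, 0.335, 0.34),
                               f_b = c(0.399, 0.30, 0.301), ...) {
  sim_a <- simulate_spt_experiment(n_cells = n_cells, n_tracks = n_tracks,
                                   f = f_a, recruitment = "late",
                                   seed = seed, ...)
  sim_b <- simulate_spt_experiment(n_cells = n_cells, n_tracks = n_tracks,
                                   f = f_b, recruitment = "early",
                                   seed = seed + 1000L, ...)
  res_a <- run_spt_pipeline(sim_a$stack, sim_a$cells)
  res_b <- run_spt_pipeline(sim_b$stack, sim_b$cells)
  short_a <- res_a$stats$length_um < stats::median(res_a$stats$length_um)
  short_b <- res_b$stats$length_um < stats::median(res_b$stats$length_um)
  ma <- res_a$stats$midcell_prop[short_a]
  mb <- res_b$stats$midcell_prop[short_b]
  wt <- wilcoxon_rank_sum(mb, ma)
  list(fit_a = res_a$fit, fit_b = res_b$fit,
       stats_a = res_a$stats, stats_b = res_b$stats,
       confined_diff = res_b$fit$f[1] - res_a$fit$f[1],
       wilcoxon = wt, midcell_short_a = ma, midcell_short_b = mb)
}
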