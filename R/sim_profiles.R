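#' Simulate a multi-channel fluorescence line profile of one cell
#'
#' Builds the along-axis intensity profile of a rod-shaped cell in three
#' channels, emulating phase contrast, a membrane stain (pole and septum
#' peaks) and a DNA stain (nucleoid blobs):
#' * membrane: one Gaussian peak at each pole (`+/- true_length/2`) plus one
#'   interior Gaussian peak per septum, septa evenly spaced along the cell,
#'   septal amplitude = pole amplitude (>= 0.8x poles);
#' * dna: one Gaussian blob per nucleoid, nucleoids distributed over the
#'   inter-septal compartments;
#' * phase: a smooth inverted plateau spanning the cell (not analysed
#'   downstream, kept for format fidelity).
#' Additive Gaussian noise of SD `noise_sd` is applied to every channel.
#'
#' @param true_length cell length (um).
#' @param n_septa number of division septa (>= 0).
#' @param n_nucleoids number of nucleoids (>= 0).
#' @param noise_sd additive Gaussian noise SD (au); peak amplitude is 100 au,
#'   so `noise_sd = 10` corresponds to SNR 10.
#' @param pixel_pitch spatial sampling pitch (um); default 0.0645 um
#'   (a 5-pixel, 322.5 nm line width).
#' @param peak_sd SD of membrane peaks (um).
#' @param blob_sd SD of nucleoid blobs (um).
#' @param seed integer RNG seed.
#' @return a list of class `cell_profile` with `position` (um, centered on
#'   the cell), `phase`, `membrane`, `dna` (au), and `truth` (list with
#'   `length`, `n_septa`, `n_nucleoids`, `septum_positions`,
#'   `nucleoid_positions`).
#' @examples
#' p <- simulate_profiles(2.5, n_septa = 1, n_nucleoids = 2, noise_sd = 0)
#' p$truth$n_septa
#' @export
simulate_profiles <- function(true_length, n_septa = 0L, n_nucleoids = 1L,
                              noise_sd = 0, pixel_pitch = 0.0645,
                              peak_sd = 0.08, blob_sd = 0.15, seed = 1L) {
  if (true_length <= 0) stop("true_length must be positive")
  if (n_septa < 0 || n_nucleoids < 0) stop("counts must be non-negative")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  # geometric feasibility: features need room to be resolvable. Membrane
  # peaks need ~4 sd of separation; two Gaussian blobs are separable by the
  # 50%-trough criterion only if their spacing exceeds ~2 sd sqrt(2 ln 4)
  # (~3.33 sd), so 3.5 sd is required with a little margin.
  min_sep <- 4 * peak_sd
  if (n_septa > 0 && true_length / (n_septa + 1) < min_sep)
    stop("too many septa for this cell length")
  n_comp <- n_septa + 1L
  comp_len <- true_length / n_comp
  if (n_nucleoids > 0) {
    per_comp <- ceiling(n_nucleoids / n_comp)
    if (comp_len / (per_comp + 1) < 3.5 * blob_sd)
      stop("too many nucleoids for this cell length")
  }
  set.seed(as.integer(seed))
  half <- true_length / 2
  pos <- seq(-half - 0.5, half + 0.5, by = pixel_pitch)
  amp <- 100

  gauss <- function(mu, sd, a) a * exp(-(pos - mu)^2 / (2 * sd^2))
  membrane <- gauss(-half, peak_sd, amp) + gauss(half, peak_sd, amp)
  septum_positions <- numeric(0)
  if (n_septa > 0) {
    septum_positions <- -half + seq_len(n_septa) * comp_len
    for (s in septum_positions) membrane <- membrane + gauss(s, peak_sd, amp)
  }

  # nucleoids: fill compartments round-robin, evenly spaced inside each
  nucleoid_positions <- numeric(0)
  if (n_nucleoids > 0) {
    comp_of <- ((seq_len(n_nucleoids) - 1L) %% n_comp) + 1L
    counts <- tabulate(comp_of, n_comp)
    bounds <- c(-half, if (n_septa > 0) septum_positions, half)
    for (ci in seq_len(n_comp)) {
      if (counts[ci] == 0) next
      lo <- bounds[ci]; hi <- bounds[ci + 1L]
      nucleoid_positions <- c(nucleoid_positions,
        lo + (hi - lo) * seq_len(counts[ci]) / (counts[ci] + 1))
    }
    nucleoid_positions <- sort(nucleoid_positions)
  }
  dna <- rep(0, length(pos))
  for (b in nucleoid_positions) dna <- dna + gauss(b, blob_sd, amp)

  phase <- amp - gauss(0, true_length / 3, amp * 0.8)

  if (noise_sd > 0) {
    membrane <- membrane + stats::rnorm(length(pos), 0, noise_sd)
    dna <- dna + stats::rnorm(length(pos), 0, noise_sd)
    phase <- phase + stats::rnorm(length(pos), 0, noise_sd)
  }

  structure(list(position = pos, phase = phase, membrane = membrane,
                 dna = dna,
                 truth = list(length = true_length, n_septa = n_septa,
                              n_nucleoids = n_nucleoids,
                              septum_positions = septum_positions,
                              nucleoid_positions = nucleoid_positions)),
            class = "cell_profile")
}
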