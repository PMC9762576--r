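#' Shuffle afferent identity within each trial
#'
#' Destroys the spatial structure of the population response: for every
#' trial, one independent random permutation of afferent identity is drawn
#' and applied identically to all time bins of that trial (the whole
#' afferent block of T columns moves as a unit). Per-bin population counts
#' summed over afferents are unchanged, so only which-afferent information
#' is removed.
#'
#' @param R A [bin_raster()] response matrix.
#' @param seed Integer seed (one permutation per trial derived from it).
#' @return A response matrix of the same shape and attributes.
#' @export
shuffle_afferents <- function(R, seed = 1L) {
  n_t <- attr(R, "n_bins")
  n_aff <- attr(R, "n_afferents")
  if (is.null(n_t) || is.null(n_aff)) {
    rlang::abort("R must be a bin_raster() response matrix")
  }
  if (n_aff < 2) rlang::abort("need at least 2 afferents to shuffle")
  Rm <- unclass(R)
  out <- Rm
  withr::with_seed(derive_seed(seed, 1307L), {
    for (m in seq_len(nrow(Rm))) {
      perm <- sample.int(n_aff)
      src <- rep((perm - 1) * n_t, each = n_t) + seq_len(n_t)
      out[m, ] <- Rm[m, src]
    }
  })
  response_matrix_like(out, R)
}

#' Jitter spike times
#'
#' Destroys fine temporal structure: every spike is shifted by an
#' independent uniform draw in `[-w, +w]` (w = `half_width_ms`). Spikes
#' shifted outside `[0, duration)` are discarded (no reflection or
#' wrapping, which would inject artificial structure); spike lists are
#' re-sorted per afferent. Refractory violations are permitted after
#' jittering. `half_width_ms = 0` returns the dataset unchanged.
#'
#' @param dataset A `spike_dataset`.
#' @param half_width_ms Jitter half-width in ms (the standard analysis uses
#'   2, 5 and 10 ms; other positive values are accepted).
#' @param seed Integer seed.
#' @return A `spike_dataset` with jittered spike times.
#' @export
jitter_spikes <- function(dataset, half_width_ms, seed = 1L) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (half_width_ms < 0) rlang::abort("half_width_ms must be >= 0")
  if (half_width_ms == 0) return(dataset)
  w <- half_width_ms / 1000
  sp <- dataset$spikes
  shift <- withr::with_seed(
    derive_seed(seed, 1979L),
    stats::runif(nrow(sp), -w, w)
  )
  sp$time <- sp$time + shift
  keep <- sp$time >= 0 & sp$time < dataset$duration_s
  sp <- sp[keep, , drop = FALSE]
  sp <- dplyr::arrange(sp, .data$trial, .data$class, .data$afferent, .data$time)
  dataset$spikes <- sp
  dataset
}

#' Re-evaluate information on perturbed data with frozen modules and decoder
#'
#' Projects a perturbed response matrix onto the modules `W` learned on the
#' intact data, feeds the resulting activation coefficients to the decoder
#' trained on the intact activations, and recomputes the confusion-matrix
#' mutual information. The result quantifies the information that survives
#' the perturbation ("space-coding removed" for afferent shuffling,
#' "time-coding removed" for spike-time jitter).
#'
#' @param R_perturbed Response matrix of the perturbed test trials
#'   (trials x TN, columns matching `W`).
#' @param W Modules fit on the intact data ([fit_nmf()] model or K x TN
#'   matrix).
#' @param model Decoder trained on the intact activations.
#' @param labels_test Presented feature levels of the test trials.
#' @param perturbation Tag recorded in the result (e.g. `"spatial_shuffle"`,
#'   `"temporal_jitter_10ms"`, `"none"`).
#' @return A one-row tibble: `perturbation`, `I_bits`, `I_norm`,
#'   `accuracy`, `n_test`, plus the confusion matrix as attribute
#'   `confusion`.
#' @export
evaluate_perturbed <- function(R_perturbed, W, model, labels_test,
                               perturbation = "none") {
  H <- project_activations(R_perturbed, W)
  cm <- confusion_matrix(model, H, labels_test)
  I <- mutual_information(cm)
  H_S <- stimulus_entropy(length(model$levels))
  out <- tibble::tibble(
    perturbation = perturbation,
    I_bits = I,
    I_norm = I / H_S,
    accuracy = sum(diag(cm)) / sum(cm),
    n_test = sum(cm)
  )
  attr(out, "confusion") <- cm
  out
}
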