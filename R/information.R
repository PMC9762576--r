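#' Plugin mutual information of a confusion matrix
#'
#' The plugin estimate of the mutual information between presented and
#' decoded stimulus levels,
#' \deqn{I(S;\hat S) = \sum_{s,\hat s} p(s,\hat s)\,
#'   \log_2 \frac{p(s,\hat s)}{p(s)\,p(\hat s)},}
#' with the joint distribution taken as the empirical frequencies of the
#' confusion matrix and the convention \eqn{0 \log 0 = 0}. Because the
#' decoded label is a deterministic function of the neural response, this
#' is a data-robust lower bound on the information carried by the
#' population activity; no bias correction is applied.
#'
#' @param cm A [confusion_matrix()] (any non-negative count matrix works).
#' @return Mutual information in bits.
#' @examples
#' mutual_information(matrix(c(30, 10, 10, 30), 2)) # ~0.1887 bits
#' @export
mutual_information <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (any(cm < 0)) rlang::abort("confusion matrix must be non-negative")
  total <- sum(cm)
  if (total == 0) rlang::abort("confusion matrix is empty")
  p <- cm / total
  ps <- rowSums(p)
  psh <- colSums(p)
  terms <- p * log2(p / outer(ps, psh))
  sum(terms[p > 0])
}

#' Entropy of the stimulus set
#'
#' \eqn{H(S) = \log_2 S_n} for a uniform set of `S_n` stimulus levels; the
#' upper bound on decodable information and the normalizer for the
#' entropy-normalized information values.
#'
#' @param S_n Number of levels the stimulus feature can take (>= 2).
#' @return Entropy in bits.
#' @export
stimulus_entropy <- function(S_n) {
  if (S_n < 2) rlang::abort("S_n must be >= 2")
  log2(S_n)
}

#' Complementary information of a reference class
#'
#' Information that the full class-set carries beyond the other classes:
#' \eqn{I_{comp}(S, ref) = I(S, all) - I(S, others)}. Reported per NMF
#' instantiation when dispersion is tracked.
#'
#' @param I_all Information (bits) of all classes together.
#' @param I_others Information (bits) of the remaining classes without the
#'   reference class.
#' @return Complementary information in bits.
#' @export
complementary_information <- function(I_all, I_others) I_all - I_others

#' Redundant information of a reference class
#'
#' Overlap between a reference class's information and the rest:
#' \eqn{I_{red}(S, ref) = I(S, ref) + I(S, others) - I(S, all)}. By
#' construction the identity
#' `complementary_information() + redundant_information() == I_ref`
#' holds exactly.
#'
#' @param I_ref Information (bits) of the reference class alone.
#' @param I_others Information (bits) of the remaining classes.
#' @param I_all Information (bits) of all classes together.
#' @return Redundant information in bits.
#' @export
redundant_information <- function(I_ref, I_others, I_all) I_ref + I_others - I_all

#' Saturation density of an information-vs-density curve
#'
#' The smallest innervation density at which the population carries the
#' asymptotic information reached at the highest simulated density. The
#' asymptote is the mean information at the top density; a density
#' qualifies when its mean information is within a tolerance of the
#' asymptote, where the tolerance defaults to the larger of one standard
#' deviation of the information across NMF instantiations at the top
#' density and 2% of the stimulus entropy.
#'
#' @param curve A tibble with columns `density`, `info_mean` and optionally
#'   `info_sd` (strictly increasing densities; >= 3 rows unless
#'   `tolerance` is supplied).
#' @param entropy_bits Stimulus entropy H(S) in bits (for the 2% floor).
#' @param tolerance Explicit tolerance in bits (overrides the default).
#' @return A list with `saturation_density`, `asymptote`, `tolerance`.
#' @export
saturation_density <- function(curve, entropy_bits = NULL, tolerance = NULL) {
  if (is.unsorted(curve$density, strictly = TRUE)) {
    rlang::abort("densities must be strictly increasing")
  }
  if (is.null(tolerance) && nrow(curve) < 3) {
    rlang::abort("need >= 3 densities (or an explicit tolerance)")
  }
  top <- nrow(curve)
  asymptote <- curve$info_mean[top]
  if (is.null(tolerance)) {
    sd_top <- if ("info_sd" %in% names(curve)) curve$info_sd[top] else 0
    if (is.na(sd_top)) sd_top <- 0
    floor_tol <- if (is.null(entropy_bits)) 0 else 0.02 * entropy_bits
    tolerance <- max(sd_top, floor_tol)
  }
  ok <- which(curve$info_mean >= asymptote - tolerance)
  list(
    saturation_density = curve$density[if (length(ok)) min(ok) else top],
    asymptote = asymptote,
    tolerance = tolerance
  )
}

#' Compare density-doubling against class-combination strategies
#'
#' For one stimulus feature, compares the information gained by doubling
#' the innervation density of the most informative class at a baseline
#' density with the information gained by keeping that class at baseline
#' and adding a population of a different class, and reports which
#' strategy wins (ordinal verdict).
#'
#' @param info A tibble with columns `class_set` (e.g. "SA1", "SA1+RA"),
#'   `density_label` (`"baseline"` or `"double"`), `I_bits`.
#' @param reference_class The most informative single class at baseline.
#' @return A list of class `strategy_verdict`: `reference_class`,
#'   `baseline_bits`, `gains` (tibble: `strategy`, `gain_bits`), `verdict`
#'   (`"increase density"`, `"add class"`, or `"tie"`).
#' @export
compare_strategies <- function(info, reference_class) {
  base <- dplyr::filter(
    info, .data$class_set == reference_class, .data$density_label == "baseline"
  )
  dbl <- dplyr::filter(
    info, .data$class_set == reference_class, .data$density_label == "double"
  )
  if (nrow(base) != 1 || nrow(dbl) != 1) {
    rlang::abort("need baseline and doubled-density rows for the reference class")
  }
  combos <- dplyr::filter(
    info,
    .data$density_label == "baseline",
    .data$class_set != reference_class,
    grepl(reference_class, .data$class_set, fixed = TRUE)
  )
  if (nrow(combos) == 0) rlang::abort("need at least one combined class-set")
  gains <- dplyr::bind_rows(
    tibble::tibble(
      strategy = sprintf("double %s density", reference_class),
      gain_bits = dbl$I_bits - base$I_bits
    ),
    tibble::tibble(
      strategy = sprintf("add %s", sub(
        paste0("\\+?", reference_class, "\\+?"), "", combos$class_set
      )),
      gain_bits = combos$I_bits - base$I_bits
    )
  )
  best_combo <- max(gains$gain_bits[-1])
  dbl_gain <- gains$gain_bits[1]
  verdict <- if (isTRUE(all.equal(dbl_gain, best_combo))) {
    "tie"
  } else if (dbl_gain > best_combo) {
    "increase density"
  } else {
    "add class"
  }
  structure(
    list(
      reference_class = reference_class,
      baseline_bits = base$I_bits,
      gains = gains,
      verdict = verdict
    ),
    class = "strategy_verdict"
  )
}

#' @export
print.strategy_verdict <- function(x, ...) {
  cat(sprintf(
    "<strategy_verdict> reference %s (%.3f bits at baseline): %s\n",
    x$reference_class, x$baseline_bits, x$verdict
  ))
  print(x$gains)
  invisible(x)
}
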