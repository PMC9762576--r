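#' Bin spike trains into a trials x (time, afferent) response matrix
#'
#' Discretizes a single-class spike dataset into counts over `bin_width_s`
#' intervals, producing the matrix \eqn{R \in \mathbb{R}^{M \times TN}}
#' (M trials, T time bins, N afferents) on which the spatiotemporal NMF
#' operates. The flattened column axis is afferent-major, time-minor: column
#' `(n-1)*T + t` holds bin `t` of afferent `n`. Total spike count is
#' conserved.
#'
#' @param dataset A single-class `spike_dataset` (see [filter_class()]).
#' @param bin_width_s Bin width in s (default 2 ms).
#' @return A numeric matrix of class `response_matrix` with attributes
#'   `n_bins` (T), `n_afferents` (N), `bin_width_s`, `trials` (the label
#'   tibble) and `class_label`.
#' @export
bin_raster <- function(dataset, bin_width_s = 0.002) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (length(dataset$populations) != 1) {
    rlang::abort("bin_raster expects a single-class dataset; use filter_class()")
  }
  dur <- dataset$duration_s
  if (abs(dur / bin_width_s - round(dur / bin_width_s)) > 1e-6) {
    rlang::abort("bin width must divide the trial duration")
  }
  n_t <- round(dur / bin_width_s)
  n_aff <- nrow(dataset$populations[[1]])
  m <- nrow(dataset$trials)
  sp <- dataset$spikes
  if (nrow(sp) > 0 && (min(sp$time) < 0 || max(sp$time) >= dur + 1e-9)) {
    rlang::abort("spike times outside [0, duration)")
  }
  trial_idx <- match(sp$trial, dataset$trials$trial)
  bin <- pmin(floor(sp$time / bin_width_s) + 1, n_t)
  col <- (sp$afferent - 1) * n_t + bin
  counts <- tabulate((col - 1) * m + trial_idx, nbins = m * n_t * n_aff)
  R <- matrix(counts, nrow = m, ncol = n_t * n_aff)
  structure(
    R,
    n_bins = n_t, n_afferents = n_aff, bin_width_s = bin_width_s,
    trials = dataset$trials,
    class_label = names(dataset$populations),
    class = c("response_matrix", "matrix", "array")
  )
}

response_matrix_like <- function(R, template) {
  structure(
    R,
    n_bins = attr(template, "n_bins"),
    n_afferents = attr(template, "n_afferents"),
    bin_width_s = attr(template, "bin_width_s"),
    trials = attr(template, "trials"),
    class_label = attr(template, "class_label"),
    class = class(template)
  )
}

subset_response <- function(R, rows) {
  out <- response_matrix_like(unclass(R)[rows, , drop = FALSE], R)
  attr(out, "trials") <- attr(R, "trials")[rows, , drop = FALSE]
  out
}

#' Stratified split of trials
#'
#' Splits trial indices into groups with given fractions, stratified by a
#' label (the full condition id by default) so that every condition is
#' represented in every group, as required for the balanced 25/75
#' module-selection/analysis split and the equal train/test split.
#'
#' @param labels Stratification labels, one per trial.
#' @param fractions Named or unnamed fractions summing to 1.
#' @param seed Integer seed.
#' @return An integer vector of group indices (1-based, same order as
#'   `labels`).
#' @export
stratified_split <- function(labels, fractions = c(0.25, 0.75), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) rlang::abort("fractions must sum to 1")
  groups <- integer(length(labels))
  withr::with_seed(derive_seed(seed, 691L), {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- sample(idx)
      n <- length(idx)
      # largest-remainder apportionment keeps every group non-empty per
      # stratum whenever n >= number of groups
      quota <- n * fractions
      base <- floor(quota)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      groups[idx] <- rep.int(seq_along(fractions), base)
    }
  })
  groups
}

#' Stratified k-fold assignment
#' @param labels Stratification labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Fold index (1..k) per element.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  folds <- integer(length(labels))
  withr::with_seed(derive_seed(seed, 877L), {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# HALS (hierarchical alternating least squares) non-negative matrix
# factorization of R (M x P) into H (M x K) %*% W (K x P), minimizing the
# Frobenius reconstruction error. Block coordinate descent over the K
# components; seeded uniform random initialization.
nmf_hals <- function(R, K, seed = 1L, max_iter = 500, tol = 1e-4) {
  R <- unclass(R)
  M <- nrow(R)
  P <- ncol(R)
  scale0 <- sqrt(max(mean(R), .Machine$double.eps) / K)
  init <- withr::with_seed(derive_seed(seed, 409L), {
    list(
      H = matrix(stats::runif(M * K, 0, 1), M, K) * scale0,
      W = matrix(stats::runif(K * P, 0, 1), K, P) * scale0
    )
  })
  H <- init$H
  W <- init$W
  r_norm2 <- sum(R^2)
  if (r_norm2 == 0) {
    # degenerate all-zero input: represent exactly with zero coefficients
    return(list(
      W = matrix(0, K, P), H = matrix(0, M, K),
      explained_variance = 1, converged = TRUE, n_iter = 0L
    ))
  }
  eps <- 1e-12
  prev_loss <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # update H with W fixed
    WWt <- tcrossprod(W)
    RWt <- tcrossprod(R, W)
    for (k in seq_len(K)) {
      denom <- WWt[k, k]
      if (denom < eps) next
      hk <- H[, k] + (RWt[, k] - H %*% WWt[, k]) / denom
      H[, k] <- pmax(hk, 0)
    }
    # update W with H fixed
    HtH <- crossprod(H)
    HtR <- crossprod(H, R)
    for (k in seq_len(K)) {
      denom <- HtH[k, k]
      if (denom < eps) {
        # dead component: reseed deterministically from the residual row
        # with largest norm to keep K effective components
        next
      }
      wk <- W[k, ] + (HtR[k, ] - HtH[k, ] %*% W) / denom
      W[k, ] <- pmax(wk, 0)
    }
    if (it %% 10 == 0 || it == max_iter) {
      loss <- sum((R - H %*% W)^2)
      if (is.finite(prev_loss) && abs(prev_loss - loss) <= tol * max(prev_loss, eps)) {
        converged <- TRUE
        prev_loss <- loss
        break
      }
      prev_loss <- loss
    }
  }
  loss <- sum((R - H %*% W)^2)
  list(
    W = W, H = H,
    explained_variance = 1 - loss / r_norm2,
    converged = converged, n_iter = it
  )
}

#' Fit a spatiotemporal NMF model
#'
#' Factorizes a non-negative response matrix as \eqn{R = HW +}
#' residuals, with \eqn{H} (trials x K) the non-negative activation
#' coefficients and \eqn{W} (K x TN) the non-negative spatiotemporal
#' modules, minimizing the Frobenius reconstruction error by block
#' coordinate descent (HALS) from a seeded random non-negative
#' initialization. Explained variance is
#' \eqn{1 - \|R - HW\|_F^2 / \|R\|_F^2}. An all-zero input is represented
#' exactly by zero coefficients and reported with explained variance 1.
#'
#' @param R A [bin_raster()] matrix (or any non-negative matrix).
#' @param K Number of modules, `1 <= K <= min(dim(R))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol Solver controls; a warning is raised on
#'   non-convergence at `max_iter`.
#' @return An object of class `nmf_model`: list with `W`, `H`, `K`,
#'   `explained_variance`, `fit_seed`, `converged`, `n_iter`.
#' @export
fit_nmf <- function(R, K, seed = 1L, max_iter = 500, tol = 1e-4) {
  if (K < 1 || K > min(dim(R))) {
    rlang::abort("K must satisfy 1 <= K <= min(dim(R))")
  }
  if (any(R < 0)) rlang::abort("R must be non-negative")
  fit <- nmf_hals(R, K, seed = seed, max_iter = max_iter, tol = tol)
  if (!fit$converged && sum(unclass(R)^2) > 0) {
    rlang::warn(sprintf("NMF did not converge in %d iterations (K = %d)", max_iter, K))
  }
  structure(
    list(
      W = fit$W, H = fit$H, K = K,
      explained_variance = fit$explained_variance,
      fit_seed = seed, converged = fit$converged, n_iter = fit$n_iter
    ),
    class = "nmf_model"
  )
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf(
    "<nmf_model> K = %d, explained variance = %.3f (%d iterations)\n",
    x$K, x$explained_variance, x$n_iter
  ))
  invisible(x)
}

#' Tidy an NMF model: modules in long form
#' @param x An `nmf_model`.
#' @param ... Unused.
#' @return Tibble with columns `module`, `column`, `weight`.
#' @export
tidy.nmf_model <- function(x, ...) {
  tibble::tibble(
    module = rep(seq_len(x$K), each = ncol(x$W)),
    column = rep(seq_len(ncol(x$W)), times = x$K),
    weight = as.vector(t(x$W))
  )
}

#' One-row summary of an NMF model
#' @param x An `nmf_model`.
#' @param ... Unused.
#' @return Tibble with `K`, `explained_variance`, `n_iter`, `converged`.
#' @export
glance.nmf_model <- function(x, ...) {
  tibble::tibble(
    K = x$K, explained_variance = x$explained_variance,
    n_iter = x$n_iter, converged = x$converged
  )
}

# explained variance of the best of n_restarts fits at a given K
best_nmf <- function(R, K, seed, n_restarts = 1, ...) {
  fits <- lapply(seq_len(n_restarts), function(r) {
    fit_nmf(R, K, seed = derive_seed(seed, K, r), ...)
  })
  fits[[which.max(vapply(fits, function(f) f$explained_variance, numeric(1)))]]
}

#' Select the number of NMF modules across densities of a class
#'
#' Implements the two-stage module-count protocol. For each density's
#' module-selection (25%) response matrix, the explained variance is swept
#' over increasing K until the gain from adding one module falls below
#' `variance_saturation_tol` (1 percentage point); the explained variance
#' reached there is that population's saturation level. Saturation levels
#' are averaged across the densities of the class, giving a single class
#' variance threshold; the final module count for each density is the
#' minimal K whose explained variance reaches that threshold. Densities
#' whose sweep cannot reach the class threshold are flagged and use the K
#' at their own saturation.
#'
#' @param R25_list A (possibly named) list of response matrices, one per
#'   density of the class.
#' @param variance_saturation_tol Saturation tolerance on the explained-
#'   variance gain per added module (default 0.01 = 1 percentage point).
#' @param K_max Largest K considered (default: min(12, matrix dims)).
#' @param seed Integer seed.
#' @param n_restarts Restarts per K (best kept).
#' @return A list of class `module_selection`: `class_threshold`,
#'   `per_density` (tibble: `density_index`, `saturation_level`,
#'   `K_saturation`, `K_selected`, `reached_threshold`), and `sweeps`
#'   (tibble of K vs explained variance per density).
#' @export
select_num_modules <- function(R25_list, variance_saturation_tol = 0.01,
                               K_max = NULL, seed = 1L, n_restarts = 1) {
  if (!is.list(R25_list)) R25_list <- list(R25_list)
  n_d <- length(R25_list)
  sweeps <- vector("list", n_d)
  sat_level <- numeric(n_d)
  k_sat <- integer(n_d)
  for (d in seq_len(n_d)) {
    R <- R25_list[[d]]
    kmax <- if (is.null(K_max)) min(12L, min(dim(R))) else min(K_max, min(dim(R)))
    ev <- numeric(0)
    k <- 0L
    repeat {
      k <- k + 1L
      ev[k] <- best_nmf(R, k, seed = derive_seed(seed, d), n_restarts = n_restarts)$explained_variance
      if (k >= 2 && (ev[k] - ev[k - 1]) < variance_saturation_tol) {
        # gain from (k-1) -> k below tolerance: variance saturates at k-1
        k_sat[d] <- k - 1L
        sat_level[d] <- ev[k - 1]
        break
      }
      if (k >= kmax) {
        k_sat[d] <- k
        sat_level[d] <- ev[k]
        break
      }
    }
    sweeps[[d]] <- tibble::tibble(
      density_index = d, K = seq_along(ev), explained_variance = ev
    )
  }
  threshold <- mean(sat_level)
  sweeps <- dplyr::bind_rows(sweeps)
  per_density <- purrr::map_dfr(seq_len(n_d), function(d) {
    sw <- dplyr::filter(sweeps, .data$density_index == d)
    hit <- which(sw$explained_variance >= threshold)
    reached <- length(hit) > 0
    tibble::tibble(
      density_index = d,
      saturation_level = sat_level[d],
      K_saturation = k_sat[d],
      K_selected = if (reached) min(hit) else k_sat[d],
      reached_threshold = reached
    )
  })
  if (!is.null(names(R25_list))) per_density$density <- names(R25_list)
  structure(
    list(class_threshold = threshold, per_density = per_density, sweeps = sweeps),
    class = "module_selection"
  )
}

#' @export
print.module_selection <- function(x, ...) {
  cat(sprintf("<module_selection> class variance threshold = %.3f\n", x$class_threshold))
  print(x$per_density)
  invisible(x)
}

#' Project trials onto fixed NMF modules
#'
#' Computes, per trial, the non-negative least-squares activation
#' coefficients of the fixed modules `W`: used to carry the modules learned
#' on the selection (25%) set onto the analysis (75%) set and to re-project
#' perturbed data onto modules learned on intact data. Deterministic
#' (Lawson-Hanson active set on the reduced normal equations).
#'
#' @param R Response matrix (trials x TN), columns matching `W`.
#' @param W Module matrix (K x TN), e.g. from [fit_nmf()].
#' @return Matrix H (trials x K) of non-negative coefficients.
#' @export
project_activations <- function(R, W) {
  if (inherits(W, "nmf_model")) W <- W$W
  R <- unclass(R)
  if (ncol(R) != ncol(W)) rlang::abort("column dimension of R must match W")
  K <- nrow(W)
  G <- tcrossprod(W) + diag(1e-10, K)
  U <- chol(G)
  B <- tcrossprod(R, W) # M x K, rows are W %*% r_m
  H <- matrix(0, nrow(R), K)
  for (m in seq_len(nrow(R))) {
    d <- forwardsolve(t(U), B[m, ])
    H[m, ] <- pracma::lsqnonneg(U, d)$x
  }
  H
}

#' Spatial-NMF control decomposition
#'
#' Alternative low-dimensional representation used as a robustness control:
#' NMF on the whole-trial spike-count matrix `R_count` (trials x afferents)
#' yields purely spatial modules `W_space` capturing which afferents fire
#' together; each trial's binned population vector is then projected
#' bin-by-bin onto the fixed spatial modules, giving `K_space * T`
#' activation coefficients per trial (more than the K per trial of the
#' spatiotemporal factorization).
#'
#' @param R A [bin_raster()] matrix (needed for its time/afferent layout).
#' @param K_space Number of spatial modules.
#' @param seed Integer seed.
#' @return List of class `spatial_nmf`: `W_space` (K x N), `H_t`
#'   (trials x (K*T), module-major: column `(k-1)*T + t`), `count_model`
#'   (the `nmf_model` on `R_count`), `n_bins`.
#' @export
spatial_nmf <- function(R, K_space, seed = 1L) {
  n_t <- attr(R, "n_bins")
  n_aff <- attr(R, "n_afferents")
  if (is.null(n_t) || is.null(n_aff)) {
    rlang::abort("R must be a bin_raster() response matrix")
  }
  M <- nrow(R)
  Rm <- unclass(R)
  # whole-trial counts per afferent: sum bins within each afferent block
  R_count <- vapply(
    seq_len(n_aff),
    function(n) rowSums(Rm[, (n - 1) * n_t + seq_len(n_t), drop = FALSE]),
    numeric(M)
  )
  R_count <- matrix(R_count, nrow = M)
  fit <- fit_nmf(R_count, K_space, seed = seed)
  # per time bin, project the population vector across afferents
  H_t <- matrix(0, M, K_space * n_t)
  for (t in seq_len(n_t)) {
    Rt <- Rm[, (seq_len(n_aff) - 1) * n_t + t, drop = FALSE] # M x N
    Ht <- project_activations(Rt, fit$W)
    H_t[, (seq_len(K_space) - 1) * n_t + t] <- Ht
  }
  structure(
    list(W_space = fit$W, H_t = H_t, count_model = fit, n_bins = n_t),
    class = "spatial_nmf"
  )
}
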