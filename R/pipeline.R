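#' Innervation-density presets for regions of the human hand
#'
#' Estimated innervation densities (afferents per square cm) of the three
#' afferent classes in the palm, finger and fingertip, plus the lower and
#' upper limits of the simulated range.
#'
#' @return A tibble with columns `region`, `SA1`, `RA`, `PC`.
#' @export
density_presets <- function() {
  tibble::tibble(
    region = c("lower_limit", "palm", "finger", "fingertip", "upper_limit"),
    SA1 = c(1, 10, 30, 70, 140),
    RA = c(1, 25, 40, 140, 140),
    PC = c(1, 10, 10, 25, 140)
  )
}

#' Default 16-point log-spaced density grid
#' @param n Number of grid points.
#' @param range Density range (afferents per square cm).
#' @return Numeric vector of densities.
#' @export
density_grid <- function(n = 16, range = c(1, 140)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

default_class_sets <- function(classes, combine) {
  sets <- as.list(classes)
  if (combine && length(classes) > 1) {
    for (k in 2:length(classes)) {
      cmb <- utils::combn(classes, k, simplify = FALSE)
      sets <- c(sets, cmb)
    }
  }
  vapply(sets, paste, character(1), collapse = "+")
}

#' Build an experiment configuration
#'
#' Collects every tunable of the full analysis grid: which stimulus designs
#' to decode (one per feature), the afferent classes and their density
#' grids, trial counts, NMF instantiations, bin width, perturbations and
#' the master seed from which every random draw is derived. The defaults
#' are the full-scale study conditions (800-condition design, 40 trials, 16
#' log-spaced densities, 50 NMF instantiations) and are long-running; pass
#' reduced designs/densities for desk-scale runs.
#'
#' @param features Feature columns to decode (any of `size_mm`,
#'   `ramp_amplitude_mm`, `ramp_time_s`, `frequency_hz`).
#' @param designs Named list (by feature) of design tibbles from
#'   [build_design()]; a single tibble is recycled for all features.
#' @param classes Afferent classes simulated.
#' @param densities Named list (by class) of equal-length density vectors;
#'   a single numeric vector is recycled for all classes. Entry `i` of each
#'   class defines density setting `i` of the grid.
#' @param n_trials Trials per condition (40 at full scale).
#' @param n_instantiations NMF instantiations (50 at full scale; 10 is a
#'   reasonable desk default).
#' @param bin_width_s Spike-count bin width in s (2 ms).
#' @param duration_s,dt_s Trial duration and simulation step (s).
#' @param sine_amplitude_mm Base vibration amplitude (mm).
#' @param noise A [motor_noise()] specification.
#' @param combine_classes Also analyze multi-class sets (pairs and the
#'   triple), enabling complementary/redundant decomposition.
#' @param K_max Largest module count considered during module-count
#'   selection (numerical cap on the variance sweep).
#' @param perturbations Character vector among `"spatial_shuffle"`,
#'   `"temporal_jitter_2"`, `"temporal_jitter_5"`, `"temporal_jitter_10"`
#'   (or `temporal_jitter_<w>` for any half-width w in ms); applied to
#'   single-class sets.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for the run archive (CSV tables + JSON
#'   manifest); `NULL` keeps everything in memory.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(features = c("size_mm", "ramp_amplitude_mm",
                                           "ramp_time_s", "frequency_hz"),
                              designs = build_design(),
                              classes = c("SA1", "RA", "PC"),
                              densities = density_grid(),
                              n_trials = 40,
                              n_instantiations = 50,
                              bin_width_s = 0.002,
                              duration_s = 0.5,
                              dt_s = 1e-4,
                              sine_amplitude_mm = 0.1,
                              noise = motor_noise(),
                              combine_classes = FALSE,
                              K_max = 12,
                              perturbations = character(0),
                              master_seed = 1L,
                              out_dir = NULL) {
  if (is.data.frame(designs)) {
    designs <- stats::setNames(rep(list(designs), length(features)), features)
  }
  if (!all(features %in% names(designs))) {
    rlang::abort("designs must be named by feature")
  }
  if (is.numeric(densities)) {
    densities <- stats::setNames(rep(list(densities), length(classes)), classes)
  }
  if (!all(classes %in% names(densities))) {
    rlang::abort("densities must be named by class")
  }
  n_d <- unique(lengths(densities[classes]))
  if (length(n_d) != 1) rlang::abort("density vectors must have equal length")
  stopifnot(n_trials >= 1, n_instantiations >= 1)
  bad <- setdiff(
    perturbations,
    c("spatial_shuffle", grep("^temporal_jitter_", perturbations, value = TRUE))
  )
  if (length(bad)) rlang::abort(paste("unknown perturbations:", paste(bad, collapse = ", ")))
  structure(
    list(
      features = features, designs = designs[features],
      classes = classes, densities = densities[classes],
      n_density = n_d,
      n_trials = n_trials, n_instantiations = n_instantiations,
      bin_width_s = bin_width_s, duration_s = duration_s, dt_s = dt_s,
      sine_amplitude_mm = sine_amplitude_mm, noise = noise,
      combine_classes = combine_classes, K_max = K_max,
      perturbations = perturbations,
      master_seed = as.integer(master_seed), out_dir = out_dir
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<experiment_config> %d feature(s), %d class(es) x %d density setting(s), ",
      "%d trials/condition, %d instantiation(s), seed %d\n"
    ),
    length(x$features), length(x$classes), x$n_density,
    x$n_trials, x$n_instantiations, x$master_seed
  ))
  invisible(x)
}

config_manifest <- function(config) {
  list(
    package = "tactilepop",
    version = as.character(utils::packageVersion("tactilepop")),
    features = config$features,
    designs = lapply(config$designs, function(d) as.data.frame(d)),
    classes = config$classes,
    densities = config$densities,
    n_trials = config$n_trials,
    n_instantiations = config$n_instantiations,
    bin_width_s = config$bin_width_s,
    duration_s = config$duration_s,
    dt_s = config$dt_s,
    sine_amplitude_mm = config$sine_amplitude_mm,
    noise = unclass(config$noise),
    combine_classes = config$combine_classes,
    K_max = config$K_max,
    perturbations = config$perturbations,
    master_seed = config$master_seed
  )
}

#' Rebuild an experiment configuration from a run manifest
#' @param path Path to a `manifest.json` written by [run_experiment()].
#' @param out_dir Optional new output directory.
#' @return An `experiment_config`.
#' @export
read_manifest <- function(path, out_dir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    features = m$features,
    designs = lapply(m$designs, tibble::as_tibble),
    classes = m$classes,
    densities = lapply(m$densities, as.numeric),
    n_trials = m$n_trials,
    n_instantiations = m$n_instantiations,
    bin_width_s = m$bin_width_s,
    duration_s = m$duration_s,
    dt_s = m$dt_s,
    sine_amplitude_mm = m$sine_amplitude_mm,
    noise = motor_noise(
      m$noise$location_jitter_mm,
      m$noise$sine_amplitude_jitter_mm,
      m$noise$ramp_amplitude_jitter_mm
    ),
    combine_classes = m$combine_classes,
    K_max = m$K_max,
    perturbations = as.character(m$perturbations),
    master_seed = m$master_seed,
    out_dir = out_dir
  )
}

set_density_label <- function(config, set, di) {
  cls <- strsplit(set, "+", fixed = TRUE)[[1]]
  paste(sprintf("%s=%g", cls, vapply(
    cls, function(cl) config$densities[[cl]][di], numeric(1)
  )), collapse = ",")
}

# one analysis cell: every class-set and instantiation for one
# (feature, density setting); returns the long info tibble for the cell
run_cell <- function(config, fi, di, binned, dataset, K_by_class) {
  feature <- config$features[fi]
  trials <- dataset$trials
  labels_all <- trials[[feature]]
  seed0 <- derive_seed(config$master_seed, fi, di)

  split25 <- stratified_split(trials$condition_id, c(0.25, 0.75),
                              seed = derive_seed(seed0, 25L))
  i75 <- which(split25 == 2)
  tt <- stratified_split(trials$condition_id[i75], c(0.5, 0.5),
                         seed = derive_seed(seed0, 50L))
  itr <- i75[tt == 1]
  ite <- i75[tt == 2]
  labels_tr <- labels_all[itr]
  labels_te <- labels_all[ite]

  sets <- default_class_sets(config$classes, config$combine_classes)
  rows <- list()
  for (inst in seq_len(config$n_instantiations)) {
    fits <- list()
    H75 <- list()
    for (ci in seq_along(config$classes)) {
      cl <- config$classes[ci]
      R <- binned[[cl]]
      R25 <- unclass(R)[split25 == 1, , drop = FALSE]
      fit <- fit_nmf(R25, K_by_class[[cl]], seed = derive_seed(seed0, ci, inst))
      fits[[cl]] <- fit
      H75[[cl]] <- project_activations(unclass(R)[i75, , drop = FALSE], fit$W)
    }
    names(H75) <- config$classes
    # positions of train/test trials within the 75-set ordering
    pos_tr <- match(itr, i75)
    pos_te <- match(ite, i75)
    for (set in sets) {
      cls <- strsplit(set, "+", fixed = TRUE)[[1]]
      H <- do.call(cbind, H75[cls])
      model <- train_decoder(
        H[pos_tr, , drop = FALSE], labels_tr,
        seed = derive_seed(seed0, inst, match(set, sets))
      )
      cm <- confusion_matrix(model, H[pos_te, , drop = FALSE], labels_te)
      I <- mutual_information(cm)
      H_S <- stimulus_entropy(length(model$levels))
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = feature, class_set = set, density_index = di,
        density = set_density_label(config, set, di),
        instantiation = inst, perturbation = "none",
        K = if (length(cls) == 1) K_by_class[[set]] else sum(unlist(K_by_class[cls])),
        I_bits = I, I_norm = I / H_S,
        accuracy = sum(diag(cm)) / sum(cm), n_test = sum(cm)
      )
      if (length(cls) == 1 && length(config$perturbations) > 0) {
        cl <- cls
        R <- binned[[cl]]
        for (pert in config$perturbations) {
          pseed <- derive_seed(seed0, inst, match(set, sets),
                               match(pert, config$perturbations))
          if (pert == "spatial_shuffle") {
            R_pert <- shuffle_afferents(subset_response(R, ite), seed = pseed)
          } else {
            w_ms <- as.numeric(sub("temporal_jitter_", "", pert))
            ds_j <- jitter_spikes(filter_class(dataset, cl), w_ms, seed = pseed)
            Rj <- bin_raster(ds_j, config$bin_width_s)
            R_pert <- subset_response(Rj, ite)
          }
          ev <- evaluate_perturbed(R_pert, fits[[cl]]$W, model, labels_te,
                                   perturbation = pert)
          rows[[length(rows) + 1]] <- tibble::tibble(
            feature = feature, class_set = set, density_index = di,
            density = set_density_label(config, set, di),
            instantiation = inst, perturbation = pert,
            K = K_by_class[[cl]],
            I_bits = ev$I_bits, I_norm = ev$I_norm,
            accuracy = ev$accuracy, n_test = ev$n_test
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full population-coding experiment
#'
#' Orchestrates, for every decoded feature and density setting of the
#' configuration: spiking simulation of all afferent classes to the
#' motor-noise-jittered stimuli, 2-ms binning, the 25/75 stratified split,
#' module-count selection per class across densities, per-instantiation
#' spatiotemporal NMF on the selection set and projection of the analysis
#' set, stratified train/test decoding of the feature, confusion-matrix
#' mutual information, and (optionally) spatial-shuffle and temporal-jitter
#' perturbations evaluated with frozen modules and decoders.
#'
#' Every random draw derives deterministically from `master_seed` via a
#' hierarchical scheme indexed by (feature, density setting, class,
#' instantiation), so reruns reproduce results exactly. When `out_dir` is
#' set, the run archive is plain text: one CSV per analysis cell
#' (`info_<feature>_d<i>.csv`), one module-selection CSV per feature, and a
#' `manifest.json` that round-trips the configuration; existing cell files
#' are reused on resume, so deleting one cell's CSV recomputes only that
#' cell.
#'
#' @param config An [experiment_config()].
#' @return A list of class `tactile_experiment`: `info` (long tibble:
#'   `feature`, `class_set`, `density_index`, `density`, `instantiation`,
#'   `perturbation`, `K`, `I_bits`, `I_norm`, `accuracy`, `n_test`),
#'   `modules` (module-selection summary per feature x class x density),
#'   `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      config_manifest(config),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  all_info <- list()
  all_modules <- list()
  for (fi in seq_along(config$features)) {
    feature <- config$features[fi]
    design_f <- config$designs[[feature]]
    n_d <- config$n_density
    cell_file <- function(di) {
      file.path(out_dir, sprintf("info_%s_d%d.csv", feature, di))
    }
    mod_file <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("modules_%s.csv", feature))
    }
    have_cell <- if (!is.null(out_dir)) {
      vapply(seq_len(n_d), function(di) file.exists(cell_file(di)), logical(1))
    } else {
      rep(FALSE, n_d)
    }
    have_modules <- !is.null(out_dir) && file.exists(mod_file)
    need_sim <- which(!have_cell)
    if (have_modules && length(need_sim) == 0) {
      all_modules[[feature]] <- readr::read_csv(mod_file, show_col_types = FALSE)
      for (di in seq_len(n_d)) {
        all_info[[paste(feature, di)]] <-
          readr::read_csv(cell_file(di), show_col_types = FALSE)
      }
      next
    }
    # simulate the densities we need: all of them when module selection must
    # be (re)done, otherwise only the missing cells
    sim_idx <- if (have_modules) need_sim else seq_len(n_d)
    datasets <- vector("list", n_d)
    binned <- vector("list", n_d)
    for (di in sim_idx) {
      pops <- lapply(seq_along(config$classes), function(ci) {
        cl <- config$classes[ci]
        place_population(cl, config$densities[[cl]][di],
                         seed = derive_seed(config$master_seed, fi, di, ci))
      })
      ds <- simulate_dataset(
        design_f, pops,
        n_trials = config$n_trials, noise = config$noise,
        master_seed = derive_seed(config$master_seed, fi, di),
        duration_s = config$duration_s, dt_s = config$dt_s,
        sine_amplitude_mm = config$sine_amplitude_mm
      )
      datasets[[di]] <- ds
      binned[[di]] <- stats::setNames(lapply(config$classes, function(cl) {
        bin_raster(filter_class(ds, cl), config$bin_width_s)
      }), config$classes)
    }
    # module-count selection per class across densities
    if (have_modules) {
      mods <- readr::read_csv(mod_file, show_col_types = FALSE)
    } else {
      mod_rows <- list()
      for (ci in seq_along(config$classes)) {
        cl <- config$classes[ci]
        R25s <- lapply(seq_len(n_d), function(di) {
          R <- binned[[di]][[cl]]
          seed0 <- derive_seed(config$master_seed, fi, di)
          s25 <- stratified_split(
            attr(R, "trials")$condition_id, c(0.25, 0.75),
            seed = derive_seed(seed0, 25L)
          )
          unclass(R)[s25 == 1, , drop = FALSE]
        })
        sel <- select_num_modules(R25s, K_max = config$K_max,
                                  seed = derive_seed(config$master_seed, fi, 7L, ci))
        mod_rows[[ci]] <- dplyr::mutate(
          sel$per_density,
          feature = feature, class = cl,
          density = config$densities[[cl]][.data$density_index],
          class_threshold = sel$class_threshold,
          .before = 1
        )
      }
      mods <- dplyr::bind_rows(mod_rows)
      if (!is.null(out_dir)) readr::write_csv(mods, mod_file)
    }
    all_modules[[feature]] <- mods
    for (di in seq_len(n_d)) {
      if (have_cell[di]) {
        all_info[[paste(feature, di)]] <-
          readr::read_csv(cell_file(di), show_col_types = FALSE)
        next
      }
      K_by_class <- stats::setNames(lapply(config$classes, function(cl) {
        m <- dplyr::filter(mods, .data$class == cl, .data$density_index == di)
        m$K_selected[1]
      }), config$classes)
      cell <- tryCatch(
        run_cell(config, fi, di, binned[[di]], datasets[[di]], K_by_class),
        error = function(e) {
          rlang::warn(sprintf(
            "cell (%s, density setting %d) failed and was skipped: %s",
            feature, di, conditionMessage(e)
          ))
          NULL
        }
      )
      if (is.null(cell)) next
      if (!is.null(out_dir)) readr::write_csv(cell, cell_file(di))
      all_info[[paste(feature, di)]] <- cell
    }
  }
  info <- dplyr::bind_rows(all_info)
  modules <- dplyr::bind_rows(all_modules)
  if (!is.null(out_dir)) {
    readr::write_csv(info, file.path(out_dir, "info_all.csv"))
  }
  structure(
    list(info = info, modules = modules, config = config),
    class = "tactile_experiment"
  )
}

#' @export
print.tactile_experiment <- function(x, ...) {
  cat(sprintf(
    "<tactile_experiment> %d info rows (%d feature(s), %d class-set(s))\n",
    nrow(x$info), length(unique(x$info$feature)),
    length(unique(x$info$class_set))
  ))
  invisible(x)
}

#' Mean and dispersion of information across NMF instantiations
#'
#' @param x A `tactile_experiment` or its `info` tibble.
#' @return Tibble grouped by feature, class_set, density_index,
#'   perturbation with `info_mean`, `info_sd` (bits), `norm_mean`,
#'   `norm_sd`, `n`.
#' @export
summarize_information <- function(x) {
  info <- if (inherits(x, "tactile_experiment")) x$info else x
  dplyr::summarise(
    dplyr::group_by(
      info, .data$feature, .data$class_set, .data$density_index,
      .data$density, .data$perturbation
    ),
    info_mean = mean(.data$I_bits), info_sd = stats::sd(.data$I_bits),
    norm_mean = mean(.data$I_norm), norm_sd = stats::sd(.data$I_norm),
    n = dplyr::n(), .groups = "drop"
  )
}

#' Complementary/redundant decomposition across afferent classes
#'
#' For every feature, density setting and NMF instantiation with all three
#' single classes, the three pairs and the triple available, computes per
#' reference class the complementary information (triple minus the
#' complementary pair) and the redundant information (reference plus pair
#' minus triple), together with the complementary fraction
#' `I_comp / I_ref`.
#'
#' @param x A `tactile_experiment` or its `info` tibble (needs
#'   `combine_classes = TRUE` runs).
#' @return Long tibble: `feature`, `density_index`, `instantiation`,
#'   `reference_class`, `I_ref`, `I_others`, `I_all`, `I_comp`, `I_red`,
#'   `comp_fraction`.
#' @export
complementarity <- function(x) {
  info <- if (inherits(x, "tactile_experiment")) x$info else x
  info <- dplyr::filter(info, .data$perturbation == "none")
  classes <- unique(unlist(strsplit(
    info$class_set[!grepl("\\+", info$class_set)], "+", fixed = TRUE
  )))
  if (length(classes) < 2) rlang::abort("need at least two single classes")
  all_set <- paste(classes, collapse = "+")
  grp <- dplyr::distinct(
    info, .data$feature, .data$density_index, .data$instantiation
  )
  purrr::pmap_dfr(grp, function(feature, density_index, instantiation) {
    sub <- dplyr::filter(
      info, .data$feature == !!feature,
      .data$density_index == !!density_index,
      .data$instantiation == !!instantiation
    )
    lookup <- stats::setNames(sub$I_bits, sub$class_set)
    if (!all_set %in% names(lookup)) return(NULL)
    purrr::map_dfr(classes, function(ref) {
      others <- setdiff(classes, ref)
      others_set <- paste(others, collapse = "+")
      if (!others_set %in% names(lookup) || !ref %in% names(lookup)) {
        return(NULL)
      }
      I_ref <- lookup[[ref]]
      I_others <- lookup[[others_set]]
      I_all <- lookup[[all_set]]
      I_comp <- complementary_information(I_all, I_others)
      I_red <- redundant_information(I_ref, I_others, I_all)
      tibble::tibble(
        feature = feature, density_index = density_index,
        instantiation = instantiation, reference_class = ref,
        I_ref = I_ref, I_others = I_others, I_all = I_all,
        I_comp = I_comp, I_red = I_red,
        comp_fraction = if (I_ref > 0) I_comp / I_ref else NA_real_
      )
    })
  })
}

#' Saturation densities for every feature and class
#'
#' Applies [saturation_density()] to each single-class information-vs-
#' density curve of an experiment.
#'
#' @param x A `tactile_experiment`.
#' @return Tibble: `feature`, `class`, `saturation_density`,
#'   `asymptote_bits`, `tolerance_bits`.
#' @export
saturation_summary <- function(x) {
  stopifnot(inherits(x, "tactile_experiment"))
  smry <- summarize_information(x)
  smry <- dplyr::filter(
    smry, .data$perturbation == "none", !grepl("\\+", .data$class_set)
  )
  grp <- dplyr::distinct(smry, .data$feature, .data$class_set)
  purrr::pmap_dfr(grp, function(feature, class_set) {
    sub <- dplyr::arrange(
      dplyr::filter(
        smry, .data$feature == !!feature, .data$class_set == !!class_set
      ),
      .data$density_index
    )
    dens <- x$config$densities[[class_set]][sub$density_index]
    design_levels <- length(unique(x$config$designs[[feature]][[feature]]))
    curve <- tibble::tibble(
      density = dens, info_mean = sub$info_mean, info_sd = sub$info_sd
    )
    sat <- saturation_density(curve, entropy_bits = stimulus_entropy(design_levels))
    tibble::tibble(
      feature = feature, class = class_set,
      saturation_density = sat$saturation_density,
      asymptote_bits = sat$asymptote,
      tolerance_bits = sat$tolerance
    )
  })
}

#' Information-vs-density curves
#' @param x A `tactile_experiment` or a [summarize_information()] tibble.
#' @return A ggplot: normalized information against density setting, one
#'   line per class-set, faceted by feature, ribbons = 1 SD across NMF
#'   instantiations.
#' @export
plot_info_curves <- function(x) {
  smry <- if (inherits(x, "tactile_experiment")) summarize_information(x) else x
  smry <- dplyr::filter(smry, .data$perturbation == "none")
  ggplot2::ggplot(
    smry,
    ggplot2::aes(.data$density_index, .data$norm_mean,
                 colour = .data$class_set, fill = .data$class_set)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$norm_mean - .data$norm_sd,
                   ymax = .data$norm_mean + .data$norm_sd),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(
      x = "Density setting", y = "Information / H(S)",
      colour = "Class set", fill = "Class set"
    ) +
    ggplot2::ylim(0, 1)
}

#' Complementary/redundant information bars
#' @param comp A [complementarity()] tibble.
#' @return A ggplot: stacked complementary + redundant bits per reference
#'   class, faceted by feature.
#' @export
plot_complementarity <- function(comp) {
  long <- tidyr::pivot_longer(
    dplyr::summarise(
      dplyr::group_by(comp, .data$feature, .data$reference_class),
      I_comp = mean(.data$I_comp), I_red = mean(.data$I_red),
      .groups = "drop"
    ),
    cols = c("I_comp", "I_red"),
    names_to = "component", values_to = "bits"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$reference_class, .data$bits, fill = .data$component)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "Reference class", y = "Information (bits)", fill = NULL)
}

#' Perturbation information losses
#' @param x A `tactile_experiment` or a [summarize_information()] tibble.
#' @return A ggplot: mean normalized information per perturbation and
#'   class, faceted by feature.
#' @export
plot_perturbation <- function(x) {
  smry <- if (inherits(x, "tactile_experiment")) summarize_information(x) else x
  smry <- dplyr::filter(smry, !grepl("\\+", .data$class_set))
  ggplot2::ggplot(
    smry,
    ggplot2::aes(.data$perturbation, .data$norm_mean, fill = .data$class_set)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$norm_mean - .data$norm_sd,
                   ymax = .data$norm_mean + .data$norm_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = NULL, y = "Information / H(S)", fill = "Class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
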