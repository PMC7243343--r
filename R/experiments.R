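#' @title Sweep experiments over the six stimulus conditions
#' @description Internal helpers shared by the sweep runners.
#' @name experiments
#' @keywords internal
NULL

new_sweep <- function(records, crossover = NA_real_, settings = list()) {
  structure(list(records = records,
                 crossover_intensity = crossover,
                 settings = settings),
            class = "msi_sweep")
}

#' @export
print.msi_sweep <- function(x, ...) {
  cat("<msi_sweep> ", nrow(x$records), " records; conditions: ",
      paste(unique(x$records$condition), collapse = ", "), "\n", sep = "")
  if (!is.na(x$crossover_intensity)) {
    cat("  additivity-index crossover at intensity ",
        signif(x$crossover_intensity, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Interpolated intensity where the additivity index crosses 1
#'
#' Scans the (intensity, index) curve for the first adjacent pair straddling 1
#' from above (super- to sub-additive, the inverse-effectiveness transition)
#' and linearly interpolates the crossing intensity. `NA` entries (undefined
#' index at zero response) are skipped; `NA` is returned when the curve never
#' crosses.
#'
#' @param intensity Increasing intensity grid.
#' @param index Additivity index at each intensity (may contain `NA`).
#' @return Interpolated crossing intensity, or `NA`.
#' @export
crossover_intensity <- function(intensity, index) {
  keep <- !is.na(index)
  x <- intensity[keep]; y <- index[keep]
  if (length(x) < 2L) return(NA_real_)
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] >= 1 && y[i + 1L] < 1) {
      return(x[i] + (y[i] - 1) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i]))
    }
  }
  NA_real_
}

# Run a set of (condition, intensity, offset) cells in one batched integration
# and return the equilibrium membrane response at the readout channel per cell.
run_condition_cells <- function(cells, params, sigma_z, readout_loc) {
  n <- params$n_neurons
  inputs <- lapply(seq_len(nrow(cells)), function(k) {
    cond <- condition_spec(
      cells$condition[k],
      audio = stimulus_spec(readout_loc, sigma_z, cells$intensity[k]),
      visual = stimulus_spec(readout_loc + cells$offset[k], sigma_z,
                             cells$intensity[k])
    )
    build_condition_inputs(cond, n)
  })
  out <- simulate_batch(inputs, params)
  out$membrane[readout_loc + 1L, ]
}

# Assemble metric records for a grid of offsets x intensities given the
# readout responses of the four informative conditions.
records_from_responses <- function(grid, resp, lam) {
  recs <- lapply(seq_len(nrow(grid)), function(k) {
    key <- function(cond) resp[[paste(cond, grid$intensity[k], grid$offset[k])]]
    V <- key("unimodal_visual"); A <- key("unimodal_audio")
    rbind(
      metric_record(key("bimodal_full"), V, A, "bimodal_full",
                    grid$intensity[k], grid$offset[k], lam),
      metric_record(key("bimodal_no_cortex"), V, A, "bimodal_no_cortex",
                    grid$intensity[k], grid$offset[k], lam),
      metric_record(V, V, A, "unimodal_visual",
                    grid$intensity[k], grid$offset[k], lam),
      metric_record(A, V, A, "unimodal_audio",
                    grid$intensity[k], grid$offset[k], lam)
    )
  })
  do.call(rbind, recs)
}

#' Inverse-effectiveness experiment
#'
#' Spatially aligned bimodal stimuli at the readout location are presented at
#' `n_intensities` equally spaced intensities in `[0, 1]` under all six
#' stimulus conditions; the response of the audio-aligned SC neuron is read
#' out and the additivity index `M/(V+A)` computed per condition and
#' intensity. The feedback-on bimodal curve starts super-additive at low
#' intensity and crosses below 1 as intensity grows; the interpolated crossing
#' intensity is returned as `crossover_intensity`.
#'
#' @param params An `msi_params` object.
#' @param n_intensities Number of intensity samples, default 11.
#' @param sigma_z Stimulus width, default 1.
#' @param readout_loc Location (0-based) of the stimuli and readout neuron,
#'   default 8.
#' @return An `msi_sweep`: `records` (one row per condition and intensity,
#'   all six conditions), `crossover_intensity`, `settings`.
#' @export
run_inverse_effectiveness <- function(params = msi_params(),
                                      n_intensities = 11L,
                                      sigma_z = 1,
                                      readout_loc = 8L) {
  intensities <- seq(0, 1, length.out = n_intensities)
  cells <- expand.grid(condition = MSI_CONDITIONS, intensity = intensities,
                       offset = 0, stringsAsFactors = FALSE)
  rates <- run_condition_cells(cells, params, sigma_z, readout_loc)
  resp <- stats::setNames(as.list(rates),
                          paste(cells$condition, cells$intensity, cells$offset))
  recs <- lapply(seq_len(nrow(cells)), function(k) {
    key <- function(cond) resp[[paste(cond, cells$intensity[k], 0)]]
    metric_record(rates[k], key("unimodal_visual"), key("unimodal_audio"),
                  cells$condition[k], cells$intensity[k], 0, params$lam)
  })
  records <- do.call(rbind, recs)
  on_rows <- records[records$condition == "bimodal_full", ]
  on_rows <- on_rows[order(on_rows$intensity), ]
  cross <- crossover_intensity(on_rows$intensity, on_rows$additivity_index)
  new_sweep(records, cross,
            list(experiment = "inverse_effectiveness",
                 n_intensities = n_intensities, sigma_z = sigma_z,
                 readout_loc = readout_loc))
}

#' Additivity index across modulatory feedback gains
#'
#' Repeats the inverse-effectiveness sweep for several values of the feedback
#' gain `lambda`. With `lambda = 0` the modulatory factor is identically 1 and
#' the feedback-on curve coincides with the ablated circuit; larger gains
#' raise the additivity index and shift the crossover to higher intensities.
#'
#' @inheritParams run_inverse_effectiveness
#' @param lam_values Feedback gains to test.
#' @return An `msi_sweep` with records tagged by `lam` and a `crossovers`
#'   element in `settings` (one interpolated crossover per gain, `NA` when the
#'   curve never crosses 1).
#' @export
run_lambda_sweep <- function(params = msi_params(),
                             lam_values = c(0, 0.1, 0.2, 0.4, 0.6, 0.8),
                             n_intensities = 11L, sigma_z = 1,
                             readout_loc = 8L) {
  stopifnot(all(lam_values >= 0))
  sweeps <- lapply(lam_values, function(lv) {
    pl <- params; pl$lam <- lv
    run_inverse_effectiveness(pl, n_intensities, sigma_z, readout_loc)
  })
  records <- do.call(rbind, lapply(sweeps, `[[`, "records"))
  crossovers <- vapply(sweeps, `[[`, numeric(1), "crossover_intensity")
  default <- which(abs(lam_values - params$lam) < 1e-12)
  cross <- if (length(default) > 0) crossovers[default[1]] else NA_real_
  new_sweep(records, cross,
            list(experiment = "lambda_sweep", lam_values = lam_values,
                 crossovers = crossovers, n_intensities = n_intensities,
                 sigma_z = sigma_z, readout_loc = readout_loc))
}

#' Spatial-principle experiment
#'
#' The auditory stimulus stays fixed at the readout location; the visual
#' stimulus (and its cortical copy) is shifted by each offset, expressed in
#' multiples of the stimulus width `sigma_z`. For every offset the intensity
#' sweep is repeated and the additivity index computed at the audio-aligned
#' neuron. Moderate offsets (around 3 sigma) suppress the bimodal response
#' below the unimodal sum; beyond that the modalities no longer interact and
#' the index returns to 1.
#'
#' @inheritParams run_inverse_effectiveness
#' @param offsets_sigma Offsets in multiples of `sigma_z`, default 0..5.
#' @return An `msi_sweep`; `settings$index_range_by_offset` summarizes the
#'   feedback-on index range per offset (over intensities >= 0.2).
#' @export
run_spatial_principle <- function(params = msi_params(),
                                  offsets_sigma = 0:5,
                                  n_intensities = 11L, sigma_z = 1,
                                  readout_loc = 8L) {
  stopifnot(all(offsets_sigma >= 0))
  intensities <- seq(0, 1, length.out = n_intensities)
  conds <- c("bimodal_full", "bimodal_no_cortex",
             "unimodal_visual", "unimodal_audio")
  cells <- expand.grid(condition = conds, intensity = intensities,
                       offset = offsets_sigma * sigma_z,
                       stringsAsFactors = FALSE)
  rates <- run_condition_cells(cells, params, sigma_z, readout_loc)
  resp <- stats::setNames(as.list(rates),
                          paste(cells$condition, cells$intensity, cells$offset))
  grid <- unique(cells[, c("intensity", "offset")])
  records <- records_from_responses(grid, resp, params$lam)
  on <- records[records$condition == "bimodal_full" & records$intensity >= 0.2, ]
  rng <- do.call(rbind, lapply(split(on, on$offset), function(d) {
    data.frame(offset = d$offset[1],
               index_min = min(d$additivity_index, na.rm = TRUE),
               index_max = max(d$additivity_index, na.rm = TRUE))
  }))
  new_sweep(records, NA_real_,
            list(experiment = "spatial_principle",
                 offsets_sigma = offsets_sigma, sigma_z = sigma_z,
                 n_intensities = n_intensities, readout_loc = readout_loc,
                 index_range_by_offset = rng))
}

#' Within-modality interaction experiment
#'
#' Two auditory stimuli (A at the readout location, B shifted by each offset)
#' are presented via [build_within_modality_inputs()], with auditory cortical
#' feedback following stimulus A and no visual cortical activity. Because the
#' cross-modal feedback circuit requires both cortical modalities, no
#' modulatory signal is generated: combined responses exceed the single-input
#' responses but show essentially no super-additivity except at low intensity,
#' and a B stimulus outside the receptive field suppresses the response below
#' the single-input level.
#'
#' @inheritParams run_spatial_principle
#' @return An `msi_sweep` with condition `"within_combined"` rows (M = A+B
#'   response, A = input-A-alone response, V = input-B-alone response).
#' @export
run_within_modality <- function(params = msi_params(),
                                offsets_sigma = 0:5,
                                n_intensities = 11L, sigma_z = 1,
                                readout_loc = 8L) {
  stopifnot(all(offsets_sigma >= 0))
  n <- params$n_neurons
  intensities <- seq(0, 1, length.out = n_intensities)
  grid <- expand.grid(intensity = intensities,
                      offset = offsets_sigma * sigma_z)
  build_cell <- function(intensity, offset, which) {
    a <- stimulus_spec(readout_loc, sigma_z, intensity)
    b <- stimulus_spec(readout_loc + offset, sigma_z, intensity)
    switch(which,
      combined = build_within_modality_inputs(a, b, n),
      a_alone = build_within_modality_inputs(a, stimulus_spec(readout_loc + offset, sigma_z, 0), n),
      b_alone = msi_inputs(numeric(n), gaussian_input(b, n), numeric(n), numeric(n))
    )
  }
  kinds <- c("combined", "a_alone", "b_alone")
  cells <- merge(grid, data.frame(kind = kinds), by = NULL)
  inputs <- lapply(seq_len(nrow(cells)), function(k) {
    build_cell(cells$intensity[k], cells$offset[k], cells$kind[k])
  })
  out <- simulate_batch(inputs, params)
  rates <- out$membrane[readout_loc + 1L, ]
  resp <- stats::setNames(as.list(rates),
                          paste(cells$kind, cells$intensity, cells$offset))
  recs <- lapply(seq_len(nrow(grid)), function(k) {
    key <- function(kind) resp[[paste(kind, grid$intensity[k], grid$offset[k])]]
    metric_record(key("combined"), key("b_alone"), key("a_alone"),
                  "within_combined", grid$intensity[k], grid$offset[k],
                  params$lam)
  })
  new_sweep(do.call(rbind, recs), NA_real_,
            list(experiment = "within_modality",
                 offsets_sigma = offsets_sigma, sigma_z = sigma_z,
                 n_intensities = n_intensities, readout_loc = readout_loc))
}

#' Enhancement vs. additivity scatter
#'
#' Draws `n_samples` random stimulus configurations (intensity, spatial
#' offset, and independent auditory/visual widths in `[0.5, 5]`), runs each
#' with cortical feedback on and off, and returns per draw the cross-modal
#' enhancement and the response additivity of the readout neuron. With
#' feedback off, no configuration is super-additive; super-additivity and
#' enhancement appear only with active feedback and favor weak, aligned
#' stimuli.
#'
#' @inheritParams run_inverse_effectiveness
#' @param n_samples Number of random draws.
#' @param seed Integer seed; the scatter is deterministic given the seed.
#' @param offset_grid Offsets (in multiples of the visual width) sampled
#'   uniformly, default 0..5.
#' @return A data frame with one row per draw and feedback flag:
#'   `intensity`, `offset`, `sigma_a`, `sigma_v`, `feedback`, `M`, `V`, `A`,
#'   `enhancement`, `response_additivity`.
#' @export
run_enhancement_scatter <- function(params = msi_params(),
                                    n_samples = 50L,
                                    seed = 1L,
                                    offset_grid = 0:5,
                                    readout_loc = 8L) {
  stopifnot(n_samples >= 1L)
  n <- params$n_neurons
  rng <- rng_stream(seed, 10L)
  draws <- data.frame(
    intensity = 0.1 + 0.9 * rng(n_samples),
    offset_mult = offset_grid[floor(rng(n_samples) * length(offset_grid)) + 1L],
    sigma_a = 0.5 + 4.5 * rng(n_samples),
    sigma_v = 0.5 + 4.5 * rng(n_samples)
  )
  build <- function(k, condition) {
    off <- draws$offset_mult[k] * draws$sigma_v[k]
    cond <- condition_spec(
      condition,
      audio = stimulus_spec(readout_loc, draws$sigma_a[k], draws$intensity[k]),
      visual = stimulus_spec(readout_loc + off, draws$sigma_v[k],
                             draws$intensity[k])
    )
    build_condition_inputs(cond, n)
  }
  conds <- c("bimodal_full", "bimodal_no_cortex",
             "unimodal_visual", "unimodal_audio")
  cells <- expand.grid(k = seq_len(n_samples), condition = conds,
                       stringsAsFactors = FALSE)
  inputs <- lapply(seq_len(nrow(cells)),
                   function(i) build(cells$k[i], cells$condition[i]))
  out <- simulate_batch(inputs, params)
  rates <- out$membrane[readout_loc + 1L, ]
  get <- function(k, condition) rates[cells$k == k & cells$condition == condition]
  rows <- lapply(seq_len(n_samples), function(k) {
    V <- get(k, "unimodal_visual"); A <- get(k, "unimodal_audio")
    do.call(rbind, lapply(c(TRUE, FALSE), function(fb) {
      M <- get(k, if (fb) "bimodal_full" else "bimodal_no_cortex")
      data.frame(intensity = draws$intensity[k],
                 offset = draws$offset_mult[k] * draws$sigma_v[k],
                 sigma_a = draws$sigma_a[k], sigma_v = draws$sigma_v[k],
                 feedback = fb, M = M, V = V, A = A,
                 enhancement = response_enhancement(M, V, A),
                 response_additivity = response_additivity(M, V, A))
    }))
  })
  do.call(rbind, rows)
}
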