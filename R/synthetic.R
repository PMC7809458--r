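#' Define a synthetic seasonality scenario
#'
#' A scenario inverts the inference chain as a forward model: per-layer
#' seasonal temperature regimes are mapped through the inverse transfer
#' calibration to a sinusoidal enamel d18O signal along the tooth growth
#' axis, attenuated by the mineralization/drill-sampling averaging windows,
#' sampled at discrete positions, and perturbed with analytical noise.
#' Strontium ratios are drawn around a local baseline and collagen values
#' per layer, so every pipeline stage has structured input with known
#' truth.
#'
#' @param layers A tibble with one row per layer: `layer_id`, `T_warmest`,
#'   `T_coldest` (degrees C), `n_teeth`, `samples_per_tooth`.
#' @param cal A [transfer_calibration()] used both to generate and (by the
#'   pipeline under test) to invert.
#' @param lam_mm Annual-cycle wavelength along the growth axis, mm.
#' @param maturation_length,sample_length Averaging-window widths, mm
#'   (0 disables damping).
#' @param noise_sd Analytical noise sd on each enamel sample, permil
#'   (default 0.2, typical replicate reproducibility).
#' @param tooth_T_sd Between-tooth sd of the seasonal extreme temperatures
#'   within a layer, degrees C (inter-individual and inter-annual
#'   variability).
#' @param span_cycles Length-2 range; each tooth's sampled span in annual
#'   cycles is drawn uniformly from it.
#' @param n_nonsinusoidal Number of planted flat (non-seasonal) teeth.
#' @param sr_mean,sr_sd Enamel Sr baseline the local teeth are drawn from.
#' @param n_sr_teeth,sr_samples_per_tooth Size of the Sr subset.
#' @param n_migratory Number of Sr-subset teeth given nonlocal excursions.
#' @param migratory_offset Size of the migratory excursion (87Sr/86Sr).
#' @param collagen A tibble per layer: `layer_id`, `n`, `d13C_mean`,
#'   `d13C_sd`, `d15N_mean`, `d15N_sd`; or `NULL` for no collagen table.
#' @param seed Integer seed recorded in the scenario.
#' @return An object of class `"seasonal_scenario"`.
#' @seealso [paper_like_scenario()], [simulate_isotopes()]
#' @export
seasonal_scenario <- function(layers, cal, lam_mm = 35,
                              maturation_length = 12, sample_length = 1.5,
                              noise_sd = 0.2, tooth_T_sd = 0.9,
                              span_cycles = c(0.9, 1.4),
                              n_nonsinusoidal = 0,
                              sr_mean = 0.7104, sr_sd = 0.0003,
                              n_sr_teeth = 0, sr_samples_per_tooth = 2,
                              n_migratory = 0, migratory_offset = 0.004,
                              collagen = NULL, seed = 1L) {
  stopifnot(inherits(cal, "transfer_calibration"))
  req <- c("layer_id", "T_warmest", "T_coldest", "n_teeth",
           "samples_per_tooth")
  required_cols(layers, req, "scenario layers")
  if (any(layers$T_warmest < layers$T_coldest)) {
    stop_paleoseas("T_warmest must be >= T_coldest in every layer",
                   "paleoseas_config_error")
  }
  if (any(layers$n_teeth < 1)) {
    stop_paleoseas("each layer needs n_teeth >= 1",
                   "paleoseas_config_error")
  }
  assert_number(lam_mm, "lam_mm", lower = 1e-6)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(seed, "seed")
  structure(
    list(layers = as_tibble(layers), cal = cal, lam_mm = lam_mm,
         maturation_length = maturation_length,
         sample_length = sample_length, noise_sd = noise_sd,
         tooth_T_sd = tooth_T_sd, span_cycles = span_cycles,
         n_nonsinusoidal = n_nonsinusoidal,
         sr_mean = sr_mean, sr_sd = sr_sd, n_sr_teeth = n_sr_teeth,
         sr_samples_per_tooth = sr_samples_per_tooth,
         n_migratory = n_migratory, migratory_offset = migratory_offset,
         collagen = collagen, seed = as.integer(seed)),
    class = "seasonal_scenario"
  )
}

#' @export
print.seasonal_scenario <- function(x, ...) {
  cat(sprintf(
    "Seasonal scenario: %d layers, %d teeth, lambda = %.1f mm, noise %.2f permil, seed %d\n",
    nrow(x$layers), sum(x$layers$n_teeth), x$lam_mm, x$noise_sd, x$seed))
  print(x$layers)
  invisible(x)
}

#' A scenario mirroring a three-layer cave-site study design
#'
#' Thirteen teeth across layers 2, 5A and 5B (about 180 enamel samples),
#' one planted non-seasonal tooth, a seven-tooth Sr subset (about 15
#' measurements) around a 0.7104 +/- 0.0003 local signal, and 28 collagen
#' specimens across layers 1 through 5B. Winter temperatures are lowest in
#' Layer 2 with a slight cooling from 5A to 5B; all layer temperature
#' regimes sit near the modern southwest-France reference (July 20.5
#' degrees C, January 4.9 degrees C) with winters above freezing. With
#' `migratory = TRUE` one Sr-subset tooth is given nonlocal excursions.
#'
#' @param seed Integer seed.
#' @param migratory Plant one migratory tooth in the Sr table?
#' @return A [seasonal_scenario()].
#' @export
paper_like_scenario <- function(seed = 101L, migratory = FALSE) {
  layers <- tibble(
    layer_id = c("2", "5A", "5B"),
    T_warmest = c(21.5, 21.0, 20.5),
    T_coldest = c(1.5, 4.5, 3.5),
    n_teeth = c(5L, 4L, 4L),
    samples_per_tooth = c(14L, 14L, 14L)
  )
  collagen <- tibble(
    layer_id = c("1", "2", "3", "4", "5A", "5B"),
    n = c(4L, 6L, 4L, 4L, 5L, 5L),
    d13C_mean = c(-19.6, -19.2, -19.8, -20.0, -20.4, -20.2),
    d13C_sd = 0.3,
    d15N_mean = c(4.8, 5.6, 5.2, 5.0, 4.4, 4.6),
    d15N_sd = 0.4
  )
  seasonal_scenario(
    layers = layers, cal = example_calibration(),
    lam_mm = 35, maturation_length = 12, sample_length = 1.5,
    noise_sd = 0.2, tooth_T_sd = 0.9, span_cycles = c(0.9, 1.4),
    n_nonsinusoidal = 1,
    sr_mean = 0.7104, sr_sd = 0.0003,
    n_sr_teeth = 7, sr_samples_per_tooth = 2,
    n_migratory = if (migratory) 1 else 0,
    collagen = collagen, seed = seed
  )
}

#' Generate synthetic isotope tables from a scenario
#'
#' Runs the forward model of [seasonal_scenario()]: per tooth, the layer's
#' seasonal temperature sinusoid (with tooth-level jitter and a uniform
#' random birth phase) is mapped through the exact inverse of the transfer
#' calibration to a dense enamel d18O signal, attenuated with
#' [forward_convolve()], sampled at near-regular jittered positions, and
#' perturbed with Gaussian analytical noise. The truth table records every
#' generator parameter per tooth.
#'
#' @param scenario A [seasonal_scenario()].
#' @param seed Integer seed; defaults to the scenario's recorded seed. The
#'   caller's RNG state is untouched, and a fixed seed gives identical
#'   tables.
#' @return A list of tibbles: `enamel`, `sr`, `collagen`, `truth`, plus
#'   the `scenario`.
#' @export
simulate_isotopes <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "seasonal_scenario"))
  with_local_seed(seed, simulate_isotopes_impl(scenario))
}

simulate_isotopes_impl <- function(sc) {
  cal <- sc$cal
  pw <- stage_forward(cal$pw, "phosphate_to_water")
  wt <- stage_forward(cal$wt, "water_to_temperature")
  # temperature -> enamel d18O, exact affine inverse of the two stages
  t_to_enamel <- function(t_val) {
    dw <- (t_val - wt["b"]) / wt["a"]
    unname((dw - pw["b"]) / pw["a"])
  }
  delta_slope <- unname(1 / (wt["a"] * pw["a"]))  # permil enamel per deg C

  lam <- sc$lam_mm
  f <- if (sc$maturation_length + sc$sample_length > 0) {
    damping_factor(sc$maturation_length, sc$sample_length, lam)
  } else 1

  tooth_tbl <- sc$layers %>%
    tidyr::uncount(.data$n_teeth, .id = "tooth_num") %>%
    mutate(tooth_id = sprintf("%s-T%d", .data$layer_id, .data$tooth_num))
  n_teeth <- nrow(tooth_tbl)
  flat <- rep(FALSE, n_teeth)
  if (sc$n_nonsinusoidal > 0) {
    flat[seq_len(min(sc$n_nonsinusoidal, n_teeth))] <- TRUE
  }

  enamel <- vector("list", n_teeth)
  truth <- vector("list", n_teeth)
  for (i in seq_len(n_teeth)) {
    row <- tooth_tbl[i, ]
    t_warm <- row$T_warmest + rnorm(1, 0, sc$tooth_T_sd)
    t_cold <- row$T_coldest + rnorm(1, 0, sc$tooth_T_sd)
    if (t_cold > t_warm) {
      tmp <- t_warm; t_warm <- t_cold; t_cold <- tmp
    }
    Mp <- t_to_enamel((t_warm + t_cold) / 2)
    Ap <- if (flat[i]) 0 else abs(delta_slope) * (t_warm - t_cold) / 2
    phi <- runif(1, 0, 2 * pi)
    span <- runif(1, sc$span_cycles[1], sc$span_cycles[2]) * lam
    x0 <- runif(1, 3, 10)  # offset of the sampled window from the ERJ

    n_s <- row$samples_per_tooth
    pos <- seq(0, span, length.out = n_s)
    jit <- rnorm(n_s, 0, 0.05 * span / max(1, n_s - 1))
    pos <- sort(pmin(span, pmax(0, pos + jit)))
    # jitter must not collapse two drill positions onto each other
    pos <- pos + seq(0, 1e-6, length.out = n_s)

    if (sc$maturation_length + sc$sample_length > 0) {
      margin <- sc$maturation_length + sc$sample_length + lam / 50
      dx <- lam / 200
      grid <- seq(-margin, span + margin, by = dx)
      dense <- tibble(position_mm = grid,
                      value = Mp + Ap * sin(2 * pi * (grid + x0) / lam + phi))
      damped <- forward_convolve(dense, sc$maturation_length,
                                 sc$sample_length, lam = lam)
      clean <- stats::spline(damped$position_mm, damped$value,
                             xout = pos)$y
    } else {
      clean <- Mp + Ap * sin(2 * pi * (pos + x0) / lam + phi)
    }
    vals <- clean + rnorm(n_s, 0, sc$noise_sd)

    enamel[[i]] <- tibble(
      tooth_id = row$tooth_id, layer_id = row$layer_id,
      position_mm = x0 + pos, d18O = vals, replicate_sd = sc$noise_sd
    )
    truth[[i]] <- tibble(
      tooth_id = row$tooth_id, layer_id = row$layer_id,
      T_warmest_true = t_warm, T_coldest_true = t_cold,
      enamel_mean_true = Mp, enamel_amplitude_true = Ap,
      lam_true = lam, phase_true = phi, damping_f_true = f,
      span_mm = span, nonsinusoidal = flat[i]
    )
  }
  enamel <- bind_rows(enamel)
  truth <- bind_rows(truth)

  sr <- NULL
  if (sc$n_sr_teeth > 0) {
    # spread the Sr subset across layers, skipping planted flat teeth
    candidates <- tooth_tbl$tooth_id[!flat]
    pick <- candidates[round(seq(1, length(candidates),
                                 length.out = min(sc$n_sr_teeth,
                                                  length(candidates))))]
    migratory_ids <- head(pick, sc$n_migratory)
    sr <- purrr::map(pick, function(tid) {
      k <- sc$sr_samples_per_tooth + (match(tid, pick) == 1L)
      vals <- rnorm(k, sc$sr_mean, sc$sr_sd)
      if (tid %in% migratory_ids) {
        vals[seq(1, k, by = 2)] <- vals[seq(1, k, by = 2)] +
          sc$migratory_offset
      }
      tibble(tooth_id = tid,
             position_mm = seq(5, 5 + 10 * (k - 1), by = 10),
             sr_ratio = vals)
    }) %>% bind_rows()
    truth$migratory <- truth$tooth_id %in% migratory_ids
  }

  collagen <- NULL
  if (!is.null(sc$collagen)) {
    collagen <- sc$collagen %>%
      tidyr::uncount(.data$n, .id = "spec_num") %>%
      mutate(
        specimen_id = sprintf("C-%s-%d", .data$layer_id, .data$spec_num),
        d13C = rnorm(dplyr::n(), .data$d13C_mean, .data$d13C_sd),
        d15N = rnorm(dplyr::n(), .data$d15N_mean, .data$d15N_sd),
        pct_C = rnorm(dplyr::n(), 42, 2),
        pct_N = rnorm(dplyr::n(), 15, 1),
        CN_ratio = rnorm(dplyr::n(), 3.2, 0.12)
      ) %>%
      select("specimen_id", "layer_id", "d13C", "d15N", "pct_C", "pct_N",
             "CN_ratio")
  }

  list(enamel = enamel, sr = sr, collagen = collagen, truth = truth,
       scenario = sc)
}
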