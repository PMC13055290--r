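#' Simulate one closed-chamber concentration series
#'
#' Inverts the flux equation to the implied ppmv h^-1 slope and emits a
#' timed headspace series (0/15/30 min by default) with Gaussian vial noise.
#' The planted flux is recorded in the `truth` attribute.
#'
#' @param true_flux planted flux, mg CH4 m^-2 h^-1.
#' @param height_m chamber height, m.
#' @param temp_c in-chamber temperature, degC.
#' @param noise_sd_ppm vial-level Gaussian noise SD, ppmv.
#' @param seed RNG seed.
#' @param baseline_ppm ambient CH4 at closure (default 2 ppmv).
#' @param times_min sampling times, minutes.
#' @param constants see [gas_constants()].
#' @return Tibble `t_min`, `conc_ppm`, with attribute `truth` (list with
#'   `true_flux`, `slope_ppm_h`, `height_m`, `temp_c`, `seed`).
#' @export
gen_chamber_series <- function(true_flux, height_m = 1, temp_c = 25,
                               noise_sd_ppm = 0, seed = NULL,
                               baseline_ppm = 2, times_min = c(0, 15, 30),
                               constants = gas_constants()) {
  if (noise_sd_ppm < 0) abort("noise SD must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  slope <- true_flux / (constants$rho * height_m *
                          constants$kelvin_offset / (constants$kelvin_offset + temp_c))
  conc <- baseline_ppm + slope * times_min / 60 + rnorm(length(times_min), 0, noise_sd_ppm)
  out <- tibble::tibble(t_min = times_min, conc_ppm = conc)
  attr(out, "truth") <- list(generator = "gen_chamber_series", seed = seed,
                             true_flux = true_flux, slope_ppm_h = slope,
                             height_m = height_m, temp_c = temp_c)
  out
}

#' Simulate an ASV table under the Sloan neutral model
#'
#' Metacommunity relative abundances come from a long-tailed stick-breaking
#' distribution over `pool_size` taxa. Each sample draws per-taxon local
#' weights from Beta(Nm p, Nm (1 - p)) with `Nm = m * N_reads`, renormalises
#' them, and samples `N_reads` reads multinomially. The planted immigration
#' rate is recorded in the `truth` attribute.
#'
#' @param m immigration rate, in (0, 1).
#' @param N_reads reads per sample (>= 100).
#' @param n_samples number of samples.
#' @param pool_size metacommunity taxon pool size.
#' @param break_prop mean stick-breaking proportion controlling how
#'   long-tailed the metacommunity is (default 0.01).
#' @param seed RNG seed.
#' @return Count tibble with attribute `truth` (`m`, `Nm`, `N_reads`,
#'   `metacommunity_p`, `seed`).
#' @export
gen_neutral_community <- function(m, N_reads = 20000, n_samples = 28,
                                  pool_size = 1000, break_prop = 0.01,
                                  seed = NULL) {
  if (m <= 0 || m >= 1) abort("immigration rate m must lie in (0, 1)")
  if (N_reads < 100) abort("need at least 100 reads per sample")
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rbeta(pool_size, 1, 1 / break_prop - 1)
  p <- b * cumprod(c(1, 1 - b[-pool_size]))
  p <- p / sum(p)
  Nm <- m * N_reads
  counts <- t(vapply(seq_len(n_samples), function(s) {
    w <- stats::rbeta(pool_size, Nm * p, Nm * (1 - p))
    w[!is.finite(w)] <- 0
    if (sum(w) == 0) w <- p
    as.integer(rmultinom(1, N_reads, w))
  }, integer(pool_size)))
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("ASV", seq_len(pool_size)))
  out <- count_tibble(counts)
  attr(out, "truth") <- list(generator = "gen_neutral_community", seed = seed,
                             m = m, Nm = Nm, N_reads = N_reads,
                             metacommunity_p = p)
  out
}

#' Simulate a habitat-structured ASV table with planted specialists
#'
#' Background ASVs are Poisson-uniform across all habitats; each planted
#' specialist concentrates a fraction `effect` of its expected abundance in
#' one habitat (the remainder spread over the others) and is guaranteed
#' present in every replicate of that habitat. The planted list is recorded
#' in the `truth` attribute.
#'
#' @param n_habitats number of habitats (e.g. 4 sequenced treatments).
#' @param reps samples per habitat (>= 3).
#' @param n_specialists planted specialists per habitat.
#' @param n_background uniform background ASVs.
#' @param effect fraction of a specialist's abundance in its home habitat,
#'   in (0, 1].
#' @param base_lambda expected specialist reads in its home habitat.
#' @param bg_lambda expected background reads per ASV per sample.
#' @param seed RNG seed.
#' @return Count tibble plus `habitat` labels and planted truth in
#'   attributes `habitat` and `truth`.
#' @export
gen_habitat_community <- function(n_habitats = 4, reps = 7, n_specialists = 2,
                                  n_background = 30, effect = 1.0,
                                  base_lambda = 200, bg_lambda = 50,
                                  seed = NULL) {
  if (reps < 3) abort("need at least 3 replicates per habitat")
  if (effect <= 0 || effect > 1) abort("effect must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  habs <- paste0("H", seq_len(n_habitats))
  habitat <- rep(habs, each = reps)
  n_samp <- n_habitats * reps
  n_spec <- n_habitats * n_specialists
  spec_ids <- if (n_spec > 0) paste0("SPEC", seq_len(n_spec)) else character()
  home <- rep(habs, each = n_specialists)
  bg_ids <- if (n_background > 0) paste0("BG", seq_len(n_background)) else character()
  counts <- matrix(0, n_samp, n_spec + n_background,
                   dimnames = list(paste0("S", seq_len(n_samp)), c(spec_ids, bg_ids)))
  for (k in seq_len(n_spec)) {
    lam_focal <- effect * base_lambda
    lam_other <- (1 - effect) * base_lambda / (n_habitats - 1)
    for (h in habs) {
      rows <- which(habitat == h)
      lam <- if (h == home[k]) lam_focal else lam_other
      counts[rows, k] <- if (lam > 0) rpois(length(rows), lam) else 0
    }
    counts[habitat == home[k], k] <- pmax(counts[habitat == home[k], k], 1)
  }
  for (k in seq_along(bg_ids)) {
    counts[, n_spec + k] <- rpois(n_samp, bg_lambda)
  }
  out <- count_tibble(counts)
  attr(out, "habitat") <- setNames(habitat, rownames(counts))
  attr(out, "truth") <- list(generator = "gen_habitat_community", seed = seed,
                             specialists = tibble::tibble(asv_id = spec_ids, habitat = home),
                             effect = effect)
  out
}

season_flux_curve <- function(day, peak_flux = 15, peak_day = 30, width = 0.55) {
  # lognormal-shaped seasonal pulse, unit peak at peak_day
  shape <- exp(-(log(pmax(day, 0.5) / peak_day))^2 / (2 * width^2))
  peak_flux * shape
}

#' Simulate a vial-level field sheet for a mock rice season
#'
#' Study conditions mirror a 7-treatment x 4-replicate randomized paddy
#' trial: N rates 100/80/60/0% of conventional, with Fe-amended companions
#' at 80/60/0%. Each plot's true flux follows a lognormal-shaped seasonal
#' pulse peaking around day 30 (tillering flood), scaled by an N-rate factor
#' and by `1 + fe_effect` for Fe-amended plots, with plot-level lognormal
#' variability; every sampled date emits a 0/15/30-min chamber series with
#' vial noise. Truth (per-plot daily flux and cumulative emission) is
#' recorded.
#'
#' @param fe_effect multiplicative Fe amendment effect on flux (default
#'   -0.5, i.e. a 50% suppression; 0 for a null run).
#' @param reps replicates per treatment.
#' @param n_dates number of sampling dates across the 100-day season.
#' @param noise_sd_ppm vial noise SD, ppmv.
#' @param plot_cv plot-level lognormal coefficient of variation.
#' @param peak_flux peak of the baseline seasonal curve, mg m^-2 h^-1.
#' @param seed RNG seed.
#' @param transplant_date calendar date of transplanting.
#' @return Tibble field sheet (`plot_id`, `treatment`, `n_rate`, `fe`,
#'   `date`, `t_min`, `conc_ppm`, `chamber_height_m`, `temp_c`) with
#'   attribute `truth` (per-plot true fluxes and cumulative emissions).
#' @export
gen_field_season <- function(fe_effect = -0.5, reps = 4, n_dates = 10,
                             noise_sd_ppm = 0.05, plot_cv = 0.15,
                             peak_flux = 15, seed = NULL,
                             transplant_date = as.Date("2023-06-20")) {
  if (n_dates < 5) abort("need at least 5 sampling dates")
  if (!is.null(seed)) set.seed(seed)
  design <- tibble::tibble(
    treatment = c("100N", "80N", "60N", "0N", "80N+Fe", "60N+Fe", "0N+Fe"),
    n_rate = c(100, 80, 60, 0, 80, 60, 0),
    fe = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  days <- round(seq(5, 100, length.out = n_dates))
  plots <- design[rep(seq_len(nrow(design)), each = reps), ]
  plots$plot_id <- paste0(plots$treatment, "_R", rep(seq_len(reps), times = nrow(design)))
  # N effect: flux rises modestly with fertilisation rate
  plots$scale <- (0.7 + 0.3 * plots$n_rate / 100) *
    ifelse(plots$fe, 1 + fe_effect, 1) *
    rlnorm(nrow(plots), -0.5 * log(1 + plot_cv^2), sqrt(log(1 + plot_cv^2)))
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(plots))) {
    true_flux <- plots$scale[i] * season_flux_curve(days, peak_flux = peak_flux)
    for (k in seq_along(days)) {
      H <- round(runif(1, 0.6, 1.2), 2)
      Tc <- round(runif(1, 20, 32), 1)
      series <- gen_chamber_series(true_flux[k], height_m = H, temp_c = Tc,
                                   noise_sd_ppm = noise_sd_ppm)
      rows[[length(rows) + 1]] <- tibble::tibble(
        plot_id = plots$plot_id[i], treatment = plots$treatment[i],
        n_rate = plots$n_rate[i], fe = plots$fe[i],
        date = transplant_date + days[k],
        t_min = series$t_min, conc_ppm = series$conc_ppm,
        chamber_height_m = H, temp_c = Tc
      )
    }
    truths[[i]] <- tibble::tibble(
      plot_id = plots$plot_id[i], treatment = plots$treatment[i],
      true_cumulative_S = trapezoid_emission(transplant_date + days, true_flux),
      true_mean_flux = mean(true_flux)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(generator = "gen_field_season", seed = seed,
                             fe_effect = fe_effect,
                             per_plot = dplyr::bind_rows(truths))
  out
}

#' Simulate a qPCR run (standards plus unknowns)
#'
#' Cq values follow `Cq = intercept + slope * log10(copies)` with
#' `slope = -1 / log10(1 + efficiency)` and Gaussian Cq noise. Standards
#' cover the conventional 10^2-10^6 plasmid gradient; unknown samples carry
#' the planted copy numbers.
#'
#' @param true_copies named numeric vector of planted template copies per
#'   unknown sample (names become sample ids).
#' @param gene gene label written to the tables.
#' @param efficiency amplification efficiency as a fraction, in (0.7, 1.1].
#' @param cq_noise_sd Cq noise SD.
#' @param intercept Cq at a single template copy (default 38).
#' @param n_reps technical replicates per unknown.
#' @param seed RNG seed.
#' @return List with `standards` (gene, log10_copies, cq), `samples`
#'   (sample_id, gene, cq, rep, dilution_factor), and `truth`.
#' @export
gen_qpcr_run <- function(true_copies, gene = "mcrA", efficiency = 1.0,
                         cq_noise_sd = 0, intercept = 38, n_reps = 3,
                         seed = NULL) {
  if (efficiency <= 0.7 || efficiency > 1.1) abort("efficiency must lie in (0.7, 1.1]")
  if (!is.null(seed)) set.seed(seed)
  slope <- -1 / log10(1 + efficiency)
  lv <- 2:6
  standards <- tibble::tibble(
    gene = gene, log10_copies = lv,
    cq = intercept + slope * lv + rnorm(length(lv), 0, cq_noise_sd)
  )
  ids <- names(true_copies) %||% paste0("U", seq_along(true_copies))
  tc <- setNames(as.numeric(true_copies), ids)
  samples <- tidyr::expand_grid(sample_id = ids, rep = seq_len(n_reps)) |>
    dplyr::mutate(
      gene = gene,
      cq = intercept + slope * log10(tc[.data$sample_id]) +
        rnorm(dplyr::n(), 0, cq_noise_sd),
      dilution_factor = 1
    )
  list(standards = standards, samples = samples,
       truth = list(generator = "gen_qpcr_run", seed = seed,
                    true_copies = setNames(as.numeric(true_copies), ids),
                    efficiency = efficiency, slope = slope, intercept = intercept))
}
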