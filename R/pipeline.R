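pipeline_defaults <- function() {
  list(
    field_sheet = NULL, standards = NULL, qpcr_samples = NULL,
    asv_table = NULL, metadata = NULL, taxonomy = NULL, soil = NULL,
    out_dir = "ricemethane_out", seed = 1,
    rho = 0.717, temp_kelvin_offset = 273,
    slope_method = "ols", qc_r2 = NULL,
    habitat_col = "treatment", spec_occu_threshold = 0.7,
    ncm_reps = 1000, ncm_d = NULL,
    network_r_min = 0.6, network_p_max = 0.05, network_prevalence = 0.5,
    mantel_perms = 999, mantel_method = "spearman",
    soil_vars = NULL
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates flux -> qPCR -> community -> neutral model -> SPEC-OCCU ->
#' network -> Mantel over whichever inputs the configuration provides,
#' writing stage outputs (CSV/TSV/JSON) plus a machine-readable manifest to
#' the output directory. Unknown configuration keys are rejected; the
#' effective (defaults-merged) configuration is echoed alongside the
#' outputs. Deterministic under a fixed `seed`.
#'
#' @param config named list or path to a YAML/JSON configuration file. Keys:
#'   input paths (`field_sheet`, `standards`, `qpcr_samples`, `asv_table`,
#'   `metadata`, `taxonomy`, `soil`), `out_dir`, `seed`, and stage
#'   parameters (`rho`, `temp_kelvin_offset`, `slope_method`, `qc_r2`,
#'   `habitat_col`, `spec_occu_threshold`, `ncm_reps`, `ncm_d`,
#'   `network_r_min`, `network_p_max`, `network_prevalence`,
#'   `mantel_perms`, `mantel_method`, `soil_vars`).
#' @return Invisibly, the run manifest (list of stages with inputs, outputs
#'   and parameters), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$field_sheet) && is.null(cfg$asv_table) && is.null(cfg$standards)) {
    abort("config provides no inputs: need at least one of field_sheet, standards, asv_table")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  manifest <- list(seed = cfg$seed, stages = list())
  writeLines(yaml::as.yaml(cfg[!vapply(cfg, is.null, logical(1))]),
             file.path(cfg$out_dir, "config_effective.yml"))
  constants <- gas_constants(rho = cfg$rho, kelvin_offset = cfg$temp_kelvin_offset)
  log_stage <- function(name, inputs, outputs, params, n_records) {
    message(sprintf("[%s] %d records -> %s", name, n_records,
                    paste(basename(outputs), collapse = ", ")))
    manifest$stages[[name]] <<- list(inputs = inputs, outputs = outputs,
                                     parameters = params, n_records = n_records)
  }
  emissions <- NULL

  if (!is.null(cfg$field_sheet)) {
    fs <- readr::read_csv(cfg$field_sheet, show_col_types = FALSE)
    fluxes <- chamber_fluxes(fs, constants = constants,
                             slope_method = cfg$slope_method, qc_r2 = cfg$qc_r2)
    emissions <- cumulative_emission(fluxes)
    f1 <- file.path(cfg$out_dir, "fluxes.csv")
    f2 <- file.path(cfg$out_dir, "season_emissions.csv")
    readr::write_csv(fluxes, f1); readr::write_csv(emissions, f2)
    outs <- c(f1, f2)
    if ("treatment" %in% names(emissions) &&
        min(table(emissions$treatment)) >= 2 && length(unique(emissions$treatment)) >= 2) {
      an <- compare_treatments(
        dplyr::mutate(emissions,
                      n_rate = if ("n_rate" %in% names(fs)) fs$n_rate[match(emissions$plot_id, fs$plot_id)] else NA,
                      fe = if ("fe" %in% names(fs)) fs$fe[match(emissions$plot_id, fs$plot_id)] else NA),
        response = "cumulative_S",
        n_rate = if ("n_rate" %in% names(fs)) "n_rate",
        fe = if ("fe" %in% names(fs)) "fe"
      )
      f3 <- file.path(cfg$out_dir, "anova.json")
      jsonlite::write_json(list(oneway = an$oneway, twoway = an$twoway, tukey = an$tukey),
                           f3, auto_unbox = TRUE, digits = NA)
      outs <- c(outs, f3)
    }
    log_stage("flux", cfg$field_sheet, outs,
              cfg[c("rho", "temp_kelvin_offset", "slope_method")], nrow(fluxes))
  }

  if (!is.null(cfg$standards) && !is.null(cfg$qpcr_samples)) {
    stds <- readr::read_csv(cfg$standards, show_col_types = FALSE)
    smp <- readr::read_csv(cfg$qpcr_samples, show_col_types = FALSE)
    curves <- fit_standard_curves(stds)
    quants <- quantify_copies(smp, curves)
    f1 <- file.path(cfg$out_dir, "gene_copies.csv")
    readr::write_csv(quants, f1)
    outs <- f1
    genes <- unique(quants$gene)
    if (all(c("mcrA", "pmoA") %in% genes)) {
      f2 <- file.path(cfg$out_dir, "mcra_pmoa_ratio.csv")
      readr::write_csv(gene_ratio(quants, "mcrA", "pmoA"), f2)
      outs <- c(outs, f2)
    }
    log_stage("qpcr", c(cfg$standards, cfg$qpcr_samples), outs,
              list(curves = lapply(curves, glance)), nrow(quants))
  }

  if (!is.null(cfg$asv_table) && !is.null(cfg$metadata)) {
    counts <- read_asv_table(cfg$asv_table)
    counts <- filter_singletons(counts)
    meta <- readr::read_tsv(cfg$metadata, show_col_types = FALSE)
    habitat <- setNames(as.character(meta[[cfg$habitat_col]]), meta$sample_id)
    f_rel <- file.path(cfg$out_dir, "relative_abundance.tsv")
    readr::write_tsv(to_relative(counts), f_rel)
    f_div <- file.path(cfg$out_dir, "alpha_diversity.tsv")
    readr::write_tsv(alpha_diversity(counts), f_div)
    bc <- bray_curtis(counts)
    f_bc <- file.path(cfg$out_dir, "bray_curtis.tsv")
    readr::write_tsv(tibble::as_tibble(bc, rownames = "sample_id"), f_bc)
    f_venn <- file.path(cfg$out_dir, "core_asvs.json")
    jsonlite::write_json(core_asvs(counts, habitat), f_venn, auto_unbox = TRUE, digits = NA)
    outs <- c(f_rel, f_div, f_bc, f_venn)
    if (!is.null(cfg$taxonomy)) {
      tax <- readr::read_tsv(cfg$taxonomy, show_col_types = FALSE)
      f_tax <- file.path(cfg$out_dir, "phylum_abundance.tsv")
      readr::write_tsv(aggregate_taxonomy(counts, tax, "phylum"), f_tax)
      outs <- c(outs, f_tax)
    }
    log_stage("community", cfg$asv_table, outs, list(habitat_col = cfg$habitat_col),
              nrow(counts))

    fit <- ncm_fit(counts, d = cfg$ncm_d)
    fit <- ncm_bootstrap(fit, reps = cfg$ncm_reps, seed = cfg$seed)
    f_ncm <- file.path(cfg$out_dir, "ncm_fit.json")
    jsonlite::write_json(glance(fit), f_ncm, auto_unbox = TRUE, digits = NA)
    f_ncm2 <- file.path(cfg$out_dir, "ncm_per_asv.tsv")
    readr::write_tsv(tidy(fit), f_ncm2)
    log_stage("ncm", cfg$asv_table, c(f_ncm, f_ncm2),
              list(reps = cfg$ncm_reps, d = fit$d), nrow(fit$stats))

    scores <- spec_occu(counts, habitat, threshold = cfg$spec_occu_threshold)
    f_so <- file.path(cfg$out_dir, "spec_occu.tsv")
    readr::write_tsv(scores, f_so)
    f_sp <- file.path(cfg$out_dir, "specialists.json")
    jsonlite::write_json(dplyr::filter(scores, .data$specialist), f_sp,
                         auto_unbox = TRUE, digits = NA)
    log_stage("spec_occu", cfg$asv_table, c(f_so, f_sp),
              list(threshold = cfg$spec_occu_threshold), nrow(scores))

    cors <- correlation_matrix(counts, prevalence_min = cfg$network_prevalence)
    net <- build_network(cors, r_min = cfg$network_r_min, p_max = cfg$network_p_max)
    mets <- network_metrics(net)
    f_e <- file.path(cfg$out_dir, "network_edges.tsv")
    readr::write_tsv(net$edges, f_e)
    f_m <- file.path(cfg$out_dir, "network_metrics.json")
    jsonlite::write_json(mets$summary, f_m, auto_unbox = TRUE, digits = NA)
    outs <- c(f_e, f_m)
    if (!is.null(emissions) && "plot_id" %in% names(meta)) {
      mac <- module_abundance_correlation(net, counts, emissions,
                                          setNames(as.character(meta$plot_id), meta$sample_id))
      f_mac <- file.path(cfg$out_dir, "module_emission_correlation.tsv")
      readr::write_tsv(mac, f_mac)
      outs <- c(outs, f_mac)
    }
    log_stage("network", cfg$asv_table, outs,
              cfg[c("network_r_min", "network_p_max", "network_prevalence")],
              nrow(net$edges))

    if (!is.null(cfg$soil)) {
      soil <- readr::read_tsv(cfg$soil, show_col_types = FALSE)
      dsoil <- property_distance(soil, variables = cfg$soil_vars)
      common <- intersect(rownames(bc), rownames(dsoil))
      mt <- mantel_test(bc[common, common], dsoil[common, common],
                        n_perm = cfg$mantel_perms, method = cfg$mantel_method,
                        seed = cfg$seed)
      f_mt <- file.path(cfg$out_dir, "mantel.json")
      jsonlite::write_json(glance(mt), f_mt, auto_unbox = TRUE, digits = NA)
      log_stage("mantel", cfg$soil, f_mt,
                list(perms = cfg$mantel_perms, method = cfg$mantel_method),
                length(common))
    }
  }

  f_man <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
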