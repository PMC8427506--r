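#' Pipeline configuration
#'
#' Bundles every constant of the analysis with the simulation settings.
#' Defaults equal the operational constants used throughout the package
#' (dV/dt threshold 30 V/s, burst ISI bound 10 ms, event gate 6-100 pA,
#' QC bounds 30 MOhm / -60 mV); any override is recorded in the run
#' manifest through the config hash.
#'
#' @param n_per_class_per_genotype Simulated cells per class per genotype.
#' @param seed Master seed.
#' @param effect_spec Genotype effect offsets passed to [make_cohort()].
#' @param noise_sd Current-noise SD (pA).
#' @param sepsc Simulate and analyze sEPSC traces.
#' @param sepsc_duration_s Gap-free sEPSC duration (s).
#' @param step_range f-I step range (pA) used by the mixed ANOVA.
#' @param detection_criterion Template-search threshold.
#' @param qc [qc_rule()] bounds.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class_per_genotype = 5, seed = 1L,
                            effect_spec = list(AS = list(e_l_mv = -1.5, g_l_ns = 0.25)),
                            noise_sd = 5, sepsc = FALSE,
                            sepsc_duration_s = 30,
                            step_range = c(50, 300),
                            detection_criterion = 3.0,
                            qc = qc_rule()) {
  structure(list(n_per_class_per_genotype = n_per_class_per_genotype,
                 seed = as.integer(seed), effect_spec = effect_spec,
                 noise_sd = noise_sd, sepsc = sepsc,
                 sepsc_duration_s = sepsc_duration_s,
                 step_range = step_range,
                 detection_criterion = detection_criterion,
                 qc = unclass(qc)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulate -> QC -> classify -> features -> (events) -> statistics.
#' Writes `features.csv`, `labels.csv`, `distribution.csv`, `chisq.csv`,
#' `ttests.csv`, `fi_anova.csv`, optionally `events.csv`, and a
#' `manifest.json` with the config, its hash and the QC exclusions.
#' Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `features`, `labels`, `distribution`,
#'   `chisq`, `ttests`, `fi_anova`, `events`, `qc_report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- make_cohort(config$n_per_class_per_genotype,
                        effect_spec = config$effect_spec,
                        seed = config$seed, noise_sd = config$noise_sd,
                        sepsc = config$sepsc,
                        sepsc_duration_s = config$sepsc_duration_s)
  cohort <- apply_qc_cohort(cohort, qc_rule(config$qc$max_series_resistance_mohm,
                                            config$qc$max_rmp_mv))
  qc_report <- attr(cohort, "qc_report")
  keep <- vapply(cohort, `[[`, TRUE, "qc_pass")
  features <- extract_features_cohort(cohort[keep])
  labels <- features[, c("cell_id", "genotype", "class")]
  names(labels)[3] <- "label"
  dist_tab <- distribution_table(labels)
  counts <- function(g) {
    sub <- dist_tab[dist_tab$genotype == g, ]
    stats::setNames(sub$n, sub$class)
  }
  chisq <- chisq_distribution(counts("WT"), counts("AS"))
  # per-class genotype comparisons of the scalar features
  measures <- c("max_rate_150pa_hz", "input_resistance_mohm", "mahp_mv",
                "rmp_mv", "threshold_mv", "rheobase_pa", "amplitude_mv",
                "half_width_ms", "isi_ratio")
  ttests <- list()
  fi_anova <- list()
  fi_cols <- grep("^fi_", names(features), value = TRUE)
  fi_steps <- as.numeric(sub("^fi_([0-9]+)pa_hz$", "\\1", fi_cols))
  use_fi <- fi_cols[fi_steps >= config$step_range[1] &
                      fi_steps <= config$step_range[2]]
  for (cl in c("SB", "WB", "RF")) {
    sub <- features[!is.na(features$class) & features$class == cl, ]
    if (min(table(sub$genotype)) < 2 || length(unique(sub$genotype)) < 2) next
    for (m in measures) {
      tt <- tryCatch(ttest_unpaired(sub[[m]][sub$genotype == "WT"],
                                    sub[[m]][sub$genotype == "AS"]),
                     error = function(e) NULL)
      if (is.null(tt)) next
      ttests[[length(ttests) + 1L]] <-
        data.frame(class = cl, measure = m, t = tt$t, df = tt$df, p = tt$p,
                   mean_wt = tt$mean[1], mean_as = tt$mean[2],
                   n_wt = tt$n[1], n_as = tt$n[2],
                   significant = !is.na(tt$p) & tt$p < 0.05)
    }
    an <- tryCatch(anova2_rm(sub[, use_fi], sub$genotype),
                   error = function(e) NULL)
    if (!is.null(an))
      fi_anova[[length(fi_anova) + 1L]] <-
        data.frame(class = cl,
                   effect = c("genotype", "interaction"),
                   F = c(an$genotype$F, an$interaction$F),
                   df1 = c(an$genotype$df1, an$interaction$df1),
                   df2 = c(an$genotype$df2, an$interaction$df2),
                   p = c(an$genotype$p, an$interaction$p))
  }
  ttests <- do.call(rbind, ttests)
  fi_anova <- do.call(rbind, fi_anova)
  events <- NULL
  if (config$sepsc) {
    events <- do.call(rbind, lapply(cohort[keep], function(rec) {
      sw <- rec$sweeps$sepsc_gapfree[[1]]
      ev <- gate_events(detect_events(sw, criterion = config$detection_criterion))
      sm <- summarize_events(ev)
      data.frame(cell_id = rec$cell_id, genotype = rec$genotype,
                 class = NA_character_, n_events = length(ev$amplitudes_pa),
                 mean_amplitude_pa = sm$mean_amplitude_pa,
                 frequency_hz = sm$frequency_hz)
    }))
    events$class <- labels$label[match(events$cell_id, labels$cell_id)]
  }
  manifest <- list(package_version = as.character(utils::packageVersion("subispike")),
                   config = unclass(config),
                   config_hash = .config_hash(config),
                   n_cells = length(cohort),
                   n_excluded = sum(!keep),
                   exclusions = qc_report[!qc_report$qc_pass, , drop = FALSE])
  res <- list(features = features, labels = labels, distribution = dist_tab,
              chisq = chisq, ttests = ttests, fi_anova = fi_anova,
              events = events, qc_report = qc_report, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    write.csv(dist_tab, file.path(out_dir, "distribution.csv"), row.names = FALSE)
    write.csv(chisq, file.path(out_dir, "chisq.csv"), row.names = FALSE)
    if (!is.null(ttests))
      write.csv(ttests, file.path(out_dir, "ttests.csv"), row.names = FALSE)
    if (!is.null(fi_anova))
      write.csv(fi_anova, file.path(out_dir, "fi_anova.csv"), row.names = FALSE)
    if (!is.null(events))
      write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(res)
}

# Stable hash of the configuration: serialize to canonical JSON, then md5.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
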