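# End-to-end orchestration: simulate (or read) -> filter -> diversity /
# similarity -> SHM networks -> cohort statistics -> survival, with a
# machine-readable run manifest. Every stage output is a pure function of
# (inputs, config, seed); rerunning an identical configuration reproduces
# identical files.

#' Assemble a pipeline run configuration
#'
#' @param input_dir directory of AIRR TSVs named
#'   `<patient>_<tissue>_<chain>.tsv` plus `clinical.csv` (and optionally
#'   `covariates.tsv`); mutually exclusive with `simulation`.
#' @param simulation a [sim_config()] to generate inputs on the fly.
#' @param out_dir output directory.
#' @param levels feature levels to compute.
#' @param run_survival fit median-split survival curves per endpoint.
#' @param survival_feature cohort column used for stratification; default
#'   picks tumor IGH (or first-chain) CDR3aa NSDE.
#' @param endpoints survival endpoints to fit.
#' @param bh apply Benjamini-Hochberg adjustment to the comparison table.
#' @param max_aa_dist SHM network edge threshold, see [build_network()].
#' @param seed master seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulation = NULL, out_dir,
                       levels = c("CDR3aa", "VDJ"), run_survival = TRUE,
                       survival_feature = NULL,
                       endpoints = c("PFS", "RFS", "OS"), bh = FALSE,
                       max_aa_dist = 1, seed = 1) {
  if (is.null(input_dir) == is.null(simulation))
    stopf("exactly one of input_dir or simulation must be given")
  structure(list(input_dir = input_dir, simulation = simulation,
                 out_dir = out_dir, levels = levels,
                 run_survival = run_survival,
                 survival_feature = survival_feature,
                 endpoints = endpoints, bh = bh,
                 max_aa_dist = max_aa_dist, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

read_cohort_dir <- function(dir) {
  reps <- list.files(dir, pattern = "^.+_(tumor|non_tumor)_[A-Z]+\\.tsv$",
                     full.names = TRUE)
  if (!length(reps)) stopf("no repertoire TSVs found in %s", dir)
  samples <- lapply(reps, function(f) {
    parts <- regmatches(basename(f),
                        regexec("^(.+?)_(non_tumor|tumor)_([A-Z]+)\\.tsv$",
                                basename(f)))[[1]]
    repertoire_sample(parts[2], parts[3], parts[4], read_airr_table(f))
  })
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stopf("clinical file not found: %s", clin_path)
  cov_path <- file.path(dir, "covariates.tsv")
  covariates <- if (file.exists(cov_path))
    utils::read.delim(cov_path, stringsAsFactors = FALSE) else NULL
  list(samples = samples, clinical = read_clinical(clin_path),
       covariates = covariates)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  close(con)
  path
}

#' Run the full repertoire analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or directory read),
#' productive filtering, per-sample diversity features, paired tumor /
#' non-tumor Morisita-Horn similarity, SHM network statistics (IGH),
#' cohort assembly with paired tumor-vs-non-tumor and early-vs-advanced
#' comparisons, and median-split survival stratification. Writes
#' `features.tsv`, `mhsi.tsv`, `comparisons.tsv`, `survival_curves.tsv`
#' and `run_manifest.json` (config echo, seed, per-stage row counts, file
#' checksums) under `out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, the run report: per-stage status and row counts,
#'   result tables, and the manifest path.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list())
  note <- function(name, rows) report$stages[[name]] <<- list(status = "ok",
                                                              rows = rows)
  inputs <- stage("input", {
    if (!is.null(config$simulation)) {
      sim_dir <- file.path(config$out_dir, "simulated_input")
      simulate_cohort(config$simulation, sim_dir)
      read_cohort_dir(sim_dir)
    } else read_cohort_dir(config$input_dir)
  })
  note("input", length(inputs$samples))

  samples <- stage("filter", lapply(inputs$samples, function(s) {
    repertoire_sample(s$patient_id, s$tissue, s$chain,
                      filter_productive(s$clonotypes))
  }))
  note("filter", sum(vapply(samples, function(s) nrow(s$clonotypes),
                            integer(1))))

  features <- stage("diversity", diversity_features(samples, config$levels))
  note("diversity", nrow(features))

  mhsi_tab <- stage("similarity", {
    rows <- list()
    key <- vapply(samples, function(s) paste(s$patient_id, s$chain),
                  character(1))
    for (k in unique(key)) {
      grp <- samples[key == k]
      tis <- vapply(grp, `[[`, character(1), "tissue")
      if (!all(c("tumor", "non_tumor") %in% tis)) next
      tum <- grp[[match("tumor", tis)]]; non <- grp[[match("non_tumor", tis)]]
      if (nrow(tum$clonotypes) == 0 || nrow(non$clonotypes) == 0) next
      for (lev in config$levels) {
        mh <- morisita_horn(collapse_profile(tum, lev),
                            collapse_profile(non, lev))
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = tum$patient_id, chain = tum$chain, level = lev,
          mhsi = mh$mhsi, n_shared_labels = mh$n_shared_labels,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows) %||% data.frame()
  })
  note("similarity", nrow(mhsi_tab))

  shm_tab <- stage("shm", shm_features(samples,
                                       max_aa_dist = config$max_aa_dist))
  note("shm", nrow(shm_tab))

  cohort <- stage("cohort", {
    mhsi_long <- if (nrow(mhsi_tab)) data.frame(
      patient_id = mhsi_tab$patient_id, tissue = "pair",
      chain = mhsi_tab$chain, isotype_view = "all", level = mhsi_tab$level,
      metric = "mhsi", value = mhsi_tab$mhsi, stringsAsFactors = FALSE)
      else data.frame()
    cohort_table(rbind(features, shm_tab, mhsi_long), inputs$clinical,
                 inputs$covariates)
  })
  note("cohort", nrow(cohort))

  comparisons <- stage("comparisons", {
    rows <- list()
    long <- rbind(features, shm_tab)
    num_feats <- unique(paste(long$chain, long$isotype_view,
                              long$level, long$metric, sep = "_"))
    for (f in num_feats) {
      # columns are chain_iso_tissue_level_metric; rebuild both tissues
      parts <- strsplit(f, "_")[[1]]
      base <- function(tissue) paste(c(parts[1], parts[2], tissue,
                                       parts[3:length(parts)]), collapse = "_")
      ct <- base("tumor"); cn <- base("non_tumor")
      if (!all(c(ct, cn) %in% names(cohort))) next
      x <- cohort[[ct]]; y <- cohort[[cn]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(x[ok] != y[ok]) < 3) next
      res <- paired_wilcoxon(x[ok], y[ok])
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, comparison = "tumor_vs_non_tumor",
        statistic = res$statistic, p = res$p_value, n = res$n,
        method = res$method, stringsAsFactors = FALSE)
      if ("stage_group" %in% names(cohort)) {
        grp <- cohort$stage_group
        a <- x[ok & grp == "early"]; b <- x[ok & grp == "advanced"]
        if (length(a) >= 2 && length(b) >= 2) {
          res2 <- mann_whitney(a, b)
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, comparison = "early_vs_advanced_tumor",
            statistic = res2$statistic, p = res2$p_value, n = res2$n,
            method = res2$method, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows) %||%
      data.frame(feature = character(0), comparison = character(0),
                 statistic = numeric(0), p = numeric(0), n = integer(0),
                 method = character(0))
    out$q <- if (config$bh && nrow(out)) adjust_bh(out$p) else NA_real_
    out
  })
  note("comparisons", nrow(comparisons))

  surv_tab <- data.frame()
  surv_tests <- list()
  if (config$run_survival) {
    surv_tab <- stage("survival", {
      if (!all(c("os_months", "os_event") %in% names(cohort)))
        stopf("clinical data lacks survival columns")
      feat <- config$survival_feature
      if (is.null(feat)) {
        cand <- grep("_all_tumor_CDR3aa_nsde$", names(cohort), value = TRUE)
        cand <- c(grep("^IGH", cand, value = TRUE), cand)
        if (!length(cand)) stopf("no NSDE feature available for stratification")
        feat <- cand[1]
      }
      rows <- list()
      for (ep in config$endpoints) {
        km <- km_logrank(cohort, feat, ep)
        surv_tests[[ep]] <- km$test
        for (g in c("low", "high")) {
          cv <- km[[g]]
          if (is.null(cv)) next
          rows[[length(rows) + 1]] <- data.frame(
            endpoint = ep, feature = feat, group = g, times = cv$times,
            survival = cv$survival, at_risk = cv$at_risk,
            p_logrank = km$test$p_value, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows) %||% data.frame()
    })
    note("survival", nrow(surv_tab))
  }

  paths <- c(features = write_tsv(rbind(features, shm_tab),
                                  file.path(config$out_dir, "features.tsv")),
             mhsi = write_tsv(mhsi_tab, file.path(config$out_dir, "mhsi.tsv")),
             comparisons = write_tsv(comparisons,
                                     file.path(config$out_dir,
                                               "comparisons.tsv")),
             survival = write_tsv(surv_tab,
                                  file.path(config$out_dir,
                                            "survival_curves.tsv")))
  manifest <- list(
    seed = config$seed,
    levels = config$levels,
    endpoints = config$endpoints,
    bh = config$bh,
    max_aa_dist = config$max_aa_dist,
    stages = report$stages,
    outputs = as.list(tools::md5sum(unname(paths))))
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$outputs <- paths
  report$manifest_path <- manifest_path
  report$cohort <- cohort
  report$comparisons <- comparisons
  report$survival_tests <- surv_tests
  class(report) <- "repsig_run"
  invisible(report)
}

#' @export
print.repsig_run <- function(x, ...) {
  cat("<repsig_run>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s (%d rows)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$rows))
  cat("  manifest:", x$manifest_path, "\n")
  invisible(x)
}
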