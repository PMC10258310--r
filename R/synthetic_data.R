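# Deterministic paired tumor / non-tumor repertoire simulator with ground
# truth, used both as test scaffolding and as a power-analysis tool.
#
# Clone labels are drawn by V(D)J recombination from per-chain segment
# pools; clone abundances follow a Zipf (power-law) rank-size law, the
# canonical repertoire clone-size model. Sharing between paired tissues is
# implemented at the label level with rank alignment, so the Morisita-Horn
# index of a pair responds to both support overlap and abundance
# correlation. All randomness flows from one master seed through string-
# keyed substreams, so adding patients or chains never perturbs the draws
# of existing samples.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed sense codon per amino acid (no stop codons)
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              `*` = "TAA")

aa_to_nt <- function(aa) {
  paste(CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
}

#' Default V/D/J segment pools per chain
#'
#' Each chain maps to V, D and J label vectors with usage probabilities
#' (normalized 1/rank weights). Chains without a D segment use the empty
#' label with probability 1.
#'
#' @return named list of per-chain pools.
#' @export
default_segment_pools <- function() {
  mk <- function(labels) {
    w <- 1 / seq_along(labels)
    list(labels = labels, probs = w / sum(w))
  }
  no_d <- list(labels = "", probs = 1)
  list(
    TRA = list(V = mk(paste0("TRAV", 1:8)), D = no_d,
               J = mk(paste0("TRAJ", c(4, 9, 23, 33, 42, 49)))),
    TRB = list(V = mk(c("TRBV2", "TRBV5-1", "TRBV6-1", "TRBV7-9", "TRBV19",
                        "TRBV20-1", "TRBV28", "TRBV30")),
               D = mk(c("TRBD1", "TRBD2")),
               J = mk(c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3",
                        "TRBJ2-5", "TRBJ2-7"))),
    TRG = list(V = mk(paste0("TRGV", c(2, 4, 8, 9))), D = no_d,
               J = mk(c("TRGJ1", "TRGJP1", "TRGJ2"))),
    TRD = list(V = mk(paste0("TRDV", 1:3)),
               D = mk(c("TRDD2", "TRDD3")),
               J = mk(paste0("TRDJ", 1:4))),
    IGH = list(V = mk(c("IGHV1-2", "IGHV1-69", "IGHV3-7", "IGHV3-23",
                        "IGHV3-30", "IGHV4-34", "IGHV4-39", "IGHV5-51")),
               D = mk(c("IGHD2-2", "IGHD3-10", "IGHD3-22", "IGHD6-19")),
               J = mk(c("IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6")))
  )
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Clinical category
#' frequencies default to the printed cohort composition of the study this
#' pipeline targets (64 patients: 55 male, age bands 11/39/14, 33 advanced,
#' 35 recurrence / 5 unknown); survival is exponential with median overall
#' survival 60 months and independent exponential censoring (median 96
#' months), and the stratifying repertoire feature multiplies the hazard by
#' `feature_hazard_ratio` in the above-median group.
#'
#' @param n_patients number of patients.
#' @param chains chains to simulate, subset of TRA/TRB/TRG/TRD/IGH.
#' @param clones_per_sample clones per repertoire sample (S).
#' @param reads_per_sample total read mass distributed over clones.
#' @param zipf_alpha named vector `c(tumor=, non_tumor=)` of Zipf skew
#'   exponents (larger = more clonal).
#' @param shared_fraction expected fraction of tumor clones sharing labels
#'   with the paired non-tumor sample, in [0, 1].
#' @param segment_pools per-chain V/D/J pools, see
#'   [default_segment_pools()].
#' @param cdr3_lengths,cdr3_length_probs discrete CDR3aa length
#'   distribution (lengths >= 4).
#' @param nonproductive_rate fraction of extra nonproductive clones
#'   injected per sample to exercise the productive filter.
#' @param abundance_noise `"none"` (deterministic Zipf masses) or
#'   `"multinomial"` (resampled read counts).
#' @param shm list: `mutation_prob` (per-clone probability of being
#'   mutated), `lineage_geom_p` (geometric lineage-size parameter; 1 =
#'   founders only), `mismatch_lambda` (Poisson extra V mismatches).
#' @param isotype_probs probabilities over IgA/IgG/IgM.
#' @param clinical list: `male_prob`, `age_band_probs`,
#'   `stage_advanced_prob`, `recurrence_probs` (yes/no/unknown),
#'   `os_rate`, `censor_rate`, `feature_hazard_ratio`,
#'   `covariate_cor` (target correlation of the immune-score covariate
#'   with IGH richness).
#' @param seed master integer seed.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 8,
                       chains = c("TRB", "IGH"),
                       clones_per_sample = 500,
                       reads_per_sample = 20 * clones_per_sample,
                       zipf_alpha = c(tumor = 1.2, non_tumor = 1.0),
                       shared_fraction = 0.3,
                       segment_pools = default_segment_pools(),
                       cdr3_lengths = 8:20,
                       cdr3_length_probs = stats::dnorm(8:20, 14, 2.5),
                       nonproductive_rate = 0.05,
                       abundance_noise = c("none", "multinomial"),
                       shm = list(mutation_prob = 0.5, lineage_geom_p = 0.5,
                                  mismatch_lambda = 3),
                       isotype_probs = c(IgA = 0.3, IgG = 0.4, IgM = 0.3),
                       clinical = list(),
                       seed = 1) {
  abundance_noise <- match.arg(abundance_noise)
  chains <- match.arg(chains, VALID_CHAINS, several.ok = TRUE)
  stopifnot(n_patients >= 1, clones_per_sample >= 1,
            all(zipf_alpha > 0), shared_fraction >= 0, shared_fraction <= 1,
            all(cdr3_lengths >= 4), nonproductive_rate >= 0,
            shm$mutation_prob >= 0, shm$mutation_prob <= 1,
            shm$lineage_geom_p > 0, shm$lineage_geom_p <= 1)
  if (abs(sum(isotype_probs) - 1) > 1e-9)
    stopf("isotype_probs must sum to 1")
  clin_defaults <- list(
    male_prob = 55 / 64,
    age_band_probs = c(`<40` = 11, `40-60` = 39, `>60` = 14) / 64,
    stage_advanced_prob = 33 / 64,
    recurrence_probs = c(yes = 35, no = 24, unknown = 5) / 64,
    os_rate = log(2) / 60, censor_rate = log(2) / 96,
    feature_hazard_ratio = 0.4,
    covariate_cor = 0.6)
  clinical <- utils::modifyList(clin_defaults, clinical)
  structure(list(n_patients = n_patients, chains = chains,
                 clones_per_sample = clones_per_sample,
                 reads_per_sample = reads_per_sample,
                 zipf_alpha = zipf_alpha, shared_fraction = shared_fraction,
                 segment_pools = segment_pools,
                 cdr3_lengths = cdr3_lengths,
                 cdr3_length_probs = cdr3_length_probs / sum(cdr3_length_probs),
                 nonproductive_rate = nonproductive_rate,
                 abundance_noise = abundance_noise,
                 shm = shm, isotype_probs = isotype_probs,
                 clinical = clinical, seed = as.integer(seed)),
            class = "sim_config")
}

zipf_counts <- function(s, alpha, total, noise = "none") {
  p <- seq_len(s)^(-alpha)
  p <- p / sum(p)
  if (noise == "multinomial") {
    cnt <- as.integer(stats::rmultinom(1, total, p))
    pmax(1L, cnt)
  } else {
    pmax(1L, as.integer(round(total * p)))
  }
}

random_cdr3 <- function(len, taken) {
  repeat {
    aa <- paste0("C", paste(sample(AA20, len - 1, replace = TRUE),
                            collapse = ""))
    if (!aa %in% taken) return(aa)
  }
}

gen_clones <- function(config, chain, n, taken = character(0)) {
  pool <- config$segment_pools[[chain]]
  lens <- sample(config$cdr3_lengths, n, replace = TRUE,
                 prob = config$cdr3_length_probs)
  aa <- character(n)
  for (i in seq_len(n)) {
    aa[i] <- random_cdr3(lens[i], taken)
    taken <- c(taken, aa[i])
  }
  data.frame(
    cdr3_aa = aa,
    cdr3_nt = vapply(aa, aa_to_nt, character(1), USE.NAMES = FALSE),
    v_call = sample(pool$V$labels, n, replace = TRUE, prob = pool$V$probs),
    d_call = sample(pool$D$labels, n, replace = TRUE, prob = pool$D$probs),
    j_call = sample(pool$J$labels, n, replace = TRUE, prob = pool$J$probs),
    stringsAsFactors = FALSE)
}

# Extra clones violating one productive rule each (stop codon, off-frame,
# short CDR3), cycled; returns a clonotype-column data.frame.
gen_nonproductive <- function(config, chain, n, taken) {
  if (n == 0) return(NULL)
  kind <- rep(c("stop", "offframe", "short"), length.out = n)
  base <- gen_clones(config, chain, n, taken)
  for (i in seq_len(n)) {
    if (kind[i] == "stop") {
      aa <- base$cdr3_aa[i]
      pos <- sample(2:nchar(aa), 1)
      substr(aa, pos, pos) <- "*"
      base$cdr3_aa[i] <- aa
      base$cdr3_nt[i] <- aa_to_nt(aa)
    } else if (kind[i] == "offframe") {
      base$cdr3_nt[i] <- paste0(base$cdr3_nt[i], "A")
      base$cdr3_aa[i] <- ""
    } else {
      aa <- substr(base$cdr3_aa[i], 1, 3)
      base$cdr3_aa[i] <- aa
      base$cdr3_nt[i] <- aa_to_nt(aa)
    }
  }
  base
}

#' Simulate one paired tumor / non-tumor repertoire
#'
#' Draws the non-tumor sample first, then the tumor sample. A nested random
#' subset of `round(shared_fraction * S)` clone ranks copies the non-tumor
#' clone identity (CDR3 and gene calls) at the same abundance rank, so the
#' shared sets for increasing `shared_fraction` are nested under a fixed
#' seed; non-shared tumor clones are rejection-sampled to be disjoint from
#' the non-tumor label space. Nonproductive clones (stop codon, off-frame,
#' short CDR3) are appended at the configured rate and recorded in the
#' ground truth.
#'
#' @param config `sim_config`.
#' @param patient_id patient identifier string.
#' @param chain chain to simulate (defaults to the config's first chain).
#' @return list with `tumor` and `non_tumor` (`repertoire_sample`s,
#'   unfiltered) and `truth` (shared labels, nonproductive ids, parameters).
#' @export
simulate_pair <- function(config, patient_id, chain = config$chains[1]) {
  s <- config$clones_per_sample
  n_shared <- round(config$shared_fraction * s)
  if (s == 0 && config$shared_fraction > 0)
    stopf("shared_fraction > 0 requires clones_per_sample > 0")
  n_bad <- round(config$nonproductive_rate * s)

  nt <- with_substream(config$seed, c(patient_id, chain, "non_tumor"), {
    cl <- gen_clones(config, chain, s)
    bad <- gen_nonproductive(config, chain, n_bad, cl$cdr3_aa)
    list(cl = cl, bad = bad,
         counts = zipf_counts(s, config$zipf_alpha[["non_tumor"]],
                              config$reads_per_sample, config$abundance_noise))
  })
  tm <- with_substream(config$seed, c(patient_id, chain, "tumor"), {
    perm <- sample(s)            # drawn first: nested shared sets across theta
    shared_ranks <- sort(perm[seq_len(n_shared)])
    cl <- nt$cl                  # rank-aligned template
    fresh <- setdiff(seq_len(s), shared_ranks)
    if (length(fresh))
      cl[fresh, ] <- gen_clones(config, chain, length(fresh), nt$cl$cdr3_aa)
    bad <- gen_nonproductive(config, chain, n_bad, c(nt$cl$cdr3_aa, cl$cdr3_aa))
    list(cl = cl, bad = bad, shared_ranks = shared_ranks,
         counts = zipf_counts(s, config$zipf_alpha[["tumor"]],
                              config$reads_per_sample, config$abundance_noise))
  })

  build <- function(gen, tissue) {
    cl <- rbind(gen$cl, gen$bad)
    n_tot <- nrow(cl)
    counts <- c(gen$counts, rep(1L, n_tot - s))
    iso <- if (chain == "IGH")
      with_substream(config$seed, c(patient_id, chain, tissue, "isotype"),
                     sample(names(config$isotype_probs), n_tot, replace = TRUE,
                            prob = config$isotype_probs))
    else NA_character_
    ids <- sprintf("%s.%s.%s.c%04d", patient_id, tissue, chain, seq_len(n_tot))
    tab <- clonotype_table(count = counts, cdr3_nt = cl$cdr3_nt,
                           cdr3_aa = cl$cdr3_aa, v_call = cl$v_call,
                           j_call = cl$j_call, d_call = cl$d_call,
                           chain = chain, isotype = iso, clone_id = ids)
    repertoire_sample(patient_id, tissue, chain, tab)
  }
  tumor <- build(tm, "tumor")
  non_tumor <- build(nt, "non_tumor")
  truth <- list(patient_id = patient_id, chain = chain,
                zipf_alpha = config$zipf_alpha,
                shared_fraction = config$shared_fraction,
                shared_ranks = tm$shared_ranks,
                shared_labels = nt$cl$cdr3_aa[tm$shared_ranks],
                nonproductive_ids = list(
                  tumor = utils::tail(tumor$clonotypes$clone_id, n_bad),
                  non_tumor = utils::tail(non_tumor$clonotypes$clone_id, n_bad)),
                n_productive = s, n_nonproductive = n_bad)
  list(tumor = tumor, non_tumor = non_tumor, truth = truth)
}

#' Overlay somatic hypermutation structure on an IGH sample
#'
#' Each clone becomes mutated independently with probability
#' `shm$mutation_prob`; mutated founders receive `1 + Poisson(lambda)` V
#' mismatches and spawn a star lineage of geometric size: `k` descendant
#' clones (lineage size `1 + k`, `k ~ Geometric(lineage_geom_p)` on 0, 1,
#' ...) that share the founder's V/J and differ from its CDR3aa at exactly
#' one position each, at pairwise-distinct positions (so descendant pairs
#' are at Hamming distance 2). Originals keep 0 mismatches.
#'
#' @param config `sim_config`.
#' @param sample IGH `repertoire_sample` (e.g. from [simulate_pair()]).
#' @return the sample with `v_mismatches` set and descendant clones
#'   appended; ground truth (status and lineage sizes per founder) in
#'   `attr(, "shm_truth")`.
#' @export
simulate_shm <- function(config, sample) {
  if (sample$chain != "IGH") stopf("SHM simulation requires an IGH sample")
  cl <- sample$clonotypes
  n <- nrow(cl)
  out <- with_substream(config$seed,
                        c(sample$patient_id, sample$tissue, "shm"), {
    mutated <- stats::rbinom(n, 1, config$shm$mutation_prob) == 1
    vm <- ifelse(mutated, 1L + stats::rpois(n, config$shm$mismatch_lambda), 0L)
    cl$v_mismatches <- as.integer(vm)
    desc <- list()
    lineage_sizes <- rep(1L, n)
    for (i in which(mutated)) {
      len <- nchar(cl$cdr3_aa[i])
      k <- stats::rgeom(1, config$shm$lineage_geom_p)
      # lineages descend from productive founders only, so descendants are
      # productive too and the nonproductive manifest stays exact
      productive <- len >= 4 && !grepl("[*_]", cl$cdr3_aa[i]) &&
        nchar(cl$cdr3_nt[i]) %% 3 == 0
      k <- if (productive) min(k, len - 1) else 0L
      lineage_sizes[i] <- 1L + k
      if (k == 0) next
      pos <- sample(2:len, k)
      for (j in seq_len(k)) {
        aa <- cl$cdr3_aa[i]
        old <- substr(aa, pos[j], pos[j])
        substr(aa, pos[j], pos[j]) <- sample(setdiff(AA20, old), 1)
        desc[[length(desc) + 1]] <- data.frame(
          clone_id = sprintf("%s.d%d", cl$clone_id[i], j),
          count = max(1L, stats::rbinom(1, cl$count[i], 0.2)),
          cdr3_nt = aa_to_nt(aa), cdr3_aa = aa,
          v_call = cl$v_call[i], d_call = cl$d_call[i], j_call = cl$j_call[i],
          chain = "IGH", isotype = cl$isotype[i],
          v_mismatches = cl$v_mismatches[i] + 1L,
          stringsAsFactors = FALSE)
      }
    }
    list(cl = if (length(desc)) rbind(cl, do.call(rbind, desc)) else cl,
         mutated = mutated, lineage_sizes = lineage_sizes)
  })
  res <- repertoire_sample(sample$patient_id, sample$tissue, "IGH",
                           validate_clonotypes(out$cl))
  attr(res, "shm_truth") <- list(founder_ids = cl$clone_id,
                                 mutated = out$mutated,
                                 lineage_sizes = out$lineage_sizes)
  res
}

#' Build a single star lineage IGH sample
#'
#' One mutated founder plus `k` descendant clones, each differing from the
#' founder CDR3aa at one distinct position: the canonical fixture whose
#' mutated-clone network has exactly `k` edges and average degree
#' 2k/(k+1).
#'
#' @param k number of descendants.
#' @param cdr3_len founder CDR3aa length (must exceed `k`).
#' @param seed RNG seed.
#' @return IGH `repertoire_sample` of `k + 1` mutated clones.
#' @export
simulate_star_lineage <- function(k, cdr3_len = max(12, k + 2), seed = 1) {
  stopifnot(cdr3_len - 1 >= k)
  with_substream(seed, "star", {
    founder <- paste0("C", paste(sample(AA20, cdr3_len - 1, replace = TRUE),
                                 collapse = ""))
    aa <- founder
    pos <- if (k > 0) sample(2:cdr3_len, k) else integer(0)
    desc <- vapply(seq_len(k), function(j) {
      s <- founder
      old <- substr(s, pos[j], pos[j])
      substr(s, pos[j], pos[j]) <- sample(setdiff(AA20, old), 1)
      s
    }, character(1))
    aa <- c(founder, desc)
    tab <- clonotype_table(count = rep(1L, k + 1),
                           cdr3_nt = vapply(aa, aa_to_nt, character(1)),
                           cdr3_aa = aa, v_call = "IGHV3-23",
                           j_call = "IGHJ4", d_call = "IGHD3-10",
                           chain = "IGH", isotype = "IgG",
                           v_mismatches = c(1L, rep(2L, k)),
                           clone_id = sprintf("star.c%03d", 0:k))
    repertoire_sample("star", "tumor", "IGH", tab)
  })
}

#' Simulate a clinical cohort with an optional repertoire-feature effect
#'
#' Categorical variables follow the configured cohort frequencies. Survival
#' endpoints are exponential with independent exponential censoring; when a
#' numeric `feature` vector is supplied, patients above its median have
#' their hazard multiplied by `clinical$feature_hazard_ratio` for every
#' endpoint (PFS/RFS use 1.6x/1.4x the OS baseline rate).
#'
#' @param config `sim_config`.
#' @param feature optional per-patient numeric feature driving the hazard.
#' @param patient_ids optional ids; default `P001...`.
#' @return clinical data.frame (one row per patient).
#' @export
simulate_clinical <- function(config, feature = NULL, patient_ids = NULL) {
  n <- if (!is.null(feature)) length(feature) else config$n_patients
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_len(n))
  cc <- config$clinical
  with_substream(config$seed, "clinical", {
    sex <- ifelse(stats::runif(n) < cc$male_prob, "male", "female")
    age_band <- sample(names(cc$age_band_probs), n, replace = TRUE,
                       prob = cc$age_band_probs)
    tnm <- ifelse(stats::runif(n) < cc$stage_advanced_prob,
                  sample(2:4, n, replace = TRUE), 1L)
    recurrence <- sample(names(cc$recurrence_probs), n, replace = TRUE,
                         prob = cc$recurrence_probs)
    hr_mult <- rep(1, n)
    if (!is.null(feature))
      hr_mult[feature > stats::median(feature)] <- cc$feature_hazard_ratio
    endpoint <- function(rate_mult) {
      rate <- cc$os_rate * rate_mult * hr_mult
      t_ev <- stats::rexp(n, rate)
      t_cn <- stats::rexp(n, cc$censor_rate)
      list(months = round(pmin(t_ev, t_cn), 2),
           event = as.integer(t_ev <= t_cn))
    }
    pfs <- endpoint(1.6); rfs <- endpoint(1.4); os <- endpoint(1.0)
    data.frame(patient_id = patient_ids, sex = sex, age_band = age_band,
               tnm_stage = tnm, recurrence = recurrence,
               pfs_months = pfs$months, pfs_event = pfs$event,
               rfs_months = rfs$months, rfs_event = rfs$event,
               os_months = os$months, os_event = os$event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort and write it to disk
#'
#' Writes one AIRR TSV per (patient, tissue, chain), a clinical CSV, a
#' covariate TSV (`immune_score` correlated with tumor IGH richness at the
#' configured coefficient) and a JSON ground-truth manifest. Survival
#' hazards are driven by tumor IGH NSDE (CDR3aa level, post-filter) when
#' IGH is simulated, otherwise by the first chain's tumor NSDE. Identical
#' (config, seed) yields byte-identical outputs.
#'
#' @param config `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, list with `files`, `manifest` (parsed) and
#'   `manifest_path`.
#' @export
simulate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  patient_ids <- sprintf("P%03d", seq_len(config$n_patients))
  files <- character(0)
  truths <- list()
  feature_chain <- if ("IGH" %in% config$chains) "IGH" else config$chains[1]
  nsde_feature <- setNames(numeric(length(patient_ids)), patient_ids)
  richness_feature <- nsde_feature
  nonproductive <- list()
  for (pid in patient_ids) {
    for (chain in config$chains) {
      pair <- simulate_pair(config, pid, chain)
      samples <- list(tumor = pair$tumor, non_tumor = pair$non_tumor)
      if (chain == "IGH")
        samples <- lapply(samples, function(s) simulate_shm(config, s))
      for (tissue in names(samples)) {
        fn <- file.path(out_dir, sprintf("%s_%s_%s.tsv", pid, tissue, chain))
        write_clonotypes(samples[[tissue]]$clonotypes, fn)
        files <- c(files, fn)
        nonproductive[[basename(fn)]] <- pair$truth$nonproductive_ids[[tissue]]
      }
      if (chain == feature_chain) {
        filt <- filter_productive(samples$tumor$clonotypes)
        d <- diversity(collapse_profile(filt, "CDR3aa"))
        nsde_feature[pid] <- d$nsde
        richness_feature[pid] <- d$richness
      }
      truths[[paste(pid, chain, sep = ".")]] <- pair$truth
    }
  }
  clinical <- simulate_clinical(config, feature = as.numeric(nsde_feature),
                                patient_ids = patient_ids)
  clin_path <- file.path(out_dir, "clinical.csv")
  utils::write.csv(clinical, clin_path, row.names = FALSE, quote = FALSE)
  rho <- config$clinical$covariate_cor
  covariates <- with_substream(config$seed, "covariates", {
    z <- as.numeric(scale(richness_feature))
    data.frame(patient_id = patient_ids,
               immune_score = round(1000 + 300 * (rho * z +
                 sqrt(1 - rho^2) * stats::rnorm(length(z))), 2),
               stringsAsFactors = FALSE)
  })
  cov_path <- file.path(out_dir, "covariates.tsv")
  con <- file(cov_path, open = "wb")
  utils::write.table(covariates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  close(con)
  manifest <- list(
    seed = config$seed,
    n_patients = config$n_patients,
    chains = config$chains,
    clones_per_sample = config$clones_per_sample,
    zipf_alpha = as.list(config$zipf_alpha),
    shared_fraction = config$shared_fraction,
    shm = config$shm,
    feature_chain = feature_chain,
    survival_feature = as.list(round(nsde_feature, 10)),
    repertoire_files = basename(files),
    declared_totals = lapply(setNames(files, basename(files)), function(f)
      sum(read_airr_table(f)$count)),
    nonproductive_ids = nonproductive,
    truths = truths)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(files = c(files, clin_path, cov_path, manifest_path),
                 manifest = manifest, manifest_path = manifest_path))
}
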