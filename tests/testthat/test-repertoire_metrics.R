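test_that("collapse aggregates counts by CDR3aa and by VDJ combination", {
  cl <- make_clones(c("CASSF", "CASSF"), count = c(3, 2))
  prof <- collapse_profile(igh_to_sample <- repertoire_sample("p", "tumor",
                                                              "TRB", cl),
                           "CDR3aa")
  expect_equal(unname(prof$counts["CASSF"]), 5L)
  expect_equal(length(prof$counts), 1)

  cl2 <- clonotype_table(count = c(4, 1), cdr3_aa = c("CASSA", "CASSB"),
                         cdr3_nt = strrep("GCT", 5),
                         v_call = "TRBV19", d_call = c("TRBD1", "TRBD2"),
                         j_call = "TRBJ2-1", chain = "TRB")
  prof2 <- collapse_profile(cl2, "VDJ")
  expect_equal(length(prof2$counts), 2)  # distinct D genes split the key
  expect_equal(prof2$total, 5L)
})

test_that("collapse conserves total counts on random samples", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    cl <- make_clones(replicate(n, paste(sample(LETTERS[1:20], 8, TRUE),
                                         collapse = "")),
                      count = sample(100, n, TRUE))
    for (lev in c("CDR3aa", "VDJ"))
      expect_equal(collapse_profile(cl, lev)$total, sum(cl$count))
  }
})

test_that("diversity matches hand-computed entropy oracles", {
  uniform <- abundance_profile(setNames(rep(5, 8), letters[1:8]))
  expect_equal(diversity(uniform)$nsde, 1.0, tolerance = 1e-12)

  single <- abundance_profile(c(A = 100))
  d <- diversity(single)
  expect_equal(d$richness, 1)
  expect_equal(d$shannon, 0)
  expect_equal(d$nsde, 0)

  skewed <- abundance_profile(c(A = 1, B = 1, C = 2))
  d <- diversity(skewed)
  h_expected <- -(0.25 * log(0.25) * 2 + 0.5 * log(0.5))
  expect_equal(d$shannon, h_expected, tolerance = 1e-12)
  expect_equal(d$nsde, h_expected / log(3), tolerance = 1e-12)

  empty <- suppressWarnings(collapse_profile(make_clones(character(0))))
  expect_error(diversity(empty), "undefined")
})

test_that("entropy agrees with vegan and respects concentration monotonicity", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:25) {
    prof <- random_profile(n_labels = sample(2:40, 1))
    d <- diversity(prof)
    expect_equal(d$shannon, unname(vegan::diversity(prof$counts)),
                 tolerance = 1e-12)
    expect_lte(d$shannon, log(d$richness) + 1e-12)
    # move one unit of mass from a smaller to a strictly larger clone
    o <- order(prof$counts)
    small <- o[1]; large <- o[length(o)]
    if (prof$counts[small] > 1 && prof$counts[large] > prof$counts[small]) {
      shifted <- prof$counts
      shifted[small] <- shifted[small] - 1
      shifted[large] <- shifted[large] + 1
      expect_lt(entropy_oracle(shifted), d$shannon)
    }
  }
})

test_that("Morisita-Horn matches closed-form examples", {
  a <- abundance_profile(c(A = 1, B = 1))
  b <- abundance_profile(c(A = 1, C = 1))
  expect_equal(morisita_horn(a, b)$mhsi, 0.5, tolerance = 1e-12)
  expect_equal(morisita_horn(a, b)$n_shared_labels, 1)

  p <- random_profile(10)
  expect_equal(morisita_horn(p, p)$mhsi, 1.0, tolerance = 1e-12)

  disjoint <- abundance_profile(c(X = 3, Y = 9))
  expect_equal(morisita_horn(a, disjoint)$mhsi, 0)
  expect_equal(morisita_horn(a, disjoint)$n_shared_labels, 0)
})

test_that("Morisita-Horn errors on level mismatch and empty profiles", {
  a <- abundance_profile(c(A = 1), level = "CDR3aa")
  b <- abundance_profile(c(A = 1), level = "VDJ")
  expect_error(morisita_horn(a, b), "level")
  empty <- abundance_profile(setNames(integer(0), character(0)))
  expect_error(morisita_horn(a, empty), "empty")
})

test_that("Morisita-Horn is symmetric, bounded, scale-invariant and agrees with vegan", {
  has_vegan <- requireNamespace("vegan", quietly = TRUE)
  set.seed(7)
  for (i in 1:200) {
    a <- random_profile(prefix = "A")
    b <- random_profile(prefix = if (runif(1) < 0.5) "A" else "B")
    m1 <- morisita_horn(a, b)
    m2 <- morisita_horn(b, a)
    expect_equal(m1$mhsi, m2$mhsi, tolerance = 1e-12)
    expect_gte(m1$mhsi, 0)
    expect_lte(m1$mhsi, 1 + 1e-12)
    expect_equal(m1$mhsi == 0, m1$n_shared_labels == 0)
    expect_equal(m1$mhsi, mh_oracle(a$counts, b$counts), tolerance = 1e-12)
    scaled <- abundance_profile(a$counts * 7L, a$level)
    expect_equal(morisita_horn(scaled, b)$mhsi, m1$mhsi, tolerance = 1e-12)
    if (has_vegan && m1$n_shared_labels > 0) {
      labels <- union(names(a$counts), names(b$counts))
      mat <- rbind(sapply(labels, function(l) unname(a$counts[l])),
                   sapply(labels, function(l) unname(b$counts[l])))
      mat[is.na(mat)] <- 0
      expect_equal(m1$mhsi,
                   1 - as.numeric(vegan::vegdist(mat, method = "horn")),
                   tolerance = 1e-9)
    }
  }
})

test_that("richness is invariant under permutation and rescaling", {
  set.seed(3)
  prof <- random_profile(17)
  perm <- sample(length(prof$counts))
  d0 <- diversity(prof)
  expect_equal(diversity(abundance_profile(prof$counts[perm]))$richness,
               d0$richness)
  expect_equal(diversity(abundance_profile(prof$counts * 3L))$richness,
               d0$richness)
})

test_that("usage matrix rows are normalized frequencies over the label union", {
  s1 <- repertoire_sample("p1", "tumor", "TRB",
    make_clones(c("CAAAA", "CBBBB"), count = c(3, 1),
                v_call = c("TRBV19", "TRBV20-1")))
  s2 <- repertoire_sample("p1", "non_tumor", "TRB",
    make_clones("CCCCC", count = 2, v_call = "TRBV28"))
  m <- usage_matrix(list(s1, s2), segment = "V")
  expect_equal(sort(colnames(m)), sort(c("TRBV19", "TRBV20-1", "TRBV28")))
  expect_equal(unname(m["p1.tumor.TRB", "TRBV19"]), 0.75)
  expect_equal(unname(m["p1.tumor.TRB", "TRBV20-1"]), 0.25)
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-9)
  # identical usage gives identical rows
  m2 <- usage_matrix(list(s1, s1), segment = "V")
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
})

test_that("usage frequencies converge to generator segment probabilities", {
  # near-uniform clone abundances so the count-weighted frequency is an
  # average over ~S independent segment assignments
  cfg <- sim_config(n_patients = 1, chains = "TRB",
                    clones_per_sample = 2000, reads_per_sample = 1e5,
                    zipf_alpha = c(tumor = 0.1, non_tumor = 0.1),
                    nonproductive_rate = 0, seed = 99)
  pair <- simulate_pair(cfg, "P001", "TRB")
  m <- usage_matrix(list(pair$non_tumor), segment = "V")
  pool <- cfg$segment_pools$TRB$V
  for (i in seq_along(pool$labels))
    expect_lt(abs(m[1, pool$labels[i]] - pool$probs[i]), 0.05)
})

test_that("ordination is deterministic and MDS reproduces PCA geometry", {
  set.seed(21)
  mat <- matrix(runif(8 * 5), nrow = 8,
                dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  mat <- mat / rowSums(mat)
  mat <- rbind(mat, mat[1, , drop = FALSE])  # duplicated sample
  rownames(mat)[9] <- "s1dup"
  pca <- ordinate(mat, "PCA")
  mds <- ordinate(mat, "MDS")
  expect_equal(unname(pca["s1", ]), unname(pca["s1dup", ]), tolerance = 1e-12)
  expect_equal(unname(mds["s1", ]), unname(mds["s1dup", ]), tolerance = 1e-9)
  # classical MDS on Euclidean distances equals PCA scores up to axis sign
  err <- min(sapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                    function(s) sum((sweep(unclass(mds), 2, s, `*`) -
                                     unclass(pca))^2)))
  expect_lt(err, 1e-16)
  expect_error(ordinate(mat[1:2, ]), "3 samples")
})

test_that("ordination separates tissues under a simulated V-usage shift", {
  # tumor and non-tumor IGH samples drawn with reversed V-segment usage
  set.seed(31)
  pools <- default_segment_pools()
  v <- pools$IGH$V$labels
  shift <- function(probs) probs / sum(probs)
  p_tumor <- shift(seq_along(v))
  p_non <- shift(rev(seq_along(v)))
  samples <- list()
  for (i in 1:6) {
    for (tis in c("tumor", "non_tumor")) {
      p <- if (tis == "tumor") p_tumor else p_non
      vg <- sample(v, 300, TRUE, prob = p)
      cl <- clonotype_table(count = rpois(300, 10) + 1,
                            cdr3_aa = replicate(300, paste0("C",
                              paste(sample(LETTERS[1:20], 11, TRUE),
                                    collapse = ""))),
                            cdr3_nt = strrep("GCT", 12), v_call = vg,
                            j_call = "IGHJ4", chain = "IGH", isotype = "IgG")
      samples[[length(samples) + 1]] <-
        repertoire_sample(paste0("P", i), tis, "IGH", cl)
    }
  }
  m <- usage_matrix(samples, "V")
  coords <- ordinate(m, "PCA")
  labels <- grepl("non_tumor", rownames(m))
  expect_gt(silhouette_mean(unclass(coords), labels), 0)
})
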