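# Shared fixtures and independent oracles used across test files.

# Minimal clonotype table builder with sensible defaults.
make_clones <- function(cdr3_aa, count = 1, v_call = "TRBV19",
                        j_call = "TRBJ2-1", d_call = "TRBD1",
                        chain = "TRB", isotype = NA_character_,
                        v_mismatches = NA_integer_,
                        cdr3_nt = NULL) {
  if (is.null(cdr3_nt))
    cdr3_nt <- vapply(cdr3_aa, function(aa)
      paste(rep("GCT", max(1, nchar(aa))), collapse = ""), character(1))
  clonotype_table(count = rep_len(count, length(cdr3_aa)), cdr3_nt = cdr3_nt,
                  cdr3_aa = cdr3_aa, v_call = rep_len(v_call, length(cdr3_aa)),
                  j_call = rep_len(j_call, length(cdr3_aa)), d_call = d_call,
                  chain = chain, isotype = isotype,
                  v_mismatches = v_mismatches)
}

make_igh <- function(cdr3_aa, v_mismatches, isotype = "IgG", ...) {
  make_clones(cdr3_aa, v_call = "IGHV3-23", j_call = "IGHJ4",
              d_call = "IGHD3-10", chain = "IGH", isotype = isotype,
              v_mismatches = v_mismatches, ...)
}

igh_sample <- function(clonotypes, tissue = "tumor") {
  repertoire_sample("pt1", tissue, "IGH", clonotypes)
}

# Write a raw AIRR-style TSV from a data.frame of character columns.
write_raw_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random abundance profile (for property tests).
random_profile <- function(n_labels = NULL, max_count = 50, level = "CDR3aa",
                           prefix = "L") {
  if (is.null(n_labels)) n_labels <- sample(1:30, 1)
  counts <- sample(max_count, n_labels, replace = TRUE)
  abundance_profile(setNames(counts, paste0(prefix, seq_len(n_labels))), level)
}

# Independent Shannon entropy oracle.
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# Independent Morisita-Horn oracle written directly from the definition,
# looping over the union of labels.
mh_oracle <- function(a, b) {
  labels <- union(names(a), names(b))
  x <- sapply(labels, function(l) if (l %in% names(a)) a[[l]] else 0)
  y <- sapply(labels, function(l) if (l %in% names(b)) b[[l]] else 0)
  2 * sum(x * y) /
    ((sum(x^2) / sum(x)^2 + sum(y^2) / sum(y)^2) * sum(x) * sum(y))
}

# Brute-force exact two-sided signed-rank p-value by recursive enumeration
# over sign vectors (distinct code path from the implementation's bitmask).
signed_rank_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  mean(abs(stats - mu) >= abs(w - mu) - 1e-12)
}

# Brute-force exact two-sided Mann-Whitney p-value over all group splits.
mann_whitney_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  splits <- combn(length(pooled), na)
  stats <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(stats - mu) >= abs(u_obs - mu) - 1e-12)
}

# Fisher two-sided p for a 2x2 table by hypergeometric enumeration with the
# point-probability rule.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(tab[1, 1], m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mean silhouette width on 2-D coordinates for a 2-group labelling.
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
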