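# Diversity, similarity and gene-usage features of repertoire samples.
#
# Repertoire features are computed at two levels: CDR3aa (unique CDR3
# amino-acid sequences) and VDJ (unique V-D-J gene-segment combinations,
# alleles stripped, empty D allowed for chains lacking a D segment).

#' Collapse a repertoire sample to an abundance profile
#'
#' Aggregates clonotype counts at the chosen feature level. At the CDR3aa
#' level clones are keyed by the CDR3 amino-acid string; at the VDJ level by
#' the joint (V, D, J) gene combination.
#'
#' @param sample a `repertoire_sample` (filtered) or clonotype `data.frame`.
#' @param level `"CDR3aa"` or `"VDJ"`.
#' @return an `abundance_profile`: list with `level`, `counts` (named
#'   positive counts) and `total`.
#' @export
collapse_profile <- function(sample, level = c("CDR3aa", "VDJ")) {
  level <- match.arg(level)
  cl <- if (inherits(sample, "repertoire_sample")) sample$clonotypes else sample
  if (nrow(cl) == 0) {
    warnf("collapsing an empty sample: profile has total 0")
    return(abundance_profile(setNames(integer(0), character(0)), level))
  }
  key <- if (level == "CDR3aa") cl$cdr3_aa
         else paste(cl$v_call, cl$d_call, cl$j_call, sep = "|")
  counts <- tapply(cl$count, key, sum)
  abundance_profile(setNames(as.integer(counts), names(counts)), level)
}

#' Construct an abundance profile from a named count vector
#'
#' @param counts named vector of positive clone counts (unique labels).
#' @param level `"CDR3aa"` or `"VDJ"`.
#' @return an `abundance_profile` object.
#' @export
abundance_profile <- function(counts, level = "CDR3aa") {
  if (length(counts) && (is.null(names(counts)) || anyDuplicated(names(counts))))
    stopf("abundance profile labels must be unique and named")
  if (any(counts <= 0)) stopf("abundance profile counts must be positive")
  structure(list(level = level, counts = counts, total = sum(counts)),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> level=%s, %d labels, total %d\n",
              x$level, length(x$counts), x$total))
  invisible(x)
}

#' Richness, Shannon entropy and normalized Shannon diversity entropy
#'
#' Richness S is the number of unique clone labels. Shannon entropy is
#' H = -sum p_i log p_i in nats with p_i the clone frequencies. The
#' normalized Shannon diversity entropy (NSDE, Pielou evenness) is
#' H / log(S); a single-clone repertoire has NSDE 0 by convention (maximal
#' clonality).
#'
#' @param profile nonempty `abundance_profile`.
#' @return list with `richness`, `shannon`, `nsde`.
#' @export
diversity <- function(profile) {
  counts <- profile$counts
  if (length(counts) == 0)
    stopf("diversity is undefined for an empty profile")
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  s <- length(counts)
  list(richness = s, shannon = h, nsde = if (s >= 2) h / log(s) else 0)
}

#' Morisita-Horn similarity of two abundance profiles
#'
#' With counts x_i, y_i of label i, X = sum x_i, Y = sum y_i,
#' d_x = sum x_i^2 / X^2, d_y = sum y_i^2 / Y^2:
#' MHSI = 2 sum(x_i y_i) / ((d_x + d_y) X Y). Symmetric, in [0, 1],
#' 1 for identical relative abundances, 0 iff no shared labels.
#'
#' @param a,b nonempty `abundance_profile`s at the same level.
#' @return list with `mhsi` and `n_shared_labels`.
#' @export
morisita_horn <- function(a, b) {
  if (!identical(a$level, b$level))
    stopf("profiles must share a feature level (%s vs %s)", a$level, b$level)
  if (length(a$counts) == 0 || length(b$counts) == 0)
    stopf("Morisita-Horn similarity is undefined for an empty profile")
  shared <- intersect(names(a$counts), names(b$counts))
  x <- as.numeric(a$counts); y <- as.numeric(b$counts)
  X <- sum(x); Y <- sum(y)
  d_x <- sum(x^2) / X^2
  d_y <- sum(y^2) / Y^2
  cross <- sum(as.numeric(a$counts[shared]) * as.numeric(b$counts[shared]))
  list(mhsi = 2 * cross / ((d_x + d_y) * X * Y),
       n_shared_labels = length(shared))
}

#' Count-weighted gene-segment usage matrix across samples
#'
#' One row per sample, one column per gene-segment label (union across
#' samples), values the count-weighted relative frequency of the segment in
#' the sample. Rows of nonempty samples sum to 1; empty samples give an
#' all-zero row recorded in the `"empty_rows"` attribute.
#'
#' @param samples list of filtered `repertoire_sample`s.
#' @param segment `"V"`, `"J"`, or `"VDJ"` (joint combination).
#' @return numeric matrix with sample-id rownames.
#' @export
usage_matrix <- function(samples, segment = c("V", "J", "VDJ")) {
  segment <- match.arg(segment)
  seg_key <- function(cl) switch(segment,
    V = cl$v_call, J = cl$j_call,
    VDJ = paste(cl$v_call, cl$d_call, cl$j_call, sep = "|"))
  ids <- vapply(samples, function(s)
    paste(s$patient_id, s$tissue, s$chain, sep = "."), character(1))
  per <- lapply(samples, function(s) {
    cl <- s$clonotypes
    if (nrow(cl) == 0) return(numeric(0))
    tapply(cl$count, seg_key(cl), sum)
  })
  labels <- sort(unique(unlist(lapply(per, names))))
  mat <- matrix(0, nrow = length(samples), ncol = length(labels),
                dimnames = list(ids, labels))
  for (i in seq_along(per)) {
    v <- per[[i]]
    if (length(v)) mat[i, names(v)] <- v / sum(v)
  }
  empty <- which(vapply(per, length, integer(1)) == 0)
  if (length(empty)) {
    warnf("usage matrix has %d empty (all-zero) row(s)", length(empty))
    attr(mat, "empty_rows") <- ids[empty]
  }
  mat
}

#' Ordinate samples from a usage matrix
#'
#' PCA operates on column-centered (not variance-scaled) frequencies and
#' returns projections on the top principal axes. MDS is classical (metric)
#' multidimensional scaling of pairwise Euclidean row distances. Both are
#' deterministic; per-axis sign is fixed so the largest-magnitude loading
#' (PCA) or coordinate (MDS) on each axis is positive.
#'
#' @param mat usage matrix (samples x segments), at least 3 rows.
#' @param method `"PCA"` or `"MDS"`.
#' @param n_components number of output axes, below `min(dim(mat))`.
#' @return coordinates matrix (samples x components); for PCA the loadings
#'   and explained variance fractions are attached as attributes.
#' @export
ordinate <- function(mat, method = c("PCA", "MDS"), n_components = 2) {
  method <- match.arg(method)
  if (nrow(mat) < 3) stopf("ordination requires at least 3 samples")
  if (n_components >= min(dim(mat)))
    stopf("n_components must be < min(samples, segments)")
  if (method == "PCA") {
    fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(fit$x))
    scores <- fit$x[, seq_len(k), drop = FALSE]
    load <- fit$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      top <- which.max(abs(load[, j]))
      if (load[top, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
    }
    ev <- fit$sdev^2
    structure(scores, loadings = load,
              explained = ev[seq_len(k)] / sum(ev), method = "PCA")
  } else {
    coords <- stats::cmdscale(stats::dist(mat), k = n_components)
    for (j in seq_len(ncol(coords))) {
      top <- which.max(abs(coords[, j]))
      if (coords[top, j] < 0) coords[, j] <- -coords[, j]
    }
    structure(coords, method = "MDS")
  }
}

#' Tidy per-sample diversity feature table
#'
#' Convenience wrapper computing richness, Shannon entropy and NSDE for each
#' sample at both feature levels, in the long format consumed by the cohort
#' stage.
#'
#' @param samples list of filtered `repertoire_sample`s.
#' @param levels feature levels to compute.
#' @return data.frame (patient_id, tissue, chain, isotype_view, level,
#'   metric, value).
#' @export
diversity_features <- function(samples, levels = c("CDR3aa", "VDJ")) {
  rows <- list()
  for (s in samples) {
    for (lev in levels) {
      if (nrow(s$clonotypes) == 0) next
      d <- diversity(collapse_profile(s, lev))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = s$patient_id, tissue = s$tissue, chain = s$chain,
        isotype_view = if (is.na(s$isotype_view)) "all" else s$isotype_view,
        level = lev,
        metric = c("richness", "shannon", "nsde"),
        value = c(d$richness, d$shannon, d$nsde),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
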