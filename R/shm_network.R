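# B-cell somatic hypermutation (SHM) statistics and mutated-clone networks.
#
# A clone with >= 1 nucleotide mismatch of its V-region alignment to
# germline is "mutated"; clones with 0 mismatches are "original"; clones
# whose aligner did not report a mismatch count are "unknown" and excluded
# from SHM percentages and networks (but not from diversity).

#' Classify IGH clonotypes as original, mutated or unknown
#'
#' @param clonotypes IGH clonotype `data.frame`.
#' @return character vector: `"original"` (0 mismatches), `"mutated"`
#'   (>= 1), `"unknown"` (mismatch count missing).
#' @export
classify_mutated <- function(clonotypes) {
  if (nrow(clonotypes) && any(clonotypes$chain != "IGH"))
    stopf("mutation status is defined for IGH clonotypes only")
  vm <- clonotypes$v_mismatches
  ifelse(is.na(vm), "unknown", ifelse(vm >= 1, "mutated", "original"))
}

#' SHM percentages and isotype composition of an IGH sample
#'
#' Mutated/original percentages are clone-based (unweighted by read count)
#' over clones with known mutation status, computed for combined IgH and per
#' isotype. With no known-status clone the percentages are `NA`, not 0.
#'
#' @param sample filtered IGH `repertoire_sample`.
#' @param weighted if `TRUE`, weight clones by read count instead.
#' @return list with `by_view` data.frame (view, n_known, original_pct,
#'   mutated_pct) and `isotype_pct` (percent of clones per isotype,
#'   summing to 100 over isotypes present).
#' @export
shm_percentages <- function(sample, weighted = FALSE) {
  if (sample$chain != "IGH") stopf("SHM percentages require an IGH sample")
  cl <- sample$clonotypes
  status <- classify_mutated(cl)
  w <- if (weighted) cl$count else rep(1, nrow(cl))
  pct_for <- function(idx) {
    known <- idx & status != "unknown"
    tot <- sum(w[known])
    if (tot == 0) return(c(n_known = sum(known), original_pct = NA_real_,
                           mutated_pct = NA_real_))
    mut <- sum(w[known & status == "mutated"])
    c(n_known = sum(known), original_pct = 100 * (tot - mut) / tot,
      mutated_pct = 100 * mut / tot)
  }
  views <- c("all", VALID_ISOTYPES)
  by_view <- do.call(rbind, lapply(views, function(v) {
    idx <- if (v == "all") rep(TRUE, nrow(cl)) else !is.na(cl$isotype) & cl$isotype == v
    data.frame(view = v, t(pct_for(idx)), stringsAsFactors = FALSE)
  }))
  iso_tab <- tapply(w, cl$isotype, sum)
  isotype_pct <- 100 * iso_tab / sum(iso_tab)
  list(by_view = by_view, isotype_pct = isotype_pct)
}

#' Build the mutated-clone network of an IGH sample
#'
#' Nodes are the sample's mutated clones; two nodes are connected iff they
#' share the V gene and the J gene, have equal CDR3aa length, and their
#' CDR3aa Hamming distance is at most `max_aa_dist` — the standard
#' clonal-lineage relatedness convention. No self-loops, no duplicate edges.
#'
#' @param sample filtered IGH `repertoire_sample` (optionally an isotype
#'   view via [subset_isotype()]).
#' @param max_aa_dist maximum CDR3aa Hamming distance for an edge.
#' @return `mutation_network`: list with `nodes` (clone ids), `edges`
#'   (two-column data.frame, from < to lexicographically), `degree`
#'   (named integer vector).
#' @export
build_network <- function(sample, max_aa_dist = 1) {
  if (sample$chain != "IGH") stopf("mutation networks require an IGH sample")
  cl <- sample$clonotypes
  mut <- cl[classify_mutated(cl) == "mutated", , drop = FALSE]
  ids <- mut$clone_id
  edges_from <- character(0); edges_to <- character(0)
  if (nrow(mut) > 1) {
    grp <- paste(mut$v_call, mut$j_call, nchar(mut$cdr3_aa), sep = "|")
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < 2) next
      for (a in seq_len(length(idx) - 1)) {
        for (b in seq(a + 1, length(idx))) {
          i <- idx[a]; j <- idx[b]
          if (hamming(mut$cdr3_aa[i], mut$cdr3_aa[j]) <= max_aa_dist) {
            pair <- sort(c(ids[i], ids[j]))
            edges_from <- c(edges_from, pair[1])
            edges_to <- c(edges_to, pair[2])
          }
        }
      }
    }
  }
  mutation_network(ids, data.frame(from = edges_from, to = edges_to,
                                   stringsAsFactors = FALSE))
}

#' Construct a mutation network from explicit nodes and edges
#'
#' @param nodes node identifiers.
#' @param edges data.frame with columns `from`, `to` (unordered pairs).
#' @return `mutation_network` object with degrees computed.
#' @export
mutation_network <- function(nodes, edges = data.frame(from = character(0),
                                                       to = character(0))) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stopf("duplicate node ids")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stopf("duplicate edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes))
      stopf("edges reference unknown nodes")
  }
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = nodes, edges = edges, degree = degree),
            class = "mutation_network")
}

#' @export
print.mutation_network <- function(x, ...) {
  cat(sprintf("<mutation_network> %d nodes, %d edges, average degree %.3f\n",
              length(x$nodes), nrow(x$edges), average_degree(x)))
  invisible(x)
}

#' Average degree of a mutation network
#'
#' The number of connections each node has with other nodes, summed and
#' divided by the total number of nodes: 2E/N. Empty network gives 0.
#'
#' @param net `mutation_network`.
#' @return non-negative real.
#' @export
average_degree <- function(net) {
  n <- length(net$nodes)
  if (n == 0) return(0)
  sum(net$degree) / n
}

#' Average degree after removing nodes with exactly one connection (EXd1)
#'
#' All nodes of degree exactly 1 are removed in a single simultaneous pass
#' (degree-0 nodes are retained), incident edges are dropped, and the
#' average degree of the remaining graph is returned (0 if no node
#' remains). The pruning is not iterated.
#'
#' @param net `mutation_network`.
#' @return non-negative real.
#' @export
average_degree_exd1 <- function(net) {
  keep <- net$nodes[net$degree[net$nodes] != 1]
  if (length(keep) == 0) return(0)
  e <- net$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  average_degree(mutation_network(keep, e))
}

#' Export a mutation network as edge-list and node-attribute tables
#'
#' @param net `mutation_network`.
#' @param sample optional originating `repertoire_sample` supplying isotype
#'   node attributes.
#' @return list of data.frames `edges` (from, to) and `nodes`
#'   (node, degree, isotype).
#' @export
export_network <- function(net, sample = NULL) {
  iso <- rep(NA_character_, length(net$nodes))
  if (!is.null(sample)) {
    m <- match(net$nodes, sample$clonotypes$clone_id)
    iso <- sample$clonotypes$isotype[m]
  }
  list(edges = net$edges,
       nodes = data.frame(node = net$nodes,
                          degree = as.integer(net$degree[net$nodes]),
                          isotype = iso, stringsAsFactors = FALSE))
}

#' Tidy SHM feature table for IGH samples
#'
#' Computes mutated/original percentages, isotype shares and network average
#' degrees (plain and EXd1) for combined IgH and each isotype view.
#'
#' @param samples list of filtered IGH `repertoire_sample`s.
#' @param max_aa_dist edge rule distance threshold, see [build_network()].
#' @return data.frame (patient_id, tissue, chain, isotype_view, level,
#'   metric, value) aligned with [diversity_features()].
#' @export
shm_features <- function(samples, max_aa_dist = 1) {
  rows <- list()
  add <- function(s, view, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = s$patient_id, tissue = s$tissue, chain = s$chain,
      isotype_view = view, level = "SHM", metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  for (s in samples) {
    if (s$chain != "IGH" || nrow(s$clonotypes) == 0) next
    stats <- shm_percentages(s)
    for (i in seq_len(nrow(stats$by_view))) {
      v <- stats$by_view$view[i]
      add(s, v, "mutated_pct", stats$by_view$mutated_pct[i])
      add(s, v, "original_pct", stats$by_view$original_pct[i])
    }
    for (iso in names(stats$isotype_pct))
      add(s, iso, "isotype_pct", as.numeric(stats$isotype_pct[iso]))
    views <- c(list(all = s),
               setNames(lapply(VALID_ISOTYPES, function(i) subset_isotype(s, i)),
                        VALID_ISOTYPES))
    for (v in names(views)) {
      net <- build_network(views[[v]], max_aa_dist = max_aa_dist)
      add(s, v, "avg_degree", average_degree(net))
      add(s, v, "avg_degree_exd1", average_degree_exd1(net))
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
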