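# Reading, validating and filtering clonotype tables and clinical metadata.
#
# A clonotype table is a plain data.frame with one row per rearrangement and
# the fixed columns below; repertoire_sample() wraps a table with its sample
# identity (patient, tissue, chain).

CLONOTYPE_COLUMNS <- c("clone_id", "count", "cdr3_nt", "cdr3_aa",
                       "v_call", "d_call", "j_call", "chain", "isotype",
                       "v_mismatches")

VALID_CHAINS   <- c("TRA", "TRB", "TRG", "TRD", "IGH")
VALID_ISOTYPES <- c("IgA", "IgG", "IgM")

#' Construct a clonotype table
#'
#' Builds the package's canonical clonotype data.frame: one row per
#' rearrangement record with a read/duplicate count, CDR3 nucleotide and
#' amino-acid sequences, V/D/J gene calls (allele suffixes stripped), chain,
#' isotype (IgH only) and the number of V-region nucleotide mismatches to
#' germline (`NA` when the aligner did not report it).
#'
#' @param count non-negative integer read/duplicate counts.
#' @param cdr3_nt,cdr3_aa CDR3 nucleotide / amino-acid sequences.
#' @param v_call,d_call,j_call gene-segment names; `d_call` may be `""` for
#'   chains without a D segment.
#' @param chain one of TRA, TRB, TRG, TRD, IGH.
#' @param isotype one of IgA, IgG, IgM for IGH rows, `NA` otherwise.
#' @param v_mismatches non-negative integer or `NA`.
#' @param clone_id unique identifiers; generated when omitted.
#' @return a `data.frame` with the canonical clonotype columns.
#' @export
clonotype_table <- function(count, cdr3_nt, cdr3_aa, v_call, j_call,
                            d_call = "", chain = "TRB", isotype = NA_character_,
                            v_mismatches = NA_integer_, clone_id = NULL) {
  n <- length(count)
  if (is.null(clone_id)) clone_id <- sprintf("clone%04d", seq_len(n))
  df <- data.frame(
    clone_id = as.character(clone_id),
    count = as.integer(count),
    cdr3_nt = as.character(cdr3_nt),
    cdr3_aa = as.character(cdr3_aa),
    v_call = as.character(v_call),
    d_call = rep_len(as.character(d_call), n),
    j_call = as.character(j_call),
    chain = rep_len(as.character(chain), n),
    isotype = rep_len(as.character(isotype), n),
    v_mismatches = rep_len(suppressWarnings(as.integer(v_mismatches)), n),
    stringsAsFactors = FALSE
  )
  validate_clonotypes(df)
}

validate_clonotypes <- function(df) {
  missing <- setdiff(CLONOTYPE_COLUMNS, names(df))
  if (length(missing))
    stopf("clonotype table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(df$count < 0, na.rm = TRUE)) stopf("clonotype counts must be >= 0")
  bad_chain <- !df$chain %in% VALID_CHAINS
  if (any(bad_chain))
    stopf("invalid chain value(s): %s",
          paste(unique(df$chain[bad_chain]), collapse = ", "))
  # chain == IGH <=> isotype present
  igh <- df$chain == "IGH"
  if (any(igh & is.na(df$isotype)))
    stopf("IGH clonotypes must carry an isotype (IgA/IgG/IgM)")
  if (any(!igh & !is.na(df$isotype)))
    stopf("non-IGH clonotypes must have isotype NA")
  bad_iso <- igh & !df$isotype %in% VALID_ISOTYPES
  if (any(bad_iso))
    stopf("invalid isotype value(s): %s",
          paste(unique(df$isotype[bad_iso]), collapse = ", "))
  df[CLONOTYPE_COLUMNS]
}

#' Default AIRR Rearrangement column mapping
#'
#' Maps canonical clonotype fields to AIRR Rearrangement column names
#' (junction, junction_aa, duplicate_count, v_call, ...). Pass a modified
#' copy to [read_airr_table()] to read other dialects.
#'
#' @return named list: canonical field -> input column name.
#' @export
airr_column_map <- function() {
  list(clone_id = "sequence_id", count = "duplicate_count",
       cdr3_nt = "junction", cdr3_aa = "junction_aa",
       v_call = "v_call", d_call = "d_call", j_call = "j_call",
       chain = "locus", isotype = "c_call", v_mismatches = "v_mismatch_count")
}

#' MiXCR export column mapping
#'
#' Column mapping for MiXCR `exportClones`-style TSV files
#' (cloneCount, nSeqCDR3, aaSeqCDR3, allVHitsWithScore, ...). Gene-call
#' cleaning handles the `GENE*allele(score)` format and keeps the
#' top-scoring hit.
#'
#' @return named list: canonical field -> input column name.
#' @export
mixcr_column_map <- function() {
  list(clone_id = "cloneId", count = "cloneCount",
       cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
       v_call = "allVHitsWithScore", d_call = "allDHitsWithScore",
       j_call = "allJHitsWithScore", chain = "chain", isotype = "isotype",
       v_mismatches = "vMismatchCount")
}

# Reduce a raw gene-call field to a single gene-level name: take the first
# (top-scoring) comma-separated hit, drop any "(score)" suffix and the
# allele suffix after '*'.
clean_gene_call <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*$", "", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

infer_chain <- function(v_call, j_call) {
  src <- ifelse(nzchar(v_call), v_call, j_call)
  ch <- toupper(substr(src, 1, 3))
  ch[substr(src, 1, 2) == "IG"] <- "IGH"
  ch
}

normalize_isotype <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[grepl("^(IGHA|IGA)", up) | up == "IGA" | x == "IgA"] <- "IgA"
  out[grepl("^(IGHG|IGG)", up) | x == "IgG"] <- "IgG"
  out[grepl("^(IGHM|IGM)", up) | x == "IgM"] <- "IgM"
  out
}

#' Read a clonotype table from an AIRR or MiXCR-style TSV
#'
#' Reads a tab-separated rearrangement table with a header row and returns a
#' canonical clonotype table. Gene calls are truncated to gene level (allele
#' suffix after `*` dropped); multi-hit calls keep the first, top-scoring
#' hit. Rows whose count does not parse as a number are dropped with a
#' warning. Chain is taken from the mapped chain column when present and
#' otherwise inferred from the V (or J) call prefix; isotype is normalized
#' from the constant-region call for IGH rows.
#'
#' @param path TSV file path.
#' @param column_map named list mapping canonical fields to input column
#'   names; see [airr_column_map()] and [mixcr_column_map()]. Fields
#'   `count`, `cdr3_nt`, `cdr3_aa`, `v_call` and `j_call` must resolve to
#'   existing columns.
#' @return a clonotype `data.frame` (possibly empty).
#' @export
read_airr_table <- function(path, column_map = airr_column_map()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  required <- c("count", "cdr3_nt", "cdr3_aa", "v_call", "j_call")
  for (field in required) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      stopf("required column '%s' (field '%s') not found in %s",
            col %||% "<unmapped>", field, path)
  }
  if (nrow(raw) == 0) {
    warnf("empty clonotype file: %s", path)
    return(empty_clonotypes())
  }
  get_col <- function(field, default = "") {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  count_raw <- suppressWarnings(as.numeric(get_col("count")))
  keep <- is.finite(count_raw)
  if (any(!keep))
    warnf("dropping %d row(s) with unparseable counts in %s", sum(!keep), path)
  raw <- raw[keep, , drop = FALSE]
  count <- as.integer(round(count_raw[keep]))
  if (nrow(raw) == 0) return(empty_clonotypes())

  v_call <- clean_gene_call(get_col("v_call"))
  d_call <- clean_gene_call(get_col("d_call"))
  j_call <- clean_gene_call(get_col("j_call"))
  chain <- get_col("chain", default = NA_character_)
  chain <- ifelse(is.na(chain) | !nzchar(chain), infer_chain(v_call, j_call),
                  toupper(chain))
  chain[substr(chain, 1, 2) == "IG"] <- "IGH"
  isotype <- normalize_isotype(get_col("isotype"))
  isotype[chain != "IGH"] <- NA_character_
  # IGH rows without a parseable constant-region call default to IgM (naive
  # default) only if the table carries no isotype column at all; otherwise
  # they are dropped to avoid fabricating class-switch state.
  if (!is.null(column_map[["isotype"]]) &&
      column_map[["isotype"]] %in% names(raw)) {
    bad_iso <- chain == "IGH" & is.na(isotype)
    if (any(bad_iso)) {
      warnf("dropping %d IGH row(s) with unrecognized isotype in %s",
            sum(bad_iso), path)
      sel <- !bad_iso
      raw <- raw[sel, , drop = FALSE]; count <- count[sel]
      v_call <- v_call[sel]; d_call <- d_call[sel]; j_call <- j_call[sel]
      chain <- chain[sel]; isotype <- isotype[sel]
    }
  } else {
    isotype[chain == "IGH" & is.na(isotype)] <- "IgM"
  }
  vm_raw <- if (!is.null(column_map[["v_mismatches"]]) &&
                column_map[["v_mismatches"]] %in% names(raw))
    suppressWarnings(as.integer(raw[[column_map[["v_mismatches"]]]]))
  else rep(NA_integer_, nrow(raw))
  ids <- if (!is.null(column_map[["clone_id"]]) &&
             column_map[["clone_id"]] %in% names(raw)) raw[[column_map[["clone_id"]]]]
  else sprintf("row%05d", seq_len(nrow(raw)))

  clonotype_table(count = count,
                  cdr3_nt = toupper(raw[[column_map[["cdr3_nt"]]]]),
                  cdr3_aa = raw[[column_map[["cdr3_aa"]]]],
                  v_call = v_call, d_call = d_call, j_call = j_call,
                  chain = chain, isotype = isotype,
                  v_mismatches = vm_raw, clone_id = ids)
}

empty_clonotypes <- function() {
  clonotype_table(count = integer(0), cdr3_nt = character(0),
                  cdr3_aa = character(0), v_call = character(0),
                  j_call = character(0), d_call = character(0),
                  chain = character(0), isotype = character(0),
                  v_mismatches = integer(0), clone_id = character(0))
}

#' Write a clonotype table as a normalized AIRR-style TSV
#'
#' Fixed column order, tab-separated, UTF-8, LF line endings. The output is
#' readable back with [read_airr_table()] and the default column map.
#'
#' @param clonotypes clonotype `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(clonotypes, path) {
  clonotypes <- validate_clonotypes(clonotypes)
  out <- data.frame(
    sequence_id = clonotypes$clone_id,
    duplicate_count = clonotypes$count,
    junction = clonotypes$cdr3_nt,
    junction_aa = clonotypes$cdr3_aa,
    v_call = clonotypes$v_call,
    d_call = clonotypes$d_call,
    j_call = clonotypes$j_call,
    locus = clonotypes$chain,
    c_call = ifelse(is.na(clonotypes$isotype), "", clonotypes$isotype),
    v_mismatch_count = ifelse(is.na(clonotypes$v_mismatches), "",
                              clonotypes$v_mismatches),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

has_stop_codon <- function(cdr3_nt, cdr3_aa) {
  # amino-acid symbols when available ('*' stop, '_' frameshift), otherwise
  # translate the nucleotide sequence in frame 0 and scan for stop codons
  if (!is.na(cdr3_aa) && nzchar(cdr3_aa)) return(grepl("[*_]", cdr3_aa))
  if (is.na(cdr3_nt) || !nzchar(cdr3_nt)) return(FALSE)
  n <- nchar(cdr3_nt) %/% 3
  if (n == 0) return(FALSE)
  codons <- substring(cdr3_nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  any(codons %in% STOP_CODONS)
}

#' Filter clonotypes to productive rearrangements
#'
#' Retains exactly the clonotypes that satisfy all three productive-read
#' rules: CDR3 amino-acid length >= 4, CDR3 nucleotide length a multiple of
#' 3, and no stop codon (no `*` or `_` in the amino-acid sequence; when the
#' amino-acid sequence is absent the nucleotide sequence is translated in
#' frame 0). Row order and counts are untouched; the filter is idempotent.
#'
#' @param clonotypes clonotype `data.frame`.
#' @return the retained rows.
#' @export
filter_productive <- function(clonotypes) {
  if (nrow(clonotypes) == 0) return(clonotypes)
  aa_len_ok <- nchar(clonotypes$cdr3_aa) >= 4
  frame_ok <- nchar(clonotypes$cdr3_nt) %% 3 == 0
  no_stop <- !mapply(has_stop_codon, clonotypes$cdr3_nt, clonotypes$cdr3_aa)
  clonotypes[aa_len_ok & frame_ok & no_stop, , drop = FALSE]
}

#' Bundle a clonotype table with its sample identity
#'
#' @param patient_id patient identifier.
#' @param tissue `"tumor"` or `"non_tumor"`.
#' @param chain receptor chain of the sample; all clonotypes must share it.
#' @param clonotypes clonotype `data.frame`.
#' @param isotype_view optional isotype restriction recorded on the sample.
#' @return an object of class `repertoire_sample`.
#' @export
repertoire_sample <- function(patient_id, tissue, chain, clonotypes,
                              isotype_view = NA_character_) {
  tissue <- match.arg(tissue, c("tumor", "non_tumor"))
  chain <- match.arg(chain, VALID_CHAINS)
  clonotypes <- validate_clonotypes(clonotypes)
  if (nrow(clonotypes) && any(clonotypes$chain != chain))
    stopf("all clonotypes must have chain %s", chain)
  structure(list(patient_id = as.character(patient_id), tissue = tissue,
                 chain = chain, isotype_view = isotype_view,
                 clonotypes = clonotypes),
            class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf("<repertoire_sample> %s / %s / %s: %d clonotypes, %d reads\n",
              x$patient_id, x$tissue, x$chain, nrow(x$clonotypes),
              sum(x$clonotypes$count)))
  invisible(x)
}

#' Restrict an IGH sample to one isotype
#'
#' @param sample a `repertoire_sample` with chain IGH.
#' @param isotype one of IgA, IgG, IgM.
#' @return a `repertoire_sample` containing only that isotype's clonotypes.
#' @export
subset_isotype <- function(sample, isotype) {
  if (sample$chain != "IGH") stopf("isotype views require an IGH sample")
  isotype <- match.arg(isotype, VALID_ISOTYPES)
  keep <- !is.na(sample$clonotypes$isotype) & sample$clonotypes$isotype == isotype
  repertoire_sample(sample$patient_id, sample$tissue, sample$chain,
                    sample$clonotypes[keep, , drop = FALSE],
                    isotype_view = isotype)
}

#' Read clinical metadata
#'
#' Reads a clinical table (CSV or TSV by extension) with one row per patient.
#' The TNM stage column is collapsed to a stage group: stage 1 is early,
#' stage 2 and above advanced. Survival times must be non-negative and event
#' flags 0/1.
#'
#' @param path CSV/TSV file path with a header row. Expected columns:
#'   `patient_id`, `tnm_stage` (or `stage`), `recurrence`, and per-endpoint
#'   `pfs_months`/`pfs_event`, `rfs_months`/`rfs_event`,
#'   `os_months`/`os_event`; other columns (sex, age band, covariates) pass
#'   through unchanged.
#' @return a `data.frame` with a derived `stage_group` factor column.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stage_col <- intersect(c("tnm_stage", "stage"), names(df))[1]
  if (!is.na(stage_col)) {
    stage_num <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1",
                                                 as.character(df[[stage_col]]))))
    df$stage_group <- ifelse(is.na(stage_num), NA_character_,
                             ifelse(stage_num <= 1, "early", "advanced"))
  }
  time_cols <- intersect(c("pfs_months", "rfs_months", "os_months"), names(df))
  for (col in time_cols) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stopf("negative %s in row(s): %s", col, paste(bad, collapse = ", "))
  }
  event_cols <- intersect(c("pfs_event", "rfs_event", "os_event"), names(df))
  for (col in event_cols) {
    df[[col]] <- as.integer(df[[col]])
    if (any(!df[[col]] %in% c(0L, 1L), na.rm = TRUE))
      stopf("%s must be 0/1", col)
  }
  df
}
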