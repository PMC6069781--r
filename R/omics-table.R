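#' Per-gene multi-omic table
#'
#' An `omics_table` holds the continuous omic values attached to each gene of
#' the organism: protein abundance (`pa`, parts per million), codon adaptation
#' index (`cai`, in \[0, 1\]) and one protein-variation column per treatment
#' (`pv:<treatment-id>`).  Values may be missing (`NA`); missing values
#' propagate through normalization and exclude the gene from discretized
#' patterns.
#'
#' @param gene_id character vector of unique locus tags (e.g. b-numbers).
#' @param pa numeric vector of protein abundances, non-negative where present.
#' @param cai numeric vector of codon adaptation indices in \[0, 1\].
#' @param pv optional data.frame (or named list of numeric vectors) with one
#'   column per treatment id.
#'
#' @return An object of class `omics_table`: a data.frame with columns
#'   `gene_id`, `pa`, `cai` and one `pv:<id>` column per treatment.
#' @export
omics_table <- function(gene_id, pa = NULL, cai = NULL, pv = NULL) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop_mora("duplicate gene_id: %s", paste(dup, collapse = ", "))
  }
  pa <- if (is.null(pa)) rep(NA_real_, n) else as.numeric(pa)
  cai <- if (is.null(cai)) rep(NA_real_, n) else as.numeric(cai)
  if (length(pa) != n || length(cai) != n)
    stop_mora("pa and cai must have one value per gene")
  bad_cai <- which(!is.na(cai) & (cai < 0 | cai > 1))
  if (length(bad_cai))
    stop_mora("cai outside [0,1] for gene(s): %s",
              paste(gene_id[bad_cai], collapse = ", "))
  bad_pa <- which(!is.na(pa) & pa < 0)
  if (length(bad_pa))
    stop_mora("negative pa for gene(s): %s",
              paste(gene_id[bad_pa], collapse = ", "))
  tab <- data.frame(gene_id = gene_id, pa = pa, cai = cai,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(pv)) {
    pv <- as.data.frame(pv, check.names = FALSE)
    if (nrow(pv) != n) stop_mora("pv must have one row per gene")
    nm <- names(pv)
    names(pv) <- ifelse(startsWith(nm, "pv:"), nm, paste0("pv:", nm))
    tab <- cbind(tab, pv)
  }
  class(tab) <- c("omics_table", "data.frame")
  tab
}

#' Treatment ids present in an omics table
#' @param table an `omics_table`.
#' @return character vector of treatment ids (without the `pv:` prefix).
#' @export
treatments <- function(table) {
  nm <- names(table)
  sub("^pv:", "", nm[startsWith(nm, "pv:")])
}

#' Read a per-gene multi-omic table from TSV
#'
#' Expects a tab-separated file with header columns `gene_id`, `pa`, `cai`
#' and optionally one column per treatment named `pv:<treatment-id>`.
#' Lines starting with `#` are comments.  Unparsable numeric cells become
#' missing values.
#'
#' @param path path to the TSV file.
#' @return an [omics_table].
#' @export
read_omics_table <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  need <- c("gene_id", "pa", "cai")
  if (!all(need %in% names(raw)))
    stop_mora("omics TSV must have columns %s", paste(need, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  pvcols <- names(raw)[startsWith(names(raw), "pv:")]
  pv <- if (length(pvcols)) {
    as.data.frame(lapply(raw[pvcols], num), check.names = FALSE,
                  col.names = pvcols)
  } else NULL
  omics_table(raw$gene_id, num(raw$pa), num(raw$cai), pv)
}

#' Write a multi-omic table to TSV
#' @param table an [omics_table].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_omics_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
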