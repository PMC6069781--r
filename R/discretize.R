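#' Zero-mean unit-variance normalization
#'
#' Standardizes a numeric vector to mean 0 and population variance 1
#' (denominator n).  Missing values are excluded from the mean and variance
#' and stay missing in the output.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @param what label used in error messages (the omic being normalized).
#' @return numeric vector of z-scores, same length as `values`.
#' @export
zscore <- function(values, what = "values") {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop_mora("zscore(%s): need at least 2 non-missing values", what)
  mu <- mean(values[ok])
  s2 <- mean((values[ok] - mu)^2)
  if (s2 <= .Machine$double.eps * max(1, mu^2))
    stop_mora("zscore(%s): zero variance", what)
  (values - mu) / sqrt(s2)
}

#' Local and global effect vectors for one pathway
#'
#' The dual normalization: each omic is z-scored twice, once over the whole
#' organism (global effect, `mov2`) and once over the pathway members only
#' (local effect, `mov1`).  The dynamic omic is protein abundance in steady
#' state, or protein variation under a treatment; the static omic is always
#' the codon adaptation index.  Genes with a missing value in either omic are
#' excluded from both vectors (a message reports the count), so the two
#' vectors always have equal length and identical gene order.
#'
#' @param table an [omics_table] covering the pathway members.
#' @param pathway a [gene_ordered_pathway].
#' @param condition `"steady"`, `"avg"` (average over all treatments of the
#'   globally/locally normalized protein variations, averaged before
#'   discretization), or a treatment id present in the table.
#' @return object of class `effect_vectors`: list with `gene_ids` (usable
#'   members in gene order), `local` and `global` (each a list with numeric
#'   `dyn` and `cai`), `condition`, `n_excluded`.
#' @export
effect_vectors <- function(table, pathway, condition = "steady") {
  stopifnot(inherits(table, "omics_table"),
            inherits(pathway, "gene_ordered_pathway"))
  idx <- match(pathway$members, table$gene_id)
  if (anyNA(idx))
    stop_mora("pathway %s: member(s) absent from the omics table: %s",
              pathway$pathway_id,
              paste(pathway$members[is.na(idx)], collapse = ", "))

  dyn_cols <- dynamic_columns(table, condition)
  # Global z-scores over ALL genes, then subset to the pathway in gene order.
  g_dyn_all <- dyn_normalized(table, dyn_cols, scope = seq_len(nrow(table)))
  g_cai_all <- zscore(table$cai, "cai")
  g_dyn <- g_dyn_all[idx]
  g_cai <- g_cai_all[idx]

  usable <- !is.na(g_dyn) & !is.na(g_cai)
  if (sum(usable) < 2L)
    stop_mora("pathway %s: fewer than 2 members with usable omic values",
              pathway$pathway_id)
  n_excluded <- sum(!usable)
  if (n_excluded)
    message(sprintf("pathway %s: excluded %d gene(s) with missing omics",
                    pathway$pathway_id, n_excluded))

  keep <- idx[usable]
  # Local z-scores computed over the pathway members only (usable ones).
  l_dyn <- dyn_normalized(table, dyn_cols, scope = keep)[keep]
  l_cai <- zscore(replace(rep(NA_real_, nrow(table)), keep,
                          table$cai[keep]), "cai")[keep]

  structure(list(gene_ids = table$gene_id[keep],
                 local = list(dyn = l_dyn, cai = l_cai),
                 global = list(dyn = g_dyn[usable], cai = g_cai[usable]),
                 condition = condition,
                 n_excluded = n_excluded),
            class = "effect_vectors")
}

# Resolve the dynamic-omic column(s) for a condition.
#' @noRd
dynamic_columns <- function(table, condition) {
  if (identical(condition, "steady")) return("pa")
  trts <- treatments(table)
  if (identical(condition, "avg") || identical(condition, "treatment_average")) {
    if (!length(trts)) stop_mora("no treatment columns in the omics table")
    return(paste0("pv:", trts))
  }
  col <- paste0("pv:", condition)
  if (!col %in% names(table))
    stop_mora("unknown condition '%s' (expected 'steady', 'avg' or one of: %s)",
              condition, paste(trts, collapse = ", "))
  col
}

# z-score the dynamic omic within `scope` row indices; for multi-column
# (treatment-average) conditions each treatment is normalized separately and
# the normalized values are averaged, before any discretization.
#' @noRd
dyn_normalized <- function(table, cols, scope) {
  n <- nrow(table)
  zs <- lapply(cols, function(cl) {
    x <- rep(NA_real_, n)
    x[scope] <- table[[cl]][scope]
    zscore(x, cl)
  })
  if (length(zs) == 1L) return(zs[[1L]])
  m <- do.call(cbind, zs)
  out <- rowMeans(m, na.rm = TRUE)
  out[!rowSums(!is.na(m))] <- NA_real_
  out
}

#' Binary discretization of effect vectors
#'
#' Each gene's two normalized omics are averaged and thresholded at zero:
#' class 1 when `(dyn + cai)/2 >= 0` (the boundary is inclusive), class 0
#' otherwise.  Applied to the local and the global effect independently.
#'
#' @param effects an [effect_vectors] object.
#' @return list with `mov1` (local) and `mov2` (global), both
#'   [binary_pattern]s over the same positions.
#' @export
binarize <- function(effects) {
  stopifnot(inherits(effects, "effect_vectors"))
  one <- function(v) {
    s <- (v$dyn + v$cai) / 2
    binary_pattern(as.integer(s >= 0), effects$gene_ids, 2L)
  }
  list(mov1 = one(effects$local), mov2 = one(effects$global))
}

#' OR-combination of local and global oscillations
#'
#' Scans adjacent index pairs left to right.  Where the local pattern does
#' not alternate (`|e_j - e_{j+1}| = 0`) but the global pattern does
#' alternate at the same pair, the global pair of values is copied into the
#' result; positions already substituted by an earlier pair are not
#' overwritten.  This combines the pathway-local response with the
#' organism-wide one in the binary field.
#'
#' @param mov1_bin local-effect [binary_pattern].
#' @param mov2_bin global-effect [binary_pattern], same length.
#' @return the combined [binary_pattern].
#' @export
combine_local_global <- function(mov1_bin, mov2_bin) {
  v1 <- mov1_bin$values
  v2 <- mov2_bin$values
  if (length(v1) != length(v2))
    stop_mora("local and global patterns must have equal length")
  out <- v1
  substituted <- logical(length(v1))
  for (j in seq_len(length(v1) - 1L)) {
    if (v1[j] == v1[j + 1L] && v2[j] != v2[j + 1L]) {
      for (z in c(j, j + 1L)) {
        if (!substituted[z]) {
          out[z] <- v2[z]
          substituted[z] <- TRUE
        }
      }
    }
  }
  binary_pattern(out, mov1_bin$positions, mov1_bin$n_levels)
}

#' Organism-wide binary values for one condition
#'
#' Discretizes every gene of the table using the global normalization only
#' (the global effect of the dual scheme).  Used to value nodes inserted by
#' path extension, which predate no pathway-local normalization.
#'
#' @inheritParams effect_vectors
#' @return named integer vector (0/1) over genes with usable values; genes
#'   with missing omics are absent.
#' @export
global_binary_values <- function(table, condition = "steady") {
  dyn <- dyn_normalized(table, dynamic_columns(table, condition),
                        scope = seq_len(nrow(table)))
  cai <- zscore(table$cai, "cai")
  s <- (dyn + cai) / 2
  ok <- !is.na(s)
  stats::setNames(as.integer(s[ok] >= 0), table$gene_id[ok])
}
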