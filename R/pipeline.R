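#' Combined / competitor classification
#'
#' An MLS is *combined* when oscillating multi-omics are present at the same
#' time on the pattern and on the network motif: similarity strictly above
#' `sigma_threshold` and anti-dyadic magnitude strictly above
#' `anti_threshold`.  Anything else (including an undefined anti-dyadic
#' magnitude, which warns) is a *competitor*.
#'
#' @param sigma_obs pattern similarity in \[0, 1\].
#' @param hat_anti anti-dyadic magnitude (may be `NA`).
#' @param sigma_threshold default 0.7.
#' @param anti_threshold default 1.0.
#' @return logical: `TRUE` for combined.
#' @export
classify_combined <- function(sigma_obs, hat_anti, sigma_threshold = 0.7,
                              anti_threshold = 1.0) {
  if (is.na(hat_anti)) {
    warn_mora("undefined anti-dyadic magnitude: classified competitor")
    return(FALSE)
  }
  sigma_obs > sigma_threshold && hat_anti > anti_threshold
}

# One pathway x setup x condition summary row.
#' @noRd
summarize_mls <- function(m, config, sigma_threshold, anti_threshold) {
  osc <- similarity(m$pattern)
  labels <- mls_node_labels(m)
  sub <- induced_network(m$pathway$subgraph, names(labels))
  dy <- dyad_magnitudes(count_dyads(sub, labels))
  iv <- mora(m, config)
  comb <- suppressWarnings(classify_combined(osc$sigma_obs, dy$hat_anti,
                                             sigma_threshold, anti_threshold))
  mo <- suppressWarnings(mainly_oscillating(dy))
  data.frame(pathway_id = m$pathway$pathway_id,
             setup = m$setup, condition = m$condition,
             sigma_obs = osc$sigma_obs,
             hat10 = dy$hat_anti, hat0011 = dy$hat0011,
             ri = iv$ri,
             combined = comb, mainly_oscillating = mo,
             stringsAsFactors = FALSE)
}

#' Run the full oscillation pipeline
#'
#' For each pathway, experimental set-up and condition: dual-normalize and
#' binarize the omics (OR-combining local and global oscillations), apply
#' the MLS modification of the set-up, then score the pattern
#' (`sigma_obs`), the network motif (dyadic/anti-dyadic magnitudes) and the
#' sequence-pathway interplay (MORA RI), and classify the MLS as combined
#' or competitor.  Failing pathways are logged and skipped; the run
#' continues.
#'
#' @param omics an [omics_table].
#' @param network the global [metabolic_network].
#' @param pathways list of [gene_ordered_pathway] (e.g. from
#'   [read_pathways()]).
#' @param operons an [operon_map] (needed by the `opc` set-ups; may be
#'   `NULL` when none requested).
#' @param setups subset of `c("plain", "opc", "ext", "opc+ext")`.
#' @param conditions character vector: `"steady"`, `"avg"` and/or
#'   treatment ids.
#' @param sigma_threshold,anti_threshold combined-classification thresholds.
#' @param apl_ceiling optional override of `ceiling(APL)` of the global
#'   network.
#' @param include_wraparound passed to [mora_config()].
#' @return data.frame of summary rows, sorted by pathway, setup, condition.
#' @export
run_pipeline <- function(omics, network, pathways, operons = NULL,
                         setups = c("plain", "opc", "ext", "opc+ext"),
                         conditions = "steady",
                         sigma_threshold = 0.7, anti_threshold = 1.0,
                         apl_ceiling = NULL, include_wraparound = TRUE) {
  setups <- match.arg(setups, several.ok = TRUE)
  if (any(grepl("opc", setups)) && is.null(operons))
    stop_mora("operon map required for the opc set-ups")
  ceiling_val <- apl_ceiling %||% ceiling(average_path_length(network))
  config <- mora_config(ceiling_val, include_wraparound = include_wraparound)

  rows <- list()
  for (cond in conditions) {
    gvals <- global_binary_values(omics, cond)
    for (pw in pathways) {
      res <- tryCatch({
        ev <- suppressMessages(effect_vectors(omics, pw, cond))
        bins <- binarize(ev)
        pattern <- combine_local_global(bins$mov1, bins$mov2)
        base <- build_mls(pw, pattern, setup = "plain", condition = cond)
        lapply(setups, function(s) {
          m <- base
          if (grepl("opc", s))
            m <- suppressWarnings(operon_compression(m, operons))
          if (grepl("ext", s))
            m <- suppressWarnings(
              path_extension(m, network, gvals, config))
          m$setup <- s
          summarize_mls(m, config, sigma_threshold, anti_threshold)
        })
      }, error = function(e) {
        message(sprintf("pathway %s [%s]: skipped (%s)",
                        pw$pathway_id, cond, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows <- c(rows, res)
    }
  }
  if (!length(rows))
    stop_mora("all pathways failed; nothing to summarize")
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway_id, out$setup, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pipeline summaries to TSV
#'
#' Stable column order `pathway_id, setup, condition, sigma_obs, hat10,
#' hat0011, ri, combined, mainly_oscillating`; floats at 4 decimals; rows
#' sorted by `(pathway_id, setup)`.
#'
#' @param rows data.frame from [run_pipeline()] (non-empty).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_summaries <- function(rows, path) {
  if (!is.data.frame(rows) || !nrow(rows))
    stop_mora("no summary rows to write")
  cols <- c("pathway_id", "setup", "condition", "sigma_obs", "hat10",
            "hat0011", "ri", "combined", "mainly_oscillating")
  if (!all(cols %in% names(rows)))
    stop_mora("summary rows lack column(s): %s",
              paste(setdiff(cols, names(rows)), collapse = ", "))
  rows <- rows[order(rows$pathway_id, rows$setup), cols, drop = FALSE]
  out <- rows
  for (cl in c("sigma_obs", "hat10", "hat0011", "ri")) out[[cl]] <- fmt4(rows[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a summary TSV written by [write_summaries()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_summaries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Cohort statistics over pipeline summaries
#'
#' Median and sample standard deviation of each score, plus combined and
#' mainly-oscillating counts, per (setup, condition) cell — the per-cohort
#' view used to compare experimental set-ups.
#'
#' @param rows data.frame from [run_pipeline()].
#' @return data.frame with one row per (setup, condition).
#' @export
cohort_stats <- function(rows) {
  cells <- split(rows, list(rows$setup, rows$condition), drop = TRUE)
  out <- lapply(cells, function(d) {
    data.frame(setup = d$setup[[1L]], condition = d$condition[[1L]],
               n = nrow(d),
               median_sigma = stats::median(d$sigma_obs, na.rm = TRUE),
               sd_sigma = stats::sd(d$sigma_obs, na.rm = TRUE),
               median_hat10 = stats::median(d$hat10, na.rm = TRUE),
               sd_hat10 = stats::sd(d$hat10, na.rm = TRUE),
               median_ri = stats::median(d$ri, na.rm = TRUE),
               sd_ri = stats::sd(d$ri, na.rm = TRUE),
               n_combined = sum(d$combined),
               n_mainly_oscillating = sum(d$mainly_oscillating),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$setup, out$condition), , drop = FALSE]
}
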