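## Ratio-to-pooled-reference quantification and cross-plex merging.
##
## Each plex carries one or more pooled internal-reference channels made by
## mixing every sample of the study equally. Per protein, the reference
## abundance is the arithmetic mean of that plex's pooled channels, and each
## sample's relative abundance is its summed reporter intensity divided by
## the reference. Because the reference sits inside the plex, any plex-wide
## scale factor (labeling efficiency, instrument response, injection amount)
## cancels exactly, which is what makes ratios comparable across plexes.

#' Relative abundance against the pooled reference (one plex)
#'
#' Per protein, reference abundance is the arithmetic mean of the plex's
#' pooled-reference channel intensities (missing pooled channels are ignored;
#' the mean of those observed is used). Sample values are intensity divided
#' by the reference. Proteins whose reference is entirely missing or zero are
#' dropped and reported in the `dropped` field.
#'
#' @param table A `reporter_table` from [read_intensity_table()] or
#'   [simulate_plexes()].
#' @param design The matching [plex_design()].
#' @return A `rel_abundance` object: list with `accessions`, `annotations`,
#'   `samples` (sample_id, plex_id, group, replicate), `values` (protein x
#'   sample ratio matrix), `reference_columns` (per-protein ratios of the
#'   individual pooled channels to their mean, kept for CV QC) and `dropped`.
#' @export
relative_abundance <- function(table, design) {
  if (!identical(sort(colnames(table$intensities)), sort(design$channel))) {
    stop("intensity table channels do not match design channels for plex ",
         design_plex_id(design), call. = FALSE)
  }
  ints <- table$intensities[, design$channel, drop = FALSE]
  is_ref <- design$group == .POOLED_REF
  refvals <- ints[, design$channel[is_ref], drop = FALSE]
  ref <- rowMeans(refvals, na.rm = TRUE)
  keep <- is.finite(ref) & ref > 0
  if (!any(keep)) {
    stop("no quantifiable proteins: every protein has missing or zero ",
         "pooled-reference intensity in plex ", design_plex_id(design),
         call. = FALSE)
  }
  dropped <- table$accessions[!keep]
  if (length(dropped) > 0L) {
    message(length(dropped), " protein(s) dropped in plex ",
            design_plex_id(design), " (missing or zero pooled reference)")
  }
  samp_idx <- which(!is_ref)
  values <- ints[keep, design$channel[samp_idx], drop = FALSE] / ref[keep]
  colnames(values) <- design$sample_id[samp_idx]
  ref_cols <- refvals[keep, , drop = FALSE] / ref[keep]
  colnames(ref_cols) <- paste(design_plex_id(design),
                              design$channel[is_ref], sep = ":")
  samples <- data.frame(sample_id = design$sample_id[samp_idx],
                        plex_id = design_plex_id(design),
                        group = design$group[samp_idx],
                        replicate = design$replicate[samp_idx],
                        stringsAsFactors = FALSE)
  structure(list(accessions = table$accessions[keep],
                 annotations = table$annotations[keep, , drop = FALSE],
                 samples = samples, values = values,
                 reference_columns = ref_cols, dropped = dropped),
            class = "rel_abundance")
}

#' Merge per-plex relative-abundance matrices over common proteins
#'
#' Keeps only proteins quantified (non-missing) in every sample column and
#' every retained pooled-reference column of every plex - the
#' "commonly detected" set that downstream differential and pathway analyses
#' use as their universe - and concatenates sample columns. Counts of total
#' detected versus overlapping proteins are stored as attributes
#' `n_total_detected` and `n_overlap`.
#'
#' @param matrices List of `rel_abundance` objects with disjoint samples.
#' @return A merged `rel_abundance`.
#' @export
merge_common <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  samp <- unlist(lapply(matrices, function(m) m$samples$sample_id))
  if (anyDuplicated(samp)) {
    stop("sample_ids are not disjoint across matrices", call. = FALSE)
  }
  complete_in <- function(m) {
    ok <- rowSums(is.na(m$values)) == 0L & rowSums(is.na(m$reference_columns)) == 0L
    m$accessions[ok]
  }
  common <- Reduce(intersect, lapply(matrices, complete_in))
  n_total <- length(unique(unlist(lapply(matrices, function(m) m$accessions))))
  if (length(common) == 0L) {
    stop("no protein is quantified in every sample of every plex; ",
         "inspect per-plex missingness before merging", call. = FALSE)
  }
  common <- sort(common)
  pick <- function(m) {
    i <- match(common, m$accessions)
    list(values = m$values[i, , drop = FALSE],
         refs = m$reference_columns[i, , drop = FALSE],
         ann = m$annotations[i, , drop = FALSE])
  }
  parts <- lapply(matrices, pick)
  out <- structure(list(
    accessions = common,
    annotations = parts[[1L]]$ann,
    samples = do.call(rbind, lapply(matrices, function(m) m$samples)),
    values = do.call(cbind, lapply(parts, function(p) p$values)),
    reference_columns = do.call(cbind, lapply(parts, function(p) p$refs)),
    dropped = unique(unlist(lapply(matrices, function(m) m$dropped)))),
    class = "rel_abundance")
  rownames(out$samples) <- NULL
  attr(out, "n_total_detected") <- n_total
  attr(out, "n_overlap") <- length(common)
  out
}

#' Pooled-channel coefficient-of-variation report
#'
#' Reproducibility QC: per protein, the coefficient of variation (sample
#' standard deviation over mean, reported in percent) of the retained
#' pooled-reference channel ratios, combined across all plexes and per plex
#' (plexes contributing at least two pooled channels). Summaries give the
#' fraction of proteins under 5% CV and the median CV.
#'
#' @param merged A `rel_abundance` with at least two pooled-reference columns.
#' @return A `cv_report`: list with `per_protein` (data frame of CVs in
#'   percent) and `summary` (named list of fractions and medians).
#' @export
pooled_cv <- function(merged) {
  refs <- merged$reference_columns
  if (is.null(refs) || ncol(refs) < 2L) {
    stop("pooled CV needs at least 2 pooled-reference ratio columns",
         call. = FALSE)
  }
  cv_pct <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    100 * s / mu
  }
  per <- data.frame(accession = merged$accessions,
                    cv_percent = cv_pct(refs),
                    stringsAsFactors = FALSE)
  plex_of <- sub(":.*$", "", colnames(refs))
  summary <- list(
    n_pooled_columns = ncol(refs),
    median_cv_percent = stats::median(per$cv_percent),
    frac_cv_lt5 = mean(per$cv_percent < 5))
  for (p in unique(plex_of)) {
    cols <- which(plex_of == p)
    if (length(cols) >= 2L) {
      v <- cv_pct(refs[, cols, drop = FALSE])
      per[[paste0("cv_percent_", p)]] <- v
      summary[[paste0("frac_cv_lt5_", p)]] <- mean(v < 5)
      summary[[paste0("median_cv_percent_", p)]] <- stats::median(v)
    }
  }
  structure(list(per_protein = per, summary = summary), class = "cv_report")
}
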