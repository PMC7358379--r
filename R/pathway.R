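## Pathway-level statistics: the treatment-specific dysregulation score
## (percent change versus percent coverage), right-tailed Fisher
## (hypergeometric) enrichment with a selectable background universe, and a
## functional-class breakdown of changed mitochondrial proteins.

#' Treatment-specific pathway dysregulation
#'
#' For each pathway: `percent_coverage` is 100 times the number of pathway
#' members among the commonly detected proteins divided by the pathway's full
#' annotated size. Per treatment, `percent_change` is 100 times the number of
#' significantly changed detected members divided by the number of detected
#' members. A (pathway, treatment) pair is flagged treatment-specific when
#' its percent change meets or exceeds the percent coverage (`tie = "ge"`,
#' the default; `tie = "gt"` requires a strict excess). Pathways with no
#' detected member get `percent_coverage = 0`, undefined (`NA`) percent
#' change and no flags.
#'
#' @param pathways List of `pathway_annotation` objects (see [read_gmt()]).
#' @param detected Character vector: the commonly detected protein universe.
#' @param changed_by_treatment Named list of character vectors: per treatment,
#'   the significantly changed proteins (subsets of `detected`).
#' @param tie `"ge"` (flag on percent_change >= percent_coverage) or `"gt"`.
#' @return Long data frame: one row per (pathway, treatment) with
#'   `pathway_id`, `treatment`, `n_annotated`, `n_detected`,
#'   `percent_coverage`, `n_changed`, `percent_change`, `flag`.
#' @export
pathway_dysregulation <- function(pathways, detected, changed_by_treatment,
                                  tie = c("ge", "gt")) {
  tie <- match.arg(tie)
  detected <- unique(detected)
  treatments <- names(changed_by_treatment)
  stopifnot(length(treatments) >= 1L)
  for (g in treatments) {
    extra <- setdiff(changed_by_treatment[[g]], detected)
    if (length(extra) > 0L) {
      stop("changed set for '", g, "' contains proteins outside the ",
           "detected universe: ", paste(utils::head(extra, 3L), collapse = ", "),
           call. = FALSE)
    }
  }
  rows <- lapply(pathways, function(p) {
    members <- unique(p$members)
    det <- intersect(members, detected)
    n_det <- length(det)
    cov <- 100 * n_det / length(members)
    n_changed <- vapply(treatments, function(g)
      length(intersect(det, changed_by_treatment[[g]])), integer(1L))
    pct <- if (n_det > 0L) 100 * n_changed / n_det else rep(NA_real_, length(treatments))
    flag <- if (n_det > 0L) {
      if (tie == "ge") pct >= cov else pct > cov
    } else rep(FALSE, length(treatments))
    data.frame(pathway_id = p$pathway_id, treatment = treatments,
               n_annotated = length(members), n_detected = n_det,
               percent_coverage = cov, n_changed = n_changed,
               percent_change = pct, flag = flag,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Right-tailed Fisher (hypergeometric) enrichment of one pathway
#'
#' Tests over-representation of changed proteins among a pathway's members
#' against a chosen background universe: `p = P(X >= k)` for a
#' hypergeometric draw of `n = |changed|` from `N = |background|` containing
#' `K` pathway members, where `k` is the observed overlap. The
#' `background_mode` label records whether the background is the full
#' annotation universe (`"global_annotation"`) or the study's commonly
#' detected proteins (`"user_dataset"`); restricting the background to
#' detected proteins removes detection bias from the test.
#'
#' @param pathway A `pathway_annotation`.
#' @param changed Character vector of changed proteins (subset of
#'   `background`).
#' @param background Character vector: the background universe.
#' @param mode `"user_dataset"` or `"global_annotation"` (label only; the
#'   universe itself is `background`).
#' @return An `enrichment_result` list with `pathway_id`, `background_mode`,
#'   `k`, `K`, `n`, `N`, `p_value` and the `overlap` member vector.
#' @export
fisher_enrichment <- function(pathway, changed, background,
                              mode = c("user_dataset", "global_annotation")) {
  mode <- match.arg(mode)
  background <- unique(background)
  changed <- unique(changed)
  if (length(background) == 0L) stop("background is empty", call. = FALSE)
  if (length(setdiff(changed, background)) > 0L) {
    stop("changed set is not a subset of the background", call. = FALSE)
  }
  members <- intersect(unique(pathway$members), background)
  overlap <- intersect(changed, members)
  k <- length(overlap); K <- length(members)
  n <- length(changed); N <- length(background)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(pathway_id = pathway$pathway_id, background_mode = mode,
                 k = k, K = K, n = n, N = N, p_value = p, overlap = overlap),
            class = "enrichment_result")
}

#' Enrichment table across pathways and treatments
#'
#' Runs [fisher_enrichment()] for every pathway and every treatment's changed
#' set against one background.
#'
#' @param pathways List of `pathway_annotation` objects.
#' @param changed_by_treatment Named list of changed-protein sets.
#' @param background Background universe.
#' @param mode Background label, as in [fisher_enrichment()].
#' @return Data frame with one row per (treatment, pathway):
#'   `treatment`, `pathway_id`, `background_mode`, `k`, `K`, `n`, `N`,
#'   `p_value`.
#' @export
enrichment_table <- function(pathways, changed_by_treatment, background,
                             mode = c("user_dataset", "global_annotation")) {
  mode <- match.arg(mode)
  rows <- lapply(names(changed_by_treatment), function(g) {
    res <- lapply(pathways, fisher_enrichment,
                  changed = changed_by_treatment[[g]],
                  background = background, mode = mode)
    data.frame(treatment = g,
               pathway_id = vapply(res, `[[`, character(1L), "pathway_id"),
               background_mode = mode,
               k = vapply(res, `[[`, integer(1L), "k"),
               K = vapply(res, `[[`, integer(1L), "K"),
               n = vapply(res, `[[`, integer(1L), "n"),
               N = vapply(res, `[[`, integer(1L), "N"),
               p_value = vapply(res, `[[`, numeric(1L), "p_value"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top enriched pathways per treatment
#'
#' @param enr A data frame from [enrichment_table()].
#' @param n Number of pathways to keep per treatment (default 5).
#' @return Data frame restricted to the `n` smallest p-values per treatment,
#'   in ascending p order within treatment.
#' @export
top_enriched <- function(enr, n = 5L) {
  parts <- lapply(split(enr, enr$treatment), function(sub) {
    sub <- sub[order(sub$p_value, sub$pathway_id), , drop = FALSE]
    utils::head(sub, n)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Functional-class breakdown of changed mitochondrial proteins
#'
#' Counts changed proteins per functional class (OXPHOS, TCA cycle, lipid
#' metabolism, redox, transport, ...), overall and optionally per treatment.
#' Each protein belongs to exactly one class; proteins missing from
#' `class_map` are counted as `"unassigned"` and reported via a message.
#'
#' @param changed Character vector of changed (mitochondrial) proteins.
#' @param class_map Named character vector: accession to class (see
#'   [read_class_map()]).
#' @param changed_by_treatment Optional named list of per-treatment changed
#'   sets; when given, per-treatment counts are appended.
#' @return Data frame with `treatment` (`"all"` for the overall breakdown),
#'   `class`, `n_changed`.
#' @export
classify_functional <- function(changed, class_map,
                                changed_by_treatment = NULL) {
  count_set <- function(set, label) {
    set <- unique(set)
    cls <- unname(class_map[set])
    n_unmapped <- sum(is.na(cls))
    if (n_unmapped > 0L) {
      message(n_unmapped, " changed protein(s) without a functional class ",
              "counted as 'unassigned' (", label, ")")
      cls[is.na(cls)] <- "unassigned"
    }
    if (length(cls) == 0L) {
      return(data.frame(treatment = character(0L), class = character(0L),
                        n_changed = integer(0L), stringsAsFactors = FALSE))
    }
    tab <- table(cls)
    data.frame(treatment = label, class = names(tab),
               n_changed = as.integer(tab), stringsAsFactors = FALSE)
  }
  out <- count_set(changed, "all")
  if (!is.null(changed_by_treatment)) {
    per <- lapply(names(changed_by_treatment), function(g)
      count_set(changed_by_treatment[[g]], g))
    out <- do.call(rbind, c(list(out), per))
  }
  rownames(out) <- NULL
  out
}
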