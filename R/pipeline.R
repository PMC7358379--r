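## End-to-end orchestration: read inputs, quantify, QC, differential
## statistics, localization split, correlations, pathway dysregulation,
## enrichment and functional classes, with every stage written as TSV and a
## machine-readable summary rebuilt from those TSVs.

#' Pipeline run configuration
#'
#' Collects input paths, the control group and the thresholds of a full run.
#' Intensity tables are matched to plexes by position in `tables` versus the
#' design file's plex order unless `tables` is named by plex id.
#'
#' @param design Path to the design TSV.
#' @param tables Character vector of intensity TSV paths (one per plex).
#' @param gmt Path to the pathway GMT file.
#' @param out_dir Output directory.
#' @param localization Optional localization TSV (overrides table
#'   annotations).
#' @param classes Optional functional-class TSV.
#' @param control Control group name.
#' @param thresholds A [de_thresholds()] object.
#' @param protein_gate Gate for the changed-protein counts and localization
#'   split (default `"p_fc"`).
#' @param pathway_gate Gate feeding pathway statistics (default `"power"`).
#' @param tie Dysregulation tie rule, `"ge"` or `"gt"`.
#' @param background Enrichment background modes to run (subset of
#'   `"user_dataset"`, `"global_annotation"`).
#' @return A `run_config` list.
#' @export
run_config <- function(design, tables, gmt, out_dir,
                       localization = NULL, classes = NULL,
                       control = "DMSO", thresholds = de_thresholds(),
                       protein_gate = "p_fc", pathway_gate = "power",
                       tie = c("ge", "gt"),
                       background = c("user_dataset", "global_annotation")) {
  tie <- match.arg(tie)
  background <- match.arg(background, several.ok = TRUE)
  for (p in c(design, tables, gmt, localization, classes)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(list(design = design, tables = tables, gmt = gmt,
                 out_dir = out_dir, localization = localization,
                 classes = classes, control = control,
                 thresholds = thresholds, protein_gate = protein_gate,
                 pathway_gate = pathway_gate, tie = tie,
                 background = background),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes quantification, pooled-CV QC, differential statistics, the
#' mitochondrial / non-mitochondrial split, treatment correlations, pathway
#' dysregulation, Fisher enrichment and (when a class map is supplied) the
#' functional-class breakdown. Each stage's table is written to
#' `out_dir`; the summary JSON is then rebuilt from those files by
#' [summarize_run()], so every summary number is re-derivable from the stage
#' outputs. A plain-text `run.log` records package version, parameters and
#' headline counts.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("tmtbridge ", as.character(utils::packageVersion("tmtbridge"))),
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("control: ", config$control),
    paste0("alpha=", config$thresholds$alpha,
           " beta=", config$thresholds$beta,
           " fc_mode=", config$thresholds$fc_mode,
           " fc_bounds=[", config$thresholds$fc_lower, ",",
           config$thresholds$fc_upper, "]",
           " p_cutoff=", config$thresholds$p_cutoff),
    paste0("protein_gate=", config$protein_gate,
           " pathway_gate=", config$pathway_gate,
           " tie=", config$tie))

  designs <- .stage("read_design", read_design(config$design))
  tbl_paths <- config$tables
  if (is.null(names(tbl_paths)) || !all(names(designs) %in% names(tbl_paths))) {
    if (length(tbl_paths) != length(designs)) {
      stop("number of intensity tables (", length(tbl_paths),
           ") does not match number of plexes (", length(designs), ")",
           call. = FALSE)
    }
    names(tbl_paths) <- names(designs)
  }
  tables <- .stage("read_intensity_table", lapply(names(designs), function(id)
    read_intensity_table(tbl_paths[[id]], designs[[id]])))
  pathways <- .stage("read_gmt", read_gmt(config$gmt))

  rel <- .stage("relative_abundance", lapply(seq_along(designs), function(i)
    relative_abundance(tables[[i]], designs[[i]])))
  merged <- .stage("merge_common", merge_common(rel))

  if (!is.null(config$localization)) {
    loc_map <- .stage("read_localization", read_localization(config$localization))
    loc <- unname(loc_map[merged$accessions])
    loc[is.na(loc)] <- "unknown"
    merged$annotations$localization <- loc
  }
  n_unknown <- sum(merged$annotations$localization == "unknown")
  if (n_unknown > 0L) {
    message(n_unknown, " protein(s) without localization treated as ",
            "non-mitochondrial")
  }
  is_mito <- merged$annotations$localization == "mitochondrial"
  mito_acc <- merged$accessions[is_mito]

  merged_df <- data.frame(accession = merged$accessions,
                          gene_symbol = merged$annotations$gene_symbol,
                          localization = merged$annotations$localization,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (s in colnames(merged$values)) merged_df[[s]] <- merged$values[, s]
  for (r in colnames(merged$reference_columns))
    merged_df[[paste0("poolref.", r)]] <- merged$reference_columns[, r]
  .write_tsv(merged_df, file.path(out, "merged.tsv"))

  cv <- .stage("pooled_cv", pooled_cv(merged))
  .write_tsv(cv$per_protein, file.path(out, "cv_report.tsv"))
  .write_tsv(data.frame(metric = names(cv$summary),
                        value = unlist(cv$summary), stringsAsFactors = FALSE),
             file.path(out, "cv_summary.tsv"))

  diff <- .stage("differential_table",
                 differential_table(merged, config$control, config$thresholds))
  .write_tsv(diff, file.path(out, "differential.tsv"))

  protein_sets <- changed_sets(diff, config$protein_gate)
  pathway_sets <- changed_sets(diff, config$pathway_gate)
  changed_union <- attr(protein_sets, "union")
  mito_changed <- intersect(changed_union, mito_acc)
  nonmito_changed <- setdiff(changed_union, mito_acc)

  treatments <- unique(diff$treatment)
  cor_rows <- list()
  if (length(treatments) >= 2L) {
    for (nm in c("mitochondrial", "non-mitochondrial")) {
      set <- if (nm == "mitochondrial") mito_changed else nonmito_changed
      if (length(set) >= 3L) {
        cm <- .stage("treatment_correlation", correlation_matrix(diff, set))
        cm$subset <- nm
        cor_rows[[nm]] <- cm
      }
    }
  }
  cor_df <- if (length(cor_rows) > 0L) do.call(rbind, cor_rows) else
    data.frame(group_a = character(0L), group_b = character(0L),
               r = numeric(0L), n_proteins = integer(0L),
               subset = character(0L), stringsAsFactors = FALSE)
  rownames(cor_df) <- NULL
  .write_tsv(cor_df, file.path(out, "correlations.tsv"))

  dys <- .stage("pathway_dysregulation",
                pathway_dysregulation(pathways, merged$accessions,
                                      pathway_sets, tie = config$tie))
  .write_tsv(dys, file.path(out, "pathway_dysregulation.tsv"))

  enr_parts <- lapply(config$background, function(mode) {
    bg <- if (mode == "user_dataset") merged$accessions
          else unique(c(merged$accessions,
                        unlist(lapply(pathways, `[[`, "members"))))
    sets <- lapply(pathway_sets, intersect, y = bg)
    enrichment_table(pathways, sets, bg, mode)
  })
  enr <- do.call(rbind, enr_parts)
  rownames(enr) <- NULL
  .stage("fisher_enrichment", .write_tsv(enr, file.path(out, "enrichment.tsv")))

  if (!is.null(config$classes)) {
    class_map <- .stage("read_class_map", read_class_map(config$classes))
    fc <- .stage("classify_functional",
                 classify_functional(mito_changed, class_map,
                                     lapply(protein_sets, intersect, y = mito_acc)))
    .write_tsv(fc, file.path(out, "functional_classes.tsv"))
  }

  counts <- data.frame(
    metric = c("n_total_detected", "n_overlap", "n_mitochondrial_detected",
               "n_changed_union", "n_mitochondrial_changed",
               "n_non_mitochondrial_changed"),
    value = c(attr(merged, "n_total_detected"), attr(merged, "n_overlap"),
              length(mito_acc), length(changed_union), length(mito_changed),
              length(nonmito_changed)),
    stringsAsFactors = FALSE)
  .write_tsv(counts, file.path(out, "counts.tsv"))

  summary <- summarize_run(out)
  log_lines <- c(log_lines,
                 paste0("detected=", attr(merged, "n_total_detected"),
                        " overlap=", attr(merged, "n_overlap")),
                 paste0("changed_union=", length(changed_union),
                        " (mito=", length(mito_changed),
                        ", non-mito=", length(nonmito_changed), ")"))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(summary)
}

#' Build the machine-readable run summary from stage outputs
#'
#' Reads the stage TSVs in `out_dir` and writes `summary.json` with the
#' headline counts, CV QC summary, per-treatment changed-protein counts
#' under the p-value and power gates, flagged dysregulated pathways, and the
#' top enriched pathways (ascending p) per treatment and background mode.
#' Re-running on the same directory is idempotent.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param top_n Number of top enrichment hits per treatment (default 5).
#' @return The summary list, invisibly; `summary.json` is (re)written.
#' @export
summarize_run <- function(out_dir, top_n = 5L) {
  need <- c("counts.tsv", "cv_summary.tsv", "differential.tsv",
            "pathway_dysregulation.tsv", "enrichment.tsv")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing pipeline output: ", f, call. = FALSE)
    }
  }
  read_num_tsv <- function(f) {
    utils::read.delim(file.path(out_dir, f), sep = "\t", header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  counts <- read_num_tsv("counts.tsv")
  cvsum <- read_num_tsv("cv_summary.tsv")
  diff <- read_num_tsv("differential.tsv")
  dys <- read_num_tsv("pathway_dysregulation.tsv")
  enr <- read_num_tsv("enrichment.tsv")

  n_overlap <- counts$value[counts$metric == "n_overlap"]
  per_gate <- function(keep) {
    tab <- tapply(keep, diff$treatment, sum)
    as.list(setNames(as.integer(tab), names(tab)))
  }
  changed_p_fc <- per_gate(diff$pass_p & diff$pass_fc)
  changed_power <- per_gate(diff$pass_power)
  flagged <- dys[dys$flag %in% TRUE, c("pathway_id", "treatment"), drop = FALSE]
  top <- lapply(split(enr, enr$background_mode), function(sub) {
    lapply(split(sub, sub$treatment), function(s) {
      s <- s[order(s$p_value, s$pathway_id), , drop = FALSE]
      s <- utils::head(s, top_n)
      lapply(seq_len(nrow(s)), function(i)
        list(pathway_id = s$pathway_id[i], p_value = s$p_value[i],
             k = s$k[i], K = s$K[i]))
    })
  })
  summary <- list(
    counts = as.list(setNames(counts$value, counts$metric)),
    changed_fraction_p_fc = lapply(changed_p_fc, function(x) x / n_overlap),
    changed_fraction_power = lapply(changed_power, function(x) x / n_overlap),
    changed_per_treatment_p_fc = changed_p_fc,
    changed_per_treatment_power = changed_power,
    cv = as.list(setNames(cvsum$value, cvsum$metric)),
    flagged_pathways = if (nrow(flagged) > 0L)
      lapply(seq_len(nrow(flagged)), function(i)
        list(pathway_id = flagged$pathway_id[i],
             treatment = flagged$treatment[i]))
      else list(),
    top_enrichment = top)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
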