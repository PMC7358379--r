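## Readers and writers for the plain-text inputs of a multi-plex TMT study:
## plex designs, protein-level reporter intensity tables, GMT pathway sets and
## subcellular localization maps. All files are tab-separated UTF-8 with a
## header row; empty cells and "NA" both mean missing.

.read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("", "NA"),
                    quote = "", comment.char = "", stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Construct a single-plex TMT channel design
#'
#' A plex design maps each TMT reporter channel of one labeling set to a
#' sample, its treatment group and replicate number. Channels whose group is
#' `POOLED_REF` (matched case-insensitively) hold the pooled internal
#' reference - an equal mixture of every sample in the study - and serve as
#' the denominator for relative abundance and as the bridge between plexes.
#'
#' @param plex_id Identifier of the labeling set (e.g. `"set1"`).
#' @param channel Character vector of TMT tag names (e.g. `"126"`, `"127N"`).
#' @param sample_id Sample identifiers, one per channel.
#' @param group Treatment/control group per channel, or `POOLED_REF`.
#' @param replicate Positive integer replicate index per channel.
#'
#' @return A `plex_design`: a data frame with columns `channel`, `sample_id`,
#'   `group`, `replicate` and a `plex_id` attribute.
#' @seealso [read_design()], [validate_designs()]
#' @export
plex_design <- function(plex_id, channel, sample_id, group, replicate) {
  group <- as.character(group)
  group[toupper(group) == .POOLED_REF] <- .POOLED_REF
  x <- data.frame(channel = as.character(channel),
                  sample_id = as.character(sample_id),
                  group = group,
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  attr(x, "plex_id") <- as.character(plex_id)
  class(x) <- c("plex_design", "data.frame")
  validate_plex_design(x)
}

#' Plex identifier of a design
#' @param design A `plex_design`.
#' @return Character scalar.
#' @export
design_plex_id <- function(design) attr(design, "plex_id")

#' Validate one plex design
#'
#' Checks the within-plex invariants: unique channel labels, at least one
#' pooled-reference channel, and positive replicate indices.
#'
#' @param design A `plex_design`.
#' @return The design, invisibly usable, after validation (errors otherwise).
#' @export
validate_plex_design <- function(design) {
  id <- design_plex_id(design)
  dup <- design$channel[duplicated(design$channel)]
  if (length(dup) > 0L) {
    stop("plex ", id, ": duplicate channel label(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!any(design$group == .POOLED_REF)) {
    stop("plex ", id, ": no pooled-reference channel (group POOLED_REF)",
         call. = FALSE)
  }
  if (anyNA(design$replicate) || any(design$replicate < 1L)) {
    stop("plex ", id, ": replicate must be a positive integer", call. = FALSE)
  }
  design
}

#' Validate a set of plex designs as one experiment
#'
#' Cross-plex invariants: every non-reference sample appears in exactly one
#' plex, and every treatment/control group carries at least two replicates
#' (a two-sample t-test needs a variance estimate on each side).
#'
#' @param designs A list of `plex_design` objects.
#' @return The list, invisibly, after validation.
#' @export
validate_designs <- function(designs) {
  stopifnot(length(designs) >= 1L)
  for (d in designs) validate_plex_design(d)
  samp <- unlist(lapply(designs, function(d) d$sample_id[d$group != .POOLED_REF]))
  dup <- unique(samp[duplicated(samp)])
  if (length(dup) > 0L) {
    stop("sample_id(s) present in more than one plex: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  grp <- unlist(lapply(designs, function(d) d$group[d$group != .POOLED_REF]))
  n_rep <- table(grp)
  bad <- names(n_rep)[n_rep < 2L]
  if (length(bad) > 0L) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(designs)
}

#' Read plex designs from a TSV file
#'
#' The file needs columns `plex_id`, `channel`, `sample_id`, `group` and
#' `replicate`; one row per channel. Rows whose group equals `POOLED_REF` in
#' any letter case mark pooled internal-reference channels.
#'
#' @param path Path to the design TSV.
#' @return Named list of validated [plex_design()] objects, one per plex, in
#'   file order.
#' @export
read_design <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("plex_id", "channel", "sample_id", "group", "replicate"), path)
  if (anyNA(df$plex_id) || anyNA(df$channel) || anyNA(df$group)) {
    stop("file ", path, ": plex_id, channel and group must not be missing",
         call. = FALSE)
  }
  ids <- unique(df$plex_id)
  designs <- lapply(ids, function(id) {
    rows <- df[df$plex_id == id, , drop = FALSE]
    plex_design(id, rows$channel, rows$sample_id, rows$group,
                suppressWarnings(as.integer(rows$replicate)))
  })
  names(designs) <- ids
  validate_designs(designs)
  designs
}

#' Write plex designs to a TSV file
#' @param designs List of `plex_design` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(designs, path) {
  rows <- do.call(rbind, lapply(designs, function(d) {
    data.frame(plex_id = design_plex_id(d), channel = d$channel,
               sample_id = d$sample_id, group = d$group,
               replicate = d$replicate, stringsAsFactors = FALSE)
  }))
  .write_tsv(rows, path)
}

.norm_localization <- function(x) {
  out <- rep("unknown", length(x))
  x_low <- tolower(trimws(ifelse(is.na(x), "", x)))
  out[x_low %in% c("mitochondrial", "mitochondria", "mito")] <- "mitochondrial"
  out[x_low %in% c("non-mitochondrial", "non_mitochondrial", "nonmitochondrial")] <-
    "non-mitochondrial"
  out
}

#' Read a protein-level reporter-intensity table
#'
#' Expects a Proteome-Discoverer-style protein export: one row per protein
#' accession, one intensity column per TMT channel of `design` (column names
#' equal to the channel labels), plus optional annotation columns
#' `gene_symbol`, `localization` and `psm_count`. Blank or `NA` cells are
#' missing values; intensities must be non-negative.
#'
#' @param path Path to the intensity TSV.
#' @param design The [plex_design()] the table belongs to.
#' @return A `reporter_table`: list with `plex_id`, `accessions`,
#'   `annotations` (data frame) and `intensities` (protein x channel matrix
#'   in design channel order).
#' @export
read_intensity_table <- function(path, design) {
  df <- .read_tsv(path)
  .require_columns(df, "accession", path)
  missing_ch <- setdiff(design$channel, names(df))
  if (length(missing_ch) > 0L) {
    stop("file ", path, " is missing intensity column(s) for channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  acc <- df$accession
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    stop("file ", path, ": duplicate protein accession(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  ints <- matrix(NA_real_, nrow = nrow(df), ncol = nrow(design),
                 dimnames = list(acc, design$channel))
  for (ch in design$channel) {
    raw <- df[[ch]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop("file ", path, ": non-numeric intensity for accession ",
           acc[bad[1L]], ", channel ", ch, call. = FALSE)
    }
    neg <- which(!is.na(val) & val < 0)
    if (length(neg) > 0L) {
      stop("file ", path, ": negative intensity for accession ",
           acc[neg[1L]], ", channel ", ch, call. = FALSE)
    }
    ints[, ch] <- val
  }
  ann <- data.frame(
    accession = acc,
    gene_symbol = if ("gene_symbol" %in% names(df)) df$gene_symbol else NA_character_,
    localization = if ("localization" %in% names(df))
      .norm_localization(df$localization) else "unknown",
    psm_count = if ("psm_count" %in% names(df))
      suppressWarnings(as.integer(df$psm_count)) else NA_integer_,
    stringsAsFactors = FALSE)
  structure(list(plex_id = design_plex_id(design), accessions = acc,
                 annotations = ann, intensities = ints),
            class = "reporter_table")
}

#' Write a reporter-intensity table to TSV
#' @param table A `reporter_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  df <- data.frame(accession = table$accessions,
                   gene_symbol = table$annotations$gene_symbol,
                   localization = table$annotations$localization,
                   psm_count = table$annotations$psm_count,
                   stringsAsFactors = FALSE, check.names = FALSE)
  ints <- table$intensities
  for (ch in colnames(ints)) df[[ch]] <- ints[, ch]
  .write_tsv(df, path)
}

#' Read pathway annotations from a GMT file
#'
#' Standard gene-matrix-transposed format: each line is
#' `name TAB description TAB member TAB member ...`. The description field is
#' retained as the pathway's `source`. Members are the pathway's full
#' annotated universe and may include proteins never detected in a study.
#'
#' @param path Path to the GMT file.
#' @return Named list of `pathway_annotation` objects, each a list with
#'   `pathway_id`, `source` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT file ", path, ", line ", line_no[i],
           ": expected at least 3 tab-separated fields (name, description, ",
           ">= 1 member)", call. = FALSE)
    }
    members <- unique(fields[-c(1L, 2L)])
    out[[i]] <- structure(list(pathway_id = fields[[1L]], source = fields[[2L]],
                               members = members),
                          class = "pathway_annotation")
  }
  ids <- vapply(out, function(p) p$pathway_id, character(1L))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("GMT file ", path, ": duplicate pathway id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  names(out) <- ids
  out
}

#' Write pathway annotations to a GMT file
#' @param pathways List of `pathway_annotation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, p$source, p$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein localization map
#'
#' Two-column TSV (`accession`, `localization`). Duplicated accessions are
#' allowed only when consistent. Accessions absent from the map default to
#' non-mitochondrial downstream (the analysis treats localization as a binary
#' mitochondrial / non-mitochondrial partition).
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping accession to a localization tag in
#'   `mitochondrial`, `non-mitochondrial`, `unknown`.
#' @export
read_localization <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) return(setNames(character(0L), character(0L)))
  .require_columns(df, c("accession", "localization"), path)
  bad <- which(is.na(df$accession) | is.na(df$localization))
  if (length(bad) > 0L) {
    stop("file ", path, ", data line ", bad[1L],
         ": accession and localization must both be present", call. = FALSE)
  }
  tag <- .norm_localization(df$localization)
  split_tags <- split(tag, df$accession)
  conflict <- names(split_tags)[vapply(split_tags, function(v)
    length(unique(v)) > 1L, logical(1L))]
  if (length(conflict) > 0L) {
    stop("file ", path, ": conflicting localization for accession(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  first <- !duplicated(df$accession)
  setNames(tag[first], df$accession[first])
}

#' Write a protein localization map
#' @param map Named character vector (accession to localization).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization <- function(map, path) {
  .write_tsv(data.frame(accession = names(map), localization = unname(map),
                        stringsAsFactors = FALSE), path)
}

#' Read a functional-class map
#'
#' Two-column TSV (`accession`, `class`) assigning each protein to one
#' functional class (e.g. OXPHOS, TCA cycle, redox). Multi-class annotations
#' separated by `;` are resolved to the first-listed class with a warning.
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping accession to class.
#' @export
read_class_map <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) return(setNames(character(0L), character(0L)))
  .require_columns(df, c("accession", "class"), path)
  cls <- df$class
  multi <- grepl(";", cls, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-class annotation(s) resolved to the ",
            "first-listed class", call. = FALSE)
    cls[multi] <- vapply(strsplit(cls[multi], ";", fixed = TRUE),
                         function(v) trimws(v[[1L]]), character(1L))
  }
  dup <- duplicated(df$accession)
  if (any(dup)) {
    stop("file ", path, ": duplicate accession(s): ",
         paste(unique(df$accession[dup]), collapse = ", "), call. = FALSE)
  }
  setNames(cls, df$accession)
}
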