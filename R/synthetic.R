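## Ground-truthed synthetic data emulating a two-plex TMT toxicant study:
## six groups (five treatments plus a DMSO control) in biological triplicate,
## split over two 11-channel plexes, each carrying two pooled-reference
## channels mixed equally from all 18 samples. Channel noise is
## multiplicative log-normal (reporter intensities are positive and CVs are
## scale-free); plex-level batch scale factors and per-plex protein dropout
## model between-run variation. Emitted intensities are rounded to integer
## counts, as protein-level summed reporter intensities are exported; at the
## simulated intensity scale (~1e6) the quantization is ~1e-7 relative and,
## because integer scaling is exact in double arithmetic, makes the pooled
## reference's batch-scale cancellation exactly verifiable.

.FUNCTIONAL_CLASSES <- c(
  "OXPHOS", "TCA cycle", "lipid metabolism", "redox", "transport",
  "cell death/defense", "signaling", "protease", "protein targeting",
  "RNA/DNA/protein synthesis", "nucleotide metabolism",
  "carbohydrate metabolism")

.TMT11 <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131N", "131C")

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Two-plex study design mirroring a six-group toxicant experiment
#'
#' Two 11-channel TMT plexes: set 1 holds triplicates of FCCP, dinoterb and
#' picoxystrobin; set 2 holds triplicates of pinacyanol, triclocarban and the
#' DMSO control. Each set closes with two pooled-reference channels.
#'
#' @return Named list of two [plex_design()] objects.
#' @export
paper_design <- function() {
  build <- function(id, groups) {
    samples <- c(paste(rep(groups, each = 3L), rep(1:3, times = 3L), sep = "_"),
                 paste0("pool_", id, "_", c("a", "b")))
    plex_design(id, .TMT11, samples,
                c(rep(groups, each = 3L), .POOLED_REF, .POOLED_REF),
                c(rep(1:3, times = 3L), 1L, 2L))
  }
  list(set1 = build("set1", c("FCCP", "dinoterb", "picoxystrobin")),
       set2 = build("set2", c("pinacyanol", "triclocarban", "DMSO")))
}

#' Minimal single-plex design for smoke tests
#'
#' One plex with duplicate control and treatment samples plus two pooled
#' channels.
#'
#' @param control Control group name.
#' @param treatment Treatment group name.
#' @return Named list with one [plex_design()].
#' @export
minimal_design <- function(control = "DMSO", treatment = "TREAT") {
  list(plex1 = plex_design(
    "plex1", .TMT11[1:6],
    c(paste(control, 1:2, sep = "_"), paste(treatment, 1:2, sep = "_"),
      "pool_a", "pool_b"),
    c(control, control, treatment, treatment, .POOLED_REF, .POOLED_REF),
    c(1L, 2L, 1L, 2L, 1L, 2L)))
}

#' Generate the ground truth of a synthetic study
#'
#' Draws per-protein baseline abundances (log-normal), a mitochondrial /
#' non-mitochondrial localization partition, one functional class per
#' mitochondrial protein, per-treatment sets of truly perturbed proteins with
#' ratio effects sampled uniformly from `effect_range` and its reciprocal
#' (even up/down mix), and pathway memberships including, per treatment, one
#' "planted" pathway preferentially populated from that treatment's perturbed
#' set. Pathway universes are padded with undetectable accessions so that
#' detection coverage falls below 100%.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_pathways Number of pathways (must be at least the number of
#'   treatments when `frac_de > 0`, to fit the planted pathways).
#' @param frac_de Fraction of proteins truly perturbed per treatment
#'   (0 gives a null dataset with no effects).
#' @param effect_range Ratio range for up-regulated effects; down effects are
#'   reciprocals.
#' @param frac_mito Fraction of proteins tagged mitochondrial.
#' @param treatments Treatment group names.
#' @param control Control group name (effects fixed at 1).
#' @param noise_sigma Standard deviation of log-normal channel noise.
#' @param plex_scale Per-plex batch multipliers (named by plex id, or
#'   recycled positionally at simulation time).
#' @param dropout Per-plex probability that a protein is not identified in a
#'   given plex (all its channels missing there).
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   truth exactly.
#' @return A `tmt_truth` list.
#' @export
generate_truth <- function(n_proteins = 5000L, n_pathways = 40L,
                           frac_de = 0.10, effect_range = c(1.15, 2),
                           frac_mito = 0.12,
                           treatments = c("FCCP", "dinoterb", "picoxystrobin",
                                          "pinacyanol", "triclocarban"),
                           control = "DMSO", noise_sigma = 0.02,
                           plex_scale = c(1, 1.3), dropout = 0.03,
                           seed = 20200707L) {
  stopifnot(n_proteins >= 2L, frac_de >= 0, frac_de < 1,
            effect_range[1L] > 1, effect_range[2L] >= effect_range[1L],
            frac_mito >= 0, frac_mito <= 1, noise_sigma >= 0,
            dropout >= 0, dropout < 1)
  n_de <- round(frac_de * n_proteins)
  if (frac_de > 0 && n_de < 1L) {
    stop("frac_de * n_proteins < 1: no protein would be perturbed",
         call. = FALSE)
  }
  .with_seed(seed, {
    acc <- sprintf("P%05d", seq_len(n_proteins))
    baseline <- stats::rlnorm(n_proteins, meanlog = log(2e6), sdlog = 1.2)
    names(baseline) <- acc
    loc <- setNames(rep("non-mitochondrial", n_proteins), acc)
    mito <- sample(acc, round(frac_mito * n_proteins))
    loc[mito] <- "mitochondrial"
    ## OXPHOS-heavy class mix for mitochondrial proteins
    class_w <- c(4, 2, 2, 2, 1.5, 1.5, 1, 1, 1, 1.5, 1, 1)
    classes <- setNames(sample(.FUNCTIONAL_CLASSES, length(mito),
                               replace = TRUE, prob = class_w), mito)
    psm <- setNames(pmax(1L, stats::rpois(n_proteins, 8)), acc)

    effects <- matrix(1, n_proteins, length(treatments),
                      dimnames = list(acc, treatments))
    de_sets <- setNames(vector("list", length(treatments)), treatments)
    for (g in treatments) {
      de <- if (n_de > 0L) sample(acc, n_de) else character(0L)
      de_sets[[g]] <- de
      if (length(de) > 0L) {
        u <- stats::runif(length(de), effect_range[1L], effect_range[2L])
        up <- stats::runif(length(de)) < 0.5
        effects[de, g] <- ifelse(up, u, 1 / u)
      }
    }

    ## pathways: one planted per treatment (when effects exist), rest random
    planted <- setNames(character(0L), character(0L))
    pathways <- list()
    pw_id <- function(i) sprintf("pathway_%03d", i)
    i <- 0L
    if (n_de > 0L) {
      if (n_pathways < length(treatments)) {
        stop("n_pathways must be >= number of treatments to fit the planted ",
             "pathways", call. = FALSE)
      }
      for (g in treatments) {
        i <- i + 1L
        size <- min(n_proteins, 30L)
        n_from_de <- min(length(de_sets[[g]]), round(0.8 * size))
        members <- unique(c(sample(de_sets[[g]], n_from_de),
                            sample(acc, size - n_from_de)))
        pathways[[pw_id(i)]] <- .pad_pathway(pw_id(i), members, "planted")
        planted[g] <- pw_id(i)
      }
    }
    while (i < n_pathways) {
      i <- i + 1L
      size <- sample(seq(min(15L, n_proteins), min(40L, n_proteins)), 1L)
      members <- sample(acc, size)
      pathways[[pw_id(i)]] <- .pad_pathway(pw_id(i), members, "random")
    }

    structure(list(
      seed = as.integer(seed), accessions = acc, baseline = baseline,
      localization = loc, classes = classes, psm = psm,
      treatments = treatments, control = control, effects = effects,
      de_sets = de_sets, pathways = pathways, planted = planted,
      noise_sigma = noise_sigma, plex_scale = plex_scale, dropout = dropout,
      frac_de = frac_de, effect_range = effect_range),
      class = "tmt_truth")
  })
}

## Pad a pathway's member list with undetectable accessions so detection
## coverage lands in roughly 40-80%.
.pad_pathway <- function(id, members, source) {
  coverage <- stats::runif(1L, 0.4, 0.8)
  n_annot <- ceiling(length(members) / coverage)
  pad <- sprintf("UNDET_%s_%03d", id, seq_len(n_annot - length(members)))
  structure(list(pathway_id = id, source = source,
                 members = c(members, pad)),
            class = "pathway_annotation")
}

#' Simulate reporter-intensity tables for a set of plex designs
#'
#' Each sample channel measures `baseline * effect(protein, group) *
#' plex_scale * exp(N(0, sigma^2))`. Pooled-reference channels measure the
#' equal-weight mean of all simulated sample signals (the physical equal
#' mixing, taken before plex scaling) times the plex scale, with their own
#' independent channel noise. Intensities are rounded to integer counts.
#' Dropout removes a protein from all channels of a plex with the truth's
#' per-plex probability. Groups absent from the truth's treatment list
#' (including the control) have effect 1.
#'
#' @param truth A `tmt_truth` from [generate_truth()].
#' @param designs List of [plex_design()] objects covering all samples.
#' @return Named list of `reporter_table` objects, one per plex.
#' @export
simulate_plexes <- function(truth, designs) {
  n <- length(truth$accessions)
  all_groups <- unique(unlist(lapply(designs, function(d)
    d$group[d$group != .POOLED_REF])))
  unknown <- setdiff(all_groups, c(truth$treatments, truth$control))
  eff <- function(g) {
    if (g %in% colnames(truth$effects)) truth$effects[, g] else rep(1, n)
  }
  if (length(unknown) > 0L) {
    message("group(s) treated as unperturbed (effect 1): ",
            paste(unknown, collapse = ", "))
  }
  ## true signal per sample (no noise, no plex scale)
  signals <- list()
  for (d in designs) {
    for (j in which(d$group != .POOLED_REF)) {
      signals[[d$sample_id[j]]] <- truth$baseline * eff(d$group[j])
    }
  }
  pooled_signal <- rowMeans(do.call(cbind, signals))

  scale_for <- function(idx, id) {
    ps <- truth$plex_scale
    if (!is.null(names(ps)) && id %in% names(ps)) ps[[id]]
    else ps[[(idx - 1L) %% length(ps) + 1L]]
  }
  ann <- data.frame(accession = truth$accessions,
                    gene_symbol = sprintf("GENE%d", seq_len(n)),
                    localization = unname(truth$localization),
                    psm_count = unname(truth$psm),
                    stringsAsFactors = FALSE)
  .with_seed(truth$seed + 1L, {
    tables <- list()
    for (idx in seq_along(designs)) {
      d <- designs[[idx]]
      id <- design_plex_id(d)
      sc <- scale_for(idx, id)
      ints <- matrix(NA_real_, n, nrow(d),
                     dimnames = list(truth$accessions, d$channel))
      for (j in seq_len(nrow(d))) {
        base <- if (d$group[j] == .POOLED_REF) pooled_signal
                else signals[[d$sample_id[j]]]
        noise <- if (truth$noise_sigma > 0)
          exp(stats::rnorm(n, 0, truth$noise_sigma)) else 1
        ints[, j] <- pmax(1, round(base * sc * noise))
      }
      if (truth$dropout > 0) {
        out_rows <- stats::runif(n) < truth$dropout
        ints[out_rows, ] <- NA_real_
      }
      tables[[id]] <- structure(
        list(plex_id = id, accessions = truth$accessions,
             annotations = ann, intensities = ints),
        class = "reporter_table")
    }
    tables
  })
}

#' Write a complete fixture set to disk
#'
#' Emits everything the pipeline reads - design TSV, one intensity TSV per
#' plex, pathway GMT, localization TSV, functional-class TSV - plus a
#' `truth.json` holding the generator parameters and ground truth needed for
#' recovery scoring. Re-running with the same truth produces byte-identical
#' files.
#'
#' @param truth A `tmt_truth`.
#' @param tables Output of [simulate_plexes()].
#' @param designs The designs used for simulation.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_set <- function(truth, tables, designs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(design = file.path(out_dir, "design.tsv"))
  write_design(designs, paths[["design"]])
  for (id in names(tables)) {
    p <- file.path(out_dir, paste0("intensities_", id, ".tsv"))
    write_intensity_table(tables[[id]], p)
    paths[[paste0("intensities_", id)]] <- p
  }
  paths[["gmt"]] <- file.path(out_dir, "pathways.gmt")
  write_gmt(truth$pathways, paths[["gmt"]])
  paths[["localization"]] <- file.path(out_dir, "localization.tsv")
  write_localization(truth$localization, paths[["localization"]])
  paths[["classes"]] <- file.path(out_dir, "classes.tsv")
  .write_tsv(data.frame(accession = names(truth$classes),
                        class = unname(truth$classes),
                        stringsAsFactors = FALSE), paths[["classes"]])
  paths[["truth"]] <- file.path(out_dir, "truth.json")
  de_effects <- lapply(truth$treatments, function(g) {
    de <- truth$de_sets[[g]]
    as.list(setNames(truth$effects[de, g], de))
  })
  names(de_effects) <- truth$treatments
  truth_json <- list(
    seed = truth$seed, n_proteins = length(truth$accessions),
    frac_de = truth$frac_de, effect_range = truth$effect_range,
    noise_sigma = truth$noise_sigma, dropout = truth$dropout,
    plex_scale = as.list(truth$plex_scale),
    treatments = truth$treatments, control = truth$control,
    de_sets = truth$de_sets, de_effects = de_effects,
    planted = as.list(truth$planted))
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a preset fixture
#'
#' Presets: `"paper"` - the full two-plex, six-group study shape (5,000
#' proteins, 10% perturbed per treatment at ratios 1.15-2, sigma 0.02,
#' plex scales 1 and 1.3, 3% per-plex dropout); `"null"` - the same design
#' with no true effects (1,000 proteins); `"minimal"` - a 3-protein,
#' single-plex smoke fixture.
#'
#' @param preset `"paper"`, `"null"` or `"minimal"`.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, [write_fixture_set()] is
#'   called and the paths are returned in `files`.
#' @return List with `truth`, `designs`, `tables` and (optionally) `files`.
#' @export
simulate_fixture <- function(preset = c("paper", "null", "minimal"),
                             seed = 20200707L, out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    designs <- paper_design()
    truth <- generate_truth(seed = seed)
  } else if (preset == "null") {
    designs <- paper_design()
    truth <- generate_truth(n_proteins = 1000L, n_pathways = 20L,
                            frac_de = 0, seed = seed)
  } else {
    designs <- minimal_design()
    truth <- generate_truth(n_proteins = 3L, n_pathways = 2L, frac_de = 0.34,
                            effect_range = c(1.6, 2), frac_mito = 1 / 3,
                            treatments = "TREAT", control = "DMSO",
                            plex_scale = 1, dropout = 0, seed = seed)
  }
  tables <- simulate_plexes(truth, designs)
  out <- list(truth = truth, designs = designs, tables = tables)
  if (!is.null(out_dir)) {
    out$files <- write_fixture_set(truth, tables, designs, out_dir)
  }
  out
}
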