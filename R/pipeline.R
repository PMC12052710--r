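#' Analysis thresholds and group-construction parameters
#'
#' @param group_n extreme-group size (default 10).
#' @param sd_multiplier outlier-trimming multiplier (default 2).
#' @param trait_alpha threshold for trait comparisons (default 0.05).
#' @param genus_alpha threshold for genus-level differential abundance
#'   (default 0.01).
#' @param spearman_alpha threshold inside the correlation classification
#'   (default 0.01).
#' @param strict_bounds literal strict inequalities in
#'   [classify_correlation()] (default `FALSE`).
#' @param pseudocount CLR pseudocount (default 0.5).
#' @param diff_scale scale for differential-abundance t-tests: `"clr"`
#'   (default; symmetric and compositionally coherent) or `"normalized"`
#'   (depth-normalized abundances).
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(group_n = 10L, sd_multiplier = 2,
                            trait_alpha = 0.05, genus_alpha = 0.01,
                            spearman_alpha = 0.01, strict_bounds = FALSE,
                            pseudocount = 0.5,
                            diff_scale = c("clr", "normalized")) {
  stopifnot(trait_alpha > 0, trait_alpha < 1, genus_alpha > 0,
            genus_alpha < 1, spearman_alpha > 0, spearman_alpha < 1)
  structure(list(group_n = as.integer(group_n),
                 sd_multiplier = sd_multiplier, trait_alpha = trait_alpha,
                 genus_alpha = genus_alpha, spearman_alpha = spearman_alpha,
                 strict_bounds = isTRUE(strict_bounds),
                 pseudocount = pseudocount,
                 diff_scale = match.arg(diff_scale)),
            class = "pipeline_params")
}

#' Write a simulated cohort to disk as the three standard TSVs
#'
#' Emits `abundance.tsv`, `phenotype.tsv`, `taxonomy.tsv` and `truth.tsv`
#' (generator ground truth: causal genera, classes, effects) into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
simulate_cohort_files <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(config)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_abundance_tsv(cohort$abundance, paths["abundance"])
  write_tsv(cohort$phenotype, paths["phenotype"])
  write_tsv(cohort$taxonomy, paths["taxonomy"])
  write_tsv(cohort$truth$causal, paths["truth"])
  invisible(paths)
}

#' Run the full degradation-rate / microbiota analysis
#'
#' End-to-end orchestration: derive degradation rates from marker
#' concentrations where needed, derive FCR from the body-weight series and
#' intake where needed, normalize the abundance table, build extreme
#' high/low groups per target phenotype, run the three screens (Spearman,
#' two-part MWAS, differential abundance), and intersect them into the
#' consensus per phenotype.
#'
#' @param abundance a `composition_matrix` of raw counts, or a path to an
#'   abundance TSV.
#' @param phenotype a phenotype data.frame with `sample_id`, or a path to a
#'   phenotype TSV. If a target column (e.g. `NDFD`) is absent it is
#'   computed from the marker columns `AIA_feed`, `AIA_digesta`,
#'   `<fiber>_feed`, `<fiber>_digesta`; if `FCR` is absent it is computed
#'   from `BW_80`/`BW_180` and `ADFI`.
#' @param taxonomy taxonomy data.frame, path, or `NULL`.
#' @param targets phenotype columns to analyze (default `c("NDFD", "ADFD")`).
#' @param spec an [mwas_spec()].
#' @param params a [pipeline_params()].
#' @param out_dir if non-`NULL`, every intermediate table plus a run
#'   manifest is written there as TSV.
#' @return list with `phenotype` (augmented), `normalized`, `clr`, and per
#'   target: `groups`, `trait_comparison`, `spearman`, `mwas`,
#'   `differential`, `consensus`; plus `group_overlap` between the first two
#'   targets when applicable.
#' @export
run_pipeline <- function(abundance, phenotype, taxonomy = NULL,
                         targets = c("NDFD", "ADFD"), spec = mwas_spec(),
                         params = pipeline_params(), out_dir = NULL) {
  if (is.character(abundance)) abundance <- read_abundance_tsv(abundance)
  if (is.character(phenotype)) phenotype <- read_phenotype_tsv(phenotype)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_tsv(taxonomy)
  if (!"sample_id" %in% colnames(phenotype)) {
    stop("phenotype table must contain a `sample_id` column", call. = FALSE)
  }

  ab_ids <- rownames(abundance)
  ph_ids <- as.character(phenotype$sample_id)
  only_ab <- setdiff(ab_ids, ph_ids)
  only_ph <- setdiff(ph_ids, ab_ids)
  if (length(only_ab) || length(only_ph)) {
    stop("sample-ID mismatch between abundance and phenotype tables; ",
         "abundance-only: ",
         paste(utils::head(only_ab, 5L), collapse = ", "),
         "; phenotype-only: ",
         paste(utils::head(only_ph, 5L), collapse = ", "), call. = FALSE)
  }
  phenotype <- phenotype[match(ab_ids, ph_ids), , drop = FALSE]

  phenotype <- derive_degradation_columns(phenotype, targets)
  phenotype <- derive_fcr_column(phenotype)

  normalized <- normalize_to_min_depth(abundance)
  clr <- clr_transform(normalized, params$pseudocount)

  trait_cols <- setdiff(colnames(phenotype)[vapply(phenotype, is.numeric,
                                                   logical(1))], targets)
  out <- list(phenotype = phenotype, normalized = normalized, clr = clr)

  for (tg in targets) {
    y <- stats::setNames(phenotype[[tg]], phenotype$sample_id)
    groups <- extreme_groups(y, n = params$group_n,
                             sd_multiplier = params$sd_multiplier,
                             phenotype = tg)
    traits <- as.matrix(phenotype[, trait_cols, drop = FALSE])
    rownames(traits) <- phenotype$sample_id
    trait_cmp <- group_comparison(traits, groups, alpha = params$trait_alpha)
    spearman <- correlation_screen(normalized, y, target = tg,
                                   alpha = params$spearman_alpha,
                                   strict_bounds = params$strict_bounds)
    mwas <- mwas_screen(normalized, y, spec, target = tg)
    diff_mat <- if (params$diff_scale == "clr") clr else normalized
    diff <- group_comparison(diff_mat, groups, alpha = params$genus_alpha)
    cons <- consensus_report(spearman, mwas, diff, taxonomy, target = tg)
    out[[tg]] <- list(groups = groups, trait_comparison = trait_cmp,
                      spearman = spearman, mwas = mwas, differential = diff,
                      consensus = cons)
  }
  if (length(targets) >= 2L) {
    out$group_overlap <- group_overlap(out[[targets[1L]]]$groups,
                                       out[[targets[2L]]]$groups)
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, targets, out_dir, spec,
                                                params)
  out
}

derive_degradation_columns <- function(phenotype, targets) {
  fiber_of <- c(NDFD = "NDF", ADFD = "ADF")
  for (tg in intersect(targets, names(fiber_of))) {
    if (tg %in% colnames(phenotype)) next
    fiber <- fiber_of[[tg]]
    need <- c("AIA_feed", "AIA_digesta", paste0(fiber, "_feed"),
              paste0(fiber, "_digesta"))
    missing <- setdiff(need, colnames(phenotype))
    if (length(missing)) {
      stop("cannot compute ", tg, ": phenotype table lacks column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- marker_measurement(A = phenotype$AIA_feed,
                            B = phenotype$AIA_digesta,
                            FA = phenotype[[paste0(fiber, "_feed")]],
                            FB = phenotype[[paste0(fiber, "_digesta")]],
                            fiber_kind = fiber)
    phenotype[[tg]] <- degradation_rate(m)
  }
  missing_tg <- setdiff(targets, colnames(phenotype))
  if (length(missing_tg)) {
    stop("target phenotype(s) not available and not derivable: ",
         paste(missing_tg, collapse = ", "), call. = FALSE)
  }
  phenotype
}

derive_fcr_column <- function(phenotype) {
  if ("FCR" %in% colnames(phenotype)) return(phenotype)
  bw_cols <- grep("^BW_", colnames(phenotype), value = TRUE)
  if (length(bw_cols) < 2L || !"ADFI" %in% colnames(phenotype)) {
    return(phenotype)       # FCR simply unavailable; screens skip it
  }
  ages <- as.integer(sub("^BW_", "", bw_cols))
  ord <- order(ages)
  first <- bw_cols[ord[1L]]
  last <- bw_cols[ord[length(ord)]]
  days <- ages[ord[length(ord)]] - ages[ord[1L]]
  adg <- (phenotype[[last]] - phenotype[[first]]) / days
  phenotype$FCR <- ifelse(adg == 0, NA_real_, phenotype$ADFI / adg)
  phenotype
}

write_pipeline_outputs <- function(out, targets, out_dir, spec, params) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv(out$phenotype, file.path(out_dir, "phenotype_augmented.tsv"))
  for (tg in targets) {
    r <- out[[tg]]
    grp <- data.frame(
      sample_id = c(r$groups$high_ids, r$groups$low_ids,
                    r$groups$excluded_ids),
      phenotype = tg,
      value = r$groups$values[c(r$groups$high_ids, r$groups$low_ids,
                                r$groups$excluded_ids)],
      group = c(rep("high", length(r$groups$high_ids)),
                rep("low", length(r$groups$low_ids)),
                rep("excluded", length(r$groups$excluded_ids))),
      stringsAsFactors = FALSE)
    write_tsv(grp, file.path(out_dir, paste0("groups_", tg, ".tsv")))
    write_tsv(r$trait_comparison,
              file.path(out_dir, paste0("trait_comparison_", tg, ".tsv")))
    write_tsv(r$spearman, file.path(out_dir, paste0("spearman_", tg, ".tsv")))
    write_tsv(r$mwas, file.path(out_dir, paste0("mwas_", tg, ".tsv")))
    write_tsv(r$differential,
              file.path(out_dir, paste0("differential_", tg, ".tsv")))
    cons <- r$consensus
    write_tsv(data.frame(genus = cons$consensus, stringsAsFactors = FALSE),
              file.path(out_dir, paste0("consensus_", tg, ".tsv")))
    if (!is.null(cons$phylum_counts)) {
      write_tsv(data.frame(phylum = names(cons$phylum_counts),
                           count = as.integer(cons$phylum_counts),
                           stringsAsFactors = FALSE),
                file.path(out_dir, paste0("phylum_tally_", tg, ".tsv")))
    }
    write_tsv(data.frame(genus = rownames(cons$membership),
                         cons$membership, stringsAsFactors = FALSE),
              file.path(out_dir, paste0("membership_", tg, ".tsv")))
  }
  manifest <- data.frame(
    key = c("package_version", "r_version", "targets", "seed",
            "n_permutations", "n_pcs", "prevalence_threshold", "alpha",
            "group_n", "sd_multiplier", "trait_alpha", "genus_alpha",
            "pseudocount", "diff_scale"),
    value = c(as.character(utils::packageVersion("rumenMWAS")),
              paste(R.version$major, R.version$minor, sep = "."),
              paste(targets, collapse = ","), spec$seed,
              spec$n_permutations, spec$n_pcs, spec$prevalence_threshold,
              spec$alpha, params$group_n, params$sd_multiplier,
              params$trait_alpha, params$genus_alpha, params$pseudocount,
              params$diff_scale),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
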