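# End-to-end orchestration: simulate (or load) -> unigene reduction ->
# expression atlas -> fuzzy clustering -> enrichment -> family annotation,
# with a machine-readable count report.

default_config <- function() {
  list(
    outdir = "atlas_out",
    seed = 1,
    simulate = list(enabled = TRUE, n_genes = 2000, isoform_rate = 0.3,
                    contained_rate = 0.05, contaminant_frac = 0.09,
                    noise_cv = 0.2, replicates = 4),
    inputs = list(fasta = NULL, expression = NULL, taxa = NULL, terms = NULL),
    unigenes = list(e_max = 1e-05, excluded = c("bacteria", "plants")),
    expression = list(tpm_min = 1, top_n = 500),
    clustering = list(enabled = TRUE, c = 8, m = 1.25, alpha = 0.6,
                      restarts = 20, max_iter = 300, tol = 1e-8),
    enrichment = list(min_genes = 10, fdr_max = 0.001),
    families = list(enabled = TRUE, e_max = 1e-3, cov_min = 0.4,
                    min_identity = 20, max_rounds = 5)
  )
}

# overlay user values on the defaults, rejecting unknown keys
merge_config <- function(user, defaults = default_config(), path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (!key %in% names(defaults)) stopf("unknown config key: '%s'", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])))
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Build (and validate) a pipeline run configuration
#'
#' Defaults mirror the atlas analysis thresholds: taxon filter e < 1e-05,
#' presence > 1 TPM, Top-500 groups, 8 fuzzy clusters with retention
#' alpha > 0.6, enrichment minimum term size 10 with FDR < 0.001, homology
#' cutoffs e <= 1e-3 and query coverage > 40%. Unknown keys are rejected.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full atlas pipeline
#'
#' Executes the stages in order: simulate (or load inputs) -> unigene
#' reduction -> expression atlas -> fuzzy clustering -> enrichment -> family
#' annotation -> summaries. All outputs are written under `config$outdir`;
#' the returned report (also written as JSON) lists the gene counts entering
#' and surviving every stage, keyed by the config hash and seed, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config a [run_config()] (or list/YAML path coerced through it).
#' @param quiet suppress stage log lines on stderr.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  report <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                 counts = list(), stages = character(0))
  run_stage <- function(name, expr) {
    log(name, "starting")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log(name, "done (%.1fs)", proc.time()[["elapsed"]] - t0)
    report$stages <<- c(report$stages, name)
    res
  }

  # --- simulate or load -----------------------------------------------------
  panels <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- run_stage("simulate", {
      spec <- synthetic_spec(
        n_genes = cfg$simulate$n_genes,
        isoform_rate = cfg$simulate$isoform_rate,
        contained_rate = cfg$simulate$contained_rate,
        contaminant_frac = cfg$simulate$contaminant_frac,
        noise_cv = cfg$simulate$noise_cv,
        replicates = cfg$simulate$replicates,
        seed = cfg$seed)
      s <- simulate_atlas(spec)
      write_synthetic(s, file.path(outdir, "simulated"))
      s
    })
    records <- sim$records
    taxa <- sim$taxa
    terms <- sim$terms
    expr <- sim$expression
    panels <- sim$panels
  } else {
    sim <- NULL
    records <- run_stage("load", {
      seqs <- read_fasta(cfg$inputs$fasta)
      as_unigene_records(seqs)
    })
    taxa <- read_annotation_tsv(cfg$inputs$taxa)
    terms <- read_annotation_tsv(cfg$inputs$terms)
    expr <- read_expression_tsv(cfg$inputs$expression)
  }

  # --- unigene reduction ----------------------------------------------------
  uni <- run_stage("unigenes", build_unigene_set(
    records, taxa, e_max = cfg$unigenes$e_max, excluded = cfg$unigenes$excluded))
  write_fasta(stats::setNames(uni$unigenes$sequence, uni$unigenes$accession),
              file.path(outdir, "unigenes.fa"))
  report$counts$records_in <- unname(uni$counts[["records_in"]])
  report$counts$genes <- unname(uni$counts[["genes"]])
  report$counts$after_dedup <- unname(uni$counts[["after_dedup"]])
  report$counts$removed_contained <- length(uni$removed_contained)
  report$counts$removed_taxon <- nrow(uni$removed_taxon)
  report$counts$unigenes <- nrow(uni$unigenes)
  universe <- uni$unigenes$gene_id

  # --- expression atlas -----------------------------------------------------
  atlas <- run_stage("expression", {
    ex <- expr[intersect(rownames(expr), universe), , drop = FALSE]
    means <- average_replicates(ex)
    presence <- presence_calls(means, tpm_min = cfg$expression$tpm_min)
    venn <- overlap_partition(presence)
    n_top <- min(cfg$expression$top_n, nrow(means))
    tops <- lapply(c("M1", "M2", "M3", "M4"), function(t)
      top_n(means, t, n_top))
    names(tops) <- paste0(c("M1", "M2", "M3", "M4"), "_Top", n_top)
    pca <- pca_summary(ex)
    # the bacterial-like genes are profiled before being discarded
    removed_ids <- intersect(uni$removed_taxon$gene_id, rownames(expr))
    anova_removed <- if (length(removed_ids) >= 1)
      anova_by_region(expr, gene_subset = removed_ids) else NULL
    list(matrix = ex, means = means, presence = presence, venn = venn,
         tops = tops, pca = pca, anova_removed = anova_removed)
  })
  write_expression_tsv(atlas$means, file.path(outdir, "mean_tpm.tsv"))
  write_expression_tsv(atlas$presence * 1, file.path(outdir, "presence.tsv"))
  utils::write.table(
    data.frame(pattern = names(atlas$venn), count = atlas$venn),
    file.path(outdir, "venn_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(atlas$tops))
    writeLines(atlas$tops[[nm]], file.path(outdir, paste0(nm, ".txt")))
  report$counts$expressed_somewhere <- sum(atlas$venn)
  report$counts$shared_all_four <- unname(atlas$venn[["M1&M2&M3&M4"]])
  if (!is.null(atlas$anova_removed))
    report$counts$bacterial_anova_significant <-
      sum(atlas$anova_removed$significant)

  # --- fuzzy clustering -----------------------------------------------------
  groups <- atlas$tops
  if (isTRUE(cfg$clustering$enabled)) {
    clus <- run_stage("clustering", {
      z <- standardize(atlas$means, tpm_min = cfg$expression$tpm_min)
      params <- cluster_params(c = cfg$clustering$c, m = cfg$clustering$m,
                               tol = cfg$clustering$tol,
                               max_iter = cfg$clustering$max_iter,
                               restarts = cfg$clustering$restarts,
                               alpha = cfg$clustering$alpha, seed = cfg$seed)
      res <- fuzzy_cmeans(z, params)
      members <- assign_members(res, alpha = cfg$clustering$alpha)
      list(z = z, result = res, members = members)
    })
    utils::write.table(
      data.frame(gene_id = rownames(clus$result$membership),
                 clus$result$membership, check.names = FALSE),
      file.path(outdir, "membership.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cl_groups <- clus$members[lengths(clus$members) > 0]
    names(cl_groups) <- paste0(names(cl_groups), "_fuzzycluster")
    groups <- c(groups, cl_groups)
    report$counts$clustered_genes <- nrow(clus$z)
    report$counts$cluster_members <- sum(lengths(clus$members))
  } else clus <- NULL

  # --- enrichment -----------------------------------------------------------
  enr <- run_stage("enrichment", enrich_groups(
    groups, terms, universe,
    min_genes = cfg$enrichment$min_genes, fdr_max = cfg$enrichment$fdr_max))
  utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$counts$groups_tested <- length(groups)
  report$counts$enrichment_tests <- attr(enr, "n_tested") %||% 0L
  report$counts$enriched_rows <- nrow(enr)

  # --- family annotation ----------------------------------------------------
  if (isTRUE(cfg$families$enabled) && length(panels %||% list()) > 0) {
    fam <- run_stage("families", {
      seqs <- stats::setNames(uni$unigenes$sequence, uni$unigenes$gene_id)
      calls <- iterative_annotate(seqs, panels,
                                  e_max = cfg$families$e_max,
                                  cov_min = cfg$families$cov_min,
                                  min_identity = cfg$families$min_identity,
                                  max_rounds = cfg$families$max_rounds)
      summary <- summarize_family_expression(calls, atlas$means)
      list(calls = calls, summary = summary)
    })
    utils::write.table(fam$calls, file.path(outdir, "family_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fam$summary, file.path(outdir, "family_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$counts$family_calls <- nrow(fam$calls)
  } else fam <- NULL

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, sim = sim, unigenes = uni, atlas = atlas,
                 clustering = clus, enrichment = enr, families = fam))
}
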