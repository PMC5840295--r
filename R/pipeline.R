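stage_error <- function(stage, msg) {
  abort(paste0("[stage ", stage, "] ", msg))
}

default_config <- function() {
  list(
    seed = NULL,
    out_dir = "spectracall_out",
    stages = c("simulate_apms", "enrich", "score", "call", "classify", "export"),
    apms = list(n_proteins = 200, n_interactors = 20, enrichment_factor = 8,
                dispersion = 0.05),
    criteria = list(),
    rnaseq = list(n_genes = 2000, n_yfp = 20, n_matr3 = 10, effect_log2 = 1,
                  yfp_effect_log2 = 1.5, dispersion = 0.005)
  )
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in order, logging parameters and the
#' seed, and writes a run manifest with an md5 checksum for every file
#' produced, so a re-run can be verified bit-for-bit. Stages:
#'
#' * `simulate_apms` - seeded synthetic spectral-count matrix + truth
#' * `enrich` - per-prey enrichment statistics ([compute_enrichment()])
#' * `score` - background model + SAINT-style scores
#' * `call` - consensus interactor calls ([call_interactors()])
#' * `classify` - bait correction + domain-deletion classes
#' * `export` - SIF/GraphML/TSV network files
#' * `simulate_rnaseq`, `de_filter`, `endogenous`, `concordance` - the
#'   RNA-seq branch
#' * `phenotype` - validate/summarise a phenotype count TSV
#'
#' Stages that consume a spectral-count matrix either take it from a
#' preceding `simulate_apms` stage or read `apms$counts_file` /
#' `apms$run_meta_file` from the config.
#'
#' @param config path to a YAML config file, or an equivalent named list;
#'   see the packaged example
#'   `system.file("extdata", "pipeline_config.yaml", package = "spectracall")`
#' @param dry_run print the resolved stage plan and write nothing
#' @return invisibly, a tibble manifest (file, md5) of everything written
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed)) abort("The config must set an explicit `seed`.")
  stages <- cfg$stages
  if (dry_run) {
    message("Resolved stage plan (dry run, nothing written):")
    message(paste0("  ", seq_along(stages), ". ", stages, collapse = "\n"))
    message("  seed = ", cfg$seed, ", out_dir = ", cfg$out_dir)
    return(invisible(tibble(file = character(), md5 = character())))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_tsv(x, p)
    written <<- c(written, p)
    p
  }

  state <- new.env(parent = emptyenv())
  criteria <- do.call(call_criteria, cfg$criteria)

  need_matrix <- function(stage) {
    if (!is.null(state$counts)) return(invisible())
    cf <- cfg$apms$counts_file; rf <- cfg$apms$run_meta_file
    if (is.null(cf) || is.null(rf)) {
      stage_error(stage, paste0(
        "no spectral-count matrix available: run the simulate_apms stage ",
        "first or set apms$counts_file and apms$run_meta_file"))
    }
    state$counts <- read_spectral_counts(cf)
    state$run_meta <- read_run_meta(rf)
    if (!any(state$run_meta$construct == "control")) {
      stage_error(stage, "the run metadata contains no control runs")
    }
  }

  for (stage in stages) {
    message("[stage ", stage, "] seed=", cfg$seed)
    switch(stage,
      simulate_apms = {
        a <- cfg$apms
        design <- apms_design()
        truth <- apms_truth(
          n_proteins = a$n_proteins,
          interactors = {
            ids <- default_interactors(a$n_proteins, a$n_interactors)
            list(WT = ids, S85C = ids, F115C = ids)
          },
          enrichment_factor = a$enrichment_factor,
          dispersion = a$dispersion
        )
        sim <- simulate_apms(design, truth, seed = cfg$seed)
        state$counts <- sim$counts; state$run_meta <- sim$run_meta
        emit(sim$counts, "apms_counts.tsv")
        emit(sim$run_meta, "apms_run_meta.tsv")
        emit(sim$truth, "apms_truth.tsv")
      },
      enrich = {
        need_matrix(stage)
        state$enrichment <- compute_enrichment(state$counts, state$run_meta,
                                               construct = "WT",
                                               g_alpha = criteria$g_alpha)
        emit(state$enrichment, "enrichment.tsv")
      },
      score = {
        need_matrix(stage)
        bg <- fit_background(state$counts, state$run_meta)
        state$scores <- saint_scores(state$counts, state$run_meta, bg, "WT")
        emit(state$scores, "saint_scores.tsv")
      },
      call = {
        if (is.null(state$enrichment) || is.null(state$scores)) {
          stage_error(stage, "run the enrich and score stages first")
        }
        state$calls <- call_interactors(state$enrichment, state$scores, criteria)
        emit(state$calls, "interactor_calls.tsv")
      },
      classify = {
        need_matrix(stage)
        if (is.null(state$calls)) stage_error(stage, "run the call stage first")
        fac <- bait_correction(state$counts, state$run_meta)
        corrected <- apply_correction(state$counts, state$run_meta, fac)
        state$domain <- classify_domain_dependence(corrected, state$run_meta,
                                                   state$calls,
                                                   g_alpha = criteria$g_alpha)
        emit(fac, "correction_factors.tsv")
        emit(state$domain, "domain_dependence.tsv")
      },
      export = {
        if (is.null(state$calls)) stage_error(stage, "run the call stage first")
        paths <- export_network(state$calls, cfg$out_dir)
        written <- c(written, unname(paths))
      },
      simulate_rnaseq = {
        r <- cfg$rnaseq
        ng <- r$n_genes
        # plant effects on well-expressed genes; sets disjoint by construction
        yfp_idx <- round(seq(0.60, 0.75, length.out = r$n_yfp) * ng)
        m3_idx <- round(seq(0.80, 0.92, length.out = r$n_matr3) * ng)
        truth <- rnaseq_truth(
          n_genes = ng, dispersion = r$dispersion,
          yfp_effects = stats::setNames(rep(r$yfp_effect_log2, r$n_yfp), yfp_idx),
          matr3_effects = stats::setNames(rep(r$effect_log2, r$n_matr3), m3_idx),
          transgene = list(gene = ng - 1L, shared_exons = 1:3, multiplier = 30)
        )
        state$rnaseq <- simulate_rnaseq(truth, seed = cfg$seed)
        emit(state$rnaseq$gene_counts, "gene_counts.tsv")
        emit(state$rnaseq$exon_counts, "exon_counts.tsv")
        emit(state$rnaseq$annotation, "exon_annotation.tsv")
        emit(state$rnaseq$sample_meta, "rnaseq_samples.tsv")
        emit(state$rnaseq$truth, "rnaseq_truth.tsv")
      },
      de_filter = {
        if (is.null(state$rnaseq)) stage_error(stage, "run simulate_rnaseq first (or call nb_de_test directly on your own tables)")
        sm <- state$rnaseq$sample_meta
        de_wt <- nb_de_test(state$rnaseq$gene_counts, sm, "WT", "YFP")
        de_yfp <- nb_de_test(state$rnaseq$gene_counts, sm, "YFP", "untransfected")
        spec <- matr3_specific_filter(de_wt, de_yfp)
        emit(de_wt, "de_wt_vs_yfp.tsv")
        emit(de_yfp, "de_yfp_vs_untransfected.tsv")
        emit(spec, "matr3_specific_genes.tsv")
      },
      endogenous = {
        if (is.null(state$rnaseq)) stage_error(stage, "run simulate_rnaseq first")
        ex <- state$rnaseq$exon_counts
        host <- state$rnaseq$truth$gene_id[state$rnaseq$truth$class == "transgene_host"]
        if (!length(host)) stage_error(stage, "the simulated data plant no transgene")
        shared <- sprintf("%s_e%d", host, 1:3)
        emit(endogenous_expression(ex, host, shared), "endogenous_rpkm.tsv")
      },
      concordance = {
        if (is.null(state$rnaseq)) stage_error(stage, "run simulate_rnaseq first")
        r <- rpkm(state$rnaseq$gene_counts)
        conc <- pairwise_pearson(r)
        emit(tidy(conc), "pairwise_pearson.tsv")
      },
      phenotype = {
        path <- cfg$phenotype$counts_file %||%
          system.file("extdata", "phenotype_counts.tsv", package = "spectracall")
        emit(read_phenotype_table(path), "phenotype_summary.tsv")
      },
      stage_error(stage, "unknown stage")
    )
  }
  manifest <- tibble(file = written,
                     md5 = unname(tools::md5sum(written)))
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(manifest)
}
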