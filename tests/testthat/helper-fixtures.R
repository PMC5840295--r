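# Shared fixtures, all built in code at test time.

# A tiny hand-written spectral-count table: 3 proteins x 2 control + 2 WT
# runs, with the bait in row 1.
tiny_counts <- function() {
  tibble::tibble(
    protein_id = c("BAIT", "P1", "P2"),
    control_1A = c(5L, 2L, 0L),
    control_2B = c(7L, 4L, 1L),
    WT_1A = c(60L, 20L, 0L),
    WT_2B = c(64L, 24L, 2L)
  )
}

tiny_meta <- function() {
  tibble::tibble(
    run_id = c("control_1A", "control_2B", "WT_1A", "WT_2B"),
    construct = c("control", "control", "WT", "WT"),
    batch = c("A", "B", "A", "B"),
    replicate = c(1L, 2L, 1L, 2L)
  )
}

# Study-condition AP-MS simulation: 200 proteins, 20 planted interactors
# shared by WT and the point mutants, default design and calibration.
std_apms <- function(seed, enrichment_overrides = NULL, all_constructs = FALSE) {
  ids <- default_interactors(200, 20)
  cons <- if (all_constructs) {
    c("WT", "S85C", "F115C", "dRRM1", "dRRM2", "dZnF1", "dZnF2")
  } else {
    c("WT", "S85C", "F115C")
  }
  truth <- apms_truth(
    interactors = stats::setNames(rep(list(ids), length(cons)), cons),
    enrichment_overrides = enrichment_overrides
  )
  simulate_apms(apms_design(), truth, seed = seed)
}

# Run enrichment + scoring + calling on a simulation.
call_pipeline <- function(sim, criteria = call_criteria()) {
  e <- compute_enrichment(sim$counts, sim$run_meta, "WT", g_alpha = criteria$g_alpha)
  bg <- fit_background(sim$counts, sim$run_meta)
  sc <- suppressWarnings(saint_scores(sim$counts, sim$run_meta, bg, "WT"))
  call_interactors(e, sc, criteria)
}

# Planted domain-dependence scenario: one robust prey losing binding on
# RRM1 deletion (0.1x WT), one gaining 4x on RRM2 deletion.
domain_scenario <- function(seed) {
  ids <- default_interactors(200, 20)
  reduced_prey <- sprintf("P%04d", ids[15])
  enhanced_prey <- sprintf("P%04d", ids[18])
  ov <- tibble::tibble(
    construct = c("dRRM1", "dRRM2"),
    protein = c(ids[15], ids[18]),
    factor = c(0.8, 32)   # 0.1x and 4x the 8-fold WT enrichment
  )
  sim <- std_apms(seed, enrichment_overrides = ov, all_constructs = TRUE)
  calls <- call_pipeline(sim)
  fac <- bait_correction(sim$counts, sim$run_meta)
  corrected <- apply_correction(sim$counts, sim$run_meta, fac)
  records <- suppressWarnings(
    classify_domain_dependence(corrected, sim$run_meta, calls)
  )
  list(sim = sim, calls = calls, factors = fac, corrected = corrected,
       records = records, reduced_prey = reduced_prey,
       enhanced_prey = enhanced_prey)
}

# Study-condition RNA-seq simulation with planted transfection artifacts,
# bait-specific genes and a 30x transgene on a highly expressed host.
std_rnaseq <- function(seed, n_genes = 2000, transgene_multiplier = 30) {
  rnaseq_sim_truth <- rnaseq_truth(
    n_genes = n_genes,
    yfp_effects = stats::setNames(rep(1.5, 20),
                                  round(seq(0.60, 0.75, length.out = 20) * n_genes)),
    matr3_effects = stats::setNames(rep(c(1, -1), 5),
                                    round(seq(0.80, 0.92, length.out = 10) * n_genes)),
    transgene = list(gene = round(0.975 * n_genes), shared_exons = 1:2,
                     multiplier = transgene_multiplier)
  )
  sim <- simulate_rnaseq(rnaseq_sim_truth, seed = seed)
  sim$config <- rnaseq_sim_truth
  sim
}

# Direct, index-free evaluation of G = 2 * sum O*ln(O/E) on the 2x2 table,
# used as the independent oracle for g_test().
g_oracle <- function(xb, nb, xc, nc) {
  O <- c(xb, nb - xb, xc, nc - xc)
  N <- nb + nc
  E <- c((xb + xc) * nb, (N - xb - xc) * nb,
         (xb + xc) * nc, (N - xb - xc) * nc) / N
  terms <- ifelse(O == 0, 0, O * log(O / E))
  2 * sum(terms)
}
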