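#' AP-MS run design
#'
#' Builds the run layout of a spectral-counting affinity-capture study:
#' untransfected bead controls, a wild-type bait, point mutants and
#' single-domain deletion constructs, processed in two batches (A/B).
#' The default layout is 5 control runs, 4 wild-type runs, 3 runs per
#' point mutant and 2 runs per deletion construct.
#'
#' @param n_control,n_wt,n_point,n_deletion replicate runs per construct class
#' @param point_constructs,deletion_constructs construct labels
#' @return tibble with columns `run_id`, `construct`, `batch`, `replicate`
#' @export
#' @examples
#' apms_design()
apms_design <- function(n_control = 5, n_wt = 4, n_point = 3, n_deletion = 2,
                        point_constructs = c("S85C", "F115C"),
                        deletion_constructs = c("dRRM1", "dRRM2", "dZnF1", "dZnF2")) {
  if (n_control < 2) abort("At least 2 control runs are required.")
  one <- function(construct, n) {
    # first half of replicates in batch A, remainder in batch B
    batch <- ifelse(seq_len(n) <= ceiling(n / 2), "A", "B")
    tibble(
      run_id = sprintf("%s_%d%s", construct, seq_len(n), batch),
      construct = construct, batch = batch, replicate = seq_len(n)
    )
  }
  dplyr::bind_rows(
    one("control", n_control),
    one("WT", n_wt),
    purrr::map_dfr(point_constructs, one, n = n_point),
    purrr::map_dfr(deletion_constructs, one, n = n_deletion)
  )
}

#' Ground-truth configuration for the AP-MS simulator
#'
#' Describes the generating process: a per-protein sticky-background mean
#' (spectra expected in any run from non-specific bead binding), shared
#' negative-binomial dispersion, per-construct sets of true interactors
#' whose means are multiplied by `enrichment_factor` in that construct's
#' runs, a multiplicative batch effect, and a per-construct capture level
#' for the bait protein itself (so correction factors are estimable
#' downstream).
#'
#' @param n_proteins number of proteins (preys plus the bait row)
#' @param background_mean per-protein background mean; scalar recycled or
#'   vector of length `n_proteins`. Default draws nothing: a fixed
#'   log-spaced grade of stickiness from 0.2 to 12 spectra per run.
#' @param dispersion shared NB dispersion (variance = mu + dispersion*mu^2);
#'   0 gives Poisson counts. The default 0.05 is calibrated by method of
#'   moments to published replicate spectral counts, which are highly
#'   consistent within batch
#' @param interactors named list, construct label -> integer protein indices
#'   that are true interactors of that construct
#' @param enrichment_factor mean multiplier for a true interactor in its
#'   construct's runs; must be >= 1
#' @param enrichment_overrides optional tibble (construct, protein, factor)
#'   replacing `enrichment_factor` for specific pairs, e.g. to plant a
#'   domain-deletion-dependent prey
#' @param batch_multiplier named multiplier per batch, e.g. c(A = 1, B = 1.3)
#' @param bait_capture named per-construct mean spectral count of the bait
#'   protein itself; the "control" entry is the bait's background level.
#'   A true interactor's enrichment scales with the construct's captured
#'   bait relative to `reference_construct` (co-capture is proportional
#'   to how much bait is on the beads), which is what the downstream
#'   bait-level correction factors compensate
#' @param reference_construct construct whose capture level defines scale 1
#'   (default "WT")
#' @param bait_protein index of the bait row (default 1)
#' @return list of class `apms_truth`
#' @export
apms_truth <- function(n_proteins = 200,
                       background_mean = NULL,
                       dispersion = 0.05,
                       interactors = list(),
                       enrichment_factor = 8,
                       enrichment_overrides = NULL,
                       batch_multiplier = c(A = 1, B = 1.3),
                       bait_capture = c(control = 5, WT = 150, S85C = 150,
                                        F115C = 150, dRRM1 = 150, dRRM2 = 150,
                                        dZnF1 = 125, dZnF2 = 75),
                       reference_construct = "WT",
                       bait_protein = 1L) {
  if (is.null(background_mean)) {
    background_mean <- exp(seq(log(0.2), log(12), length.out = n_proteins))
  }
  background_mean <- rep_len(background_mean, n_proteins)
  if (any(background_mean <= 0)) abort("All background means must be positive.")
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  if (enrichment_factor < 1) abort("`enrichment_factor` must be >= 1.")
  if (any(batch_multiplier <= 0)) abort("Batch multipliers must be positive.")
  if (any(bait_capture <= 0)) abort("Bait capture levels must be positive.")
  if (bait_protein < 1 || bait_protein > n_proteins) {
    abort("`bait_protein` must be an index within 1..n_proteins.")
  }
  if (!reference_construct %in% names(bait_capture)) {
    abort("`reference_construct` needs an entry in `bait_capture`.")
  }
  interactors <- lapply(interactors, as.integer)
  structure(
    list(n_proteins = n_proteins, background_mean = background_mean,
         dispersion = dispersion, interactors = interactors,
         enrichment_factor = enrichment_factor,
         enrichment_overrides = enrichment_overrides,
         batch_multiplier = batch_multiplier, bait_capture = bait_capture,
         reference_construct = reference_construct,
         bait_protein = as.integer(bait_protein)),
    class = "apms_truth"
  )
}

#' Default planted-interactor indices
#'
#' Evenly spaced preys from the upper half of the background-abundance
#' ladder, so that at the default 8x enrichment their bait-run counts
#' fall in the 10-100 spectra range typical of robustly detected
#' interactors in published spectral-count tables.
#'
#' @param n_proteins number of proteins in the design
#' @param n number of interactors to plant (default 20)
#' @param bait_protein bait index to avoid (default 1)
#' @return integer vector of protein indices
#' @export
default_interactors <- function(n_proteins, n = 20, bait_protein = 1L) {
  idx <- unique(round(seq(0.5, 1, length.out = n) * n_proteins))
  idx <- setdiff(idx, bait_protein)
  if (length(idx) < n) {
    pool <- setdiff(seq(ceiling(n_proteins / 2), n_proteins), c(idx, bait_protein))
    idx <- sort(c(idx, pool[seq_len(n - length(idx))]))
  }
  idx
}

protein_ids <- function(n, bait_protein) {
  ids <- sprintf("P%04d", seq_len(n))
  ids[bait_protein] <- "BAIT"
  ids
}

# Expected count for every (protein, run) cell under the truth config.
apms_mean_matrix <- function(design, truth) {
  n <- truth$n_proteins
  mu <- matrix(truth$background_mean, nrow = n, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    cons <- design$construct[j]
    bm <- truth$batch_multiplier[[design$batch[j]]]
    if (is.null(bm)) abort(paste0("No batch multiplier for batch ", design$batch[j]))
    if (cons != "control") {
      # bait-dependent binding scales with how much bait this construct
      # captures relative to the reference; sticky background does not
      cap_rel <- truth$bait_capture[[cons]] /
        truth$bait_capture[[truth$reference_construct]]
      idx <- truth$interactors[[cons]]
      if (length(idx)) {
        mu[idx, j] <- mu[idx, j] * truth$enrichment_factor * cap_rel
      }
      ov <- truth$enrichment_overrides
      if (!is.null(ov)) {
        ovc <- ov[ov$construct == cons, , drop = FALSE]
        if (nrow(ovc)) {
          mu[ovc$protein, j] <- truth$background_mean[ovc$protein] *
            ovc$factor * cap_rel
        }
      }
    }
    cap <- truth$bait_capture[[cons]]
    if (is.null(cap)) abort(paste0("No bait capture level for construct ", cons))
    mu[truth$bait_protein, j] <- cap
    mu[, j] <- mu[, j] * bm
  }
  rownames(mu) <- protein_ids(n, truth$bait_protein)
  colnames(mu) <- design$run_id
  mu
}

#' Simulate an AP-MS spectral-count matrix with known ground truth
#'
#' Draws negative-binomial spectral counts per (protein, run) cell with
#' mean = background x batch multiplier, times the enrichment factor when
#' the protein is a true interactor of the run's construct; the bait row
#' follows the construct-specific capture level instead. Identical
#' (design, truth, seed) triples give byte-identical tables.
#'
#' @param design run layout from [apms_design()]
#' @param truth generating configuration from [apms_truth()]
#' @param seed integer seed; required, no global RNG state is consumed
#' @return list with `counts` (wide tibble, first column `protein_id`),
#'   `run_meta` (the design), `truth` (tibble `protein_id`, `class` with
#'   class one of bait/interactor/background), and `interactions`
#'   (tibble `construct`, `protein_id` of planted interactions)
#' @export
#' @examples
#' sim <- simulate_apms(apms_design(), apms_truth(interactors = list(WT = 2:21)), seed = 1)
#' sim$counts[1:3, 1:4]
simulate_apms <- function(design, truth, seed) {
  stopifnot(inherits(truth, "apms_truth"), is.data.frame(design))
  if (anyDuplicated(design$run_id)) abort("Run ids must be unique.")
  if (sum(design$construct == "control") < 2) {
    abort("The design needs at least 2 control runs.")
  }
  mu <- apms_mean_matrix(design, truth)
  counts <- with_seed(seed, {
    matrix(rnbinom_mu(length(mu), mu = as.vector(mu), dispersion = truth$dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  })
  ids <- rownames(mu)
  inter_idx <- sort(unique(unlist(truth$interactors, use.names = FALSE)))
  ov <- truth$enrichment_overrides
  if (!is.null(ov)) inter_idx <- sort(unique(c(inter_idx, ov$protein)))
  cls <- rep("background", truth$n_proteins)
  cls[inter_idx] <- "interactor"
  cls[truth$bait_protein] <- "bait"
  interactions <- purrr::imap_dfr(truth$interactors, function(idx, cons) {
    tibble(construct = cons, protein_id = ids[idx])
  })
  list(
    counts = dplyr::bind_cols(tibble(protein_id = ids), as_tibble(counts)),
    run_meta = as_tibble(design),
    truth = tibble(protein_id = ids, class = cls),
    interactions = interactions
  )
}
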