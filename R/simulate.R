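#' Configuration for the synthetic three-condition experiment
#'
#' Bundles every knob of the generator suite with the defaults that
#' define the emulated study: a bulk RNA-seq experiment with control,
#' perturbed and perturbed-plus-drug conditions, a pathway catalogue, a
#' TF-regulon catalogue, an L1000-style drug-profile library and a
#' drug-target table, all carrying planted signal with a ground-truth
#' manifest.
#'
#' @param n_genes gene universe size.
#' @param n_per_condition replicates per condition.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene baseline mean expression.
#' @param dispersion NB dispersion (`variance = mu + dispersion * mu^2`).
#' @param n_up_down,n_down_up planted flip genes (induction reversed /
#'   repression reversed).
#' @param n_perturbed_only_up,n_perturbed_only_down planted DEGs that the
#'   drug does not revert.
#' @param perturb_lfc log2 effect size of the perturbation.
#' @param drug_revert_fraction fraction of the perturbation effect
#'   removed by the drug in flip genes (in `(0, 1]`).
#' @param drug_overshoot extra log2 shift past baseline in the drug
#'   condition so flip genes cross the drug-contrast DEG rule.
#' @param n_pathways decoy pathway count; `pathway_size_range` their size
#'   range; `planted_pathway_size` and `planted_pathway_fraction` define
#'   the two planted pathways (one per flip class, that fraction of
#'   members drawn from the class).
#' @param pathway_size_range,planted_pathway_size,planted_pathway_fraction
#'   see above.
#' @param n_regulons decoy regulon count; `regulon_size_range` their
#'   sizes; `planted_regulon_size`/`planted_regulon_fraction` define the
#'   planted TF regulon (drawn mostly from flip genes).
#' @param regulon_size_range,planted_regulon_size,planted_regulon_fraction
#'   see above.
#' @param n_drugs,profiles_per_drug library plan.
#' @param n_planted_mimics drugs whose profiles mimic the flip signature.
#' @param mimic_overlap_fraction fraction of each signature flank of a
#'   planted mimic profile that is flip-concordant.
#' @param n_sig signature flank size used when planting mimics.
#' @param low_quality_rate,non_fda_rate rates at which decoy profiles /
#'   drugs are flagged out, exercising the quality filter.
#' @param n_targets target-table plan; the planted target annotates
#'   `planted_target_coverage` of the mimic drugs and `background_rate`
#'   of the others; decoy targets annotate drugs at `background_rate`.
#' @param planted_target_coverage,background_rate see above.
#' @param seed master seed; every generator derives its stream from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_per_condition = 5L,
                       baseline_log_mean = 4, baseline_log_sd = 1.5,
                       dispersion = 0.1,
                       n_up_down = 80L, n_down_up = 120L,
                       n_perturbed_only_up = 100L,
                       n_perturbed_only_down = 100L,
                       perturb_lfc = 3, drug_revert_fraction = 1,
                       drug_overshoot = 1.5,
                       n_pathways = 200L, pathway_size_range = c(10L, 40L),
                       planted_pathway_size = 40L,
                       planted_pathway_fraction = 0.6,
                       n_regulons = 50L, regulon_size_range = c(20L, 60L),
                       planted_regulon_size = 30L,
                       planted_regulon_fraction = 0.8,
                       n_drugs = 200L, profiles_per_drug = 2L,
                       n_planted_mimics = 10L,
                       mimic_overlap_fraction = 0.6, n_sig = 100L,
                       low_quality_rate = 0.1, non_fda_rate = 0.1,
                       n_targets = 30L, planted_target_coverage = 0.8,
                       background_rate = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- n_up_down + n_down_up + n_perturbed_only_up +
    n_perturbed_only_down
  if (any(c(n_up_down, n_down_up, n_perturbed_only_up,
            n_perturbed_only_down) < 0))
    stop("planted gene counts must be non-negative")
  if (n_planted > n_genes)
    stop("planted gene classes (", n_planted, ") exceed n_genes (",
         n_genes, ")")
  if (drug_revert_fraction <= 0 || drug_revert_fraction > 1)
    stop("drug_revert_fraction must lie in (0, 1]")
  if (n_planted_mimics > 0L &&
      mimic_overlap_fraction * n_sig > min(n_up_down, n_down_up))
    stop("mimic_overlap_fraction * n_sig exceeds a flip class size")
  if (n_planted_mimics > n_drugs)
    stop("n_planted_mimics exceeds n_drugs")
  stopifnot(dispersion > 0, perturb_lfc >= 0, seed == floor(seed))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d genes, %d per condition, perturb_lfc = %g, seed = %d\n",
    "  planted: %d up_down, %d down_up, %d+%d perturbed-only\n"),
    x$n_genes, x$n_per_condition, x$perturb_lfc, x$seed,
    x$n_up_down, x$n_down_up, x$n_perturbed_only_up,
    x$n_perturbed_only_down))
  invisible(x)
}

# Offsets separating the generator streams derived from the master seed.
SIM_SEED_OFFSETS <- c(counts = 0L, pathways = 101L, regulons = 202L,
                      library = 303L)

#' Simulate the three-condition count matrix with ground truth
#'
#' Per-gene baseline means are log-normal; counts are negative binomial
#' with `variance = mu + dispersion * mu^2` around
#' `size_factor * mu * 2^delta`, where `delta` is 0 in the control,
#' `+/- perturb_lfc` for planted perturbed genes, and - for flip genes
#' in the drug condition - reversed by `drug_revert_fraction` of the
#' perturbation plus a beyond-baseline `drug_overshoot`, so the
#' drug-vs-control contrast crosses a mild DEG rule in the opposite
#' direction. Sample depth factors are Uniform(0.7, 1.3). Bit-identical
#' output for a fixed config.
#'
#' @param cfg a [sim_config()].
#' @return List with `cm` (a [count_matrix()]) and `truth` (class
#'   `ground_truth`): per-gene class vector plus the planted gene lists.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SIM_SEED_OFFSETS[["counts"]])
  n <- cfg$n_per_condition
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(n)),
               sprintf("pert_%d", seq_len(n)),
               sprintf("drug_%d", seq_len(n)))
  condition <- setNames(rep(CONDITION_LEVELS, each = n), samples)

  counts_per_class <- c(up_down = cfg$n_up_down, down_up = cfg$n_down_up,
                        perturbed_only_up = cfg$n_perturbed_only_up,
                        perturbed_only_down = cfg$n_perturbed_only_down)
  planted_idx <- sample.int(cfg$n_genes, sum(counts_per_class))
  gene_class <- setNames(rep("null", cfg$n_genes), genes)
  gene_class[planted_idx] <- rep(names(counts_per_class), counts_per_class)

  sign_of <- c(up_down = 1, down_up = -1, perturbed_only_up = 1,
               perturbed_only_down = -1, null = 0)
  sgn <- unname(sign_of[gene_class])
  delta_pert <- sgn * cfg$perturb_lfc
  is_flip <- gene_class %in% c("up_down", "down_up")
  delta_drug <- ifelse(
    is_flip,
    sgn * (cfg$perturb_lfc * (1 - cfg$drug_revert_fraction) -
             cfg$drug_overshoot),
    delta_pert)

  mu <- rlnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  sf <- runif(3L * n, 0.7, 1.3)
  delta <- cbind(matrix(0, cfg$n_genes, n),
                 matrix(delta_pert, cfg$n_genes, n),
                 matrix(delta_drug, cfg$n_genes, n))
  mu_mat <- (mu * 2^delta) %*% diag(sf)
  counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                           size = 1 / cfg$dispersion),
                   cfg$n_genes, 3L * n,
                   dimnames = list(genes, samples))
  truth <- structure(list(
    gene_class = gene_class,
    up_down = genes[gene_class == "up_down"],
    down_up = genes[gene_class == "down_up"],
    perturbed_only_up = genes[gene_class == "perturbed_only_up"],
    perturbed_only_down = genes[gene_class == "perturbed_only_down"]),
    class = "ground_truth")
  list(cm = count_matrix(counts, condition), truth = truth)
}

# sample `size` genes, `frac` of them from `pool`, the rest from `other`
sample_planted_set <- function(pool, other, size, frac) {
  n_in <- min(round(frac * size), length(pool))
  c(sample(pool, n_in), sample(other, size - n_in))
}

#' Simulate a pathway catalogue with planted flip pathways
#'
#' Two planted pathways - one per flip class - draw
#' `planted_pathway_fraction` of their members from that class and the
#' rest uniformly; decoy pathways sample uniformly from the universe.
#'
#' @param cfg a [sim_config()].
#' @param truth the `ground_truth` from [simulate_counts()].
#' @return List with `sets` (a [gene_set_collection()]) and `planted`
#'   (named character: planted set id per flip class).
#' @export
simulate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(cfg$seed + SIM_SEED_OFFSETS[["pathways"]])
  universe <- names(truth$gene_class)
  sets <- list()
  for (cls in c("up_down", "down_up")) {
    sets[[paste0("planted_", cls)]] <- sample_planted_set(
      truth[[cls]], setdiff(universe, truth[[cls]]),
      cfg$planted_pathway_size, cfg$planted_pathway_fraction)
  }
  sizes <- sample(seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L]),
                  cfg$n_pathways, replace = TRUE)
  for (i in seq_len(cfg$n_pathways))
    sets[[sprintf("decoy_%03d", i)]] <- sample(universe, sizes[i])
  list(sets = gene_set_collection(sets),
       planted = c(up_down = "planted_up_down", down_up = "planted_down_up"))
}

#' Simulate a TF-regulon catalogue with one planted flip TF
#'
#' The planted regulon draws `planted_regulon_fraction` of its members
#' from the flip classes (both directions, proportional to their sizes);
#' decoys are uniform draws.
#'
#' @inheritParams simulate_pathways
#' @return List with `sets` (a [gene_set_collection()]) and `planted`
#'   (the planted TF id).
#' @export
simulate_regulons <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(cfg$seed + SIM_SEED_OFFSETS[["regulons"]])
  universe <- names(truth$gene_class)
  flip <- c(truth$up_down, truth$down_up)
  sets <- list(TF_planted = sample_planted_set(
    flip, setdiff(universe, flip), cfg$planted_regulon_size,
    cfg$planted_regulon_fraction))
  sizes <- sample(seq(cfg$regulon_size_range[1L], cfg$regulon_size_range[2L]),
                  cfg$n_regulons, replace = TRUE)
  for (i in seq_len(cfg$n_regulons))
    sets[[sprintf("TF_decoy_%02d", i)]] <- sample(universe, sizes[i])
  list(sets = gene_set_collection(sets), planted = "TF_planted")
}

#' Simulate the drug-profile library and drug-target table
#'
#' Decoy profiles score every gene as standard normal noise. Planted
#' mimic profiles additionally push `mimic_overlap_fraction * n_sig`
#' flip genes per flank beyond the noise range in the drug-concordant
#' direction (down for induction-reversed flips, up for
#' repression-reversed ones). A fraction of decoy profiles is flagged
#' low-quality and a fraction of decoy drugs non-FDA-approved; planted
#' mimic drugs always pass the filter. The planted target annotates
#' `planted_target_coverage` of the mimic drugs plus background decoys;
#' decoy targets annotate drugs at `background_rate`.
#'
#' @inheritParams simulate_pathways
#' @return List with `library` (a [drug_profile_library()]), `targets`
#'   (a `drug_target_table`), `planted_drugs`, `planted_target`.
#' @export
simulate_drug_library <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(cfg$seed + SIM_SEED_OFFSETS[["library"]])
  genes <- names(truth$gene_class)
  drugs <- sprintf("drug_%03d", seq_len(cfg$n_drugs))
  planted_drugs <- drugs[seq_len(cfg$n_planted_mimics)]
  profile_ids <- as.vector(t(outer(drugs, seq_len(cfg$profiles_per_drug),
                                   function(d, k) sprintf("%s_p%d", d, k))))
  drug_of <- rep(drugs, each = cfg$profiles_per_drug)
  scores <- matrix(rnorm(length(genes) * length(profile_ids)),
                   length(genes), length(profile_ids),
                   dimnames = list(genes, profile_ids))
  n_conc <- round(cfg$mimic_overlap_fraction * cfg$n_sig)
  for (j in which(drug_of %in% planted_drugs)) {
    dn <- sample(truth$up_down, n_conc)
    up <- sample(truth$down_up, n_conc)
    scores[dn, j] <- -runif(n_conc, 6, 10)
    scores[up, j] <- runif(n_conc, 6, 10)
  }
  fda_drug <- setNames(runif(cfg$n_drugs) >= cfg$non_fda_rate, drugs)
  fda_drug[planted_drugs] <- TRUE
  quality <- runif(length(profile_ids)) >= cfg$low_quality_rate
  quality[drug_of %in% planted_drugs] <- TRUE
  meta <- data.frame(profile_id = profile_ids, drug_id = drug_of,
                     quality = quality,
                     fda_approved = unname(fda_drug[drug_of]),
                     stringsAsFactors = FALSE)
  lib <- drug_profile_library(scores, meta)

  target_ids <- c("target_planted",
                  sprintf("target_decoy_%02d", seq_len(cfg$n_targets - 1L)))
  rows <- list()
  covered <- sample(planted_drugs,
                    round(cfg$planted_target_coverage * length(planted_drugs)))
  decoy_drugs <- setdiff(drugs, planted_drugs)
  bg <- decoy_drugs[runif(length(decoy_drugs)) < cfg$background_rate]
  rows[[1L]] <- data.frame(drug_id = c(covered, bg),
                           target_id = "target_planted",
                           stringsAsFactors = FALSE)
  for (t in target_ids[-1L]) {
    hit <- drugs[runif(cfg$n_drugs) < cfg$background_rate]
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(drug_id = hit, target_id = t,
                                              stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, rows)
  targets$source_db <- sample(DRUG_TARGET_SOURCES, nrow(targets),
                              replace = TRUE)
  targets <- targets[!duplicated(targets[c("drug_id", "target_id")]), ]
  rownames(targets) <- NULL
  class(targets) <- c("drug_target_table", "data.frame")
  list(library = lib, targets = targets, planted_drugs = planted_drugs,
       planted_target = "target_planted")
}

#' Generate every pipeline input from one configuration
#'
#' Convenience driver calling the four generators in order.
#'
#' @param cfg a [sim_config()].
#' @return List with `cm`, `truth`, `pathways`, `regulons`, `library`,
#'   `targets`, `planted` (pathway ids, TF id, drug ids, target id) and
#'   the `cfg` itself.
#' @export
simulate_all <- function(cfg) {
  counts <- simulate_counts(cfg)
  paths <- simulate_pathways(cfg, counts$truth)
  regs <- simulate_regulons(cfg, counts$truth)
  lib <- simulate_drug_library(cfg, counts$truth)
  list(cm = counts$cm, truth = counts$truth,
       pathways = paths$sets, regulons = regs$sets,
       library = lib$library, targets = lib$targets,
       planted = list(pathways = paths$planted, tf = regs$planted,
                      drugs = lib$planted_drugs,
                      target = lib$planted_target),
       cfg = cfg)
}

#' Write a simulated experiment to a directory
#'
#' Emits every input file the pipeline reads (counts + conditions TSV,
#' pathway and regulon GMT, profile library + metadata TSV, drug-target
#' TSV) plus a `manifest.json` ground-truth record. All files are plain
#' text and byte-reproducible for a fixed config.
#'
#' @param sim a [simulate_all()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts(sim$cm, p("counts.tsv"), p("conditions.tsv"))
  write_gmt(sim$pathways, p("pathways.gmt"))
  write_gmt(sim$regulons, p("regulons.gmt"))
  write_drug_profiles(sim$library, p("profiles.tsv"), p("profile_meta.tsv"))
  write_drug_targets(sim$targets, p("targets.tsv"))
  manifest <- list(
    gene_class = as.list(sim$truth$gene_class),
    planted = sim$planted,
    config = unclass(sim$cfg))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(c("counts.tsv", "conditions.tsv", "pathways.gmt",
                     "regulons.gmt", "profiles.tsv", "profile_meta.tsv",
                     "targets.tsv", "manifest.json"), p, ""))
}
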