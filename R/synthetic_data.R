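#' Configuration for the latent-factor expression simulator
#'
#' The generator emulates the statistical structure that coordination
#' analysis exploits in genetically diverse individuals: a per-individual
#' latent stress-pathway activity `u`, a tightly coordinated pathway module
#' loading on `u`, a planted hidden target gene loading on the same factor,
#' a partially coordinated gene split between `u` and an independent second
#' factor `v`, and unstructured background genes. Treatment enters as a mean
#' shift `delta` of the latent activity in treated samples, so pooling
#' control and treated samples strengthens the module correlations.
#'
#' Model, per sample i and gene g (all noise Gaussian):
#' \describe{
#'   \item{latents}{`u_i ~ N(0, sigma_u^2) + delta * treated_i`;
#'     `v_i ~ N(0, sigma_u^2)` independent of `u`.}
#'   \item{module / planted target}{`x_gi = mu_g + lambda * u_i + eps_gi`}
#'   \item{dual-loading}{`x_gi = mu_g + (lambda / 2) * u_i +
#'     rho_secondary * v_i + eps_gi`}
#'   \item{background}{`x_gi = mu_g + eps_gi`}
#' }
#' with `mu_g ~ N(baseline_mean, baseline_sd^2)` drawn once per gene and
#' `eps_gi ~ N(0, sigma_e^2)`.
#'
#' @param n_samples Number of samples (individuals), >= 3.
#' @param n_background Number of unstructured background genes.
#' @param module_genes Number of coordinated pathway-module genes.
#' @param planted_targets Number of hidden target genes on the same factor.
#' @param dual_loading_genes Number of genes split across the two factors.
#' @param baseline_mean,baseline_sd Mean and SD of the per-gene baseline
#'   `mu_g` (log2-normalized-expression scale).
#' @param lambda Loading of module/target genes on the latent factor `u`.
#' @param sigma_u SD of the latent activity across individuals.
#' @param sigma_e Residual noise SD.
#' @param delta Latent-activity offset added for treated samples.
#' @param treated_fraction Fraction of samples labeled treated.
#' @param rho_secondary Loading of dual genes on the second factor `v`.
#' @param seed Integer seed; mandatory — all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 12, n_background = 2000,
                             module_genes = 6, planted_targets = 1,
                             dual_loading_genes = 1,
                             baseline_mean = 8, baseline_sd = 2,
                             lambda = 1, sigma_u = 1, sigma_e = 0.5,
                             delta = 1, treated_fraction = 0.5,
                             rho_secondary = 1, seed) {
  if (missing(seed)) stop("seed is mandatory (no implicit entropy)")
  stopifnot(n_samples >= 3, n_background >= 0, module_genes >= 0,
            planted_targets >= 0, dual_loading_genes >= 0,
            baseline_sd > 0, sigma_u > 0, sigma_e >= 0,
            treated_fraction >= 0, treated_fraction <= 1)
  structure(list(
    n_samples = as.integer(n_samples),
    n_background = as.integer(n_background),
    module_genes = as.integer(module_genes),
    planted_targets = as.integer(planted_targets),
    dual_loading_genes = as.integer(dual_loading_genes),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    lambda = lambda, sigma_u = sigma_u, sigma_e = sigma_e,
    delta = delta, treated_fraction = treated_fraction,
    rho_secondary = rho_secondary, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Draws one realization of the model described in [synthetic_config()].
#' Structured genes come first (module, then planted targets, then dual
#' genes), followed by the background. Optional `gene_aliases` rename the
#' leading structured genes (e.g. to the pathway panel's familiar symbols).
#' The output is flagged `"normalized"`: downstream correlation runs on these
#' values directly.
#'
#' @param config A [synthetic_config()].
#' @param gene_aliases Optional character vector of ids for the leading
#'   structured genes (recycled onto `MODULE_k`, `TARGET_k`, `DUAL_k`
#'   defaults).
#' @return List with `matrix` (an [expression_matrix]) and `truth` (a
#'   `ground_truth`: per-gene `role` from background/module/planted_target/
#'   dual, latent `u` and `v` per sample, and the `config` echoed).
#' @export
generate_expression <- function(config, gene_aliases = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_struct <- cfg$module_genes + cfg$planted_targets + cfg$dual_loading_genes
  n_genes <- n_struct + cfg$n_background
  if (n_genes < 1) stop("config generates no genes")
  if (n_struct > n_genes) stop("structured genes exceed total genes")
  set.seed(cfg$seed)
  n_treated <- round(cfg$n_samples * cfg$treated_fraction)
  treated <- rep(c(FALSE, TRUE), c(cfg$n_samples - n_treated, n_treated))
  u <- stats::rnorm(cfg$n_samples, 0, cfg$sigma_u) + cfg$delta * treated
  v <- stats::rnorm(cfg$n_samples, 0, cfg$sigma_u)
  roles <- c(rep("module", cfg$module_genes),
             rep("planted_target", cfg$planted_targets),
             rep("dual", cfg$dual_loading_genes),
             rep("background", cfg$n_background))
  ids <- c(sprintf("MODULE_%d", seq_len(cfg$module_genes)),
           sprintf("TARGET_%d", seq_len(cfg$planted_targets)),
           sprintf("DUAL_%d", seq_len(cfg$dual_loading_genes)),
           sprintf("BG_%04d", seq_len(cfg$n_background)))
  if (!is.null(gene_aliases)) {
    k <- min(length(gene_aliases), n_struct)
    ids[seq_len(k)] <- gene_aliases[seq_len(k)]
  }
  mu <- stats::rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  eps <- matrix(stats::rnorm(n_genes * cfg$n_samples, 0, cfg$sigma_e),
                nrow = n_genes)
  loading_u <- ifelse(roles %in% c("module", "planted_target"), cfg$lambda,
                      ifelse(roles == "dual", cfg$lambda / 2, 0))
  loading_v <- ifelse(roles == "dual", cfg$rho_secondary, 0)
  values <- mu + outer(loading_u, u) + outer(loading_v, v) + eps
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  mat <- expression_matrix(values, ids, sample_ids,
                           condition = ifelse(treated, "treated", "control"),
                           units = "normalized")
  truth <- structure(
    list(role = stats::setNames(roles, ids), u = stats::setNames(u, sample_ids),
         v = stats::setNames(v, sample_ids), config = cfg),
    class = "ground_truth")
  list(matrix = mat, truth = truth)
}

# ids mirroring the canonical ER-stress panel plus the planted/dual genes
F1_ALIASES <- c("HSPA5", "DNAJB9", "HSP90B1", "ATF4", "DNAJC3", "DDIT3",
                "RASSF1", "DDIT3alt")

#' The canonical test fixture F1
#'
#' A fixed simulation used throughout the test suite: 12 samples (6 control +
#' 6 treated), 2000 background genes, a 6-gene coordinated module aliased to
#' the familiar ER-stress panel symbols (HSPA5, DNAJB9, HSP90B1, ATF4,
#' DNAJC3, DDIT3), one planted hidden target (RASSF1), one dual-loading gene
#' (DDIT3alt), with `lambda = 1`, `sigma_u = 1`, `sigma_e = 0.5`,
#' `delta = 1`, `rho_secondary = 1`, seed 20230214. 2008 genes in total.
#'
#' @param seed Override the fixture seed (used by replicate-based checks).
#' @return As [generate_expression()].
#' @export
fixture_F1 <- function(seed = 20230214) {
  cfg <- synthetic_config(
    n_samples = 12, n_background = 2000, module_genes = 6,
    planted_targets = 1, dual_loading_genes = 1,
    lambda = 1, sigma_u = 1, sigma_e = 0.5, delta = 1,
    treated_fraction = 0.5, rho_secondary = 1, seed = seed)
  generate_expression(cfg, gene_aliases = F1_ALIASES)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression TSV and sample sheet consumed by [load_expression()],
#' plus the ground truth as a JSON sidecar.
#'
#' @param sim A list from [generate_expression()] or [fixture_F1()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"synthetic"`).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- file.path(dir, paste0(prefix, "_expression.tsv"))
  sheet <- file.path(dir, paste0(prefix, "_samples.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  write_expression(sim$matrix, expr, sample_sheet = sheet)
  jsonlite::write_json(
    list(role = as.list(sim$truth$role),
         u = as.list(sim$truth$u), v = as.list(sim$truth$v),
         config = unclass(sim$truth$config)),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(expression = expr, sample_sheet = sheet, truth = truth))
}
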