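# known config keys with defaults (NULL = required or optional-without-default)
CONFIG_DEFAULTS <- list(
  expression = NULL,        # required: expression TSV
  sample_sheet = NULL,      # optional sample sheet TSV
  gmt = NULL,               # optional gene-set collection
  promoters = NULL,         # optional promoter FASTA
  panel = NULL,             # required: character vector of panel gene ids
  query_gene = NULL,        # optional: overrides the scan's top candidate
  units = "normalized",     # "counts" applies log2(x+1) before analysis
  alpha = 0.05,
  direction = "positive",
  aggregation = "mean",
  permutations = 0,         # B = 0 disables the permutation test
  seed = 1,
  motif_consensus = "TGATGNAAN",
  max_edit = 2,
  both_strands = FALSE,
  min_overlap = 2,
  output_dir = "coordscan_out"
)

#' Validate a YAML run configuration
#'
#' Reads the YAML, rejects unknown keys (suggesting the nearest known key),
#' fills defaults, checks types, ranges and that every referenced file
#' exists. All problems are reported in a single error.
#'
#' @param path Path to the YAML config.
#' @return A fully defaulted, validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  problems <- character()
  known <- names(CONFIG_DEFAULTS)
  for (key in setdiff(names(raw), known)) {
    d <- utils::adist(key, known)
    hint <- known[which.min(d)]
    problems <- c(problems,
                  sprintf("unknown key '%s' (did you mean '%s'?)", key, hint))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw[intersect(names(raw), known)])
  if (is.null(cfg$expression)) {
    problems <- c(problems, "missing required key 'expression'")
  }
  if (is.null(cfg$panel) || !length(cfg$panel)) {
    problems <- c(problems, "missing required key 'panel'")
  } else {
    cfg$panel <- as.character(cfg$panel)
  }
  num_check <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      problems <<- c(problems,
                     sprintf("'%s' must be a number in [%s, %s]", key, lo, hi))
    }
  }
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1 ||
      cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "'alpha' must lie strictly in (0, 1)")
  }
  num_check("max_edit", 0, 100)
  num_check("min_overlap", 1, 1e6)
  num_check("seed", -2^31, 2^31)
  if (!is.numeric(cfg$permutations) ||
      (cfg$permutations != 0 && cfg$permutations < 99)) {
    problems <- c(problems, "'permutations' must be 0 (off) or >= 99")
  }
  if (!cfg$direction %in% c("positive", "both")) {
    problems <- c(problems, "'direction' must be 'positive' or 'both'")
  }
  if (!cfg$aggregation %in% c("mean", "min")) {
    problems <- c(problems, "'aggregation' must be 'mean' or 'min'")
  }
  if (!cfg$units %in% c("normalized", "counts")) {
    problems <- c(problems, "'units' must be 'normalized' or 'counts'")
  }
  for (key in c("expression", "sample_sheet", "gmt", "promoters")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("'%s' file not found: %s", key, p))
    }
  }
  if (length(problems)) {
    stop("invalid config ", path, ":\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

#' Run the end-to-end coordination pipeline
#'
#' Stages: load and prepare the expression matrix; scan all genes for
#' coordination with the panel; pick the query gene (the scan's top candidate
#' unless `query_gene` is set); select its correlated gene set at `alpha`;
#' if a GMT is configured, test that set for over-representation; if
#' promoters are configured, scan them for the consensus motif. Writes
#' `scan.tsv`, `gene_set.tsv`, `enrichment.tsv`, `motif_hits.tsv` and a
#' `report.json` capturing parameters, seed and headline results into
#' `output_dir`. Outputs are byte-identical across runs with the same inputs
#' and seed; on any stage failure the stage name is reported and partial
#' outputs are removed.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   YAML file.
#' @return The run report (named list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "expression_io"
    mat <- load_expression(config$expression,
                           sample_sheet = config$sample_sheet,
                           units = config$units)
    if (mat$units == "counts") mat <- normalize_log(mat)
    filt <- filter_invariant_genes(mat)
    mat <- filt$matrix

    stage <- "coordination_scan"
    scan <- coordination_scan(mat, config$panel)
    scan_df <- scan$candidates
    if (config$aggregation == "min") {
      ord <- order(-scan_df$min_coordination, scan_df$candidate)
      scan_df <- scan_df[ord, , drop = FALSE]
      scan_df$rank <- cumsum(!duplicated(scan_df$min_coordination))
    }
    scan_path <- file.path(out_dir, "scan.tsv")
    write_tsv(scan_df, scan_path)
    written <- c(written, scan_path)
    top_candidate <- scan_df$candidate[1]
    query_gene <- if (!is.null(config$query_gene)) config$query_gene else
      top_candidate

    perm <- NULL
    if (config$permutations >= 99) {
      stage <- "permutation_test"
      perm <- permutation_pvalue(mat, query_gene, config$panel[1],
                                 n_permutations = config$permutations,
                                 seed = config$seed)
    }

    stage <- "correlated_gene_set"
    gene_set <- correlated_gene_set(mat, query_gene, alpha = config$alpha,
                                    direction = config$direction)
    gs_path <- file.path(out_dir, "gene_set.tsv")
    write_tsv(gene_set, gs_path)
    written <- c(written, gs_path)

    enrichment <- NULL
    if (!is.null(config$gmt)) {
      stage <- "enrichment"
      collection <- read_gmt(config$gmt)
      enrichment <- enrich(gene_set$gene, mat$gene_ids, collection,
                           min_overlap = config$min_overlap)
      enr_path <- file.path(out_dir, "enrichment.tsv")
      write_tsv(enrichment, enr_path)
      written <- c(written, enr_path)
    }

    motif_hits <- NULL
    if (!is.null(config$promoters)) {
      stage <- "promoter_motif"
      promoters <- read_promoters(config$promoters)
      pattern <- motif_pattern(config$motif_consensus, config$max_edit)
      motif_hits <- do.call(rbind, lapply(promoters, scan_consensus,
                                          pattern = pattern,
                                          both_strands = config$both_strands))
      rownames(motif_hits) <- NULL
      motif_path <- file.path(out_dir, "motif_hits.tsv")
      write_tsv(motif_hits, motif_path)
      written <- c(written, motif_path)
    }

    stage <- "report"
    report <- list(
      package = "coordscan",
      version = as.character(utils::packageVersion("coordscan")),
      parameters = unclass(config),
      n_genes = length(mat$gene_ids),
      n_samples = mat$n_samples,
      panel = config$panel,
      top_candidate = top_candidate,
      query_gene = query_gene,
      top_mean_coordination = scan_df$mean_coordination[1],
      permutation = if (!is.null(perm)) list(
        p = perm$p_permutation, B = perm$n_permutations, seed = perm$seed),
      gene_set_size = nrow(gene_set),
      top_enriched_term = if (!is.null(enrichment) && nrow(enrichment))
        enrichment$term[1],
      n_motif_hits = if (!is.null(motif_hits)) nrow(motif_hits),
      outputs = basename(written))
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, report_path)
    report
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# deterministic TSV writer shared by all pipeline outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
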