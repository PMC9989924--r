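# Fixture F1 is expensive enough to build once and share across files.
.fixture_cache <- new.env(parent = emptyenv())

upr_panel <- c("HSPA5", "DNAJB9", "HSP90B1", "ATF4", "DNAJC3", "DDIT3")

get_F1 <- function() {
  if (is.null(.fixture_cache$f1)) .fixture_cache$f1 <- coordscan::fixture_F1()
  .fixture_cache$f1
}

get_F1_scan <- function() {
  if (is.null(.fixture_cache$scan)) {
    .fixture_cache$scan <- coordscan::coordination_scan(get_F1()$matrix,
                                                        upr_panel)
  }
  .fixture_cache$scan
}

# a small all-background matrix for null-distribution checks
null_matrix <- function(n_genes = 100, n_samples = 12, seed = 1) {
  cfg <- coordscan::synthetic_config(
    n_samples = n_samples, n_background = n_genes, module_genes = 0,
    planted_targets = 0, dual_loading_genes = 0, delta = 0, seed = seed)
  coordscan::generate_expression(cfg)$matrix
}

# small GMT on disk: the planted module as one term plus decoys
write_f1_gmt <- function(path) {
  mat <- get_F1()$matrix
  bg <- grep("^BG_", mat$gene_ids, value = TRUE)
  lines <- c(
    paste(c("UPR_LIKE", "planted coordinated module", upr_panel),
          collapse = "\t"),
    paste(c("DECOY_A", "random background 1", bg[1:20]), collapse = "\t"),
    paste(c("DECOY_B", "random background 2", bg[21:60]), collapse = "\t"),
    paste(c("DECOY_C", "random background 3", bg[61:80]), collapse = "\t"))
  writeLines(lines, path)
  path
}
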