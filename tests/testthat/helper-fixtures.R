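suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# shared, lazily built fixtures (the default synthetic study is used by
# several files; build it once per test run)
.fixtures <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- simulate_mzt_study(synthetic_config(seed = 42))
  }
  .fixtures$bundle
}

default_xtev <- function() {
  if (is.null(.fixtures$xtev)) {
    b <- default_bundle()
    .fixtures$xtev <- run_xtev(b$reference, b$evidence, b$junctions,
                               b$counts, b$peaks, b$rnapii)
  }
  .fixtures$xtev
}

default_llr_table <- function() {
  if (is.null(.fixtures$llr)) {
    .fixtures$llr <- build_llr_table(mzt_default_coding_table(),
                                     mzt_default_noncoding_table())
  }
  .fixtures$llr
}

default_scores <- function() {
  if (is.null(.fixtures$scores)) {
    b <- default_bundle()
    .fixtures$scores <- score_models(default_xtev()$candidates, b$genome,
                                     default_llr_table())
  }
  .fixtures$scores
}

dropout_xtev <- function() {
  if (is.null(.fixtures$dropout_xtev)) {
    b <- simulate_mzt_study(synthetic_config(seed = 42, h3k4me3_dropout = 0.2),
                            with_genome = FALSE)
    .fixtures$dropout_bundle <- b
    .fixtures$dropout_xtev <- run_xtev(b$reference, b$evidence, b$junctions,
                                       b$counts, b$peaks, b$rnapii)
  }
  .fixtures$dropout_xtev
}

dropout_bundle <- function() {
  dropout_xtev()
  .fixtures$dropout_bundle
}

planted_lnc_models <- function(bundle) {
  paste0("asm_", names(bundle$truth$classes)[
    bundle$truth$classes == "lncRNA_standalone"])
}

# quick model-set builder: exon coordinates as list of c(start, end) pairs
make_model <- function(chrom, exon_pairs, strand = "+") {
  GRanges(chrom,
          IRanges(vapply(exon_pairs, `[`, numeric(1), 1),
                  vapply(exon_pairs, `[`, numeric(1), 2)),
          strand = strand)
}

make_set <- function(..., source = "reference") {
  gene_model_set(GRangesList(...), source = source)
}

# counts table builder
make_counts <- function(df) {
  df$count <- as.integer(df$count)
  class(df) <- c("exon_counts", "data.frame")
  df
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else NULL
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}
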