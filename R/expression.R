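#' @importFrom stats kmeans cor sd
NULL

# effective gene id: models not yet grouped count as their own gene
effective_gene_ids <- function(models) {
  ifelse(is.na(models$meta$gene_id), models$meta$model_id, models$meta$gene_id)
}

# long exon table: one row per (model, exon) with identity key and length
exon_table <- function(models) {
  ex <- models$exons
  nex <- elementNROWS(ex)
  flat <- unlist(ex, use.names = FALSE)
  data.frame(
    model_id = rep(models$meta$model_id, nex),
    gene_id = rep(effective_gene_ids(models), nex),
    exon_index = unlist(lapply(nex, seq_len)),
    key = exon_keys(flat),
    len = width(flat),
    stringsAsFactors = FALSE
  )
}

#' Per-gene RPKM for one library condition
#'
#' Implements the exon-model RPKM rule used throughout the package: each
#' exon scores \code{count / (length/1000) / (total_mapped/1e6)} and a
#' gene's RPKM is the arithmetic mean over the gene's \emph{non-redundant}
#' exons, i.e. an exon shared (identical coordinates and strand) between
#' isoforms contributes once. Counts must already exclude multi-mapped
#' reads (an upstream contract of the count table).
#'
#' @param counts \code{exon_counts} table (see \code{\link{read_counts}})
#' @param models \code{GeneModelSet}; \code{gene_id} metadata (when set)
#'   defines the isoform grouping
#' @param total_mapped total mapped reads in the library (> 0)
#' @param stage,library condition to extract from \code{counts}
#' @return named numeric vector of RPKM per gene
#' @examples
#' ex <- GRangesList(m1 = GRanges("chr1", IRanges(1, 1000), strand = "+"))
#' gms <- gene_model_set(ex)
#' cts <- data.frame(model_id = "m1", exon_index = 1, stage = "oocyte",
#'                   library = "PA", count = 10L)
#' class(cts) <- c("exon_counts", "data.frame")
#' compute_gene_rpkm(cts, gms, 1e6, "oocyte", "PA")  # 10
#' @export
compute_gene_rpkm <- function(counts, models, total_mapped, stage, library) {
  if (total_mapped <= 0) stop("total_mapped must be positive")
  et <- exon_table(models)
  if (any(et$len == 0L)) stop("exon of length 0")
  sub <- counts[counts$stage == stage & counts$library == library, , drop = FALSE]
  idx <- match(paste(et$model_id, et$exon_index),
               paste(sub$model_id, sub$exon_index))
  cnt <- ifelse(is.na(idx), 0L, sub$count[idx])
  rpkm <- cnt / (et$len / 1000) / (total_mapped / 1e6)
  # non-redundant exons within a gene: identical exons collapse to one
  # value (their reads are the same reads; disagreement keeps the max)
  gk <- paste(et$gene_id, et$key, sep = "\r")
  ded <- tapply(rpkm, gk, max)
  gene_of <- sub("\r.*$", "", names(ded))
  out <- tapply(as.numeric(ded), gene_of, mean)
  res <- as.numeric(out)
  names(res) <- names(out)
  # genes present in the model set but with no exons in counts still appear
  all_genes <- unique(et$gene_id)
  res[setdiff(all_genes, names(res))] <- 0
  res[all_genes]
}

#' Build a gene x condition RPKM matrix
#'
#' @param counts \code{exon_counts} table
#' @param models \code{GeneModelSet}
#' @param totals data frame with columns \code{stage}, \code{library},
#'   \code{total_mapped} (one row per sequenced library)
#' @param stages optional explicit stage order (default: order of first
#'   appearance in \code{totals})
#' @return object of class \code{ExpressionMatrix}: list with \code{rpkm}
#'   (genes x conditions matrix, columns named \code{stage.library}),
#'   \code{conditions} (data frame), \code{stages}, and the provenance
#'   inputs (\code{counts}, \code{totals})
#' @export
expression_matrix <- function(counts, models, totals, stages = NULL) {
  if (is.null(stages)) stages <- unique(totals$stage)
  totals <- totals[order(match(totals$stage, stages), totals$library), ]
  cols <- paste(totals$stage, totals$library, sep = ".")
  mats <- lapply(seq_len(nrow(totals)), function(i) {
    compute_gene_rpkm(counts, models, totals$total_mapped[i],
                      totals$stage[i], totals$library[i])
  })
  rpkm <- do.call(cbind, mats)
  colnames(rpkm) <- cols
  structure(list(rpkm = rpkm,
                 conditions = data.frame(stage = totals$stage,
                                         library = totals$library,
                                         stringsAsFactors = FALSE),
                 stages = stages,
                 counts = counts, totals = totals),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$rpkm), "genes x", ncol(x$rpkm),
      "conditions (", paste(x$stages, collapse = ", "), ")\n")
  invisible(x)
}

em_column <- function(em, stage, library) {
  col <- paste(stage, library, sep = ".")
  if (!col %in% colnames(em$rpkm)) {
    stop("condition not present: ", stage, " / ", library)
  }
  v <- em$rpkm[, col]
  names(v) <- rownames(em$rpkm)  # single-gene matrices drop names otherwise
  v
}

#' log2 PA/RZ polyadenylation ratio at one stage
#'
#' The PA (polyA-selected) and RZ (ribo-depleted) libraries sample the
#' same transcripts with and without dependence on the poly(A) tail; their
#' log ratio is a proxy for relative polyadenylation state. A pseudocount
#' keeps the ratio finite for silent genes (and exactly 0 when both are 0).
#'
#' @param em \code{ExpressionMatrix}
#' @param stage stage id
#' @param pseudocount added to both numerator and denominator (default 0.01)
#' @return named numeric vector, one log2 ratio per gene
#' @export
log2_pa_rz <- function(em, stage, pseudocount = 0.01) {
  stopifnot(pseudocount >= 0)
  pa <- em_column(em, stage, "PA")
  rz <- em_column(em, stage, "RZ")
  # pseudocount 0 is allowed when no zeros are present; 0/0 then yields
  # NaN, which the selectors treat as "not called"
  log2((pa + pseudocount) / (rz + pseudocount))
}

#' log2 PA/RZ ratio matrix over stages
#' @param em \code{ExpressionMatrix}
#' @param stages stages to include (default all)
#' @param pseudocount see \code{\link{log2_pa_rz}}
#' @return genes x stages matrix of log2 ratios
#' @export
pa_rz_ratio_matrix <- function(em, stages = em$stages, pseudocount = 0.01) {
  m <- vapply(stages, function(s) log2_pa_rz(em, s, pseudocount),
              numeric(nrow(em$rpkm)))
  colnames(m) <- stages
  m
}

#' Select maternal transcripts
#'
#' A gene is called maternal when its oocyte expression reaches the RPKM
#' threshold in either library (polyA+ or ribo-depleted).
#'
#' @param em \code{ExpressionMatrix}
#' @param threshold RPKM floor (default 1)
#' @param oocyte_stage stage id of the oocyte condition
#' @return character vector of maternal gene ids
#' @export
select_maternal <- function(em, threshold = 1, oocyte_stage = "oocyte") {
  cols <- paste(oocyte_stage, c("PA", "RZ"), sep = ".")
  have <- cols %in% colnames(em$rpkm)
  if (!any(have)) stop("no oocyte condition in matrix")
  vals <- em$rpkm[, cols[have], drop = FALSE]
  rownames(em$rpkm)[apply(vals >= threshold, 1L, any)]
}

#' Select embryonic (zygotically induced) transcripts
#'
#' A gene is embryonic when some post-oocyte stage shows at least
#' \code{fold} times the oocyte expression, assessed on the polyA+ library
#' by default, with a pseudocount guarding zero oocyte values.
#'
#' @param em \code{ExpressionMatrix}
#' @param fold induction threshold (default 10)
#' @param pseudocount added to numerator and denominator
#' @param library library used for the fold test (default \code{"PA"})
#' @param oocyte_stage stage id of the oocyte condition
#' @return character vector of embryonic gene ids
#' @export
select_embryonic <- function(em, fold = 10, pseudocount = 0.01,
                             library = "PA", oocyte_stage = "oocyte") {
  later <- setdiff(em$stages, oocyte_stage)
  if (length(later) == 0L) stop("no post-oocyte stage in matrix")
  ooc <- em_column(em, oocyte_stage, library)
  folds <- vapply(later, function(s) {
    (em_column(em, s, library) + pseudocount) / (ooc + pseudocount)
  }, numeric(nrow(em$rpkm)))
  folds <- matrix(folds, nrow = nrow(em$rpkm))
  hit <- apply(folds >= fold, 1L, function(r) isTRUE(any(r, na.rm = TRUE)))
  rownames(em$rpkm)[hit]
}

#' Select RZ-enriched (putatively deadenylated) transcripts at a stage
#'
#' Genes whose log2 PA/RZ ratio falls at or below the threshold at the
#' given stage: their abundance in total RNA exceeds what the polyA+
#' library sees, the signature of a deadenylated transcript. By default
#' only maternally called genes are eligible, so that silent genes cannot
#' enter via pseudocount artifacts.
#'
#' @param em \code{ExpressionMatrix}
#' @param stage stage id (the oocyte, 6 and 9 stages are those of interest)
#' @param threshold log2 ratio ceiling (default -0.5)
#' @param pseudocount see \code{\link{log2_pa_rz}}
#' @param require_maternal restrict to \code{\link{select_maternal}} output
#' @param maternal_threshold RPKM floor for the maternal gate
#' @param oocyte_stage stage id of the oocyte condition
#' @return character vector of RZ-enriched gene ids at that stage
#' @export
select_rz_enriched <- function(em, stage, threshold = -0.5,
                               pseudocount = 0.01, require_maternal = TRUE,
                               maternal_threshold = 1,
                               oocyte_stage = "oocyte") {
  ratio <- log2_pa_rz(em, stage, pseudocount)
  ids <- names(ratio)[which(ratio <= threshold)]
  if (require_maternal) {
    ids <- intersect(ids, select_maternal(em, maternal_threshold, oocyte_stage))
  }
  ids
}

#' Scale expression rows to sum to one
#'
#' Each gene's profile is divided by its row sum (the transform used for
#' profile-shape clustering). All-zero rows are returned as zeros and
#' flagged in the \code{"flagged_zero"} attribute rather than dropped.
#'
#' @param mat numeric matrix (genes x stages), non-negative
#' @return matrix of the same shape whose non-flagged rows sum to 1
#' @export
scale_rows <- function(mat) {
  mat <- as.matrix(mat)
  rs <- rowSums(mat)
  zero <- rs == 0
  out <- mat
  out[!zero, ] <- mat[!zero, , drop = FALSE] / rs[!zero]
  attr(out, "flagged_zero") <- zero
  out
}

#' K-means clustering of expression profiles
#'
#' @param mat numeric matrix of per-gene profiles (e.g. RPKM over stages)
#' @param k number of clusters (>= 1, <= number of genes)
#' @param seed RNG seed; fixed seed gives identical labels
#' @param transform \code{"log"} (log2(x + pseudocount)), \code{"scaled"}
#'   (rows scaled to sum 1) or \code{"none"}
#' @param pseudocount used by the log transform
#' @param nstart random restarts passed to \code{\link[stats]{kmeans}}
#' @return list of class \code{ClusterResult}: \code{labels} (named integer
#'   vector in 1..k), \code{k}, \code{seed}, \code{transform},
#'   \code{centers}
#' @export
cluster_kmeans <- function(mat, k, seed, transform = c("log", "scaled", "none"),
                           pseudocount = 0.01, nstart = 10L) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  if (k < 1L || k > nrow(mat)) stop("k must be in 1..number of genes")
  x <- switch(transform,
              log = log2(mat + pseudocount),
              scaled = scale_rows(mat),
              none = mat)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
  labels <- fit$cluster
  names(labels) <- rownames(mat)
  structure(list(labels = labels, k = k, seed = seed,
                 transform = transform, centers = fit$centers),
            class = "ClusterResult")
}

#' Condition-by-condition correlation matrix
#'
#' @param em \code{ExpressionMatrix} or plain genes x conditions matrix
#' @param method \code{"pearson"} or \code{"spearman"}
#' @return symmetric correlation matrix; conditions with zero variance get
#'   \code{NA} against everything (including themselves)
#' @export
correlation_matrix <- function(em, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- if (is(em, "ExpressionMatrix")) em$rpkm else as.matrix(em)
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  suppressWarnings(cc <- cor(mat, method = method))
  ok <- apply(mat, 2L, sd) > 0
  diag(cc)[ok] <- 1
  cc
}

#' Cumulative induction timing of embryonic genes
#'
#' For each post-oocyte stage, the fraction of embryonic genes whose
#' earliest stage reaching \code{fold}-times oocyte expression is at or
#' before that stage. Genes never reaching the fold contribute to no
#' stage, so the final cumulative value can be below 1.
#'
#' @param em \code{ExpressionMatrix}
#' @param embryonic_ids genes to profile (subset of the matrix)
#' @param fold induction fold (default 4)
#' @param pseudocount ratio pseudocount
#' @param library library profiled (default \code{"PA"})
#' @param oocyte_stage stage id of the oocyte condition
#' @return named numeric vector of cumulative fractions per later stage
#' @export
induction_timing <- function(em, embryonic_ids, fold = 4, pseudocount = 0.01,
                             library = "PA", oocyte_stage = "oocyte") {
  if (length(embryonic_ids) == 0L) stop("empty embryonic set")
  stopifnot(all(embryonic_ids %in% rownames(em$rpkm)))
  later <- setdiff(em$stages, oocyte_stage)
  ooc <- em_column(em, oocyte_stage, library)[embryonic_ids]
  ratio <- vapply(later, function(s) {
    (em_column(em, s, library)[embryonic_ids] + pseudocount) / (ooc + pseudocount)
  }, numeric(length(embryonic_ids)))
  ratio <- matrix(ratio, nrow = length(embryonic_ids),
                  dimnames = list(embryonic_ids, later))
  first <- apply(ratio >= fold, 1L, function(r) {
    w <- which(r)  # NAs (0/0 under pseudocount 0) never count as reached
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  cum <- vapply(seq_along(later), function(i) {
    mean(!is.na(first) & first <= i)
  }, numeric(1))
  names(cum) <- later
  cum
}

#' Fraction of genes peaking per stage
#'
#' Assigns each gene to the stage of its expression maximum (ties broken
#' by the earliest stage) and returns the per-stage fractions, which sum
#' to 1.
#'
#' @param em \code{ExpressionMatrix}
#' @param ids genes to profile
#' @param library library profiled (default \code{"PA"})
#' @return named numeric vector over all stages, summing to 1
#' @export
peak_stage_fractions <- function(em, ids, library = "PA") {
  if (length(ids) == 0L) stop("empty gene set")
  prof <- vapply(em$stages, function(s) em_column(em, s, library)[ids],
                 numeric(length(ids)))
  prof <- matrix(prof, nrow = length(ids),
                 dimnames = list(ids, em$stages))
  peak <- apply(prof, 1L, which.max)  # which.max takes the earliest tie
  frac <- tabulate(peak, nbins = length(em$stages)) / length(ids)
  names(frac) <- em$stages
  frac
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per gene and stage: dCt = Ct_gene - Ct_normalizer; ddCt relative to the
#' reference stage; fold change = 2^-ddCt.
#'
#' @param table a \code{\link{qpcr_table}}
#' @return data frame with columns \code{gene}, \code{stage}, \code{ddct},
#'   \code{fold}
#' @export
ddct_fold_change <- function(table) {
  stopifnot(is(table, "qpcr_table"))
  df <- table$data
  norm <- df[df$gene == table$normalizer, ]
  norm_ct <- norm$ct[match(df$stage, norm$stage)]
  if (any(is.na(norm_ct))) stop("missing normalizer Ct for some stage")
  dct <- df$ct - norm_ct
  genes <- df[df$gene != table$normalizer, ]
  dct <- dct[df$gene != table$normalizer]
  ref_key <- paste(genes$gene, table$reference_stage)
  ref_dct <- dct[match(ref_key, paste(genes$gene, genes$stage))]
  if (any(is.na(ref_dct))) stop("missing reference-stage Ct for some gene")
  ddct <- dct - ref_dct
  data.frame(gene = genes$gene, stage = genes$stage,
             ddct = ddct, fold = 2^(-ddct),
             stringsAsFactors = FALSE)
}
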