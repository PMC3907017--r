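#' Configuration for the gene-model validation pipeline
#'
#' @param min_junction_reads minimum spliced-read support for a junction
#'   to be trusted (default 5)
#' @param expressed_min_reads per-exon read floor for the expression test
#'   (default 3)
#' @param expressed_fraction fraction of a model's exons that must reach
#'   the read floor for the model to count as expressed (default 1/3,
#'   compared as an exact rational)
#' @param rnapii_body_ratio minimum ratio of upstream-region RNAPII to
#'   gene-body RNAPII for upstream TSS rescue (default 0.5)
#' @param max_upstream_search how far upstream of a gene's 5' exon to look
#'   for a rescue peak, in bp (default 50000)
#' @param max_peak_gap unused reserve for overlap slop (default 0: overlap
#'   means >= 1 shared bp)
#' @param ngm_same_strand restrict the new-gene-model overlap test to the
#'   same strand (default \code{FALSE}: strand-blind, the conservative
#'   reading for calling novelty)
#' @param require_both_evidence for NGM-vv, require RNA-seq expression AND
#'   EST support rather than either (default \code{FALSE})
#' @return list of class \code{xtev_config}
#' @export
xtev_config <- function(min_junction_reads = 5L, expressed_min_reads = 3L,
                        expressed_fraction = 1/3, rnapii_body_ratio = 0.5,
                        max_upstream_search = 50000L, max_peak_gap = 0L,
                        ngm_same_strand = FALSE, require_both_evidence = FALSE) {
  stopifnot(min_junction_reads > 0, expressed_min_reads > 0,
            expressed_fraction > 0, expressed_fraction <= 1,
            rnapii_body_ratio > 0)
  structure(list(min_junction_reads = min_junction_reads,
                 expressed_min_reads = expressed_min_reads,
                 expressed_fraction = expressed_fraction,
                 rnapii_body_ratio = rnapii_body_ratio,
                 max_upstream_search = max_upstream_search,
                 max_peak_gap = max_peak_gap,
                 ngm_same_strand = ngm_same_strand,
                 require_both_evidence = require_both_evidence),
            class = "xtev_config")
}

#' Filter splice junctions by read support
#' @param junctions \code{GRanges} with \code{read_support}
#' @param min_reads keep junctions with support >= this (default 5)
#' @return filtered \code{GRanges}
#' @export
filter_junctions <- function(junctions, min_reads = 5L) {
  junctions[junctions$read_support >= min_reads]
}

#' Group gene models by shared exons
#'
#' Models sharing at least one exon -- exact chromosome, strand, start and
#' end identity -- are considered multiple models of a single gene; the
#' grouping is the connected components of that relation (so A-B and B-C
#' sharing different exons still form one gene). Each gene is named after
#' the lexicographically smallest member model id.
#'
#' @param models \code{GeneModelSet}
#' @return named character vector: gene id per model id
#' @export
group_gene_models <- function(models) {
  n <- n_models(models)
  ids <- model_ids(models)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  et <- exon_table(models)
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  midx <- match(et$model_id, ids)
  for (grp in split(midx, et$key)) {
    grp <- unique(grp)
    if (length(grp) > 1L) {
      r <- find(grp[1L])
      for (m in grp[-1L]) {
        r2 <- find(m)
        if (r2 != r) { parent[max(r, r2)] <- min(r, r2); r <- min(r, r2) }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gene_of_root <- tapply(ids, roots, function(v) sort(v)[1L])
  out <- as.character(gene_of_root[as.character(roots)])
  names(out) <- ids
  out
}

#' Assign grouped gene ids to a GeneModelSet
#' @param models \code{GeneModelSet}
#' @return the set with \code{meta$gene_id} filled by
#'   \code{\link{group_gene_models}}
#' @export
assign_gene_ids <- function(models) {
  g <- group_gene_models(models)
  models$meta$gene_id <- unname(g[models$meta$model_id])
  models
}

#' Update gene models with evidence transcripts
#'
#' Evidence transcripts (EST clusters, assembled transcripts) on the same
#' strand that share at least one exact splice junction with a model
#' contribute their exons to it, typically extending the 5' and 3' ends.
#' Original exons are never removed; overlapping contributions are merged.
#' Only junctions present in \code{junctions} (the trusted, filtered set)
#' establish linkage; pass \code{NULL} to trust all evidence junctions.
#'
#' @param models \code{GeneModelSet} to update
#' @param evidence \code{GeneModelSet} of evidence transcripts
#' @param junctions filtered junction \code{GRanges}, or \code{NULL}
#' @return the updated \code{GeneModelSet}; changed models get source
#'   \code{"updated"} and the attribute \code{"updates"} records each
#'   added region with its placement (\code{five_prime}, \code{internal},
#'   \code{three_prime})
#' @export
update_models_with_evidence <- function(models, evidence, junctions = NULL) {
  trusted <- if (is.null(junctions)) NULL else junction_keys(junctions)
  ev_introns <- lapply(evidence$exons, introns_of)
  ev_keys <- lapply(ev_introns, function(gr) {
    k <- junction_keys(gr)
    if (is.null(trusted)) k else intersect(k, trusted)
  })
  ev_strand <- vapply(evidence$exons, function(gr) as.character(strand(gr))[1L],
                      character(1))
  updates <- list()
  new_exons <- as.list(models$exons)
  changed <- logical(n_models(models))
  for (i in seq_len(n_models(models))) {
    gr <- models$exons[[i]]
    mk <- junction_keys(introns_of(gr))
    if (length(mk) == 0L) next
    st <- as.character(strand(gr))[1L]
    linked <- which(ev_strand == st &
                      vapply(ev_keys, function(k) length(intersect(k, mk)) > 0L,
                             logical(1)))
    if (length(linked) == 0L) next
    contrib <- unlist(GRangesList(as.list(evidence$exons[linked])), use.names = FALSE)
    merged <- reduce(c(gr, contrib))
    added <- GenomicRanges::setdiff(merged, reduce(gr))
    if (length(added) > 0L) {
      span0 <- model_span(gr)
      minus <- st == "-"
      place <- ifelse(end(added) < start(span0),
                      if (minus) "three_prime" else "five_prime",
                      ifelse(start(added) > end(span0),
                             if (minus) "five_prime" else "three_prime",
                             "internal"))
      updates[[length(updates) + 1L]] <- data.frame(
        model_id = models$meta$model_id[i],
        chrom = as.character(seqnames(added)),
        start = start(added), end = end(added),
        placement = place, stringsAsFactors = FALSE)
      strand(merged) <- st
      new_exons[[i]] <- merged
      changed[i] <- TRUE
    }
  }
  out <- models
  out$exons <- GRangesList(new_exons, compress = TRUE)
  names(out$exons) <- models$meta$model_id
  out$meta$source[changed] <- "updated"
  out$meta$spliced <- elementNROWS(out$exons) >= 2L
  attr(out, "updates") <- if (length(updates)) do.call(rbind, updates) else NULL
  validate_gene_models(out)
  out
}

#' Expression test for a gene model
#'
#' A model counts as expressed when at least the configured fraction of
#' its exons (default one third, compared exactly) carry at least
#' \code{min_reads} pooled RNA-seq reads (default 3).
#'
#' @param exon_counts numeric vector of pooled read counts, one per exon
#' @param min_reads per-exon read floor
#' @param fraction required fraction of qualifying exons
#' @return logical
#' @examples
#' is_expressed(c(3, 0, 0))     # TRUE  (1/3 of exons)
#' is_expressed(c(3, 0, 0, 0))  # FALSE (1/4 < 1/3)
#' @export
is_expressed <- function(exon_counts, min_reads = 3L, fraction = 1/3) {
  n <- length(exon_counts)
  if (n == 0L) stop("model with zero exons")
  sum(exon_counts >= min_reads) >= fraction * n
}

#' Validate a model's TSS against H3K4me3 peaks
#'
#' The transcription start site counts as validated (status V) when the
#' strand-aware first exon overlaps a peak by at least one base.
#'
#' @param exons sorted exon \code{GRanges} of one model
#' @param peaks peak \code{GRanges}
#' @return logical: \code{TRUE} for status V
#' @export
validate_tss <- function(exons, peaks) {
  st <- as.character(strand(exons))[1L]
  if (st == "*") stop("TSS validation needs a stranded model")
  fe <- first_exon(exons)
  length(peaks) > 0L && countOverlaps(fe, peaks, ignore.strand = TRUE) > 0L
}

#' Attempt upstream TSS rescue for a gene
#'
#' For a gene none of whose models has a validated TSS, looks for an
#' H3K4me3 peak upstream of the gene's 5' exon (strand-aware, within
#' \code{max_upstream_search}) such that (a) no model of a different gene
#' lies between the peak and the 5' exon and (b) the mean RNAPII signal
#' over that intervening region is at least \code{rnapii_body_ratio}
#' times the mean over the gene body (5'-most exon start to 3'-most exon
#' end, introns included). Peaks are tried nearest first.
#'
#' @param gene_exons \code{GRanges}: the union of the gene's models' exons
#'   (same chrom/strand)
#' @param peaks peak \code{GRanges}
#' @param rnapii RNAPII \code{SignalTrack} (see \code{\link{read_signal}})
#' @param other_spans \code{GRanges} of the spans of models belonging to
#'   other genes (rescue blockers)
#' @param config an \code{\link{xtev_config}}
#' @return \code{NULL} when no rescue, else a list with \code{peak}
#'   (\code{GRanges}) and \code{tss} (putative TSS position at the peak)
#' @export
rescue_upstream_tss <- function(gene_exons, peaks, rnapii, other_spans,
                                config = xtev_config()) {
  if (length(peaks) == 0L) return(NULL)
  chr <- as.character(seqnames(gene_exons))[1L]
  st <- as.character(strand(gene_exons))[1L]
  if (st == "*") stop("rescue needs a stranded gene")
  gstart <- min(start(gene_exons)); gend <- max(end(gene_exons))
  body <- GRanges(chr, IRanges(gstart, gend))
  pk <- peaks[as.character(seqnames(peaks)) == chr]
  if (st == "+") {
    cand <- pk[end(pk) < gstart & end(pk) >= gstart - config$max_upstream_search]
    cand <- cand[order(end(cand), decreasing = TRUE)]
  } else {
    cand <- pk[start(pk) > gend & start(pk) <= gend + config$max_upstream_search]
    cand <- cand[order(start(cand))]
  }
  for (i in seq_along(cand)) {
    p <- cand[i]
    region <- if (st == "+") {
      IRanges(end(p) + 1L, gstart - 1L)
    } else {
      IRanges(gend + 1L, start(p) - 1L)
    }
    if (width(region) >= 1L) {
      rg <- GRanges(chr, region)
      if (length(other_spans) &&
          any(countOverlaps(rg, other_spans, ignore.strand = TRUE) > 0L)) next
      body_mean <- signal_mean(rnapii, body)
      region_mean <- signal_mean(rnapii, rg)
      if (region_mean < config$rnapii_body_ratio * body_mean) next
    }
    tss <- if (st == "+") end(p) else start(p)
    return(list(peak = p, tss = tss))
  }
  NULL
}

#' Flag a putative alternative downstream TSS
#'
#' \code{TRUE} when a peak overlaps the model's span strictly downstream
#' of its first exon (peaks beyond the 3' end of the model do not count).
#'
#' @param exons sorted exon \code{GRanges} of one model
#' @param peaks peak \code{GRanges}
#' @return logical
#' @export
flag_downstream_alt_tss <- function(exons, peaks) {
  st <- as.character(strand(exons))[1L]
  if (st == "*") stop("needs a stranded model")
  if (length(peaks) == 0L) return(FALSE)
  fe <- first_exon(exons)
  sp <- model_span(exons)
  if (st == "+") {
    if (end(fe) >= end(sp)) return(FALSE)
    region <- GRanges(seqnames(sp), IRanges(end(fe) + 1L, end(sp)))
  } else {
    if (start(fe) <= start(sp)) return(FALSE)
    region <- GRanges(seqnames(sp), IRanges(start(sp), start(fe) - 1L))
  }
  any(countOverlaps(region, peaks, ignore.strand = TRUE) > 0L)
}

#' Choose the representative model of a gene
#'
#' Lexicographic comparison, in decreasing importance: validated TSS
#' (V or U), number of expressed exons, number of exons; ties broken by
#' the longest genomic span, then the smallest model id.
#'
#' @param candidates data frame with columns \code{model_id},
#'   \code{tss_ok} (logical), \code{n_expressed_exons}, \code{n_exons},
#'   \code{span_width}
#' @return the winning \code{model_id}
#' @export
select_representative <- function(candidates) {
  if (nrow(candidates) == 0L) stop("empty gene")
  o <- order(-as.integer(candidates$tss_ok),
             -candidates$n_expressed_exons,
             -candidates$n_exons,
             -candidates$span_width,
             candidates$model_id)
  candidates$model_id[o[1L]]
}

#' Identify new gene models among candidates
#'
#' Spliced candidate transcripts whose exons overlap no reference-model
#' exon (by >= 1 bp, strand-blind by default) are new gene models (NGM);
#' unspliced single-exon candidates are routed to the excluded list.
#'
#' @param candidates \code{GeneModelSet} of candidate transcripts
#' @param reference \code{GeneModelSet} of known models
#' @param config an \code{\link{xtev_config}}
#' @return list with character vectors \code{ngm} and
#'   \code{single_exon_excluded}
#' @export
identify_ngm <- function(candidates, reference, config = xtev_config()) {
  spliced <- candidates$meta$spliced
  excluded <- candidates$meta$model_id[!spliced]
  keep <- candidates$meta$model_id[spliced]
  if (length(keep) == 0L || n_models(reference) == 0L) {
    return(list(ngm = keep, single_exon_excluded = excluded))
  }
  ref_ex <- unlist(reference$exons, use.names = FALSE)
  ngm <- character(0)
  for (id in keep) {
    ov <- countOverlaps(candidates$exons[[id]], ref_ex,
                        ignore.strand = !config$ngm_same_strand)
    if (all(ov == 0L)) ngm <- c(ngm, id)
  }
  list(ngm = ngm, single_exon_excluded = excluded)
}

#' Promote NGM to validated-and-expressed status (NGM-vv)
#'
#' An NGM becomes NGM-vv when it is supported by expression evidence
#' (RNA-seq expression or EST support; both required under
#' \code{require_both_evidence}) and carries a validated TSS (first-exon
#' H3K4me3 peak).
#'
#' @param ngm_ids character vector of NGM model ids
#' @param expressed named logical vector (RNA-seq expression per model)
#' @param est_support named logical vector (EST evidence per model)
#' @param tss_v named logical vector (status V per model)
#' @param config an \code{\link{xtev_config}}
#' @return character vector of NGM-vv model ids
#' @export
classify_ngm_vv <- function(ngm_ids, expressed, est_support, tss_v,
                            config = xtev_config()) {
  if (length(ngm_ids) == 0L) return(character(0))
  expr_ok <- if (config$require_both_evidence) {
    expressed[ngm_ids] & est_support[ngm_ids]
  } else {
    expressed[ngm_ids] | est_support[ngm_ids]
  }
  ngm_ids[expr_ok & tss_v[ngm_ids]]
}

# pooled (all stages, both libraries) read count per unique exon key,
# resolved from per-model count rows; identical exons share one value
pooled_exon_counts <- function(counts, models) {
  et <- exon_table(models)
  key_mi <- paste(counts$model_id, counts$exon_index)
  pooled_mi <- tapply(counts$count, key_mi, sum)
  idx <- match(paste(et$model_id, et$exon_index), names(pooled_mi))
  cnt <- ifelse(is.na(idx), 0L, as.integer(pooled_mi[idx]))
  out <- tapply(cnt, et$key, max)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

model_pooled_counts <- function(models, pooled_by_key) {
  lapply(seq_len(n_models(models)), function(i) {
    k <- exon_keys(models$exons[[i]])
    v <- pooled_by_key[k]
    v[is.na(v)] <- 0
    unname(v)
  })
}

#' Run the full gene-model validation pipeline
#'
#' Executes, in order: (1) collection of reference models and adoption of
#' evidence transcripts that share an exact exon with a reference model
#' as additional isoforms; (2) evidence-based model updating through
#' trusted splice junctions and shared-exon gene grouping; (3) expression
#' validation from pooled RNA-seq exon counts; (4) TSS validation against
#' H3K4me3 peaks with upstream RNAPII-supported rescue and downstream
#' alternative-TSS flagging; (5) representative-model selection per gene,
#' plus discovery of new gene models (NGM) among non-adopted evidence
#' transcripts and their promotion to NGM-vv.
#'
#' @param reference \code{GeneModelSet} of known gene models
#' @param evidence \code{GeneModelSet} of evidence transcripts (EST
#'   clusters and assembled transcripts)
#' @param junctions junction \code{GRanges} with \code{read_support}
#' @param counts \code{exon_counts} table covering reference and evidence
#'   models
#' @param peaks H3K4me3 peak \code{GRanges}
#' @param rnapii RNAPII \code{SignalTrack}
#' @param config an \code{\link{xtev_config}}
#' @return object of class \code{XtevResult}: list with \code{collection}
#'   (the grouped, updated annotation \code{GeneModelSet}),
#'   \code{candidates} (non-adopted evidence models), \code{meta} (one
#'   row per input model: gene id, statuses, flags), \code{ngm},
#'   \code{ngm_vv}, \code{single_exon_excluded}, \code{rescued_tss}
#'   (named vector of putative rescued TSS positions per gene) and
#'   \code{log} (machine-readable status transitions)
#' @export
run_xtev <- function(reference, evidence, junctions, counts, peaks, rnapii,
                     config = xtev_config()) {
  log_rows <- list()
  note <- function(model_id, status, rule) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      model_id = model_id, status = status, rule = rule,
      stringsAsFactors = FALSE)
  }

  # step 1: collect models; adopt exact-exon-sharing evidence as isoforms
  ref_keys <- unique(unlist(lapply(reference$exons, exon_keys)))
  shares_ref <- vapply(evidence$exons, function(gr) {
    any(exon_keys(gr) %in% ref_keys)
  }, logical(1))
  adopted <- subset_models(evidence, model_ids(evidence)[shares_ref])
  candidates <- subset_models(evidence, model_ids(evidence)[!shares_ref])
  collection <- combine_models(reference, adopted)
  for (id in model_ids(adopted)) note(id, "ADOPTED", "shares_exact_exon_with_reference")

  # step 2: update with junction-linked evidence, then group into genes
  jf <- filter_junctions(junctions, config$min_junction_reads)
  collection <- update_models_with_evidence(collection, candidates, jf)
  upd <- attr(collection, "updates")
  if (!is.null(upd)) {
    for (id in unique(upd$model_id)) note(id, "UPDATED", "shared_trusted_junction")
  }
  collection <- assign_gene_ids(collection)

  # step 3: expression validation (pooled over stages and libraries);
  # counts are keyed to the input models' exon indices, so the pooled
  # per-exon values are resolved against reference + evidence as supplied
  # and then looked up by exact exon coordinates for the updated models
  pooled <- pooled_exon_counts(counts, combine_models(reference, evidence))
  coll_counts <- model_pooled_counts(collection, pooled)
  cand_counts <- model_pooled_counts(candidates, pooled)
  n_expr <- function(v) sum(v >= config$expressed_min_reads)
  coll_expressed <- vapply(coll_counts, function(v) {
    is_expressed(v, config$expressed_min_reads, config$expressed_fraction)
  }, logical(1))
  cand_expressed <- vapply(cand_counts, function(v) {
    is_expressed(v, config$expressed_min_reads, config$expressed_fraction)
  }, logical(1))
  for (id in model_ids(collection)[coll_expressed]) {
    note(id, "EXPRESSED", "exon_fraction_read_floor")
  }

  # step 4: TSS validation, rescue, downstream flag
  coll_v <- vapply(collection$exons, validate_tss, logical(1), peaks = peaks)
  genes <- collection$meta$gene_id
  spans <- unlist(GRangesList(lapply(collection$exons, model_span)),
                  use.names = FALSE)
  tss_status <- ifelse(coll_v, "V", "X")
  rescued_tss <- numeric(0)
  for (g in unique(genes)) {
    member <- which(genes == g)
    if (any(coll_v[member])) next
    gex <- reduce(unlist(collection$exons[member], use.names = FALSE))
    strand(gex) <- as.character(strand(collection$exons[[member[1L]]]))[1L]
    other <- spans[genes != g]
    res <- rescue_upstream_tss(gex, peaks, rnapii, other, config)
    if (!is.null(res)) {
      tss_status[member] <- "U"
      rescued_tss[g] <- res$tss
      for (id in collection$meta$model_id[member]) {
        note(id, "TSS_UPSTREAM_RESCUED", "upstream_peak_rnapii_ratio")
      }
    }
  }
  for (id in model_ids(collection)[tss_status == "V"]) {
    note(id, "TSS_VALIDATED", "first_exon_peak_overlap")
  }
  downstream <- vapply(collection$exons, flag_downstream_alt_tss, logical(1),
                       peaks = peaks)

  # step 5: representative per gene
  n_exons <- elementNROWS(collection$exons)
  n_expressed_exons <- vapply(coll_counts, n_expr, numeric(1))
  span_width <- width(spans)
  selected <- logical(n_models(collection))
  for (g in unique(genes)) {
    member <- which(genes == g)
    win <- select_representative(data.frame(
      model_id = collection$meta$model_id[member],
      tss_ok = tss_status[member] %in% c("V", "U"),
      n_expressed_exons = n_expressed_exons[member],
      n_exons = n_exons[member],
      span_width = span_width[member],
      stringsAsFactors = FALSE))
    selected[collection$meta$model_id == win] <- TRUE
    note(win, "SELECTED", "tss_expressed_exons_exons_span_id")
  }

  # NGM discovery among non-adopted evidence transcripts
  ngm_res <- identify_ngm(candidates, reference, config)
  for (id in ngm_res$single_exon_excluded) note(id, "SINGLE_EXON_EXCLUDED", "unspliced")
  for (id in ngm_res$ngm) note(id, "NGM", "no_exonic_overlap_with_reference")
  cand_v <- if (n_models(candidates)) {
    vapply(candidates$exons, validate_tss, logical(1), peaks = peaks)
  } else logical(0)
  names(cand_v) <- model_ids(candidates)
  names(cand_expressed) <- model_ids(candidates)
  est_keys <- unique(unlist(lapply(
    candidates$exons[candidates$meta$source == "est"], exon_keys)))
  est_support <- vapply(seq_len(n_models(candidates)), function(i) {
    candidates$meta$source[i] == "est" ||
      any(exon_keys(candidates$exons[[i]]) %in% est_keys)
  }, logical(1))
  names(est_support) <- model_ids(candidates)
  ngm_vv <- classify_ngm_vv(ngm_res$ngm, cand_expressed, est_support, cand_v,
                            config)
  for (id in ngm_vv) note(id, "NGM_VV", "expression_or_est_and_tss_v")

  cand_gene <- group_gene_models(candidates)
  meta <- rbind(
    data.frame(model_id = model_ids(collection),
               gene_id = genes,
               role = ifelse(model_ids(collection) %in% model_ids(reference),
                             "reference", "adopted"),
               source = collection$meta$source,
               n_exons = as.integer(n_exons),
               n_expressed_exons = as.integer(n_expressed_exons),
               expressed = coll_expressed,
               tss_status = tss_status,
               downstream_alt_tss = downstream,
               selected = selected,
               ngm = FALSE, ngm_vv = FALSE,
               single_exon_excluded = FALSE,
               stringsAsFactors = FALSE),
    data.frame(model_id = model_ids(candidates),
               gene_id = unname(cand_gene[model_ids(candidates)]),
               role = "candidate",
               source = candidates$meta$source,
               n_exons = as.integer(elementNROWS(candidates$exons)),
               n_expressed_exons = vapply(cand_counts, n_expr, integer(1)),
               expressed = unname(cand_expressed),
               tss_status = ifelse(cand_v, "V", "X"),
               downstream_alt_tss = vapply(candidates$exons,
                                           flag_downstream_alt_tss, logical(1),
                                           peaks = peaks),
               selected = FALSE,
               ngm = model_ids(candidates) %in% ngm_res$ngm,
               ngm_vv = model_ids(candidates) %in% ngm_vv,
               single_exon_excluded =
                 model_ids(candidates) %in% ngm_res$single_exon_excluded,
               stringsAsFactors = FALSE)
  )
  rownames(meta) <- NULL
  # gene-level TSS verdict, used downstream by lncRNA curation
  gene_tss <- tapply(meta$tss_status[meta$role != "candidate"],
                     meta$gene_id[meta$role != "candidate"], function(v) {
                       if (any(v == "V")) "V" else if (any(v == "U")) "U" else "X"
                     })
  structure(list(collection = collection,
                 candidates = candidates,
                 meta = meta,
                 gene_tss = gene_tss,
                 ngm = ngm_res$ngm,
                 ngm_vv = ngm_vv,
                 single_exon_excluded = ngm_res$single_exon_excluded,
                 rescued_tss = rescued_tss,
                 config = config,
                 log = do.call(rbind, log_rows)),
            class = "XtevResult")
}

#' @export
print.XtevResult <- function(x, ...) {
  cat("XtevResult:", n_models(x$collection), "annotation models in",
      length(unique(x$meta$gene_id[x$meta$role != "candidate"])), "genes;",
      length(x$ngm), "NGM,", length(x$ngm_vv), "NGM-vv,",
      length(x$single_exon_excluded), "single-exon excluded\n")
  invisible(x)
}
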