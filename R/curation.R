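#' Configuration for lncRNA candidate curation
#'
#' @param max_orf_aa maximal allowed ORF length in amino acids (default 100)
#' @param min_exon_rpkm per-exon RPKM floor; every exon of a candidate must
#'   reach it (default 1)
#' @param require_splicing_evidence require at least one exactly matching
#'   supported splice junction (default \code{TRUE})
#' @param max_downstream_distance how far 3' of a candidate to look for a
#'   promoter-less downstream gene, in bp (default 10000)
#' @param exclusion_list model ids removed by external homology/manual
#'   screening (a stand-in hook for BLAST-based curation)
#' @return list of class \code{curation_config}
#' @export
curation_config <- function(max_orf_aa = 100L, min_exon_rpkm = 1,
                            require_splicing_evidence = TRUE,
                            max_downstream_distance = 10000L,
                            exclusion_list = character(0)) {
  stopifnot(max_orf_aa > 0, min_exon_rpkm > 0, max_downstream_distance > 0)
  structure(list(max_orf_aa = max_orf_aa, min_exon_rpkm = min_exon_rpkm,
                 require_splicing_evidence = require_splicing_evidence,
                 max_downstream_distance = max_downstream_distance,
                 exclusion_list = exclusion_list),
            class = "curation_config")
}

#' ORF-length filter
#' @param candidate_ids character vector of candidate model ids
#' @param scores \code{\link{score_models}} output covering all candidates
#' @param max_aa keep candidates with maximal ORF <= this many amino acids
#' @return surviving candidate ids
#' @export
filter_orf <- function(candidate_ids, scores, max_aa = 100L) {
  idx <- match(candidate_ids, scores$model_id)
  if (anyNA(idx)) {
    stop("missing coding-potential score for: ",
         paste(candidate_ids[is.na(idx)], collapse = ", "))
  }
  candidate_ids[scores$max_orf_aa[idx] <= max_aa]
}

#' Downstream promoter-less gene filter
#'
#' Removes a candidate when the nearest downstream gene on the same strand
#' (within \code{max_distance} of the candidate's 3' end) has no validated
#' TSS of its own (gene-level status X or U): such a candidate is
#' plausibly that gene's stray 5'-UTR fragment rather than an independent
#' transcription unit.
#'
#' @param candidate_ids candidate model ids
#' @param candidates \code{GeneModelSet} containing the candidates
#' @param xtev an \code{\link{run_xtev}} result (supplies the annotation
#'   models and their gene-level TSS statuses)
#' @param max_distance search range from the candidate 3' end, bp
#' @return surviving candidate ids
#' @export
filter_downstream_gene <- function(candidate_ids, candidates, xtev,
                                   max_distance = 10000L) {
  ann <- xtev$meta[xtev$meta$role != "candidate", , drop = FALSE]
  if (nrow(ann) == 0L) return(candidate_ids)
  spans <- unlist(GRangesList(lapply(
    xtev$collection$exons[ann$model_id], model_span)), use.names = FALSE)
  keep <- vapply(candidate_ids, function(id) {
    ex <- candidates$exons[[id]]
    st <- as.character(strand(ex))[1L]
    chr <- as.character(seqnames(ex))[1L]
    same <- which(as.character(strand(spans)) == st &
                    as.character(seqnames(spans)) == chr)
    if (length(same) == 0L) return(TRUE)
    if (st == "+") {
      e3 <- max(end(ex))
      ds <- same[start(spans)[same] > e3 &
                   start(spans)[same] <= e3 + max_distance]
      if (length(ds) == 0L) return(TRUE)
      nearest <- ds[which.min(start(spans)[ds])]
    } else {
      e3 <- min(start(ex))
      ds <- same[end(spans)[same] < e3 &
                   end(spans)[same] >= e3 - max_distance]
      if (length(ds) == 0L) return(TRUE)
      nearest <- ds[which.max(end(spans)[ds])]
    }
    g <- ann$gene_id[nearest]
    !(xtev$gene_tss[[g]] %in% c("X", "U"))
  }, logical(1))
  candidate_ids[keep]
}

#' Per-exon expression filter
#'
#' Keeps a candidate only when every one of its exons reaches the RPKM
#' floor. Exon RPKM is the pooled maximum over stages and libraries: a
#' transcript strongly expressed at one stage should not fail a
#' stage-averaged floor.
#'
#' @param candidate_ids candidate model ids
#' @param exon_rpkm data frame with columns \code{model_id},
#'   \code{exon_index}, \code{rpkm} (see \code{\link{exon_rpkm_pooled}})
#' @param min RPKM floor (default 1)
#' @return surviving candidate ids
#' @export
filter_exon_rpkm <- function(candidate_ids, exon_rpkm, min = 1) {
  vapply(candidate_ids, function(id) {
    v <- exon_rpkm$rpkm[exon_rpkm$model_id == id]
    if (length(v) == 0L) stop("no exon RPKM for candidate ", id)
    all(v >= min)
  }, logical(1)) -> ok
  candidate_ids[ok]
}

#' Pooled per-exon RPKM
#'
#' For each exon of each model, computes RPKM per (stage, library) and
#' takes the maximum across conditions.
#'
#' @param counts \code{exon_counts} table
#' @param models \code{GeneModelSet}
#' @param totals totals table (see \code{\link{read_totals}})
#' @return data frame: \code{model_id}, \code{exon_index}, \code{rpkm}
#' @export
exon_rpkm_pooled <- function(counts, models, totals) {
  et <- exon_table(models)
  best <- rep(0, nrow(et))
  for (i in seq_len(nrow(totals))) {
    sub <- counts[counts$stage == totals$stage[i] &
                    counts$library == totals$library[i], , drop = FALSE]
    idx <- match(paste(et$model_id, et$exon_index),
                 paste(sub$model_id, sub$exon_index))
    cnt <- ifelse(is.na(idx), 0L, sub$count[idx])
    rpkm <- cnt / (et$len / 1000) / (totals$total_mapped[i] / 1e6)
    best <- pmax(best, rpkm)
  }
  data.frame(model_id = et$model_id, exon_index = et$exon_index,
             rpkm = best, stringsAsFactors = FALSE)
}

#' Splicing-evidence filter
#'
#' Keeps a candidate when at least one of its introns exactly matches
#' (donor and acceptor, same strand) a supported splice junction.
#'
#' @param candidate_ids candidate model ids
#' @param candidates \code{GeneModelSet} containing the candidates
#' @param junctions filtered junction \code{GRanges} (output of
#'   \code{\link{filter_junctions}})
#' @param all_introns require all introns supported instead of >= 1
#' @return surviving candidate ids
#' @export
filter_splicing <- function(candidate_ids, candidates, junctions,
                            all_introns = FALSE) {
  jk <- junction_keys(junctions)
  keep <- vapply(candidate_ids, function(id) {
    ik <- junction_keys(introns_of(candidates$exons[[id]]))
    if (length(ik) == 0L) return(FALSE)
    if (all_introns) all(ik %in% jk) else any(ik %in% jk)
  }, logical(1))
  candidate_ids[keep]
}

#' Apply the external exclusion list
#'
#' Hook consuming the result of manual/homology screening (e.g. BLASTN or
#' BLASTP hits against protein-coding sequence): listed ids are dropped.
#' Ids not among the survivors are ignored with a warning.
#'
#' @param candidate_ids candidate model ids
#' @param exclusion_list model ids to remove
#' @return surviving candidate ids
#' @export
apply_exclusion_list <- function(candidate_ids, exclusion_list) {
  stray <- setdiff(exclusion_list, candidate_ids)
  if (length(stray)) {
    warning("excluded ids not among survivors: ", paste(stray, collapse = ", "))
  }
  setdiff(candidate_ids, exclusion_list)
}

#' Mean conservation over a model's exons
#'
#' Length-weighted mean of per-base conservation scores over exonic
#' positions; bases without a score are excluded from both numerator and
#' denominator. Returns \code{NA} when no exonic base is covered.
#'
#' @param exons sorted exon \code{GRanges} of one model
#' @param track conservation \code{GRanges} with \code{score} in [0, 1]
#'   (see \code{\link{read_conservation}})
#' @return numeric in [0, 1], or \code{NA}
#' @export
mean_conservation <- function(exons, track) {
  if (length(track) == 0L) return(NA_real_)
  ov <- findOverlaps(track, exons, ignore.strand = TRUE)
  if (length(ov) == 0L) return(NA_real_)
  seg <- track[S4Vectors::queryHits(ov)]
  tgt <- exons[S4Vectors::subjectHits(ov)]
  w <- pmin(end(seg), end(tgt)) - pmax(start(seg), start(tgt)) + 1L
  sum(seg$score * w) / sum(w)
}

#' Curate NGM-vv candidates into high-confidence stand-alone lncRNAs
#'
#' Applies, in order, the ORF-length filter, the downstream promoter-less
#' gene filter, the per-exon RPKM floor, the splicing-evidence filter and
#' the external exclusion list. The filters are intersective, so the
#' final set does not depend on their order; the report records each
#' filter's verdict per candidate together with structural and expression
#' summaries.
#'
#' @param xtev an \code{\link{run_xtev}} result
#' @param scores \code{\link{score_models}} output for the candidates
#' @param counts \code{exon_counts} table
#' @param totals totals table
#' @param junctions raw junction \code{GRanges} (filtered internally with
#'   the pipeline's junction threshold)
#' @param conservation optional conservation track
#' @param config a \code{\link{curation_config}}
#' @param candidate_ids set to curate (default: the NGM-vv set)
#' @return list of class \code{CurationReport}: \code{report} (one row
#'   per candidate with per-filter passes, verdict, exon count,
#'   transcript length, mean conservation), \code{final} (surviving model
#'   ids), \code{attrition} (named funnel counts)
#' @export
curate <- function(xtev, scores, counts, totals, junctions,
                   conservation = NULL, config = curation_config(),
                   candidate_ids = xtev$ngm_vv) {
  cand <- xtev$candidates
  stopifnot(all(candidate_ids %in% model_ids(cand)))
  jf <- filter_junctions(junctions, xtev$config$min_junction_reads)
  rpkm <- exon_rpkm_pooled(counts, cand, totals)

  p_orf <- filter_orf(candidate_ids, scores, config$max_orf_aa)
  p_ds <- filter_downstream_gene(candidate_ids, cand, xtev,
                                 config$max_downstream_distance)
  p_rpkm <- filter_exon_rpkm(candidate_ids, rpkm, config$min_exon_rpkm)
  p_spl <- if (config$require_splicing_evidence) {
    filter_splicing(candidate_ids, cand, jf)
  } else candidate_ids

  survivors <- Reduce(intersect, list(p_orf, p_ds, p_rpkm, p_spl))
  final <- apply_exclusion_list(survivors, config$exclusion_list)

  sidx <- match(candidate_ids, scores$model_id)
  report <- data.frame(
    model_id = candidate_ids,
    pass_orf = candidate_ids %in% p_orf,
    pass_downstream = candidate_ids %in% p_ds,
    pass_exon_rpkm = candidate_ids %in% p_rpkm,
    pass_splicing = candidate_ids %in% p_spl,
    excluded = candidate_ids %in% config$exclusion_list,
    verdict = candidate_ids %in% final,
    max_orf_aa = scores$max_orf_aa[sidx],
    max_llr = scores$max_llr[sidx],
    n_exons = vapply(candidate_ids,
                     function(id) length(cand$exons[[id]]), integer(1)),
    tx_length = vapply(candidate_ids,
                       function(id) sum(width(cand$exons[[id]])), integer(1)),
    mean_conservation = vapply(candidate_ids, function(id) {
      if (is.null(conservation)) NA_real_
      else mean_conservation(cand$exons[[id]], conservation)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attrition <- c(input = length(candidate_ids),
                 orf = length(p_orf),
                 downstream = length(intersect(p_orf, p_ds)),
                 exon_rpkm = length(Reduce(intersect, list(p_orf, p_ds, p_rpkm))),
                 splicing = length(survivors),
                 final = length(final))
  structure(list(report = report, final = final, attrition = attrition,
                 config = config),
            class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("CurationReport:", x$attrition["input"], "candidates ->",
      length(x$final), "high-confidence stand-alone lncRNA candidates\n")
  print(x$attrition)
  invisible(x)
}
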