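#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame elementNROWS
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand "strand<-" findOverlaps countOverlaps reduce sort
NULL

#' Construct a set of gene models
#'
#' A \code{GeneModelSet} is the package's container for transcript models:
#' a named \code{GRangesList} of exons (one element per model, exons sorted
#' 5'-agnostically by start, non-overlapping, all on one chromosome and
#' strand) plus per-model metadata (\code{gene_id}, \code{source},
#' \code{spliced}, free-form \code{status} codes).
#'
#' @param exons named \code{GRangesList}, one element per transcript model.
#'   Names are the model ids and must be unique.
#' @param gene_id character vector of gene ids (one per model) or \code{NA}
#'   if not yet grouped (see \code{\link{group_gene_models}}).
#' @param source character vector or scalar: one of \code{"reference"},
#'   \code{"est"}, \code{"assembly"}, \code{"updated"}.
#' @param status character vector of semicolon-separated status codes
#'   (usually filled in by \code{\link{run_xtev}}).
#' @return an object of class \code{GeneModelSet} with components
#'   \code{exons} (\code{GRangesList}) and \code{meta} (\code{data.frame}
#'   with columns \code{model_id}, \code{gene_id}, \code{source},
#'   \code{spliced}, \code{status}).
#' @examples
#' ex <- GRangesList(
#'   m1 = GRanges("chr1", IRanges(c(101, 501), c(200, 700)), strand = "+")
#' )
#' gms <- gene_model_set(ex)
#' n_models(gms)
#' @export
gene_model_set <- function(exons, gene_id = NA_character_,
                           source = "reference", status = "") {
  if (!is(exons, "GRangesList")) {
    exons <- GRangesList(exons)
  }
  ids <- names(exons)
  if (length(exons) == 0L) ids <- character(0)
  if (length(exons) > 0L &&
      (is.null(ids) || anyDuplicated(ids) || any(ids == ""))) {
    stop("model ids (names of 'exons') must be present and unique")
  }
  exons <- GRangesList(lapply(exons, function(gr) {
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  }), compress = TRUE)
  names(exons) <- ids
  meta <- data.frame(
    model_id = ids,
    gene_id = rep_len(as.character(gene_id), length(ids)),
    source = rep_len(as.character(source), length(ids)),
    spliced = elementNROWS(exons) >= 2L,
    status = rep_len(as.character(status), length(ids)),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- NULL
  out <- structure(list(exons = exons, meta = meta), class = "GeneModelSet")
  validate_gene_models(out)
  out
}

#' Validate a GeneModelSet
#'
#' Checks the structural invariants: unique model ids, every model has at
#' least one exon, exons of a model sorted and non-overlapping, and all on
#' a single chromosome and strand.
#'
#' @param x a \code{GeneModelSet}
#' @return \code{x}, invisibly; errors describe the offending model.
#' @export
validate_gene_models <- function(x) {
  stopifnot(is(x, "GeneModelSet"))
  if (length(x$exons) != nrow(x$meta)) {
    stop("exons and meta are out of step")
  }
  for (i in seq_along(x$exons)) {
    gr <- x$exons[[i]]
    id <- x$meta$model_id[i]
    if (length(gr) == 0L) stop("model ", id, " has no exons")
    if (length(unique(as.character(seqnames(gr)))) != 1L ||
        length(unique(as.character(strand(gr)))) != 1L) {
      stop("model ", id, " has exons on multiple chromosomes or strands")
    }
    s <- start(gr); e <- end(gr)
    if (is.unsorted(s)) stop("model ", id, ": exons not sorted by start")
    if (length(gr) > 1L && any(s[-1L] <= e[-length(e)])) {
      stop("model ", id, ": consecutive exons overlap or touch ambiguously")
    }
  }
  invisible(x)
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet with", n_models(x), "models (",
      sum(x$meta$spliced), "spliced )\n")
  cat("sources:", paste(names(table(x$meta$source)),
                        table(x$meta$source), collapse = ", "), "\n")
  invisible(x)
}

#' Number of models in a GeneModelSet
#' @param x a \code{GeneModelSet}
#' @return integer count of models
#' @export
n_models <- function(x) length(x$exons)

#' Model identifiers of a GeneModelSet
#' @param x a \code{GeneModelSet}
#' @return character vector of model ids
#' @export
model_ids <- function(x) x$meta$model_id

#' Exons of one model
#' @param x a \code{GeneModelSet}
#' @param id model id
#' @return \code{GRanges} of the model's exons, sorted by start
#' @export
model_exons <- function(x, id) {
  if (!id %in% names(x$exons)) stop("unknown model id: ", id)
  x$exons[[id]]
}

#' Subset a GeneModelSet by model id
#' @param x a \code{GeneModelSet}
#' @param ids model ids to keep (order preserved)
#' @return a \code{GeneModelSet} restricted to \code{ids}
#' @export
subset_models <- function(x, ids) {
  stopifnot(all(ids %in% x$meta$model_id))
  keep <- match(ids, x$meta$model_id)
  out <- structure(list(exons = x$exons[keep],
                        meta = x$meta[keep, , drop = FALSE]),
                   class = "GeneModelSet")
  rownames(out$meta) <- NULL
  out
}

#' Combine two GeneModelSets
#' @param x,y \code{GeneModelSet}s with disjoint model ids
#' @return the concatenated \code{GeneModelSet}
#' @export
combine_models <- function(x, y) {
  if (n_models(y) == 0L) return(x)
  if (n_models(x) == 0L) return(y)
  if (any(model_ids(y) %in% model_ids(x))) {
    stop("model ids overlap between the two sets")
  }
  structure(list(exons = c(x$exons, y$exons),
                 meta = rbind(x$meta, y$meta)),
            class = "GeneModelSet")
}

# exact-identity key for an exon; the unit of "sharing an exon" and of
# non-redundant exon deduplication
exon_keys <- function(gr) {
  paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr), ":",
         as.character(strand(gr)))
}

# strand-blind exon key (peaks, NGM overlap tests use range overlap instead)
exon_keys_unstranded <- function(gr) {
  paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
}

#' Intron intervals of an exon chain
#'
#' Returns the introns (donor..acceptor, inclusive internal coordinates) of
#' a sorted exon \code{GRanges}; an unspliced model yields an empty result.
#'
#' @param exons \code{GRanges} of one model's exons, sorted by start
#' @return \code{GRanges} of introns, same strand
#' @export
introns_of <- function(exons) {
  n <- length(exons)
  if (n < 2L) {
    return(GRanges(seqnames = character(0), ranges = IRanges()))
  }
  GRanges(seqnames(exons)[-n],
          IRanges(end(exons)[-n] + 1L, start(exons)[-1L] - 1L),
          strand = strand(exons)[-n])
}

# junction identity keys (strand-aware, exact donor/acceptor coordinates)
junction_keys <- function(gr) exon_keys(gr)

#' Strand-aware first (5') exon of a model
#' @param exons sorted exon \code{GRanges}
#' @return \code{GRanges} of length 1: the 5'-most exon
#' @export
first_exon <- function(exons) {
  if (as.character(strand(exons))[1] == "-") exons[length(exons)] else exons[1L]
}

#' Genomic span of a model
#' @param exons sorted exon \code{GRanges}
#' @return \code{GRanges} of length 1 covering first-exon start to
#'   last-exon end (introns included)
#' @export
model_span <- function(exons) {
  GRanges(seqnames(exons)[1L],
          IRanges(min(start(exons)), max(end(exons))),
          strand = strand(exons)[1L])
}

#' Strand-aware transcription start position of a model
#' @param exons sorted exon \code{GRanges}
#' @return integer genomic position of the 5' end
#' @export
tss_position <- function(exons) {
  if (as.character(strand(exons))[1] == "-") max(end(exons)) else min(start(exons))
}
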