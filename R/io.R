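#' @importFrom rtracklayer import export blocks
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom utils read.delim write.table
NULL

guess_dialect <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         gff = , gff3 = "gff3",
         gtf = "gtf",
         bed = , bed12 = "bed12",
         stop("cannot guess dialect from extension '", ext,
              "'; pass dialect= explicitly"))
}

#' Read gene models from GFF3, GTF or BED12
#'
#' Coordinates are converted by the parser to the internal 1-based closed
#' convention shared by the whole package (GFF/GTF are native; BED12 blocks
#' are shifted from 0-based half-open). Transcript/exon hierarchies are
#' resolved via \code{Parent} (GFF3) or \code{transcript_id} (GTF)
#' attributes; BED12 block fields become exons.
#'
#' @param path input file
#' @param dialect one of \code{"auto"} (by extension), \code{"gff3"},
#'   \code{"gtf"}, \code{"bed12"}
#' @return a \code{\link{gene_model_set}}; \code{gene_id}, \code{source}
#'   and \code{status} attributes are restored when present in the file.
#' @export
read_gene_models <- function(path, dialect = c("auto", "gff3", "gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) {
      return(gene_model_set(GRangesList()[0]))
    }
    grl <- rtracklayer::blocks(gr)
    flat <- unlist(grl, use.names = FALSE)
    mcols(flat) <- NULL
    strand(flat) <- rep(strand(gr), elementNROWS(grl))
    grl <- GenomicRanges::split(flat, rep(seq_along(gr), elementNROWS(grl)))
    names(grl) <- gr$name
    return(gene_model_set(grl, source = "assembly"))
  }
  gr <- rtracklayer::import(path, format = ifelse(dialect == "gtf", "gtf", "gff3"))
  ex <- gr[tolower(gr$type) == "exon"]
  if (length(ex) == 0L) return(gene_model_set(GRangesList()[0]))
  if (dialect == "gtf") {
    parent <- as.character(ex$transcript_id)
  } else {
    pl <- ex$Parent
    if (any(elementNROWS(pl) != 1L)) {
      stop("exon with zero or multiple Parent attributes")
    }
    parent <- as.character(unlist(pl))
  }
  grl <- GenomicRanges::split(ex[, NULL], factor(parent, levels = unique(parent)))
  # per-transcript attributes from the transcript features, if present
  tx <- gr[tolower(gr$type) %in% c("transcript", "mrna")]
  tid <- if (length(tx)) as.character(if (dialect == "gtf") tx$transcript_id else tx$ID) else character(0)
  pull_attr <- function(col, default) {
    if (length(tx) && col %in% names(mcols(tx))) {
      v <- as.character(mcols(tx)[[col]])
      out <- v[match(names(grl), tid)]
      ifelse(is.na(out), default, out)
    } else rep(default, length(grl))
  }
  # verify exons fall inside their transcript span when declared
  if (length(tx)) {
    m <- match(names(grl), tid)
    for (i in which(!is.na(m))) {
      sp <- tx[m[i]]
      if (min(start(grl[[i]])) < start(sp) || max(end(grl[[i]])) > end(sp)) {
        stop("exons of model ", names(grl)[i], " extend outside transcript span")
      }
    }
  }
  gene_model_set(grl,
                 gene_id = pull_attr("gene_id", NA_character_),
                 source = pull_attr("source_class", "reference"),
                 status = pull_attr("status", ""))
}

#' Write gene models to GFF3 or BED12
#'
#' GFF3 output carries \code{gene_id}, \code{source_class} and
#' \code{status} transcript attributes so that a write/read round trip
#' restores the full \code{GeneModelSet}. BED12 output is structural only
#' (exon blocks, strand, model id as name).
#'
#' @param x a \code{GeneModelSet}
#' @param path output file
#' @param dialect \code{"gff3"} or \code{"bed12"}
#' @return \code{path}, invisibly
#' @export
write_gene_models <- function(x, path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  validate_gene_models(x)
  if (dialect == "bed12") {
    grl <- x$exons
    rtracklayer::export(grl, path, format = "bed")
    return(invisible(path))
  }
  feats <- GRanges()
  if (n_models(x) > 0L) {
    tx <- unlist(GRangesList(lapply(x$exons, model_span)), use.names = FALSE)
    mcols(tx) <- DataFrame(
      type = "transcript",
      ID = x$meta$model_id,
      gene_id = x$meta$gene_id,
      source_class = x$meta$source,
      status = x$meta$status
    )
    ex <- unlist(x$exons, use.names = TRUE)
    mcols(ex) <- DataFrame(
      type = "exon",
      ID = NA_character_,
      Parent = rep(x$meta$model_id, elementNROWS(x$exons)),
      gene_id = NA_character_,
      source_class = NA_character_,
      status = NA_character_
    )
    names(ex) <- NULL
    mcols(tx)$Parent <- NA_character_
    feats <- c(tx, ex[, names(mcols(tx))])
  }
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}

#' Read a BED peak file
#'
#' @param path BED3+ file; column 5 (when present) is kept as \code{score}.
#' @return \code{GRanges} of peaks with strand set to \code{*} (histone
#'   modification peaks are strandless).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(GRanges())
  }
  gr <- rtracklayer::import(path, format = "bed")
  strand(gr) <- "*"
  if (any(width(gr) < 1L)) stop("peak with start >= end")
  gr
}

#' Write peaks to BED
#' @param peaks \code{GRanges}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_peaks <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "bed")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' The returned \code{GRanges} (one \code{score} per interval) is the
#' package's \code{SignalTrack}; intervals within a chromosome must not
#' overlap. Positions absent from the file are treated as coverage 0 by
#' \code{\link{signal_mean}}.
#'
#' @param path bedGraph file
#' @return \code{GRanges} with numeric \code{score}, all values >= 0
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0L) return(GRanges(score = numeric(0)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  strand(gr) <- "*"
  validate_signal(gr)
  gr
}

validate_signal <- function(gr) {
  if (length(gr) && any(gr$score < 0)) stop("negative signal value")
  if (length(gr) > 1L) {
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0L) stop("overlapping intervals in signal track")
  }
  invisible(gr)
}

#' Write a signal track to bedGraph
#' @param track \code{GRanges} with \code{score}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_signal <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Mean signal over a region
#'
#' Length-weighted mean of the track over one genomic interval; positions
#' not covered by the track contribute 0.
#'
#' @param track \code{GRanges} with \code{score} (see \code{\link{read_signal}})
#' @param region \code{GRanges} of length 1 with positive width
#' @return numeric mean signal
#' @examples
#' tr <- GRanges("chr1", IRanges(1, 100), score = 2)
#' signal_mean(tr, GRanges("chr1", IRanges(1, 200)))  # 1.0
#' @export
signal_mean <- function(track, region) {
  stopifnot(length(region) == 1L)
  if (width(region) <= 0L) stop("zero-length region")
  if (length(track) == 0L) return(0)
  ov <- findOverlaps(track, region, ignore.strand = TRUE)
  if (length(ov) == 0L) return(0)
  seg <- track[S4Vectors::queryHits(ov)]
  w <- pmin(end(seg), end(region)) - pmax(start(seg), start(region)) + 1L
  sum(seg$score * w) / width(region)
}

#' Read a splice-junction table
#'
#' BED-like tab file: chrom, start (0-based), end, name, read support,
#' strand. Each record is one intron (donor..acceptor).
#'
#' @param path junction file
#' @return \code{GRanges} of introns (1-based closed) with integer
#'   \code{read_support}
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0L) {
    return(GRanges(read_support = integer(0)))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("junction file needs 6 columns (BED6 with support as score)")
  if (any(df[[5L]] < 0)) stop("negative junction read support")
  GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]), strand = df[[6L]],
          read_support = as.integer(df[[5L]]))
}

#' Write a splice-junction table
#' @param junctions \code{GRanges} with \code{read_support}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_junctions <- function(junctions, path) {
  df <- data.frame(
    chrom = as.character(seqnames(junctions)),
    start = start(junctions) - 1L,
    end = end(junctions),
    name = if (length(junctions)) paste0("jx", seq_along(junctions)) else character(0),
    score = junctions$read_support,
    strand = as.character(strand(junctions))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-exon read-count table
#'
#' Tab-delimited with header: \code{model_id}, \code{exon_index} (1-based,
#' in start order), \code{stage}, \code{library} (PA or RZ), \code{count}.
#' Missing combinations are treated as count 0 by the accessors; duplicate
#' keys are an error.
#'
#' @param path TSV file
#' @return \code{data.frame} of class \code{exon_counts}
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("model_id", "exon_index", "stage", "library", "count")
  if (!all(need %in% names(df))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (any(df$count < 0)) stop("negative count")
  if (!all(df$library %in% c("PA", "RZ"))) stop("library must be PA or RZ")
  key <- paste(df$model_id, df$exon_index, df$stage, df$library, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (model, exon, stage, library) key")
  df$count <- as.integer(df$count)
  class(df) <- c("exon_counts", "data.frame")
  df
}

#' Write a per-exon count table
#' @param counts \code{exon_counts} data frame
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Look up one exon count
#'
#' @param counts \code{exon_counts} table
#' @param model_id,exon_index,stage,library key of the exon observation
#' @return integer count; 0 when the combination is absent
#' @export
count_for <- function(counts, model_id, exon_index, stage, library) {
  hit <- counts$model_id == model_id & counts$exon_index == exon_index &
    counts$stage == stage & counts$library == library
  if (!any(hit)) return(0L)
  counts$count[which(hit)[1L]]
}

#' Read per-library total mapped read counts
#' @param path TSV with header columns \code{stage}, \code{library},
#'   \code{total_mapped}
#' @return \code{data.frame}
#' @export
read_totals <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("stage", "library", "total_mapped")
  if (!all(need %in% names(df))) {
    stop("totals table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$total_mapped <= 0)) stop("total_mapped must be positive")
  df[, need]
}

#' Read a genome FASTA
#' @param path FASTA file
#' @return \code{DNAStringSet}; names truncated at the first whitespace
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a phastCons-style conservation track
#'
#' bedGraph with per-interval scores in [0, 1]; gaps (bases with no score)
#' are allowed and are excluded from averages by
#' \code{\link{mean_conservation}}.
#'
#' @param path bedGraph file
#' @return \code{GRanges} with \code{score} in [0, 1]
#' @export
read_conservation <- function(path) {
  gr <- read_signal(path)
  if (length(gr) && (any(gr$score < 0) || any(gr$score > 1))) {
    stop("conservation scores must lie in [0, 1]")
  }
  gr
}

#' Read a qPCR Ct table
#'
#' @param path TSV with header columns \code{gene}, \code{stage}, \code{ct}
#' @param normalizer id of the normalising gene (e.g. \code{"odc1"})
#' @param reference_stage stage against which fold changes are expressed
#' @return list of class \code{qpcr_table} with components \code{data},
#'   \code{normalizer}, \code{reference_stage}
#' @export
read_qpcr <- function(path, normalizer, reference_stage) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "stage", "ct")
  if (!all(need %in% names(df))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  qpcr_table(df[, need], normalizer, reference_stage)
}

#' Construct a qPCR Ct table from a data frame
#' @param data data.frame with columns \code{gene}, \code{stage}, \code{ct}
#' @param normalizer normalising gene id
#' @param reference_stage reference stage id
#' @return list of class \code{qpcr_table}
#' @export
qpcr_table <- function(data, normalizer, reference_stage) {
  stages_used <- unique(data$stage)
  norm_stages <- unique(data$stage[data$gene == normalizer])
  if (!all(stages_used %in% norm_stages)) {
    stop("normalizer '", normalizer, "' missing for some stages")
  }
  structure(list(data = data, normalizer = normalizer,
                 reference_stage = reference_stage),
            class = "qpcr_table")
}
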