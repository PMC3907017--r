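#' @importFrom Biostrings DNAString DNAStringSet reverseComplement GENETIC_CODE
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

codons_in_frame <- function(s, offset) {
  n <- nchar(s)
  if (n - 2L < 1L + offset) return(character(0))
  starts <- seq.int(1L + offset, n - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

read_triplet_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.delim(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  names(x)[1:2] <- c("triplet", "weight")
  x$triplet <- toupper(x$triplet)
  x$triplet <- chartr("U", "T", x$triplet)
  all64 <- names(Biostrings::GENETIC_CODE)
  if (!setequal(x$triplet, all64) || anyDuplicated(x$triplet)) {
    stop("table must contain each of the 64 triplets exactly once")
  }
  w <- x$weight[match(all64, x$triplet)]
  if (any(w < 0) || !any(w > 0)) stop("triplet weights must be non-negative, not all zero")
  names(w) <- all64
  w
}

# additive smoothing: when a table contains zero weights, every triplet
# gains half the smallest positive weight so all LLRs stay finite
smooth_weights <- function(w) {
  if (any(w == 0)) w <- w + 0.5 * min(w[w > 0])
  w
}

#' Build a codon-bias log-likelihood-ratio table
#'
#' From a coding codon-usage table and a noncoding triplet-frequency table
#' (any common scale: counts, per-thousand, frequencies), computes for each
#' codon \code{i} encoding amino acid \code{a_i} the conditional
#' likelihoods \code{c_i} (coding) and \code{n_i} (noncoding) --
#' frequencies renormalised within each amino-acid class, stop codons
#' forming their own class -- and the log-likelihood ratio
#' \code{LLR_i = log2(c_i / n_i)} in bits. Zero weights are smoothed by
#' adding half the smallest positive weight of the table so every LLR is
#' finite.
#'
#' @param coding TSV path or data frame (columns: triplet, weight) of
#'   coding-sequence codon frequencies
#' @param noncoding TSV path or data frame of noncoding triplet frequencies
#' @return data frame of class \code{codon_llr_table} with columns
#'   \code{codon}, \code{aa}, \code{c}, \code{n}, \code{llr}
#' @examples
#' tab <- build_llr_table(mzt_default_coding_table(),
#'                        mzt_default_noncoding_table())
#' tab[tab$codon == "ATG", ]  # single-codon class: llr 0
#' @export
build_llr_table <- function(coding, noncoding) {
  cw <- smooth_weights(read_triplet_table(coding))
  nw <- smooth_weights(read_triplet_table(noncoding))
  if (any(cw == 0) || any(nw == 0)) stop("zero frequency after smoothing")
  aa <- Biostrings::GENETIC_CODE[names(cw)]
  cc <- as.numeric(cw / tapply(cw, aa, sum)[aa])
  nn <- as.numeric(nw / tapply(nw, aa, sum)[aa])
  out <- data.frame(codon = names(cw), aa = unname(aa),
                    c = cc, n = nn, llr = log2(cc / nn),
                    stringsAsFactors = FALSE)
  class(out) <- c("codon_llr_table", "data.frame")
  out
}

llr_lookup <- function(table) {
  stopifnot(is(table, "codon_llr_table"))
  v <- table$llr
  names(v) <- table$codon
  v
}

#' Maximal open-reading-frame length over six frames
#'
#' Scans all three frames of both strands for ORFs running from an ATG to
#' the first in-frame stop. The length in amino acids counts the Met
#' through the last sense codon (the stop is excluded); an ORF reaching
#' the sequence end without a stop counts its full codon run. Codons
#' containing N never match ATG or a stop.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive)
#' @return integer: the maximal ORF length in amino acids (0 if no ATG)
#' @examples
#' max_orf_aa("ATGAAATAG")  # 2 (Met-Lys)
#' @export
max_orf_aa <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 3L) return(0L)
  best <- 0L
  for (str in c(s, revcomp(s))) {
    for (off in 0:2) {
      cod <- codons_in_frame(str, off)
      nc <- length(cod)
      if (nc == 0L) next
      atg <- which(cod == "ATG")
      if (length(atg) == 0L) next
      stops <- which(cod %in% STOP_CODONS)
      nxt <- findInterval(atg, stops) + 1L
      len <- ifelse(nxt <= length(stops), stops[nxt] - atg, nc - atg + 1L)
      best <- max(best, max(len))
    }
  }
  as.integer(best)
}

# per-frame codon LLR values; codons with N contribute 0
frame_llr_values <- function(cod, lut) {
  v <- unname(lut[cod])
  v[is.na(v)] <- 0
  v
}

#' Maximal codon-bias window score
#'
#' Sums per-codon LLR values over every codon-aligned window of
#' \code{window_bp} (default 90 bp = 30 codons) in all six reading frames
#' (three offsets on each strand), sliding by one codon, and returns the
#' maximum window score. Sequences shorter than the window are scored
#' over their single maximal in-frame codon run. Codons containing N
#' contribute 0.
#'
#' @param sequence nucleotide string (length >= 3)
#' @param table a \code{\link{build_llr_table}} result
#' @param window_bp window size in bp, divisible by 3
#' @param details if \code{TRUE} return a list with the score, best frame
#'   label (\code{"+0"} .. \code{"-2"}, offset within the scored strand)
#'   and 1-based codon-run start of the best window on that strand
#' @return numeric max window score in bits (or the detail list)
#' @export
max_window_llr <- function(sequence, table, window_bp = 90, details = FALSE) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 3L) stop("sequence shorter than 3 bp")
  if (window_bp %% 3 != 0) stop("window_bp must be divisible by 3")
  w <- window_bp %/% 3L
  lut <- llr_lookup(table)
  best <- -Inf; best_frame <- NA_character_; best_start <- NA_integer_
  strands <- c("+", "-")
  seqs <- c(s, revcomp(s))
  for (k in 1:2) {
    for (off in 0:2) {
      cod <- codons_in_frame(seqs[k], off)
      nc <- length(cod)
      if (nc == 0L) next
      v <- frame_llr_values(cod, lut)
      if (nc <= w) {
        sums <- sum(v); starts <- 1L
      } else {
        cs <- c(0, cumsum(v))
        starts <- seq_len(nc - w + 1L)
        sums <- cs[starts + w] - cs[starts]
      }
      i <- which.max(sums)
      if (sums[i] > best) {
        best <- sums[i]
        best_frame <- paste0(strands[k], off)
        best_start <- off + 1L + (starts[i] - 1L) * 3L
      }
    }
  }
  if (details) {
    list(max_llr = best, best_frame = best_frame, best_window_start = best_start)
  } else best
}

#' Score gene models for coding potential
#'
#' Extracts each model's spliced transcript sequence from the genome
#' (exons concatenated in genomic order, reverse-complemented for minus
#' strand models) and computes the six-frame maximal ORF length and the
#' maximal 90-bp codon-bias window score.
#'
#' @param models \code{GeneModelSet}
#' @param genome \code{DNAStringSet} (see \code{\link{read_genome}})
#' @param table a \code{\link{build_llr_table}} result
#' @param window_bp window size in bp
#' @return data frame with one row per model: \code{model_id},
#'   \code{tx_length}, \code{max_orf_aa}, \code{max_llr},
#'   \code{best_frame}, \code{best_window_start}
#' @export
score_models <- function(models, genome, table, window_bp = 90) {
  seqs <- model_sequences(models, genome)
  res <- lapply(seqs, function(s) {
    d <- if (nchar(s) >= 3L) {
      max_window_llr(s, table, window_bp, details = TRUE)
    } else list(max_llr = NA_real_, best_frame = NA_character_,
                best_window_start = NA_integer_)
    data.frame(tx_length = nchar(s), max_orf_aa = max_orf_aa(s),
               max_llr = d$max_llr, best_frame = d$best_frame,
               best_window_start = d$best_window_start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(model_id = names(seqs), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Spliced transcript sequences of gene models
#'
#' @param models \code{GeneModelSet}
#' @param genome \code{DNAStringSet}
#' @return named character vector of transcript sequences (5' to 3')
#' @export
model_sequences <- function(models, genome) {
  out <- character(n_models(models))
  names(out) <- model_ids(models)
  for (i in seq_along(out)) {
    gr <- models$exons[[i]]
    chr <- as.character(seqnames(gr))[1L]
    if (!chr %in% names(genome)) {
      stop("model ", names(out)[i], ": chromosome ", chr, " not in genome")
    }
    if (max(end(gr)) > length(genome[[chr]]) || min(start(gr)) < 1L) {
      stop("model ", names(out)[i], ": exon outside genome bounds")
    }
    pieces <- vapply(seq_along(gr), function(j) {
      as.character(Biostrings::subseq(genome[[chr]], start(gr)[j], end(gr)[j]))
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (as.character(strand(gr))[1L] == "-") s <- revcomp(s)
    out[i] <- s
  }
  out
}

#' Bundled coding codon-usage table (synthetic default)
#'
#' A representative vertebrate codon-usage table (values per thousand
#' codons), shipped as a stand-in default; substitute an organism-specific
#' table via the \code{coding} argument of \code{\link{build_llr_table}}
#' for real analyses.
#'
#' @return data frame with columns \code{triplet}, \code{weight}
#' @export
mzt_default_coding_table <- function() {
  path <- system.file("extdata", "codon_usage_coding_synthetic.tsv",
                      package = "mztscope", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled noncoding triplet-frequency table (synthetic default)
#'
#' Triplet frequencies implied by independent nucleotides at an AT-rich
#' intergenic composition (33\% A, 33\% T, 17\% C, 17\% G), shipped as a
#' stand-in default for the noncoding background.
#'
#' @return data frame with columns \code{triplet}, \code{weight}
#' @export
mzt_default_noncoding_table <- function() {
  path <- system.file("extdata", "triplet_freq_noncoding_synthetic.tsv",
                      package = "mztscope", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
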