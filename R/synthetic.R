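#' @importFrom stats rpois runif rbinom rlnorm setNames
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

GENE_CLASSES <- c("maternal_poly", "maternal_deadenylated",
                  "maternal_embryonic", "embryonic_only", "lncRNA_standalone")
ARTIFACT_CLASSES <- c("utr_fragment", "broken_gene", "unspliced_single_exon")

#' Configuration of the synthetic developmental-transcriptome study
#'
#' Defines the planted study: gene counts per transcript class, assembly
#' artifact counts, the six developmental stages with paired polyA+ (PA)
#' and ribo-depleted (RZ) libraries, sequencing depth and chromatin
#' parameters. Defaults emulate a compact version of an early-embryo
#' time course: oocyte through late tailbud, ~20 mapped reads per exon
#' kilobase at RPKM 1 per library (2e7 total mapped reads).
#'
#' @param seed integer seed governing every random choice downstream
#' @param n_genes named integer vector over the five transcript classes
#' @param n_artifacts named integer vector over the three artifact classes
#' @param stages ordered character vector of stages (first = oocyte)
#' @param depth_per_kb expected reads per exon kilobase at RPKM 1
#'   (total mapped reads = \code{depth_per_kb * 1e6})
#' @param h3k4me3_dropout probability that a gene's promoter peak is
#'   missing from the simulated ChIP data
#' @param n_noise_junctions spurious junctions emitted at read support
#'   below the trust threshold
#' @param deadenylated_stages stages at which the deadenylated class is
#'   constructed to satisfy log2(PA/RZ) <= -0.5
#' @param chrom chromosome name of the synthetic genome
#' @return list of class \code{synthetic_config}
#' @export
synthetic_config <- function(seed = 42L,
                             n_genes = c(maternal_poly = 10L,
                                         maternal_deadenylated = 10L,
                                         maternal_embryonic = 10L,
                                         embryonic_only = 10L,
                                         lncRNA_standalone = 10L),
                             n_artifacts = c(utr_fragment = 3L,
                                             broken_gene = 3L,
                                             unspliced_single_exon = 5L),
                             stages = c("oocyte", "st6", "st9",
                                        "st12", "st16", "st30"),
                             depth_per_kb = 20,
                             h3k4me3_dropout = 0,
                             n_noise_junctions = 5L,
                             deadenylated_stages = c("st6", "st9"),
                             chrom = "chrS") {
  n_genes <- n_genes[GENE_CLASSES]
  names(n_genes) <- GENE_CLASSES
  n_genes[is.na(n_genes)] <- 0L
  n_artifacts <- n_artifacts[ARTIFACT_CLASSES]
  names(n_artifacts) <- ARTIFACT_CLASSES
  n_artifacts[is.na(n_artifacts)] <- 0L
  if (all(n_genes == 0L)) stop("zero genes in every class")
  if (any(n_genes < 0L) || any(n_artifacts < 0L)) stop("negative counts")
  if (length(stages) == 0L) stop("stages must be non-empty")
  if (h3k4me3_dropout < 0 || h3k4me3_dropout > 1) stop("dropout must be in [0,1]")
  if (n_artifacts["utr_fragment"] > n_genes["maternal_embryonic"]) {
    stop("need at least as many maternal_embryonic genes as utr_fragment artifacts")
  }
  if (n_artifacts["broken_gene"] > n_genes["maternal_poly"]) {
    stop("need at least as many maternal_poly genes as broken_gene artifacts")
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_artifacts = n_artifacts, stages = stages,
                 depth_per_kb = depth_per_kb,
                 h3k4me3_dropout = h3k4me3_dropout,
                 n_noise_junctions = as.integer(n_noise_junctions),
                 deadenylated_stages = deadenylated_stages,
                 chrom = chrom),
            class = "synthetic_config")
}

split_length <- function(total, k, min_len = 60L) {
  if (k == 1L) return(total)
  free <- total - k * min_len
  stopifnot(free >= 0L)
  cuts <- sort(sample.int(free + 1L, k - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, free))
  as.integer(parts + min_len)
}

#' Generate the planted ground truth
#'
#' Lays out the planted genes on a synthetic chromosome and draws their
#' true expression profiles. Construction guarantees the class-defining
#' properties: maternal classes have oocyte RPKM >= 1 (well above, so the
#' classification boundary is only approached by count noise),
#' deadenylated profiles satisfy log2(PA/RZ) <= -0.5 at the configured
#' stages, embryonic-only genes are silent in the oocyte and rise
#' >= 10-fold at a random onset stage, and stand-alone lncRNAs are
#' spliced 2-4 exon genes with their own TSS and roughly one third the
#' median expression of the coding classes. The first
#' \code{utr_fragment}-count maternal-embryonic genes double as
#' upstream-TSS rescue cases (their reference model will be 5'-truncated)
#' and the first \code{broken_gene}-count maternal-polyadenylated genes
#' as fragmented-model cases.
#'
#' @param config a \code{\link{synthetic_config}}
#' @return list of class \code{SyntheticTruth}: \code{models} (intact
#'   planted models, one per gene), \code{classes} (named class labels),
#'   \code{true_tss}, \code{profiles} (long data frame gene x stage x
#'   library of true RPKM), \code{rescue_parents}, \code{broken_parents},
#'   \code{est_genes}, \code{noise_exons}, \code{genome_length},
#'   \code{config}
#' @export
generate_truth <- function(config = synthetic_config()) {
  stopifnot(is(config, "synthetic_config"))
  with_seed(config$seed, generate_truth_impl(config))
}

generate_truth_impl <- function(config) {
  n_per <- config$n_genes
  classes <- rep(names(n_per), n_per)
  N <- length(classes)
  gene_ids <- sprintf("g%03d", seq_len(N))
  names(classes) <- gene_ids

  rescue_parents <- gene_ids[classes == "maternal_embryonic"]
  rescue_parents <- utils::head(rescue_parents, config$n_artifacts["utr_fragment"])
  broken_parents <- gene_ids[classes == "maternal_poly"]
  broken_parents <- utils::head(broken_parents, config$n_artifacts["broken_gene"])
  est_pool <- setdiff(gene_ids[classes == "maternal_embryonic"], rescue_parents)
  est_genes <- utils::head(est_pool, 2L)

  # transcript structure
  n_exons <- integer(N); tx_len <- integer(N)
  for (i in seq_len(N)) {
    g <- gene_ids[i]
    if (classes[i] == "lncRNA_standalone") {
      n_exons[i] <- sample(2:4, 1L)
      tx_len[i] <- sample(400:1200, 1L)
    } else {
      n_exons[i] <- if (g %in% rescue_parents) sample(5:6, 1L)
                    else if (g %in% broken_parents) sample(4:6, 1L)
                    else sample(3:6, 1L)
      n_sense <- sample(150:400, 1L)        # Met..last sense codon count
      tx_len[i] <- 3L * (n_sense + 1L)      # + terminal stop codon
    }
  }

  # chromosome layout: shuffled genes first, rescue parents in a distal
  # block so no lncRNA candidate acquires a promoter-less downstream
  # neighbour by accident
  main <- sample(setdiff(gene_ids, rescue_parents))
  order_ids <- c(main, rescue_parents)
  exon_sets <- vector("list", N); names(exon_sets) <- gene_ids
  strands <- setNames(sample(c("+", "-"), N, replace = TRUE), gene_ids)
  gap_regions <- NULL
  cur <- 10000L
  for (g in order_ids) {
    i <- match(g, gene_ids)
    gap <- if (g %in% rescue_parents) 12000L else sample(3000:6000, 1L)
    gap_regions <- rbind(gap_regions,
                         data.frame(start = cur + 1L, end = cur + gap - 2000L))
    cur <- cur + gap
    lens <- split_length(tx_len[i], n_exons[i])
    starts <- integer(n_exons[i]); ends <- integer(n_exons[i])
    pos <- cur
    for (j in seq_len(n_exons[i])) {
      starts[j] <- pos
      ends[j] <- pos + lens[j] - 1L
      pos <- ends[j] + sample(200:1500, 1L) + 1L
    }
    exon_sets[[g]] <- GRanges(config$chrom, IRanges(starts, ends),
                              strand = strands[g])
    cur <- max(ends)
  }
  genome_length <- cur + 5000L

  models <- gene_model_set(GRangesList(exon_sets), gene_id = gene_ids,
                           source = "reference")
  true_tss <- vapply(exon_sets, tss_position, numeric(1))

  # expression profiles
  stages <- config$stages
  oocyte <- stages[1L]
  later <- stages[-1L]
  profs <- list()
  add_prof <- function(gene, stage, lib, rpkm) {
    profs[[length(profs) + 1L]] <<- data.frame(
      gene_id = gene, stage = stage, library = lib, rpkm = rpkm,
      stringsAsFactors = FALSE)
  }
  base_level <- function() min(max(rlnorm(1, log(10), 0.6), 1.5), 80)
  early <- stages[seq_len(min(3L, length(stages)))]
  late <- setdiff(stages, early)
  for (g in gene_ids) {
    cls <- classes[g]
    if (cls == "maternal_poly") {
      B <- base_level()
      for (s in stages) {
        lev <- if (s %in% early) B else 0.5 * B
        add_prof(g, s, "PA", lev); add_prof(g, s, "RZ", lev)
      }
    } else if (cls == "maternal_deadenylated") {
      B <- base_level()
      r <- runif(1, -3, -0.5)
      for (s in stages) {
        rz <- if (s %in% early) B else 0.5 * B
        pa <- if (s == oocyte) B
              else if (s %in% config$deadenylated_stages) B * 2^r
              else 0.25 * B * 2^r
        add_prof(g, s, "PA", pa); add_prof(g, s, "RZ", rz)
      }
    } else if (cls == "maternal_embryonic") {
      B <- runif(1, 1.5, 5)
      onset <- sample(intersect(c("st9", "st12"), later), 1L)
      f <- runif(1, 15, 40)
      oi <- match(onset, stages)
      for (s in stages) {
        lev <- if (match(s, stages) >= oi) B * f else B
        add_prof(g, s, "PA", lev); add_prof(g, s, "RZ", lev)
      }
    } else if (cls == "embryonic_only") {
      onset <- sample(later[-1L], 1L,
                      prob = utils::head(c(0.35, 0.35, 0.2, 0.1),
                                         length(later) - 1L))
      L <- min(max(rlnorm(1, log(10), 0.6), 2), 80)
      oi <- match(onset, stages)
      for (s in stages) {
        si <- match(s, stages)
        lev <- if (si < oi) 0 else min(L * 1.5^(si - oi), 100)
        add_prof(g, s, "PA", lev); add_prof(g, s, "RZ", lev)
      }
    } else { # lncRNA_standalone: zygotic, about one third of coding median
      L <- min(max(rlnorm(1, log(10 / 3), 0.5), 1.5), 20)
      oi <- match("st9", stages)
      for (s in stages) {
        lev <- if (match(s, stages) >= oi) L else 0
        add_prof(g, s, "PA", lev); add_prof(g, s, "RZ", lev)
      }
    }
  }
  profiles <- do.call(rbind, profs)

  # unspliced single-exon artifact positions, parked in intergenic gaps
  k <- config$n_artifacts["unspliced_single_exon"]
  noise_exons <- GRanges()
  if (k > 0L) {
    rows <- gap_regions[sample.int(nrow(gap_regions), k), , drop = FALSE]
    st <- pmax(rows$start + 700L, rows$start)
    noise_exons <- GRanges(config$chrom, IRanges(st, st + 399L),
                           strand = sample(c("+", "-"), k, replace = TRUE))
  }

  structure(list(models = models, classes = classes, true_tss = true_tss,
                 profiles = profiles, rescue_parents = rescue_parents,
                 broken_parents = broken_parents, est_genes = est_genes,
                 noise_exons = noise_exons, genome_length = genome_length,
                 config = config),
            class = "SyntheticTruth")
}

gene_profile <- function(truth, gene, stage, lib) {
  p <- truth$profiles
  p$rpkm[p$gene_id == gene & p$stage == stage & p$library == lib]
}

# strand-aware split of a model's exons into its 5' part (n5 exons) and
# the remainder
five_prime_split <- function(exons, n5) {
  n <- length(exons)
  stopifnot(n5 < n)
  if (as.character(strand(exons))[1L] == "-") {
    list(five = exons[(n - n5 + 1L):n], rest = exons[1:(n - n5)])
  } else {
    list(five = exons[1:n5], rest = exons[(n5 + 1L):n])
  }
}

#' Emit the reference annotation and the evidence transcript set
#'
#' The reference set contains one model per planted coding gene (rescue
#' parents 5'-truncated by two exons, emulating models that miss their
#' true first exons) and omits the stand-alone lncRNAs, which are
#' therefore discoverable as new gene models. The evidence set contains
#' assembled transcripts for the lncRNAs, 5'-UTR fragments of the rescue
#' parents (their two omitted 5' exons), fragmented "broken" halves of
#' the designated parents (each sharing exact exons with the intact
#' reference model), EST-like partial duplicates of a couple of genes,
#' and unspliced single-exon models in intergenic space.
#'
#' @param truth a \code{\link{generate_truth}} result
#' @return list with \code{reference} and \code{evidence}
#'   \code{GeneModelSet}s and \code{gene_of} (named map model id ->
#'   planted gene id)
#' @export
emit_evidence <- function(truth) {
  cfg <- truth$config
  ref_ex <- list(); ref_gene <- character(0)
  ev_ex <- list(); ev_gene <- character(0); ev_src <- character(0)
  for (g in names(truth$classes)) {
    exons <- truth$models$exons[[g]]
    cls <- truth$classes[g]
    if (cls == "lncRNA_standalone") {
      ev_ex[[paste0("asm_", g)]] <- exons
      ev_gene <- c(ev_gene, setNames(g, paste0("asm_", g)))
      ev_src <- c(ev_src, "assembly")
      next
    }
    if (g %in% truth$rescue_parents) {
      sp <- five_prime_split(exons, 2L)
      ref_ex[[paste0("ref_", g)]] <- sp$rest
      ev_ex[[paste0("frag_", g)]] <- sp$five
      ev_gene <- c(ev_gene, setNames(g, paste0("frag_", g)))
      ev_src <- c(ev_src, "assembly")
    } else {
      ref_ex[[paste0("ref_", g)]] <- exons
    }
    ref_gene <- c(ref_gene, g)
    if (g %in% truth$broken_parents) {
      n <- length(exons)
      h <- n %/% 2L
      ev_ex[[paste0("brkA_", g)]] <- exons[1:h]
      ev_ex[[paste0("brkB_", g)]] <- exons[(h + 1L):n]
      ev_gene <- c(ev_gene, setNames(c(g, g),
                                     paste0(c("brkA_", "brkB_"), g)))
      ev_src <- c(ev_src, "assembly", "assembly")
    }
    if (g %in% truth$est_genes) {
      n <- length(exons)
      ev_ex[[paste0("est_", g)]] <- exons[2:n]
      ev_gene <- c(ev_gene, setNames(g, paste0("est_", g)))
      ev_src <- c(ev_src, "est")
    }
  }
  for (i in seq_along(truth$noise_exons)) {
    id <- sprintf("sx_%02d", i)
    ev_ex[[id]] <- truth$noise_exons[i]
    ev_gene <- c(ev_gene, setNames(NA_character_, id))
    ev_src <- c(ev_src, "assembly")
  }
  reference <- gene_model_set(GRangesList(ref_ex), source = "reference")
  evidence <- gene_model_set(GRangesList(ev_ex), source = ev_src)
  ref_map <- setNames(ref_gene, names(ref_ex))
  list(reference = reference, evidence = evidence,
       gene_of = c(ref_map, ev_gene))
}

#' Simulate per-exon read counts and splice junctions
#'
#' Counts follow the inverse of the RPKM formula: an exon of length L bp
#' in a library with total mapped reads T at true RPKM r receives
#' Poisson(r * L/1000 * T/1e6) reads. Identical exons shared between
#' models (fragments, broken halves, ESTs) receive one draw, reused.
#' Junctions of expressed spliced planted models get read support
#' 5 + Poisson(mean RPKM); spurious noise junctions get support 1-4.
#'
#' @param truth a \code{\link{generate_truth}} result
#' @param sets output of \code{\link{emit_evidence}} (recomputed when
#'   omitted)
#' @return list: \code{counts} (\code{exon_counts} data frame),
#'   \code{totals}, \code{junctions} (\code{GRanges} with
#'   \code{read_support})
#' @export
simulate_counts <- function(truth, sets = emit_evidence(truth)) {
  cfg <- truth$config
  with_seed(cfg$seed + 1L, simulate_counts_impl(truth, sets, cfg))
}

simulate_counts_impl <- function(truth, sets, cfg) {
  total_mapped <- cfg$depth_per_kb * 1e6
  allm <- combine_models(sets$reference, sets$evidence)
  gene_of <- sets$gene_of
  stages <- cfg$stages
  et <- exon_table(allm)
  et$gene <- unname(gene_of[et$model_id])
  # one Poisson draw per unique exon per condition; shared exons (UTR
  # fragments, broken halves, ESTs) reuse the draw of their parent exon
  uk <- et[!duplicated(et$key), c("key", "len", "gene")]
  prof <- truth$profiles
  prof_key <- paste(prof$gene_id, prof$stage, prof$library)
  cond <- expand.grid(stage = stages, library = c("PA", "RZ"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    r <- prof$rpkm[match(paste(uk$gene, cond$stage[i], cond$library[i]),
                         prof_key)]
    r[is.na(r)] <- 0
    lam <- r * (uk$len / 1000) * (total_mapped / 1e6)
    draw <- integer(length(lam))
    nz <- lam > 0
    draw[nz] <- rpois(sum(nz), lam[nz])
    blocks[[i]] <- data.frame(
      model_id = et$model_id, exon_index = et$exon_index,
      stage = cond$stage[i], library = cond$library[i],
      count = draw[match(et$key, uk$key)], stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  class(counts) <- c("exon_counts", "data.frame")
  totals <- expand.grid(stage = stages, library = c("PA", "RZ"),
                        stringsAsFactors = FALSE)
  totals$total_mapped <- total_mapped
  totals <- totals[order(match(totals$stage, stages), totals$library), ]
  rownames(totals) <- NULL

  # true junctions from the intact planted models
  jx_list <- list()
  for (g in names(truth$classes)) {
    exons <- truth$models$exons[[g]]
    if (length(exons) < 2L) next
    meanr <- mean(truth$profiles$rpkm[truth$profiles$gene_id == g])
    if (meanr <= 0) next
    intr <- introns_of(exons)
    intr$read_support <- 5L + rpois(length(intr), meanr)
    jx_list[[g]] <- intr
  }
  junctions <- unlist(GRangesList(jx_list), use.names = FALSE)
  if (cfg$n_noise_junctions > 0L) {
    pos <- sort(sample.int(truth$genome_length - 2000L,
                           cfg$n_noise_junctions)) + 500L
    noise <- GRanges(cfg$chrom, IRanges(pos, pos + sample(200:800,
                                                          cfg$n_noise_junctions,
                                                          replace = TRUE)),
                     strand = sample(c("+", "-"), cfg$n_noise_junctions,
                                     replace = TRUE),
                     read_support = sample(1:4, cfg$n_noise_junctions,
                                           replace = TRUE))
    junctions <- c(junctions, noise)
  }
  list(counts = counts, totals = totals, junctions = junctions)
}

#' Simulate H3K4me3 peaks and RNAPII coverage
#'
#' Every expressed planted gene receives a promoter peak overlapping its
#' true first exon with probability 1 - dropout; rescue parents instead
#' receive a peak strictly upstream of their 5'-UTR fragment with
#' connecting RNAPII signal at gene-body level, so upstream-TSS rescue
#' holds by construction. Unspliced and fragment artifacts get no peak of
#' their own. RNAPII covers each expressed gene's body at a constant
#' level.
#'
#' @param truth a \code{\link{generate_truth}} result
#' @return list: \code{peaks} (\code{GRanges}), \code{rnapii}
#'   (\code{GRanges} with \code{score})
#' @export
simulate_chromatin <- function(truth) {
  cfg <- truth$config
  with_seed(cfg$seed + 2L, simulate_chromatin_impl(truth, cfg))
}

simulate_chromatin_impl <- function(truth, cfg) {
  peak_list <- list(); sig_list <- list()
  body_level <- 2
  for (g in names(truth$classes)) {
    exons <- truth$models$exons[[g]]
    expressed <- any(truth$profiles$rpkm[truth$profiles$gene_id == g] > 0)
    if (!expressed) next
    st <- as.character(strand(exons))[1L]
    gstart <- min(start(exons)); gend <- max(end(exons))
    if (g %in% truth$rescue_parents) {
      if (st == "+") {
        pk <- GRanges(cfg$chrom, IRanges(gstart - 600L, gstart - 150L))
        sig <- GRanges(cfg$chrom, IRanges(gstart - 600L, gend),
                       score = body_level)
      } else {
        pk <- GRanges(cfg$chrom, IRanges(gend + 150L, gend + 600L))
        sig <- GRanges(cfg$chrom, IRanges(gstart, gend + 600L),
                       score = body_level)
      }
    } else {
      tss <- truth$true_tss[[g]]
      pk <- GRanges(cfg$chrom, IRanges(max(1L, tss - 150L), tss + 150L))
      sig <- GRanges(cfg$chrom, IRanges(gstart, gend), score = body_level)
    }
    if (rbinom(1L, 1L, 1 - cfg$h3k4me3_dropout) == 1L) {
      peak_list[[g]] <- pk
    }
    sig_list[[g]] <- sig
  }
  peaks <- if (length(peak_list)) {
    unlist(GRangesList(peak_list), use.names = FALSE)
  } else GRanges()
  rnapii <- if (length(sig_list)) {
    unlist(GRangesList(sig_list), use.names = FALSE)
  } else GRanges(score = numeric(0))
  list(peaks = peaks, rnapii = rnapii)
}

#' Sample a coding transcript sequence
#'
#' ATG, then codons drawn from the coding codon-usage table renormalised
#' over the 61 sense codons, then a stop codon drawn from the stop-class
#' distribution: a transcript whose single frame is one long ORF.
#'
#' @param n_sense number of codons from Met through the last sense codon
#' @param coding_table data frame (triplet, weight)
#' @return nucleotide string of length \code{3 * (n_sense + 1)}
#' @export
sample_coding_tx <- function(n_sense, coding_table = mzt_default_coding_table()) {
  w <- read_triplet_table(coding_table)
  aa <- Biostrings::GENETIC_CODE[names(w)]
  sense <- names(w)[aa != "*"]
  stops <- names(w)[aa == "*"]
  body <- sample(sense, n_sense - 1L, replace = TRUE, prob = w[sense])
  stop_c <- sample(stops, 1L, prob = w[stops])
  paste(c("ATG", body, stop_c), collapse = "")
}

#' Sample a noncoding sequence from the triplet background
#'
#' @param len sequence length in bp
#' @param noncoding_table data frame (triplet, weight)
#' @param max_orf optional: rejection-sample until the six-frame maximal
#'   ORF is at most this many amino acids (\code{NULL} to skip)
#' @return nucleotide string of length \code{len}
#' @export
sample_noncoding_seq <- function(len, noncoding_table = mzt_default_noncoding_table(),
                                 max_orf = NULL) {
  w <- read_triplet_table(noncoding_table)
  for (try in 1:200) {
    s <- paste(sample(names(w), ceiling(len / 3), replace = TRUE, prob = w),
               collapse = "")
    s <- substr(s, 1L, len)
    if (is.null(max_orf) || max_orf_aa(s) <= max_orf) return(s)
  }
  stop("could not sample a sequence with max ORF <= ", max_orf,
       " in 200 attempts")
}

#' Synthesize the genome sequence
#'
#' Background (intergenic and intronic) sequence is sampled triplet-wise
#' from the noncoding table; the spliced transcript of each coding-class
#' gene is sampled codon-wise from the coding table (ATG start, terminal
#' stop, single frame) and written across its exons in transcript
#' orientation; lncRNA exon sequence is noncoding with the maximal ORF
#' rejection-capped at 100 amino acids.
#'
#' @param truth a \code{\link{generate_truth}} result
#' @param coding_table,noncoding_table triplet tables (bundled defaults)
#' @return \code{DNAStringSet} with one chromosome
#' @export
synthesize_sequences <- function(truth,
                                 coding_table = mzt_default_coding_table(),
                                 noncoding_table = mzt_default_noncoding_table()) {
  cfg <- truth$config
  with_seed(cfg$seed + 3L, {
    chars <- strsplit(sample_noncoding_seq(truth$genome_length,
                                           noncoding_table), "")[[1]]
    for (g in names(truth$classes)) {
      exons <- truth$models$exons[[g]]
      txlen <- sum(width(exons))
      cls <- truth$classes[g]
      tx <- if (cls == "lncRNA_standalone") {
        sample_noncoding_seq(txlen, noncoding_table, max_orf = 100L)
      } else {
        sample_coding_tx(txlen / 3L - 1L, coding_table)
      }
      genomic <- if (as.character(strand(exons))[1L] == "-") revcomp(tx) else tx
      pieces <- strsplit(genomic, "")[[1]]
      off <- 0L
      for (j in seq_along(exons)) {
        w <- width(exons)[j]
        chars[start(exons)[j]:end(exons)[j]] <- pieces[(off + 1L):(off + w)]
        off <- off + w
      }
    }
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- cfg$chrom
    genome
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper producing every input the analysis consumes:
#' genome, reference annotation, evidence transcripts, per-exon counts,
#' library totals, splice junctions, H3K4me3 peaks, RNAPII signal -- all
#' deterministic in \code{config$seed} -- plus the planted truth.
#'
#' @param config a \code{\link{synthetic_config}}
#' @param with_genome also synthesize the genome sequence (slowest step)
#' @return list of class \code{SyntheticBundle} with components
#'   \code{truth}, \code{reference}, \code{evidence}, \code{gene_of},
#'   \code{counts}, \code{totals}, \code{junctions}, \code{peaks},
#'   \code{rnapii}, and \code{genome} (or \code{NULL})
#' @export
simulate_mzt_study <- function(config = synthetic_config(), with_genome = TRUE) {
  truth <- generate_truth(config)
  sets <- emit_evidence(truth)
  cj <- simulate_counts(truth, sets)
  chrom <- simulate_chromatin(truth)
  genome <- if (with_genome) synthesize_sequences(truth) else NULL
  structure(list(truth = truth, reference = sets$reference,
                 evidence = sets$evidence, gene_of = sets$gene_of,
                 counts = cj$counts, totals = cj$totals,
                 junctions = cj$junctions, peaks = chrom$peaks,
                 rnapii = chrom$rnapii, genome = genome),
            class = "SyntheticBundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes genome.fa, reference.gff3, evidence.gff3, counts.tsv,
#' totals.tsv, junctions.bed, h3k4me3.bed, rnapii.bedgraph and truth.tsv
#' (planted class labels) into a directory.
#'
#' @param bundle a \code{\link{simulate_mzt_study}} result
#' @param outdir output directory (created if missing)
#' @return \code{outdir}, invisibly
#' @export
write_synthetic_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$genome)) {
    Biostrings::writeXStringSet(bundle$genome, file.path(outdir, "genome.fa"))
  }
  write_gene_models(bundle$reference, file.path(outdir, "reference.gff3"))
  write_gene_models(bundle$evidence, file.path(outdir, "evidence.gff3"))
  write_counts(bundle$counts, file.path(outdir, "counts.tsv"))
  write.table(bundle$totals, file.path(outdir, "totals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_junctions(bundle$junctions, file.path(outdir, "junctions.bed"))
  write_peaks(bundle$peaks, file.path(outdir, "h3k4me3.bed"))
  write_signal(bundle$rnapii, file.path(outdir, "rnapii.bedgraph"))
  tr <- data.frame(gene_id = names(bundle$truth$classes),
                   class = unname(bundle$truth$classes),
                   true_tss = unname(bundle$truth$true_tss))
  write.table(tr, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
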