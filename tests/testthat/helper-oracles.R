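# independent reference implementations used to check the package's
# computations; deliberately simple and loop-based

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# ORF scan: for every ATG in every frame of both strands, walk codon by
# codon to the first stop; count Met..last sense codon, open ends count
orf_oracle <- function(s) {
  s <- toupper(s)
  best <- 0L
  for (str in c(s, revcomp_oracle(s))) {
    n <- nchar(str)
    for (off in 0:2) {
      starts <- seq(1 + off, n - 2, by = 3)
      if (length(starts) == 0) next
      cods <- substring(str, starts, starts + 2)
      for (i in seq_along(cods)) {
        if (cods[i] != "ATG") next
        len <- 0L
        j <- i
        while (j <= length(cods) && !(cods[j] %in% c("TAA", "TAG", "TGA"))) {
          len <- len + 1L
          j <- j + 1L
        }
        best <- max(best, len)
      }
    }
  }
  best
}

# exhaustive window enumeration: every codon-aligned 90-bp substring of
# both strands scored independently; short sequences score their single
# maximal in-frame codon run
window_oracle <- function(s, table, window_bp = 90) {
  s <- toupper(s)
  lut <- setNames(table$llr, table$codon)
  score_run <- function(str, from, n_codons) {
    tot <- 0
    for (k in seq_len(n_codons)) {
      cod <- substr(str, from + 3 * (k - 1), from + 3 * k - 1)
      v <- lut[cod]
      tot <- tot + ifelse(is.na(v), 0, v)
    }
    tot
  }
  best <- -Inf
  w <- window_bp / 3
  for (str in c(s, revcomp_oracle(s))) {
    n <- nchar(str)
    for (off in 0:2) {
      n_cod <- (n - off) %/% 3
      if (n_cod < 1) next
      if (n_cod <= w) {
        best <- max(best, score_run(str, off + 1, n_cod))
      } else {
        for (st in seq_len(n_cod - w + 1)) {
          best <- max(best, score_run(str, off + 1 + 3 * (st - 1), w))
        }
      }
    }
  }
  best
}

pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

# adjusted Rand index between two labelings
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# brute-force connected components of the shared-exon graph via igraph
grouping_oracle <- function(models) {
  ids <- model_ids(models)
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  keys <- lapply(ids, function(id) mztscope:::exon_keys(model_exons(models, id)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(keys[[i]], keys[[j]])) > 0) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- vapply(split(ids, comp), function(v) sort(v)[1], character(1))[
    as.character(comp)]
  names(out) <- ids
  out
}

# per-base conservation average
conservation_oracle <- function(exons, track) {
  vals <- c()
  for (i in seq_along(track)) {
    for (pos in start(track)[i]:end(track)[i]) {
      inside <- any(pos >= start(exons) & pos <= end(exons))
      if (inside) vals <- c(vals, track$score[i])
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}
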