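test_that("junction filtering keeps the at-least-5-reads boundary", {
  jx <- GRanges("chr1", IRanges(c(100, 200, 300), c(150, 250, 350)),
                strand = "+", read_support = c(5L, 4L, 0L))
  kept <- filter_junctions(jx)
  expect_equal(start(kept), 100)
  expect_equal(length(filter_junctions(jx[0])), 0L)
})

test_that("gene grouping is the transitive closure of exact exon sharing", {
  shared1 <- c(1000, 1200); shared2 <- c(3000, 3300)
  g <- make_set(
    A = make_model("chr1", list(shared1, c(2000, 2100))),
    B = make_model("chr1", list(shared1, shared2)),
    C = make_model("chr1", list(shared2, c(5000, 5100))),
    D = make_model("chr1", list(c(990, 1210))),          # overlaps, not equal
    E = make_model("chr1", list(shared1), strand = "-")) # same coords, other strand
  grp <- group_gene_models(g)
  expect_equal(grp[["A"]], grp[["B"]])
  expect_equal(grp[["B"]], grp[["C"]])
  expect_equal(grp[["A"]], "A")  # lexicographically smallest member
  expect_false(grp[["D"]] == grp[["A"]])
  expect_false(grp[["E"]] == grp[["A"]])
})

test_that("gene grouping matches a brute-force graph oracle on random sets", {
  skip_if_not_installed("igraph")
  set.seed(51)
  for (rep in 1:5) {
    pool <- lapply(1:30, function(i) c(i * 1000, i * 1000 + 100))
    n <- 40
    grl <- list()
    for (i in seq_len(n)) {
      k <- sample(1:3, 1)
      idx <- sort(sample(30, k))
      grl[[sprintf("m%02d", i)]] <- make_model("chr1", pool[idx])
    }
    models <- gene_model_set(GRangesList(grl))
    expect_identical(group_gene_models(models), grouping_oracle(models))
  }
})

test_that("evidence updates extend models through shared trusted junctions", {
  # model with one intron; evidence shares it and adds an upstream exon
  m <- make_set(base = make_model("chr1", list(c(2000, 2200), c(3000, 3200))))
  ev_ok <- make_set(ev1 = make_model("chr1", list(c(1000, 1100),
                                                  c(2100, 2200), c(3000, 3100))),
                    source = "assembly")
  jx <- introns_of(model_exons(m, "base"))
  jx$read_support <- 10L
  upd <- update_models_with_evidence(m, ev_ok, jx)
  ex <- model_exons(upd, "base")
  expect_equal(length(ex), 3L)
  expect_equal(start(ex)[1], 1000)
  expect_equal(upd$meta$source[1], "updated")
  expect_equal(attr(upd, "updates")$placement, "five_prime")
  # original exons are never removed
  expect_true(all(mztscope:::exon_keys(model_exons(m, "base")) %in%
                    mztscope:::exon_keys(ex)))

  # opposite strand: no update
  ev_minus <- make_set(ev2 = make_model("chr1", list(c(1000, 1100),
                                                     c(2100, 2200), c(3000, 3100)),
                                        strand = "-"), source = "assembly")
  upd2 <- update_models_with_evidence(m, ev_minus, jx)
  expect_equal(length(model_exons(upd2, "base")), 2L)

  # no shared junction: no update
  ev_far <- make_set(ev3 = make_model("chr1", list(c(1000, 1100), c(1500, 1600))),
                     source = "assembly")
  upd3 <- update_models_with_evidence(m, ev_far, jx)
  expect_equal(length(model_exons(upd3, "base")), 2L)

  # junction below the trust threshold does not link
  jx_low <- jx; jx_low$read_support <- 4L
  upd4 <- update_models_with_evidence(m, ev_ok, filter_junctions(jx_low))
  expect_equal(length(model_exons(upd4, "base")), 2L)
})

test_that("the expression rule compares the exon fraction exactly", {
  expect_true(is_expressed(c(3, 0, 0)))       # exactly 1/3
  expect_false(is_expressed(c(3, 0, 0, 0)))   # 1/4 < 1/3
  expect_false(is_expressed(c(2, 2, 2)))      # below the read floor
  expect_false(is_expressed(c(0, 0, 0)))
  expect_true(is_expressed(c(5)))
  expect_error(is_expressed(numeric(0)), "zero exons")
})

test_that("TSS validation is first-exon, strand-aware, one-base overlap", {
  plus <- make_model("chr1", list(c(1000, 1200), c(2000, 2200)))
  minus <- make_model("chr1", list(c(1000, 1200), c(2000, 2200)), strand = "-")
  # 1-bp overlap with the first exon validates
  expect_true(validate_tss(plus, GRanges("chr1", IRanges(900, 1000))))
  expect_false(validate_tss(plus, GRanges("chr1", IRanges(900, 999))))
  # peak over an internal exon does not validate
  expect_false(validate_tss(plus, GRanges("chr1", IRanges(2000, 2100))))
  # minus strand: the first exon is the rightmost
  expect_true(validate_tss(minus, GRanges("chr1", IRanges(2100, 2300))))
  expect_false(validate_tss(minus, GRanges("chr1", IRanges(1000, 1100))))
  un <- make_model("chr1", list(c(1, 100)), strand = "*")
  expect_error(validate_tss(un, GRanges()), "stranded")
})

test_that("upstream rescue enforces the RNAPII ratio and clear-region rules", {
  gene <- make_model("chr1", list(c(5000, 5200), c(6000, 6200)))
  peak <- GRanges("chr1", IRanges(3000, 3400))
  body_sig <- GRanges("chr1", IRanges(5000, 6200), score = 2)
  mk_sig <- function(level) {
    c(GRanges("chr1", IRanges(3401, 4999), score = level), body_sig)
  }
  # ratio exactly 0.5 rescues
  res <- rescue_upstream_tss(gene, peak, mk_sig(1.0), GRanges())
  expect_false(is.null(res))
  expect_equal(res$tss, 3400)
  # ratio below 0.5 does not
  expect_null(rescue_upstream_tss(gene, peak, mk_sig(0.8), GRanges()))
  # a different gene's model in between blocks the rescue
  blocker <- GRanges("chr1", IRanges(4000, 4300))
  expect_null(rescue_upstream_tss(gene, peak, mk_sig(1.0), blocker))
  # peaks beyond the search cap are ignored
  cfg <- xtev_config(max_upstream_search = 1000L)
  expect_null(rescue_upstream_tss(gene, peak, mk_sig(1.0), GRanges(),
                                  config = cfg))
  # minus strand: upstream is to the right
  gene_m <- make_model("chr1", list(c(5000, 5200), c(6000, 6200)), strand = "-")
  peak_m <- GRanges("chr1", IRanges(8000, 8400))
  sig_m <- c(GRanges("chr1", IRanges(5000, 6200), score = 2),
             GRanges("chr1", IRanges(6201, 7999), score = 1.5))
  res_m <- rescue_upstream_tss(gene_m, peak_m, sig_m, GRanges())
  expect_false(is.null(res_m))
  expect_equal(res_m$tss, 8000)
})

test_that("downstream alternative-TSS flags stay within the model span", {
  m3 <- make_model("chr1", list(c(1000, 1200), c(2000, 2200), c(3000, 3200)))
  expect_true(flag_downstream_alt_tss(m3, GRanges("chr1", IRanges(2050, 2150))))
  expect_false(flag_downstream_alt_tss(m3, GRanges("chr1", IRanges(1000, 1150))))
  # beyond the 3' end of the model: not flagged
  expect_false(flag_downstream_alt_tss(m3, GRanges("chr1", IRanges(3300, 3500))))
  # minus strand: downstream is leftward
  m3m <- make_model("chr1", list(c(1000, 1200), c(2000, 2200), c(3000, 3200)),
                    strand = "-")
  expect_true(flag_downstream_alt_tss(m3m, GRanges("chr1", IRanges(1100, 1300))))
  expect_false(flag_downstream_alt_tss(m3m, GRanges("chr1", IRanges(3100, 3300))))
})

test_that("representative selection follows the stated priority order", {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  # validated TSS beats many exons
  expect_equal(select_representative(df(
    model_id = c("noV", "withV"), tss_ok = c(FALSE, TRUE),
    n_expressed_exons = c(9, 1), n_exons = c(9, 2),
    span_width = c(9000, 2000))), "withV")
  # among validated: expressed exons decide
  expect_equal(select_representative(df(
    model_id = c("a", "b"), tss_ok = c(TRUE, TRUE),
    n_expressed_exons = c(3, 5), n_exons = c(8, 5),
    span_width = c(1, 1))), "b")
  # then raw exon count
  expect_equal(select_representative(df(
    model_id = c("a", "b"), tss_ok = c(TRUE, TRUE),
    n_expressed_exons = c(3, 3), n_exons = c(4, 6),
    span_width = c(1, 1))), "b")
  # full tie: longest span, then smallest id
  expect_equal(select_representative(df(
    model_id = c("a", "b"), tss_ok = c(TRUE, TRUE),
    n_expressed_exons = c(3, 3), n_exons = c(4, 4),
    span_width = c(100, 900))), "b")
  expect_equal(select_representative(df(
    model_id = c("b", "a"), tss_ok = c(TRUE, TRUE),
    n_expressed_exons = c(3, 3), n_exons = c(4, 4),
    span_width = c(100, 100))), "a")
  expect_error(select_representative(df(model_id = character(0),
                                        tss_ok = logical(0),
                                        n_expressed_exons = numeric(0),
                                        n_exons = numeric(0),
                                        span_width = numeric(0))), "empty")
})

test_that("NGM discovery excludes unspliced models and any exonic overlap", {
  ref <- make_set(r1 = make_model("chr1", list(c(10000, 10500), c(11000, 11500))))
  cand <- make_set(
    clean = make_model("chr1", list(c(20000, 20200), c(21000, 21200))),
    onebp = make_model("chr1", list(c(9800, 10000), c(10600, 10800))),
    single = make_model("chr1", list(c(30000, 30400))),
    anti = make_model("chr1", list(c(10400, 10600), c(11000, 11100)),
                      strand = "-"),
    source = "assembly")
  res <- identify_ngm(cand, ref)
  expect_setequal(res$ngm, "clean")  # 1-bp overlap disqualifies, strand-blind
  expect_setequal(res$single_exon_excluded, "single")
  # same-strand mode re-admits the antisense transcript
  res2 <- identify_ngm(cand, ref, xtev_config(ngm_same_strand = TRUE))
  expect_setequal(res2$ngm, c("clean", "anti"))
})

test_that("NGM-vv requires expression or EST support plus a validated TSS", {
  ngm <- c("a", "b", "c", "d")
  expressed <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  est <- c(a = FALSE, b = FALSE, c = TRUE, d = FALSE)
  tssv <- c(a = TRUE, b = FALSE, c = TRUE, d = TRUE)
  expect_setequal(classify_ngm_vv(ngm, expressed, est, tssv), c("a", "c"))
  # strict mode: both kinds of evidence required
  expect_setequal(
    classify_ngm_vv(ngm, expressed, est, tssv,
                    xtev_config(require_both_evidence = TRUE)),
    character(0))
})

test_that("the full pipeline recovers planted structure on the synthetic study", {
  b <- default_bundle()
  xr <- default_xtev()
  # NGM-vv equals the planted stand-alone lncRNA set exactly
  expect_setequal(xr$ngm_vv, planted_lnc_models(b))
  # no 5'-UTR fragment or broken-gene half contaminates NGM-vv
  expect_length(grep("^(frag|brk)", xr$ngm_vv), 0)
  # unspliced artifacts all land in the excluded list
  expect_setequal(xr$single_exon_excluded,
                  grep("^sx_", model_ids(b$evidence), value = TRUE))
  # broken halves group with their intact parent; the parent wins selection
  for (g in b$truth$broken_parents) {
    rows <- xr$meta[xr$meta$model_id %in%
                      paste0(c("ref_", "brkA_", "brkB_"), g), ]
    expect_equal(length(unique(rows$gene_id)), 1L)
    expect_identical(rows$model_id[rows$selected], paste0("ref_", g))
  }
  # rescue parents carry U; their putative TSS lies upstream of the model
  for (g in b$truth$rescue_parents) {
    row <- xr$meta[xr$meta$model_id == paste0("ref_", g), ]
    expect_equal(row$tss_status, "U")
  }
  # every input model appears exactly once in the result table
  expect_setequal(xr$meta$model_id,
                  c(model_ids(b$reference), model_ids(b$evidence)))
  expect_false(anyDuplicated(xr$meta$model_id) > 0)
  # exactly one SELECTED per gene among annotation models
  ann <- xr$meta[xr$meta$role != "candidate", ]
  expect_true(all(tapply(ann$selected, ann$gene_id, sum) == 1))
})

test_that("the selected annotation is a fixed point of the pipeline", {
  b <- default_bundle()
  xr <- default_xtev()
  ann <- xr$meta[xr$meta$role != "candidate" & xr$meta$selected, ]
  selected <- subset_models(xr$collection, ann$model_id)
  selected$meta$gene_id <- NA_character_
  xr2 <- run_xtev(selected, b$evidence, b$junctions, b$counts, b$peaks,
                  b$rnapii)
  m1 <- xr$meta[match(ann$model_id, xr$meta$model_id), ]
  m2 <- xr2$meta[match(ann$model_id, xr2$meta$model_id), ]
  expect_identical(m1$tss_status, m2$tss_status)
  expect_identical(m1$expressed, m2$expressed)
  expect_true(all(m2$selected))
  expect_setequal(xr2$ngm_vv, xr$ngm_vv)
})

test_that("raising evidence thresholds never grows expressed or NGM-vv sets", {
  b <- default_bundle()
  x_loose <- default_xtev()
  x_tight <- run_xtev(b$reference, b$evidence, b$junctions, b$counts,
                      b$peaks, b$rnapii,
                      xtev_config(min_junction_reads = 8L,
                                  expressed_min_reads = 30000L))
  expect_true(all(x_tight$meta$model_id[x_tight$meta$expressed] %in%
                    x_loose$meta$model_id[x_loose$meta$expressed]))
  expect_true(all(x_tight$ngm_vv %in% x_loose$ngm_vv))
})

test_that("peak dropout translates into the expected V rate", {
  xr <- dropout_xtev()
  b <- dropout_bundle()
  t <- b$truth
  # planted genes carrying their own promoter peak draw: reference
  # non-rescue genes plus lncRNA candidates
  own_peak_models <- c(
    paste0("ref_", setdiff(names(t$classes)[t$classes != "lncRNA_standalone"],
                           t$rescue_parents)),
    planted_lnc_models(b))
  rows <- xr$meta[match(own_peak_models, xr$meta$model_id), ]
  rows <- rows[rows$expressed, ]
  v_rate <- mean(rows$tss_status == "V")
  p <- 1 - 0.2
  sigma <- sqrt(p * (1 - p) / nrow(rows))
  expect_lt(abs(v_rate - p), 3 * sigma)
})
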