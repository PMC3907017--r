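simple_em <- function(rpkm_by_cond, stages) {
  # build an ExpressionMatrix directly from a named list of per-condition
  # vectors, for boundary tests that need exact RPKM values
  mat <- do.call(cbind, rpkm_by_cond)
  conds <- do.call(rbind, strsplit(names(rpkm_by_cond), "\\."))
  structure(list(rpkm = mat,
                 conditions = data.frame(stage = conds[, 1],
                                         library = conds[, 2]),
                 stages = stages),
            class = "ExpressionMatrix")
}

test_that("exon RPKM follows the closed form and genes average non-redundant exons", {
  g <- make_set(m1 = make_model("chr1", list(c(1, 1000))))
  ct <- make_counts(data.frame(model_id = "m1", exon_index = 1,
                               stage = "oocyte", library = "PA", count = 10))
  expect_equal(unname(compute_gene_rpkm(ct, g, 1e6, "oocyte", "PA")), 10)
  expect_error(compute_gene_rpkm(ct, g, 0, "oocyte", "PA"), "positive")

  # gene RPKM is the mean over exon RPKMs: exons at 4 and 6 give 5
  g2 <- make_set(m2 = make_model("chr1", list(c(1, 1000), c(2001, 3000))))
  ct2 <- make_counts(data.frame(model_id = "m2", exon_index = 1:2,
                                stage = "oocyte", library = "PA",
                                count = c(4, 6)))
  expect_equal(unname(compute_gene_rpkm(ct2, g2, 1e6, "oocyte", "PA")), 5)

  # an exon shared between two isoforms of one gene contributes once:
  # exon RPKMs {A=4 (shared), B=6} average to 5, not (4+4+6)/3
  iso <- gene_model_set(GRangesList(
    i1 = make_model("chr1", list(c(1, 1000))),
    i2 = make_model("chr1", list(c(1, 1000), c(2001, 3000)))),
    gene_id = c("g", "g"))
  ct3 <- make_counts(data.frame(
    model_id = c("i1", "i2", "i2"), exon_index = c(1, 1, 2),
    stage = "oocyte", library = "PA", count = c(4, 4, 6)))
  expect_equal(unname(compute_gene_rpkm(ct3, iso, 1e6, "oocyte", "PA")), 5)
})

test_that("RPKM is linear in counts and inversely linear in library size", {
  set.seed(21)
  g <- gene_model_set(GRangesList(
    a = make_model("chr1", list(c(1, 500), c(1001, 1800))),
    b = make_model("chr1", list(c(5001, 5300)), strand = "-")))
  base <- data.frame(model_id = c("a", "a", "b"), exon_index = c(1, 2, 1),
                     stage = "s", library = "PA",
                     count = sample(5:50, 3))
  r1 <- compute_gene_rpkm(make_counts(base), g, 2e6, "s", "PA")
  doubled <- base; doubled$count <- doubled$count * 2L
  r2 <- compute_gene_rpkm(make_counts(doubled), g, 2e6, "s", "PA")
  expect_equal(r2, 2 * r1)
  r3 <- compute_gene_rpkm(make_counts(base), g, 4e6, "s", "PA")
  expect_equal(r3, r1 / 2)
})

test_that("PA/RZ log ratios respect the pseudocount contract", {
  em <- simple_em(list(oocyte.PA = c(g1 = 5, g2 = 1, g3 = 0),
                       oocyte.RZ = c(g1 = 5, g2 = 2, g3 = 0)), "oocyte")
  r <- log2_pa_rz(em, "oocyte", pseudocount = 1e-9)
  expect_equal(unname(r["g1"]), 0)
  expect_equal(unname(r["g2"]), -1, tolerance = 1e-6)
  expect_equal(unname(r["g3"]), 0)  # 0/0 is symmetric under pseudocount
  expect_error(log2_pa_rz(em, "st6"), "not present")
  expect_error(log2_pa_rz(em, "oocyte", pseudocount = -1))
})

boundary_em <- function() {
  # hand-built 12-gene table covering every classification boundary
  stages <- c("oocyte", "st6", "st9", "st12")
  pa <- rbind(
    m_pa_edge    = c(1.00, 1, 1, 1),     # maternal via PA exactly at 1
    m_rz_edge    = c(0.50, 1, 1, 1),     # maternal via RZ exactly at 1
    m_below      = c(0.99, 1, 1, 1),     # just below in both -> not maternal
    e_edge       = c(0.50, 0.5, 5.0, 1), # exactly 10-fold at st9
    e_below      = c(0.50, 0.5, 4.9, 1), # 9.8-fold -> not embryonic
    e_fromzero   = c(0.00, 0, 3, 0),     # 0 -> 3: pseudocount fold >> 10
    rz_at_edge   = c(2.00, 2, 2, 2),     # ratio exactly -0.5 at st6
    rz_above     = c(2.00, 2, 2, 2),     # ratio -0.49 -> excluded
    rz_notmat    = c(0.20, 0.2, 0.2, 0.2), # deep ratio but not maternal
    quiet        = c(0.00, 0, 0, 0),
    m_and_e      = c(2.00, 2, 40, 40),   # maternal-embryonic
    m_flat       = c(8.00, 8, 8, 8))
  rz <- rbind(
    m_pa_edge    = c(0.00, 1, 1, 1),
    m_rz_edge    = c(1.20, 1, 1, 1),
    m_below      = c(0.99, 1, 1, 1),
    e_edge       = c(0.50, 0.5, 5.0, 1),
    e_below      = c(0.50, 0.5, 4.9, 1),
    e_fromzero   = c(0.00, 0, 3, 0),
    rz_at_edge   = c(2.00, 2 * 2^0.5, 2, 2),
    rz_above     = c(2.00, 2 * 2^0.49, 2, 2),
    rz_notmat    = c(0.20, 0.8, 0.2, 0.2),
    quiet        = c(0.00, 0, 0, 0),
    m_and_e      = c(2.00, 2, 40, 40),
    m_flat       = c(8.00, 8, 8, 8))
  cols <- c(paste0(stages, ".PA"), paste0(stages, ".RZ"))
  mat <- cbind(pa, rz)
  colnames(mat) <- cols
  simple_em(setNames(lapply(seq_len(ncol(mat)), function(i) mat[, i]), cols),
            stages)
}

test_that("maternal, embryonic and RZ-enriched calls hit their exact boundaries", {
  em <- boundary_em()
  # zero pseudocount keeps the planted ratios exactly on the boundaries
  pc <- 0
  maternal <- select_maternal(em)
  expect_setequal(maternal,
                  c("m_pa_edge", "m_rz_edge", "rz_at_edge", "rz_above",
                    "m_and_e", "m_flat"))
  embryonic <- select_embryonic(em, pseudocount = pc)
  expect_setequal(embryonic, c("e_edge", "e_fromzero", "m_and_e"))
  # 0 -> 3 with the default pseudocount: (3.01)/(0.01) = 301-fold
  expect_true("e_fromzero" %in% select_embryonic(em, pseudocount = 0.01))
  rz6 <- select_rz_enriched(em, "st6", pseudocount = pc)
  expect_true("rz_at_edge" %in% rz6)    # ratio exactly -0.5 included
  expect_false("rz_above" %in% rz6)     # ratio -0.49 excluded
  expect_false("rz_notmat" %in% rz6)    # deep ratio but not maternal
  expect_true("rz_notmat" %in%
                select_rz_enriched(em, "st6", pseudocount = pc,
                                   require_maternal = FALSE))
})

test_that("selections shrink as thresholds tighten", {
  b <- default_bundle()
  em <- expression_matrix(b$counts, assign_gene_ids(b$reference), b$totals)
  m1 <- select_maternal(em, threshold = 1)
  m2 <- select_maternal(em, threshold = 2)
  expect_true(all(m2 %in% m1))
  e1 <- select_embryonic(em, fold = 10)
  e2 <- select_embryonic(em, fold = 20)
  expect_true(all(e2 %in% e1))
  r1 <- select_rz_enriched(em, "st6", threshold = -0.5)
  r2 <- select_rz_enriched(em, "st6", threshold = -1)
  expect_true(all(r2 %in% r1))
})

test_that("planted maternal and embryonic labels are recovered from counts", {
  b <- default_bundle()
  em <- expression_matrix(b$counts, assign_gene_ids(b$reference), b$totals)
  rows <- rownames(em$rpkm)
  planted <- sub("^ref_", "", rows)
  cls <- b$truth$classes[planted]
  truth_mat <- cls %in% c("maternal_poly", "maternal_deadenylated",
                          "maternal_embryonic")
  truth_emb <- cls %in% c("maternal_embryonic", "embryonic_only")
  called_mat <- rows %in% select_maternal(em)
  called_emb <- rows %in% select_embryonic(em)
  acc <- mean(c(called_mat == truth_mat, called_emb == truth_emb))
  expect_gte(acc, 0.95)
  # deadenylated recovery at the designated stages (boundary genes may
  # flip by Poisson noise; planted ratios reach to the -0.5 edge)
  rz <- select_rz_enriched(em, "st6")
  dead <- rows[cls == "maternal_deadenylated"]
  expect_gte(length(intersect(rz, dead)) / length(dead), 0.8)
})

test_that("row scaling normalises profiles and flags silent genes", {
  m <- rbind(a = c(2, 2, 4), b = c(7, 0, 0), c = c(0, 0, 0))
  s <- scale_rows(m)
  expect_equal(s["a", ], c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  expect_equal(unname(rowSums(s)[c("a", "b")]), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(s["c", ]), c(0, 0, 0))
  expect_equal(unname(attr(s, "flagged_zero")), c(FALSE, FALSE, TRUE))
  expect_equal(unname(scale_rows(matrix(7, 1, 1))[1, 1]), 1)
})

test_that("k-means clustering is seed-deterministic and recovers planted groups", {
  set.seed(31)
  g1 <- matrix(rep(c(10, 10, 1, 1, 1, 1), each = 20), nrow = 20) +
    matrix(rnorm(120, sd = 0.1), nrow = 20)
  g2 <- matrix(rep(c(1, 1, 1, 1, 10, 10), each = 20), nrow = 20) +
    matrix(rnorm(120, sd = 0.1), nrow = 20)
  mat <- abs(rbind(g1, g2))
  rownames(mat) <- paste0("g", 1:40)
  truth <- rep(1:2, each = 20)
  r1 <- cluster_kmeans(mat, k = 2, seed = 9, transform = "scaled")
  r2 <- cluster_kmeans(mat, k = 2, seed = 9, transform = "scaled")
  expect_identical(r1$labels, r2$labels)
  expect_equal(ari_oracle(r1$labels, truth), 1)
  expect_equal(unname(cluster_kmeans(mat, k = 1, seed = 1)$labels),
               rep(1L, 40))
  expect_error(cluster_kmeans(mat, k = 41, seed = 1), "k must be")
})

test_that("correlation matrices match the textbook formulas", {
  # worked cases
  m <- cbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(1, 4, 9))
  cc <- correlation_matrix(m, "pearson")
  expect_equal(cc["x", "x"], 1)
  expect_equal(cc["x", "y"], 1)
  expect_lt(cc["x", "z"], 1)
  cs <- correlation_matrix(m, "spearman")
  expect_equal(cs["x", "z"], 1)
  # zero-variance condition reported missing
  m2 <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_true(is.na(correlation_matrix(m2)["a", "b"]))
  # random matrices against the brute-force implementation
  set.seed(41)
  for (i in 1:5) {
    mm <- matrix(runif(60), nrow = 10, ncol = 6,
                 dimnames = list(NULL, paste0("c", 1:6)))
    cp <- correlation_matrix(mm, "pearson")
    cs <- correlation_matrix(mm, "spearman")
    for (a in 1:6) for (b in 1:6) {
      expect_equal(cp[a, b], pearson_oracle(mm[, a], mm[, b]),
                   tolerance = 1e-12)
      expect_equal(cs[a, b], spearman_oracle(mm[, a], mm[, b]),
                   tolerance = 1e-12)
    }
  }
})

test_that("induction timing and peak-stage fractions count genes correctly", {
  stages <- c("oocyte", "st6", "st9", "st12", "st16", "st30")
  prof <- rbind(
    a = c(1, 1, 4, 4, 4, 4),   # first reaches 4-fold at st9
    b = c(1, 1, 4, 4, 4, 4),   # st9
    c = c(1, 1, 1, 4, 4, 4),   # st12
    d = c(1, 1, 1, 1, 1, 4))   # st30
  cols <- paste0(stages, ".PA")
  em <- simple_em(setNames(lapply(seq_along(cols),
                                  function(i) prof[, i]), cols), stages)
  timing <- induction_timing(em, rownames(prof), fold = 4, pseudocount = 0)
  expect_equal(unname(timing["st9"]), 0.5)
  expect_equal(unname(timing["st6"]), 0)
  expect_equal(unname(timing["st30"]), 1)
  expect_error(induction_timing(em, character(0)), "empty")

  pk <- peak_stage_fractions(em, rownames(prof))
  expect_equal(sum(pk), 1)
  # flat gene peaks at the earliest stage by the tie rule
  em2 <- simple_em(setNames(lapply(seq_along(cols),
                                   function(i) c(flat = 2)), cols), stages)
  expect_equal(unname(peak_stage_fractions(em2, "flat")["oocyte"]), 1)
})

test_that("ddCt fold changes follow the 2^-ddCt rule", {
  df <- data.frame(
    gene = c("x", "x", "odc1", "odc1"),
    stage = c("st9", "st12", "st9", "st12"),
    ct = c(22, 20, 18, 18))
  q <- qpcr_table(df, "odc1", "st9")
  fc <- ddct_fold_change(q)
  # reference stage against itself: fold 1
  expect_equal(fc$fold[fc$stage == "st9"], 1)
  # dCt 2 at st12 vs dCt 4 at reference: ddCt -2, fold 4
  expect_equal(fc$fold[fc$stage == "st12"], 4)
  # ddCt of +1 halves the signal
  df2 <- data.frame(gene = c("y", "y", "n", "n"),
                    stage = c("r", "s", "r", "s"),
                    ct = c(20, 21, 20, 20))
  fc2 <- ddct_fold_change(qpcr_table(df2, "n", "r"))
  expect_equal(fc2$fold[fc2$stage == "s"], 0.5)
  # missing normalizer is an error
  df3 <- data.frame(gene = c("x", "x", "odc1"),
                    stage = c("st9", "st12", "st9"), ct = c(22, 20, 18))
  expect_error(qpcr_table(df3, "odc1", "st9"), "missing")
})
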