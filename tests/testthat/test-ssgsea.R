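# The single-sample enrichment engine: exhaustive equivalence with the
# direct-summation oracle, rank-only dependence, directional monotonicity and
# replicate stability.

test_that("rank_genes ranks largest-first with average ties", {
  expect_equal(unname(rank_genes(c(a = 5, b = 1, c = 3))), c(3, 1, 2))
  expect_equal(unname(rank_genes(c(a = 2, b = 2, c = 2))), rep(2, 3))
  v <- c(a = 1, b = 4, c = 2, d = NA)
  expect_equal(names(rank_genes(v)), c("a", "b", "c"))
  expect_equal(rank_genes(exp(v[1:3])), rank_genes(v[1:3]))
  expect_error(rank_genes(c(a = NA, b = NA)), "non-missing")
})

test_that("ssgsea_es equals the direct-summation oracle on small instances", {
  # hand-enumerable 4-gene case, singleton set at the top rank, alpha = 0:
  # positions (desc rank): in-set ECDF 1,1,1,1; out ECDF 0,1/3,2/3,1
  v <- c(g1 = 9, g2 = 5, g3 = 3, g4 = 1)
  expect_equal(ssgsea_es(v, "g1", ssgsea_params(alpha = 0)),
               (1 - 0) + (1 - 1 / 3) + (1 - 2 / 3) + (1 - 1))
  set.seed(31)
  for (i in 1:5) {
    vals <- setNames(rnorm(6), sprintf("g%d", 1:6))
    for (k in 1:4) {
      sub <- sample(names(vals), k)
      for (al in c(0, 0.75, 1.5)) {
        expect_equal(ssgsea_es(vals, sub, ssgsea_params(alpha = al)),
                     oracle_es(vals, sub, al), tolerance = 1e-12)
      }
    }
  }
})

test_that("ssgsea_es symmetry, rank-dependence and error contracts", {
  v <- setNames(7:1, letters[1:7])
  p0 <- ssgsea_params(alpha = 0)
  expect_equal(ssgsea_es(v, c("a", "b"), p0), -ssgsea_es(v, c("f", "g"), p0))
  # invariant under strictly monotone transforms
  expect_equal(ssgsea_es(exp(v / 2), c("a", "d"), ssgsea_params()),
               ssgsea_es(v, c("a", "d"), ssgsea_params()))
  expect_error(ssgsea_es(v, c("zz")), "missing")
  expect_error(ssgsea_es(v, letters[1:7]), "complement")
})

test_that("score_signature is maximal when up genes top the ranking", {
  # exhaustive over all 720 permutations of one sample's values (6 genes)
  genes <- sprintf("g%d", 1:6)
  sig <- signature_gene_set("s", up = c("g1", "g2"), dn = c("g5", "g6"))
  vals <- c(70, 60, 40, 30, 20, 10)
  perms <- all_perms(6)
  params <- ssgsea_params(alpha = 0.75)
  scores <- apply(perms, 1, function(idx) {
    m <- matrix(vals[idx], ncol = 1, dimnames = list(genes, "s1"))
    score_signature(expression_matrix(m), sig, params)[[1]]
  })
  # identity permutation: up genes hold the top ranks, dn genes the bottom
  ident <- which(apply(perms, 1, function(p) all(p == 1:6)))
  expect_equal(max(scores), scores[ident])
  expect_equal(min(scores),
               scores[which(apply(perms, 1, function(p) all(p == 6:1)))])
})

test_that("directional score is monotone in an up-gene's expression", {
  genes <- sprintf("g%d", 1:8)
  sig <- signature_gene_set("s", up = c("g1", "g2"), dn = c("g7", "g8"))
  set.seed(37)
  for (i in 1:10) {
    base <- setNames(rnorm(8, 8), genes)
    lo <- hi <- base
    hi["g1"] <- hi["g1"] + runif(1, 0.1, 3)
    m <- expression_matrix(cbind(s_lo = lo, s_hi = hi))
    sc <- score_signature(m, sig)
    expect_gte(sc[["s_hi"]], sc[["s_lo"]])
  }
})

test_that("identical rank vectors give identical scores; replicates are stable", {
  expr <- tiny_expr(60, 2, seed = 41)
  m <- unclass(expr)
  m[, 2] <- 2 * m[, 1] + 5  # same ranks as sample 1
  sig <- signature_gene_set("s", up = rownames(m)[1:3], dn = rownames(m)[4:9])
  sc <- score_signature(expression_matrix(m), sig)
  expect_equal(sc[[1]], sc[[2]])
  # duplicate a cohort with small noise: replicate score correlation >= 0.9
  set.seed(43)
  base <- matrix(rnorm(500 * 30, 8, 1.5), 500, 30,
                 dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:30)))
  rep2 <- base + rnorm(length(base), 0, 0.05)
  colnames(rep2) <- sprintf("r%02d", 1:30)
  sig2 <- signature_gene_set("s", up = rownames(base)[1:3],
                             dn = rownames(base)[4:13])
  s_a <- score_signature(expression_matrix(base), sig2)
  s_b <- score_signature(expression_matrix(rep2), sig2)
  expect_gte(cor(s_a, s_b), 0.9)
})

test_that("score_signature overlap guards fire at the documented levels", {
  expr <- tiny_expr(10, 3)
  sig <- signature_gene_set("s", up = c("g01", "nope"), dn = "g02")
  expect_warning(score_signature(expr, sig), "absent")
  sig2 <- signature_gene_set("s", up = c("x1", "x2"), dn = c("x3", "g01"))
  expect_error(suppressWarnings(score_signature(expr, sig2)), "missing")
})

test_that("score_collection matches per-sample ES and permutes consistently", {
  expr <- tiny_expr(30, 5, seed = 47)
  sets <- gene_set_collection(list(A = rownames(expr)[1:4],
                                   B = rownames(expr)[5:10]))
  es <- score_collection(expr, sets)
  expect_equal(dim(es), c(2L, 5L))
  for (j in 1:5) {
    expect_equal(es["A", j], ssgsea_es(expr[, j], sets$A))
  }
  perm <- c(3, 1, 5, 2, 4)
  es_p <- score_collection(expression_matrix(unclass(expr)[, perm]), sets)
  expect_equal(es_p, es[, perm])
  expect_warning(
    es2 <- score_collection(expr, gene_set_collection(
      list(A = rownames(expr)[1:4], Z = c("none1", "none2")))),
    "no expressed gene")
  expect_equal(rownames(es2), "A")
  # 48-set collection has the contracted shape
  cfg <- generator_config(n_genes = 1400, n_panel = 100)
  fp <- generate_feature_panels(cfg, 5)
  es48 <- score_collection(fp$expr, fp$hallmarks)
  expect_equal(dim(es48), c(48L, 100L))
  expect_true(all(is.finite(es48)))
})
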