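# Independent brute-force oracles.  These deliberately avoid the code paths
# they check: exhaustive enumeration, explicit sums, direct formulas.

# Two-sided paired signed-rank p by exhaustive enumeration over all 2^n sign
# assignments of the absolute-difference ranks.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mid <- sum(r) / 2
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, 1)
  mean(abs(vs - mid) >= abs(v_obs - mid))
}

# Two-sided Mann-Whitney p by exhaustive enumeration over all C(n, na)
# assignments of the pooled ranks to group a.
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  us <- combn(length(pooled), na, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Kruskal-Wallis H by the rank-sum formula with tie correction.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) * sum(vapply(splits, function(ri)
    length(ri) * (mean(ri) - (n + 1) / 2)^2, 1))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Group-effect F for a balanced two-factor additive design by explicit sums
# of squares.
oracle_anova_f <- function(values, group, block) {
  group <- factor(group); block <- factor(block)
  n <- length(values)
  gm <- mean(values)
  ss_group <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ss_block <- sum(tapply(values, block, function(v) length(v) * (mean(v) - gm)^2))
  cellmeans <- tapply(values, list(group, block), mean)
  fitted <- outer(tapply(values, group, mean) - gm,
                  tapply(values, block, mean) - gm, "+") + gm
  ss_res <- sum((values - fitted[cbind(group, block)])^2)
  df_res <- n - nlevels(group) - nlevels(block) + 1
  (ss_group / (nlevels(group) - 1)) / (ss_res / df_res)
}

# Cox partial log-likelihood for a single covariate, distinct event times
# (no ties, so Breslow = Efron).
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Direct double-summation ssGSEA ES: recompute both running ECDFs from
# scratch at every position.
oracle_es <- function(values, set, alpha) {
  r <- rank(values, ties.method = "average")
  ord <- order(-r, names(values))
  in_set <- names(values) %in% set
  w <- r^alpha
  sw <- sum(w[in_set]); nout <- sum(!in_set)
  es <- 0
  for (pos in seq_along(ord)) {
    idx <- ord[seq_len(pos)]
    es <- es + sum(w[idx][in_set[idx]]) / sw - sum(!in_set[idx]) / nout
  }
  es
}

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Small deterministic expression fixture.
tiny_expr <- function(n_genes = 6, n_samples = 4, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m)
}

# Simple survival frame helper.
surv_frame <- function(time, event, age = 60, node = 0, tumor = 0) {
  n <- length(time)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), time = time,
             event = event, age = rep_len(age, n),
             node_stage = rep_len(node, n), tumor_stage = rep_len(tumor, n),
             stringsAsFactors = FALSE)
}
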