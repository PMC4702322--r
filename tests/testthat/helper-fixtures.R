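# Shared fixtures, built in code at test time.

# A small deterministic count matrix with unequal depths.
toy_counts <- function() {
  set.seed(42)
  m <- matrix(rnbinom(10 * 6, mu = 50, size = 5), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[1, ] <- m[1, ] * 4          # one high-count gene
  count_matrix(m)
}

# A small factorial study reused across tests (cached per session).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cf <- simulation_config(n_genes = 400, n_intergenic = 150,
                              a = 4, b = 2, c = 2, n_per_cell = 4,
                              n_spikeins = 16, rng_seed = 101)
      cache <<- simulate_experiment(cf)
    }
    cache
  }
})

# --- brute-force oracles (kept deliberately naive) --------------------------

oracle_tc <- function(m, N = colSums(m)) {
  out <- m
  for (k in seq_len(ncol(m))) out[, k] <- m[, k] / (N[k] / mean(N))
  out
}

oracle_uq_factors <- function(m) {
  keep <- apply(m, 1, function(r) any(r > 0))
  uq <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) uq[k] <- quantile(m[keep, k], 0.75, type = 7)
  uq / mean(uq)
}

oracle_med_factors <- function(m) {
  keep <- apply(m, 1, function(r) any(r > 0))
  md <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) md[k] <- median(m[keep, k])
  md / mean(md)
}

oracle_deseq_factors <- function(m) {
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  keep <- gm > 0 & is.finite(gm)
  unname(apply(m, 2, function(col) median(col[keep] / gm[keep])))
}

oracle_quantile <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (k in seq_len(ncol(m))) {
    col <- m[, k]
    for (i in seq_along(col)) {
      # positions the tie block occupies in the sorted column
      lo <- sum(col < col[i]) + 1
      hi <- sum(col <= col[i])
      out[i, k] <- mean(target[lo:hi])
    }
  }
  out
}

oracle_tmm_factor <- function(xk, xr, Nk, Nr, trim_M = 0.30, trim_A = 0.05) {
  ok <- xk > 0 & xr > 0
  M <- log2((xk[ok] / Nk) / (xr[ok] / Nr))
  A <- 0.5 * (log2(xk[ok] / Nk) + log2(xr[ok] / Nr))
  w <- 1 / ((Nk - xk[ok]) / (Nk * xk[ok]) + (Nr - xr[ok]) / (Nr * xr[ok]))
  inM <- M >= quantile(M, trim_M, type = 7) & M <= quantile(M, 1 - trim_M, type = 7)
  inA <- A >= quantile(A, trim_A, type = 7) & A <= quantile(A, 1 - trim_A, type = 7)
  g <- inM & inA
  2^(sum(w[g] * M[g]) / sum(w[g]))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) m / j * p[o[j]])
    q[o[i]] <- min(1, min(cand))
  }
  q
}

oracle_agreement_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(union(a, b)) == 0) return(100)
  100 * length(intersect(a, b)) / length(union(a, b))
}
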