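# Shared fixtures. Audio fixtures use short sentences and, where accuracy
# permits, a 22.05 kHz rate to keep the suite fast; they are built lazily
# and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# stationary clean voice, full rate
clean_voice <- function() fixture("clean_voice", function() {
  synthesize_voice(voice_spec(1.2, 181, 181, jitter_frac = 0, noise_db = -60),
                   seed = 1L)
})

# gaussian feature table with group structure: p features, the first
# `informative` of which separate the groups
make_feature_table <- function(G, n_per, p, informative = p, sep = 3,
                               seed = 1, feat_names = paste0("x", seq_len(p))) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(G), function(g) {
    mu <- numeric(p)
    mu[seq_len(informative)] <- sep * stats::rnorm(informative)
    X <- matrix(stats::rnorm(n_per * p), n_per, p)
    X <- sweep(X, 2, mu, "+")
    cbind(data.frame(speaker_id = sprintf("G%02d", g)),
          stats::setNames(as.data.frame(X), feat_names))
  }))
  rows
}

# brute-force canonical discriminant oracle: eigen of solve(W) %*% B with
# the same definitions, normalized to a' W a = 1, sign-aligned
oracle_lda <- function(tbl, features) {
  g <- factor(tbl$speaker_id)
  X <- as.matrix(tbl[, features])
  N <- nrow(X); G <- nlevels(g)
  means <- apply(X, 2, function(col) tapply(col, g, mean))
  Xc <- X - means[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc) / (N - G)
  n_g <- as.numeric(table(g))
  mbar <- colSums(means * n_g) / N
  Mc <- sweep(means, 2, mbar) * sqrt(n_g)
  B <- crossprod(Mc) / (G - 1)
  eg <- eigen(solve(W) %*% B)
  nf <- min(G - 1, ncol(X))
  A <- Re(eg$vectors[, seq_len(nf), drop = FALSE])
  for (k in seq_len(nf)) {
    a <- A[, k]
    A[, k] <- a / sqrt(drop(t(a) %*% W %*% a))
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) A[, k] <- -A[, k]
  }
  list(A = A, eigenvalues = Re(eg$values[seq_len(nf)]))
}
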