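# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (triple loops, explicit
# enumeration) and share no code with the package internals.

# classic triple-loop Floyd-Warshall on a weight matrix (0 = absent edge)
oracle_apsp <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- w[i, j]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_radius <- function(w) {
  n <- nrow(w)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  d <- oracle_apsp(w)
  ecc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fin <- d[i, -i][is.finite(d[i, -i])]
    if (length(fin)) ecc[i] <- max(fin)
  }
  if (all(is.na(ecc))) NA_real_ else min(ecc, na.rm = TRUE)
}

# mean shortest path over finite pairs, lengths = 1/weight
oracle_cpl <- function(w_mi) {
  L <- w_mi
  L[L > 0] <- 1 / L[L > 0]
  d <- oracle_apsp(L)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

# Onnela weighted clustering, triple loop, weights pre-normalized by max
oracle_clustering <- function(w) {
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  n <- nrow(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(wn[i, ] > 0)
    if (k_i < 2) next
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n))
      if (j != i && k != i && j != k)
        s <- s + (wn[i, j] * wn[j, k] * wn[k, i])^(1 / 3)
    cc[i] <- s / (k_i * (k_i - 1))
  }
  cc
}

# local efficiency: efficiency of the neighbor-induced subgraph on
# inverse normalized weights; unreachable pairs contribute 0
oracle_local_eff <- function(w) {
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  n <- nrow(w)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) next
    L <- wn[nb, nb, drop = FALSE]
    L[L > 0] <- 1 / L[L > 0]
    d <- oracle_apsp(L)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    le[i] <- mean(inv)
  }
  le
}

# AUC as the all-pairs concordance (Mann-Whitney) statistic, ties = 1/2
oracle_auc <- function(values, labels) {
  pos <- values[labels]
  neg <- values[!labels]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# MATLAB-style percentile: sorted value k sits at 100*(k-0.5)/n, linear
# interpolation between, clamped at the extremes
oracle_prctile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  pts <- 100 * (seq_len(n) - 0.5) / n
  if (p <= pts[1]) return(s[1])
  if (p >= pts[n]) return(s[n])
  approx(pts, s, xout = p)$y
}

# random symmetric weight matrix with a given edge density
random_weight_matrix <- function(n, density = 0.7, wmin = 0.1, wmax = 5) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (runif(1) < density)
      w[i, j] <- w[j, i] <- runif(1, wmin, wmax)
  w
}

small_patient <- function(contacts, events, duration_min = 20, engel = 1L,
                          id = "T1") {
  patient_record(id, contacts, events, duration_min, engel)
}

# a hand-built patient: 4 contacts on a line, two resected, mixed events
fixture_patient <- function() {
  ct <- contact_table(
    contact_id = c("A1", "A2", "B1", "B2"),
    electrode = c("A", "A", "B", "B"),
    x = c(0, 5, 40, 45), y = 0, z = 0,
    soz = c(TRUE, TRUE, FALSE, FALSE),
    resected = c(TRUE, TRUE, FALSE, FALSE)
  )
  ev <- event_table(
    contact_id = c("A1", "A1", "A2", "B1", "B1", "B2"),
    onset_s = c(10, 50, 30, 100, 200, 300),
    event_class = c("fRonO", "fRonS", "fRonO", "fRonO", "RonO", "fRonS"),
    freq_hz = c(400, 280, 340, 500, 140, 260)
  )
  small_patient(ct, ev)
}
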