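# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# B-spline evaluation by the textbook de Boor / Cox recursion.
deboor_basis <- function(knots, x, degree) {
  m <- length(knots) - degree - 1L
  B <- sapply(seq_len(m), function(i) {
    vapply(x, function(xx) deboor_one(knots, i, degree, xx), numeric(1))
  })
  matrix(B, nrow = length(x))
}
deboor_one <- function(t, i, p, x) {
  if (p == 0) {
    # half-open intervals, closed at the right end of the spline's support
    hi <- t[i + 1]
    lo <- t[i]
    last <- max(which(t < max(t)))
    if (x >= lo && (x < hi || (hi == max(t) && x <= hi))) 1 else 0
  } else {
    a <- if (t[i + p] > t[i])
      (x - t[i]) / (t[i + p] - t[i]) * deboor_one(t, i, p - 1, x) else 0
    b <- if (t[i + p + 1] > t[i + 1])
      (t[i + p + 1] - x) / (t[i + p + 1] - t[i + 1]) *
        deboor_one(t, i + 1, p - 1, x) else 0
    a + b
  }
}

# Exhaustive enumeration of all monotone warping paths (right / down /
# diagonal moves), the brute-force counterpart of the DTW recurrence.
dtw_oracle <- function(A, B) {
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  if (is.vector(B)) B <- matrix(B, ncol = 1)
  n <- nrow(A); m <- nrow(B)
  cost <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  best
}

# Brute-force k-medoids: minimum cost over all C(n, k) medoid sets.
pam_oracle <- function(D, k) {
  n <- nrow(D)
  sets <- combn(n, k)
  costs <- apply(sets, 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min)))
  min(costs)
}

# Exact permutation distribution of Spearman's rho (tie-free data, n small).
spearman_perm <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  r0 <- cor(rank(x), rank(y))
  rs <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  list(rho = r0, p = mean(abs(rs) >= abs(r0) - 1e-12))
}
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# Rank-mean z statistic for one Dunn pairwise comparison (no ties).
dunn_z_oracle <- function(a, b, rest = list()) {
  groups <- c(list(a, b), rest)
  values <- unlist(groups)
  r <- rank(values)
  N <- length(values)
  idx <- rep(seq_along(groups), lengths(groups))
  m1 <- mean(r[idx == 1]); m2 <- mean(r[idx == 2])
  (m1 - m2) / sqrt(N * (N + 1) / 12 * (1 / length(a) + 1 / length(b)))
}

# tiny two-level registry used by several ingest tests
toy_registry <- function() {
  tibble::tibble(
    taxon = c("Zooplankton", "Copepoda", "Calanoida", "Calanidae",
              "Oithonidae", "Cyclopoida", "Chaetognatha"),
    parent = c(NA, "Zooplankton", "Copepoda", "Calanoida", "Cyclopoida",
               "Copepoda", "Zooplankton"),
    level = c("root", "class", "order", "family", "family", "order",
              "group"),
    bucket = FALSE)
}

toy_objects <- function(taxa, station = "st001", net = "WP2",
                        esd = rep(200, length(taxa))) {
  tibble::tibble(
    object_id = sprintf("o%03d", seq_along(taxa)),
    station_id = station, net_id = net, taxon = taxa,
    ellipse_major_um = esd * sqrt(2), ellipse_minor_um = esd / sqrt(2),
    esd_um = esd)
}
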