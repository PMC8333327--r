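# Partitioning around medoids on a distance matrix, cluster-validity
# indices, model selection over k, and classical MDS embedding.

#' Partitioning around medoids (PAM)
#'
#' Classic BUILD phase (greedy medoid addition minimizing total cost)
#' followed by a steepest-descent SWAP phase (accept the best
#' medoid/non-medoid swap that lowers the total distance-to-medoid cost,
#' repeat to a local optimum).  Ties are broken at random; after the BUILD
#' run, the remaining `restarts - 1` runs restart the swap descent from
#' random medoid sets, and the best run wins, deterministically under
#' `seed`.
#'
#' @param D Symmetric distance matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @param restarts Number of randomized runs (default 10).
#' @param seed Integer seed (or NULL to use the current RNG stream).
#' @return A `zc_pam` list: `k`, `medoids` (indices), `medoid_ids`,
#'   `assignment` (integer vector), `cost`, `cost_trace` (accepted-swap
#'   trace of the winning run).
#' @export
pam_cluster <- function(D, k, restarts = 10, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 2 || k >= n)
    abort("need 2 <= k < n", class = "zoopcurves_input_error")
  ids <- rownames(D) %||% as.character(seq_len(n))

  run_once <- function(random_init = FALSE) {
    if (random_init) {
      meds <- sample.int(n, k)
    } else {
      meds <- tie_argmin(colSums(D))
      while (length(meds) < k) {
        dnear <- apply(D[, meds, drop = FALSE], 1, min)
        cand <- setdiff(seq_len(n), meds)
        gains <- vapply(cand, function(h) sum(pmax(dnear - D[, h], 0)),
                        numeric(1))
        meds <- c(meds, cand[tie_argmax(gains)])
      }
    }
    cost <- function(m) sum(apply(D[, m, drop = FALSE], 1, min))
    cur <- cost(meds)
    trace <- cur
    repeat {
      best_delta <- 0
      best_swap <- NULL
      nonmeds <- setdiff(seq_len(n), meds)
      for (mi in seq_along(meds)) {
        for (h in nonmeds) {
          trial <- meds
          trial[mi] <- h
          dlt <- cost(trial) - cur
          if (dlt < best_delta - 1e-12) {
            best_delta <- dlt
            best_swap <- c(mi, h)
          }
        }
      }
      if (is.null(best_swap)) break
      meds[best_swap[1]] <- best_swap[2]
      cur <- cur + best_delta
      trace <- c(trace, cur)
    }
    list(meds = sort(meds), cost = cur, trace = trace)
  }

  # first run starts from the greedy BUILD; later restarts explore from
  # random medoid sets so the swap descent can escape BUILD's basin
  best <- with_seed(seed, {
    runs <- lapply(seq_len(restarts), function(i) run_once(i > 1))
    runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  })
  assignment <- apply(D[, best$meds, drop = FALSE], 1, which.min)
  # a medoid always belongs to its own cluster
  assignment[best$meds] <- seq_along(best$meds)
  out <- list(k = k, medoids = best$meds, medoid_ids = ids[best$meds],
              assignment = setNames(as.integer(assignment), ids),
              cost = best$cost, cost_trace = best$trace)
  class(out) <- "zc_pam"
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, takes the top eigenpairs, and clips
#' negative eigenvalues to zero (their count is reported; DTW distances need
#' not be Euclidean).
#'
#' @param D Symmetric distance matrix.
#' @param dim Embedding dimension (default 2).
#' @return List with `points` (n x dim), `eig` (all eigenvalues),
#'   `n_clipped` (negative eigenvalues clipped).
#' @export
classical_mds <- function(D, dim = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) abort("need n >= 3", class = "zoopcurves_input_error")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eg$values
  n_clipped <- sum(vals < -1e-9 * max(abs(vals), 1e-300))
  pos <- pmax(vals, 0)
  dim <- min(dim, n - 1)
  pts <- eg$vectors[, seq_len(dim), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(dim)]), dim)
  rownames(pts) <- rownames(D)
  list(points = pts, eig = vals, n_clipped = n_clipped)
}

#' Cluster-validity indices
#'
#' Silhouette and Dunn's index are computed directly from the distance
#' matrix (Dunn = minimum between-cluster distance over maximum
#' within-cluster diameter; singleton silhouettes are 0 by convention).
#' Calinski-Harabasz and the classic and modified Davies-Bouldin indices
#' need centroids and are computed on a classical-MDS embedding of the
#' distances (dimension `min(n - 1, 5)` by default).  The modified
#' Davies-Bouldin is the max-separation variant: for each cluster the
#' maximal scatter sum over the minimal centroid separation.
#'
#' @param D Distance matrix.
#' @param assignment Integer cluster labels (>= 2 non-empty clusters).
#' @param coords Optional embedding coordinates; computed from `D` if NULL.
#' @return List: `calinski_harabasz`, `dunn`, `mean_silhouette`,
#'   `davies_bouldin`, `davies_bouldin_modified`.
#' @export
validity_indices <- function(D, assignment, coords = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  cl <- as.integer(assignment)
  ks <- sort(unique(cl))
  if (length(ks) < 2)
    abort("need at least 2 non-empty clusters", class = "zoopcurves_input_error")
  if (is.null(coords))
    coords <- classical_mds(D, dim = min(n - 1, 5))$points

  # silhouette from D
  sil <- vapply(seq_len(n), function(i) {
    own <- cl[i]
    mates <- which(cl == own & seq_len(n) != i)
    if (length(mates) == 0) return(0)
    a <- mean(D[i, mates])
    b <- min(vapply(setdiff(ks, own),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))

  # Dunn from D
  seps <- c()
  diams <- c()
  for (g in ks) {
    idx <- which(cl == g)
    diams <- c(diams, if (length(idx) > 1) max(D[idx, idx]) else 0)
    for (h in ks[ks > g]) seps <- c(seps, min(D[idx, cl == h, drop = FALSE]))
  }
  dunn <- if (max(diams) == 0) Inf else min(seps) / max(diams)

  # centroid-based indices on the embedding
  cent <- t(vapply(ks, function(g)
    colMeans(coords[cl == g, , drop = FALSE]), numeric(ncol(coords))))
  scat <- vapply(seq_along(ks), function(gi) {
    idx <- which(cl == ks[gi])
    mean(sqrt(rowSums((coords[idx, , drop = FALSE] -
                         matrix(cent[gi, ], length(idx), ncol(coords),
                                byrow = TRUE))^2)))
  }, numeric(1))
  gmean <- colMeans(coords)
  wss <- sum(vapply(seq_along(ks), function(gi) {
    idx <- which(cl == ks[gi])
    sum(rowSums((coords[idx, , drop = FALSE] -
                   matrix(cent[gi, ], length(idx), ncol(coords),
                          byrow = TRUE))^2))
  }, numeric(1)))
  bss <- sum(vapply(seq_along(ks), function(gi) {
    sum(cl == ks[gi]) * sum((cent[gi, ] - gmean)^2)
  }, numeric(1)))
  kk <- length(ks)
  ch <- if (wss <= 1e-300) Inf else (bss / (kk - 1)) / (wss / (n - kk))

  M <- as.matrix(stats::dist(cent))
  rij_max <- vapply(seq_len(kk), function(i)
    max(vapply(setdiff(seq_len(kk), i),
               function(j) (scat[i] + scat[j]) / M[i, j], numeric(1))),
    numeric(1))
  db <- mean(rij_max)
  db_mod <- mean(vapply(seq_len(kk), function(i) {
    num <- max(vapply(setdiff(seq_len(kk), i),
                      function(j) scat[i] + scat[j], numeric(1)))
    den <- min(M[i, setdiff(seq_len(kk), i)])
    num / den
  }, numeric(1)))

  list(calinski_harabasz = ch, dunn = dunn, mean_silhouette = mean(sil),
       davies_bouldin = db, davies_bouldin_modified = db_mod)
}

#' Choose the number of clusters by index vote
#'
#' Runs PAM for each candidate k, computes the five validity indices, lets
#' each index vote for its best k (maximize Calinski-Harabasz, Dunn and
#' silhouette; minimize both Davies-Bouldin variants), and returns the
#' plurality winner (ties resolved to the smallest k).
#'
#' The centroid-based indices (Calinski-Harabasz and the two
#' Davies-Bouldin variants) are degenerate on partitions containing
#' singleton clusters: a singleton's scatter is structurally zero, which
#' inflates the between/within ratio and deflates Davies-Bouldin no matter
#' what the data look like, so isolating any outlier always "improves"
#' them.  Those three indices therefore vote only among candidate ks whose
#' partition has every cluster of size >= 2 (all ks, if none qualifies);
#' silhouette and Dunn, which have well-defined singleton conventions, vote
#' over the full range.  All index values are still reported for every k.
#'
#' @param D Distance matrix.
#' @param k_range Candidate ks (default 2:10, truncated to n - 1).
#' @param restarts PAM restarts per k.
#' @param seed Integer seed.
#' @return List: `k` (chosen), `table` (per-k indices), `votes` (named
#'   integer vector), `clusterings` (list of `zc_pam` by k).
#' @export
choose_k <- function(D, k_range = 2:10, restarts = 10, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  coords <- classical_mds(D, dim = min(n - 1, 5))$points
  rows <- list()
  clusterings <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    pam <- pam_cluster(D, k, restarts = restarts,
                       seed = if (is.null(seed)) NULL else seed + k)
    vi <- validity_indices(D, pam$assignment, coords)
    rows[[i]] <- tibble::tibble(k = k,
                                min_size = min(table(pam$assignment)),
                                calinski_harabasz = vi$calinski_harabasz,
                                dunn = vi$dunn,
                                mean_silhouette = vi$mean_silhouette,
                                davies_bouldin = vi$davies_bouldin,
                                davies_bouldin_modified =
                                  vi$davies_bouldin_modified)
    clusterings[[as.character(k)]] <- pam
  }
  tab <- dplyr::bind_rows(rows)
  nontrivial <- tab$min_size >= 2
  if (!any(nontrivial)) nontrivial <- rep(TRUE, nrow(tab))
  vote_max <- function(v, elig = rep(TRUE, nrow(tab))) {
    kk <- tab$k[elig]
    kk[which.max(v[elig])]
  }
  vote_min <- function(v, elig = rep(TRUE, nrow(tab))) {
    kk <- tab$k[elig]
    kk[which.min(v[elig])]
  }
  votes <- c(calinski_harabasz = vote_max(tab$calinski_harabasz, nontrivial),
             dunn = vote_max(tab$dunn),
             mean_silhouette = vote_max(tab$mean_silhouette),
             davies_bouldin = vote_min(tab$davies_bouldin, nontrivial),
             davies_bouldin_modified =
               vote_min(tab$davies_bouldin_modified, nontrivial))
  list(k = vote_plurality(votes), table = tab, votes = votes,
       clusterings = clusterings)
}

# plurality vote over per-index best ks; ties resolved to the smallest k
vote_plurality <- function(votes) {
  cnt <- table(votes)
  winners <- as.integer(names(cnt)[cnt == max(cnt)])
  min(winners)
}
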