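# Cluster-based Monte Carlo permutation inference.
#
# Paired designs use exact sign-flip nulls on per-subject difference maps;
# correlation designs permute the behaviour vector across subjects. The
# cluster statistic is the mass (sum of point-wise t, or r-derived t, within
# the cluster); positive and negative clusters are formed separately and each
# observed cluster is compared against the permutation distribution of the
# maximum absolute mass, giving two-tailed family-wise control. Monte Carlo
# p-values use the add-one rule and can never fall below 1/(n_perm + 1).

#' Channel adjacency from montage geometry
#'
#' Neighbours are channel pairs closer than a distance threshold chosen as the
#' smallest threshold for which the median neighbour count reaches
#' `target_degree` (default 6, a typical scalp-montage neighbourhood size).
#'
#' @param montage Montage tibble with `channel`, `x`, `y`, `z`.
#' @param target_degree Desired median number of neighbours.
#' @return Object of class `channel_adjacency`: `adj` (symmetric, irreflexive
#'   logical matrix), `channels`, `threshold`, `isolated` (channels without
#'   neighbours, flagged).
#' @export
channel_adjacency <- function(montage, target_degree = 6) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cand <- sort(unique(d[upper.tri(d)]))
  thr <- NA_real_
  for (ca in cand) {
    if (median(rowSums(d <= ca) - 1) >= target_degree) { thr <- ca; break }
  }
  if (is.na(thr)) thr <- max(cand)
  adj <- d <= thr & d > 0
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$channel, montage$channel)
  structure(list(adj = adj, channels = montage$channel, threshold = thr,
                 isolated = montage$channel[rowSums(adj) == 0]),
            class = "channel_adjacency")
}

#' @export
print.channel_adjacency <- function(x, ...) {
  cat(sprintf("<channel_adjacency> %d channels, threshold %.3f, median degree %g\n",
              length(x$channels), x$threshold, median(rowSums(x$adj))))
  if (length(x$isolated)) cat("isolated:", paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname channel_adjacency
#' @param x A `channel_adjacency`.
#' @param ... Unused.
tidy.channel_adjacency <- function(x, ...) {
  idx <- which(x$adj & upper.tri(x$adj), arr.ind = TRUE)
  tibble::tibble(channel1 = x$channels[idx[, 1]], channel2 = x$channels[idx[, 2]])
}

# connected components among `supra` nodes; adj_list: integer neighbour lists
components_bfs <- function(supra, adj_list) {
  idx <- which(supra)
  if (length(idx) == 0) return(list())
  visited <- !supra
  comps <- list()
  for (v in idx) {
    if (visited[v]) next
    stack <- v
    visited[v] <- TRUE
    comp <- integer(0)
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, u)
      nb <- adj_list[[u]]
      nb <- nb[!visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# clusters (members, mass, sign) of a statistic vector over a graph
form_clusters <- function(stat, thresh, adj_list) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- is.finite(stat) & sgn * stat > thresh
    for (comp in components_bfs(supra, adj_list)) {
      out[[length(out) + 1L]] <- list(members = comp,
                                      mass = sum(stat[comp]), sign = sgn)
    }
  }
  if (length(out)) out[order(-abs(vapply(out, `[[`, numeric(1), "mass")))] else out
}

max_cluster_mass <- function(stat, thresh, adj_list) {
  m <- 0
  for (sgn in c(1, -1)) {
    supra <- is.finite(stat) & sgn * stat > thresh
    for (comp in components_bfs(supra, adj_list)) {
      m <- max(m, abs(sum(stat[comp])))
    }
  }
  m
}

# sign-flip permutation t statistics: D (n x m), S (n x P) of +/-1
perm_t <- function(D, S) {
  n <- nrow(D)
  q <- colSums(D^2)
  m1 <- crossprod(S, D) / n               # P x m means
  v <- sweep(-n * m1^2, 2, q, "+") / (n - 1)
  t <- m1 / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

paired_t <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  s <- apply(D, 2, sd)
  t <- mu / (s / sqrt(n))
  t[s < 1e-12] <- NA_real_
  t
}

as_subject_matrix <- function(x, value_col = "value") {
  if (is.matrix(x)) return(x)
  abort_if(!all(c("subject", "channel", value_col) %in% names(x)),
           "need a subjects x channels matrix or a subject/channel/value tibble")
  wide <- tidyr::pivot_wider(x[, c("subject", "channel", value_col)],
                             names_from = "channel",
                             values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject
  m
}

new_cluster_result <- function(type, statistic, clusters, null_max, n_perm,
                               cluster_alpha, alpha, threshold, extra = list()) {
  structure(c(list(type = type, statistic = statistic, clusters = clusters,
                   null_max = null_max, n_perm = n_perm,
                   cluster_alpha = cluster_alpha, alpha = alpha,
                   threshold = threshold), extra),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result:%s> %d cluster(s), %d permutations\n",
              x$type, nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) {
    print(x$clusters[, setdiff(names(x$clusters), "members")])
  }
  invisible(x)
}

#' @export
#' @rdname topo_cluster_test
#' @param x A `cluster_result`.
#' @param ... Unused.
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
#' @rdname topo_cluster_test
glance.cluster_result <- function(x, ...) {
  tibble::tibble(type = x$type, n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
                 n_perm = x$n_perm, cluster_alpha = x$cluster_alpha,
                 alpha = x$alpha)
}

#' Cluster-based permutation test of band topographies against baseline
#'
#' Per-channel paired t-tests of subject topographies against a reference
#' (zero dB by default, i.e. no change from baseline), clustering
#' suprathreshold channels of equal sign through the montage adjacency, with a
#' sign-flip Monte Carlo null for the maximum cluster mass.
#'
#' @param x Subjects x channels matrix, or a tibble with `subject`, `channel`
#'   and `value` columns.
#' @param adjacency A [channel_adjacency()] matching the channel order of `x`.
#' @param reference Scalar or subjects x channels matrix subtracted from `x`
#'   before testing (default 0).
#' @param n_perm Number of random sign-flip permutations (default 5000).
#' @param cluster_alpha Point-wise threshold for cluster formation (two-tailed,
#'   default 0.05).
#' @param alpha Cluster-level significance level (two-tailed, default 0.05).
#' @param seed Optional seed for the permutation stream.
#' @return A `cluster_result` with per-channel t values and a cluster table
#'   (`members` = channel indices; `channels` = channel names).
#' @export
topo_cluster_test <- function(x, adjacency, reference = 0, n_perm = 5000,
                              cluster_alpha = 0.05, alpha = 0.05, seed = NULL) {
  D <- as_subject_matrix(x) - reference
  n <- nrow(D)
  abort_if(n < 2, "need at least two subjects")
  abort_if(ncol(D) != length(adjacency$channels),
           "channel count mismatch with adjacency")
  adj_list <- apply(adjacency$adj, 1, which, simplify = FALSE)
  thresh <- qt(1 - cluster_alpha / 2, n - 1)

  t_obs <- paired_t(D)
  obs <- form_clusters(t_obs, thresh, adj_list)

  if (!is.null(seed)) set.seed(seed)
  S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  Tp <- perm_t(D, S)
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_mass(Tp[p, ], thresh, adj_list)
  }, numeric(1))

  clusters <- cluster_table(obs, null_max, n_perm, alpha,
                            labels = adjacency$channels)
  new_cluster_result("topography",
                     tibble::tibble(channel = adjacency$channels, t = t_obs),
                     clusters, null_max, n_perm, cluster_alpha, alpha, thresh,
                     extra = list(channels = adjacency$channels,
                                  isolated = adjacency$isolated))
}

cluster_table <- function(obs, null_max, n_perm, alpha, labels = NULL) {
  if (length(obs) == 0) {
    return(tibble::tibble(cluster = integer(), sign = numeric(),
                          mass = numeric(), n_members = integer(),
                          p = numeric(), significant = logical(),
                          members = list()))
  }
  tibble::tibble(
    cluster = seq_along(obs),
    sign = vapply(obs, `[[`, numeric(1), "sign"),
    mass = vapply(obs, `[[`, numeric(1), "mass"),
    n_members = vapply(obs, function(o) length(o$members), integer(1)),
    p = vapply(obs, function(o) {
      (1 + sum(null_max >= abs(o$mass))) / (n_perm + 1)
    }, numeric(1)),
    significant = .data$p < alpha,
    members = lapply(obs, function(o) {
      if (is.null(labels)) o$members else labels[o$members]
    })
  )
}

# full 4-connected neighbour lists for an F x T grid, as linear indices
grid_adj_list <- function(nr, nc) {
  n <- nr * nc
  lapply(seq_len(n), function(i) {
    r <- (i - 1L) %% nr + 1L
    cc <- (i - 1L) %/% nr + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, i - 1L)
    if (r < nr) nb <- c(nb, i + 1L)
    if (cc > 1L) nb <- c(nb, i - nr)
    if (cc < nc) nb <- c(nb, i + nr)
    nb
  })
}

#' Cluster-based permutation test of a time-frequency map against baseline
#'
#' For one channel: each subject's dB map is reduced to a difference map by
#' subtracting the subject's mean baseline dB per frequency bin; paired t
#' values over subjects are clustered by full 2-D time-frequency adjacency
#' (4-connectivity, joining across frequencies), with a sign-flip null.
#'
#' @param x Array subjects x frequency x time of dB values on a common grid.
#' @param freqs,times Grid coordinates (Hz, s).
#' @param baseline Baseline window (s), default `c(-2, -1)`.
#' @param post Post-stimulus analysis window (s), default `c(0, 14)`.
#' @param n_perm,cluster_alpha,alpha,seed See [topo_cluster_test()].
#' @return A `cluster_result`; cluster members are rows of a `freq`/`time`
#'   tibble stored in the `members` list-column.
#' @export
tf_cluster_test <- function(x, freqs, times, baseline = c(-2, -1),
                            post = c(0, 14), n_perm = 5000,
                            cluster_alpha = 0.05, alpha = 0.05, seed = NULL) {
  dims <- dim(x)
  abort_if(length(dims) != 3, "x must be subjects x frequency x time")
  n <- dims[1]
  abort_if(n < 2, "need at least two subjects")
  base_idx <- which(times >= baseline[1] & times <= baseline[2])
  post_idx <- which(times >= post[1] & times <= post[2])
  abort_if(length(base_idx) == 0 || length(post_idx) == 0,
           "baseline or post window outside the time grid")

  base_mean <- apply(x[, , base_idx, drop = FALSE], c(1, 2), mean)
  D3 <- x[, , post_idx, drop = FALSE] - as.vector(base_mean)
  nf <- dims[2]; nt <- length(post_idx)
  D <- matrix(D3, n, nf * nt)

  adj_list <- grid_adj_list(nf, nt)
  thresh <- qt(1 - cluster_alpha / 2, n - 1)
  t_obs <- paired_t(D)
  obs <- form_clusters(t_obs, thresh, adj_list)

  if (!is.null(seed)) set.seed(seed)
  S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  Tp <- perm_t(D, S)
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_mass(Tp[p, ], thresh, adj_list)
  }, numeric(1))

  # linear index i maps to (freq = (i-1) %% nf + 1, time = (i-1) %/% nf + 1)
  clusters <- cluster_table(obs, null_max, n_perm, alpha)
  clusters$members <- lapply(clusters$members, function(m) {
    tibble::tibble(freq = freqs[(m - 1L) %% nf + 1L],
                   time = times[post_idx][(m - 1L) %/% nf + 1L])
  })
  stat <- tibble::tibble(freq = rep(freqs, times = nt),
                         time = rep(times[post_idx], each = nf),
                         t = t_obs)
  new_cluster_result("time_frequency", stat, clusters, null_max, n_perm,
                     cluster_alpha, alpha, thresh,
                     extra = list(freqs = freqs, times = times[post_idx]))
}

#' Cluster-corrected topography-behaviour correlation
#'
#' Correlates a per-subject scalar (e.g. the over-session change in heart-rate
#' deceleration) with the band topography at every channel; channels whose |r|
#' exceeds the r value corresponding to the two-tailed `cluster_alpha`
#' threshold at the sample size are clustered through the adjacency, the
#' cluster mass being the sum of r-derived t values. The null permutes the
#' behaviour vector across subjects. For every cluster the correlation between
#' the cluster-mean signal and the behaviour is also reported (`cluster_r`).
#'
#' @param x Subjects x channels matrix (or subject/channel/value tibble).
#' @param behavior Per-subject scalar, finite and non-constant.
#' @param adjacency A [channel_adjacency()].
#' @param n_perm,cluster_alpha,alpha,seed See [topo_cluster_test()].
#' @return A `cluster_result` with per-channel `r` and per-cluster `cluster_r`.
#' @export
topo_cluster_correlation <- function(x, behavior, adjacency, n_perm = 5000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     seed = NULL) {
  X <- as_subject_matrix(x)
  n <- nrow(X)
  abort_if(n < 4, "need at least four subjects")
  abort_if(any(!is.finite(behavior)) || length(behavior) != n,
           "behavior must be finite, one value per subject")
  abort_if(sd(behavior) < 1e-12, "behavior vector is constant; correlation undefined")
  abort_if(ncol(X) != length(adjacency$channels),
           "channel count mismatch with adjacency")
  adj_list <- apply(adjacency$adj, 1, which, simplify = FALSE)

  df <- n - 2
  t_crit <- qt(1 - cluster_alpha / 2, df)
  r_crit <- t_crit / sqrt(df + t_crit^2)

  r_to_t <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt(df / (1 - r^2))
  }
  r_obs <- as.vector(cor(X, behavior))
  t_obs <- r_to_t(r_obs)
  obs <- form_clusters(t_obs, r_to_t(r_crit) * (1 - 1e-12), adj_list)

  if (!is.null(seed)) set.seed(seed)
  B <- vapply(seq_len(n_perm), function(p) behavior[sample.int(n)], numeric(n))
  R <- cor(X, B)                      # channels x n_perm
  Tp <- r_to_t(R)
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_mass(Tp[, p], r_to_t(r_crit) * (1 - 1e-12), adj_list)
  }, numeric(1))

  clusters <- cluster_table(obs, null_max, n_perm, alpha,
                            labels = adjacency$channels)
  clusters$cluster_r <- vapply(seq_len(nrow(clusters)), function(i) {
    memb <- match(clusters$members[[i]], adjacency$channels)
    cm <- rowMeans(X[, memb, drop = FALSE])
    cor(cm, behavior)
  }, numeric(1))

  new_cluster_result("correlation",
                     tibble::tibble(channel = adjacency$channels, r = r_obs,
                                    t = t_obs),
                     clusters, null_max, n_perm, cluster_alpha, alpha, r_crit,
                     extra = list(channels = adjacency$channels))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] for the scatter statistics
#' reported alongside cluster results.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 3, "need at least three observations")
  abort_if(any(!is.finite(x)) || any(!is.finite(y)), "inputs must be finite")
  abort_if(sd(x) < 1e-12 || sd(y) < 1e-12, "constant input; correlation undefined")
  stats::cor(x, y)
}
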