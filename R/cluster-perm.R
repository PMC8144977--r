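# Maximal connected-component sizes among a set of supra-threshold parcels.
# Hand-rolled breadth-first search: called once per permutation inside the
# null-distribution loop, so per-call overhead matters.
.cluster_sizes <- function(supra, adj) {
  if (!length(supra)) return(list(sizes = integer(0), members = list()))
  in_set <- logical(length(adj))
  in_set[supra] <- TRUE
  seen <- logical(length(adj))
  sizes <- integer(0)
  members <- list()
  for (s in supra) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, length(comp))
    members[[length(members) + 1L]] <- sort(comp)
  }
  list(sizes = sizes, members = members)
}

.max_cluster_size <- function(supra, adj) {
  cs <- .cluster_sizes(supra, adj)$sizes
  if (length(cs)) max(cs) else 0L
}

#' Sign-permutation cluster correction for group contrast maps
#'
#' One-sample t test per parcel across subjects, cluster formation among
#' parcels exceeding the (two-sided) cluster-forming threshold on the
#' adjacency graph, and a max-cluster-size null distribution obtained by
#' randomly flipping the sign of each subject's map (equivalent to
#' permuting the sign on the design matrix). Cluster p values are
#' `(1 + #{permutation max >= observed size}) / (n_perm + 1)`; clusters
#' with corrected p below `cluster_alpha` are returned.
#'
#' @param contrast_maps Subjects x parcels matrix of contrast estimates.
#' @param adjacency Adjacency list as from [parcel_lattice_adjacency()].
#' @param cluster_alpha Corrected family-wise alpha (default 0.01).
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed Integer seed.
#' @param forming_alpha Two-sided per-parcel alpha forming candidate
#'   clusters.
#' @return Object of class `cluster_result`: data.frame `clusters`
#'   (`cluster, size, p, parcels`), the per-parcel `t` map, the threshold
#'   used and the permutation null of max cluster size.
#' @export
cluster_permutation <- function(contrast_maps, adjacency, cluster_alpha = 0.01,
                                n_perm = 1000L, seed = 1,
                                forming_alpha = 0.01) {
  maps <- as.matrix(contrast_maps)
  n_sub <- nrow(maps)
  n_parcel <- ncol(maps)
  if (n_sub < 2L) .stopf("need at least 2 subjects")
  if (n_perm < 100L) .stopf("n_perm must be at least 100")
  if (length(adjacency) != n_parcel) {
    .stopf("adjacency covers %d parcels but maps have %d", length(adjacency), n_parcel)
  }
  set.seed(as.integer(seed))

  ss <- colSums(maps^2)  # invariant under sign flips
  t_of <- function(m) {
    v <- (ss - n_sub * m^2) / (n_sub - 1L)
    m / sqrt(pmax(v, .Machine$double.eps) / n_sub)
  }
  t_obs <- t_of(colMeans(maps))
  t_crit <- stats::qt(1 - forming_alpha / 2, df = n_sub - 1L)

  obs <- .cluster_sizes(which(abs(t_obs) > t_crit), adjacency)

  signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
  perm_means <- (signs %*% maps) / n_sub
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    tp <- t_of(perm_means[p, ])
    null_max[p] <- .max_cluster_size(which(abs(tp) > t_crit), adjacency)
  }

  if (length(obs$sizes)) {
    pvals <- vapply(obs$sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1), 0)
    keep <- which(pvals < cluster_alpha)
    clusters <- data.frame(
      cluster = seq_along(keep),
      size = obs$sizes[keep],
      p = pvals[keep],
      parcels = vapply(obs$members[keep], paste, "", collapse = ","),
      stringsAsFactors = FALSE
    )
  } else {
    clusters <- data.frame(cluster = integer(0), size = integer(0),
                           p = numeric(0), parcels = character(0),
                           stringsAsFactors = FALSE)
  }

  structure(
    list(clusters = clusters, t = t_obs, t_critical = t_crit,
         null_max_size = null_max, cluster_alpha = cluster_alpha,
         n_perm = n_perm),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d significant cluster(s) at corrected p < %g (%d permutations)\n",
              nrow(x$clusters), x$cluster_alpha, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters[, c("cluster", "size", "p")])
  invisible(x)
}
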