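#' Parameters for the stimulus-vs-baseline cluster permutation test
#'
#' @param n_permutations Number of sign-flip permutations.
#' @param cluster_forming_p One-sided p-value threshold converted to a t
#'   threshold (df = subjects - 1) for cluster inclusion.
#' @param cluster_alpha Familywise significance level applied to the
#'   corrected cluster p-values.
#' @param adjacency "4" (edge neighbors only, default) or "8" (include
#'   diagonals) on the fP x fA grid.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `cluster_test_params`.
#' @export
cluster_test_params <- function(n_permutations = 5000,
                                cluster_forming_p = 0.01,
                                cluster_alpha = 0.05,
                                adjacency = c("4", "8"),
                                seed = 1L) {
  stopifnot(cluster_forming_p > 0, cluster_forming_p < 1,
            cluster_alpha > 0, cluster_alpha < 1,
            n_permutations >= 100)
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_forming_p = cluster_forming_p,
                 cluster_alpha = cluster_alpha,
                 adjacency = match.arg(adjacency),
                 seed = seed),
            class = "cluster_test_params")
}

# Coerce per-subject comodulograms (list of comodulogram objects or matrices)
# to a subjects x fP x fA array.
.comodulogram_stack <- function(x) {
  mats <- lapply(x, function(el) {
    if (inherits(el, "comodulogram")) el$values else as.matrix(el)
  })
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stop("comodulogram grids differ across subjects")
  dn <- dimnames(mats[[1]])
  arr <- array(0, c(length(mats), d),
               dimnames = if (!is.null(dn)) c(list(NULL), dn))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' Paired t-statistic map across subjects
#'
#' Per comodulogram cell, the paired t statistic of (stimulus - baseline)
#' across subjects, df = n_subjects - 1.
#'
#' @param stim,base Per-subject comodulograms: lists of `comodulogram`
#'   objects or of fP x fA matrices, same subjects in the same order.
#' @return A list with `t_map` (fP x fA), `df`, and `diffs` (subjects x cells
#'   difference matrix, used by the permutation test).
#' @export
paired_t_map <- function(stim, base) {
  S <- .comodulogram_stack(stim)
  B <- .comodulogram_stack(base)
  if (!all(dim(S) == dim(B))) stop("stimulus and baseline grids do not match")
  n <- dim(S)[1]
  if (n < 3) stop("paired t map requires at least 3 subjects")
  D <- matrix(S - B, nrow = n)              # subjects x cells, column-major grid
  mu <- colMeans(D)
  sdv <- sqrt((colSums(D^2) - n * mu^2) / (n - 1))
  if (any(sdv == 0))
    stop("zero-variance difference at ", sum(sdv == 0),
         " cell(s); paired t undefined")
  tmap <- matrix(mu / (sdv / sqrt(n)), dim(S)[2], dim(S)[3],
                 dimnames = dimnames(S)[2:3])
  list(t_map = tmap, df = n - 1, diffs = D)
}

# Integer component labels of a logical grid under 4- or 8-adjacency.
.label_components <- function(mask, adjacency = "4") {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  steps <- if (adjacency == "8")
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (k in seq_len(nrow(steps))) {
        ii <- i + steps[k, 1]; jj <- j + steps[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && labels[ii, jj] == 0L) {
          nxt <- (jj - 1L) * nr + ii
          labels[nxt] <- lab
          stack <- c(stack, nxt)
        }
      }
    }
  }
  labels
}

#' Form supra-threshold clusters on a t map
#'
#' Cells with `t >= t_crit` are grouped into connected components under the
#' declared adjacency; each cluster's mass is the sum of its member t values.
#'
#' @param t_map fP x fA matrix of t statistics.
#' @param t_crit Cluster-forming t threshold (one-sided).
#' @param adjacency "4" or "8".
#' @return A list of clusters, each with `cells` (two-column index matrix),
#'   `mass`, and `peak_cell`; empty list if no cell is supra-threshold.
#' @export
form_clusters <- function(t_map, t_crit, adjacency = "4") {
  mask <- t_map >= t_crit
  if (!any(mask)) return(list())
  labels <- .label_components(mask, adjacency)
  lapply(seq_len(max(labels)), function(l) {
    cells <- which(labels == l, arr.ind = TRUE)
    tv <- t_map[cells]
    list(cells = cells, mass = sum(tv),
         peak_cell = cells[which.max(tv), , drop = TRUE])
  })
}

# Maximum cluster mass of one t vector (grid in column-major order).
.max_cluster_mass <- function(tvec, t_crit, nr, nc, adjacency) {
  sup <- tvec >= t_crit
  nsup <- sum(sup)
  if (nsup == 0L) return(0)
  if (nsup == 1L) return(tvec[sup])
  labels <- .label_components(matrix(sup, nr, nc), adjacency)
  max(tapply(tvec[sup], labels[labels > 0L], sum))
}

#' Cluster-based permutation test of stimulus vs baseline coupling
#'
#' One-tailed (stimulus > baseline) paired test with familywise error control
#' by the maximum-cluster-mass permutation distribution. Each permutation
#' flips the stimulus/baseline labels independently per subject (sign-flip of
#' the paired differences), recomputes the t map and records the largest
#' cluster mass (0 if no cell is supra-threshold). The corrected p-value of an
#' observed cluster is `(1 + #{perm max >= observed mass}) / (1 + n_perm)`.
#'
#' @param stim,base Per-subject comodulograms (lists of `comodulogram`
#'   objects or fP x fA matrices), paired by position.
#' @param params A [cluster_test_params()].
#' @return An object of class `cluster_test`: `clusters` (data.frame with
#'   `cluster_id`, `n_cells`, `mass`, `p_corrected`, `significant`, peak and
#'   range columns), `cluster_cells` (list of index matrices), `t_map`,
#'   `t_crit`, `df`, `null_max_mass`, `params`.
#' @export
cluster_permutation_test <- function(stim, base, params = cluster_test_params()) {
  stopifnot(inherits(params, "cluster_test_params"))
  tm <- paired_t_map(stim, base)
  D <- tm$diffs
  n <- nrow(D); K <- ncol(D)
  nr <- nrow(tm$t_map); nc <- ncol(tm$t_map)
  t_crit <- stats::qt(1 - params$cluster_forming_p, df = tm$df)
  if (2^n < 100)
    warning("only ", 2^n, " distinct sign patterns with ", n,
            " subjects; permutation p resolution is limited")

  clusters <- form_clusters(tm$t_map, t_crit, params$adjacency)

  nperm <- params$n_permutations
  null_max <- numeric(nperm)
  SS <- colSums(D^2)
  with_local_seed(params$seed, {
    flips <- matrix(sample(c(-1, 1), nperm * n, replace = TRUE), nperm, n)
    M <- (flips %*% D) / n
    V <- sweep(-n * M^2, 2, SS, "+") / (n - 1)
    Tm <- M / sqrt(pmax(V, .Machine$double.eps) / n)
    for (p in seq_len(nperm))
      null_max[p] <- .max_cluster_mass(Tm[p, ], t_crit, nr, nc, params$adjacency)
  })

  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    pval <- (1 + sum(null_max >= cl$mass)) / (1 + nperm)
    fp <- rownames(tm$t_map); fa <- colnames(tm$t_map)
    data.frame(cluster_id = i,
               n_cells = nrow(cl$cells),
               mass = cl$mass,
               p_corrected = pval,
               significant = pval < params$cluster_alpha,
               peak_fP = if (!is.null(fp)) as.numeric(fp[cl$peak_cell[1]]) else cl$peak_cell[1],
               peak_fA = if (!is.null(fa)) as.numeric(fa[cl$peak_cell[2]]) else cl$peak_cell[2],
               fP_min = if (!is.null(fp)) min(as.numeric(fp[cl$cells[, 1]])) else min(cl$cells[, 1]),
               fP_max = if (!is.null(fp)) max(as.numeric(fp[cl$cells[, 1]])) else max(cl$cells[, 1]),
               fA_min = if (!is.null(fa)) min(as.numeric(fa[cl$cells[, 2]])) else min(cl$cells[, 2]),
               fA_max = if (!is.null(fa)) max(as.numeric(fa[cl$cells[, 2]])) else max(cl$cells[, 2]))
  })
  structure(list(clusters = if (length(rows)) do.call(rbind, rows) else
                   data.frame(cluster_id = integer(), n_cells = integer(),
                              mass = numeric(), p_corrected = numeric(),
                              significant = logical(), peak_fP = numeric(),
                              peak_fA = numeric(), fP_min = numeric(),
                              fP_max = numeric(), fA_min = numeric(),
                              fA_max = numeric()),
                 cluster_cells = lapply(clusters, `[[`, "cells"),
                 t_map = tm$t_map, t_crit = t_crit, df = tm$df,
                 null_max_mass = null_max, params = params),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> one-tailed paired sign-flip test, %d permutations, t_crit = %.2f (df = %d)\n",
              x$params$n_permutations, x$t_crit, x$df))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}
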