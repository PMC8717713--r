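# Data-dependent temporal basis construction: shape clustering of voxel
# time-courses, cross-validation guided backwards elimination, and the
# residue-model (NPRM) variant with protected AIF and Patlak elements.

#' Temporal basis container
#'
#' @param X T x K matrix of sub-TACs evaluated at the frame mid-times.
#' @param names element names.
#' @param residues optional list of [residue_model()]s, one per column.
#' @param delays per-element arterial delays (minutes).
#' @param aif_col,patlak_col column indices of the AIF and Patlak elements
#'   (NA if absent).
#' @return object of class `temporal_basis`.
#' @export
temporal_basis <- function(X, names = NULL, residues = NULL, delays = NULL,
                           aif_col = NA_integer_, patlak_col = NA_integer_) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("basis needs at least one column")
  if (any(!is.finite(X))) stop("non-finite basis entries")
  if (any(colSums(abs(X)) == 0)) stop("basis contains an all-zero column")
  if (is.null(names)) names <- paste0("mu", seq_len(ncol(X)))
  colnames(X) <- names
  if (is.null(delays)) delays <- rep(0, ncol(X))
  structure(list(X = X, residues = residues, delays = delays,
                 aif_col = as.integer(aif_col),
                 patlak_col = as.integer(patlak_col)),
            class = "temporal_basis")
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("temporal_basis: T = %d frames, K = %d elements (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

basis_matrix <- function(basis) {
  if (inherits(basis, "temporal_basis")) basis$X else as.matrix(basis)
}

#' Shape clustering of voxel time-courses
#'
#' Recursive bisection (2-means, largest within-cluster scatter first) on
#' weighted, unit-normalized time-courses, so members of a cluster are
#' approximate scalar multiples of the cluster mean.  Background voxels
#' (frame-weighted mean below 1% of the volume maximum) are excluded and
#' assigned cluster 0.
#'
#' @param study a [dynamic_image()] or N x T matrix.
#' @param target_clusters requested number of clusters L.
#' @param weights per-frame weights (strictly positive); default uniform.
#' @param seed integer seed (the split initialization is deterministic, the
#'   seed protects the k-means refinement).
#' @return object of class `cluster_set`: `assignment` (0..L per voxel),
#'   `means` (L x T raw-data cluster means), `sizes`.
#' @export
cluster_timecourses <- function(study, target_clusters, weights = NULL,
                                seed = 1L) {
  z <- if (inherits(study, "dynamic_image")) study$values else as.matrix(study)
  N <- nrow(z); T_ <- ncol(z)
  if (is.null(weights)) weights <- rep(1, T_)
  stopifnot(all(weights > 0), length(weights) == T_)
  L <- as.integer(target_clusters)
  if (L < 1L || L > N) stop("target_clusters must be in [1, N]")

  wbar <- weights / sum(weights)
  level <- as.numeric(z %*% wbar)
  fg <- which(level > 0.01 * max(level))
  if (!length(fg)) fg <- which.max(level)

  v <- z[fg, , drop = FALSE] * rep(sqrt(weights), each = length(fg))
  nrm <- sqrt(rowSums(v^2))
  v <- v / pmax(nrm, 1e-300)

  assign_fg <- rep(1L, length(fg))
  n_cl <- 1L
  sse <- function(idx) {
    if (length(idx) < 2L) return(0)
    ctr <- colMeans(v[idx, , drop = FALSE])
    sum(sweep(v[idx, , drop = FALSE], 2, ctr)^2)
  }
  scatter <- c(sse(seq_along(fg)))
  with_seed(seed, {
    while (n_cl < L) {
      cand <- order(scatter, decreasing = TRUE)
      split_done <- FALSE
      for (cl in cand) {
        idx <- which(assign_fg == cl)
        if (length(idx) < 2L || scatter[cl] <= 1e-24) next
        vv <- v[idx, , drop = FALSE]
        ctr <- colMeans(vv)
        d0 <- rowSums(sweep(vv, 2, ctr)^2)
        c1 <- vv[which.max(d0), ]
        d1 <- rowSums(sweep(vv, 2, c1)^2)
        c2 <- vv[which.max(d1), ]
        km <- suppressWarnings(
          stats::kmeans(vv, centers = rbind(c1, c2), iter.max = 50L))
        if (length(unique(km$cluster)) < 2L) next
        n_cl <- n_cl + 1L
        assign_fg[idx[km$cluster == 2L]] <- n_cl
        scatter[cl] <- sse(which(assign_fg == cl))
        scatter[n_cl] <- sse(which(assign_fg == n_cl))
        split_done <- TRUE
        break
      }
      if (!split_done) {
        warning(sprintf(
          "only %d distinct shapes available; returning %d clusters",
          n_cl, n_cl))
        break
      }
    }
  })
  assignment <- integer(N)
  assignment[fg] <- assign_fg
  means <- t(vapply(seq_len(n_cl), function(l) {
    colMeans(z[fg[assign_fg == l], , drop = FALSE])
  }, numeric(T_)))
  sizes <- as.integer(tabulate(assign_fg, n_cl))
  structure(list(assignment = assignment, means = means, sizes = sizes,
                 L = n_cl, weights = weights),
            class = "cluster_set")
}

# weighted NNLS representation error of each cluster mean in candidate set S
gcv_score <- function(candidates, means, sizes, weights, S) {
  T_ <- ncol(means)
  if (length(S) >= T_) stop("GCV undefined for |S| >= T (ill-posed basis)")
  sw <- sqrt(weights)
  A <- t(candidates[S, , drop = FALSE]) * sw      # T x |S|
  B <- t(means) * sw                              # T x L
  coefs <- .nnls_multi(A, B)
  wrss <- colSums((B - A %*% coefs)^2)
  sum(sizes * wrss) / (1 - length(S) / T_)^2
}

#' Cross-validation guided backwards elimination of basis candidates
#'
#' Starting from the full candidate set, greedily removes the column whose
#' removal minimizes the generalized cross-validation score
#' `GCV(S) = sum_l |C_l| WRSS_l(S) / (1 - |S|/T)^2`, where `WRSS_l` is the
#' weighted non-negative least-squares representation error of the l'th
#' cluster mean in the candidate subset S.  Elimination continues to
#' `min_k` columns and the subset with the smallest GCV along the path is
#' returned.  Protected columns are never eliminated; ties are broken by
#' the lowest column index.
#'
#' @param initial_basis candidate sub-TACs, a K0 x T matrix (rows are
#'   candidates).
#' @param cluster_means a `cluster_set` (or list with `means`, `sizes`).
#' @param weights per-frame weights.
#' @param min_k minimum retained subset size.
#' @param protect integer indices of protected candidates.
#' @return a `temporal_basis` (columns = surviving candidates, original
#'   order) with attributes `selected` (indices) and `gcv_path`.
#' @export
backward_eliminate <- function(initial_basis, cluster_means, weights = NULL,
                               min_k = 2L, protect = integer(0)) {
  cand <- as.matrix(initial_basis)
  T_ <- ncol(cand); K0 <- nrow(cand)
  if (is.null(weights)) weights <- rep(1, T_)
  if (K0 >= T_)
    stop("initial basis has |S| >= T columns: GCV undefined (ill-posed)")
  means <- cluster_means$means; sizes <- cluster_means$sizes
  stopifnot(ncol(means) == T_, length(sizes) == nrow(means))
  min_k <- max(as.integer(min_k), length(protect), 1L)

  S <- seq_len(K0)
  path <- list(list(S = S, gcv = gcv_score(cand, means, sizes, weights, S)))
  while (length(S) > min_k) {
    removable <- setdiff(S, protect)
    if (!length(removable)) break
    scores <- vapply(removable, function(j) {
      gcv_score(cand, means, sizes, weights, setdiff(S, j))
    }, 0)
    drop_j <- removable[which.min(scores)]   # which.min: lowest index on tie
    S <- setdiff(S, drop_j)
    path[[length(path) + 1L]] <- list(S = S, gcv = min(scores))
  }
  gcvs <- vapply(path, `[[`, 0, "gcv")
  best <- path[[max(which(gcvs <= min(gcvs) + 1e-12))]]$S
  nm <- rownames(cand) %||% paste0("c", seq_len(K0))
  out <- temporal_basis(t(cand[best, , drop = FALSE]), names = nm[best])
  attr(out, "selected") <- best
  attr(out, "gcv_path") <- gcvs
  out
}

#' Build the NPRM temporal basis
#'
#' Replaces each cluster-mean time-course by its monotone residue-model fit
#' (falling back to the raw mean with a warning when the fit fails),
#' prepends the protected AIF element (spiked residue, duration <= 5 s) and
#' Patlak element (constant residue, sub-TAC = running integral of the
#' input function), and delegates subset selection to
#' [backward_eliminate()].
#'
#' @param cluster_means a `cluster_set` from [cluster_timecourses()].
#' @param aif an [input_function()] covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param weights per-frame weights for elimination and residue fitting.
#' @param min_k minimum basis size (>= 2: AIF + Patlak).
#' @param delay_grid candidate delays for the residue fits.
#' @return a `temporal_basis` with residues, delays, and AIF/Patlak flags.
#' @export
build_nprm_basis <- function(cluster_means, aif, schedule, weights = NULL,
                             min_k = 2L,
                             delay_grid = seq(0, 0.5, by = 2.5 / 60)) {
  means <- cluster_means$means
  L <- nrow(means); T_ <- ncol(means)
  if (is.null(weights)) weights <- rep(1, T_)
  T_end <- max(schedule$mid_times + schedule$durations / 2)

  R_aif <- spike_residue(duration = 5 / 60, T_E = T_end)
  R_pat <- constant_residue(1, T_E = T_end)
  residues <- list(R_aif, R_pat)
  cols <- list(residue_subtac(R_aif, aif, schedule),
               residue_subtac(R_pat, aif, schedule))
  names_ <- c("aif", "patlak")
  for (l in seq_len(L)) {
    Rl <- tryCatch(
      fit_residue_model(means[l, ], aif, schedule, weights = weights,
                        delay_grid = delay_grid),
      error = function(e) NULL)
    if (is.null(Rl) || all(Rl$values == 0)) {
      warning("residue fit failed for cluster ", l,
              "; using raw cluster mean")
      residues[l + 2L] <- list(NULL)
      cols[[l + 2L]] <- means[l, ]
    } else {
      residues[[l + 2L]] <- Rl
      cols[[l + 2L]] <- residue_subtac(Rl, aif, schedule)
    }
    names_ <- c(names_, paste0("cluster", l))
  }
  keep <- vapply(cols, function(v) any(abs(v) > 0), TRUE)
  cols <- cols[keep]; names_ <- names_[keep]
  residues <- residues[which(keep)]
  cand <- do.call(rbind, cols)
  rownames(cand) <- names_
  if (nrow(cand) >= T_) {
    stop("candidate count (", nrow(cand), ") must be < T (", T_, "); ",
         "reduce target_clusters")
  }
  sel <- backward_eliminate(cand, cluster_means, weights = weights,
                            min_k = max(min_k, 2L), protect = c(1L, 2L))
  idx <- attr(sel, "selected")
  delays <- vapply(residues[idx], function(r) r$delay %||% 0, 0)
  out <- temporal_basis(sel$X, names = names_[idx],
                        residues = residues[idx], delays = delays,
                        aif_col = match(1L, idx),
                        patlak_col = match(2L, idx))
  attr(out, "gcv_path") <- attr(sel, "gcv_path")
  out
}
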