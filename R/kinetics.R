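# Non-parametric residue mapping of kinetic parameters: voxel-level
# non-negative fits and the linear maps from coefficients to parameter
# images.  Parameter columns are V_b (vascular blood volume), V_d
# (distribution volume), K_d (flow, 1/min), K_i (flux, 1/min), MTT
# (minutes) and extraction K_i / K_1 with K_1 = K_i + K_d.

KINETIC_PARAMS <- c("Vb", "Vd", "Kd", "Ki", "MTT", "KiK1")

#' Voxel-level non-negative least squares coefficients
#'
#' Per-voxel weighted NNLS fit of the data onto the basis sub-TACs; the
#' implied voxel residue is the same non-negative combination of the basis
#' residues.
#'
#' @param z N x T data matrix or [dynamic_image()].
#' @param X T x K basis (or `temporal_basis`).
#' @param w per-frame weights.
#' @return N x K non-negative coefficient matrix.
#' @export
nnls_map <- function(z, X, w) {
  if (inherits(z, "dynamic_image")) z <- z$values
  X <- basis_matrix(X)
  T_ <- ncol(z)
  stopifnot(nrow(X) == T_, length(w) == T_, all(w > 0))
  if (qr(X)$rank < ncol(X))
    stop("singular design: basis columns are linearly dependent")
  sw <- sqrt(w)
  t(.nnls_multi(X * sw, t(z) * sw))
}

#' Per-element kinetic summaries of a basis
#'
#' @param basis a `temporal_basis` carrying residues and delays.
#' @param T_B vascular bound (minutes).
#' @param T_E evaluation horizon (minutes; default: end of each residue
#'   grid).
#' @return data frame with one row per basis element: `V_B, K_D, V_D, K_i,
#'   delay`.
#' @export
basis_kinetic_summaries <- function(basis, T_B = 1 / 12, T_E = NULL) {
  stopifnot(inherits(basis, "temporal_basis"))
  if (is.null(basis$residues))
    stop("basis has no residue models; use an NPRM basis")
  rows <- lapply(seq_along(basis$residues), function(k) {
    R <- basis$residues[[k]]
    if (is.null(R))
      return(data.frame(V_B = 0, K_D = 0, V_D = 0, K_i = 0, delay = 0))
    s <- residue_summaries(R, T_B = T_B,
                           T_E = T_E %||% max(R$times))
    as.data.frame(s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- colnames(basis$X)
  out
}

#' Kinetic parameter maps from non-negative coefficients
#'
#' Voxel maps by linearity of the residue decomposition:
#' `V_b = sum_k alpha_k V_Bk` and similarly for `V_d`, `K_d`, `K_i`;
#' `K_1 = K_i + K_d`; `MTT = sum_k w_k (delta_k + V_Dk / K_Dk)` with flow
#' weights `w_k ~ alpha_k K_Dk` (elements with zero flow excluded);
#' extraction `K_i / K_1` where `K_1 > 0`.  Voxels where a denominator
#' vanishes get `NA` (the undefined marker), not zero.
#'
#' @param alpha N x K non-negative coefficients.
#' @param summaries per-element summaries from [basis_kinetic_summaries()]
#'   (or a data frame with those columns).
#' @return N x 6 matrix with columns `Vb, Vd, Kd, Ki, MTT, KiK1`.
#' @export
kinetic_params <- function(alpha, summaries) {
  alpha <- as.matrix(alpha)
  K <- ncol(alpha)
  stopifnot(nrow(summaries) == K)
  if (any(alpha < -1e-9)) stop("alpha must be non-negative")
  alpha <- pmax(alpha, 0)
  Vb <- as.numeric(alpha %*% summaries$V_B)
  Kd <- as.numeric(alpha %*% summaries$K_D)
  Vd <- as.numeric(alpha %*% summaries$V_D)
  Ki <- as.numeric(alpha %*% summaries$K_i)
  K1 <- Ki + Kd
  # flow-weighted delay: elements with K_Dk = 0 carry no flow weight
  flow_w <- sweep(alpha, 2, summaries$K_D, "*")
  wsum <- rowSums(flow_w)
  delta_w <- ifelse(wsum > 0,
                    as.numeric(flow_w %*% summaries$delay) / wsum, NA_real_)
  MTT <- ifelse(Kd > 0, delta_w + Vd / Kd, NA_real_)
  KiK1 <- ifelse(K1 > 0, Ki / K1, NA_real_)
  out <- cbind(Vb = Vb, Vd = Vd, Kd = Kd, Ki = Ki, MTT = MTT, KiK1 = KiK1)
  out
}

#' Kinetic maps and uncertainty maps across bootstrap replicates
#'
#' Value replicates (image or projection domain) are refitted per replicate
#' with [nnls_map()]; coefficient replicates (recycled) skip refitting and
#' are clamped at zero before mapping.  Returns per-voxel means and
#' standard deviations across replicates of every kinetic parameter, plus
#' the per-replicate maps.
#'
#' @param samples a `bootstrap_set`, or list of N x T value matrices /
#'   N x K coefficient matrices.
#' @param basis `temporal_basis` with residues.
#' @param w per-frame weights (used for value replicates).
#' @param T_B,T_E passed to [basis_kinetic_summaries()].
#' @return list with `mean` and `sd` (N x 6 matrices; SD statistics skip
#'   undefined markers) and `maps` (list of per-replicate N x 6 matrices).
#' @export
map_bootstrap_kinetics <- function(samples, basis, w, T_B = 1 / 12,
                                   T_E = NULL) {
  kind <- if (inherits(samples, "bootstrap_set")) samples$kind else "image"
  reps <- if (inherits(samples, "bootstrap_set")) samples$replicates
          else samples
  summaries <- basis_kinetic_summaries(basis, T_B = T_B, T_E = T_E)
  K <- ncol(basis$X)
  maps <- lapply(reps, function(rep_data) {
    alpha <- if (kind == "recycled") {
      stopifnot(ncol(rep_data) == K)
      pmax(rep_data, 0)
    } else {
      nnls_map(rep_data, basis, w)
    }
    kinetic_params(alpha, summaries)
  })
  arr <- simplify2array(maps)     # N x 6 x B
  mean_map <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sd_map <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  mean_map[!is.finite(mean_map)] <- NA_real_
  sd_map[!is.finite(sd_map)] <- NA_real_
  colnames(mean_map) <- colnames(sd_map) <- KINETIC_PARAMS
  list(mean = mean_map, sd = sd_map, maps = maps)
}

#' Bootstrap distribution of a VOI percentile
#'
#' For each replicate map, computes the q-th percentile of one parameter
#' within the mask; the returned sample underlies histograms and bootstrap
#' tests of VOI differences.
#'
#' @param maps list of per-replicate N x P parameter matrices (e.g.
#'   `map_bootstrap_kinetics()$maps`).
#' @param mask a [voi_mask()].
#' @param q percentile in `[0, 100]`.
#' @param parameter column name or index.
#' @return numeric vector, one percentile per replicate.
#' @export
voi_percentile_distribution <- function(maps, mask, q = 95,
                                        parameter = "Ki") {
  stopifnot(inherits(mask, "voi_mask"))
  idx <- which(mask$indicator)
  if (!length(idx)) stop("empty VOI mask")
  vapply(maps, function(m) {
    v <- m[idx, parameter]
    stats::quantile(v, probs = q / 100, na.rm = TRUE, names = FALSE,
                    type = 7)
  }, 0)
}

#' Write kinetic parameter maps as NIfTI volumes
#'
#' @param maps N x P parameter matrix (e.g. the `mean` or `sd` component of
#'   [map_bootstrap_kinetics()]).
#' @param grid a [voxel_grid()].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return character vector of the written paths.
#' @export
write_kinetic_maps <- function(maps, grid, dir, prefix = "param") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in colnames(maps)) {
    v <- maps[, p]
    v[!is.finite(v)] <- 0
    path <- file.path(dir, sprintf("%s_%s.nii", prefix, p))
    write_nifti(array(v, dim = grid$dim), path, spacing = grid$spacing)
    paths <- c(paths, path)
  }
  paths
}
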