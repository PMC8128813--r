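# Principal component reduction of the nine texture maps.

#' Fit a PCA model on pooled texture-map voxels
#'
#' Features are standardised per-feature by the training mean and standard
#' deviation, then decomposed; the number of retained components is the
#' smallest count whose cumulative explained variance reaches
#' `variance_target`, capped at `m_cap`. If even `m_cap` components fall
#' below the target the model is flagged (`capped = TRUE`) and `m_cap`
#' components are kept.
#'
#' @param training_stacks a [texture_map_stack()] or list of them.
#' @param m_cap maximum retained components (default 6).
#' @param variance_target cumulative explained-variance fraction to reach
#'   (default 0.90).
#' @return Object of class `pca_model` with fields `mean`, `scale`,
#'   `loadings` (9 x m, orthonormal columns), `explained` (all 9 fractions,
#'   non-increasing), `m`, `capped`.
#' @export
fit_pca <- function(training_stacks, m_cap = 6L, variance_target = 0.90) {
  if (inherits(training_stacks, "texture_map_stack"))
    training_stacks <- list(training_stacks)
  X <- do.call(rbind, lapply(training_stacks, function(s)
    s$features[s$valid, , drop = FALSE]))
  d <- ncol(X)
  if (nrow(X) < d)
    stop("insufficient training data: fewer voxels than features")
  if (nrow(X) < 10 * d)
    warning("fewer than 10 voxels per feature; PCA may be unstable")
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  zero_var <- sc <= .Machine$double.eps
  if (any(zero_var)) {
    warning(sprintf("feature(s) with zero variance excluded from standardisation: %s",
                    paste(colnames(X)[zero_var], collapse = ", ")))
    sc[zero_var] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sc, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(explained)
  m <- which(cum >= variance_target)[1]
  capped <- FALSE
  if (is.na(m) || m > m_cap) {
    m <- as.integer(m_cap)
    capped <- cum[m] < variance_target
    if (capped)
      warning(sprintf(
        "cumulative explained variance %.3f below target %.2f at the %d-component cap",
        cum[m], variance_target, m))
  }
  structure(list(mean = mu, scale = sc,
                 loadings = pc$rotation[, seq_len(m), drop = FALSE],
                 explained = explained, m = as.integer(m), capped = capped,
                 variance_target = variance_target,
                 feature_names = colnames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components retained (%.1f%% of variance%s)\n",
              x$m, 100 * sum(x$explained[seq_len(x$m)]),
              if (x$capped) ", capped" else ""))
  invisible(x)
}

#' Project a texture map stack onto a fitted PCA model
#'
#' @param stack a [texture_map_stack()].
#' @param pca a [pca_model] from [fit_pca()] or [read_pca_model()].
#' @return Matrix (n_valid x m) of per-voxel principal component scores.
#' @export
project_pca <- function(stack, pca) {
  if (!inherits(pca, "pca_model")) stop("pca must be a pca_model")
  X <- stack$features[stack$valid, , drop = FALSE]
  if (ncol(X) != length(pca$mean))
    stop("stack/model feature dimension mismatch")
  Z <- sweep(sweep(X, 2, pca$mean), 2, pca$scale, "/")
  Z %*% pca$loadings
}

#' Serialise a PCA model to JSON
#'
#' A portable representation so that a model fitted on one cohort can be
#' re-used as a fixed reference on new lesions.
#'
#' @param pca a `pca_model`.
#' @param path output .json file.
#' @return Invisibly, `path`.
#' @export
write_pca_model <- function(pca, path) {
  obj <- list(mean = unname(pca$mean), scale = unname(pca$scale),
              loadings = unname(pca$loadings), explained = pca$explained,
              m = pca$m, capped = pca$capped,
              variance_target = pca$variance_target,
              feature_names = pca$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialised PCA model
#'
#' @param path .json file written by [write_pca_model()].
#' @return A `pca_model`.
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(as.numeric(obj$loadings), ncol = obj$m)
  structure(list(mean = as.numeric(obj$mean), scale = as.numeric(obj$scale),
                 loadings = loadings, explained = as.numeric(obj$explained),
                 m = as.integer(obj$m), capped = isTRUE(obj$capped),
                 variance_target = obj$variance_target,
                 feature_names = obj$feature_names),
            class = "pca_model")
}
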