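# Principal components of elliptic Fourier descriptors.  The study ran
# two PCAs on the 100-coefficient descriptors: a strain-diversity PCA
# (components prefixed "s") and a mapping-experiment PCA over all mapping
# flies and their progenitors (prefix "m"); mPC1 is the mapped shape
# trait.

#' Principal components of a shape-descriptor matrix
#'
#' Wraps [stats::prcomp()] (centered, unscaled, as in the study) with a
#' deterministic sign convention: each component is flipped, if needed, so
#' a designated reference row scores nonnegatively on it.  With the
#' reference chosen as a parent-B-like (Sam-like) outline, a higher PC1
#' means a more Sam-like (squatter, lower H:W) lobe.
#'
#' @param X Outlines-by-descriptors numeric matrix (no missing values).
#' @param ref Row index of the sign-reference outline (default: row 1).
#' @param prefix Component-name prefix: `"m"` for mapping-style, `"s"` for
#'   diversity-style.
#' @return Object of class `shape_space`: `loadings`, `center`, `scores`,
#'   `var_frac` (fractions of variance, summing to 1), `prefix`.
#' @export
shape_pca <- function(X, ref = 1L, prefix = "m") {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 outlines")
  if (anyNA(X)) stop("missing values in the descriptor matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- ifelse(pc$x[ref, ] < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  sco <- sweep(pc$x, 2, flip, `*`)
  v <- pc$sdev^2
  nm <- paste0(prefix, "PC", seq_along(v))
  colnames(rot) <- colnames(sco) <- nm
  structure(list(loadings = rot, center = pc$center, scores = sco,
                 var_frac = stats::setNames(v / sum(v), nm),
                 prefix = prefix),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space (", x$prefix, "-PCA): ", nrow(x$scores), " outlines, ",
      ncol(x$loadings), " components\n", sep = "")
  vf <- round(100 * x$var_frac[seq_len(min(6, length(x$var_frac)))], 1)
  cat("  % variance:", paste(names(vf), vf, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Project new descriptor rows into an existing shape space
#'
#' @param object A `shape_space`.
#' @param newdata Descriptor matrix with the columns the space was fit on.
#' @param ... Unused.
#' @return Score matrix.
#' @export
predict.shape_space <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$loadings
}
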