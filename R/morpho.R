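#' Landmark configuration set
#'
#' Container for a set of homologous landmark configurations: one `k x d`
#' coordinate block per specimen plus named substructure masks (subsets of
#' landmark indices such as neurocranium, viscerocranium and mandible).
#'
#' @param coords numeric array `n x k x d` (specimens by landmarks by
#'   dimensions, `d` 2 or 3).
#' @param specimen_ids character vector of length `n`.
#' @param masks named list of integer landmark-index vectors (1-based),
#'   each a subset of `1:k`. May be empty.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, specimen_ids = NULL, masks = list()) {
  if (length(dim(coords)) != 3L)
    stop("coords must be a 3-d array (specimens x landmarks x dims)")
  d <- dim(coords)[3L]
  if (!d %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  n <- dim(coords)[1L]
  k <- dim(coords)[2L]
  if (is.null(specimen_ids)) specimen_ids <- sprintf("spec%03d", seq_len(n))
  if (length(specimen_ids) != n) stop("specimen_ids length mismatch")
  for (m in names(masks)) {
    idx <- masks[[m]]
    if (any(idx < 1L | idx > k)) stop("mask '", m, "' indexes outside 1..k")
  }
  ## degenerate specimens (all landmarks identical) break superimposition
  for (i in seq_len(n)) {
    ci <- coords[i, , , drop = TRUE]
    if (all(abs(sweep(ci, 2, ci[1L, ], "-")) < .Machine$double.eps * 100))
      stop("specimen '", specimen_ids[i], "' has all-identical landmarks")
  }
  structure(list(coords = coords, specimen_ids = specimen_ids,
                 k = k, d = d, masks = masks),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", length(x$specimen_ids), "specimens,",
      x$k, "landmarks,", x$d, "dims\n")
  if (length(x$masks))
    cat("  masks:", paste(sprintf("%s(%d)", names(x$masks),
                                  lengths(x$masks)), collapse = ", "), "\n")
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared deviations of the landmarks from
#' their centroid -- the size measure extracted by a Procrustes fit.
#'
#' @param config numeric `k x d` matrix of landmark coordinates, `k >= 2`.
#' @return positive scalar, in the units of the coordinates.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 landmarks")
  dev <- sweep(config, 2, colMeans(config), "-")
  cs <- sqrt(sum(dev^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks identical")
  cs
}

## Optimal proper rotation (det = +1) taking X onto Y in the least-squares
## sense (Kabsch).  X, Y are k x d with centroids at the origin.
.rotation_onto <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- ncol(X)
  sg <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(rep(1, d - 1L), sg), d) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each configuration
#' is centred and scaled to unit centroid size, rotated onto the current
#' consensus by the proper-rotation (det = +1) solution of the
#' cross-covariance decomposition, and the consensus (mean shape, re-scaled
#' to unit centroid size) is updated until it stabilises.  Pre-alignment
#' centroid sizes are recorded: they are the size phenotype.
#'
#' @param landmarks a [landmark_set].
#' @param mask optional mask name (or integer landmark indices) restricting
#'   the fit to a substructure.
#' @param tol convergence tolerance on the root-summed-squared change of the
#'   consensus between iterations.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return An object of class `gpa_fit` with elements `aligned`
#'   (`n x k x d`), `centroid_sizes` (pre-alignment, per specimen),
#'   `consensus` (`k x d`, unit centroid size), `iterations`, `converged`.
#' @export
gpa <- function(landmarks, mask = NULL, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(landmarks, "landmark_set"))
  idx <- .resolve_mask(landmarks, mask)
  coords <- landmarks$coords[, idx, , drop = FALSE]
  n <- dim(coords)[1L]
  if (n < 2L) stop("need at least 2 specimens")
  k <- dim(coords)[2L]; d <- dim(coords)[3L]

  cs <- numeric(n)
  conf <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- matrix(coords[i, , ], k, d)
    cs[i] <- centroid_size(ci)
    ci <- sweep(ci, 2, colMeans(ci), "-")
    conf[[i]] <- ci / cs[i]
  }

  ## symmetric (order-invariant) initialization: mean of the scaled configs
  consensus <- Reduce(`+`, conf) / n
  consensus <- sweep(consensus, 2, colMeans(consensus), "-")
  consensus <- consensus / centroid_size(consensus)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) conf[[i]] <- conf[[i]] %*% .rotation_onto(conf[[i]], consensus)
    newc <- Reduce(`+`, conf) / n
    newc <- sweep(newc, 2, colMeans(newc), "-")
    newc <- newc / centroid_size(newc)
    delta <- sqrt(sum((newc - consensus)^2))
    consensus <- newc
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")

  ## canonical orientation: rotate the whole solution so the consensus
  ## principal axes coincide with the coordinate axes (deterministic signs,
  ## det +1), making the output invariant to specimen order and to
  ## similarity transforms of the inputs
  Rc <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  for (j in seq_len(d)) {
    cj <- consensus %*% Rc[, j]
    if (cj[which.max(abs(cj))] < 0) Rc[, j] <- -Rc[, j]
  }
  if (det(Rc) < 0) Rc[, d] <- -Rc[, d]
  consensus <- consensus %*% Rc
  for (i in seq_len(n)) conf[[i]] <- conf[[i]] %*% Rc

  aligned <- array(NA_real_, c(n, k, d),
                   dimnames = list(landmarks$specimen_ids, NULL, NULL))
  for (i in seq_len(n)) aligned[i, , ] <- conf[[i]]
  structure(list(aligned = aligned,
                 centroid_sizes = stats::setNames(cs, landmarks$specimen_ids),
                 consensus = consensus, iterations = iter,
                 converged = converged, landmark_index = idx, d = d),
            class = "gpa_fit")
}

.resolve_mask <- function(landmarks, mask) {
  if (is.null(mask)) return(seq_len(landmarks$k))
  if (is.character(mask)) {
    if (!mask %in% names(landmarks$masks))
      stop("unknown mask '", mask, "'")
    return(landmarks$masks[[mask]])
  }
  mask <- as.integer(mask)
  if (any(mask < 1L | mask > landmarks$k)) stop("mask indices out of range")
  mask
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("gpa_fit:", dim(x$aligned)[1L], "specimens aligned in", x$iterations,
      "iterations (converged:", x$converged, ")\n")
  invisible(x)
}

## Flatten aligned shapes to an n x (k*d) matrix (landmark-major:
## x1,y1[,z1],x2,...) so regression/PCA operate on coordinate vectors.
flatten_shapes <- function(x) {
  if (inherits(x, "gpa_fit")) x <- x$aligned
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1L]; k <- dim(x)[2L]; d <- dim(x)[3L]
  out <- matrix(NA_real_, n, k * d)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(matrix(x[i, , ], k, d)))
  rownames(out) <- dimnames(x)[[1L]]
  out
}

#' Allometric regression of shape on a size predictor
#'
#' Multivariate least squares of the aligned shape coordinates on a single
#' size predictor (typically the neurocranium centroid size, used as a proxy
#' of body size).  The percentage of pooled shape variance predicted by size
#' is assessed by a permutation test that shuffles the predictor across
#' specimens.  The residuals carry the size-corrected shape variation and
#' feed [shape_pca()].
#'
#' @param shapes a [gpa] fit, an `n x k x d` array, or an `n x (k*d)` matrix
#'   of shape coordinates.
#' @param predictor positive per-specimen size values (same order as shapes).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation draw (mandatory).
#' @return An object of class `allometry_fit` with `residuals`
#'   (`n x (k*d)`), `pct_predicted` (0..100), `perm_p`, `n_perm`, `slope`
#'   (length `k*d`, shape change per unit predictor), `fitted`.
#' @export
allometric_regression <- function(shapes, predictor, n_perm = 10000L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  Y <- if (is.matrix(shapes)) shapes else flatten_shapes(shapes)
  n <- nrow(Y)
  if (length(predictor) != n) stop("predictor length must match specimen count")
  if (any(predictor <= 0)) stop("predictor values must be positive")
  if (stats::sd(predictor) == 0) stop("constant predictor: regression undefined")

  Yc <- sweep(Y, 2, colMeans(Y), "-")
  xc <- predictor - mean(predictor)
  sxx <- sum(xc^2)
  b <- drop(crossprod(Yc, xc)) / sxx          # per-coordinate slope
  fitted <- outer(xc, b)
  resid <- Yc - fitted
  ss_tot <- sum(Yc^2)
  ss_mod <- sum(b^2) * sxx
  pct <- 100 * ss_mod / ss_tot

  set.seed(seed)
  nb <- as.integer(n_perm)
  Xp <- matrix(xc[vapply(seq_len(nb), function(i) sample.int(n), integer(n))], n, nb)
  P <- crossprod(Yc, Xp)                      # (k*d) x n_perm
  pct_perm <- 100 * colSums(P^2) / (colSums(Xp^2) * ss_tot)
  perm_p <- (1 + sum(pct_perm >= pct)) / (nb + 1)

  structure(list(residuals = resid, pct_predicted = pct, perm_p = perm_p,
                 n_perm = nb, slope = b, fitted = fitted,
                 predictor = predictor),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("allometry_fit: %.1f%% of shape variance predicted by size (permutation p = %.4g, %d permutations)\n",
              x$pct_predicted, x$perm_p, x$n_perm))
  invisible(x)
}

#' Principal component analysis of shape residuals
#'
#' Eigendecomposition of the specimen covariance matrix of the (allometry-
#' corrected) shape coordinates; scores are the centred residuals projected
#' on the loadings.  Sign convention: within each component the
#' largest-magnitude loading element is made positive, so results are
#' deterministic; see [orient_pc()] to impose a biological polarity.
#'
#' @param residuals `n x p` matrix (e.g. `allometry_fit$residuals`).
#' @return An object of class `shape_pca` with orthonormal `loadings`
#'   (`p x r`), `scores` (`n x r`) and `var_fraction` (length `r`,
#'   non-increasing, summing to 1).
#' @export
shape_pca <- function(residuals) {
  if (inherits(residuals, "allometry_fit")) residuals <- residuals$residuals
  Y <- as.matrix(residuals)
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 specimens")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  sv <- svd(Yc)
  r <- sum(sv$d > sv$d[1L] * 1e-12)
  r <- max(r, 1L)
  load <- sv$v[, seq_len(r), drop = FALSE]
  ## fix signs: largest-magnitude element of each loading made positive
  for (j in seq_len(r)) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Yc %*% load
  ev <- sv$d[seq_len(r)]^2
  structure(list(loadings = load, scores = scores,
                 var_fraction = ev / sum(sv$d^2)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- utils::head(x$var_fraction, 3)
  cat("shape_pca:", ncol(x$scores), "components;",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", "),
      "\n")
  invisible(x)
}

#' Orient a principal component against a reference group
#'
#' PCA component polarity is arbitrary; this flips the requested component
#' so that the mean score of a designated reference group (e.g. the
#' brachycephalic specimens) is negative, matching the field convention of
#' reporting shortened-rostrum shapes at negative PC1.
#'
#' @param pca a [shape_pca] object.
#' @param reference logical or integer index of the reference specimens.
#' @param component which component to orient (default 1).
#' @return the `shape_pca` object with the component (scores and loadings)
#'   possibly negated.
#' @export
orient_pc <- function(pca, reference, component = 1L) {
  stopifnot(inherits(pca, "shape_pca"))
  m <- mean(pca$scores[reference, component])
  if (is.na(m)) stop("reference selects no specimens")
  if (m > 0) {
    pca$scores[, component] <- -pca$scores[, component]
    pca$loadings[, component] <- -pca$loadings[, component]
  }
  pca
}

#' Two-group t test on component scores
#'
#' Two-sided Student's (pooled, default) or Welch t test of PC scores
#' between exactly two groups, as used to compare knockout versus control
#' skull shapes.
#'
#' @param scores numeric vector of per-specimen scores.
#' @param group_labels factor-like with exactly two levels, each `n >= 2`.
#' @param pooled use the pooled-variance Student's statistic (default);
#'   `FALSE` for Welch.
#' @return list with `statistic`, `df`, `p.value`, group means.
#' @export
group_pc_test <- function(scores, group_labels, pooled = TRUE) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  ht <- stats::t.test(scores ~ g, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value,
       means = stats::setNames(as.numeric(ht$estimate), levels(g)))
}

#' Average object-symmetric landmark configurations
#'
#' Optional pre-step emulating object-symmetry averaging: each configuration
#' is reflected, left/right-paired landmarks are relabelled, the reflected
#' copies are re-superimposed with the originals and the two are averaged.
#' Requires a left/right pairing map; unpaired (midline) landmarks map to
#' themselves.
#'
#' @param landmarks a [landmark_set].
#' @param pairing two-column integer matrix of (left, right) landmark
#'   indices.
#' @param axis coordinate axis to reflect (default 1).
#' @return a new `landmark_set` of symmetrised configurations.
#' @export
symmetrize_landmarks <- function(landmarks, pairing, axis = 1L) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pairing <- as.matrix(pairing)
  perm <- seq_len(landmarks$k)
  perm[pairing[, 1L]] <- pairing[, 2L]
  perm[pairing[, 2L]] <- pairing[, 1L]
  co <- landmarks$coords
  n <- dim(co)[1L]
  out <- co
  for (i in seq_len(n)) {
    orig <- matrix(co[i, , ], landmarks$k, landmarks$d)
    refl <- orig
    refl[, axis] <- -refl[, axis]
    refl <- refl[perm, , drop = FALSE]
    ## superimpose the relabelled reflection back onto the original
    oc <- sweep(orig, 2, colMeans(orig), "-")
    rc <- sweep(refl, 2, colMeans(refl), "-")
    rc <- rc * (centroid_size(oc) / centroid_size(rc))
    rc <- rc %*% .rotation_onto(rc, oc)
    out[i, , ] <- (oc + rc) / 2
  }
  landmark_set(out, landmarks$specimen_ids, landmarks$masks)
}
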