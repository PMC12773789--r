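#' Principal components of the standardized unpredictability indices
#'
#' Z-scores the four indices (sample standard deviation) and
#' eigendecomposes their correlation matrix — equivalent to covariance PCA
#' on the standardized data, which is what standardizing to mean 0 /
#' variance 1 forces. Components are sorted by descending eigenvalue and
#' each is sign-flipped so its loading on the variance-changepoint index is
#' non-negative; when that anchor loading is negligible (|loading| <= 0.1)
#' the component's largest-magnitude loading decides the flip instead, so
#' the orientation is never set by numerical noise. Scores are the z-data
#' projected on the unit-norm
#' eigenvectors; no rotation is applied.
#'
#' @param stats_tbl Tibble with one row per family (needs `family_id` and
#'   the feature columns).
#' @param features Character vector of feature columns (default the four
#'   unpredictability indices).
#' @param k Components retained for the composite (default 2).
#' @return Object of class `unpred_pca`: `loadings` (features x components,
#'   unit-norm), `eigenvalues`, `variance_explained` (proportions summing
#'   to 1 over all components), `scores` (tibble with `family_id` and
#'   `PC1`..), centering/scaling vectors, `k`.
#' @export
fit_pca <- function(stats_tbl,
                    features = c("cv", "n_cpt_mean", "n_cpt_var", "noise_unpred"),
                    k = 2) {
  stopifnot(all(features %in% names(stats_tbl)), k >= 1, k <= length(features))
  if (nrow(stats_tbl) < 5) stop("need at least 5 families to fit a PCA",
                                call. = FALSE)
  M <- as.matrix(stats_tbl[features])
  sds <- apply(M, 2, sd)
  zero <- features[sds == 0 | !is.finite(sds)]
  if (length(zero)) {
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  mus <- colMeans(M)
  Z <- scale(M, center = mus, scale = sds)
  eig <- eigen(stats::cor(M), symmetric = TRUE)
  vecs <- eig$vectors
  vals <- pmax(eig$values, 0)
  # orientation: anchor on the variance-changepoint loading when it carries
  # real weight; a near-zero anchor would make the sign arbitrary, so fall
  # back to the largest-magnitude loading of that component
  ref_row <- match("n_cpt_var", features)
  for (j in seq_len(ncol(vecs))) {
    s <- if (!is.na(ref_row) && abs(vecs[ref_row, j]) > 0.1) {
      vecs[ref_row, j]
    } else {
      vecs[which.max(abs(vecs[, j])), j]
    }
    if (s < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(features, paste0("PC", seq_along(features)))
  scores <- Z %*% vecs
  structure(list(
    features = features,
    center = mus,
    scale = sds,
    loadings = vecs,
    eigenvalues = vals,
    variance_explained = vals / length(features),
    k = as.integer(k),
    n = nrow(stats_tbl),
    scores = dplyr::bind_cols(
      tibble(family_id = stats_tbl$family_id),
      as_tibble(scores)
    )
  ), class = "unpred_pca")
}

#' @export
print.unpred_pca <- function(x, ...) {
  cat("<unpred_pca> ", length(x$features), " features, n = ", x$n,
      ", retained k = ", x$k, "\n", sep = "")
  cat("variance explained:",
      paste0(sprintf("%.2f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Variance-explained-weighted composite unpredictability index
#'
#' One number per family: the weighted average of the retained component
#' scores, with each component's proportion of variance explained as its
#' weight (normalized to sum 1 over the retained components, the natural
#' reading of a weighted average; `normalize = FALSE` keeps the raw
#' variance-proportion weights for sensitivity runs).
#'
#' @param model A fitted [fit_pca()] object.
#' @param normalize Normalize weights to sum 1 (default TRUE).
#' @return Tibble: `family_id`, `composite`.
#' @export
composite_index <- function(model, normalize = TRUE) {
  stopifnot(inherits(model, "unpred_pca"))
  k <- model$k
  w <- model$variance_explained[seq_len(k)]
  if (normalize) w <- w / sum(w)
  S <- as.matrix(model$scores[paste0("PC", seq_len(k))])
  tibble(
    family_id = model$scores$family_id,
    composite = as.numeric(S %*% w)
  )
}

#' @rdname fit_pca
#' @param x An `unpred_pca` object.
#' @param ... Unused.
#' @export
tidy.unpred_pca <- function(x, ...) {
  tibble(
    component = rep(colnames(x$loadings), each = length(x$features)),
    feature = rep(x$features, times = ncol(x$loadings)),
    loading = as.numeric(x$loadings),
    eigenvalue = rep(x$eigenvalues, each = length(x$features)),
    variance_explained = rep(x$variance_explained, each = length(x$features))
  )
}

#' @rdname fit_pca
#' @export
glance.unpred_pca <- function(x, ...) {
  tibble(
    n = x$n,
    k = x$k,
    pc1_variance = x$variance_explained[1],
    pc2_variance = if (length(x$variance_explained) > 1) x$variance_explained[2] else NA_real_,
    retained_variance = sum(x$variance_explained[seq_len(x$k)])
  )
}

#' @rdname fit_pca
#' @param object An `unpred_pca` object.
#' @export
autoplot.unpred_pca <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$component %in% paste0("PC", seq_len(object$k)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$loading,
                                  fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~ .data$component) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "loading",
                  title = "Unpredictability index loadings") +
    ggplot2::theme_minimal()
}
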