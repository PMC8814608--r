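# De-novo signature extraction by non-negative matrix factorisation
# (Frobenius objective, multiplicative updates, multi-restart), rank
# selection by restart-cluster silhouette, cosine annotation against a
# reference catalogue, and per-sample exposure attribution by NNLS.

#' Cosine similarity between vectors or matrix columns
#'
#' @param a,b numeric vectors, or matrices compared column-by-column
#'   (`a` columns x `b` columns similarity matrix).
#' @return scalar or matrix of similarities in `[-1, 1]` (0 for a zero
#'   vector).
#' @export
cosine_similarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- as.matrix(a); b <- as.matrix(b)
    na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
    na[na == 0] <- Inf; nb[nb == 0] <- Inf
    return(crossprod(a, b) / outer(na, nb))
  }
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# One NMF run: X (n x m) ~ W (n x k) H (k x m), multiplicative updates for
# the Frobenius objective. Returns W, H, per-iteration objective.
nmf_once <- function(X, k, tol = 1e-6, max_iter = 2000L) {
  n <- nrow(X); m <- ncol(X)
  eps <- .Machine$double.eps
  mx <- mean(X)
  W <- matrix(stats::runif(n * k, min = eps, max = 1), n, k) * sqrt(mx)
  H <- matrix(stats::runif(k * m, min = eps, max = 1), k, m) * sqrt(mx)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((X - W %*% H)^2))
    obj <- c(obj, e)
    if (is.finite(prev) && (prev - e) < tol * max(prev, 1)) break
    prev <- e
  }
  list(W = W, H = H, objective = obj, error = obj[length(obj)])
}

#' Extract de-novo mutational signatures by NMF
#'
#' Factorises a catalog into `k` nonnegative signatures and per-sample
#' exposures, minimising the Frobenius reconstruction error with
#' multiplicative updates. The best of `n_restarts` random initialisations
#' is kept; the run is deterministic given `seed`. Signatures are
#' column-normalised to sum to 1 with the scale pushed into the exposures,
#' so each sample's exposures are on the mutation-count scale.
#'
#' @param catalog a `mutscape_catalog` (or samples x channels matrix).
#' @param k number of signatures, `1 <= k <= min(n_samples, n_channels)`.
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed.
#' @param tol relative-improvement convergence tolerance (default 1e-6).
#' @param max_iter update-iteration cap (default 2000).
#' @return object of class `mutscape_signatures`: list with
#'   `signatures` (channels x k, columns sum to 1), `exposures`
#'   (samples x k), `dominant` (per-sample index of the largest relative
#'   exposure, NA for empty samples), and `diagnostics` (reconstruction
#'   error, objective trace of the best run, restarts, seed).
#' @export
extract_signatures <- function(catalog, k, n_restarts = 20L, seed = 1L,
                               tol = 1e-6, max_iter = 2000L) {
  X <- if (inherits(catalog, "mutscape_catalog")) catalog$counts else catalog
  X <- as.matrix(X)
  if (all(X == 0)) stop("all-zero catalog: nothing to factorise")
  if (k < 1L || k > min(nrow(X), ncol(X))) {
    stop("k must be in [1, min(n_samples, n_channels)]")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    fit <- nmf_once(X, k, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  sig <- t(best$H)                       # channels x k
  scale <- colSums(sig)
  scale[scale == 0] <- 1
  sig <- sweep(sig, 2, scale, "/")
  expo <- sweep(best$W, 2, scale, "*")   # samples x k
  colnames(sig) <- colnames(expo) <- paste0("S", seq_len(k))
  rownames(sig) <- colnames(X)
  rownames(expo) <- rownames(X)
  tot <- rowSums(expo)
  dominant <- ifelse(tot > 0, max.col(expo / pmax(tot, .Machine$double.eps),
                                      ties.method = "first"), NA_integer_)
  names(dominant) <- rownames(X)
  structure(list(
    signatures = sig, exposures = expo, dominant = dominant,
    diagnostics = list(error = best$error, objective = best$objective,
                       n_restarts = n_restarts, seed = seed, k = k)),
    class = "mutscape_signatures")
}

#' @export
print.mutscape_signatures <- function(x, ...) {
  cat("mutscape signatures: k =", ncol(x$signatures), "on",
      nrow(x$signatures), "channels,", nrow(x$exposures), "samples;",
      "reconstruction error", signif(x$diagnostics$error, 4), "\n")
  invisible(x)
}

# greedy one-to-one assignment maximising cosine similarity
match_signatures <- function(sim) {
  k <- nrow(sim)
  assign <- integer(k)
  s <- sim
  for (i in seq_len(k)) {
    idx <- arrayInd(which.max(s), dim(s))
    assign[idx[1]] <- idx[2]
    s[idx[1], ] <- -Inf; s[, idx[2]] <- -Inf
  }
  assign
}

# Mean silhouette width of restart signatures clustered by one-to-one
# matching against the best run (cosine distance). The one-to-one
# constraint is essential: when the factorisation rank exceeds the data
# rank, restarts produce near-duplicate signatures which a one-to-one
# matching forces into separate, poorly separated clusters, driving the
# silhouette down. k = 1 is a single perfect cluster by convention.
restart_silhouette <- function(sig_list, best_idx) {
  k <- ncol(sig_list[[best_idx]])
  if (k == 1L) return(1)
  labels <- unlist(lapply(sig_list, function(s)
    match_signatures(cosine_similarity(s, sig_list[[best_idx]]))))
  pool <- do.call(cbind, sig_list)
  d <- 1 - cosine_similarity(pool, pool)
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Choose the number of signatures by bootstrap stability
#'
#' For each candidate rank, factorises Poisson-resampled replicates of the
#' catalog (one per restart), matches every replicate's signatures
#' one-to-one to those of a reference fit on the original catalog, and
#' scores the resulting clustering by mean silhouette width under cosine
#' distance. Resampling is essential: repeated factorisations of the
#' identical noisy matrix reproduce the same noise-driven components and
#' overstate stability. The chosen rank is the largest one whose
#' silhouette reaches `silhouette_min`; if none does, the rank with the
#' highest silhouette is returned.
#'
#' @param catalog a `mutscape_catalog` or counts matrix.
#' @param k_range integer vector of candidate ranks.
#' @param seed integer seed.
#' @param n_restarts restarts per rank (default 10).
#' @param silhouette_min stability threshold (default 0.8).
#' @param ... passed to the NMF runs (`tol`, `max_iter`).
#' @return list with `k` (chosen rank) and `table` (data.table of rank,
#'   mean silhouette, best reconstruction error).
#' @export
select_k <- function(catalog, k_range = 1:6, seed = 1L, n_restarts = 10L,
                     silhouette_min = 0.8, ...) {
  if (length(k_range) == 0L) stop("k_range is empty")
  X <- if (inherits(catalog, "mutscape_catalog")) catalog$counts else catalog
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & k_range <= min(dim(X))]
  if (length(k_range) == 0L) stop("no admissible rank in k_range")
  norm_sig <- function(fit) {
    s <- t(fit$H)
    cs <- colSums(s); cs[cs == 0] <- 1
    sweep(s, 2, cs, "/")
  }
  rows <- lapply(k_range, function(k) {
    # reference fit on the original catalog (also supplies the error)
    set.seed(seed * 1000L + k * 100L)
    ref_fit <- nmf_once(X, k, ...)
    sigs <- vector("list", n_restarts + 1L)
    sigs[[1L]] <- norm_sig(ref_fit)
    for (r in seq_len(n_restarts)) {
      set.seed(seed * 1000L + k * 100L + r)
      Xr <- matrix(stats::rpois(length(X), lambda = X), nrow(X), ncol(X))
      sigs[[r + 1L]] <- norm_sig(nmf_once(Xr, k, ...))
    }
    data.table::data.table(
      k = k,
      silhouette = restart_silhouette(sigs, 1L),
      error = ref_fit$error)
  })
  tab <- data.table::rbindlist(rows)
  stable <- tab$k[tab$silhouette >= silhouette_min]
  k_hat <- if (length(stable) > 0L) max(stable) else tab$k[which.max(tab$silhouette)]
  list(k = k_hat, table = tab)
}

#' Read a reference signature matrix (COSMIC-style TSV)
#'
#' First column holds channel labels; remaining columns are reference
#' signatures (each summing to 1 up to rounding).
#'
#' @param path TSV path.
#' @return numeric matrix channels x signatures with channel rownames.
#' @export
read_signature_reference <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Annotate extracted signatures against a reference set
#'
#' Matches each extracted signature to the reference signature with the
#' highest cosine similarity; matches below `threshold` are reported as
#' `"novel"`.
#'
#' @param signature_set a `mutscape_signatures` object (or channels x k
#'   matrix with channel rownames).
#' @param reference channels x signatures matrix with channel rownames
#'   (see [read_signature_reference()]).
#' @param threshold minimum similarity to accept an annotation
#'   (default 0.75).
#' @return data.table with `signature`, `best_match`, `similarity`,
#'   `annotation` (best match or `"novel"`).
#' @export
cosine_annotate <- function(signature_set, reference, threshold = 0.75) {
  sig <- if (inherits(signature_set, "mutscape_signatures"))
    signature_set$signatures else as.matrix(signature_set)
  if (is.null(rownames(sig)) || is.null(rownames(reference))) {
    stop("both signature and reference matrices need channel rownames")
  }
  if (!setequal(rownames(sig), rownames(reference))) {
    stop("channel label mismatch between signatures and reference")
  }
  reference <- reference[rownames(sig), , drop = FALSE]
  sim <- cosine_similarity(sig, reference)
  best <- max.col(sim, ties.method = "first")
  best_sim <- sim[cbind(seq_len(nrow(sim)), best)]
  data.table::data.table(
    signature = colnames(sig),
    best_match = colnames(reference)[best],
    similarity = as.numeric(best_sim),
    annotation = ifelse(best_sim >= threshold,
                        colnames(reference)[best], "novel"))
}

#' Attribute per-sample exposures to fixed signatures
#'
#' Solves a nonnegative least-squares fit of each sample's channel counts
#' onto a fixed signature matrix.
#'
#' @param catalog a `mutscape_catalog` or samples x channels matrix.
#' @param signatures channels x k matrix (e.g. extracted or reference
#'   signatures); channel labels must match the catalog's.
#' @return list with `exposures` (samples x k), `residual` (per-sample
#'   Euclidean residual), `dominant` (per-sample argmax of relative
#'   exposure, NA when all-zero).
#' @export
attribute_exposures <- function(catalog, signatures) {
  X <- if (inherits(catalog, "mutscape_catalog")) catalog$counts else catalog
  X <- as.matrix(X)
  S <- as.matrix(signatures)
  if (!is.null(rownames(S)) && !is.null(colnames(X))) {
    if (!setequal(rownames(S), colnames(X))) {
      stop("channel label mismatch between catalog and signatures")
    }
    S <- S[colnames(X), , drop = FALSE]
  } else if (nrow(S) != ncol(X)) {
    stop("signature rows must match catalog channels")
  }
  k <- ncol(S)
  E <- matrix(0, nrow(X), k, dimnames = list(rownames(X), colnames(S)))
  resid <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (all(x == 0)) next
    fit <- pracma::lsqnonneg(S, x)
    E[i, ] <- fit$x
    resid[i] <- sqrt(sum((x - S %*% fit$x)^2))
  }
  tot <- rowSums(E)
  dominant <- ifelse(tot > 0, max.col(E / pmax(tot, .Machine$double.eps),
                                      ties.method = "first"), NA_integer_)
  names(dominant) <- rownames(X)
  list(exposures = E, residual = resid, dominant = dominant)
}

#' Test signature enrichment against binary clinical groupings
#'
#' For every signature and every binary grouping, tests the 2x2 table
#' (dominant in that signature vs not) x (group A vs B) with a two-sided
#' Fisher exact test, then applies Benjamini-Hochberg FDR across all
#' performed tests. Groupings with an empty arm are skipped and flagged.
#'
#' @param dominant named per-sample dominant-signature assignment (index or
#'   label), as produced by [extract_signatures()] /
#'   [attribute_exposures()].
#' @param groupings named list of per-sample two-level factors (names =
#'   sample ids), e.g. from [build_groupings()].
#' @return data.table: `signature`, `grouping`, the four table cells,
#'   `odds_ratio`, `p`, `fdr`, `skipped`.
#' @export
signature_clinical_tests <- function(dominant, groupings) {
  sig_levels <- sort(unique(dominant[!is.na(dominant)]))
  rows <- list()
  for (g in names(groupings)) {
    grp <- groupings[[g]]
    common <- intersect(names(dominant), names(grp))
    grp <- droplevels(factor(grp[common]))
    dom <- dominant[common]
    keep <- !is.na(dom) & !is.na(grp)
    grp <- grp[keep]; dom <- dom[keep]
    skipped <- nlevels(grp) != 2L || min(table(grp)) == 0L
    for (s in sig_levels) {
      if (skipped) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          signature = as.character(s), grouping = g,
          n_dom_A = NA_integer_, n_dom_B = NA_integer_,
          n_other_A = NA_integer_, n_other_B = NA_integer_,
          odds_ratio = NA_real_, p = NA_real_, skipped = TRUE)
        next
      }
      tab <- table(factor(dom == s, levels = c(TRUE, FALSE)), grp)
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        signature = as.character(s), grouping = g,
        n_dom_A = tab[1, 1], n_dom_B = tab[1, 2],
        n_other_A = tab[2, 1], n_other_B = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value, skipped = FALSE)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, fdr := NA_real_]
  out[skipped == FALSE, fdr := stats::p.adjust(p, method = "BH")]
  out[]
}
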