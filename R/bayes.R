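#' Parameters of the Bayesian scoring model
#'
#' The model scores a labeling as: background localizations uniform on the
#' ROI with prior probability `p_b` each; clustered localizations partitioned
#' under a Chinese-restaurant-process prior with concentration `alpha`; each
#' cluster an isotropic 2D Gaussian whose center is uniform on the ROI
#' (integrated in closed form over the plane) and whose spread sigma is
#' marginalized over a discrete grid with uniform weights; each localization
#' contributes its own precision, so the per-point variance is
#' `sigma^2 + sd_i^2`.
#'
#' @param roi an [roi()]; supplies the reference area A.
#' @param p_b prior background proportion, in (0, 1). Default 0.5.
#' @param alpha Dirichlet-process concentration. Default 20.
#' @param sigma_grid_nm candidate cluster standard deviations in nm; default
#'   20 logarithmically spaced values from 5 to 300 nm.
#' @return A `bayes_params` object.
#' @export
bayes_params <- function(roi, p_b = 0.5, alpha = 20,
                         sigma_grid_nm = default_sigma_grid()) {
  stopifnot(inherits(roi, "roi"), p_b > 0, p_b < 1, alpha > 0,
            length(sigma_grid_nm) >= 1, all(sigma_grid_nm > 0))
  structure(list(roi = roi, p_b = p_b, alpha = alpha,
                 sigma_grid_nm = sort(as.numeric(sigma_grid_nm))),
            class = "bayes_params")
}

#' @rdname bayes_params
#' @export
default_sigma_grid <- function() exp(seq(log(5), log(300), length.out = 20))

#' Build the (radius, threshold) proposal grid
#'
#' Cartesian product of the two parameter sequences, row-major with the
#' radius as the outer loop, inclusive bounds. The defaults are the search
#' sequences 5 to 300 and 5 to 500 in steps of 5 (6000 proposals).
#'
#' @param r_lo,r_hi,r_step radius sequence (nm).
#' @param T_lo,T_hi,T_step threshold sequence (integer grid).
#' @return A data frame with columns `r_nm` and `T`.
#' @export
make_proposal_grid <- function(r_lo = 5, r_hi = 300, r_step = 5,
                               T_lo = 5, T_hi = 500, T_step = 5) {
  stopifnot(r_step > 0, T_step > 0, r_lo <= r_hi, T_lo <= T_hi)
  r <- seq(r_lo, r_hi, by = r_step)
  tt <- seq(T_lo, T_hi, by = T_step)
  data.frame(r_nm = rep(r, each = length(tt)),
             T = rep(tt, times = length(r)))
}

# Precomputed per-table, per-sigma quantities so scoring a labeling reduces
# to grouped column sums. Columns blocks of M (n x 6S): 1/v, log v, x/v,
# x^2/v, y/v, y^2/v with v = sigma_s^2 + sd_i^2.
score_context <- function(tbl, params) {
  sig2 <- params$sigma_grid_nm^2
  S <- length(sig2)
  v <- outer(tbl$sd_nm^2, sig2, `+`)
  inv_v <- 1 / v
  list(
    n = nrow(tbl), S = S,
    A = roi_area_nm2(params$roi),
    log_pb_over_A = log(params$p_b) - log(roi_area_nm2(params$roi)),
    log_1mpb = log1p(-params$p_b),
    alpha = params$alpha,
    M = cbind(inv_v, log(v), tbl$x_nm * inv_v, tbl$x_nm^2 * inv_v,
              tbl$y_nm * inv_v, tbl$y_nm^2 * inv_v)
  )
}

score_with_context <- function(ctx, labels) {
  n <- ctx$n
  S <- ctx$S
  bg <- labels == 0L
  n_c <- n - sum(bg)
  K <- if (n_c) max(labels) else 0L
  score <- sum(bg) * ctx$log_pb_over_A + n_c * ctx$log_1mpb +
    lgamma(ctx$alpha) - lgamma(ctx$alpha + n_c)
  if (K == 0L) return(score)
  nk <- tabulate(labels[!bg], nbins = K)
  if (any(nk == 0L))
    stop("labels contain an empty cluster (labels 1..K must be contiguous)",
         call. = FALSE)
  G <- rowsum(ctx$M[!bg, , drop = FALSE], group = labels[!bg], reorder = TRUE)
  cols <- function(b) G[, ((b - 1) * S + 1):(b * S), drop = FALSE]
  Sinv <- cols(1); Slog <- cols(2)
  Sx <- cols(3); Sx2 <- cols(4); Sy <- cols(5); Sy2 <- cols(6)
  log2pi <- log(2 * pi)
  base <- -(nk - 1) * log2pi - Slog - log(Sinv)  # both dims combined
  quad <- (Sx2 - Sx^2 / Sinv) + (Sy2 - Sy^2 / Sinv)
  logm <- -log(ctx$A) + base - 0.5 * quad  # K x S
  mx <- apply(logm, 1L, max)
  log_mk <- mx + log(rowSums(exp(logm - mx))) - log(S)
  score + K * log(ctx$alpha) + sum(lgamma(nk)) + sum(log_mk)
}

#' Score a labeling under the Bayesian model
#'
#' Returns the log posterior score (natural log, up to an additive constant
#' shared by all labelings of the same table under the same parameters):
#' the sum of a uniform-background term `log(p_b / A)` per background
#' localization, `log(1 - p_b)` per clustered localization, the
#' Chinese-restaurant-process partition prior
#' `K log(alpha) + sum(log Gamma(n_k)) + log Gamma(alpha) -
#' log Gamma(alpha + n_c)`, and each cluster's marginal likelihood with the
#' cluster center integrated over the plane (uniform 1/A prior) and the
#' cluster sigma averaged over the discrete grid.
#'
#' @param tbl a [localization_table()].
#' @param labels integer labels (0 = background, clusters 1..K contiguous).
#' @param params a [bayes_params()].
#' @return A single finite log score.
#' @export
score_labels <- function(tbl, labels, params) {
  tbl <- validate_localizations(tbl)
  stopifnot(inherits(params, "bayes_params"), length(labels) == nrow(tbl),
            all(labels >= 0))
  score_with_context(score_context(tbl, params), as.integer(labels))
}

#' Enumerate and score all cluster proposals
#'
#' Runs the chosen clusterer(s) at every (radius, threshold) grid point,
#' scores every labeling under the Bayesian model, and identifies the best
#' proposal. Proposals are independent, so they can be computed on several
#' workers; results are bit-identical regardless of `n_workers` (scheduling
#' is deterministic and the floating-point summation order per proposal is
#' fixed).
#'
#' @param tbl a [localization_table()].
#' @param method one or more of `"ripley"`, `"dbscan"`, `"tomato"`.
#' @param grid a proposal grid from [make_proposal_grid()].
#' @param params a [bayes_params()].
#' @param n_workers number of parallel workers (forked; 1 = sequential).
#' @param keep_labels keep the labels of every proposal (`TRUE`, default) or
#'   only of the best per method (`FALSE`, saves memory on large grids).
#' @return A `scored_proposals` object: `scores` (data frame with `method`,
#'   `r_nm`, `T`, `n_clusters`, `log_score`), `labels` (list, aligned with
#'   `scores` rows; `NULL` entries when dropped), and `best` (per-method list
#'   of [select_best()] results).
#' @export
run_engine <- function(tbl, method = c("tomato", "dbscan", "ripley"), grid,
                       params, n_workers = 1, keep_labels = TRUE) {
  tbl <- validate_localizations(tbl)
  method <- match.arg(method, several.ok = TRUE)
  stopifnot(is.data.frame(grid), all(c("r_nm", "T") %in% names(grid)),
            inherits(params, "bayes_params"), n_workers >= 1)
  ctx <- score_context(tbl, params)
  funs <- lapply(setNames(method, method), cluster_fun)

  r_values <- unique(grid$r_nm)  # grid order preserved
  one_radius <- function(r) {
    nb <- .nbr_csr_cpp(tbl$x_nm, tbl$y_nm, as.numeric(r))
    tt <- grid$T[grid$r_nm == r]
    res <- vector("list", length(method))
    names(res) <- method
    for (m in method) {
      labs <- lapply(tt, function(T) funs[[m]](nb, T))
      res[[m]] <- list(
        scores = data.frame(
          method = m, r_nm = r, T = tt,
          n_clusters = vapply(labs, function(l) max(0L, l), 0L),
          log_score = vapply(labs, function(l) score_with_context(ctx, l), 0)),
        labels = labs)
    }
    res
  }
  blocks <- if (n_workers > 1) {
    parallel::mclapply(r_values, one_radius, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(r_values, one_radius)
  }
  err <- vapply(blocks, inherits, TRUE, what = "try-error")
  if (any(err))
    stop("engine worker failed at r = ", r_values[which(err)[1]],
         call. = FALSE)

  scores <- do.call(rbind, unlist(lapply(method, function(m)
    lapply(blocks, function(b) b[[m]]$scores)), recursive = FALSE))
  rownames(scores) <- NULL
  labels <- unlist(lapply(method, function(m)
    lapply(blocks, function(b) b[[m]]$labels)), recursive = FALSE)
  labels <- do.call(c, labels)

  out <- structure(list(scores = scores, labels = labels), class = "scored_proposals")
  out$best <- setNames(lapply(method, function(m) select_best(out, m)), method)
  if (!keep_labels) {
    keep <- vapply(out$best, function(b) b$index, 0L)
    out$labels <- lapply(seq_along(out$labels),
                         function(i) if (i %in% keep) out$labels[[i]] else NULL)
  }
  out
}

#' Select the highest-scoring proposal
#'
#' Maximum log score; ties are broken by smaller radius, then smaller
#' threshold.
#'
#' @param scored a `scored_proposals` object.
#' @param method restrict the selection to one method (default: all rows).
#' @return A list with `method`, `r_nm`, `T`, `n_clusters`, `log_score`,
#'   `labels`, and the row `index` into `scored$scores`.
#' @export
select_best <- function(scored, method = NULL) {
  stopifnot(inherits(scored, "scored_proposals"))
  sc <- scored$scores
  rows <- if (is.null(method)) seq_len(nrow(sc)) else which(sc$method == method)
  if (!length(rows)) stop("no proposals to select from", call. = FALSE)
  o <- rows[order(-sc$log_score[rows], sc$r_nm[rows], sc$T[rows])][1]
  list(method = sc$method[o], r_nm = sc$r_nm[o], T = sc$T[o],
       n_clusters = sc$n_clusters[o], log_score = sc$log_score[o],
       labels = scored$labels[[o]], index = o)
}

#' @export
print.scored_proposals <- function(x, ...) {
  cat("<scored_proposals> ", nrow(x$scores), " proposals (",
      paste(unique(x$scores$method), collapse = ", "), ")\n", sep = "")
  for (b in x$best)
    cat(sprintf("  best %-7s r = %g, T = %g, K = %d, log score = %.3f\n",
                b$method, b$r_nm, b$T, b$n_clusters, b$log_score))
  invisible(x)
}
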