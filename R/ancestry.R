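#' PCA of a genotype matrix
#'
#' Missing genotypes are imputed with the locus mean dosage, columns are
#' centered, and (optionally) scaled by sqrt(p(1-p)) before
#' eigendecomposition of the individual covariance. All-missing loci are
#' dropped with a warning.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param n_components number of components to return.
#' @param scale logical; scale loci by sqrt(p(1-p)) (drift-variance scaling).
#' @return list with `scores` (individuals x components),
#'   `variance_explained` (non-increasing, sums to <= 1) and `loadings`.
#' @export
pca_genotypes <- function(gm, n_components = 10, scale = FALSE) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  storage.mode(g) <- "double"
  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing locus/loci dropped")
    g <- g[, !all_missing, drop = FALSE]
  }
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]
  X <- sweep(g, 2, mu)
  if (scale) {
    p <- mu / 2
    sd_l <- sqrt(pmax(p * (1 - p), 1e-12))
    X <- sweep(X, 2, sd_l, "/")
  }
  k <- min(n_components, nrow(X) - 1, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  eig <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       variance_explained = (eig / sum(eig))[seq_len(k)],
       loadings = sv$v)
}

## log-likelihood of the binomial admixture model from the masked matrices
## (G0: dosages, 0 at missing; H0: 2 - dosage, 0 at missing)
admix_loglik <- function(G0, H0, PI) {
  PI <- pmin(pmax(PI, 1e-12), 1 - 1e-12)
  sum(G0 * log(PI)) + sum(H0 * log(1 - PI))
}

## One EM update of (Q, F). The E-step quantities come from the current
## parameters and both M-step updates use the same expected counts, so a
## single step never decreases the log-likelihood.
## G0 is the dosage matrix with missing entries set to 0 and H0 the masked
## complement (2 - g, zero at missing entries), so neither ratio needs an
## explicit mask inside the loop.
admix_em_step <- function(G0, H0, Li, Q, Fm) {
  PI <- Q %*% Fm
  PI <- pmin(pmax(PI, 1e-9), 1 - 1e-9)
  rg <- G0 / PI                                 # g / pi (0 where missing)
  rh <- H0 / (1 - PI)                           # (2-g) / (1-pi)
  CA <- crossprod(rg, Q)                        # L x K: sum_i rg * q_ik
  CB <- crossprod(rh, Q)
  RA <- rg %*% t(Fm)                            # n x K: sum_l rg * f_kl
  RB <- rh %*% t(1 - Fm)
  A <- t(Fm) * CA                               # expected alt-allele counts
  B <- t(1 - Fm) * CB
  Fm2 <- pmin(pmax(t(A / pmax(A + B, 1e-300)), 1e-6), 1 - 1e-6)
  Q2 <- Q * (RA + RB) / (2 * Li)
  Q2 <- pmax(Q2, 1e-12)
  Q2 <- Q2 / rowSums(Q2)
  list(Q = Q2, F = Fm2)
}

## project an extrapolated parameter pair back to the feasible region
admix_project <- function(th) {
  th$F <- pmin(pmax(th$F, 1e-6), 1 - 1e-6)
  th$Q <- pmax(th$Q, 1e-12)
  th$Q <- th$Q / rowSums(th$Q)
  th
}

## EM with SQUAREM-style extrapolation: two EM steps give a step direction,
## a steplength from the squared residual ratio extrapolates along it, and
## the move is kept only when it does not lower the log-likelihood (falling
## back to the plain double EM step otherwise), so the recorded
## log-likelihood sequence stays non-decreasing while converging far faster
## than plain multiplicative EM near the simplex boundary.
em_admixture_once <- function(G, M, K, tol, max_iter, seed) {
  set.seed(seed)
  n <- nrow(G); L <- ncol(G)
  G0 <- G; G0[!M] <- 0
  H0 <- (2 - G) * M; H0[!M] <- 0
  Li <- rowSums(M)
  p_obs <- colSums(G0) / pmax(2 * colSums(M), 1)
  th <- list(
    Q = {Q <- matrix(rgamma(n * K, 1), n, K); Q / rowSums(Q)},
    F = matrix(pmin(pmax(p_obs + runif(K * L, -0.1, 0.1), 1e-3), 1 - 1e-3),
               K, L, byrow = TRUE))
  ll <- admix_loglik(G0, H0, th$Q %*% th$F)
  ll_trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    th1 <- admix_em_step(G0, H0, Li, th$Q, th$F)
    th2 <- admix_em_step(G0, H0, Li, th1$Q, th1$F)
    it <- it + 2L
    rQ <- th1$Q - th$Q; rF <- th1$F - th$F
    vQ <- th2$Q - th1$Q - rQ; vF <- th2$F - th1$F - rF
    vnorm <- sqrt(sum(vQ^2) + sum(vF^2))
    cand <- th2
    if (vnorm > 0) {
      alpha <- -sqrt(sum(rQ^2) + sum(rF^2)) / vnorm
      alpha <- min(alpha, -1)                   # never shorter than 2 EM steps
      ex <- admix_project(list(Q = th$Q - 2 * alpha * rQ + alpha^2 * vQ,
                               F = th$F - 2 * alpha * rF + alpha^2 * vF))
      if (admix_loglik(G0, H0, ex$Q %*% ex$F) >=
          admix_loglik(G0, H0, th2$Q %*% th2$F)) {
        ## one EM polish keeps the accelerated point an ascent step
        cand <- admix_em_step(G0, H0, Li, ex$Q, ex$F)
        it <- it + 1L
      }
    }
    ll_new <- admix_loglik(G0, H0, cand$Q %*% cand$F)
    if (ll_new < ll) {                          # safeguard: fall back
      cand <- th2
      ll_new <- admix_loglik(G0, H0, th2$Q %*% th2$F)
    }
    th <- cand
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol) {               # absolute log-lik change
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(Q = th$Q, F = th$F, log_likelihood = ll,
       ll_trace = ll_trace, converged = converged, n_iter = it)
}

#' Fit the admixture model by EM
#'
#' Maximizes the binomial admixture likelihood
#' sum_il [ g_il log pi_il + (2 - g_il) log(1 - pi_il) ],
#' pi_il = sum_k q_ik f_kl, over individual ancestry proportions Q (rows on
#' the simplex) and population allele frequencies F, using multiplicative EM
#' updates whose log-likelihood is non-decreasing. Missing genotypes simply
#' drop their terms. The best of `n_restarts` random restarts (seeds derived
#' from `seed`) is returned. For K = 1 the closed-form MLE is returned
#' exactly: Q is all ones and F the observed allele frequencies.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param K number of ancestral populations (>= 1).
#' @param n_restarts random restarts (default 10).
#' @param tol absolute log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @param seed integer master seed.
#' @return object of class `ancestry_result`: `Q`, `F`, `log_likelihood`,
#'   `K`, `converged`, `ll_trace`, `cv_error` (NULL here; see [select_K()]).
#' @export
fit_admixture <- function(gm, K, n_restarts = 10, tol = 1e-6,
                          max_iter = 2000, seed = 1) {
  stopifnot(K >= 1)
  G <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  storage.mode(G) <- "double"
  M <- !is.na(G)
  if (K == 1) {
    G0 <- G; G0[!M] <- 0
    H0 <- (2 - G) * M; H0[!M] <- 0
    Fm <- matrix(colSums(G0) / pmax(2 * colSums(M), 1), 1)
    Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
    Q <- matrix(1, nrow(G), 1)
    res <- list(Q = Q, F = Fm,
                log_likelihood = admix_loglik(G0, H0, Q %*% Fm),
                ll_trace = numeric(0), converged = TRUE, n_iter = 0L)
  } else {
    seeds <- derive_seeds(seed, n_restarts)
    fits <- lapply(seeds, function(s)
      em_admixture_once(G, M, K, tol, max_iter, s))
    res <- fits[[which.max(vapply(fits, `[[`, numeric(1), "log_likelihood"))]]
  }
  rownames(res$Q) <- rownames(G)
  structure(c(res, list(K = K, cv_error = NULL)), class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("<ancestry_result> K =", x$K, " logLik =", signif(x$log_likelihood, 8),
      if (!x$converged) " (not converged)", "\n")
  invisible(x)
}

#' Choose K by cross-validation on masked genotype entries
#'
#' Non-missing genotype entries are partitioned into `folds` folds; each fold
#' is masked in turn, the model refit, and the masked dosages predicted as
#' 2 * pi_hat. The CV error for a K is the mean squared prediction error over
#' masked entries, and the best K minimizes it.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param K_range candidate K values (default 1:5).
#' @param folds number of entry folds (>= 2).
#' @param seed integer seed controlling fold assignment and restarts.
#' @param n_restarts,tol,max_iter EM settings for the fold refits; the
#'   defaults are much lighter than a final fit because the prediction
#'   error plateaus long before the parameters polish, and the K ranking is
#'   insensitive to the remaining drift.
#' @return list with `cv_error` (named by K) and `best_K`.
#' @export
select_K <- function(gm, K_range = 1:5, folds = 5, seed = 1,
                     n_restarts = 1, tol = 0.5, max_iter = 100) {
  if (folds < 2) stop("need >= 2 folds (masking fraction must be positive)")
  G <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  storage.mode(G) <- "double"
  obs_idx <- which(!is.na(G))
  if (!length(obs_idx)) stop("no genotyped entries to mask")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
  cv <- vapply(K_range, function(K) {
    se <- 0; nmask <- 0
    for (f in seq_len(folds)) {
      mask <- obs_idx[fold_of == f]
      Gf <- G
      Gf[mask] <- NA
      fit <- fit_admixture(Gf, K, n_restarts = n_restarts, tol = tol,
                           max_iter = max_iter,
                           seed = derive_seeds(seed + K, folds)[f])
      pred <- 2 * (fit$Q %*% fit$F)
      se <- se + sum((G[mask] - pred[mask])^2)
      nmask <- nmask + length(mask)
    }
    se / nmask
  }, numeric(1))
  names(cv) <- K_range
  list(cv_error = cv, best_K = K_range[which.min(cv)])
}

#' Align fitted ancestry components to a reference
#'
#' Admixture components are identifiable only up to label switching. This
#' finds the permutation of components maximizing the summed correlation
#' between rows of the fitted and reference allele-frequency matrices, and
#' applies it to Q and F. Recovery metrics should be computed after
#' alignment.
#'
#' @param fit an `ancestry_result`.
#' @param F_ref reference K x L frequency matrix (truth, or another run).
#' @return the fit with `Q`, `F` permuted and the permutation in `perm`.
#' @export
align_components <- function(fit, F_ref) {
  K <- fit$K
  stopifnot(nrow(F_ref) == K)
  if (K == 1) { fit$perm <- 1L; return(fit) }
  perms <- perms_of(K)
  score <- vapply(seq_len(nrow(perms)), function(i) {
    sum(vapply(seq_len(K), function(k)
      stats::cor(fit$F[perms[i, k], ], F_ref[k, ]), numeric(1)))
  }, numeric(1))
  best <- perms[which.max(score), ]
  fit$Q <- fit$Q[, best, drop = FALSE]
  fit$F <- fit$F[best, , drop = FALSE]
  fit$perm <- best
  fit
}

perms_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(K - 1)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
          sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
  }))
}

#' Assign individuals to genetic groups from a Q matrix
#'
#' Each individual is assigned to its maximum-Q component (ties, e.g. an
#' exact 0.5/0.5 split, go to the lower-index component). Individuals whose
#' maximum Q-score is below `admix_cutoff` are flagged as putatively admixed
#' but still assigned, and per-location admixed proportions are reported
#' when metadata is given. Raising `admix_cutoff` never unflags an
#' individual.
#'
#' @param Q n x K membership matrix (rows sum to 1), or an
#'   `ancestry_result`.
#' @param assign_cutoff membership proportion needed for confident
#'   assignment (recorded; with K = 2 the argmax rule is equivalent to
#'   Q > 0.5).
#' @param admix_cutoff maximum-Q threshold below which an individual is
#'   putatively admixed (default 0.7).
#' @param metadata optional data.frame with `individual_id` and `location`
#'   matching the rows of Q.
#' @param group_names optional component names (default group1..groupK).
#' @return object of class `group_assignment`: data.frame `assignments`
#'   (id, group, max_q, admixed) and, with metadata, `by_location`
#'   (n, n_admixed, prop_admixed).
#' @export
assign_groups <- function(Q, assign_cutoff = 0.5, admix_cutoff = 0.7,
                          metadata = NULL, group_names = NULL) {
  if (inherits(Q, "ancestry_result")) Q <- Q$Q
  Q <- as.matrix(Q)
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  K <- ncol(Q)
  gn <- group_names %||% paste0("group", seq_len(K))
  idx <- max.col(Q, ties.method = "first")
  max_q <- Q[cbind(seq_len(nrow(Q)), idx)]
  ids <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  assignments <- data.frame(
    individual_id = ids, group = gn[idx], max_q = max_q,
    admixed = max_q < admix_cutoff, stringsAsFactors = FALSE)
  by_location <- NULL
  if (!is.null(metadata)) {
    loc <- metadata$location[match(ids, metadata$individual_id)]
    by_location <- do.call(rbind, lapply(unique(loc[!is.na(loc)]),
                                         function(lv) {
      sel <- !is.na(loc) & loc == lv
      data.frame(location = lv, n = sum(sel),
                 n_admixed = sum(assignments$admixed[sel]),
                 prop_admixed = mean(assignments$admixed[sel]))
    }))
  }
  structure(list(assignments = assignments, by_location = by_location,
                 assign_cutoff = assign_cutoff, admix_cutoff = admix_cutoff),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> ", nrow(x$assignments), " individuals; ",
      sum(x$assignments$admixed), " putatively admixed (max Q < ",
      x$admix_cutoff, ")\n", sep = "")
  if (!is.null(x$by_location)) print(x$by_location, row.names = FALSE)
  invisible(x)
}
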