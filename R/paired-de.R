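#' Fit a paired negative binomial mixed model for one gene
#'
#' Maximizes the marginal likelihood of an NB2 model with log link, fixed
#' effects (intercept, tumor indicator), a fixed offset (here, the log
#' total protein-coding expression per sample) and a normal random
#' intercept per subject:
#'
#' \deqn{y_{ij} \sim NB(\mu_{ij}, k), \quad
#'   \log \mu_{ij} = o_{ij} + \beta_0 + \beta_1 \, tumor_{ij} + u_i, \quad
#'   u_i \sim N(0, \sigma^2)}
#'
#' The random intercept is integrated out by adaptive Gauss-Hermite
#' quadrature (per-subject mode and curvature found by Newton iteration;
#' default 9 nodes; 1 node gives the Laplace approximation). The NB2
#' dispersion k (variance \eqn{\mu + \mu^2/k}) is profiled jointly with
#' the other parameters, bounded within `[1e-4, 1e4]`. `raw_p` is the Wald
#' test on the tumor coefficient; a likelihood-ratio test is available via
#' `test = "lrt"`.
#'
#' @param gene_counts integer vector of per-sample counts.
#' @param offsets per-sample log exposure (log protein-coding total).
#' @param tissue_status per-sample `"tumor"`/`"normal"` (or 0/1 with 1 =
#'   tumor).
#' @param subject_ids per-sample subject identifiers; each subject must
#'   contribute exactly one tumor and one normal sample.
#' @param nagq number of quadrature nodes (>= 1; default 9).
#' @param dispersion optional fixed NB2 size k; default `NULL` (estimated).
#' @param test `"wald"` (default) or `"lrt"` for the p-value on the tumor
#'   coefficient.
#' @param control list: `rel_tol` (default 1e-8), `max_iter` (default 200).
#' @return list of class `nb_mixed_fit`: `beta_tumor` (log fold change),
#'   `fold_change = exp(beta_tumor)`, `beta_intercept`, `dispersion`,
#'   `subject_sd`, `se_beta_tumor`, `raw_p`, `loglik`, `converged`,
#'   `n_pairs`. An all-zero gene returns `converged = FALSE` with `NA`
#'   estimates rather than an error.
#' @export
fit_nb_mixed <- function(gene_counts, offsets, tissue_status, subject_ids,
                         nagq = 9, dispersion = NULL, test = c("wald", "lrt"),
                         control = list()) {
  test <- match.arg(test)
  ctrl <- modifyList(list(rel_tol = 1e-8, max_iter = 200), control)
  d <- arrange_pairs(gene_counts, offsets, tissue_status, subject_ids)
  n_pairs <- length(d$y_n)

  na_fit <- function(reason) {
    structure(list(beta_tumor = NA_real_, fold_change = NA_real_,
                   beta_intercept = NA_real_, dispersion = NA_real_,
                   subject_sd = NA_real_, se_beta_tumor = NA_real_,
                   raw_p = NA_real_, loglik = NA_real_, converged = FALSE,
                   n_pairs = n_pairs, reason = reason),
              class = "nb_mixed_fit")
  }
  if (all(d$y_n == 0) && all(d$y_t == 0)) return(na_fit("all counts zero"))

  gh <- pracma::gaussHermite(max(1L, as.integer(nagq)))
  est_k <- is.null(dispersion)

  u_prev <- rep(0, n_pairs)
  nll <- function(par) {
    b0 <- par[1]; b1 <- par[2]; sigma <- exp(par[3])
    k <- if (est_k) exp(par[4]) else dispersion
    ll <- agq_subject_loglik(d, b0, b1, sigma, k, gh, u_start = u_prev)
    u_prev <<- attr(ll, "u_mode")
    -sum(ll)
  }

  start <- nb_mixed_start(d, est_k, dispersion)
  lower <- c(-50, -50, log(1e-8), if (est_k) log(1e-4))
  upper <- c(50, 50, log(50), if (est_k) log(1e4))
  opt <- tryCatch(
    nlminb(start, nll, lower = lower, upper = upper,
           control = list(rel.tol = ctrl$rel_tol, iter.max = ctrl$max_iter)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective))
    return(na_fit("optimizer failure"))

  # Newton polish: nlminb stops at its tolerance; one or two exact steps on
  # the quadratic model sharpen the optimum to near machine precision so
  # that algebraically equivalent reparameterizations (e.g. a constant
  # offset shift) land on numerically identical estimates.
  par <- opt$par
  obj <- opt$objective
  H <- NULL
  for (polish in 1:2) {
    H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
    if (is.null(H) || !all(is.finite(H))) break
    g <- num_grad_central(nll, par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- pmin(pmax(par - step, lower), upper)
    cand_obj <- nll(cand)
    if (!is.finite(cand_obj) || cand_obj > obj + 1e-8) break
    par <- cand; obj <- cand_obj
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  se <- tryCatch({
    if (is.null(H)) H <- optimHess(par, nll)
    V <- solve(H)
    if (V[2, 2] > 0) sqrt(V[2, 2]) else NA_real_
  }, error = function(e) NA_real_)

  raw_p <- if (test == "wald") {
    if (is.finite(se)) 2 * pnorm(-abs(par[2]) / se) else NA_real_
  } else {
    nll0 <- function(q) nll(c(q[1], 0, q[2:length(q)]))
    opt0 <- nlminb(start[-2], nll0, lower = lower[-2], upper = upper[-2],
                   control = list(rel.tol = ctrl$rel_tol,
                                  iter.max = ctrl$max_iter))
    stats::pchisq(2 * (opt0$objective - obj), df = 1,
                  lower.tail = FALSE)
  }

  structure(list(
    beta_tumor = par[2], fold_change = exp(par[2]), beta_intercept = par[1],
    dispersion = if (est_k) exp(par[4]) else dispersion,
    subject_sd = exp(par[3]), se_beta_tumor = se, raw_p = raw_p,
    loglik = -obj,
    converged = opt$convergence == 0 && (test == "lrt" || is.finite(se)),
    n_pairs = n_pairs, reason = NULL
  ), class = "nb_mixed_fit")
}

#' @export
print.nb_mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<nb_mixed_fit: FC %.3f (log %.3f, SE %.3f), k %.3g, subject SD %.3f, p %.3g, %s>\n",
    x$fold_change, x$beta_tumor, x$se_beta_tumor, x$dispersion,
    x$subject_sd, x$raw_p, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Central-difference gradient, accurate enough for Newton polishing.
num_grad_central <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    hi <- h * max(1, abs(par[i]))
    e <- rep(0, length(par)); e[i] <- hi
    (fn(par + e) - fn(par - e)) / (2 * hi)
  }, numeric(1))
}

# Reorder per-sample vectors into aligned (normal, tumor) pairs per subject.
arrange_pairs <- function(y, off, tissue, subject) {
  if (is.numeric(tissue)) tissue <- ifelse(tissue > 0, "tumor", "normal")
  tissue <- as.character(tissue)
  subject <- as.character(subject)
  lens <- lengths(list(y, off, tissue, subject))
  if (length(unique(lens)) != 1)
    pm_stop("per-sample vectors must have equal length")
  if (any(!is.finite(off))) pm_stop("offsets must be finite")
  md <- data.frame(sample_id = seq_along(y), subject_id = subject,
                   tissue_status = tissue, stringsAsFactors = FALSE)
  subjects <- paired_subjects(md)  # errors on unpaired subjects
  i_n <- match(paste0(subjects, ".normal"), paste0(subject, ".", tissue))
  i_t <- match(paste0(subjects, ".tumor"), paste0(subject, ".", tissue))
  list(y_n = y[i_n], y_t = y[i_t], o_n = off[i_n], o_t = off[i_t])
}

# Marginal log-likelihood contributions, one per subject, via adaptive
# Gauss-Hermite quadrature. Vectorized over subjects and nodes; `u_start`
# lets successive objective evaluations warm-start the mode search.
agq_subject_loglik <- function(d, b0, b1, sigma, k, gh, u_start = NULL) {
  eta_n <- d$o_n + b0
  eta_t <- d$o_t + b0 + b1
  y_n <- d$y_n; y_t <- d$y_t
  n <- length(y_n)
  inv_s2 <- 1 / sigma^2
  # NB2 log-pmf terms that do not involve u
  const <- lgamma(y_n + k) + lgamma(y_t + k) - 2 * lgamma(k) -
    lgamma(y_n + 1) - lgamma(y_t + 1) + 2 * k * log(k)

  # Newton for the per-subject posterior mode of u
  u <- u_start %||% rep(0, n)
  for (it in 1:50) {
    mu_n <- exp(eta_n + u); mu_t <- exp(eta_t + u)
    grad <- (y_n - (y_n + k) * mu_n / (mu_n + k)) +
      (y_t - (y_t + k) * mu_t / (mu_t + k)) - u * inv_s2
    hess <- -((y_n + k) * k * mu_n / (mu_n + k)^2 +
              (y_t + k) * k * mu_t / (mu_t + k)^2) - inv_s2
    step <- grad / hess
    step <- pmax(pmin(step, 2), -2)   # damp far-from-mode jumps
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  mu_n <- exp(eta_n + u); mu_t <- exp(eta_t + u)
  hess <- -((y_n + k) * k * mu_n / (mu_n + k)^2 +
            (y_t + k) * k * mu_t / (mu_t + k)^2) - inv_s2
  s <- sqrt(-1 / hess)

  # log integrand (NB x NB x normal prior) at all shifted nodes at once
  U <- u + sqrt(2) * (s %o% gh$x)          # n x nodes
  G <- y_n * (eta_n + U) - (y_n + k) * log(exp(eta_n + U) + k) +
    y_t * (eta_t + U) - (y_t + k) * log(exp(eta_t + U) + k) -
    0.5 * U * U * inv_s2
  logm <- sweep(G, 2, gh$x^2 + log(gh$w), `+`)
  m <- logm[, 1]
  for (q in seq_len(ncol(logm))[-1]) m <- pmax(m, logm[, q])
  ll <- m + log(rowSums(exp(logm - m))) + const - log(sigma) -
    0.5 * log(2 * pi) + 0.5 * log(2) + log(s)
  attr(ll, "u_mode") <- u
  ll
}

# Data-driven starting values on the working scale.
nb_mixed_start <- function(d, est_k, dispersion) {
  rate_n <- (sum(d$y_n) + 0.5) / sum(exp(d$o_n))
  rate_t <- (sum(d$y_t) + 0.5) / sum(exp(d$o_t))
  b0 <- log(rate_n)
  b1 <- log(rate_t) - log(rate_n)
  k0 <- if (est_k) {
    r <- c(d$y_n / exp(d$o_n), d$y_t / exp(d$o_t))
    mu <- mean(r)
    v <- stats::var(r)
    ex <- v - mu * mean(1 / exp(c(d$o_n, d$o_t)))
    k <- if (is.finite(ex) && ex > 0) mu^2 / ex else 10
    min(max(k, 1e-3), 1e3)
  }
  c(b0, b1, log(0.3), if (est_k) log(k0))
}

#' Classify a fold change against the dysregulation cutpoints
#'
#' `"up"` for fold change >= `fc_up`, `"down"` for <= `fc_down`,
#' `"neither"` otherwise. Defaults are the conventional 1.50 / 0.67
#' cutpoints.
#'
#' @param fold_change positive numeric vector.
#' @param fc_up,fc_down cutpoints (defaults 1.50 and 0.67).
#' @return character vector in `{"up", "down", "neither"}`.
#' @export
#' @examples
#' classify_direction(c(2.02, 0.76, 1.0, 0.28))
classify_direction <- function(fold_change, fc_up = 1.50, fc_down = 0.67) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    pm_stop("fold_change must be positive and finite")
  ifelse(fold_change >= fc_up, "up",
         ifelse(fold_change <= fc_down, "down", "neither"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotone enforcement, order-preserving
#' with the input (a validating wrapper around [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise >= input and <= 1.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) pm_stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Paired differential expression over a gene set
#'
#' Runs [fit_nb_mixed()] for every gene in `gene_set`, with per-sample
#' offsets equal to the log total count over the cohort's protein-coding
#' genes, then adjusts p-values by Benjamini-Hochberg across the genes
#' tested in this run (non-converged fits are excluded from the adjustment
#' with a warning). Group means are arithmetic means of RPMPCG-normalized
#' expression; alongside the model fold change, the ratio of those means
#' is recorded (`ratio_of_means`) for report parity with printed tables.
#'
#' @param cohort a `paired_cohort` (or any list with `gene_counts`,
#'   `metadata`, `protein_coding_ids`).
#' @param gene_set gene ids to test; default the cohort's pathway panel.
#' @param stratum `"overall"` (default), `"MSI"` or `"MSS"`; strata subset
#'   subjects by `msi_status`, keeping complete pairs only, and require at
#'   least 3 pairs.
#' @param fc_up,fc_down direction cutpoints (defaults 1.50 / 0.67).
#' @param pseudocount added to both means for `ratio_of_means` (default 0).
#' @param ... passed to [fit_nb_mixed()].
#' @return data.frame, one row per gene: `gene`, `stratum`, `tumor_mean`,
#'   `normal_mean`, `fold_change` (model), `ratio_of_means`, `beta_tumor`,
#'   `dispersion`, `subject_sd`, `raw_p`, `fdr_p`, `direction`,
#'   `converged`, `n_pairs`.
#' @export
run_de <- function(cohort, gene_set = cohort$pathway_genes,
                   stratum = c("overall", "MSI", "MSS"), fc_up = 1.50,
                   fc_down = 0.67, pseudocount = 0, ...) {
  stratum <- match.arg(stratum)
  md <- validate_metadata(cohort$metadata)
  counts <- as_feature_matrix(cohort$gene_counts, "gene_counts")
  if (is.null(gene_set)) pm_stop("gene_set must be supplied")
  missing_genes <- setdiff(gene_set, rownames(counts))
  if (length(missing_genes) > 0)
    pm_stop(sprintf("gene_set ids absent from count matrix: %s",
                    paste(utils::head(missing_genes, 5), collapse = ", ")))

  if (stratum != "overall") {
    if (!"msi_status" %in% names(md))
      pm_stop("metadata lacks msi_status; cannot stratify")
    md <- md[md$msi_status == stratum, , drop = FALSE]
  }
  keep <- paired_subjects(md, complete_only = TRUE)
  if (length(keep) < 3)
    pm_stop(sprintf("stratum %s has %d complete pairs; need at least 3",
                    stratum, length(keep)))
  md <- md[md$subject_id %in% keep, , drop = FALSE]
  counts <- counts[, md$sample_id, drop = FALSE]

  pc_ids <- cohort$protein_coding_ids %||% rownames(counts)
  norm <- rpmpcg(counts, pc_ids)
  offsets <- log(colSums(counts[rownames(counts) %in% pc_ids, ,
                                drop = FALSE]))
  is_tumor <- md$tissue_status == "tumor"

  fits <- lapply(gene_set, function(g)
    fit_nb_mixed(counts[g, ], offsets, md$tissue_status, md$subject_id, ...))

  res <- data.frame(
    gene = gene_set, stratum = stratum,
    tumor_mean = rowMeans(norm$values[gene_set, is_tumor, drop = FALSE]),
    normal_mean = rowMeans(norm$values[gene_set, !is_tumor, drop = FALSE]),
    fold_change = vapply(fits, `[[`, numeric(1), "fold_change"),
    beta_tumor = vapply(fits, `[[`, numeric(1), "beta_tumor"),
    dispersion = vapply(fits, `[[`, numeric(1), "dispersion"),
    subject_sd = vapply(fits, `[[`, numeric(1), "subject_sd"),
    raw_p = vapply(fits, `[[`, numeric(1), "raw_p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_pairs = length(keep),
    stringsAsFactors = FALSE
  )
  res$ratio_of_means <- fold_change_from_means(
    res$tumor_mean, res$normal_mean, digits = NA, pseudocount = pseudocount)

  res$fdr_p <- NA_real_
  ok <- res$converged & is.finite(res$raw_p)
  if (any(!ok))
    warning(sprintf("%d gene fit(s) did not converge; excluded from FDR",
                    sum(!ok)))
  res$fdr_p[ok] <- bh_fdr(res$raw_p[ok])
  res$direction <- NA_character_
  res$direction[ok] <- classify_direction(res$fold_change[ok], fc_up, fc_down)
  res[c("gene", "stratum", "tumor_mean", "normal_mean", "fold_change",
        "ratio_of_means", "beta_tumor", "dispersion", "subject_sd",
        "raw_p", "fdr_p", "direction", "converged", "n_pairs")]
}
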