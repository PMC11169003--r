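#' Brownian-motion covariance of a tree
#'
#' Under Brownian motion a trait's covariance between two tips equals the
#' shared root-to-MRCA path length, and its variance at a tip equals the
#' root-to-tip depth. This wraps [ape::vcv.phylo()] with the validity
#' checks the signal tests rely on.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Symmetric positive semi-definite matrix, tips x tips, ordered as
#'   `tree$tip.label`.
#' @export
brownian_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  V <- ape::vcv.phylo(tree)
  if (any(diag(V) <= 0)) stop("zero root-to-tip depth: degenerate tree", call. = FALSE)
  V
}

# scale off-diagonal covariance by lambda, keep tip variances
.lambda_transform <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# profile log-likelihood of a trait under N(mu 1, sigma2 * V):
# mu and sigma2 maximised analytically, returns the profiled logLik
.mvn_profile_loglik <- function(y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) {
    stop("singular covariance (condition estimate ", format(kappa(V)), ")",
         call. = FALSE)
  })
  logdet <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  sigma2 <- sum(r * Vi_r) / n
  if (sigma2 <= 0) stop("zero trait variance: degenerate input", call. = FALSE)
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

# match a named trait vector to the tree's tips
.match_trait <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait vector must be named by species", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(trait))
  extra <- setdiff(names(trait), tree$tip.label)
  if (length(miss) || length(extra)) {
    stop("trait/tree mismatch: missing [", paste(miss, collapse = ","),
         "], extra [", paste(extra, collapse = ","), "]", call. = FALSE)
  }
  y <- as.numeric(trait[tree$tip.label])
  if (anyNA(y)) stop("trait contains missing values", call. = FALSE)
  if (stats::var(y) == 0) stop("constant trait: phylogenetic signal undefined", call. = FALSE)
  y
}

#' Pagel's lambda test of phylogenetic signal
#'
#' Estimates lambda by maximum likelihood: the trait is modelled as
#' multivariate normal with mean `mu`, scale `sigma2`, and covariance equal
#' to the Brownian matrix with off-diagonal entries multiplied by lambda
#' (tip variances unscaled). `mu` and `sigma2` are profiled analytically
#' and lambda is maximised by bounded 1-D search on `[0, 1]`
#' (tolerance 1e-6). lambda = 0 means tips are independent; lambda = 1 is
#' pure Brownian motion. The p-value is a likelihood-ratio test against
#' lambda = 0 on chi-squared with 1 df (no boundary correction; pass
#' `mixture_null = TRUE` for the 50:50 point-mass mixture).
#'
#' @param trait Named numeric vector, names matching the tree's tips.
#' @param tree Rooted `phylo` with branch lengths, >= 4 tips.
#' @param mixture_null Use the 50:50 chi-squared boundary mixture for the
#'   LR p-value.
#' @return An object of class `signal_result`: list with `statistic_name`
#'   (`"lambda"`), `estimate`, `test_stat` (LR), `p_value`, `n_tips`,
#'   `loglik`, `loglik0`.
#' @export
pagel_lambda <- function(trait, tree, mixture_null = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) stop("need >= 4 tips", call. = FALSE)
  y <- .match_trait(trait, tree)
  V <- brownian_covariance(tree)
  ll <- function(lambda) .mvn_profile_loglik(y, .lambda_transform(V, lambda))
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  # the optimizer can miss a boundary optimum by its tolerance; check ends
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll(0), ll(1))
  best <- which.max(lls)
  lambda_hat <- cand[best]
  ll_hat <- lls[best]
  ll0 <- lls[2]
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (mixture_null) p <- if (lr == 0) 1 else p / 2
  structure(
    list(statistic_name = "lambda", estimate = lambda_hat, test_stat = lr,
         p_value = p, n_tips = length(y), loglik = ll_hat, loglik0 = ll0),
    class = "signal_result"
  )
}

# Blomberg's variance ratio: observed MSE0/MSE at the phylogenetic mean
.k_ratio <- function(y, Vi, n) {
  ahat <- sum(Vi %*% y) / sum(Vi)
  r <- y - ahat
  mse0 <- sum(r * r) / (n - 1)
  mse <- as.numeric(t(r) %*% Vi %*% r) / (n - 1)
  mse0 / mse
}

#' Blomberg's K test of phylogenetic signal
#'
#' K compares the observed ratio of the trait's raw variance (about the
#' phylogenetic GLS mean) to its phylogenetically corrected variance, with
#' the ratio expected under Brownian motion on the given tree:
#' `K = (MSE0/MSE) / E_BM[MSE0/MSE]`, where
#' `E_BM = (tr(V) - n / sum(V^-1)) / (n - 1)`. K is about 1 under Brownian
#' motion, below 1 when close relatives resemble each other less than BM
#' predicts. Significance is assessed by permuting trait values across
#' tips: the p-value is the smoothed proportion of permutations whose
#' variance ratio reaches the observed one,
#' `(1 + #extreme) / (1 + n_permutations)`.
#'
#' @inheritParams pagel_lambda
#' @param n_permutations Number of tip-label permutations (default 999);
#'   0 skips the test and returns `p_value = NA`.
#' @param seed Integer seed for the permutations (required when
#'   `n_permutations > 0`).
#' @return A `signal_result`: `statistic_name` (`"K"`), `estimate`,
#'   `test_stat` (the observed variance ratio), `p_value`, `n_tips`,
#'   `n_permutations`.
#' @export
blomberg_k <- function(trait, tree, n_permutations = 999L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) stop("need >= 4 tips", call. = FALSE)
  y <- .match_trait(trait, tree)
  V <- brownian_covariance(tree)
  n <- length(y)
  Vi <- solve(V)
  expected_ratio <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  obs_ratio <- .k_ratio(y, Vi, n)
  K <- obs_ratio / expected_ratio
  p <- NA_real_
  if (n_permutations > 0L) {
    if (is.null(seed)) stop("supply a seed for the permutation test", call. = FALSE)
    set.seed(seed)
    perm <- vapply(seq_len(n_permutations), function(i) {
      .k_ratio(sample(y), Vi, n)
    }, numeric(1))
    p <- (1 + sum(perm >= obs_ratio)) / (1 + n_permutations)
  }
  structure(
    list(statistic_name = "K", estimate = K, test_stat = obs_ratio,
         p_value = p, n_tips = n, n_permutations = as.integer(n_permutations)),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4g (n_tips = %d), p = %.3g\n",
              x$statistic_name, x$estimate, x$n_tips, x$p_value))
  invisible(x)
}
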