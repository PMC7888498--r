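#' Chain settings for the Gibbs sampler
#'
#' The defaults follow the conventional single-chain protocol for this
#' model family: 250,000 cycles, the first 50,000 discarded as burn-in,
#' and every 50th subsequent draw stored, giving 4,000 posterior
#' samples.
#'
#' @param n_cycles Total Gibbs cycles.
#' @param burn_in Cycles discarded before storage begins.
#' @param thin Store every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed applied with [set.seed()] at the
#'   start of the run.
#' @return An object of class `"ltm_chain"`.
#' @export
ltm_chain <- function(n_cycles = 250000L, burn_in = 50000L, thin = 50L,
                      seed = NULL) {
  n_cycles <- as.integer(n_cycles); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_cycles) stop("burn_in must be smaller than n_cycles")
  if (thin < 1L) stop("thin must be >= 1")
  if ((n_cycles - burn_in) %% thin != 0L)
    stop("(n_cycles - burn_in) must be divisible by thin")
  structure(list(n_cycles = n_cycles, burn_in = burn_in, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ltm_chain")
}

#' Number of samples a chain configuration stores
#' @param chain An [ltm_chain()] object.
#' @export
n_stored <- function(chain) {
  stopifnot(inherits(chain, "ltm_chain"))
  (chain$n_cycles - chain$burn_in) %/% chain$thin
}

#' @export
print.ltm_chain <- function(x, ...) {
  cat(sprintf("Gibbs chain: %d cycles, burn-in %d, thin %d -> %d stored samples\n",
              x$n_cycles, x$burn_in, x$thin, n_stored(x)))
  invisible(x)
}

#' Prior settings for the covariance matrices
#'
#' Inverse-Wishart priors for the additive covariance G and the free
#' part of the residual covariance R (fixed effects always carry flat
#' priors). The default is weakly informative: degrees of freedom equal
#' to the trait dimension plus one, with a diagonal scale set at fit
#' time to the starting variances (half the observed phenotypic
#' variance per trait). Scaling the prior to the data's own order of
#' magnitude matters: with an arbitrarily small scale the
#' inverse-Wishart density, conditional on variances the data place at
#' O(1) or larger, diverges as any correlation approaches +/-1, and
#' Gibbs chains get trapped near singular covariance matrices. With the
#' scale at the data's order, the implied prior on each correlation is
#' proper and near-flat while the posterior remains dominated by the
#' data (the prior carries dimension+1 degrees of freedom against
#' thousands of animals and records).
#'
#' `flat = TRUE` selects the improper flat convention (zero scale, zero
#' degrees of freedom), under which the conditional for a single
#' variance reduces to a scaled inverse chi-square with posterior mean
#' SS/(n - 2); intended for the degenerate single-trait checks.
#'
#' Fixed effects on continuous traits carry flat priors. Fixed effects
#' on the binary trait get a proper N(0, `beta_sd_binary`^2) prior
#' (default SD 1 on the liability scale). A proper prior is required
#' there: contemporary groups in which every sow has the same
#' stayability outcome make the flat-prior conditional improper (the
#' extreme-category problem of threshold models), and more generally a
#' large set of free subclass effects on the latent probit scale
#' inflates the liability variance components. An SD of 1 allows group
#' effects spanning success probabilities from about 0.16 to 0.84
#' around the mean before shrinkage bites, far beyond plausible
#' herd-year-season differences, so it is weakly informative in the
#' sense of Gelman-style default priors for probit/logit scales.
#'
#' @param flat Use the flat (improper) convention for both G and R.
#' @param nu_G,nu_R Degrees of freedom (default dimension + 1, resolved
#'   at fit time).
#' @param S_G,S_R Scale matrices (default diagonal of the starting
#'   variances, resolved at fit time).
#' @param beta_sd_binary Prior SD for fixed effects of the binary
#'   trait; `Inf` for flat (used automatically when `flat = TRUE`).
#' @return An object of class `"ltm_priors"`.
#' @export
ltm_priors <- function(flat = FALSE, nu_G = NULL, nu_R = NULL,
                       S_G = NULL, S_R = NULL, beta_sd_binary = 1) {
  structure(list(flat = isTRUE(flat), nu_G = nu_G, nu_R = nu_R,
                 S_G = S_G, S_R = S_R,
                 beta_sd_binary = beta_sd_binary),
            class = "ltm_priors")
}

resolve_priors <- function(priors, nt, G_scale, R_scale) {
  pick <- function(nu, S, default_S) {
    if (priors$flat) {
      list(nu = 0, S = matrix(0, nt, nt))
    } else {
      list(nu = if (is.null(nu)) nt + 1 else nu,
           S = if (is.null(S)) default_S else as.matrix(S))
    }
  }
  list(G = pick(priors$nu_G, priors$S_G, G_scale),
       R = pick(priors$nu_R, priors$S_R, R_scale))
}

#' Fit a multiple-trait linear-threshold animal model by Gibbs sampling
#'
#' Fits `y = Xb + Za + e` with `a ~ N(0, A (x) G)` and
#' `e ~ N(0, I (x) R)` jointly over a set of continuous traits and at
#' most one binary trait. The binary trait is modelled on the liability
#' scale: its record-level liabilities are augmented from truncated
#' normals (threshold at 0), and its residual variance is pinned to 1
#' at every cycle via a conditional inverse-Wishart draw of R. Missing
#' trait cells (e.g. litter sizes after culling, censored stayability)
#' are handled by data augmentation, so all conditionals operate on
#' complete records.
#'
#' Fixed effects are a contemporary-group factor and an optional linear
#' covariate per trait; the covariate is centered internally. No
#' explicit identifiability constraint is placed on the fixed effects:
#' only variance parameters and derived ratios (heritabilities,
#' correlations), which are invariant, are reported by default.
#'
#' @param data Data frame with one row per recorded animal.
#' @param pedigree A `renum_ped` from [ped_renumber()], a raw pedigree
#'   data frame (renumbered internally), or `NULL` for a model without
#'   an additive genetic effect (useful for degenerate checks).
#' @param traits Character vector of continuous trait columns (may be
#'   empty).
#' @param binary Name of the binary (0/1/NA) trait column, or `NULL`.
#' @param id Column holding the animal identifier (matched against the
#'   pedigree when one is supplied).
#' @param cg Column holding the contemporary-group factor, or `NULL`
#'   for an intercept-only model.
#' @param covariate Column holding a linear covariate (e.g. age at
#'   first farrowing), or `NULL`.
#' @param covariate_traits Traits the covariate applies to; default all
#'   traits.
#' @param chain An [ltm_chain()] object.
#' @param priors An [ltm_priors()] object.
#' @param inbreeding Account for inbreeding when building A-inverse.
#' @param rcov_zero Constrain residual covariances between the binary
#'   trait and the continuous traits to zero (simplified fallback);
#'   default `FALSE` (they are estimated).
#' @param verbose Print progress (with running heritabilities) every
#'   1,000 cycles.
#' @return An object of class `"ltm_fit"` containing the stored draws
#'   (`$store`, an `ltm_store`), posterior means of location effects,
#'   and fit metadata.
#' @seealso [summary.ltm_fit()], [derive_samples()]
#' @export
ltm_fit <- function(data, pedigree = NULL,
                    traits = c("nba1", "nba2", "nba3"), binary = "stay14",
                    id = "sow", cg = "cg", covariate = "aff",
                    covariate_traits = NULL,
                    chain = ltm_chain(), priors = ltm_priors(),
                    inbreeding = TRUE, rcov_zero = FALSE, verbose = FALSE) {
  cl <- match.call()
  stopifnot(is.data.frame(data), inherits(chain, "ltm_chain"))
  trait_names <- c(traits, binary)
  nt <- length(trait_names)
  if (nt < 1L) stop("at least one trait is required")
  if (length(binary) > 1L) stop("at most one binary trait is supported")
  for (col in c(trait_names, id, cg, covariate))
    if (!is.null(col) && !col %in% names(data))
      stop("column not found in data: ", col)
  bidx <- if (is.null(binary)) -1L else nt  # 1-based; binary trait is last

  n <- nrow(data)
  Y <- matrix(NA_real_, n, nt, dimnames = list(NULL, trait_names))
  for (k in seq_along(traits)) Y[, k] <- as.numeric(data[[traits[k]]])
  ybin <- rep(-1L, n)
  if (!is.null(binary)) {
    bv <- data[[binary]]
    if (!all(bv %in% c(0, 1, NA)))
      stop("binary trait must contain only 0, 1 or NA")
    ybin <- ifelse(is.na(bv), -1L, as.integer(bv))
    # initial liabilities consistent with the observed category
    Y[, nt] <- ifelse(ybin == 1L, 0.7, ifelse(ybin == 0L, -0.7, 0))
  }
  miss <- matrix(0L, n, nt)
  if (length(traits)) {
    miss[, seq_along(traits)] <- is.na(Y[, seq_along(traits), drop = FALSE]) * 1L
    for (k in seq_along(traits)) {
      mu <- mean(Y[, k], na.rm = TRUE)
      if (is.nan(mu)) stop("trait has no observed values: ", traits[k])
      Y[is.na(Y[, k]), k] <- mu
    }
  }
  if (!is.null(binary)) miss[, nt] <- (ybin == -1L) * 1L

  cgv <- if (is.null(cg)) factor(rep("(all)", n)) else factor(data[[cg]])
  cg_idx <- as.integer(cgv)
  ncg <- nlevels(cgv)

  use_cov <- !is.null(covariate)
  cov_center <- 0
  xcov <- numeric(n)
  if (use_cov) {
    xcov <- as.numeric(data[[covariate]])
    if (anyNA(xcov)) stop("covariate contains missing values")
    cov_center <- mean(xcov)
    xcov <- xcov - cov_center
  }
  cov_use <- rep(1L, nt)
  if (!is.null(covariate_traits))
    cov_use <- as.integer(trait_names %in% covariate_traits)

  use_animal <- !is.null(pedigree)
  anim <- integer(n); Ainv <- Matrix::sparseMatrix(i = 1, j = 1, x = 1)
  Fbar <- NA_real_
  if (use_animal) {
    if (!inherits(pedigree, "renum_ped")) pedigree <- ped_renumber(pedigree)
    anim <- ped_code(pedigree, as.character(data[[id]]))
    Ainv <- ped_a_inverse(pedigree, inbreeding = inbreeding)
    Fbar <- mean(ped_inbreeding(pedigree))
  }

  # starting covariances: split the observed phenotypic variance evenly;
  # liability variance starts modest with the residual pinned at 1
  vstart <- rep(0.5, nt)
  for (k in seq_along(traits))
    vstart[k] <- max(stats::var(Y[, k]) / 2, 1e-3)
  Gstart <- diag(ifelse(seq_len(nt) == bidx, 0.2, vstart), nt)
  Rstart <- diag(ifelse(seq_len(nt) == bidx, 1.0, vstart), nt)
  pr <- resolve_priors(priors, nt, Gstart, Rstart)
  beta_prec <- rep(0, nt)
  if (bidx > 0 && !priors$flat && is.finite(priors$beta_sd_binary))
    beta_prec[bidx] <- 1 / priors$beta_sd_binary^2

  if (!is.null(chain$seed)) set.seed(chain$seed)
  t0 <- proc.time()[["elapsed"]]
  out <- gibbs_ltm_cpp(
    Y, miss, ybin, bidx - 1L, cg_idx, ncg, xcov, cov_use, use_cov,
    anim, methods::as(Ainv, "generalMatrix"), use_animal,
    chain$n_cycles, chain$burn_in, chain$thin,
    pr$G$S, pr$G$nu, pr$R$S, pr$R$nu, Gstart, Rstart, beta_prec,
    isTRUE(rcov_zero), if (isTRUE(verbose)) 1000L else 0L)
  elapsed <- proc.time()[["elapsed"]] - t0

  store <- new_ltm_store(
    G = if (use_animal) out$G else NULL, R = out$R, cycle = out$cycle,
    traits = trait_names, binary = if (is.null(binary)) NA_character_ else binary,
    chain = chain)
  dimnames(out$beta_cg) <- list(levels(cgv), trait_names)

  structure(list(
    store = store, chain = chain, priors = priors,
    traits = trait_names, binary = binary, binary_index = if (bidx > 0) bidx else NA_integer_,
    n_records = n, n_animals = if (use_animal) pedigree$n else 0L,
    n_cg = ncg, use_animal = use_animal, mean_inbreeding = Fbar,
    beta_cg = out$beta_cg, slope = stats::setNames(drop(out$bcov), trait_names),
    a_mean = if (use_animal) {
      am <- out$a; dimnames(am) <- list(pedigree$id, trait_names); am
    } else NULL,
    covariate = covariate, covariate_center = cov_center,
    rcov_zero = isTRUE(rcov_zero), elapsed = elapsed, call = cl),
    class = "ltm_fit")
}

#' @export
print.ltm_fit <- function(x, ...) {
  cat("Linear-threshold animal model fit (Gibbs sampling)\n")
  cat(sprintf("  traits: %s%s\n", paste(x$traits, collapse = ", "),
              if (!is.null(x$binary))
                sprintf("  [%s binary on the liability scale]", x$binary)
              else ""))
  cat(sprintf("  records: %d   pedigree animals: %d   contemporary groups: %d\n",
              x$n_records, x$n_animals, x$n_cg))
  print(x$chain)
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Posterior means of the fixed effects
#' @param object An `ltm_fit`.
#' @param ... Unused.
#' @return A list with the contemporary-group effect matrix and the
#'   covariate slopes (posterior means over post-burn-in cycles).
#' @export
coef.ltm_fit <- function(object, ...) {
  list(cg = object$beta_cg, slope = object$slope)
}

#' Trace plots of per-draw heritabilities
#' @param x An `ltm_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ltm_fit <- function(x, ...) {
  d <- derive_samples(x$store)
  h2 <- as.matrix(d[grep("^h2_", names(d))])
  graphics::matplot(x$store$cycle, h2, type = "l", lty = 1,
                    xlab = "cycle", ylab = expression(h^2), ...)
  graphics::legend("topright", legend = sub("^h2_", "", colnames(h2)),
                   col = seq_len(ncol(h2)), lty = 1, bty = "n")
  invisible(x)
}
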